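# Cohort selection, age/time-to-onset binning, constituent-ratio summary.

test_that("cohort selection matches keyword in drugname or prod_ai, PS only", {
  demo <- make_demo(primaryid = as.character(1:4))
  drug <- data.table::rbindlist(list(
    drug_row("1", "ALPRAZOLAM.", role_cod = "PS"),
    drug_row("2", "XANAX", role_cod = "PS", prod_ai = "ALPRAZOLAM"),
    drug_row("3", "ALPRAZOLAM", role_cod = "C"),
    drug_row("4", "IBUPROFEN", role_cod = "PS")))
  b <- make_bundle(demo, drug)
  expect_equal(select_cohort(b, cohort_spec("alprazolam")), c("1", "2"))
  # widening the role set pulls in the concomitant report
  expect_equal(select_cohort(b, cohort_spec("alprazolam", roles = c("PS", "C"))),
               c("1", "2", "3"))
  # restricting match fields drops the prod_ai-only match
  expect_equal(select_cohort(b, cohort_spec("alprazolam",
                                            match_fields = "drugname")), "1")
  expect_warning(select_cohort(b, cohort_spec("nosuchdrug")), "empty cohort")
})

test_that("age bins are half-open and partition the non-negative reals", {
  expect_equal(as.character(age_bin(c(17.9, 18, 44.99, 45, 64.9, 65, 74.5, 75, 90))),
               c("<18", "18-45", "18-45", "45-65", "45-65", "65-75", "65-75",
                 ">=75", ">=75"))
  expect_equal(as.character(age_bin(NA)), "Unknown")
  expect_warning(out <- age_bin(-3), "negative")
  expect_equal(as.character(out), "Unknown")
  # partition property: each grid age falls in exactly one non-Unknown bin
  grid <- seq(0, 120, by = 0.25)
  bins <- age_bin(grid)
  expect_false(any(bins == "Unknown"))
  expect_false(any(is.na(bins)))
})

test_that("time to onset is event date minus earliest matched therapy start", {
  demo <- rbind(make_demo("1", event_dt = "20200115"),
                make_demo("2", event_dt = "202001"),
                make_demo("3", event_dt = "20200101"))
  drug <- data.table::rbindlist(list(
    drug_row("1", "TARGETOL"), drug_row("2", "TARGETOL"),
    drug_row("3", "TARGETOL")))
  ther <- data.table::data.table(
    primaryid = c("1", "1", "2", "3"), dsg_drug_seq = "1",
    start_dt = c("20200101", "20200110", "20200101", "20200201"))
  b <- make_bundle(demo, drug, ther = ther)
  spec <- cohort_spec("targetol")
  expect_warning(tto <- time_to_onset_days(b, c("1", "2", "3"), spec),
                 "event date before therapy start")
  expect_equal(tto[primaryid == "1", days], 14L)   # earliest start wins
  expect_true(is.na(tto[primaryid == "2", days]))  # partial event date
  expect_true(is.na(tto[primaryid == "3", days]))  # negative difference
})

test_that("onset-delay bins follow the reporting intervals", {
  expect_equal(as.character(tto_bin(c(0, 30, 31, 60, 180, 181, 360, 361))),
               c("0-30", "0-30", "31-60", "31-60", "151-180", "181-360",
                 "181-360", ">360"))
  expect_equal(as.character(tto_bin(NA)), "Unknown")
})

test_that("a one-report cohort summarizes to 100.00%", {
  demo <- make_demo("1", sex = "M", fda_dt = "20190506")
  drug <- drug_row("1", "TARGETOL")
  b <- make_bundle(demo, drug)
  s <- summarize_cohort(b, "1", cohort_spec("targetol"))
  expect_equal(s[dimension == "Gender" & category == "Male", pct], 100)
  expect_equal(s[dimension == "Gender" & category == "Male", count], 1L)
  expect_equal(s[dimension == "Report year" & category == "2019", count], 1L)
})

test_that("gender and year percentages sum to ~100 and counts to the cohort", {
  set.seed(3)
  gen <- generate_corpus(sim_config(n_reports = 800, n_drugs = 10, n_pts = 40,
                                    seed = 21))
  dd <- dedup_bundle(gen$bundle)
  spec <- cohort_spec("drug_001")
  ids <- select_cohort(dd$bundle, spec)
  s <- suppressWarnings(summarize_cohort(dd$bundle, ids, spec))
  n <- attr(s, "denominator")
  expect_equal(n, length(ids))
  for (dim in c("Gender", "Age", "Report year")) {
    expect_equal(sum(s[dimension == dim, count]), n, info = dim)
    # half-up rounding moves each category by at most half a ULP (0.005)
    n_cat <- nrow(s[dimension == dim])
    expect_lt(abs(sum(s[dimension == dim, pct]) - 100), 0.005 * n_cat + 1e-9)
  }
  # serious outcomes count reports once per code, never more than the cohort
  expect_true(all(s[dimension == "Serious outcomes", count] <= n))
})

test_that("reports outside the cohort do not perturb the summary (locality)", {
  demo <- rbind(make_demo("1", sex = "F", fda_dt = "20200101"),
                make_demo("2", sex = "M", fda_dt = "20210101"))
  drug <- data.table::rbindlist(list(drug_row("1", "TARGETOL"),
                                     drug_row("2", "OTHEROL")))
  b <- make_bundle(demo, drug)
  spec <- cohort_spec("targetol")
  s1 <- summarize_cohort(b, "1", spec)
  demo3 <- rbind(demo, make_demo("3", sex = "M", fda_dt = "20220101"))
  drug3 <- rbind(drug, drug_row("3", "OTHEROL"))
  b3 <- make_bundle(demo3, drug3)
  s2 <- summarize_cohort(b3, "1", spec)
  expect_equal(s1$count, s2$count)
  expect_equal(s1$pct, s2$pct)
})

test_that("constituent ratios reproduce known numerator/denominator pairs", {
  expect_equal(constituent_ratio(13326, 23575), 56.53)
  expect_equal(constituent_ratio(c(1, 1), 3), c(33.33, 33.33))
  expect_equal(round_half_up(2.675, 2), 2.68)  # not banker's rounding
  expect_equal(round_half_up(-2.675, 2), -2.68)
})
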