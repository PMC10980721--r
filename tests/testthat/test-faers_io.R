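# FAERS-dialect ingestion, date parsing, age conversion, PT->SOC map.

write_lines <- function(lines, file) {
  writeLines(lines, file)
  file
}

quarter_paths <- function(dir, demo_lines,
                          drug_lines = "primaryid$drug_seq$role_cod$drugname$prod_ai",
                          reac_lines = "primaryid$pt",
                          outc_lines = "primaryid$outc_cod",
                          ther_lines = "primaryid$dsg_drug_seq$start_dt") {
  list(demo = write_lines(demo_lines, file.path(dir, "DEMO.txt")),
       drug = write_lines(drug_lines, file.path(dir, "DRUG.txt")),
       reac = write_lines(reac_lines, file.path(dir, "REAC.txt")),
       outc = write_lines(outc_lines, file.path(dir, "OUTC.txt")),
       ther = write_lines(ther_lines, file.path(dir, "THER.txt")))
}

test_that("read_quarter parses $-delimited tables into typed records", {
  dir <- withr::local_tempdir()
  paths <- quarter_paths(dir, c("primaryid$caseid$fda_dt$sex",
                                "1001$100$20200115$F",
                                "1002$101$20200301$M"))
  b <- read_quarter(paths, "2020Q1")
  expect_s3_class(b, "faers_bundle")
  expect_equal(nrow(b$demo), 2L)
  expect_equal(b$demo$primaryid, c("1001", "1002"))
  expect_equal(b$demo$fda_date, as.Date(c("2020-01-15", "2020-03-01")))
  expect_equal(b$demo$quarter, rep("2020Q1", 2))
  # optional columns absent from the file come back missing, not dropped
  expect_true(all(is.na(b$demo$age)))
})

test_that("malformed dates become missing without losing the row", {
  dir <- withr::local_tempdir()
  paths <- quarter_paths(dir, c("primaryid$caseid$fda_dt$sex",
                                "1001$100$2020013$F"))  # 7 digits
  expect_message(b <- read_quarter(paths), "malformed date")
  expect_equal(nrow(b$demo), 1L)
  expect_true(is.na(b$demo$fda_dt))
  expect_true(is.na(b$demo$fda_date))
})

test_that("partial dates keep their raw form but no parsed date", {
  p <- parse_faers_date(c("20200115", "202001", "2020", "20200230", "1/2/20", NA))
  expect_equal(p$raw, c("20200115", "202001", "2020", "20200230", NA, NA))
  expect_equal(p$date[1], as.Date("2020-01-15"))
  # 8-digit but not a real calendar day: raw kept, parsed date missing
  expect_true(is.na(p$date[4]))
  expect_equal(p$n_malformed, 1L)
})

test_that("a missing required column is a named format error", {
  dir <- withr::local_tempdir()
  paths <- quarter_paths(dir, c("primaryid$fda_dt", "1001$20200101"))
  expect_error(read_quarter(paths), "caseid")
  expect_error(read_quarter(paths), "DEMO")
})

test_that("an empty table file yields an empty collection with a warning", {
  dir <- withr::local_tempdir()
  paths <- quarter_paths(dir, c("primaryid$caseid", "1001$100"))
  file.create(paths$reac)  # truncate to zero bytes
  expect_warning(b <- read_quarter(paths), "empty")
  expect_equal(nrow(b$reac), 0L)
  expect_equal(nrow(b$demo), 1L)
})

test_that("write_quarter then read_quarter is the identity on records", {
  set.seed(7)
  gen <- generate_corpus(sim_config(n_reports = 150, n_drugs = 8, n_pts = 30,
                                    seed = 99))
  dir <- withr::local_tempdir()
  paths <- write_quarter(gen$bundle, dir)
  b2 <- read_quarter(paths, gen$bundle$demo$quarter[1])
  for (tb in c("demo", "drug", "reac", "outc", "ther")) {
    orig <- data.table::as.data.table(gen$bundle[[tb]])
    back <- data.table::as.data.table(b2[[tb]])
    expect_equal(back, orig, info = tb)
  }
  expect_equal(sort(b2$deleted_caseids), sort(gen$bundle$deleted_caseids))
})

test_that("row accounting: no data row is silently dropped", {
  dir <- withr::local_tempdir()
  rows <- c("primaryid$caseid$fda_dt", paste0(2000 + 1:25, "$", 3000 + 1:25, "$20210401"))
  paths <- quarter_paths(dir, rows)
  b <- read_quarter(paths)
  expect_equal(nrow(b$demo), 25L)
})

test_that("PT->SOC map normalizes, deduplicates and rejects conflicts", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "map.tsv")
  writeLines(c("Drug abuse\tPsychiatric disorders\t10037175",
               "Somnolence\tNervous system disorders\t10029205",
               "Somnolence\tNervous system disorders\t10029205"), f)
  map <- load_meddra_map(f)
  expect_equal(nrow(map), 2L)
  expect_equal(soc_for_pt(map, "somnolence"), "Nervous system disorders")
  expect_equal(soc_for_pt(map, "  DRUG ABUSE "), "Psychiatric disorders")
  expect_true(is.na(soc_for_pt(map, "Tremor")))

  writeLines(c("Coma\tNervous system disorders",
               "Coma\tPsychiatric disorders"), f)
  expect_error(load_meddra_map(f), "Coma")
})

test_that("meddra map round-trips through write/load", {
  map <- generate_meddra_fixture(40)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "fixture.tsv")
  write_meddra_map(map, f)
  back <- load_meddra_map(f)
  expect_equal(back$pt, map$pt)
  expect_equal(back$soc_name, map$soc_name)
})

test_that("age conversion to years follows the unit codes", {
  expect_equal(age_in_years(c(50, 5, 24, 730.5), c("YR", "DEC", "MON", "DY")),
               c(50, 50, 2, 2))
  expect_warning(out <- age_in_years(30, NA), "treated as years")
  expect_equal(out, 30)
})
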