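# The four disproportionality statistics, thresholds and rankings.
#
# Frozen expected values for the (6,4,3,8) fixture were computed with the
# independent scalar oracle in helper-oracle.R before the implementation
# was written.

test_that("the (6,4,3,8) fixture reproduces the hand-derived statistics", {
  s <- compute_signal_stats(data.frame(event = "X", a = 6, b = 4, c = 3, d = 8))
  expect_equal(s$ror, 4)
  expect_equal(s$ror_lo, 0.6394686010, tolerance = 1e-9)
  expect_equal(s$ror_hi, 25.0207750215, tolerance = 1e-9)
  expect_equal(s$prr, 2.2)
  expect_equal(s$prr_lo, 0.7399126355, tolerance = 1e-9)
  expect_equal(s$prr_hi, 6.5413128092, tolerance = 1e-9)
  expect_equal(s$chi2, 1.1494318182, tolerance = 1e-9)
  expect_equal(s$gamma, 529 / 110)
  expect_equal(s$ic, log2(1.4))
  expect_equal(s$e_ic, 0.3833117004, tolerance = 1e-9)
  expect_equal(s$v_ic, 0.4159592851, tolerance = 1e-9)
  expect_equal(s$ic025, -0.9065864120, tolerance = 1e-9)
  expect_equal(s$ebgm, 1.4)
  expect_equal(s$ebgm05, 0.2238140104, tolerance = 1e-9)
  su <- compute_signal_stats(data.frame(event = "X", a = 6, b = 4, c = 3, d = 8),
                             chi2_variant = "uncorrected")
  expect_equal(su$chi2, 2.2909090909, tolerance = 1e-9)
})

test_that("a balanced table is null under every statistic", {
  s <- compute_signal_stats(data.frame(event = "X", a = 10, b = 10, c = 10,
                                       d = 10))
  expect_equal(s$ror, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$ebgm, 1)
  expect_equal(s$ic, 0)
  expect_false(any(unlist(s[, .(ror_flag, prr_flag, bcpnn_flag, ebgm_flag,
                                signal)])))
  # the shrinkage expectation tends to 0 as the balanced table grows
  big <- bcpnn_stats(1e5, 1e5, 1e5, 1e5)
  expect_lt(abs(big$e_ic), 1e-4)
})

test_that("zero cells give non-computable markers, never corrections", {
  s <- compute_signal_stats(data.frame(event = "X", a = 0, b = 5, c = 5, d = 5))
  expect_true(is.na(s$ror))
  expect_true(is.na(s$ic))
  # the BCPNN shrinkage chain stays defined at a = 0 (priors regularize)
  expect_false(is.na(s$e_ic))
  expect_false(is.na(s$ic025))
  expect_lt(s$ic025, 0)
  b0 <- bcpnn_stats(0, 10, 10, 100)
  expect_equal(b0$e_ic, -0.9822501312, tolerance = 1e-9)
  expect_equal(b0$ic025, -4.084391205, tolerance = 1e-8)
  # degenerate margin: a = N
  sm <- ebgm_stats(5, 0, 0, 0)
  expect_equal(sm$ebgm, 1)
  expect_true(is.na(sm$ebgm05))
})

test_that("threshold flags follow the published criteria", {
  s <- data.table::data.table(a = 2, ror_lo = 5, prr_lo = 5, ic025 = 1,
                              ebgm05 = 3)
  f <- evaluate_signal(s)
  expect_false(f$ror_flag)  # a < 3 vetoes despite the strong CI
  expect_false(f$prr_flag)
  expect_true(f$bcpnn_flag)
  expect_true(f$ebgm_flag)
  expect_false(f$signal)
  expect_true(evaluate_signal(s, policy = "any")$signal)
  strong <- compute_signal_stats(data.frame(event = "S", a = 500, b = 500,
                                            c = 500, d = 498500))
  expect_true(all(unlist(strong[, .(ror_flag, prr_flag, bcpnn_flag,
                                    ebgm_flag, signal)])))
})

test_that("ranking is a stable descending sort with the stated tie rule", {
  s <- compute_signal_stats(data.frame(event = c("B", "A", "C"),
                                       a = c(5, 9, 7), b = 100, c = 50,
                                       d = 1000))
  expect_equal(rank_results(s, "case_reports")$event, c("A", "C", "B"))
  expect_equal(nrow(rank_results(s, "case_reports", top_n = 0)), 0L)
  expect_equal(rank_results(s, "case_reports", top_n = 2)$event, c("A", "C"))
  tie <- compute_signal_stats(data.frame(event = c("zeta", "alpha"), a = 5,
                                         b = 10, c = 10, d = 100))
  expect_equal(rank_results(tie, "case_reports")$event, c("alpha", "zeta"))
  expect_equal(rank_results(tie, "ebgm")$event, c("alpha", "zeta"))
})

test_that("all statistics agree with the independent oracle on random tables", {
  tabs <- random_tables(300, seed = 4)
  s <- compute_signal_stats(tabs)
  su <- compute_signal_stats(tabs, chi2_variant = "uncorrected")
  pri <- bcpnn_priors(gamma11 = 0.5, alpha1 = 2, beta1 = 3, alpha = 4, beta = 5)
  sp <- compute_signal_stats(tabs, priors = pri)
  for (i in seq_len(nrow(tabs))) {
    o <- oracle_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    for (col in c("ror", "ror_lo", "ror_hi", "prr", "prr_lo", "prr_hi",
                  "ic", "e_ic", "v_ic", "ic025", "gamma", "ebgm",
                  "ebgm05", "ebgm95"))
      expect_lt(rel_err(s[[col]][i], o[[col]]), 1e-10)
    expect_lt(rel_err(s$chi2[i], o$chi2_yates), 1e-10)
    expect_lt(rel_err(su$chi2[i], o$chi2_uncorrected), 1e-10)
    op <- oracle_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i],
                       g11 = 0.5, a1 = 2, b1 = 3, al = 4, be = 5)
    for (col in c("e_ic", "v_ic", "ic025", "gamma"))
      expect_lt(rel_err(sp[[col]][i], op[[col]]), 1e-10)
  }
})

test_that("algebraic identities: ROR vs PRR, IC vs EBGM, label swap", {
  tabs <- random_tables(500, seed = 12)
  s <- compute_signal_stats(tabs)
  expect_true(all(sign(s$ror - 1) == sign(s$prr - 1)))
  expect_true(all(s$ror[s$prr > 1] > s$prr[s$prr > 1]))
  expect_equal(s$ic, log2(s$ebgm), tolerance = 1e-12)
  sw <- ror_stats(tabs$c, tabs$d, tabs$a, tabs$b)
  expect_equal(sw$ror, 1 / s$ror, tolerance = 1e-12)
})

test_that("more data tightens the shrinkage bound at fixed disproportion", {
  k <- c(1, 2, 5, 10, 50, 200)
  ic025 <- bcpnn_stats(6 * k, 4 * k, 3 * k, 8 * k)$ic025
  expect_true(all(diff(ic025) > 0))
})

test_that("invalid BCPNN priors are rejected", {
  expect_error(bcpnn_priors(gamma11 = 0), "positive")
  expect_error(bcpnn_priors(alpha = -1), "positive")
})
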