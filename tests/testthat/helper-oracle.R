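# Independent, naively coded oracle for the four disproportionality
# statistics: scalar transliteration of the printed formulas, with the
# chi-squared routed through stats::chisq.test as a second opinion.
# Deliberately separate from the vectorized implementation under test.

oracle_stats <- function(a, b, c, d, g11 = 1, a1 = 1, b1 = 1, al = 2, be = 2) {
  stopifnot(length(a) == 1L)
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  chi_y <- unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic)
  chi_u <- unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic)
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  eic <- log2((a + g11) * (N + al) * (N + be) /
                ((N + gam) * (a + b + a1) * (a + c + b1)))
  vic <- ((N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
          (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
          (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be))) / log(2)^2
  ebgm <- a * N / ((a + c) * (a + b))
  list(ror = ror,
       ror_lo = exp(log(ror) - 1.96 * se), ror_hi = exp(log(ror) + 1.96 * se),
       prr = prr,
       prr_lo = exp(log(prr) - 1.96 * se_prr),
       prr_hi = exp(log(prr) + 1.96 * se_prr),
       chi2_yates = chi_y, chi2_uncorrected = chi_u,
       ic = log2(a * N / ((a + b) * (a + c))),
       e_ic = eic, v_ic = vic, ic025 = eic - 2 * sqrt(vic), gamma = gam,
       ebgm = ebgm,
       ebgm05 = exp(log(ebgm) - 1.96 * se),
       ebgm95 = exp(log(ebgm) + 1.96 * se))
}

# random all-positive 2x2 tables for property tests
random_tables <- function(n, seed = 1L) {
  set.seed(seed)
  data.table::data.table(
    a = sample(1:500, n, replace = TRUE),
    b = sample(1:5000, n, replace = TRUE),
    c = sample(1:5000, n, replace = TRUE),
    d = sample(100:1000000, n, replace = TRUE))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), 1e-12)
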