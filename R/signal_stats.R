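# The four disproportionality statistics on 2x2 contingency tables.
#
# Notation: for one drug-event pair, a = target drug with the event,
# b = target drug without it, c = other drugs with it, d = other drugs
# without it, N = a + b + c + d.
#
#   ROR  = ad/bc, 95% CI on the log scale with SE = sqrt(1/a+1/b+1/c+1/d)
#   PRR  = [a/(a+b)] / [c/(c+d)], SE(lnPRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))
#   chi2 = Yates-corrected Pearson N(|ad-bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d)),
#          floored at 0; uncorrected variant available
#   BCPNN information component IC = log2[aN/((a+b)(a+c))] with shrinkage
#          expectation E(IC) and variance V(IC) under Dirichlet priors;
#          IC025 = E(IC) - 2*sqrt(V(IC))
#   EBGM = aN/((a+c)(a+b)) (closed-form relative reporting ratio) with a
#          Wald CI on the log scale (same SE as the ROR)
#
# Signal thresholds: ROR/PRR a >= 3 and CI lower bound > 1; IC025 > 0;
# EBGM05 > 2. No continuity corrections: tables with a zero cell in a
# required term are flagged non-computable (NA), never silently dropped.

.Z95 <- 1.96

#' BCPNN hyperparameters
#'
#' Dirichlet/beta prior parameters of the information-component shrinkage:
#' `gamma11` for the joint cell, `alpha1`/`beta1` for the two margins,
#' `alpha`/`beta` for the margin totals; `gamma` is derived as
#' `gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`. Defaults are the
#' standard choice 1, 1, 1, 2, 2.
#'
#' @param gamma11,alpha1,beta1,alpha,beta positive reals.
#' @return object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(gamma11 = 1, alpha1 = 1, beta1 = 1,
                         alpha = 2, beta = 2) {
  vals <- c(gamma11, alpha1, beta1, alpha, beta)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all BCPNN prior parameters must be positive and finite", call. = FALSE)
  structure(list(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
                 alpha = alpha, beta = beta), class = "bcpnn_priors")
}

#' Reporting odds ratio with 95% CI
#'
#' Non-computable (all-`NA`) when any cell is zero; no continuity
#' correction is applied.
#'
#' @param a,b,c,d cell counts (vectors recycle as usual).
#' @return data.table with `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.table::data.table(ror = ror,
                         ror_lo = exp(log(ror) - .Z95 * se),
                         ror_hi = exp(log(ror) + .Z95 * se))
}

#' Proportional reporting ratio with 95% CI and chi-squared
#'
#' The point estimate requires `a+b > 0`, `c+d > 0` and `c > 0`; the CI
#' additionally requires `a > 0`. The chi-squared statistic (computable
#' whenever all four margins are positive) defaults to the Yates-corrected
#' Pearson form, floored at 0 when `|ad-bc| < N/2`.
#'
#' @param a,b,c,d cell counts.
#' @param chi2_variant `"yates"` (default) or `"uncorrected"`.
#' @return data.table with `prr`, `prr_lo`, `prr_hi`, `chi2`.
#' @export
prr_stats <- function(a, b, c, d, chi2_variant = c("yates", "uncorrected")) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  chi2_variant <- match.arg(chi2_variant)
  n <- a + b + c + d
  ok_pt <- (a + b) > 0 & (c + d) > 0 & c > 0
  prr <- ifelse(ok_pt, (a / (a + b)) / (c / (c + d)), NA_real_)
  ok_ci <- ok_pt & a > 0
  se <- ifelse(ok_ci, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  lo <- ifelse(ok_ci, exp(log(prr) - .Z95 * se), NA_real_)
  hi <- ifelse(ok_ci, exp(log(prr) + .Z95 * se), NA_real_)
  ok_chi <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  det <- a * d - b * c
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  num <- if (chi2_variant == "yates") pmax(abs(det) - n / 2, 0)^2 else det^2
  chi2 <- ifelse(ok_chi, n * num / denom, NA_real_)
  data.table::data.table(prr = prr, prr_lo = lo, prr_hi = hi, chi2 = chi2)
}

#' BCPNN information component with shrinkage bounds
#'
#' The observed IC is non-computable when `a = 0`, but the shrinkage
#' quantities E(IC), V(IC) and IC025 remain defined (the priors
#' regularize).
#'
#' @param a,b,c,d cell counts.
#' @param priors a [bcpnn_priors()] object.
#' @return data.table with `ic`, `e_ic`, `v_ic`, `ic025` and the derived
#'   prior weight `gamma`.
#' @export
bcpnn_stats <- function(a, b, c, d, priors = bcpnn_priors()) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  stopifnot(inherits(priors, "bcpnn_priors"))
  n <- a + b + c + d
  g11 <- priors$gamma11; a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha; be <- priors$beta
  gamma <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ok_ic <- a > 0 & (a + b) > 0 & (a + c) > 0
  ic <- ifelse(ok_ic, log2(a * n / ((a + b) * (a + c))), NA_real_)
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + gamma) * (a + b + a1) * (a + c + b1)))
  v_ic <- (1 / log(2)^2) * (
    (n - a + gamma - g11) / ((a + g11) * (1 + n + gamma)) +
    (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
    (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be)))
  data.table::data.table(ic = ic, e_ic = e_ic, v_ic = v_ic,
                         ic025 = e_ic - 2 * sqrt(v_ic), gamma = gamma)
}

#' Empirical Bayes geometric mean (closed form) with 95% CI
#'
#' The closed-form relative reporting ratio `aN/((a+c)(a+b))` with a Wald
#' CI on the log scale (same SE term as the ROR) — not a posterior from a
#' fitted gamma mixture. Bounds are non-computable when any cell in the SE
#' term is zero; the point estimate is still returned when defined.
#'
#' @param a,b,c,d cell counts.
#' @return data.table with `ebgm`, `ebgm05`, `ebgm95`.
#' @export
ebgm_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ok_pt <- (a + b) > 0 & (a + c) > 0
  ebgm <- ifelse(ok_pt, a * n / ((a + c) * (a + b)), NA_real_)
  ok_ci <- a > 0 & b > 0 & c > 0 & d > 0
  se <- ifelse(ok_ci, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  lo <- ifelse(ok_ci, exp(log(ebgm) - .Z95 * se), NA_real_)
  hi <- ifelse(ok_ci, exp(log(ebgm) + .Z95 * se), NA_real_)
  data.table::data.table(ebgm = ebgm, ebgm05 = lo, ebgm95 = hi)
}

#' Apply the signal thresholds
#'
#' Per-method flags: ROR and PRR require `a >= 3` and a CI lower bound
#' above 1; BCPNN requires `IC025 > 0`; EBGM requires `EBGM05 > 2`.
#' Non-computable statistics never flag. The combined `signal` column uses
#' `policy`: `"all"` (default, all four methods agree) or `"any"`.
#'
#' @param stats data.table holding at least `a`, `ror_lo`, `prr_lo`,
#'   `ic025`, `ebgm05`.
#' @param policy `"all"` or `"any"`.
#' @return the data.table with `ror_flag`, `prr_flag`, `bcpnn_flag`,
#'   `ebgm_flag` and `signal` columns added.
#' @export
evaluate_signal <- function(stats, policy = c("all", "any")) {
  policy <- match.arg(policy)
  s <- data.table::as.data.table(stats)
  s[, ror_flag := !is.na(ror_lo) & a >= 3 & ror_lo > 1]
  s[, prr_flag := !is.na(prr_lo) & a >= 3 & prr_lo > 1]
  s[, bcpnn_flag := !is.na(ic025) & ic025 > 0]
  s[, ebgm_flag := !is.na(ebgm05) & ebgm05 > 2]
  if (policy == "all") {
    s[, signal := ror_flag & prr_flag & bcpnn_flag & ebgm_flag]
  } else {
    s[, signal := ror_flag | prr_flag | bcpnn_flag | ebgm_flag]
  }
  s[]
}

#' Compute all four statistics for a table collection
#'
#' @param tables output of [build_tables()] (or any data.table with
#'   columns `a`, `b`, `c`, `d`).
#' @param chi2_variant passed to [prr_stats()].
#' @param priors passed to [bcpnn_stats()].
#' @param policy passed to [evaluate_signal()].
#' @return data.table: the input columns plus every statistic, bound and
#'   flag.
#' @export
compute_signal_stats <- function(tables, chi2_variant = "yates",
                                 priors = bcpnn_priors(),
                                 policy = "all") {
  t <- data.table::as.data.table(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(t)))
  out <- cbind(t,
               ror_stats(t$a, t$b, t$c, t$d),
               prr_stats(t$a, t$b, t$c, t$d, chi2_variant = chi2_variant),
               bcpnn_stats(t$a, t$b, t$c, t$d, priors = priors),
               ebgm_stats(t$a, t$b, t$c, t$d))
  evaluate_signal(out, policy = policy)
}

#' Rank signal results
#'
#' Stable descending sort by case reports (`a`) or by `ebgm`; ties broken
#' by `a` descending then event label ascending. Non-computable sort keys
#' rank last.
#'
#' @param stats output of [compute_signal_stats()].
#' @param by `"case_reports"` or `"ebgm"`.
#' @param top_n rows to keep; `top_n <= 0` gives an empty result.
#' @return the ranked (truncated) data.table.
#' @export
rank_results <- function(stats, by = c("case_reports", "ebgm"), top_n = 30L) {
  by <- match.arg(by)
  s <- data.table::as.data.table(stats)
  if (top_n <= 0) return(s[0L])
  key <- if (by == "case_reports") as.numeric(s$a) else s$ebgm
  key[is.na(key)] <- -Inf
  o <- order(-key, -as.numeric(s$a), s$event)
  s[o][seq_len(min(top_n, nrow(s)))]
}

#' Format a signal table for reporting
#'
#' Renders the statistics in the conventional publication layout:
#' `ROR (95% CI)`, `PRR (95% CI)`, chi-squared, `IC (IC025)`,
#' `EBGM (EBGM05)`, all at 2 decimals.
#'
#' @param stats output of [compute_signal_stats()].
#' @return data.table of formatted character columns.
#' @export
format_signal_table <- function(stats) {
  s <- data.table::as.data.table(stats)
  f2 <- function(x) ifelse(is.na(x), "NC", sprintf("%.2f", x))
  data.table::data.table(
    event = s$event,
    level = if ("level" %in% names(s)) s$level else NA_character_,
    case_reports = s$a,
    `ROR (95% CI)` = sprintf("%s (%s-%s)", f2(s$ror), f2(s$ror_lo), f2(s$ror_hi)),
    `PRR (95% CI)` = sprintf("%s (%s-%s)", f2(s$prr), f2(s$prr_lo), f2(s$prr_hi)),
    chi2 = f2(s$chi2),
    `IC (IC025)` = sprintf("%s (%s)", f2(s$ic), f2(s$ic025)),
    `EBGM (EBGM05)` = sprintf("%s (%s)", f2(s$ebgm), f2(s$ebgm05)),
    signal = s$signal)
}
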