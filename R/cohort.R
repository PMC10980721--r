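# Target-drug cohort selection and descriptive (constituent-ratio) summaries.

#' Cohort selection settings
#'
#' A report enters the cohort when at least one of its drug rows has a role
#' in `roles` and a match field containing `drug_keyword` (case-insensitive
#' substring after trimming). The default selects primary-suspect (PS)
#' reports only.
#'
#' @param drug_keyword search keyword (default `"alprazolam"`).
#' @param match_fields fields searched, subset of `drugname`, `prod_ai`.
#' @param roles drug role codes accepted, subset of PS/SS/C/I.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(drug_keyword = "alprazolam",
                        match_fields = c("drugname", "prod_ai"),
                        roles = "PS") {
  match_fields <- match.arg(match_fields, c("drugname", "prod_ai"),
                            several.ok = TRUE)
  roles <- match.arg(roles, c("PS", "SS", "C", "I"), several.ok = TRUE)
  drug_keyword <- tolower(trimws(drug_keyword))
  if (!nzchar(drug_keyword)) stop("drug_keyword must be non-empty", call. = FALSE)
  structure(list(drug_keyword = drug_keyword, match_fields = match_fields,
                 roles = roles), class = "cohort_spec")
}

# logical mask over rows of a DRUG table matching the spec
match_drug_rows <- function(drug, spec) {
  m <- rep(FALSE, nrow(drug))
  for (f in spec$match_fields) {
    v <- drug[[f]]
    if (is.null(v)) next
    m <- m | (!is.na(v) & grepl(spec$drug_keyword, tolower(trimws(v)), fixed = TRUE))
  }
  m & !is.na(drug$role_cod) & drug$role_cod %in% spec$roles
}

#' Select the target-drug cohort
#'
#' @param bundle a deduplicated [faers_bundle()].
#' @param spec a [cohort_spec()].
#' @return sorted character vector of cohort `primaryid`s.
#' @export
select_cohort <- function(bundle, spec = cohort_spec()) {
  stopifnot(inherits(bundle, "faers_bundle"), inherits(spec, "cohort_spec"))
  rows <- match_drug_rows(bundle$drug, spec)
  ids <- sort(unique(bundle$drug$primaryid[rows]))
  ids <- ids[ids %chin% bundle$demo$primaryid]
  if (!length(ids))
    warning(sprintf("empty cohort for keyword '%s'", spec$drug_keyword),
            call. = FALSE)
  ids
}

#' Assign ages to the reporting age bins
#'
#' Bins are left-closed right-open so every non-negative age maps to exactly
#' one bin: [0,18), [18,45), [45,65), [65,75), [75,Inf). Missing or negative
#' ages map to `"Unknown"` (negative with a warning).
#'
#' @param age_years numeric vector of ages in years.
#' @return factor with levels `<18`, `18-45`, `45-65`, `65-75`, `>=75`,
#'   `Unknown`.
#' @export
age_bin <- function(age_years) {
  labs <- c("<18", "18-45", "45-65", "65-75", ">=75")
  x <- as.numeric(age_years)
  neg <- !is.na(x) & x < 0
  if (any(neg))
    warning(sprintf("%d negative age(s) set to Unknown", sum(neg)), call. = FALSE)
  x[neg] <- NA
  b <- cut(x, breaks = c(0, 18, 45, 65, 75, Inf), right = FALSE,
           labels = labs)
  out <- as.character(b)
  out[is.na(out)] <- "Unknown"
  factor(out, levels = c(labs, "Unknown"))
}

#' Days from therapy start to event onset
#'
#' For each cohort report: event date minus the earliest therapy start date
#' among therapy rows linked to the matched (target-drug) drug rows. Both
#' dates must be full valid YYYYMMDD; otherwise the value is missing.
#' Negative differences become missing with a warning.
#'
#' @param bundle a [faers_bundle()].
#' @param cohort_ids cohort `primaryid`s.
#' @param spec the [cohort_spec()] used to select the cohort.
#' @return data.table with columns `primaryid`, `days` (integer or `NA`).
#' @export
time_to_onset_days <- function(bundle, cohort_ids, spec = cohort_spec()) {
  drug <- bundle$drug[primaryid %chin% cohort_ids]
  tgt <- drug[match_drug_rows(drug, spec), .(primaryid, drug_seq)]
  ther <- bundle$ther[tgt, on = c("primaryid", dsg_drug_seq = "drug_seq"),
                      nomatch = NULL]
  ther <- ther[!is.na(start_date)]
  starts <- if (nrow(ther)) {
    ther[, .(start_date = min(start_date)), by = primaryid]
  } else {
    data.table::data.table(primaryid = character(),
                           start_date = as.Date(character()))
  }
  out <- data.table::data.table(primaryid = cohort_ids)
  out <- starts[out, on = "primaryid"]
  out <- bundle$demo[, .(primaryid, event_date)][out, on = "primaryid"]
  out[, days := as.integer(event_date - start_date)]
  n_neg <- sum(!is.na(out$days) & out$days < 0)
  if (n_neg > 0L)
    warning(sprintf("%d report(s) with event date before therapy start set to missing",
                    n_neg), call. = FALSE)
  out[!is.na(days) & days < 0, days := NA_integer_]
  out[, .(primaryid, days)]
}

#' Bin onset delays (days) into the reporting intervals
#'
#' @param days integer vector of onset delays.
#' @return factor with levels `0-30`, `31-60`, ..., `181-360`, `>360`,
#'   `Unknown`.
#' @export
tto_bin <- function(days) {
  labs <- c("0-30", "31-60", "61-90", "91-120", "121-150", "151-180",
            "181-360", ">360")
  b <- cut(as.numeric(days),
           breaks = c(-0.5, 30.5, 60.5, 90.5, 120.5, 150.5, 180.5, 360.5, Inf),
           labels = labs)
  out <- as.character(b)
  out[is.na(out)] <- "Unknown"
  factor(out, levels = c(labs, "Unknown"))
}

.reporter_display <- c(CN = "Consumer", PH = "Pharmacist", MD = "Physician",
                       HP = "Other health professional",
                       OT = "Other health professional", LW = "Lawyer")

.outcome_display <- c(DE = "Death", LT = "Life-Threatening",
                      HO = "Hospitalization-initial or prolonged",
                      DS = "Disability", CA = "Congenital anomaly",
                      RI = "Required intervention", OT = "Other serious")

#' Descriptive constituent-ratio summary of a cohort
#'
#' Counts and percentages (of the cohort size) per category: gender, age
#' bin, reporter type, reporting country, report year (year of the kept
#' version's FDA receive date), serious outcomes, and time-to-onset bins.
#' Serious outcomes are counted per report with multiplicity across outcome
#' codes, so that dimension need not sum to 100%. Time-to-onset rows cover
#' only reports with computable onset delays.
#'
#' @param bundle a deduplicated [faers_bundle()].
#' @param cohort_ids cohort `primaryid`s (non-empty).
#' @param spec the [cohort_spec()] used for selection (needed for onset
#'   delays).
#' @return data.table of class `faers_summary` with columns `dimension`,
#'   `category`, `count`, `pct`; attribute `denominator` holds the cohort
#'   size.
#' @export
summarize_cohort <- function(bundle, cohort_ids, spec = cohort_spec()) {
  stopifnot(length(cohort_ids) > 0L)
  n <- length(cohort_ids)
  demo <- bundle$demo[data.table::chmatch(cohort_ids, primaryid)]

  gender <- ifelse(demo$sex %in% c("F", "M"),
                   c(F = "Female", M = "Male")[demo$sex], "Unknown")
  gender <- factor(gender, levels = c("Female", "Male", "Unknown"))

  agey <- suppressWarnings(age_in_years(demo$age, demo$age_cod))
  ab <- age_bin(agey)

  occ <- toupper(trimws(as.character(demo$occp_cod)))
  reporter <- ifelse(occ %in% names(.reporter_display),
                     .reporter_display[occ], "Unknown")

  country <- trimws(as.character(demo$occr_country))
  country[is.na(country) | country == ""] <- "Unknown"

  year <- ifelse(is.na(demo$fda_date), "Unknown",
                 format(demo$fda_date, "%Y"))

  oc <- unique(bundle$outc[primaryid %chin% cohort_ids, .(primaryid, outc_cod)])
  oc <- oc[!is.na(outc_cod) & outc_cod %chin% names(.outcome_display)]
  oc[, outcome := .outcome_display[outc_cod]]

  tto <- time_to_onset_days(bundle, cohort_ids, spec)
  n_tto_missing <- sum(is.na(tto$days))
  if (n_tto_missing > 0L)
    message(sprintf("time-to-onset missing for %d of %d cohort reports (%.1f%%)",
                    n_tto_missing, n, 100 * n_tto_missing / n))
  tb <- tto_bin(tto$days[!is.na(tto$days)])

  count_dim <- function(dimension, x, drop_zero = FALSE) {
    tab <- table(x)
    dt <- data.table::data.table(dimension = rep(dimension, length(tab)),
                                 category = as.character(names(tab)),
                                 count = as.integer(tab))
    if (drop_zero) dt <- dt[count > 0L]
    dt
  }
  out <- data.table::rbindlist(list(
    count_dim("Gender", gender),
    count_dim("Age", ab),
    count_dim("Reporter", reporter, drop_zero = TRUE),
    count_dim("Reported countries", country, drop_zero = TRUE),
    count_dim("Report year", year, drop_zero = TRUE),
    count_dim("Serious outcomes", oc$outcome, drop_zero = TRUE),
    count_dim("Time to onset (days)", tb)
  ))
  out[, pct := constituent_ratio(count, n)]
  data.table::setattr(out, "denominator", n)
  data.table::setattr(out, "class", c("faers_summary", class(out)))
  out[]
}
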