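# 2x2 contingency tables per event (PT or SOC) for target drug vs all
# other drugs.
#
# Counting unit: the distinct (report, event) pair. A report listing the
# same PT twice contributes one unit; at SOC level a report contributes one
# unit per distinct SOC. Margins b and d are unit-based, which makes N
# identical across events at a given level.

#' Build distinct (report, event) units
#'
#' @param bundle a deduplicated [faers_bundle()].
#' @param cohort_ids cohort `primaryid`s.
#' @param level `"PT"` or `"SOC"`.
#' @param map a `meddra_map`; required at SOC level. PTs with no mapping go
#'   to the `"UNMAPPED"` bucket (counted and reported).
#' @return object of class `event_units`: list with the `units` data.table
#'   (`primaryid`, `event`, `in_cohort`), the unit margins and the level.
#' @export
build_event_units <- function(bundle, cohort_ids, level = c("PT", "SOC"),
                              map = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(bundle, "faers_bundle"))
  reac <- bundle$reac[!is.na(pt) & nzchar(trimws(pt))]
  n_unmapped <- 0L
  if (level == "SOC") {
    if (is.null(map))
      stop("a PT->SOC map is required at SOC level", call. = FALSE)
    soc <- soc_for_pt(map, reac$pt)
    n_unmapped <- sum(is.na(soc))
    if (n_unmapped > 0L)
      message(sprintf("%d reaction row(s) with unmapped PT assigned to 'UNMAPPED'",
                      n_unmapped))
    soc[is.na(soc)] <- "UNMAPPED"
    units <- data.table::data.table(primaryid = reac$primaryid, event = soc)
  } else {
    # distinctness is case-insensitive; the first-seen casing is the label
    units <- data.table::data.table(primaryid = reac$primaryid,
                                    ev_key = tolower(trimws(reac$pt)),
                                    lab = trimws(reac$pt))
    units[, event := lab[1L], by = "ev_key"]
    units[, c("ev_key", "lab") := NULL]
  }
  units <- unique(units[, .(primaryid, event)])
  units[, in_cohort := primaryid %chin% cohort_ids]
  structure(list(units = units,
                 level = level,
                 cohort_units = sum(units$in_cohort),
                 noncohort_units = sum(!units$in_cohort),
                 n_unmapped = n_unmapped),
            class = "event_units")
}

#' Build the per-event 2x2 contingency tables
#'
#' For each distinct event e: `a` = units with e among cohort reports,
#' `c` = units with e among non-cohort reports, `b` = total cohort units
#' minus `a`, `d` = total non-cohort units minus `c`. Events absent from
#' the cohort (a = 0) are retained so coverage accounting stays explicit.
#'
#' @param units an `event_units` object from [build_event_units()].
#' @return data.table with columns `event`, `level`, `a`, `b`, `c`, `d`,
#'   `N`, ordered by `a` descending.
#' @export
build_tables <- function(units) {
  stopifnot(inherits(units, "event_units"))
  u <- units$units
  tab <- u[, .(a = sum(in_cohort), ac = .N), by = event]
  tab[, c := ac - a]
  tab[, ac := NULL]
  tab[, b := units$cohort_units - a]
  tab[, d := units$noncohort_units - c]
  tab[, N := a + b + c + d]
  tab[, level := units$level]
  data.table::setorder(tab, -a, event)
  tab[, .(event, level, a, b, c, d, N)]
}
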