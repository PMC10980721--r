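# FDA-recommended duplicate removal and deleted-report handling.
#
# Reports are versions of a case: rows sharing a CASEID. For each case the
# version with the largest FDA_DT is kept; FDA_DT ties are broken by the
# largest PRIMARYID. Deleted-case lists (shipped with quarterly packages
# since 2019Q1) are applied after deduplication.

#' Deduplicate DEMO records by case
#'
#' For each CASEID exactly one report survives: the maximum by
#' (FDA_DT, then PRIMARYID). Comparison uses the integer value of the raw
#' date string, so partial dates order deterministically and a missing
#' FDA_DT sorts lowest (a dated version always beats an undated one).
#' Records with a missing CASEID are kept unconditionally.
#'
#' @param demo a DEMO data.table with columns `primaryid`, `caseid`, `fda_dt`.
#' @return an object of class `dedup_result`: a list with
#'   `kept_primaryids` (sorted), `kept_cases` (primaryid/caseid pairs for
#'   kept records with a caseid), `removed_as_duplicate`,
#'   `removed_as_deleted`, `n_missing_caseid` and `n_input`.
#' @export
deduplicate <- function(demo) {
  d <- data.table::as.data.table(demo)
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(d)))
  n_input <- nrow(d)
  key <- data.table::data.table(
    primaryid = as.character(d$primaryid),
    caseid = trimws(as.character(d$caseid)),
    fda_key = suppressWarnings(as.numeric(d$fda_dt)),
    pid_key = suppressWarnings(as.numeric(d$primaryid)))
  key[is.na(fda_key), fda_key := -1]
  miss <- is.na(key$caseid) | key$caseid == ""
  if (any(miss))
    message(sprintf("deduplicate: %d record(s) with missing caseid kept unconditionally",
                    sum(miss)))
  with_case <- key[!miss]
  data.table::setorder(with_case, caseid, fda_key, pid_key, primaryid)
  kept_cases <- with_case[with_case[, .I[.N], by = caseid]$V1,
                          .(primaryid, caseid)]
  kept <- sort(c(kept_cases$primaryid, key$primaryid[miss]))
  structure(list(kept_primaryids = kept,
                 kept_cases = kept_cases,
                 removed_as_duplicate = n_input - length(kept),
                 removed_as_deleted = 0L,
                 n_missing_caseid = sum(miss),
                 n_input = n_input),
            class = "dedup_result")
}

#' Remove deleted cases from a dedup result
#'
#' Drops every kept report whose CASEID appears on the (union of the)
#' deleted-report list(s). Must run after [deduplicate()]. Deleted caseids
#' never seen in the data are ignored.
#'
#' @param result a `dedup_result`.
#' @param deleted_caseids character vector of case identifiers.
#' @return the updated `dedup_result`.
#' @export
apply_deletions <- function(result, deleted_caseids) {
  stopifnot(inherits(result, "dedup_result"))
  del <- unique(trimws(as.character(deleted_caseids)))
  del <- del[!is.na(del) & del != ""]
  hit <- result$kept_cases$caseid %in% del
  unseen <- setdiff(del, result$kept_cases$caseid)
  if (length(unseen))
    message(sprintf("apply_deletions: %d deleted caseid(s) not present in the data",
                    length(unseen)))
  removed_ids <- result$kept_cases$primaryid[hit]
  result$kept_cases <- result$kept_cases[!hit]
  result$kept_primaryids <- setdiff(result$kept_primaryids, removed_ids)
  result$removed_as_deleted <- result$removed_as_deleted + sum(hit)
  result
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("<dedup_result>\n")
  cat(sprintf("  input reports:        %d\n", x$n_input))
  cat(sprintf("  kept:                 %d\n", length(x$kept_primaryids)))
  cat(sprintf("  removed as duplicate: %d\n", x$removed_as_duplicate))
  cat(sprintf("  removed as deleted:   %d\n", x$removed_as_deleted))
  invisible(x)
}

#' Deduplicate a whole bundle
#'
#' Runs [deduplicate()] then [apply_deletions()] with the bundle's own
#' deleted-case list, and drops child-table rows (DRUG/REAC/OUTC/THER) of
#' removed reports in the same pass.
#'
#' @param bundle a [faers_bundle()].
#' @return list with `bundle` (filtered) and `result` (the `dedup_result`).
#' @export
dedup_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  res <- deduplicate(bundle$demo)
  res <- apply_deletions(res, bundle$deleted_caseids)
  keep <- res$kept_primaryids
  out <- bundle
  for (tb in .faers_table_names)
    out[[tb]] <- bundle[[tb]][primaryid %chin% keep]
  out$deleted_caseids <- character()
  list(bundle = out, result = res)
}
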