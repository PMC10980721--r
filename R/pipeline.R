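# End-to-end orchestration: ingest -> dedup -> cohort -> contingency ->
# signal statistics -> ranked reports, with stage row-count accounting.

#' Pipeline run settings
#'
#' Exactly one of `input` (file paths for [read_quarter()]) or `sim`
#' (a [sim_config()]) must be supplied.
#'
#' @param input named list of table paths (`demo`, `drug`, `reac`, `outc`,
#'   `ther`, optional `deleted`), or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param quarter_label label attached to ingested records.
#' @param drug_keyword,match_fields,roles forwarded to [cohort_spec()].
#' @param levels aggregation levels to analyse, subset of `"PT"`, `"SOC"`.
#' @param meddra path to a PT->SOC TSV ([load_meddra_map()]); required for
#'   SOC level with file input (simulated runs use the built-in fixture).
#' @param chi2_variant,priors,policy forwarded to [compute_signal_stats()].
#' @param top_n rows in the ranked tables.
#' @param out_dir optional output directory for TSVs and the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = NULL,
                       quarter_label = NA_character_,
                       drug_keyword = "alprazolam",
                       match_fields = c("drugname", "prod_ai"),
                       roles = "PS",
                       levels = c("PT", "SOC"),
                       meddra = NULL,
                       chi2_variant = "yates",
                       priors = bcpnn_priors(),
                       policy = "all",
                       top_n = 30L,
                       out_dir = NULL) {
  if (is.null(input) == is.null(sim))
    stop("supply exactly one of 'input' (file paths) or 'sim' (a sim_config)",
         call. = FALSE)
  levels <- match.arg(levels, c("PT", "SOC"), several.ok = TRUE)
  if ("SOC" %in% levels && is.null(sim) && is.null(meddra))
    stop("SOC-level analysis of file input requires a 'meddra' map path",
         call. = FALSE)
  structure(list(input = input, sim = sim, quarter_label = quarter_label,
                 cohort = cohort_spec(drug_keyword, match_fields, roles),
                 levels = levels, meddra = meddra,
                 chi2_variant = chi2_variant, priors = priors,
                 policy = policy, top_n = as.integer(top_n),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Stages: ingest (or simulate) -> deduplicate and apply deletions ->
#' select the target-drug cohort -> descriptive summary -> per-level
#' contingency tables -> four disproportionality statistics with threshold
#' flags -> ranked tables by case reports and by EBGM. When
#' `config$out_dir` is set, writes `descriptive_summary.tsv`,
#' `signals_<level>.tsv`, `top_by_case_reports_PT.tsv`,
#' `top_by_ebgm_PT.tsv` and `manifest.json`.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `manifest`, `summary`, `signals` (one
#'   data.table per level), `ranked` (by case reports / by EBGM at PT
#'   level), `cohort_ids` and, for simulated runs, `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$sim)) {
    gen <- generate_corpus(config$sim)
    bundle <- gen$bundle
    map <- gen$meddra
    truth <- gen$truth
  } else {
    bundle <- read_quarter(config$input, config$quarter_label)
    map <- if (!is.null(config$meddra)) load_meddra_map(config$meddra)
  }
  n_raw <- nrow(bundle$demo)

  dd <- dedup_bundle(bundle)
  bundle <- dd$bundle
  res <- dd$result

  ids <- select_cohort(bundle, config$cohort)
  summ <- summarize_cohort(bundle, ids, config$cohort)

  signals <- list()
  ranked <- list()
  stage_counts <- list(raw_reports = n_raw,
                       deduped_reports = length(res$kept_primaryids),
                       removed_as_duplicate = res$removed_as_duplicate,
                       removed_as_deleted = res$removed_as_deleted,
                       cohort_size = length(ids))
  for (lv in config$levels) {
    units <- build_event_units(bundle, ids, lv,
                               map = if (lv == "SOC") map)
    tabs <- build_tables(units)
    stats <- compute_signal_stats(tabs, chi2_variant = config$chi2_variant,
                                  priors = config$priors,
                                  policy = config$policy)
    signals[[lv]] <- stats
    stage_counts[[paste0("units_", lv)]] <- units$cohort_units + units$noncohort_units
    stage_counts[[paste0("cohort_units_", lv)]] <- units$cohort_units
    stage_counts[[paste0("events_", lv)]] <- nrow(stats)
    stage_counts[[paste0("signals_", lv)]] <- sum(stats$signal)
    if (lv == "PT") {
      ranked$by_case_reports <- rank_results(stats, "case_reports", config$top_n)
      ranked$by_ebgm <- rank_results(stats, "ebgm", config$top_n)
    }
  }

  manifest <- list(
    stages = stage_counts,
    config = list(drug_keyword = config$cohort$drug_keyword,
                  roles = config$cohort$roles,
                  match_fields = config$cohort$match_fields,
                  levels = config$levels,
                  chi2_variant = config$chi2_variant,
                  policy = config$policy,
                  top_n = config$top_n,
                  priors = unclass(config$priors),
                  simulated = !is.null(config$sim),
                  sim_seed = if (!is.null(config$sim)) config$sim$seed),
    package_version = as.character(utils::packageVersion("pvsignal")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(summ, file.path(config$out_dir, "descriptive_summary.tsv"),
                       sep = "\t", quote = FALSE)
    for (lv in names(signals))
      data.table::fwrite(signals[[lv]],
                         file.path(config$out_dir, sprintf("signals_%s.tsv", lv)),
                         sep = "\t", quote = FALSE)
    if (!is.null(ranked$by_case_reports)) {
      data.table::fwrite(format_signal_table(ranked$by_case_reports),
                         file.path(config$out_dir, "top_by_case_reports_PT.tsv"),
                         sep = "\t", quote = FALSE)
      data.table::fwrite(format_signal_table(ranked$by_ebgm),
                         file.path(config$out_dir, "top_by_ebgm_PT.tsv"),
                         sep = "\t", quote = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(manifest = manifest, summary = summ, signals = signals,
                 ranked = ranked, cohort_ids = ids, truth = truth))
}
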