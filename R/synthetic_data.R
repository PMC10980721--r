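# Synthetic FAERS-like corpus generator with known ground truth.
#
# The generator emulates the structural features the pipeline must survive:
# multi-row cases sharing a CASEID, several drugs per report with role codes
# (one primary suspect each), several PTs per report, partial and missing
# dates, duplicate report versions, and a deleted-case list. Drug-event
# signals are injected multiplicatively on the per-report inclusion odds of
# a PT for reports whose primary-suspect drug matches, so the true
# reporting odds ratio of an injected pair equals lambda asymptotically.

# The 27 System Organ Classes used for the synthetic PT->SOC fixture
# (standard MedDRA primary SOC names).
.soc_catalogue <- c(
  "Psychiatric disorders",
  "General disorders and administration site conditions",
  "Nervous system disorders",
  "Injury, poisoning and procedural complications",
  "Gastrointestinal disorders",
  "Respiratory, thoracic and mediastinal disorders",
  "Cardiac disorders",
  "Investigations",
  "Musculoskeletal and connective tissue disorders",
  "Skin and subcutaneous tissue disorders",
  "Vascular disorders",
  "Eye disorders",
  "Product issues",
  "Metabolism and nutrition disorders",
  "Infections and infestations",
  "Social circumstances",
  "Immune system disorders",
  "Renal and urinary disorders",
  "Hepatobiliary disorders",
  "Ear and labyrinth disorders",
  "Blood and lymphatic system disorders",
  "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
  "Surgical and medical procedures",
  "Congenital, familial and genetic disorders",
  "Pregnancy, puerperium and perinatal conditions",
  "Reproductive system and breast disorders",
  "Endocrine disorders")

#' Simulation settings for the synthetic corpus
#'
#' Defaults describe a mid-sized spontaneous-report corpus: 50 drugs and
#' 200 PTs with power-law popularity, about two drugs and two reactions per
#' report, a female-majority sex mix and reporter/country mixtures typical
#' of consumer-dominated reporting, 10% duplicated cases and a 2% deleted
#' list.
#'
#' @param n_reports number of base cases.
#' @param n_drugs,n_pts catalogue sizes.
#' @param drug_weight_exponent,pt_weight_exponent power-law exponents of
#'   the popularity weights (weight of rank r is r^-exponent).
#' @param mean_pts_per_report expected reactions per report (each PT enters
#'   independently with weight-proportional probability).
#' @param mean_extra_drugs expected non-primary-suspect drugs per report
#'   (geometric, capped at 4).
#' @param signal_specs data.frame/list with columns `drug`, `pt`, `lambda`:
#'   multiplicative reporting-rate signals on the inclusion odds.
#' @param duplicate_rate fraction of cases emitted twice (second version
#'   has a later FDA date and a fresh primaryid).
#' @param deletion_rate fraction of caseids placed on the deleted list.
#' @param missing_date_rate,partial_date_rate event/therapy date
#'   degradation rates.
#' @param missing_age_rate,missing_sex_rate demographic missingness.
#' @param female_prob probability of female among known-sex reports.
#' @param year_range two-element integer vector of therapy-start years;
#'   later years are weighted more heavily (reporting grows over time).
#' @param seed integer RNG seed; the corpus is reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_reports = 20000L, n_drugs = 50L, n_pts = 200L,
                       drug_weight_exponent = 1, pt_weight_exponent = 1,
                       mean_pts_per_report = 2, mean_extra_drugs = 1,
                       signal_specs = NULL,
                       duplicate_rate = 0.10, deletion_rate = 0.02,
                       missing_date_rate = 0.10, partial_date_rate = 0.10,
                       missing_age_rate = 0.25, missing_sex_rate = 0.076,
                       female_prob = 0.612,
                       year_range = c(2004L, 2023L), seed = 1L) {
  rates <- c(duplicate_rate, deletion_rate, missing_date_rate,
             partial_date_rate, missing_age_rate, missing_sex_rate,
             female_prob)
  if (any(rates < 0 | rates > 1))
    stop("all rates/probabilities must lie in [0, 1]", call. = FALSE)
  if (n_reports < 1L || n_drugs < 1L || n_pts < 1L)
    stop("n_reports, n_drugs and n_pts must be positive", call. = FALSE)
  if (mean_pts_per_report <= 0 || mean_pts_per_report > n_pts)
    stop("mean_pts_per_report must be in (0, n_pts]", call. = FALSE)
  if (length(year_range) != 2L || year_range[2] < year_range[1])
    stop("year_range must be c(first, last) with first <= last", call. = FALSE)
  sig <- normalize_signal_specs(signal_specs, n_drugs, n_pts)
  structure(list(n_reports = as.integer(n_reports),
                 n_drugs = as.integer(n_drugs), n_pts = as.integer(n_pts),
                 drug_weight_exponent = drug_weight_exponent,
                 pt_weight_exponent = pt_weight_exponent,
                 mean_pts_per_report = mean_pts_per_report,
                 mean_extra_drugs = mean_extra_drugs,
                 signal_specs = sig,
                 duplicate_rate = duplicate_rate,
                 deletion_rate = deletion_rate,
                 missing_date_rate = missing_date_rate,
                 partial_date_rate = partial_date_rate,
                 missing_age_rate = missing_age_rate,
                 missing_sex_rate = missing_sex_rate,
                 female_prob = female_prob,
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

normalize_signal_specs <- function(signal_specs, n_drugs, n_pts) {
  if (is.null(signal_specs) || (is.data.frame(signal_specs) && !nrow(signal_specs)))
    return(data.table::data.table(drug = character(), pt = character(),
                                  lambda = numeric()))
  if (!is.data.frame(signal_specs))
    signal_specs <- data.table::rbindlist(lapply(signal_specs, as.list))
  sig <- data.table::as.data.table(signal_specs)[, .(drug = as.character(drug),
                                                     pt = as.character(pt),
                                                     lambda = as.numeric(lambda))]
  if (any(!is.finite(sig$lambda) | sig$lambda <= 0))
    stop("signal lambdas must be positive and finite", call. = FALSE)
  valid_drugs <- sprintf("DRUG_%03d", seq_len(n_drugs))
  valid_pts <- sprintf("PT_%03d", seq_len(n_pts))
  bad <- c(setdiff(sig$drug, valid_drugs), setdiff(sig$pt, valid_pts))
  if (length(bad))
    stop(sprintf("signal spec references unknown drug/PT: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  sig
}

#' Synthetic PT to SOC mapping fixture
#'
#' Assigns the synthetic PT catalogue deterministically (round-robin) to a
#' fixed list of 27 standard System Organ Class names, with synthetic SOC
#' codes.
#'
#' @param n_pts number of PTs in the catalogue.
#' @param path optional TSV output path (written via [write_meddra_map()]).
#' @return a `meddra_map`.
#' @export
generate_meddra_fixture <- function(n_pts, path = NULL) {
  stopifnot(n_pts >= 1L)
  idx <- (seq_len(n_pts) - 1L) %% length(.soc_catalogue) + 1L
  map <- meddra_map(pt = sprintf("PT_%03d", seq_len(n_pts)),
                    soc_name = .soc_catalogue[idx],
                    soc_code = as.character(10000000L + idx))
  if (!is.null(path)) write_meddra_map(map, path)
  map
}

# stochastic degradation of full YYYYMMDD strings to YYYYMM/YYYY/missing
degrade_dates <- function(raw, partial_rate, missing_rate) {
  n <- length(raw)
  u <- runif(n)
  out <- raw
  out[u < missing_rate] <- NA_character_
  part <- u >= missing_rate & u < missing_rate + partial_rate
  half <- runif(n) < 0.5
  out[part & half] <- substr(out[part & half], 1, 6)
  out[part & !half] <- substr(out[part & !half], 1, 4)
  out
}

random_case_style <- function(x) {
  u <- runif(length(x))
  out <- toupper(x)
  out[u < 0.15] <- tolower(out[u < 0.15])
  dot <- runif(length(x)) < 0.10
  out[dot] <- paste0(out[dot], ".")
  out
}

#' Generate a synthetic FAERS-like corpus
#'
#' Reproducible from `cfg$seed` (the function sets the RNG seed). Reports
#' draw a primary-suspect drug and additional drugs from power-law
#' popularity weights; each PT enters a report independently with
#' weight-proportional probability, multiplied on the odds scale by
#' `lambda` for reports whose primary suspect is in a signal spec. A
#' fraction of cases is duplicated with a later FDA date and fresh
#' primaryid (clinical fields untouched), and a fraction of caseids is
#' placed on the deleted list.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, the quarter files,
#'   deleted list, PT->SOC fixture (`meddra.tsv`) and truth JSON
#'   (`truth.json`) are written there.
#' @return list with `bundle` (a [faers_bundle()]), `truth` (class
#'   `synthetic_truth`: the signal specs with realized post-dedup counts,
#'   seed and corpus sizes) and `meddra` (the fixture map).
#' @export
generate_corpus <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reports
  drugs <- sprintf("DRUG_%03d", seq_len(cfg$n_drugs))
  pts <- sprintf("PT_%03d", seq_len(cfg$n_pts))
  w_d <- seq_len(cfg$n_drugs)^(-cfg$drug_weight_exponent)
  w_d <- w_d / sum(w_d)
  w_p <- seq_len(cfg$n_pts)^(-cfg$pt_weight_exponent)
  w_p <- w_p / sum(w_p)

  caseid <- as.character(1000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  ## drugs: one primary suspect + extras
  ps_idx <- sample.int(cfg$n_drugs, n, replace = TRUE, prob = w_d)
  ps_drug <- drugs[ps_idx]
  n_extra <- pmin(rgeom(n, 1 / (1 + cfg$mean_extra_drugs)), 4L)
  extra_rep <- rep(seq_len(n), n_extra)
  extra_idx <- sample.int(cfg$n_drugs, length(extra_rep), replace = TRUE,
                          prob = w_d)
  drug_dt <- data.table::rbindlist(list(
    data.table::data.table(ridx = seq_len(n), didx = ps_idx, role_cod = "PS"),
    data.table::data.table(ridx = extra_rep, didx = extra_idx,
                           role_cod = sample(c("SS", "C"), length(extra_rep),
                                             replace = TRUE, prob = c(0.6, 0.4)))
  ))
  drug_dt[, pri := role_cod != "PS"]  # PS first within report
  data.table::setorder(drug_dt, ridx, pri, didx)
  drug_dt[, pri := NULL]
  drug_dt[, drug_seq := seq_len(.N), by = ridx]
  drug_dt[, drugname := random_case_style(drugs[didx])]
  drug_dt[, prod_ai := toupper(drugs[didx])]

  ## reactions: independent Bernoulli inclusion per PT, odds scaled by lambda
  base_p <- pmin(cfg$mean_pts_per_report * w_p, 0.6)
  sig <- cfg$signal_specs
  inc <- vector("list", cfg$n_pts)
  for (j in seq_len(cfg$n_pts)) {
    p <- rep(base_p[j], n)
    srows <- sig[pt == pts[j]]
    if (nrow(srows)) {
      for (k in seq_len(nrow(srows))) {
        m <- ps_drug == srows$drug[k]
        lam <- srows$lambda[k]
        p[m] <- lam * p[m] / (1 + (lam - 1) * p[m])
      }
    }
    hit <- which(runif(n) < p)
    if (length(hit))
      inc[[j]] <- data.table::data.table(ridx = hit, ptidx = j)
  }
  reac_pairs <- data.table::rbindlist(inc)
  # every report carries at least one reaction
  none <- setdiff(seq_len(n), unique(reac_pairs$ridx))
  if (length(none))
    reac_pairs <- rbind(reac_pairs,
                        data.table::data.table(
                          ridx = none,
                          ptidx = sample.int(cfg$n_pts, length(none),
                                             replace = TRUE, prob = w_p)))
  data.table::setorder(reac_pairs, ridx, ptidx)

  ## dates: therapy start -> event onset -> FDA receipt
  years <- seq(cfg$year_range[1], cfg$year_range[2])
  yr <- sample(years, n, replace = TRUE, prob = seq_along(years))
  start_date <- as.Date(sprintf("%d-%02d-%02d", yr,
                                sample.int(12L, n, replace = TRUE),
                                sample.int(28L, n, replace = TRUE)))
  tto <- rgeom(n, 1 / 12)
  long <- runif(n) < 0.03
  tto[long] <- sample(361:700, sum(long), replace = TRUE)
  event_date <- start_date + tto
  fda_date <- event_date + rgeom(n, 1 / 20) + 1L
  fda_raw <- format(fda_date, "%Y%m%d")
  event_raw <- degrade_dates(format(event_date, "%Y%m%d"),
                             cfg$partial_date_rate, cfg$missing_date_rate)
  start_raw <- degrade_dates(format(start_date, "%Y%m%d"),
                             cfg$partial_date_rate / 2, cfg$missing_date_rate / 2)

  ## demographics
  p_sex <- c((1 - cfg$missing_sex_rate) * cfg$female_prob,
             (1 - cfg$missing_sex_rate) * (1 - cfg$female_prob),
             cfg$missing_sex_rate)
  sex <- sample(c("F", "M", NA_character_), n, replace = TRUE, prob = p_sex)
  age <- round(pmin(pmax(rnorm(n, 46, 20), 0.5), 99), 1)
  age[runif(n) < cfg$missing_age_rate] <- NA_real_
  age_cod <- ifelse(is.na(age), NA_character_, "YR")
  occp <- sample(c("CN", "MD", "PH", "OT", "LW", NA_character_), n,
                 replace = TRUE,
                 prob = c(0.354, 0.300, 0.198, 0.126, 0.003, 0.019))
  country <- sample(c("US", "FR", "IT", "BR", "JP", "OTHER"), n,
                    replace = TRUE,
                    prob = c(0.544, 0.186, 0.100, 0.032, 0.019, 0.119))

  ## outcomes: independent per code
  outc_prob <- c(DE = 0.12, HO = 0.25, LT = 0.04, DS = 0.02, OT = 0.15)
  outc_dt <- data.table::rbindlist(lapply(names(outc_prob), function(code) {
    hit <- which(runif(n) < outc_prob[[code]])
    data.table::data.table(ridx = hit, outc_cod = code)
  }))
  data.table::setorder(outc_dt, ridx, outc_cod)

  demo_raw <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_raw,
    event_dt = event_raw, sex = sex,
    age = ifelse(is.na(age), NA_character_, format(age, trim = TRUE)),
    age_cod = age_cod, occp_cod = occp, occr_country = country)

  ## duplicate versions: same clinical content, later fda_dt, new primaryid
  n_dup <- round(cfg$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer()
  if (length(dup_idx)) {
    dup_demo <- demo_raw[dup_idx]
    dup_demo[, primaryid := paste0(caseid, "2")]
    dup_demo[, fda_dt := format(fda_date[dup_idx] +
                                  sample.int(60L, length(dup_idx), replace = TRUE),
                                "%Y%m%d")]
    demo_all <- rbind(demo_raw, dup_demo)
  } else {
    demo_all <- demo_raw
  }

  expand_children <- function(dt) {
    # dt has ridx; emit one copy per report version
    base <- data.table::copy(dt)[, primaryid := primaryid[ridx]]
    if (length(dup_idx)) {
      dup <- dt[ridx %in% dup_idx]
      dup <- data.table::copy(dup)[, primaryid := paste0(caseid[ridx], "2")]
      base <- rbind(base, dup)
    }
    base
  }

  drug_all <- expand_children(drug_dt)[, .(primaryid,
                                           drug_seq = as.character(drug_seq),
                                           role_cod, drugname, prod_ai)]
  reac_all <- expand_children(reac_pairs)[, .(primaryid, pt = pts[ptidx])]
  outc_all <- expand_children(outc_dt)[, .(primaryid, outc_cod)]
  ther_base <- data.table::data.table(ridx = seq_len(n), dsg_drug_seq = "1",
                                      start_dt = start_raw)
  ther_all <- expand_children(ther_base)[, .(primaryid, dsg_drug_seq, start_dt)]

  ## deleted-case list
  n_del <- round(cfg$deletion_rate * n)
  deleted <- if (n_del > 0) sort(sample(caseid, n_del)) else character()

  bundle <- faers_bundle(
    canonicalize_table(demo_all, "demo", sprintf("SYN%dQ1", cfg$year_range[2])),
    canonicalize_table(drug_all, "drug"),
    canonicalize_table(reac_all, "reac"),
    canonicalize_table(outc_all, "outc"),
    canonicalize_table(ther_all, "ther"),
    deleted)

  ## ground truth: realized counts on the surviving (post-dedup, post-
  ## deletion) corpus; duplicates collapse back onto their base case
  surviving <- !(caseid %in% deleted)
  truth_sig <- data.table::copy(cfg$signal_specs)
  if (nrow(truth_sig)) {
    truth_sig[, realized_a := vapply(seq_len(.N), function(k) {
      j <- match(truth_sig$pt[k], pts)
      rids <- reac_pairs[ptidx == j, unique(ridx)]
      sum(ps_drug[rids] == truth_sig$drug[k] & surviving[rids])
    }, integer(1))]
  } else {
    truth_sig[, realized_a := integer()]
  }
  truth <- structure(list(signal_specs = truth_sig,
                          seed = cfg$seed,
                          n_reports = n,
                          n_surviving = sum(surviving),
                          n_duplicates = length(dup_idx),
                          n_deleted = length(deleted)),
                     class = "synthetic_truth")

  map <- generate_meddra_fixture(cfg$n_pts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_quarter(bundle, out_dir)
    write_meddra_map(map, file.path(out_dir, "meddra.tsv"))
    jsonlite::write_json(
      list(signal_specs = truth_sig, seed = cfg$seed,
           n_reports = n, n_surviving = truth$n_surviving,
           n_duplicates = truth$n_duplicates, n_deleted = truth$n_deleted),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  list(bundle = bundle, truth = truth, meddra = map)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat(sprintf("  seed %d: %d base cases, %d surviving, %d duplicates, %d deleted\n",
              x$seed, x$n_reports, x$n_surviving, x$n_duplicates, x$n_deleted))
  if (nrow(x$signal_specs)) {
    cat("  injected signals:\n")
    print(x$signal_specs)
  } else cat("  no injected signals (null corpus)\n")
  invisible(x)
}
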