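# Small hand-built corpora used across test files.

make_demo <- function(primaryid, caseid = primaryid, fda_dt = "20200101",
                      event_dt = NA_character_, sex = NA_character_,
                      age = NA_character_, age_cod = NA_character_,
                      occp_cod = NA_character_, occr_country = NA_character_) {
  data.table::data.table(primaryid = as.character(primaryid),
                         caseid = as.character(caseid),
                         fda_dt = fda_dt, event_dt = event_dt, sex = sex,
                         age = age, age_cod = age_cod, occp_cod = occp_cod,
                         occr_country = occr_country)
}

empty_tab <- function(table) {
  cols <- list(
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    ther = c("primaryid", "dsg_drug_seq", "start_dt"))[[table]]
  data.table::setDT(stats::setNames(rep(list(character()), length(cols)), cols))
}

# bundle builder from compact row specs; all args are data.tables of raw
# character columns (canonicalization applied as in read_quarter)
make_bundle <- function(demo, drug = empty_tab("drug"), reac = empty_tab("reac"),
                        outc = empty_tab("outc"), ther = empty_tab("ther"),
                        deleted = character()) {
  canon <- getFromNamespace("canonicalize_table", "pvsignal")
  faers_bundle(canon(demo, "demo", "TESTQ1"), canon(drug, "drug"),
               canon(reac, "reac"), canon(outc, "outc"), canon(ther, "ther"),
               deleted)
}

drug_row <- function(primaryid, drugname, role_cod = "PS", drug_seq = "1",
                     prod_ai = NA_character_) {
  data.table::data.table(primaryid = as.character(primaryid),
                         drug_seq = as.character(drug_seq),
                         role_cod = role_cod, drugname = drugname,
                         prod_ai = prod_ai)
}

reac_row <- function(primaryid, pt) {
  data.table::data.table(primaryid = as.character(primaryid), pt = pt)
}

# two-drug corpus: reports 1..n_t take the target drug (PS), the rest a
# comparator; each report has the listed PTs
two_drug_bundle <- function(target_pts, other_pts, target = "TARGETOL",
                            other = "OTHEROL") {
  n_t <- length(target_pts)
  n_o <- length(other_pts)
  ids <- as.character(seq_len(n_t + n_o))
  demo <- make_demo(ids)
  drug <- data.table::rbindlist(c(
    lapply(seq_len(n_t), function(i) drug_row(ids[i], target)),
    lapply(seq_len(n_o), function(i) drug_row(ids[n_t + i], other))))
  reac <- data.table::rbindlist(c(
    lapply(seq_len(n_t), function(i) reac_row(ids[i], target_pts[[i]])),
    lapply(seq_len(n_o), function(i) reac_row(ids[n_t + i], other_pts[[i]]))))
  make_bundle(demo, drug, reac)
}

# brute-force contingency oracle: double loop over reports and events
brute_force_tables <- function(bundle, cohort_ids, level = "PT", map = NULL) {
  pairs <- list()
  for (i in seq_len(nrow(bundle$reac))) {
    pid <- bundle$reac$primaryid[i]
    ev <- trimws(bundle$reac$pt[i])
    if (is.na(ev) || !nzchar(ev)) next
    if (level == "SOC") {
      ev <- soc_for_pt(map, ev)
      if (is.na(ev)) ev <- "UNMAPPED"
    } else {
      ev <- tolower(ev)
    }
    pairs[[length(pairs) + 1L]] <- c(pid, ev)
  }
  mat <- unique(do.call(rbind, pairs))
  in_cohort <- mat[, 1] %in% cohort_ids
  tot_coh <- sum(in_cohort)
  tot_non <- sum(!in_cohort)
  events <- sort(unique(mat[, 2]))
  out <- lapply(events, function(e) {
    a <- sum(in_cohort & mat[, 2] == e)
    c_ <- sum(!in_cohort & mat[, 2] == e)
    data.table::data.table(event = e, a = a, b = tot_coh - a, c = c_,
                           d = tot_non - c_)
  })
  data.table::rbindlist(out)
}
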