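# FAERS-format quarterly ASCII ingestion and the PT -> SOC terminology layer.
#
# FAERS quarterly packages ship one "$"-delimited text file per table
# (DEMO, DRUG, REAC, OUTC, THER), a header line first, no quoting. Dates are
# 8-digit YYYYMMDD integers that may be truncated to YYYYMM or YYYY or absent.

.faers_table_names <- c("demo", "drug", "reac", "outc", "ther")

.faers_required_cols <- list(
  demo = c("primaryid", "caseid"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt")
)

# columns carried in the canonical in-memory form (raw text dialect)
.faers_raw_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "occp_cod", "occr_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt")
)

#' Parse FAERS-style dates
#'
#' A date field is kept raw when it is a 4, 6 or 8 digit string (YYYY,
#' YYYYMM, YYYYMMDD); anything else becomes missing. The parsed `date`
#' component is set only for 8-digit strings that are valid calendar dates.
#'
#' @param x character vector of raw date fields.
#' @return list with `raw` (normalized character), `date` (Date, `NA` unless
#'   a full valid date) and `n_malformed` (count of non-empty values that
#'   were not 4/6/8-digit strings).
#' @export
#' @examples
#' parse_faers_date(c("20200115", "202001", "2020", "2020013"))$raw
parse_faers_date <- function(x) {
  raw <- trimws(as.character(x))
  raw[!is.na(raw) & raw == ""] <- NA_character_
  shape_ok <- !is.na(raw) & grepl("^[0-9]{4}([0-9]{2}){0,2}$", raw)
  n_malformed <- sum(!is.na(raw) & !shape_ok)
  raw[!is.na(raw) & !shape_ok] <- NA_character_
  date <- rep(as.Date(NA), length(raw))
  full <- !is.na(raw) & nchar(raw) == 8L
  if (any(full)) date[full] <- as.Date(raw[full], format = "%Y%m%d")
  list(raw = raw, date = date, n_malformed = n_malformed)
}

#' Convert reported ages to years
#'
#' FAERS ages carry a unit code. Conversion factors: YR x1, DEC x10,
#' MON /12, WK /52.1775, DY /365.25, HR /8766. An age with a missing or
#' unrecognized unit is treated as years, with a warning.
#'
#' @param age numeric vector of reported ages.
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years.
#' @export
age_in_years <- function(age, age_cod) {
  factors <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
               DY = 1 / 365.25, HR = 1 / 8766)
  cod <- toupper(trimws(as.character(age_cod)))
  cod[!is.na(cod) & cod == ""] <- NA_character_
  f <- unname(factors[cod])
  n_assumed <- sum(!is.na(age) & is.na(f))
  if (n_assumed > 0L)
    warning(sprintf("%d age value(s) with missing/unknown unit code treated as years",
                    n_assumed), call. = FALSE)
  f[is.na(f)] <- 1
  as.numeric(age) * f
}

read_faers_table <- function(path, table) {
  table <- match.arg(table, .faers_table_names)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines_present <- length(readLines(path, n = 2L, warn = FALSE))
  empty_canon <- function() {
    dt <- data.table::setDT(stats::setNames(
      rep(list(character()), length(.faers_raw_cols[[table]])),
      .faers_raw_cols[[table]]))
    dt
  }
  if (lines_present == 0L) {
    warning(sprintf("%s: empty file, returning empty %s table", path, toupper(table)),
            call. = FALSE)
    return(empty_canon())
  }
  dt <- data.table::fread(path, sep = "$", header = TRUE, quote = "",
                          colClasses = "character", na.strings = c("", "NA"),
                          showProgress = FALSE)
  data.table::setnames(dt, tolower(names(dt)))
  missing_cols <- setdiff(.faers_required_cols[[table]], names(dt))
  if (length(missing_cols))
    stop(sprintf("%s table '%s' is missing required column(s): %s",
                 toupper(table), path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  for (col in setdiff(.faers_raw_cols[[table]], names(dt)))
    dt[, (col) := NA_character_]
  dt[, .SD, .SDcols = .faers_raw_cols[[table]]]
}

# Attach parsed/typed companions to the raw columns of one table.
canonicalize_table <- function(dt, table, quarter_label = NA_character_) {
  dt <- data.table::copy(dt)
  n_bad_dates <- 0L
  if (table == "demo") {
    fd <- parse_faers_date(dt$fda_dt)
    ed <- parse_faers_date(dt$event_dt)
    n_bad_dates <- fd$n_malformed + ed$n_malformed
    dt[, `:=`(fda_dt = fd$raw, fda_date = fd$date,
              event_dt = ed$raw, event_date = ed$date)]
    dt[, age := suppressWarnings(as.numeric(age))]
    dt[, sex := toupper(trimws(sex))]
    dt[, quarter := quarter_label]
  } else if (table == "ther") {
    sd <- parse_faers_date(dt$start_dt)
    n_bad_dates <- sd$n_malformed
    dt[, `:=`(start_dt = sd$raw, start_date = sd$date)]
  } else if (table == "drug") {
    dt[, role_cod := toupper(trimws(role_cod))]
  }
  if (n_bad_dates > 0L)
    message(sprintf("%s: %d malformed date value(s) set to missing",
                    toupper(table), n_bad_dates))
  dt
}

#' Construct a FAERS quarter bundle
#'
#' Bundles the five FAERS tables plus the deleted-case list into one object.
#' Child-table rows whose `primaryid` does not appear in DEMO are flagged
#' with a warning (they are retained so row accounting stays explicit).
#'
#' @param demo,drug,reac,outc,ther canonical data.tables (see [read_quarter()]).
#' @param deleted_caseids character vector of case identifiers slated for
#'   removal.
#' @return an object of class `faers_bundle`.
#' @export
faers_bundle <- function(demo, drug, reac, outc, ther,
                         deleted_caseids = character()) {
  b <- structure(list(demo = data.table::as.data.table(demo),
                      drug = data.table::as.data.table(drug),
                      reac = data.table::as.data.table(reac),
                      outc = data.table::as.data.table(outc),
                      ther = data.table::as.data.table(ther),
                      deleted_caseids = unique(trimws(as.character(deleted_caseids)))),
                 class = "faers_bundle")
  for (tb in .faers_table_names) {
    need <- .faers_required_cols[[tb]]
    if (!all(need %in% names(b[[tb]])))
      stop(sprintf("%s table lacks required column(s): %s", toupper(tb),
                   paste(setdiff(need, names(b[[tb]])), collapse = ", ")),
           call. = FALSE)
  }
  for (tb in setdiff(.faers_table_names, "demo")) {
    orphans <- sum(!(b[[tb]]$primaryid %in% b$demo$primaryid))
    if (orphans > 0L)
      warning(sprintf("%s: %d row(s) reference a primaryid absent from DEMO",
                      toupper(tb), orphans), call. = FALSE)
  }
  b
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle>\n")
  for (tb in .faers_table_names)
    cat(sprintf("  %-5s %7d rows\n", toupper(tb), nrow(x[[tb]])))
  cat(sprintf("  deleted caseids: %d\n", length(x$deleted_caseids)))
  invisible(x)
}

#' Read one FAERS-style quarter
#'
#' Reads the five "$"-delimited ASCII tables (header line first, no quoting)
#' and, if supplied, the deleted-case list (plain text, one CASEID per line).
#' Unparseable dates become missing rather than failing the row.
#'
#' @param paths named list/vector with elements `demo`, `drug`, `reac`,
#'   `outc`, `ther` and optionally `deleted`.
#' @param quarter_label source quarter label, e.g. `"2019Q1"`.
#' @return a [faers_bundle()].
#' @export
read_quarter <- function(paths, quarter_label = NA_character_) {
  paths <- as.list(paths)
  missing_tables <- setdiff(.faers_table_names, names(paths))
  if (length(missing_tables))
    stop(sprintf("paths must name all five tables; missing: %s",
                 paste(missing_tables, collapse = ", ")), call. = FALSE)
  tabs <- lapply(.faers_table_names, function(tb)
    canonicalize_table(read_faers_table(paths[[tb]], tb), tb, quarter_label))
  names(tabs) <- .faers_table_names
  deleted <- if (!is.null(paths$deleted)) read_deleted_list(paths$deleted)
             else character()
  faers_bundle(tabs$demo, tabs$drug, tabs$reac, tabs$outc, tabs$ther, deleted)
}

#' Read a deleted-case list
#'
#' @param path plain-text file, one CASEID per line.
#' @return character vector of case identifiers.
#' @export
read_deleted_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[x != ""])
}

#' Write a quarter bundle to FAERS-dialect files
#'
#' Emits one "$"-delimited file per table plus `DELETED.txt`;
#' `read_quarter()` on the result reproduces the records field by field.
#'
#' @param bundle a [faers_bundle()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written file paths.
#' @export
write_quarter <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  paths <- character()
  for (tb in .faers_table_names) {
    p <- file.path(out_dir, paste0(toupper(tb), ".txt"))
    out <- bundle[[tb]][, .SD, .SDcols = .faers_raw_cols[[tb]]]
    data.table::fwrite(out, p, sep = "$", quote = FALSE, na = "",
                       col.names = TRUE)
    paths[tb] <- p
  }
  p <- file.path(out_dir, "DELETED.txt")
  writeLines(bundle$deleted_caseids, p)
  paths["deleted"] <- p
  paths
}

#' Load a PT to SOC mapping
#'
#' MedDRA itself is licensed and not bundled; the mapping is supplied as a
#' two- or three-column TSV (PT, SOC name, optional SOC code). Lookup is
#' case-insensitive after trimming. Duplicate PT rows are tolerated when
#' consistent; conflicting duplicates are an error.
#'
#' @param path TSV file path.
#' @return an object of class `meddra_map` (a data.table with columns
#'   `pt_key`, `pt`, `soc_name`, `soc_code`).
#' @export
load_meddra_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = "character", showProgress = FALSE)
  if (ncol(dt) < 2L)
    stop("PT->SOC map must have at least two tab-separated columns", call. = FALSE)
  if (ncol(dt) == 2L) dt[, V3 := NA_character_]
  data.table::setnames(dt, 1:3, c("pt", "soc_name", "soc_code"))
  if (nrow(dt) && tolower(trimws(dt$pt[1])) %in% c("pt", "preferred_term"))
    dt <- dt[-1L]
  meddra_map(dt$pt, dt$soc_name, dt$soc_code)
}

#' Construct a PT to SOC map from vectors
#'
#' @param pt character vector of Preferred Terms.
#' @param soc_name primary System Organ Class per PT.
#' @param soc_code optional SOC code.
#' @return `meddra_map` object.
#' @export
meddra_map <- function(pt, soc_name, soc_code = NA_character_) {
  dt <- data.table::data.table(pt = trimws(as.character(pt)),
                               soc_name = trimws(as.character(soc_name)),
                               soc_code = as.character(soc_code))
  dt[, pt_key := tolower(pt)]
  conflicts <- dt[, data.table::uniqueN(soc_name), by = pt_key][V1 > 1L, pt_key]
  if (length(conflicts))
    stop(sprintf("conflicting SOC assignment for PT(s): %s",
                 paste(unique(dt[pt_key %in% conflicts, pt]), collapse = ", ")),
         call. = FALSE)
  dt <- unique(dt, by = "pt_key")
  data.table::setcolorder(dt, c("pt_key", "pt", "soc_name", "soc_code"))
  data.table::setattr(dt, "class", c("meddra_map", class(dt)))
  dt[]
}

#' Look up the primary SOC for PTs
#'
#' @param map a `meddra_map`.
#' @param pts character vector of PT strings (any casing/padding).
#' @return character vector of SOC names, `NA` where unmapped.
#' @export
soc_for_pt <- function(map, pts) {
  stopifnot(inherits(map, "meddra_map"))
  map$soc_name[match(tolower(trimws(pts)), map$pt_key)]
}

#' Write a PT to SOC map as TSV
#'
#' @param map a `meddra_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meddra_map <- function(map, path) {
  stopifnot(inherits(map, "meddra_map"))
  data.table::fwrite(map[, .(pt, soc_name, soc_code)], path, sep = "\t",
                     quote = FALSE, na = "", col.names = FALSE)
  invisible(path)
}
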