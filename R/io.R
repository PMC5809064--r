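# canonical index-table layout: the per-beam record table distributed as the
# study's supplementary material, columns A-I
INDEX_COLUMNS <- c(patient_id = "A", reference_plan = "B", pathology = "C",
                machine_id = "D", beam = "E", fraction = "F",
                r_value = "G", gamma_percent = "H", gamma_mean = "I")

#' Normalize a treatment-site label
#'
#' Maps free-text pathology labels onto the five canonical sites via a
#' documented synonym table. Unknown labels trigger a warning and map to NA
#' (they pass through record round trips but are excluded from site-grouped
#' summaries).
#'
#' @param x character vector of site/pathology labels.
#' @return character vector with values in
#'   `c("breast", "thorax", "abdomen", "pelvis", "HN")` or `NA`.
#' @export
normalize_site <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  map <- c(hn = "HN", headandneck = "HN", headneck = "HN", nasopharynx = "HN",
           breast = "breast", mammary = "breast",
           thorax = "thorax", lung = "thorax", chest = "thorax",
           abdomen = "abdomen", abdominal = "abdomen",
           pelvis = "pelvis", pelvic = "pelvis", prostate = "pelvis",
           rectum = "pelvis", bladder = "pelvis", cervix = "pelvis")
  out <- unname(map[key])
  unknown <- is.na(out) & !is.na(x)
  if (any(unknown))
    warning("unknown site labels mapped to NA: ",
            paste(unique(x[unknown]), collapse = ", "))
  out
}

#' Infer the treatment technique from the reference-plan label
#'
#' The index table does not carry a documented technique column; the
#' technique is inferred from the reference-plan field by a configurable
#' regular expression (default: plans matching "vmat" or "arc" are VMAT,
#' everything else IMRT).
#'
#' @param reference_plan character vector.
#' @param vmat_regex case-insensitive regex identifying VMAT plans.
#' @export
infer_technique <- function(reference_plan, vmat_regex = "vmat|arc") {
  ifelse(grepl(vmat_regex, reference_plan, ignore.case = TRUE), "VMAT", "IMRT")
}

# --- minimal XLSX sheet reader -------------------------------------------
# An .xlsx file is a zip of XML parts; no installed R package reads the
# format, so the two parts needed for a rectangular value sheet are parsed
# directly: xl/sharedStrings.xml and the first worksheet.

xlsx_col_number <- function(ref) {
  letters_part <- gsub("[0-9]", "", ref)
  ch <- utf8ToInt(letters_part) - utf8ToInt("A") + 1L
  as.integer(sum(ch * 26^(rev(seq_along(ch)) - 1L)))
}

read_xlsx_sheet <- function(path) {
  td <- tempfile("xlsx")
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = td)
  read_xlsx_parts(td)
}

# parse the extracted XML parts of a workbook (sharedStrings + first sheet)
read_xlsx_parts <- function(td) {
  shared <- character(0)
  ss_path <- file.path(td, "xl", "sharedStrings.xml")
  if (file.exists(ss_path)) {
    ss <- xml2::read_xml(ss_path)
    xml2::xml_ns_strip(ss)
    shared <- xml2::xml_text(xml2::xml_find_all(ss, "./si"))
  }
  sheets <- sort(list.files(file.path(td, "xl", "worksheets"),
                            pattern = "^sheet.*\\.xml$", full.names = TRUE))
  if (length(sheets) == 0) stop("no worksheet found in ", path)
  ws <- xml2::read_xml(sheets[1])
  xml2::xml_ns_strip(ws)
  cells <- xml2::xml_find_all(ws, ".//row/c")
  if (length(cells) == 0) return(matrix(character(0), 0, 0))
  refs <- xml2::xml_attr(cells, "r")
  types <- xml2::xml_attr(cells, "t")
  vals <- vapply(cells, function(c) {
    v <- xml2::xml_find_first(c, "./v")
    if (inherits(v, "xml_missing")) {
      is_node <- xml2::xml_find_first(c, "./is")
      if (inherits(is_node, "xml_missing")) NA_character_
      else xml2::xml_text(is_node)
    } else xml2::xml_text(v)
  }, character(1))
  is_shared <- !is.na(types) & types == "s"
  vals[is_shared] <- shared[as.integer(vals[is_shared]) + 1L]
  ri <- as.integer(gsub("[A-Z]", "", refs))
  ci <- vapply(refs, xlsx_col_number, integer(1))
  m <- matrix(NA_character_, max(ri), max(ci))
  m[cbind(ri, ci)] <- vals
  m
}

# --- index table reading --------------------------------------------------

#' Read a per-beam index record table
#'
#' Reads the per-beam record table of IVD indices (one row per beam tested, columns
#' A-I: patient ID, reference plan, pathology, machine ID, beam, fraction
#' label, R, gamma%, gamma_mean) from CSV or XLSX. Rows whose numeric index
#' cells do not parse, or violate the basic invariants (R > 0, gamma% in
#' [0, 100], gamma_mean >= 0), are routed to a rejects table and counted,
#' never silently dropped. Pathology labels are normalized to the canonical
#' sites in the added `site` column.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`.
#' @return list of class `index_table`: `records` (clean typed rows),
#'   `rejects`, `n_read`.
#' @export
read_index_table <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
    have <- names(INDEX_COLUMNS) %in% names(raw)
    if (!all(have))
      stop("missing column ", paste(INDEX_COLUMNS[!have], collapse = ", "),
           " (", paste(names(INDEX_COLUMNS)[!have], collapse = ", "), ")")
    raw <- raw[names(INDEX_COLUMNS)]
  } else {
    m <- read_xlsx_sheet(path)
    if (ncol(m) < 9) {
      missing <- LETTERS[(ncol(m) + 1):9]
      stop("missing column ", paste(missing, collapse = ", "))
    }
    m <- m[, 1:9, drop = FALSE]
    # drop a header row when the numeric columns are not numeric there
    if (nrow(m) > 0 && is.na(suppressWarnings(as.numeric(m[1, 7]))))
      m <- m[-1, , drop = FALSE]
    raw <- as.data.frame(m, stringsAsFactors = FALSE)
    names(raw) <- names(INDEX_COLUMNS)
  }
  n_read <- nrow(raw)
  num <- function(v) suppressWarnings(as.numeric(v))
  r <- num(raw$r_value); gp <- num(raw$gamma_percent); gm <- num(raw$gamma_mean)
  ok <- !is.na(r) & !is.na(gp) & !is.na(gm) &
        r > 0 & gp >= 0 & gp <= 100 & gm >= 0
  records <- raw[ok, , drop = FALSE]
  records$r_value <- r[ok]
  records$gamma_percent <- gp[ok]
  records$gamma_mean <- gm[ok]
  records$site <- normalize_site(records$pathology)
  rownames(records) <- NULL
  rejects <- raw[!ok, , drop = FALSE]
  rownames(rejects) <- NULL
  if (nrow(rejects) > 0)
    message(nrow(rejects), " of ", n_read, " rows rejected (unparseable or out-of-range indices)")
  structure(list(records = records, rejects = rejects, n_read = n_read),
            class = "index_table")
}

#' Write a per-beam index record table as CSV
#'
#' Writes records in the canonical column order (A-I) with a deterministic row order
#' (patient, beam, fraction), so write-read-write round trips are
#' byte-identical.
#'
#' @param records data.frame with the columns of [read_index_table] records
#'   (a `site` column, if present, is dropped on write), or a cohort test
#'   table from [simulate_cohort] (columns are mapped).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if ("beam_id" %in% names(records) && !"beam" %in% names(records)) {
    # cohort test table -> canonical layout
    records <- data.frame(patient_id = records$patient_id,
                          reference_plan = records$reference_plan,
                          pathology = records$site,
                          machine_id = records$machine_id,
                          beam = records$beam_id,
                          fraction = records$fraction,
                          r_value = records$r_value,
                          gamma_percent = records$gamma_percent,
                          gamma_mean = records$gamma_mean,
                          stringsAsFactors = FALSE)
  }
  have <- names(INDEX_COLUMNS) %in% names(records)
  if (!all(have))
    stop("missing column ", paste(INDEX_COLUMNS[!have], collapse = ", "))
  records <- records[names(INDEX_COLUMNS)]
  # the fraction/date column is preserved verbatim as text
  records$fraction <- as.character(records$fraction)
  ord <- order(records$patient_id, records$beam, records$fraction)
  utils::write.csv(records[ord, , drop = FALSE], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Recompute cohort aggregates from an index table
#'
#' Re-derives the study-style aggregate results from a per-beam index table:
#' raw row and patient counts, tolerance flags per test, two-stage per-patient
#' means, and the T%/P% tables per (site, technique) — reported both half-up
#' rounded and truncated, since the display rounding convention of integer
#' percentage tables is not self-evident.
#'
#' @param path path to the index table (CSV or XLSX).
#' @param tol a [tolerance_config].
#' @param vmat_regex regex for [infer_technique].
#' @return list: `n_rows_read`, `n_records`, `n_rejects`, `n_patients`,
#'   `tests` (flagged records), `cohort` (unrounded + half-up display
#'   columns), `cohort_truncated` (display columns truncated instead).
#' @export
recompute_cohort_summary <- function(path, tol = tolerance_config(), vmat_regex = "vmat|arc") {
  tab <- read_index_table(path)
  rec <- tab$records
  if (nrow(rec) == 0) stop("no valid records in ", path)
  rec$technique <- infer_technique(rec$reference_plan, vmat_regex)
  rec$beam_id <- rec$beam
  rec$pass_r <- rec$r_value >= tol$r_low & rec$r_value <= tol$r_high
  rec$pass_gamma_percent <- rec$gamma_percent >= tol$gamma_percent_min
  rec$pass_gamma_mean <- rec$gamma_mean <= tol$gamma_mean_max
  rec$warning <- !(rec$pass_r & rec$pass_gamma_percent & rec$pass_gamma_mean)
  grouped <- rec[!is.na(rec$site), , drop = FALSE]
  summaries <- lapply(split(grouped, grouped$patient_id),
                      summarize_patient, tol = tol)
  cohort <- aggregate_cohort(grouped, summaries)
  cohort_trunc <- cohort
  for (col in grep("_disp$", names(cohort_trunc), value = TRUE))
    cohort_trunc[[col]] <- trunc(cohort_trunc[[sub("_disp$", "", col)]])
  list(n_rows_read = tab$n_read,
       n_records = nrow(rec),
       n_rejects = nrow(tab$rejects),
       n_patients = length(unique(rec$patient_id)),
       tests = rec, cohort = cohort, cohort_truncated = cohort_trunc)
}
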