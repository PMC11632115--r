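#' @name faers_io
#' @title Reading and writing FAERS quarterly ASCII tables
#'
#' @description
#' FAERS quarterly extracts are distributed as five `"$"`-delimited ASCII
#' files per quarter (demographics, drugs, reactions, outcomes, therapy
#' dates), one header line each, no quoting or escaping. [read_faers_quarter()]
#' parses the five files for one quarter into plain character data frames;
#' [write_faers_quarter()] writes them back in the same layout, so that a
#' write/read round trip is the identity on field values.
#'
#' All identifiers are kept as text (leading zeros are significant in FAERS
#' ids) and dates are kept as digit strings (`YYYY`, `YYYYMM` or `YYYYMMDD`)
#' until arithmetic is actually needed.
NULL

# Required columns per table kind. Files may carry extra columns; these are
# preserved as opaque character fields.
faers_required_columns <- list(
  DEMO = c("PRIMARYID", "CASEID", "CASEVERSION", "FDA_DT", "EVENT_DT",
           "AGE", "AGE_COD", "SEX", "OCCP_COD", "REPORTER_COUNTRY"),
  DRUG = c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME", "PROD_AI"),
  REAC = c("PRIMARYID", "PT"),
  OUTC = c("PRIMARYID", "OUTC_COD"),
  THER = c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT")
)

faers_table_kinds <- names(faers_required_columns)

# FAERS file naming: DEMO18Q4.txt for quarter label "2018Q4".
faers_file_name <- function(kind, quarter_label) {
  if (!grepl("^[0-9]{4}Q[1-4]$", quarter_label))
    stopf("quarter_label must look like '2018Q4', got '%s'", quarter_label)
  paste0(kind, substr(quarter_label, 3, 4), substr(quarter_label, 5, 6), ".txt")
}

#' Read one FAERS quarter
#'
#' Parses the five `"$"`-delimited ASCII files (`DEMO`, `DRUG`, `REAC`,
#' `OUTC`, `THER`) of a FAERS quarterly extract. Field values are
#' whitespace-trimmed, column names upper-cased, and every column is kept as
#' character. A line whose trailing `"$"` produces one extra empty field is
#' accepted (the empty field is dropped with a warning); any other
#' header/field-count mismatch is handled per `on_bad_line`.
#'
#' @param directory Directory holding the quarter's files.
#' @param quarter_label Quarter label such as `"2018Q4"`.
#' @param on_bad_line `"warn"` (drop the offending line with a warning) or
#'   `"abort"`.
#' @param quiet Suppress the per-table row-count message.
#' @return Named list of character data frames, one per table kind, each with
#'   attributes `table_kind` and `quarter`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' demo <- data.frame(PRIMARYID = "10011", CASEID = "1001", CASEVERSION = "1",
#'                    FDA_DT = "20190315", EVENT_DT = "20190301", AGE = "64",
#'                    AGE_COD = "YR", SEX = "F", OCCP_COD = "MD",
#'                    REPORTER_COUNTRY = "US")
#' write_faers_quarter(list(DEMO = demo), dir, "2019Q1")
#' read_faers_quarter(dir, "2019Q1", quiet = TRUE)$DEMO$CASEID
#' @seealso [write_faers_quarter()]
#' @export
read_faers_quarter <- function(directory, quarter_label,
                               on_bad_line = c("warn", "abort"),
                               quiet = FALSE) {
  on_bad_line <- match.arg(on_bad_line)
  out <- list()
  for (kind in faers_table_kinds) {
    path <- file.path(directory, faers_file_name(kind, quarter_label))
    if (!file.exists(path))
      stopf("missing FAERS file for table %s: %s", kind, path)
    out[[kind]] <- read_faers_file(path, kind, quarter_label, on_bad_line)
    if (!quiet)
      message(sprintf("%s %s: %d rows", quarter_label, kind, nrow(out[[kind]])))
  }
  out
}

read_faers_file <- function(path, kind, quarter_label, on_bad_line = "warn") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)            # tolerate CRLF
  if (length(lines) == 0L) stopf("%s: empty file (no header line)", path)
  header <- toupper(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  ncol <- length(header)
  missing_cols <- setdiff(faers_required_columns[[kind]], header)
  if (length(missing_cols))
    stopf("%s (%s): missing required column(s) %s",
          path, kind, paste(missing_cols, collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]                # tolerate trailing newline
  fields <- strsplit(body, "$", fixed = TRUE)
  # A line ending in "$" loses its final empty field under strsplit; a line
  # with a spurious trailing "$" before a value gains one. Normalise counts.
  n <- lengths(fields)
  short <- n == ncol - 1L & endsWith(body, "$")
  fields[short] <- lapply(fields[short], function(f) c(f, ""))
  n[short] <- ncol
  extra <- n == ncol + 1L & vapply(fields, function(f) !nzchar(f[length(f)]), logical(1))
  if (any(extra)) {
    fields[extra] <- lapply(fields[extra], function(f) f[-length(f)])
    n[extra] <- ncol
    warnf("%s: dropped a trailing empty field on %d line(s)", path, sum(extra))
  }
  bad <- n != ncol
  if (any(bad)) {
    msg <- sprintf("%s (%s): %d line(s) with field count != %d",
                   path, kind, sum(bad), ncol)
    if (on_bad_line == "abort") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    fields <- fields[!bad]
  }
  mat <- if (length(fields)) {
    matrix(trimws(unlist(fields)), ncol = ncol, byrow = TRUE)
  } else {
    matrix(character(), ncol = ncol)
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  if (any(!nzchar(df$PRIMARYID)))
    warnf("%s (%s): %d row(s) with empty PRIMARYID", path, kind,
          sum(!nzchar(df$PRIMARYID)))
  attr(df, "table_kind") <- kind
  attr(df, "quarter") <- quarter_label
  df
}

#' Write one FAERS quarter
#'
#' Writes record sets in the FAERS `"$"`-delimited ASCII layout. The format
#' has no quoting mechanism, so a field value containing the delimiter is an
#' error. `read_faers_quarter(write_faers_quarter(x))` reproduces `x`
#' field-for-field.
#'
#' @param records Named list of data frames keyed by table kind (any subset
#'   of `DEMO`, `DRUG`, `REAC`, `OUTC`, `THER`).
#' @param directory Output directory (created if needed).
#' @param quarter_label Quarter label such as `"2018Q4"`.
#' @return Invisibly, the paths written.
#' @export
write_faers_quarter <- function(records, directory, quarter_label) {
  if (!dir.exists(directory) && !dir.create(directory, recursive = TRUE))
    stopf("cannot create directory %s", directory)
  bad_kind <- setdiff(names(records), faers_table_kinds)
  if (length(bad_kind))
    stopf("unknown table kind(s): %s", paste(bad_kind, collapse = ", "))
  paths <- character(0)
  for (kind in names(records)) {
    df <- records[[kind]]
    path <- file.path(directory, faers_file_name(kind, quarter_label))
    cells <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) > 0 && any(grepl("$", cells, fixed = TRUE)))
      stopf("%s: field values may not contain the '$' delimiter", kind)
    lines <- c(paste(toupper(names(df)), collapse = "$"),
               if (nrow(df) > 0)
                 apply(matrix(cells, nrow = nrow(df)), 1L, paste, collapse = "$"))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a formatted signal table
#'
#' Writes disproportionality results as a comma-delimited table shaped like a
#' published signal table: one row per term with the report count and the
#' four statistics, estimates rounded to 2 decimal places and confidence
#' bounds rendered as `"est (low, high)"`.
#'
#' @param results A `pvsignal` fit or the data frame from
#'   [as.data.frame.pvsignal()].
#' @param path Output file path.
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_signal_table <- function(results, path) {
  df <- as.data.frame(results)
  fmt <- data.frame(
    term = df$term,
    n = df$a,
    ror_ci = fmt_est_ci(df$ror, df$ror_lo, df$ror_hi),
    prr_ci = fmt_est_ci(df$prr, df$prr_lo, df$prr_hi),
    chi_squared = fmt_num2(df$chi2),
    ic_ic025 = sprintf("%s (%s)", fmt_num2(df$ic), fmt_num2(df$ic025)),
    ebgm_ebgm05 = sprintf("%s (%s)", fmt_num2(df$ebgm), fmt_num2(df$ebgm05)),
    significant_any = df$significant_any,
    significant_all = df$significant_all,
    stringsAsFactors = FALSE
  )
  names(fmt) <- c("term", "n", "ROR (95% CI)", "PRR (95% CI)", "Chi-squared",
                  "IC (IC025)", "EBGM (EBGM05)", "significant_any",
                  "significant_all")
  utils::write.csv(fmt, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(fmt)
}
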