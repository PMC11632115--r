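#' @name cohort_summary
#' @title Descriptive summary of the reporting cohort
#'
#' @description
#' The classic first table of a pharmacovigilance study: counts and
#' percentages of the deduplicated, drug-selected reports by receipt year,
#' reporter occupation, reporting country and seriousness outcome. Year,
#' reporter and country sections use all reports as denominator; the outcome
#' section counts one outcome per report — the most severe, in the priority
#' order death > life-threatening > hospitalization > disability >
#' congenital anomaly > required intervention > other — over the reports
#' that carry any outcome at all, since a report need not be
#' outcome-classified.
NULL

outcome_priority <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

outcome_labels <- c(DE = "Death", LT = "Life threatening",
                    HO = "Hospitalization", DS = "Disability",
                    CA = "Congenital anomaly", RI = "Required intervention",
                    OT = "Other serious")

occupation_labels <- c(PH = "Pharmacist", MD = "Physician",
                       OT = "Other health-professional", CN = "Consumer",
                       LW = "Lawyer")

most_severe_outcome <- function(outcomes) {
  codes <- strsplit(outcomes, ",", fixed = TRUE)
  vapply(codes, function(x) {
    x <- intersect(outcome_priority, x)
    if (length(x)) x[1] else NA_character_
  }, character(1))
}

section_rows <- function(level, count, denominator) {
  data.frame(level = level, count = as.integer(count),
             percent = round_half_up(100 * count / denominator, 2),
             stringsAsFactors = FALSE)
}

#' Summarize the reporting cohort
#'
#' @param reports Deduplicated, drug-selected reports from
#'   [collect_reports()] / [deduplicate_reports()].
#' @param top_k_countries Number of countries listed individually before the
#'   remainder is pooled into `"Other"`.
#' @return Object of class `cohort_summary`: a list of section data frames
#'   (`year`, `reporter`, `country`, `outcome`), each with columns `level`,
#'   `count`, `percent`, plus `n_reports` and `n_outcome_reports`.
#' @export
summarize_cohort <- function(reports, top_k_countries = 3) {
  n <- nrow(reports)
  if (n == 0L) stopf("no reports to summarize")

  yr <- table(reports$receipt_year, useNA = "no")
  year <- section_rows(names(yr), as.integer(yr), n)

  occ <- reports$occp_cod
  occ_lab <- unname(occupation_labels[occ])
  occ_lab[is.na(occ_lab) | is.na(occ)] <- "Unknown"
  rt <- sort(table(occ_lab), decreasing = TRUE)
  reporter <- section_rows(names(rt), as.integer(rt), n)

  country <- top_countries(reports, k = top_k_countries)

  sev <- most_severe_outcome(reports$outcomes)
  sev <- sev[!is.na(sev)]
  n_out <- length(sev)
  if (n_out > 0) {
    ot <- table(factor(sev, levels = outcome_priority))
    ot <- ot[ot > 0]
    ot <- sort(ot, decreasing = TRUE)
    outcome <- section_rows(unname(outcome_labels[names(ot)]),
                            as.integer(ot), n_out)
  } else {
    outcome <- section_rows(character(), integer(), 1)
  }

  structure(list(year = year, reporter = reporter, country = country,
                 outcome = outcome, n_reports = n,
                 n_outcome_reports = n_out),
            class = "cohort_summary")
}

#' Top reporting countries with pooled remainder
#'
#' Ranks countries by report count; the top `k` are listed individually and
#' everything else (including reports with a missing country) is pooled into
#' an `"Other"` row, so the rows always sum to the report total. When `k`
#' covers every country and nothing is missing, no `"Other"` row is emitted.
#'
#' @param reports Report table with a `reporter_country` column.
#' @param k Number of individually listed countries.
#' @return Data frame `level`, `count`, `percent` (percent of all reports).
#' @export
top_countries <- function(reports, k = 3) {
  n <- nrow(reports)
  cn <- reports$reporter_country
  cn[is.na(cn) | !nzchar(cn)] <- NA_character_
  tab <- sort(table(cn, useNA = "no"), decreasing = TRUE)
  top <- utils::head(tab, k)
  other <- n - sum(top)
  rows <- section_rows(names(top), as.integer(top), n)
  if (other > 0)
    rows <- rbind(rows, section_rows("Other", other, n))
  rows
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Reporting cohort: %d reports (%d outcome-classified)\n",
              x$n_reports, x$n_outcome_reports))
  for (sec in c("year", "reporter", "country", "outcome")) {
    cat(sprintf("\n%s\n", switch(sec, year = "Year", reporter = "Reporter",
                                 country = "Reported countries",
                                 outcome = "Outcomes")))
    df <- x[[sec]]
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-28s %6d (%.2f%%)\n", df$level[i], df$count[i],
                  df$percent[i]))
  }
  invisible(x)
}

#' Write a cohort summary as a sectioned CSV
#'
#' @param x A `cohort_summary`.
#' @param path Output path.
#' @return Invisibly, the flat data frame written.
#' @export
write_cohort_summary <- function(x, path) {
  secs <- c(year = "Year", reporter = "Reporter",
            country = "Reported countries", outcome = "Outcomes")
  flat <- do.call(rbind, lapply(names(secs), function(s)
    cbind(variable = secs[[s]], x[[s]])))
  utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(flat)
}
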