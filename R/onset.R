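#' @name onset_time
#' @title Time-to-onset analysis
#'
#' @description
#' Time to onset (TTO) is the number of calendar days from the start of
#' therapy with the suspect drug to the onset of the adverse event. Only
#' reports with full 8-digit therapy-start and event dates and a
#' non-negative interval are usable; exclusions are counted by reason so the
#' attrition is auditable.
NULL

#' Compute onset intervals for the target drug
#'
#' For every selected report, takes the earliest full therapy start date
#' among the target drug's therapy rows and the report's event date, and
#' computes the interval in days. Records are excluded (and counted by
#' reason) when the start or event date is missing or partial, a full date
#' is not a real calendar date, or the interval is negative.
#'
#' @param reports Deduplicated, drug-selected reports (need `primaryid`,
#'   `event_date`).
#' @param drug_rows DRUG table with `std_name`, restricted or not; only rows
#'   matching `target_drug` are used.
#' @param ther THER table (`PRIMARYID`, `DSG_DRUG_SEQ`, `START_DT`).
#' @param target_drug Canonical target drug name.
#' @return Data frame `primaryid`, `therapy_start`, `event_date`, `days`
#'   with attribute `exclusions` (named integer vector of counts by reason).
#' @examples
#' # start 2019-01-01, event 2019-01-22 -> 21 days
#' @export
compute_onsets <- function(reports, drug_rows, ther, target_drug) {
  dr <- drug_rows[!is.na(drug_rows$std_name) &
                    drug_rows$std_name == target_drug, , drop = FALSE]
  key_drug <- paste(dr$PRIMARYID, dr$DRUG_SEQ)
  key_ther <- paste(ther$PRIMARYID, ther$DSG_DRUG_SEQ)
  ther_t <- ther[key_ther %in% key_drug &
                   ther$PRIMARYID %in% reports$primaryid, , drop = FALSE]

  reasons <- c("missing start date", "partial start date",
               "invalid start date", "missing event date",
               "partial event date", "invalid event date",
               "negative interval")
  excl <- stats::setNames(integer(length(reasons)), reasons)
  out <- vector("list", nrow(reports))
  for (i in seq_len(nrow(reports))) {
    pid <- reports$primaryid[i]
    starts <- ther_t$START_DT[ther_t$PRIMARYID == pid]
    starts <- starts[!is.na(starts) & nzchar(starts)]
    if (length(starts) == 0L) { excl["missing start date"] <- excl["missing start date"] + 1L; next }
    full <- starts[is_full_date(starts)]
    if (length(full) == 0L) { excl["partial start date"] <- excl["partial start date"] + 1L; next }
    start_d <- suppressWarnings(parse_full_date(full))
    start_d <- start_d[!is.na(start_d)]
    if (length(start_d) == 0L) { excl["invalid start date"] <- excl["invalid start date"] + 1L; next }
    start <- min(start_d)                       # earliest therapy episode
    ev <- reports$event_date[i]
    if (is.na(ev) || !nzchar(ev)) { excl["missing event date"] <- excl["missing event date"] + 1L; next }
    if (!is_full_date(ev)) { excl["partial event date"] <- excl["partial event date"] + 1L; next }
    ev_d <- suppressWarnings(parse_full_date(ev))
    if (is.na(ev_d)) { excl["invalid event date"] <- excl["invalid event date"] + 1L; next }
    days <- as.integer(ev_d - start)
    if (days < 0) { excl["negative interval"] <- excl["negative interval"] + 1L; next }
    out[[i]] <- data.frame(primaryid = pid,
                           therapy_start = format(start, "%Y%m%d"),
                           event_date = ev, days = days,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(primaryid = character(), therapy_start = character(),
                      event_date = character(), days = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "exclusions") <- excl
  res
}

#' Median and interquartile range of onset times
#'
#' Quartiles use the inclusive linear-interpolation convention
#' (`quantile(type = 6)`) by default; the convention is configurable since
#' published IQRs rarely state one.
#'
#' @param days Integer vector of onset days, or the data frame from
#'   [compute_onsets()].
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Named list `n`, `median`, `q1`, `q3`.
#' @export
onset_summary <- function(days, type = 6) {
  if (is.data.frame(days)) days <- days$days
  if (length(days) == 0L) stopf("no onset records")
  q <- unname(stats::quantile(days, c(0.25, 0.5, 0.75), type = type))
  list(n = length(days), median = q[2], q1 = q[1], q3 = q[3])
}

#' Distribution of onset times over intervals
#'
#' Bins onset days into intervals right-inclusive at each listed edge — with
#' the default edges `c(7, 30, 60)`: at most a week, days 8-30, days 31-60,
#' and beyond 60 days — and reports counts and percentage shares that sum to
#' 100% before rounding.
#'
#' @param days Integer vector of onset days, or a [compute_onsets()] frame.
#' @param edges Increasing positive bin edges, in days.
#' @return Data frame `bin`, `n`, `share_pct`.
#' @export
interval_distribution <- function(days, edges = c(7, 30, 60)) {
  if (is.data.frame(days)) days <- days$days
  if (length(days) == 0L) stopf("no onset records")
  stopifnot(all(diff(edges) > 0), all(edges > 0))
  breaks <- c(-Inf, edges, Inf)
  labels <- c(paste0("<=", edges[1]),
              if (length(edges) > 1)
                paste0(edges[-length(edges)] + 1, "-", edges[-1]),
              paste0(">", edges[length(edges)]))
  bins <- cut(days, breaks = breaks, labels = labels, right = TRUE)
  counts <- as.integer(table(bins))
  data.frame(bin = labels, n = counts,
             share_pct = 100 * counts / length(days),
             stringsAsFactors = FALSE)
}
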