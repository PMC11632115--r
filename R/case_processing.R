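#' @name case_processing
#' @title Case deduplication, suspect-drug selection and MedDRA mapping
#'
#' @description
#' Spontaneous reports arrive in versions: the same case (identified by its
#' case id) can appear in several quarters with increasing case versions and
#' receipt dates. Analysis keeps one report per case — the most recent one —
#' then restricts to reports naming the drug of interest as primary suspect,
#' standardizes free-text drug names against a synonym table, drops preferred
#' terms reported fewer than a minimum number of times for the target drug,
#' and maps each preferred term (PT) to its primary system organ class (SOC).
NULL

#' Assemble safety reports from DEMO and OUTC tables
#'
#' Builds one candidate report row per DEMO row, attaching the set of
#' seriousness outcome codes reported for that case version. Multiple
#' quarters are combined by concatenating their DEMO/OUTC tables first.
#'
#' @param demo DEMO table (or several rbind-ed quarters).
#' @param outc OUTC table, or `NULL` when outcomes were not extracted.
#' @return Data frame with one row per DEMO row: `primaryid`, `caseid`,
#'   `caseversion` (integer), `fda_date`, `event_date`, `age`, `age_cod`,
#'   `sex`, `occp_cod`, `reporter_country`, `receipt_year` (integer) and
#'   `outcomes` (comma-joined outcome codes, `""` when none).
#' @export
collect_reports <- function(demo, outc = NULL) {
  cv <- suppressWarnings(as.integer(demo$CASEVERSION))
  if (any(is.na(cv) & nzchar(demo$CASEVERSION)))
    warnf("%d CASEVERSION value(s) did not parse as integers",
          sum(is.na(cv) & nzchar(demo$CASEVERSION)))
  outcomes <- rep("", nrow(demo))
  if (!is.null(outc) && nrow(outc)) {
    split_codes <- split(outc$OUTC_COD, outc$PRIMARYID)
    joined <- vapply(split_codes, function(x)
      paste(sort(unique(x[nzchar(x)])), collapse = ","), character(1))
    outcomes <- unname(joined[match(demo$PRIMARYID, names(joined))])
    outcomes[is.na(outcomes)] <- ""
  }
  data.frame(
    primaryid = demo$PRIMARYID,
    caseid = demo$CASEID,
    caseversion = cv,
    fda_date = demo$FDA_DT,
    event_date = demo$EVENT_DT,
    age = demo$AGE,
    age_cod = demo$AGE_COD,
    sex = demo$SEX,
    occp_cod = demo$OCCP_COD,
    reporter_country = demo$REPORTER_COUNTRY,
    receipt_year = suppressWarnings(as.integer(substr(demo$FDA_DT, 1, 4))),
    outcomes = outcomes,
    stringsAsFactors = FALSE
  )
}

#' Deduplicate case reports
#'
#' Retains, for each case id, the single most recent candidate: the maximum
#' under the lexicographic key (receipt date, case version, primary id).
#' Candidates with a missing case id cannot be linked across versions and are
#' kept keyed by their primary id, with a warning. The output is sorted by
#' case id, so the result is deterministic and independent of input order.
#'
#' @param reports Candidate reports from [collect_reports()].
#' @return The surviving reports, one row per case id.
#' @examples
#' r <- data.frame(primaryid = c("7771", "7772"), caseid = c("777", "777"),
#'                 caseversion = 1:2, fda_date = c("20190101", "20190601"))
#' deduplicate_reports(r)$primaryid   # "7772": version 2 survives
#' @export
deduplicate_reports <- function(reports) {
  if (nrow(reports) == 0L) return(reports)
  key_case <- reports$caseid
  missing_case <- is.na(key_case) | !nzchar(key_case)
  if (any(missing_case)) {
    warnf("%d candidate(s) without caseid kept keyed by primaryid",
          sum(missing_case))
    key_case[missing_case] <- paste0("PRIMARYID:", reports$primaryid[missing_case])
  }
  cv <- reports$caseversion
  cv[is.na(cv)] <- 0L
  fd <- reports$fda_date
  fd[is.na(fd)] <- ""
  ord <- order(key_case, fd, cv, reports$primaryid, method = "radix")
  sorted <- reports[ord, , drop = FALSE]
  keep <- !duplicated(key_case[ord], fromLast = TRUE)   # last = max key
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a free-text drug name
#'
#' Case-folds, replaces punctuation by spaces, collapses whitespace, and
#' drops a trailing suffix token when it appears in `strip_suffixes` (FAERS
#' free text frequently carries the four-letter biologic suffix, e.g.
#' `"-kpkc"`).
#'
#' @param name Character vector of drug names.
#' @param strip_suffixes Lower-case suffix tokens to drop when trailing.
#' @return Normalized names.
#' @export
normalize_drug_name <- function(name, strip_suffixes = c("kpkc")) {
  x <- tolower(name)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(gsub(" +", " ", x))
  if (length(strip_suffixes)) {
    pat <- paste0(" (", paste(strip_suffixes, collapse = "|"), ")$")
    x <- sub(pat, "", x)
  }
  x
}

#' Standardize drug names against a synonym table
#'
#' Exact lookup of the normalized name in a synonym table mapping brand,
#' generic and misspelled variants to one canonical ingredient. Unmatched
#' names yield `NA` (no-match); they are not guessed.
#'
#' @param name Character vector of raw drug names.
#' @param synonym_table Data frame with columns `variant` and `ingredient`.
#' @param strip_suffixes Passed to [normalize_drug_name()].
#' @return Character vector of canonical ingredient names, `NA` for no-match.
#' @examples
#' syn <- data.frame(variant = c("POTELIGEO", "mogamulizumab"),
#'                   ingredient = "mogamulizumab")
#' standardize_drug(c("Poteligeo", "Mogamulizumab-kpkc", "aspirin"), syn)
#' @export
standardize_drug <- function(name, synonym_table, strip_suffixes = c("kpkc")) {
  stopifnot(all(c("variant", "ingredient") %in% names(synonym_table)))
  key <- normalize_drug_name(synonym_table$variant, strip_suffixes)
  val <- as.character(synonym_table$ingredient)
  out <- val[match(normalize_drug_name(name, strip_suffixes), key)]
  out
}

#' Select reports naming the target drug as suspect
#'
#' A report is selected when at least one of its drug rows has a suspect role
#' (primary suspect only under the default policy) and a standardized name
#' equal to the target drug. A report qualifies at most once however many
#' qualifying rows it has.
#'
#' @param reports Deduplicated reports.
#' @param drug_rows DRUG table rows carrying a standardized-name column
#'   `std_name` (see [standardize_drug()]).
#' @param target_drug Canonical ingredient name.
#' @param role_policy `"PS_only"` (default) or `"PS_and_SS"`.
#' @return The selected subset of `reports`.
#' @export
select_suspect_reports <- function(reports, drug_rows, target_drug,
                                   role_policy = c("PS_only", "PS_and_SS")) {
  role_policy <- match.arg(role_policy)
  roles <- if (role_policy == "PS_only") "PS" else c("PS", "SS")
  stopifnot("std_name" %in% names(drug_rows))
  hit <- drug_rows$ROLE_COD %in% roles &
    !is.na(drug_rows$std_name) & drug_rows$std_name == target_drug
  ids <- unique(drug_rows$PRIMARYID[hit])
  out <- reports[reports$primaryid %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Suspect drug per report
#'
#' Returns one standardized suspect drug per report: the primary-suspect row
#' with the lowest drug sequence number. Reports without a usable PS row (or
#' whose PS drug failed standardization) are dropped.
#'
#' @param drug_rows DRUG table with `std_name` column.
#' @return Data frame `primaryid`, `drug`.
#' @export
suspect_drug_per_report <- function(drug_rows) {
  ps <- drug_rows[drug_rows$ROLE_COD == "PS" & !is.na(drug_rows$std_name), ,
                  drop = FALSE]
  if (nrow(ps) == 0L)
    return(data.frame(primaryid = character(), drug = character(),
                      stringsAsFactors = FALSE))
  seq_no <- suppressWarnings(as.integer(ps$DRUG_SEQ))
  seq_no[is.na(seq_no)] <- .Machine$integer.max
  ord <- order(ps$PRIMARYID, seq_no, method = "radix")
  ps <- ps[ord, , drop = FALSE]
  first <- !duplicated(ps$PRIMARYID)
  data.frame(primaryid = ps$PRIMARYID[first], drug = ps$std_name[first],
             stringsAsFactors = FALSE)
}

#' Build drug-event pairs
#'
#' Forms the analysis unit of disproportionality counting: one row per
#' distinct (report, suspect drug, preferred term). A report listing the same
#' PT twice contributes once.
#'
#' @param reac REAC table (columns `PRIMARYID`, `PT`).
#' @param suspect Data frame `primaryid`, `drug` from
#'   [suspect_drug_per_report()]; reactions from reports with no suspect
#'   assignment are dropped.
#' @return Data frame `primaryid`, `drug`, `pt`.
#' @export
drug_event_pairs <- function(reac, suspect) {
  pt <- trimws(reac$PT)
  keep <- nzchar(pt)
  drug <- suspect$drug[match(reac$PRIMARYID, suspect$primaryid)]
  keep <- keep & !is.na(drug)
  pairs <- data.frame(primaryid = reac$PRIMARYID[keep], drug = drug[keep],
                      pt = pt[keep], stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  pairs
}

#' Exclude rarely reported preferred terms for the target drug
#'
#' Removes the target drug's PTs reported in fewer than `min_count` distinct
#' reports. Background (non-target) pairs are not filtered. The dropped PTs
#' and their counts are attached as attribute `"removed"`.
#'
#' @param pairs Pair table from [drug_event_pairs()].
#' @param target_drug Canonical target drug name.
#' @param min_count Minimum number of distinct reports per PT (default 3).
#' @return Filtered pair table.
#' @export
apply_min_count_filter <- function(pairs, target_drug, min_count = 3) {
  if (min_count < 1) stopf("min_count must be >= 1, got %s", min_count)
  is_target <- pairs$drug == target_drug
  counts <- table(pairs$pt[is_target])
  drop_pts <- names(counts)[counts < min_count]
  drop <- is_target & pairs$pt %in% drop_pts
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  removed <- data.frame(pt = drop_pts,
                        n_reports = as.integer(counts[drop_pts]),
                        stringsAsFactors = FALSE)
  attr(out, "removed") <- removed[order(removed$pt), , drop = FALSE]
  out
}

#' Map preferred terms to system organ classes
#'
#' Annotates each pair with its PT's primary SOC. Pairs whose PT is absent
#' from the map are dropped or kept flagged (`soc = NA`) per policy; the
#' number of unmapped pairs is attached as attribute `"n_unmapped"`.
#'
#' @param pairs Pair table.
#' @param pt_soc_map Data frame with columns `pt` and `soc`; each PT must map
#'   to exactly one SOC.
#' @param unmapped_policy `"keep_flagged"` (default) or `"drop"`.
#' @return Pair table with an added `soc` column.
#' @export
map_to_soc <- function(pairs, pt_soc_map,
                       unmapped_policy = c("keep_flagged", "drop")) {
  unmapped_policy <- match.arg(unmapped_policy)
  stopifnot(all(c("pt", "soc") %in% names(pt_soc_map)))
  if (nrow(pt_soc_map) == 0L) stopf("empty PT to SOC map")
  if (anyDuplicated(pt_soc_map$pt))
    stopf("PT to SOC map assigns some PT more than one SOC")
  pairs$soc <- as.character(pt_soc_map$soc[match(pairs$pt, pt_soc_map$pt)])
  n_unmapped <- sum(is.na(pairs$soc))
  if (unmapped_policy == "drop") {
    pairs <- pairs[!is.na(pairs$soc), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  attr(pairs, "n_unmapped") <- n_unmapped
  pairs
}
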