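#' @name pipeline
#' @title End-to-end signal detection pipeline
#'
#' @description
#' Orchestrates the full analysis in the standard order — ingest quarters,
#' deduplicate cases, select primary-suspect reports, filter rare preferred
#' terms, map to system organ classes, fit the four disproportionality
#' algorithms at PT and SOC level, rank signals, summarize the cohort and
#' analyze time to onset — recording stage-by-stage record counts in a run
#' manifest, because the attrition trail is the only way to audit a
#' spontaneous-reporting analysis.
NULL

#' Pipeline configuration
#'
#' @param input_dir Directory of FAERS quarterly ASCII files, or `NULL` when
#'   `tables` is given.
#' @param quarters Character vector of quarter labels (e.g.
#'   `c("2018Q4", "2019Q1")`).
#' @param tables In-memory named list of FAERS tables (as produced by
#'   [simulate_faers()]), bypassing file ingestion.
#' @param target_drug Canonical target drug name.
#' @param synonyms Synonym table (data frame `variant`, `ingredient`) or path
#'   to a two-column delimited file.
#' @param pt_soc_map PT-to-SOC map (data frame `pt`, `soc`) or path.
#' @param exclusions Terms excluded from ranking (e.g. disease-progression
#'   terms), as a character vector or path to a one-column file.
#' @param role_policy,min_pt_count,unmapped_policy Processing options; see
#'   [select_suspect_reports()], [apply_min_count_filter()], [map_to_soc()].
#' @param yates,z,thresholds,prior_init Statistical options; see
#'   [disproportionality()].
#' @param sort_key,top_k Ranking options; see [rank_signals()].
#' @param onset_bins Interval edges for [interval_distribution()].
#' @param output_dir Directory for output files, or `NULL` to only return
#'   results.
#' @return Object of class `pv_run_config`.
#' @export
pipeline_config <- function(input_dir = NULL, quarters = NULL, tables = NULL,
                            target_drug, synonyms, pt_soc_map,
                            exclusions = character(),
                            role_policy = "PS_only", min_pt_count = 3,
                            unmapped_policy = "keep_flagged",
                            yates = TRUE, z = 1.96,
                            thresholds = signal_thresholds(),
                            prior_init = mgps_prior(),
                            sort_key = "ror", top_k = 40,
                            onset_bins = c(7, 30, 60),
                            output_dir = NULL) {
  if (is.null(tables)) {
    if (is.null(input_dir) || is.null(quarters))
      stopf("either in-memory tables or input_dir + quarters must be given")
    if (!dir.exists(input_dir)) stopf("input_dir does not exist: %s", input_dir)
    if (any(!grepl("^[0-9]{4}Q[1-4]$", quarters)))
      stopf("malformed quarter label(s)")
  }
  if (is.character(synonyms) && length(synonyms) == 1L) {
    if (!file.exists(synonyms)) stopf("synonym file not found: %s", synonyms)
    synonyms <- utils::read.csv(synonyms, colClasses = "character")
  }
  if (is.character(pt_soc_map) && length(pt_soc_map) == 1L) {
    if (!file.exists(pt_soc_map)) stopf("PT-SOC file not found: %s", pt_soc_map)
    pt_soc_map <- utils::read.csv(pt_soc_map, colClasses = "character")
  }
  if (length(exclusions) == 1L && file.exists(exclusions))
    exclusions <- readLines(exclusions, warn = FALSE)
  structure(list(input_dir = input_dir, quarters = quarters, tables = tables,
                 target_drug = target_drug, synonyms = synonyms,
                 pt_soc_map = pt_soc_map, exclusions = exclusions,
                 role_policy = role_policy, min_pt_count = min_pt_count,
                 unmapped_policy = unmapped_policy, yates = yates, z = z,
                 thresholds = thresholds, prior_init = prior_init,
                 sort_key = sort_key, top_k = top_k, onset_bins = onset_bins,
                 output_dir = output_dir),
            class = "pv_run_config")
}

#' Run the end-to-end pipeline
#'
#' Executes all stages on the configured inputs. Any stage error aborts with
#' the failing stage named; the manifest accumulated up to that point is
#' attached to the condition as the `"manifest"` attribute.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pv_run`: list with `signal_pt`, `signal_soc`
#'   (`pvsignal` fits), `ranked_pt`, `cohort`, `onsets`, `onset_summary`,
#'   `onset_distribution`, `manifest`, and `output_files` when written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pv_run_config"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pvsignal")),
    target_drug = config$target_drug,
    options = list(role_policy = config$role_policy,
                   min_pt_count = config$min_pt_count,
                   unmapped_policy = config$unmapped_policy,
                   yates = config$yates, z = config$z,
                   thresholds = config$thresholds,
                   sort_key = config$sort_key, top_k = config$top_k,
                   onset_bins = config$onset_bins),
    stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s': %s", name,
                                  conditionMessage(e)))
      attr(cond, "manifest") <- manifest
      stop(cond)
    })
  }

  tables <- stage("faers_io", {
    if (!is.null(config$tables)) {
      config$tables
    } else {
      files <- unlist(lapply(config$quarters, function(q)
        file.path(config$input_dir,
                  vapply(faers_table_kinds, faers_file_name, character(1),
                         quarter_label = q))))
      manifest$input_checksums <- as.list(tools::md5sum(files[file.exists(files)]))
      per_q <- lapply(config$quarters, function(q)
        read_faers_quarter(config$input_dir, q, quiet = TRUE))
      stats::setNames(lapply(faers_table_kinds, function(kind)
        do.call(rbind, lapply(per_q, `[[`, kind))), faers_table_kinds)
    }
  })
  manifest$stages$ingest <- lapply(tables, nrow)

  reports <- stage("case_processing", {
    cand <- collect_reports(tables$DEMO, tables$OUTC)
    manifest$stages$candidates <- nrow(cand)
    deduplicate_reports(cand)
  })
  manifest$stages$deduplicated <- nrow(reports)

  drug_rows <- stage("case_processing", {
    dr <- tables$DRUG[tables$DRUG$PRIMARYID %in% reports$primaryid, ,
                      drop = FALSE]
    dr$std_name <- standardize_drug(dr$DRUGNAME, config$synonyms)
    dr
  })
  manifest$stages$drug_rows_standardized <- sum(!is.na(drug_rows$std_name))

  selected <- stage("case_processing",
                    select_suspect_reports(reports, drug_rows,
                                           config$target_drug,
                                           config$role_policy))
  manifest$stages$suspect_reports <- nrow(selected)

  pairs <- stage("case_processing", {
    suspect <- suspect_drug_per_report(drug_rows)
    reac <- tables$REAC[tables$REAC$PRIMARYID %in% reports$primaryid, ,
                        drop = FALSE]
    drug_event_pairs(reac, suspect)
  })
  manifest$stages$pairs_total <- nrow(pairs)
  manifest$stages$pairs_target <-
    sum(pairs$drug == config$target_drug)

  pairs <- stage("case_processing", {
    p <- apply_min_count_filter(pairs, config$target_drug,
                                config$min_pt_count)
    manifest$stages$pts_removed_by_min_count <- nrow(attr(p, "removed"))
    p <- map_to_soc(p, config$pt_soc_map, config$unmapped_policy)
    manifest$stages$pairs_unmapped_soc <- attr(p, "n_unmapped")
    p
  })
  manifest$stages$pairs_after_filter <-
    sum(pairs$drug == config$target_drug)

  signal_pt <- stage("disproportionality",
                     disproportionality(pairs, config$target_drug, "PT",
                                        yates = config$yates, z = config$z,
                                        thresholds = config$thresholds,
                                        prior_init = config$prior_init))
  signal_soc <- stage("disproportionality",
                      disproportionality(pairs, config$target_drug, "SOC",
                                         yates = config$yates, z = config$z,
                                         thresholds = config$thresholds,
                                         prior_init = config$prior_init))
  manifest$stages$pt_terms <- nrow(signal_pt$stats)
  manifest$stages$soc_terms <- nrow(signal_soc$stats)
  manifest$stages$pt_significant_any <- sum(signal_pt$stats$significant_any)
  manifest$stages$pt_significant_all <- sum(signal_pt$stats$significant_all)

  ranked_pt <- stage("signal_classification",
                     rank_signals(signal_pt, config$sort_key, config$top_k,
                                  config$exclusions))

  cohort <- stage("cohort_summary", summarize_cohort(selected))

  onsets <- stage("onset_time",
                  compute_onsets(selected, drug_rows, tables$THER,
                                 config$target_drug))
  manifest$stages$onset_usable <- nrow(onsets)
  manifest$stages$onset_exclusions <- as.list(attr(onsets, "exclusions"))
  onset_sum <- if (nrow(onsets) > 0) onset_summary(onsets) else NULL
  onset_dist <- if (nrow(onsets) > 0)
    interval_distribution(onsets, config$onset_bins) else NULL

  out <- list(signal_pt = signal_pt, signal_soc = signal_soc,
              ranked_pt = ranked_pt, cohort = cohort, onsets = onsets,
              onset_summary = onset_sum, onset_distribution = onset_dist,
              manifest = manifest)
  class(out) <- "pv_run"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(x) file.path(config$output_dir, x)
    write_signal_table(signal_pt, f("signals_pt.csv"))
    write_signal_table(signal_soc, f("signals_soc.csv"))
    write_signal_table(ranked_pt, f("signals_pt_ranked.csv"))
    write_cohort_summary(cohort, f("cohort_summary.csv"))
    if (!is.null(onset_dist)) {
      utils::write.csv(cbind(data.frame(n = onset_sum$n,
                                        median = onset_sum$median,
                                        q1 = onset_sum$q1, q3 = onset_sum$q3)),
                       f("onset_summary.csv"), row.names = FALSE)
      utils::write.csv(onset_dist, f("onset_distribution.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$output_files <- list.files(config$output_dir, full.names = TRUE)
  }
  out
}

#' @export
print.pv_run <- function(x, ...) {
  cat("Signal detection run\n")
  s <- x$manifest$stages
  cat(sprintf("  candidates %s -> deduplicated %s -> suspect reports %s\n",
              s$candidates, s$deduplicated, s$suspect_reports))
  cat(sprintf("  pairs %s (target %s; %s after PT filter)\n",
              s$pairs_total, s$pairs_target, s$pairs_after_filter))
  cat(sprintf("  PT terms %s (any-criteria %s, all-criteria %s); SOC terms %s\n",
              s$pt_terms, s$pt_significant_any, s$pt_significant_all,
              s$soc_terms))
  if (!is.null(x$onset_summary))
    cat(sprintf("  onset: n=%d, median %.0f d (IQR %.0f-%.0f)\n",
                x$onset_summary$n, x$onset_summary$median,
                x$onset_summary$q1, x$onset_summary$q3))
  invisible(x)
}
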