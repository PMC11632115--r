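#' Fit disproportionality signal statistics for a target drug
#'
#' The central fitting function of the package. Given the processed
#' drug-event pair table, it builds one 2x2 contingency table per term
#' (preferred term or system organ class) for the target drug against the
#' database background, computes the four disproportionality statistics —
#' ROR and PRR with 95% Wald intervals, the (optionally Yates-corrected)
#' chi-squared statistic, the BCPNN information component with IC025, and
#' the MGPS EBGM with EBGM05 under a maximum-likelihood gamma mixture prior
#' fitted to all drug-event pairs — and applies the signal criteria of each
#' algorithm. `significant_any` is the OR of the four flags,
#' `significant_all` their AND.
#'
#' @param pairs Pair table from [drug_event_pairs()] (after
#'   [apply_min_count_filter()] and, for SOC level, [map_to_soc()]).
#' @param target_drug Canonical target drug name.
#' @param level `"PT"` or `"SOC"`.
#' @param yates Use the Yates continuity correction for chi-squared.
#' @param z Normal quantile for the 95% intervals (1.96).
#' @param thresholds Signal criteria from [signal_thresholds()].
#' @param prior A fitted [mgps_prior()], or `NULL` to fit one on all pairs at
#'   the requested level.
#' @param prior_init Starting values for the prior fit when `prior = NULL`.
#' @return An object of class `pvsignal`: a list with elements `stats` (one
#'   row per term: counts, the four statistics, per-algorithm flags, joint
#'   flags), `target_drug`, `level`, `N`, `n_target_pairs`, `prior`,
#'   `thresholds`, `yates`, `call`.
#' @seealso [rank_signals()], [forest_plot_data()], [write_signal_table()]
#' @examples
#' pairs <- data.frame(
#'   primaryid = as.character(1:600),
#'   drug = rep(c("drugX", "other"), c(60, 540)),
#'   pt = c(rep(c("E1", "E2", "E3"), c(25, 20, 15)),
#'          sample(rep(paste0("E", 1:3), c(30, 200, 310)))))
#' fit <- disproportionality(pairs, "drugX")
#' summary(fit)
#' @export
disproportionality <- function(pairs, target_drug,
                               level = c("PT", "SOC"),
                               yates = TRUE, z = 1.96,
                               thresholds = signal_thresholds(),
                               prior = NULL, prior_init = mgps_prior()) {
  level <- match.arg(level)
  tab <- build_contingency_tables(pairs, target_drug, level)
  N <- attr(tab, "N")
  if (is.null(prior)) {
    all_counts <- all_pair_counts(pairs, level)
    prior <- fit_mgps_prior(all_counts$a, all_counts$E, init = prior_init)
  }
  stopifnot(inherits(prior, "mgps_prior"))
  ror <- ror_with_ci(tab$a, tab$b, tab$c, tab$d, z = z)
  prr <- prr_with_ci(tab$a, tab$b, tab$c, tab$d, z = z)
  chi2 <- chi_squared(tab$a, tab$b, tab$c, tab$d, yates = yates)
  ic <- bcpnn_ic(tab$a, tab$b, tab$c, tab$d)
  eb <- mgps_score(tab$a, tab$b, tab$c, tab$d, prior = prior)
  freq <- frequentist_flags(tab$a, ror$ror_lo, prr$prr, chi2, thresholds)
  stats <- cbind(tab, ror, prr, chi2 = chi2, ic, eb, freq)
  stats$ic_signal <- !is.na(stats$ic025) & stats$ic025 > thresholds$ic025_min
  stats$ebgm_signal <- !is.na(stats$ebgm05) &
    stats$ebgm05 > thresholds$ebgm05_min
  stats <- classify_signals(stats)
  structure(list(stats = stats, target_drug = target_drug, level = level,
                 N = N, n_target_pairs = sum(tab$a), prior = prior,
                 thresholds = thresholds, yates = yates,
                 call = match.call()),
            class = "pvsignal")
}

#' Combine the four algorithm flags into joint significance calls
#'
#' Adds `significant_any` (at least one of the ROR, PRR, BCPNN and MGPS
#' criteria met) and `significant_all` (all four met) to a statistics table.
#' All four per-algorithm flag columns must be present.
#'
#' @param stats Data frame with logical columns `ror_signal`, `prr_signal`,
#'   `ic_signal`, `ebgm_signal`.
#' @return `stats` with the two joint columns appended.
#' @export
classify_signals <- function(stats) {
  need <- c("ror_signal", "prr_signal", "ic_signal", "ebgm_signal")
  missing <- setdiff(need, names(stats))
  if (length(missing))
    stopf("missing algorithm flag column(s): %s", paste(missing, collapse = ", "))
  flags <- as.matrix(stats[need])
  flags[is.na(flags)] <- FALSE
  stats$significant_any <- rowSums(flags) > 0
  stats$significant_all <- rowSums(flags) == 4L
  stats
}

#' Rank, exclude and truncate signal results
#'
#' Removes user-listed terms (e.g. manifestations of the underlying disease
#' itself), sorts the remainder in decreasing order of the chosen key with
#' deterministic tie-breaking (larger `n` first, then term name), and
#' truncates to the top `k`.
#'
#' @param x A `pvsignal` fit or its statistics data frame.
#' @param sort_key `"ror"` or `"n"`.
#' @param top_k Number of rows to keep (default all).
#' @param exclude Character vector of terms to drop before ranking.
#' @return The ranked (and truncated) statistics data frame.
#' @export
rank_signals <- function(x, sort_key = c("ror", "n"), top_k = Inf,
                         exclude = character()) {
  sort_key <- match.arg(sort_key)
  df <- if (inherits(x, "pvsignal")) x$stats else x
  df <- df[!(df$term %in% exclude), , drop = FALSE]
  key <- if (sort_key == "ror") df$ror else df$a
  key[is.na(key)] <- -Inf
  ord <- order(-key, -df$a, df$term, method = "radix")
  df <- df[ord, , drop = FALSE]
  if (is.finite(top_k)) df <- utils::head(df, top_k)
  rownames(df) <- NULL
  df
}

#' Forest-plot-ready rows for a chosen term subset
#'
#' Extracts `(term, n, ror, ci_low, ci_high)` for the requested terms, in the
#' requested order — a pass-through of the fitted values, suitable for a
#' log-scale forest plot. Terms absent from the fit, or with an undefined
#' ROR, are skipped and listed in the `"skipped"` attribute.
#'
#' @param x A `pvsignal` fit.
#' @param terms Character vector of term names (e.g. autoimmune PTs).
#' @return Data frame `term`, `n`, `ror`, `ci_low`, `ci_high` with attribute
#'   `skipped`.
#' @export
forest_plot_data <- function(x, terms) {
  df <- if (inherits(x, "pvsignal")) x$stats else x
  idx <- match(terms, df$term)
  skipped <- terms[is.na(idx)]
  idx <- idx[!is.na(idx)]
  out <- data.frame(term = df$term[idx], n = df$a[idx], ror = df$ror[idx],
                    ci_low = df$ror_lo[idx], ci_high = df$ror_hi[idx],
                    stringsAsFactors = FALSE)
  undef <- !is.finite(out$ror) | !is.finite(out$ci_low) | out$ci_low <= 0
  skipped <- c(skipped, out$term[undef])
  out <- out[!undef, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.pvsignal <- function(x, ...) {
  cat(sprintf("Disproportionality fit: %s at %s level\n",
              x$target_drug, x$level))
  cat(sprintf("  %d terms, %d target-drug pairs, N = %d database pairs\n",
              nrow(x$stats), x$n_target_pairs, x$N))
  cat(sprintf("  signals: %d by any algorithm, %d by all four\n",
              sum(x$stats$significant_any), sum(x$stats$significant_all)))
  invisible(x)
}

#' @param object,x A `pvsignal` fit.
#' @param top_k Rows to display.
#' @param ... Unused.
#' @rdname disproportionality
#' @export
summary.pvsignal <- function(object, top_k = 10, ...) {
  ranked <- rank_signals(object, sort_key = "ror", top_k = top_k)
  out <- list(fit = object, top = ranked)
  class(out) <- "summary.pvsignal"
  out
}

#' @export
print.summary.pvsignal <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nTop %d terms by ROR:\n", nrow(x$top)))
  show <- data.frame(
    term = x$top$term, n = x$top$a,
    `ROR (95% CI)` = fmt_est_ci(x$top$ror, x$top$ror_lo, x$top$ror_hi),
    `PRR (95% CI)` = fmt_est_ci(x$top$prr, x$top$prr_lo, x$top$prr_hi),
    chi2 = fmt_num2(x$top$chi2),
    `IC (IC025)` = sprintf("%s (%s)", fmt_num2(x$top$ic), fmt_num2(x$top$ic025)),
    `EBGM (EBGM05)` = sprintf("%s (%s)", fmt_num2(x$top$ebgm),
                              fmt_num2(x$top$ebgm05)),
    all4 = x$top$significant_all,
    check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @rdname disproportionality
#' @param row.names,optional Passed through (unused).
#' @export
as.data.frame.pvsignal <- function(x, row.names = NULL, optional = FALSE, ...) {
  x$stats
}

#' Forest plot of reporting odds ratios
#'
#' Draws a base-graphics forest plot (log-scaled x axis) of the ROR and its
#' 95% interval for the chosen terms.
#'
#' @param x A `pvsignal` fit.
#' @param terms Terms to plot; default: the top 20 by ROR.
#' @param ... Further arguments passed to [graphics::plot.default()].
#' @return Invisibly, the plotted [forest_plot_data()] rows.
#' @export
plot.pvsignal <- function(x, terms = NULL, ...) {
  if (is.null(terms)) terms <- rank_signals(x, "ror", top_k = 20)$term
  fd <- forest_plot_data(x, terms)
  if (nrow(fd) == 0L) stopf("no plottable terms")
  fd <- fd[rev(seq_len(nrow(fd))), ]
  y <- seq_len(nrow(fd))
  graphics::plot(fd$ror, y, log = "x", pch = 15,
                 xlim = range(c(fd$ci_low, fd$ci_high, 1)),
                 yaxt = "n", ylab = "", xlab = "ROR (95% CI), log scale", ...)
  graphics::segments(fd$ci_low, y, fd$ci_high, y)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = paste0(fd$term, " (n=", fd$n, ")"),
                 las = 1, cex.axis = 0.7)
  invisible(fd)
}
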