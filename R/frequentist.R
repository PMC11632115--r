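#' @name disproportionality_stats
#' @title Frequentist disproportionality statistics
#'
#' @description
#' Each drug-event term is tested against the database background through a
#' 2x2 contingency table: `a` reports pair the target drug with the term,
#' `b` pair it with other terms, `c` pair other drugs with the term, and `d`
#' is the remainder; `N = a + b + c + d`. The reporting odds ratio
#' `ROR = ad/bc` and proportional reporting ratio
#' `PRR = [a/(a+b)] / [c/(c+d)]` get Wald 95% confidence intervals on the
#' log scale; the chi-squared statistic uses the Yates continuity correction
#' by default. Zero cells leave the statistic undefined and flagged rather
#' than imputed (no Haldane-Anscombe 0.5 correction by default).
NULL

#' Build 2x2 contingency tables per term
#'
#' Tallies, for every term at the chosen level, the cells of the 2x2 table of
#' the target drug against the database background. `N` is identical across
#' terms and the `a` column partitions the target drug's total pair count.
#'
#' @param pairs Pair table (`primaryid`, `drug`, `pt` and, for SOC level,
#'   `soc` from [map_to_soc()]).
#' @param target_drug Canonical target drug name; an error if absent from
#'   `pairs`.
#' @param level `"PT"` or `"SOC"`. At SOC level a report contributes one pair
#'   per (report, PT) as at PT level, so a report with two PTs in one SOC
#'   contributes 2 to that SOC.
#' @return Data frame `term`, `a`, `b`, `c`, `d` with attribute `N`.
#' @examples
#' pairs <- data.frame(
#'   primaryid = as.character(1:135),
#'   drug = rep(c("drugX", "other"), c(15, 120)),
#'   pt = rep(c("E1", "E2", "E1", "E2"), c(5, 10, 20, 100)))
#' build_contingency_tables(pairs, "drugX")   # E1: a=5 b=10 c=20 d=100
#' @export
build_contingency_tables <- function(pairs, target_drug,
                                     level = c("PT", "SOC")) {
  level <- match.arg(level)
  term <- if (level == "PT") pairs$pt else pairs$soc
  keep <- !is.na(term)
  term <- term[keep]
  is_target <- pairs$drug[keep] == target_drug
  if (!any(is_target)) stopf("target drug '%s' absent from pairs", target_drug)
  N <- length(term)
  drug_total <- sum(is_target)
  a_tab <- table(factor(term[is_target], levels = sort(unique(term[is_target]))))
  event_total <- table(term)[names(a_tab)]
  a <- as.integer(a_tab)
  cc <- as.integer(event_total) - a
  b <- drug_total - a
  d <- N - a - b - cc
  out <- data.frame(term = names(a_tab), a = a, b = b, c = cc, d = d,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "level") <- level
  out
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = ad/bc`; the 100(1-alpha)% interval is
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell leaves
#' the result undefined (`NA`, `defined = FALSE`).
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return Data frame `ror`, `ror_lo`, `ror_hi`, `ror_defined`.
#' @export
ror_with_ci <- function(a, b, c, d, z = 1.96) {
  defined <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(defined, (a * d) / (b * c), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ror = ror,
             ror_lo = exp(log(ror) - z * se),
             ror_hi = exp(log(ror) + z * se),
             ror_defined = defined)
}

#' Proportional reporting ratio with Wald confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the interval is
#' `exp(log PRR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Undefined
#' (flagged) when `a = 0` or `c = 0`.
#'
#' @inheritParams ror_with_ci
#' @return Data frame `prr`, `prr_lo`, `prr_hi`, `prr_defined`.
#' @export
prr_with_ci <- function(a, b, c, d, z = 1.96) {
  defined <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  prr <- ifelse(defined, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(defined,
               sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  data.frame(prr = prr,
             prr_lo = exp(log(prr) - z * se),
             prr_hi = exp(log(prr) + z * se),
             prr_defined = defined)
}

#' Chi-squared statistic for a 2x2 table
#'
#' Pearson's statistic, with the Yates continuity correction by default:
#' `N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, floored at 0 when
#' `|ad - bc| <= N/2`. Undefined (`NA`) when a margin is zero.
#'
#' @inheritParams ror_with_ci
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return Numeric vector of statistics.
#' @export
chi_squared <- function(a, b, c, d, yates = TRUE) {
  N <- a + b + c + d
  denom <- as.numeric(a + b) * (c + d) * (a + c) * (b + d)
  defined <- denom > 0
  dev <- abs(as.numeric(a) * d - as.numeric(b) * c)
  if (yates) dev <- pmax(dev - N / 2, 0)
  ifelse(defined, N * dev^2 / denom, NA_real_)
}

#' Frequentist signal flags
#'
#' Conventional criteria: the ROR flags a signal when `a >= 3` and the lower
#' 95% bound exceeds 1; the PRR flags when `a >= 3`, `PRR >= 2` and
#' `chi-squared >= 4` (inclusive boundaries). Undefined statistics never
#' flag.
#'
#' @param a Cell-a counts.
#' @param ror_lo Lower ROR confidence bound.
#' @param prr PRR point estimate.
#' @param chi2 Chi-squared statistic.
#' @param thresholds Threshold set from [signal_thresholds()].
#' @return Data frame `ror_signal`, `prr_signal` (logical, `NA`-free).
#' @export
frequentist_flags <- function(a, ror_lo, prr, chi2,
                              thresholds = signal_thresholds()) {
  ror_signal <- a >= thresholds$ror_min_a & !is.na(ror_lo) &
    ror_lo > thresholds$ror_ci_low
  prr_signal <- a >= thresholds$prr_min_a & !is.na(prr) &
    prr >= thresholds$prr_min & !is.na(chi2) & chi2 >= thresholds$chi2_min
  data.frame(ror_signal = ror_signal, prr_signal = prr_signal)
}

#' Signal thresholds
#'
#' The conventional FAERS disproportionality criteria, each configurable:
#' ROR needs `a >= 3` reports and lower CI bound `> 1`; PRR needs `a >= 3`,
#' `PRR >= 2`, `chi-squared >= 4`; BCPNN needs `IC025 > 0`; MGPS needs
#' `EBGM05 > 2`.
#'
#' @param ror_min_a,ror_ci_low ROR criteria.
#' @param prr_min_a,prr_min,chi2_min PRR criteria.
#' @param ic025_min BCPNN criterion (exclusive lower bound).
#' @param ebgm05_min MGPS criterion (exclusive lower bound).
#' @return Named list of thresholds.
#' @export
signal_thresholds <- function(ror_min_a = 3, ror_ci_low = 1,
                              prr_min_a = 3, prr_min = 2, chi2_min = 4,
                              ic025_min = 0, ebgm05_min = 2) {
  list(ror_min_a = ror_min_a, ror_ci_low = ror_ci_low,
       prr_min_a = prr_min_a, prr_min = prr_min, chi2_min = chi2_min,
       ic025_min = ic025_min, ebgm05_min = ebgm05_min)
}
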