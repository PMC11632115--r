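#' @name mgps
#' @title Multi-item gamma Poisson shrinker (MGPS)
#'
#' @description
#' MGPS models the observed count `a` of a drug-event pair as Poisson with
#' mean `lambda * E`, where `E = (a+b)(a+c)/N` is the count expected under
#' independence and the rate ratio `lambda` is drawn from a two-component
#' gamma mixture prior `w Ga(alpha1, beta1) + (1-w) Ga(alpha2, beta2)`
#' (shape/rate). Marginally `a` is then a mixture of negative binomials;
#' the hyperparameters are fitted by maximum marginal likelihood over all
#' drug-event pairs in the database. The posterior for each pair is again a
#' gamma mixture, giving the empirical-Bayes geometric mean
#' `EBGM = 2^{E[log2 lambda | a]}` and its 5th posterior percentile
#' `EBGM05`; `EBGM05 > 2` is the conventional signal criterion. Shrinkage
#' toward the prior is what makes the method robust for rare events.
NULL

#' Gamma mixture prior hyperparameters
#'
#' Constructor/validator for the MGPS prior. The defaults are the classical
#' DuMouchel starting values used to initialize the fit.
#'
#' @param alpha1,beta1 Shape and rate of the first gamma component.
#' @param alpha2,beta2 Shape and rate of the second gamma component.
#' @param w Mixture weight of the first component, in (0, 1).
#' @return Object of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                       w = 1 / 3) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w > 0, w < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2, w = w),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma mixture prior (shape/rate):\n")
  cat(sprintf("  component 1: Ga(%.4g, %.4g)  weight %.4g\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Ga(%.4g, %.4g)  weight %.4g\n",
              x$alpha2, x$beta2, 1 - x$w))
  ll <- attr(x, "logLik")
  if (!is.null(ll)) cat(sprintf("  log marginal likelihood: %.4f\n", ll))
  invisible(x)
}

#' @export
logLik.mgps_prior <- function(object, ...) {
  ll <- attr(object, "logLik")
  if (is.null(ll)) stopf("prior carries no fitted log-likelihood")
  structure(ll, df = 5L, class = "logLik")
}

# Log marginal likelihood of counts a given expectations E under the mixture
# prior: a ~ w NB(size alpha1, prob beta1/(beta1+E)) + (1-w) NB(alpha2, .).
mgps_marginal_loglik <- function(a, E, prior) {
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- pmax(l1 + log(prior$w), l2 + log1p(-prior$w))
  sum(m + log(exp(l1 + log(prior$w) - m) + exp(l2 + log1p(-prior$w) - m)))
}

#' Fit the MGPS gamma mixture prior by maximum marginal likelihood
#'
#' Maximizes the summed log marginal (negative-binomial mixture) likelihood
#' over all drug-event pairs, in unconstrained space (log for the four
#' positive hyperparameters, logit for the weight). A Nelder-Mead search is
#' followed by a BFGS polish; the fit is deterministic given `init` and the
#' data.
#'
#' @param a Observed counts, one per drug-event pair.
#' @param E Expected counts under independence, same length.
#' @param init Starting hyperparameters ([mgps_prior()] defaults).
#' @param max_iter Iteration cap passed to [stats::optim()].
#' @param tol Relative convergence tolerance on the objective.
#' @return Fitted `mgps_prior` with attributes `logLik`, `converged`,
#'   `n_pairs`.
#' @export
fit_mgps_prior <- function(a, E, init = mgps_prior(), max_iter = 2000,
                           tol = 1e-10) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (all(a == 0)) stopf("degenerate data: all observed counts are zero")
  if (length(a) < 100)
    warnf("fitting the prior on only %d pairs; >= 100 recommended", length(a))
  unpack <- function(theta)
    mgps_prior(exp(theta[1]), exp(theta[2]), exp(theta[3]), exp(theta[4]),
               stats::plogis(theta[5]))
  nll <- function(theta) {
    p <- tryCatch(unpack(theta), error = function(e) NULL)
    if (is.null(p)) return(1e300)
    v <- -mgps_marginal_loglik(a, E, p)
    if (!is.finite(v)) 1e300 else v
  }
  theta0 <- c(log(init$alpha1), log(init$beta1), log(init$alpha2),
              log(init$beta2), stats::qlogis(init$w))
  o1 <- stats::optim(theta0, nll, method = "Nelder-Mead",
                     control = list(maxit = max_iter, reltol = tol))
  o2 <- stats::optim(o1$par, nll, method = "BFGS",
                     control = list(maxit = max_iter, reltol = tol))
  best <- if (o2$value <= o1$value) o2 else o1
  if (best$value > -mgps_marginal_loglik(a, E, init) + 1e-9)
    warnf("optimizer did not improve on the starting values")
  converged <- (o1$convergence == 0L || o2$convergence == 0L)
  if (!converged)
    warnf("MGPS prior fit did not converge in %d iterations; returning best so far",
          max_iter)
  fit <- unpack(best$par)
  attr(fit, "logLik") <- -best$value
  attr(fit, "converged") <- converged
  attr(fit, "n_pairs") <- length(a)
  fit
}

# Posterior mixture for one pair: weight of component 1 and the two gamma
# components Ga(alpha_j + a, rate beta_j + E).
mgps_posterior <- function(a, E, prior) {
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE) +
    log(prior$w)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE) +
    log1p(-prior$w)
  m <- pmax(l1, l2)
  q <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  list(q = q,
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + E,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + E)
}

#' Posterior mixture CDF of the rate ratio
#'
#' @param x Evaluation points.
#' @param a,E Observed and expected count of the pair (scalars).
#' @param prior Fitted `mgps_prior`.
#' @return `P(lambda <= x | a)`.
#' @export
mgps_posterior_cdf <- function(x, a, E, prior) {
  p <- mgps_posterior(a, E, prior)
  p$q * stats::pgamma(x, p$shape1, rate = p$rate1) +
    (1 - p$q) * stats::pgamma(x, p$shape2, rate = p$rate2)
}

#' Posterior quantile of the rate ratio
#'
#' Solves the posterior mixture CDF by bracketed root-finding between the two
#' component quantiles, followed by one Newton polish using the mixture
#' density, to about 1e-10 relative accuracy.
#'
#' @param p Probability level (e.g. 0.05 for EBGM05).
#' @inheritParams mgps_posterior_cdf
#' @return The posterior `p`-quantile of `lambda`.
#' @export
mgps_posterior_quantile <- function(p, a, E, prior) {
  post <- mgps_posterior(a, E, prior)
  q1 <- stats::qgamma(p, post$shape1, rate = post$rate1)
  q2 <- stats::qgamma(p, post$shape2, rate = post$rate2)
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (hi - lo < .Machine$double.eps * hi) return(q1)
  f <- function(x) mgps_posterior_cdf(x, a, E, prior) - p
  # the mixture quantile lies between the component quantiles; nudge the
  # bracket outward against floating-point sign slips at the endpoints
  lo <- max(lo * (1 - 1e-9), 1e-300)
  hi <- hi * (1 + 1e-9)
  it <- 0L
  while (f(lo) > 0 && it < 60L) { lo <- lo / 4; it <- it + 1L }
  it <- 0L
  while (f(hi) < 0 && it < 60L) { hi <- hi * 4; it <- it + 1L }
  root <- stats::uniroot(f, lower = lo, upper = hi,
                         tol = max(1e-14, 1e-12 * hi))$root
  dens <- post$q * stats::dgamma(root, post$shape1, rate = post$rate1) +
    (1 - post$q) * stats::dgamma(root, post$shape2, rate = post$rate2)
  if (is.finite(dens) && dens > 0) {
    step <- f(root) / dens
    cand <- root - step
    if (is.finite(cand) && cand > 0 && abs(f(cand)) <= abs(f(root)))
      root <- cand
  }
  root
}

#' Score a drug-event pair under a fitted MGPS prior
#'
#' Computes the empirical-Bayes geometric mean of the posterior rate ratio,
#' `EBGM = 2^{E[log2 lambda | a]}` (digamma closed form per gamma component),
#' and its 5th posterior percentile `EBGM05`.
#'
#' @param a,b,c,d 2x2 cell counts (vectorized); `E = (a+b)(a+c)/N`.
#' @param prior Fitted `mgps_prior`.
#' @return Data frame `expected`, `rr`, `ebgm`, `ebgm05`.
#' @examples
#' pr <- mgps_prior(1, 1, 2, 4, w = 0.999999)   # effectively Ga(1,1)
#' mgps_score(3, 7, 3, 17, prior = pr)          # E = 2, posterior ~ Ga(4, 3)
#' @export
mgps_score <- function(a, b, c, d, prior) {
  N <- as.numeric(a) + b + c + d
  E <- (a + b) * (a + c) / N
  mgps_score_ae(a, E, prior)
}

#' Score from observed and expected counts directly
#'
#' @param a Observed counts.
#' @param E Expected counts under independence.
#' @param prior Fitted `mgps_prior`.
#' @return Data frame `expected`, `rr`, `ebgm`, `ebgm05`.
#' @export
mgps_score_ae <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"), all(E > 0))
  post <- mgps_posterior(a, E, prior)
  elog2 <- (post$q * (digamma(post$shape1) - log(post$rate1)) +
            (1 - post$q) * (digamma(post$shape2) - log(post$rate2))) / log(2)
  ebgm <- 2^elog2
  ebgm05 <- vapply(seq_along(a), function(i)
    mgps_posterior_quantile(0.05, a[i], E[i], prior), numeric(1))
  data.frame(expected = E, rr = a / E, ebgm = ebgm, ebgm05 = ebgm05)
}

#' Observed and expected counts for every drug-event combination
#'
#' Builds the full database pair grid used to fit the MGPS prior: one row
#' per (drug, term) combination — including unobserved combinations, whose
#' `a = 0` rows carry real likelihood information — with the observed pair
#' count and the independence expectation `E = row_total * col_total / N`.
#' Restricting the fit to observed pairs only would truncate the marginal
#' likelihood and bias the prior upward.
#'
#' @param pairs Pair table (`primaryid`, `drug`, `pt`, optional `soc`).
#' @param level `"PT"` or `"SOC"`.
#' @return Data frame `drug`, `term`, `a`, `E` with one row per combination
#'   of an observed drug and an observed term.
#' @export
all_pair_counts <- function(pairs, level = c("PT", "SOC")) {
  level <- match.arg(level)
  term <- if (level == "PT") pairs$pt else pairs$soc
  keep <- !is.na(term)
  drug <- pairs$drug[keep]; term <- term[keep]
  N <- length(term)
  counts <- table(factor(drug), factor(term))
  drug_tot <- rowSums(counts)
  term_tot <- colSums(counts)
  out <- data.frame(
    drug = rep(rownames(counts), times = ncol(counts)),
    term = rep(colnames(counts), each = nrow(counts)),
    a = as.integer(counts),
    E = as.numeric(outer(drug_tot, term_tot) / N),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
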