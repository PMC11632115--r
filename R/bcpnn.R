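#' Bayesian confidence propagation neural network information component
#'
#' The information component IC measures the log2 ratio of the joint
#' reporting probability of a drug-event pair to the product of its
#' marginals. Under independent Beta posteriors for the joint and marginal
#' probabilities (marginal priors Beta(1, 1), joint prior calibrated so that
#' the prior expectation of the joint equals the product of the marginal
#' expectations), the posterior expectation and variance of IC have the
#' closed forms
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}}
#' with \eqn{\gamma = \gamma_{11}(N+\alpha)(N+\beta) /
#' [(a+b+\alpha_1)(a+c+\beta_1)]}, and hyperparameters
#' \eqn{\alpha_1=\beta_1=1}, \eqn{\alpha=\beta=2}, \eqn{\gamma_{11}=1}.
#' `IC025 = IC - 2 sd` is the conventional lower bound; it flags a signal
#' when positive. Defined for `a = 0`.
#'
#' @param a,b,c,d 2x2 cell counts (vectorized).
#' @return Data frame `ic`, `ic_sd`, `ic025` (bits).
#' @examples
#' bcpnn_ic(a = 1000, b = 9000, c = 9000, d = 81000)$ic  # ~0: independence
#' @export
bcpnn_ic <- function(a, b, c, d) {
  N <- as.numeric(a) + b + c + d
  a1 <- 1; b1 <- 1           # marginal Beta(1, 1) priors
  alpha <- 2; beta <- 2      # marginal prior denominators
  g11 <- 1
  row1 <- a + b + a1         # drug margin posterior numerator
  col1 <- a + c + b1         # event margin posterior numerator
  gamma <- g11 * (N + alpha) * (N + beta) / (row1 * col1)
  ic <- log2((a + g11) * (N + alpha) * (N + beta) / ((N + gamma) * row1 * col1))
  v <- (1 / log(2))^2 * (
    (N - a + gamma - g11) / ((a + g11) * (1 + N + gamma)) +
    (N - (a + b) + alpha - a1) / (row1 * (1 + N + alpha)) +
    (N - (a + c) + beta - b1) / (col1 * (1 + N + beta)))
  ic_sd <- sqrt(v)
  data.frame(ic = ic, ic_sd = ic_sd, ic025 = ic - 2 * ic_sd)
}
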