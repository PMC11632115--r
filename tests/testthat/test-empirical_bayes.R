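test_that("IC is near zero when observed equals expected", {
  # a = 1000, both margins 10000, N = 100000: independence
  r <- bcpnn_ic(1000, 9000, 9000, 81000)
  expect_lt(abs(r$ic), 0.01)
  expect_true(r$ic025 < r$ic)
  expect_equal(r$ic025, r$ic - 2 * r$ic_sd)
})

test_that("IC approaches the log2 rate ratio at large counts", {
  # a twice its expectation -> IC ~ 1 bit
  a <- 2000; m <- 10000; N <- 1e5
  r <- bcpnn_ic(a, m - a, m - a, N - 2 * m + a)
  expect_equal(r$ic, 1, tolerance = 0.01)
  # |IC - log2(a/E)| < 0.02 once the observed and expected counts are both
  # large (the prior corrections decay like 1/a and E/N-type terms)
  set.seed(8)
  for (i in 1:20) {
    row <- sample(50000:100000, 1); col <- sample(50000:100000, 1)
    N <- round(runif(1, 5e5, 2e6))
    E <- as.numeric(row) * col / N
    a <- round(E * runif(1, 0.5, 2))
    r <- bcpnn_ic(a, row - a, col - a, N - row - col + a)
    expect_lt(abs(r$ic - log2(a / E)), 0.02)
  }
})

test_that("IC matches the Monte-Carlo posterior of the Beta model", {
  set.seed(21)
  a <- 100; b <- 200; c <- 400; d <- 2000
  N <- a + b + c + d
  g <- (N + 2)^2 / ((a + b + 1) * (a + c + 1))
  draws <- 1e6
  p11 <- rbeta(draws, a + 1, N - a + g - 1)
  px <- rbeta(draws, a + b + 1, N - (a + b) + 1)
  py <- rbeta(draws, a + c + 1, N - (a + c) + 1)
  ic_draws <- log2(p11 / (px * py))
  r <- bcpnn_ic(a, b, c, d)
  expect_equal(r$ic, mean(ic_draws), tolerance = 0.01)
  expect_equal(r$ic_sd, sd(ic_draws), tolerance = 0.05)
})

test_that("degenerate-prior MGPS scores match the gamma closed form", {
  # equal components make the prior effectively Ga(1, 1); with a = 3, E = 1
  # the posterior is Ga(4, 2)
  pr <- mgps_prior(1, 1, 1, 1, w = 0.5)
  s <- mgps_score_ae(3, 1, pr)
  expect_equal(s$ebgm, exp(digamma(4) - log(2)), tolerance = 1e-10)
  expect_equal(s$ebgm, 1.756, tolerance = 1e-3)
  expect_equal(s$ebgm05, qgamma(0.05, 4, rate = 2), tolerance = 1e-9)
  expect_equal(s$ebgm05, qchisq(0.05, 8) / 4, tolerance = 1e-9)  # chi2_8 / 4
  expect_equal(s$ebgm05, 0.683, tolerance = 1e-3)
})

test_that("data overwhelm any proper prior", {
  for (pr in list(mgps_prior(), mgps_prior(0.5, 2, 4, 1, 0.7))) {
    s <- mgps_score_ae(500, 100, pr)
    expect_equal(s$ebgm, 5, tolerance = 0.02)  # within 2% of rr
  }
})

test_that("EBGM shrinks monotonically in a and the posterior CDF closes", {
  pr <- mgps_prior(0.3, 0.2, 2, 3, 0.4)
  s <- mgps_score_ae(0:50, rep(2, 51), pr)
  expect_true(all(diff(s$ebgm) > 0))
  for (a in c(0, 1, 5, 20, 50)) {
    s1 <- mgps_score_ae(a, 2, pr)
    e95 <- mgps_posterior_quantile(0.95, a, 2, pr)
    expect_true(s1$ebgm05 < s1$ebgm && s1$ebgm < e95)
    expect_equal(mgps_posterior_cdf(s1$ebgm05, a, 2, pr), 0.05,
                 tolerance = 1e-8)
  }
})

test_that("prior fitting ascends the marginal likelihood and recovers shape", {
  set.seed(12)
  n <- 5000
  true <- mgps_prior(0.6, 0.8, 4, 2, w = 0.5)
  E <- rlnorm(n, 0, 1)
  comp <- runif(n) < true$w
  lam <- ifelse(comp, rgamma(n, true$alpha1, rate = true$beta1),
                rgamma(n, true$alpha2, rate = true$beta2))
  a <- rpois(n, lam * E)
  ll <- function(p) pvsignal:::mgps_marginal_loglik(a, E, p)
  init <- mgps_prior()
  fit <- fit_mgps_prior(a, E, init = init)
  expect_gte(attr(fit, "logLik"), ll(init))          # ascent property
  expect_gte(attr(fit, "logLik"), ll(true) - 1e-6)   # at least as good as truth
  grid <- exp(seq(log(1e-4), log(50), length.out = 500))
  expect_lt(max(abs(prior_cdf(fit, grid) - prior_cdf(true, grid))), 0.05)
})

test_that("the fitted optimum is stable under random restarts", {
  set.seed(13)
  n <- 2000
  E <- rlnorm(n, 0, 0.8)
  lam <- rgamma(n, 2, rate = 2)
  a <- rpois(n, lam * E)
  base <- fit_mgps_prior(a, E)
  for (s in 1:3) {
    set.seed(100 + s)
    init <- mgps_prior(exp(runif(1, -2, 1)), exp(runif(1, -2, 1)),
                       exp(runif(1, -1, 2)), exp(runif(1, -1, 2)),
                       runif(1, 0.2, 0.8))
    alt <- fit_mgps_prior(a, E, init = init)
    expect_equal(attr(alt, "logLik"), attr(base, "logLik"), tolerance = 1e-4)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_mgps_prior(c(0, 0, 0), c(1, 1, 1)), "zero")
  expect_error(mgps_prior(w = 1), "w")
  expect_error(mgps_prior(alpha1 = -1), "alpha1")
})
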