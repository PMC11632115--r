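test_that("contingency tables tally the pair corpus", {
  tab <- build_contingency_tables(toy_pairs(), "drugX")
  e1 <- tab[tab$term == "E1", ]
  expect_equal(unlist(e1[c("a", "b", "c", "d")]),
               c(a = 5, b = 10, c = 20, d = 100))
  expect_equal(attr(tab, "N"), 135L)
  # the a column partitions the drug's total pair count, N is constant
  expect_equal(sum(tab$a), 15L)
  expect_true(all(tab$a + tab$b + tab$c + tab$d == 135L))
  # permutation invariance (set semantics)
  shuffled <- toy_pairs()[sample(135), ]
  expect_equal(build_contingency_tables(shuffled, "drugX"), tab)
  expect_error(build_contingency_tables(toy_pairs(), "absent"), "absent")
})

test_that("ROR, PRR and chi-squared reproduce the worked 2x2 example", {
  r <- ror_with_ci(5, 10, 20, 100)
  expect_equal(r$ror, 2.5)                         # ad/bc = 500/200
  expect_equal(c(r$ror_lo, r$ror_hi),
               exp(log(2.5) + c(-1, 1) * 1.96 * sqrt(1/5 + 1/10 + 1/20 + 1/100)))
  expect_equal(round(c(r$ror_lo, r$ror_hi), 2), c(0.77, 8.10))
  p <- prr_with_ci(5, 10, 20, 100)
  expect_equal(p$prr, 2)                           # (1/3)/(1/6)
  expect_equal(round(c(p$prr_lo, p$prr_hi), 2), c(0.88, 4.54))
  expect_equal(chi_squared(5, 10, 20, 100, yates = FALSE),
               135 * 300^2 / (15 * 120 * 25 * 110))
  expect_equal(round(chi_squared(5, 10, 20, 100, yates = FALSE), 4), 2.4545)
  expect_equal(chi_squared(5, 10, 20, 100, yates = TRUE),
               135 * (300 - 67.5)^2 / (15 * 120 * 25 * 110))
  expect_equal(round(chi_squared(5, 10, 20, 100, yates = TRUE), 4), 1.4743)
})

test_that("statistics match direct formula evaluation on random tables", {
  t <- random_tables(1000, seed = 5)
  with(t, {
    r <- ror_with_ci(a, b, c, d)
    expect_equal(r$ror, a * d / (b * c), tolerance = 1e-12)
    se <- sqrt(1/a + 1/b + 1/c + 1/d)
    expect_equal(r$ror_lo, exp(log(a * d / (b * c)) - 1.96 * se),
                 tolerance = 1e-12)
    p <- prr_with_ci(a, b, c, d)
    expect_equal(p$prr, (a / (a + b)) / (c / (c + d)), tolerance = 1e-12)
    x2 <- chi_squared(a, b, c, d, yates = FALSE)
    N <- as.numeric(a + b + c + d)
    expect_equal(x2, N * (as.numeric(a) * d - as.numeric(b) * c)^2 /
                   (as.numeric(a + b) * (c + d) * (a + c) * (b + d)),
                 tolerance = 1e-12)
  })
})

test_that("uncorrected chi-squared equals the generic Pearson statistic", {
  t <- random_tables(200, seed = 6)
  pearson <- vapply(seq_len(nrow(t)), function(i) {
    m <- matrix(unlist(t[i, ]), 2, 2, byrow = TRUE)
    unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic)
  }, numeric(1))
  got <- with(t, chi_squared(a, b, c, d, yates = FALSE))
  expect_equal(got, pearson, tolerance = 1e-9)
})

test_that("independence and symmetry behave as expected", {
  # a=b=c=d: ROR = 1 with the interval straddling 1; chi-squared 0
  r <- ror_with_ci(8, 8, 8, 8)
  expect_equal(r$ror, 1)
  expect_true(r$ror_lo < 1 && r$ror_hi > 1)
  expect_equal(chi_squared(6, 3, 8, 4, yates = FALSE), 0)  # ad = bc
  expect_equal(chi_squared(6, 3, 8, 4, yates = TRUE), 0)
  # transposing drug/event axes leaves ROR and chi-squared unchanged
  t <- random_tables(50, seed = 7)
  expect_equal(with(t, ror_with_ci(a, b, c, d)$ror),
               with(t, ror_with_ci(a, c, b, d)$ror))
  expect_equal(with(t, chi_squared(a, b, c, d)),
               with(t, chi_squared(a, c, b, d)))
})

test_that("ROR exceeds PRR exceeds 1 whenever a/b > c/d (all cells in 1..6)", {
  g <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  g <- g[g$a / g$b > g$c / g$d, ]
  ror <- with(g, ror_with_ci(a, b, c, d)$ror)
  prr <- with(g, prr_with_ci(a, b, c, d)$prr)
  expect_true(all(ror > prr))
  expect_true(all(prr > 1))
})

test_that("ROR and PRR agree in the large-background limit", {
  big <- 1e6
  r <- ror_with_ci(20, big, 50, big)$ror
  p <- prr_with_ci(20, big, 50, big)$prr
  expect_equal(r, p, tolerance = 1e-3)
})

test_that("zero cells yield flagged undefined results, not imputations", {
  r <- ror_with_ci(0, 10, 20, 100)
  expect_false(r$ror_defined)
  expect_true(is.na(r$ror))
  p <- prr_with_ci(5, 10, 0, 100)
  expect_false(p$prr_defined)
  expect_true(is.na(chi_squared(0, 0, 20, 100)))  # zero margin
})

test_that("frequentist flags apply inclusive boundaries and the count gate", {
  f <- frequentist_flags(a = 3, ror_lo = 1.01, prr = 2.0, chi2 = 4.0)
  expect_true(f$ror_signal)
  expect_true(f$prr_signal)     # prr >= 2 and chi2 >= 4 inclusive
  expect_false(frequentist_flags(2, 50, 100, 1000)$ror_signal)  # a < 3
  expect_false(frequentist_flags(3, 0.99, 1.99, 4)$prr_signal)
  expect_false(frequentist_flags(3, NA, NA, NA)$ror_signal)
})
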