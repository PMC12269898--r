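test_that("fold-ratio classification is strict at the threshold", {
  cls <- classify_pair(c(0.10, 0.10, 0.08, 0.125, 0.10),
                       c(0.10, 0.125, 0.099, 0.10, 0.1249))
  expect_equal(as.character(cls),
               c("concordant",   # ratio 1
                 "b_higher",     # ratio exactly 1.25 counts as discordant
                 "concordant",   # fold 1.2375 < 1.25
                 "a_higher",
                 "concordant"))
  expect_error(classify_pair(0.1, 0), "positive")
  expect_error(classify_pair(c(0.1, 0.2), 0.1), "length")
})

test_that("classification is invariant to expressing risks as percentages", {
  set.seed(2)
  a <- runif(500, 0.01, 0.5)
  b <- a * exp(rnorm(500, 0, 0.4))
  expect_identical(classify_pair(a, b), classify_pair(100 * a, 100 * b))
})

test_that("weighted shares are normalized and scale invariant", {
  cls <- factor(c("concordant", "a_higher"),
                levels = c("concordant", "a_higher", "b_higher"))
  expect_equal(unname(weighted_share(cls, c(3, 1))), c(0.75, 0.25, 0))

  all_conc <- factor(rep("concordant", 4),
                     levels = levels(cls))
  expect_equal(unname(weighted_share(all_conc, runif(4, 1, 9))[1]), 1)

  set.seed(4)
  cls2 <- factor(sample(levels(cls), 200, replace = TRUE),
                 levels = levels(cls))
  w <- rlnorm(200)
  expect_equal(weighted_share(cls2, w), weighted_share(cls2, 10 * w))
  expect_error(weighted_share(cls2, w[-1]), "length")
})

test_that("stratification cut points are lower-bound inclusive", {
  main <- default_schemes()$main
  expect_equal(stratify(c(0.0999, 0.10, 0.1999, 0.20, 0.55), main),
               c(1L, 2L, 2L, 3L, 3L))
  expect_error(stratify(1.2, main), "inside")
  expect_error(stratification_scheme("bad", c(20, 10)), "increasing")
  expect_error(stratification_scheme("bad", c(0, 10)), "increasing|inside")
  esc <- default_schemes()$esc_eas
  expect_equal(esc$cuts, c(10, 15, 30))
  expect_equal(default_schemes()$aha_acc$cuts, c(5, 7.5, 20))
})

test_that("weighted contingency tables hold normalized masses", {
  perfect <- build_contingency(c(1, 2, 2), c(1, 2, 2), c(1, 1, 1), 2)
  expect_equal(sum(diag(perfect$p)), 1)
  expect_equal(perfect$p[1, 2], 0)

  spread <- build_contingency(c(1, 1, 2, 2), c(1, 2, 1, 2), rep(2, 4), 2)
  expect_equal(spread$p, matrix(0.25, 2, 2))

  weighted <- build_contingency(c(1, 1, 2), c(1, 1, 2), c(2, 1, 1), 2)
  expect_equal(diag(weighted$p), c(0.75, 0.25))
  expect_equal(sum(weighted$p), 1, tolerance = 1e-12)
  expect_error(build_contingency(3, 1, 1, 2), "1..q")
})

test_that("Gwet AC1 reproduces closed-form cases", {
  perfect <- build_contingency(1:3, 1:3, rep(1, 3), 3)
  expect_equal(gwet_ac1(perfect), 1)
  # uniform independent 2x2: Pa = 0.5, pi = (0.5, 0.5), Pe = 0.5 -> 0
  expect_equal(gwet_ac1(matrix(0.25, 2, 2)), 0)
})

test_that("AC1 resists the prevalence paradox that deflates kappa", {
  skewed <- list(
    matrix(c(0.90, 0.05, 0.04, 0.01), 2, 2),
    matrix(c(0.85, 0.10, 0.04, 0.01), 2, 2),
    matrix(c(0.94, 0.02, 0.03, 0.01), 2, 2)
  )
  for (p in skewed) {
    expect_gt(gwet_ac1(p), cohen_kappa(p))
  }
})

test_that("agreement statistics are symmetric and weight-scale invariant", {
  set.seed(8)
  n <- 400
  a <- runif(n, 0.01, 0.6)
  b <- pmin(0.95, a * exp(rnorm(n, 0, 0.5)))
  w <- rlnorm(n)
  fwd <- agreement_pair(a, b, w)
  rev <- agreement_pair(b, a, w)
  expect_equal(fwd$shares[["concordant"]], rev$shares[["concordant"]])
  expect_equal(fwd$shares[["a_higher"]], rev$shares[["b_higher"]])
  for (s in names(fwd$by_scheme)) {
    expect_equal(fwd$by_scheme[[s]]$pa, rev$by_scheme[[s]]$pa)
    expect_equal(fwd$by_scheme[[s]]$ac1, rev$by_scheme[[s]]$ac1)
    expect_equal(fwd$by_scheme[[s]]$table$p,
                 t(rev$by_scheme[[s]]$table$p))
  }
  scaled <- agreement_pair(a, b, w * 13)
  expect_equal(fwd$shares, scaled$shares)
  for (s in names(fwd$by_scheme)) {
    expect_equal(fwd$by_scheme[[s]]$ac1, scaled$by_scheme[[s]]$ac1,
                 tolerance = 1e-12)
  }
})

test_that("weighted quantiles follow the left-continuous inverse CDF", {
  expect_equal(weighted_quantile(c(1, 2, 3), c(1, 1, 1), 0.5), 2)
  # cumulative weight 0.9 at the first value already covers p = 0.5
  expect_equal(weighted_quantile(c(1, 10), c(9, 1), 0.5), 1)
  expect_equal(weighted_quantile(c(5, 1, 3), c(1, 1, 1), 0), 1)
  expect_equal(weighted_quantile(c(5, 1, 3), c(1, 1, 1), 1), 5)
  expect_error(weighted_quantile(numeric(0), numeric(0), 0.5), "empty")
  # interpolating rule stays between the order statistics
  qi <- weighted_quantile(c(1, 2, 3, 4), rep(1, 4), c(0.3, 0.6),
                          type = "interpolate")
  expect_true(all(qi >= 1 & qi <= 4) && !is.unsorted(qi))
  iqr <- weighted_iqr(c(1, 2, 3, 4, 100), rep(1, 5))
  expect_equal(unname(iqr), c(2, 3, 4))
})
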