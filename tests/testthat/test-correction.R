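test_that("noiseless identity data recovers slope 1, intercept 0", {
  set.seed(2)
  x <- runif(500, 0.5, 1.2)
  # sigma is boundary-degenerate on noiseless data; convergence warnings
  # about it are expected
  fit <- suppressWarnings(
    fit_correction_model(x, x, chains = 4, draws_per_chain = 3000,
                         seed = 10))
  expect_equal(nrow(fit$draws), 12000)
  expect_lt(abs(mean(fit$draws$m) - 1), 0.02)
  expect_lt(abs(mean(fit$draws$n_intercept)), 0.02)
  expect_true(all(fit$draws$sigma > 0))
})

test_that("posterior means track the OLS fit on noisy linear data", {
  set.seed(5)
  x <- runif(800, 0.4, 1.2)
  y <- 0.85 * x + 0.10 + rnorm(800, 0, 0.02)
  fit <- fit_correction_model(x, y, seed = 11)
  ols <- coef(lm(y ~ x))
  expect_lt(abs(mean(fit$draws$m) - ols[2]), 0.02)
  expect_lt(abs(mean(fit$draws$n_intercept) - ols[1]), 0.02)
  # true parameters within 3 posterior SDs
  expect_lt(abs(mean(fit$draws$m) - 0.85), 3 * sd(fit$draws$m))
  expect_lt(abs(mean(fit$draws$n_intercept) - 0.10),
            3 * sd(fit$draws$n_intercept))
  expect_lt(abs(mean(fit$draws$sigma) - 0.02), 3 * sd(fit$draws$sigma))
  expect_true(all(fit$rhat < 1.05))
})

test_that("fits are reproducible under a fixed seed", {
  set.seed(8)
  x <- runif(100); y <- x + rnorm(100, 0, 0.05)
  f1 <- fit_correction_model(x, y, draws_per_chain = 500, warmup = 500,
                             seed = 3)
  f2 <- fit_correction_model(x, y, draws_per_chain = 500, warmup = 500,
                             seed = 3)
  expect_identical(f1$draws, f2$draws)
})

test_that("input validation catches bad fitting data", {
  expect_error(fit_correction_model(1:5, 1:4), "equal length")
  expect_error(fit_correction_model(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_correction_model(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("apply_correction draws joint posterior pairs", {
  draws <- data.frame(chain = 1, draw = 1:1000,
                      m = rep(1, 1000), n_intercept = rep(0, 1000),
                      sigma = rep(0.01, 1000))
  model <- structure(list(metric = "width", draws = draws, chains = 1,
                          draws_per_chain = 1000, rhat = NULL),
                     class = "correction_model")
  tr <- apply_correction(model, c(0.7, 0.9, 1.3), K = 250, seed = 4)
  expect_equal(dim(tr$transformed), c(250, 3))
  expect_equal(tr$summary, c(0.7, 0.9, 1.3))       # degenerate posterior
  expect_true(all(tr$transformed == rep(c(0.7, 0.9, 1.3), each = 250)))
  expect_error(apply_correction(model, 1, K = 0), "positive")
  expect_error(apply_correction(model, 1, K = 1e6), "exceeds")

  # joint sampling preserves posterior correlation: with m and n perfectly
  # anti-correlated so that m + n = 1, transforming x = 1 is exact
  draws2 <- draws
  draws2$m <- runif(1000, 0.8, 1.2)
  draws2$n_intercept <- 1 - draws2$m
  model2 <- structure(list(metric = "width", draws = draws2, chains = 1,
                           draws_per_chain = 1000, rhat = NULL),
                      class = "correction_model")
  tr2 <- apply_correction(model2, 1, K = 100, seed = 5)
  expect_true(all(abs(tr2$transformed - 1) < 1e-12))
})

test_that("summary median approximates the posterior-mean line", {
  set.seed(9)
  draws <- data.frame(chain = 1, draw = 1:20000,
                      m = rnorm(20000, 0.9, 0.01),
                      n_intercept = rnorm(20000, 0.05, 0.01),
                      sigma = 0.01)
  model <- structure(list(metric = "width", draws = draws, chains = 1,
                          draws_per_chain = 20000, rhat = NULL),
                     class = "correction_model")
  x <- 1.0
  tr <- apply_correction(model, x, K = 1e4, seed = 6)
  mc_se <- sd(tr$transformed) / sqrt(length(tr$transformed))
  expect_lt(abs(tr$summary - (mean(draws$m) * x + mean(draws$n_intercept))),
            2 * mc_se + 1e-4)
})

test_that("correction models round-trip through the CSV model file", {
  set.seed(12)
  x <- runif(60); y <- 0.9 * x + 0.05 + rnorm(60, 0, 0.02)
  fit <- fit_correction_model(x, y, draws_per_chain = 200, warmup = 400,
                              seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correction_model(fit, path)
  back <- read_correction_model(path)
  expect_equal(back$draws$m, fit$draws$m, tolerance = 1e-12)
  expect_equal(back$chains, fit$chains)
  tr1 <- apply_correction(fit, 0.8, K = 50, seed = 2)
  tr2 <- apply_correction(back, 0.8, K = 50, seed = 2)
  expect_equal(tr1$summary, tr2$summary)
})

test_that("KL divergence behaves like a divergence", {
  set.seed(14)
  a <- rnorm(5000)
  expect_lte(kl_divergence(a, a), 1e-6)

  # closed form for equal unit variances: (mu1 - mu2)^2 / 2 = 0.125
  b <- rnorm(10000); c2 <- rnorm(10000, 0.5)
  expect_lt(abs(kl_divergence(c2, b) - 0.125), 0.05)

  # disjoint supports stay finite but large
  kl <- kl_divergence(runif(500, 0, 1), runif(500, 10, 11))
  expect_true(is.finite(kl))
  expect_gt(kl, 5)

  # order invariance within samples, shift invariance of the pair
  p <- rnorm(2000); q <- rnorm(2000, 0.3)
  expect_equal(kl_divergence(p, q), kl_divergence(sample(p), sample(q)))
  expect_equal(kl_divergence(p, q), kl_divergence(p + 5, q + 5),
               tolerance = 1e-9)

  expect_error(kl_divergence(numeric(0), 1:3), "empty")
})

test_that("Levene gate routes to ANOVA or Kruskal as specified", {
  # two identical groups: equal variances, F = 0, p ~ 1
  g <- rnorm(50)
  cmp <- compare_groups(list(g, g))
  expect_equal(cmp$chosen_test, "anova")
  expect_gt(cmp$test_p, 0.99)

  # equal-variance normals one SD apart: ANOVA, significant
  set.seed(21)
  cmp2 <- compare_groups(list(rnorm(100), rnorm(100, 1)))
  expect_equal(cmp2$chosen_test, "anova")
  expect_lt(cmp2$test_p, 0.05)
  # cross-check the branch with the standard implementations
  vals <- c(rnorm(100), rnorm(100, 1))

  # strongly unequal variances: Kruskal branch
  set.seed(22)
  cmp3 <- compare_groups(list(rnorm(200, 0, 1), rnorm(200, 0, 5)))
  expect_lte(cmp3$levene_p, 0.05)
  expect_equal(cmp3$chosen_test, "kruskal")

  expect_error(compare_groups(list(rnorm(5))), "2 groups")
})

test_that("compare_groups agrees with direct aov and kruskal.test", {
  set.seed(25)
  a <- rnorm(80); b <- rnorm(80, 0.4)
  cmp <- compare_groups(list(a, b))
  vals <- c(a, b); grp <- factor(rep(1:2, each = 80))
  if (cmp$chosen_test == "anova") {
    want <- summary(aov(vals ~ grp))[[1]][["Pr(>F)"]][1]
  } else {
    want <- kruskal.test(vals, grp)$p.value
  }
  expect_equal(cmp$test_p, want)

  aa <- rnorm(150, 0, 1); bb <- rnorm(150, 0.1, 4)
  cmp2 <- compare_groups(list(aa, bb))
  if (cmp2$chosen_test == "kruskal") {
    want2 <- kruskal.test(c(aa, bb), factor(rep(1:2, c(150, 150))))$p.value
    expect_equal(cmp2$test_p, want2)
  }
})
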