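test_that("inverse-variance weights are reciprocals of total variance", {
  expect_equal(unname(study_weights(studies("a", 1, variance = 0.25))), 4)
  expect_equal(unname(study_weights(studies("a", 1, variance = 0.25),
                                    tau2 = 0.25)), 2)
  x <- studies(c("a", "b", "c"), c(0, 0, 0), variance = c(0.1, 0.2, 0.4))
  expect_equal(unname(study_weights(x)), c(10, 5, 2.5))
  # tau2 = 0 reproduces fixed-effect weights exactly
  expect_identical(study_weights(x, 0), study_weights(x))
  expect_error(studies("a", 1, variance = 0), "a")
  expect_error(studies("a", 1, variance = -1), "positive")
})

test_that("pooled estimate, se and CI match hand arithmetic", {
  fit <- meta_fit(effect = 0.5, variance = 0.25, label = "solo")
  expect_equal(coef(fit), c(estimate = 0.5))
  expect_equal(fit$se, 0.5)
  expect_equal(fit$ci, 0.5 + c(-1, 1) * qnorm(0.975) * 0.5, tolerance = 1e-9)
  expect_lt(max(abs(fit$ci - c(-0.48, 1.48))), 0.01)

  expect_equal(coef(meta_fit(effect = c(0.2, 0.4), variance = c(1, 1))),
               c(estimate = 0.3))

  fit3 <- meta_fit(effect = c(1, 0, -0.5), variance = c(0.1, 0.2, 0.4))
  expect_equal(unname(coef(fit3)), 8.75 / 17.5)  # direct weighted average
  expect_equal(fit3$se, 1 / sqrt(17.5))
})

test_that("empty and malformed study sets are rejected", {
  expect_error(studies(character(0), numeric(0), variance = numeric(0)),
               "empty")
  expect_error(meta_fit(effect = c(1, NA), variance = c(1, 1)),
               "non-finite")
  expect_error(meta_fit(effect = 1, variance = 1, alpha = 1), "alpha")
})

test_that("per-study one-sided p-value is Phi(-sqrt(w) y)", {
  expect_equal(study_p_value(0, 4), 0.5)
  expect_equal(study_p_value(1.6449, 1), pnorm(-1.6449))
  expect_equal(study_p_value(1.6449, 1), 0.05, tolerance = 1e-4)
  expect_equal(study_p_value(0.98, 4), pnorm(-1.96))
  # strictly decreasing in effect at fixed weight
  p <- study_p_value(seq(-2, 2, by = 0.5), 3)
  expect_true(all(diff(p) < 0))
  expect_error(study_p_value(1, 0), "positive")
})

test_that("pooled p-value reduces correctly and matches the normal CDF", {
  expect_equal(pooled_p_value(meta_fit(effect = 0, variance = 1)), 0.5)
  # single-study pooled p equals the per-study p exactly
  fit1 <- meta_fit(effect = 0.7, variance = 0.3)
  expect_equal(pooled_p_value(fit1), study_p_value(0.7, 1 / 0.3))
  # equal weights w = 1, y = (1,1): Phi(-sqrt(2))
  fit2 <- meta_fit(effect = c(1, 1), variance = c(1, 1))
  expect_equal(pooled_p_value(fit2), pnorm(-sqrt(2)))
  expect_equal(pooled_p_value(fit2), 0.0786, tolerance = 1e-3)
})

test_that("left- and two-tailed variants are consistent with right-tailed", {
  y <- c(0.3, -0.1, 0.6); v <- c(0.2, 0.3, 0.25)
  r <- meta_fit(effect = y, variance = v, sided = "right")
  l <- meta_fit(effect = y, variance = v, sided = "left")
  tw <- meta_fit(effect = y, variance = v, sided = "two")
  expect_equal(r$p + l$p, 1)
  expect_equal(tw$p, 2 * min(r$p, l$p))
})

test_that("DerSimonian-Laird estimator matches hand arithmetic and metafor", {
  expect_equal(dl_tau2(effect = c(1, 1, 1), variance = c(0.2, 0.3, 0.4)), 0)
  expect_equal(dl_tau2(effect = c(0, 1), variance = c(1, 1)), 0)  # Q-1 < 0
  expect_equal(dl_tau2(effect = c(0, 2), variance = c(1, 1)), 1)
  expect_warning(t1 <- dl_tau2(effect = 0.4, variance = 0.2), "single")
  expect_equal(t1, 0)
  # independent cross-check against metafor's DL implementation
  set.seed(42)
  for (i in 1:5) {
    y <- rnorm(7, 0.2, 0.6)
    v <- runif(7, 0.05, 0.5)
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(dl_tau2(effect = y, variance = v), ref$tau2,
                 tolerance = 1e-9)
    fit <- meta_fit(effect = y, variance = v, model = "random")
    expect_equal(unname(coef(fit)), as.numeric(ref$beta), tolerance = 1e-9)
  }
})

test_that("typical-variance heterogeneity fraction", {
  expect_equal(i_squared_typical(0, 0.17), 0)
  expect_equal(i_squared_typical(0.70, 0.17), 0.70 / 0.87)
  expect_equal(round(i_squared_typical(0.70, 0.17), 4), 0.8046)
  expect_equal(i_squared_typical(0.17, 0.17), 0.5)
  t2 <- seq(0, 2, by = 0.1)
  expect_true(all(diff(i_squared_typical(t2, 0.17)) > 0))
  expect_error(i_squared_typical(0.1, 0), "positive")
})

test_that("pooled estimate is a convex combination of study effects", {
  set.seed(11)
  for (i in 1:50) {
    x <- rand_studies(sample(2:10, 1))
    for (m in c("fixed", "random")) {
      est <- coef(meta_fit(x, model = m))
      expect_gte(est, min(x$effect))
      expect_lte(est, max(x$effect))
    }
  }
})

test_that("tau2 = 0 makes the random-effects fit identical to fixed", {
  set.seed(12)
  x <- rand_studies(6)
  f <- meta_fit(x, model = "fixed")
  r <- meta_fit(x, model = "random", tau2 = 0)
  expect_equal(coef(r), coef(f))
  expect_equal(r$se, f$se)
  expect_equal(r$ci, f$ci)
  expect_equal(r$p, f$p)
})

test_that("null pooled one-sided p-values are Uniform(0,1)", {
  set.seed(314)
  reps <- 10000; k <- 5
  v <- matrix(runif(reps * k, 0.05, 0.5), reps)
  y <- matrix(rnorm(reps * k, 0, sqrt(v)), reps)
  w <- 1 / v
  p <- pnorm(-rowSums(w * y) / sqrt(rowSums(w)))
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("the CI covers the true effect at its nominal rate", {
  set.seed(271)
  reps <- 10000; k <- 6; theta <- 0.3
  v <- matrix(runif(reps * k, 0.05, 0.5), reps)
  y <- matrix(rnorm(reps * k, theta, sqrt(v)), reps)
  w <- 1 / v
  est <- rowSums(w * y) / rowSums(w)
  half <- qnorm(0.975) / sqrt(rowSums(w))
  cover <- mean(est - half <= theta & theta <= est + half)
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("meta_fit methods are coherent", {
  x <- read_study_csv(extdata("example_studies.csv"))
  fit <- meta_fit(x, model = "random")
  expect_equal(unname(sqrt(diag(vcov(fit)))), fit$se)
  expect_equal(unname(confint(fit)[1, ]), fit$ci)
  expect_equal(sum(fit$weights * x$effect) / sum(fit$weights),
               unname(coef(fit)))
  expect_equal(unname(residuals(fit)), x$effect - fit$estimate)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "studies")
  expect_identical(sims[[1]]$variance, x$variance)
  expect_output(print(summary(fit)), "I\\^2")
  ft <- forest_table(fit)
  expect_equal(sum(ft$weight_pct, na.rm = TRUE), 100, tolerance = 1e-6)
  expect_true(ft$pooled[nrow(ft)])
})
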