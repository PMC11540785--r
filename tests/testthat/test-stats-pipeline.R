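test_that("normality test guards its domain and detects skew", {
  expect_error(normality_test(c(1, 2)), "sample size")
  expect_error(normality_test(rep(1, 10)), "constant")

  set.seed(6)
  reject_skew <- mean(replicate(50, {
    normality_test(exp(rnorm(30)))$p_value < 0.05
  }))
  expect_gt(reject_skew, 0.8)

  reject_normal <- mean(replicate(50, {
    normality_test(rnorm(30))$p_value < 0.05
  }))
  expect_lt(reject_normal, 0.2)
})

test_that("correlation matrix is symmetric with pairwise-complete handling", {
  set.seed(7)
  d <- data.frame(a = rnorm(20))
  d$b <- -d$a
  d$c <- rnorm(20)
  d$c[1:5] <- NA
  r <- correlation_matrix(d)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["a", "b"], -1)
  expect_equal(r, t(r))
  expect_equal(r["a", "c"], cor(d$a[-(1:5)], d$c[-(1:5)]))

  short <- data.frame(a = c(1, 2, NA, NA, 5), b = c(NA, NA, 3, 4, NA),
                      c = 1:5)
  expect_warning(r2 <- correlation_matrix(short), "complete pairs")
  expect_true(is.na(r2["a", "b"]))
})

test_that("metric clustering groups correlated variables", {
  # two planted blocks: |r| = 0.9 within, 0 between
  r <- diag(4)
  dimnames(r) <- list(letters[1:4], letters[1:4])
  r["a", "b"] <- r["b", "a"] <- 0.9
  r["c", "d"] <- r["d", "c"] <- -0.9
  cl <- cluster_metrics(r, selection_criteria())$clusters
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["c"]], cl[["d"]])
  expect_false(cl[["a"]] == cl[["c"]])

  # perfectly correlated metrics always share a cluster
  r2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(length(unique(cluster_metrics(r2)$clusters)), 1)

  single <- matrix(1, 1, 1, dimnames = list("only", "only"))
  expect_equal(unname(cluster_metrics(single)$clusters), 1L)
})

test_that("residual diagnostics separate clean and heteroscedastic fits", {
  set.seed(8)
  clean_pass <- mean(replicate(40, {
    x <- rnorm(40)
    y <- 1 + 2 * x + rnorm(40)
    d <- residual_diagnostics(lm(y ~ x))
    d$shapiro_p > 0.05 && d$bp_p > 0.05
  }))
  expect_gt(clean_pass, 0.7)

  hetero_flag <- mean(replicate(40, {
    x <- runif(60, 1, 4)
    y <- 1 + 2 * x + rnorm(60, 0, 0.5 * x^2)
    residual_diagnostics(lm(y ~ x))$bp_p < 0.05
  }))
  expect_gt(hetero_flag, 0.75)

  x <- 1:20
  expect_error(residual_diagnostics(lm(I(2 * x) ~ x)), "degenerate")
})

test_that("variable screening drops non-normal, ill-behaved and redundant metrics", {
  set.seed(9)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n); f3 <- rnorm(n)
  d <- data.frame(
    target = f1 + 0.3 * f2 + 0.2 * f3 + rnorm(n, 0, 0.5),
    a1 = f1 + rnorm(n, 0, 0.3), a2 = f1 + rnorm(n, 0, 0.3),
    b1 = f2 + rnorm(n, 0, 0.3), b2 = f2 + rnorm(n, 0, 0.3),
    c1 = f3 + rnorm(n, 0, 0.3),
    skewed = exp(rnorm(n)))
  out <- select_variables(d, "target")
  expect_false("skewed" %in% out$selected)
  expect_true(any(out$audit$metric == "skewed" &
                    out$audit$stage == "normality" &
                    out$audit$action == "drop"))
  # one representative per planted factor block
  expect_equal(sum(out$selected %in% c("a1", "a2")), 1)
  expect_equal(sum(out$selected %in% c("b1", "b2")), 1)

  # empty survivor set is an explicit empty result
  bad <- data.frame(target = rnorm(20), x = exp(rnorm(20, 0, 2)))
  res <- select_variables(bad, "target")
  expect_length(res$selected, 0)
})

test_that("OLS fit reports the standard regression identities", {
  # exact linear data: R = 1, zero residual error
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 3)
  m <- suppressWarnings(fit_ols(d, "y", "x")) # lm warns on a perfect fit
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_lt(m$coefficients$se[2], 1e-10)

  # single predictor: |beta| = |r| = R exactly
  set.seed(10)
  d2 <- data.frame(x = rnorm(40), e = rnorm(40))
  d2$y <- 1.5 * d2$x + d2$e
  m2 <- fit_ols(d2, "y", "x")
  r <- cor(d2$x, d2$y)
  expect_equal(m2$coefficients$beta[2], r, tolerance = 1e-12)
  expect_equal(m2$r, abs(r), tolerance = 1e-12)

  # adjusted R^2 follows the standard small-sample correction
  expect_equal(m2$adj_r2, 1 - (1 - m2$r2) * (40 - 1) / (40 - 1 - 1),
               tolerance = 1e-12)

  # rank deficiency names the collinear column
  d3 <- d2; d3$x2 <- 2 * d3$x
  expect_error(fit_ols(d3, "y", c("x", "x2")), "x2")

  # listwise deletion
  d4 <- d2; d4$x[1:3] <- NA
  expect_equal(fit_ols(d4, "y", "x")$n, 37)

  expect_error(fit_ols(d2[1:2, ], "y", "x"), "observations")
})

test_that("effect size and power follow the noncentral-F convention", {
  expect_equal(cohens_f2(0.5), 1)
  # round trip f2 <-> R
  r2 <- 0.781456
  expect_equal(cohens_f2(r2) / (1 + cohens_f2(r2)), r2, tolerance = 1e-12)

  expect_equal(posthoc_power(0, 30, 5, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  p1 <- posthoc_power(0.15, 20, 3)
  p2 <- posthoc_power(0.15, 40, 3)
  p3 <- posthoc_power(0.15, 80, 3)
  expect_true(p1 < p2 && p2 < p3)
  expect_error(posthoc_power(1, 5, 5), "exceed")
})

test_that("OLS agrees with the normal-equations oracle on random designs", {
  set.seed(11)
  for (i in 1:20) {
    X <- matrix(rnorm(30 * 5), 30, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- X %*% runif(5, -2, 2) + rnorm(30)
    d <- data.frame(y = as.numeric(y), X)
    m <- fit_ols(d, "y", paste0("x", 1:5))
    Xi <- cbind(1, X)
    oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(m$coefficients$b, as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("bootstrap validation reduces identity configs to the original fit", {
  set.seed(12)
  n <- 30
  params <- weight_normalize(data.frame(
    vj = rnorm(n, 38, 6), rm_le = rnorm(n, 55, 10), rm_lc = rnorm(n, 35, 7),
    iso_le = rnorm(n, 400, 70), iso_lc = rnorm(n, 250, 45),
    weight = rnorm(n, 66, 9)))
  std <- fit_standardizer(params)
  params$total_performance <- total_performance(params, std)
  params$speed <- 2 + 0.8 * scale(params$total_performance)[, 1] + rnorm(n, 0, 0.5)

  ident <- bootstrap_spec(noise_fraction = 0, n_repeats = 3,
                          resample = FALSE)
  bv <- bootstrap_validate(params, "speed", ident, std)
  direct <- fit_ols(params, "total_performance", "speed")
  expect_equal(bv$mean_r, direct$r, tolerance = 1e-12)
  expect_equal(bv$sd_r, 0)

  # zero-SD column refuses proportional noise
  params$flat <- 1
  noisy <- bootstrap_spec(noise_fraction = 0.1, n_repeats = 2)
  expect_error(bootstrap_validate(params, c("speed", "flat"), noisy, std),
               "flat")
})

test_that("noise attenuates the bootstrapped correlation as the closed form predicts", {
  set.seed(13)
  n <- 500
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, sqrt(1 - 0.8^2))
  d <- data.frame(x = x, y = y)
  r_hat <- abs(cor(d$x, d$y))
  q <- 0.1
  spec <- bootstrap_spec(noise_fraction = q, n_repeats = 100, seed = 2)
  bv <- bootstrap_validate(d, "x", spec, std = NULL, components = NULL,
                           target = "y")
  expect_equal(bv$mean_r, r_hat / sqrt((1 + q^2) * (1 + q^2)),
               tolerance = 0.01)
})

test_that("mean bootstrapped R is non-increasing in the noise fraction", {
  set.seed(14)
  n <- 30
  params <- weight_normalize(data.frame(
    vj = rnorm(n, 38, 6), rm_le = rnorm(n, 55, 10), rm_lc = rnorm(n, 35, 7),
    iso_le = rnorm(n, 400, 70), iso_lc = rnorm(n, 250, 45),
    weight = rnorm(n, 66, 9), age = runif(n, 23, 30),
    sex = rbinom(n, 1, 0.6)))
  std <- fit_standardizer(params)
  tp <- total_performance(params, std)
  params$speed <- 8.5 + 1.2 * tp / sd(tp) + rnorm(n, 0, 1)

  runs <- lapply(c(0.1, 0.3), function(q)
    bootstrap_validate(params, "speed",
                       bootstrap_spec(noise_fraction = q, n_repeats = 200,
                                      seed = 3), std))
  expect_lte(runs[[2]]$mean_r, runs[[1]]$mean_r)

  # demographics route: sex/age enter as predictors and the fit still works
  demo <- bootstrap_validate(params, "speed",
                             bootstrap_spec(noise_fraction = 0.1,
                                            n_repeats = 20, seed = 4,
                                            include_demographics = TRUE),
                             std)
  expect_true(is.finite(demo$mean_r))
  expect_gte(demo$mean_r, 0)
})
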