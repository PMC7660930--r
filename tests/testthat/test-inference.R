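test_that("logistic_prior is the sigmoid of the annotated linear predictor", {
  expect_equal(logistic_prior(numeric(0), 0), 0.5)
  expect_equal(logistic_prior(c(1, 1), c(0, 1, 1)), 1 / (1 + exp(-2)),
               tolerance = 1e-6)
  # monotone in any annotation with a positive coefficient
  lo <- logistic_prior(c(0.5), c(-1, 2))
  hi <- logistic_prior(c(0.8), c(-1, 2))
  expect_gt(hi, lo)
  expect_error(logistic_prior(c(1), c(0)), "length")
})

test_that("variational inclusion probabilities match exact enumeration", {
  withr::local_seed(101)
  cors <- numeric(6)
  devs <- numeric(6)
  for (r in 1:6) {
    n <- 200; p <- 7
    X <- matrix(rnorm(n * p), n, p)
    b <- numeric(p); b[sample(p, 1)] <- 1
    Y <- drop(X %*% b) + rnorm(n, sd = 0.5)
    st <- fit_single_theta(X, Y, NULL,
                           theta = list(sigma2 = 0.25, sigma_beta2 = 4,
                                        eta = 1),
                           profile_sigma2 = FALSE)
    pip <- oracle_pip(X, Y, 0.25, 4, eta = 1)
    cors[r] <- cor(st$alpha, pip)
    devs[r] <- max(abs(st$alpha - pip))
  }
  expect_true(all(cors >= 0.95))
  expect_true(all(devs <= 0.15))
})

test_that("fixed-prior fit matches two-model enumeration at p = 1", {
  withr::local_seed(7)
  X <- matrix(rnorm(200), 200, 1)
  Y <- 0.3 * X[, 1] + rnorm(200)
  st <- fit_single_theta(X, Y, NULL,
                         theta = list(sigma2 = 1, sigma_beta2 = 0.5, eta = 1),
                         profile_sigma2 = FALSE, update_omega = FALSE,
                         fixed_prior_logit = 0)
  exact <- oracle_pip(X, Y, 1, 0.5, fixed_logit = 0)
  expect_equal(st$alpha, exact, tolerance = 5e-3)
})

test_that("orthogonal phenotype keeps inclusion at or below the prior level", {
  withr::local_seed(8)
  n <- 150; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Y0 <- rnorm(n)
  Y <- drop(Y0 - Xc %*% solve(crossprod(Xc), crossprod(Xc, Y0)))
  st <- fit_single_theta(X, Y, NULL,
                         theta = list(sigma2 = 1, sigma_beta2 = 0.1, eta = 1),
                         profile_sigma2 = FALSE)
  prior_level <- 1 / (1 + exp(-st$omega_mean[1]))
  expect_true(all(st$alpha <= prior_level + 0.05))
})

test_that("pure-noise phenotype keeps mean inclusion near the fixed prior", {
  withr::local_seed(9)
  means <- replicate(60, {
    X <- matrix(rnorm(100 * 10), 100, 10)
    Y <- rnorm(100)
    st <- fit_single_theta(X, Y, NULL,
                           theta = list(sigma2 = 1, sigma_beta2 = 0.1,
                                        eta = 1),
                           profile_sigma2 = FALSE, update_omega = FALSE,
                           fixed_prior_logit = rep(log(0.1 / 0.9), 10))
    mean(st$alpha)
  })
  expect_lt(abs(mean(means) - 0.1), 0.05)
})

test_that("ELBO is non-decreasing along coordinate ascent", {
  withr::local_seed(10)
  worst <- Inf
  for (r in 1:40) {
    n <- sample(30:80, 1); p <- sample(5:30, 1)
    X <- matrix(rnorm(n * p), n, p)
    A <- matrix(rexp(p * 2), p, 2)
    b <- rnorm(p) * (runif(p) < 0.2)
    Y <- drop(X %*% b) + rnorm(n)
    st <- suppressWarnings(fit_single_theta(
      X, Y, A,
      theta = list(sigma2 = runif(1, 0.2, 2),
                   sigma_beta2 = 10^runif(1, -3, 0),
                   eta = 10^runif(1, 0, 1)),
      profile_sigma2 = (r %% 2 == 0), max_iter = 80, tol = 1e-8))
    worst <- min(worst, min(diff(st$elbo_trace)))
  }
  expect_gte(worst, -1e-8)
})

test_that("zero-annotation fit reduces exactly to the vb baseline", {
  withr::local_seed(11)
  n <- 80; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  Y <- drop(X[, 1] * 0.8) + rnorm(n)
  A0 <- matrix(0, p, 3)
  tg <- fit_grid(X, Y, A0, seed = 123)
  vb <- fit_grid(X, Y, NULL, method_tag = "vb", seed = 123)
  for (g in seq_along(tg$states)) {
    expect_equal(tg$states[[g]]$alpha, vb$states[[g]]$alpha, tolerance = 1e-6)
    expect_equal(tg$states[[g]]$mu, vb$states[[g]]$mu, tolerance = 1e-6)
  }
  expect_equal(tg$model$beta_hat, vb$model$beta_hat, tolerance = 1e-6)
  expect_equal(fit_vb_baseline(X, Y, seed = 123)$beta_hat, vb$model$beta_hat)
})

test_that("grid weights behave like a posterior over theta", {
  withr::local_seed(12)
  X <- matrix(rnorm(60 * 8), 60, 8)
  Y <- rnorm(60)
  # single-point grid: PPS is exactly that state's alpha
  cfg1 <- prior_config(theta_grid = data.frame(sigma2 = 1, sigma_beta2 = 0.1,
                                               eta = 1),
                       profile_sigma2 = FALSE)
  f1 <- fit_grid(X, Y, NULL, cfg1, method_tag = "vb")
  expect_equal(f1$model$pps, f1$states[[1]]$alpha)
  expect_equal(f1$weights, 1)
  # duplicated grid point: symmetric weights (0.5, 0.5)
  cfg2 <- prior_config(theta_grid = data.frame(sigma2 = c(1, 1),
                                               sigma_beta2 = c(0.1, 0.1),
                                               eta = c(1, 1)),
                       profile_sigma2 = FALSE)
  f2 <- fit_grid(X, Y, NULL, cfg2, method_tag = "vb")
  expect_equal(f2$weights, c(0.5, 0.5))
  expect_true(all(f2$model$pps >= 0 & f2$model$pps <= 1))
})

test_that("permuting SNPs permutes alpha, mu and pps identically", {
  withr::local_seed(13)
  n <- 70; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("s", 1:p)
  A <- matrix(rexp(p), p, 1)
  Y <- drop(X[, 3]) + rnorm(n)
  perm <- sample(p)
  cfg <- prior_config(tol = 1e-10, max_iter = 2000L)
  f1 <- fit_grid(X, Y, A, cfg, seed = 5)
  f2 <- fit_grid(X[, perm], Y, A[perm, , drop = FALSE], cfg, seed = 5)
  expect_equal(f2$model$pps, f1$model$pps[perm], tolerance = 1e-6)
  expect_equal(f2$model$beta_hat, f1$model$beta_hat[perm], tolerance = 1e-6)
})

test_that("rescaling Y with a matched theta grid rescales mu and not alpha", {
  withr::local_seed(14)
  n <- 60; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  Y <- drop(X[, 2] * 0.5) + rnorm(n)
  cc <- 3
  st1 <- fit_single_theta(X, Y, NULL,
                          theta = list(sigma2 = 1, sigma_beta2 = 0.2, eta = 1),
                          profile_sigma2 = FALSE, tol = 1e-8)
  st2 <- fit_single_theta(X, cc * Y, NULL,
                          theta = list(sigma2 = cc^2, sigma_beta2 = 0.2,
                                       eta = 1),
                          profile_sigma2 = FALSE, tol = 1e-8)
  expect_equal(st2$alpha, st1$alpha, tolerance = 1e-5)
  expect_equal(st2$mu, cc * st1$mu, tolerance = 1e-5)
})

test_that("non-finite input and non-convergence are surfaced", {
  X <- matrix(c(1, -1, 2, NA), 2, 2)
  expect_error(fit_single_theta(X, c(0, 1), NULL,
                                theta = list(sigma2 = 1, sigma_beta2 = 1,
                                             eta = 1)),
               "non-finite")
  withr::local_seed(15)
  X <- matrix(rnorm(40 * 10), 40, 10)
  Y <- rnorm(40)
  expect_warning(st <- fit_single_theta(X, Y, NULL,
                                        theta = list(sigma2 = 1,
                                                     sigma_beta2 = 0.1,
                                                     eta = 1),
                                        max_iter = 2L, tol = 1e-12),
                 "converge")
  expect_false(st$converged)
})

test_that("predict_expression applies centered dosages times beta_hat", {
  panel <- make_panel(n = 30, p = 5, seed = 16)
  snps <- panel$snps
  snps$train_mean <- colMeans(panel$dosages)
  beta <- c(2, 0, 0, 0, 0)
  m <- tgen:::new_tgen_model("g", "t", snps, beta, pps = rep(1, 5),
                             omega_hat = numeric(0), method_tag = "vb")
  pred <- predict_expression(m, panel)
  x <- panel$dosages[, 1]
  expect_equal(pred, unname(2 * (x - mean(x))))
  # zero beta -> zero vector
  m0 <- tgen:::new_tgen_model("g", "t", snps, rep(0, 5), rep(0, 5),
                              numeric(0), "vb")
  expect_equal(predict_expression(m0, panel), rep(0, 30))
  # independent matrix-product check on a random model
  withr::local_seed(17)
  beta_r <- rnorm(5)
  mr <- tgen:::new_tgen_model("g", "t", snps, beta_r, rep(0.5, 5),
                              numeric(0), "vb")
  manual <- unname(drop(sweep(panel$dosages, 2, snps$train_mean) %*% beta_r))
  expect_equal(predict_expression(mr, panel), manual, tolerance = 1e-12)
  # missing SNPs contribute zero with a warning
  sub <- tgen:::panel_subset(panel, 2:5)
  expect_warning(pm <- predict_expression(mr, sub), "absent")
  manual2 <- unname(drop(sweep(sub$dosages, 2, snps$train_mean[2:5]) %*%
                           beta_r[2:5]))
  expect_equal(pm, manual2)
})
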