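test_that("alignment pairs by nearest time within tolerance", {
  f <- structure(data.frame(t = as.numeric(1:20), p2p1 = runif(20, 0.4, 1.2),
                            hr = runif(20, 60, 90), slope = rnorm(20)),
                 class = c("feature_samples", "data.frame"))
  ref <- reference_bp(t = as.numeric(1:20), map = 80 + (1:20))
  ds <- align_series(f, ref)
  expect_equal(nrow(ds), 20)
  expect_equal(ds$y, 80 + (1:20))

  ref_off <- reference_bp(t = as.numeric(1:20) + 50, map = 80 + (1:20))
  expect_error(align_series(f, ref_off, tolerance = 2), "do not overlap")

  # jittered reference: matches a brute-force nearest-neighbor search
  set.seed(5)
  ref_j <- reference_bp(t = sort(1:20 + runif(20, -0.5, 0.5)), map = 80 + (1:20))
  ds_j <- align_series(f, ref_j, tolerance = 2)
  brute <- vapply(f$t, function(ti) ref_j$map[which.min(abs(ref_j$t - ti))], 0)
  expect_equal(ds_j$y, brute)
})

test_that("the maximum-variability window is selected with an earliest-window tie-break", {
  t <- seq(0, 3600, by = 2)
  y <- rep(90, length(t))
  swing <- t >= 1500 & t < 2700
  y[swing] <- 90 + 20 * sin(2 * pi * (t[swing] - 1500) / 600)
  ds <- structure(data.frame(t = t, p2p1 = 0.7, hr = 75, slope = 0, y = y),
                  class = c("aligned_dataset", "data.frame"))
  sp <- select_training_segment(ds, length = 1200, step = 60, buffer = 60)
  expect_gte(sp$window[1], 1440)
  expect_lte(sp$window[1], 1560)
  # train and test never overlap and are separated by the buffer
  expect_false(any(sp$train & sp$test))
  expect_gte(min(abs(t[sp$train][1] - t[sp$test])), 60)

  ds$y <- rep(90, length(t))
  sp2 <- select_training_segment(ds, 1200, 60, 60)
  expect_equal(sp2$window[1], 0)

  expect_error(select_training_segment(ds[ds$t < 1000, ], 1200, 60, 60),
               "shorter training window")
})

test_that("the linear fit exactly recovers printed generating coefficient triples", {
  triples <- list(c(epsilon = -67, a = 137.10, b = 1.16),
                  c(epsilon = -179.47, a = 143.16, b = 2.52))
  for (cf in triples) {
    set.seed(31)
    n <- 500
    ds <- structure(data.frame(t = 1:n, p2p1 = runif(n, 0.4, 1.3),
                               hr = runif(n, 50, 100), slope = rnorm(n)),
                    class = c("aligned_dataset", "data.frame"))
    ds$y <- cf[["epsilon"]] + cf[["a"]] * ds$p2p1 + cf[["b"]] * ds$hr
    fit <- fit_linear(ds)
    expect_equal(unname(fit$coefficients), unname(cf), tolerance = 1e-6)
    expect_equal(fit$r2_train, 1, tolerance = 1e-9)
  }
})

test_that("degenerate linear targets and designs are handled explicitly", {
  ds <- structure(data.frame(t = 1:50, p2p1 = runif(50, 0.4, 1.3),
                             hr = runif(50, 50, 100), slope = 0, y = 87),
                  class = c("aligned_dataset", "data.frame"))
  fit <- fit_linear(ds)
  expect_equal(unname(fit$coefficients), c(87, 0, 0), tolerance = 1e-9)

  ds2 <- ds
  ds2$hr <- 2 * ds2$p2p1   # collinear with p2p1
  expect_error(fit_linear(ds2), "collinear")
  expect_error(fit_linear(ds[1:5, ]), "at least 10")
})

test_that("coefficient standard errors match the independent least-squares oracle", {
  set.seed(12)
  n <- 12
  x1 <- runif(n, 0.4, 1.3); x2 <- runif(n, 50, 100)
  y <- -60 + 120 * x1 + 1.5 * x2 + rnorm(n, 0, 3)
  ds <- structure(data.frame(t = 1:n, p2p1 = x1, hr = x2, slope = 0, y = y),
                  class = c("aligned_dataset", "data.frame"))
  fit <- fit_linear(ds)
  oracle <- summary(lm(y ~ x1 + x2))
  expect_equal(unname(fit$coefficients), unname(coef(oracle)[, 1]),
               tolerance = 1e-9)
  expect_equal(unname(fit$se), unname(coef(oracle)[, 2]), tolerance = 1e-9)
  expect_equal(unname(fit$p), unname(coef(oracle)[, 4]), tolerance = 1e-9)
  expect_equal(fit$residual_var, oracle$sigma^2, tolerance = 1e-9)

  # zero residuals give zero standard errors
  ds$y <- -60 + 120 * ds$p2p1 + 1.5 * ds$hr
  fit0 <- fit_linear(ds)
  expect_equal(unname(fit0$se), c(0, 0, 0), tolerance = 1e-6)

  # doubling the residual magnitudes doubles every standard error
  X <- cbind(1, x1, x2)
  r <- residuals(lm(y ~ x1 + x2))
  se1 <- coefficient_standard_errors(X, r)$se
  se2 <- coefficient_standard_errors(X, 2 * r)$se
  expect_equal(se2, 2 * se1, tolerance = 1e-12)
})

test_that("linear predictions reproduce hand arithmetic", {
  fit <- structure(list(coefficients = c(epsilon = -67, a = 137.10, b = 1.16),
                        features = c("p2p1", "hr")),
                   class = "nirsbp_linear")
  p <- predict(fit, data.frame(t = 0, p2p1 = 0.8, hr = 60))
  expect_equal(p$y_hat, 112.28, tolerance = 1e-12)
  expect_error(predict(fit, data.frame(t = 0, p2p1 = 0.8)), "missing feature")
})

test_that("GPR reaches near-perfect held-out accuracy on an exactly linear surface", {
  ds <- simulate_feature_dataset(n = 600, nonlin_amp = 0, noise_sd = 0.01,
                                 seed = 21)
  cfg <- default_config(); cfg$seed <- 21L
  train <- seq_len(nrow(ds)) <= 400
  g <- fit_gpr(ds, 2, cfg, rows = train)
  te <- ds[!train, ]
  p <- predict(g, te)
  r2 <- 1 - sum((p$y_hat - te$y)^2) / sum((te$y - mean(te$y))^2)
  expect_gte(r2, 0.99)
  # near-noiseless fit interpolates its own training targets
  ptr <- predict(g, ds[train, ])
  expect_lt(max(abs(ptr$y_hat - ds$y[train])), 0.1)
})

test_that("GPR handles a constant target and saturates its posterior variance far away", {
  ds <- structure(data.frame(t = 1:60, p2p1 = runif(60, 0.4, 1.3),
                             hr = runif(60, 50, 100), slope = rnorm(60), y = 92),
                  class = c("aligned_dataset", "data.frame"))
  g <- fit_gpr(ds, 2, default_config())
  p <- predict(g, ds)
  expect_equal(p$y_hat, rep(92, 60), tolerance = 1e-6)
  expect_true(all(p$posterior_sd <= sqrt(g$noise_var) + 1e-6))

  ds2 <- simulate_feature_dataset(n = 200, nonlin_amp = 0, noise_sd = 1, seed = 4)
  g2 <- fit_gpr(ds2, 2, default_config(), rows = seq_len(nrow(ds2)) <= 100)
  far <- data.frame(t = 0, p2p1 = 50, hr = 10000, slope = 0)
  pf <- predict(g2, far)
  expect_equal(pf$posterior_sd, sqrt(g2$signal_var + g2$noise_var),
               tolerance = 1e-6)
  # and the posterior mean reverts to the training mean
  expect_equal(pf$y_hat, g2$y0, tolerance = 1e-6)

  expect_error(fit_gpr(ds2, 4), "must be 2 or 3")
  expect_error(fit_gpr(ds2[1:20, ], 2, default_config()), "at least 50")
})
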