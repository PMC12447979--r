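test_that("the first derivative is exact on ramps and accurate on tones", {
  fs <- 266
  t <- (0:999) / fs
  expect_equal(first_derivative(3.2 * t, fs), rep(3.2, 1000), tolerance = 1e-9)
  expect_equal(first_derivative(rep(5, 100), fs), rep(0, 100))
  d <- first_derivative(sin(2 * pi * t), fs)
  truth <- 2 * pi * cos(2 * pi * t)
  interior <- 3:997
  expect_lt(sqrt(mean((d - truth)[interior]^2)) / sqrt(mean(truth[interior]^2)),
            0.01)
  expect_error(first_derivative(1:4, fs), "at least 5")
})

test_that("the Gaussian-sum model matches term-by-term evaluation", {
  set.seed(10)
  x <- seq(0, 1, length.out = 200)
  cmp <- data.frame(amp = runif(4, 0.2, 1.5), mu = sort(runif(4, 0.1, 0.9)),
                    sigma = runif(4, 0.02, 0.1))
  f <- evaluate_gaussian_sum(cmp, x)
  manual <- Reduce(`+`, lapply(1:4, function(i) {
    cmp$amp[i] * exp(-(x - cmp$mu[i])^2 / (2 * cmp$sigma[i]^2))
  }))
  expect_equal(f, manual, tolerance = 1e-12)
  expect_equal(evaluate_gaussian_sum(data.frame(amp = rep(0, 4),
                                                mu = c(0.1, 0.3, 0.5, 0.7),
                                                sigma = rep(0.05, 4)), x),
               rep(0, 200))
  # at a mean with all other components >= 10 sigma away the model is ~ A
  far <- data.frame(amp = c(0.8, 0.5, 0.4, 0.3), mu = c(1, 3, 5, 7),
                    sigma = rep(0.05, 4))
  expect_equal(evaluate_gaussian_sum(far, 1), 0.8, tolerance = 1e-6)
  expect_error(gaussian_sum(1, 0.5, -0.1, x), "positive")
})

test_that("the four-Gaussian fit recovers known parameters on a noiseless pulse", {
  m <- ref_morphology()
  tg <- seq(0, 0.76, length.out = 150)
  d <- gaussian_sum(m$amps, m$mus, m$sigmas, tg)
  dec <- fit_four_gaussians(d, tg, seed = 1)
  expect_true(dec$converged)
  expect_equal(dec$components$amp, m$amps, tolerance = 0.05)
  expect_equal(dec$components$mu, m$mus, tolerance = 0.05)
  expect_equal(dec$components$sigma, m$sigmas, tolerance = 0.05)
  expect_true(all(diff(dec$components$mu) > 0))
  expect_lte(dec$sse, dec$sse_single)

  expect_error(fit_four_gaussians(rep(0, 100), seq(0, 1, length.out = 100)),
               "flat")
})

test_that("fitted means are strictly increasing across random convergent fits", {
  set.seed(99)
  for (k in 1:10) {
    amps <- runif(4, 0.3, 1.2)
    mus <- sort(runif(4, 0.05, 0.75))
    sigs <- runif(4, 0.02, 0.06)
    tg <- seq(0, 0.8, length.out = 150)
    d <- gaussian_sum(amps, mus, sigs, tg) + rnorm(150, 0, 0.01)
    dec <- tryCatch(fit_four_gaussians(d, tg, seed = k), error = function(e) NULL)
    if (!is.null(dec)) expect_true(all(diff(dec$components$mu) > 0))
  }
})

test_that("peak labeling orders the fiducials and uses full-model values", {
  cmp <- data.frame(amp = c(1, 0.6, 0.3, 0.2), mu = c(0.1, 0.3, 0.5, 0.7),
                    sigma = rep(0.03, 4))
  dec <- structure(list(components = cmp, baseline = 0, sse = 0,
                        sse_single = 1, converged = TRUE, n_iter = 1),
                   class = "gaussian_decomposition")
  pk <- label_peaks(dec)
  expect_equal(unname(pk$p1["time"]), 0.1)
  expect_equal(unname(pk$p2["time"]), 0.3)
  # well separated: values at the means are close to the raw amplitudes
  expect_equal(unname(pk$p1["value"]), 1, tolerance = 0.01)
  expect_equal(unname(pk$p2["value"]), 0.6, tolerance = 0.01)
  expect_lt(pk$p1["time"], pk$p2["time"])
  # a dicrotic notch exists between the separated second and third components
  expect_false(is.null(pk$dn))
  expect_gt(pk$dn, 0.3)
  expect_lt(pk$dn, 0.5)

  # heavily overlapping components: model monotone between means, notch absent
  cmp2 <- data.frame(amp = c(1, 0.6, 0.59, 0.2), mu = c(0.1, 0.3, 0.33, 0.7),
                     sigma = c(0.03, 0.1, 0.1, 0.05))
  dec2 <- dec; dec2$components <- cmp2
  expect_silent(pk2 <- label_peaks(dec2))
  expect_null(pk2$dn)

  dec$converged <- FALSE
  expect_error(label_peaks(dec), "converged")
})

test_that("heart rate is 60 over the mean inter-beat interval", {
  expect_equal(heart_rate(c(0, 0.75, 1.5, 2.25)), 80)
  expect_equal(heart_rate(0:3), 60)
  expect_equal(heart_rate(c(0, 0.5)), 120)
  expect_error(heart_rate(1), "at least 2")
  expect_error(heart_rate(c(1, 1)), "strictly increasing")
})

test_that("features from a noiseless constant-ratio train recover the ground truth", {
  fx <- noiseless_features()
  feats <- fx$features
  expect_gt(nrow(feats), 50)
  # generator ratio is 0.5 for every beat
  expect_equal(mean(feats$p2p1), 0.5, tolerance = 0.01)
  expect_true(all(abs(feats$p2p1 - 0.5) / 0.5 <= 0.02))
  gt_hr <- fx$sim$truth$hr[1]
  expect_true(all(abs(feats$hr - gt_hr) <= 1))
})

test_that("P2/P1 and heart rate are invariant to waveform amplitude scaling", {
  fx <- noiseless_features()
  ens <- fx$ensembles
  small <- ens
  small$waveform <- ens$waveform[1:5, , drop = FALSE]
  small$meta <- ens$meta[1:5, ]
  small$member_onsets <- ens$member_onsets[1:5]
  scaled <- small
  scaled$waveform <- 3.7 * small$waveform
  cfg <- default_config()
  f1 <- extract_features(small, cfg)
  f2 <- extract_features(scaled, cfg)
  expect_equal(f2$p2p1, f1$p2p1, tolerance = 1e-6)
  expect_equal(f2$hr, f1$hr)
  # the slope scales with the waveform
  expect_equal(f2$slope, 3.7 * f1$slope, tolerance = 1e-4)
})
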