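test_that("a single-component beat rises monotonically with its derivative peak at the mean", {
  p <- simulate_pulse(c(1, 0, 0, 0), c(0.15, 0.3, 0.5, 0.7),
                      c(0.03, 0.05, 0.06, 0.07), beat_length = 0.8)
  expect_true(all(diff(p$waveform) >= -1e-12))
  expect_equal(p$t[which.max(p$velocity)], 0.15, tolerance = 1 / 266)
  # plateau after the component has passed
  late <- p$waveform[p$t > 0.4]
  expect_lt(diff(range(late)), 1e-6 * max(p$waveform))

  flat <- simulate_pulse(c(0, 0, 0, 0), c(0.15, 0.3, 0.5, 0.7),
                         c(0.03, 0.05, 0.06, 0.07), beat_length = 0.8)
  expect_equal(flat$waveform, rep(0, length(flat$waveform)))
  expect_error(simulate_pulse(c(1, 0, 0, 0), c(0.9, 1, 1.1, 1.2),
                              rep(0.05, 4), beat_length = 0.8), "within")
})

test_that("the numerical derivative of a simulated beat matches the analytic Gaussian sum", {
  m <- ref_morphology()
  p <- simulate_pulse(m$amps, m$mus, m$sigmas, beat_length = 0.8, fs = 266)
  d_num <- first_derivative(p$waveform, 266)
  d_true <- gaussian_sum(m$amps, m$mus, m$sigmas, p$t)
  interior <- 3:(length(d_num) - 2)
  rel_rms <- sqrt(mean((d_num[interior] - d_true[interior])^2)) /
    sqrt(mean(d_true[interior]^2))
  expect_lt(rel_rms, 1e-3)
})

test_that("the pressure mapping reproduces hand arithmetic and is monotone in the ratio", {
  # patient-level generating triple: -67 + 137.10 * 0.8 + 1.16 * 60
  expect_equal(map_features_to_map(0.8, 60, c(-67, 137.10, 1.16)), 112.28,
               tolerance = 1e-12)
  # zero slopes: pressure is the intercept everywhere
  expect_equal(map_features_to_map(c(0.4, 0.9, 1.3), c(50, 75, 100), c(88, 0, 0)),
               rep(88, 3))
  # doubling the ratio with a positive slope strictly increases pressure
  lo <- map_features_to_map(0.5, 70, c(-67, 137.10, 1.16))
  hi <- map_features_to_map(1.0, 70, c(-67, 137.10, 1.16))
  expect_gt(hi, lo)
  expect_error(map_features_to_map(0.8, 200, c(-67, 137.10, 1.16)), "heart rate")
})

test_that("a constant-rate train produces the expected beat count and is seed-reproducible", {
  spec <- simulation_spec(duration = 300, hr = 80, ratio = 0.7,
                          noise = list(optical = 2, resp = 0.002,
                                       mayer = 0.001, acc = 0.02), seed = 3)
  sim <- simulate_pulse_train(spec)
  expect_gte(nrow(sim$truth), 398)
  expect_lte(nrow(sim$truth), 402)
  expect_equal(sim$truth$ratio, rep(0.7, nrow(sim$truth)), tolerance = 1e-12)
  expect_true(all(sim$reference$map > 0 & sim$reference$map < 300))

  sim2 <- simulate_pulse_train(spec)
  expect_identical(sim$recording$intensity, sim2$recording$intensity)
  expect_identical(sim$truth, sim2$truth)
})

test_that("infeasible trajectories are rejected", {
  expect_error(
    simulate_pulse_train(simulation_spec(duration = 60, hr = c(150, 200),
                                         ratio = 0.7)),
    "\\[30, 180\\]")
  expect_error(simulation_spec(duration = 30), "60 s")
  expect_error(
    simulation_spec(morphology = list(mu_frac = c(0.3, 0.2, 0.5, 0.7),
                                      sigma_frac = rep(0.05, 4),
                                      amps = c(1, 0.3, 0.15))),
    "strictly increasing")
})

test_that("artifact injection corrupts only the scheduled intervals", {
  sim <- noiseless_sim()
  rec <- sim$recording
  expect_identical(inject_artifacts(rec, list()), rec)

  rec2 <- inject_artifacts(rec, list(c(100, 105)), seed = 1)
  t <- rec$t
  inside <- t >= 100 & t < 105
  outside <- !inside
  rms <- function(v) sqrt(mean(v^2))
  acc_mag2 <- sqrt(rowSums(rec2$acc^2))
  expect_gt(rms(acc_mag2[inside]), 5 * rms(acc_mag2[outside]))
  expect_equal(rec2$intensity[outside, 1], rec$intensity[outside, 1])
  expect_equal(rec2$ambient[outside], rec$ambient[outside])
  expect_gt(mean(rec2$ambient[inside]) - mean(rec$ambient[inside]), 1000)

  expect_error(inject_artifacts(rec, list(c(500, 505))), "outside")
  expect_error(inject_artifacts(rec, list(c(10, 20), c(15, 25))), "disjoint")
})
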