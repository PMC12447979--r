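test_that("moving-median detrending removes slow trends and keeps pulsatile content", {
  fs <- 100
  expect_equal(detrend_baseline(rep(3, 1000), fs), rep(0, 1000))
  # slow ramp over 300 s: residual well below the ramp range
  t <- seq(0, 300, by = 1 / fs)
  ramp <- 0.02 * t
  expect_lt(sqrt(mean(detrend_baseline(ramp, fs)^2)), 0.05 * diff(range(ramp)))
  # 1 Hz tone preserved
  s <- sin(2 * pi * t)
  out <- detrend_baseline(s, fs)
  expect_gt(sqrt(mean(out^2)), 0.95 * sqrt(mean(s^2)))
})

test_that("beat segmentation recovers the simulated beat count with increasing onsets", {
  spec <- simulation_spec(duration = 62, hr = 60, ratio = 0.6,
                          noise = list(optical = 0, resp = 0, mayer = 0,
                                       acc = 0.002), seed = 2)
  sim <- simulate_pulse_train(spec)
  clean <- preprocess_recording(sim$recording)
  pulses <- segment_pulses(clean)
  # 60 s of interior beats at 60 bpm (boundary beats are not fully bracketed)
  expect_gte(nrow(pulses$table), 58)
  expect_lte(nrow(pulses$table), 61)
  expect_true(all(diff(pulses$table$onset) > 0))
  expect_true(all(pulses$table$end > pulses$table$onset))
  # non-overlap: each pulse ends where the next starts
  expect_equal(pulses$table$onset[-1],
               pulses$table$end[-nrow(pulses$table)])
})

test_that("segmentation fails cleanly on pulseless input", {
  flat <- structure(list(t = (0:999) / 266, value = rep(0, 1000), fs = 266,
                         mask = structure(data.frame(start = numeric(0),
                                                     end = numeric(0)),
                                          class = c("artifact_mask", "data.frame")),
                         masked = logical(1000), i0 = 1),
                    class = "clean_signal")
  expect_error(segment_pulses(flat), "no pulses")
})

test_that("shape scores are 1 for identical pulses and lowest for an inverted one", {
  tpl <- beat_template()
  ps <- make_pulse_set(rep(list(tpl), 30))
  sc <- shape_similarity_scores(ps, seq_len(nrow(ps$table)))
  expect_equal(sc, rep(1, length(sc)), tolerance = 1e-9)

  pulses <- rep(list(tpl), 30)
  pulses[[15]] <- max(tpl) - tpl
  ps2 <- make_pulse_set(pulses)
  sc2 <- shape_similarity_scores(ps2, seq_len(nrow(ps2$table)))
  expect_equal(which.min(sc2), 15)
  expect_true(all(sc2 >= -1 & sc2 <= 1))
  expect_error(shape_similarity_scores(ps2, 1:10, window = 20), "at least 20")
})

test_that("duration outliers at both extremes are rejected by the percentile rule", {
  tpl <- beat_template(0.6)
  pulses <- rep(list(tpl), 100)
  pulses[[40]] <- beat_template(0.2)   # unusually short
  pulses[[70]] <- beat_template(2.0)   # unusually long
  ps <- make_pulse_set(pulses)
  out <- reject_outlier_pulses(ps)
  expect_true(grepl("duration_outlier", out$table$flags[40]))
  expect_true(grepl("duration_outlier", out$table$flags[70]))
  expect_false(out$table$retained[40])
  expect_false(out$table$retained[70])
})

test_that("identical pulses are fully retained and (0,100) thresholds reject nothing", {
  tpl <- beat_template()
  ps <- make_pulse_set(rep(list(tpl), 40))
  # identical beats: neutralize moving-median edge effects on the amplitude
  # statistic so the degenerate-percentile tie handling is what is tested
  ps$table$amplitude <- 1
  out <- reject_outlier_pulses(ps)
  expect_true(all(out$table$retained))

  pulses <- lapply(1:40, function(i) beat_template(0.6 + 0.002 * i))
  ps2 <- make_pulse_set(pulses)
  cfg <- default_config()
  cfg$duration_percentiles <- c(0, 100)
  cfg$amplitude_percentiles <- c(0, 100)
  cfg$shape_percentiles <- c(0, 100)
  out2 <- reject_outlier_pulses(ps2, cfg)
  expect_true(all(out2$table$retained))
})

test_that("quality control never increases the pulse count and flags every rejection", {
  fx <- noiseless_features()
  tab <- fx$pulses$table
  expect_lte(sum(tab$retained), nrow(tab))
  rejected <- !tab$retained
  expect_true(all(nzchar(tab$flags[rejected])))
})

test_that("ensemble windows advance by half their width with the documented count", {
  tpl <- beat_template()
  ps8 <- make_pulse_set(rep(list(tpl), 9))   # 8 full pulses bracketed
  ps8$table <- ps8$table[1:8, ]
  ens <- ensemble_average(ps8, k = 4, overlap = 0.5)
  expect_equal(nrow(ens$waveform), 3)
  expect_equal(ens$member_onsets[[2]], ps8$table$onset[3:6])
  expect_equal(ens$member_onsets[[3]], ps8$table$onset[5:8])

  ps4 <- ps8; ps4$table <- ps8$table[1:4, ]
  expect_equal(nrow(ensemble_average(ps4, 4, 0.5)$waveform), 1)
  ps3 <- ps8; ps3$table <- ps8$table[1:3, ]
  expect_error(ensemble_average(ps3, 4, 0.5), "at least 4")
})

test_that("injected corrupt beats are all flagged on a 200-beat train", {
  tpl <- beat_template(0.75)
  pulses <- rep(list(tpl), 200)
  corrupt <- c(30, 60, 90, 120, 150, 180)
  pulses[[30]] <- beat_template(1.5)            # double duration
  pulses[[60]] <- beat_template(0.35)           # half duration
  pulses[[90]] <- 5 * tpl                       # 5x amplitude
  pulses[[120]] <- 0.1 * tpl                    # collapsed amplitude
  pulses[[150]] <- max(tpl) - tpl               # inverted shape
  pulses[[180]] <- rev(tpl)                     # reversed shape
  ps <- make_pulse_set(pulses)
  out <- reject_outlier_pulses(ps)
  for (i in corrupt) {
    expect_false(out$table$retained[i])
    expect_true(nzchar(out$table$flags[i]))
  }
})
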