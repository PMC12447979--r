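# Synthetic FlexNIRS-like recordings with known per-beat morphology, heart
# rate and mean-arterial-pressure trajectories, so that every downstream
# stage of the pipeline has an exact recovery oracle.
#
# The beat's velocity (first time derivative of the pulsatile waveform) is
# modeled directly as a sum of four Gaussians and integrated in closed form,
# which makes the feature extractor's decomposition model exactly realizable.

#' Specification for a synthetic recording
#'
#' Trajectories (`hr`, `ratio`) may be given as a scalar (constant), a
#' length-2 vector (linear ramp over the recording), or a function of time in
#' seconds.  Morphology is expressed in beat-fraction units and rescaled to
#' each beat's length; the amplitude of the second component is solved per
#' beat so that the ratio of the fitted-model values at the first two
#' component means equals the target P2/P1 ratio exactly.
#'
#' @param duration recording length in seconds (at least 60).
#' @param fs sampling rate in Hz.
#' @param hr heart-rate trajectory in bpm (30--180).
#' @param ratio target P2/P1 ratio trajectory.
#' @param morphology list with `mu_frac`, `sigma_frac` (length 4, beat
#'   fractions, means strictly increasing) and `amps` (amplitudes of
#'   components 1, 3, 4; component 2 is solved from `ratio`).
#' @param map_coeffs named vector `c(epsilon, a, b)`: intercept (mmHg), P2/P1
#'   slope (mmHg per unit ratio) and HR slope (mmHg per bpm) of the linear
#'   pressure mapping.
#' @param nonlin_amp amplitude (mmHg) of a smooth bounded nonlinear
#'   perturbation added to the linear pressure mapping (default 0).
#' @param noise list of noise/drift amplitudes: `optical` (counts SD),
#'   `resp` and `mayer` (optical-density drift amplitudes), `acc` (g SD).
#' @param od_gain optical-density excursion per unit of the integrated
#'   unit-amplitude waveform.
#' @param i0 baseline detected intensity in counts.
#' @param ambient ambient-light level in counts.
#' @param artifacts list of `c(start, end)` intervals for injected motion /
#'   ambient artifacts (see [inject_artifacts()]).
#' @param seed integer seed driving all randomness.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(duration = 5400, fs = 266,
                            hr = function(t) 75 + 8 * sin(2 * pi * t / 400),
                            ratio = function(t) 0.65 + 0.15 * sin(2 * pi * t / 600 + 1),
                            morphology = list(
                              mu_frac    = c(0.125, 0.3125, 0.5625, 0.75),
                              sigma_frac = c(0.0375, 0.0625, 0.075, 0.0875),
                              amps       = c(1, 0.3, 0.15)),
                            map_coeffs = c(epsilon = -67, a = 137.10, b = 1.16),
                            nonlin_amp = 0,
                            noise = list(optical = 8, resp = 0.004,
                                         mayer = 0.002, acc = 0.02),
                            od_gain = 0.15, i0 = 20000, ambient = 1000,
                            artifacts = list(), seed = 1L) {
  if (duration < 60) stop("duration must be at least 60 s")
  m <- morphology
  if (any(diff(m$mu_frac) <= 0)) stop("morphology means must be strictly increasing")
  if (any(m$sigma_frac <= 0)) stop("morphology standard deviations must be positive")
  spec <- list(duration = duration, fs = fs,
               hr = .as_trajectory(hr, duration),
               ratio = .as_trajectory(ratio, duration),
               morphology = m, map_coeffs = map_coeffs,
               nonlin_amp = nonlin_amp, noise = noise, od_gain = od_gain,
               i0 = i0, ambient = ambient, artifacts = artifacts,
               seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  spec
}

.as_trajectory <- function(x, duration) {
  if (is.function(x)) return(x)
  if (length(x) == 1) return(function(t) rep(x, length(t)))
  if (length(x) == 2) return(function(t) x[1] + (x[2] - x[1]) * t / duration)
  stop("trajectory must be a scalar, a length-2 ramp, or a function of time")
}

#' Evaluate a sum-of-Gaussians velocity model
#'
#' @param amps,mus,sigmas component amplitudes, means (s) and standard
#'   deviations (s); equal lengths, `sigmas > 0`.
#' @param x evaluation grid in seconds.
#' @return numeric vector of the same length as `x`.
#' @export
gaussian_sum <- function(amps, mus, sigmas, x) {
  if (any(sigmas <= 0)) stop("Gaussian standard deviations must be positive")
  out <- numeric(length(x))
  for (i in seq_along(amps)) {
    out <- out + amps[i] * exp(-(x - mus[i])^2 / (2 * sigmas[i]^2))
  }
  out
}

#' Simulate a single beat waveform
#'
#' The beat waveform is the cumulative integral (closed form, via the normal
#' CDF) of the four-Gaussian velocity curve, starting at 0, sampled at `fs`.
#'
#' @param amps,mus,sigmas Gaussian parameters (length 4; seconds for
#'   `mus`/`sigmas`).
#' @param beat_length beat duration in seconds.
#' @param fs sampling rate in Hz.
#' @return list with `t`, `waveform`, and the analytic `velocity` on the same
#'   grid.
#' @export
simulate_pulse <- function(amps, mus, sigmas, beat_length, fs = 266) {
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  if (any(mus < 0 | mus >= beat_length)) {
    stop("Gaussian means must lie within [0, beat_length)")
  }
  n <- max(2L, round(beat_length * fs))
  t <- (seq_len(n) - 1L) / fs
  w <- numeric(n)
  for (i in seq_along(amps)) {
    w <- w + amps[i] * sigmas[i] * sqrt(2 * pi) *
      (stats::pnorm((t - mus[i]) / sigmas[i]) - stats::pnorm(-mus[i] / sigmas[i]))
  }
  list(t = t, waveform = w, velocity = gaussian_sum(amps, mus, sigmas, t))
}

#' Map waveform features to mean arterial pressure
#'
#' The linear pressure model `epsilon + a * ratio + b * hr`, optionally
#' perturbed by a smooth bounded nonlinear term of amplitude `nonlin_amp`
#' mmHg (used to exercise the nonlinear calibration models).
#'
#' @param r P2/P1 ratio (positive).
#' @param hr heart rate in bpm (30--180).
#' @param coeffs named vector `c(epsilon, a, b)`.
#' @param nonlin_amp nonlinearity amplitude in mmHg.
#' @return pressure in mmHg.
#' @export
map_features_to_map <- function(r, hr, coeffs, nonlin_amp = 0) {
  if (any(r <= 0)) stop("ratio must be positive")
  if (any(hr < 30 | hr > 180)) stop("heart rate outside [30, 180] bpm")
  y <- coeffs[[1]] + coeffs[[2]] * r + coeffs[[3]] * hr
  if (nonlin_amp != 0) {
    # curvature-dominant perturbation: even in both features about the
    # center of the simulated operating range, so a plane cannot absorb it
    y <- y + nonlin_amp * cos(2 * pi * (r - 0.65) / 0.6) *
      cos(2 * pi * (hr - 75) / 40)
  }
  unname(y)
}

# Solve the amplitude of component 2 so that the model value at mu2 is
# exactly `r` times the model value at mu1, accounting for component overlap.
.solve_a2 <- function(r, amps134, mus, sigmas) {
  a <- c(amps134[1], NA, amps134[2], amps134[3])
  e <- function(i, j) exp(-(mus[i] - mus[j])^2 / (2 * sigmas[j]^2))
  oth <- c(1, 3, 4)
  num <- r * sum(a[oth] * vapply(oth, function(j) e(1, j), 0)) -
    sum(a[oth] * vapply(oth, function(j) e(2, j), 0))
  den <- 1 - r * e(1, 2)
  a2 <- num / den
  if (!is.finite(a2) || a2 <= 0) {
    stop("infeasible target P2/P1 ratio ", signif(r, 4),
         " for the given morphology (solved A2 = ", signif(a2, 4), ")")
  }
  a2
}

#' Simulate a full NIRS-PPG pulse train with ground truth
#'
#' Concatenates beats whose inter-beat interval follows the heart-rate
#' trajectory; converts the pulsatile optical-density signal to detected
#' intensity (`i0 * exp(-OD)`, so intensity decreases at systole), adds
#' respiration and Mayer-wave baseline drifts, white optical noise and the
#' ambient-light offset; builds the beat-wise reference pressure via
#' [map_features_to_map()]; and records per-beat ground truth.  Within each
#' beat, the integrated waveform is linearly detrended to its net beat
#' excursion so that blood volume stays bounded across beats (the outflow
#' balancing inflow); this leaves the beat velocity equal to the Gaussian sum
#' minus a beat-wise constant.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `recording` ([raw_recording()]), `reference`
#'   ([reference_bp()]) and `truth` (a data frame of class `ground_truth`
#'   with per-beat onset, duration, hr, ratio, slope and map, plus the
#'   artifact schedule as an attribute).
#' @export
simulate_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, .simulate_pulse_train_impl(spec))
}

.simulate_pulse_train_impl <- function(spec) {
  fs <- spec$fs
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  m <- spec$morphology

  # beat onsets from the HR trajectory
  onsets <- numeric(0)
  cur <- 0
  while (cur < spec$duration) {
    hr_b <- spec$hr(cur)
    if (hr_b < 30 || hr_b > 180) {
      stop("heart-rate trajectory leaves [30, 180] bpm at t = ", signif(cur, 5))
    }
    onsets <- c(onsets, cur)
    cur <- cur + 60 / hr_b
  }
  nb <- length(onsets)
  durations <- diff(c(onsets, cur))

  od <- numeric(n)
  truth <- data.frame(onset = onsets, duration = durations,
                      hr = 60 / durations, ratio = NA_real_, slope = NA_real_,
                      map = NA_real_)
  for (b in seq_len(nb)) {
    T_b <- durations[b]
    mus <- m$mu_frac * T_b
    sigmas <- m$sigma_frac * T_b
    r_b <- spec$ratio(onsets[b])
    a2 <- .solve_a2(r_b, m$amps, mus, sigmas)
    amps <- c(m$amps[1], a2, m$amps[2], m$amps[3])
    i0 <- round(onsets[b] * fs) + 1L
    i1 <- min(n, round((onsets[b] + T_b) * fs))
    if (i1 < i0) next
    tau <- t[i0:i1] - onsets[b]
    w <- numeric(length(tau))
    for (i in 1:4) {
      w <- w + amps[i] * sigmas[i] * sqrt(2 * pi) *
        (stats::pnorm((tau - mus[i]) / sigmas[i]) - stats::pnorm(-mus[i] / sigmas[i]))
    }
    w_end <- sum(amps * sigmas * sqrt(2 * pi) *
                   (stats::pnorm((T_b - mus) / sigmas) - stats::pnorm(-mus / sigmas)))
    od[i0:i1] <- w - (tau / T_b) * w_end
    f1 <- gaussian_sum(amps, mus, sigmas, mus[1])
    f2 <- gaussian_sum(amps, mus, sigmas, mus[2])
    truth$ratio[b] <- f2 / f1
    truth$slope[b] <- (f2 - f1) / (mus[2] - mus[1])
  }
  truth$map <- map_features_to_map(truth$ratio, truth$hr, spec$map_coeffs,
                                   spec$nonlin_amp)

  drift <- spec$noise$resp * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi)) +
    spec$noise$mayer * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi))
  intensity <- spec$i0 * exp(-(spec$od_gain * od + drift)) +
    stats::rnorm(n, 0, spec$noise$optical) + spec$ambient
  intensity <- pmax(intensity, 0)
  ambient_ch <- spec$ambient + stats::rnorm(n, 0, max(spec$noise$optical / 4, 1e-12))
  acc <- cbind(acc_x = stats::rnorm(n, 0, spec$noise$acc),
               acc_y = stats::rnorm(n, 0, spec$noise$acc),
               acc_z = 1 + stats::rnorm(n, 0, spec$noise$acc))

  channels <- data.frame(name = "intensity_850_d1", wavelength_nm = 850,
                         separation_cm = 2.8, side = "contralateral")
  rec <- raw_recording(t, matrix(intensity, ncol = 1,
                                 dimnames = list(NULL, "intensity_850_d1")),
                       ambient = ambient_ch, acc = acc, fs = fs,
                       channels = channels)
  if (length(spec$artifacts)) {
    rec <- inject_artifacts(rec, spec$artifacts)
  }
  mid <- onsets + durations / 2
  ref <- reference_bp(mid, truth$map, source = "beatwise")
  attr(truth, "artifacts") <- spec$artifacts
  class(truth) <- c("ground_truth", "data.frame")
  list(recording = rec, reference = ref, truth = truth)
}

#' Inject motion and ambient-light artifacts into a recording
#'
#' Adds high-variance accelerometer bursts, an ambient-light step, and
#' optical-channel corruption inside the scheduled intervals only.
#'
#' @param recording a [raw_recording()].
#' @param schedule list of `c(start, end)` half-open intervals in seconds;
#'   must be disjoint and lie within the recording span.
#' @param magnitudes list with `acc` (g SD of the burst), `ambient` (counts
#'   added) and `optical` (counts SD of the corruption).
#' @param seed optional seed; if `NULL` the current RNG stream is used (as
#'   when called from [simulate_pulse_train()]).
#' @return the modified recording.
#' @export
inject_artifacts <- function(recording, schedule,
                             magnitudes = list(acc = 5, ambient = 5000, optical = 500),
                             seed = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  if (!length(schedule)) return(recording)
  iv <- do.call(rbind, lapply(schedule, function(x) {
    if (length(x) != 2 || x[2] <= x[1]) stop("artifact intervals must be c(start, end) with start < end")
    x
  }))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  span <- range(recording$t)
  if (any(iv[, 1] < span[1]) || any(iv[, 2] > span[2] + 1 / recording$fs)) {
    stop("artifact interval outside recording span")
  }
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    stop("artifact intervals must be disjoint")
  }
  run <- function() {
    for (k in seq_len(nrow(iv))) {
      idx <- which(recording$t >= iv[k, 1] & recording$t < iv[k, 2])
      ni <- length(idx)
      if (!ni) next
      if (!is.null(recording$acc)) {
        recording$acc[idx, ] <- recording$acc[idx, ] +
          matrix(stats::rnorm(ni * ncol(recording$acc), 0, magnitudes$acc), ncol = ncol(recording$acc))
      }
      if (!is.null(recording$ambient)) {
        recording$ambient[idx] <- recording$ambient[idx] + magnitudes$ambient
      }
      recording$intensity[idx, ] <- pmax(
        recording$intensity[idx, , drop = FALSE] +
          matrix(stats::rnorm(ni * ncol(recording$intensity), 0, magnitudes$optical),
                 ncol = ncol(recording$intensity)), 0)
    }
    recording
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate an aligned feature/pressure dataset directly
#'
#' Draws slowly varying feature trajectories (P2/P1 ratio, heart rate, and a
#' P1-P2 slope with a component independent of the other two) and generates
#' the reference pressure from the linear mapping plus an optional smooth
#' nonlinear term of amplitude `nonlin_amp` mmHg, part of which depends on
#' the slope's independent component.  This bypasses waveform synthesis and
#' feature extraction and is the workhorse for calibration-model tests.
#'
#' @param n number of samples.
#' @param dt sampling interval of the feature stream in seconds.
#' @param coeffs linear mapping `c(epsilon, a, b)`.
#' @param nonlin_amp nonlinear perturbation amplitude, mmHg.
#' @param noise_sd additive pressure noise SD, mmHg.
#' @param seed integer seed.
#' @return a data frame of class `aligned_dataset` with columns
#'   `t, p2p1, hr, slope, y`.
#' @export
simulate_feature_dataset <- function(n = 1500, dt = 1.6,
                                     coeffs = c(epsilon = -67, a = 137.10, b = 1.16),
                                     nonlin_amp = 0, noise_sd = 1, seed = 1L) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) * dt
    smooth <- function(sd, ar = 0.98) {
      x <- stats::filter(stats::rnorm(n), ar, method = "recursive")
      as.numeric(x) / sqrt(1 / (1 - ar^2)) * sd
    }
    r <- 0.65 + 0.15 * sin(2 * pi * t / 600 + 1) + smooth(0.06)
    r <- pmin(pmax(r, 0.35), 1.4)
    hr <- 75 + 8 * sin(2 * pi * t / 400) + smooth(3)
    hr <- pmin(pmax(hr, 40), 140)
    # short-memory component: carries slope-specific information without
    # aliasing into the (ratio, hr) plane over a training window
    s_ind <- smooth(1, ar = 0.75)
    slope <- -2 + 3 * (r - 0.65) + s_ind
    y <- coeffs[[1]] + coeffs[[2]] * r + coeffs[[3]] * hr +
      nonlin_amp * (0.6 * cos(2 * pi * (r - 0.65) / 0.6) *
                      cos(2 * pi * (hr - 75) / 40) +
                      0.3 * tanh(1.5 * s_ind)) +
      stats::rnorm(n, 0, noise_sd)
    structure(data.frame(t = t, p2p1 = r, hr = hr, slope = slope, y = y),
              target = "map", dropped = 0L,
              class = c("aligned_dataset", "data.frame"))
  })
}
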