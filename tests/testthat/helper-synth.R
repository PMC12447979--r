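# Shared fixtures, built in code.  Expensive simulations are memoized for the
# session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# noise-free morphology used across decomposition tests
ref_morphology <- function(Tb = 0.8) {
  list(amps = c(1.0, 0.5, 0.3, 0.15),
       mus = c(0.10, 0.25, 0.45, 0.60) * Tb / 0.8,
       sigmas = c(0.03, 0.05, 0.06, 0.07) * Tb / 0.8)
}

# a noiseless pulse train with constant morphology ratio and ramping HR
noiseless_sim <- function() {
  if (is.null(.fixtures$noiseless_sim)) {
    spec <- simulation_spec(
      duration = 240, hr = 72, ratio = 0.5,
      noise = list(optical = 0, resp = 0, mayer = 0, acc = 0.002),
      seed = 7)
    .fixtures$noiseless_sim <- simulate_pulse_train(spec)
  }
  .fixtures$noiseless_sim
}

noiseless_features <- function() {
  if (is.null(.fixtures$noiseless_features)) {
    sim <- noiseless_sim()
    cfg <- default_config()
    clean <- preprocess_recording(sim$recording, cfg)
    pulses <- reject_outlier_pulses(segment_pulses(clean, cfg), cfg)
    ens <- ensemble_average(pulses, cfg$ensemble_size, cfg$ensemble_overlap,
                            cfg$resample_length)
    .fixtures$noiseless_features <- list(
      sim = sim, clean = clean, pulses = pulses, ensembles = ens,
      features = extract_features(ens, cfg))
  }
  .fixtures$noiseless_features
}

# construct a pulse_set directly from a list of per-pulse sample vectors
make_pulse_set <- function(pulse_list, fs = 266) {
  x <- unlist(pulse_list)
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  lens <- vapply(pulse_list, length, 0L)
  onset_idx <- cumsum(c(1L, lens[-length(lens)]))
  end_idx <- onset_idx + lens
  keep <- end_idx <= n + 1L
  onset_idx <- onset_idx[keep]
  end_idx <- pmin(end_idx[keep], n + 1L)
  clean <- structure(list(
    t = t, value = x, fs = fs,
    mask = structure(data.frame(start = numeric(0), end = numeric(0)),
                     span = c(0, n / fs),
                     class = c("artifact_mask", "data.frame")),
    masked = logical(n), i0 = 1), class = "clean_signal")
  detr <- detrend_baseline(x, fs)
  tab <- data.frame(
    onset_idx = onset_idx, end_idx = end_idx,
    onset = t[onset_idx], end = c(t, n / fs)[end_idx],
    duration = (end_idx - onset_idx) / fs,
    amplitude = vapply(seq_along(onset_idx), function(i) {
      seg <- detr[onset_idx[i]:(end_idx[i] - 1L)]
      max(seg) - min(seg)
    }, 0),
    shape_score = NA_real_, masked = FALSE, flags = "", retained = TRUE)
  structure(list(signal = clean, table = tab), class = "pulse_set")
}

# one beat sampled at fs: integral of the reference four-Gaussian velocity
beat_template <- function(Tb = 0.75, fs = 266, morph = ref_morphology(Tb)) {
  simulate_pulse(morph$amps, morph$mus, morph$sigmas, Tb, fs)$waveform
}
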