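# Daubechies-5 filter bank and the two wavelet transforms used for band-pass
# filtering of NIRS-PPG intensity fluctuations: a decimated, periodized DWT
# (high-pass role) and a circular MODWT (low-pass role).  Boundary effects are
# handled by reflecting the signal before either transform.

# Standard Daubechies-5 (10-tap) decomposition filters.
.db5_lo <- c(
   0.003335725285473771, -0.012580751999081999, -0.006241490212798274,
   0.077571493840045740, -0.032244869584638375, -0.242294887066382030,
   0.138428145901320740,  0.724308528437772900,  0.603829269797189600,
   0.160102397974192930)
.db5_hi <- c(
  -0.160102397974192930,  0.603829269797189600, -0.724308528437772900,
   0.138428145901320740,  0.242294887066382030, -0.032244869584638375,
  -0.077571493840045740, -0.006241490212798274,  0.012580751999081999,
   0.003335725285473771)

# One periodized analysis step: x (length n, n even) -> coefficients (n/2).
.dwt_step <- function(x, f) {
  n <- length(x)
  k <- seq_len(n / 2L) - 1L
  out <- numeric(n / 2L)
  for (l in seq_along(f)) {
    out <- out + f[l] * x[(2L * k + (l - 1L)) %% n + 1L]
  }
  out
}

# Adjoint (synthesis) step for the orthogonal periodized transform.
.idwt_step <- function(a, d, lo = .db5_lo, hi = .db5_hi) {
  n <- 2L * length(a)
  x <- numeric(n)
  k <- seq_len(length(a)) - 1L
  for (l in seq_along(lo)) {
    idx <- (2L * k + (l - 1L)) %% n + 1L
    x[idx] <- x[idx] + lo[l] * a + hi[l] * d
  }
  x
}

# Full periodized decomposition to `levels`; length(x) must be divisible by
# 2^levels.  Returns list(approx, details = list(d1..dJ)).
.dwt_periodized <- function(x, levels) {
  stopifnot(length(x) %% 2L^levels == 0L)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    details[[j]] <- .dwt_step(a, .db5_hi)
    a <- .dwt_step(a, .db5_lo)
  }
  list(approx = a, details = details)
}

.idwt_periodized <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- .idwt_step(a, decomp$details[[j]])
  }
  a
}

# Circular filtering with the level-j MODWT filter (10 taps upsampled by
# 2^(j-1)).  dir = -1L applies the analysis operator A_j, dir = +1L its
# adjoint.
.modwt_filter <- function(x, f, stride, dir) {
  n <- length(x)
  t0 <- seq_len(n) - 1L
  out <- numeric(n)
  for (l in seq_along(f)) {
    out <- out + f[l] * x[(t0 + dir * (l - 1L) * stride) %% n + 1L]
  }
  out
}

# MODWT multiresolution smooth at level J: the component of x below
# fs / 2^(J+1).  Computed as the scaling-filter pyramid followed by its
# adjoint, which is the standard inverse-MODWT reconstruction with all detail
# coefficients zeroed (zero-phase by construction).
.modwt_smooth <- function(x, levels) {
  g <- .db5_lo / sqrt(2)
  v <- x
  for (j in seq_len(levels)) v <- .modwt_filter(v, g, 2L^(j - 1L), -1L)
  for (j in rev(seq_len(levels))) v <- .modwt_filter(v, g, 2L^(j - 1L), +1L)
  v
}

# Reflect-pad x so that (a) boundary handling is symmetric extension and
# (b) the padded length is divisible by `block`.  Returns list(x, keep).
.reflect_pad <- function(x, pad, block = 1L) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left <- x[(pad + 1L):2L]
  right <- x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  extra <- (block - length(xp) %% block) %% block
  if (extra > 0L) {
    tail_ref <- rev(xp)[seq_len(extra) + 1L]
    xp <- c(xp, tail_ref)
  }
  list(x = xp, keep = pad + seq_len(n))
}

#' Wavelet high-pass filter (decimated db5 decomposition)
#'
#' Removes slow systemic components (baseline drift, respiration, Mayer waves)
#' by an 8-level decimated Daubechies-5 wavelet decomposition in which the
#' final approximation is zeroed before reconstruction.  At `levels = 8` the
#' retained content lies above `fs / 2^9` (about 0.52 Hz at 266 Hz sampling).
#'
#' @param x numeric signal.
#' @param levels number of decomposition levels (default 8).
#' @return filtered signal, same length as `x`.
#' @export
wavelet_highpass <- function(x, levels = 8L) {
  levels <- as.integer(levels)
  if (length(x) < 2L^levels) {
    stop("input too short for ", levels, "-level wavelet decomposition: need at least ",
         2L^levels, " samples, got ", length(x))
  }
  p <- .reflect_pad(x, pad = max(2L^levels, 4096L), block = 2L^levels)
  dec <- .dwt_periodized(p$x, levels)
  dec$approx[] <- 0
  .idwt_periodized(dec)[p$keep]
}

#' Wavelet low-pass filter (undecimated db5 smooth)
#'
#' Removes high-frequency noise by a maximal-overlap (undecimated, circular)
#' Daubechies-5 decomposition in which detail levels `1..levels` are zeroed,
#' i.e. the level-`levels` multiresolution smooth is returned.  At
#' `levels = 3` the retained content lies below `fs / 2^4` (about 16.6 Hz at
#' 266 Hz sampling).
#'
#' @param x numeric signal.
#' @param levels number of zeroed detail levels (default 3).
#' @return filtered signal, same length as `x`.
#' @export
wavelet_lowpass <- function(x, levels = 3L) {
  levels <- as.integer(levels)
  if (length(x) < 2L^levels) {
    stop("input too short for ", levels, "-level wavelet decomposition")
  }
  p <- .reflect_pad(x, pad = 1024L)
  .modwt_smooth(p$x, levels)[p$keep]
}

#' Wavelet band-pass filter for NIRS-PPG signals
#'
#' Band-limits a signal to the pulsatile range by combining
#' [wavelet_highpass()] (decimated db5, approximation zeroed) and
#' [wavelet_lowpass()] (undecimated db5 smooth).  The decomposition depths are
#' chosen from the sampling rate so that the effective half-band edges
#' `fs/2^(hp_levels+1)` and `fs/2^(lp_levels+1)` come closest to the requested
#' cutoffs; at 266 Hz and the default 0.5--15 Hz band this yields 8 high-pass
#' levels (0.52 Hz) and 3 low-pass levels (16.6 Hz).
#'
#' @param x numeric signal (at least 2^hp_levels samples).
#' @param fs sampling rate in Hz.
#' @param low,high nominal band edges in Hz.
#' @return filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 266)
#' x <- sin(2 * pi * 1.2 * t) + 3 * sin(2 * pi * 0.1 * t)
#' y <- wavelet_bandpass(x, fs = 266)
wavelet_bandpass <- function(x, fs, low = 0.5, high = 15) {
  if (!is.numeric(x)) stop("signal must be numeric")
  if (low <= 0 || high <= low || high >= fs / 2) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  hp_levels <- max(1L, as.integer(round(log2(fs / low))) - 1L)
  lp_levels <- max(1L, as.integer(round(log2(fs / high))) - 1L)
  wavelet_lowpass(wavelet_highpass(x, hp_levels), lp_levels)
}
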