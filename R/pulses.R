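# Beat segmentation, percentile-based pulse quality control, and overlapping
# ensemble averaging of the normalized delta-OD signal.

#' Remove slow baseline fluctuations with a moving median
#'
#' Subtracts a centered moving median (window truncated at the edges) from
#' the signal; used to compute per-pulse duration and amplitude statistics
#' free of residual baseline wander.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds (default 15).
#' @return detrended series.
#' @export
detrend_baseline <- function(x, fs, window = 15) {
  k <- round(window * fs)
  if (k %% 2 == 0) k <- k + 1L
  if (k >= length(x)) return(x - stats::median(x))
  x - stats::runmed(x, k, endrule = "median")
}

#' Segment a clean signal into pulses
#'
#' Beat onsets are placed at the local minima preceding systolic upstrokes:
#' upstroke regions are runs where the first derivative exceeds half its 98th
#' percentile, runs closer than the refractory period are merged, and each
#' onset is the last non-positive-derivative sample before the run (falling
#' back to the signal minimum in the preceding 0.35 s).  Pulses overlapping
#' the artifact mask are flagged `masked`.
#'
#' @param signal a `clean_signal` from [preprocess_recording()].
#' @param config pipeline configuration (refractory period, detrend window).
#' @return an object of class `pulse_set`: the signal plus a per-pulse table
#'   with onset, end, duration, amplitude and flags.
#' @export
segment_pulses <- function(signal, config = default_config()) {
  stopifnot(inherits(signal, "clean_signal"))
  x <- signal$value
  fs <- signal$fs
  n <- length(x)
  d <- first_derivative(x, fs)
  if (!any(is.finite(d)) || diff(range(d)) < 1e-12 || max(d) <= 0) {
    stop("no pulses found: signal has no positive upstrokes")
  }
  thr <- 0.5 * stats::quantile(d, 0.98, names = FALSE)
  if (thr <= 0) stop("no pulses found: derivative threshold is non-positive")
  above <- d >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  if (!length(run_start)) stop("no pulses found above the upstroke threshold")
  refr <- round(config$refractory * fs)
  keep <- c(TRUE, diff(run_start) >= refr)
  run_start <- run_start[keep]

  onset_idx <- vapply(run_start, function(s) {
    w0 <- max(1L, s - as.integer(round(0.5 * fs)))
    j <- which(d[w0:s] <= 0)
    if (length(j)) w0 + j[length(j)] - 1L
    else {
      w0 <- max(1L, s - as.integer(round(0.35 * fs)))
      w0 + which.min(x[w0:s]) - 1L
    }
  }, integer(1))
  onset_idx <- sort(unique(onset_idx))
  if (length(onset_idx) > 1) {
    keep <- c(TRUE, diff(onset_idx) >= refr)
    onset_idx <- onset_idx[keep]
  }
  if (length(onset_idx) < 2) stop("no pulses found: fewer than two beat onsets")

  starts_i <- onset_idx[-length(onset_idx)]
  ends_i <- onset_idx[-1]
  detr <- detrend_baseline(x, fs, config$detrend_window)
  amp <- vapply(seq_along(starts_i), function(i) {
    seg <- detr[starts_i[i]:(ends_i[i] - 1L)]
    max(seg) - min(seg)
  }, 0)
  masked_flag <- vapply(seq_along(starts_i), function(i) {
    any(signal$masked[starts_i[i]:(ends_i[i] - 1L)])
  }, logical(1))
  tab <- data.frame(
    onset_idx = starts_i, end_idx = ends_i,
    onset = signal$t[starts_i], end = signal$t[ends_i],
    duration = signal$t[ends_i] - signal$t[starts_i],
    amplitude = amp, shape_score = NA_real_,
    masked = masked_flag, flags = ifelse(masked_flag, "masked", ""),
    retained = !masked_flag)
  structure(list(signal = signal, table = tab), class = "pulse_set")
}

#' @export
print.pulse_set <- function(x, ...) {
  cat("<pulse_set> ", nrow(x$table), " pulses (", sum(x$table$retained),
      " retained), median duration ",
      sprintf("%.3f", stats::median(x$table$duration)), " s\n", sep = "")
  invisible(x)
}

# Resample pulse i to `len` points of the clean signal (linear interpolation).
.pulse_resampled <- function(pulses, i, len) {
  a <- pulses$table$onset_idx[i]
  b <- pulses$table$end_idx[i]
  seg <- pulses$signal$value[a:(b - 1L)]
  stats::approx(seq_along(seg), seg, xout = seq(1, length(seg), length.out = len))$y
}

#' Extract the samples of one pulse
#'
#' @param pulses a `pulse_set`.
#' @param i pulse index.
#' @return list with `t` and `value` for the half-open beat interval.
#' @export
pulse_samples <- function(pulses, i) {
  a <- pulses$table$onset_idx[i]
  b <- pulses$table$end_idx[i]
  list(t = pulses$signal$t[a:(b - 1L)], value = pulses$signal$value[a:(b - 1L)])
}

#' Shape-similarity scores over consecutive pulses
#'
#' Each pulse is resampled to a common length and min-max scaled; its score
#' is the Pearson correlation against the pointwise mean of its centered
#' `window`-pulse neighborhood (truncated at the edges).  Degenerate
#' (constant) pulses score -1.
#'
#' @param pulses a `pulse_set`.
#' @param idx indices of the pulses to score (default: currently retained).
#' @param window neighborhood size in pulses (default 20).
#' @param len resampling length.
#' @return numeric scores in `[-1, 1]`, one per element of `idx`.
#' @export
shape_similarity_scores <- function(pulses, idx = which(pulses$table$retained),
                                    window = 20, len = 100) {
  m <- length(idx)
  if (m < window) {
    stop("only ", m, " pulses available for shape scoring; need at least ",
         window, " - consider reducing the shape window")
  }
  P <- t(vapply(idx, function(i) {
    v <- .pulse_resampled(pulses, i, len)
    rg <- range(v)
    if (diff(rg) <= 0) rep(NA_real_, len) else (v - rg[1]) / diff(rg)
  }, numeric(len)))
  half <- floor(window / 2)
  scores <- numeric(m)
  csum <- apply(P, 2, function(col) cumsum(ifelse(is.na(col), 0, col)))
  cnt <- cumsum(!is.na(P[, 1]))
  for (i in seq_len(m)) {
    lo <- max(1L, i - half)
    hi <- min(m, lo + window - 1L)
    lo <- max(1L, hi - window + 1L)
    nref <- cnt[hi] - if (lo > 1) cnt[lo - 1] else 0
    ref <- (csum[hi, ] - if (lo > 1) csum[lo - 1, ] else 0) / max(nref, 1)
    if (any(is.na(P[i, ])) || stats::sd(P[i, ]) == 0 || stats::sd(ref) == 0) {
      scores[i] <- -1
    } else {
      scores[i] <- stats::cor(P[i, ], ref)
    }
  }
  scores
}

#' Reject outlier pulses by duration, amplitude and shape percentiles
#'
#' Applies the three quality-control filters in sequence, each computed over
#' the pulses surviving the previous one: duration outside the configured
#' `[p1, p99]`, amplitude outside `[p5, p95]`, and shape-similarity score
#' outside `[p7, p93]` (inclusive bounds; percentiles use linear
#' interpolation and are recomputed per recording).  With
#' `config$shape_one_sided = TRUE` only low-similarity pulses are rejected.
#'
#' @param pulses a `pulse_set`.
#' @param config pipeline configuration (percentile pairs, shape window).
#' @return the `pulse_set` with `flags`, `shape_score` and `retained`
#'   updated; a summary of flag counts is attached as attribute `report`.
#' @export
reject_outlier_pulses <- function(pulses, config = default_config()) {
  tab <- pulses$table
  cand <- which(!tab$masked)
  if (length(cand) < config$shape_window) {
    stop("only ", length(cand), " unmasked pulses; need at least ",
         config$shape_window, " for quality control - consider reducing the shape window")
  }
  add_flag <- function(flags, i, what) {
    ifelse(flags[i] == "", what, paste(flags[i], what, sep = ","))
  }
  outside <- function(x, pct) {
    q <- stats::quantile(x, pct / 100, names = FALSE, type = 7)
    # inclusive bounds with a relative epsilon so exact ties (degenerate
    # percentile distributions) are never rejected by floating-point noise
    eps <- 1e-9 * max(abs(q), 1)
    x < q[1] - eps | x > q[2] + eps
  }
  bad <- outside(tab$duration[cand], config$duration_percentiles)
  tab$flags[cand[bad]] <- add_flag(tab$flags, cand[bad], "duration_outlier")
  surv <- cand[!bad]

  bad <- outside(tab$amplitude[surv], config$amplitude_percentiles)
  tab$flags[surv[bad]] <- add_flag(tab$flags, surv[bad], "amplitude_outlier")
  surv <- surv[!bad]

  if (length(surv) < config$shape_window) {
    stop("fewer than ", config$shape_window,
         " pulses survive duration/amplitude filtering; cannot score shape - ",
         "consider reducing the shape window")
  }
  sc <- shape_similarity_scores(pulses, surv, config$shape_window,
                                config$resample_length)
  tab$shape_score[surv] <- sc
  if (isTRUE(config$shape_one_sided)) {
    q <- stats::quantile(sc, config$shape_percentiles[1] / 100, names = FALSE)
    bad <- sc < q
  } else {
    bad <- outside(sc, config$shape_percentiles)
  }
  tab$flags[surv[bad]] <- add_flag(tab$flags, surv[bad], "shape_outlier")
  surv <- surv[!bad]

  tab$retained <- seq_len(nrow(tab)) %in% surv
  if (length(surv) < 10) {
    stop("pulse quality control retained only ", length(surv),
         " pulses (minimum 10)")
  }
  pulses$table <- tab
  attr(pulses, "report") <- c(
    input = nrow(tab), masked = sum(tab$masked),
    duration = sum(grepl("duration_outlier", tab$flags)),
    amplitude = sum(grepl("amplitude_outlier", tab$flags)),
    shape = sum(grepl("shape_outlier", tab$flags)),
    retained = length(surv))
  pulses
}

#' Overlapping ensemble averages of retained pulses
#'
#' Windows of `k` consecutive retained pulses advance by `k * (1 - overlap)`
#' pulses; each ensemble waveform is the pointwise mean of its members
#' resampled to a common length.
#'
#' @param pulses a `pulse_set` after quality control.
#' @param k pulses per ensemble (default 4).
#' @param overlap fractional window overlap (default 0.5).
#' @param len common resampling length.
#' @return an object of class `pulse_ensembles`: a waveform matrix (one row
#'   per ensemble) plus per-ensemble metadata (`t_mid`, `mean_ibi`,
#'   `duration`, member onsets).
#' @export
ensemble_average <- function(pulses, k = 4, overlap = 0.5, len = 150) {
  tab <- pulses$table
  ret <- which(tab$retained)
  n <- length(ret)
  if (n < k) stop("need at least ", k, " retained pulses, have ", n)
  step <- max(1L, round(k * (1 - overlap)))
  starts <- seq(1L, n - k + 1L, by = step)
  W <- matrix(NA_real_, length(starts), len)
  meta <- data.frame(t_mid = numeric(length(starts)),
                     mean_ibi = numeric(length(starts)),
                     duration = numeric(length(starts)))
  member_onsets <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    mem <- ret[starts[w]:(starts[w] + k - 1L)]
    M <- t(vapply(mem, function(i) .pulse_resampled(pulses, i, len), numeric(len)))
    W[w, ] <- colMeans(M)
    ons <- tab$onset[mem]
    member_onsets[[w]] <- ons
    meta$t_mid[w] <- (tab$onset[mem[1]] + tab$end[mem[k]]) / 2
    meta$mean_ibi[w] <- mean(tab$duration[mem])
    meta$duration[w] <- mean(tab$duration[mem])
  }
  structure(list(waveform = W, meta = meta, member_onsets = member_onsets,
                 k = k, len = len),
            class = "pulse_ensembles")
}

#' @export
print.pulse_ensembles <- function(x, ...) {
  cat("<pulse_ensembles> ", nrow(x$waveform), " ensembles of ", x$k,
      " pulses (", x$len, " points each)\n", sep = "")
  invisible(x)
}
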