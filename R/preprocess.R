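# Raw intensity -> artifact-masked, band-limited, normalized delta-OD.

#' Subtract the ambient-light channel from detected intensity
#'
#' @param intensity detected counts.
#' @param ambient ambient counts (same length).
#' @return list with `corrected` (elementwise difference) and `invalid`
#'   (logical; samples where the corrected intensity is non-positive, later
#'   absorbed into the artifact mask).
#' @export
subtract_ambient <- function(intensity, ambient) {
  if (length(intensity) != length(ambient)) {
    stop("intensity and ambient lengths differ (", length(intensity),
         " vs ", length(ambient), ")")
  }
  corrected <- intensity - ambient
  list(corrected = corrected, invalid = corrected <= 0)
}

# ---- artifact mask -------------------------------------------------------

.new_mask <- function(intervals, span) {
  if (is.null(intervals) || !nrow(intervals)) {
    intervals <- data.frame(start = numeric(0), end = numeric(0))
  }
  structure(intervals, span = span, class = c("artifact_mask", "data.frame"))
}

# pad each interval, clip to span, merge overlaps
.pad_merge <- function(iv, pad, span) {
  if (!nrow(iv)) return(iv)
  iv$start <- pmax(iv$start - pad, span[1])
  iv$end <- pmin(iv$end + pad, span[2])
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$start[k] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[k])
    } else {
      out <- rbind(out, iv[k, ])
    }
  }
  rownames(out) <- NULL
  out
}

.runs_to_intervals <- function(flag, t, dt) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = t[starts[keep]], end = t[ends[keep]] + dt)
}

#' Logical mask vector for a time base
#'
#' @param mask an `artifact_mask`.
#' @param t time vector.
#' @return logical vector, `TRUE` where masked.
#' @export
mask_to_logical <- function(mask, t) {
  out <- logical(length(t))
  for (k in seq_len(nrow(mask))) {
    out <- out | (t >= mask$start[k] & t < mask$end[k])
  }
  out
}

#' Flag motion / ambient-light artifact segments
#'
#' Samples whose accelerometer-magnitude deviation or ambient-light deviation
#' (absolute distance from the series median) exceeds the subject-specific
#' percentile threshold are flagged; each flagged run is padded by
#' `config$artifact_pad` seconds and overlapping runs are merged.  The
#' percentile threshold is floored at `artifact_mad_guard` robust standard
#' deviations (median absolute deviation based) so that an artifact-free
#' recording is not progressively masked by its own noise tail; lowering the
#' percentile can only enlarge the mask.
#'
#' @param acc accelerometer matrix (1 or 3 columns, g) or `NULL`.
#' @param ambient ambient counts or `NULL`.
#' @param t time base in seconds.
#' @param config pipeline configuration (percentile, pad, guard).
#' @param extra_invalid optional logical vector of additional samples to mask
#'   (e.g. non-positive corrected intensity).
#' @return an `artifact_mask` (data frame of half-open `[start, end)`
#'   intervals).
#' @export
flag_artifact_segments <- function(acc, ambient, t, config = default_config(),
                                   extra_invalid = NULL) {
  n <- length(t)
  dt <- if (n > 1) stats::median(diff(t)) else 0
  span <- c(t[1], t[n] + dt)
  dev_flag <- function(x) {
    d <- abs(x - stats::median(x))
    thr <- max(stats::quantile(d, config$artifact_percentile / 100, names = FALSE),
               config$artifact_mad_guard * stats::mad(x))
    d > thr
  }
  flag <- logical(n)
  if (!is.null(acc)) {
    acc <- as.matrix(acc)
    mag <- sqrt(rowSums(acc^2))
    flag <- flag | dev_flag(mag)
  }
  if (!is.null(ambient)) flag <- flag | dev_flag(ambient)
  if (!is.null(extra_invalid)) flag <- flag | extra_invalid
  iv <- .runs_to_intervals(flag, t, dt)
  iv <- .pad_merge(iv, config$artifact_pad, span)
  mask <- .new_mask(iv, span)
  if (nrow(mask) && sum(mask$end - mask$start) >= diff(span) - dt) {
    stop("no clean data: the artifact mask covers the entire recording")
  }
  mask
}

# ---- delta-OD and normalization -----------------------------------------

#' Convert corrected intensity to delta optical density
#'
#' `dOD = ln(I0 / I(t))`, with the baseline `I0` taken as the median of the
#' unmasked corrected intensity unless supplied.  Strictly decreasing in `I`,
#' positive-going when absorption rises (systole).
#'
#' @param intensity corrected counts (positive at unmasked samples).
#' @param i0 baseline intensity; `NULL` for the median policy.
#' @param masked optional logical vector of samples excluded from the
#'   baseline statistic and the positivity requirement.
#' @return list with `od` and the `i0` used.
#' @export
compute_delta_od <- function(intensity, i0 = NULL, masked = NULL) {
  if (is.null(masked)) masked <- logical(length(intensity))
  if (any(intensity[!masked] <= 0)) {
    stop("non-positive corrected intensity at unmasked sample(s); ",
         "mask or remove them before computing delta-OD")
  }
  if (is.null(i0)) i0 <- stats::median(intensity[!masked])
  list(od = log(i0 / intensity), i0 = i0)
}

#' Interquartile-range normalization
#'
#' Centers by the median and scales by the 25th--75th percentile range,
#' computed over unmasked samples (linear interpolation between order
#' statistics).  The output has median 0 and IQR 1 over unmasked samples.
#'
#' @param x numeric series.
#' @param masked optional logical mask excluded from the statistics.
#' @return normalized series.
#' @export
iqr_normalize <- function(x, masked = NULL) {
  if (is.null(masked)) masked <- logical(length(x))
  q <- stats::quantile(x[!masked], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr <= 0) stop("cannot normalize: interquartile range of the signal is zero")
  (x - q[2]) / iqr
}

#' Preprocess a raw recording into a clean normalized delta-OD signal
#'
#' Pipeline order: ambient subtraction, artifact masking, wavelet band-pass,
#' delta-OD conversion, IQR normalization.  Masked intervals are excluded
#' from all statistics and carried forward on the result; before filtering,
#' masked samples are bridged by linear interpolation so that artifact
#' excursions do not ring into clean data (the 1-s mask padding absorbs the
#' residual boundary effect).  Set `config$od_before_filter = TRUE` to
#' convert to delta-OD before band-passing instead.
#'
#' @param recording a [raw_recording()].
#' @param config pipeline configuration.
#' @param channel intensity column name or index (default: configured
#'   channel, else the first column).
#' @return an object of class `clean_signal`: list with `t`, `value`
#'   (normalized delta-OD), `fs`, `mask`, `masked` (logical), `i0`.
#' @export
preprocess_recording <- function(recording, config = default_config(),
                                 channel = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  if (is.null(channel)) channel <- config$channel
  if (is.null(channel)) channel <- 1L
  intensity <- recording$intensity[, channel]
  t <- recording$t
  if (!is.null(recording$ambient)) {
    sub <- subtract_ambient(intensity, recording$ambient)
  } else {
    sub <- list(corrected = intensity, invalid = intensity <= 0)
  }
  mask <- flag_artifact_segments(recording$acc, recording$ambient, t, config,
                                 extra_invalid = sub$invalid)
  masked <- mask_to_logical(mask, t)
  if (all(masked)) stop("no clean data: every sample is masked")
  corrected <- .bridge_masked(sub$corrected, masked)
  i0 <- stats::median(corrected[!masked])

  if (isTRUE(config$od_before_filter)) {
    od <- compute_delta_od(corrected, i0 = i0, masked = masked)$od
    od_f <- wavelet_bandpass(od, recording$fs, config$filter_low, config$filter_high)
  } else {
    filt <- wavelet_bandpass(corrected - i0, recording$fs,
                             config$filter_low, config$filter_high)
    ifilt <- i0 + filt
    bad <- ifilt <= 0 & !masked
    if (any(bad)) {
      stop("band-passed intensity non-positive at ", sum(bad),
           " unmasked sample(s); data too corrupted for delta-OD conversion")
    }
    od_f <- log(i0 / pmax(ifilt, i0 * 1e-12))
  }
  value <- iqr_normalize(od_f, masked)
  structure(list(t = t, value = value, fs = recording$fs, mask = mask,
                 masked = masked, i0 = i0),
            class = "clean_signal")
}

# linear interpolation across masked runs (ends held at nearest clean value)
.bridge_masked <- function(x, masked) {
  if (!any(masked)) return(x)
  idx <- which(!masked)
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' @export
print.clean_signal <- function(x, ...) {
  cat("<clean_signal> ", length(x$t), " samples at ", x$fs, " Hz; ",
      nrow(x$mask), " masked interval(s) covering ",
      sprintf("%.1f", sum(x$mask$end - x$mask$start)), " s\n", sep = "")
  invisible(x)
}
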