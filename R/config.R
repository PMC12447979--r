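# Pipeline configuration: documented defaults, YAML loading, validation.

#' Default pipeline configuration
#'
#' Returns the full set of tunable pipeline parameters with their default
#' values.  All downstream functions accept such a list; [load_config()]
#' merges a YAML file over these defaults.
#'
#' Key defaults: band-pass 0.5--15 Hz; artifact threshold at the subject's
#' 99th percentile of accelerometer/ambient deviation (padded 1 s); pulse QC
#' percentiles (1, 99) for duration, (5, 95) for amplitude, (7, 93) for shape
#' similarity over 20-pulse windows; 4-beat ensembles with 50% overlap;
#' 1200-s training window scanned in 60-s steps with a 60-s train/test
#' buffer; 5 cross-validation folds; 3 seeded restarts for the GPR
#' hyperparameter search.
#'
#' @return a list of class `nirsbp_config`.
#' @export
default_config <- function() {
  structure(list(
    filter_low            = 0.5,    # Hz, high-pass edge
    filter_high           = 15,     # Hz, low-pass edge
    artifact_percentile   = 99,     # subject-specific threshold percentile
    artifact_pad          = 1,      # s added around each masked run
    artifact_mad_guard    = 8,      # threshold floor, in robust SDs
    i0_policy             = "median",
    od_before_filter      = FALSE,  # FALSE: band-pass intensity, then delta-OD
    detrend_window        = 15,     # s, moving-median window for pulse stats
    refractory            = 0.3,    # s, minimum beat separation
    duration_percentiles  = c(1, 99),
    amplitude_percentiles = c(5, 95),
    shape_percentiles     = c(7, 93),
    shape_one_sided       = FALSE,
    shape_window          = 20,     # consecutive pulses for shape reference
    resample_length       = 150,    # points per pulse for shape/ensembles
    ensemble_size         = 4,
    ensemble_overlap      = 0.5,
    slope_on_derivative   = TRUE,   # P1-P2 slope from the derivative signal
    fit_tail_trim         = 0.05,   # fraction of the pulse tail excluded
                                    # from the decomposition fit
    align_tolerance       = 2,      # s, feature/reference pairing tolerance
    train_length          = 1200,   # s, calibration segment
    train_step            = 60,     # s, scan step for segment selection
    split_buffer          = 60,     # s, train/test separation
    cv_folds              = 5,
    gpr_restarts          = 3,
    fit_linear_on         = "train",  # or "all"
    r2_method             = "ss",     # or "correlation"
    channel               = NULL,     # intensity column; NULL = first
    seed                  = 1L
  ), class = "nirsbp_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Unspecified keys take the documented defaults of [default_config()]; an
#' empty (or missing content) file yields the defaults unchanged.  Unknown
#' keys and out-of-range values are errors.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a validated `nirsbp_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param config a configuration list to validate.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  with(config, {
    if (!(filter_low > 0 && filter_high > filter_low)) {
      stop("invalid filter band: need 0 < low cutoff < high cutoff (got ",
           filter_low, ", ", filter_high, ")")
    }
    for (nm in c("duration_percentiles", "amplitude_percentiles", "shape_percentiles")) {
      p <- config[[nm]]
      if (length(p) != 2 || p[1] >= p[2] || p[1] < 0 || p[2] > 100) {
        stop("invalid percentile pair in ", nm, ": must satisfy 0 <= low < high <= 100")
      }
    }
    if (artifact_percentile <= 0 || artifact_percentile > 100) {
      stop("artifact_percentile must be in (0, 100]")
    }
    if (ensemble_size < 2) stop("ensemble_size must be at least 2")
    if (ensemble_overlap < 0 || ensemble_overlap >= 1) {
      stop("ensemble_overlap must be in [0, 1)")
    }
    if (train_length <= 0) stop("train_length must be positive")
    if (cv_folds < 2) stop("cv_folds must be at least 2")
    if (!fit_linear_on %in% c("train", "all")) stop("fit_linear_on must be 'train' or 'all'")
    if (!r2_method %in% c("ss", "correlation")) stop("r2_method must be 'ss' or 'correlation'")
    if (length(seed) != 1 || is.na(seed) || seed != round(seed)) {
      stop("seed must be a fixed integer")
    }
  })
  config$seed <- as.integer(config$seed)
  class(config) <- "nirsbp_config"
  config
}

#' @export
print.nirsbp_config <- function(x, ...) {
  cat("<nirsbp_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# Short content hash (FNV-1a over the JSON serialization) used for report
# provenance only.
.config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, null = "null")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
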