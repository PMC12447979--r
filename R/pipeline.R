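# End-to-end orchestration: recording + reference -> preprocessing -> pulse
# QC -> features -> calibration (linear, 2- and 3-feature GPR) -> held-out
# metrics, gathered into a study report.

#' Run the full pressure-estimation pipeline
#'
#' Preprocesses the recording, segments and quality-controls pulses, forms
#' ensembles, extracts the feature triple, aligns with the reference
#' pressure, selects the maximum-variability training segment, fits the
#' linear model and the 2- and 3-feature Gaussian-process models, and
#' evaluates all three on the held-out interval.  All randomness derives
#' from `config$seed`, so a fixed (config, input) pair yields an identical
#' report.
#'
#' @param recording a [raw_recording()].
#' @param reference a [reference_bp()] overlapping the recording by at least
#'   the training-segment length.
#' @param config pipeline configuration ([default_config()]).
#' @param target reference column to calibrate against.
#' @return an object of class `study_report`: fitted models, per-model
#'   [compute_metrics()] reports on the test interval, prediction series,
#'   the train/test split, a pulse-QC summary and provenance (config hash,
#'   seed).
#' @export
run_pipeline <- function(recording, reference, config = default_config(),
                         target = "map") {
  config <- validate_config(config)
  overlap <- min(max(recording$t), max(reference$t)) -
    max(min(recording$t), min(reference$t))
  if (!is.finite(overlap) || overlap < config$train_length) {
    stop("recording and reference overlap (", round(max(overlap, 0)),
         " s) is shorter than the training-segment length (",
         config$train_length, " s)")
  }
  withr::with_seed(config$seed, {
    clean <- preprocess_recording(recording, config)
    pulses <- segment_pulses(clean, config)
    pulses <- tryCatch(reject_outlier_pulses(pulses, config),
                       error = function(e) {
                         stop("pipeline failed at the pulse QC stage: ",
                              conditionMessage(e))
                       })
    qc_report <- attr(pulses, "report")
    ens <- ensemble_average(pulses, config$ensemble_size,
                            config$ensemble_overlap, config$resample_length)
    feats <- extract_features(ens, config)
    if (!nrow(feats)) stop("pipeline failed at feature extraction: no ensemble produced a convergent decomposition")
    ds <- align_series(feats, reference, config$align_tolerance, target)
    split <- select_training_segment(ds, config$train_length,
                                     config$train_step, config$split_buffer)
    lin_rows <- if (config$fit_linear_on == "train") split$train else NULL
    models <- list(
      linear = fit_linear(ds, rows = lin_rows),
      gpr2 = fit_gpr(ds, 2, config, rows = split$train),
      gpr3 = fit_gpr(ds, 3, config, rows = split$train))
    test <- ds[split$test, , drop = FALSE]
    if (nrow(test) < 3) stop("test interval too short: fewer than 3 aligned samples outside the training window")
    predictions <- lapply(models, function(m) stats::predict(m, test))
    metrics <- lapply(predictions, function(p) {
      compute_metrics(p$y_hat, test$y, config$r2_method)
    })
    structure(list(models = models, metrics = metrics,
                   predictions = predictions, split = split,
                   qc = qc_report, n_features_samples = nrow(feats),
                   n_aligned = nrow(ds), target = target, config = config,
                   provenance = list(config_hash = .config_hash(config),
                                     seed = config$seed)),
              class = "study_report")
  })
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> target: ", x$target, "; ", x$n_aligned,
      " aligned samples; training window [",
      paste(round(x$split$window), collapse = ", "), ") s; seed ",
      x$provenance$seed, " (config ", x$provenance$config_hash, ")\n", sep = "")
  cat("pulse QC: ", paste(names(x$qc), x$qc, sep = "=", collapse = ", "), "\n",
      sep = "")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-6s R2 = %s  RMSE = %.2f mmHg  MAE = %.2f mmHg  bias = %.2f [%.2f, %.2f]\n",
                nm, if (is.na(m$r2)) "NA" else sprintf("%.3f", m$r2),
                m$rmse, m$mae, m$bias, m$loa_low, m$loa_high))
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report a `study_report`.
#' @param path output file; `NULL` returns the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
write_study_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "study_report"))
  payload <- list(
    target = report$target,
    provenance = report$provenance,
    qc = as.list(report$qc),
    split_window = report$split$window,
    models = list(
      linear = list(coefficients = as.list(report$models$linear$coefficients),
                    se = as.list(report$models$linear$se),
                    r2_train = report$models$linear$r2_train),
      gpr2 = list(length_scales = report$models$gpr2$length_scales,
                  signal_var = report$models$gpr2$signal_var,
                  noise_var = report$models$gpr2$noise_var),
      gpr3 = list(length_scales = report$models$gpr3$length_scales,
                  signal_var = report$models$gpr3$signal_var,
                  noise_var = report$models$gpr3$noise_var)),
    metrics = lapply(report$metrics, function(m) {
      m <- unclass(m)
      m$r2 <- as.numeric(m$r2)
      m
    }))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
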