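# Containers and CSV I/O for raw multichannel recordings and reference
# arterial-pressure series.

#' Construct a raw NIRS-PPG recording
#'
#' Holds the multichannel optical intensity, the ambient-light channel, the
#' 3-axis accelerometer and the nominal sampling rate.  All series share one
#' time base.  Channel metadata (wavelength, source-detector separation, side
#' label) travel with the object and round-trip through the CSV sidecar
#' header.
#'
#' @param t time in seconds, strictly increasing, 0-based from recording start.
#' @param intensity numeric vector or matrix of detected counts (one column
#'   per detector channel).
#' @param ambient ambient-light counts, or `NULL` if not recorded.
#' @param acc accelerometer matrix in g (1 or 3 columns), or `NULL`.
#' @param fs nominal sampling rate in Hz (default 266).
#' @param channels optional data frame of channel metadata with columns
#'   `name`, `wavelength_nm`, `separation_cm`, `side`.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(t, intensity, ambient = NULL, acc = NULL, fs = 266,
                          channels = NULL) {
  t <- as.numeric(t)
  if (is.null(dim(intensity))) intensity <- matrix(intensity, ncol = 1,
                                                   dimnames = list(NULL, "intensity"))
  intensity <- as.matrix(intensity)
  n <- length(t)
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop("time base not strictly increasing: first violation at index ", bad[1] + 1L)
  }
  if (nrow(intensity) != n) stop("intensity length does not match time base")
  if (!all(is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative")
  }
  if (!is.null(ambient) && length(ambient) != n) {
    stop("ambient length does not match time base")
  }
  if (!is.null(acc)) {
    acc <- as.matrix(acc)
    if (nrow(acc) != n) stop("accelerometer length does not match time base")
  }
  if (n > 1) {
    med_dt <- stats::median(diff(t))
    if (abs(med_dt - 1 / fs) > 0.01 / fs) {
      stop("median sample interval ", signif(med_dt, 6),
           " s deviates more than 1% from 1/fs = ", signif(1 / fs, 6), " s")
    }
  }
  if (is.null(channels)) {
    channels <- data.frame(name = colnames(intensity),
                           wavelength_nm = NA_real_, separation_cm = NA_real_,
                           side = NA_character_)
  }
  structure(list(t = t, intensity = intensity, ambient = ambient, acc = acc,
                 fs = fs, channels = channels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> ", length(x$t), " samples, ",
      ncol(x$intensity), " optical channel(s), fs = ", x$fs, " Hz, span ",
      sprintf("%.1f", diff(range(x$t))), " s\n", sep = "")
  cat("  ambient: ", if (is.null(x$ambient)) "absent" else "present",
      "; accelerometer: ",
      if (is.null(x$acc)) "absent" else paste0(ncol(x$acc), "-axis"), "\n", sep = "")
  invisible(x)
}

#' Construct a reference blood-pressure series
#'
#' @param t time in seconds.
#' @param map mean arterial pressure, mmHg.
#' @param sbp,dbp optional systolic/diastolic pressures, mmHg.
#' @param source `"beatwise"` or `"waveform-derived"`.
#' @return an object of class `reference_bp` (a data frame).
#' @export
reference_bp <- function(t, map, sbp = NULL, dbp = NULL, source = "beatwise") {
  source <- match.arg(source, c("beatwise", "waveform-derived"))
  ok <- function(p) all(is.finite(p) & p > 0 & p < 300)
  if (!ok(map)) stop("MAP values must lie in (0, 300) mmHg")
  if (!is.null(sbp) && !ok(sbp)) stop("SBP values must lie in (0, 300) mmHg")
  if (!is.null(dbp) && !ok(dbp)) stop("DBP values must lie in (0, 300) mmHg")
  if (!is.null(sbp) && !is.null(dbp) && any(dbp > map | map > sbp)) {
    stop("pressure ordering violated: need dbp <= map <= sbp")
  }
  df <- data.frame(t = as.numeric(t), map = as.numeric(map))
  if (!is.null(sbp)) df$sbp <- as.numeric(sbp)
  if (!is.null(dbp)) df$dbp <- as.numeric(dbp)
  structure(df, source = source, class = c("reference_bp", "data.frame"))
}

# ---- CSV I/O -------------------------------------------------------------

#' Read a recording from CSV
#'
#' Expects a header row with a `t` column, one or more columns whose names
#' start with `intensity`, and optional `ambient` and `acc_*` columns (e.g.
#' `t,intensity_850_d1,intensity_850_d2,ambient,acc_x,acc_y,acc_z`).  Leading
#' `# channel:` comment lines carry channel metadata and are parsed back into
#' the object.  A `schema` list may remap column roles, e.g.
#' `list(t = "time", intensity = c("ch1", "ch2"), ambient = "amb", acc = "acc_mag")`.
#'
#' @param path CSV file path.
#' @param schema optional column map (see details).
#' @param fs nominal sampling rate in Hz.
#' @return a [raw_recording()].
#' @export
read_recording <- function(path, schema = NULL, fs = 266) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- character()
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  while (length(line <- readLines(con, n = 1)) && startsWith(line, "#")) {
    header <- c(header, line)
  }
  close(con); on.exit()
  df <- utils::read.csv(path, comment.char = "#")
  cols <- names(df)
  want <- function(role, default_cols) {
    if (!is.null(schema) && !is.null(schema[[role]])) schema[[role]] else default_cols
  }
  tcol <- want("t", "t")
  icols <- want("intensity", grep("^intensity", cols, value = TRUE))
  acol <- want("ambient", intersect("ambient", cols))
  ccols <- want("acc", grep("^acc", cols, value = TRUE))
  if (!length(icols)) stop("no intensity column found in ", path)
  for (needed in c(tcol, icols)) {
    if (!all(needed %in% cols)) {
      stop("required column missing from ", path, ": ",
           paste(setdiff(needed, cols), collapse = ", "))
    }
  }
  missing_opt <- setdiff(c(acol, ccols), cols)
  if (length(missing_opt)) stop("column named in schema not present: ",
                                paste(missing_opt, collapse = ", "))
  channels <- .parse_channel_header(header, icols)
  raw_recording(
    t = df[[tcol]],
    intensity = as.matrix(df[icols]),
    ambient = if (length(acol)) df[[acol]] else NULL,
    acc = if (length(ccols)) as.matrix(df[ccols]) else NULL,
    fs = fs, channels = channels)
}

.parse_channel_header <- function(lines, icols) {
  ch <- data.frame(name = icols, wavelength_nm = NA_real_,
                   separation_cm = NA_real_, side = NA_character_)
  for (line in grep("^# channel:", lines, value = TRUE)) {
    kv <- regmatches(line, gregexpr("[a-z_]+=[^ ]+", line))[[1]]
    fields <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
    i <- match(fields[["name"]], ch$name)
    if (is.na(i)) next
    if ("wavelength" %in% names(fields)) ch$wavelength_nm[i] <- as.numeric(fields[["wavelength"]])
    if ("separation" %in% names(fields)) ch$separation_cm[i] <- as.numeric(fields[["separation"]])
    if ("side" %in% names(fields)) ch$side[i] <- fields[["side"]]
  }
  ch
}

#' Write a recording to CSV
#'
#' Numeric columns are written at full double precision (15 significant
#' digits), so a write/read round-trip preserves values to well below 1e-9.
#' Channel metadata are written as `# channel:` comment lines.
#'
#' @param recording a [raw_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  ch <- recording$channels
  hdr <- sprintf("# channel: name=%s wavelength=%s separation=%s side=%s",
                 ch$name, ch$wavelength_nm, ch$separation_cm, ch$side)
  df <- data.frame(t = recording$t)
  df <- cbind(df, as.data.frame(recording$intensity))
  if (!is.null(recording$ambient)) df$ambient <- recording$ambient
  if (!is.null(recording$acc)) df <- cbind(df, as.data.frame(recording$acc))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a reference blood-pressure CSV (`t,map[,sbp,dbp]`)
#'
#' @param path CSV file path.
#' @param source see [reference_bp()].
#' @return a [reference_bp()].
#' @export
read_reference <- function(path, source = "beatwise") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("t", "map")) {
    if (!col %in% names(df)) stop("required column missing from ", path, ": ", col)
  }
  reference_bp(df$t, df$map, sbp = df[["sbp"]], dbp = df[["dbp"]], source = source)
}

#' @rdname read_reference
#' @param reference a [reference_bp()].
#' @export
write_reference <- function(reference, path) {
  utils::write.table(as.data.frame(reference), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
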