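#' Construct an insole recording
#'
#' An `insole_recording` holds one foot's total vertical ground reaction
#' force time series as exported by insole firmware: integer millisecond
#' timestamps and a force reading in Newton per sample. Samples lost to
#' transmission faults are represented as `NA`.
#'
#' @param subject_id character scalar identifying the subject.
#' @param side `"left"` or `"right"`.
#' @param timestamps integer vector, milliseconds since recording start,
#'   strictly increasing.
#' @param force numeric vector of total vertical force in Newton; `NA`
#'   marks a missing sample. Non-missing values must be >= 0.
#' @param sample_rate nominal sampling rate in Hz (default 100).
#' @return An object of class `insole_recording`.
#' @export
insole_recording <- function(subject_id, side, timestamps, force,
                             sample_rate = 100) {
  side <- match.arg(side, c("left", "right"))
  if (length(timestamps) != length(force))
    stop("timestamps and force must have the same length")
  timestamps <- as.numeric(timestamps)
  force <- as.numeric(force)
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(force < 0, na.rm = TRUE))
    stop("force values must be >= 0 or missing (NA)")
  structure(
    list(subject_id = as.character(subject_id), side = side,
         sample_rate = sample_rate, timestamps = timestamps, force = force),
    class = "insole_recording"
  )
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole_recording> subject %s, %s foot\n", x$subject_id, x$side))
  cat(sprintf("  %d samples at %g Hz (%.1f s), %d missing\n",
              length(x$force), x$sample_rate,
              diff(range(x$timestamps)) / 1000, sum(is.na(x$force))))
  invisible(x)
}

#' @export
length.insole_recording <- function(x) length(x$force)

#' Read an insole force recording from CSV
#'
#' Parses a CSV export of total vertical ground reaction force (one row
#' per sample) into an [insole_recording]. Empty cells, the literal
#' strings `"NaN"`/`"NA"`, and numeric NaN all map to the single missing
#' state.
#'
#' @param path file path of a UTF-8 CSV with a header row.
#' @param schema named list mapping the roles `timestamp`, `force` and
#'   optionally `side` to column names in the file.
#' @param subject_id subject identifier to attach; defaults to the file
#'   name without extension.
#' @param side foot side, used when the file has no side column.
#' @param sample_rate nominal sampling rate in Hz.
#' @return An [insole_recording].
#' @export
read_recording <- function(path,
                           schema = list(timestamp = "time", force = "force"),
                           subject_id = NULL, side = "left",
                           sample_rate = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN", "nan"))
  for (role in c("timestamp", "force")) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(df))
      stop(sprintf("column for '%s' (%s) not found in %s",
                   role, if (is.null(col)) "<unset>" else col, path))
  }
  ts_raw <- df[[schema$timestamp]]
  ts <- suppressWarnings(as.numeric(ts_raw))
  bad <- which(is.na(ts))
  if (length(bad) > 0)
    stop(sprintf("malformed timestamp at line %d of %s", bad[1] + 1L, path))
  f_raw <- df[[schema$force]]
  f <- suppressWarnings(as.numeric(f_raw))
  bad <- which(is.na(f) & !is.na(f_raw) & trimws(as.character(f_raw)) != "")
  if (length(bad) > 0)
    stop(sprintf("malformed force value at line %d of %s", bad[1] + 1L, path))
  if (!is.null(schema$side) && schema$side %in% names(df)) {
    sides <- unique(df[[schema$side]])
    if (length(sides) != 1) stop("recording mixes foot sides: ", path)
    side <- tolower(as.character(sides))
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop("timestamps not strictly increasing in ", path)
  insole_recording(subject_id, side, ts, f, sample_rate)
}

#' Read a subject anthropometrics table
#'
#' Reads one row per subject with columns `subject_id`, `age` (years),
#' `height` (cm), `weight` (kg), `grip` (kg), optionally `bmi` (kg/m^2)
#' and `sex`. When the `bmi` column is absent it is computed as
#' weight / (height/100)^2.
#'
#' @param path CSV file with a header row.
#' @return A data.frame of subject profiles.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "height", "weight", "grip")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("subjects table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subjects table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (nrow(df) == 0) {
    if (!"bmi" %in% names(df)) df$bmi <- numeric(0)
    if (!"sex" %in% names(df)) df$sex <- character(0)
    return(df)
  }
  if (any(df$weight <= 0) || any(df$height <= 0))
    stop("weight and height must be positive")
  if (!"bmi" %in% names(df)) {
    df$bmi <- df$weight / (df$height / 100)^2
  } else {
    expected <- df$weight / (df$height / 100)^2
    off <- abs(df$bmi - expected) / expected > 0.05
    if (any(off, na.rm = TRUE))
      warning("bmi deviates >5% from weight/height^2 for subject(s): ",
              paste(df$subject_id[which(off)], collapse = ", "))
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df$subject_id <- as.character(df$subject_id)
  df
}

# canonical column order of the parameter table on disk
PARAM_COLUMNS <- c("fmean_stance", "fmean_load", "fmean_mid", "fmean_unload",
                   "fz2", "fz3", "fz4", "loading_slope", "unloading_slope")
PARAM_FILE_HEADER <- c("subject_id", "side", "event_idx",
                       "Fmean_stance", "Fmean_load", "Fmean_mid",
                       "Fmean_unload", "Fz2", "Fz3", "Fz4",
                       "loading_slope", "unloading_slope")

#' Write a stance-parameter table to CSV
#'
#' One row per accepted stance event, in the canonical column order
#' (`subject_id`, `side`, `event_idx`, then the nine curve parameters).
#' Values are formatted with 9 significant digits so a write/read
#' round trip reproduces them exactly at that precision; missing values
#' are written as empty cells.
#'
#' @param params data.frame as produced by the pipeline: columns
#'   `subject_id`, `side`, `event_idx` and the nine parameters
#'   (lower-case names).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  need <- c("subject_id", "side", "event_idx", PARAM_COLUMNS)
  miss <- setdiff(need, names(params))
  if (length(miss) > 0)
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  out <- params[, need, drop = FALSE]
  names(out) <- PARAM_FILE_HEADER
  lines <- paste(PARAM_FILE_HEADER, collapse = ",")
  if (nrow(out) > 0) {
    num <- vapply(PARAM_COLUMNS, function(cn) {
      x <- params[[cn]]
      ifelse(is.na(x), "", sprintf("%.9g", x))
    }, character(nrow(out)))
    if (nrow(out) == 1) num <- matrix(num, nrow = 1)
    rows <- paste(out$subject_id, out$side, out$event_idx,
                  apply(num, 1, paste, collapse = ","), sep = ",")
    lines <- c(lines, rows)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a stance-parameter table written by [write_parameters()]
#'
#' @param path CSV path.
#' @return data.frame with lower-case parameter column names.
#' @export
read_parameters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!identical(names(df), PARAM_FILE_HEADER))
    stop("unexpected parameter table header in ", path)
  names(df) <- c("subject_id", "side", "event_idx", PARAM_COLUMNS)
  df$subject_id <- as.character(df$subject_id)
  df
}
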