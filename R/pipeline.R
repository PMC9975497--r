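#' Pipeline configuration
#'
#' Bundles every tunable of the analysis into one validated, serializable
#' object. All thresholds default to the standard protocol values
#' (segmentation: 30 N / 3 missing samples / 300-2000 ms; smoothing:
#' sigma 3, kernel 7; g = 9.81 m/s^2).
#'
#' @param seg a [seg_config].
#' @param filter a [filter_config].
#' @param g gravitational acceleration in m/s^2 used by the % body weight
#'   conversion.
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed matters when the input is simulated).
#' @param recordings_dir directory of recording CSVs named
#'   `<subject>_<side>.csv` (optional when recordings are passed
#'   in memory).
#' @param subjects_file path of the subjects CSV (optional, same).
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @param schema column mapping passed to [read_recording()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seg = seg_config(), filter = filter_config(),
                            g = 9.81, seed = 1L,
                            recordings_dir = NULL, subjects_file = NULL,
                            out_dir = NULL,
                            schema = list(timestamp = "time", force = "force")) {
  stopifnot(inherits(seg, "seg_config"), inherits(filter, "filter_config"))
  if (g <= 0) stop("g must be positive")
  structure(list(seg = seg, filter = filter, g = g, seed = as.integer(seed),
                 recordings_dir = recordings_dir,
                 subjects_file = subjects_file, out_dir = out_dir,
                 schema = schema),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipeline_config].
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   a `pipeline_config` equal to the one saved.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$seg <- unclass(x$seg)
  x$filter <- unclass(x$filter)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    seg = do.call(seg_config, x$seg),
    filter = do.call(filter_config, x$filter),
    g = x$g, seed = x$seed,
    recordings_dir = x$recordings_dir, subjects_file = x$subjects_file,
    out_dir = x$out_dir, schema = as.list(x$schema))
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# process one recording: segmentation -> normalization -> extrema ->
# parameters. Returns parameter rows, curves, and per-stage counts.
# The per-event loop avoids data.frame construction (it dominates the
# runtime on minute-long recordings); rows are accumulated as vectors.
process_recording <- function(rec, profile, config) {
  events <- detect_stance_events(rec, config$seg)
  rep <- attr(events, "report")
  n_ev <- length(events)
  curves <- vector("list", n_ev)
  params <- vector("list", n_ev)
  n_acc <- 0L
  acc_idx <- integer(n_ev)
  pmat <- matrix(NA_real_, nrow = n_ev, ncol = length(PARAM_COLUMNS),
                 dimnames = list(NULL, PARAM_COLUMNS))
  rej_idx <- integer(0)
  rej_stage <- character(0)
  rej_rule <- character(0)
  for (k in seq_len(n_ev)) {
    ev <- events[[k]]
    ns <- normalize_stance(ev, profile, config$g)
    if (is_rejection(ns)) {
      rej_idx <- c(rej_idx, k); rej_stage <- c(rej_stage, "normalize")
      rej_rule <- c(rej_rule, ns$rule)
      next
    }
    ext <- locate_extrema(ns, config$filter)
    if (is_rejection(ext)) {
      rej_idx <- c(rej_idx, k); rej_stage <- c(rej_stage, "extrema")
      rej_rule <- c(rej_rule, ext$rule)
      next
    }
    pp <- compute_parameters(ns, ext)
    if (pp$degenerate) {
      rej_idx <- c(rej_idx, k); rej_stage <- c(rej_stage, "parameters")
      rej_rule <- c(rej_rule, "degenerate_slope")
      next
    }
    n_acc <- n_acc + 1L
    acc_idx[n_acc] <- k
    curves[[n_acc]] <- ns
    params[[n_acc]] <- pp
    pmat[n_acc, ] <- c(pp$fmean_stance, pp$fmean_load, pp$fmean_mid,
                       pp$fmean_unload, pp$fz2, pp$fz3, pp$fz4,
                       pp$loading_slope, pp$unloading_slope)
  }
  rows <- if (n_acc > 0) {
    cbind(data.frame(subject_id = rep(rec$subject_id, n_acc),
                     side = rep(rec$side, n_acc),
                     event_idx = acc_idx[seq_len(n_acc)],
                     stringsAsFactors = FALSE),
          as.data.frame(pmat[seq_len(n_acc), , drop = FALSE]))
  } else NULL
  rejections <- if (length(rej_idx) > 0) {
    data.frame(subject_id = rec$subject_id, side = rec$side,
               event_idx = rej_idx, stage = rej_stage, rule = rej_rule,
               stringsAsFactors = FALSE)
  } else NULL
  list(rows = rows, curves = curves[seq_len(n_acc)],
       params = params[seq_len(n_acc)],
       rejections = rejections, seg_report = rep)
}

#' Run the full stance-phase analysis pipeline
#'
#' Orchestrates, per recording: step detection, dual-axis normalization,
#' extremum location, parameter computation; then per-subject
#' aggregation and the 18 forced-entry regression fits (nine parameters
#' x two models). When `config$out_dir` is set, writes the parameter
#' table, subject table, regression tables (CSV + JSON), rejection log
#' and a manifest with config hash, seed, per-stage counts and output
#' file checksums. Files are written atomically (temp file + rename).
#'
#' @param config a [pipeline_config].
#' @param recordings named list of recordings (per subject a list with
#'   `left`/`right`, or a flat list of [insole_recording]s); read from
#'   `config$recordings_dir` when `NULL`.
#' @param subjects subject profile data.frame; read from
#'   `config$subjects_file` when `NULL`.
#' @return object of class `stance_pipeline`: `parameters` (event-level
#'   data.frame), `aggregates`, `subject_table`, `fits`
#'   (a `stance_fits`), `rejections`, `manifest`.
#' @export
run_pipeline <- function(config, recordings = NULL, subjects = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(subjects)) {
    if (is.null(config$subjects_file))
      stop("no subjects given and no subjects_file configured")
    subjects <- read_subjects(config$subjects_file)
  }
  if (is.null(recordings)) {
    if (is.null(config$recordings_dir))
      stop("no recordings given and no recordings_dir configured")
    files <- list.files(config$recordings_dir,
                        pattern = "_(left|right)\\.csv$", full.names = TRUE)
    if (length(files) == 0) stop("no recording CSVs found in ",
                                 config$recordings_dir)
    recordings <- lapply(files, function(f) {
      base <- sub("\\.csv$", "", basename(f))
      side <- sub("^.*_", "", base)
      sid <- sub("_(left|right)$", "", base)
      read_recording(f, schema = config$schema, subject_id = sid, side = side)
    })
  }
  # flatten possibly nested per-subject lists
  flat <- list()
  for (el in recordings) {
    if (inherits(el, "insole_recording")) flat[[length(flat) + 1]] <- el
    else for (r in el) flat[[length(flat) + 1]] <- r
  }

  counts <- c(candidate_runs = 0L, gap_merges = 0L, duration_rejected = 0L,
              events_detected = 0L, accepted = 0L,
              rejected_normalize = 0L, rejected_nonstep = 0L,
              rejected_degenerate = 0L)
  by_subject <- list()
  all_rows <- list()
  all_rej <- list()
  for (rec in flat) {
    pr <- subjects[subjects$subject_id == rec$subject_id, , drop = FALSE]
    if (nrow(pr) != 1)
      stop("no unique profile for subject ", rec$subject_id)
    res <- process_recording(rec, pr, config)
    sr <- res$seg_report
    counts["candidate_runs"] <- counts["candidate_runs"] + sr$candidate_runs
    counts["gap_merges"] <- counts["gap_merges"] + sr$gap_merges
    counts["duration_rejected"] <- counts["duration_rejected"] + sr$duration_rejected
    counts["events_detected"] <- counts["events_detected"] + sr$accepted
    counts["accepted"] <- counts["accepted"] + length(res$params)
    n_rej <- 0L
    if (!is.null(res$rejections)) {
      all_rej[[length(all_rej) + 1]] <- res$rejections
      n_rej <- nrow(res$rejections)
      tab <- table(res$rejections$stage)
      for (stage in names(tab)) {
        key <- paste0("rejected_",
                      switch(stage, normalize = "normalize",
                             extrema = "nonstep", parameters = "degenerate"))
        counts[key] <- counts[key] + as.integer(tab[[stage]])
      }
    }
    if (!is.null(res$rows)) all_rows[[length(all_rows) + 1]] <- res$rows
    sid <- rec$subject_id
    if (is.null(by_subject[[sid]]))
      by_subject[[sid]] <- list(curves = list(), params = list(), rej = 0L)
    by_subject[[sid]]$curves <- c(by_subject[[sid]]$curves, res$curves)
    by_subject[[sid]]$params <- c(by_subject[[sid]]$params, res$params)
    by_subject[[sid]]$rej <- by_subject[[sid]]$rej + n_rej
  }

  parameters <- if (length(all_rows) > 0) do.call(rbind, all_rows) else
    stats::setNames(data.frame(matrix(ncol = 12, nrow = 0)),
                    c("subject_id", "side", "event_idx", PARAM_COLUMNS))
  rejections <- if (length(all_rej) > 0) do.call(rbind, all_rej) else
    data.frame(subject_id = character(0), side = character(0),
               event_idx = integer(0), stage = character(0),
               rule = character(0))

  aggregates <- list()
  for (sid in names(by_subject)) {
    agg <- suppressWarnings(
      aggregate_subject(by_subject[[sid]]$curves, by_subject[[sid]]$params,
                        by_subject[[sid]]$rej))
    if (!is.null(agg)) aggregates[[sid]] <- agg
  }
  st <- subject_table(aggregates, subjects)
  fits <- if (nrow(st) >= 6) fit_all(st) else NULL

  manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_recordings = length(flat), n_subjects = length(aggregates),
    counts = as.list(counts))

  out <- structure(list(parameters = parameters, aggregates = aggregates,
                        subject_table = st, fits = fits,
                        rejections = rejections, manifest = manifest,
                        config = config),
                   class = "stance_pipeline")
  if (!is.null(config$out_dir)) out <- write_pipeline_outputs(out)
  out
}

# atomic write helper: write to temp file in the same directory, rename
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  path
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_params <- atomic_write(function(f) write_parameters(result$parameters, f),
                           file.path(dir, "parameters.csv"))
  p_subj <- atomic_write(function(f)
    utils::write.csv(result$subject_table, f, row.names = FALSE),
    file.path(dir, "subjects_aggregated.csv"))
  p_rej <- atomic_write(function(f)
    utils::write.csv(result$rejections, f, row.names = FALSE),
    file.path(dir, "rejections.csv"))
  p_curves <- atomic_write(function(f)
    write_curve_matrix(result$aggregates, f),
    file.path(dir, "subject_curves.csv"))
  paths <- c(p_params, p_subj, p_rej, p_curves)
  if (!is.null(result$fits)) {
    p_fits <- atomic_write(function(f)
      utils::write.csv(as.data.frame(result$fits), f, row.names = FALSE),
      file.path(dir, "regression_fits.csv"))
    p_tab <- atomic_write(function(f)
      utils::write.csv(format_fit_table(result$fits), f, row.names = FALSE),
      file.path(dir, "regression_table.csv"))
    fits_json <- lapply(unclass(result$fits), function(f)
      f[c("dependent", "model", "n", "coefficients", "intercept",
          "r2", "adjusted_r2", "model_p")])
    p_json <- atomic_write(function(f)
      jsonlite::write_json(fits_json, f, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows"),
      file.path(dir, "regression_fits.json"))
    paths <- c(paths, p_fits, p_tab, p_json)
  }
  result$manifest$outputs <- as.list(tools::md5sum(paths))
  names(result$manifest$outputs) <- basename(paths)
  atomic_write(function(f)
    jsonlite::write_json(result$manifest, f, auto_unbox = TRUE, digits = NA),
    file.path(dir, "manifest.json"))
  result
}

#' @export
print.stance_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<stance_pipeline>\n")
  cat(sprintf("  %d recordings, %d subjects aggregated\n",
              m$n_recordings, m$n_subjects))
  cat(sprintf("  events: %d detected, %d accepted, %d non-step, %d degenerate\n",
              m$counts$events_detected, m$counts$accepted,
              m$counts$rejected_nonstep, m$counts$rejected_degenerate))
  if (!is.null(x$fits)) print(x$fits)
  invisible(x)
}

#' Plot group mean stance curves with 95% confidence bands
#'
#' Splits the subject aggregates by a predicate (e.g. oldest vs youngest
#' half) and draws each group's mean normalized stance curve with its
#' pointwise 95% confidence band.
#'
#' @param aggregates list of `subject_aggregate` objects (or a
#'   `stance_pipeline`, whose aggregates are used).
#' @param split logical vector, `TRUE` for group A; or the name of a
#'   profile column to median-split on when `profiles` is given.
#' @param profiles subject profiles, required when `split` is a column
#'   name.
#' @param labels legend labels for the two groups.
#' @param out_path optional file path; `.png` or `.svg` select the
#'   device. `NULL` draws on the current device.
#' @return the [group_curve_band()] result, invisibly.
#' @export
plot_group_curves <- function(aggregates, split, profiles = NULL,
                              labels = c("group A", "group B"),
                              out_path = NULL) {
  if (inherits(aggregates, "stance_pipeline")) {
    if (is.null(profiles)) profiles <- aggregates$subject_table
    aggregates <- aggregates$aggregates
  }
  if (is.character(split) && length(split) == 1) {
    if (is.null(profiles)) stop("profiles needed to split on a column name")
    ids <- vapply(aggregates, function(a) a$subject_id, character(1))
    v <- profiles[[split]][match(ids, profiles$subject_id)]
    med <- stats::median(v)
    split_vec <- v > med
    if (identical(labels, c("group A", "group B")))
      labels <- paste(split, c("> median", "<= median"))
    split <- split_vec
  }
  bands <- group_curve_band(aggregates, split)
  if (bands$A$n < 2 || bands$B$n < 2)
    stop("each group needs at least 2 subjects for a confidence band")
  if (!is.null(out_path)) {
    ext <- tolower(tools::file_ext(out_path))
    switch(ext,
           png = grDevices::png(out_path, width = 900, height = 600),
           svg = grDevices::svg(out_path, width = 9, height = 6),
           stop("unsupported figure format: ", ext))
    on.exit(grDevices::dev.off())
  }
  xs <- 0:99
  ylim <- range(unlist(lapply(bands, function(b) c(b$lower, b$upper))),
                na.rm = TRUE)
  graphics::plot(NULL, xlim = c(0, 99), ylim = ylim,
                 xlab = "% stance phase duration",
                 ylab = "force [% body weight]",
                 main = "Group mean stance curves (95% CI)")
  cols <- c(grDevices::rgb(0.9, 0.5, 0.1, 0.35),
            grDevices::rgb(0.1, 0.4, 0.8, 0.35))
  line_cols <- c("darkorange3", "dodgerblue4")
  for (i in 1:2) {
    b <- bands[[i]]
    graphics::polygon(c(xs, rev(xs)), c(b$lower, rev(b$upper)),
                      col = cols[i], border = NA)
    graphics::lines(xs, b$mean, col = line_cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = labels, col = line_cols, lwd = 2,
                   bty = "n")
  invisible(bands)
}

#' @export
plot.stance_pipeline <- function(x, split = "age", ...) {
  plot_group_curves(x, split, profiles = x$subject_table, ...)
}
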