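#' Segmentation configuration
#'
#' Thresholds for stance-phase step detection. Defaults follow the
#' standard protocol for treadmill insole data: a stance candidate is any
#' activity of consecutive force readings above 30 N, with a tolerance of
#' up to three consecutive missing samples (device faults), and candidates
#' shorter than 300 ms or longer than 2000 ms are discarded.
#'
#' @param force_threshold force in Newton; samples must be strictly above
#'   this to count as ground contact.
#' @param max_gap maximum number of consecutive missing samples bridged
#'   inside one stance event.
#' @param min_duration,max_duration inclusive duration gate in ms,
#'   measured first-to-last sample.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(force_threshold = 30, max_gap = 3,
                       min_duration = 300, max_duration = 2000) {
  if (force_threshold <= 0 || max_gap <= 0 || min_duration <= 0 ||
      max_duration <= 0)
    stop("all segmentation thresholds must be positive")
  if (min_duration >= max_duration)
    stop("min_duration must be smaller than max_duration")
  structure(list(force_threshold = force_threshold, max_gap = max_gap,
                 min_duration = min_duration, max_duration = max_duration),
            class = "seg_config")
}

#' Detect stance events in a recording
#'
#' Finds maximal runs of samples whose force is strictly above the
#' threshold. Runs separated only by short gaps of missing samples (at
#' most `max_gap` consecutive `NA`s) are merged into one event; a
#' non-missing sub-threshold sample always terminates a run. Candidates
#' whose first-to-last-sample duration falls outside the inclusive
#' `[min_duration, max_duration]` gate are discarded.
#'
#' @param rec an [insole_recording].
#' @param cfg a [seg_config].
#' @return list of `stance_event` objects in temporal order, with a
#'   `report` attribute holding stage counts (see
#'   [segmentation_report()]).
#' @export
detect_stance_events <- function(rec, cfg = seg_config()) {
  stopifnot(inherits(rec, "insole_recording"), inherits(cfg, "seg_config"))
  f <- rec$force
  n <- length(f)
  if (n == 0) {
    events <- list()
    attr(events, "report") <- list(candidate_runs = 0L, gap_merges = 0L,
                                   duration_rejected = 0L, accepted = 0L)
    attr(events, "config") <- cfg
    return(events)
  }
  # state per sample: 2 = above threshold, 1 = missing, 0 = below
  state <- integer(n)
  state[is.na(f)] <- 1L
  state[!is.na(f) & f > cfg$force_threshold] <- 2L

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  # candidate pieces: stretches of {above, missing} runs, split where a
  # missing run exceeds max_gap, then trimmed to 'above' runs at both ends
  pieces <- list()
  gap_merges <- 0L
  i <- 1L
  nr <- length(r$values)
  while (i <= nr) {
    if (r$values[i] != 2L) { i <- i + 1L; next }
    # start a piece at an 'above' run; extend over tolerated gaps
    p_start <- starts[i]
    p_end <- ends[i]
    j <- i + 1L
    merges <- 0L
    while (j + 1L <= nr && r$values[j] == 1L &&
           r$lengths[j] <= cfg$max_gap && r$values[j + 1L] == 2L) {
      merges <- merges + 1L
      p_end <- ends[j + 1L]
      j <- j + 2L
    }
    pieces[[length(pieces) + 1L]] <- c(p_start, p_end, merges)
    i <- j
  }

  events <- list()
  duration_rejected <- 0L
  gap_merges <- 0L
  for (p in pieces) {
    gap_merges <- gap_merges + p[3]
    dur <- rec$timestamps[p[2]] - rec$timestamps[p[1]]
    if (dur < cfg$min_duration || dur > cfg$max_duration) {
      duration_rejected <- duration_rejected + 1L
      next
    }
    idx <- p[1]:p[2]
    events[[length(events) + 1L]] <- structure(
      list(subject_id = rec$subject_id, side = rec$side,
           start_index = p[1], end_index = p[2],
           timestamps = rec$timestamps[idx], raw_force = f[idx],
           duration = dur, sample_rate = rec$sample_rate),
      class = "stance_event")
  }
  attr(events, "report") <- list(
    candidate_runs = length(pieces),
    gap_merges = gap_merges,
    duration_rejected = duration_rejected,
    accepted = length(events))
  attr(events, "config") <- cfg
  events
}

#' @export
print.stance_event <- function(x, ...) {
  cat(sprintf("<stance_event> subject %s (%s), samples %d-%d, %.0f ms\n",
              x$subject_id, x$side, x$start_index, x$end_index, x$duration))
  invisible(x)
}

#' Summarize a segmentation run
#'
#' Returns the stage counts collected while detecting stance events:
#' number of candidate runs, gap merges applied, candidates rejected by
#' the duration gate, and accepted events. Counts satisfy
#' `candidate_runs == accepted + duration_rejected`.
#'
#' @param rec the source [insole_recording].
#' @param events the event list returned by [detect_stance_events()];
#'   if the report attribute has been stripped, detection is re-run
#'   with the attached config.
#' @return list with elements `candidate_runs`, `gap_merges`,
#'   `duration_rejected`, `accepted`.
#' @export
segmentation_report <- function(rec, events) {
  rep <- attr(events, "report")
  if (is.null(rep)) {
    cfg <- attr(events, "config")
    if (is.null(cfg)) cfg <- seg_config()
    rep <- attr(detect_stance_events(rec, cfg), "report")
  }
  rep
}
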