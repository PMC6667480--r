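#' Score rest intervals from a minute-epoch actigraphy series
#'
#' Candidate rest runs are maximal stretches where the 11-minute centred
#' running median of activity falls below `activity_threshold`.  Candidate
#' runs separated by less than `merge_gap_min` minutes of non-rest epochs
#' are merged first (an automated analogue of manually adjusting interval
#' boundaries when they disagree with the activity/light distributions by an
#' hour or more).  A merged run qualifies as a rest interval only if its
#' mean lux is below `lux_threshold`; qualifying runs of at least three
#' hours become main rest intervals, shorter ones are marked as naps (naps
#' are excluded from the non-photic input downstream).
#'
#' The thresholds stand in for proprietary scoring software settings; they
#' are documented defaults validated against this package's synthetic
#' generator, not a replication of any commercial algorithm.
#'
#' @param series An [epoch_series()].
#' @param expected_sleep_windows Optional data.frame (`start`, `end`,
#'   POSIXct) of schedule-derived expected sleep episodes.  Scoring itself
#'   classifies by duration (naps are sub-3 h runs); the windows are
#'   consumed by [impute_offwrist_sleep()], and the argument is accepted
#'   here so both steps can share one call signature.
#' @param activity_threshold Counts/min, on the smoothed series (default 40).
#' @param lux_threshold Mean lux over the interval (default 10).
#' @param smooth_window Centred running-median width in minutes (odd,
#'   default 11).
#' @param min_main_h Minimum main rest duration in hours (default 3).
#' @param merge_gap_min Merge candidates separated by less than this many
#'   minutes (default 60).
#' @return A data.frame of class `rest_intervals` with columns `start`,
#'   `end` (POSIXct, interval covers epochs start..end inclusive of the
#'   final minute) and `kind` (`"main"` or `"nap"`); zero rows (with a
#'   warning) when nothing qualifies.
#' @export
score_rest_intervals <- function(series, expected_sleep_windows = NULL,
                                 activity_threshold = 40, lux_threshold = 10,
                                 smooth_window = 11, min_main_h = 3,
                                 merge_gap_min = 60) {
  stopifnot(inherits(series, "epoch_series"))
  if (nrow(series) < 24 * 60) stop("series must span at least 24 h")
  act <- stats::runmed(series$activity, smooth_window, endrule = "median")
  low <- act < activity_threshold
  runs <- rle_runs(low)
  runs <- runs[runs$value, , drop = FALSE]
  if (nrow(runs) > 1) {
    # merge candidates separated by short non-rest gaps
    merged <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap < merge_gap_min) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
    runs <- merged
  }
  out <- list()
  for (k in seq_len(nrow(runs))) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    if (mean(series$lux[i0:i1]) >= lux_threshold) next
    dur_h <- (i1 - i0 + 1) / 60
    kind <- if (dur_h >= min_main_h) "main" else "nap"
    out[[length(out) + 1]] <- data.frame(
      start = series$time[i0], end = series$time[i1] + 60, kind = kind)
  }
  if (length(out) == 0L) {
    warning("no rest intervals found")
    res <- data.frame(start = series$time[0], end = series$time[0],
                      kind = character(0))
  } else {
    res <- do.call(rbind, out)
  }
  class(res) <- c("rest_intervals", "data.frame")
  res
}

# maximal runs of equal values in a logical vector
rle_runs <- function(v) {
  r <- rle(v)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, value = r$values)
}

#' Impute off-wrist gaps that align with expected sleep
#'
#' Off-wrist stretches that overlap a schedule-expected sleep episode by at
#' least `min_overlap` of the episode's duration are treated as the sleep
#' episode itself: their lux and activity are zeroed and the gap becomes a
#' main rest interval of kind `imputed_offwrist`.  Remaining off-wrist gaps
#' keep lux 0 (a conservative no-light assumption) and trigger a warning.
#'
#' @param series An [epoch_series()].
#' @param intervals A `rest_intervals` data.frame (from
#'   [score_rest_intervals()]).
#' @param expected_sleep_windows Data.frame with POSIXct `start`, `end`.
#' @param min_overlap Fraction of the expected window that must be covered
#'   (default 0.5).
#' @return A list with the modified `series` and augmented `intervals`
#'   (sorted by start time).
#' @export
impute_offwrist_sleep <- function(series, intervals, expected_sleep_windows,
                                  min_overlap = 0.5) {
  stopifnot(inherits(series, "epoch_series"))
  gaps <- rle_runs(!series$worn)
  gaps <- gaps[gaps$value, , drop = FALSE]
  if (nrow(gaps) == 0L) return(list(series = series, intervals = intervals))
  extra <- list()
  unmatched <- 0L
  for (k in seq_len(nrow(gaps))) {
    g0 <- series$time[gaps$start[k]]
    g1 <- series$time[gaps$end[k]] + 60
    matched <- FALSE
    for (w in seq_len(nrow(expected_sleep_windows))) {
      w0 <- expected_sleep_windows$start[w]
      w1 <- expected_sleep_windows$end[w]
      ov <- as.numeric(difftime(min(g1, w1), max(g0, w0), units = "hours"))
      if (ov >= min_overlap * as.numeric(difftime(w1, w0, units = "hours"))) {
        idx <- gaps$start[k]:gaps$end[k]
        series$lux[idx] <- 0
        series$activity[idx] <- 0
        extra[[length(extra) + 1]] <- data.frame(
          start = g0, end = g1, kind = "imputed_offwrist")
        matched <- TRUE
        break
      }
    }
    if (!matched) unmatched <- unmatched + 1L
  }
  if (unmatched > 0)
    warning(sprintf("%d off-wrist gap(s) did not match an expected sleep window; lux carried as 0", unmatched))
  if (length(extra) > 0) {
    intervals <- rbind(as.data.frame(intervals), do.call(rbind, extra))
    intervals <- intervals[order(intervals$start), ]
    rownames(intervals) <- NULL
    class(intervals) <- c("rest_intervals", "data.frame")
  }
  list(series = series, intervals = intervals)
}

#' Average mid-sleep clock time over main rest intervals
#'
#' The mid-point of each main (or imputed) rest interval is taken as a clock
#' time and the intervals are averaged circularly on the 24 h clock, so
#' sleep episodes straddling midnight are handled correctly.  Average
#' diurnal mid-sleep is the model's heuristic estimate of the first CBT
#' nadir.
#'
#' @param intervals A `rest_intervals` data.frame.
#' @param kinds Interval kinds that count (default main and imputed).
#' @return Mean mid-sleep clock time, hours.
#' @export
mid_sleep <- function(intervals, kinds = c("main", "imputed_offwrist")) {
  keep <- intervals[intervals$kind %in% kinds, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no main rest intervals to average")
  mids <- keep$start + as.numeric(difftime(keep$end, keep$start, units = "secs")) / 2
  circular_mean_hours(hours_of_day(mids))
}

#' Build the square-wave non-photic drive from scored rest
#'
#' The rest indicator \eqn{\sigma(t)} is 1 inside main (including imputed
#' off-wrist) rest intervals and 0 elsewhere — naps are deliberately
#' excluded — and the drive is \eqn{\hat N(t) = \rho(1/3 - \sigma(t))}:
#' a small positive push while awake and a stronger negative one during the
#' main rest episode, integrating to zero over a day with 8 h rest.
#'
#' @param series An [epoch_series()] (defines the time grid).
#' @param intervals A `rest_intervals` data.frame.
#' @param params A [circ_params()] (uses `rho`).
#' @return Numeric vector of \eqn{\hat N} per epoch, same length as the
#'   series.
#' @export
build_nonphotic_input <- function(series, intervals, params = circ_params()) {
  stopifnot(inherits(series, "epoch_series"))
  sigma <- rep(0, nrow(series))
  main <- intervals[intervals$kind %in% c("main", "imputed_offwrist"), ,
                    drop = FALSE]
  for (k in seq_len(nrow(main))) {
    idx <- series$time >= main$start[k] & series$time < main$end[k]
    sigma[idx] <- 1
  }
  params$rho * (1 / 3 - sigma)
}

#' Write scored rest intervals as CSV
#' @param intervals A `rest_intervals` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rest_intervals <- function(intervals, path) {
  utils::write.csv(data.frame(
    start = format(intervals$start, "%Y-%m-%dT%H:%M:%S"),
    end = format(intervals$end, "%Y-%m-%dT%H:%M:%S"),
    kind = intervals$kind), path, row.names = FALSE)
  invisible(path)
}
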