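#' Wrap a phase difference onto (-12, 12] hours
#'
#' Phase differences on the 24 h clock are ambiguous up to whole days; this
#' maps any difference to the nearest signed offset, with the convention that
#' exactly half a cycle is reported as +12.
#'
#' @param d Numeric vector of differences in hours.
#' @return Numeric vector in (-12, 12].
#' @examples
#' wrap_hours(c(0.5 - 23.5, 13, -12.5))
#' @export
wrap_hours <- function(d) {
  w <- ((d %% 24) + 24) %% 24
  ifelse(w > 12, w - 24, w)
}

#' Clock time of a moment expressed in hours
#'
#' @param h Hours (may exceed 24 or be negative).
#' @return Clock hours in [0, 24).
#' @export
clock_hours <- function(h) ((h %% 24) + 24) %% 24

#' Duration from one clock time to the next occurrence of another
#'
#' The interval runs forward from `from_h` to the next time the clock reads
#' `to_h`, so intervals straddling midnight are handled naturally
#' (e.g. 23:16 to 07:23 is 8 h 07 min).
#'
#' @param from_h,to_h Clock times in hours, in [0, 24).
#' @return Duration in hours, in (0, 24].
#' @export
clock_duration <- function(from_h, to_h) {
  d <- (to_h - from_h) %% 24
  ifelse(d == 0, 24, d)
}

#' Circular mean of clock times
#'
#' Averages clock times as unit vectors on the 24 h circle, which is the
#' correct notion of "average time of day" when times may straddle midnight.
#'
#' @param h Clock times in hours.
#' @param na.rm Drop missing values first.
#' @return Mean clock time in [0, 24), or NA if no data.
#' @export
circular_mean_hours <- function(h, na.rm = FALSE) {
  if (na.rm) h <- h[!is.na(h)]
  if (length(h) == 0L) return(NA_real_)
  a <- 2 * pi * h / 24
  m <- atan2(mean(sin(a)), mean(cos(a)))
  clock_hours(m * 24 / (2 * pi))
}

#' Format decimal hours as HH:MM
#' @param h Clock hours.
#' @return Character vector like "03:19".
#' @export
format_clock <- function(h) {
  h <- clock_hours(h)
  mins <- round(h * 60)
  sprintf("%02d:%02d", (mins %/% 60) %% 24, mins %% 60)
}

# hours since midnight (local to the timestamp's own representation)
hours_of_day <- function(t) {
  as.numeric(difftime(t, trunc(t, "days"), units = "hours"))
}

# hours since an anchor timestamp
hours_since <- function(t, t0) as.numeric(difftime(t, t0, units = "hours"))
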