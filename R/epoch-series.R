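#' Construct a minute-epoch actigraphy series
#'
#' The canonical container for wrist-actigraph recordings: a uniform
#' one-minute grid of photopic lux, activity counts and a wear flag.
#'
#' @param time POSIXct timestamps on a uniform one-minute grid.
#' @param lux Non-negative photopic lux per epoch.
#' @param activity Non-negative activity counts per epoch.
#' @param worn Logical wear status per epoch (default all TRUE).
#' @return A data.frame of class `epoch_series`.
#' @export
epoch_series <- function(time, lux, activity, worn = NULL) {
  if (is.null(worn)) worn <- rep(TRUE, length(time))
  stopifnot(length(lux) == length(time), length(activity) == length(time),
            length(worn) == length(time))
  if (anyNA(time)) stop("timestamps contain missing values")
  d <- as.numeric(diff(time), units = "mins")
  if (length(d) > 0 && any(abs(d - 1) > 1e-6))
    stop("timestamps are not a uniform 1-minute grid")
  if (any(lux < 0, na.rm = TRUE)) stop("lux must be non-negative")
  if (any(activity < 0, na.rm = TRUE)) stop("activity must be non-negative")
  out <- data.frame(time = time, lux = lux, activity = activity,
                    worn = as.logical(worn))
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' Read minute-epoch actigraphy from a delimited text file
#'
#' Supports a generic CSV dialect (columns `time`, `lux`, `activity`,
#' optional `worn`) and an Actiwatch-Spectrum-style export profile (columns
#' `timestamp`, `white_light`, `activity`, optional `off_wrist` where 1
#' means not worn).  Rows are sorted by time; regular multi-minute epochs
#' are expanded to the 1-minute grid by replication; interior gaps are
#' filled with `worn = FALSE`, zero lux and zero activity, and a gap summary
#' is reported via `message()`.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect `"generic"` or `"actiwatch"`.
#' @param col_map Optional named character vector overriding the column
#'   names, e.g. `c(time = "ts", lux = "light", activity = "act")`.
#' @param tz Time zone for parsing timestamps (default UTC).
#' @return An [epoch_series()].
#' @export
read_actigraphy <- function(path, dialect = c("generic", "actiwatch"),
                            col_map = NULL, tz = "UTC") {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- switch(dialect,
    generic = c(time = "time", lux = "lux", activity = "activity", worn = "worn"),
    actiwatch = c(time = "timestamp", lux = "white_light",
                  activity = "activity", worn = "off_wrist"))
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  need <- map[c("time", "lux", "activity")]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  tm <- tryCatch(
    as.POSIXct(raw[[map[["time"]]]], tz = tz,
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%d %H:%M")),
    error = function(e) NA)
  if (anyNA(tm)) stop("unparseable timestamps in ", path)
  o <- order(tm)
  tm <- tm[o]
  lux <- as.numeric(raw[[map[["lux"]]]])[o]
  act <- as.numeric(raw[[map[["activity"]]]])[o]
  worn <- if (map[["worn"]] %in% names(raw)) {
    w <- raw[[map[["worn"]]]][o]
    if (dialect == "actiwatch") !(as.numeric(w) > 0) else as.logical(w)
  } else rep(TRUE, length(tm))
  if (any(lux < 0, na.rm = TRUE) || any(act < 0, na.rm = TRUE))
    stop("negative lux or activity values in ", path)
  if (anyDuplicated(tm)) stop("duplicate timestamps in ", path)

  d <- as.numeric(diff(tm), units = "mins")
  step <- if (length(d) > 0) min(d) else 1
  if (abs(step - round(step)) > 1e-6 || round(step) < 1)
    stop("irregular epoch grid in ", path, " (minimum spacing ", step, " min)")
  step <- as.integer(round(step))
  if (any(abs(d / step - round(d / step)) > 1e-6))
    stop("irregular epoch grid in ", path,
         ": spacings are not multiples of ", step, " min")
  if (step > 1) {
    # expand regular multi-minute epochs onto the 1-minute grid
    idx <- rep(seq_along(tm), each = step)
    tm <- rep(tm, each = step) + rep(0:(step - 1), length(tm)) * 60
    lux <- lux[idx]; act <- act[idx]; worn <- worn[idx]
    d <- as.numeric(diff(tm), units = "mins")
  }
  if (any(d > 1 + 1e-6)) {
    # fill interior gaps explicitly
    full <- seq(tm[1], tm[length(tm)], by = "1 min")
    hit <- match(as.numeric(full), as.numeric(tm))
    gap <- is.na(hit)
    message(sprintf("%s: filled %d missing epochs across %d gap(s) (worn = FALSE)",
                    basename(path), sum(gap), sum(diff(which(gap)) > 1) + 1L))
    lux <- ifelse(gap, 0, lux[hit])
    act <- ifelse(gap, 0, act[hit])
    worn <- ifelse(gap, FALSE, worn[hit])
    tm <- full
  }
  epoch_series(tm, lux, act, worn)
}

#' Write an epoch series in the generic actigraphy dialect
#'
#' @param series An [epoch_series()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_actigraphy <- function(series, path) {
  df <- data.frame(time = format(series$time, "%Y-%m-%dT%H:%M:%S"),
                   lux = series$lux, activity = series$activity,
                   worn = series$worn)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
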