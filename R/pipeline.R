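#' Expected sleep windows derived from a work diary
#'
#' Schedule-level expectation used for nap exclusion and off-wrist
#' imputation: a nocturnal window on every date up to the first night
#' shift, and a daytime window on the morning after each night shift.
#'
#' @param series An [epoch_series()] (defines the covered dates).
#' @param diary Data.frame with `shift_type`, POSIXct `start`, `end`.
#' @param diurnal_window,post_night_window Clock-hour templates
#'   `c(start, end)`; the diurnal window crosses midnight.
#' @return Data.frame with POSIXct `start`, `end`.
#' @export
expected_sleep_windows <- function(series, diary,
                                   diurnal_window = c(21.5, 9.5),
                                   post_night_window = c(8.5, 17)) {
  nights <- diary[diary$shift_type == "night", , drop = FALSE]
  if (nrow(nights) == 0L) stop("diary contains no night shifts")
  night_start <- min(nights$start)
  day0 <- trunc(series$time[1], "days")
  out <- list()
  d <- day0
  while (d + diurnal_window[1] * 3600 < night_start) {
    out[[length(out) + 1]] <- data.frame(
      start = d + diurnal_window[1] * 3600,
      end = d + (24 + diurnal_window[2]) * 3600)
    d <- d + 86400
  }
  for (k in seq_len(nrow(nights))) {
    morn <- trunc(nights$end[k], "days")
    out[[length(out) + 1]] <- data.frame(
      start = morn + post_night_window[1] * 3600,
      end = morn + post_night_window[2] * 3600)
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Run the phase-prediction pipeline for one subject
#'
#' Full chain: rest scoring and off-wrist imputation, average diurnal
#' mid-sleep, oscillator initialization (mid-sleep heuristic or measured
#' "oracle" acrophase), light processing, integration in photic-only and
#' photic+non-photic modes over one shared photic drive, CBTmin
#' extraction, and comparison of the dated predicted acrophases against
#' the cosinor reference phases.
#'
#' @param subject A list with `series` (an [epoch_series()]), `diary`,
#'   `urine_diurnal`, `urine_night` (see [generate_cohort()] for the
#'   shapes; file-based inputs can be loaded with [read_actigraphy()],
#'   [read_diary()], [read_urine()]).
#' @param params A [circ_params()]; `rho = 0` collapses PNP onto the
#'   photic-only model.
#' @param modes Character subset of `c("photic", "pnp")`.
#' @param init `"midsleep"` (heuristic, default) or `"oracle"` (initialize
#'   from the measured diurnal acrophase).
#' @param cbtmin_offset_h Fixed CBTmin-to-acrophase offset, hours.
#' @param substeps Runge-Kutta substeps per minute epoch.
#' @param require_significant Insist on significant cosinor fits.
#' @param keep_trajectory Attach the integrated trajectories to the report.
#' @return A list of class `subject_report`: measured fits/acrophases,
#'   per-mode predicted acrophases and shifts, wrapped errors, mid-sleep,
#'   target dates and data-coverage fields.
#' @export
run_subject <- function(subject, params = circ_params(),
                        modes = c("photic", "pnp"),
                        init = c("midsleep", "oracle"),
                        cbtmin_offset_h = 0, substeps = 1L,
                        require_significant = TRUE,
                        keep_trajectory = FALSE) {
  init <- match.arg(init)
  modes <- match.arg(modes, several.ok = TRUE)
  series <- subject$series
  diary <- subject$diary

  nights <- diary[diary$shift_type == "night", , drop = FALSE]
  if (nrow(nights) == 0L) stop("diary contains no night shifts")
  night_start <- min(nights$start)
  last_shift_end <- max(nights$end)

  esw <- expected_sleep_windows(series, diary)
  intervals <- score_rest_intervals(series, esw)
  imp <- impute_offwrist_sleep(series, intervals, esw)
  series <- imp$series
  intervals <- imp$intervals

  main <- intervals[intervals$kind %in% c("main", "imputed_offwrist"), ,
                    drop = FALSE]
  diurnal_main <- main[main$start + as.numeric(
    difftime(main$end, main$start, units = "secs")) / 2 < night_start, ,
    drop = FALSE]
  midsleep_h <- mid_sleep(diurnal_main)

  fit_d <- cosinor_fit(excretion_rates(subject$urine_diurnal))
  fit_n <- cosinor_fit(excretion_rates(subject$urine_night))
  if (require_significant && (!fit_d$significant || !fit_n$significant))
    stop("non-significant cosinor reference fit (override with require_significant = FALSE)")

  cbtmin_est <- if (init == "oracle") fit_d$acrophase else midsleep_h
  t0_clock <- hours_of_day(series$time[1])
  t0_date <- as.Date(trunc(series$time[1], "days"))
  state0 <- initial_state_from_cbtmin(t0_clock, cbtmin_est, params,
                                      lux0 = series$lux[1])

  dp <- light_processor(series$lux, params)
  Nhat <- build_nonphotic_input(series, intervals, params)

  # target dates: midpoint date of the diurnal collection; date of the
  # morning after the final night shift
  d_mid <- min(subject$urine_diurnal$block_start) +
    as.numeric(difftime(max(subject$urine_diurnal$block_end),
                        min(subject$urine_diurnal$block_start),
                        units = "secs")) / 2
  diurnal_date <- as.Date(trunc(d_mid, "days"))
  night_date <- as.Date(trunc(last_shift_end, "days"))

  res <- list()
  for (mode in modes) {
    drv <- structure(list(Bhat = dp$Bhat,
                          Nhat = if (mode == "pnp") Nhat else rep(0, length(Nhat)),
                          n = dp$n, epoch_min = 1), class = "drive_series")
    traj <- integrate_pacemaker(drv, state0, params, t0_clock_h = t0_clock,
                                t0_date = t0_date, substeps = substeps)
    pred_d <- predict_acrophase(traj, diurnal_date, cbtmin_offset_h)
    pred_n <- predict_acrophase(traj, night_date, cbtmin_offset_h)
    res[[mode]] <- list(
      predicted_diurnal_h = pred_d,
      predicted_night_h = pred_n,
      predicted_shift_h = wrap_hours(pred_d - pred_n),
      error_diurnal_h = wrap_hours(fit_d$acrophase - pred_d),
      error_night_h = wrap_hours(fit_n$acrophase - pred_n),
      trajectory = if (keep_trajectory) traj else NULL)
    res[[mode]]$error_shift_h <- wrap_hours(
      wrap_hours(fit_d$acrophase - fit_n$acrophase) - res[[mode]]$predicted_shift_h)
  }

  structure(list(
    subject_id = subject$subject_id,
    measured_diurnal_h = fit_d$acrophase,
    measured_night_h = fit_n$acrophase,
    measured_shift_h = wrap_hours(fit_d$acrophase - fit_n$acrophase),
    cosinor_diurnal = fit_d, cosinor_night = fit_n,
    midsleep_h = midsleep_h, init = init, init_cbtmin_h = cbtmin_est,
    diurnal_date = diurnal_date, night_date = night_date,
    days_before_diurnal_acrophase = as.numeric(
      diurnal_date - as.Date(trunc(series$time[1], "days"))),
    n_night_shifts = nrow(nights),
    modes = res, rest_intervals = intervals),
    class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("Subject %s (init %s, mid-sleep %s)\n",
              x$subject_id, x$init, format_clock(x$midsleep_h)))
  cat(sprintf("  measured: diurnal %s, night %s, shift %+.2f h\n",
              format_clock(x$measured_diurnal_h),
              format_clock(x$measured_night_h), x$measured_shift_h))
  for (m in names(x$modes)) {
    r <- x$modes[[m]]
    cat(sprintf("  %-6s: diurnal %s (err %+.2f), night %s (err %+.2f), shift %+.2f h\n",
                m, format_clock(r$predicted_diurnal_h), r$error_diurnal_h,
                format_clock(r$predicted_night_h), r$error_night_h,
                r$predicted_shift_h))
  }
  invisible(x)
}

#' Run the pipeline over a cohort and summarize prediction error
#'
#' Applies [run_subject()] to every subject with per-subject failure
#' isolation, then assembles the comparison table (diurnal acrophase,
#' night acrophase and phase shift, for each model mode) and the group
#' summaries, including direction-of-shift accuracy.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or any
#'   list with a `subjects` element of [run_subject()]-shaped inputs.
#' @param ... Passed to [run_subject()].
#' @return A list of class `cohort_report`: `comparisons` (long
#'   data.frame: subject_id, schedule, mode, measured_h, predicted_h,
#'   error_h, abs_error_h), `summary` (one row per schedule x mode),
#'   `direction` (per mode), `reports` (per-subject), `failures` (named
#'   character vector of error messages).
#' @export
run_cohort <- function(cohort, ...) {
  subjects <- cohort$subjects
  reports <- list()
  failures <- character(0)
  for (s in subjects) {
    r <- tryCatch(run_subject(s, ...), error = function(e) e)
    if (inherits(r, "error")) {
      failures[[s$subject_id]] <- conditionMessage(r)
    } else {
      reports[[s$subject_id]] <- r
    }
  }
  if (length(reports) == 0L)
    stop("all subjects failed; first error: ", failures[[1]])

  rows <- list()
  for (r in reports) {
    for (m in names(r$modes)) {
      md <- r$modes[[m]]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = r$subject_id,
        schedule = c("diurnal", "night", "shift"), mode = m,
        measured_h = c(r$measured_diurnal_h, r$measured_night_h,
                       r$measured_shift_h),
        predicted_h = c(md$predicted_diurnal_h, md$predicted_night_h,
                        md$predicted_shift_h),
        error_h = c(md$error_diurnal_h, md$error_night_h, md$error_shift_h))
    }
  }
  comparisons <- do.call(rbind, rows)
  comparisons$abs_error_h <- abs(comparisons$error_h)

  summaries <- list()
  direction <- list()
  for (m in unique(comparisons$mode)) {
    for (sched in c("diurnal", "night", "shift")) {
      sub <- comparisons[comparisons$mode == m & comparisons$schedule == sched, ]
      sm <- summarize_phase_errors(sub)
      summaries[[paste(sched, m, sep = "_")]] <- data.frame(
        schedule = sched, mode = m, n = sm$n,
        mean_error = sm$mean_error, sd_error = sm$sd_error,
        abs_mean_error = sm$abs_mean_error,
        abs_min_error = sm$abs_min_error, abs_max_error = sm$abs_max_error,
        pct_within_30 = sm$pct_within_30, pct_within_60 = sm$pct_within_60,
        pct_within_120 = sm$pct_within_120,
        pearson_r = sm$pearson_r, r2 = sm$r2, r_pvalue = sm$r_pvalue,
        paired_t = sm$paired_t, t_pvalue = sm$t_pvalue)
    }
    sh <- comparisons[comparisons$mode == m & comparisons$schedule == "shift", ]
    direction[[m]] <- direction_accuracy(sh$measured_h, sh$predicted_h)
  }
  structure(list(comparisons = comparisons,
                 summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 direction = direction, reports = reports,
                 failures = failures),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d subject(s), %d failure(s)\n",
              length(x$reports), length(x$failures)))
  df <- x$summary
  cat(sprintf("  %-8s %-7s mean %-6s |err| %-6s ±30' %-4s ±60' %-4s ±120'\n",
              "schedule", "mode", "", "", "", ""))
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-8s %-7s %+0.2f   %0.2f    %3.0f%%   %3.0f%%   %3.0f%%\n",
                df$schedule[i], df$mode[i], df$mean_error[i],
                df$abs_mean_error[i], df$pct_within_30[i],
                df$pct_within_60[i], df$pct_within_120[i]))
  for (m in names(x$direction))
    cat(sprintf("  direction accuracy (%s): %.0f%%\n",
                m, 100 * x$direction[[m]]$accuracy))
  invisible(x)
}

#' Write a cohort report as CSV + JSON
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed): writes
#'   `comparisons.csv`, `summary.csv` and `summary.json`.
#' @return Invisibly, `dir`.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            direction = report$direction,
                            failures = as.list(report$failures)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a cohort from a fixture directory
#'
#' Reads back the per-subject CSV layout written by [write_cohort()]: one
#' directory per subject holding `actigraphy.csv`, `diary.csv`,
#' `urine_diurnal.csv` and `urine_night.csv`, plus an optional cohort-level
#' `truth_table.csv`.
#'
#' @param dir Cohort directory.
#' @param tz Time zone for parsing timestamps (default UTC).
#' @return A list with `subjects` (run-ready per-subject inputs) and
#'   `truth` (data.frame, or NULL when no truth table is present).
#' @export
read_cohort <- function(dir, tz = "UTC") {
  sds <- list.dirs(dir, recursive = FALSE)
  if (length(sds) == 0L) stop("no subject directories under ", dir)
  subjects <- lapply(sds, function(sd) {
    list(subject_id = basename(sd),
         series = read_actigraphy(file.path(sd, "actigraphy.csv"), tz = tz),
         diary = read_diary(file.path(sd, "diary.csv"), tz = tz),
         urine_diurnal = read_urine(file.path(sd, "urine_diurnal.csv"), tz = tz),
         urine_night = read_urine(file.path(sd, "urine_night.csv"), tz = tz))
  })
  truth_path <- file.path(dir, "truth_table.csv")
  structure(list(subjects = subjects,
                 truth = if (file.exists(truth_path))
                   utils::read.csv(truth_path) else NULL),
            class = "synthetic_cohort")
}
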