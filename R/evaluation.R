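#' Pair measured and predicted acrophases
#'
#' Joins measured and predicted clock times by subject (and optional
#' schedule) keys and computes the wrapped prediction error,
#' error = measured - predicted on the (-12, 12] circle, so a positive
#' error means the rhythm was measured later than predicted.
#'
#' @param measured,predicted Data.frames with columns `subject_id`,
#'   optionally `schedule`, and `acrophase_h` (clock hours).
#' @return Data.frame with `subject_id`, `schedule` (if present),
#'   `measured_h`, `predicted_h`, `error_h`, `abs_error_h`.  Subjects
#'   present on only one side are reported via a warning, not dropped
#'   silently from the message.
#' @export
compare_phases <- function(measured, predicted) {
  keys <- intersect(c("subject_id", "schedule"),
                    intersect(names(measured), names(predicted)))
  if (length(keys) == 0L) stop("no shared key columns (subject_id, schedule)")
  m <- measured[, c(keys, "acrophase_h")]
  p <- predicted[, c(keys, "acrophase_h")]
  names(m)[names(m) == "acrophase_h"] <- "measured_h"
  names(p)[names(p) == "acrophase_h"] <- "predicted_h"
  full <- merge(m, p, by = keys, all = TRUE)
  miss <- is.na(full$measured_h) | is.na(full$predicted_h)
  if (any(miss)) {
    warning(sprintf("%d unmatched measured/predicted pair(s) dropped: %s",
                    sum(miss),
                    paste(apply(full[miss, keys, drop = FALSE], 1, paste,
                                collapse = "/"), collapse = ", ")))
    full <- full[!miss, , drop = FALSE]
  }
  full$error_h <- wrap_hours(full$measured_h - full$predicted_h)
  full$abs_error_h <- abs(full$error_h)
  rownames(full) <- NULL
  full
}

#' Group summary of phase prediction errors
#'
#' Mirrors the usual field-validation report: mean and SD of the raw
#' (signed) error, mean/min/max absolute error, the fraction of subjects
#' predicted within +/-30, 60 and 120 minutes, the Pearson correlation
#' between measured and predicted times, and a paired t-test of measured
#' vs predicted (equivalently, of the raw errors against zero).
#'
#' @param comparisons Data.frame from [compare_phases()].
#' @return A list of class `phase_summary` with fields `n`, `mean_error`,
#'   `sd_error`, `abs_mean_error`, `abs_min_error`, `abs_max_error`,
#'   `pct_within_30`, `pct_within_60`, `pct_within_120` (percentages),
#'   `pearson_r`, `r2`, `r_pvalue`, `paired_t`, `t_pvalue`.  Correlation
#'   fields are NA with a warning when n < 3; test fields are NA when
#'   n < 2.
#' @export
summarize_phase_errors <- function(comparisons) {
  e <- comparisons$error_h
  n <- length(e)
  if (n == 0L) stop("no comparisons to summarize")
  out <- list(
    n = n,
    mean_error = mean(e),
    sd_error = if (n >= 2) stats::sd(e) else NA_real_,
    abs_mean_error = mean(abs(e)),
    abs_min_error = min(abs(e)),
    abs_max_error = max(abs(e)),
    pct_within_30 = 100 * mean(abs(e) <= 0.5),
    pct_within_60 = 100 * mean(abs(e) <= 1),
    pct_within_120 = 100 * mean(abs(e) <= 2),
    pearson_r = NA_real_, r2 = NA_real_, r_pvalue = NA_real_,
    paired_t = NA_real_, t_pvalue = NA_real_
  )
  if (n >= 3 && stats::sd(comparisons$measured_h) > 0 &&
      stats::sd(comparisons$predicted_h) > 0) {
    ct <- stats::cor.test(comparisons$measured_h, comparisons$predicted_h)
    out$pearson_r <- unname(ct$estimate)
    out$r2 <- unname(ct$estimate)^2
    out$r_pvalue <- ct$p.value
  } else if (n < 3) {
    warning("n < 3: correlation fields omitted")
  }
  if (n >= 2 && stats::sd(e) > 0) {
    tt <- stats::t.test(e, mu = 0)
    out$paired_t <- unname(tt$statistic)
    out$t_pvalue <- tt$p.value
  }
  class(out) <- "phase_summary"
  out
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("Phase prediction summary (n = %d)\n", x$n))
  cat(sprintf("  error: mean %.2f h (SD %.2f), |error|: mean %.2f, range %.2f-%.2f\n",
              x$mean_error, x$sd_error, x$abs_mean_error, x$abs_min_error,
              x$abs_max_error))
  cat(sprintf("  within ±30/±60/±120 min: %.0f%% / %.0f%% / %.0f%%\n",
              x$pct_within_30, x$pct_within_60, x$pct_within_120))
  if (!is.na(x$pearson_r))
    cat(sprintf("  r = %.2f (r2 = %.2f, p = %.3g); paired t = %.2f (p = %.3g)\n",
                x$pearson_r, x$r2, x$r_pvalue, x$paired_t, x$t_pvalue))
  invisible(x)
}

#' Direction-of-shift accuracy
#'
#' Fraction of subjects whose predicted phase shift has the same sign as the
#' measured one (delay vs advance); a zero shift counts as correct only
#' against a zero.  Also reports the confusion counts: false advances
#' (predicted advance, measured delay/zero) and false delays.
#'
#' @param measured_shifts,predicted_shifts Numeric vectors of phase shifts
#'   in hours (negative = delay), aligned by subject.
#' @return A list with `accuracy` (fraction), `n`, `false_advance`,
#'   `false_delay`, `false_zero`.
#' @export
direction_accuracy <- function(measured_shifts, predicted_shifts) {
  stopifnot(length(measured_shifts) == length(predicted_shifts))
  sm <- sign(measured_shifts)
  sp <- sign(predicted_shifts)
  wrong <- sm != sp
  list(accuracy = mean(!wrong),
       n = length(sm),
       false_advance = sum(wrong & sp > 0),
       false_delay = sum(wrong & sp < 0),
       false_zero = sum(wrong & sp == 0))
}

#' Reaction-time consequence of a circadian phase error
#'
#' Given a phase-binned profile of median reaction time across the
#' biological day (0 degrees = CBTmin), computes the absolute change in
#' expected reaction time caused by mis-estimating circadian phase by
#' `error_h` hours in either direction: for each bin phi,
#' |dRT|(phi) = mean(|RT(phi + d) - RT(phi)|, |RT(phi - d) - RT(phi)|)
#' with circular indexing and d = 15 degrees per hour.  The effect size is
#' |dRT| divided by the bin's dispersion (an interpretation of a
#' standardized difference; configurable via `dispersion`).
#'
#' @param profile Data.frame with `phase_deg` (uniform bins covering 360
#'   degrees), `median_rt_ms`, and a dispersion column (`sd_ms` by
#'   default).
#' @param error_h Phase error in hours (e.g. 1 or 2).
#' @param dispersion Name of the dispersion column (default `"sd_ms"`).
#' @param double_plot Also return the cycle repeated over 360-720 degrees
#'   for conventional double-plotted display.
#' @return Data.frame with `phase_deg`, `abs_drt_ms`, `effect_size`.
#' @examples
#' prof <- data.frame(phase_deg = seq(0, 345, by = 15),
#'                    median_rt_ms = 500 + 50 * cospi(seq(0, 345, by = 15) / 180),
#'                    sd_ms = 40)
#' max(rt_consequence(prof, 1)$abs_drt_ms)  # ~ 2 * 50 * sin(7.5 deg) = 13.05
#' @export
rt_consequence <- function(profile, error_h, dispersion = "sd_ms",
                           double_plot = FALSE) {
  stopifnot(all(c("phase_deg", "median_rt_ms") %in% names(profile)),
            dispersion %in% names(profile))
  profile <- profile[order(profile$phase_deg), , drop = FALSE]
  nb <- nrow(profile)
  widths <- diff(c(profile$phase_deg, profile$phase_deg[1] + 360))
  if (any(abs(widths - widths[1]) > 1e-9))
    stop("profile bins must be uniform and cover 360 degrees")
  bw <- widths[1]
  d_deg <- 15 * error_h
  rt <- profile$median_rt_ms
  shift_bins <- d_deg / bw
  if (abs(shift_bins - round(shift_bins)) > 1e-9) {
    warning("phase error is not a multiple of the bin width; interpolating")
    grid <- c(profile$phase_deg, profile$phase_deg[1] + 360)
    rt_fun <- stats::approxfun(grid, c(rt, rt[1]))
    at <- function(deg) rt_fun(deg %% 360)
    up <- abs(at(profile$phase_deg + d_deg) - rt)
    dn <- abs(at(profile$phase_deg - d_deg) - rt)
  } else {
    k <- as.integer(round(shift_bins))
    idx_up <- ((seq_len(nb) - 1 + k) %% nb) + 1
    idx_dn <- ((seq_len(nb) - 1 - k) %% nb) + 1
    up <- abs(rt[idx_up] - rt)
    dn <- abs(rt[idx_dn] - rt)
  }
  out <- data.frame(phase_deg = profile$phase_deg,
                    abs_drt_ms = (up + dn) / 2)
  out$effect_size <- out$abs_drt_ms / profile[[dispersion]]
  if (double_plot) {
    second <- out
    second$phase_deg <- second$phase_deg + 360
    out <- rbind(out, second)
  }
  out
}
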