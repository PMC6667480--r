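#' aMT6s excretion rates from sequential urine blocks
#'
#' Each collection block contributes one excretion-rate point:
#' rate = concentration x volume / duration (ng/h), assigned to the block's
#' midpoint.  This is the input to the cosinor reference-phase fit.
#'
#' @param samples Data.frame with POSIXct `block_start`, `block_end`,
#'   `volume_ml` and `amt6s_ng_ml` columns.
#' @return Data.frame with `time` (POSIXct midpoint), `t_h` (hours since
#'   midnight of the first block's date), `rate_ng_h`, `duration_h`.
#' @export
excretion_rates <- function(samples) {
  stopifnot(all(c("block_start", "block_end", "volume_ml", "amt6s_ng_ml") %in%
                  names(samples)))
  samples <- samples[order(samples$block_start), , drop = FALSE]
  dur <- as.numeric(difftime(samples$block_end, samples$block_start,
                             units = "hours"))
  if (any(dur <= 0)) stop("block end must follow block start")
  if (any(samples$volume_ml < 0) || any(samples$amt6s_ng_ml < 0))
    stop("volume and concentration must be non-negative")
  span <- as.numeric(difftime(max(samples$block_end), min(samples$block_start),
                              units = "hours"))
  if (nrow(samples) < 5 || span < 24)
    stop(sprintf("need >= 5 blocks spanning >= 24 h (got %d blocks over %.1f h)",
                 nrow(samples), span))
  if (nrow(samples) > 1) {
    gaps <- as.numeric(difftime(samples$block_start[-1],
                                samples$block_end[-nrow(samples)],
                                units = "hours"))
    if (any(gaps < -1e-9)) warning("overlapping urine blocks")
    if (any(gaps > 2)) warning("gap(s) > 2 h between urine blocks")
  }
  mid <- samples$block_start + dur * 1800  # + duration/2 in seconds
  anchor <- trunc(min(samples$block_start), "days")
  data.frame(time = mid,
             t_h = as.numeric(difftime(mid, anchor, units = "hours")),
             rate_ng_h = samples$amt6s_ng_ml * samples$volume_ml / dur,
             duration_h = dur)
}

#' Single-component cosinor fit at a fixed 24 h period
#'
#' Fits mesor + amplitude x cos(2 pi (t - phi)/24) by ordinary least
#' squares in the linear parametrization (mesor, cosine and sine
#' coefficients), recovers the acrophase phi via `atan2`, and tests the
#' zero-amplitude null with the regression F-test.  Fits with p-value above
#' `alpha` are flagged non-significant (callers may override).
#'
#' @param rates Data.frame from [excretion_rates()], or any data.frame with
#'   `t_h` (hours; clock-anchored) and `rate_ng_h`.
#' @param period_h Fixed period, hours (default 24).
#' @param alpha Significance level for the zero-amplitude test (default
#'   0.10).
#' @return A list of class `cosinor_fit`: `mesor`, `amplitude`, `acrophase`
#'   (clock hours in [0, 24)), `p_value`, `r2`, `significant`, `n`.
#' @examples
#' t <- seq(0, 44, by = 4)
#' fit <- cosinor_fit(data.frame(t_h = t,
#'   rate_ng_h = 800 + 500 * cos(2 * pi * (t - 4) / 24)))
#' fit$acrophase  # 4
#' @export
cosinor_fit <- function(rates, period_h = 24, alpha = 0.10) {
  t <- rates$t_h
  y <- rates$rate_ng_h
  if (length(t) < 5 || diff(range(t)) < 24)
    stop("need >= 5 points spanning >= 24 h for a cosinor fit")
  cw <- cos(2 * pi * t / period_h)
  sw <- sin(2 * pi * t / period_h)
  X <- cbind(1, cw, sw)
  if (qr(X)$rank < 3)
    stop("rank-deficient cosinor design: sampling times do not resolve phase")
  if (stats::var(y) == 0) {
    # a perfectly flat series: zero amplitude, no phase information
    return(structure(list(mesor = mean(y), amplitude = 0, acrophase = 0,
                          p_value = 1, r2 = 0, significant = FALSE,
                          n = length(y)),
                     class = "cosinor_fit"))
  }
  fit <- stats::lm(y ~ cw + sw)
  b <- stats::coef(fit)
  amp <- sqrt(b[["cw"]]^2 + b[["sw"]]^2)
  phi <- clock_hours(atan2(b[["sw"]], b[["cw"]]) * period_h / (2 * pi))
  sm <- summary(fit)
  if (is.null(sm$fstatistic) || !all(is.finite(sm$fstatistic))) {
    # a flat series carries no phase information: zero-amplitude null holds
    p <- 1; r2 <- 0
  } else {
    p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE)
    r2 <- sm$r.squared
  }
  structure(list(mesor = unname(b[1]), amplitude = unname(amp),
                 acrophase = unname(phi), p_value = unname(p),
                 r2 = r2, significant = unname(p <= alpha),
                 n = length(y)),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (24 h): mesor %.1f, amplitude %.1f, acrophase %s (%.3f h)\n",
    x$mesor, x$amplitude, format_clock(x$acrophase), x$acrophase))
  cat(sprintf("  zero-amplitude test p = %.4g (%ssignificant), R2 = %.3f, n = %d\n",
              x$p_value, if (x$significant) "" else "NOT ", x$r2, x$n))
  invisible(x)
}

#' Measured phase shift between schedules
#'
#' Diurnal acrophase minus night acrophase, wrapped to (-12, 12]: negative
#' values are phase delays (the rhythm moved later on nights), positive
#' values are advances.
#'
#' @param diurnal,night `cosinor_fit` objects or plain acrophase clock
#'   hours.
#' @param require_significant Error unless both fits pass the
#'   zero-amplitude test (default TRUE; set FALSE to override, e.g. for
#'   borderline fits retained after visual inspection).
#' @return Phase shift in hours.
#' @examples
#' measured_phase_shift(3.97, 5.32)  # -1.35, a delay
#' @export
measured_phase_shift <- function(diurnal, night, require_significant = TRUE) {
  get_phi <- function(f, label) {
    if (inherits(f, "cosinor_fit")) {
      if (require_significant && !f$significant)
        stop(label, " cosinor fit is not significant (set require_significant = FALSE to override)")
      f$acrophase
    } else as.numeric(f)
  }
  wrap_hours(get_phi(diurnal, "diurnal") - get_phi(night, "night"))
}

#' Write per-subject cosinor fits as CSV
#'
#' @param fits Named list of `cosinor_fit` objects (names like
#'   `"12_diurnal"`), or a single fit.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
write_cosinor_fits <- function(fits, path) {
  if (inherits(fits, "cosinor_fit")) fits <- list(fit = fits)
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(id = nm, mesor = f$mesor, amplitude = f$amplitude,
               acrophase_h = f$acrophase, p_value = f$p_value, r2 = f$r2,
               significant = f$significant, n = f$n)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
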