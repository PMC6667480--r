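#' State-modulated photic drive
#'
#' Applies the circadian sensitivity modulator to the processed light drive:
#' \eqn{B = \hat B (1 - l_s x)(1 - l_s x_c)}, so the same light has a
#' state-dependent effect on the oscillator (the basis of the phase response
#' curve).
#'
#' @param Bhat Processed photic drive.
#' @param x,xc Oscillator state.
#' @param params A [circ_params()] object.
#' @return The drive B entering the pacemaker equations.
#' @export
photic_drive <- function(Bhat, x, xc, params = circ_params()) {
  Bhat * (1 - params$ls * x) * (1 - params$ls * xc)
}

#' State-modulated non-photic drive
#'
#' \eqn{N = \hat N (1 - \tanh(a_s x))}: the rest/activity signal acts mainly
#' around the falling phase of x (near habitual sleep onset) and saturates
#' to zero when x is high.
#'
#' @param Nhat Processed non-photic drive (square wave over rest intervals).
#' @param x Oscillator state variable.
#' @param params A [circ_params()] object.
#' @return The drive N entering the pacemaker equations.
#' @export
nonphotic_drive <- function(Nhat, x, params = circ_params()) {
  Nhat * (1 - tanh(params$as_ * x))
}

#' Pacemaker right-hand side
#'
#' Evaluates the two coupled first-order equations of the limit-cycle
#' oscillator:
#' \deqn{dx/dt = \frac{\pi}{12}\left[x_c + \mu\left(\tfrac13 x +
#'   \tfrac43 x^3 - \tfrac{256}{105} x^7\right) + B + N\right]}
#' \deqn{dx_c/dt = \frac{\pi}{12}\left\{L_q B x_c -
#'   x\left[\left(\frac{24}{0.99729\,\tau_c}\right)^2 + L_k B\right]\right\}}
#' where x tracks the daily variation of core body temperature and x_c is
#' its Lienard-transform companion.
#'
#' @param x,xc Oscillator state.
#' @param B,N Photic and non-photic drives (already state-modulated).
#' @param params A [circ_params()] object.
#' @return Numeric vector `c(dx_dt, dxc_dt)` in units per hour.
#' @export
pacemaker_derivatives <- function(x, xc, B, N, params = circ_params()) {
  w <- params$omega_scale
  kx <- (24 / (params$period_correction * params$tau_c))^2
  dx <- w * (xc + params$mu * (x / 3 + (4 / 3) * x^3 - (256 / 105) * x^7) + B + N)
  dxc <- w * (params$Lq * B * xc - x * (kx + params$Lk * B))
  c(dx, dxc)
}

#' Constant-drive series for unforced or schedule-free simulations
#'
#' @param duration_h Span to cover, hours.
#' @param Bhat,Nhat Constant drive levels (defaults 0: free run in darkness).
#' @param epoch_min Epoch length in minutes.
#' @return A `drive_series` list with `Bhat`, `Nhat`, `n`, `epoch_min`.
#' @export
constant_drives <- function(duration_h, Bhat = 0, Nhat = 0, epoch_min = 1) {
  np <- ceiling(duration_h * 60 / epoch_min)
  structure(list(Bhat = rep(Bhat, np), Nhat = rep(Nhat, np),
                 n = rep(NA_real_, np + 1), epoch_min = epoch_min),
            class = "drive_series")
}

#' Initial oscillator state from an estimated CBTmin time
#'
#' Places the state on the unit cycle assuming uniform angular velocity over
#' the 24 h day and unit amplitude: with phase angle
#' \eqn{\theta = 2\pi (t_{start} - t_{CBTmin})/24}, the state is
#' \eqn{x = -\cos\theta,\; x_c = \sin\theta}, so x is minimal at the
#' estimated nadir and rotates in the direction of the model flow.  The
#' photoreceptor fraction starts at its fixed point for the first epoch's
#' lux, removing the processor transient.
#'
#' @param t_start_clock_h Clock time of the first epoch, hours.
#' @param cbtmin_clock_h Estimated clock time of the preceding CBT nadir
#'   (e.g. average diurnal mid-sleep, or a measured acrophase), hours.
#' @param params A [circ_params()] object.
#' @param lux0 Lux of the first epoch (for the photoreceptor fixed point).
#' @return A list with `x`, `xc`, `n`.
#' @examples
#' initial_state_from_cbtmin(3.3, 3.3)       # at the nadir: x = -1
#' initial_state_from_cbtmin(9.3, 3.3)       # six hours later: xc = 1
#' @export
initial_state_from_cbtmin <- function(t_start_clock_h, cbtmin_clock_h,
                                      params = circ_params(), lux0 = 0) {
  theta <- 2 * pi * (t_start_clock_h - cbtmin_clock_h) / 24
  list(x = -cos(theta), xc = sin(theta),
       n = light_processor_steady_state(lux0, params)$n)
}

#' Integrate the pacemaker over a drive series
#'
#' Advances the oscillator with classical fixed-step fourth-order
#' Runge-Kutta on the one-minute epoch grid, holding \eqn{\hat B} and
#' \eqn{\hat N} constant within each epoch (the state-dependent modulators
#' are re-evaluated at every Runge-Kutta stage).  The scheme is fully
#' deterministic and step-refinement verified; `substeps` subdivides each
#' epoch for convergence checks.
#'
#' @param drives A `drive_series` with `Bhat` and (optionally) `Nhat`
#'   vectors; a missing/NULL `Nhat` means zero non-photic drive (photic-only
#'   mode).
#' @param initial List with `x`, `xc` (and optionally `n`), e.g. from
#'   [initial_state_from_cbtmin()].
#' @param params A [circ_params()] object.
#' @param t0_clock_h Clock time of the first epoch (hours); used to date and
#'   clock-stamp CBTmin events.
#' @param t0_date Calendar date of the first epoch (a `Date`), optional.
#' @param substeps Integer >= 1: Runge-Kutta steps per epoch.
#' @param duration_h Optional span to integrate (hours); must not exceed the
#'   drive series.
#' @return An object of class `circ_trajectory`: list with `t_h` (hours
#'   since start, epoch boundaries), `x`, `xc`, `n`, `Bhat`, `Nhat`,
#'   `t0_clock_h`, `t0_date`, `params`.
#' @export
integrate_pacemaker <- function(drives, initial, params = circ_params(),
                                t0_clock_h = 0, t0_date = NULL,
                                substeps = 1L, duration_h = NULL) {
  epoch_min <- if (!is.null(drives$epoch_min)) drives$epoch_min else 1
  Bhat <- drives$Bhat
  Nhat <- drives$Nhat
  if (is.null(Nhat)) Nhat <- rep(0, length(Bhat))
  if (length(Nhat) != length(Bhat))
    stop("Bhat and Nhat must have equal length")
  np <- length(Bhat)
  if (!is.null(duration_h)) {
    need <- ceiling(duration_h * 60 / epoch_min)
    if (need > np)
      stop(sprintf(
        "drive series covers %.2f h but %.2f h requested: missing interval (%.2f, %.2f] h",
        np * epoch_min / 60, duration_h, np * epoch_min / 60, duration_h))
    np <- need
    Bhat <- Bhat[seq_len(np)]
    Nhat <- Nhat[seq_len(np)]
  }
  substeps <- as.integer(substeps)
  stopifnot(substeps >= 1L)

  # unpack to locals: this loop dominates runtime
  w <- params$omega_scale
  mu <- params$mu; Lq <- params$Lq; Lk <- params$Lk
  ls <- params$ls; as_ <- params$as_
  kx <- (24 / (params$period_correction * params$tau_c))^2
  h <- (epoch_min / 60) / substeps

  X <- numeric(np + 1); XC <- numeric(np + 1)
  x <- initial$x; xc <- initial$xc
  X[1] <- x; XC[1] <- xc
  for (i in seq_len(np)) {
    Bh <- Bhat[i]; Nh <- Nhat[i]
    for (s in seq_len(substeps)) {
      B <- Bh * (1 - ls * x) * (1 - ls * xc)
      N <- Nh * (1 - tanh(as_ * x))
      k1x <- w * (xc + mu * (x / 3 + (4 / 3) * x^3 - (256 / 105) * x^7) + B + N)
      k1c <- w * (Lq * B * xc - x * (kx + Lk * B))
      x2 <- x + 0.5 * h * k1x; c2 <- xc + 0.5 * h * k1c
      B <- Bh * (1 - ls * x2) * (1 - ls * c2)
      N <- Nh * (1 - tanh(as_ * x2))
      k2x <- w * (c2 + mu * (x2 / 3 + (4 / 3) * x2^3 - (256 / 105) * x2^7) + B + N)
      k2c <- w * (Lq * B * c2 - x2 * (kx + Lk * B))
      x3 <- x + 0.5 * h * k2x; c3 <- xc + 0.5 * h * k2c
      B <- Bh * (1 - ls * x3) * (1 - ls * c3)
      N <- Nh * (1 - tanh(as_ * x3))
      k3x <- w * (c3 + mu * (x3 / 3 + (4 / 3) * x3^3 - (256 / 105) * x3^7) + B + N)
      k3c <- w * (Lq * B * c3 - x3 * (kx + Lk * B))
      x4 <- x + h * k3x; c4 <- xc + h * k3c
      B <- Bh * (1 - ls * x4) * (1 - ls * c4)
      N <- Nh * (1 - tanh(as_ * x4))
      k4x <- w * (c4 + mu * (x4 / 3 + (4 / 3) * x4^3 - (256 / 105) * x4^7) + B + N)
      k4c <- w * (Lq * B * c4 - x4 * (kx + Lk * B))
      x <- x + h * (k1x + 2 * k2x + 2 * k3x + k4x) / 6
      xc <- xc + h * (k1c + 2 * k2c + 2 * k3c + k4c) / 6
    }
    X[i + 1] <- x; XC[i + 1] <- xc
  }

  n_series <- drives$n
  if (is.null(n_series) || length(n_series) != np + 1)
    n_series <- rep(NA_real_, np + 1)
  structure(list(t_h = (0:np) * epoch_min / 60,
                 x = X, xc = XC, n = n_series,
                 Bhat = c(Bhat, NA_real_), Nhat = c(Nhat, NA_real_),
                 t0_clock_h = t0_clock_h, t0_date = t0_date,
                 params = params),
            class = "circ_trajectory")
}

#' @export
print.circ_trajectory <- function(x, ...) {
  cat(sprintf("Pacemaker trajectory: %.1f h at %g-min sampling, start clock %s\n",
              max(x$t_h), diff(x$t_h[1:2]) * 60, format_clock(x$t0_clock_h)))
  ev <- tryCatch(extract_cbtmin(x), error = function(e) NULL,
                 warning = function(w) suppressWarnings(extract_cbtmin(x)))
  if (!is.null(ev) && nrow(ev) > 0)
    cat(sprintf("  %d CBTmin events, last at clock %s\n",
                nrow(ev), format_clock(ev$clock_h[nrow(ev)])))
  invisible(x)
}

#' Extract daily CBTmin events from a trajectory
#'
#' CBTmin (the model's phase marker) is located at each local minimum of
#' x(t), refined by quadratic interpolation through the three samples around
#' the discrete minimum.  Minima closer together than 16 h (sub-cycle
#' ripples under strong forcing) are resolved by keeping the deeper one, so
#' at most one event is reported per subjective cycle.
#'
#' @param traj A `circ_trajectory`.
#' @param min_separation_h Minimum spacing between successive events.
#' @return A data.frame with `t_h` (hours since trajectory start),
#'   `clock_h`, and `date` (NA when the trajectory carries no start date).
#'   A trajectory spanning over a day with no minimum raises a warning and
#'   returns zero rows.
#' @export
extract_cbtmin <- function(traj, min_separation_h = 16) {
  x <- traj$x; t <- traj$t_h
  nT <- length(x)
  if (max(t) < 24) stop("trajectory must span at least one subjective day")
  i <- which(x[2:(nT - 1)] < x[1:(nT - 2)] & x[2:(nT - 1)] <= x[3:nT]) + 1L
  if (length(i) == 0L) {
    warning("no local minimum of x found: trajectory is not oscillating")
    return(data.frame(t_h = numeric(0), clock_h = numeric(0),
                      date = as.Date(character(0))))
  }
  dt <- t[2] - t[1]
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  off <- ifelse(denom > 0, 0.5 * (x[i - 1] - x[i + 1]) / denom, 0)
  t_min <- t[i] + off * dt
  depth <- x[i]
  # enforce one event per cycle: greedy pass keeping the deeper of any pair
  # closer than min_separation_h
  keep_t <- numeric(0); keep_d <- numeric(0)
  for (k in seq_along(t_min)) {
    if (length(keep_t) > 0 && t_min[k] - keep_t[length(keep_t)] < min_separation_h) {
      if (depth[k] < keep_d[length(keep_d)]) {
        keep_t[length(keep_t)] <- t_min[k]
        keep_d[length(keep_d)] <- depth[k]
      }
    } else {
      keep_t <- c(keep_t, t_min[k])
      keep_d <- c(keep_d, depth[k])
    }
  }
  abs_h <- traj$t0_clock_h + keep_t
  date <- if (!is.null(traj$t0_date))
    traj$t0_date + floor(abs_h / 24) else as.Date(NA)
  data.frame(t_h = keep_t, clock_h = clock_hours(abs_h), date = date)
}

#' Predicted aMT6s acrophase on a given date
#'
#' The model's CBTmin on the requested calendar date is reported as the
#' predicted aMT6s acrophase (the two markers are equated, with an optional
#' fixed offset).
#'
#' @param traj A `circ_trajectory` integrated with a start date.
#' @param on_date A `Date`.
#' @param offset_h Fixed CBTmin-to-acrophase offset, hours (default 0).
#' @return Predicted acrophase clock time in hours.
#' @export
predict_acrophase <- function(traj, on_date, offset_h = 0) {
  ev <- extract_cbtmin(traj)
  if (is.null(traj$t0_date) || all(is.na(ev$date)))
    stop("trajectory has no start date; pass t0_date to integrate_pacemaker()")
  hit <- which(ev$date == as.Date(on_date))
  if (length(hit) == 0L)
    stop(sprintf("no CBTmin on %s; events available on: %s",
                 format(as.Date(on_date)),
                 paste(format(ev$date), collapse = ", ")))
  clock_hours(ev$clock_h[hit[1]] + offset_h)
}

#' Export a trajectory and its CBTmin events as delimited text
#'
#' @param traj A `circ_trajectory`.
#' @param path Output file for the state series (columns `time_iso`, `x`,
#'   `xc`, `n`, `Bhat`, `Nhat`); when the trajectory has no start date,
#'   `time_iso` is replaced by hours since start.
#' @param events_path Optional second file for the CBTmin table (`date`,
#'   `clock_time_h`).
#' @return Invisibly, the state data.frame written.
#' @export
write_trajectory <- function(traj, path, events_path = NULL) {
  time_col <- if (!is.null(traj$t0_date)) {
    t0 <- as.POSIXct(paste0(format(traj$t0_date), " 00:00:00"), tz = "UTC") +
      traj$t0_clock_h * 3600
    format(t0 + traj$t_h * 3600, "%Y-%m-%dT%H:%M:%S")
  } else traj$t_h
  df <- data.frame(time_iso = time_col, x = traj$x, xc = traj$xc, n = traj$n,
                   Bhat = traj$Bhat, Nhat = traj$Nhat)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(events_path)) {
    ev <- extract_cbtmin(traj)
    utils::write.csv(data.frame(date = ev$date, clock_time_h = ev$clock_h),
                     events_path, row.names = FALSE)
  }
  invisible(df)
}
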