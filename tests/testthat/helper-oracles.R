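# independent oracles used across test files

# brute-force cosinor: grid search over acrophase, least squares in
# (mesor, amplitude) at each candidate phase, returning the SSE-minimizing
# acrophase
brute_force_acrophase <- function(t_h, y, grid_step = 0.01) {
  phis <- seq(0, 24 - grid_step, by = grid_step)
  sse <- vapply(phis, function(phi) {
    X <- cbind(1, cos(2 * pi * (t_h - phi) / 24))
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }, numeric(1))
  best <- phis[which.min(sse)]
  # amplitude may come out negative: that is the antiphase solution
  X <- cbind(1, cos(2 * pi * (t_h - best) / 24))
  if (stats::lm.fit(X, y)$coefficients[2] < 0) best <- (best + 12) %% 24
  best
}

# brute-force circular mean: minimize summed squared circular distance on a
# fine grid of candidate clock times
brute_force_circular_mean <- function(h, grid_step = 0.01) {
  cand <- seq(0, 24 - grid_step, by = grid_step)
  cost <- vapply(cand, function(m) sum(wrap_hours(h - m)^2), numeric(1))
  cand[which.min(cost)]
}

# drive series for a repeating light:dark day, through the light processor
ld_drives <- function(lux_on, hours_on, hours_off, days,
                      params = circ_params(), lights_on_clock = 8) {
  day <- c(rep(0, round(lights_on_clock * 60)),
           rep(lux_on, round(hours_on * 60)),
           rep(0, round((24 - lights_on_clock - hours_on) * 60)))
  stopifnot(length(day) == 1440, hours_on + hours_off == 24,
            lights_on_clock + hours_on <= 24)
  dp <- light_processor(rep(day, days), params)
  structure(list(Bhat = dp$Bhat, Nhat = rep(0, length(dp$Bhat)), n = dp$n,
                 epoch_min = 1), class = "drive_series")
}

# free run in darkness after a single light pulse; returns CBTmin events
pulse_run <- function(pulse_start_h, pulse_h, lux, days = 5,
                      params = circ_params(), initial = list(x = -1, xc = 0)) {
  lux_vec <- rep(0, days * 1440)
  idx <- (round(pulse_start_h * 60) + 1):round((pulse_start_h + pulse_h) * 60)
  lux_vec[idx] <- lux
  dp <- light_processor(lux_vec, params, n0 = 0)
  drv <- structure(list(Bhat = dp$Bhat, Nhat = rep(0, length(dp$Bhat)),
                        n = dp$n, epoch_min = 1), class = "drive_series")
  extract_cbtmin(integrate_pacemaker(drv, initial, params))
}
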