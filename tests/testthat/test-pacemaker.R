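p_def <- circ_params()

test_that("drive modulators evaluate exactly", {
  # photic: identity at origin, annihilated by zero drive, direct arithmetic
  expect_equal(photic_drive(1, 0, 0, p_def), 1)
  expect_equal(photic_drive(0, 0.7, -0.3, p_def), 0)
  expect_equal(photic_drive(1, 1, 1, p_def), 0.36)
  # non-photic: unit factor at x = 0, saturation at x = 1, doubling at x = -1
  expect_equal(nonphotic_drive(0.032 / 3, 0, p_def), 0.032 / 3)
  expect_lt(abs(nonphotic_drive(5, 1, p_def)), 5 * 1e-8)
  expect_equal(nonphotic_drive(0.5, -1, p_def), 1.0, tolerance = 1e-8)
})

test_that("pacemaker right-hand side matches hand arithmetic", {
  expect_equal(pacemaker_derivatives(0, 0, 0, 0, p_def), c(0, 0))
  # x = 1 alone: (pi/12) * mu * (1/3 + 4/3 - 256/105)
  d <- pacemaker_derivatives(1, 0, 0, 0, p_def)
  expect_equal(d[1], (pi / 12) * 0.13 * (5 / 3 - 256 / 105), tolerance = 1e-12)
  expect_equal(d[1], -0.026255, tolerance = 1e-5)
  # xc = 1 alone: the linear term
  expect_equal(pacemaker_derivatives(0, 1, 0, 0, p_def)[1], pi / 12)
  # photic drive enters both equations
  d <- pacemaker_derivatives(0.5, -0.2, 0.3, 0.01, p_def)
  expect_equal(d[1], (pi / 12) * (-0.2 + 0.13 * (0.5 / 3 + (4 / 3) * 0.5^3 -
                                                   (256 / 105) * 0.5^7) + 0.3 + 0.01))
  kx <- (24 / (0.99729 * 24.2))^2
  expect_equal(d[2], (pi / 12) * ((1 / 3) * 0.3 * (-0.2) - 0.5 * (kx + 0.55 * 0.3)))
})

test_that("free-running period equals the intrinsic period across tau_c", {
  for (tc in c(23.5, 24.2, 24.6)) {
    tr <- integrate_pacemaker(constant_drives(30 * 24), list(x = -1, xc = 0),
                              circ_params(tau_c = tc))
    ev <- extract_cbtmin(tr)
    expect_gt(nrow(ev), 20)
    expect_equal(mean(diff(ev$t_h)), tc, tolerance = 0.05 / tc)
  }
})

test_that("origin is a fixed point and step halving is stable", {
  tr <- integrate_pacemaker(constant_drives(48), list(x = 0, xc = 0), p_def)
  expect_true(all(tr$x == 0) && all(tr$xc == 0))
  tr1 <- integrate_pacemaker(constant_drives(14 * 24), list(x = -1, xc = 0),
                             p_def, substeps = 1)
  tr2 <- integrate_pacemaker(constant_drives(14 * 24), list(x = -1, xc = 0),
                             p_def, substeps = 2)
  expect_lt(max(abs(tr1$x - tr2$x)), 1e-6)
})

test_that("trajectories converge to a unit-amplitude limit cycle", {
  for (r in c(0.1, 0.5, 1.5)) {
    tr <- integrate_pacemaker(constant_drives(20 * 24),
                              list(x = -r, xc = 0), p_def)
    late <- tr$x[tr$t_h > 15 * 24]
    expect_equal(max(abs(late)), 1.00, tolerance = 0.05)
  }
})

test_that("RK4 agrees with an independent adaptive integrator", {
  kx <- (24 / (p_def$period_correction * p_def$tau_c))^2
  rhs <- function(t, y, parms) {
    list(c((pi / 12) * (y[2] + p_def$mu * (y[1] / 3 + (4 / 3) * y[1]^3 -
                                             (256 / 105) * y[1]^7)),
           (pi / 12) * (-y[1] * kx)))
  }
  times <- seq(0, 14 * 24, by = 1 / 60)
  ref <- deSolve::ode(c(-1, 0), times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  tr <- integrate_pacemaker(constant_drives(14 * 24), list(x = -1, xc = 0),
                            p_def)
  expect_lt(max(abs(tr$x - ref[, 2])), 1e-4)
})

test_that("integration demands a sufficient drive series", {
  expect_error(
    integrate_pacemaker(constant_drives(24), list(x = -1, xc = 0), p_def,
                        duration_h = 48),
    "missing interval")
})

test_that("CBTmin extraction finds analytic cosine minima", {
  t_h <- seq(0, 72, by = 1 / 60)
  traj <- structure(list(t_h = t_h, x = -cos(2 * pi * t_h / 24),
                         xc = sin(2 * pi * t_h / 24),
                         n = rep(0, length(t_h)), t0_clock_h = 0,
                         t0_date = as.Date("2024-03-04")),
                    class = "circ_trajectory")
  ev <- extract_cbtmin(traj)
  # interior minima of the 72 h window (the t = 0 and t = 72 minima sit on
  # the boundary and are not events)
  expect_equal(ev$t_h, c(24, 48), tolerance = 1e-3)
  expect_equal(ev$clock_h, c(0, 0), tolerance = 1e-3)
  expect_equal(as.integer(ev$date - as.Date("2024-03-04")), 1:2)
})

test_that("non-oscillating trajectories are flagged, not silently skipped", {
  flat <- structure(list(t_h = seq(0, 48, by = 1 / 60),
                         x = rep(0.3, 48 * 60 + 1), xc = rep(0, 48 * 60 + 1),
                         n = rep(0, 48 * 60 + 1), t0_clock_h = 0,
                         t0_date = NULL),
                    class = "circ_trajectory")
  expect_warning(ev <- extract_cbtmin(flat), "not oscillating")
  expect_equal(nrow(ev), 0)
  short <- structure(list(t_h = seq(0, 10, by = 1 / 60), x = rep(0, 601)),
                     class = "circ_trajectory")
  expect_error(extract_cbtmin(short), "at least one")
})

test_that("entrained oscillator locks to the 24 h light:dark cycle", {
  drv <- ld_drives(1000, 16, 8, 16)
  tr <- integrate_pacemaker(drv, initial_state_from_cbtmin(0, 4), p_def)
  ev <- extract_cbtmin(tr)
  drift <- diff(wrap_hours(ev$clock_h - ev$clock_h[1]))
  expect_true(all(abs(utils::tail(drift, 4)) < 1 / 60))
})

test_that("on-cycle initialization maps phase angle as intended", {
  s <- initial_state_from_cbtmin(3.3, 3.3)
  expect_equal(c(s$x, s$xc), c(-1, 0))
  s <- initial_state_from_cbtmin(9.3, 3.3)
  expect_equal(c(s$x, s$xc), c(0, 1), tolerance = 1e-12)
  s <- initial_state_from_cbtmin(15.3, 3.3)
  expect_equal(c(s$x, s$xc), c(1, 0), tolerance = 1e-12)
  # rotation direction: from the nadir the model flow carries x upward
  # through zero at a quarter cycle (~6 h) and to its crest at half a
  # cycle, matching the harmonic mapping
  tr <- integrate_pacemaker(constant_drives(12), list(x = -1, xc = 0), p_def)
  expect_lt(abs(tr$x[6 * 60 + 1]), 0.3)
  expect_gt(tr$xc[6 * 60 + 1], 0.8)
  expect_gt(tr$x[length(tr$x)], 0.8)
})

test_that("predicted acrophase is the dated CBTmin with optional offset", {
  tr <- integrate_pacemaker(constant_drives(5 * 24),
                            list(x = -1, xc = 0), p_def,
                            t0_clock_h = 3.917, t0_date = as.Date("2024-03-04"))
  ev <- extract_cbtmin(tr)
  d2 <- ev$date[2]
  expect_equal(predict_acrophase(tr, d2), ev$clock_h[2])
  expect_equal(predict_acrophase(tr, d2, offset_h = 0.5),
               clock_hours(ev$clock_h[2] + 0.5))
  expect_error(predict_acrophase(tr, as.Date("2030-01-01")), "available")
})

test_that("trajectory export round-trips state and events as text", {
  tr <- integrate_pacemaker(constant_drives(36), list(x = -1, xc = 0), p_def,
                            t0_clock_h = 12, t0_date = as.Date("2024-03-04"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f1, f2)
  st <- utils::read.csv(f1)
  expect_equal(nrow(st), 36 * 60 + 1)
  expect_equal(st$x, tr$x)
  expect_equal(st$time_iso[1], "2024-03-04T12:00:00")
  ev <- utils::read.csv(f2)
  expect_equal(ev$clock_time_h, extract_cbtmin(tr)$clock_h)
})
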