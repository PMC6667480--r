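mk_series <- function(lux, activity, start = "2024-03-04 00:00:00",
                      worn = NULL) {
  n <- length(lux)
  tm <- as.POSIXct(start, tz = "UTC") + 60 * (seq_len(n) - 1)
  epoch_series(tm, lux, activity, worn)
}

# a deterministic diurnal day: sleep 23:16-07:23, bright active wake
# (minute-of-day integer arithmetic keeps the boundaries exact)
noiseless_day <- function(days = 3) {
  n <- days * 1440
  tm <- as.POSIXct("2024-03-04 12:00:00", tz = "UTC") + 60 * (seq_len(n) - 1)
  mod <- (720 + seq_len(n) - 1) %% 1440
  asleep <- mod >= 23 * 60 + 16 | mod < 7 * 60 + 23
  epoch_series(tm, ifelse(asleep, 0, 150), ifelse(asleep, 0, 100))
}

test_that("noiseless sleep is recovered exactly at epoch resolution", {
  s <- noiseless_day(3)
  iv <- score_rest_intervals(s)
  main <- iv[iv$kind == "main", ]
  expect_equal(nrow(main), 3)
  expect_true(all(format(main$start, "%H:%M") == "23:16"))
  expect_true(all(format(main$end, "%H:%M") == "07:23"))
})

test_that("generator traces at default noise are recovered within 10 minutes", {
  tr <- generate_trace(schedule_spec(n_diurnal_days = 4, n_night_shifts = 3),
                       seed = 3)
  iv <- score_rest_intervals(tr$series)
  main <- iv[iv$kind == "main", ]
  truth <- tr$rest_truth
  expect_equal(nrow(main), nrow(truth))
  expect_lt(max(abs(as.numeric(difftime(main$start, truth$start,
                                        units = "mins")))), 10)
  expect_lt(max(abs(as.numeric(difftime(main$end, truth$end,
                                        units = "mins")))), 10)
})

test_that("short daytime rest is classified as a nap", {
  s <- noiseless_day(2)
  idx <- which(format(s$time, "%H:%M") >= "14:00" &
                 format(s$time, "%H:%M") < "16:00" &
                 as.Date(s$time) == as.Date("2024-03-05"))
  s$activity[idx] <- 0
  s$lux[idx] <- 2
  iv <- score_rest_intervals(s)
  expect_equal(sum(iv$kind == "nap"), 1)
  nap <- iv[iv$kind == "nap", ]
  expect_lt(as.numeric(difftime(nap$end, nap$start, units = "hours")), 3)
  # naps contribute nothing to the non-photic square wave
  Nhat <- build_nonphotic_input(s, iv[iv$kind == "nap", , drop = FALSE])
  expect_true(all(Nhat == 0.032 / 3))
})

test_that("a fully active bright series scores no rest", {
  s <- mk_series(rep(500, 1500), rep(300, 1500))
  expect_warning(iv <- score_rest_intervals(s), "no rest")
  expect_equal(nrow(iv), 0)
})

test_that("dim but active stretches are rejected by the lux criterion when active", {
  # low light alone must not create rest: activity stays high
  s <- noiseless_day(2)
  idx <- which(format(s$time, "%H:%M") >= "18:00" &
                 format(s$time, "%H:%M") < "21:00")
  s$lux[idx] <- 1
  iv <- score_rest_intervals(s)
  expect_true(all(iv$kind == "main"))
  expect_equal(nrow(iv), 2)
})

test_that("off-wrist gaps matching expected sleep are imputed as main rest", {
  s <- noiseless_day(2)
  # remove the watch 23:30-06:30 on night 1 (expected sleep 23:00-07:00)
  gap <- s$time >= as.POSIXct("2024-03-04 23:30:00", tz = "UTC") &
    s$time < as.POSIXct("2024-03-05 06:30:00", tz = "UTC")
  s$worn[gap] <- FALSE
  s$activity[gap] <- 250   # artefactual values while off wrist
  s$lux[gap] <- 400
  iv <- score_rest_intervals(s)
  esw <- data.frame(
    start = as.POSIXct(c("2024-03-04 23:00:00", "2024-03-05 23:00:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2024-03-05 07:00:00", "2024-03-06 07:00:00"),
                     tz = "UTC"))
  res <- impute_offwrist_sleep(s, iv, esw)
  imp <- res$intervals[res$intervals$kind == "imputed_offwrist", ]
  expect_equal(nrow(imp), 1)
  expect_equal(format(imp$start, "%H:%M"), "23:30")
  expect_true(all(res$series$lux[gap] == 0))
  expect_true(all(res$series$activity[gap] == 0))
})

test_that("short midday off-wrist gaps are not imputed", {
  s <- noiseless_day(2)
  gap <- s$time >= as.POSIXct("2024-03-05 12:00:00", tz = "UTC") &
    s$time < as.POSIXct("2024-03-05 13:00:00", tz = "UTC")
  s$worn[gap] <- FALSE
  iv <- score_rest_intervals(s)
  esw <- data.frame(start = as.POSIXct("2024-03-05 23:00:00", tz = "UTC"),
                    end = as.POSIXct("2024-03-06 07:00:00", tz = "UTC"))
  expect_warning(res <- impute_offwrist_sleep(s, iv, esw), "did not match")
  expect_false("imputed_offwrist" %in% res$intervals$kind)
})

test_that("imputation without gaps is the identity", {
  s <- noiseless_day(2)
  iv <- score_rest_intervals(s)
  esw <- data.frame(start = as.POSIXct("2024-03-05 23:00:00", tz = "UTC"),
                    end = as.POSIXct("2024-03-06 07:00:00", tz = "UTC"))
  res <- impute_offwrist_sleep(s, iv, esw)
  expect_identical(res$series$lux, s$lux)
  expect_identical(res$intervals, iv)
})

test_that("mid-sleep averages circularly and matches the printed group habit", {
  iv <- data.frame(
    start = as.POSIXct("2024-03-04 23:16:00", tz = "UTC"),
    end = as.POSIXct("2024-03-05 07:23:00", tz = "UTC"), kind = "main")
  expect_equal(mid_sleep(iv), 3.325)  # 03:19:30
  iv2 <- data.frame(
    start = as.POSIXct(c("2024-03-04 22:00:00", "2024-03-06 00:00:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2024-03-05 06:00:00", "2024-03-06 08:00:00"),
                     tz = "UTC"),
    kind = "main")
  expect_equal(mid_sleep(iv2), 3)
  expect_error(mid_sleep(iv2[0, ]), "no main")
})

test_that("circular mid-sleep agrees with a brute-force oracle across the wrap", {
  set.seed(42)
  for (centre in c(3.3, 23.8, 0.4, 12.6)) {
    mids <- clock_hours(centre + stats::rnorm(7, 0, 1))
    start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC") +
      (mids - 4) * 3600 + c(0:6) * 86400
    iv <- data.frame(start = start, end = start + 8 * 3600, kind = "main")
    expect_lt(abs(wrap_hours(mid_sleep(iv) - brute_force_circular_mean(mids))),
              0.02)
  }
})

test_that("the non-photic square wave takes exactly the two published levels", {
  s <- noiseless_day(2)
  iv <- score_rest_intervals(s)
  p <- circ_params()
  Nhat <- build_nonphotic_input(s, iv, p)
  expect_setequal(unique(Nhat), c(p$rho / 3, p$rho * (1 / 3 - 1)))
  expect_equal(p$rho / 3, 0.010667, tolerance = 1e-4)
  expect_equal(p$rho * (1 / 3 - 1), -0.021333, tolerance = 1e-4)
  # duty cycle identity: rest fraction equals scored main-rest share
  sigma_share <- mean(Nhat < 0)
  main <- iv[iv$kind == "main", ]
  rest_min <- sum(as.numeric(difftime(main$end, main$start, units = "mins")))
  expect_equal(sigma_share, rest_min / nrow(s))
  # rho = 0 silences the non-photic pathway
  expect_true(all(build_nonphotic_input(s, iv, circ_params(rho = 0)) == 0))
})
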