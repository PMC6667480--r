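test_that("trace generation is deterministic per seed", {
  sp <- schedule_spec(n_diurnal_days = 2, n_night_shifts = 3)
  a <- generate_trace(sp, seed = 9)
  b <- generate_trace(sp, seed = 9)
  expect_identical(a$series, b$series)
  expect_identical(a$rest_truth, b$rest_truth)
  c <- generate_trace(sp, seed = 10)
  expect_false(identical(a$series$lux, c$series$lux))
})

test_that("night-shift waking light matches the calibrated dim-light quantiles", {
  tr <- generate_trace(schedule_spec(n_diurnal_days = 3, n_night_shifts = 4),
                       seed = 7)
  s <- tr$series
  asleep <- rep(FALSE, nrow(s))
  for (k in seq_len(nrow(tr$rest_truth)))
    asleep <- asleep | (s$time >= tr$rest_truth$start[k] &
                          s$time < tr$rest_truth$end[k])
  w <- s$time >= tr$night_start & !asleep
  expect_gt(sum(w), 3 * 16 * 60)  # >= 3 night shifts' worth of waking epochs
  expect_equal(mean(s$lux[w] < 10), 0.24, tolerance = 0.05 / 0.24)
  expect_equal(mean(s$lux[w] < 100), 0.61, tolerance = 0.05 / 0.61)
})

test_that("evening weighting reorders night light without touching its marginal", {
  sp <- schedule_spec(n_diurnal_days = 2, n_night_shifts = 3)
  t0 <- generate_trace(sp, light_environment(evening_weight = 0), seed = 5)
  t1 <- generate_trace(sp, light_environment(evening_weight = 1), seed = 5)
  w <- t0$series$time >= t0$night_start
  expect_equal(sort(t0$series$lux[w]), sort(t1$series$lux[w]))
  expect_false(identical(t0$series$lux[w], t1$series$lux[w]))
})

test_that("noiseless traces are scored back to the exact schedule", {
  tr <- generate_trace(schedule_spec(n_diurnal_days = 2, n_night_shifts = 3),
                       light_environment(noise = 0), seed = 1)
  iv <- score_rest_intervals(tr$series)
  main <- iv[iv$kind == "main", ]
  expect_equal(nrow(main), nrow(tr$rest_truth))
  expect_lt(max(abs(as.numeric(difftime(main$start, tr$rest_truth$start,
                                        units = "mins")))), 1.01)
  expect_lt(max(abs(as.numeric(difftime(main$end, tr$rest_truth$end,
                                        units = "mins")))), 1.01)
})

test_that("urine generation closes the loop with the cosinor fit", {
  a <- as.POSIXct("2024-03-04 07:23:00", tz = "UTC")
  sleeps <- data.frame(start = a + (c(0, 1) * 24 + 15.88) * 3600,
                       end = a + (c(1, 2) * 24 + 0.05) * 3600)
  blocks <- urine_block_plan(a, 48, sleeps)
  expect_true(all(difftime(blocks$block_end, blocks$block_start,
                           units = "hours") >= 2))
  u0 <- generate_urine(4, 800, 600, blocks, noise_sd = 0, seed = 2)
  fit <- cosinor_fit(excretion_rates(u0))
  expect_lt(abs(wrap_hours(fit$acrophase - 4)), 0.05)
  # zero amplitude cannot be significant
  uf <- generate_urine(4, 800, 0, blocks, noise_sd = 0.05, seed = 2)
  expect_false(cosinor_fit(excretion_rates(uf))$significant)
  # determinism
  expect_identical(generate_urine(4, 800, 600, blocks, 0.2, seed = 3),
                   generate_urine(4, 800, 600, blocks, 0.2, seed = 3))
})

test_that("cohort truth moments match the configured heterogeneity", {
  co <- generate_cohort(n_subjects = 40, seed = 77, phase_sd = 1.1,
                        shift_mean_h = 1.35, shift_sd_h = 1.0)
  tr <- co$truth
  expect_equal(nrow(tr), 40)
  expect_equal(circular_mean_hours(tr$true_diurnal_acrophase), 3.97,
               tolerance = 0.6 / 3.97)
  expect_equal(mean(-tr$true_shift), 1.35, tolerance = 0.55 / 1.35)
  expect_true(all(tr$n_night_shifts %in% 3:5))
  expect_true(all(tr$n_diurnal_days >= 2 & tr$n_diurnal_days <= 14))
})

test_that("cohort fixtures re-read identically through the package readers", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(n_subjects = 2, seed = 13, dir = dir)
  s <- co$subjects[[1]]
  sd <- file.path(dir, s$subject_id)
  expect_true(file.exists(file.path(dir, "truth_table.csv")))

  series2 <- read_actigraphy(file.path(sd, "actigraphy.csv"))
  expect_equal(as.numeric(series2$time), as.numeric(s$series$time))
  expect_equal(series2$lux, s$series$lux, tolerance = 1e-12)
  expect_equal(series2$activity, s$series$activity)

  diary2 <- read_diary(file.path(sd, "diary.csv"))
  expect_equal(diary2$shift_type, s$diary$shift_type)
  expect_equal(as.numeric(diary2$start), as.numeric(s$diary$start))

  urine2 <- read_urine(file.path(sd, "urine_diurnal.csv"))
  expect_equal(urine2$volume_ml, s$urine_diurnal$volume_ml, tolerance = 1e-6)
  expect_equal(as.numeric(urine2$block_end),
               as.numeric(s$urine_diurnal$block_end))

  # regenerating with the same master seed reproduces the fixtures byte for byte
  dir2 <- withr::local_tempdir()
  generate_cohort(n_subjects = 2, seed = 13, dir = dir2)
  f1 <- file.path(sd, "actigraphy.csv")
  f2 <- file.path(dir2, s$subject_id, "actigraphy.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the actigraphy reader validates, sorts and fills", {
  dir <- withr::local_tempdir()
  tm <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC") + 60 * (0:299)
  df <- data.frame(time = format(tm, "%Y-%m-%dT%H:%M:%S"),
                   lux = stats::runif(300, 0, 100), activity = rpois(300, 50),
                   worn = TRUE)
  f <- file.path(dir, "a.csv")

  # shuffled rows come back sorted and identical to the sorted original
  utils::write.csv(df[sample(300), ], f, row.names = FALSE)
  s1 <- read_actigraphy(f)
  expect_equal(format(s1$time, "%Y-%m-%dT%H:%M:%S"), df$time)
  expect_equal(s1$lux, df$lux, tolerance = 1e-9)

  # an off-wrist block is carried through as worn = FALSE epochs
  df2 <- df; df2$worn[101:220] <- FALSE
  utils::write.csv(df2, f, row.names = FALSE)
  expect_equal(sum(!read_actigraphy(f)$worn), 120)

  # a gap is filled explicitly and reported
  utils::write.csv(df[-(150:179), ], f, row.names = FALSE)
  expect_message(s3 <- read_actigraphy(f), "filled 30 missing epochs")
  expect_equal(nrow(s3), 300)
  expect_true(all(!s3$worn[150:179]))

  # two-minute epochs are expanded onto the minute grid
  utils::write.csv(df[seq(1, 300, by = 2), ], f, row.names = FALSE)
  s4 <- read_actigraphy(f)
  expect_equal(nrow(s4), 300)
  expect_equal(s4$lux[1:2], rep(df$lux[1], 2))

  # negative values and broken timestamps are rejected
  df5 <- df; df5$lux[3] <- -4
  utils::write.csv(df5, f, row.names = FALSE)
  expect_error(read_actigraphy(f), "negative")
  df6 <- df; df6$time[5] <- "not-a-time"
  utils::write.csv(df6, f, row.names = FALSE)
  expect_error(read_actigraphy(f), "timestamp")

  # Actiwatch-style dialect maps its column names and off-wrist flag
  df7 <- data.frame(timestamp = df$time, white_light = df$lux,
                    activity = df$activity, off_wrist = c(rep(0, 290), rep(1, 10)))
  utils::write.csv(df7, f, row.names = FALSE)
  s7 <- read_actigraphy(f, dialect = "actiwatch")
  expect_equal(sum(!s7$worn), 10)
  expect_equal(s7$lux, df$lux, tolerance = 1e-9)
})
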