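#' Schedule specification for a synthetic shift worker
#'
#' Describes the simulated roster: a run of diurnal days (day/evening
#' shifts or days off with a fixed nocturnal sleep window) followed by 3-5
#' consecutive night shifts with daytime recovery sleep.  Defaults are the
#' group-mean habits of a hospital shift-work cohort: bed 23:16, wake
#' 07:23 on diurnal days; nights worked 20:00-08:30 with recovery sleep
#' 09:20-15:57.
#'
#' @param n_diurnal_days Number of diurnal days before the night block.
#' @param n_night_shifts Number of consecutive night shifts (3-5).
#' @param sleep_diurnal Clock hours `c(bed, wake)` for diurnal sleep.
#' @param sleep_post_night Clock hours `c(bed, wake)` for daytime sleep
#'   after each night shift.
#' @param night_shift Clock hours `c(start, end)` of the night shift (end
#'   on the next day).
#' @param day_shift Clock hours `c(start, end)` of a day shift (used for
#'   the simulated work diary on alternating diurnal days).
#' @param start_date First calendar date (`Date` or string); the recording
#'   starts at noon of this date.
#' @return A list of class `schedule_spec`.
#' @export
schedule_spec <- function(n_diurnal_days = 7, n_night_shifts = 4,
                          sleep_diurnal = c(23 + 16 / 60, 7 + 23 / 60),
                          sleep_post_night = c(9 + 20 / 60, 15 + 57 / 60),
                          night_shift = c(20, 8.5),
                          day_shift = c(7, 15.5),
                          start_date = "2024-03-04") {
  stopifnot(n_night_shifts %in% 3:5, n_diurnal_days >= 1)
  structure(list(n_diurnal_days = as.integer(n_diurnal_days),
                 n_night_shifts = as.integer(n_night_shifts),
                 sleep_diurnal = sleep_diurnal,
                 sleep_post_night = sleep_post_night,
                 night_shift = night_shift, day_shift = day_shift,
                 start_date = as.Date(start_date)),
            class = "schedule_spec")
}

#' Light environment for the synthetic generator
#'
#' Lux is drawn per minute from log-normal distributions by context.  On
#' night-schedule days every waking epoch is drawn from a single log-normal
#' calibrated so that about 24% of waking epochs fall below 10 lux and
#' about 61% below 100 lux (typical of hospital night work); the
#' `evening_weight` parameter then re-assigns the same draws so that
#' brighter values fall preferentially in the evening portion of the wake
#' period (the marginal distribution is untouched, only its timing).  Sleep
#' epochs are dark.
#'
#' @param indoor_median_lux,indoor_sdlog Diurnal indoor waking light.
#' @param evening_median_lux Dimmer domestic light between 20:00 and
#'   bedtime on diurnal days.
#' @param outdoor_median_lux,outdoor_sdlog,outdoor_hour_prob Outdoor
#'   excursions: each diurnal clock hour between 09:00 and 17:00 is outdoor
#'   with this probability.
#' @param night_pct_lt10,night_pct_lt100 Calibration quantiles for
#'   night-schedule waking light (fractions below 10 and 100 lux).
#' @param evening_weight In `[0, 1]`: 0 leaves night-shift light timing
#'   random, 1 sorts it brightest-first within each wake period; the
#'   default biases bright light into the evening, the pattern that drives
#'   circadian delays on night schedules.
#' @param lux_cap Upper clamp on generated lux.
#' @param noise 1 for the stochastic generator, 0 for a noiseless trace
#'   (constant 150 lux awake, 0 asleep; constant activity) whose rest
#'   intervals are exactly recoverable.
#' @return A list of class `light_environment`.
#' @export
light_environment <- function(indoor_median_lux = 150, indoor_sdlog = 0.6,
                              evening_median_lux = 40,
                              outdoor_median_lux = 2000, outdoor_sdlog = 0.5,
                              outdoor_hour_prob = 0.15,
                              night_pct_lt10 = 0.24, night_pct_lt100 = 0.61,
                              evening_weight = 0.5,
                              lux_cap = 30000, noise = 1) {
  z1 <- stats::qnorm(night_pct_lt10)
  z2 <- stats::qnorm(night_pct_lt100)
  sdlog <- (log(100) - log(10)) / (z2 - z1)
  structure(list(indoor_median_lux = indoor_median_lux,
                 indoor_sdlog = indoor_sdlog,
                 evening_median_lux = evening_median_lux,
                 outdoor_median_lux = outdoor_median_lux,
                 outdoor_sdlog = outdoor_sdlog,
                 outdoor_hour_prob = outdoor_hour_prob,
                 night_meanlog = log(10) - z1 * sdlog,
                 night_sdlog = sdlog,
                 evening_weight = evening_weight,
                 lux_cap = lux_cap, noise = noise),
            class = "light_environment")
}

# absolute hour (since 00:00 of spec start date) helpers for schedule building
sleep_windows_abs <- function(spec) {
  D <- spec$n_diurnal_days; K <- spec$n_night_shifts
  bed_d <- spec$sleep_diurnal[1]; wake_d <- spec$sleep_diurnal[2]
  bed_n <- spec$sleep_post_night[1]; wake_n <- spec$sleep_post_night[2]
  # the night following day d: a bedtime before noon means "after midnight"
  bed_abs <- (seq_len(D) - 1) * 24 + if (bed_d >= 12) bed_d else 24 + bed_d
  diurnal <- data.frame(
    start = bed_abs,
    end = bed_abs + clock_duration(bed_d, wake_d),
    diurnal = TRUE)
  post_abs <- (D + seq_len(K)) * 24 + bed_n
  post <- data.frame(
    start = post_abs,
    end = post_abs + clock_duration(bed_n, wake_n),
    diurnal = FALSE)
  rbind(diurnal, post)
}

shift_windows_abs <- function(spec) {
  D <- spec$n_diurnal_days; K <- spec$n_night_shifts
  data.frame(start = (D + seq_len(K) - 1) * 24 + spec$night_shift[1],
             end = (D + seq_len(K)) * 24 + spec$night_shift[2])
}

#' Generate a minute-epoch actigraphy trace for one subject
#'
#' Builds the full roster timeline (noon of day 1 to 20:00 of the day after
#' the last night shift), assigns sleep/wake/shift status from the
#' schedule, and draws lux and activity per minute.  Activity is a Poisson
#' count with a log-normally varying rate (bursty wake movement, near-zero
#' during sleep).  The true sleep intervals are returned as ground-truth
#' labels for validating rest scoring.  Deterministic for a given seed.
#'
#' @param spec A [schedule_spec()].
#' @param env A [light_environment()].
#' @param seed Integer RNG seed.
#' @return A list: `series` (an [epoch_series()]), `rest_truth`
#'   (data.frame `start`, `end`, `kind`, `diurnal`), `diary` (data.frame
#'   `shift_type`, `start`, `end`), `night_start`/`last_shift_end`
#'   (POSIXct), `spec`, `env`.
#' @export
generate_trace <- function(spec = schedule_spec(), env = light_environment(),
                           seed = 1) {
  set.seed(seed)
  t0_abs <- 12                                   # noon, day 1
  D <- spec$n_diurnal_days; K <- spec$n_night_shifts
  end_abs <- (D + K) * 24 + 20                   # 20:00 after last recovery sleep
  np <- round((end_abs - t0_abs) * 60)
  abs_h <- t0_abs + (seq_len(np) - 1) / 60       # epoch start times
  origin <- as.POSIXct(paste(format(spec$start_date), "00:00:00"), tz = "UTC")
  tm <- origin + round(abs_h * 3600)

  sw <- sleep_windows_abs(spec)
  shifts <- shift_windows_abs(spec)
  in_any <- function(h, win) {
    out <- rep(FALSE, length(h))
    for (k in seq_len(nrow(win)))
      out <- out | (h >= win$start[k] & h < win$end[k])
    out
  }
  asleep <- in_any(abs_h, sw)
  night_sched <- abs_h >= shifts$start[1]        # from first night shift onwards
  clock <- abs_h %% 24

  lux <- numeric(np)
  activity <- numeric(np)
  if (env$noise == 0) {
    lux[!asleep] <- 150
    activity[!asleep] <- 100
  } else {
    # --- diurnal waking light: indoor / evening / outdoor-hour mixture
    dwake <- which(!asleep & !night_sched)
    lux[dwake] <- stats::rlnorm(length(dwake), log(env$indoor_median_lux),
                                env$indoor_sdlog)
    eve <- dwake[clock[dwake] >= 20 | clock[dwake] < 4]
    lux[eve] <- stats::rlnorm(length(eve), log(env$evening_median_lux),
                              env$indoor_sdlog)
    day_hours <- unique(floor(abs_h[dwake]))
    day_hours <- day_hours[(day_hours %% 24) >= 9 & (day_hours %% 24) < 17]
    outdoor_hours <- day_hours[stats::runif(length(day_hours)) < env$outdoor_hour_prob]
    odr <- dwake[floor(abs_h[dwake]) %in% outdoor_hours]
    lux[odr] <- stats::rlnorm(length(odr), log(env$outdoor_median_lux),
                              env$outdoor_sdlog)
    # --- night-schedule waking light: calibrated marginal, evening-weighted
    nwake <- which(!asleep & night_sched)
    draws <- stats::rlnorm(length(nwake), env$night_meanlog, env$night_sdlog)
    if (env$evening_weight > 0 && length(nwake) > 1) {
      blocks <- cumsum(c(1, diff(nwake) > 1))     # contiguous wake periods
      reordered <- draws
      for (b in unique(blocks)) {
        idx <- which(blocks == b)
        nb <- length(idx)
        key <- (1 - env$evening_weight) * stats::runif(nb) +
          env$evening_weight * (seq_len(nb) / nb)
        reordered[idx[order(key)]] <- sort(draws[idx], decreasing = TRUE)
      }
      draws <- reordered
    }
    lux[nwake] <- draws
    lux <- pmin(lux, env$lux_cap)
    # --- activity: Poisson counts with log-normal rate
    lam <- ifelse(asleep, stats::rlnorm(np, log(2), 0.7),
                  stats::rlnorm(np, log(150), 0.5))
    activity <- stats::rpois(np, lam)
  }
  lux[asleep] <- 0

  series <- epoch_series(tm, lux, activity)
  rest_truth <- data.frame(
    start = origin + round(sw$start * 3600),
    end = origin + round(sw$end * 3600),
    kind = "main", diurnal = sw$diurnal)
  # work diary: night shifts plus day shifts on alternating diurnal days
  day_idx <- seq(1, D, by = 2)
  diary <- rbind(
    data.frame(shift_type = "day",
               start = origin + round(((day_idx - 1) * 24 + spec$day_shift[1]) * 3600),
               end = origin + round(((day_idx - 1) * 24 + spec$day_shift[2]) * 3600)),
    data.frame(shift_type = "night",
               start = origin + round(shifts$start * 3600),
               end = origin + round(shifts$end * 3600)))
  list(series = series, rest_truth = rest_truth, diary = diary,
       night_start = origin + round(shifts$start[1] * 3600),
       last_shift_end = origin + round(shifts$end[K] * 3600),
       spec = spec, env = env)
}

#' Urine collection block plan over a window
#'
#' Sequential blocks: 4-hourly while awake, 8-hourly (one block) during
#' sleep, following the window's sleep schedule.  A boundary that would
#' create a block shorter than `min_block_h` is absorbed into the next
#' block.
#'
#' @param start POSIXct start of the collection window.
#' @param duration_h Total collection span in hours.
#' @param sleep_windows Data.frame with POSIXct `start`, `end`.
#' @param min_block_h Minimum block duration (default 2).
#' @return Data.frame with POSIXct `block_start`, `block_end`.
#' @export
urine_block_plan <- function(start, duration_h, sleep_windows,
                             min_block_h = 2) {
  stop_at <- start + duration_h * 3600
  in_sleep <- function(t) {
    for (k in seq_len(nrow(sleep_windows)))
      if (t >= sleep_windows$start[k] && t < sleep_windows$end[k]) return(k)
    0L
  }
  next_sleep_start <- function(t) {
    st <- sleep_windows$start[sleep_windows$start > t]
    if (length(st) == 0) stop_at else min(st)
  }
  out <- list()
  t <- start
  while (t < stop_at - 1) {
    k <- in_sleep(t)
    if (k > 0) {
      e <- min(sleep_windows$end[k], t + 8 * 3600, stop_at)
    } else {
      e <- min(t + 4 * 3600, next_sleep_start(t), stop_at)
    }
    if (as.numeric(difftime(stop_at, e, units = "hours")) < min_block_h)
      e <- stop_at
    if (as.numeric(difftime(e, t, units = "hours")) < min_block_h &&
        length(out) > 0) {
      # absorb a sliver into the previous block, keeping wake/sleep
      # boundaries aligned for the blocks that follow
      out[[length(out)]]$block_end <- e
    } else {
      if (as.numeric(difftime(e, t, units = "hours")) < min_block_h) {
        k2 <- in_sleep(e + 1)
        e <- if (k2 > 0) min(sleep_windows$end[k2], stop_at)
             else min(e + 4 * 3600, next_sleep_start(e + 1), stop_at)
      }
      out[[length(out) + 1]] <- data.frame(block_start = t, block_end = e)
    }
    t <- e
  }
  do.call(rbind, out)
}

#' Generate urine aMT6s samples with a known cosine acrophase
#'
#' The true excretion-rate rhythm is mesor + amplitude x
#' cos(2 pi (t - phi)/24); each block receives the exact integral of that
#' rhythm over the block, an optional multiplicative log-normal noise
#' factor, and a random void volume, from which the assayed concentration
#' follows.
#'
#' @param true_acrophase_h True acrophase phi, clock hours.
#' @param mesor,amplitude Rate parameters, ng/h (`amplitude <= mesor` so
#'   rates stay non-negative).
#' @param blocks Data.frame with POSIXct `block_start`, `block_end` (e.g.
#'   from [urine_block_plan()]).
#' @param noise_sd SD of the log-normal noise on each block total (0 =
#'   noiseless).
#' @param seed Integer RNG seed.
#' @return Data.frame with `block_start`, `block_end`, `volume_ml`,
#'   `amt6s_ng_ml`.
#' @export
generate_urine <- function(true_acrophase_h, mesor = 800, amplitude = 600,
                           blocks, noise_sd = 0.1, seed = 1) {
  stopifnot(amplitude <= mesor, amplitude >= 0)
  set.seed(seed)
  anchor <- trunc(min(blocks$block_start), "days")
  t1 <- as.numeric(difftime(blocks$block_start, anchor, units = "hours"))
  t2 <- as.numeric(difftime(blocks$block_end, anchor, units = "hours"))
  w <- 2 * pi / 24
  total <- mesor * (t2 - t1) +
    (amplitude / w) * (sin(w * (t2 - true_acrophase_h)) -
                         sin(w * (t1 - true_acrophase_h)))
  nb <- nrow(blocks)
  if (noise_sd > 0) total <- total * stats::rlnorm(nb, 0, noise_sd)
  volume <- if (noise_sd > 0) stats::runif(nb, 150, 400) else rep(250, nb)
  data.frame(block_start = blocks$block_start, block_end = blocks$block_end,
             volume_ml = volume, amt6s_ng_ml = total / volume)
}

#' Generate a complete synthetic shift-worker cohort
#'
#' Draws per-subject schedules and circadian truth: the true diurnal
#' acrophase is normal around 03:58 (clock), the subject's habitual sleep
#' window is shifted in step with it, and the true night-schedule acrophase
#' is delayed by a normally distributed amount (mean 1.35 h) so a minority
#' of subjects advance.  Each subject gets an actigraphy trace, a work
#' diary, diurnal and night urine collections, and the truth record.
#'
#' @param n_subjects Number of subjects (default 25).
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param phase_sd SD of the true diurnal acrophase across subjects, hours.
#' @param shift_mean_h,shift_sd_h Mean and SD of the true diurnal-to-night
#'   delay in hours (positive = the night acrophase occurs later).
#' @param diurnal_days_range Integer range to draw `n_diurnal_days` from.
#' @param urine_noise_sd Log-normal noise SD on urine block totals.
#' @param env A [light_environment()]; `noise = 0` makes traces noiseless.
#' @param dir Optional directory: when given, per-subject CSV fixtures
#'   (actigraphy, diary, urine) and a cohort `truth_table.csv` are written.
#' @return A list of class `synthetic_cohort`: `subjects` (list; each has
#'   `subject_id`, `series`, `rest_truth`, `diary`, `night_start`,
#'   `last_shift_end`, `urine_diurnal`, `urine_night`, `truth`), and
#'   `truth` (data.frame across subjects).
#' @export
generate_cohort <- function(n_subjects = 25, seed = 20240304,
                            phase_sd = 1.1, shift_mean_h = 1.35,
                            shift_sd_h = 1.0,
                            diurnal_days_range = c(2L, 14L),
                            urine_noise_sd = 0.1,
                            env = light_environment(), dir = NULL) {
  stopifnot(n_subjects >= 1)
  set.seed(seed %% .Machine$integer.max)
  subj_seed <- sample.int(2^31 - 1, n_subjects * 3)
  dr <- seq(diurnal_days_range[1], diurnal_days_range[2])
  n_diurnal <- if (length(dr) == 1L) rep(dr, n_subjects) else
    sample(dr, n_subjects, replace = TRUE, prob = stats::dnorm(dr, 7.2, 2.9))
  n_nights <- sample(3:5, n_subjects, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  delta <- stats::rnorm(n_subjects, 0, phase_sd)
  true_diurnal <- clock_hours(3.97 + delta)
  delay <- stats::rnorm(n_subjects, shift_mean_h, shift_sd_h)
  true_night <- clock_hours(true_diurnal + delay)

  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    spec <- schedule_spec(
      n_diurnal_days = n_diurnal[i], n_night_shifts = n_nights[i],
      sleep_diurnal = c(clock_hours(23 + 16 / 60 + delta[i]),
                        clock_hours(7 + 23 / 60 + delta[i])),
      sleep_post_night = c(9 + 20 / 60, 15 + 57 / 60))
    tr <- generate_trace(spec, env, seed = subj_seed[i])
    origin <- as.POSIXct(paste(format(spec$start_date), "00:00:00"),
                         tz = "UTC")
    D <- spec$n_diurnal_days; K <- spec$n_night_shifts
    sleeps <- tr$rest_truth
    # diurnal collection: 48 h ending at the final diurnal wake time
    d_end <- sleeps$end[sum(sleeps$diurnal)]
    d_blocks <- urine_block_plan(d_end - 48 * 3600, 48, sleeps)
    # night collection: 32 h from the wake preceding the final shift
    n_start <- origin + round(((D + K - 1) * 24 + spec$sleep_post_night[2]) * 3600)
    n_blocks <- urine_block_plan(n_start, 32, sleeps)
    subjects[[i]] <- list(
      subject_id = sprintf("S%02d", i),
      series = tr$series, rest_truth = tr$rest_truth, diary = tr$diary,
      night_start = tr$night_start, last_shift_end = tr$last_shift_end,
      urine_diurnal = generate_urine(true_diurnal[i], 800, 600, d_blocks,
                                     urine_noise_sd, seed = subj_seed[n_subjects + i]),
      urine_night = generate_urine(true_night[i], 800, 600, n_blocks,
                                   urine_noise_sd, seed = subj_seed[2 * n_subjects + i]),
      truth = list(true_diurnal_acrophase = true_diurnal[i],
                   true_night_acrophase = true_night[i],
                   true_shift = wrap_hours(true_diurnal[i] - true_night[i]),
                   seed = subj_seed[i]))
  }
  truth <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    n_diurnal_days = n_diurnal, n_night_shifts = n_nights,
    true_diurnal_acrophase = true_diurnal,
    true_night_acrophase = true_night,
    true_shift = wrap_hours(true_diurnal - true_night),
    seed = subj_seed[seq_len(n_subjects)])
  cohort <- structure(list(subjects = subjects, truth = truth),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write cohort fixtures as CSV files
#'
#' One directory per subject containing `actigraphy.csv`, `diary.csv`,
#' `urine_diurnal.csv`, `urine_night.csv`, plus a cohort-level
#' `truth_table.csv`.  The dialects are exactly those the package readers
#' consume.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    write_actigraphy(s$series, file.path(sd, "actigraphy.csv"))
    utils::write.csv(data.frame(subject_id = s$subject_id,
                                shift_type = s$diary$shift_type,
                                start_iso = iso(s$diary$start),
                                end_iso = iso(s$diary$end)),
                     file.path(sd, "diary.csv"), row.names = FALSE)
    for (u in c("urine_diurnal", "urine_night"))
      utils::write.csv(data.frame(subject_id = s$subject_id,
                                  block_start_iso = iso(s[[u]]$block_start),
                                  block_end_iso = iso(s[[u]]$block_end),
                                  volume_ml = s[[u]]$volume_ml,
                                  amt6s_ng_ml = s[[u]]$amt6s_ng_ml),
                       file.path(sd, paste0(u, ".csv")), row.names = FALSE)
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth_table.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a urine CSV in the cohort dialect
#' @param path CSV with `block_start_iso`, `block_end_iso`, `volume_ml`,
#'   `amt6s_ng_ml`.
#' @param tz Time zone (default UTC).
#' @return Data.frame suitable for [excretion_rates()].
#' @export
read_urine <- function(path, tz = "UTC") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    subject_id = if ("subject_id" %in% names(raw)) raw$subject_id else NA,
    block_start = as.POSIXct(raw$block_start_iso, tz = tz,
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S")),
    block_end = as.POSIXct(raw$block_end_iso, tz = tz,
                           tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                          "%Y-%m-%d %H:%M:%S")),
    volume_ml = raw$volume_ml, amt6s_ng_ml = raw$amt6s_ng_ml)
}

#' Read a work-diary CSV in the cohort dialect
#' @param path CSV with `shift_type`, `start_iso`, `end_iso`.
#' @param tz Time zone (default UTC).
#' @return Data.frame with `shift_type` and POSIXct `start`, `end`.
#' @export
read_diary <- function(path, tz = "UTC") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  fm <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")
  data.frame(shift_type = raw$shift_type,
             start = as.POSIXct(raw$start_iso, tz = tz, tryFormats = fm),
             end = as.POSIXct(raw$end_iso, tz = tz, tryFormats = fm))
}
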