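# Generator contracts: cycle-train statistics, channel physics, schedule
# protocol, determinism.

test_that("zero-variance symmetric profile gives an exactly periodic train", {
  tr <- generate_cycle_train(breathing_profile(mean_ipi = 2, ipi_cv = 0,
                                               ie_ratio = 1),
                             NULL, duration = 10, seed = 1)
  expect_equal(diff(tr$cycles$insp_start), rep(2, nrow(tr$cycles) - 1))
  expect_equal(tr$cycles$exp_start - tr$cycles$insp_start,
               rep(1, nrow(tr$cycles)))
})

test_that("ground-truth inspiration/expiration ratio is exact by construction", {
  tr <- generate_cycle_train(breathing_profile(ie_ratio = 0.88), NULL,
                             duration = 120, seed = 3)
  insp <- tr$cycles$exp_start - tr$cycles$insp_start
  ex <- tr$cycles$insp_start + tr$cycles$ipi - tr$cycles$exp_start
  expect_equal(insp / ex, rep(0.88, nrow(tr$cycles)))
})

test_that("empirical mean IPI is consistent with the gamma draw", {
  # each session's empirical mean should sit within 3 SE of the target
  for (seed in c(7, 19, 101)) {
    tr <- generate_cycle_train(breathing_profile(mean_ipi = 1.5, ipi_cv = 0.1),
                               NULL, duration = 600, seed = seed)
    n <- nrow(tr$cycles)
    se <- 1.5 * 0.1 / sqrt(n)
    expect_lt(abs(mean(tr$cycles$ipi) - 1.5), 3 * se)
  }
})

test_that("too-short durations are rejected with the minimum named", {
  expect_error(generate_cycle_train(breathing_profile(mean_ipi = 2), NULL,
                                    duration = 5, seed = 1),
               "3 \\* mean_ipi")
})

test_that("generation is deterministic in the seed", {
  a <- generate_cycle_train(breathing_profile(), NULL, 60, seed = 42)
  b <- generate_cycle_train(breathing_profile(), NULL, 60, seed = 42)
  c <- generate_cycle_train(breathing_profile(), NULL, 60, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$cycles, c$cycles))

  s1 <- simulate_session(seed = 11, duration = 60, schedule = NULL,
                         with_lick = FALSE)
  s2 <- simulate_session(seed = 11, duration = 60, schedule = NULL,
                         with_lick = FALSE)
  expect_identical(s1$temperature$values, s2$temperature$values)
  expect_identical(s1$chest_movement$values, s2$chest_movement$values)
})

test_that("chest diameter peaks at inspiration end and integrates exactly", {
  tr <- generate_cycle_train(breathing_profile(mean_ipi = 2, ipi_cv = 0,
                                               ie_ratio = 1),
                             NULL, duration = 10, seed = 1)
  ch <- render_chest_channels(tr, amplitude = 1, fs = 100, noise_sd = 0, seed = 1)
  tt <- trace_times(ch$diameter)
  # maximum of each cycle within one sample of the inspiration end
  for (k in seq_len(nrow(tr$cycles))) {
    win <- tt >= tr$cycles$insp_start[k] & tt < tr$cycles$insp_start[k] + tr$cycles$ipi[k]
    tmax <- tt[win][which.max(ch$diameter$values[win])]
    expect_lt(abs(tmax - tr$cycles$exp_start[k]), 1 / 100 + 1e-12)
  }
  # inverse consistency: cumulative trapezoid of noiseless movement
  d2 <- integrate_chest_movement(ch$movement, detrend_window = 0)
  rel <- sqrt(sum((d2$values - ch$diameter$values)^2) /
              sum(ch$diameter$values^2))
  expect_lt(rel, 1e-6)
})

test_that("zero amplitude renders only the noise floor", {
  tr <- generate_cycle_train(breathing_profile(), NULL, 30, seed = 2)
  ch <- render_chest_channels(tr, amplitude = 0, fs = 50, noise_sd = 0, seed = 1)
  expect_true(all(ch$diameter$values == 0))
  expect_true(all(ch$movement$values == 0))
})

test_that("with no lag, delays and noise, temperature extrema sit on truth boundaries", {
  tr <- generate_cycle_train(breathing_profile(mean_ipi = 2, ipi_cv = 0),
                             NULL, duration = 20, seed = 1)
  sen <- sensor_model(time_constant = 0, transport_delay_per_kg = 0,
                      transport_delay_intercept = 0, noise_sd = 0)
  tm <- render_nasal_temperature(tr, sen, breathing_profile(), fs = 100, seed = 1)
  ex <- detect_extrema(tm, smooth_window = 0.03)
  # temperature maxima sit at expiration ends (= inspiration starts of the
  # following cycle); minima at expiration starts. The first and last cycles
  # abut step discontinuities at the session edges, so their boundary peaks
  # are excluded, just as the analysis drops edge cycles.
  nb <- nrow(tr$cycles)
  bounds_pk <- tr$cycles$insp_start[-1]
  pk <- ex$time[ex$kind == "peak"]
  pk <- pk[pk > tr$cycles$exp_start[1] & pk < tr$cycles$insp_start[nb] + 0.5]
  th <- ex$time[ex$kind == "trough"]
  for (p in pk) expect_lt(min(abs(p - bounds_pk)), 1 / 100)
  for (t in th) expect_lt(min(abs(t - tr$cycles$exp_start)), 1 / 100)
})

test_that("first-order lag peak delay matches the analytic phase lag", {
  fs <- 100; tau <- 0.1; f <- 0.5
  t <- (0:4000) / fs
  y <- first_order_lag(sin(2 * pi * f * t), fs, tau)
  # locate one interior output peak with sub-sample refinement
  i <- 2000 + which.max(y[2001:2400])
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  tpk <- (i - 1 + 0.5 * (y[i - 1] - y[i + 1]) / den) / fs
  # input peaks at 1/(4f) + k/f
  input_peak <- 1 / (4 * f) + round((tpk - 1 / (4 * f)) * f) / f
  measured <- tpk - input_peak
  expect_lt(abs(measured - atan(2 * pi * f * tau) / (2 * pi * f)), 1 / fs)
})

test_that("temperature peak lag grows with time constant and body weight", {
  mean_lag <- function(tau, weight) {
    p <- breathing_profile(ipi_cv = 0.05, body_weight = weight)
    sen <- sensor_model(time_constant = tau, noise_sd = 0)
    tr <- generate_cycle_train(p, NULL, 90, seed = 5)
    tm <- render_nasal_temperature(tr, sen, p, fs = 100, seed = 1)
    ex <- detect_extrema(tm)
    pk <- ex$time[ex$kind == "peak"]
    m <- match_events(pk, tr$cycles$insp_start, tolerance = 0.9)
    m$mean_delay
  }
  lags_tau <- vapply(c(0, 0.05, 0.1, 0.2), mean_lag, 0, weight = 6)
  expect_true(all(diff(lags_tau) > 0))
  lags_w <- vapply(c(5, 6, 7), function(w) mean_lag(0.1, w), 0)
  expect_true(all(diff(lags_w) > 0))
})

test_that("music blocks shorten the true IPI for every seed", {
  sch <- build_default_schedule(seed = 1)
  music <- vapply(sch$blocks, function(b) b$kind == "music", TRUE)
  for (seed in 1:8) {
    tr <- generate_cycle_train(breathing_profile(music_ipi_factor = 0.85),
                               sch, schedule_end(sch), seed = seed)
    bi <- vapply(tr$cycles$insp_start, function(t) {
      i <- NA_integer_
      for (k in seq_along(sch$blocks)) {
        b <- sch$blocks[[k]]
        if (t >= b$start && t < b$start + b$duration) i <- k
      }
      i
    }, 1L)
    in_music <- !is.na(bi) & music[ifelse(is.na(bi), 1L, bi)]
    in_noise <- !is.na(bi) & !music[ifelse(is.na(bi), 1L, bi)]
    expect_lt(mean(tr$cycles$ipi[in_music]), mean(tr$cycles$ipi[in_noise]))
  }
})

test_that("the default schedule follows the printed session protocol", {
  sch <- build_default_schedule(seed = 4)
  expect_length(sch$blocks, 6L)
  expect_equal(schedule_end(sch), 6 * 180 + 5 * 60)
  tempos <- sort(vapply(sch$blocks, `[[`, 0, "tempo_bpm"))
  expect_equal(tempos, c(0, 0, 0, 85, 113, 212))
  expect_equal(length(sch$reward_times), 36L)
  # rewards fall inside blocks with >= 10 s spacing within each block
  for (b in sch$blocks) {
    rw <- sch$reward_times[sch$reward_times >= b$start &
                           sch$reward_times <= b$start + b$duration]
    expect_length(rw, 6L)
    expect_true(all(diff(rw) >= 10))
  }
  expect_identical(build_default_schedule(seed = 4), sch)
})

test_that("lick bursts follow the rewards and stay inside their blocks", {
  sch <- build_default_schedule(seed = 2)
  lk <- render_lick_channel(sch, licks_per_reward = 8, fs = 500, seed = 1)
  expect_length(lk$truth_onsets, 36 * 8)
  # every onset inside the block of its parent reward, over several seeds
  for (seed in 1:5) {
    lk <- render_lick_channel(sch, licks_per_reward = 8, fs = 250, seed = seed)
    inside <- vapply(lk$truth_onsets, function(t) {
      any(vapply(sch$blocks, function(b) t >= b$start & t <= b$start + b$duration, TRUE))
    }, TRUE)
    expect_true(all(inside))
  }
  # no licks -> pure noise and empty truth
  lk0 <- render_lick_channel(sch, licks_per_reward = 0, fs = 250, seed = 3)
  expect_length(lk0$truth_onsets, 0L)
  expect_lt(max(abs(lk0$vibration$values)), 0.02 * 6)
})

test_that("session bundles round-trip through disk", {
  b <- simulate_session(seed = 9, schedule = build_default_schedule(9),
                        duration = 250, with_lick = TRUE)
  dir <- withr::local_tempdir()
  write_session_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("temperature.csv",
                                               "chest_movement.csv",
                                               "lick.csv", "schedule.json",
                                               "truth.json", "config.yaml")))))
  b2 <- read_session_bundle(dir)
  expect_equal(b2$temperature$values, b$temperature$values)
  expect_equal(b2$temperature$fs, b$temperature$fs)
  expect_equal(b2$truth$cycles$insp_start, b$truth$cycles$insp_start)
  expect_equal(length(b2$schedule$blocks), length(b$schedule$blocks))
  expect_equal(b2$schedule$reward_times, b$schedule$reward_times)
})
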