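# Cycle extraction: analytic extrema, brute-force oracle equivalence,
# segmentation conventions, summary arithmetic, parameter recovery.

test_that("sinusoid extrema are found at the analytic times", {
  fs <- 100
  t <- (0:2000) / fs
  tr <- sampled_trace(sin(2 * pi * 0.5 * t), fs, label = "sine")
  ex <- detect_extrema(tr)
  pk <- ex$time[ex$kind == "peak"]
  th <- ex$time[ex$kind == "trough"]
  expect_true(all(vapply(pk, function(p) min(abs(p - seq(0.5, 20, by = 2))) <= 1 / fs, TRUE)))
  expect_true(all(vapply(th, function(p) min(abs(p - seq(1.5, 20, by = 2))) <= 1 / fs, TRUE)))
  # alternation always holds
  expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
})

test_that("detection matches the exhaustive brute-force scan on random traces", {
  for (seed in 1:60) {
    tr <- random_trace(seed)
    want <- oracle_extrema(tr)
    got <- tryCatch(detect_extrema(tr), thermoresp_no_respiration = function(e) NULL)
    if (is.null(want)) {
      expect_null(got, label = sprintf("seed %d", seed))
    } else {
      expect_false(is.null(got), label = sprintf("seed %d", seed))
      expect_equal(got$index, want$index, label = sprintf("seed %d", seed))
      expect_equal(got$kind, want$kind, label = sprintf("seed %d", seed))
      expect_equal(got$time, want$time, tolerance = 1e-12,
                   label = sprintf("seed %d", seed))
    }
  }
})

test_that("degenerate traces raise the typed no-respiration error", {
  flat <- sampled_trace(rep(1, 500), 100, label = "flat")
  expect_error(detect_extrema(flat), class = "thermoresp_no_respiration")
  short <- sampled_trace(sin(1:50), 100)
  expect_error(detect_extrema(short), "refractory")
})

test_that("segmentation conventions mirror the physiology of each sensor", {
  ex <- structure(
    data.frame(time = c(1, 2, 3), kind = c("peak", "trough", "peak"),
               index = c(101, 201, 301), prominence = c(1, 1, 1)),
    class = c("resp_extrema", "data.frame"), fs = 100)
  cy_t <- segment_cycles(ex, "temperature")
  expect_equal(cy_t$insp_start, 1)
  expect_equal(cy_t$exp_start, 2)
  expect_equal(cy_t$insp_duration, 1)
  expect_equal(cy_t$exp_duration, 1)
  # same extrema read as chest diameter: phase labels swap
  ex5 <- structure(
    data.frame(time = 1:5, kind = c("peak", "trough", "peak", "trough", "peak"),
               index = seq(101, 501, by = 100), prominence = rep(1, 5)),
    class = c("resp_extrema", "data.frame"), fs = 100)
  # chest convention starts cycles at troughs: the leading peak is dropped
  # and only one full trough-peak-trough cycle fits in five extrema
  cy_c <- segment_cycles(ex5, "chest_diameter")
  expect_equal(cy_c$insp_start, 2)
  expect_equal(cy_c$exp_start, 3)
  # the same five extrema read as temperature give two full cycles
  cy_t5 <- segment_cycles(ex5, "temperature")
  expect_equal(cy_t5$insp_start, c(1, 3))
})

test_that("summaries follow the stated arithmetic", {
  cyc <- structure(
    data.frame(insp_start = c(0, 2), exp_start = c(0.9, 2.88),
               insp_duration = c(0.9, 0.88), exp_duration = c(1.0, 1.0)),
    class = c("resp_cycles", "data.frame"), signal_kind = "temperature")
  s <- summarize_cycles(cyc)
  expect_equal(s$ie_ratio, (0.9 + 0.88) / 2)
  expect_equal(s$ipi_series, 2)
  expect_equal(s$sd_ipi, NA_real_)

  per <- structure(
    data.frame(insp_start = c(0, 2, 4), exp_start = c(1, 3, 5),
               insp_duration = 1, exp_duration = 1),
    class = c("resp_cycles", "data.frame"), signal_kind = "temperature")
  sp <- summarize_cycles(per)
  expect_equal(sp$ipi_series, c(2, 2))
  expect_equal(sp$sd_ipi, 0)
  expect_error(summarize_cycles(per[1, ]), "2 cycles")
})

test_that("mean IPI and I/E ratio are recovered on noise-free sessions", {
  for (seed in 1:5) {
    p <- breathing_profile(mean_ipi = 1.8, ipi_cv = 0.1, ie_ratio = 0.88)
    sen <- sensor_model(noise_sd = 0)
    b <- simulate_session(p, sen, schedule = NULL, duration = 600, seed = seed,
                          with_chest = FALSE, with_lick = FALSE)
    s <- summarize_cycles(segment_cycles(detect_extrema(b$temperature),
                                         "temperature"))
    truth_mean <- mean(b$truth$cycles$ipi)
    expect_lt(abs(s$mean_ipi - truth_mean) / truth_mean, 0.02)
    expect_lt(abs(s$ie_ratio - 0.88), 0.05)
  }
})

test_that("temperature- and chest-derived IPI agree on the same session", {
  b <- simulate_session(breathing_profile(ipi_cv = 0.1),
                        sensor_model(noise_sd = 0.1),
                        schedule = NULL, duration = 300, seed = 21,
                        with_lick = FALSE)
  s_t <- summarize_cycles(segment_cycles(detect_extrema(b$temperature),
                                         "temperature"))
  chest <- integrate_chest_movement(b$chest_movement)
  s_c <- summarize_cycles(segment_cycles(detect_extrema(chest),
                                         "chest_diameter"))
  expect_lt(abs(s_t$mean_ipi - s_c$mean_ipi) / s_c$mean_ipi, 0.02)
})

test_that("estimation error degrades gracefully with sensor noise", {
  err_at <- function(noise_sd) {
    errs <- vapply(1:10, function(seed) {
      p <- breathing_profile(ipi_cv = 0.1, ie_ratio = 0.88)
      b <- simulate_session(p, sensor_model(noise_sd = noise_sd),
                            schedule = NULL, duration = 240, seed = seed,
                            with_chest = FALSE, with_lick = FALSE)
      s <- summarize_cycles(segment_cycles(detect_extrema(b$temperature),
                                           "temperature"))
      abs(s$ie_ratio - 0.88) +
        abs(s$mean_ipi - mean(b$truth$cycles$ipi)) / mean(b$truth$cycles$ipi)
    }, 0)
    mean(errs)
  }
  errs <- vapply(c(0, 0.45, 0.9, 1.8), err_at, 0)
  expect_true(all(diff(errs) > -1e-6))
})

test_that("integration recovers a closed-form antiderivative and kills drift", {
  fs <- 100; f <- 0.5
  t <- (0:6000) / fs
  mv <- sampled_trace(cos(2 * pi * f * t), fs, units = "au/s",
                      label = "chest_movement")
  d <- integrate_chest_movement(mv, detrend_window = 0)
  want <- sin(2 * pi * f * t) / (2 * pi * f)
  rel <- sqrt(sum((d$values - want)^2) / sum(want^2))
  expect_lt(rel, 1e-3)
  # constant offset integrates to a ramp; detrending must suppress it
  mv2 <- sampled_trace(cos(2 * pi * f * t) + 0.05, fs, units = "au/s",
                       label = "chest_movement")
  d2 <- integrate_chest_movement(mv2, detrend_window = 10)
  expect_lt(max(abs(d2$values)) , 3 * max(abs(want)))
  # zero movement integrates to zero diameter
  z <- integrate_chest_movement(sampled_trace(numeric(200), fs), 0)
  expect_true(all(z$values == 0))
})
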