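# Ground-truthed synthetic session generator.
#
# The generator emulates the physics of the recording chain: a quasi-periodic
# breathing cycle train drives (a) a chest-diameter waveform whose measured
# channel is its time-derivative ("chest movement" sensor), and (b) a nasal
# airflow-temperature waveform that reaches the thermosensor after a
# weight-dependent transport delay, attenuated by probe position, and is then
# low-passed by the sensor's first-order thermal lag. Reward deliveries spawn
# lick bursts on a vibration channel. Every channel comes with exact ground
# truth so parameter-recovery tests need no real recordings.

#' Breathing profile
#'
#' Parameters of the simulated animal's breathing.
#'
#' @param mean_ipi Mean inter-peak (inter-breath) interval in seconds.
#' @param ipi_cv Coefficient of variation of the IPI draws (>= 0; 0 gives a
#'   strictly periodic train).
#' @param ie_ratio Inspiration duration divided by expiration duration within
#'   each cycle (> 0). Default 0.88, a typical thermosensor estimate for an
#'   anesthetized macaque.
#' @param amplitude_chest Peak-to-trough chest diameter excursion (arbitrary
#'   units).
#' @param body_weight Body weight in kg; scales the airflow transport delay.
#' @param music_ipi_factor Multiplier (< 1 shortens) applied to the mean IPI
#'   while a music block is playing, emulating music-accelerated breathing.
#' @return A `breathing_profile` list.
#' @export
breathing_profile <- function(mean_ipi = 2.0, ipi_cv = 0.1, ie_ratio = 0.88,
                              amplitude_chest = 1.0, body_weight = 6.0,
                              music_ipi_factor = 0.85) {
  stopifnot(mean_ipi > 0, ipi_cv >= 0, ie_ratio > 0, body_weight > 0,
            music_ipi_factor > 0, music_ipi_factor <= 1)
  structure(list(mean_ipi = mean_ipi, ipi_cv = ipi_cv, ie_ratio = ie_ratio,
                 amplitude_chest = amplitude_chest, body_weight = body_weight,
                 music_ipi_factor = music_ipi_factor),
            class = "breathing_profile")
}

#' Thermosensor model
#'
#' Physical model of the nasal temperature probe and its placement.
#'
#' @param time_constant First-order thermal time constant in seconds
#'   (default 0.1, i.e. a 100-ms probe).
#' @param probe_position Probe tip position in mm relative to the nostril
#'   entrance; negative is outside. Allowed values -5, 0, +5.
#' @param attenuation_by_position Named gains in (0, 1] applied to the
#'   expired-air temperature excursion at each position; the signal is
#'   strongest inside the nostril.
#' @param transport_delay_per_kg Seconds of airflow transport delay per kg of
#'   body weight.
#' @param transport_delay_intercept Weight-independent part of the transport
#'   delay in seconds.
#' @param ambient_temp Ambient (inspired) air temperature in degrees C.
#' @param expired_temp Expired air temperature in degrees C; must exceed
#'   `ambient_temp`.
#' @param noise_sd Gaussian measurement noise SD in degrees C.
#' @return A `sensor_model` list.
#' @export
sensor_model <- function(time_constant = 0.1, probe_position = 5,
                         attenuation_by_position = c(`-5` = 0.5, `0` = 0.75, `5` = 1.0),
                         transport_delay_per_kg = 0.01,
                         transport_delay_intercept = 0,
                         ambient_temp = 25, expired_temp = 34,
                         noise_sd = 0.1) {
  stopifnot(time_constant >= 0, expired_temp > ambient_temp, noise_sd >= 0,
            all(attenuation_by_position > 0), all(attenuation_by_position <= 1))
  if (!as.character(probe_position) %in% names(attenuation_by_position)) {
    stop("`probe_position` must be one of: ",
         paste(names(attenuation_by_position), collapse = ", "), " (mm)",
         call. = FALSE)
  }
  structure(list(time_constant = time_constant, probe_position = probe_position,
                 attenuation_by_position = attenuation_by_position,
                 transport_delay_per_kg = transport_delay_per_kg,
                 transport_delay_intercept = transport_delay_intercept,
                 ambient_temp = ambient_temp, expired_temp = expired_temp,
                 noise_sd = noise_sd),
            class = "sensor_model")
}

# Transport delay of expired air from chest to probe, seconds.
transport_delay <- function(sensor, body_weight) {
  d <- sensor$transport_delay_intercept + sensor$transport_delay_per_kg * body_weight
  if (d < 0) stop("transport delay evaluated negative; check sensor model", call. = FALSE)
  d
}

#' Stimulus block
#'
#' One auditory stimulation block within a session.
#'
#' @param kind `"music"` or `"noise"`.
#' @param tempo_bpm Music tempo in beats/min (0 for noise).
#' @param level_db_spl Sound level in dB SPL.
#' @param start Block onset in seconds from session start.
#' @param duration Block duration in seconds (> 0).
#' @export
stimulus_block <- function(kind = c("music", "noise"), tempo_bpm = 0,
                           level_db_spl = 65, start = 0, duration = 180) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, start >= 0)
  if (kind == "music" && tempo_bpm <= 0) {
    stop("music blocks need `tempo_bpm` > 0", call. = FALSE)
  }
  structure(list(kind = kind, tempo_bpm = tempo_bpm,
                 level_db_spl = level_db_spl, start = start,
                 duration = duration),
            class = "stimulus_block")
}

#' Session schedule
#'
#' Ordered stimulus blocks plus reward delivery times.
#'
#' @param blocks List of [stimulus_block()]s, time-ordered and non-overlapping.
#' @param reward_times Reward delivery times in seconds; each must fall inside
#'   some block.
#' @param reward_volume Reward volume in ml (default 0.2).
#' @export
session_schedule <- function(blocks, reward_times = numeric(0),
                             reward_volume = 0.2) {
  stopifnot(length(blocks) >= 1L, all(vapply(blocks, inherits, TRUE, "stimulus_block")))
  starts <- vapply(blocks, `[[`, 0, "start")
  ends <- starts + vapply(blocks, `[[`, 0, "duration")
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] < ends[-length(ends)])) {
    stop("blocks must be time-ordered and non-overlapping", call. = FALSE)
  }
  if (length(reward_times)) {
    inside <- vapply(reward_times, function(r) any(r >= starts & r <= ends), TRUE)
    if (!all(inside)) stop("every reward time must fall inside a block", call. = FALSE)
  }
  structure(list(blocks = blocks, reward_times = sort(as.numeric(reward_times)),
                 reward_volume = reward_volume),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %d blocks, %d rewards, span %.0f s\n",
              length(x$blocks), length(x$reward_times), schedule_end(x)))
  for (b in x$blocks) {
    cat(sprintf("  %6.0f-%4.0f s  %-5s %s\n", b$start, b$start + b$duration,
                b$kind, if (b$kind == "music") sprintf("%g bpm", b$tempo_bpm) else ""))
  }
  invisible(x)
}

schedule_end <- function(schedule) {
  b <- schedule$blocks[[length(schedule$blocks)]]
  b$start + b$duration
}

# Index of the block containing time t, or NA.
block_at <- function(schedule, t) {
  for (i in seq_along(schedule$blocks)) {
    b <- schedule$blocks[[i]]
    if (t >= b$start && t < b$start + b$duration) return(i)
  }
  NA_integer_
}

#' Default behavioral session schedule
#'
#' Six 180-s blocks -- three music blocks at 212, 113 and 85 beats/min
#' (65-70 dB SPL) and three white-noise blocks (40 dB SPL) -- in seeded
#' shuffled order, separated by 60-s silent gaps. Six rewards per block are
#' drawn uniformly with at least 10 s spacing, emulating 0.2-ml rewards
#' delivered about once per 30 s.
#'
#' @param seed Integer seed; the same seed reproduces the same schedule.
#' @return A [session_schedule()], total span 6*180 + 5*60 = 1380 s.
#' @export
build_default_schedule <- function(seed = 1) {
  with_seed(seed, {
    spec <- list(
      list(kind = "music", tempo = 212, level = 67.5),
      list(kind = "music", tempo = 113, level = 67.5),
      list(kind = "music", tempo = 85, level = 67.5),
      list(kind = "noise", tempo = 0, level = 40),
      list(kind = "noise", tempo = 0, level = 40),
      list(kind = "noise", tempo = 0, level = 40)
    )
    spec <- spec[sample.int(6L)]
    blocks <- vector("list", 6L)
    rewards <- numeric(0)
    for (i in seq_len(6L)) {
      start <- (i - 1L) * 240
      blocks[[i]] <- stimulus_block(spec[[i]]$kind, spec[[i]]$tempo,
                                    spec[[i]]$level, start = start,
                                    duration = 180)
      rewards <- c(rewards, draw_spaced_times(6L, start + 2, start + 175,
                                              min_gap = 10))
    }
    session_schedule(blocks, rewards)
  })
}

# n sorted uniform draws on [lo, hi] with pairwise gaps >= min_gap, by
# rejection; the constraint is loose enough that this terminates quickly.
draw_spaced_times <- function(n, lo, hi, min_gap) {
  for (k in 1:10000) {
    s <- sort(stats::runif(n, lo, hi))
    if (n < 2L || all(diff(s) >= min_gap)) return(s)
  }
  stop("could not place ", n, " times with ", min_gap, " s spacing in [",
       lo, ", ", hi, "]", call. = FALSE)
}

#' Generate a ground-truth breathing cycle train
#'
#' Successive inspiration-start intervals are independent gamma draws with
#' mean equal to the effective IPI and coefficient of variation `ipi_cv`,
#' truncated below at 0.3 s (by redrawing). While a music block is playing
#' the mean is multiplied by `music_ipi_factor`, emulating music-accelerated
#' breathing. Within each cycle the inspiration lasts
#' `ipi * ie_ratio / (1 + ie_ratio)` and the expiration `ipi / (1 + ie_ratio)`.
#'
#' @param profile A [breathing_profile()].
#' @param schedule A [session_schedule()], or `NULL` for no stimulus
#'   modulation.
#' @param duration Session duration in seconds; must exceed 3 * `mean_ipi`.
#' @param seed Integer seed; identical seeds reproduce identical trains.
#' @return A `ground_truth` object: `$cycles` is a data frame with columns
#'   `insp_start`, `exp_start`, `ipi` (seconds); `$duration` the session
#'   length; `$lick_onsets` is filled in by [render_lick_channel()] wrappers.
#' @export
generate_cycle_train <- function(profile, schedule = NULL, duration, seed = 1) {
  stopifnot(inherits(profile, "breathing_profile"))
  min_dur <- 3 * profile$mean_ipi
  if (duration <= min_dur) {
    stop(sprintf("`duration` must exceed 3 * mean_ipi = %.3f s", min_dur),
         call. = FALSE)
  }
  with_seed(seed, {
    insp <- numeric(0)
    exp_ <- numeric(0)
    ipis <- numeric(0)
    t <- 0.2  # fixed small offset so the first cycle is fully observed
    repeat {
      m <- profile$mean_ipi
      if (!is.null(schedule)) {
        bi <- block_at(schedule, t)
        if (!is.na(bi) && schedule$blocks[[bi]]$kind == "music") {
          m <- m * profile$music_ipi_factor
        }
      }
      ipi <- draw_ipi(m, profile$ipi_cv)
      if (t + ipi > duration) break
      insp <- c(insp, t)
      exp_ <- c(exp_, t + ipi * profile$ie_ratio / (1 + profile$ie_ratio))
      ipis <- c(ipis, ipi)
      t <- t + ipi
    }
    structure(list(cycles = data.frame(insp_start = insp, exp_start = exp_,
                                       ipi = ipis),
                   duration = duration, lick_onsets = numeric(0)),
              class = "ground_truth")
  })
}

# One gamma IPI draw with the given mean and CV, truncated below at 0.3 s.
draw_ipi <- function(mean, cv) {
  if (cv == 0) {
    if (mean < 0.3) stop("mean IPI below the 0.3 s truncation point", call. = FALSE)
    return(mean)
  }
  shape <- 1 / cv^2
  rate <- shape / mean
  for (k in 1:10000) {
    x <- stats::rgamma(1L, shape = shape, rate = rate)
    if (x >= 0.3) return(x)
  }
  stop("IPI truncation rejected 10000 draws; mean/cv imply implausible breathing",
       call. = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cycles over %.0f s (mean IPI %.3f s)%s\n",
              nrow(x$cycles), x$duration, mean(x$cycles$ipi),
              if (length(x$lick_onsets)) sprintf(", %d lick onsets", length(x$lick_onsets)) else ""))
  invisible(x)
}

# Evaluate the noiseless chest diameter waveform at times tt: raised-cosine
# rise over each inspiration, raised-cosine fall over each expiration, zero
# between cycles.
chest_diameter_at <- function(truth, tt, amplitude) {
  cy <- truth$cycles
  d <- numeric(length(tt))
  if (nrow(cy) == 0L || amplitude == 0) return(d)
  idx <- findInterval(tt, cy$insp_start)
  ok <- idx >= 1L
  ok[ok] <- tt[ok] < cy$insp_start[idx[ok]] + cy$ipi[idx[ok]]
  i <- idx[ok]
  u <- tt[ok]
  insp_dur <- cy$exp_start[i] - cy$insp_start[i]
  exp_dur <- cy$insp_start[i] + cy$ipi[i] - cy$exp_start[i]
  in_insp <- u < cy$exp_start[i]
  val <- numeric(length(u))
  val[in_insp] <- amplitude *
    (1 - cos(pi * (u[in_insp] - cy$insp_start[i][in_insp]) / insp_dur[in_insp])) / 2
  val[!in_insp] <- amplitude *
    (1 + cos(pi * (u[!in_insp] - cy$exp_start[i][!in_insp]) / exp_dur[!in_insp])) / 2
  d[ok] <- val
  d
}

#' Render chest diameter and chest movement channels
#'
#' The chest diameter rises over each inspiration and falls over each
#' expiration (raised-cosine segments, peak at inspiration end). The measured
#' channel is the movement sensor output: the finite-difference derivative of
#' the noiseless diameter plus white noise. The finite difference is
#' trapezoid-consistent -- cumulative trapezoidal integration of the
#' noiseless movement reproduces the diameter to machine precision -- so that
#' integration is the exact inverse used by the analysis.
#'
#' @param truth A `ground_truth` from [generate_cycle_train()].
#' @param amplitude Peak chest-diameter excursion (arbitrary units).
#' @param fs Sampling rate in Hz (>= 20).
#' @param noise_sd SD of white noise added to the movement channel.
#' @param seed Integer seed for the noise.
#' @return List with `diameter` (noiseless, units `au`) and `movement`
#'   (noisy derivative, units `au/s`), both [sampled_trace()]s.
#' @export
render_chest_channels <- function(truth, amplitude = 1, fs = 100,
                                  noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (fs < 20) stop("`fs` must be at least 20 Hz", call. = FALSE)
  n <- floor(truth$duration * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  d <- chest_diameter_at(truth, tt, amplitude)
  # trapezoid-conjugate finite difference: solves (m[k-1]+m[k])/(2 fs) =
  # d[k]-d[k-1] so that cumtrapz() inverts it exactly
  m <- numeric(n)
  if (n > 1L) {
    # recursion m[k] = 2 fs (d[k]-d[k-1]) - m[k-1], m[1] = 0, solved in
    # closed form via an alternating cumulative sum
    b <- 2 * fs * diff(d)
    sgn <- rep_len(c(-1, 1), n - 1L)
    m[-1L] <- cumsum(b * sgn) * sgn
  }
  mv <- with_seed(seed, m + stats::rnorm(n, sd = noise_sd))
  list(
    diameter = sampled_trace(d, fs, units = "au", label = "chest_diameter"),
    movement = sampled_trace(mv, fs, units = "au/s", label = "chest_movement")
  )
}

# Evaluate the idealized airflow temperature at the probe at times tt:
# ambient during (the tail of) inspiration, raised-cosine ramp toward
# ambient + gain * (expired - ambient) over expiration, falling back over the
# next inspiration. `tt` are already transport-delay-shifted by the caller.
airflow_temperature_at <- function(truth, tt, ambient, amp) {
  cy <- truth$cycles
  x <- rep(ambient, length(tt))
  if (nrow(cy) == 0L || amp == 0) return(x)
  idx <- findInterval(tt, cy$insp_start)
  ok <- idx >= 1L
  ok[ok] <- tt[ok] < cy$insp_start[idx[ok]] + cy$ipi[idx[ok]]
  i <- idx[ok]
  u <- tt[ok]
  insp_dur <- cy$exp_start[i] - cy$insp_start[i]
  exp_dur <- cy$insp_start[i] + cy$ipi[i] - cy$exp_start[i]
  in_insp <- u < cy$exp_start[i]
  val <- numeric(length(u))
  # inspiration: cool from the expiration-end maximum back to ambient
  val[in_insp] <- amp *
    (1 + cos(pi * (u[in_insp] - cy$insp_start[i][in_insp]) / insp_dur[in_insp])) / 2
  # expiration: warm from ambient toward the attenuated expired temperature
  val[!in_insp] <- amp *
    (1 - cos(pi * (u[!in_insp] - cy$exp_start[i][!in_insp]) / exp_dur[!in_insp])) / 2
  x[ok] <- ambient + val
  x
}

#' Render the nasal temperature channel
#'
#' The idealized airflow temperature at the probe (ambient during
#' inspiration, ramping toward the attenuated expired-air temperature during
#' expiration, with its maximum exactly at each expiration end) is shifted by
#' the transport delay `intercept + per_kg * body_weight`, filtered by the
#' exact discrete first-order lag with the sensor's time constant, and
#' corrupted with Gaussian noise. Output maxima therefore lag the true
#' expiration-end times by an amount that grows with the time constant and
#' with body weight.
#'
#' @param truth A `ground_truth` from [generate_cycle_train()].
#' @param sensor A [sensor_model()].
#' @param profile The [breathing_profile()] (supplies `body_weight`).
#' @param fs Sampling rate in Hz (>= 20).
#' @param seed Integer seed for the measurement noise.
#' @return A [sampled_trace()] in degrees C, label `"temperature"`.
#' @export
render_nasal_temperature <- function(truth, sensor, profile, fs = 100, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(sensor, "sensor_model"),
            inherits(profile, "breathing_profile"))
  if (fs < 20) stop("`fs` must be at least 20 Hz", call. = FALSE)
  gain <- sensor$attenuation_by_position[[as.character(sensor$probe_position)]]
  amp <- gain * (sensor$expired_temp - sensor$ambient_temp)
  delay <- transport_delay(sensor, profile$body_weight)
  n <- floor(truth$duration * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  x <- airflow_temperature_at(truth, tt - delay, sensor$ambient_temp, amp)
  y <- first_order_lag(x, fs, sensor$time_constant)
  y <- with_seed(seed, y + stats::rnorm(n, sd = sensor$noise_sd))
  sampled_trace(y, fs, units = "degC", label = "temperature")
}

#' Render the lick vibration channel
#'
#' Each reward spawns a burst of licks (default 8 at about 4 Hz with jitter),
#' rendered as damped high-frequency transients on a Gaussian noise floor --
#' the signature of a vibration sensor attached to the reward spout. Only the
#' onset times matter downstream; the burst microstructure is plumbing.
#'
#' @param schedule A [session_schedule()] supplying reward times.
#' @param licks_per_reward Licks per burst (default 8; 0 gives pure noise).
#' @param fs Sampling rate in Hz (>= 100); vibration sensors are sampled
#'   faster than the slow channels.
#' @param seed Integer seed.
#' @param duration Channel duration in seconds (default: schedule end + 2).
#' @param noise_sd Noise floor SD (arbitrary units).
#' @param lick_rate Within-burst lick rate in Hz.
#' @return List with `vibration` (a [sampled_trace()]) and `truth_onsets`
#'   (exact lick onset times in seconds).
#' @export
render_lick_channel <- function(schedule, licks_per_reward = 8, fs = 1000,
                                seed = 1, duration = NULL, noise_sd = 0.02,
                                lick_rate = 4) {
  stopifnot(inherits(schedule, "session_schedule"))
  if (fs < 100) stop("`fs` must be at least 100 Hz for the vibration channel",
                     call. = FALSE)
  duration <- duration %||% (schedule_end(schedule) + 2)
  n <- floor(duration * fs) + 1L
  with_seed(seed, {
    v <- stats::rnorm(n, sd = noise_sd)
    onsets <- numeric(0)
    if (licks_per_reward > 0) {
      for (r in schedule$reward_times) {
        t <- r + 0.15 + abs(stats::rnorm(1, sd = 0.03))
        for (k in seq_len(licks_per_reward)) {
          onsets <- c(onsets, t)
          t <- t + max(0.15, 1 / lick_rate + stats::rnorm(1, sd = 0.02))
        }
      }
      onsets <- onsets[onsets < duration - 0.1]
      f_tr <- min(150, 0.25 * fs)    # transient frequency, below Nyquist
      seg <- seq(0, 0.06, by = 1 / fs)
      shape <- exp(-seg / 0.02) * sin(2 * pi * f_tr * seg)
      for (on in onsets) {
        i0 <- floor(on * fs) + 1L
        ii <- i0:min(n, i0 + length(seg) - 1L)
        v[ii] <- v[ii] + shape[seq_along(ii)]
      }
    }
    list(vibration = sampled_trace(v, fs, units = "au", label = "lick"),
         truth_onsets = sort(onsets))
  })
}

#' Simulate a complete session bundle
#'
#' Runs the full generator: cycle train, nasal temperature, chest channels
#' and lick channel, tied together by one master seed (sub-seeds are derived
#' deterministically). The returned bundle is the in-memory analogue of the
#' on-disk layout written by [write_session_bundle()].
#'
#' @param profile A [breathing_profile()].
#' @param sensor A [sensor_model()].
#' @param schedule A [session_schedule()], or `NULL` (then `duration` is
#'   required and no lick channel is rendered).
#' @param fs Sampling rate for the slow channels (temperature, chest), Hz.
#' @param lick_fs Sampling rate for the lick vibration channel, Hz.
#' @param seed Master integer seed.
#' @param duration Session duration in seconds (default: schedule end + 2).
#' @param licks_per_reward Licks per reward burst; 0 disables licking.
#' @param with_chest,with_lick Logical; render the optional channels.
#' @return A `session_bundle` list with elements `temperature`,
#'   `chest_movement`, `chest_diameter`, `lick`, `schedule`, `truth`,
#'   `profile`, `sensor`, `fs`, `seed`.
#' @export
simulate_session <- function(profile = breathing_profile(),
                             sensor = sensor_model(),
                             schedule = build_default_schedule(seed),
                             fs = 100, lick_fs = 1000, seed = 1,
                             duration = NULL, licks_per_reward = 8,
                             with_chest = TRUE, with_lick = !is.null(schedule)) {
  if (is.null(schedule) && is.null(duration)) {
    stop("`duration` is required when no schedule is given", call. = FALSE)
  }
  duration <- duration %||% (schedule_end(schedule) + 2)
  truth <- generate_cycle_train(profile, schedule, duration, seed = seed)
  temp <- render_nasal_temperature(truth, sensor, profile, fs = fs,
                                   seed = seed + 1L)
  bundle <- list(temperature = temp, schedule = schedule, truth = truth,
                 profile = profile, sensor = sensor, fs = fs, seed = seed)
  if (with_chest) {
    ch <- render_chest_channels(truth, amplitude = profile$amplitude_chest,
                                fs = fs, seed = seed + 2L)
    bundle$chest_movement <- ch$movement
    bundle$chest_diameter <- ch$diameter
  }
  if (with_lick && !is.null(schedule) && licks_per_reward > 0) {
    lk <- render_lick_channel(schedule, licks_per_reward, fs = lick_fs,
                              seed = seed + 3L, duration = duration)
    bundle$lick <- lk$vibration
    bundle$truth$lick_onsets <- lk$truth_onsets
  }
  structure(bundle, class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  chans <- intersect(c("temperature", "chest_movement", "chest_diameter", "lick"),
                     names(x))
  cat(sprintf("<session_bundle> seed %s, %.0f s, channels: %s\n",
              format(x$seed), x$truth$duration, paste(chans, collapse = ", ")))
  invisible(x)
}

#' Write / read a session bundle directory
#'
#' On disk a bundle is one CSV per channel (see [write_channel_csv()] for the
#' dialect), `schedule.json` (blocks and rewards), `truth.json` (cycle
#' boundaries and lick onsets, when ground truth exists) and `config.yaml`
#' echoing the generator parameters and seed.
#'
#' @param bundle A `session_bundle` from [simulate_session()].
#' @param dir Directory to create/fill.
#' @return `write_session_bundle` returns `dir` invisibly;
#'   `read_session_bundle` returns a `session_bundle` (with `truth`/`profile`
#'   components only if present on disk).
#' @export
write_session_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("temperature", "chest_movement", "lick")) {
    if (!is.null(bundle[[ch]])) {
      write_channel_csv(bundle[[ch]], file.path(dir, paste0(ch, ".csv")))
    }
  }
  if (!is.null(bundle$schedule)) {
    jsonlite::write_json(schedule_to_list(bundle$schedule),
                         file.path(dir, "schedule.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(
      list(cycles = bundle$truth$cycles, duration = bundle$truth$duration,
           lick_onsets = bundle$truth$lick_onsets),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  cfg <- list(seed = bundle$seed, fs = bundle$fs,
              profile = unclass(bundle$profile),
              sensor = lapply(unclass(bundle$sensor), function(v) {
                if (!is.null(names(v))) as.list(v) else v
              }))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

schedule_to_list <- function(schedule) {
  list(blocks = lapply(schedule$blocks, unclass),
       reward_times = schedule$reward_times,
       reward_volume = schedule$reward_volume)
}

schedule_from_list <- function(x) {
  bl <- x$blocks
  if (is.data.frame(bl)) bl <- lapply(seq_len(nrow(bl)), function(i) as.list(bl[i, ]))
  blocks <- lapply(bl, function(b) {
    stimulus_block(b$kind, b$tempo_bpm, b$level_db_spl, b$start, b$duration)
  })
  session_schedule(blocks, as.numeric(unlist(x$reward_times)),
                   x$reward_volume %||% 0.2)
}

#' @rdname write_session_bundle
#' @export
read_session_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("no such bundle directory: ", dir, call. = FALSE)
  bundle <- list()
  for (ch in c("temperature", "chest_movement", "lick")) {
    p <- file.path(dir, paste0(ch, ".csv"))
    if (file.exists(p)) bundle[[ch]] <- read_channel_csv(p, label = ch)
  }
  sp <- file.path(dir, "schedule.json")
  if (file.exists(sp)) {
    bundle$schedule <- schedule_from_list(jsonlite::read_json(sp, simplifyVector = TRUE))
  }
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tj <- jsonlite::read_json(tp, simplifyVector = TRUE)
    bundle$truth <- structure(list(cycles = as.data.frame(tj$cycles),
                                   duration = tj$duration,
                                   lick_onsets = as.numeric(unlist(tj$lick_onsets))),
                              class = "ground_truth")
  }
  cp <- file.path(dir, "config.yaml")
  if (file.exists(cp)) {
    cfg <- yaml::read_yaml(cp)
    bundle$seed <- cfg$seed
    bundle$fs <- cfg$fs
  }
  structure(bundle, class = "session_bundle")
}
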