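# End-to-end analysis of one session: load channels, extract cycles, split
# IPIs by stimulus block, run the music-vs-noise and among-music contrasts,
# and assemble a structured report.

#' Default analysis configuration
#'
#' Every tunable default of the pipeline in one place, overridable per call.
#'
#' @param smooth_window,min_prominence_frac,refractory See [detect_extrema()].
#' @param ipi_anchor See [summarize_cycles()].
#' @param k_mad,lick_refractory,lick_window See [detect_lick_onsets()] and
#'   [triggered_average()].
#' @param variant t-test variant, see [ttest_unpaired()].
#' @param delay_mode See [session_delay()].
#' @param detrend_window See [integrate_chest_movement()].
#' @param exclude_after_reward Seconds after each reward whose IPIs are
#'   dropped from block contrasts (0 = keep all, the default).
#' @param p_adjust `"none"` (default, raw p-values) or `"holm"` for the
#'   per-contrast table.
#' @return A named list.
#' @export
default_config <- function(smooth_window = 0.15, min_prominence_frac = 0.3,
                           refractory = 0.6, ipi_anchor = "peak",
                           k_mad = 5, lick_refractory = 0.1,
                           lick_window = c(2, 2), variant = "pooled",
                           delay_mode = "physiological", detrend_window = 30,
                           exclude_after_reward = 0, p_adjust = "none") {
  list(smooth_window = smooth_window,
       min_prominence_frac = min_prominence_frac,
       refractory = refractory, ipi_anchor = ipi_anchor, k_mad = k_mad,
       lick_refractory = lick_refractory, lick_window = lick_window,
       variant = variant, delay_mode = delay_mode,
       detrend_window = detrend_window,
       exclude_after_reward = exclude_after_reward, p_adjust = p_adjust)
}

#' Assign inter-peak intervals to stimulus blocks
#'
#' An IPI is assigned to a block if and only if both of its bounding anchor
#' events fall inside that block; IPIs straddling a block boundary or lying
#' in an inter-block gap are counted as discarded, so assigned plus discarded
#' always equals the total.
#'
#' @param anchor_times Sorted anchor event times in seconds (the IPI between
#'   consecutive anchors is the assigned quantity).
#' @param schedule A [session_schedule()].
#' @return A list: `assignments` (data frame `block`, `kind`, `tempo_bpm`,
#'   `ipi`), `n_discarded`, `n_total`.
#' @export
split_by_block <- function(anchor_times, schedule) {
  if (is.null(schedule) || !length(schedule$blocks)) {
    stop("empty schedule: nothing to split by", call. = FALSE)
  }
  stopifnot(!is.unsorted(anchor_times))
  n_ipi <- max(0L, length(anchor_times) - 1L)
  if (n_ipi == 0L) {
    return(list(assignments = data.frame(ipi_index = integer(0),
                                         block = integer(0), kind = character(0),
                                         tempo_bpm = numeric(0), ipi = numeric(0)),
                n_discarded = 0L, n_total = 0L))
  }
  a0 <- anchor_times[-length(anchor_times)]
  a1 <- anchor_times[-1]
  starts <- vapply(schedule$blocks, `[[`, 0, "start")
  ends <- starts + vapply(schedule$blocks, `[[`, 0, "duration")
  block <- rep(NA_integer_, n_ipi)
  for (i in seq_along(schedule$blocks)) {
    inside <- a0 >= starts[i] & a1 <= ends[i]
    block[inside] <- i
  }
  keep <- !is.na(block)
  kinds <- vapply(schedule$blocks, `[[`, "", "kind")
  tempos <- vapply(schedule$blocks, `[[`, 0, "tempo_bpm")
  list(assignments = data.frame(ipi_index = which(keep), block = block[keep],
                                kind = kinds[block[keep]],
                                tempo_bpm = tempos[block[keep]],
                                ipi = (a1 - a0)[keep]),
       n_discarded = sum(!keep), n_total = n_ipi)
}

#' Analyze a session end-to-end
#'
#' Runs the full pipeline on a session bundle (a directory on disk or an
#' in-memory bundle from [simulate_session()]): respiratory cycle extraction
#' from the temperature channel, block-wise IPI splitting, the music-vs-noise
#' unpaired t contrast (pooling the three music blocks) and the among-music
#' one-way ANOVA; when a chest channel is present, the thermosensor-vs-chest
#' delay; when a lick channel is present, lick detection and the
#' lick-triggered temperature average. The analysis is deterministic given
#' its inputs.
#'
#' @param bundle Directory path or `session_bundle`.
#' @param config A [default_config()] list (partial lists are merged over
#'   the defaults).
#' @return A `session_report` list; see Details for fields.
#' @details Report fields: `per_block_summaries` (one entry per block:
#'   `kind`, `tempo_bpm`, `n_ipi`, `mean_ipi`, `sd_ipi`), `ie_ratio`,
#'   `n_cycles`, `n_discarded_ipi`, `music_vs_noise` (`ttest_result`),
#'   `among_music` (`anova_result`), `contrast_table` (tidy data frame of the
#'   contrasts), optional `delay_report` and `lick_report`, and `provenance`
#'   (`config_hash`, `seed`, `version`).
#' @export
analyze_session <- function(bundle, config = list()) {
  config <- utils::modifyList(default_config(), config)
  if (is.character(bundle)) bundle <- read_session_bundle(bundle)
  if (is.null(bundle$temperature)) {
    stop("bundle is missing the mandatory 'temperature' channel", call. = FALSE)
  }
  if (is.null(bundle$schedule)) {
    stop("bundle is missing the mandatory 'schedule'", call. = FALSE)
  }

  ex <- run_stage("respiration_core", detect_extrema(
    bundle$temperature, config$smooth_window, config$min_prominence_frac,
    config$refractory))
  cycles <- run_stage("respiration_core", segment_cycles(ex, "temperature"))
  summ <- run_stage("respiration_core", summarize_cycles(cycles, config$ipi_anchor))

  anchors <- summ$anchor_times
  blocks_split <- run_stage("split_by_block", split_by_block(anchors, bundle$schedule))
  asg <- blocks_split$assignments
  if (config$exclude_after_reward > 0 && length(bundle$schedule$reward_times)) {
    rw <- bundle$schedule$reward_times
    w <- config$exclude_after_reward
    a0 <- anchors[-length(anchors)]
    post_reward <- vapply(a0, function(t0) any(t0 >= rw & t0 < rw + w), TRUE)
    asg <- asg[!post_reward[asg$ipi_index], , drop = FALSE]
  }

  kinds <- vapply(bundle$schedule$blocks, `[[`, "", "kind")
  tempos <- vapply(bundle$schedule$blocks, `[[`, 0, "tempo_bpm")
  per_block <- lapply(seq_along(bundle$schedule$blocks), function(i) {
    ipi <- asg$ipi[asg$block == i]
    list(block = i, kind = kinds[i], tempo_bpm = tempos[i],
         n_ipi = length(ipi),
         mean_ipi = if (length(ipi)) mean(ipi) else NA_real_,
         sd_ipi = if (length(ipi) > 1) stats::sd(ipi) else NA_real_)
  })

  music_ipi <- asg$ipi[asg$kind == "music"]
  noise_ipi <- asg$ipi[asg$kind == "noise"]
  music_vs_noise <- if (length(music_ipi) >= 2 && length(noise_ipi) >= 2) {
    run_stage("condition_stats",
              ttest_unpaired(music_ipi, noise_ipi, config$variant))
  }
  music_groups <- split(asg$ipi[asg$kind == "music"],
                        asg$tempo_bpm[asg$kind == "music"])
  among_music <- if (length(music_groups) >= 2 &&
                     all(vapply(music_groups, length, 0L) >= 2)) {
    run_stage("condition_stats", anova_oneway(music_groups))
  }

  contrasts <- build_contrast_table(music_vs_noise, among_music, config$p_adjust)

  report <- list(
    per_block_summaries = per_block,
    ie_ratio = summ$ie_ratio,
    mean_ipi = summ$mean_ipi,
    n_cycles = summ$n_cycles,
    n_assigned_ipi = nrow(asg),
    n_discarded_ipi = blocks_split$n_discarded,
    music_vs_noise = music_vs_noise,
    among_music = among_music,
    contrast_table = contrasts
  )

  if (!is.null(bundle$chest_movement) || !is.null(bundle$chest_diameter)) {
    chest <- bundle$chest_diameter %||%
      integrate_chest_movement(bundle$chest_movement, config$detrend_window)
    report$delay_report <- run_stage("multimodal_delay", session_delay(
      bundle$temperature, chest, mode = config$delay_mode,
      smooth_window = config$smooth_window,
      min_prominence_frac = config$min_prominence_frac,
      refractory = config$refractory))
  }
  if (!is.null(bundle$lick)) {
    licks <- run_stage("event_analysis", detect_lick_onsets(
      bundle$lick, k_mad = config$k_mad, refractory = config$lick_refractory))
    if (licks$n >= 1) {
      report$lick_report <- run_stage("event_analysis", triggered_average(
        bundle$temperature, licks$onsets, window = config$lick_window))
      report$lick_report$n_detected <- licks$n
    }
  }

  report$provenance <- list(
    config_hash = fnv1a_hex(jsonlite::toJSON(config, auto_unbox = TRUE)),
    config = config,
    seed = bundle$seed %||% NA,
    version = as.character(utils::packageVersion("thermoresp"))
  )
  structure(report, class = "session_report")
}

# Wrap a pipeline stage so failures carry the stage name.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "thermoresp_stage_error")) stop(e)
    stop(structure(class = c("thermoresp_stage_error", "error", "condition"),
                   list(message = paste0("[stage ", stage, "] ",
                                         conditionMessage(e)),
                        call = NULL)))
  })
}

build_contrast_table <- function(music_vs_noise, among_music, p_adjust) {
  rows <- list()
  if (!is.null(music_vs_noise)) {
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = "music_vs_noise", statistic = music_vs_noise$t,
      df = music_vs_noise$df, p = music_vs_noise$p)
  }
  if (!is.null(among_music)) {
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = "among_music", statistic = among_music$F,
      df = among_music$df_between, p = among_music$p)
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  if (identical(p_adjust, "holm")) {
    tab$p_adj <- stats::p.adjust(tab$p, method = "holm")
  }
  tab
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d cycles, mean IPI %.3f s, I/E %.3f\n",
              x$n_cycles, x$mean_ipi, x$ie_ratio))
  for (b in x$per_block_summaries) {
    cat(sprintf("  block %d %-5s %s: %3d IPIs, mean %.3f s\n", b$block,
                b$kind, if (b$kind == "music") sprintf("%3g bpm", b$tempo_bpm) else "       ",
                b$n_ipi, b$mean_ipi))
  }
  if (!is.null(x$music_vs_noise)) {
    cat("  music vs noise: "); print(x$music_vs_noise)
  }
  if (!is.null(x$among_music)) {
    cat("  among music:    "); print(x$among_music)
  }
  if (!is.null(x$delay_report)) {
    cat("  delay:          "); print(x$delay_report)
  }
  if (!is.null(x$lick_report)) {
    cat(sprintf("  licks:          %d detected, modulation index %.3f\n",
                x$lick_report$n_detected, x$lick_report$modulation_index))
  }
  invisible(x)
}

#' Write / read a session report as JSON
#'
#' The on-disk schema is versioned through the report's provenance block;
#' reading restores the same structure (timestamps are never stored, so the
#' round trip is byte-stable).
#'
#' @param report A `session_report`.
#' @param path Output/input file.
#' @export
write_session_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

report_to_list <- function(report) {
  x <- unclass(report)
  for (nm in c("music_vs_noise", "among_music")) {
    if (!is.null(x[[nm]])) x[[nm]] <- unclass(x[[nm]])
  }
  if (!is.null(x$delay_report)) x$delay_report <- unclass(x$delay_report)
  if (!is.null(x$lick_report)) x$lick_report <- unclass(x$lick_report)
  x
}

#' @rdname write_session_report
#' @export
read_session_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("music_vs_noise", "among_music")) {
    if (!is.null(x[[nm]])) {
      cls <- if (nm == "among_music") "anova_result" else "ttest_result"
      x[[nm]] <- structure(as.list(x[[nm]]), class = cls)
    }
  }
  if (!is.null(x$per_block_summaries) && is.data.frame(x$per_block_summaries)) {
    x$per_block_summaries <- lapply(seq_len(nrow(x$per_block_summaries)),
                                    function(i) as.list(x$per_block_summaries[i, ]))
  }
  structure(x, class = "session_report")
}
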