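# Discrete-event task engine: trial scheduling, stimulus selection, online
# outcome adjudication, reward and punishment, driven by a pluggable lick
# source.

#' Quantize lick times to the sensor grid
#'
#' Capacitive lickometers report contact at a fixed resolution (30 ms by
#' default); events collapsing onto the same grid point are merged because the
#' sensor cannot distinguish them.
#'
#' @param t_s Numeric lick times (seconds).
#' @param quantum_s Grid spacing in seconds.
#' @return Sorted, de-duplicated lick times on the grid.
#' @export
quantize_licks <- function(t_s, quantum_s = 0.03) {
  if (!length(t_s)) return(numeric(0))
  g <- sort(unique(round(t_s / quantum_s)))
  g * quantum_s
}

#' Draw an intertrial interval
#'
#' @param config A [task_config()].
#' @param stream An [new_rng_stream()] RNG substream.
#' @return Seconds, uniform on the configured ITI interval (5--9 s default).
#' @export
draw_iti <- function(config, stream) {
  r <- config$iti_range_s
  stream_eval(stream, function() stats::runif(1, r[1], r[2]))
}

#' Draw a lick-refrain requirement
#'
#' @inheritParams draw_iti
#' @return Seconds, uniform on the configured refrain interval
#'   (5--25 s for detection/discrimination, exactly 5 s for shaping).
#' @export
draw_refrain <- function(config, stream) {
  r <- config$refrain_range_s
  if (r[1] == r[2]) return(r[1])
  stream_eval(stream, function() stats::runif(1, r[1], r[2]))
}

#' Draw the stimulus category (and roving frequency/level) for a trial
#'
#' Detection presents the target tone on every non-probe trial; discrimination
#' presents target and nontarget with the configured mixture (50/50 default).
#' When `freq_list_khz` is set (audiogram mode) the tone frequency and level
#' are additionally drawn uniformly from their lists.
#'
#' @inheritParams draw_iti
#' @return A list with `category`, `freq_khz` (NA for silent probes) and
#'   `level_db`.
#' @export
draw_trial_category <- function(config, stream) {
  p_nt <- if (config$phase == "discrimination") config$nontarget_frac else 0
  p_pr <- config$probe_frac
  if (p_nt + p_pr > 1) {
    stop(errorCondition("nontarget_frac + probe_frac exceed 1",
                        class = c("homecage_config_error", "error",
                                  "condition")))
  }
  roving <- !is.null(config$freq_list_khz)
  draw <- stream_eval(stream, function() {
    u <- stats::runif(1)
    f <- if (roving) {
      config$freq_list_khz[sample.int(length(config$freq_list_khz), 1)]
    } else NA_real_
    l <- if (length(config$level_db) > 1) {
      config$level_db[sample.int(length(config$level_db), 1)]
    } else config$level_db
    list(u = u, f = f, l = l)
  })
  category <- if (draw$u < p_pr) {
    "silent_probe"
  } else if (draw$u < p_pr + p_nt) {
    "nontarget"
  } else {
    "target"
  }
  freq <- if (category == "silent_probe") {
    NA_real_
  } else if (roving) {
    draw$f
  } else if (category == "target") {
    config$target_freq_khz
  } else {
    config$nontarget_freq_khz
  }
  list(category = category, freq_khz = freq, level_db = draw$l)
}

#' Adjudicate one trial from its lick latencies
#'
#' The first lick of the trial decides the outcome: a first lick during the
#' prestimulus silence is an early response (punished in detection and
#' discrimination); a first lick inside the response window is a hit on target
#' trials (rewarded) and a false alarm on nontarget trials (punished); trials
#' without a qualifying first lick are misses (target) or correct rejections
#' (nontarget). Silent probes are adjudicated against the target rule but are
#' never rewarded and never punished.
#'
#' @param trial_licks Lick times relative to trial start, sorted ascending,
#'   within `[0, trial_duration]`.
#' @param category `"target"`, `"nontarget"` or `"silent_probe"`.
#' @param config A [task_config()].
#' @return A list with `outcome`, `rewarded`, `timeout_applied` and
#'   `first_lick_latency_s` (NA when the trial has no licks).
#' @export
adjudicate_trial <- function(trial_licks, category, config) {
  stopifnot(category %in% category_levels)
  if (length(trial_licks) && is.unsorted(trial_licks, strictly = FALSE)) {
    stop(errorCondition("trial_licks must be sorted ascending",
                        class = c("homecage_format_error", "error",
                                  "condition")))
  }
  go_like <- category %in% c("target", "silent_probe")
  first <- if (length(trial_licks)) trial_licks[1] else NA_real_
  win_lo <- config$pre_stim_s
  win_hi <- config$pre_stim_s + config$response_window_s
  if (is.na(first) || first > win_hi) {
    outcome <- if (go_like) "miss" else "correct_rejection"
  } else if (first < win_lo) {
    outcome <- "early"
  } else {
    outcome <- if (go_like) "hit" else "false_alarm"
  }
  rewarded <- outcome == "hit" && category == "target"
  timeout <- (outcome == "early" && config$punish_early ||
                outcome == "false_alarm" && config$punish_fa) &&
    category != "silent_probe"
  list(outcome = outcome, rewarded = rewarded, timeout_applied = timeout,
       first_lick_latency_s = first)
}

#' Schedule the start of the next trial
#'
#' The next trial starts at the earliest time `t` such that (i) `t` is at
#' least the previous trial end plus a freshly drawn ITI plus any accrued
#' timeout, and (ii) the cage has not licked for at least a freshly drawn
#' refrain duration before `t`. Licking during the ITI per se does not delay
#' the trial; only licks inside the trailing refrain window do. Both draws are
#' made once per trial.
#'
#' @param prev_trial_end_s End time of the previous trial (seconds).
#' @param timeout_s_accrued Timeout carried from the previous trial (0 or
#'   `config$timeout_s`).
#' @param lick_source Either a sorted numeric vector of lick times, or a
#'   function `f(t0, t1)` returning the lick times in `(t0, t1)`.
#' @param config A [task_config()].
#' @param streams Named list with `iti` and `refrain` RNG substreams
#'   (see [rng_streams()]).
#' @param cap_s Give-up horizon: if no refrain-satisfying start is found
#'   within `cap_s` seconds past the earliest admissible start, an error of
#'   class `homecage_schedule_error` is raised (a lick source that never stops
#'   licking would otherwise stall the session forever).
#' @return A list with `start_s`, `iti_s`, `refrain_s`.
#' @export
schedule_next_trial <- function(prev_trial_end_s, timeout_s_accrued,
                                lick_source, config, streams,
                                cap_s = config$schedule_cap_s) {
  iti <- draw_iti(config, streams$iti)
  refrain <- draw_refrain(config, streams$refrain)
  licks_in <- if (is.function(lick_source)) {
    lick_source
  } else {
    function(t0, t1) lick_source[lick_source > t0 & lick_source < t1]
  }
  earliest <- prev_trial_end_s + iti + timeout_s_accrued
  cand <- earliest
  repeat {
    # A lick exactly `refrain` seconds before the candidate satisfies the
    # constraint (t - lick >= refrain); the small tolerance keeps the open
    # window robust to floating-point round-off of cand - refrain.
    w <- licks_in(cand - refrain + 1e-6, cand)
    if (!length(w)) {
      return(list(start_s = cand, iti_s = iti, refrain_s = refrain))
    }
    cand <- max(w) + refrain
    if (cand - earliest > cap_s) {
      stop(errorCondition(
        sprintf("no lick-free refrain window found within %.0f s", cap_s),
        class = c("homecage_schedule_error", "error", "condition")))
    }
  }
}

# Count of elements of sorted vector v that are <= x. A bare bisection:
# findInterval() re-validates the whole vector on every call, which is
# quadratic over a session's growing lick stream.
count_le <- function(v, x) {
  lo <- 0L
  hi <- length(v)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (v[mid] <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Consumption burst emitted while the reward valve is open: n licks at a fixed
# inter-lick gap, starting one gap after the rewarded first lick.
consumption_licks <- function(at_s, params) {
  at_s + params$consumption_burst_gap_s * seq_len(params$consumption_burst_n)
}

#' Run one continuous training session
#'
#' Simulates a cage running a training phase for `duration_s` seconds of
#' continuous (24 h/day) operation: trials are scheduled under the ITI,
#' refrain and timeout rules, stimuli drawn, the virtual mouse's licks
#' generated, outcomes adjudicated online, and water accounted. The run is
#' fully deterministic given `(config, mouse, schedule, seed)`.
#'
#' Habituation ignores adjudication: trials occur at random 30--300 s
#' intervals and the valve opens for 5 s each time. Shaping adds automatic
#' rewards on 20% of trials, released 0.5 s after tone onset whether or not
#' the cage licked.
#'
#' @param config A [task_config()].
#' @param mouse A [mouse_params()] virtual-mouse parameter set.
#' @param duration_s Session length in seconds (e.g. `7 * 86400`).
#' @param schedule A [light_schedule()].
#' @param seed Integer root seed; independent named substreams are derived
#'   for ITI, refrain, category, auto-reward and mouse behaviour.
#' @param cage_id Cage label stored in the log.
#' @return A `session_log`: list with `cage_id`, `config`, `schedule`,
#'   `licks` (quantized, strictly increasing), `stimuli` and `trials` data
#'   frames, `total_water_ml`, `seed`, `duration_s`.
#' @export
run_session <- function(config, mouse = default_calibration(config$phase),
                        duration_s, schedule = light_schedule(), seed = 1,
                        cage_id = "cage01") {
  validate_task_config(config)
  validate_mouse_params(mouse)
  stopifnot(duration_s > 0)
  streams <- rng_streams(seed)
  q <- config$lick_quantum_s
  dur <- trial_duration(config)

  if (config$phase == "discrimination" &&
      (!is.finite(config$nontarget_freq_khz))) {
    stop(errorCondition("discrimination requires a nontarget frequency",
                        class = c("homecage_config_error", "error",
                                  "condition")))
  }

  eng_phase <- engagement_phase(mouse, streams$engagement)
  background <- background_licks(0, duration_s + 60, mouse, schedule,
                                 streams$background, quantum_s = q,
                                 engagement_phase_h = eng_phase)

  if (config$phase == "habituation") {
    return(run_habituation(config, mouse, duration_s, schedule, seed,
                           cage_id, streams, background))
  }

  n_guess <- ceiling(duration_s / (dur + config$iti_range_s[1])) + 1
  tr_iti <- numeric(n_guess); tr_ref <- numeric(n_guess)
  tr_start <- numeric(n_guess); tr_cat <- character(n_guess)
  tr_freq <- numeric(n_guess); tr_lev <- numeric(n_guess)
  tr_first <- numeric(n_guess); tr_out <- character(n_guess)
  tr_rew <- logical(n_guess); tr_auto <- logical(n_guess)
  tr_to <- logical(n_guess)
  lick_chunks <- vector("list", n_guess)

  # Only licks from the trailing minute can fall inside a refrain window
  # (refrain <= 25 s, ITI >= 5 s), so scheduling consults the full background
  # stream plus a rolling buffer of recently emitted trial licks.
  recent <- numeric(0)
  lick_src <- function(t0, t1) {
    i0 <- count_le(background, t0)
    i1 <- count_le(background, t1)
    if (i1 > i0 && background[i1] == t1) i1 <- i1 - 1L
    bg <- if (i1 > i0) background[(i0 + 1L):i1] else numeric(0)
    c(bg, recent[recent > t0 & recent < t1])
  }

  n <- 0L
  prev_end <- 0
  timeout_acc <- 0
  water <- 0
  repeat {
    # Inside a session the only consequence of an unbroken stretch of licking
    # is that the next trial starts later, so the scheduling horizon is the
    # remaining session, not the 30 min diagnostic default.
    sched <- tryCatch(
      schedule_next_trial(prev_end, timeout_acc, lick_src, config, streams,
                          cap_s = duration_s - prev_end + 60),
      homecage_schedule_error = function(e) NULL)
    if (is.null(sched)) break
    start <- sched$start_s
    if (start + dur > duration_s) break
    stim <- draw_trial_category(config, streams$category)
    auto <- config$auto_reward_frac > 0 &&
      stream_eval(streams$auto,
                  function() stats::runif(1)) < config$auto_reward_frac

    i0 <- count_le(background, start - 1e-9)
    i1 <- count_le(background, start + dur)
    bg_in <- if (i1 > i0) background[(i0 + 1L):i1] else numeric(0)
    evoked <- trial_response_licks(stim$category, start, mouse, schedule,
                                   eng_phase, streams$mouse, config)
    beh <- quantize_licks(c(bg_in, evoked), q)
    beh <- beh[beh >= start - 1e-9 & beh <= start + dur + 1e-9]
    adj <- adjudicate_trial(beh - start, stim$category, config)

    rewarded <- adj$rewarded || auto
    all_licks <- beh
    if (adj$rewarded) {
      burst <- consumption_licks(start + adj$first_lick_latency_s, mouse)
      all_licks <- quantize_licks(c(beh, burst), q)
    }
    if (rewarded) water <- water + config$reward_ml

    n <- n + 1L
    tr_iti[n] <- sched$iti_s
    tr_ref[n] <- sched$refrain_s
    tr_start[n] <- start
    tr_cat[n] <- stim$category
    tr_freq[n] <- stim$freq_khz
    tr_lev[n] <- stim$level_db
    first_all <- if (length(all_licks)) all_licks[1] - start else NA_real_
    tr_first[n] <- first_all
    tr_out[n] <- adj$outcome
    tr_rew[n] <- rewarded
    tr_auto[n] <- auto
    tr_to[n] <- adj$timeout_applied
    lick_chunks[[n]] <- all_licks

    recent <- c(recent[recent > start - 60], all_licks)
    prev_end <- start + dur
    timeout_acc <- if (adj$timeout_applied) config$timeout_s else 0
  }

  idx <- seq_len(n)
  trials <- data.frame(
    index = idx,
    start_s = tr_start[idx],
    tone_onset_s = tr_start[idx] + config$pre_stim_s,
    category = tr_cat[idx],
    freq_khz = tr_freq[idx],
    level_db = tr_lev[idx],
    first_lick_latency_s = tr_first[idx],
    outcome = tr_out[idx],
    rewarded = tr_rew[idx],
    auto_rewarded = tr_auto[idx],
    timeout_applied = tr_to[idx],
    iti_s = tr_iti[idx],
    refrain_s = tr_ref[idx],
    stringsAsFactors = FALSE
  )
  non_probe <- trials$category != "silent_probe"
  stimuli <- data.frame(
    onset_s = trials$tone_onset_s,
    duration_s = ifelse(non_probe, config$tone_s, config$tone_s),
    freq_khz = trials$freq_khz,
    level_db = trials$level_db,
    category = trials$category,
    stringsAsFactors = FALSE
  )
  licks <- quantize_licks(c(background, unlist(lick_chunks[idx])), q)
  licks <- licks[licks <= duration_s]
  new_session_log(cage_id, config, schedule, licks, stimuli, trials,
                  water, seed, duration_s)
}

run_habituation <- function(config, mouse, duration_s, schedule, seed,
                            cage_id, streams, background) {
  q <- config$lick_quantum_s
  dur <- config$habituation_water_s
  starts <- numeric(0)
  t <- stream_eval(streams$iti, function()
    stats::runif(1, config$habituation_interval_s[1],
                 config$habituation_interval_s[2]))
  while (t + dur <= duration_s) {
    starts <- c(starts, t)
    gap <- stream_eval(streams$iti, function()
      stats::runif(1, config$habituation_interval_s[1],
                   config$habituation_interval_s[2]))
    t <- t + dur + gap
  }
  # The cage drinks from each free-water release.
  bursts <- unlist(lapply(starts, function(s)
    consumption_licks(s + 0.5, mouse)))
  licks <- quantize_licks(c(background, bursts), q)
  licks <- licks[licks <= duration_s]
  first <- vapply(starts, function(s) {
    w <- licks[licks >= s & licks <= s + dur]
    if (length(w)) w[1] - s else NA_real_
  }, numeric(1))
  n <- length(starts)
  trials <- data.frame(
    index = seq_len(n), start_s = starts, tone_onset_s = NA_real_,
    category = rep(NA_character_, n), freq_khz = NA_real_,
    level_db = NA_real_, first_lick_latency_s = first,
    outcome = rep(NA_character_, n), rewarded = rep(TRUE, n),
    auto_rewarded = rep(TRUE, n), timeout_applied = rep(FALSE, n),
    iti_s = NA_real_, refrain_s = NA_real_,
    stringsAsFactors = FALSE
  )
  stimuli <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                        freq_khz = numeric(0), level_db = numeric(0),
                        category = character(0), stringsAsFactors = FALSE)
  water <- n * config$reward_ml *
    (config$habituation_water_s / config$reward_open_s)
  new_session_log(cage_id, config, schedule, licks, stimuli, trials,
                  water, seed, duration_s)
}

new_session_log <- function(cage_id, config, schedule, licks, stimuli,
                            trials, total_water_ml, seed, duration_s) {
  structure(list(cage_id = cage_id, config = config, schedule = schedule,
                 licks = licks, stimuli = stimuli, trials = trials,
                 total_water_ml = total_water_ml, seed = seed,
                 duration_s = duration_s),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("<session_log> %s: %s phase, %.1f d, %d trials, %d licks, %.2f ml water\n",
              x$cage_id, x$config$phase, x$duration_s / 86400, n,
              length(x$licks), x$total_water_ml))
  if (n && !all(is.na(x$trials$outcome))) {
    print(table(outcome = x$trials$outcome))
  }
  invisible(x)
}
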