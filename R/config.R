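# Task configuration and wall-clock light schedule.

phase_levels <- c("habituation", "shaping", "detection", "discrimination")
category_levels <- c("target", "nontarget", "silent_probe")
outcome_levels <- c("hit", "miss", "early", "false_alarm", "correct_rejection")

#' Task configuration for one training phase
#'
#' Bundles every timing and contingency parameter of a training phase. Shipped
#' defaults follow the standard home-cage protocol: 4 s trials (1 s silence,
#' 1 s tone, 2 s silence), a 3 s response window from tone onset, intertrial
#' intervals randomised on 5--9 s, a lick-refrain requirement of 5--25 s
#' (fixed at 5 s during shaping), 20 s timeouts for punished responses,
#' 0.075 ml of water per hit delivered over a 2 s valve opening, and 20%
#' automatic rewards (0.5 s after tone onset) during shaping only.
#'
#' @param phase Training phase, one of `"habituation"`, `"shaping"`,
#'   `"detection"`, `"discrimination"`.
#' @param ... Named overrides of any configuration field (see Details).
#'
#' @details Fields: `pre_stim_s`, `tone_s`, `post_stim_s`, `response_window_s`,
#' `iti_range_s`, `refrain_range_s`, `timeout_s`, `habituation_interval_s`,
#' `habituation_water_s`, `reward_open_s`, `reward_ml`, `auto_reward_frac`,
#' `auto_reward_delay_s`, `target_freq_khz`, `nontarget_freq_khz`,
#' `nontarget_frac`, `probe_frac`, `level_db` (scalar, or vector for roving
#' levels), `freq_list_khz` (vector enabling roving-frequency audiogram mode),
#' `lick_quantum_s` (sensor resolution, 0.03 s), `punish_early`, `punish_fa`,
#' `schedule_cap_s` (give-up horizon when a lick source never stops licking).
#'
#' @return An object of class `task_config` (a validated named list).
#' @examples
#' cfg <- task_config("detection")
#' cfg$iti_range_s
#' @export
task_config <- function(phase = c("detection", "discrimination",
                                  "shaping", "habituation"), ...) {
  phase <- match.arg(phase)
  cfg <- list(
    phase = phase,
    pre_stim_s = 1.0,
    tone_s = 1.0,
    post_stim_s = 2.0,
    response_window_s = 3.0,
    iti_range_s = c(5, 9),
    refrain_range_s = if (phase == "shaping") c(5, 5) else c(5, 25),
    timeout_s = 20,
    habituation_interval_s = c(30, 300),
    habituation_water_s = 5,
    reward_open_s = 2,
    reward_ml = 0.075,
    auto_reward_frac = if (phase == "shaping") 0.2 else 0,
    auto_reward_delay_s = 0.5,
    target_freq_khz = if (phase == "discrimination") 5 else 11.3,
    nontarget_freq_khz = if (phase == "discrimination") 2 else NA_real_,
    nontarget_frac = if (phase == "discrimination") 0.5 else 0,
    probe_frac = 0,
    level_db = 60,
    freq_list_khz = NULL,
    lick_quantum_s = 0.03,
    punish_early = phase %in% c("detection", "discrimination"),
    punish_fa = phase == "discrimination",
    schedule_cap_s = 1800
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("unknown task_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  err <- function(...) stop(errorCondition(paste0(...),
                                           class = c("homecage_config_error",
                                                     "error", "condition")))
  pos <- c("pre_stim_s", "tone_s", "post_stim_s", "response_window_s",
           "habituation_water_s", "reward_open_s", "lick_quantum_s")
  for (f in pos) if (!isTRUE(cfg[[f]] > 0)) err(f, " must be > 0")
  nonneg <- c("timeout_s", "reward_ml", "schedule_cap_s")
  for (f in nonneg) if (!isTRUE(cfg[[f]] >= 0)) err(f, " must be >= 0")
  for (f in c("iti_range_s", "refrain_range_s", "habituation_interval_s")) {
    r <- cfg[[f]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0)
      err(f, " must be an ordered non-negative interval")
  }
  for (f in c("auto_reward_frac", "nontarget_frac", "probe_frac")) {
    if (!isTRUE(cfg[[f]] >= 0 && cfg[[f]] <= 1)) err(f, " must be in [0, 1]")
  }
  if (cfg$nontarget_frac + cfg$probe_frac > 1)
    err("nontarget_frac + probe_frac must not exceed 1")
  if (cfg$response_window_s > cfg$tone_s + cfg$post_stim_s)
    err("response_window_s must not exceed tone_s + post_stim_s")
  if (cfg$phase == "discrimination" &&
      (!is.finite(cfg$nontarget_freq_khz) || cfg$nontarget_frac <= 0))
    err("discrimination requires a nontarget frequency and nontarget_frac > 0")
  if (!is.null(cfg$freq_list_khz) &&
      any(cfg$freq_list_khz < 1 | cfg$freq_list_khz > 45))
    err("freq_list_khz must lie within the calibrated 1-45 kHz band")
  invisible(cfg)
}

#' Total trial duration in seconds
#' @param config A [task_config()].
#' @return Numeric seconds (4.0 for the default phases).
#' @export
trial_duration <- function(config) {
  config$pre_stim_s + config$tone_s + config$post_stim_s
}

#' Light/dark schedule anchoring simulation time to the wall clock
#'
#' The default schedule matches a reversed-light housing room: dark (red
#' light) from 05:00 to 17:00, light from 17:00 to 05:00. Sessions are
#' anchored at a wall-clock time of day, so circadian analyses can convert
#' seconds-since-session-start to time of day.
#'
#' @param dark_start_h,dark_end_h Dark-cycle bounds, hours of day in `[0, 24)`.
#' @param session_start_tod_h Time of day at which the session starts
#'   (default 5, i.e. dark onset, so multi-day runs contain whole cycles).
#' @param anchor_date ISO date string of the first session day (bookkeeping
#'   only; all analysis runs on seconds-since-start plus time of day).
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(dark_start_h = 5, dark_end_h = 17,
                           session_start_tod_h = 5,
                           anchor_date = "2024-03-04") {
  stopifnot(dark_start_h >= 0, dark_start_h < 24,
            dark_end_h >= 0, dark_end_h < 24,
            dark_start_h != dark_end_h,
            session_start_tod_h >= 0, session_start_tod_h < 24)
  structure(list(dark_start_h = dark_start_h, dark_end_h = dark_end_h,
                 session_start_tod_h = session_start_tod_h,
                 anchor_date = anchor_date),
            class = "light_schedule")
}

#' Time of day for session times
#' @param t_s Seconds since session start.
#' @param schedule A [light_schedule()].
#' @return Hours of day in `[0, 24)`.
#' @export
time_of_day <- function(t_s, schedule) {
  (schedule$session_start_tod_h + t_s / 3600) %% 24
}

#' Is a session time inside the dark cycle?
#' @inheritParams time_of_day
#' @return Logical vector.
#' @export
is_dark <- function(t_s, schedule) {
  tod <- time_of_day(t_s, schedule)
  ds <- schedule$dark_start_h
  de <- schedule$dark_end_h
  if (ds < de) tod >= ds & tod < de else tod >= ds | tod < de
}

#' Enumerate light/dark cycles covered by a session
#'
#' @param duration_s Session duration in seconds.
#' @param schedule A [light_schedule()].
#' @return A data frame with columns `start_s`, `end_s`, `cycle`
#'   (`"dark"`/`"light"`) and `complete` (whether the full half-cycle lies
#'   inside the session).
#' @export
cycle_table <- function(duration_s, schedule) {
  ds <- schedule$dark_start_h
  de <- schedule$dark_end_h
  first_at <- function(h) ((h - schedule$session_start_tod_h) %% 24) * 3600
  day_seq <- function(from) {
    if (from > duration_s) numeric(0) else seq(from, duration_s, by = 86400)
  }
  b <- sort(unique(c(day_seq(first_at(ds)), day_seq(first_at(de)))))
  b <- b[b > 1e-9 & b < duration_s - 1e-9]
  edges <- c(0, b, duration_s)
  span_h <- ((de - ds) %% 24)
  out <- data.frame(start_s = edges[-length(edges)], end_s = edges[-1])
  out$cycle <- ifelse(is_dark((out$start_s + out$end_s) / 2, schedule),
                      "dark", "light")
  full_len <- ifelse(out$cycle == "dark", span_h, 24 - span_h) * 3600
  out$complete <- abs((out$end_s - out$start_s) - full_len) < 1e-6
  out
}

#' Calendar-day index of session times
#'
#' Days are calendar days from the schedule anchor (boundaries at midnight
#' wall clock), so "per day" statistics match daily housekeeping records.
#'
#' @inheritParams time_of_day
#' @return Integer day index (0-based; day 0 contains the session start).
#' @export
day_index <- function(t_s, schedule) {
  floor((schedule$session_start_tod_h * 3600 + t_s) / 86400)
}

# Complete calendar days (0-based indices) fully inside [0, duration_s].
complete_days <- function(duration_s, schedule) {
  off <- schedule$session_start_tod_h * 3600
  d <- unique(day_index(seq(0, duration_s, by = 3600), schedule))
  d[(d * 86400 - off) >= -1e-9 & ((d + 1) * 86400 - off) <= duration_s + 1e-9]
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> phase:", x$phase, "\n")
  cat("  trial:", x$pre_stim_s, "s silence +", x$tone_s, "s tone +",
      x$post_stim_s, "s silence; response window", x$response_window_s,
      "s from tone onset\n")
  cat("  ITI", paste(x$iti_range_s, collapse = "-"), "s; refrain",
      paste(x$refrain_range_s, collapse = "-"), "s; timeout", x$timeout_s,
      "s; reward", x$reward_ml, "ml/hit\n")
  invisible(x)
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> dark %02d:00-%02d:00, session starts %05.2f h\n",
              x$dark_start_h, x$dark_end_h, x$session_start_tod_h))
  invisible(x)
}
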