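# Multi-cage experiments and the summary statistics reported for them.

#' Run a multi-cage experiment
#'
#' Simulates `n_cages` independent cages on the same phase and schedule, each
#' with its own seed.
#'
#' @param n_cages Number of cages.
#' @param days Days of continuous training per cage.
#' @param phase Training phase.
#' @param params A [mouse_params()] set (shared across cages).
#' @param config A [task_config()].
#' @param schedule A [light_schedule()].
#' @param seeds Integer vector of per-cage seeds (length `n_cages`).
#' @return A list of `session_log`s, class `experiment`.
#' @export
run_experiment <- function(n_cages = 12, days = 7, phase = "detection",
                           params = default_calibration(phase),
                           config = task_config(phase),
                           schedule = light_schedule(),
                           seeds = seq_len(n_cages)) {
  stopifnot(length(seeds) == n_cages)
  logs <- lapply(seq_len(n_cages), function(i) {
    run_session(config, params, duration_s = days * 86400,
                schedule = schedule, seed = seeds[i],
                cage_id = sprintf("cage%02d", i))
  })
  class(logs) <- "experiment"
  logs
}

#' Per-cage detection summary statistics
#'
#' Computes, for each cage, the statistics used to characterise a detection
#' experiment: engaged trials per complete dark/light cycle, trials per
#' minute, rewarded trials per day, dark- and light-cycle hit and early
#' rates, dark-cycle hit/early AULH shares, and the peak of the all-response
#' latency histogram.
#'
#' @param logs An `experiment` (list of `session_log`s).
#' @param bin_width_s Latency histogram bin width.
#' @return A data frame with one row per cage plus the across-cage means in
#'   `attr(, "means")`.
#' @export
detection_summary <- function(logs, bin_width_s = 0.1) {
  rows <- lapply(logs, function(log) {
    sch <- log$schedule
    tr <- log$trials
    eng <- engagement_summary(tr, log$licks, sch,
                              duration_s = log$duration_s,
                              trial_dur_s = trial_duration(log$config))
    rr <- response_rates(tr, "cycle", sch)
    dark <- tr[is_dark(tr$start_s, sch), , drop = FALSE]
    a <- suppressWarnings(aulh(list(
      hit = latency_histogram(dark, "hit", bin_width_s),
      early = latency_histogram(dark, "early", bin_width_s))))
    h_all <- latency_histogram(tr, "all", bin_width_s)
    peak <- if (h_all$n) h_all$mid[which.max(h_all$counts)] else NA_real_
    data.frame(
      cage = log$cage_id,
      engaged_dark = eng$engaged_dark_per_cycle,
      engaged_light = eng$engaged_light_per_cycle,
      trials_per_min = eng$trials_per_min,
      rewarded_per_day = eng$rewarded_per_day,
      hit_dark_pct = rr$hit_pct[rr$bin == "dark"],
      hit_light_pct = rr$hit_pct[rr$bin == "light"],
      early_dark_pct = rr$early_pct[rr$bin == "dark"],
      early_light_pct = rr$early_pct[rr$bin == "light"],
      aulh_hit_dark_pct = unname(a$percent["hit"]),
      aulh_early_dark_pct = unname(a$percent["early"]),
      latency_peak_s = peak,
      water_ml_per_mouse_day = water_budget(tr, log$config, n_mice = 2,
                                            schedule = sch,
                                            duration_s = log$duration_s),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  attr(out, "means") <- colMeans(out[, num, drop = FALSE], na.rm = TRUE)
  out
}
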