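# Offline analysis suite: trial classification, response-rate series,
# engagement, latency histograms, AULH, d-prime, light/dark comparisons,
# ultradian periodicity, water budget. Works on any conforming event log,
# whether simulated or recorded.

#' Classify trials offline from raw licks and stimuli
#'
#' Recomputes every trial outcome purely from the lick stream and the
#' stimulus table, with the same adjudication semantics as the online engine
#' ([adjudicate_trial()]): on engine-produced logs the outcomes are identical.
#'
#' @param licks Sorted lick times (seconds).
#' @param stimuli Data frame with `onset_s` and `category` (as written by
#'   [write_session()]); silent probes appear with `category =
#'   "silent_probe"`.
#' @param config A [task_config()].
#' @return A trial data frame with the same columns as `session_log$trials`
#'   (`auto_rewarded` is `NA`: auto-rewards are not recoverable from licks).
#' @export
classify_trials <- function(licks, stimuli, config) {
  fmt_err <- function(msg) stop(errorCondition(
    msg, class = c("homecage_format_error", "error", "condition")))
  if (length(licks) && is.unsorted(licks)) fmt_err("licks must be sorted")
  if (!all(c("onset_s", "category") %in% names(stimuli)))
    fmt_err("stimuli must have onset_s and category columns")
  starts <- stimuli$onset_s - config$pre_stim_s
  if (is.unsorted(starts)) fmt_err("stimuli must be sorted by onset")
  dur <- trial_duration(config)
  if (any(diff(starts) < dur - 1e-9)) fmt_err("overlapping trials")
  n <- nrow(stimuli)
  win_lo <- config$pre_stim_s
  win_hi <- config$pre_stim_s + config$response_window_s
  first <- rep(NA_real_, n)
  if (length(licks)) {
    i <- findInterval(starts - 1e-9, licks) + 1L
    ok <- i <= length(licks)
    lat <- rep(NA_real_, n)
    lat[ok] <- licks[i[ok]] - starts[ok]
    first <- ifelse(!is.na(lat) & lat <= dur + 1e-9, lat, NA_real_)
  }
  go_like <- stimuli$category %in% c("target", "silent_probe")
  outcome <- ifelse(is.na(first) | first > win_hi,
                    ifelse(go_like, "miss", "correct_rejection"),
                    ifelse(first < win_lo, "early",
                           ifelse(go_like, "hit", "false_alarm")))
  rewarded <- outcome == "hit" & stimuli$category == "target"
  timeout <- (outcome == "early" & config$punish_early |
                outcome == "false_alarm" & config$punish_fa) &
    stimuli$category != "silent_probe"
  data.frame(
    index = seq_len(n),
    start_s = starts,
    tone_onset_s = stimuli$onset_s,
    category = stimuli$category,
    freq_khz = if ("freq_khz" %in% names(stimuli)) stimuli$freq_khz else NA,
    level_db = if ("level_db" %in% names(stimuli)) stimuli$level_db else NA,
    first_lick_latency_s = first,
    outcome = outcome,
    rewarded = rewarded,
    auto_rewarded = NA,
    timeout_applied = timeout,
    iti_s = NA_real_,
    refrain_s = NA_real_,
    stringsAsFactors = FALSE
  )
}

rate_block <- function(trials) {
  n <- nrow(trials)
  n_t <- sum(trials$category == "target", na.rm = TRUE)
  n_nt <- sum(trials$category == "nontarget", na.rm = TRUE)
  pct <- function(k, d) if (d > 0) 100 * k / d else NA_real_
  data.frame(
    n = n, n_target = n_t, n_nontarget = n_nt,
    early_pct = pct(sum(trials$outcome == "early", na.rm = TRUE), n),
    hit_pct = pct(sum(trials$outcome == "hit", na.rm = TRUE), n_t),
    miss_pct = pct(sum(trials$outcome == "miss", na.rm = TRUE), n_t),
    fa_pct = pct(sum(trials$outcome == "false_alarm", na.rm = TRUE), n_nt),
    cr_pct = pct(sum(trials$outcome == "correct_rejection", na.rm = TRUE),
                 n_nt)
  )
}

#' Behavioural response rates
#'
#' Rates use the standard denominators: early responses as a percentage of
#' all trials, hit/miss as a percentage of target trials, false alarm/correct
#' rejection as a percentage of nontarget trials (so hit + miss = 100 and
#' fa + cr = 100 whenever the denominator is non-empty).
#'
#' @param trials A trial data frame (from a `session_log` or
#'   [classify_trials()]).
#' @param grouping One of `"total"` (one row), `"cycle"` (dark/light),
#'   `"hour"` (hour of day, 0--23), `"day"` (calendar day), `"hour_series"`
#'   (consecutive hours since session start) or `"window"` (sliding window of
#'   `window` consecutive trials stepped by 1).
#' @param schedule A [light_schedule()] (required for time groupings).
#' @param window Sliding-window width in trials (default 25).
#' @return A data frame of rates per bin; empty bins have `n = 0` and `NA`
#'   rates.
#' @export
response_rates <- function(trials,
                           grouping = c("total", "cycle", "hour", "day",
                                        "hour_series", "window"),
                           schedule = light_schedule(), window = 25L) {
  grouping <- match.arg(grouping)
  if (!nrow(trials)) {
    return(cbind(data.frame(bin = character(0)), rate_block(trials)[0, ]))
  }
  if (grouping == "total") {
    return(cbind(data.frame(bin = "all"), rate_block(trials)))
  }
  if (grouping == "window") {
    w <- as.integer(window)
    n <- nrow(trials)
    if (n < w) return(cbind(data.frame(window_start = integer(0)),
                            rate_block(trials)[0, ]))
    out <- do.call(rbind, lapply(seq_len(n - w + 1L), function(i)
      rate_block(trials[i:(i + w - 1L), ])))
    return(cbind(data.frame(window_start = seq_len(n - w + 1L)), out))
  }
  key <- switch(grouping,
    cycle = ifelse(is_dark(trials$start_s, schedule), "dark", "light"),
    hour = floor(time_of_day(trials$start_s, schedule)),
    day = day_index(trials$start_s, schedule),
    hour_series = floor(trials$start_s / 3600)
  )
  levels <- switch(grouping,
    cycle = c("dark", "light"),
    hour = 0:23,
    sort(unique(key))
  )
  out <- do.call(rbind, lapply(levels, function(lv)
    rate_block(trials[!is.na(key) & key == lv, , drop = FALSE])))
  cbind(data.frame(bin = levels), out)
}

#' Task-engagement summary
#'
#' A trial is engaged when at least one lick falls within it. Summarises the
#' mean number of engaged trials per complete 12 h dark and light cycle, and
#' the mean number of trials per minute over complete calendar days.
#'
#' @param trials Trial data frame.
#' @param licks Sorted lick times of the session.
#' @param schedule A [light_schedule()].
#' @param duration_s Session duration (defaults to the last trial end).
#' @param trial_dur_s Trial duration in seconds.
#' @return An object of class `engagement_summary`: list with
#'   `engaged_dark_per_cycle`, `engaged_light_per_cycle`, `trials_per_min`,
#'   `rewarded_per_day`, `n_dark_cycles`, `n_light_cycles`, `n_days`,
#'   `partial_excluded`, and the per-cycle table `cycles`.
#' @export
engagement_summary <- function(trials, licks, schedule = light_schedule(),
                               duration_s = NULL, trial_dur_s = 4) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(trials)) max(trials$start_s) + trial_dur_s else 0
  }
  n_in <- findInterval(trials$start_s + trial_dur_s + 1e-9, licks) -
    findInterval(trials$start_s - 1e-9, licks)
  engaged <- n_in > 0
  cyc <- cycle_table(duration_s, schedule)
  cyc$trials <- 0L
  cyc$engaged <- 0L
  if (nrow(trials)) {
    ci <- findInterval(trials$start_s, cyc$start_s)
    tab_t <- table(factor(ci, levels = seq_len(nrow(cyc))))
    tab_e <- table(factor(ci[engaged], levels = seq_len(nrow(cyc))))
    cyc$trials <- as.integer(tab_t)
    cyc$engaged <- as.integer(tab_e)
  }
  full <- cyc[cyc$complete, , drop = FALSE]
  days <- complete_days(duration_s, schedule)
  di <- day_index(trials$start_s, schedule)
  trials_per_day <- vapply(days, function(d) sum(di == d), numeric(1))
  rewarded_per_day <- vapply(days, function(d)
    sum(di == d & trials$rewarded), numeric(1))
  structure(list(
    engaged_dark_per_cycle = mean(full$engaged[full$cycle == "dark"]),
    engaged_light_per_cycle = mean(full$engaged[full$cycle == "light"]),
    trials_per_min = mean(trials_per_day) / 1440,
    rewarded_per_day = mean(rewarded_per_day),
    n_dark_cycles = sum(full$cycle == "dark"),
    n_light_cycles = sum(full$cycle == "light"),
    n_days = length(days),
    partial_excluded = any(!cyc$complete),
    cycles = cyc
  ), class = "engagement_summary")
}

#' @export
print.engagement_summary <- function(x, ...) {
  cat(sprintf("<engagement_summary> engaged/cycle dark %.1f (n=%d), light %.1f (n=%d)\n",
              x$engaged_dark_per_cycle, x$n_dark_cycles,
              x$engaged_light_per_cycle, x$n_light_cycles))
  cat(sprintf("  %.3f trials/min over %d complete day(s); %.1f rewarded trials/day\n",
              x$trials_per_min, x$n_days, x$rewarded_per_day))
  invisible(x)
}

#' First-lick latency histogram
#'
#' Histogram of the delay from trial onset until the first lick of the trial,
#' over `[0, trial_dur_s]`, for one response category (trials without a first
#' lick are excluded).
#'
#' @param trials Trial data frame.
#' @param category `"hit"`, `"early"`, `"false_alarm"`, or `"all"` (any trial
#'   with a first lick).
#' @param bin_width_s Bin width; must divide the trial duration evenly.
#' @param trial_dur_s Trial duration.
#' @return An object of class `latency_histogram`: list with `breaks`, `mid`,
#'   `counts`, `density` (integrates to 1 when non-empty), `n`, `category`.
#' @export
latency_histogram <- function(trials, category = "hit", bin_width_s = 0.1,
                              trial_dur_s = 4) {
  if (!category %in% c(outcome_levels, "all")) {
    stop("unknown category: ", category, call. = FALSE)
  }
  k <- trial_dur_s / bin_width_s
  if (abs(k - round(k)) > 1e-9) {
    stop("bin_width_s must divide the trial duration evenly", call. = FALSE)
  }
  lat <- trials$first_lick_latency_s
  sel <- !is.na(lat) & (if (category == "all") TRUE else
    trials$outcome == category)
  lat <- pmin(pmax(lat[sel], 0), trial_dur_s)
  breaks <- seq(0, trial_dur_s, by = bin_width_s)
  counts <- if (length(lat)) {
    bin <- pmin(floor(lat / bin_width_s), k - 1)
    tabulate(bin + 1L, nbins = k)
  } else {
    integer(k)
  }
  density <- if (sum(counts)) counts / (sum(counts) * bin_width_s) else
    rep(0, k)
  structure(list(breaks = breaks, mid = breaks[-length(breaks)] +
                   bin_width_s / 2,
                 counts = counts, density = density, n = sum(counts),
                 category = category),
            class = "latency_histogram")
}

#' Percentage of area under the latency histogram (AULH) per category
#'
#' The latency-based accuracy metric: each category's share of the total
#' first-lick latency-histogram area across the included categories
#' (hit + early for detection; hit + early + false alarm for discrimination).
#'
#' @param histograms Named list of [latency_histogram()] objects (names are
#'   the categories).
#' @return An object of class `aulh_result`: list with `percent` (named,
#'   summing to 100), `areas`, and `defined` (`FALSE` with all-`NA` shares
#'   when every included histogram is empty).
#' @export
aulh <- function(histograms) {
  stopifnot(length(histograms) >= 1, !is.null(names(histograms)))
  areas <- vapply(histograms, function(h) sum(h$counts), numeric(1))
  tot <- sum(areas)
  if (tot == 0) {
    warning("all latency histograms are empty; AULH undefined")
    pct <- stats::setNames(rep(NA_real_, length(areas)), names(areas))
    return(structure(list(percent = pct, areas = areas, defined = FALSE),
                     class = "aulh_result"))
  }
  structure(list(percent = 100 * areas / tot, areas = areas, defined = TRUE),
            class = "aulh_result")
}

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = qnorm(hit) - qnorm(fa)` with the 1/(2n) correction for extreme
#' proportions: 0 is replaced by `1/(2n)` and 1 by `1 - 1/(2n)` (using the
#' respective trial counts), keeping d-prime finite.
#'
#' @param hit_prop,fa_prop Hit and false-alarm proportions in `[0, 1]`
#'   (vectorised).
#' @param n_target,n_nontarget Trial counts behind each proportion.
#' @return Numeric d-prime (NA where a count is zero).
#' @export
dprime <- function(hit_prop, fa_prop, n_target, n_nontarget) {
  stopifnot(all(hit_prop >= 0 & hit_prop <= 1, na.rm = TRUE),
            all(fa_prop >= 0 & fa_prop <= 1, na.rm = TRUE))
  clamp <- function(p, n) {
    n <- rep_len(n, length(p))
    p <- ifelse(p <= 0, 1 / (2 * n), ifelse(p >= 1, 1 - 1 / (2 * n), p))
    p[n < 1] <- NA_real_
    p
  }
  stats::qnorm(clamp(hit_prop, n_target)) -
    stats::qnorm(clamp(fa_prop, n_nontarget))
}

#' Hourly d-prime series
#'
#' Discrimination sensitivity for each hour of the day. `mode = "rate"` uses
#' the per-hour hit and false-alarm response proportions; `mode = "latency"`
#' uses the per-hour AULH shares of the hit and false-alarm categories (one
#' reading of a latency-based d-prime; see the methods vignette).
#'
#' @param trials Discrimination-phase trial data frame.
#' @param schedule A [light_schedule()].
#' @param mode `"rate"` or `"latency"`.
#' @param bin_width_s Histogram bin width for `mode = "latency"`.
#' @return A data frame with `hour`, `dprime`, `hit_prop`, `fa_prop`,
#'   `n_target`, `n_nontarget`, `defined`.
#' @export
hourly_dprime <- function(trials, schedule = light_schedule(),
                          mode = c("rate", "latency"), bin_width_s = 0.1) {
  mode <- match.arg(mode)
  if (!any(trials$category == "nontarget")) {
    stop(errorCondition(
      "hourly_dprime requires nontarget trials (discrimination phase)",
      class = c("homecage_format_error", "error", "condition")))
  }
  hr <- floor(time_of_day(trials$start_s, schedule))
  out <- do.call(rbind, lapply(0:23, function(h) {
    tr <- trials[hr == h, , drop = FALSE]
    n_t <- sum(tr$category == "target")
    n_nt <- sum(tr$category == "nontarget")
    if (mode == "rate") {
      hp <- if (n_t) sum(tr$outcome == "hit") / n_t else NA_real_
      fp <- if (n_nt) sum(tr$outcome == "false_alarm") / n_nt else NA_real_
      nh <- n_t; nf <- n_nt
    } else {
      hists <- list(hit = latency_histogram(tr, "hit", bin_width_s),
                    early = latency_histogram(tr, "early", bin_width_s),
                    false_alarm = latency_histogram(tr, "false_alarm",
                                                    bin_width_s))
      a <- suppressWarnings(aulh(hists))
      hp <- unname(a$percent["hit"] / 100)
      fp <- unname(a$percent["false_alarm"] / 100)
      nh <- hists$hit$n + hists$early$n + hists$false_alarm$n
      nf <- nh
    }
    defined <- !is.na(hp) && !is.na(fp) && nh >= 1 && nf >= 1
    data.frame(hour = h, hit_prop = hp, fa_prop = fp, n_target = n_t,
               n_nontarget = n_nt,
               dprime = if (defined) dprime(hp, fp, nh, nf) else NA_real_,
               defined = defined)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample two-sided Kolmogorov--Smirnov comparison
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return An object of class `ks_result`: list with `D` (the maximum ECDF
#'   gap), asymptotic two-sided `p`, and sample sizes.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) {
    stop(errorCondition("both samples must be non-empty",
                        class = c("homecage_format_error", "error",
                                  "condition")))
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        alternative = "two.sided",
                                        exact = FALSE))
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 n_a = length(sample_a), n_b = length(sample_b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.4g (n = %d, %d)\n",
              x$D, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Dark-versus-light summary table across cages
#'
#' For each metric column: dark and light means and SDs across cages, and the
#' two-sided KS p-value comparing the per-cage dark values against the
#' per-cage light values (omitted with a single cage).
#'
#' @param per_cage Data frame with columns `cage`, `cycle` (`"dark"`/
#'   `"light"`) and one column per metric.
#' @param metrics Character vector of metric column names (default: all
#'   numeric columns except `cage`/`cycle`).
#' @return A data frame with one row per metric.
#' @export
light_dark_table <- function(per_cage, metrics = NULL) {
  stopifnot(all(c("cage", "cycle") %in% names(per_cage)))
  if (is.null(metrics)) {
    metrics <- setdiff(names(per_cage)[vapply(per_cage, is.numeric,
                                              logical(1))],
                       c("cage", "cycle"))
  }
  n_cages <- length(unique(per_cage$cage))
  if (n_cages < 1) stop("need at least one cage", call. = FALSE)
  out <- do.call(rbind, lapply(metrics, function(m) {
    d <- per_cage[[m]][per_cage$cycle == "dark"]
    l <- per_cage[[m]][per_cage$cycle == "light"]
    p <- if (n_cages >= 2 && sum(!is.na(d)) && sum(!is.na(l))) {
      ks_compare(d[!is.na(d)], l[!is.na(l)])$p
    } else NA_real_
    data.frame(metric = m,
               dark_mean = mean(d, na.rm = TRUE),
               dark_sd = stats::sd(d, na.rm = TRUE),
               light_mean = mean(l, na.rm = TRUE),
               light_sd = stats::sd(l, na.rm = TRUE),
               ks_p = p)
  }))
  rownames(out) <- NULL
  out
}

#' Dominant ultradian period of an hourly rate series
#'
#' Estimates the dominant period of a slow (ultradian, 2--6 h) modulation in
#' an hourly rate series by a least-squares periodogram: each segment (e.g.
#' each dark cycle) is linearly detrended, then for every candidate period a
#' sinusoid (coherent in global time across segments, since a physiological
#' oscillator keeps running between dark cycles) is fitted by least squares;
#' the dominant period maximises the explained variance. Strength is the
#' explained-variance fraction at the peak: near 1 for a pure oscillation,
#' near 0 for white noise.
#'
#' @param x Numeric series of hourly values (dark-cycle samples when studying
#'   dark-cycle engagement), `NA`s allowed (dropped).
#' @param segment Segment identifier per element (e.g. dark-cycle index); the
#'   series is detrended within segments. Default: one segment.
#' @param t_h Sample times in hours (global, so that gaps between segments
#'   are respected). Default: consecutive samples `dt_h` apart.
#' @param period_range_h Candidate period range in hours.
#' @param dt_h Sampling interval in hours (used for the default `t_h` and
#'   the candidate grid).
#' @param grid_h Candidate-period step (default 0.05 h).
#' @return A list with `period_h` and `strength` (in `[0, 1]`).
#' @export
periodicity <- function(x, segment = rep(1L, length(x)),
                        t_h = (seq_along(x) - 1) * dt_h,
                        period_range_h = c(2, 6), dt_h = 1, grid_h = 0.05) {
  stopifnot(length(x) == length(segment), length(x) == length(t_h),
            period_range_h[1] > 0, period_range_h[1] < period_range_h[2])
  if (length(x) * dt_h < 2 * period_range_h[2]) {
    stop(errorCondition(
      "series too short: need >= 2x the maximum candidate period",
      class = c("homecage_format_error", "error", "condition")))
  }
  # Per-segment linear detrend.
  r <- rep(NA_real_, length(x))
  for (s in unique(segment)) {
    sel <- segment == s & !is.na(x)
    if (sum(sel) < 3) next
    fit <- stats::lm.fit(cbind(1, t_h[sel]), x[sel])
    r[sel] <- fit$residuals
  }
  ok <- !is.na(r)
  if (sum(ok) < 8) return(list(period_h = NA_real_, strength = 0))
  rr <- r[ok]
  tt <- t_h[ok]
  ss0 <- sum(rr^2)
  if (ss0 <= 0) return(list(period_h = NA_real_, strength = 0))
  periods <- seq(period_range_h[1], period_range_h[2], by = grid_h)
  expl <- vapply(periods, function(P) {
    w <- 2 * pi * tt / P
    X <- cbind(cos(w), sin(w))
    f <- stats::lm.fit(X, rr)
    1 - sum(f$residuals^2) / ss0
  }, numeric(1))
  i <- which.max(expl)
  list(period_h = periods[i], strength = max(0, min(1, expl[i])))
}

#' Hourly rate series with dark-cycle segments
#'
#' Convenience wrapper binding [response_rates()] hourly bins to the light
#' schedule: one row per consecutive hour with rates, the dark flag, and the
#' index of the complete dark cycle containing the hour (NA outside), the
#' form consumed by [periodicity()].
#'
#' @param trials Trial data frame.
#' @param schedule A [light_schedule()].
#' @param duration_s Session duration in seconds.
#' @return A data frame with `t_h` (bin centre, hours since session start),
#'   `dark`, `dark_cycle`, and the rate columns of [response_rates()].
#' @export
hourly_series <- function(trials, schedule = light_schedule(),
                          duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- max(trials$start_s) + 4
  rr <- response_rates(trials, "hour_series", schedule)
  hours <- seq_len(floor(duration_s / 3600)) - 1L
  j <- match(hours, as.numeric(rr$bin))
  rr <- rr[j, , drop = FALSE]
  rr$n[is.na(j)] <- 0L
  rr$n_target[is.na(j)] <- 0L
  rr$n_nontarget[is.na(j)] <- 0L
  rownames(rr) <- NULL
  mid_s <- (hours + 0.5) * 3600
  cyc <- cycle_table(duration_s, schedule)
  dk <- cyc[cyc$cycle == "dark" & cyc$complete, , drop = FALSE]
  seg <- rep(NA_integer_, length(mid_s))
  if (nrow(dk)) {
    j <- findInterval(mid_s, dk$start_s)
    inside <- j >= 1 & mid_s <= dk$end_s[pmax(j, 1L)]
    seg[inside] <- j[inside]
  }
  cbind(data.frame(t_h = hours + 0.5, dark = is_dark(mid_s, schedule),
                   dark_cycle = seg), rr[, -1, drop = FALSE])
}

#' Daily water intake per mouse
#'
#' Rewarded trials per day times the per-hit reward volume, divided evenly
#' among the cage mates (the rig cannot attribute licks to individuals).
#'
#' @param trials Trial data frame with `rewarded` and `start_s`.
#' @param config A [task_config()] (for `reward_ml`).
#' @param n_mice Mice per cage.
#' @param schedule Optional [light_schedule()]; when given, only complete
#'   calendar days are averaged, otherwise the observed span is used.
#' @param duration_s Session duration (needed with `schedule`).
#' @return Millilitres per mouse per day.
#' @export
water_budget <- function(trials, config, n_mice = 2, schedule = NULL,
                         duration_s = NULL) {
  stopifnot(n_mice >= 1)
  if (!nrow(trials)) return(0)
  if (!is.null(schedule)) {
    if (is.null(duration_s)) duration_s <- max(trials$start_s) + 4
    days <- complete_days(duration_s, schedule)
    if (!length(days)) stop("no complete day inside the session",
                            call. = FALSE)
    di <- day_index(trials$start_s, schedule)
    per_day <- vapply(days, function(d) sum(trials$rewarded[di == d]),
                      numeric(1))
    rew_per_day <- mean(per_day)
  } else {
    span_d <- max(1e-9, (max(trials$start_s) - min(trials$start_s)) / 86400)
    rew_per_day <- sum(trials$rewarded) / max(span_d, 1)
  }
  rew_per_day * config$reward_ml / n_mice
}
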