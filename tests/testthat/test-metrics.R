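# Analysis suite: offline classification, rates, engagement, latency
# histograms, AULH, d-prime, KS, light/dark tables, periodicity, water.

test_that("offline classification reproduces hand-traced outcomes", {
  cfg <- task_config("detection")
  # three trials at 0, 60, 120 s; first licks at 0.4 (early), 61.2 (hit), none
  licks <- quantize_licks(c(0.42, 1.8, 61.2, 62.0))
  stimuli <- data.frame(onset_s = c(1, 61, 121), duration_s = 1,
                        freq_khz = 11.3, level_db = 60, category = "target",
                        stringsAsFactors = FALSE)
  tr <- classify_trials(licks, stimuli, cfg)
  expect_equal(tr$outcome, c("early", "hit", "miss"))
  expect_equal(tr$rewarded, c(FALSE, TRUE, FALSE))
  expect_equal(tr$timeout_applied, c(TRUE, FALSE, FALSE))

  # nontarget with a window lick is a false alarm
  dcfg <- task_config("discrimination")
  st2 <- data.frame(onset_s = 1, duration_s = 1, freq_khz = 2, level_db = 60,
                    category = "nontarget", stringsAsFactors = FALSE)
  tr2 <- classify_trials(quantize_licks(1.5), st2, dcfg)
  expect_equal(tr2$outcome, "false_alarm")
  expect_true(tr2$timeout_applied)

  expect_error(classify_trials(c(2, 1), st2, dcfg),
               class = "homecage_format_error")
  over <- data.frame(onset_s = c(1, 3), duration_s = 1, freq_khz = 2,
                     level_db = 60, category = "target",
                     stringsAsFactors = FALSE)
  expect_error(classify_trials(numeric(0), over, cfg),
               class = "homecage_format_error")
})

test_that("engine and offline classifier agree on full sessions (round trip)", {
  for (log in list(detection_day(), discrimination_day())) {
    off <- classify_trials(log$licks, log$stimuli, log$config)
    expect_equal(off$outcome, log$trials$outcome)
    expect_equal(off$first_lick_latency_s, log$trials$first_lick_latency_s)
    expect_equal(off$rewarded, log$trials$rewarded)
    expect_equal(off$timeout_applied, log$trials$timeout_applied)
  }
})

test_that("response rates use the documented denominators", {
  tr <- make_trials(c(rep("early", 6), rep("miss", 94)))
  rr <- response_rates(tr, "total")
  expect_equal(rr$early_pct, 6)

  tr2 <- make_trials(c(rep("hit", 30), rep("miss", 20),
                       rep("false_alarm", 5), rep("correct_rejection", 15)),
                     category = c(rep("target", 50), rep("nontarget", 20)))
  rr2 <- response_rates(tr2, "total")
  expect_equal(rr2$hit_pct, 60)
  expect_equal(rr2$miss_pct, 40)
  expect_equal(rr2$hit_pct + rr2$miss_pct, 100)
  expect_equal(rr2$fa_pct, 25)
  expect_equal(rr2$fa_pct + rr2$cr_pct, 100)
  expect_equal(rr2$early_pct, 0)

  # 25-trial sliding window over alternating hits and misses
  alt <- make_trials(rep(c("hit", "miss"), 30))
  w <- response_rates(alt, "window", window = 25)
  expect_equal(nrow(w), 60 - 25 + 1)
  expect_true(all(round(w$hit_pct, 6) %in%
                    round(100 * c(12 / 25, 13 / 25), 6)))

  expect_equal(nrow(response_rates(tr[0, ], "total")), 0)
})

test_that("engagement summary counts engaged trials per cycle and trials per minute", {
  sch <- light_schedule()
  # one full day: 50 dark trials (40 with licks), 50 light trials (10 with licks)
  dark_tr <- make_trials(rep("miss", 50), t0_s = 1000, spacing_s = 600)
  light_tr <- make_trials(rep("miss", 50), t0_s = 12 * 3600 + 1000,
                          spacing_s = 600)
  trials <- rbind(dark_tr, light_tr)
  trials$index <- seq_len(nrow(trials))
  licks <- quantize_licks(c(dark_tr$start_s[1:40] + 2,
                            light_tr$start_s[1:10] + 2))
  es <- engagement_summary(trials, licks, sch, duration_s = 86400)
  expect_equal(es$engaged_dark_per_cycle, 40)
  expect_equal(es$engaged_light_per_cycle, 10)
  expect_equal(es$n_dark_cycles, 1)
  expect_equal(es$n_light_cycles, 1)
  # 100 trials over one day
  sch0 <- light_schedule(session_start_tod_h = 0)
  es2 <- engagement_summary(trials, licks, sch0, duration_s = 86400)
  expect_equal(es2$trials_per_min, 100 / 1440)
})

test_that("latency histograms bin first licks over the 4 s trial", {
  tr <- make_trials(rep("hit", 3), latency = c(1.05, 1.15, 2.05))
  h <- latency_histogram(tr, "hit", bin_width_s = 0.1)
  cnt_at <- function(x) h$counts[which.min(abs(h$mid - x))]
  expect_equal(cnt_at(1.05), 1)
  expect_equal(cnt_at(1.15), 1)
  expect_equal(cnt_at(2.05), 1)
  expect_equal(sum(h$counts), 3)
  expect_equal(sum(h$density) * 0.1, 1)

  empty <- latency_histogram(make_trials("miss"), "hit")
  expect_true(all(empty$counts == 0))
  expect_error(latency_histogram(tr, "banana"))
  expect_error(latency_histogram(tr, "hit", bin_width_s = 0.3))
})

test_that("AULH shares are percentages of total histogram area", {
  tr <- make_trials(c(rep("hit", 3), "early"))
  hists <- list(hit = latency_histogram(tr, "hit"),
                early = latency_histogram(tr, "early"))
  a <- aulh(hists)
  expect_equal(unname(a$percent["hit"]), 75)
  expect_equal(unname(a$percent["early"]), 25)
  expect_equal(sum(a$percent), 100, tolerance = 1e-12)

  solo <- aulh(list(hit = latency_histogram(tr, "hit")))
  expect_equal(unname(solo$percent["hit"]), 100)

  none <- make_trials("miss")
  expect_warning(z <- aulh(list(hit = latency_histogram(none, "hit"))))
  expect_false(z$defined)
  expect_true(all(is.na(z$percent)))
})

test_that("d-prime matches normal quantiles with extreme-proportion correction", {
  expect_equal(dprime(0.5, 0.5, 100, 100), 0)
  expect_equal(dprime(0.69, 0.31, 1e6, 1e6),
               qnorm(0.69) - qnorm(0.31), tolerance = 1e-12)
  expect_lt(abs(dprime(0.69, 0.31, 1e6, 1e6) - 0.9918), 1e-3)
  # correction: 1 -> 1 - 1/(2n), 0 -> 1/(2n)
  expect_equal(dprime(1, 0.5, 50, 50), qnorm(1 - 1 / 100) - qnorm(0.5))
  expect_equal(dprime(0, 0.5, 25, 50), qnorm(1 / 50) - qnorm(0.5))
  expect_true(is.finite(dprime(1, 0, 20, 20)))
  # antisymmetry and monotonicity
  for (h in c(0.2, 0.5, 0.8)) for (f in c(0.1, 0.4, 0.7)) {
    expect_equal(dprime(h, f, 40, 40), -dprime(f, h, 40, 40))
  }
  hgrid <- seq(0.05, 0.95, by = 0.1)
  d <- dprime(hgrid, 0.3, 100, 100)
  expect_true(all(diff(d) > 0))
  d2 <- dprime(0.7, hgrid, 100, 100)
  expect_true(all(diff(d2) < 0))
})

test_that("hourly d-prime is flat for identical hourly proportions", {
  # 24 hours x (10 target with 7 hits, 10 nontarget with 3 FA)
  mk_hour <- function(h) {
    tr <- make_trials(c(rep("hit", 7), rep("miss", 3),
                        rep("false_alarm", 3), rep("correct_rejection", 7)),
                      category = c(rep("target", 10), rep("nontarget", 10)),
                      t0_s = h * 3600, spacing_s = 60)
    tr
  }
  trials <- do.call(rbind, lapply(0:23, mk_hour))
  trials$index <- seq_len(nrow(trials))
  dp <- hourly_dprime(trials, light_schedule(session_start_tod_h = 0), "rate")
  expect_equal(nrow(dp), 24)
  expect_true(all(dp$defined))
  expect_equal(stats::sd(dp$dprime), 0)
  expect_equal(dp$dprime[1], dprime(0.7, 0.3, 10, 10))

  det <- make_trials(rep("hit", 5))
  expect_error(hourly_dprime(det, light_schedule(), "rate"),
               class = "homecage_format_error")
})

test_that("KS comparison equals the brute-force ECDF gap", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_compare(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_compare(c(1, 3), c(2, 4))$D, 0.5)
  expect_error(ks_compare(numeric(0), 1:3),
               class = "homecage_format_error")
  # property: D equals the exhaustive ECDF-gap oracle on random instances
  st <- new_rng_stream(99)
  for (i in 1:60) {
    ab <- stream_eval(st, function() {
      na <- sample(1:20, 1); nb <- sample(1:20, 1)
      list(a = round(stats::runif(na, 0, 5), 1),
           b = round(stats::runif(nb, 0, 5), 1))
    })
    expect_equal(ks_compare(ab$a, ab$b)$D, ks_brute_force(ab$a, ab$b),
                 tolerance = 1e-12)
  }
})

test_that("light/dark tables aggregate per-cage metrics with KS tests", {
  per_cage <- data.frame(
    cage = rep(sprintf("c%02d", 1:4), each = 2),
    cycle = rep(c("dark", "light"), 4),
    hit_pct = c(6, 4, 7, 3, 6.5, 4.5, 5.5, 3.5)
  )
  tab <- light_dark_table(per_cage)
  expect_equal(tab$dark_mean, mean(c(6, 7, 6.5, 5.5)))
  expect_equal(tab$light_mean, mean(c(4, 3, 4.5, 3.5)))
  expect_equal(tab$dark_sd, stats::sd(c(6, 7, 6.5, 5.5)))
  expect_true(tab$ks_p < 0.2)
  # self-comparison sanity: identical samples give p = 1
  expect_equal(ks_compare(c(6, 7, 6.5, 5.5), c(6, 7, 6.5, 5.5))$p, 1)
  solo <- light_dark_table(per_cage[per_cage$cage == "c01", ])
  expect_true(is.na(solo$ks_p))
})

test_that("periodicity finds pure oscillations and rejects white noise", {
  t <- 0:47
  ps <- periodicity(sin(2 * pi * t / 4), t_h = t)
  expect_equal(ps$period_h, 4, tolerance = 0.05)
  expect_gt(ps$strength, 0.9)

  ps35 <- periodicity(cos(2 * pi * t / 3.5 + 1), t_h = t)
  expect_equal(ps35$period_h, 3.5, tolerance = 0.05)

  st <- new_rng_stream(5)
  strengths <- vapply(1:5, function(i) {
    x <- stream_eval(st, function() stats::rnorm(48))
    periodicity(x, t_h = t)$strength
  }, numeric(1))
  expect_true(all(strengths < 0.5))
  expect_lt(mean(strengths), 0.3)

  expect_error(periodicity(stats::rnorm(8), t_h = 0:7),
               class = "homecage_format_error")
})

test_that("water budget divides rewarded volume among cage mates", {
  cfg <- task_config("detection")
  tr <- make_trials(c(rep("hit", 64), rep("miss", 36)), spacing_s = 600)
  expect_equal(water_budget(tr, cfg, n_mice = 2), 64 * 0.075 / 2)
  expect_equal(water_budget(tr, cfg, n_mice = 2), 2.4)
  expect_equal(water_budget(make_trials("miss"), cfg, 2), 0)
  tr4 <- make_trials(rep("hit", 100), spacing_s = 600)
  expect_equal(water_budget(tr4, cfg, n_mice = 4), 1.875)
})
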