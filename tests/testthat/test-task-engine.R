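# Task engine: draws, adjudication, trial scheduling, session invariants.

test_that("intertrial interval draws are uniform on the configured range", {
  cfg <- task_config("detection")
  st <- new_rng_stream(1)
  draws <- replicate(200, draw_iti(cfg, st))
  expect_true(all(draws >= 5 & draws <= 9))

  cfg55 <- task_config("detection", iti_range_s = c(5, 5))
  expect_identical(draw_iti(cfg55, st), 5)

  st1 <- new_rng_stream(1)
  big <- stream_eval(st1, function() stats::runif(1e5, 5, 9))
  se <- (4 / sqrt(12)) / sqrt(1e5)
  expect_lt(abs(mean(big) - 7), 3 * se)
})

test_that("stimulus category draws honour the configured mixture", {
  det <- task_config("detection")
  st <- new_rng_stream(2)
  cats <- replicate(200, draw_trial_category(det, st)$category)
  expect_true(all(cats == "target"))

  disc <- task_config("discrimination")
  st7 <- new_rng_stream(7)
  cats <- replicate(1e4, draw_trial_category(disc, st7)$category)
  p_nt <- mean(cats == "nontarget")
  se <- sqrt(0.5 * 0.5 / 1e4)
  expect_lt(abs(p_nt - 0.5), 3 * se)

  aud <- task_config("detection", freq_list_khz = c(4, 8, 16, 32, 45),
                     level_db = c(30, 45, 60))
  st3 <- new_rng_stream(3)
  freqs <- replicate(1e4, draw_trial_category(aud, st3)$freq_khz)
  tab <- table(freqs) / 1e4
  se <- sqrt(0.2 * 0.8 / 1e4)
  expect_equal(length(tab), 5L)
  expect_true(all(abs(tab - 0.2) < 4 * se))

  bad <- task_config("discrimination")
  bad$probe_frac <- 0.7  # nontarget_frac 0.5 + 0.7 > 1
  st4 <- new_rng_stream(4)
  expect_error(draw_trial_category(bad, st4),
               class = "homecage_config_error")
})

test_that("trial adjudication follows the first-lick contingencies", {
  cfg <- task_config("detection")
  # early: first lick in the prestimulus silence
  a <- adjudicate_trial(c(0.5, 1.8), "target", cfg)
  expect_equal(a$outcome, "early")
  expect_false(a$rewarded)
  expect_true(a$timeout_applied)
  # hit: first lick in the response window after the target
  a <- adjudicate_trial(1.8, "target", cfg)
  expect_equal(a$outcome, "hit")
  expect_true(a$rewarded)
  expect_false(a$timeout_applied)
  # no-go trial without licks
  a <- adjudicate_trial(numeric(0), "nontarget", task_config("discrimination"))
  expect_equal(a$outcome, "correct_rejection")
  expect_false(a$rewarded)
  expect_false(a$timeout_applied)
  # false alarm on a nontarget
  a <- adjudicate_trial(2.1, "nontarget", task_config("discrimination"))
  expect_equal(a$outcome, "false_alarm")
  expect_true(a$timeout_applied)
  # window boundaries are inclusive
  expect_equal(adjudicate_trial(4.0, "target", cfg)$outcome, "hit")
  expect_equal(adjudicate_trial(1.0, "target", cfg)$outcome, "hit")
  # probes use the target rule but are never rewarded or punished
  a <- adjudicate_trial(1.8, "silent_probe", cfg)
  expect_equal(a$outcome, "hit")
  expect_false(a$rewarded)
  a <- adjudicate_trial(0.2, "silent_probe", cfg)
  expect_equal(a$outcome, "early")
  expect_false(a$timeout_applied)
  # shaping does not punish early licks
  a <- adjudicate_trial(0.5, "target", task_config("shaping"))
  expect_equal(a$outcome, "early")
  expect_false(a$timeout_applied)

  expect_error(adjudicate_trial(c(2, 1), "target", cfg),
               class = "homecage_format_error")
})

test_that("trial scheduling composes ITI, refrain and timeout correctly", {
  streams <- rng_streams(1)
  cfg68 <- task_config("detection", iti_range_s = c(6, 6),
                       refrain_range_s = c(8, 8))
  # a lick right at the previous trial end forces the refrain to dominate
  s <- schedule_next_trial(100, 0, c(100), cfg68, streams)
  expect_equal(s$start_s, 108)  # prev_end + max(ITI 6, refrain 8)
  # empty lick stream: only the ITI matters
  s <- schedule_next_trial(100, 0, numeric(0), cfg68, streams)
  expect_equal(s$start_s, 106)
  # a timeout is added to the ITI
  cfg55 <- task_config("detection", iti_range_s = c(5, 5),
                       refrain_range_s = c(5, 5))
  s <- schedule_next_trial(100, 20, numeric(0), cfg55, streams)
  expect_equal(s$start_s, 125)
  # a lick 2 s before the candidate start postpones to lick + refrain
  cfg10 <- task_config("detection", iti_range_s = c(5, 5),
                       refrain_range_s = c(10, 10))
  s <- schedule_next_trial(100, 0, c(103), cfg10, streams)
  expect_equal(s$start_s, 113)
  # an ITI lick inside the trailing refrain window postpones the same way
  s <- schedule_next_trial(100, 0, c(100.5), cfg10, streams)
  expect_equal(s$start_s, 110.5)
  # a source that never stops licking trips the diagnostic cap
  dense <- seq(0, 4000, by = 1)
  expect_error(schedule_next_trial(0, 0, dense, cfg10, streams),
               class = "homecage_schedule_error")
})

test_that("habituation opens water at random 30-300 s intervals", {
  cfg <- task_config("habituation")
  log <- run_session(cfg, default_calibration("habituation"),
                     duration_s = 2 * 3600, seed = 5)
  starts <- log$trials$start_s
  expect_gt(length(starts), 10)
  gaps <- diff(starts) - cfg$habituation_water_s
  expect_true(all(gaps >= 30 - 1e-9 & gaps <= 300 + 1e-9))
  expect_equal(log$total_water_ml,
               nrow(log$trials) * cfg$reward_ml *
                 cfg$habituation_water_s / cfg$reward_open_s)
})

test_that("shaping auto-rewards the configured fraction of trials", {
  log <- shaping_quarter_day()
  tr <- log$trials
  expect_gt(nrow(tr), 300)
  frac <- mean(tr$auto_rewarded)
  se <- sqrt(0.2 * 0.8 / nrow(tr))
  expect_lt(abs(frac - 0.2), 3 * se)
  # water released on every rewarded trial, rewarded <=> hit or auto
  expect_equal(tr$rewarded, tr$outcome == "hit" | tr$auto_rewarded)
  expect_equal(log$total_water_ml, sum(tr$rewarded) * log$config$reward_ml)
  expect_false(any(tr$timeout_applied))
})

test_that("a mute mouse misses every trial and receives no water", {
  log <- run_session(task_config("detection"), mute_mouse(),
                     duration_s = 4 * 3600, seed = 9)
  expect_gt(nrow(log$trials), 100)
  expect_true(all(log$trials$outcome == "miss"))
  expect_identical(log$total_water_ml, 0)
  expect_length(log$licks, 0)
})

test_that("sessions are deterministic and invariant-satisfying", {
  log <- detection_day()
  log2 <- run_session(task_config("detection"),
                      default_calibration("detection"),
                      duration_s = 86400, seed = 7, cage_id = "fix01")
  expect_identical(log, log2)

  tr <- log$trials
  # trials are time-ordered, non-overlapping, 4 s long
  expect_true(all(diff(tr$start_s) >= 4))
  expect_equal(tr$tone_onset_s, tr$start_s + 1)
  # lick stream strictly increasing on the 30 ms grid
  expect_true(all(diff(log$licks) >= 0.03 - 1e-9))
  expect_true(all(abs(log$licks / 0.03 - round(log$licks / 0.03)) < 1e-6))
  # timeout and reward conservation
  expect_equal(sum(tr$timeout_applied),
               sum(tr$outcome %in% c("early", "false_alarm")))
  expect_equal(sum(tr$rewarded), sum(tr$outcome == "hit"))
  expect_equal(log$total_water_ml, sum(tr$rewarded) * log$config$reward_ml)
  # every trial's stimulus is logged
  expect_equal(nrow(log$stimuli), nrow(tr))
  # ITI respected: start - prev_end >= iti (+ timeout when punished)
  gap <- tr$start_s[-1] - (tr$start_s[-nrow(tr)] + 4)
  owed <- tr$iti_s[-1] + ifelse(tr$timeout_applied[-nrow(tr)], 20, 0)
  expect_true(all(gap >= owed - 1e-6))
  # refrain respected: no lick in the refrain window before each start
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    w <- log$licks[log$licks > tr$start_s[i] - tr$refrain_s[i] + 1e-6 &
                     log$licks < tr$start_s[i]]
    length(w) == 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("discrimination sessions punish false alarms and log nontargets", {
  log <- discrimination_day()
  tr <- log$trials
  expect_gt(sum(tr$category == "nontarget"), 100)
  expect_equal(sum(tr$timeout_applied),
               sum(tr$outcome %in% c("early", "false_alarm")))
  expect_true(all(tr$freq_khz[tr$category == "nontarget"] == 2))
  expect_true(all(tr$freq_khz[tr$category == "target"] == 5))
  expect_equal(sum(tr$rewarded), sum(tr$outcome == "hit"))
})
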