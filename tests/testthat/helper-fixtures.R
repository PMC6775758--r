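# Shared fixtures: small simulations are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# One full day (one dark + one light cycle) of detection with the shipped
# calibration.
detection_day <- function() {
  cached_fixture("detection_day", function() {
    run_session(task_config("detection"), default_calibration("detection"),
                duration_s = 86400, seed = 7, cage_id = "fix01")
  })
}

# One full day of discrimination.
discrimination_day <- function() {
  cached_fixture("discrimination_day", function() {
    run_session(task_config("discrimination"),
                default_calibration("discrimination"),
                duration_s = 86400, seed = 8, cage_id = "fix02")
  })
}

# Six hours of shaping (auto-rewards active).
shaping_quarter_day <- function() {
  cached_fixture("shaping_quarter_day", function() {
    run_session(task_config("shaping"), default_calibration("shaping"),
                duration_s = 6 * 3600, seed = 3, cage_id = "fix03")
  })
}

# A virtual mouse that never licks and never responds.
mute_mouse <- function() {
  mouse_params(spont_rate_light_hz = 0, spont_rate_dark_hz = 0,
               p_hit_given_engaged = 0, p_fa_given_engaged = 0, p_early = 0,
               contact_lick_hz = 0)
}

# Hand-built trial table: categories/outcomes/latencies fully controlled.
# Trials are laid down every `spacing_s` seconds starting at `t0_s`.
make_trials <- function(outcome, category = rep("target", length(outcome)),
                        latency = NULL, t0_s = 0, spacing_s = 60) {
  n <- length(outcome)
  if (is.null(latency)) {
    latency <- ifelse(outcome == "early", 0.5,
                      ifelse(outcome %in% c("hit", "false_alarm"), 1.8,
                             NA_real_))
  }
  start <- t0_s + spacing_s * (seq_len(n) - 1)
  data.frame(
    index = seq_len(n), start_s = start, tone_onset_s = start + 1,
    category = category, freq_khz = 11.3, level_db = 60,
    first_lick_latency_s = latency, outcome = outcome,
    rewarded = outcome == "hit" & category == "target",
    auto_rewarded = FALSE,
    timeout_applied = outcome %in% c("early", "false_alarm"),
    iti_s = NA_real_, refrain_s = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Brute-force two-sample KS statistic: maximum ECDF gap evaluated at every
# sample point (independent oracle for ks_compare).
ks_brute_force <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(fa - fb))
}

# High-precision standard-normal quantile by inverting pnorm with uniroot
# (independent of qnorm).
qnorm_oracle <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(z) stats::pnorm(z) - pp, c(-10, 10),
                   tol = 1e-12)$root
  }, numeric(1))
}
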