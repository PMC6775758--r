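{
  "phase": "detection",
  "pre_stim_s": 1,
  "tone_s": 1,
  "post_stim_s": 2,
  "response_window_s": 3,
  "iti_range_s": [5, 9],
  "refrain_range_s": [5, 25],
  "timeout_s": 20,
  "habituation_interval_s": [30, 300],
  "habituation_water_s": 5,
  "reward_open_s": 2,
  "reward_ml": 0.075,
  "auto_reward_frac": 0,
  "auto_reward_delay_s": 0.5,
  "target_freq_khz": 11.3,
  "nontarget_freq_khz": null,
  "nontarget_frac": 0,
  "probe_frac": 0,
  "level_db": 60,
  "freq_list_khz": null,
  "lick_quantum_s": 0.03,
  "punish_early": true,
  "punish_fa": false,
  "schedule_cap_s": 1800,
  "mouse": {
    "n_mice": 2,
    "spont_rate_light_hz": 0.0005,
    "spont_rate_dark_hz": 0.001,
    "circadian_peak_tod": 11,
    "circadian_sharpness": 0.4,
    "p_hit_given_engaged": 0.053,
    "p_fa_given_engaged": 0.018,
    "p_early": 0.008,
    "latency_mode_s": 1.75,
    "latency_spread": 0.5,
    "engagement_period_h": 0,
    "engagement_depth": 0.8,
    "engagement_phase_h": null,
    "consumption_burst_n": 12,
    "consumption_burst_gap_s": 0.15,
    "contact_dur_dark_s": 600,
    "contact_gap_dark_s": 165,
    "contact_dur_light_s": 2100,
    "contact_gap_light_s": 140,
    "contact_lick_hz": 2
  }
}
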