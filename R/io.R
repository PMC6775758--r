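# Session-log serialization: three CSV tables (licks, stimuli, trials) plus a
# JSON metadata sidecar. Any external lickometer data mapped to the same
# columns is accepted by the analysis functions.

lick_cols <- "t_s"
stim_cols <- c("onset_s", "duration_s", "freq_khz", "level_db", "category")
trial_cols <- c("index", "start_s", "tone_onset_s", "category", "freq_khz",
                "level_db", "first_lick_latency_s", "outcome", "rewarded",
                "auto_rewarded", "timeout_applied", "iti_s", "refrain_s")

fmt_num <- function(x) ifelse(is.na(x), NA, sprintf("%.3f", x))

#' Write a session log to a directory
#'
#' Emits `licks.csv` (`t_s`), `stimuli.csv`, `trials.csv` and `meta.json`
#' (cage id, seed, schedule, config echo, water total). Times are seconds
#' since session start with 3 decimal places; the wall-clock anchor lives in
#' the metadata, keeping the CSVs timezone-free.
#'
#' @param log A `session_log` from [run_session()] or [read_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(log, dir) {
  stopifnot(inherits(log, "session_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  licks <- data.frame(t_s = fmt_num(log$licks))
  utils::write.csv(licks, file.path(dir, "licks.csv"), row.names = FALSE,
                   quote = FALSE)
  st <- log$stimuli
  st$onset_s <- fmt_num(st$onset_s)
  st$duration_s <- fmt_num(st$duration_s)
  utils::write.csv(st, file.path(dir, "stimuli.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- log$trials
  for (cc in c("start_s", "tone_onset_s", "first_lick_latency_s",
               "iti_s", "refrain_s")) {
    tr[[cc]] <- fmt_num(tr[[cc]])
  }
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- unclass(log$config)
  cfg$freq_list_khz <- if (is.null(cfg$freq_list_khz)) NULL else
    cfg$freq_list_khz
  meta <- list(cage_id = log$cage_id, seed = log$seed,
               duration_s = log$duration_s,
               total_water_ml = log$total_water_ml,
               schedule = unclass(log$schedule),
               config = cfg,
               format = "homecage-session/1")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

session_format_error <- function(msg) {
  stop(errorCondition(msg, class = c("homecage_format_error", "error",
                                     "condition")))
}

#' Read a session log from a directory
#'
#' Validates the bundle on the way in: required columns, parseable
#' non-negative times, sorted streams, and lick times on the sensor grid
#' (30 ms by default). Errors name the offending row. `write_session()`
#' followed by `read_session()` is the identity up to 3-decimal float
#' formatting.
#'
#' @param dir Directory holding `licks.csv`, `stimuli.csv`, `trials.csv`,
#'   `meta.json`.
#' @param requantize Accept off-grid lick times by snapping them to the grid
#'   (default `FALSE`: off-grid times are a format error).
#' @return A `session_log`.
#' @export
read_session <- function(dir, requantize = FALSE) {
  need <- c("licks.csv", "stimuli.csv", "trials.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    session_format_error(paste("missing file(s):",
                               paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg_in <- meta$config
  cfg_in <- cfg_in[!vapply(cfg_in, is.null, logical(1))]
  fixed <- cfg_in[setdiff(names(cfg_in), "phase")]
  config <- do.call(task_config, c(list(phase = cfg_in$phase), fixed))
  schedule <- do.call(light_schedule, meta$schedule[c(
    "dark_start_h", "dark_end_h", "session_start_tod_h", "anchor_date")])

  licks_df <- utils::read.csv(file.path(dir, "licks.csv"))
  if (!all(lick_cols %in% names(licks_df))) {
    session_format_error("licks.csv must have column t_s")
  }
  licks <- as.numeric(licks_df$t_s)
  if (anyNA(licks)) {
    session_format_error(paste("licks.csv: unparseable time at row",
                               which(is.na(licks))[1]))
  }
  if (any(licks < 0)) {
    session_format_error(paste("licks.csv: negative time at row",
                               which(licks < 0)[1]))
  }
  if (is.unsorted(licks)) {
    session_format_error(paste("licks.csv: unsorted time at row",
                               which(diff(licks) < 0)[1] + 1L))
  }
  q <- config$lick_quantum_s
  off <- abs(licks / q - round(licks / q)) > 1e-6
  if (any(off)) {
    if (!requantize) {
      session_format_error(paste0("licks.csv: off-grid time at row ",
                                  which(off)[1],
                                  " (use requantize = TRUE to snap)"))
    }
    licks <- quantize_licks(licks, q)
  }

  stimuli <- utils::read.csv(file.path(dir, "stimuli.csv"),
                             colClasses = c(category = "character"))
  if (!all(stim_cols %in% names(stimuli))) {
    session_format_error("stimuli.csv: missing column(s)")
  }
  if (nrow(stimuli) && is.unsorted(stimuli$onset_s)) {
    session_format_error("stimuli.csv: onsets not sorted")
  }
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            colClasses = c(category = "character",
                                           outcome = "character"))
  if (!all(trial_cols %in% names(trials))) {
    session_format_error("trials.csv: missing column(s)")
  }
  new_session_log(meta$cage_id, config, schedule, licks, stimuli, trials,
                  meta$total_water_ml, meta$seed, meta$duration_s)
}

#' Generate the demonstration dataset
#'
#' A small simulated bundle used by the documentation and tests: two cages of
#' two days of detection, one cage of two days of discrimination, and a
#' synthetic speaker magnitude response.
#'
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @return Named list of the emitted paths, invisibly.
#' @export
make_demo_dataset <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (i in 1:2) {
    log <- run_session(task_config("detection"),
                       default_calibration("detection"),
                       duration_s = 2 * 86400, seed = seed * 100 + i,
                       cage_id = sprintf("det%02d", i))
    p <- file.path(out_dir, sprintf("det%02d", i))
    write_session(log, p)
    paths[[sprintf("det%02d", i)]] <- p
  }
  log <- run_session(task_config("discrimination"),
                     default_calibration("discrimination"),
                     duration_s = 2 * 86400, seed = seed * 100 + 3,
                     cage_id = "disc01")
  p <- file.path(out_dir, "disc01")
  write_session(log, p)
  paths$disc01 <- p
  resp <- synthetic_speaker_response()
  rp <- file.path(out_dir, "speaker_response.csv")
  utils::write.csv(data.frame(freq_khz = resp$freq_khz,
                              magnitude_db = resp$magnitude_db),
                   rp, row.names = FALSE, quote = FALSE)
  paths$speaker_response <- rp
  jsonlite::write_json(list(seed = seed, paths = paths,
                            tool = paste0("homecage ",
                                          as.character(utils::packageVersion("homecage")))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
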