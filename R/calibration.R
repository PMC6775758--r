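# Speaker-whitening calibration: invert a measured magnitude response so that
# pure tones presented through the speaker are spectrally flat.

#' Measured (or synthetic) speaker magnitude response
#'
#' @param freq_khz Strictly ascending frequency grid in kHz.
#' @param magnitude_db Magnitude in dB (arbitrary reference), finite.
#' @return An object of class `magnitude_response` (a data frame).
#' @export
magnitude_response <- function(freq_khz, magnitude_db) {
  stopifnot(length(freq_khz) == length(magnitude_db), length(freq_khz) >= 2,
            all(is.finite(freq_khz)), all(is.finite(magnitude_db)),
            all(freq_khz > 0))
  if (is.unsorted(freq_khz, strictly = TRUE)) {
    stop("frequency grid must be strictly ascending", call. = FALSE)
  }
  structure(data.frame(freq_khz = freq_khz, magnitude_db = magnitude_db),
            class = c("magnitude_response", "data.frame"))
}

#' Synthetic speaker response with spectral ripple
#'
#' A reproducible test response over the calibrated band: a raised-cosine
#' ripple in log-frequency (extremal at the band edges, so edge behaviour is
#' well conditioned) plus an optional linear tilt and measurement noise.
#'
#' @param n Grid points (log-spaced).
#' @param f_lo_khz,f_hi_khz Band edges in kHz.
#' @param ripple_db_pp Peak-to-peak ripple in dB.
#' @param ripple_cycles Ripple cycles across the band (in log-frequency).
#' @param tilt_db End-to-end linear tilt in dB.
#' @param noise_sd_db SD of additive Gaussian measurement noise (0 = none).
#' @param seed Seed for the noise draw.
#' @return A [magnitude_response()].
#' @export
synthetic_speaker_response <- function(n = 257, f_lo_khz = 1, f_hi_khz = 45,
                                       ripple_db_pp = 12, ripple_cycles = 2,
                                       tilt_db = 0, noise_sd_db = 0,
                                       seed = 1) {
  u <- seq(0, 1, length.out = n)
  f <- f_lo_khz * (f_hi_khz / f_lo_khz) ^ u
  mag <- (ripple_db_pp / 2) * cos(2 * pi * ripple_cycles * u) + tilt_db * u
  if (noise_sd_db > 0) {
    s <- new_rng_stream(seed)
    mag <- mag + stream_eval(s, function() stats::rnorm(n, 0, noise_sd_db))
  }
  magnitude_response(f, mag)
}

# Fractional-octave box smoother with symmetric edge clipping: at each grid
# point the window is +/- half the bandwidth, shrunk symmetrically near the
# band edges to avoid first-order edge bias.
smooth_octave <- function(freq_khz, mag_db, bandwidth_oct) {
  if (bandwidth_oct <= 0) return(mag_db)
  lf <- log2(freq_khz)
  half <- bandwidth_oct / 2
  vapply(seq_along(lf), function(i) {
    h <- min(half, lf[i] - lf[1], lf[length(lf)] - lf[i])
    if (h <= 0) return(mag_db[i])
    w <- abs(lf - lf[i]) <= h + 1e-12
    mean(mag_db[w])
  }, numeric(1))
}

#' Design a whitening filter for a speaker response
#'
#' Computes the per-frequency gain that flattens the response: the magnitude
#' is smoothed with a fractional-octave box filter (to avoid inverting
#' measurement noise), and the gain at each grid frequency is the band-mean
#' reference level minus the smoothed magnitude. The residual ripple is the
#' max-minus-min of the corrected response (`magnitude + gain`).
#'
#' @param response A [magnitude_response()].
#' @param smoothing_oct Fractional-octave smoothing bandwidth (default 1/6
#'   octave; 0 disables smoothing, giving exact inversion on the grid).
#' @return An object of class `whitening_filter`: list with `freq_khz`,
#'   `gain_db`, `reference_db`, `residual_ripple_db`.
#' @export
design_whitening_filter <- function(response, smoothing_oct = 1 / 6) {
  stopifnot(inherits(response, "magnitude_response"), smoothing_oct >= 0)
  sm <- smooth_octave(response$freq_khz, response$magnitude_db, smoothing_oct)
  ref <- mean(response$magnitude_db)
  gain <- ref - sm
  corrected <- response$magnitude_db + gain
  structure(list(freq_khz = response$freq_khz, gain_db = gain,
                 reference_db = ref,
                 residual_ripple_db = max(corrected) - min(corrected),
                 smoothing_oct = smoothing_oct),
            class = "whitening_filter")
}

#' Gain applied to a pure tone
#'
#' Linear interpolation of the whitening gain in log-frequency.
#'
#' @param filter A [design_whitening_filter()] result.
#' @param freq_khz Tone frequency (vectorised); must lie within the grid span.
#' @return Gain in dB.
#' @export
tone_gain <- function(filter, freq_khz) {
  stopifnot(inherits(filter, "whitening_filter"))
  rng <- range(filter$freq_khz)
  if (any(freq_khz < rng[1] - 1e-12 | freq_khz > rng[2] + 1e-12)) {
    stop(errorCondition(
      sprintf("tone frequency outside the calibrated band [%.3g, %.3g] kHz",
              rng[1], rng[2]),
      class = c("homecage_calibration_error", "error", "condition")))
  }
  stats::approx(log(filter$freq_khz), filter$gain_db, xout = log(freq_khz),
                rule = 1)$y
}

#' Residual magnitude variability of corrected tones
#'
#' Applies the whitening filter to a set of tone frequencies and reports the
#' max-minus-min of the corrected levels (the calibration quality figure;
#' < 1 dB is the usual acceptance bound).
#'
#' @param response A [magnitude_response()].
#' @param filter A [design_whitening_filter()] result for that speaker.
#' @param tone_freq_khz Tone frequencies to check (default: 50 log-spaced
#'   tones across the response span).
#' @return Residual variability in dB.
#' @export
corrected_tone_ripple <- function(response, filter, tone_freq_khz = NULL) {
  if (is.null(tone_freq_khz)) {
    rng <- range(response$freq_khz)
    tone_freq_khz <- rng[1] * (rng[2] / rng[1]) ^ seq(0, 1, length.out = 50)
  }
  mag <- stats::approx(log(response$freq_khz), response$magnitude_db,
                       xout = log(tone_freq_khz), rule = 1)$y
  lvl <- mag + tone_gain(filter, tone_freq_khz)
  max(lvl) - min(lvl)
}

#' @export
print.whitening_filter <- function(x, ...) {
  cat(sprintf("<whitening_filter> %d points, %.3g-%.3g kHz; residual ripple %.3f dB (smoothing %.3g oct)\n",
              length(x$freq_khz), min(x$freq_khz), max(x$freq_khz),
              x$residual_ripple_db, x$smoothing_oct))
  invisible(x)
}
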