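# FFT-based ideal low-pass of a (possibly complex) series: zero all bins with
# |frequency| > cutoff. Segments are long relative to the QRS so the implicit
# periodicity assumption is immaterial.
fft_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- ifelse(f > fs / 2, f - fs, f)
  X[abs(f) > cutoff] <- 0 + 0i
  stats::fft(X, inverse = TRUE) / n
}

#' QRS-band reconstruction by variable-frequency complex demodulation
#'
#' Decomposes the signal with a bank of complex demodulators at center
#' frequencies spaced `fs / vfcdm_spacing_div` apart, extracts each component
#' with a low-pass of half the spacing, and sums back only the components
#' whose center frequencies lie in the QRS band (default 5-25 Hz; the low
#' edge sits below the usual 8 Hz so that wide ectopic QRS complexes keep
#' band energy). The result
#' has the same length as the input, with baseline wander and P/T-wave energy
#' strongly attenuated — the substrate for R-peak detection.
#'
#' @param samples numeric amplitude vector (mV).
#' @param fs sampling frequency (Hz).
#' @param config an [af_config()]; uses `qrs_band_low_hz`, `qrs_band_high_hz`,
#'   `vfcdm_spacing_div`.
#' @return numeric vector, same length as `samples`.
#' @export
reconstruct_qrs_band <- function(samples, fs, config = af_config()) {
  config <- as_af_config(config)
  n <- length(samples)
  if (n < fs) stop("segment too short for QRS-band reconstruction", call. = FALSE)
  x <- samples
  x[!is.finite(x)] <- 0
  x <- x - mean(x)
  spacing <- fs / config$vfcdm_spacing_div
  centers <- seq(spacing, fs / 2 - spacing / 2, by = spacing)
  centers <- centers[centers >= config$qrs_band_low_hz &
                     centers <= config$qrs_band_high_hz]
  if (!length(centers)) stop("QRS band contains no VFCDM component", call. = FALSE)
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (fc in centers) {
    carrier <- exp(-2i * pi * fc * t)
    z <- fft_lowpass(x * carrier, fs, spacing / 2)
    out <- out + 2 * Re(z * Conj(carrier))
  }
  out
}

# Band-pass + analytic-signal envelope, the simpler fallback detector front end
envelope_qrs_band <- function(samples, fs, config = af_config()) {
  config <- as_af_config(config)
  n <- length(samples)
  x <- samples
  x[!is.finite(x)] <- 0
  x <- x - mean(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- ifelse(f > fs / 2, f - fs, f)
  X[abs(f) < config$qrs_band_low_hz | abs(f) > config$qrs_band_high_hz] <- 0 + 0i
  # analytic signal: double positive frequencies, zero negative ones
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 } else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Detect R-peaks in a segment
#'
#' Adaptive-threshold peak picking on the squared (and lightly smoothed)
#' QRS-band reconstruction. The running threshold is `peak_frac` of an
#' exponentially updated estimate of recent peak amplitude; a refractory
#' period of `refractory_s` (default 0.25 s, a 240 bpm ceiling) suppresses
#' double detections, keeping the larger candidate. Accepted peaks are
#' refined to the local maximum of the ORIGINAL signal within `refine_ms`.
#'
#' @param samples original segment samples (mV).
#' @param fs sampling frequency (Hz).
#' @param config an [af_config()]; `detector` selects the "vfcdm"
#'   reconstruction (default) or the "envelope" fallback.
#' @param start_time segment start (s); peak times are reported
#'   record-relative.
#' @return A list of class `"beat_series"`: `r_times` (s), `rr` (s), `hr`
#'   (bpm), `n_beats`, `insufficient` (TRUE when fewer than `min_beats` beats
#'   were found), `lead`, `segment_index`.
#' @export
detect_r_peaks <- function(samples, fs, config = af_config(), start_time = 0,
                           lead = NA_character_, segment_index = NA_integer_) {
  config <- as_af_config(config)
  recon <- switch(config$detector,
    vfcdm = reconstruct_qrs_band(samples, fs, config),
    envelope = envelope_qrs_band(samples, fs, config),
    stop("unknown detector: ", config$detector, call. = FALSE))
  env <- recon^2
  w <- max(3L, round(0.12 * fs))
  env <- stats::filter(env, rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  n <- length(env)
  refr <- round(config$refractory_s * fs)
  is_max <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                     env[2:(n - 1)] >= env[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(empty_beat_series(lead, segment_index))
  spk <- stats::quantile(env[cand], 0.95, names = FALSE)
  if (!is.finite(spk) || spk <= 0) {
    return(empty_beat_series(lead, segment_index))
  }
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (env[i] < config$peak_frac * spk) next
    if (i - last < refr) {
      if (length(peaks) && env[i] > env[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
        last <- i
        spk <- 0.875 * spk + 0.125 * env[i]
      }
      next
    }
    peaks <- c(peaks, i)
    last <- i
    spk <- 0.875 * spk + 0.125 * env[i]
  }
  # refine to the local maximum of the raw signal
  half <- round(config$refine_ms / 1000 * fs)
  raw <- samples
  raw[!is.finite(raw)] <- -Inf
  peaks <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(raw[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after refinement (drop the smaller peak)
  if (length(peaks) > 1L) {
    keep <- rep(TRUE, length(peaks))
    last <- peaks[1]
    for (j in 2:length(peaks)) {
      if (peaks[j] - last < refr) {
        if (raw[peaks[j]] > raw[last]) {
          keep[which(peaks == last)] <- FALSE
          last <- peaks[j]
        } else keep[j] <- FALSE
      } else last <- peaks[j]
    }
    peaks <- peaks[keep]
  }
  r_times <- start_time + (peaks - 1) / fs
  rr <- diff(r_times)
  structure(list(
    r_times = r_times, rr = rr, hr = 60 / rr,
    n_beats = length(r_times),
    insufficient = length(r_times) < config$min_beats,
    lead = lead, segment_index = segment_index
  ), class = "beat_series")
}

empty_beat_series <- function(lead = NA_character_, segment_index = NA_integer_) {
  structure(list(r_times = numeric(0), rr = numeric(0), hr = numeric(0),
                 n_beats = 0L, insufficient = TRUE,
                 lead = lead, segment_index = segment_index),
            class = "beat_series")
}

#' Build a beat series from known R-peak times
#'
#' Useful for feeding reference beat times (e.g. synthetic ground truth)
#' through the rhythm stages.
#' @param r_times strictly increasing R-peak instants (s).
#' @return A `"beat_series"`.
#' @export
beat_series_from_times <- function(r_times, lead = NA_character_,
                                   segment_index = NA_integer_,
                                   min_beats = 10) {
  if (is.unsorted(r_times, strictly = TRUE)) {
    stop("`r_times` must be strictly increasing", call. = FALSE)
  }
  rr <- diff(r_times)
  structure(list(r_times = r_times, rr = rr, hr = 60 / rr,
                 n_beats = length(r_times),
                 insufficient = length(r_times) < min_beats,
                 lead = lead, segment_index = segment_index),
            class = "beat_series")
}

#' RR and heart-rate difference series
#'
#' @param beats a `"beat_series"` with at least 3 R-peaks.
#' @return A list: `rr` (s, length n-1), `hr` (bpm, length n-1), `dhr`
#'   (successive heart-rate differences, bpm, length n-2).
#' @export
rr_series <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (beats$n_beats < 3L) stop("need at least 3 R-peaks", call. = FALSE)
  list(rr = beats$rr, hr = beats$hr, dhr = diff(beats$hr))
}
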