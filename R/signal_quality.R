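#' Signal-quality assessment of a short ECG sub-window
#'
#' Rule-based quality index applied to fixed sub-windows (default 5 s) before
#' any rhythm analysis. A sub-window is flagged noisy if ANY of four checks
#' fires:
#' \enumerate{
#'   \item flat-line: sample variance below `flatline_var_floor`, more than
#'     `flatline_rep_frac` identical consecutive samples, or any NaN (dropout);
#'   \item clipping: more than `clip_frac` of samples pinned at the rails
#'     (the extreme quantiles of the window);
#'   \item spectral distortion: power fraction in the 5-40 Hz ECG band below
#'     `bandpower_min` (baseline wander / low-frequency artifact dominance) or
#'     power fraction above 40 Hz exceeding `hf_frac_max` (EMG / broadband
#'     noise dominance);
#'   \item amplitude outliers: robust z-score of the largest local-peak
#'     amplitude against the window's other peak amplitudes above
#'     `amp_z_max` (electrode motion spikes dwarfing the QRS complexes).
#' }
#'
#' @param samples numeric amplitude vector (mV), at least 2 s of data.
#' @param fs sampling frequency (Hz).
#' @param config an [af_config()] (or named-list overrides).
#' @return A list: `clean` (logical) and `scores` (named numeric vector of the
#'   component statistics, for logging).
#' @export
assess_subwindow <- function(samples, fs, config = af_config()) {
  config <- as_af_config(config)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  n <- length(samples)
  if (n < 2 * fs) stop("sub-window must contain at least 2 s of samples", call. = FALSE)

  nan_frac <- mean(!is.finite(samples))
  if (nan_frac > 0) {
    return(list(clean = FALSE, scores = c(
      nan_frac = nan_frac, var = NA, rep_frac = NA, clip_frac = NA,
      band_frac = NA, hf_frac = NA, amp_z = NA)))
  }
  v <- stats::var(samples)
  rep_frac <- mean(diff(samples) == 0)
  flat <- v < config$flatline_var_floor || rep_frac > config$flatline_rep_frac

  # clipping: a mass of samples pinned exactly at the rails
  rng <- diff(range(samples))
  clipf <- (sum(samples == max(samples)) + sum(samples == min(samples))) / n
  clipped <- rng > 0 && clipf > config$clip_frac

  x <- samples - mean(samples)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  ptot <- sum(p[half][freqs[half] > 0])
  band_frac <- if (ptot > 0) sum(p[half & freqs >= 5 & freqs <= 40]) / ptot else 0
  hf_frac <- if (ptot > 0) sum(p[half & freqs > 40]) / ptot else 0
  spectral <- band_frac < config$bandpower_min || hf_frac > config$hf_frac_max

  # amplitude outliers among local peaks (electrode-motion spikes): compare
  # each peak of |x| against the population of peaks, not against baseline
  amp_z <- 0
  pk <- peak_amplitudes(abs(x - stats::median(x)), fs)
  if (length(pk) >= 4L) {
    mad_ <- stats::mad(pk)
    amp_z <- if (mad_ > 0) (max(pk) - stats::median(pk)) / mad_
             else if (max(pk) > stats::median(pk)) Inf else 0
  }
  outlier <- is.infinite(amp_z) || amp_z > config$amp_z_max

  noisy <- flat || clipped || spectral || outlier
  list(clean = !noisy,
       scores = c(nan_frac = nan_frac, var = v, rep_frac = rep_frac,
                  clip_frac = clipf, band_frac = band_frac, hf_frac = hf_frac,
                  amp_z = amp_z))
}

# Local maxima of a rectified signal with a 200 ms minimum separation;
# returns their amplitudes (used by the amplitude-outlier check).
peak_amplitudes <- function(ax, fs, min_sep_s = 0.2) {
  n <- length(ax)
  if (n < 3L) return(numeric(0))
  is_max <- c(FALSE, ax[2:(n - 1)] > ax[1:(n - 2)] & ax[2:(n - 1)] >= ax[3:n], FALSE)
  idx <- which(is_max)
  if (!length(idx)) return(numeric(0))
  sep <- round(min_sep_s * fs)
  keep <- integer(0)
  for (i in idx[order(-ax[idx])]) {
    if (all(abs(i - keep) >= sep)) keep <- c(keep, i)
  }
  ax[sort(keep)]
}

#' Segment-level quality report
#'
#' Splits a 2-minute segment into `subwindow_s`-second sub-windows, assesses
#' each, and calls the segment usable when a strict majority (>
#' `usable_threshold` fraction) of sub-windows are clean.
#'
#' @param seg a segment from [segment_record()], or a bare numeric vector.
#' @param fs sampling frequency (Hz); taken from `config` callers.
#' @param config an [af_config()].
#' @return A list of class `"quality_report"`: `segment_index`, `lead`,
#'   `subwindow_flags` (logical), `clean_fraction`, `usable`.
#' @export
assess_segment <- function(seg, fs, config = af_config()) {
  config <- as_af_config(config)
  samples <- if (is.list(seg)) seg$samples else seg
  spw <- round(config$subwindow_s * fs)
  k <- length(samples) %/% spw
  if (k < 1L) stop("segment shorter than one sub-window", call. = FALSE)
  flags <- vapply(seq_len(k) - 1L, function(i) {
    assess_subwindow(samples[(i * spw + 1L):((i + 1L) * spw)], fs, config)$clean
  }, logical(1))
  cf <- mean(flags)
  structure(list(
    segment_index = if (is.list(seg)) seg$index else NA_integer_,
    lead = if (is.list(seg)) seg$lead else NA_character_,
    subwindow_flags = flags,
    clean_fraction = cf,
    usable = cf > config$usable_threshold
  ), class = "quality_report")
}

#' Record-level analyzability
#'
#' A record can be run through the AF detector only if at least one run of
#' `k` consecutive usable segments exists on some lead — the minimum evidence
#' the episode rule (3 consecutive 2-minute segments) can ever act on.
#' Records failing this are reported as unanalyzable rather than scored.
#'
#' @param reports list of [assess_segment()] reports for one lead, ordered by
#'   segment index (or a logical vector of usable flags).
#' @param k minimum run length (default 3).
#' @return logical scalar.
#' @export
record_analyzable <- function(reports, k = 3) {
  flags <- if (is.logical(reports)) reports else
    vapply(reports, function(r) isTRUE(r$usable), logical(1))
  if (!length(flags)) return(FALSE)
  r <- rle(flags)
  any(r$values & r$lengths >= k)
}
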