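# Premature-beat (PAC/PVC) vs AF discrimination for segments the sample
# entropy screen flagged as possible AF. Two independent evidence streams:
# the geometry of the Poincare plot of heart-rate differences, and the
# P-to-R-wave ratio from an EMD-based P-wave detector.

#' Poincare ectopy score of a heart-rate difference series
#'
#' Premature beats produce a stereotyped short-long RR signature: a jump in
#' heart rate followed by an opposite jump of nearly equal size as the
#' compensatory pause returns the rhythm to baseline. In the Poincare plot of
#' successive heart-rate differences (\eqn{\Delta HR_i} vs
#' \eqn{\Delta HR_{i+1}}) this places points in repeated lobes off the
#' origin, whereas AF scatters diffusely. A point i is an ectopy-lobe point
#' when (1) either coordinate exceeds `d_min_bpm`, (2) the two coordinates
#' have opposite signs (the +/- or -/+ limb pattern), and (3) the pair nearly
#' closes: \eqn{|\Delta HR_i + \Delta HR_{i+1}| <
#' tol \cdot \max(|\Delta HR_i|, |\Delta HR_{i+1}|)}. The score is the
#' fraction of large-deflection points that are ectopy-lobe points.
#'
#' @param dhr successive heart-rate differences (bpm), length >= 10.
#' @param config an [af_config()]; uses `d_min_bpm`, `closure_tol`.
#' @return triangular score in \[0, 1\] (0 when no point exceeds
#'   `d_min_bpm`).
#' @export
poincare_ectopy_score <- function(dhr, config = af_config()) {
  config <- as_af_config(config)
  if (length(dhr) < 10L) stop("need at least 10 heart-rate differences", call. = FALSE)
  a <- dhr[-length(dhr)]
  b <- dhr[-1L]
  big <- pmax(abs(a), abs(b)) > config$d_min_bpm
  if (!any(big)) return(0)
  opposite <- sign(a) * sign(b) < 0
  closure <- abs(a + b) < config$closure_tol * pmax(abs(a), abs(b))
  sum(big & opposite & closure) / sum(big)
}

#' Poincare plot points of a heart-rate difference series
#' @param dhr successive heart-rate differences (bpm).
#' @return two-column matrix of (dHR_i, dHR_{i+1}) pairs.
#' @export
poincare_points <- function(dhr) {
  cbind(dhr_i = dhr[-length(dhr)], dhr_next = dhr[-1L])
}

# ---- empirical mode decomposition --------------------------------------

# Standard sifting EMD with cubic-spline envelopes through the local extrema
# (endpoints appended to both envelopes). Stops a sift when the normalized
# squared change falls below sd_tol; stops decomposing when the residual has
# fewer than 3 interior extrema or max_imfs is reached.
emd_decompose <- function(x, max_imfs = 8, max_sift = 10, sd_tol = 0.3) {
  n <- length(x)
  idx <- seq_len(n)
  imfs <- list()
  res <- x
  for (k in seq_len(max_imfs)) {
    h <- res
    for (s in seq_len(max_sift)) {
      d <- diff(h)
      up <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L   # local maxima
      dn <- which(d[-length(d)] < 0 & d[-1L] >= 0) + 1L   # local minima
      if (length(up) + length(dn) < 3L) {
        if (s == 1L) return(list(imfs = imfs, residual = res))
        break
      }
      ui <- unique(c(1L, up, n)); di <- unique(c(1L, dn, n))
      eu <- stats::spline(ui, h[ui], xout = idx)$y
      ed <- stats::spline(di, h[di], xout = idx)$y
      m <- (eu + ed) / 2
      h_new <- h - m
      crit <- sum(m^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (crit < sd_tol) break
    }
    imfs[[k]] <- h
    res <- res - h
    d <- diff(res)
    if (sum(d[-length(d)] * d[-1L] < 0) < 3L) break   # residual ~ monotone/trend
  }
  list(imfs = imfs, residual = res)
}

# Dominant frequency of a component from its zero-crossing rate (Hz)
dominant_freq <- function(x, fs) {
  x <- x - mean(x)
  zc <- sum(x[-length(x)] * x[-1L] < 0)
  zc / 2 * fs / length(x)
}

#' P-wave detection by empirical mode decomposition
#'
#' Blanks the QRS complexes (linear interpolation across R +/- 60 ms) and
#' the T-wave zone, decomposes the remainder by EMD, reconstructs a P-band
#' signal from the intrinsic mode functions whose dominant frequencies fall
#' in `p_band_hz` (default 1.5-15 Hz), and searches each pre-R window
#' (`[R - p_window_ms[1], R - p_window_ms[2]]`, default \[R-280, R-80\] ms)
#' for a positive deflection exceeding `p_amp_frac` of the median R
#' amplitude. AF segments, whose P-waves are replaced by low-amplitude
#' fibrillatory waves, yield low P-to-R ratios.
#'
#' @param samples original segment samples (mV).
#' @param fs sampling frequency (Hz).
#' @param beats a `"beat_series"` for the segment (record-relative times).
#' @param config an [af_config()].
#' @param start_time segment start time (s) used to map beat times to sample
#'   indices.
#' @return A list: `p_count`, `r_count`, `p_to_r` (capped at 1).
#' @export
detect_p_waves <- function(samples, fs, beats, config = af_config(),
                           start_time = NULL) {
  config <- as_af_config(config)
  stopifnot(inherits(beats, "beat_series"))
  n <- length(samples)
  if (is.null(start_time)) {
    start_time <- if (length(beats$r_times)) floor(min(beats$r_times) / 120) * 120 else 0
  }
  r_idx <- round((beats$r_times - start_time) * fs) + 1L
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]
  if (!length(r_idx)) return(list(p_count = 0L, r_count = 0L, p_to_r = 0))

  x <- samples
  x[!is.finite(x)] <- 0
  baseline <- stats::median(x)
  r_amp <- stats::median(abs(x[r_idx] - baseline))

  # blank the QRS complex and the T-wave zone so neither leaks into the P
  # band: at short RR the preceding T-wave would otherwise invade the pre-R
  # search window and mimic a P deflection
  xb <- x
  blank_span <- function(xb, lo, hi) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (lo >= hi) return(xb)
    xb[lo:hi] <- xb[lo] + (xb[hi] - xb[lo]) * (0:(hi - lo)) / (hi - lo)
    xb
  }
  for (i in r_idx) xb <- blank_span(xb, i - round(0.06 * fs), i + round(0.06 * fs))
  for (i in r_idx) xb <- blank_span(xb, i + round(0.14 * fs), i + round(0.44 * fs))
  # suppress EMG-band noise before sifting; otherwise the first intrinsic
  # mode absorbs broadband noise and mixes the P-waves into excluded modes
  xb <- Re(fft_lowpass(xb - mean(xb), fs, 20))

  dec <- tryCatch(emd_decompose(xb),
                  error = function(e) NULL)
  if (is.null(dec) || !length(dec$imfs)) {
    warning("EMD failed on degenerate input; reporting no P-waves")
    return(list(p_count = 0L, r_count = length(r_idx), p_to_r = 0))
  }
  fdom <- vapply(dec$imfs, dominant_freq, numeric(1), fs = fs)
  sel <- fdom >= config$p_band_hz[1] & fdom <= config$p_band_hz[2]
  if (!any(sel)) {
    return(list(p_count = 0L, r_count = length(r_idx), p_to_r = 0))
  }
  pband <- Reduce(`+`, dec$imfs[sel])

  w_lo <- round(config$p_window_ms[1] / 1000 * fs)
  w_hi <- round(config$p_window_ms[2] / 1000 * fs)
  thr <- config$p_amp_frac * r_amp
  p_count <- 0L
  for (i in r_idx) {
    lo <- i - w_lo; hi <- i - w_hi
    if (lo < 1L) next
    if (max(pband[lo:hi]) >= thr) p_count <- p_count + 1L
  }
  list(p_count = p_count, r_count = length(r_idx),
       p_to_r = min(1, p_count / length(r_idx)))
}

#' Adjudicate a possible-AF segment: true AF or premature-beat mimic
#'
#' In "poincare_only" mode a segment is demoted to ECTOPY when its
#' triangular Poincare score reaches `tri_threshold`. In
#' "poincare_plus_pwave" mode either evidence stream can veto AF: a high
#' triangular score OR a high P-to-R ratio (AF should have absent P-waves)
#' yields ECTOPY. This stage only ever demotes possible-AF segments, so
#' specificity is monotone non-decreasing across modes.
#'
#' @param triangular_score Poincare score in \[0, 1\] (NA treated as 0).
#' @param p_to_r P-to-R ratio in \[0, 1\] (NA treated as 0).
#' @param config an [af_config()]; uses `tri_threshold`, `pr_threshold`,
#'   `mode`.
#' @param mode override of `config$mode`.
#' @return "AF" or "ECTOPY".
#' @export
adjudicate <- function(triangular_score, p_to_r = NA_real_,
                       config = af_config(), mode = NULL) {
  config <- as_af_config(config)
  if (is.null(mode)) mode <- config$mode
  mode <- match.arg(mode, c("none", "poincare_only", "poincare_plus_pwave"))
  ts <- if (is.na(triangular_score)) 0 else triangular_score
  pr <- if (is.na(p_to_r)) 0 else p_to_r
  ect <- switch(mode,
    none = FALSE,
    poincare_only = ts >= config$tri_threshold,
    poincare_plus_pwave = ts >= config$tri_threshold || pr >= config$pr_threshold)
  if (ect) "ECTOPY" else "AF"
}
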