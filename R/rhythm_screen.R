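#' Sample entropy of a numeric series
#'
#' SampEn(m, r, N) = -ln(A/B), where B counts pairs of distinct length-`m`
#' templates whose Chebyshev distance is <= `r`, and A counts the same for
#' length `m + 1`. Templates are taken at starts 1..N-m so that every
#' length-`m` template has a length-`m+1` extension, and self-matches are
#' excluded. Higher values mean a more irregular series; AF RR series are
#' expected to score above sinus rhythm.
#'
#' Degenerate outcomes follow the conditional-probability reading: if no
#' length-`m+1` pair matches (A = 0) while B > 0 the series is "maximally
#' irregular" and `Inf` is returned; if no length-`m` pair matches (B = 0)
#' the statistic is undefined and `NA` is returned.
#'
#' @param series numeric vector, length >= m + 2.
#' @param m template length (beats).
#' @param r tolerance, same units as `series` (> 0).
#' @return non-negative number, `Inf`, or `NA` (undefined).
#' @examples
#' sample_entropy(rep(0.8, 50), m = 1, r = 0.05)  # 0: perfectly regular
#' @export
sample_entropy <- function(series, m = 1, r = 0.03) {
  n <- length(series)
  if (!is.numeric(series) || n < m + 2) {
    stop("series too short: need at least m + 2 points", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("`r` must be a positive tolerance", call. = FALSE)
  }
  nt <- n - m
  idx <- seq_len(nt)
  D <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    v <- series[idx + k]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  Bm <- D <= r
  vA <- series[idx + m]
  Am <- pmax(D, abs(outer(vA, vA, "-"))) <= r
  B <- (sum(Bm) - nt) / 2  # exclude self-matches, count unordered pairs
  A <- (sum(Am) - nt) / 2
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

#' Initial AF screening of a segment from its RR series
#'
#' Computes the sample entropy of the segment's RR intervals and labels the
#' segment `POSSIBLE_AF` when it meets or exceeds `af_screen_threshold`,
#' `NOT_AF` otherwise. This screen is deliberately sensitive: segments
#' dominated by premature atrial/ventricular beats also exceed the threshold
#' and are resolved by the downstream ectopy discrimination stage.
#'
#' @param beats a `"beat_series"`.
#' @param config an [af_config()]; uses `sampen_m`, `sampen_r_mode`
#'   ("absolute": `sampen_r` is seconds; "sd_fraction": `sampen_r` times the
#'   RR standard deviation), `sampen_r`, `af_screen_threshold`.
#' @return A list of class `"rhythm_features"`: `sampen`, `m`, `r`,
#'   `n_beats`, `label` in {"NOT_AF", "POSSIBLE_AF", "INSUFFICIENT"}.
#' @export
screen_segment <- function(beats, config = af_config()) {
  config <- as_af_config(config)
  stopifnot(inherits(beats, "beat_series"))
  m <- config$sampen_m
  if (beats$insufficient || beats$n_beats < m + 3) {
    return(structure(list(sampen = NA_real_, m = m, r = NA_real_,
                          n_beats = beats$n_beats, label = "INSUFFICIENT"),
                     class = "rhythm_features"))
  }
  rr <- beats$rr
  r <- switch(config$sampen_r_mode,
    absolute = config$sampen_r,
    sd_fraction = config$sampen_r * stats::sd(rr),
    stop("unknown sampen_r_mode: ", config$sampen_r_mode, call. = FALSE))
  if (!is.finite(r) || r <= 0) {
    # zero-variance RR with sd_fraction tolerance: perfectly regular
    return(structure(list(sampen = 0, m = m, r = r, n_beats = beats$n_beats,
                          label = "NOT_AF"), class = "rhythm_features"))
  }
  se <- sample_entropy(rr, m = m, r = r)
  label <- if (is.na(se)) "INSUFFICIENT"
           else if (se >= config$af_screen_threshold) "POSSIBLE_AF"
           else "NOT_AF"
  structure(list(sampen = se, m = m, r = r, n_beats = beats$n_beats,
                 label = label), class = "rhythm_features")
}
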