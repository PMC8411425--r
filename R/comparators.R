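# Previously published RR-interval AF detectors, run under the same
# segmentation and episode logic as the ensemble for head-to-head comparison.
# Both operate on the raw RR series with no premature-beat discrimination -
# the deficit the ensemble's ectopy stage addresses.

#' Root mean square of successive differences
#' @param rr RR intervals (s), length >= 2.
#' @return RMSSD in seconds.
#' @export
rmssd <- function(rr) {
  if (length(rr) < 2L) stop("need at least 2 RR intervals", call. = FALSE)
  sqrt(mean(diff(rr)^2))
}

#' Normalized Shannon entropy of the RR distribution
#'
#' Trims the `outlier_trim` most extreme values (split across both tails),
#' bins the remainder into `n_bins` equal-width bins, and returns
#' \eqn{-\sum p \log p / \log(n_{bins})}, in \[0, 1\].
#'
#' @param rr RR intervals (s), length >= `n_bins`.
#' @param n_bins number of histogram bins.
#' @param outlier_trim total fraction of extreme values removed before
#'   binning.
#' @return normalized entropy in \[0, 1\]; 0 for a degenerate (constant)
#'   series.
#' @export
shannon_entropy_rr <- function(rr, n_bins = 16, outlier_trim = 0.05) {
  n <- length(rr)
  if (n < n_bins) stop("need at least `n_bins` RR intervals", call. = FALSE)
  k <- floor(n * outlier_trim / 2)
  x <- sort(rr)
  if (k > 0) x <- x[(k + 1):(n - k)]
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  b <- findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1),
                    rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(b, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_bins)
}

#' Turning point ratio
#'
#' Counts interior points that are strict local extrema of the series and
#' normalizes by the random-series expectation 2(n-2)/3, so a fully random
#' series scores about 1. Tied neighbours are not turning points (strict
#' inequalities).
#'
#' @param rr numeric series, length >= 3.
#' @return normalized turning point ratio (>= 0).
#' @export
turning_point_ratio <- function(rr) {
  n <- length(rr)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  a <- rr[1:(n - 2)]; b <- rr[2:(n - 1)]; c <- rr[3:n]
  tp <- sum((b > a & b > c) | (b < a & b < c))
  tp / (2 * (n - 2) / 3)
}

#' Dash-style statistical AF detector for one segment
#'
#' Flags AF when all three RR statistics agree: normalized RMSSD
#' (RMSSD / mean RR) at or above `dash_rmssd_min`, normalized Shannon entropy
#' at or above `dash_she_min`, and normalized turning point ratio inside
#' `dash_tpr_range` (the randomness band around 1).
#'
#' @param rr RR intervals (s) of one segment.
#' @param config an [af_config()].
#' @return A list: `label` ("AF"/"NOT_AF"), `features` (rmssd_norm,
#'   shannon_entropy, tpr), `insufficient` flag.
#' @export
dash_af_detector <- function(rr, config = af_config()) {
  config <- as_af_config(config)
  if (length(rr) < max(config$she_bins, 3L)) {
    return(list(label = "NOT_AF",
                features = c(rmssd_norm = NA, shannon_entropy = NA, tpr = NA),
                insufficient = TRUE))
  }
  rn <- rmssd(rr) / mean(rr)
  she <- shannon_entropy_rr(rr, config$she_bins, config$she_trim)
  tpr <- turning_point_ratio(rr)
  af <- rn >= config$dash_rmssd_min &&
    she >= config$dash_she_min &&
    tpr >= config$dash_tpr_range[1] && tpr <= config$dash_tpr_range[2]
  list(label = if (af) "AF" else "NOT_AF",
       features = c(rmssd_norm = rn, shannon_entropy = she, tpr = tpr),
       insufficient = FALSE)
}

#' Coefficient of sample entropy (COSEn)
#'
#' Rate-corrected sample entropy for short RR series:
#' `SampEn(m, r) + ln(2r) - ln(mean RR)`. Scaling the RR series and `r`
#' by a common factor leaves SampEn unchanged while the two log terms cancel,
#' making COSEn scale-invariant.
#'
#' @param rr RR intervals (s), length >= m + 2.
#' @param m template length.
#' @param r tolerance in seconds.
#' @return COSEn value (can be negative), `Inf`, or `NA` when SampEn is
#'   undefined.
#' @export
cosen <- function(rr, m = 1, r = 0.03) {
  se <- sample_entropy(rr, m = m, r = r)
  se + log(2 * r) - log(mean(rr))
}

#' COSEn AF detector for one segment
#' @param rr RR intervals (s).
#' @param config an [af_config()]; uses `cosen_m`, `cosen_r`,
#'   `cosen_threshold`.
#' @return A list: `label` ("AF"/"NOT_AF"), `cosen`, `insufficient` flag.
#' @export
cosen_af_detector <- function(rr, config = af_config()) {
  config <- as_af_config(config)
  if (length(rr) < config$cosen_m + 2) {
    return(list(label = "NOT_AF", cosen = NA_real_, insufficient = TRUE))
  }
  cs <- cosen(rr, m = config$cosen_m, r = config$cosen_r)
  label <- if (!is.na(cs) && cs >= config$cosen_threshold) "AF" else "NOT_AF"
  list(label = label, cosen = cs, insufficient = FALSE)
}
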