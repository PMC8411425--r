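#' Pipeline configuration
#'
#' Builds the resolved configuration used by every stage of the AF detection
#' pipeline. All tunable constants live here; unknown keys are rejected so a
#' typo in an override cannot silently fall back to a default.
#'
#' Key groups (units in parentheses):
#' \describe{
#'   \item{segmentation}{`segment_length_s` (s), record inclusion bounds
#'     `min_hours`/`max_hours` (h, closed interval).}
#'   \item{signal quality}{`subwindow_s` (s), `usable_threshold` (strict-majority
#'     fraction of clean sub-windows), `flatline_var_floor` (mV^2),
#'     `flatline_rep_frac` (fraction of identical consecutive samples),
#'     `clip_frac` (fraction of samples at rail), `bandpower_min` (minimum
#'     power fraction in the 5-40 Hz ECG band), `hf_frac_max` (maximum power
#'     fraction above 40 Hz), `amp_z_max` (robust z bound on peak amplitudes).}
#'   \item{beat detection}{`detector` ("vfcdm" or "envelope"), `qrs_band_low_hz`,
#'     `qrs_band_high_hz`, `vfcdm_spacing_div` (center-frequency spacing =
#'     fs / this), `refractory_s`, `min_beats` per 2-minute segment,
#'     `refine_ms` (half-window for refining peaks on the raw signal).}
#'   \item{rhythm screen}{`sampen_m`, `sampen_r_mode` ("absolute" seconds or
#'     "sd_fraction"), `sampen_r`, `af_screen_threshold` (on SampEn).}
#'   \item{ectopy discrimination}{`mode` ("none", "poincare_only",
#'     "poincare_plus_pwave"), `d_min_bpm`, `closure_tol`, `tri_threshold`,
#'     `pr_threshold`, `p_window_ms` (search window before R, c(start, end)),
#'     `p_band_hz` (P-wave band), `p_amp_frac` (minimum P amplitude as a
#'     fraction of the median R amplitude), `emd_variant` ("emd").}
#'   \item{episode logic}{`k_consecutive` segments required for an AF episode,
#'     `fusion` ("best_quality_lead" or "any_lead").}
#'   \item{comparators}{Dash-method thresholds `dash_rmssd_min`, `dash_she_min`,
#'     `dash_tpr_range` (normalized turning-point ratio, expectation 1), with
#'     `she_bins`/`she_trim` for the Shannon entropy; COSEn `cosen_m`,
#'     `cosen_r`, `cosen_threshold`.}
#' }
#'
#' @param ... name = value overrides of any default.
#' @return A list of class `"af_config"`.
#' @examples
#' cfg <- af_config(af_screen_threshold = 1.0)
#' cfg$k_consecutive
#' @export
af_config <- function(...) {
  defaults <- list(
    # segmentation / inclusion
    segment_length_s = 120,
    min_hours = 6,
    max_hours = 55,
    # signal quality
    subwindow_s = 5,
    usable_threshold = 0.5,
    flatline_var_floor = 1e-4,
    flatline_rep_frac = 0.5,
    clip_frac = 0.05,
    clip_quantile = 0.999,
    bandpower_min = 0.15,
    hf_frac_max = 0.20,
    amp_z_max = 8,
    # beat detection
    detector = "vfcdm",
    qrs_band_low_hz = 5,
    qrs_band_high_hz = 25,
    vfcdm_spacing_div = 64,
    refractory_s = 0.25,
    min_beats = 10,
    refine_ms = 50,
    peak_frac = 0.3,
    # rhythm screen
    sampen_m = 1,
    sampen_r_mode = "absolute",
    sampen_r = 0.03,
    af_screen_threshold = 1.0,
    # ectopy discrimination
    mode = "poincare_plus_pwave",
    d_min_bpm = 15,
    closure_tol = 0.25,
    tri_threshold = 0.5,
    pr_threshold = 0.6,
    p_window_ms = c(280, 80),
    p_band_hz = c(1.5, 15),
    p_amp_frac = 0.10,
    emd_variant = "emd",
    # episode logic
    k_consecutive = 3,
    fusion = "best_quality_lead",
    # comparators
    dash_rmssd_min = 0.1,
    dash_she_min = 0.7,
    dash_tpr_range = c(0.81, 1.155),
    she_bins = 16,
    she_trim = 0.05,
    cosen_m = 1,
    cosen_r = 0.03,
    cosen_threshold = -1.2,
    # evaluation
    ci_method = "clopper_pearson"
  )
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[nm] <- overrides
  }
  structure(defaults, class = "af_config")
}

#' @export
print.af_config <- function(x, ...) {
  cat("<af_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

as_af_config <- function(config) {
  if (is.null(config)) return(af_config())
  if (inherits(config, "af_config")) return(config)
  if (is.list(config)) return(do.call(af_config, config))
  stop("`config` must be NULL, an af_config, or a named list", call. = FALSE)
}
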