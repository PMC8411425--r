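# End-to-end detection: segmentation -> quality gating -> beat detection ->
# entropy screening -> ectopy discrimination -> lead fusion -> episode logic.

# Classify one segment on one lead. Returns a one-row data.frame of the full
# decision trace. `detector` selects the ensemble or a comparator; the
# comparators share the quality and beat-detection front end but skip the
# screening/ectopy stages (they run on the raw RR series).
classify_segment <- function(seg, fs, config, detector = "ensemble",
                             compute_pwave = TRUE) {
  q <- assess_segment(seg, fs, config)
  row <- data.frame(
    lead = seg$lead, index = seg$index, start_time = seg$start_time,
    clean_fraction = q$clean_fraction, usable = q$usable,
    n_beats = NA_integer_, sampen = NA_real_, screen = NA_character_,
    tri_score = NA_real_, p_to_r = NA_real_, label = "NOISE",
    stringsAsFactors = FALSE
  )
  if (!q$usable) return(row)
  beats <- detect_r_peaks(seg$samples, fs, config, start_time = seg$start_time,
                          lead = seg$lead, segment_index = seg$index)
  row$n_beats <- beats$n_beats
  if (beats$insufficient) {
    row$label <- "INSUFFICIENT"
    return(row)
  }
  if (detector == "dash") {
    row$label <- dash_af_detector(beats$rr, config)$label
    return(row)
  }
  if (detector == "cosen") {
    row$label <- cosen_af_detector(beats$rr, config)$label
    return(row)
  }
  feat <- screen_segment(beats, config)
  row$sampen <- feat$sampen
  row$screen <- feat$label
  if (feat$label != "POSSIBLE_AF") {
    row$label <- feat$label
    return(row)
  }
  dhr <- diff(beats$hr)
  if (length(dhr) >= 10L) {
    row$tri_score <- poincare_ectopy_score(dhr, config)
  }
  if (compute_pwave) {
    pw <- detect_p_waves(seg$samples, fs, beats, config,
                         start_time = seg$start_time)
    row$p_to_r <- pw$p_to_r
  }
  row$label <- adjudicate(row$tri_score, row$p_to_r, config)
  row
}

#' Run the AF detector on one record
#'
#' Executes the full per-segment pipeline on every lead, fuses leads
#' according to `config$fusion`, and applies the consecutive-segment episode
#' rule. A record is analyzable only if some lead offers a run of at least
#' `k_consecutive` usable segments.
#'
#' @param rec an [ecg_record()].
#' @param config an [af_config()].
#' @param detector "ensemble" (default), "dash" or "cosen".
#' @param enforce_inclusion apply [check_inclusion()] and fail on records
#'   outside the 6-55 h window (off by default so short test records run).
#' @return A list of class `"patient_result"`: `record_id`, `analyzable`,
#'   `af_status`, `episodes` (data.frame), `first_onset_s`, `fused_labels`,
#'   `segments` (per-segment decision trace across leads).
#' @export
detect_af <- function(rec, config = af_config(), detector = c("ensemble", "dash", "cosen"),
                      enforce_inclusion = FALSE) {
  config <- as_af_config(config)
  detector <- match.arg(detector)
  if (enforce_inclusion) {
    ok <- check_inclusion(rec, config$min_hours, config$max_hours)
    if (!ok) stop("record excluded: ", attr(ok, "reason"), call. = FALSE)
  }
  segs <- segment_record(rec, config$segment_length_s)
  # P-waves only matter in the full ensemble mode
  pwave <- detector == "ensemble" && config$mode == "poincare_plus_pwave"
  log <- do.call(rbind, lapply(rec$leads, function(ld) {
    do.call(rbind, lapply(segs[[ld]], classify_segment, fs = rec$fs,
                          config = config, detector = detector,
                          compute_pwave = pwave))
  }))
  finalize_result(rec$record_id, log, rec$leads, config)
}

# Fuse the per-lead log into patient-level output.
finalize_result <- function(record_id, log, leads, config) {
  labels_by_lead <- lapply(leads, function(ld) log$label[log$lead == ld])
  clean_by_lead <- lapply(leads, function(ld) log$clean_fraction[log$lead == ld])
  names(labels_by_lead) <- names(clean_by_lead) <- leads
  analyzable <- any(vapply(labels_by_lead, function(l)
    record_analyzable(l != "NOISE", config$k_consecutive), logical(1)))
  fused <- fuse_leads(labels_by_lead, clean_by_lead, config$fusion)
  eps <- find_episodes(fused, config$k_consecutive, config$segment_length_s)
  structure(list(
    record_id = record_id,
    analyzable = analyzable,
    af_status = nrow(eps) > 0,
    episodes = eps,
    first_onset_s = if (nrow(eps)) min(eps$onset_s) else NA_real_,
    fused_labels = fused,
    segments = log
  ), class = "patient_result")
}

#' @export
print.patient_result <- function(x, ...) {
  cat(sprintf("<patient_result> %s: AF=%s, %d episode(s)%s%s\n",
              x$record_id, x$af_status, nrow(x$episodes),
              if (x$af_status) sprintf(", first onset %.0f s", x$first_onset_s) else "",
              if (!x$analyzable) " [UNANALYZABLE]" else ""))
  invisible(x)
}

#' Re-adjudicate a detection log under a different ectopy mode or fusion
#'
#' The expensive per-segment features (quality, beats, sample entropy,
#' Poincare score, P-to-R ratio) do not depend on the ectopy mode or the
#' lead-fusion strategy, so ablation experiments re-derive patient results
#' from a stored decision trace instead of re-running the signal pipeline.
#'
#' @param result a `"patient_result"` from [detect_af()] run in
#'   "poincare_plus_pwave" mode (so that all features are populated).
#' @param mode ectopy mode to re-apply ("none", "poincare_only",
#'   "poincare_plus_pwave").
#' @param fusion lead-fusion strategy to re-apply.
#' @param config an [af_config()].
#' @return A `"patient_result"` under the requested configuration.
#' @export
readjudicate <- function(result, mode = NULL, fusion = NULL,
                         config = af_config()) {
  config <- as_af_config(config)
  if (!is.null(mode)) config$mode <- mode
  if (!is.null(fusion)) config$fusion <- fusion
  log <- result$segments
  poss <- !is.na(log$screen) & log$screen == "POSSIBLE_AF"
  log$label[poss] <- vapply(which(poss), function(i) {
    adjudicate(log$tri_score[i], log$p_to_r[i], config)
  }, character(1))
  leads <- unique(log$lead)
  finalize_result(result$record_id, log, leads, config)
}

#' Run a detector over a synthetic corpus
#'
#' @param corpus output of [build_validation_corpus()] (in-memory form).
#' @param config an [af_config()].
#' @param detector "ensemble", "dash" or "cosen".
#' @return A list: `results` (list of `"patient_result"`), `summary`
#'   (data.frame with record_id, truth, prediction, analyzability, onset
#'   times and onset delta in minutes).
#' @export
run_corpus <- function(corpus, config = af_config(),
                       detector = c("ensemble", "dash", "cosen")) {
  detector <- match.arg(detector)
  config <- as_af_config(config)
  results <- lapply(corpus$cases, function(case) {
    detect_af(case$record, config, detector = detector)
  })
  summarize_runs(results, corpus)
}

summarize_runs <- function(results, corpus) {
  summary <- do.call(rbind, lapply(seq_along(results), function(j) {
    r <- results[[j]]
    case <- corpus$cases[[j]]
    delta <- onset_delta(r$first_onset_s, case$onset_s)
    data.frame(record_id = r$record_id, truth_af = case$af_status,
               pred_af = r$af_status, analyzable = r$analyzable,
               truth_onset_s = case$onset_s, pred_onset_s = r$first_onset_s,
               onset_delta_min = as.numeric(delta),
               stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary)
}

#' Score corpus predictions against ground truth
#'
#' @param summary the `summary` data.frame from [run_corpus()].
#' @param ci_method CI method for [af_metrics()].
#' @return A list: `contingency`, `metrics`, `onset` (onset-delta summary
#'   over true-positive records, or NULL when none).
#' @export
evaluate_corpus <- function(summary, ci_method = "clopper_pearson") {
  pred <- stats::setNames(summary$pred_af, summary$record_id)
  gold <- stats::setNames(summary$truth_af, summary$record_id)
  ct <- contingency(pred, gold, analyzable = stats::setNames(summary$analyzable,
                                                             summary$record_id))
  deltas <- summary$onset_delta_min[summary$truth_af & summary$pred_af &
                                    summary$analyzable]
  deltas <- deltas[!is.na(deltas)]
  list(contingency = ct,
       metrics = af_metrics(ct, ci_method),
       onset = if (length(deltas)) onset_summary(deltas) else NULL)
}

#' Stepwise ablation of the ensemble on a corpus
#'
#' Runs the signal pipeline once with every feature enabled, then
#' re-adjudicates under the stepwise configurations mirroring the
#' algorithm-development sequence: entropy-only screening, + Poincare
#' premature-beat discrimination, + P-wave evidence, and the all-leads
#' fusion variant of the full ensemble.
#'
#' @param corpus output of [build_validation_corpus()].
#' @param config an [af_config()].
#' @return A list with per-mode elements (`entropy_only`, `poincare_only`,
#'   `poincare_plus_pwave`, `all_leads`), each containing `summary`,
#'   `contingency`, `metrics`; plus `accuracy` (named vector) and
#'   `sensitivity` (named vector).
#' @export
ablation_run <- function(corpus, config = af_config()) {
  config <- as_af_config(config)
  config$mode <- "poincare_plus_pwave"
  base <- lapply(corpus$cases, function(case) detect_af(case$record, config))
  modes <- list(
    entropy_only = list(mode = "none", fusion = config$fusion),
    poincare_only = list(mode = "poincare_only", fusion = config$fusion),
    poincare_plus_pwave = list(mode = "poincare_plus_pwave", fusion = config$fusion),
    all_leads = list(mode = "poincare_plus_pwave", fusion = "any_lead")
  )
  out <- lapply(modes, function(md) {
    res <- lapply(base, readjudicate, mode = md$mode, fusion = md$fusion,
                  config = config)
    run <- summarize_runs(res, corpus)
    ev <- evaluate_corpus(run$summary)
    list(summary = run$summary, contingency = ev$contingency,
         metrics = ev$metrics, onset = ev$onset)
  })
  get_metric <- function(m, which) m$metrics$estimate[m$metrics$metric == which]
  out$accuracy <- vapply(out[names(modes)], get_metric, numeric(1), which = "accuracy")
  out$sensitivity <- vapply(out[names(modes)], get_metric, numeric(1), which = "sensitivity")
  out
}
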