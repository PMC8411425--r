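#' Find AF episodes from a per-segment label sequence
#'
#' An AF episode is a maximal run of consecutive segments labelled "AF" with
#' run length >= `k` (default 3 two-minute segments = 6 minutes of continuous
#' AF). Any other label — including "NOISE" and "INSUFFICIENT" — breaks a
#' run: the rule demands continuous AF evidence. Episode onset is the start
#' time of the run's first segment; offset is the end of its last segment.
#'
#' @param labels character vector of per-segment labels ordered by segment
#'   index (0-based segment i covers `[i*L, (i+1)*L)`).
#' @param k minimum run length in segments.
#' @param L segment length in seconds.
#' @return A data.frame with columns `onset_s`, `offset_s`, `n_segments`
#'   (zero rows when no episode qualifies).
#' @examples
#' find_episodes(c("NOT_AF", "AF", "AF", "AF", "NOT_AF"))
#' @export
find_episodes <- function(labels, k = 3, L = 120) {
  r <- rle(labels == "AF")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= k)
  data.frame(
    onset_s = (starts[sel] - 1L) * L,
    offset_s = ends[sel] * L,
    n_segments = r$lengths[sel]
  )
}

#' Fuse per-lead segment labels into one label sequence
#'
#' Two strategies:
#' \describe{
#'   \item{best_quality_lead}{per segment, take the label of the lead with
#'     the highest clean fraction (ties go to the first lead in record
#'     order) — the primary single-lead configuration;}
#'   \item{any_lead}{a segment is AF if ANY usable lead calls AF — the
#'     exploratory all-leads configuration, whose AF set is by construction
#'     a superset of every single lead's.}
#' }
#' Segments with no usable lead are labelled "NOISE".
#'
#' @param labels_by_lead named list (by lead) of equal-length label vectors;
#'   "NOISE" marks an unusable lead-segment.
#' @param clean_frac_by_lead named list of equal-length numeric clean
#'   fractions.
#' @param strategy "best_quality_lead" or "any_lead".
#' @return character vector of fused labels.
#' @export
fuse_leads <- function(labels_by_lead, clean_frac_by_lead,
                       strategy = c("best_quality_lead", "any_lead")) {
  strategy <- match.arg(strategy)
  stopifnot(length(labels_by_lead) >= 1L,
            length(labels_by_lead) == length(clean_frac_by_lead))
  n <- unique(lengths(labels_by_lead))
  if (length(n) != 1L || !all(lengths(clean_frac_by_lead) == n)) {
    stop("all leads must share the same segment indexing", call. = FALSE)
  }
  lab <- do.call(rbind, labels_by_lead)       # leads x segments
  cf <- do.call(rbind, clean_frac_by_lead)
  vapply(seq_len(n), function(j) {
    usable <- lab[, j] != "NOISE"
    if (!any(usable)) return("NOISE")
    if (strategy == "any_lead" && any(lab[usable, j] == "AF")) return("AF")
    best <- which.max(cf[, j])                 # ties -> first lead
    if (!usable[best]) best <- which(usable)[which.max(cf[usable, j])]
    lab[best, j]
  }, character(1))
}

#' Onset-time difference between algorithm and reference
#'
#' @param algorithm_onset,reference_onset onset times in record-relative
#'   seconds; `NA` when the corresponding side did not call AF.
#' @return signed difference in minutes (positive = algorithm late), or `NA`
#'   with attribute `undefined = TRUE` when either onset is missing.
#' @export
onset_delta <- function(algorithm_onset, reference_onset) {
  if (is.null(algorithm_onset) || is.null(reference_onset) ||
      is.na(algorithm_onset) || is.na(reference_onset)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (algorithm_onset - reference_onset) / 60
}
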