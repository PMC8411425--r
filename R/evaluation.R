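#' 2x2 contingency table against a gold standard
#'
#' @param pred named logical vector of predicted patient-level AF status.
#' @param gold named logical vector of gold-standard AF status over the same
#'   patients (no missing values).
#' @param analyzable optional named logical vector; patients the detector
#'   could not analyze are excluded from the cells and counted in
#'   `n_excluded` (they are reported, not silently dropped).
#' @return A list of class `"contingency_result"`: `tp`, `fp`, `fn`, `tn`,
#'   `n`, `n_excluded`, `excluded_ids`.
#' @export
contingency <- function(pred, gold, analyzable = NULL) {
  if (!is.null(names(pred)) && !is.null(names(gold))) {
    if (!setequal(names(pred), names(gold))) {
      stop("mismatched patient sets between predictions and gold standard",
           call. = FALSE)
    }
    gold <- gold[names(pred)]
    if (!is.null(analyzable)) analyzable <- analyzable[names(pred)]
  } else if (length(pred) != length(gold)) {
    stop("predictions and gold standard differ in length", call. = FALSE)
  }
  if (anyNA(gold)) stop("gold standard contains missing values", call. = FALSE)
  keep <- if (is.null(analyzable)) rep(TRUE, length(pred)) else analyzable
  excluded_ids <- if (!is.null(names(pred))) names(pred)[!keep] else which(!keep)
  p <- pred[keep]; g <- gold[keep]
  out <- list(
    tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g),
    n = sum(keep), n_excluded = sum(!keep), excluded_ids = excluded_ids
  )
  class(out) <- "contingency_result"
  out
}

#' Construct a contingency result from cell counts
#' @param tp,fp,fn,tn nonnegative cell counts.
#' @export
contingency_from_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn,
                 n_excluded = 0L, excluded_ids = character(0)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency> tp=%d fp=%d fn=%d tn=%d (n=%d, excluded=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n, x$n_excluded))
  invisible(x)
}

#' Binomial confidence interval
#'
#' @param x successes, `n` trials.
#' @param method "clopper_pearson" (exact, default) or "wilson" (score).
#' @param conf confidence level.
#' @return numeric length-2 vector (lower, upper).
#' @export
binom_ci <- function(x, n, method = c("clopper_pearson", "wilson"),
                     conf = 0.95) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "clopper_pearson") {
    as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- x / n
    den <- 1 + z^2 / n
    mid <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, mid - hw), min(1, mid + hw))
  }
}

#' Diagnostic metrics with 95% confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy from a 2x2 table, each with an exact (Clopper-Pearson) binomial
#' 95% CI by default. Metrics with a zero denominator are returned as `NA`
#' (undefined), never as 0.
#'
#' @param ct a `"contingency_result"`.
#' @param ci_method "clopper_pearson" or "wilson".
#' @return A data.frame with columns `metric`, `x`, `n`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @examples
#' af_metrics(contingency_from_counts(23, 1, 2, 24))
#' @export
af_metrics <- function(ct, ci_method = c("clopper_pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(ct, "contingency_result"))
  cells <- list(
    sensitivity = c(ct$tp, ct$tp + ct$fn),
    specificity = c(ct$tn, ct$tn + ct$fp),
    ppv = c(ct$tp, ct$tp + ct$fp),
    npv = c(ct$tn, ct$tn + ct$fn),
    accuracy = c(ct$tp + ct$tn, ct$n)
  )
  rows <- lapply(names(cells), function(nm) {
    x <- cells[[nm]][1]; n <- cells[[nm]][2]
    if (n == 0) {
      data.frame(metric = nm, x = x, n = n, estimate = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
    } else {
      ci <- binom_ci(x, n, ci_method)
      data.frame(metric = nm, x = x, n = n, estimate = x / n,
                 ci_low = ci[1], ci_high = ci[2])
    }
  })
  do.call(rbind, rows)
}

#' Compare the accuracy of two classifiers
#'
#' With per-patient paired correctness supplied, performs the exact McNemar
#' test on the discordant pairs (binomial test of the discordant split
#' against 0.5). Without pairing, falls back to Fisher's exact test on the
#' two correct/incorrect counts.
#'
#' @param ct_a,ct_b `"contingency_result"` objects for the two classifiers
#'   (same gold standard).
#' @param paired_correct optional list/data.frame with logical elements `a`
#'   and `b`: per-patient correctness of each classifier over the same
#'   patients.
#' @return A list: `p_value`, `method`, `discordant` (named counts, paired
#'   only).
#' @export
compare_accuracy <- function(ct_a, ct_b, paired_correct = NULL) {
  if (!is.null(paired_correct)) {
    a <- paired_correct$a; b <- paired_correct$b
    stopifnot(is.logical(a), is.logical(b), length(a) == length(b))
    if (length(a) < 2L) stop("need at least 2 paired patients", call. = FALSE)
    b10 <- sum(a & !b)  # a correct, b wrong
    b01 <- sum(!a & b)
    if (b10 + b01 == 0L) {
      return(list(p_value = 1.0, method = "mcnemar_exact",
                  discordant = c(a_only = 0L, b_only = 0L)))
    }
    p <- stats::binom.test(b10, b10 + b01, p = 0.5)$p.value
    list(p_value = p, method = "mcnemar_exact",
         discordant = c(a_only = b10, b_only = b01))
  } else {
    stopifnot(inherits(ct_a, "contingency_result"),
              inherits(ct_b, "contingency_result"))
    tab <- matrix(c(ct_a$tp + ct_a$tn, ct_a$n - ct_a$tp - ct_a$tn,
                    ct_b$tp + ct_b$tn, ct_b$n - ct_b$tp - ct_b$tn),
                  nrow = 2, byrow = TRUE)
    list(p_value = stats::fisher.test(tab)$p.value, method = "fisher_exact",
         discordant = NULL)
  }
}

#' Summary of onset-time differences
#'
#' @param deltas signed onset differences in minutes (NAs from undefined
#'   comparisons are dropped).
#' @return A list: `median`, `q25`, `q75` (linear interpolation between
#'   order statistics, i.e. [stats::quantile()] type 7), `n`.
#' @export
onset_summary <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  if (!length(deltas)) stop("no defined onset differences", call. = FALSE)
  q <- stats::quantile(deltas, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(deltas),
       quantile_convention = "linear interpolation (type 7)")
}
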