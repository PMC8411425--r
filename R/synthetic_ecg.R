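# Synthetic multi-lead telemetry ECG with exact ground truth. Beats are
# rendered from Gaussian-bump wave templates (P, Q, R, S, T); rhythm
# structure lives in the RR generator. This is sufficient for everything the
# detector measures - RR statistics, P-wave presence, QRS-band energy -
# while keeping beat-level truth exact.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate an RR-interval sequence for one rhythm epoch
#'
#' Rhythm models:
#' \describe{
#'   \item{NSR}{base interval plus respiratory sinus modulation (0.25 Hz) and
#'     white jitter, coefficient of variation about 3%.}
#'   \item{AF}{independent draws from a two-component lognormal mixture
#'     (short/long interval clusters), serially decorrelated, CV about
#'     20-25% — the irregularly irregular signature.}
#'   \item{BIGEMINY}{every second beat premature: coupling interval
#'     0.6 x base, followed by a compensatory pause 2 x base - coupling, so
#'     the pair sums to two base intervals.}
#'   \item{PAC_SPORADIC / PVC_SPORADIC}{sinus rhythm with premature beats
#'     placed at `ectopy_rate` per minute (no two adjacent), same
#'     coupling/compensatory-pause rule.}
#' }
#'
#' @param rhythm one of "NSR", "AF", "BIGEMINY", "PAC_SPORADIC",
#'   "PVC_SPORADIC".
#' @param epoch_length_s epoch duration (s).
#' @param mean_hr mean heart rate (bpm), must be physiological (20-250).
#' @param ectopy_rate premature beats per minute for the sporadic modes.
#' @param jitter scale factor on all stochastic timing components (0 gives
#'   the deterministic skeleton; 1 is the default calibration).
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return A list: `rr` (s), `beat_types` (length `length(rr) + 1`, values
#'   "SINUS", "PAC", "PVC").
#' @export
generate_rr <- function(rhythm = c("NSR", "AF", "BIGEMINY", "PAC_SPORADIC",
                                   "PVC_SPORADIC"),
                        epoch_length_s, mean_hr = NULL, ectopy_rate = 6,
                        jitter = 1, seed = NULL) {
  rhythm <- match.arg(rhythm)
  if (is.null(mean_hr)) mean_hr <- if (rhythm == "AF") 110 else 75
  if (mean_hr < 20 || mean_hr > 250) {
    stop("nonphysiological mean_hr: ", mean_hr, call. = FALSE)
  }
  with_seed(seed, {
    base <- 60 / mean_hr
    n_max <- ceiling(epoch_length_s / (0.4 * base)) + 4L
    rr <- switch(rhythm,
      NSR = , PAC_SPORADIC = , PVC_SPORADIC = {
        t <- cumsum(rep(base, n_max))
        base * (1 + jitter * 0.04 * sin(2 * pi * 0.25 * t)) +
          jitter * stats::rnorm(n_max, 0, 0.012 * base)
      },
      AF = {
        comp <- stats::runif(n_max) < 0.55
        out <- ifelse(comp,
                      stats::rlnorm(n_max, log(0.85 * base), 0.15),
                      stats::rlnorm(n_max, log(1.25 * base), 0.16))
        pmin(pmax(out, 0.30), 2.5)
      },
      BIGEMINY = {
        ncyc <- ceiling(n_max / 2)
        couple <- 0.6 * base + jitter * stats::rnorm(ncyc, 0, 0.12 * base)
        pause <- 2 * base * (1 + jitter * stats::rnorm(ncyc, 0, 0.02)) - couple +
          jitter * stats::rnorm(ncyc, 0, 0.05 * base)
        c(base, as.vector(rbind(couple, pause)))
      })
    types <- rep("SINUS", length(rr) + 1L)
    if (rhythm == "BIGEMINY") {
      # beats ending the coupling intervals are the premature ones
      types[seq(3L, length(types), by = 2L)] <- "PAC"
    }
    if (rhythm %in% c("PAC_SPORADIC", "PVC_SPORADIC")) {
      q <- min(0.45, ectopy_rate * base / 60)
      ect <- which(stats::runif(length(rr) - 1L) < q) + 1L  # interval index into beat
      ect <- ect[ect < length(rr)]
      ect <- ect[c(TRUE, diff(ect) > 1L)]                   # no two adjacent
      for (i in ect) {
        couple <- 0.6 * base + jitter * stats::rnorm(1, 0, 0.05 * base)
        rr[i] <- couple
        rr[i + 1L] <- 2 * base - couple
        types[i + 1L] <- if (rhythm == "PAC_SPORADIC") "PAC" else "PVC"
      }
    }
    keep <- cumsum(rr) <= epoch_length_s
    rr <- rr[keep]
    list(rr = rr, beat_types = types[seq_len(length(rr) + 1L)])
  })
}

# Add a Gaussian bump of amplitude `amp` (mV) and width `sd_s` centered at
# `center_s` into signal vector `x` (in place value-return).
add_bump <- function(x, fs, center_s, amp, sd_s) {
  n <- length(x)
  c_i <- center_s * fs + 1
  lo <- max(1L, floor(c_i - 4 * sd_s * fs))
  hi <- min(n, ceiling(c_i + 4 * sd_s * fs))
  if (lo > n || hi < 1L || lo > hi) return(x)
  t <- ((lo:hi) - c_i) / fs
  x[lo:hi] <- x[lo:hi] + amp * exp(-t^2 / (2 * sd_s^2))
  x
}

render_beat <- function(x, fs, t, type, p_present, amp_scale = 1) {
  if (type == "PVC") {
    x <- add_bump(x, fs, t, 1.25 * amp_scale, 0.030)            # wide QRS
    x <- add_bump(x, fs, t + 0.06, -0.30 * amp_scale, 0.020)
    x <- add_bump(x, fs, t + 0.32, -0.30 * amp_scale, 0.060)    # discordant T
  } else {
    if (p_present) x <- add_bump(x, fs, t - 0.20, 0.15 * amp_scale, 0.025)
    x <- add_bump(x, fs, t - 0.040, -0.10 * amp_scale, 0.010)
    x <- add_bump(x, fs, t, 1.00 * amp_scale, 0.012)
    x <- add_bump(x, fs, t + 0.040, -0.15 * amp_scale, 0.010)
    x <- add_bump(x, fs, t + 0.30, 0.35 * amp_scale, 0.060)
  }
  x
}

#' Default ICU noise configuration
#'
#' Amplitudes in mV; `dropout_prob` is the per-2-minute-segment probability
#' of a zeroed span of 5-30 s (flat-line dropout).
#' @param baseline_wander,emg,powerline,dropout_prob component levels.
#' @export
noise_config <- function(baseline_wander = 0.10, emg = 0.02,
                         powerline = 0.02, dropout_prob = 0.05) {
  list(baseline_wander = baseline_wander, emg = emg,
       powerline = powerline, dropout_prob = dropout_prob)
}

#' Render a waveform from beat times and types
#'
#' Each beat is drawn from Gaussian-bump templates. Beats inside AF
#' intervals lose their P-wave and a 4-9 Hz fibrillatory baseline is added
#' there; PVC beats use a widened QRS with no P and a discordant T. Noise
#' processes (baseline wander, EMG, powerline, dropout) are generated per
#' lead.
#'
#' @param beat_times R-peak instants (s, record-relative).
#' @param beat_types "SINUS"/"PAC"/"PVC" per beat.
#' @param fs sampling frequency (Hz).
#' @param duration_s record duration (s).
#' @param af_intervals data.frame (start_s, end_s) of AF epochs (may be
#'   empty).
#' @param leads lead names; each lead scales the template amplitudes by the
#'   corresponding `lead_scales` entry.
#' @param lead_scales amplitude scale per lead.
#' @param noise a [noise_config()].
#' @param record_id identifier for the resulting record.
#' @param seed optional integer for reproducible noise.
#' @return A list: `record` (an [ecg_record()]) and `truth` (list with
#'   `beat_times`, `beat_types`, `p_wave_present`, `annotation`).
#' @export
render_waveform <- function(beat_times, beat_types, fs, duration_s,
                            af_intervals = NULL,
                            leads = c("II", "V"), lead_scales = c(1, 0.6),
                            noise = noise_config(), record_id = "synth",
                            seed = NULL) {
  stopifnot(length(beat_times) == length(beat_types))
  with_seed(seed, {
    n <- round(duration_s * fs)
    t_axis <- (seq_len(n) - 1) / fs
    in_af <- rep(FALSE, length(beat_times))
    if (!is.null(af_intervals) && nrow(af_intervals)) {
      for (k in seq_len(nrow(af_intervals))) {
        in_af <- in_af | (beat_times >= af_intervals$start_s[k] &
                          beat_times < af_intervals$end_s[k])
      }
    }
    p_present <- beat_types != "PVC" & !in_af
    amp_jit <- 1 + stats::rnorm(length(beat_times), 0, 0.03)

    sig <- matrix(0, n, length(leads))
    for (L in seq_along(leads)) {
      x <- numeric(n)
      for (b in seq_along(beat_times)) {
        x <- render_beat(x, fs, beat_times[b], beat_types[b], p_present[b],
                         amp_scale = lead_scales[L] * amp_jit[b])
      }
      if (!is.null(af_intervals) && nrow(af_intervals)) {
        ff <- stats::runif(4, 4, 9)
        ph <- stats::runif(4, 0, 2 * pi)
        fib <- rowSums(sapply(1:4, function(k)
          0.025 * sin(2 * pi * ff[k] * t_axis + ph[k])))
        for (k in seq_len(nrow(af_intervals))) {
          span <- t_axis >= af_intervals$start_s[k] & t_axis < af_intervals$end_s[k]
          x[span] <- x[span] + fib[span] * lead_scales[L]
        }
      }
      x <- x + noise$baseline_wander *
        (sin(2 * pi * 0.30 * t_axis + stats::runif(1, 0, 2 * pi)) +
         0.5 * sin(2 * pi * 0.05 * t_axis + stats::runif(1, 0, 2 * pi)))
      x <- x + stats::rnorm(n, 0, noise$emg)
      x <- x + noise$powerline * sin(2 * pi * 50 * t_axis)
      if (noise$dropout_prob > 0) {
        n_seg <- duration_s %/% 120
        for (s in seq_len(n_seg)) {
          if (stats::runif(1) < noise$dropout_prob) {
            len <- stats::runif(1, 5, 30)
            st <- (s - 1) * 120 + stats::runif(1, 0, 120 - len)
            x[t_axis >= st & t_axis < st + len] <- 0
          }
        }
      }
      sig[, L] <- x
    }
    ann <- af_annotation(af_intervals, duration_s)
    list(record = ecg_record(record_id, sig, fs = fs, leads = leads),
         truth = list(beat_times = beat_times, beat_types = beat_types,
                      p_wave_present = p_present, annotation = ann))
  })
}

# Rhythm annotation covering [0, duration): AF intervals as given, the
# complement labelled NOT_AF.
af_annotation <- function(af_intervals, duration_s) {
  if (is.null(af_intervals) || !nrow(af_intervals)) {
    return(rhythm_annotation(0, duration_s, "NOT_AF", "gold"))
  }
  af <- af_intervals[order(af_intervals$start_s), , drop = FALSE]
  starts <- c(); ends <- c(); labs <- c()
  cur <- 0
  for (k in seq_len(nrow(af))) {
    if (af$start_s[k] > cur) {
      starts <- c(starts, cur); ends <- c(ends, af$start_s[k]); labs <- c(labs, "NOT_AF")
    }
    starts <- c(starts, af$start_s[k]); ends <- c(ends, min(af$end_s[k], duration_s))
    labs <- c(labs, "AF")
    cur <- min(af$end_s[k], duration_s)
  }
  if (cur < duration_s) {
    starts <- c(starts, cur); ends <- c(ends, duration_s); labs <- c(labs, "NOT_AF")
  }
  rhythm_annotation(starts, ends, labs, "gold")
}

#' Simulate one telemetry record from a rhythm script
#'
#' @param record_id identifier.
#' @param rhythm_script data.frame with columns `start_s`, `end_s`, `rhythm`
#'   (and optionally `mean_hr`); epochs must partition `[0, duration_s)`.
#' @param duration_s total record length (s).
#' @param fs sampling frequency (Hz).
#' @param ectopy_rate premature beats per minute in sporadic epochs.
#' @param leads,lead_scales,noise passed to [render_waveform()].
#' @param seed optional integer; fixes both rhythm and noise draws.
#' @return As [render_waveform()]: list(record, truth).
#' @export
simulate_record <- function(record_id, rhythm_script, duration_s, fs = 125,
                            ectopy_rate = 6, leads = c("II", "V"),
                            lead_scales = c(1, 0.6), noise = noise_config(),
                            seed = NULL) {
  sc <- rhythm_script[order(rhythm_script$start_s), , drop = FALSE]
  if (sc$start_s[1] != 0 || sc$end_s[nrow(sc)] != duration_s ||
      (nrow(sc) > 1 && any(abs(sc$start_s[-1] - sc$end_s[-nrow(sc)]) > 1e-9))) {
    stop("rhythm_script epochs must partition [0, duration_s)", call. = FALSE)
  }
  with_seed(seed, {
    beat_times <- numeric(0)
    beat_types <- character(0)
    for (k in seq_len(nrow(sc))) {
      len <- sc$end_s[k] - sc$start_s[k]
      hr <- if ("mean_hr" %in% names(sc) && !is.na(sc$mean_hr[k])) sc$mean_hr[k] else NULL
      g <- generate_rr(sc$rhythm[k], epoch_length_s = len, mean_hr = hr,
                       ectopy_rate = ectopy_rate)
      tt <- sc$start_s[k] + 0.4 + cumsum(c(0, g$rr))
      keep <- tt < sc$end_s[k] - 0.05
      beat_times <- c(beat_times, tt[keep])
      beat_types <- c(beat_types, g$beat_types[keep])
    }
    af_int <- sc[sc$rhythm == "AF", c("start_s", "end_s"), drop = FALSE]
    render_waveform(beat_times, beat_types, fs, duration_s,
                    af_intervals = af_int, leads = leads,
                    lead_scales = lead_scales, noise = noise,
                    record_id = record_id)
  })
}

#' Build the synthetic validation corpus
#'
#' Emulates a patient-level validation set: `n_af` records containing an AF
#' episode (sinus onset, then AF to the end of the record, onset uniform in
#' the first 40% of the record) and `n_not_af` AF-free records of which
#' `ectopy_fraction` are ectopy-rich confounders (continuous atrial bigeminy
#' or frequent sporadic premature beats) and the rest clean sinus rhythm.
#'
#' @param n_af,n_not_af record counts.
#' @param ectopy_fraction fraction of non-AF records that are ectopy-rich.
#' @param duration_s record length in seconds (default 6 h, the inclusion
#'   minimum; tests use short records).
#' @param fs sampling frequency (Hz).
#' @param noise a [noise_config()].
#' @param seed integer; the whole corpus is reproducible from it.
#' @param dir optional directory: when given, each record is written as a
#'   WFDB record/header pair with a truth CSV and a manifest JSON, and only
#'   the manifest is returned.
#' @return When `dir` is NULL: list with `cases` (each list(record, truth,
#'   af_status, onset_s, rhythm_class)) and `manifest` (data.frame).
#'   Otherwise the manifest data.frame (invisibly).
#' @export
build_validation_corpus <- function(n_af = 25, n_not_af = 25,
                                    ectopy_fraction = 0.4,
                                    duration_s = 21600, fs = 125,
                                    noise = noise_config(), seed = 17,
                                    dir = NULL) {
  stopifnot(n_af >= 0, n_not_af >= 0, n_af + n_not_af > 0)
  with_seed(seed, {
    n_ect <- round(ectopy_fraction * n_not_af)
    specs <- list()
    for (i in seq_len(n_af)) {
      onset <- stats::runif(1, 0, 0.4 * duration_s)
      specs[[length(specs) + 1L]] <- list(
        id = sprintf("af%02d", i), af = TRUE, onset = onset,
        class = "AF",
        script = data.frame(start_s = c(0, onset), end_s = c(onset, duration_s),
                            rhythm = c("NSR", "AF"),
                            mean_hr = c(stats::runif(1, 60, 90),
                                        stats::runif(1, 95, 130))))
    }
    for (i in seq_len(n_not_af)) {
      if (i <= n_ect) {
        rhythm <- if (i %% 2 == 1) "BIGEMINY" else "PAC_SPORADIC"
        cls <- "ECTOPY"
      } else {
        rhythm <- "NSR"
        cls <- "NSR"
      }
      specs[[length(specs) + 1L]] <- list(
        id = sprintf("ctl%02d", i), af = FALSE, onset = NA_real_, class = cls,
        script = data.frame(start_s = 0, end_s = duration_s, rhythm = rhythm,
                            mean_hr = stats::runif(1, 60, 90)))
    }
    seeds <- sample.int(.Machine$integer.max %/% 2, length(specs))
    cases <- vector("list", length(specs))
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      sim <- simulate_record(sp$id, sp$script, duration_s, fs = fs,
                             ectopy_rate = 8, noise = noise, seed = seeds[j])
      cases[[j]] <- list(record = sim$record, truth = sim$truth,
                         af_status = sp$af, onset_s = sp$onset,
                         rhythm_class = sp$class)
      if (!is.null(dir)) {
        write_wfdb(sim$record, dir)
        utils::write.csv(sim$truth$annotation,
                         file.path(dir, paste0(sp$id, "_rhythm.csv")),
                         row.names = FALSE)
        utils::write.csv(data.frame(beat_time_s = sim$truth$beat_times,
                                    beat_type = sim$truth$beat_types,
                                    p_wave = sim$truth$p_wave_present),
                         file.path(dir, paste0(sp$id, "_beats.csv")),
                         row.names = FALSE)
        cases[[j]]$record <- NULL   # keep memory flat when writing out
        cases[[j]]$truth <- NULL
      }
    }
    manifest <- data.frame(
      record_id = vapply(specs, `[[`, character(1), "id"),
      af_status = vapply(specs, `[[`, logical(1), "af"),
      onset_s = vapply(specs, `[[`, numeric(1), "onset"),
      rhythm_class = vapply(specs, `[[`, character(1), "class"),
      seed = seeds
    )
    if (!is.null(dir)) {
      jsonlite::write_json(
        list(seed = seed, n_af = n_af, n_not_af = n_not_af,
             ectopy_fraction = ectopy_fraction, duration_s = duration_s,
             fs = fs, manifest = manifest),
        file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
      return(invisible(manifest))
    }
    list(cases = cases, manifest = manifest)
  })
}
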