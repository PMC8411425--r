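#' Construct a multi-lead ECG record
#'
#' Container for a continuous multi-lead ECG waveform. All leads must be the
#' same length; amplitudes are in millivolts; `t0` is the absolute start time
#' in seconds (record-relative 0 by default). NaN samples are allowed and are
#' treated as signal dropout by the quality stage.
#'
#' @param record_id character scalar identifier.
#' @param signal numeric matrix, one column per lead, or a named list of
#'   equal-length numeric vectors.
#' @param fs sampling frequency in Hz (> 0).
#' @param leads optional character vector of lead names (defaults to column
#'   names or "lead1", "lead2", ...).
#' @param t0 absolute start time in seconds.
#' @return An object of class `"ecg_record"` with elements `record_id`,
#'   `leads`, `signal` (matrix, samples x leads), `fs`, `t0`.
#' @export
ecg_record <- function(record_id, signal, fs, leads = NULL, t0 = 0) {
  if (is.list(signal) && !is.matrix(signal)) {
    lens <- lengths(signal)
    if (length(unique(lens)) != 1L) {
      stop("all leads must have the same number of samples", call. = FALSE)
    }
    if (is.null(leads)) leads <- names(signal)
    signal <- do.call(cbind, lapply(signal, as.numeric))
  }
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (nrow(signal) == 0L) stop("empty record: zero-length signal", call. = FALSE)
  if (ncol(signal) == 0L) stop("record must have at least one lead", call. = FALSE)
  if (is.null(leads)) leads <- colnames(signal)
  if (is.null(leads)) leads <- paste0("lead", seq_len(ncol(signal)))
  if (length(leads) != ncol(signal)) {
    stop("length of `leads` must match the number of signal columns", call. = FALSE)
  }
  colnames(signal) <- leads
  structure(
    list(record_id = as.character(record_id), leads = as.character(leads),
         signal = signal, fs = fs, t0 = t0),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d lead(s) [%s], %d samples @ %g Hz (%.2f h)\n",
              x$record_id, length(x$leads), paste(x$leads, collapse = ", "),
              nrow(x$signal), x$fs, record_duration_s(x) / 3600))
  invisible(x)
}

#' Record duration in seconds
#' @param rec an `ecg_record`.
#' @return duration in seconds (n samples / fs).
#' @export
record_duration_s <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  nrow(rec$signal) / rec$fs
}

#' Read an ECG record from disk
#'
#' Supports two formats: plain CSV (one column per lead, header row of lead
#' names, amplitudes in mV; `fs_override` is then required) and WFDB
#' record/header pairs (format-16 .dat with a text .hea header; a minimal
#' reader is built in because no installed package provides one). NaN samples
#' are preserved and interpreted as dropout downstream.
#'
#' @param path file path: the CSV file, or the WFDB record name / .hea path.
#' @param format "csv" or "wfdb".
#' @param fs_override sampling frequency in Hz; required for csv, overrides
#'   the header value for wfdb when given.
#' @param record_id identifier; defaults to the file base name.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs_override = NULL,
                        record_id = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(fs_override)) {
      stop("`fs_override` must be given for csv input", call. = FALSE)
    }
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    dat <- utils::read.csv(path, check.names = FALSE)
    if (nrow(dat) == 0L) stop("empty record: zero-length signal", call. = FALSE)
    if (!all(vapply(dat, is.numeric, logical(1)))) {
      stop("format error: non-numeric column in csv signal file", call. = FALSE)
    }
    if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
    ecg_record(record_id, as.matrix(dat), fs = fs_override)
  } else {
    read_wfdb(path, fs_override = fs_override, record_id = record_id)
  }
}

# Minimal WFDB reader: format 16 (16-bit little-endian two's complement),
# single-segment, all leads in one .dat file. Header lines beyond the signal
# specifications and comment lines (#) are ignored.
read_wfdb <- function(path, fs_override = NULL, record_id = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("unreadable header: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3L) stop("format error: malformed WFDB header", call. = FALSE)
  rec_name <- top[1]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*", "", top[3]))
  n_samp <- if (length(top) >= 4L) as.integer(top[4]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1L) stop("format error: bad signal count", call. = FALSE)
  sig_lines <- lines[seq(2L, length.out = n_sig)]
  spec <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  dat_file <- vapply(spec, `[`, character(1), 1L)
  if (length(unique(dat_file)) != 1L) {
    stop("format error: multi-file WFDB records are not supported", call. = FALSE)
  }
  fmt <- vapply(spec, `[`, character(1), 2L)
  if (!all(sub("x.*", "", fmt) == "16")) {
    stop("format error: only WFDB format 16 is supported", call. = FALSE)
  }
  gain <- vapply(spec, function(s) {
    g <- if (length(s) >= 3L) as.numeric(sub("[(/].*", "", s[3])) else NA_real_
    if (is.na(g) || g == 0) 200 else g   # WFDB default gain: 200 adu/mV
  }, numeric(1))
  baseline <- vapply(spec, function(s) {
    if (length(s) >= 3L && grepl("\\(", s[3])) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", s[3]))
    } else 0
  }, numeric(1))
  lead_names <- vapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    if (length(s) >= 9L) paste(s[9:length(s)], collapse = "_") else paste0("sig", i)
  }, character(1))
  dat_path <- file.path(dirname(hea), dat_file[1])
  if (!file.exists(dat_path)) stop("unreadable signal file: ", dat_path, call. = FALSE)
  raw_n <- file.size(dat_path) / 2L
  vals <- readBin(dat_path, integer(), n = raw_n, size = 2L,
                  signed = TRUE, endian = "little")
  if (length(vals) %% n_sig != 0L) vals <- vals[seq_len(length(vals) %/% n_sig * n_sig)]
  m <- matrix(vals, ncol = n_sig, byrow = TRUE)
  if (!is.na(n_samp) && n_samp > 0L && nrow(m) >= n_samp) m <- m[seq_len(n_samp), , drop = FALSE]
  if (nrow(m) == 0L) stop("empty record: zero-length signal", call. = FALSE)
  # WFDB convention: stored value -32768 marks an invalid (missing) sample
  m[m == -32768L] <- NA_real_
  phys <- sweep(sweep(m, 2L, baseline, "-"), 2L, gain, "/")
  if (is.null(record_id)) record_id <- rec_name
  ecg_record(record_id, phys, fs = if (is.null(fs_override)) fs else fs_override,
             leads = lead_names)
}

#' Write an ECG record as a WFDB format-16 record/header pair
#'
#' @param rec an [ecg_record()].
#' @param dir output directory.
#' @param gain analog-to-digital gain in adu/mV.
#' @return Invisibly, the path of the written header file.
#' @export
write_wfdb <- function(rec, dir, gain = 200) {
  stopifnot(inherits(rec, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  name <- rec$record_id
  dat <- paste0(name, ".dat")
  x <- rec$signal * gain
  x[is.na(x)] <- -32768
  x <- round(pmax(pmin(x, 32767), -32768))
  vals <- as.integer(t(x))
  writeBin(vals, file.path(dir, dat), size = 2L, endian = "little")
  hdr <- c(
    sprintf("%s %d %g %d", name, ncol(rec$signal), rec$fs, nrow(rec$signal)),
    vapply(seq_along(rec$leads), function(i) {
      sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", dat, gain, rec$leads[i])
    }, character(1))
  )
  writeLines(hdr, file.path(dir, paste0(name, ".hea")))
  invisible(file.path(dir, paste0(name, ".hea")))
}

#' Record-level inclusion rule
#'
#' Continuous telemetry records are analyzed only when their duration lies in
#' the closed interval \[`min_hours`, `max_hours`\] (default 6-55 h): very
#' short recordings carry too little rhythm evidence and very long ones are
#' typically concatenation artifacts.
#'
#' @param rec an [ecg_record()].
#' @param min_hours,max_hours inclusion bounds in hours.
#' @return A logical scalar with attribute `"reason"` ("" when included,
#'   "too short" / "too long" otherwise).
#' @export
check_inclusion <- function(rec, min_hours = 6, max_hours = 55) {
  stopifnot(inherits(rec, "ecg_record"))
  h <- record_duration_s(rec) / 3600
  if (h < min_hours) {
    structure(FALSE, reason = "too short")
  } else if (h > max_hours) {
    structure(FALSE, reason = "too long")
  } else {
    structure(TRUE, reason = "")
  }
}

#' Slice a record into fixed-length analysis segments
#'
#' Divides each lead into consecutive non-overlapping windows of
#' `segment_length` seconds covering `[i*L, (i+1)*L)`; the trailing partial
#' window is discarded. Indices are 0-based.
#'
#' @param rec an [ecg_record()].
#' @param segment_length window length in seconds (default 120 = 2 minutes).
#' @return A list with one element per lead; each is a list of segments, each
#'   segment a list with `record_id`, `lead`, `index`, `start_time`,
#'   `end_time`, `samples`.
#' @export
segment_record <- function(rec, segment_length = 120) {
  stopifnot(inherits(rec, "ecg_record"))
  spp <- round(segment_length * rec$fs)    # samples per segment
  n <- nrow(rec$signal)
  k <- n %/% spp
  if (k < 1L) {
    stop("record shorter than one segment (", segment_length, " s)", call. = FALSE)
  }
  out <- lapply(rec$leads, function(ld) {
    col <- rec$signal[, ld]
    lapply(seq_len(k) - 1L, function(i) {
      idx <- (i * spp + 1L):((i + 1L) * spp)
      list(record_id = rec$record_id, lead = ld, index = i,
           start_time = i * segment_length,
           end_time = (i + 1) * segment_length,
           samples = col[idx])
    })
  })
  names(out) <- rec$leads
  out
}

#' Rhythm annotation intervals
#'
#' Validates and orders a set of rhythm intervals. Intervals are half-open
#' `[start, end)` in record-relative seconds and must not overlap.
#'
#' @param start_s,end_s numeric vectors of interval bounds (seconds).
#' @param label character vector, each "AF" or "NOT_AF".
#' @param source label provenance: "gold", "nurse", "icd9" or "algorithm".
#' @return A data.frame of class `"rhythm_annotation"` sorted by start, with
#'   columns start_s, end_s, label, source.
#' @export
rhythm_annotation <- function(start_s = numeric(), end_s = numeric(),
                              label = character(), source = "gold") {
  stopifnot(length(start_s) == length(end_s), length(start_s) == length(label))
  if (length(label) && !all(label %in% c("AF", "NOT_AF"))) {
    stop("labels must be AF or NOT_AF", call. = FALSE)
  }
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label),
                   source = rep_len(as.character(source), length(start_s)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)])) {
    stop("validation error: overlapping rhythm intervals", call. = FALSE)
  }
  if (nrow(df) && any(df$end_s <= df$start_s)) {
    stop("validation error: intervals must have end > start", call. = FALSE)
  }
  class(df) <- c("rhythm_annotation", "data.frame")
  df
}

#' Read rhythm annotations from a delimited file
#'
#' Expects a CSV with columns `start_s,end_s,label,source`. An empty file (or
#' header-only file) yields an empty annotation, which is interpreted as
#' patient-level NOT_AF by convention.
#'
#' @param path annotation CSV path.
#' @return A [rhythm_annotation()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(rhythm_annotation())
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(dat) == 0L) return(rhythm_annotation())
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(dat))) {
    stop("annotation file must have columns start_s,end_s,label[,source]",
         call. = FALSE)
  }
  src <- if ("source" %in% names(dat)) dat$source else "gold"
  rhythm_annotation(dat$start_s, dat$end_s, dat$label, src)
}

#' AF status of an annotation over a window
#'
#' @param ann a [rhythm_annotation()].
#' @return TRUE if any interval is labelled AF.
#' @export
annotation_af_status <- function(ann) {
  nrow(ann) > 0L && any(ann$label == "AF")
}

#' First AF onset of an annotation
#' @param ann a [rhythm_annotation()].
#' @return onset time in seconds, or NA if no AF interval.
#' @export
annotation_first_onset <- function(ann) {
  af <- ann$start_s[ann$label == "AF"]
  if (length(af)) min(af) else NA_real_
}
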