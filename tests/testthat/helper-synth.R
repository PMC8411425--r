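# Shared fixtures, all generated in code. Expensive objects are built once
# per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# One rendered 2-minute segment of a given rhythm, 125 Hz, noise-free unless
# asked otherwise. Returns samples, truth beat times/types, beat series from
# the detector, and the record.
synth_segment <- function(rhythm, seed = 7, mean_hr = NULL, fs = 125,
                          noise = noise_config(dropout_prob = 0),
                          config = af_config()) {
  g <- generate_rr(rhythm, 120, mean_hr = mean_hr, seed = seed)
  bt <- 0.4 + cumsum(c(0, g$rr))
  keep <- bt < 119.5
  bt <- bt[keep]; ty <- g$beat_types[keep]
  af_int <- if (rhythm == "AF") data.frame(start_s = 0, end_s = 120) else NULL
  rw <- render_waveform(bt, ty, fs, 120, af_intervals = af_int, noise = noise,
                        seed = seed + 1)
  x <- rw$record$signal[, 1]
  beats <- detect_r_peaks(x, fs, config, start_time = 0, lead = "II",
                          segment_index = 0L)
  list(samples = x, fs = fs, truth_times = bt, truth_types = ty,
       beats = beats, record = rw$record, truth = rw$truth)
}

# Small end-to-end corpus shared by pipeline tests: 10-minute records.
small_corpus <- function() {
  fixture("small_corpus", function() {
    build_validation_corpus(n_af = 5, n_not_af = 5, ectopy_fraction = 0.4,
                            duration_s = 600, fs = 125, seed = 17)
  })
}

# Brute-force O(N^2) sample entropy oracle: direct template enumeration,
# independent of the packaged implementation.
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

# Brute-force run-length scanner for AF episodes.
episodes_bruteforce <- function(labels, k = 3, L = 120) {
  onset <- c(); offset <- c(); nseg <- c()
  i <- 1; n <- length(labels)
  while (i <= n) {
    if (labels[i] == "AF") {
      j <- i
      while (j < n && labels[j + 1] == "AF") j <- j + 1
      if (j - i + 1 >= k) {
        onset <- c(onset, (i - 1) * L)
        offset <- c(offset, j * L)
        nseg <- c(nseg, j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  data.frame(onset_s = if (length(onset)) onset else numeric(0),
             offset_s = if (length(offset)) offset else numeric(0),
             n_segments = if (length(nseg)) as.integer(nseg) else integer(0))
}

# A cheap low-rate record of a given duration (hours) for inclusion tests.
dummy_record <- function(hours, fs = 1) {
  ecg_record("dummy", matrix(sin(seq_len(round(hours * 3600 * fs))), ncol = 1),
             fs = fs)
}
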