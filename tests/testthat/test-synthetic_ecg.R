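test_that("bigeminy RR skeleton follows the coupling/compensatory-pause rule", {
  g <- generate_rr("BIGEMINY", 10, mean_hr = 75, jitter = 0, seed = 1)
  # base 0.8 s: normal, then alternating premature 0.48 / pause 1.12
  expect_equal(g$rr[1:5], c(0.8, 0.48, 1.12, 0.48, 1.12))
  expect_equal(g$beat_types[1:4], c("SINUS", "SINUS", "PAC", "SINUS"))
})

test_that("rhythm RR statistics match their design targets", {
  nsr <- generate_rr("NSR", 120, seed = 3)
  expect_equal(length(nsr$rr), 149, tolerance = 3)   # ~150 beats at 75 bpm
  expect_lt(sd(nsr$rr) / mean(nsr$rr), 0.05)

  af <- generate_rr("AF", 120, seed = 3)
  cv <- sd(af$rr) / mean(af$rr)
  expect_gt(cv, 0.15)
  lag1 <- cor(af$rr[-1], af$rr[-length(af$rr)])
  expect_lt(abs(lag1), 0.1)                          # serially decorrelated

  pac <- generate_rr("PAC_SPORADIC", 300, ectopy_rate = 8, seed = 3)
  expect_gt(sum(pac$beat_types == "PAC"), 10)
  expect_error(generate_rr("NSR", 60, mean_hr = 10), "nonphysiological")
})

test_that("rendering is deterministic and keeps beat-level truth exact", {
  a <- simulate_record("r1", data.frame(start_s = 0, end_s = 240,
                                        rhythm = "NSR"), 240, seed = 5)
  b <- simulate_record("r1", data.frame(start_s = 0, end_s = 240,
                                        rhythm = "NSR"), 240, seed = 5)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$truth$beat_times, b$truth$beat_times)
  expect_equal(length(a$truth$beat_times), length(a$truth$beat_types))
})

test_that("AF epochs lose P-waves and carry fibrillatory baseline", {
  sc <- data.frame(start_s = c(0, 240), end_s = c(240, 480),
                   rhythm = c("NSR", "AF"), mean_hr = c(75, 110))
  sim <- simulate_record("mix", sc, 480, seed = 9)
  in_af <- sim$truth$beat_times >= 240
  expect_true(all(!sim$truth$p_wave_present[in_af]))
  expect_true(all(sim$truth$p_wave_present[!in_af]))
  ann <- sim$truth$annotation
  expect_equal(ann$label, c("NOT_AF", "AF"))
  expect_true(annotation_af_status(ann))
  expect_equal(annotation_first_onset(ann), 240)
})

test_that("noise-free sinus records are fully usable; total dropout is not", {
  clean <- simulate_record("c", data.frame(start_s = 0, end_s = 600,
                                           rhythm = "NSR"), 600,
                           noise = noise_config(0, 0, 0, 0), seed = 2)
  segs <- segment_record(clean$record, 120)
  usable <- vapply(segs[["II"]], function(s)
    assess_segment(s, 125)$usable, logical(1))
  expect_true(all(usable))

  x <- clean$record$signal
  x[] <- 0   # full-record dropout
  dead <- ecg_record("d", x, fs = 125)
  dsegs <- segment_record(dead, 120)
  dusable <- vapply(dsegs[[1]], function(s)
    assess_segment(s, 125)$usable, logical(1))
  expect_true(all(!dusable))
})

test_that("the validation corpus has the requested composition and is reproducible", {
  corp <- small_corpus()
  m <- corp$manifest
  expect_equal(sum(m$af_status), 5)
  expect_equal(sum(!m$af_status), 5)
  expect_equal(sum(m$rhythm_class == "ECTOPY"), 2)   # 40% of non-AF
  expect_true(all(is.na(m$onset_s[!m$af_status])))
  expect_true(all(m$onset_s[m$af_status] <= 0.4 * 600))

  again <- build_validation_corpus(n_af = 5, n_not_af = 5,
                                   ectopy_fraction = 0.4, duration_s = 600,
                                   fs = 125, seed = 17)
  expect_identical(corp$cases[[3]]$record$signal, again$cases[[3]]$record$signal)
})

test_that("corpus export writes WFDB pairs, truth files and a manifest", {
  d <- withr::local_tempdir()
  m <- build_validation_corpus(n_af = 1, n_not_af = 1, duration_s = 240,
                               seed = 8, dir = d)
  expect_true(file.exists(file.path(d, "af01.hea")))
  expect_true(file.exists(file.path(d, "af01.dat")))
  expect_true(file.exists(file.path(d, "ctl01_rhythm.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  rec <- read_record(file.path(d, "af01"), format = "wfdb")
  expect_equal(rec$leads, c("II", "V"))
  mani <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(mani$seed, 8)
})
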