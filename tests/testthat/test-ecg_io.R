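test_that("csv records read correctly and require a sampling rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  sig <- data.frame(II = sin(1:500 / 10), V = cos(1:500 / 10))
  write.csv(sig, f, row.names = FALSE)

  rec <- read_record(f, format = "csv", fs_override = 250)
  expect_s3_class(rec, "ecg_record")
  expect_equal(rec$leads, c("II", "V"))
  expect_equal(rec$fs, 250)
  expect_equal(nrow(rec$signal), 500)
  expect_equal(record_duration_s(rec), 2)

  expect_error(read_record(f, format = "csv"), "fs_override")

  one <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(II = rnorm(100)), one, row.names = FALSE)
  rec1 <- read_record(one, format = "csv", fs_override = 250)
  expect_length(rec1$leads, 1)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("II,V", empty)
  expect_error(read_record(empty, format = "csv", fs_override = 250), "empty")
})

test_that("WFDB format-16 records round-trip through write_wfdb/read_record", {
  rec <- ecg_record("rt01",
                    cbind(II = sin(1:2000 / 5), V = 0.5 * cos(1:2000 / 7)),
                    fs = 125)
  d <- withr::local_tempdir()
  write_wfdb(rec, d, gain = 2000)
  back <- read_record(file.path(d, "rt01"), format = "wfdb")
  expect_equal(back$leads, rec$leads)
  expect_equal(back$fs, 125)
  # quantized at 1/gain mV resolution
  expect_lt(max(abs(back$signal - rec$signal)), 1 / 2000)
  expect_error(read_record(file.path(d, "missing"), format = "wfdb"),
               "header")
})

test_that("record inclusion window is the closed interval [6 h, 55 h]", {
  expect_false(check_inclusion(dummy_record(5.9)))
  expect_equal(attr(check_inclusion(dummy_record(5.9)), "reason"), "too short")
  expect_true(check_inclusion(dummy_record(6)))
  expect_true(check_inclusion(dummy_record(55)))
  expect_false(check_inclusion(dummy_record(60)))
  expect_equal(attr(check_inclusion(dummy_record(60)), "reason"), "too long")
})

test_that("segmentation partitions the record into complete 2-minute windows", {
  rec6h <- dummy_record(6, fs = 2)
  segs <- segment_record(rec6h, 120)
  expect_length(segs[[1]], 180)   # 21600 / 120

  idx <- vapply(segs[[1]], `[[`, numeric(1), "index")
  st <- vapply(segs[[1]], `[[`, numeric(1), "start_time")
  en <- vapply(segs[[1]], `[[`, numeric(1), "end_time")
  expect_equal(idx, 0:179)
  expect_equal(en - st, rep(120, 180))
  expect_equal(st[-1], en[-length(en)])   # abutting half-open windows

  # trailing partial window is discarded
  rec121 <- ecg_record("x", matrix(rnorm(121 * 10), ncol = 1), fs = 10)
  expect_length(segment_record(rec121, 120)[[1]], 1)
  rec119 <- ecg_record("x", matrix(rnorm(119 * 10), ncol = 1), fs = 10)
  expect_error(segment_record(rec119, 120), "shorter")
})

test_that("read -> segment -> reassemble reproduces the signal bit-exactly", {
  rec <- small_corpus()$cases[[1]]$record
  segs <- segment_record(rec, 120)
  for (ld in rec$leads) {
    reass <- unlist(lapply(segs[[ld]], `[[`, "samples"))
    expect_identical(reass, rec$signal[seq_along(reass), ld])
  }
})

test_that("rhythm annotations are validated, ordered, and default to NOT_AF", {
  ann <- rhythm_annotation(c(3600, 0), c(7200, 3600), c("NOT_AF", "AF"))
  expect_equal(ann$start_s, c(0, 3600))   # sorted
  expect_true(annotation_af_status(ann))
  expect_equal(annotation_first_onset(ann), 0)

  expect_error(rhythm_annotation(c(0, 5), c(10, 20), c("AF", "NOT_AF")),
               "overlap")
  expect_error(rhythm_annotation(0, 10, "FLUTTER"), "AF or NOT_AF")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("start_s,end_s,label,source", f)
  empty <- read_annotations(f)
  expect_equal(nrow(empty), 0)
  expect_false(annotation_af_status(empty))  # patient-level NOT_AF convention

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(start_s = 0, end_s = 3600, label = "AF",
                       source = "gold"), f2, row.names = FALSE)
  expect_equal(nrow(read_annotations(f2)), 1)
})
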