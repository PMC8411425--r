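test_that("sample entropy matches the brute-force template oracle", {
  set.seed(31)
  cases <- list(
    list(x = rep(0.8, 50), m = 1, r = 0.05),
    list(x = rep(c(1, 2), 4), m = 1, r = 0.1),
    list(x = runif(60), m = 1, r = 0.2),
    list(x = runif(140, 0.4, 1.2), m = 1, r = 0.03),
    list(x = rnorm(80), m = 2, r = 0.3),
    list(x = cumsum(rnorm(100)), m = 2, r = 0.5),
    list(x = rnorm(200), m = 3, r = 0.4)
  )
  for (cs in cases) {
    expect_equal(sample_entropy(cs$x, cs$m, cs$r),
                 sampen_bruteforce(cs$x, cs$m, cs$r),
                 tolerance = 1e-12)
  }
  # identity case: a constant series is perfectly regular
  expect_identical(sample_entropy(rep(0.8, 50), 1, 0.05), 0)
})

test_that("sample entropy handles degenerate match counts explicitly", {
  # B > 0 but no (m+1)-template match: maximally irregular sentinel
  expect_identical(sample_entropy(c(0, 0, 10, 20, 30), m = 1, r = 0.5), Inf)
  # no m-template match at all: undefined
  expect_true(is.na(sample_entropy(c(1, 2, 4, 8, 16), m = 1, r = 0.5)))
  expect_error(sample_entropy(c(1, 2), m = 1, r = 0.1), "short")
  expect_error(sample_entropy(1:10, m = 1, r = 0), "tolerance")
})

test_that("sample entropy is shift-invariant and jointly scale-invariant", {
  set.seed(5)
  x <- runif(80, 0.5, 1.1)
  base <- sample_entropy(x, 1, 0.04)
  expect_equal(sample_entropy(x + 3.7, 1, 0.04), base)
  expect_equal(sample_entropy(x * 10, 1, 0.4), base)
  # i.i.d. series is more entropic than near-constant
  irregular <- runif(140)
  regular <- 0.8 + rnorm(140, 0, 0.003)
  expect_gt(sample_entropy(irregular, 1, 0.03),
            sample_entropy(regular, 1, 0.03))
})

test_that("AF RR series score above NSR at every seed in a 100-seed sweep", {
  se <- sapply(1:100, function(s) {
    c(af = sample_entropy(generate_rr("AF", 120, seed = s)$rr, 1, 0.03),
      nsr = sample_entropy(generate_rr("NSR", 120, seed = s)$rr, 1, 0.03))
  })
  expect_true(all(se["af", ] > se["nsr", ]))
})

test_that("segment screening separates NSR from AF and flags ectopy as possible AF", {
  cfg <- af_config()
  lab <- function(rh, seed) {
    g <- generate_rr(rh, 120, seed = seed)
    screen_segment(beat_series_from_times(0.4 + cumsum(c(0, g$rr))), cfg)$label
  }
  for (s in 1:20) {
    expect_equal(lab("NSR", s), "NOT_AF")
    expect_equal(lab("AF", s), "POSSIBLE_AF")
    expect_equal(lab("BIGEMINY", s), "POSSIBLE_AF")  # false positive by design
  }
  short <- beat_series_from_times(c(0, 0.8, 1.6))
  expect_equal(screen_segment(short, cfg)$label, "INSUFFICIENT")
})
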