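test_that("episodes require 3 consecutive AF segments and report onset/offset", {
  e1 <- find_episodes(c("NOT_AF", "AF", "AF", "AF", "NOT_AF"))
  expect_equal(nrow(e1), 1)
  expect_equal(e1$onset_s, 120)
  expect_equal(e1$offset_s, 480)
  expect_equal(e1$n_segments, 3L)

  expect_equal(nrow(find_episodes(c("AF", "AF", "NOT_AF", "AF", "AF"))), 0)

  e3 <- find_episodes(rep("AF", 5))
  expect_equal(e3$onset_s, 0)
  expect_equal(e3$n_segments, 5L)

  # NOISE and INSUFFICIENT break runs (continuous AF required)
  expect_equal(nrow(find_episodes(c("AF", "AF", "NOISE", "AF", "AF"))), 0)
  expect_equal(nrow(find_episodes(c("AF", "AF", "INSUFFICIENT", "AF"))), 0)
})

test_that("find_episodes equals brute-force run-length scanning on random sequences", {
  set.seed(99)
  labels <- c("AF", "NOT_AF", "NOISE", "INSUFFICIENT", "ECTOPY")
  for (i in 1:10000) {
    n <- sample(1:30, 1)
    seq_i <- sample(labels, n, replace = TRUE, prob = c(0.4, 0.3, 0.1, 0.1, 0.1))
    got <- find_episodes(seq_i)
    want <- episodes_bruteforce(seq_i)
    expect_identical(got$onset_s, want$onset_s)
    expect_identical(got$offset_s, want$offset_s)
    if (nrow(got)) {
      expect_true(all(got$offset_s - got$onset_s >= 360))  # >= 6 minutes
    }
  }
})

test_that("lead fusion follows quality ranking or any-lead AF evidence", {
  labs <- list(I = c("AF", "NOT_AF"), II = c("NOT_AF", "NOT_AF"))
  cf <- list(I = c(0.8, 0.8), II = c(0.9, 0.9))   # lead II cleaner
  expect_equal(fuse_leads(labs, cf, "best_quality_lead"), c("NOT_AF", "NOT_AF"))
  expect_equal(fuse_leads(labs, cf, "any_lead"), c("AF", "NOT_AF"))

  # both leads unusable in segment 1 -> NOISE
  labs2 <- list(I = c("NOISE", "AF"), II = c("NOISE", "NOT_AF"))
  cf2 <- list(I = c(0, 0.7), II = c(0, 0.9))
  expect_equal(fuse_leads(labs2, cf2, "best_quality_lead")[1], "NOISE")
  # ties go to the first lead in record order
  expect_equal(fuse_leads(list(A = "AF", B = "NOT_AF"),
                          list(A = 0.8, B = 0.8), "best_quality_lead"), "AF")
  expect_error(fuse_leads(list(A = c("AF", "AF"), B = "AF"),
                          list(A = c(1, 1), B = 1)), "indexing")
})

test_that("any-lead fusion AF set contains every single lead's AF set", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(2:4, 1); n <- sample(5:20, 1)
    labs <- replicate(k, sample(c("AF", "NOT_AF", "NOISE"), n, TRUE,
                                prob = c(0.4, 0.4, 0.2)), simplify = FALSE)
    cf <- replicate(k, ifelse(labs[[1]] == "", 0, runif(n)), simplify = FALSE)
    for (j in 1:k) cf[[j]] <- ifelse(labs[[j]] == "NOISE", runif(n, 0, 0.5), runif(n, 0.5, 1))
    names(labs) <- names(cf) <- paste0("L", 1:k)
    fused <- fuse_leads(labs, cf, "any_lead")
    for (j in 1:k) {
      lead_af <- labs[[j]] == "AF"
      expect_true(all(!lead_af | fused == "AF" | labs[[j]] == "NOISE"))
    }
  }
})

test_that("onset deltas are signed minutes with an undefined flag", {
  expect_equal(as.numeric(onset_delta(3600, 1800)), 30)
  expect_equal(as.numeric(onset_delta(1800, 1800)), 0)
  d <- onset_delta(3600, NA)
  expect_true(is.na(d))
  expect_true(attr(d, "undefined"))
})
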