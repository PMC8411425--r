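test_that("contingency counts cells and reports unanalyzable patients separately", {
  ids <- paste0("p", 1:6)
  pred <- setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), ids)
  gold <- setNames(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), ids)
  ct <- contingency(pred, gold)
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(2, 1, 1, 2))

  ana <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE), ids)
  ct2 <- contingency(pred, gold, analyzable = ana)
  expect_equal(ct2$n, 5)
  expect_equal(ct2$n_excluded, 1)
  expect_equal(ct2$excluded_ids, "p5")
  expect_equal(ct2$tp, 1)

  expect_error(contingency(setNames(TRUE, "a"), setNames(TRUE, "b")),
               "mismatched")
})

test_that("metrics satisfy the accuracy decomposition and stay inside their CIs", {
  set.seed(21)
  for (i in 1:200) {
    cells <- rmultinom(1, size = sample(10:200, 1), prob = runif(4, 0.05, 1))
    ct <- contingency_from_counts(cells[1], cells[2], cells[3], cells[4])
    m <- af_metrics(ct)
    est <- setNames(m$estimate, m$metric)
    P <- ct$tp + ct$fn; N <- ct$tn + ct$fp
    if (P > 0 && N > 0) {
      expect_equal(est["accuracy"],
                   (est["sensitivity"] * P + est["specificity"] * N) / ct$n,
                   ignore_attr = TRUE)
    }
    ok <- !is.na(m$estimate)
    expect_true(all(m$ci_low[ok] <= m$estimate[ok] + 1e-12))
    expect_true(all(m$ci_high[ok] >= m$estimate[ok] - 1e-12))
    expect_true(all(m$ci_low[ok] >= 0 & m$ci_high[ok] <= 1))
  }
})

test_that("undefined metrics are flagged, not reported as zero", {
  ct <- contingency_from_counts(0, 0, 3, 7)
  m <- af_metrics(ct)
  expect_true(is.na(m$estimate[m$metric == "ppv"]))
  expect_false(is.na(m$estimate[m$metric == "accuracy"]))
})

test_that("Wilson intervals differ from exact intervals but bracket the estimate", {
  cp <- binom_ci(47, 50, "clopper_pearson")
  wi <- binom_ci(47, 50, "wilson")
  expect_false(isTRUE(all.equal(cp, wi)))
  expect_true(wi[1] < 47 / 50 && wi[2] > 47 / 50)
})

test_that("paired accuracy comparison is the exact McNemar discordant-pair test", {
  a <- rep(TRUE, 50)
  b <- c(rep(FALSE, 10), rep(TRUE, 40))
  out <- compare_accuracy(paired_correct = list(a = a, b = b))
  # 10 discordant pairs, all favouring a: exact two-sided p = 2 * (1/2)^10
  expect_equal(out$p_value, 0.001953125)
  expect_equal(unname(out$discordant["a_only"]), 10L)

  same <- compare_accuracy(paired_correct = list(a = a, b = a))
  expect_equal(same$p_value, 1.0)

  expect_error(compare_accuracy(paired_correct = list(a = TRUE, b = FALSE)),
               "at least 2")

  # unpaired fallback
  ct_a <- contingency_from_counts(23, 1, 2, 24)
  ct_b <- contingency_from_counts(16, 7, 9, 18)
  un <- compare_accuracy(ct_a, ct_b)
  expect_equal(un$method, "fisher_exact")
  expect_lt(un$p_value, 0.05)
})

test_that("onset summaries use linear quantile interpolation", {
  s <- onset_summary(c(0, 30, 208))
  expect_equal(s$median, 30)
  expect_equal(s$q25, 15)
  expect_equal(s$q75, 119)
  expect_equal(onset_summary(5)$median, 5)
  expect_equal(onset_summary(c(-10, 10))$median, 0)
  expect_error(onset_summary(NA_real_), "no defined")
})
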