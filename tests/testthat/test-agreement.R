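test_that("contingency tables match an exhaustive 4-way count oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    a <- runif(n) < 0.3
    b <- runif(n) < 0.3
    tab <- build_contingency(a, b)
    counts <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (j in seq_len(n)) {
      cell <- if (a[j] && b[j]) "tp" else if (a[j]) "fp" else if (b[j]) "fn" else "tn"
      counts[cell] <- counts[cell] + 1L
    }
    expect_equal(c(tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn), counts)
    expect_equal(tab$total, n)
  }
  ident <- build_contingency(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(ident$fp + ident$fn, 0L)
})

test_that("the printed subsegment counts reproduce the true-negative total", {
  # 97 concordant positives, 1 reference-only, 3 index-only, rest of 214 x 28
  n_total <- 214L * 28L
  tn <- n_total - 97L - 1L - 3L
  expect_equal(tn, 5891L)
  idx <- c(rep(TRUE, 97), FALSE, rep(TRUE, 3), rep(FALSE, tn))
  ref <- c(rep(TRUE, 97), TRUE, rep(FALSE, 3), rep(FALSE, tn))
  tab <- build_contingency(idx, ref)
  expect_equal(tab$tn, 5891L)
  expect_equal(tab$total, 5992L)
})

test_that("accuracy metrics reproduce the printed study values", {
  pat <- accuracy(contingency_from_counts(tp = 22, fp = 1, fn = 1, tn = 190,
                                          level = "patient"),
                  digits = "display")
  expect_equal(pat$estimate[pat$metric == "sensitivity"], 96)
  expect_equal(pat$estimate[pat$metric == "npv"], 99.5)

  sub <- accuracy(contingency_from_counts(tp = 97, fp = 3, fn = 1, tn = 5891),
                  digits = "display")
  expect_equal(sub$estimate[sub$metric == "sensitivity"], 99)
  expect_equal(sub$estimate[sub$metric == "ppv"], 97.0)

  perfect <- accuracy(contingency_from_counts(tp = 10, fp = 0, fn = 0, tn = 90))
  expect_equal(perfect$estimate, rep(100, 4))
})

test_that("zero denominators yield undefined metrics, not zero", {
  none_pos <- accuracy(contingency_from_counts(tp = 0, fp = 0, fn = 0, tn = 50))
  expect_true(is.na(none_pos$estimate[none_pos$metric == "sensitivity"]))
  expect_true(is.na(none_pos$estimate[none_pos$metric == "ppv"]))
  expect_equal(none_pos$estimate[none_pos$metric == "specificity"], 100)
})

test_that("Clopper-Pearson intervals bracket the point estimate", {
  tab <- contingency_from_counts(tp = 22, fp = 1, fn = 1, tn = 190)
  acc <- accuracy(tab)
  expect_true(all(acc$ci_low <= acc$estimate & acc$estimate <= acc$ci_high))
  expect_true(all(acc$ci_method == "clopper-pearson"))
})

test_that("Bland-Altman matches closed forms and a direct recomputation", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd_difference, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  # d = {+1, -1}: mean 0, sd sqrt(2), limits +/- 1.96 sqrt(2)
  ba <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  set.seed(33)
  a <- rnorm(50, 10, 2)
  b <- a + rnorm(50, 0.3, 0.5)
  ba2 <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba2$mean_difference, sum(d) / 50, tolerance = 1e-12)
  expect_equal(ba2$sd_difference,
               sqrt(sum((d - mean(d))^2) / 49), tolerance = 1e-12)
  expect_equal(ba2$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
})

test_that("ICC recovers a known variance-component ratio", {
  # sigma2_subject = 9, sigma2_error = 1 -> ICC = 0.9
  set.seed(77)
  n <- 500
  s <- rnorm(n, 0, 3)
  a <- s + rnorm(n, 0, 1)
  b <- s + rnorm(n, 0, 1)
  fit <- icc_absolute(a, b)
  expect_equal(fit$icc, 0.9, tolerance = 0.02)
  expect_true(fit$ci_low < fit$icc && fit$icc < fit$ci_high)
})

test_that("ICC is 1 for identical nonconstant vectors and penalizes bias", {
  x <- c(1, 3, 7, 2, 9)
  expect_equal(icc_absolute(x, x)$icc, 1)
  shifted <- icc_absolute(x, x + 2)
  expect_lt(shifted$icc, 1)
  expect_equal(cor(x, x + 2), 1)
})

test_that("paired tests match the closed-form t statistic", {
  set.seed(55)
  a <- rnorm(40, 5, 1)
  b <- a - rnorm(40, 0.2, 0.3)
  res <- paired_tests(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$paired_t, t_hand, tolerance = 1e-9)
  expect_equal(res$pearson_r, cor(a, b), tolerance = 1e-12)
  expect_equal(res$median_a, median(a))
})

test_that("degenerate paired inputs are reported as undefined", {
  res <- paired_tests(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(res$wilcoxon_p))
  expect_true(is.na(res$paired_t))
  res2 <- paired_tests(c(1, 2, 3), -c(1, 2, 3))
  expect_equal(res2$pearson_r, -1)
  resc <- paired_tests(c(2, 2, 2), c(1, 3, 5))
  expect_true(is.na(resc$pearson_r))
})
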