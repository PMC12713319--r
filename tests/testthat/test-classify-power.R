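# LOSO midpoint-threshold classifier, exact binomial testing, and paired-t
# power analysis.

test_that("midpoint thresholding follows the documented rule", {
  # two training subjects define M-mean 1.2, NM-mean 0.2 -> threshold 0.7
  values <- c(1.2, 0.2, 1.2, 0.2, 0.9, 0.5)
  labels <- c("M", "NM", "M", "NM", "M", "NM")
  subjects <- c("A", "A", "B", "B", "C", "C")
  res <- loso_classify(values, labels, subjects, positive = "M")
  expect_equal(unname(res$thresholds["C"]), 0.7)
  expect_equal(res$predicted[5], "M")   # 0.9 > 0.7
  expect_equal(res$predicted[6], "NM")  # 0.5 < 0.7
  # tie at the threshold goes to the reference class
  res_tie <- loso_classify(c(values[1:4], 0.7, 0.7), labels, subjects,
                           positive = "M")
  expect_equal(res_tie$predicted[5:6], c("NM", "NM"))

  # mean-of-subject-means training variant: differs when trial counts are
  # unbalanced, agrees with pooling when they are not
  res_subj <- loso_classify(values, labels, subjects, positive = "M",
                            fold_means = "subject")
  expect_equal(res_subj$thresholds, res$thresholds)
  v2 <- c(2.0, 1.0, 0.2, 0.6, 0.4, 0.9, 0.5)   # A has two M trials, B one
  l2 <- c("M", "M", "NM", "M", "NM", "M", "NM")
  s2 <- c("A", "A", "A", "B", "B", "C", "C")
  pooled <- loso_classify(v2, l2, s2, positive = "M")
  bysubj <- loso_classify(v2, l2, s2, positive = "M", fold_means = "subject")
  expect_equal(unname(pooled$thresholds["C"]), (mean(c(2, 1, 0.6)) + 0.3) / 2)
  expect_equal(unname(bysubj$thresholds["C"]), (mean(c(1.5, 0.6)) + 0.3) / 2)
})

test_that("perfect separation classifies every trial correctly", {
  set.seed(3)
  n_s <- 8
  df <- data.frame(
    subject = rep(sprintf("S%d", seq_len(n_s)), each = 10),
    label = rep(c("M", "NM"), n_s * 5))
  df$value <- ifelse(df$label == "M", 1, 0)
  res <- loso_classify(df$value, df$label, df$subject, positive = "M")
  expect_equal(res$accuracy, 1)
  expect_equal(res$n_total, n_s * 10)
  expect_equal(res$p0, 0.5)
})

test_that("held-out subjects never influence their own threshold", {
  set.seed(17)
  df <- data.frame(subject = rep(sprintf("S%d", 1:6), each = 8),
                   label = rep(c("M", "NM"), 24),
                   value = rnorm(48))
  res <- loso_classify(df$value, df$label, df$subject, positive = "M")
  mutated <- df$value
  mutated[df$subject == "S3"] <- mutated[df$subject == "S3"] + 100
  res2 <- loso_classify(mutated, df$label, df$subject, positive = "M")
  expect_equal(res2$thresholds[["S3"]], res$thresholds[["S3"]])
})

test_that("label-shuffled data classifies at the majority rate", {
  set.seed(29)
  n <- 1200
  df <- data.frame(subject = rep(sprintf("S%02d", 1:20), each = n / 20),
                   value = rnorm(n),
                   label = sample(rep(c("M", "NM"), c(n * 0.6, n * 0.4))))
  res <- loso_classify(df$value, df$label, df$subject, positive = "M")
  expect_lt(abs(res$accuracy - max(res$p0, 1 - res$p0)), 0.1)
  expect_gt(res$p_value, 0.05)
})

test_that("exact binomial tail matches closed forms and brute-force PMF sums", {
  expect_equal(binomial_vs_majority(9, 10, 0.5), 11 / 1024, tolerance = 1e-12)
  expect_equal(binomial_vs_majority(10, 10, 0.7), 0.7^10, tolerance = 1e-12)
  expect_gt(binomial_vs_majority(5, 10, 0.5), 0.5)
  # paper-scale non-significant pattern: correct count below chance
  expect_gt(binomial_vs_majority(61, 133, 61 / 133 + 0.05), 0.5)

  set.seed(41)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    oracle <- sum(dbinom(k:n, n, p0))
    expect_equal(binomial_vs_majority(k, n, p0), oracle, tolerance = 1e-12)
  }
})

test_that("classifier fold missing a class is skipped with accounting", {
  df <- data.frame(subject = c("A", "A", "B", "B", "C", "C"),
                   label = c("M", "M", "M", "NM", "M", "NM"),
                   value = c(1, 1, 1, 0, 1, 0))
  # removing subject B or C leaves training data with both classes, but
  # removing both M-carriers never happens; construct a missing-class fold:
  df2 <- data.frame(subject = c("A", "A", "B", "B"),
                    label = c("M", "M", "M", "NM"),
                    value = c(1, 1, 1, 0))
  expect_warning(res <- loso_classify(df2$value, df2$label, df2$subject,
                                      positive = "M"),
                 "missing a class")
  expect_equal(res$skipped_subjects, "B")
  expect_equal(res$n_total, 2)  # only subject A scored
})

test_that("simulated power matches size at d = 0 and the noncentral-t oracle", {
  r0 <- simulate_power(n = 20, d = 0, alpha = 0.05, sided = "one",
                       reps = 20000, seed = 2)
  expect_lt(abs(r0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))

  grid <- expand.grid(n = c(10, 15, 20, 30), d = c(0.3, 0.6, 0.9))
  for (i in seq_len(nrow(grid))) {
    r <- simulate_power(grid$n[i], grid$d[i], 0.05, "one",
                        reps = 5000, seed = 100 + i)
    expect_lt(abs(r$power - r$analytic_power),
              3 * sqrt(r$analytic_power * (1 - r$analytic_power) / r$reps) + 1e-9)
  }
})

test_that("power is monotone in n and d, and analytic power has its closed forms", {
  expect_equal(analytic_power_paired_t(20, 0, 0.05, "one"), 0.05,
               tolerance = 1e-10)
  pw_n <- sapply(c(5, 10, 20, 40, 80), analytic_power_paired_t,
                 d = 0.4, alpha = 0.05, sided = "one")
  expect_true(all(diff(pw_n) > 0))
  pw_d <- sapply(c(0.1, 0.3, 0.6, 0.9), function(d)
    analytic_power_paired_t(20, d, 0.05, "two"))
  expect_true(all(diff(pw_d) > 0))

  cur <- power_curve(c(10, 20), d = 0.6, sided = "one", reps = 2000, seed = 5)
  expect_equal(nrow(cur), 2)
  expect_gt(cur$power[2], cur$power[1])
})
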