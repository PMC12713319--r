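# FDR control, pointwise and window statistics, mixed models, ICC.

test_that("BH step-up matches the worked example and the brute-force oracle", {
  expect_identical(fdr_bh(c(0.01, 0.02, 0.04, 0.8), q = 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(fdr_bh(rep(1, 10)), rep(FALSE, 10))

  set.seed(12)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(c(1, 3), 1), 3)  # include ties and small values
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(fdr_bh(p, q), bh_oracle(p, q))
  }
})

test_that("one- and two-sided p-values relate as documented", {
  set.seed(5)
  a <- matrix(rnorm(8 * 20), 8, dimnames = list(paste0("S", 1:8), NULL))
  b <- matrix(rnorm(8 * 20), 8, dimnames = list(paste0("S", 1:8), NULL))
  ts <- seq(0, 5, length.out = 20)
  one <- pointwise_paired_tests(a, b, ts, sided = "greater")
  two <- pointwise_paired_tests(a, b, ts, sided = "two.sided")
  expect_equal(two$p, 2 * pmin(one$p, 1 - one$p), tolerance = 1e-12)
  # identical inputs: t = 0, one-sided p = 0.5 everywhere, no discoveries
  same <- pointwise_paired_tests(a, a + 0, ts, sided = "greater")
  expect_true(all(same$t_stat == 0))
  expect_true(all(same$p == 0.5))
  expect_false(any(same$fdr_mask))
})

test_that("pointwise tests pair by subject id, not row order", {
  set.seed(6)
  ids <- paste0("S", 1:10)
  a <- matrix(rnorm(10 * 30), 10, dimnames = list(ids, NULL))
  b <- matrix(rnorm(10 * 30), 10, dimnames = list(ids, NULL))
  ts <- seq(0, 5, length.out = 30)
  r1 <- pointwise_paired_tests(a, b, ts)
  r2 <- pointwise_paired_tests(a[sample(ids), ], b[rev(ids), ], ts)
  expect_equal(r1$t_stat, r2$t_stat, tolerance = 1e-12)

  expect_warning(
    expect_null(pointwise_paired_tests(a[1, , drop = FALSE], b, ts)),
    "fewer than 2")
})

test_that("the 2-4 s analysis window covers samples 300..500 of the epoch", {
  ts <- seq(-1, 5, by = 0.01)
  idx <- which(ts >= 2 & ts <= 4)
  expect_identical(idx, 301:501)  # 0-based 300..500
  expect_length(idx, 201)
})

test_that("window statistics are zero for zero epochs and invariant to trial order", {
  coh <- generate_cohort(cb_config(), n_subjects = 5, seed = 23)
  prep <- suppressWarnings(preprocess_cohort(coh))
  tm <- window_trial_means(prep)
  ws <- window_stats(tm)
  expect_true(all(abs(ws$normalized[ws$group == "BASE"]) < 1e-12))

  tm_shuffled <- tm[sample(nrow(tm)), ]
  ws2 <- window_stats(tm_shuffled)
  ws2 <- ws2[order(ws2$subject, ws2$group), ]
  wso <- ws[order(ws$subject, ws$group), ]
  expect_equal(wso$mean, ws2$mean, tolerance = 1e-12)

  # all-zero epochs: every mean 0, directional tests p = 0.5, two-sided NaN-free
  prep0 <- prep
  for (id in names(prep0)) prep0[[id]]$epochs$data[] <- 0
  ws0 <- window_stats(window_trial_means(prep0))
  expect_true(all(ws0$mean[ws0$n_trials > 0] == 0))
  wt <- window_tests(ws0)
  est <- wt[wt$estimable & wt$sided == "greater", ]
  expect_true(all(est$p == 0.5))
})

test_that("window test battery uses the documented sidedness and handles low n", {
  coh <- generate_cohort(cb_config(), n_subjects = 6, seed = 29)
  prep <- suppressWarnings(preprocess_cohort(coh))
  wt <- window_tests(window_stats(window_trial_means(prep)))
  expect_true(all(wt$sided[grepl(">", wt$contrast)] == "greater"))
  expect_true(all(wt$sided[grepl("vs", wt$contrast)] == "two.sided"))
  expect_true(all(c("M > BASE", "M > NM", "CR vs NCR") %in% wt$contrast))
  # comparisons with fewer than 2 paired subjects are flagged, not dropped
  expect_true(all(!wt$estimable | wt$n >= 2))
})

test_that("ICC arithmetic and degenerate cases", {
  expect_equal(icc(0.2, 0.6), 0.25)
  expect_equal(icc(0, 5), 0)
  expect_equal(icc(3, 0), 1)
  expect_true(is.na(icc(0, 0)))
  expect_error(icc(-1, 1))
})

test_that("GLMM flags separation on a constant outcome", {
  df <- data.frame(subject = rep(paste0("S", 1:10), each = 8),
                   condition = "M", m_order = rep(1:8, 10),
                   confidence = 5, similarity = "similar",
                   concurrent_code = "report", retrospective_flag = TRUE)
  fit <- fit_report_glmm(df, "concurrent")
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_null(fit$coef)
})

test_that("GLMM recovers a known trial-order odds ratio", {
  set.seed(71)
  bp <- behavior_params(b0 = 0.3, b_trial = log(1.9), b_conf = 0.2,
                        b_dissim = 0.4, p_report_all = 1, possible_rate = 0)
  rows <- lapply(1:200, function(s) {
    tr <- m_trial_frame(confidence = pmin(9, pmax(1, round(rnorm(8, 6, 1.8)))),
                        similarity = sample(c("similar", "dissimilar"), 8,
                                            replace = TRUE))
    out <- generate_behavior("all_report", bp, tr, "exp1")
    out$subject <- sprintf("S%03d", s)
    out
  })
  df <- do.call(rbind, rows)
  fit <- fit_report_glmm(df, "concurrent")
  or_trial <- fit$coef$or[fit$coef$term == "m_order"]
  expect_gt(or_trial, 1.7)
  expect_lt(or_trial, 2.1)
  expect_true(fit$converged)
})

test_that("LMM recovers variance components and flags singular fits", {
  set.seed(81)
  n_s <- 200; n_t <- 30
  u <- rnorm(n_s, 0, sqrt(0.2))
  df <- data.frame(subject = rep(sprintf("S%03d", 1:n_s), each = n_t),
                   value = rep(u, each = n_t) + rnorm(n_s * n_t, 0, sqrt(0.6)),
                   x = rnorm(n_s * n_t))
  fit <- fit_pupil_lmm(df, "x")
  expect_equal(fit$icc, 0.25, tolerance = 0.15)
  expect_false(fit$singular)

  df0 <- df
  df0$value <- rnorm(n_s * n_t)  # no between-subject variance
  fit0 <- fit_pupil_lmm(df0, "x")
  expect_lt(fit0$icc, 0.02)
  expect_true(fit0$singular)
})

test_that("mixed-model Wald CIs achieve nominal coverage under the null", {
  set.seed(91)
  n_s <- 30; n_t <- 12
  cover_lmm <- 0
  reps_lmm <- 400
  for (r in seq_len(reps_lmm)) {
    u <- rnorm(n_s, 0, 0.5)
    df <- data.frame(subject = rep(seq_len(n_s), each = n_t),
                     x = rnorm(n_s * n_t))
    df$value <- u[df$subject] + rnorm(n_s * n_t)
    fit <- fit_pupil_lmm(df, "x")
    i <- fit$coef$term == "x"
    cover_lmm <- cover_lmm + (fit$coef$ci_lo[i] <= 0 && 0 <= fit$coef$ci_hi[i])
  }
  # 95% nominal; band = 3 binomial SEs at 400 replicates (~ +-3.3%)
  expect_gt(cover_lmm / reps_lmm, 0.917)
  expect_lt(cover_lmm / reps_lmm, 0.983)

  cover_glmm <- 0
  reps_glmm <- 250
  for (r in seq_len(reps_glmm)) {
    u <- rnorm(n_s, 0, 0.7)
    df <- data.frame(subject = rep(sprintf("S%02d", seq_len(n_s)), each = n_t),
                     condition = "M",
                     m_order = rep(seq_len(n_t), n_s) %% 8 + 1,
                     confidence = sample(1:9, n_s * n_t, replace = TRUE),
                     similarity = sample(c("similar", "dissimilar"),
                                         n_s * n_t, replace = TRUE))
    # outcome independent of every covariate
    p_rep <- plogis(0.3 + u[as.integer(factor(df$subject))])
    df$concurrent_code <- ifelse(runif(n_s * n_t) < p_rep, "report", "none")
    df$retrospective_flag <- FALSE
    fit <- suppressMessages(fit_report_glmm(df, "concurrent"))
    i <- fit$coef$term == "confidence"
    cover_glmm <- cover_glmm + (fit$coef$ci_lo[i] <= 1 && 1 <= fit$coef$ci_hi[i])
  }
  # band = 3 binomial SEs at 250 replicates (~ +-4.1%)
  expect_gt(cover_glmm / reps_glmm, 0.909)
  expect_lt(cover_glmm / reps_glmm, 0.991)
})
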