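test_that("window_starts reproduces the reference geometry", {
  st <- window_starts(70000, 30000, 31)
  expect_length(st, 31)
  expect_equal(st[1], 0L)
  expect_equal(st[31], 40000L)
  expect_true(all(diff(st) >= 0))
  expect_true(all(abs(diff(st) - 40000 / 30) <= 1))
  expect_equal(window_starts(70000, 30000, 1), 0L)
  expect_equal(window_starts(70000, 30000, 2), c(0L, 40000L))
  expect_error(window_starts(100, 200, 5), "window_length")
})

test_that("nn_classify returns the nearest label with stable ties", {
  train <- matrix(c(0, 1), ncol = 1)
  expect_equal(nn_classify(0.2, train, c("N", "CHF")), "N")
  expect_equal(nn_classify(0.9, train, c("N", "CHF")), "CHF")
  # exact match wins at distance zero
  tr2 <- matrix(c(0.1, 0.4, 0.9, 0.2, 0.5, 0.8), ncol = 2)
  expect_equal(nn_classify(c(0.4, 0.5), tr2, c("A", "B", "C")), "B")
  # equidistant training rows resolve to the lowest index
  tr3 <- matrix(c(1, 1), ncol = 1)
  expect_equal(nn_classify(1, tr3, c("first", "second")), "first")
  expect_error(nn_classify(c(1, 2), train, c("N", "CHF")), "dimension")
  expect_error(nn_classify(0.2, train, "N"), "label per training row")
})

test_that("mahalanobis ranking equals euclidean under identity covariance", {
  set.seed(42)
  for (rep in 1:100) {
    p <- sample(2:4, 1)
    raw <- matrix(stats::rnorm(12 * p), ncol = p)
    # whiten so the sample covariance is exactly the identity
    W <- backsolve(chol(stats::cov(raw)), diag(p))
    train <- raw %*% W
    labels <- paste0("L", seq_len(nrow(train)))
    test <- stats::rnorm(p)
    expect_equal(
      nn_classify(test, train, labels, distance = "mahalanobis"),
      nn_classify(test, train, labels, distance = "euclidean"))
  }
})

test_that("vote thresholds pin the 29-vs-30-of-31 boundary", {
  cfg <- ensemble_config(window_length = 10, train_length = 20, mc = 31,
                         feature_set = "ctm")
  # 30 of 31 wrong: 30/31 = 0.9677 > 0.95 -> flagged, and with fg = 1 the
  # single flag decides (1/1 > 0.95)
  r30 <- sodphrv:::classify_subject_features(1, vote_fixture(30, 31), cfg)
  expect_equal(r30$P, 1L)
  expect_true(r30$misclassified)
  # 29 of 31 wrong: 0.9355 <= 0.95 -> not flagged
  r29 <- sodphrv:::classify_subject_features(1, vote_fixture(29, 31), cfg)
  expect_equal(r29$P, 0L)
  expect_false(r29$misclassified)
  # all realizations correct
  r0 <- sodphrv:::classify_subject_features(1, vote_fixture(0, 31), cfg)
  expect_false(r0$misclassified)
})

test_that("group vote is strict across feature subsets", {
  # two features -> fg = 3 subsets; doctor the fixture so only some flag
  feats <- vote_fixture(31, 31)
  feats$train <- cbind(feats$train, d_mean = c(0, 0, 1))
  feats$test <- lapply(feats$test, function(m) {
    cbind(m, d_mean = rep(0, nrow(m)))     # d_mean always correct for N
  })
  cfg <- ensemble_config(window_length = 10, train_length = 20, mc = 31,
                         feature_set = c("ctm", "d_mean"))
  res <- sodphrv:::classify_subject_features(1, feats, cfg)
  # {ctm} flags (all wrong); {d_mean} and {ctm,d_mean} classify correctly,
  # so 1 of 3 groups <= 0.95 and the subject is not misclassified
  expect_length(res$P, 3)
  expect_false(res$misclassified)
})

test_that("held-out subject is provably absent from training", {
  feats <- vote_fixture(0, 5)
  feats$train[1, ] <- NA_real_   # poison the held-out subject's train row
  cfg <- ensemble_config(window_length = 10, train_length = 20, mc = 5,
                         feature_set = "ctm")
  # if row 1 ever entered the training set or covariance this would error
  res <- sodphrv:::classify_subject_features(1, feats, cfg)
  expect_false(res$misclassified)
  cfg_m <- ensemble_config(distance = "mahalanobis", window_length = 10,
                           train_length = 20, mc = 5, feature_set = "ctm")
  expect_no_error(sodphrv:::classify_subject_features(1, feats, cfg_m))
})

test_that("missing feature values count realizations as misclassified", {
  feats <- vote_fixture(0, 4)
  feats$test[[1]][, 1] <- NA_real_   # every realization lacks the feature
  cfg <- ensemble_config(window_length = 10, train_length = 20, mc = 4,
                         feature_set = "ctm")
  res <- sodphrv:::classify_subject_features(1, feats, cfg)
  expect_true(res$misclassified)
})

test_that("classify_subject matches the cohort-level run", {
  cohort <- small_cohort(n_per_group = 3, n_beats = 1500, seed = 33)
  cfg <- ensemble_config(window_length = 700, train_length = 1500, mc = 5,
                         feature_set = c("ctm", "d_mean"))
  single <- classify_subject(cohort[[2]], cohort, cfg)
  reports <- run_experiment(cohort, list(cfg))
  expect_equal(single$misclassified,
               reports[[1]]$per_subject$misclassified[2])
  expect_equal(single$P, reports[[1]]$P[2, ])
  expect_length(single$P, 3)
  expect_error(classify_subject(generate_subject(
    cohort_spec(1, 1500, seed = 99), "N", 7), cohort, cfg), "not in cohort")
})

test_that("experiments are deterministic and report counts consistently", {
  cohort <- small_cohort(n_per_group = 4, n_beats = 1500, seed = 44,
                         succ_chf = 0.03, sd_chf = 0.06)
  cfgs <- table_grid_configs(window_length = 700, train_length = 1500, mc = 5)
  r1 <- run_experiment(cohort, cfgs)
  r2 <- run_experiment(cohort, cfgs)
  expect_identical(lapply(r1, `[[`, "per_subject"),
                   lapply(r2, `[[`, "per_subject"))
  expect_length(r1, 8)
  for (rep in r1) {
    mis <- rep$per_subject$misclassified
    expect_equal(rep$n_misclassified_n, sum(mis & rep$per_subject$group == "N"))
    expect_equal(rep$n_misclassified_chf,
                 sum(mis & rep$per_subject$group == "CHF"))
  }
})

test_that("misclassification never increases with larger separation", {
  count_errors <- function(succ_chf, sd_chf) {
    cohort <- small_cohort(n_per_group = 5, n_beats = 1200, seed = 77,
                           succ_chf = succ_chf, sd_chf = sd_chf)
    cfg <- ensemble_config(window_length = 500, train_length = 1200, mc = 5)
    rep <- run_experiment(cohort, list(cfg))[[1]]
    rep$n_misclassified_n + rep$n_misclassified_chf
  }
  ladder <- c(
    count_errors(succ_chf = 0.039, sd_chf = 0.078),  # nearly null
    count_errors(succ_chf = 0.030, sd_chf = 0.060),
    count_errors(succ_chf = 0.015, sd_chf = 0.040))  # strong contrast
  expect_true(all(diff(ladder) <= 0))
})

test_that("sdrr_threshold_baseline optimizes and counts errors", {
  vals <- c(0.09, 0.08, 0.085, 0.03, 0.035, 0.04)
  labs <- c("N", "N", "N", "CHF", "CHF", "CHF")
  res <- sdrr_threshold_baseline(vals, labs)
  expect_equal(res$n_misclassified, 0)
  expect_gt(res$threshold, 0.04)
  expect_lt(res$threshold, 0.08)
  # fixed threshold path
  res2 <- sdrr_threshold_baseline(vals, labs, threshold = 0.087)
  expect_equal(res2$n_misclassified, 2)
  # degenerate: identical values -> best achievable is the smaller class
  res3 <- sdrr_threshold_baseline(rep(0.05, 6), c("N", "N", "N", "N",
                                                  "CHF", "CHF"))
  expect_equal(res3$n_misclassified, 2)
})

test_that("ensemble is at least as robust as a single-window classifier", {
  wins <- 0L
  n_rep <- 20
  for (k in seq_len(n_rep)) {
    cohort <- small_cohort(n_per_group = 4, n_beats = 1200, seed = 300 + k,
                           succ_chf = 0.034, sd_chf = 0.068)
    cfg_ens <- ensemble_config(window_length = 400, train_length = 1200,
                               mc = 9)
    cfg_one <- ensemble_config(window_length = 400, train_length = 1200,
                               mc = 1)
    reps <- run_experiment(cohort, list(cfg_ens, cfg_one))
    err <- vapply(reps, function(r) {
      r$n_misclassified_n + r$n_misclassified_chf
    }, integer(1))
    if (err[1] <= err[2]) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})
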