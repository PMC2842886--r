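test_that("pooled t agrees with the stats::t.test reference", {
  set.seed(71)
  for (rep in 1:50) {
    a <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1),
                      sd = stats::runif(1, 0.1, 2))
    b <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1),
                      sd = stats::runif(1, 0.1, 2))
    mine <- two_sample_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$ci, as.numeric(ref$conf.int), tolerance = 1e-10)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$h, as.integer(ref$p.value < 0.05))
  }
})

test_that("h, p and ci are mutually consistent", {
  set.seed(72)
  for (rep in 1:30) {
    a <- stats::rnorm(12)
    b <- stats::rnorm(12, mean = stats::runif(1, 0, 1.5))
    res <- two_sample_t(a, b)
    expect_equal(res$h, as.integer(res$p < 0.05))
    ci_excludes_zero <- res$ci[1] > 0 || res$ci[2] < 0
    expect_equal(res$h == 1L, ci_excludes_zero)
  }
})

test_that("degenerate groups are handled explicitly", {
  expect_message(res <- two_sample_t(rep(1, 4), rep(1, 4)), "p = 1")
  expect_equal(res$p, 1)
  expect_equal(res$h, 0L)
  res2 <- two_sample_t(rep(0, 4), rep(1, 4))
  expect_equal(res2$h, 1L)
  expect_equal(res2$p, 0)
  expect_false(res2$ci[1] <= 0 && res2$ci[2] >= 0)
  # clear separation with tiny jitter
  set.seed(73)
  res3 <- two_sample_t(stats::rnorm(4, 0, 1e-6), stats::rnorm(4, 1, 1e-6))
  expect_equal(res3$h, 1L)
  expect_true(res3$ci[2] < 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

# hand-built long-format feature table: group means differ only for radii
# inside [0.01, 0.02]
toy_feature_table <- function(grid, n_per = 10, seed = 5) {
  set.seed(seed)
  rows <- list()
  for (g in c("N", "CHF")) {
    for (i in seq_len(n_per)) {
      shift <- ifelse(grid >= 0.01 & grid <= 0.02 & g == "CHF", 0.3, 0)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = paste0(g, i), group = g, feature = "ctm", r = grid,
        value = 0.5 + shift + stats::rnorm(length(grid), 0, 0.05))
    }
  }
  do.call(rbind, rows)
}

test_that("sweep_radius returns the argmin-p radius with a full trace", {
  grid <- seq(0.005, 0.05, by = 0.005)
  tbl <- toy_feature_table(grid)
  sel <- sweep_radius(tbl, "ctm", grid)
  expect_s3_class(sel, "radius_selection")
  expect_gte(sel$r_best, 0.01)
  expect_lte(sel$r_best, 0.02)
  expect_equal(sel$p, min(sel$grid$p))
  expect_true(all(sel$p <= sel$grid$p))
  expect_equal(nrow(sel$grid), length(grid))
  # single-point grid selects that point
  sel1 <- sweep_radius(tbl, "ctm", 0.015)
  expect_equal(sel1$r_best, 0.015)
})

test_that("sweep_radius breaks p ties toward the smaller radius", {
  # identical values at every radius make every p equal
  grid <- c(0.01, 0.02, 0.03)
  rows <- expand.grid(subject_id = paste0("S", 1:8), r = grid)
  rows$group <- rep(c("N", "CHF"), each = 4)[match(rows$subject_id,
                                                   paste0("S", 1:8))]
  set.seed(6)
  vals <- stats::rnorm(8)
  rows$value <- vals[match(rows$subject_id, paste0("S", 1:8))]
  rows$feature <- "ctm"
  expect_message(sel <- sweep_radius(rows, "ctm", grid), "smaller r")
  expect_equal(sel$r_best, 0.01)
})

test_that("sweep_radius errors name the missing or undefined subject", {
  grid <- c(0.01, 0.02)
  tbl <- toy_feature_table(grid, n_per = 3)
  expect_error(sweep_radius(tbl[tbl$subject_id != "N1" |
                                  tbl$r != 0.01, ], "ctm", grid), "N1")
  tbl2 <- tbl
  tbl2$value[tbl2$subject_id == "CHF2" & tbl2$r == 0.02] <- NA
  expect_error(sweep_radius(tbl2, "ctm", grid), "CHF2")
  expect_error(sweep_radius(tbl, "nope", grid), "not in table")
})

test_that("select_radii covers every feature on a real synthetic cohort", {
  cohort <- small_cohort(n_per_group = 5, n_beats = 3000, seed = 14)
  grid <- seq(0.005, 0.05, by = 0.005)
  gtab <- feature_radius_grid(cohort, grid)
  tab <- select_radii(gtab, grid)
  expect_setequal(tab$feature,
                  c("ctm", "d_mean", paste0("cctm", 1:4), "sdrr"))
  # strong separation: every feature should reject the null here
  expect_true(all(tab$h == 1))
  expect_true(is.na(tab$r_best[tab$feature == "sdrr"]))
  # CTM-type confidence intervals are negative (N below CHF), SDRR positive
  expect_lt(tab$ci_high[tab$feature == "ctm"], 0)
  expect_gt(tab$ci_low[tab$feature == "sdrr"], 0)
})

test_that("type-I error at a fixed radius is nominal on null cohorts", {
  # identical generative parameters for both groups; ctm at r = 0.015
  n_rep <- 200
  hits <- 0L
  for (k in seq_len(n_rep)) {
    cohort <- small_cohort(n_per_group = 6, n_beats = 400, seed = 1000 + k,
                           succ_chf = 0.04, sd_chf = 0.08)
    ft <- cohort_feature_table(cohort)
    res <- two_sample_t(ft$ctm[ft$group == "N"], ft$ctm[ft$group == "CHF"])
    hits <- hits + res$h
  }
  bounds <- stats::qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})
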