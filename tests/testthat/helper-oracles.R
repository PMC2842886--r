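# Independent brute-force oracles and small fixture builders. The oracles
# recompute every feature with explicit per-point loops straight from the
# defining sums, sharing no code with the package implementation.

naive_sodp <- function(x) {
  n <- length(x)
  xx <- numeric(n - 2)
  yy <- numeric(n - 2)
  for (i in seq_len(n - 2)) {
    xx[i] <- x[i + 1] - x[i]
    yy[i] <- x[i + 2] - x[i + 1]
  }
  list(xx = xx, yy = yy, n = n)
}

naive_ctm <- function(x, r) {
  p <- naive_sodp(x)
  cnt <- 0L
  for (i in seq_along(p$xx)) {
    if (sqrt(p$xx[i]^2 + p$yy[i]^2) < r) cnt <- cnt + 1L
  }
  cnt / (p$n - 2)
}

naive_d_mean <- function(x, r) {
  p <- naive_sodp(x)
  acc <- numeric(0)
  for (i in seq_along(p$xx)) {
    d <- sqrt(p$xx[i]^2 + p$yy[i]^2)
    if (d < r) acc <- c(acc, d)
  }
  if (length(acc) == 0) NA_real_ else mean(acc)
}

naive_cctm <- function(x, r) {
  p <- naive_sodp(x)
  cnt <- integer(4)
  for (i in seq_along(p$xx)) {
    xx <- p$xx[i]; yy <- p$yy[i]
    if (sqrt(xx^2 + yy^2) >= r) next
    q <- if (xx == 0 && yy == 0) 1L
    else if (xx >= 0 && yy > 0) 1L
    else if (xx < 0 && yy >= 0) 2L
    else if (xx <= 0 && yy < 0) 3L
    else 4L
    cnt[q] <- cnt[q] + 1L
  }
  cnt / (p$n - 2)
}

# Raw sodp_points from given difference streams (bypasses a source series;
# used for spec-style point-level examples).
points_fixture <- function(xx, yy) {
  structure(list(xx = xx, yy = yy, n_source = length(xx) + 2L),
            class = "sodp_points")
}

random_rr <- function(n, sd = 0.03, mean_rr = 0.8) {
  rr_series(pmax(0.2, mean_rr + stats::rnorm(n, 0, sd)),
            subject_id = "RND", group = "unknown")
}

# Small two-group cohort for classifier tests; succ-diff scales control the
# separation.
small_cohort <- function(n_per_group = 6, n_beats = 2000, seed = 1,
                         succ_n = 0.04, succ_chf = 0.015,
                         sd_n = 0.08, sd_chf = 0.04, ...) {
  generate_cohort(
    cohort_spec(n_per_group, n_beats, sd_base_s = sd_n,
                succ_diff_sd_s = succ_n, seed = seed, ...),
    cohort_spec(n_per_group, n_beats, sd_base_s = sd_chf,
                succ_diff_sd_s = succ_chf, seed = seed, ...))
}

# Hand-built leave-one-out feature bundle for vote-boundary tests: subject 1
# (true N) has `wrong` of `mc` realizations nearer the CHF training vector.
# After subject 1 is held out the training set is {0 -> N, 1 -> CHF}.
vote_fixture <- function(wrong, mc) {
  test1 <- matrix(c(rep(1, wrong), rep(0, mc - wrong)), ncol = 1,
                  dimnames = list(NULL, "ctm"))
  filler <- matrix(1, nrow = mc, ncol = 1, dimnames = list(NULL, "ctm"))
  list(train = matrix(c(0, 0, 1), ncol = 1,
                      dimnames = list(c("N01", "N02", "CHF01"), "ctm")),
       test = list(test1, filler, filler),
       labels = c("N", "N", "CHF"),
       subject_ids = c("N01", "N02", "CHF01"))
}
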