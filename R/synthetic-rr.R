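#' Specification of one synthetic cohort
#'
#' Describes the generative model for one group of subjects. The clean signal
#' is a stationary mean-reverting AR(1) on the RR values: the two scale
#' parameters control the two axes the SODP features probe independently —
#' `sd_base_s` is the long-term (stationary) SD and `succ_diff_sd_s` the SD of
#' successive differences, giving `phi = 1 - succ_diff_sd_s^2 / (2 sd_base_s^2)`
#' and innovation SD `sd_base_s * sqrt(1 - phi^2)`. A CHF-like cohort uses a
#' smaller `succ_diff_sd_s` than an N-like cohort (depressed short-term
#' variability).
#'
#' @param n_subjects_per_group Number of subjects this spec generates.
#' @param n_beats Beats per subject (default 70000, a full Holter-scale
#'   record).
#' @param mean_rr_s Mean RR interval in seconds (default 0.8 s, 75 bpm).
#' @param sd_base_s Long-term SD of the clean signal, seconds.
#' @param succ_diff_sd_s SD of successive differences of the clean signal,
#'   seconds; must be < 2 * `sd_base_s`. Zero gives a noiseless constant
#'   series (degenerate but allowed for testing).
#' @param trend_amplitude_s Amplitude of an added slow sinusoid (two cycles
#'   over the record), seconds; 0 disables.
#' @param ectopic_rate Per-beat probability of injecting an ectopic
#'   (short beat followed by a compensatory pause); in [0, 0.5).
#' @param seed Master seed; per-subject streams are derived from it so a
#'   cohort is order-independent.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group, n_beats = 70000L,
                        mean_rr_s = 0.8, sd_base_s = 0.08,
                        succ_diff_sd_s = 0.04, trend_amplitude_s = 0,
                        ectopic_rate = 0, seed = 1L) {
  n_subjects_per_group <- as.integer(n_subjects_per_group)
  n_beats <- as.integer(n_beats)
  if (n_subjects_per_group < 1L) stop("cohort_spec: need >= 1 subject")
  if (n_beats < 3L) stop("cohort_spec: need >= 3 beats")
  if (mean_rr_s <= 0 || sd_base_s < 0 || succ_diff_sd_s < 0 ||
      trend_amplitude_s < 0) {
    stop("cohort_spec: scale parameters must be non-negative, mean_rr_s > 0")
  }
  if (succ_diff_sd_s > 0 && succ_diff_sd_s >= 2 * sd_base_s) {
    stop("cohort_spec: succ_diff_sd_s must be < 2 * sd_base_s ",
         "(AR(1) feasibility)")
  }
  if (ectopic_rate < 0 || ectopic_rate >= 0.5) {
    stop("cohort_spec: ectopic_rate must be in [0, 0.5)")
  }
  structure(
    list(n_subjects_per_group = n_subjects_per_group, n_beats = n_beats,
         mean_rr_s = mean_rr_s, sd_base_s = sd_base_s,
         succ_diff_sd_s = succ_diff_sd_s,
         trend_amplitude_s = trend_amplitude_s,
         ectopic_rate = ectopic_rate, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Deterministic per-subject substream seed: a small multiplicative hash of
# (master seed, group, subject index), kept inside the 32-bit signed range.
subject_stream_seed <- function(seed, group, subject_index) {
  g <- if (identical(group, "CHF")) 2L else 1L
  m <- 2147483629               # large prime < 2^31
  h <- (as.double(seed) %% m)
  h <- (h * 48271 + g * 7919) %% m
  h <- (h * 48271 + as.double(subject_index) * 104729) %% m
  as.integer(h)
}

#' Generate one synthetic subject
#'
#' Clean signal: stationary AR(1) around `mean_rr_s` (see [cohort_spec()]).
#' Then, optionally, a slow sinusoidal trend is added and ectopic beats are
#' injected by replacing a randomly chosen beat with a short interval (0.6 x
#' the local median) followed by a compensatory pause (1.4 x), the standard
#' premature-beat morphology.
#'
#' @param spec A [cohort_spec()].
#' @param group `"N"` or `"CHF"` — the label attached to the series (the
#'   generative parameters come from `spec`; build one spec per group).
#' @param subject_index 1-based index within the group; part of the stream
#'   seed, so subjects are reproducible individually.
#' @return An [rr_series()] of `spec$n_beats` beats,
#'   `preprocessed = FALSE`. Injected ectopic positions are recorded in
#'   `meta$ectopic_idx`.
#' @export
generate_subject <- function(spec, group = c("N", "CHF"), subject_index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  subject_index <- as.integer(subject_index)
  n <- spec$n_beats

  stream <- subject_stream_seed(spec$seed, group, subject_index)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(stream)

  if (spec$succ_diff_sd_s == 0 || spec$sd_base_s == 0) {
    z <- numeric(n)                               # noiseless degenerate case
  } else {
    phi <- 1 - spec$succ_diff_sd_s^2 / (2 * spec$sd_base_s^2)
    sig_e <- spec$sd_base_s * sqrt(1 - phi^2)
    e <- stats::rnorm(n, 0, sig_e)
    z0 <- stats::rnorm(1, 0, spec$sd_base_s)       # stationary start
    z <- as.numeric(stats::filter(e, phi, method = "recursive", init = z0))
  }
  x <- spec$mean_rr_s + z
  if (spec$trend_amplitude_s > 0) {
    x <- x + spec$trend_amplitude_s * sin(2 * pi * 2 * seq_len(n) / n)
  }

  ect_idx <- integer(0)
  if (spec$ectopic_rate > 0 && n >= 14L) {
    flag <- stats::runif(n) < spec$ectopic_rate
    cand <- which(flag)
    cand <- cand[cand >= 12L & cand <= n - 1L]
    # an ectopic occupies beats (i, i+1); drop candidates colliding with the
    # previous kept one
    if (length(cand) > 1L) {
      kept <- cand[1L]
      for (i in cand[-1L]) {
        if (i > kept[length(kept)] + 1L) kept <- c(kept, i)
      }
      cand <- kept
    }
    for (i in cand) {
      m_loc <- stats::median(x[(i - 11L):(i - 1L)])
      x[i] <- 0.6 * m_loc
      x[i + 1L] <- 1.4 * m_loc
    }
    ect_idx <- cand
  }

  rr_series(x, subject_id = sprintf("%s%02d", group, subject_index),
            group = group, preprocessed = FALSE,
            meta = list(stream_seed = stream, ectopic_idx = ect_idx))
}

#' Generate a labeled two-cohort dataset
#'
#' @param spec_n [cohort_spec()] for the N-like group.
#' @param spec_chf [cohort_spec()] for the CHF-like group. For a paper-like
#'   contrast its `succ_diff_sd_s` should be below `spec_n`'s.
#' @return List of [rr_series()], N subjects first, then CHF.
#' @export
generate_cohort <- function(spec_n, spec_chf) {
  stopifnot(inherits(spec_n, "cohort_spec"), inherits(spec_chf, "cohort_spec"))
  c(
    lapply(seq_len(spec_n$n_subjects_per_group),
           function(i) generate_subject(spec_n, "N", i)),
    lapply(seq_len(spec_chf$n_subjects_per_group),
           function(i) generate_subject(spec_chf, "CHF", i))
  )
}

#' Write a cohort to per-subject RR files plus a manifest
#'
#' One plain-text file per subject (one interval in seconds per line) and a
#' `manifest.csv` with columns `subject_id, group, path`, readable back with
#' [read_rr_manifest()].
#'
#' @param cohort List of [rr_series()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_rr_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    fname <- paste0(s$subject_id, ".rr.txt")
    writeLines(formatC(s$rr_s, format = "f", digits = 6),
               file.path(dir, fname))
    data.frame(subject_id = s$subject_id, group = s$group, path = fname,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}
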