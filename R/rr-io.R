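#' Read a single-column RR-interval file
#'
#' Reads the plain-text format used by PhysioNet-style RR databases: one
#' numeric interval per line, `#` comment lines skipped. Values are taken as
#' seconds; if every parsed value exceeds 10 the file is assumed to be in
#' milliseconds and is divided by 1000 (a message notes the conversion).
#'
#' @param path Path to the file.
#' @param subject_id Subject identifier to attach.
#' @param group Cohort label (`"N"`, `"CHF"`, `"unknown"`).
#' @return An [rr_series()] with `preprocessed = FALSE`.
#' @export
read_rr_file <- function(path, subject_id, group = "unknown") {
  if (!file.exists(path)) stop("read_rr_file: no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  line_no <- seq_along(raw)
  txt <- trimws(raw)
  keep <- nzchar(txt) & !startsWith(txt, "#")
  txt <- txt[keep]
  line_no <- line_no[keep]
  if (length(txt) == 0L) stop("read_rr_file: empty input: ", path)
  vals <- suppressWarnings(as.numeric(txt))
  if (anyNA(vals)) {
    bad <- line_no[which(is.na(vals))[1L]]
    stop(sprintf("read_rr_file: non-numeric value at line %d of %s", bad, path))
  }
  if (all(vals > 10)) {
    message("read_rr_file: values look like milliseconds; dividing by 1000 (",
            path, ")")
    vals <- vals / 1000
  }
  rr_series(vals, subject_id = subject_id, group = group, preprocessed = FALSE)
}

#' Remove ectopic beats by a running-median percentage filter
#'
#' Walks the series keeping a buffer of accepted beats; a beat deviating from
#' the median of the preceding 11 accepted beats by more than
#' `tolerance_fraction` (relative to that median) is deleted. The first 11
#' beats are accepted unconditionally. Surviving intervals are unchanged, so
#' a second pass at the same tolerance removes nothing.
#'
#' @param series An [rr_series()].
#' @param tolerance_fraction Relative deviation threshold in (0, 1);
#'   default 0.2.
#' @return The filtered `rr_series` (same `preprocessed` flag). Indices of
#'   removed beats (in the input series) are stored in
#'   `meta$removed_ectopic_idx`.
#' @export
remove_ectopic <- function(series, tolerance_fraction = 0.2) {
  stopifnot(inherits(series, "rr_series"))
  if (!(tolerance_fraction > 0 && tolerance_fraction < 1)) {
    stop("remove_ectopic: tolerance_fraction must be in (0, 1)")
  }
  x <- series$rr_s
  n <- length(x)
  if (n < 12L) {
    warning("remove_ectopic: fewer than 12 beats; series returned unchanged")
    return(series)
  }
  keep <- rep(TRUE, n)
  acc <- numeric(n)        # accepted beats, in order
  acc[1:11] <- x[1:11]
  n_acc <- 11L
  for (i in 12:n) {
    med <- stats::median(acc[(n_acc - 10L):n_acc])
    if (abs(x[i] - med) / med > tolerance_fraction) {
      keep[i] <- FALSE
    } else {
      n_acc <- n_acc + 1L
      acc[n_acc] <- x[i]
    }
  }
  out <- series
  out$rr_s <- x[keep]
  out$meta$removed_ectopic_idx <- which(!keep)
  out
}

#' Remove slow trends by centered moving-average subtraction
#'
#' Subtracts a centered moving average of width `window_beats` and adds back
#' the global mean, so the absolute RR scale (and hence radii in seconds)
#' stays meaningful. At the series ends the window shrinks symmetrically,
#' which preserves length. A series shorter than the window falls back to a
#' global least-squares linear detrend (noted by a message).
#'
#' @param series An [rr_series()].
#' @param window_beats Odd window width in beats, at least 3; default 501.
#' @return The detrended `rr_series`, same length as the input. If detrending
#'   would produce a non-positive interval an error is raised: that signals
#'   pathological input rather than something to clip away.
#' @export
remove_trend <- function(series, window_beats = 501L) {
  stopifnot(inherits(series, "rr_series"))
  window_beats <- as.integer(window_beats)
  if (window_beats < 3L || window_beats %% 2L == 0L) {
    stop("remove_trend: window_beats must be odd and >= 3")
  }
  x <- series$rr_s
  n <- length(x)
  if (n < window_beats) {
    message("remove_trend: series shorter than window; using linear detrend")
    t_ <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, t_), x)
    out_x <- fit$residuals + mean(x)
  } else {
    halfw <- (window_beats - 1L) %/% 2L
    k <- pmin(halfw, seq_len(n) - 1L, n - seq_len(n))
    lo <- seq_len(n) - k
    hi <- seq_len(n) + k
    s <- c(0, cumsum(x))
    ma <- (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
    out_x <- x - ma + mean(x)
  }
  if (any(out_x <= 0)) {
    stop("remove_trend: detrending produced non-positive intervals; ",
         "input looks pathological")
  }
  out <- series
  out$rr_s <- out_x
  out
}

#' Full RR preprocessing: ectopic removal then detrending
#'
#' @param series An [rr_series()].
#' @param tolerance_fraction Passed to [remove_ectopic()].
#' @param window_beats Passed to [remove_trend()].
#' @return The cleaned `rr_series` with `preprocessed = TRUE`.
#' @export
preprocess_rr <- function(series, tolerance_fraction = 0.2,
                          window_beats = 501L) {
  out <- remove_ectopic(series, tolerance_fraction)
  out <- remove_trend(out, window_beats)
  out$preprocessed <- TRUE
  out
}

#' Read a cohort manifest and load all subjects
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `path`; relative
#' paths resolve against the manifest's directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return List of [rr_series()].
#' @export
read_rr_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("read_rr_manifest: no such file: ", manifest_path)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(man))) {
    stop("read_rr_manifest: manifest must have columns ",
         paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_rr_file(p, subject_id = man$subject_id[i], group = man$group[i])
  })
}
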