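#' RR-interval series container
#'
#' Bundles one subject's ordered RR intervals (seconds) with its identity and
#' cohort label. This is the unit every downstream stage operates on.
#'
#' @param rr_s Numeric vector of RR intervals in seconds, strictly positive
#'   and finite, length at least 3 (the second-order difference plot needs
#'   triples).
#' @param subject_id Character scalar identifying the subject.
#' @param group Cohort label, one of `"N"`, `"CHF"`, `"unknown"`.
#' @param preprocessed Logical; `TRUE` once trend and ectopic-beat removal
#'   have been applied.
#' @param meta Optional list of provenance (stream seed, injected ectopic
#'   indices, ...). Not interpreted by the analysis code.
#'
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(rr_s, subject_id, group = c("unknown", "N", "CHF"),
                      preprocessed = FALSE, meta = list()) {
  group <- match.arg(group, c("unknown", "N", "CHF"))
  rr_s <- as.numeric(rr_s)
  if (length(rr_s) < 3L) {
    stop("rr_series: need at least 3 RR intervals, got ", length(rr_s))
  }
  if (!all(is.finite(rr_s)) || any(rr_s <= 0)) {
    stop("rr_series: RR intervals must be finite and strictly positive")
  }
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    stop("rr_series: subject_id must be a non-empty string")
  }
  structure(
    list(subject_id = subject_id, group = group, rr_s = rr_s,
         preprocessed = isTRUE(preprocessed), meta = meta),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s [%s], %d beats, mean RR %.3f s, preprocessed=%s\n",
              x$subject_id, x$group, length(x$rr_s), mean(x$rr_s),
              x$preprocessed))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr_s)

#' Take a contiguous window of beats from a series
#'
#' @param series An [rr_series()].
#' @param start Zero-based offset of the first beat of the window.
#' @param n_beats Window length in beats.
#' @return An `rr_series` covering the requested beats; `preprocessed` and
#'   labels are inherited.
#' @export
rr_window <- function(series, start, n_beats) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$rr_s)
  if (start < 0 || n_beats < 3 || start + n_beats > n) {
    stop(sprintf("rr_window: window [%d, %d) infeasible for %d beats",
                 start, start + n_beats, n))
  }
  out <- series
  out$rr_s <- series$rr_s[(start + 1L):(start + n_beats)]
  out
}
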