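#' Pooled two-sample t-test (Student)
#'
#' Equal-variance two-sided t-test of mean(N) - mean(CHF), computed in closed
#' form with the pooled standard deviation. The confidence interval is at
#' level `1 - alpha` for the difference in means, N minus CHF.
#'
#' Degenerate input (pooled SD exactly zero) is handled explicitly: identical
#' means give `p = 1` (noted by a message); distinct means with zero spread
#' give `p = 0` and a degenerate interval at the observed difference.
#'
#' @param values_n Numeric vector, N group (>= 2 finite values).
#' @param values_chf Numeric vector, CHF group (>= 2 finite values).
#' @param alpha Significance level, default 0.05.
#' @return List with `h` (1 if `p < alpha`), `p`, `ci` (length-2 numeric),
#'   `t`, `df`.
#' @export
two_sample_t <- function(values_n, values_chf, alpha = 0.05) {
  if (length(values_n) < 2L || length(values_chf) < 2L) {
    stop("two_sample_t: each group needs at least 2 values")
  }
  if (!all(is.finite(values_n)) || !all(is.finite(values_chf))) {
    stop("two_sample_t: non-finite values")
  }
  n1 <- length(values_n)
  n2 <- length(values_chf)
  d <- mean(values_n) - mean(values_chf)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(values_n) +
          (n2 - 1) * stats::var(values_chf)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (d == 0) {
      message("two_sample_t: both groups constant and equal; p = 1")
      return(list(h = 0L, p = 1, ci = c(0, 0), t = 0, df = df))
    }
    return(list(h = 1L, p = 0, ci = c(d, d),
                t = sign(d) * Inf, df = df))
  }
  tval <- d / se
  p <- 2 * stats::pt(-abs(tval), df)
  hw <- stats::qt(1 - alpha / 2, df) * se
  list(h = as.integer(p < alpha), p = p, ci = c(d - hw, d + hw),
       t = tval, df = df)
}

#' Per-feature values on a radius grid for a whole cohort
#'
#' Evaluates each radius-dependent SODP feature at every grid radius for
#' every series (SDRR, which has no radius, is included once with `r = NA`).
#' This is the long-format table [sweep_radius()] consumes.
#'
#' @param cohort List of [rr_series()].
#' @param grid Numeric vector of radii in seconds.
#' @return `data.frame` with columns `subject_id`, `group`, `feature`, `r`,
#'   `value`.
#' @export
feature_radius_grid <- function(cohort, grid) {
  if (length(grid) == 0L || any(grid <= 0)) {
    stop("feature_radius_grid: grid must be non-empty positive radii")
  }
  grid <- sort(unique(grid))
  rows <- lapply(cohort, function(s) {
    pts <- make_sodp(s)
    per_r <- lapply(grid, function(r) {
      cc <- cctm(pts, r)
      data.frame(
        feature = c("ctm", "d_mean", paste0("cctm", 1:4)),
        r = r,
        value = c(ctm(pts, r), sodp_mean_distance(pts, r), unname(cc)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, per_r)
    out <- rbind(out, data.frame(feature = "sdrr", r = NA_real_,
                                 value = sdrr(s), stringsAsFactors = FALSE))
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     stringsAsFactors = FALSE), out)
  })
  do.call(rbind, rows)
}

#' Select the radius that best separates the cohorts for one feature
#'
#' Runs [two_sample_t()] at every grid radius and returns the radius with the
#' smallest p (ties broken toward the smaller radius, noted by a message).
#' An empty-disc `NA` value for any subject at some radius is an error naming
#' the subject: the grid should not extend below the cohort's resolution.
#'
#' @param feature_tbl Long table from [feature_radius_grid()].
#' @param feature Feature name (`"ctm"`, `"d_mean"`, `"cctm1"`..`"cctm4"`).
#' @param grid Radii to consider (must be present in the table for every
#'   subject).
#' @param alpha Significance level for `h` and the confidence level.
#' @return Object of class `radius_selection`: list with `feature`, `r_best`,
#'   `p`, `h`, `ci` and the full `grid` trace (`data.frame` of `r`, `p`).
#' @export
sweep_radius <- function(feature_tbl, feature, grid, alpha = 0.05) {
  if (length(grid) == 0L) stop("sweep_radius: empty grid")
  grid <- sort(unique(grid))
  sub <- feature_tbl[feature_tbl$feature == feature, , drop = FALSE]
  if (nrow(sub) == 0L) stop("sweep_radius: feature not in table: ", feature)
  subjects <- unique(feature_tbl$subject_id)
  res <- lapply(grid, function(r) {
    at_r <- sub[!is.na(sub$r) & sub$r == r, , drop = FALSE]
    miss <- setdiff(subjects, at_r$subject_id)
    if (length(miss) > 0L) {
      stop(sprintf("sweep_radius: feature %s missing at r=%g for subject %s",
                   feature, r, miss[1L]))
    }
    if (anyNA(at_r$value)) {
      bad <- at_r$subject_id[which(is.na(at_r$value))[1L]]
      stop(sprintf("sweep_radius: feature %s undefined at r=%g for subject %s",
                   feature, r, bad))
    }
    two_sample_t(at_r$value[at_r$group == "N"],
                 at_r$value[at_r$group == "CHF"], alpha)
  })
  ps <- vapply(res, `[[`, numeric(1), "p")
  best <- which.min(ps)                      # ties -> first, i.e. smaller r
  if (sum(ps == ps[best]) > 1L) {
    message("sweep_radius: p tie on grid; choosing smaller r")
  }
  structure(
    list(feature = feature, r_best = grid[best], p = ps[best],
         h = res[[best]]$h, ci = res[[best]]$ci,
         grid = data.frame(r = grid, p = ps)),
    class = "radius_selection"
  )
}

#' @export
print.radius_selection <- function(x, ...) {
  cat(sprintf("<radius_selection> %s: r=%g, p=%.3g, h=%d, ci=[%.4g, %.4g]\n",
              x$feature, x$r_best, x$p, x$h, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Radius-selection table across all SODP features
#'
#' Convenience wrapper mirroring a per-feature selection table: sweeps every
#' radius-dependent feature and appends the (radius-free) SDRR t-test row.
#'
#' @inheritParams sweep_radius
#' @return `data.frame` with columns `feature`, `r_best`, `p`, `h`,
#'   `ci_low`, `ci_high`.
#' @export
select_radii <- function(feature_tbl, grid, alpha = 0.05) {
  feats <- c("ctm", "d_mean", paste0("cctm", 1:4))
  rows <- lapply(feats, function(f) {
    s <- sweep_radius(feature_tbl, f, grid, alpha)
    data.frame(feature = f, r_best = s$r_best, p = s$p, h = s$h,
               ci_low = s$ci[1], ci_high = s$ci[2],
               stringsAsFactors = FALSE)
  })
  sd_tbl <- feature_tbl[feature_tbl$feature == "sdrr", , drop = FALSE]
  if (nrow(sd_tbl) > 0L) {
    tt <- two_sample_t(sd_tbl$value[sd_tbl$group == "N"],
                       sd_tbl$value[sd_tbl$group == "CHF"], alpha)
    rows <- c(rows, list(data.frame(
      feature = "sdrr", r_best = NA_real_, p = tt$p, h = tt$h,
      ci_low = tt$ci[1], ci_high = tt$ci[2], stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}
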