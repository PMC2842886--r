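#' Configuration of the ensemble 1-NN classifier
#'
#' Defaults follow the reference analysis: `k = 1`; training vectors from
#' 70000-beat records; `mc = 31` test windows of 30000 beats evenly placed
#' within each held-out subject's record; voting thresholds of 0.95 (strict)
#' for both the realization vote and the feature-group vote; all six SODP
#' features.
#'
#' @param distance `"euclidean"` or `"mahalanobis"`.
#' @param k Number of neighbours (odd; default 1).
#' @param window_length Test-window length in beats.
#' @param train_length Training-record length in beats
#'   (`>= window_length`).
#' @param mc Number of test-window realizations per subject.
#' @param realization_threshold Strict fraction of wrong realizations above
#'   which a feature group flags the subject.
#' @param group_threshold Strict fraction of flagged feature groups above
#'   which the subject is declared misclassified.
#' @param feature_set Character subset of
#'   `c("ctm", "d_mean", "cctm1".."cctm4", "sdrr")`; voting runs over all
#'   `2^m - 1` non-empty subsets of it.
#' @param scale_features Z-score features by the training columns before
#'   distance computation (off by default; Mahalanobis rescales inherently).
#' @param window_scheme `"even"` (deterministic, default) or `"random"`
#'   window starts.
#' @param seed Seed for `window_scheme = "random"`.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(distance = c("euclidean", "mahalanobis"),
                            k = 1L, window_length = 30000L,
                            train_length = 70000L, mc = 31L,
                            realization_threshold = 0.95,
                            group_threshold = 0.95,
                            feature_set = c("ctm", "d_mean", "cctm1",
                                            "cctm2", "cctm3", "cctm4"),
                            scale_features = FALSE,
                            window_scheme = c("even", "random"),
                            seed = 1L) {
  distance <- match.arg(distance)
  window_scheme <- match.arg(window_scheme)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("ensemble_config: k must be odd, >= 1")
  window_length <- as.integer(window_length)
  train_length <- as.integer(train_length)
  mc <- as.integer(mc)
  if (window_length < 3L || window_length > train_length) {
    stop("ensemble_config: need 3 <= window_length <= train_length")
  }
  if (mc < 1L) stop("ensemble_config: mc must be >= 1")
  for (th in c(realization_threshold, group_threshold)) {
    if (!(th > 0 && th <= 1)) {
      stop("ensemble_config: thresholds must be in (0, 1]")
    }
  }
  all_feats <- c("ctm", "d_mean", paste0("cctm", 1:4), "sdrr")
  feature_set <- unique(feature_set)
  if (length(feature_set) == 0L || !all(feature_set %in% all_feats)) {
    stop("ensemble_config: feature_set must be a non-empty subset of ",
         paste(all_feats, collapse = ", "))
  }
  structure(
    list(distance = distance, k = k, window_length = window_length,
         train_length = train_length, mc = mc,
         realization_threshold = realization_threshold,
         group_threshold = group_threshold, feature_set = feature_set,
         scale_features = isTRUE(scale_features),
         window_scheme = window_scheme, seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' Evenly spaced test-window start offsets
#'
#' `mc` starts `floor(j * (train_length - window_length) / (mc - 1))` for
#' `j = 0 .. mc-1` (zero-based offsets; a single start 0 when `mc = 1`), so
#' the first window begins at the first beat and the last ends at beat
#' `train_length`.
#'
#' @param train_length,window_length Lengths in beats,
#'   `window_length <= train_length`.
#' @param mc Number of windows, >= 1.
#' @return Integer vector of zero-based offsets, nondecreasing.
#' @export
window_starts <- function(train_length, window_length, mc) {
  if (window_length > train_length || mc < 1L) {
    stop("window_starts: need window_length <= train_length and mc >= 1")
  }
  if (mc == 1L) return(0L)
  span <- as.double(train_length - window_length)
  as.integer(floor((seq_len(mc) - 1) * span / (mc - 1)))
}

# All 2^m - 1 non-empty subsets of a feature set, ordered by size then
# lexicographically; each element is a character vector of feature names.
feature_subsets <- function(feature_set) {
  m <- length(feature_set)
  out <- list()
  for (size in seq_len(m)) {
    cmb <- utils::combn(feature_set, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Regularize a covariance matrix if near-singular: ridge of
# 1e-8 * trace / dim on the diagonal.
regularize_cov <- function(S) {
  p <- nrow(S)
  ok <- tryCatch({
    rc <- rcond(S)
    is.finite(rc) && rc > 1e-10
  }, error = function(e) FALSE)
  if (!ok) {
    lam <- 1e-8 * sum(diag(S)) / p
    if (lam <= 0) lam <- 1e-12
    S <- S + diag(lam, p)
  }
  S
}

# Predict labels for each row of test_mat by k-NN against train_mat.
# Mahalanobis uses the covariance of the training rows; both metrics are
# computed in a whitened space so the inner loop is a single matrix product.
# Distance ties resolve to the lowest training row index (order() is stable).
nn_predict <- function(test_mat, train_mat, train_labels,
                       distance = "euclidean", k = 1L) {
  if (nrow(train_mat) == 0L) stop("nn_predict: empty training set")
  if (!all(is.finite(train_mat)) || !all(is.finite(test_mat))) {
    stop("nn_predict: non-finite feature values")
  }
  if (distance == "mahalanobis") {
    S <- regularize_cov(stats::cov(train_mat))
    U <- chol(S)
    W <- backsolve(U, diag(ncol(train_mat)))   # right-multiplying whitener
    train_mat <- train_mat %*% W
    test_mat <- test_mat %*% W
  }
  d2 <- outer(rowSums(test_mat^2), rowSums(train_mat^2), `+`) -
    2 * tcrossprod(test_mat, train_mat)
  apply_rows <- function(row) {
    nn <- order(row)[seq_len(k)]
    lab <- train_labels[nn]
    names(which.max(table(lab)))
  }
  if (k == 1L) {
    train_labels[max.col(-d2, ties.method = "first")]
  } else {
    apply(d2, 1L, apply_rows)
  }
}

#' Classify one feature vector by k-nearest neighbours
#'
#' @param test Numeric feature vector.
#' @param train Numeric matrix of training vectors (rows), same columns as
#'   `test`.
#' @param train_labels Character labels, one per training row.
#' @param distance `"euclidean"` or `"mahalanobis"` (covariance of the
#'   training rows, ridge-regularized if near-singular).
#' @param k Odd neighbour count, default 1.
#' @return Predicted label. Distance ties go to the lowest training row
#'   index.
#' @export
nn_classify <- function(test, train, train_labels,
                        distance = c("euclidean", "mahalanobis"), k = 1L) {
  distance <- match.arg(distance)
  train <- as.matrix(train)
  if (length(test) != ncol(train)) {
    stop("nn_classify: dimension mismatch between test and train")
  }
  if (length(train_labels) != nrow(train)) {
    stop("nn_classify: one label per training row required")
  }
  nn_predict(matrix(as.numeric(test), nrow = 1L), train, train_labels,
             distance, as.integer(k))
}

# Feature matrices for the leave-one-out experiment: per subject one
# full-record training vector and mc windowed test vectors. Shared across
# configs that agree on the window geometry and radii.
ensemble_features <- function(cohort, config, radii = default_radii()) {
  labels <- vapply(cohort, `[[`, character(1), "group")
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  feat_names <- c("ctm", "d_mean", paste0("cctm", 1:4), "sdrr")
  train <- matrix(NA_real_, nrow = length(cohort), ncol = length(feat_names),
                  dimnames = list(ids, feat_names))
  test <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    n <- length(s$rr_s)
    eff <- min(config$train_length, n)
    if (eff < config$train_length) {
      message(sprintf("ensemble_features: %s has %d < %d beats; using all",
                      s$subject_id, n, config$train_length))
    }
    if (config$window_length > eff) {
      stop("ensemble_features: series shorter than window_length: ",
           s$subject_id)
    }
    train[i, ] <- extract_features(rr_window(s, 0L, eff), radii)
    starts <- if (config$window_scheme == "even") {
      window_starts(eff, config$window_length, config$mc)
    } else {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(config$seed + i)
      st <- sample.int(eff - config$window_length + 1L, config$mc,
                       replace = TRUE) - 1L
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      st
    }
    tm <- matrix(NA_real_, nrow = config$mc, ncol = length(feat_names),
                 dimnames = list(NULL, feat_names))
    for (l in seq_along(starts)) {
      tm[l, ] <- extract_features(
        rr_window(s, starts[l], config$window_length), radii,
        window_id = l)
    }
    test[[i]] <- tm
  }
  list(train = train, test = test, labels = labels, subject_ids = ids)
}

# Eq.-style two-stage vote for one held-out subject given precomputed
# features. Returns the misclassified flag and the per-group vote row.
classify_subject_features <- function(i, feats, config, subsets = NULL) {
  if (is.null(subsets)) subsets <- feature_subsets(config$feature_set)
  fg <- length(subsets)
  labels <- feats$labels
  truth <- labels[i]
  train_all <- feats$train[-i, , drop = FALSE]
  train_labels <- labels[-i]
  test_all <- feats$test[[i]]
  mc <- nrow(test_all)
  P <- integer(fg)
  for (j in seq_len(fg)) {
    cols <- subsets[[j]]
    train <- train_all[, cols, drop = FALSE]
    test <- test_all[, cols, drop = FALSE]
    tr_ok <- stats::complete.cases(train)
    if (!all(tr_ok)) {
      train <- train[tr_ok, , drop = FALSE]
      train_labels_j <- train_labels[tr_ok]
      if (nrow(train) == 0L) {
        stop("classify_subject: no usable training vectors for subset ",
             paste(cols, collapse = "+"))
      }
    } else {
      train_labels_j <- train_labels
    }
    if (config$scale_features) {
      mu <- colMeans(train)
      sg <- apply(train, 2L, stats::sd)
      sg[sg == 0] <- 1
      train <- sweep(sweep(train, 2L, mu), 2L, sg, "/")
      test <- sweep(sweep(test, 2L, mu), 2L, sg, "/")
    }
    te_ok <- stats::complete.cases(test)
    wrong <- rep(TRUE, mc)        # NA feature => realization counts as wrong
    if (any(te_ok)) {
      pred <- nn_predict(test[te_ok, , drop = FALSE], train, train_labels_j,
                         config$distance, config$k)
      wrong[te_ok] <- pred != truth
    }
    P[j] <- as.integer(sum(wrong) / mc > config$realization_threshold)
  }
  list(misclassified = sum(P) / fg > config$group_threshold, P = P)
}

#' Leave-one-out ensemble classification of one subject
#'
#' Holds the subject out, trains on the full-record feature vectors of the
#' remaining subjects, classifies each of the `mc` windowed realizations of
#' the held-out subject within every non-empty subset of
#' `config$feature_set`, and applies the two strict voting thresholds: a
#' feature group flags the subject when more than
#' `realization_threshold` of its realizations are misclassified, and the
#' subject is misclassified when more than `group_threshold` of the groups
#' flag it.
#'
#' @param subject The held-out [rr_series()] (matched within `cohort` by
#'   `subject_id`).
#' @param cohort List of labeled [rr_series()] including `subject`.
#' @param config An [ensemble_config()].
#' @param radii Feature radii, see [extract_features()].
#' @return List with `misclassified` (logical) and `P` (integer vector of
#'   per-feature-group flags, length `2^m - 1`).
#' @export
classify_subject <- function(subject, cohort, config,
                             radii = default_radii()) {
  stopifnot(inherits(subject, "rr_series"), inherits(config, "ensemble_config"))
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  i <- match(subject$subject_id, ids)
  if (is.na(i)) stop("classify_subject: subject not in cohort")
  feats <- ensemble_features(cohort, config, radii)
  classify_subject_features(i, feats, config)
}

# Full leave-one-out pass over precomputed features for one config.
classify_cohort_features <- function(feats, config) {
  subsets <- feature_subsets(config$feature_set)
  res <- lapply(seq_along(feats$labels), function(i) {
    classify_subject_features(i, feats, config, subsets)
  })
  mis <- vapply(res, `[[`, logical(1), "misclassified")
  P <- do.call(rbind, lapply(res, `[[`, "P"))
  per_subject <- data.frame(
    subject_id = feats$subject_ids, group = feats$labels,
    misclassified = mis, stringsAsFactors = FALSE)
  structure(
    list(per_subject = per_subject, P = P,
         feature_groups = vapply(subsets, paste, character(1),
                                 collapse = "+"),
         n_misclassified_n = sum(mis & feats$labels == "N"),
         n_misclassified_chf = sum(mis & feats$labels == "CHF"),
         config = config),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %s | {%s} | misclassified N=%d CHF=%d of %d\n",
    x$config$distance, paste(x$config$feature_set, collapse = ","),
    x$n_misclassified_n, x$n_misclassified_chf, nrow(x$per_subject)))
  invisible(x)
}

#' Run the ensemble experiment for several configurations
#'
#' Computes the train/test feature matrices once per distinct window
#' geometry and evaluates every configuration on them (the feature matrices
#' do not depend on the distance or the feature subset).
#'
#' @param cohort List of labeled [rr_series()].
#' @param configs List of [ensemble_config()] objects.
#' @param radii Feature radii, see [extract_features()].
#' @return List of `classification_report` objects, one per config.
#' @export
run_experiment <- function(cohort, configs, radii = default_radii()) {
  if (inherits(configs, "ensemble_config")) configs <- list(configs)
  geom_key <- vapply(configs, function(cf) {
    paste(cf$window_length, cf$train_length, cf$mc, cf$window_scheme,
          cf$seed, sep = "|")
  }, character(1))
  feats_by_geom <- list()
  lapply(seq_along(configs), function(ci) {
    key <- geom_key[ci]
    if (is.null(feats_by_geom[[key]])) {
      feats_by_geom[[key]] <<- ensemble_features(cohort, configs[[ci]], radii)
    }
    classify_cohort_features(feats_by_geom[[key]], configs[[ci]])
  })
}

#' The reference experiment grid
#'
#' The four feature sets of the headline comparison — CTM alone,
#' {CTM, D}, all six SODP features, and SDRR alone — crossed with the
#' Euclidean and Mahalanobis distances.
#'
#' @param ... Overrides passed to every [ensemble_config()] (e.g. scaled-down
#'   `window_length`, `train_length`, `mc`).
#' @return List of 8 configs.
#' @export
table_grid_configs <- function(...) {
  sets <- list(
    "ctm",
    c("ctm", "d_mean"),
    c("ctm", "d_mean", paste0("cctm", 1:4)),
    "sdrr"
  )
  out <- list()
  for (d in c("euclidean", "mahalanobis")) {
    for (fs in sets) {
      out <- c(out, list(ensemble_config(distance = d, feature_set = fs, ...)))
    }
  }
  out
}

#' SDRR simple-threshold baseline
#'
#' Predicts CHF when a subject's SDRR falls below a threshold — the
#' one-feature rule the ensemble is compared against. With `threshold = NULL`
#' the threshold minimizing the error count is searched over midpoints of
#' the sorted SDRR values (ties go to the lower threshold).
#'
#' @param sdrr_values Named numeric vector of per-subject SDRR (seconds).
#' @param labels Character vector of true groups (`"N"`/`"CHF"`), aligned
#'   with `sdrr_values`.
#' @param threshold Seconds, or `NULL` to optimize.
#' @return List with `n_misclassified`, `threshold`, and the logical
#'   `misclassified` vector.
#' @export
sdrr_threshold_baseline <- function(sdrr_values, labels, threshold = NULL) {
  if (length(sdrr_values) != length(labels)) {
    stop("sdrr_threshold_baseline: values and labels must align")
  }
  if (anyNA(sdrr_values)) stop("sdrr_threshold_baseline: missing SDRR values")
  errs_at <- function(th) {
    pred <- ifelse(sdrr_values < th, "CHF", "N")
    pred != labels
  }
  if (is.null(threshold)) {
    s <- sort(unique(sdrr_values))
    cand <- if (length(s) == 1L) s else (s[-length(s)] + s[-1L]) / 2
    cand <- c(s[1L] - 1e-9, cand, s[length(s)] + 1e-9)
    errs <- vapply(cand, function(th) sum(errs_at(th)), integer(1))
    threshold <- cand[which.min(errs)]
  }
  mis <- errs_at(threshold)
  list(n_misclassified = sum(mis), threshold = threshold,
       misclassified = mis)
}
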