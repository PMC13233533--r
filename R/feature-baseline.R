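# Feature-regression baseline: per-participant ridge regression from
# precomputed item features to responses, with closed-form leave-one-out
# cross-validation. Feature extraction itself (e.g. CNN embeddings) is out of
# scope — any items x features matrix plugs in.

#' Construct an item-feature matrix
#'
#' @param values items x features numeric matrix, no missing values.
#' @param item_ids item identifiers (rows).
#' @param source_tag free-text provenance tag (e.g. `"fc7-4096"`,
#'   `"synthetic-latent"`).
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, item_ids = rownames(values),
                           source_tag = "features") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values))
    stop("feature_matrix: missing values not allowed", call. = FALSE)
  item_ids <- as.character(item_ids)
  if (nrow(values) != length(item_ids))
    stop("feature_matrix: row/id mismatch", call. = FALSE)
  rownames(values) <- item_ids
  structure(list(values = values, item_ids = item_ids,
                 feature_dim = ncol(values), source_tag = source_tag),
            class = "feature_matrix")
}

#' Ridge regression with closed-form leave-one-out cross-validation
#'
#' Fits `y ~ X b` with an L2 penalty `alpha` (no intercept; standardize the
#' features and use centered responses) and computes the exact LOOCV
#' predictions through the hat-matrix identity
#' `loo_i = y_i - (y_i - yhat_i) / (1 - h_ii)`, avoiding n refits. The
#' penalty is selected from `alpha_grid` to maximize the Pearson correlation
#' between LOOCV predictions and responses. The default grid is
#' decade-spaced over 1e-3..1e4.
#'
#' @param features a [feature_matrix()] (or plain matrix).
#' @param responses numeric vector, one response per item.
#' @param alpha_grid positive candidate penalties.
#' @return list with `alpha` (selected), `loocv_predictions`, `r` (its
#'   correlation with the responses), `coef` (ridge coefficients at the
#'   selected alpha refit on all items), and `score_table`.
#' @export
fit_ridge_loocv <- function(features, responses, alpha_grid = 10^seq(-3, 4)) {
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  y <- as.numeric(responses)
  m <- nrow(X)
  if (length(y) != m)
    stop("fit_ridge_loocv: ", m, " items but ", length(y), " responses",
         call. = FALSE)
  if (m < 4L) stop("fit_ridge_loocv: need at least 4 items", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("fit_ridge_loocv: constant responses — correlation undefined",
         call. = FALSE)
  if (any(alpha_grid <= 0))
    stop("fit_ridge_loocv: alphas must be positive", call. = FALSE)
  sv <- svd(X)
  uy <- crossprod(sv$u, y)                     # U'y
  best <- list(r = -Inf)
  scores <- numeric(length(alpha_grid))
  for (a in seq_along(alpha_grid)) {
    alpha <- alpha_grid[a]
    shrink <- sv$d^2 / (sv$d^2 + alpha)
    yhat <- sv$u %*% (shrink * uy)
    h <- rowSums(sweep(sv$u^2, 2, shrink, "*"))  # diag of the hat matrix
    loo <- y - (y - yhat) / (1 - h)
    r <- if (stats::sd(loo) > 0) stats::cor(loo, y) else NA_real_
    scores[a] <- r
    if (!is.na(r) && r > best$r)
      best <- list(alpha = alpha, loo = as.numeric(loo), r = r)
  }
  if (!is.finite(best$r))
    stop("fit_ridge_loocv: all candidate alphas gave undefined scores",
         call. = FALSE)
  coef <- sv$v %*% ((sv$d / (sv$d^2 + best$alpha)) * uy)
  list(alpha = best$alpha, loocv_predictions = best$loo, r = best$r,
       coef = as.numeric(coef),
       score_table = data.frame(alpha = alpha_grid, loocv_r = scores))
}

# Standardize feature columns with the source domain's statistics.
# Zero-variance columns are zeroed out rather than divided by zero.
standardize_features <- function(X, center, scale) {
  Xs <- sweep(X, 2, center)
  ok <- scale > 0
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, scale[ok], "/")
  Xs[, !ok] <- 0
  Xs
}

#' Feature-baseline prediction condition
#'
#' Runs the per-participant ridge baseline for one (source, target) pair.
#' Within-domain (`source == target`): each participant's LOOCV predictions
#' are scored against their own responses. Cross-domain: the penalty is
#' selected by source-domain LOOCV, the model refit once on all source
#' items, then applied to the target items' features and scored against the
#' target responses. Features are standardized per column with
#' source-domain statistics in both cases; responses should be normalized.
#'
#' @param source,target domain labels.
#' @param features named list of [feature_matrix()] per domain; the two
#'   domains must share the feature dimension.
#' @param ratings named list of normalized [rating_matrix()] per domain.
#' @param alpha_grid candidate ridge penalties.
#' @return an `evaluation_report` (predictor `"feature_baseline"`).
#' @export
baseline_condition <- function(source, target, features, ratings,
                               alpha_grid = 10^seq(-3, 4)) {
  fs <- features[[source]]; ft <- features[[target]]
  rs <- ratings[[source]]; rt <- ratings[[target]]
  if (is.null(fs) || is.null(ft) || is.null(rs) || is.null(rt))
    stop("baseline_condition: missing features or ratings for '", source,
         "' / '", target, "'", call. = FALSE)
  if (fs$feature_dim != ft$feature_dim)
    stop("baseline_condition: feature dimension differs (", fs$feature_dim,
         " vs ", ft$feature_dim, ")", call. = FALSE)
  ctr <- colMeans(fs$values)
  scl <- apply(fs$values, 2, stats::sd)
  Xs <- standardize_features(fs$values, ctr, scl)
  within <- identical(source, target)
  Xt <- if (within) NULL else standardize_features(ft$values, ctr, scl)
  n <- length(rs$participant_ids)
  pred <- matrix(NA_real_, nrow(rt$values), n,
                 dimnames = list(rt$item_ids, rt$participant_ids))
  for (j in seq_len(n)) {
    y <- rs$values[, j]
    keep <- !is.na(y)
    fit <- fit_ridge_loocv(Xs[keep, , drop = FALSE], y[keep], alpha_grid)
    if (within) {
      pred[keep, j] <- fit$loocv_predictions
    } else {
      pred[, j] <- Xt %*% fit$coef
    }
  }
  if (within) {
    keep_rows <- rowSums(!is.na(pred)) > 0
    pred <- pred[keep_rows, , drop = FALSE]
  }
  ps <- structure(list(predicted = pred, item_ids = rownames(pred),
                       participant_ids = rt$participant_ids,
                       condition = list(source_domain = source,
                                        target_domain = target,
                                        predictor = "feature_baseline"),
                       fallbacks = 0L),
                  class = "prediction_set")
  # within-domain LOOCV leaves NA at items a participant did not rate; those
  # pairs are already excluded by evaluate() through the truth's missingness
  if (anyNA(ps$predicted)) ps$predicted[is.na(ps$predicted)] <- 0
  evaluate(ps, rt)
}
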