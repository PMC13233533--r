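# Model evaluation: MSE, per-participant correlations aggregated through
# Fisher's z, paired t-tests on transformed correlations, and the
# weight-shuffling permutation test.

#' Fisher z transformation and its inverse
#'
#' `fisher_z(r) = 0.5 * log((1 + r) / (1 - r))` = `atanh(r)`. Correlations are
#' clipped to `1 - 1e-7` in magnitude first so the transform stays finite.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param z Fisher z value(s).
#' @return transformed vector.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# Fisher-averaged group correlation: transform, average, back-transform.
fisher_mean_r <- function(r) tanh(mean(fisher_z(r)))

# Column-wise Pearson correlation between two conforming matrices, NA in
# `O` excluded per column; returns NA where either side has zero variance.
colwise_cor <- function(P, O) {
  if (!anyNA(O)) {
    Pc <- sweep(P, 2, colMeans(P))
    Oc <- sweep(O, 2, colMeans(O))
    den <- sqrt(colSums(Pc^2) * colSums(Oc^2))
    r <- ifelse(den > 0, colSums(Pc * Oc) / ifelse(den > 0, den, 1), NA_real_)
    return(r)
  }
  vapply(seq_len(ncol(O)), function(j) {
    keep <- !is.na(O[, j])
    if (sum(keep) < 3L) return(NA_real_)
    p <- P[keep, j]; o <- O[keep, j]
    if (stats::sd(p) == 0 || stats::sd(o) == 0) return(NA_real_)
    stats::cor(p, o)
  }, numeric(1))
}

#' Mean squared error
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return mean of squared differences; pairs with a missing observation are
#'   dropped.
#' @export
mse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("mse: lengths differ (", length(observed), " vs ",
         length(predicted), ")", call. = FALSE)
  if (length(observed) < 1L) stop("mse: empty input", call. = FALSE)
  keep <- !is.na(observed) & !is.na(predicted)
  d <- observed[keep] - predicted[keep]
  mean(d^2)
}

#' Evaluate predictions against observed responses
#'
#' Computes, for each participant, the Pearson correlation between predicted
#' and observed responses over the evaluated items, aggregates these to a
#' group correlation via Fisher's z (transform, average, back-transform), and
#' pools the squared errors over all participant-item pairs into one MSE.
#' A participant whose predictions have zero variance has an undefined
#' correlation; they are excluded from the Fisher mean and listed in
#' `excluded`.
#'
#' @param pred a `prediction_set` from [predict_slim()],
#'   [predict_neighborhood()], or the feature baseline.
#' @param truth [rating_matrix()] holding the observed responses (normalized
#'   scale expected; only the predicted items are used).
#' @param participants optional subset of participant ids to evaluate.
#' @return object of class `evaluation_report`: `per_participant_r` (named),
#'   `per_participant_mse` (named), `group_r`, `mse`, `condition`,
#'   `n_items_tested`, `excluded`.
#' @export
evaluate <- function(pred, truth, participants = NULL) {
  stopifnot(inherits(pred, "prediction_set"), inherits(truth, "rating_matrix"))
  tr <- subset_items(truth, pred$item_ids)
  if (!identical(tr$item_ids, pred$item_ids))
    stop("evaluate: item ordering mismatch", call. = FALSE)
  pids <- pred$participant_ids
  if (!identical(tr$participant_ids, pids))
    stop("evaluate: participant ids differ", call. = FALSE)
  if (!is.null(participants)) {
    keep <- pids %in% participants
    if (!any(keep)) stop("evaluate: no matching participants", call. = FALSE)
  } else {
    keep <- rep(TRUE, length(pids))
  }
  P <- pred$predicted[, keep, drop = FALSE]
  O <- tr$values[, keep, drop = FALSE]
  pids <- pids[keep]
  n <- length(pids)
  r <- mse_i <- stats::setNames(rep(NA_real_, n), pids)
  for (j in seq_len(n)) {
    obs <- !is.na(O[, j])
    if (sum(obs) < 3L)
      stop("evaluate: participant '", pids[j], "' has fewer than 3 observed ",
           "test responses", call. = FALSE)
    p <- P[obs, j]; o <- O[obs, j]
    mse_i[j] <- mean((o - p)^2)
    if (stats::sd(p) > 0 && stats::sd(o) > 0) r[j] <- stats::cor(p, o)
  }
  excluded <- pids[is.na(r)]
  valid <- r[!is.na(r)]
  structure(list(per_participant_r = r,
                 per_participant_mse = mse_i,
                 group_r = if (length(valid)) fisher_mean_r(valid) else NA_real_,
                 mse = stats::weighted.mean(mse_i, colSums(!is.na(O))),
                 condition = pred$condition,
                 n_items_tested = length(pred$item_ids),
                 excluded = excluded),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cond <- x$condition
  cat(sprintf(
    "<evaluation_report> %s -> %s (%s): group r = %.3f, MSE = %.3f over %d items\n",
    cond$source_domain %||% "?", cond$target_domain %||% "?",
    cond$predictor %||% "?", x$group_r, x$mse, x$n_items_tested))
  invisible(x)
}

#' Paired t-test from the textbook formulas
#'
#' `t = dbar / (s_d / sqrt(n))` with `d = x1 - x2`, `dbar` the sample mean of
#' the differences and `s_d` their sample standard deviation (n - 1
#' denominator); two-tailed p from the t distribution with n - 1 degrees of
#' freedom. When comparing correlation coefficients, Fisher-transform them
#' first ([fisher_z()]).
#'
#' @param x1,x2 paired numeric vectors of equal length `n >= 2`.
#' @return object of class `paired_test_result`: `t`, `dof`, `p_two_tailed`,
#'   `mean_diff`, `sd_diff`, `n`.
#' @export
paired_ttest <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop("paired_ttest: lengths differ", call. = FALSE)
  n <- length(x1)
  if (n < 2L) stop("paired_ttest: need at least 2 pairs", call. = FALSE)
  d <- x1 - x2
  dbar <- mean(d)
  s_d <- stats::sd(d)
  if (s_d == 0) {
    if (dbar == 0) {
      t_stat <- 0
    } else {
      stop("paired_ttest: zero-variance differences with nonzero mean — ",
           "statistic undefined", call. = FALSE)
    }
  } else {
    t_stat <- dbar / (s_d / sqrt(n))
  }
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  structure(list(t = t_stat, dof = n - 1L, p_two_tailed = p,
                 mean_diff = dbar, sd_diff = s_d, n = n),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> t(%d) = %.3f, p = %.4g, mean diff = %.4f\n",
              x$dof, x$t, x$p_two_tailed, x$mean_diff))
  invisible(x)
}

#' Weight-shuffling permutation test of prediction accuracy
#'
#' Tests whether SLIM transfer performance is driven by the specific peer
#' mapping rather than population-level consensus. The weights are fit on the
#' full source domain (no split); the observed statistic is the group
#' correlation (or negative MSE) of predictions for all target items. Each of
#' `B` null iterations applies one random permutation to the rows of W —
#' relabeling which peer each weight points to while preserving every
#' column's weight multiset — and recomputes the statistic. A permuted
#' weight that lands on the diagonal is zeroed, so a participant's own
#' response never enters their prediction in either the observed or the
#' null computation (such leakage systematically inflates the null and
#' destroys the test's calibration).
#'
#' @param W a [fit_slim()] result (fit on the complete source domain).
#' @param target_ratings normalized [rating_matrix()] for the target domain.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param statistic `"group_r"` (default) or `"neg_mse"`.
#' @param shuffle `"rows"` (default; one permutation of peer identities) or
#'   `"per_column"` (independent reassignment of each column's weights among
#'   that column's n - 1 peers).
#' @param convention `"raw"`: `p = #(null >= observed) / B` (the reported
#'   proportion); `"add_one"`: `(1 + #) / (B + 1)`, which avoids exact zeros
#'   and is the convention used in calibration checks.
#' @return object of class `permutation_result`: `observed`,
#'   `null_distribution`, `p_value`, `B`, `seed`, `convention`.
#' @export
permutation_test <- function(W, target_ratings, B = 1000L, seed = 1L,
                             statistic = c("group_r", "neg_mse"),
                             shuffle = c("rows", "per_column"),
                             convention = c("raw", "add_one")) {
  stopifnot(inherits(W, "slim_weights"), inherits(target_ratings, "rating_matrix"))
  statistic <- match.arg(statistic)
  shuffle <- match.arg(shuffle)
  convention <- match.arg(convention)
  if (B < 100L) warning("permutation_test: B < 100 gives a coarse null")
  Wv <- W$values
  if (all(Wv == 0))
    stop("permutation_test: degenerate all-zero weight matrix", call. = FALSE)
  R0 <- target_ratings$values
  Omask <- !is.na(R0)
  R0[!Omask] <- 0
  n <- ncol(R0)
  stat_of <- function(Wmat) {
    pred <- R0 %*% Wmat
    if (statistic == "neg_mse")
      return(-mean((target_ratings$values - pred)[Omask]^2))
    rs <- colwise_cor(pred, target_ratings$values)
    fisher_mean_r(rs[!is.na(rs)])
  }
  observed <- stat_of(Wv)
  null_dist <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      Wp <- if (shuffle == "rows") {
        # one permutation of peer identities; a weight that lands on the
        # diagonal would let a participant predict themselves, so it is
        # zeroed out (the identity permutation is unaffected: diag(W) = 0)
        Wr <- Wv[sample.int(n), , drop = FALSE]
        diag(Wr) <- 0
        Wr
      } else {
        # reassign each column's peer weights among the n - 1 peers,
        # never touching the zero diagonal
        Wp <- Wv
        for (u in seq_len(n)) {
          idx <- seq_len(n)[-u]
          Wp[idx, u] <- Wv[idx[sample.int(n - 1L)], u]
        }
        Wp
      }
      stat_of(Wp)
    }, numeric(1))
  })
  hits <- sum(null_dist >= observed)
  p <- if (convention == "raw") hits / B else (1 + hits) / (B + 1)
  structure(list(observed = observed, null_distribution = null_dist,
                 p_value = p, B = as.integer(B), seed = as.integer(seed),
                 statistic = statistic, shuffle = shuffle,
                 convention = convention),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %s = %.3f, null mean = %.3f, p = %.4g (B = %d)\n",
    x$statistic, x$observed, mean(x$null_distribution), x$p_value, x$B))
  invisible(x)
}
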