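# The two predictors: the neighborhood collaborative-filtering formula and
# the SLIM aggregation-weight model, plus the grid search that tunes it.

as_values <- function(x) {
  if (inherits(x, "rating_matrix")) x$values else as.matrix(x)
}

#' Neighborhood collaborative-filtering prediction
#'
#' Predicts participant u's response to item i as the similarity-weighted
#' average of the other participants' centered responses:
#' `r_hat[u,i] = rbar_u + sum_v sim[u,v] * (r[v,i] - rbar_v) / sum_v |sim[u,v]|`,
#' the neighborhood being every other participant with an observed response to
#' item i. On normalized data the `rbar` terms vanish. If the absolute
#' similarity mass for a (participant, item) is zero, the prediction falls
#' back to `rbar_u` and the event is counted in the result's `fallbacks`.
#'
#' @param sim a [pairwise_similarity()] result over the same participants.
#' @param ratings a [rating_matrix()] carrying the peers' responses.
#' @param items item ids to predict (default: all items of `ratings`).
#' @return object of class `prediction_set`: `predicted` (items x
#'   participants), `item_ids`, `participant_ids`, `condition`, `fallbacks`.
#' @export
predict_neighborhood <- function(sim, ratings, items = ratings$item_ids) {
  stopifnot(inherits(sim, "similarity_matrix"),
            inherits(ratings, "rating_matrix"))
  if (!identical(sim$participant_ids, ratings$participant_ids))
    stop("predict_neighborhood: participant ids differ between similarity ",
         "and ratings", call. = FALSE)
  rsub <- subset_items(ratings, items)
  V <- rsub$values
  rbar <- colMeans(ratings$values, na.rm = TRUE)
  S <- sim$values
  diag(S) <- 0
  obs <- !is.na(V)
  Vc <- sweep(V, 2, rbar)          # centered responses
  Vc[!obs] <- 0
  num <- Vc %*% S                  # sum_v sim_uv (r_vi - rbar_v)
  den <- obs %*% abs(S)            # sum over observed peers of |sim_uv|
  pred <- sweep(ifelse(den > 0, num / ifelse(den > 0, den, 1), 0), 2, rbar, "+")
  n_fallback <- sum(den == 0)
  dimnames(pred) <- list(rsub$item_ids, rsub$participant_ids)
  structure(list(predicted = pred, item_ids = rsub$item_ids,
                 participant_ids = rsub$participant_ids,
                 condition = list(source_domain = sim$domain,
                                  target_domain = ratings$domain,
                                  predictor = "neighborhood"),
                 fallbacks = n_fallback),
            class = "prediction_set")
}

#' SLIM objective value
#'
#' Evaluates `0.5 * ||A - A W||_F^2 + (beta/2) * ||W||_F^2 + lambda * ||W||_1`.
#' Missing entries of `A` are excluded from the residual term (and contribute
#' zero inside the product `A W`).
#'
#' @param A rating matrix (object or plain matrix), items x participants.
#' @param W aggregation weights (`slim_weights` or plain matrix).
#' @param beta ridge penalty, `>= 0`.
#' @param lam lasso penalty, `>= 0`.
#' @return scalar objective value.
#' @export
slim_objective <- function(A, W, beta, lam) {
  if (beta < 0 || lam < 0)
    stop("slim_objective: beta and lam must be nonnegative", call. = FALSE)
  Av <- as_values(A)
  Wv <- if (inherits(W, "slim_weights")) W$values else as.matrix(W)
  A0 <- Av
  A0[is.na(A0)] <- 0
  R <- Av - A0 %*% Wv
  0.5 * sum(R^2, na.rm = TRUE) + beta / 2 * sum(Wv^2) + lam * sum(abs(Wv))
}

#' Fit SLIM aggregation weights
#'
#' Learns a nonnegative, zero-diagonal participants x participants matrix W
#' minimizing `0.5||A - AW||_F^2 + (beta/2)||W||_F^2 + lambda||W||_1` subject
#' to `W >= 0`, `diag(W) = 0`. The problem is column-separable: each
#' participant's column is a nonnegative elastic-net regression of their
#' responses on all other participants' responses, solved by cyclic
#' coordinate descent on the Gram matrix. The penalties multiply the bare
#' objective above — no rescaling by the number of items is applied.
#'
#' @param A_train rating matrix (normalized responses recommended; plain
#'   matrices accepted), items x participants.
#' @param beta ridge penalty `>= 0`.
#' @param lam lasso penalty `>= 0`.
#' @param max_iter coordinate-descent sweep budget per column.
#' @param tol convergence threshold on the largest coefficient change in a
#'   sweep.
#' @return object of class `slim_weights`: `values` (n x n, nonnegative, zero
#'   diagonal), `participant_ids`, `source_domain`, `beta`, `lam`.
#' @export
fit_slim <- function(A_train, beta, lam, max_iter = 10000L, tol = 1e-10) {
  if (beta < 0 || lam < 0)
    stop("fit_slim: beta and lam must be nonnegative", call. = FALSE)
  Av <- as_values(A_train)
  n <- ncol(Av)
  if (n < 2L) stop("fit_slim: need at least 2 participants", call. = FALSE)
  pid <- colnames(Av) %||% paste0("P", seq_len(n))
  domain <- if (inherits(A_train, "rating_matrix")) A_train$domain else "matrix"
  A0 <- Av
  has_na <- anyNA(Av)
  if (has_na) A0[is.na(A0)] <- 0
  G_full <- crossprod(A0)
  W <- matrix(0, n, n, dimnames = list(pid, pid))
  worst <- 0
  for (u in seq_len(n)) {
    if (has_na && anyNA(Av[, u])) {
      rows <- !is.na(Av[, u])
      Gu <- crossprod(A0[rows, , drop = FALSE])
    } else {
      Gu <- G_full
    }
    fit <- slim_cd_col(Gu, Gu[, u], u - 1L, beta, lam,
                       as.integer(max_iter), tol)
    if (!fit$converged) {
      g <- Gu %*% fit$w - Gu[, u] + beta * fit$w
      stop("fit_slim: column '", pid[u], "' did not converge in ", max_iter,
           " sweeps (gradient norm ", signif(sqrt(sum(g^2)), 3), ")",
           call. = FALSE)
    }
    W[, u] <- fit$w
    worst <- max(worst, fit$last_delta)
  }
  W[W < 0] <- 0          # guard against sign noise; solver never goes negative
  diag(W) <- 0
  structure(list(values = W, participant_ids = pid, source_domain = domain,
                 beta = beta, lam = lam),
            class = "slim_weights")
}

#' @export
print.slim_weights <- function(x, ...) {
  cat(sprintf(paste0("<slim_weights> source=%s  %d participants, beta=%g, ",
                     "lambda=%g, %.1f%% nonzero\n"),
              x$source_domain, length(x$participant_ids), x$beta, x$lam,
              100 * mean(x$values > 0)))
  invisible(x)
}

#' Predict a target domain's responses with fitted SLIM weights
#'
#' For participant u and item i, the prediction is the weighted sum of the
#' other participants' observed responses to i: `r_hat[u,i] = sum_v W[v,u] *
#' r[v,i]`. Because `diag(W) = 0`, a participant's own response is never used
#' to predict itself; missing peer responses contribute zero (the mean of the
#' normalized scale). A participant whose weight column is all zero receives
#' the zero prediction and is counted in `fallbacks`.
#'
#' @param W a [fit_slim()] result over the same participants.
#' @param target_ratings normalized [rating_matrix()] in the target domain.
#' @param items item ids to predict (default: all).
#' @return a `prediction_set`.
#' @export
predict_slim <- function(W, target_ratings, items = target_ratings$item_ids) {
  stopifnot(inherits(W, "slim_weights"), inherits(target_ratings, "rating_matrix"))
  if (!identical(W$participant_ids, target_ratings$participant_ids))
    stop("predict_slim: participant ids differ between weights and ratings",
         call. = FALSE)
  rsub <- subset_items(target_ratings, items)
  R0 <- rsub$values
  R0[is.na(R0)] <- 0
  pred <- R0 %*% W$values
  dimnames(pred) <- list(rsub$item_ids, rsub$participant_ids)
  structure(list(predicted = pred, item_ids = rsub$item_ids,
                 participant_ids = rsub$participant_ids,
                 condition = list(source_domain = W$source_domain,
                                  target_domain = target_ratings$domain,
                                  predictor = "slim"),
                 fallbacks = sum(colSums(W$values) == 0)),
            class = "prediction_set")
}

#' Half-split grid search over SLIM regularization parameters
#'
#' For every (beta, lambda) pair the training items are randomly divided into
#' two halves `repeats` times; the model is fit on one half and scored on the
#' other, and the mean validation score over repeats selects the winning
#' pair, with which the weights are refit on all training items. The default
#' score is the Fisher-averaged per-participant Pearson correlation between
#' predicted and observed validation responses; negative MSE is selectable.
#' The default grids are decade-spaced: beta over 1e-4..1e12, lambda over
#' 1e-3..1e2.
#'
#' @param A_train normalized [rating_matrix()] of training items.
#' @param beta_grid,lam_grid numeric vectors of candidate penalties.
#' @param repeats number of seeded half-splits per pair.
#' @param seed integer seed for the half-splits.
#' @param metric `"fisher_r"` (default) or `"mse"`.
#' @return object of class `grid_search_result`: `best_beta`, `best_lam`,
#'   `score_table` (beta, lam, mean_score, repeats), `seed`, and `weights` —
#'   the refit [fit_slim()] result.
#' @export
grid_search <- function(A_train, beta_grid = 10^seq(-4, 12),
                        lam_grid = 10^seq(-3, 2), repeats = 20L, seed = 1L,
                        metric = c("fisher_r", "mse")) {
  stopifnot(inherits(A_train, "rating_matrix"))
  metric <- match.arg(metric)
  if (!length(beta_grid) || !length(lam_grid))
    stop("grid_search: empty grid", call. = FALSE)
  if (length(A_train$item_ids) < 4L)
    stop("grid_search: need at least 4 training items", call. = FALSE)
  split_seeds <- derive_seeds(seed, repeats)
  halves <- lapply(split_seeds, function(s) split_items(A_train, 0.5, s))
  grid <- expand.grid(beta = beta_grid, lam = lam_grid,
                      KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow(grid), repeats)
  for (r in seq_len(repeats)) {
    fit_rm <- subset_items(A_train, halves[[r]]$train_items)
    val_rm <- subset_items(A_train, halves[[r]]$test_items)
    for (g in seq_len(nrow(grid))) {
      W <- fit_slim(fit_rm, grid$beta[g], grid$lam[g])
      pred <- predict_slim(W, val_rm)
      scores[g, r] <- score_predictions(pred$predicted, val_rm$values, metric)
    }
  }
  mean_score <- rowMeans(scores, na.rm = TRUE)
  if (all(is.na(mean_score) | is.nan(mean_score)))
    stop("grid_search: every candidate produced undefined validation scores",
         call. = FALSE)
  best <- which.max(mean_score)
  weights <- fit_slim(A_train, grid$beta[best], grid$lam[best])
  structure(list(best_beta = grid$beta[best], best_lam = grid$lam[best],
                 score_table = data.frame(beta = grid$beta, lam = grid$lam,
                                          mean_score = mean_score,
                                          repeats = repeats),
                 seed = as.integer(seed), metric = metric, weights = weights),
            class = "grid_search_result")
}

# Validation score used by the grid search: Fisher-averaged per-participant
# correlation (or negative MSE). Undefined correlations (zero-variance
# predictions) are dropped from the Fisher mean.
score_predictions <- function(pred, obs, metric = "fisher_r") {
  if (metric == "mse") {
    d <- (obs - pred)[!is.na(obs)]
    return(-mean(d^2))
  }
  rs <- colwise_cor(pred, obs)
  if (all(is.na(rs))) return(NA_real_)
  fisher_mean_r(rs[!is.na(rs)])
}
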