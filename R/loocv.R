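#' Leave-one-out cross-validated elastic-net grid search
#'
#' For every (alpha, lambda) pair of the grid, each subject is predicted
#' by a model trained on all other subjects; the N pooled out-of-fold
#' probabilities are scored by ROC AUC (pooling is the natural choice
#' with single-subject folds). The pair maximizing pooled AUC is
#' selected — ties break toward the sparser model, larger lambda first,
#' then larger alpha — and the final model is refit on all data at that
#' pair. Missing feature values (e.g. densities of out-of-range ROIs)
#' are median-imputed using the training fold only, so no information
#' leaks from the held-out subject.
#'
#' @param X Numeric feature matrix (subjects x features); may contain NA.
#' @param y Binary 0/1 labels, N >= 10.
#' @param config An [enet_config()].
#' @return An `enet_cv` object: `best_alpha`, `best_lambda`, `oof`
#'   (tibble of pooled out-of-fold probabilities at the selected pair),
#'   `roc` ([delong_roc()] of those probabilities), `fit` (the final
#'   all-data `enet_fit`), `auc_grid` (tibble of pooled AUC per grid
#'   pair) and `n_degenerate` folds.
#' @export
loocv_grid_search <- function(X, y, config = enet_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  N <- nrow(X)
  if (N < 10L) {
    abort("LOOCV grid search needs N >= 10.",
          class = "radbone_invalid_parameter")
  }
  if (length(y) != N || !all(y %in% c(0L, 1L))) {
    abort("`y` must be 0/1 labels matching rows of `X`.",
          class = "radbone_invalid_parameter")
  }
  n_alpha <- length(config$alpha_grid)
  n_lambda <- length(config$lambda_grid)
  lam_desc <- rev(config$lambda_grid)
  prob <- array(NA_real_, c(N, n_alpha, n_lambda))
  n_degenerate <- 0L
  for (i in seq_len(N)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    Xtr <- median_impute(X[-i, , drop = FALSE])
    xte <- impute_row(X[i, ], attr(Xtr, "medians"))
    for (a in seq_len(n_alpha)) {
      g <- quiet_small_class(
        glmnet::glmnet(Xtr, ytr, family = "binomial",
                       alpha = config$alpha_grid[a], lambda = lam_desc,
                       standardize = config$standardize,
                       thresh = config$tol, maxit = config$max_iter))
      p <- predict(g, newx = matrix(xte, nrow = 1), s = config$lambda_grid,
                   type = "response")
      prob[i, a, ] <- as.numeric(p)
    }
  }
  if (n_degenerate > 0.1 * N) {
    abort(sprintf("%d of %d LOOCV folds lost a class entirely.",
                  n_degenerate, N),
          class = "radbone_invalid_parameter")
  }
  keep <- !is.na(prob[, 1, 1])
  auc_grid <- expand.grid(alpha = config$alpha_grid,
                          lambda = config$lambda_grid)
  auc_grid$auc <- NA_real_
  for (a in seq_len(n_alpha)) {
    for (l in seq_len(n_lambda)) {
      auc_grid$auc[auc_grid$alpha == config$alpha_grid[a] &
                     auc_grid$lambda == config$lambda_grid[l]] <-
        auc_rank(prob[keep, a, l], y[keep])
    }
  }
  # maximize pooled AUC; ties -> larger lambda, then larger alpha
  ord <- order(auc_grid$auc, auc_grid$lambda, auc_grid$alpha,
               decreasing = TRUE)
  best <- auc_grid[ord[1], ]
  ai <- which(config$alpha_grid == best$alpha)
  li <- which(config$lambda_grid == best$lambda)
  oof <- tibble(subject = seq_len(N)[keep], label = y[keep],
                probability = prob[keep, ai, li])
  fit <- fit_elastic_net_logistic(median_impute(X), y,
                                  alpha = best$alpha, lambda = best$lambda,
                                  config = config)
  structure(
    list(best_alpha = best$alpha, best_lambda = best$lambda,
         oof = oof, roc = delong_roc(oof$probability, oof$label),
         fit = fit, auc_grid = as_tibble(auc_grid),
         n_degenerate = n_degenerate),
    class = "enet_cv")
}

#' @method print enet_cv
#' @export
print.enet_cv <- function(x, ...) {
  cat(sprintf("<enet_cv> selected alpha = %g, lambda = %g; pooled LOOCV ",
              x$best_alpha, x$best_lambda))
  print(x$roc)
  invisible(x)
}

#' @rdname loocv_grid_search
#' @param x,object An `enet_cv`.
#' @param ... Unused.
#' @method glance enet_cv
#' @export
glance.enet_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(best_alpha = x$best_alpha, best_lambda = x$best_lambda,
           n_nonzero = x$fit$n_nonzero, n_degenerate = x$n_degenerate),
    glance(x$roc))
}

#' @rdname loocv_grid_search
#' @method tidy enet_cv
#' @export
tidy.enet_cv <- function(x, ...) tidy(x$fit)

#' @rdname loocv_grid_search
#' @method autoplot enet_cv
#' @export
autoplot.enet_cv <- function(object, ...) autoplot(object$roc, ...)

# column-wise median imputation; medians recorded for reuse on new rows
median_impute <- function(X) {
  med <- apply(X, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  attr(X, "medians") <- med
  X
}

impute_row <- function(x, medians) {
  nas <- is.na(x)
  if (any(nas)) x[nas] <- medians[nas]
  x
}
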