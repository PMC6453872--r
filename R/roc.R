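#' ROC AUC with DeLong 95% confidence interval
#'
#' AUC is the Mann-Whitney probability that a positive scores above a
#' negative (ties count 1/2), with the orientation fixed so that higher
#' scores mean the positive class — reversing the sign of the scores
#' maps AUC to 1 - AUC. The variance comes from DeLong's structural
#' components (via pROC), and the 95% CI is `auc +/- 1.96 * SE`, clipped
#' to \[0, 1\].
#'
#' @param scores Numeric classifier scores/probabilities.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return A `roc_result` object: `auc`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`, plus the scores/labels for plotting.
#' @export
delong_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || anyNA(scores) ||
      !all(labels %in% c(0L, 1L))) {
    abort("`scores` and 0/1 `labels` must be complete and matched.",
          class = "radbone_invalid_parameter")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC undefined: one class is empty.",
          class = "radbone_invalid_parameter")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(r$auc)
  # pROC warns that the DeLong CI of a degenerate (AUC = 1) curve is
  # the point {1}; that is the intended, documented behavior here
  ci <- withCallingHandlers(
    tryCatch(as.numeric(pROC::ci.auc(r, method = "delong")),
             error = function(e) c(auc, auc, auc)),
    warning = function(w) {
      if (grepl("always 1-1", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    })
  structure(
    list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
         n_pos = n_pos, n_neg = n_neg,
         scores = scores, labels = labels),
    class = "roc_result")
}

#' @method print roc_result
#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname delong_roc
#' @param x,object A `roc_result`.
#' @param ... Unused.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname delong_roc
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  thr <- c(Inf, sort(unique(x$scores), decreasing = TRUE))
  purrr::map_dfr(thr, function(t) {
    tibble(threshold = t,
           tpr = mean(x$scores[x$labels == 1L] >= t),
           fpr = mean(x$scores[x$labels == 0L] >= t))
  })
}

#' @rdname delong_roc
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC AUC %.2f (95%% CI %.2f-%.2f)",
                         object$auc, object$ci_low, object$ci_high)) +
    theme_minimal()
}

# fast tie-aware Mann-Whitney AUC used inside the LOOCV grid search
auc_rank <- function(scores, labels) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  (sum(rank(scores)[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
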