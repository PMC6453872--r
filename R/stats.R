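#' Correlation-strength label from the absolute coefficient
#'
#' Closed two-decimal bins: 0.00-0.19 very weak, 0.20-0.39 weak,
#' 0.40-0.59 moderate, 0.60-0.79 strong, 0.80-1.00 very strong. The
#' estimate is rounded to two decimals before binning, so 0.59 is
#' "moderate" and 0.60 is "strong".
#'
#' @param estimate Correlation coefficient in \[-1, 1\].
#' @return One of `"very weak"`, `"weak"`, `"moderate"`, `"strong"`,
#'   `"very strong"`.
#' @export
correlation_strength <- function(estimate) {
  check_number(estimate, "estimate", min = -1, max = 1)
  a <- round(abs(estimate), 2)
  if (a <= 0.19) "very weak"
  else if (a <= 0.39) "weak"
  else if (a <= 0.59) "moderate"
  else if (a <= 0.79) "strong"
  else "very strong"
}

# Shapiro-Wilk normality p; constant or too-short vectors count as
# non-normal (the test is undefined there)
shapiro_p <- function(x) {
  if (length(x) < 3L || length(unique(x)) == 1L) return(0)
  n <- length(x)
  if (n > 5000L) x <- x[seq(1L, n, length.out = 5000L)]
  tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
}

#' Normality-routed correlation with strength label
#'
#' Runs Shapiro-Wilk on each variable; Pearson's r is used when both look
#' normal at `normality_alpha`, otherwise Spearman's rank correlation.
#' The two-sided p-value and the fixed strength label accompany the
#' estimate.
#'
#' @param x,y Paired numeric vectors, n >= 4, no missing values.
#' @param normality_alpha Shapiro-Wilk threshold (default 0.05).
#' @return One-row tibble: `method, estimate, p_value, strength_label,
#'   shapiro_p_x, shapiro_p_y, n`.
#' @export
correlate <- function(x, y, normality_alpha = 0.05) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 4L || anyNA(x) || anyNA(y)) {
    abort("`x` and `y` must be paired complete numeric vectors, n >= 4.",
          class = "radbone_invalid_parameter")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in x or y.",
          class = "radbone_undefined_correlation")
  }
  px <- shapiro_p(x)
  py <- shapiro_p(y)
  method <- if (px >= normality_alpha && py >= normality_alpha)
    "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(method = method, estimate = unname(ct$estimate),
         p_value = ct$p.value,
         strength_label = correlation_strength(unname(ct$estimate)),
         shapiro_p_x = px, shapiro_p_y = py, n = length(x))
}

#' Dunn's pairwise rank test
#'
#' Post hoc for Kruskal-Wallis: pooled midranks, pairwise z statistics
#' with the tie-corrected variance
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{[N(N+1)/12 - \sum(t^3 - t)/(12(N-1))] (1/n_i + 1/n_j)}}
#' and two-sided normal p-values.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`.
#' @return Tibble: `group_i, group_j, z, p_value` per unordered pair.
#' @export
dunn_pairwise <- function(values, groups) {
  if (length(values) != length(groups) || anyNA(values)) {
    abort("`values` and `groups` must be complete and the same length.",
          class = "radbone_invalid_parameter")
  }
  if (length(unique(values)) == 1L) {
    abort("Dunn's test undefined: all values tied.",
          class = "radbone_invalid_parameter")
  }
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) {
    abort("need at least two groups.", class = "radbone_invalid_parameter")
  }
  N <- length(values)
  rk <- rank(values) # midranks for ties
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term
  mean_rank <- tapply(rk, groups, mean)
  n_by <- tapply(rk, groups, length)
  pairs <- utils::combn(lev, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    z <- (mean_rank[[i]] - mean_rank[[j]]) /
      sqrt(var_core * (1 / n_by[[i]] + 1 / n_by[[j]]))
    tibble(group_i = i, group_j = j, z = z, p_value = 2 * pnorm(-abs(z)))
  })
}

#' Three-group comparison with normality routing and post hoc tests
#'
#' Shapiro-Wilk is run per group; when all three groups look normal at
#' `normality_alpha` the omnibus is one-way ANOVA with pooled-variance
#' pairwise t tests as uncorrected post hoc, otherwise Kruskal-Wallis
#' with Dunn's pairwise z tests. Bonferroni multiplies each pairwise p by
#' the family size 3 (capped at 1); no correction is applied across
#' variables. Constant input (all values tied) is routed to the
#' rank-based branch with all p-values 1.
#'
#' @param values Numeric response vector.
#' @param groups Labels in `{0, 1, 2}`, >= 2 observations per group.
#' @param normality_alpha Shapiro-Wilk threshold (default 0.05).
#' @return A `group_comparison` tibble: one row per pairwise comparison
#'   (`0-1`, `0-2`, `1-2`) with `omnibus_test`, `omnibus_p`,
#'   `p_uncorrected`, `p_bonferroni`, plus per-group normality p-values
#'   in the attribute `"shapiro_p"`.
#' @export
compare_three_groups <- function(values, groups, normality_alpha = 0.05) {
  groups <- as.integer(as.character(groups))
  if (!all(sort(unique(groups)) == 0:2)) {
    abort("`groups` must contain all of 0, 1, 2.",
          class = "radbone_invalid_parameter")
  }
  if (any(table(groups) < 2L) || anyNA(values) ||
      length(values) != length(groups)) {
    abort("need >= 2 complete observations per group.",
          class = "radbone_invalid_parameter")
  }
  sw <- vapply(0:2, function(g) shapiro_p(values[groups == g]), numeric(1))
  all_tied <- length(unique(values)) == 1L
  pair_ids <- list(c(0L, 1L), c(0L, 2L), c(1L, 2L))
  if (all(sw >= normality_alpha) && !all_tied) {
    omnibus_test <- "anova"
    omnibus_p <- anova(aov(values ~ factor(groups)))[["Pr(>F)"]][1]
    p_unc <- vapply(pair_ids, function(p) {
      t.test(values[groups == p[1]], values[groups == p[2]],
             var.equal = TRUE)$p.value
    }, numeric(1))
  } else {
    omnibus_test <- "kruskal_wallis"
    if (all_tied) {
      omnibus_p <- 1
      p_unc <- rep(1, 3)
    } else {
      omnibus_p <- kruskal.test(values, factor(groups))$p.value
      dunn <- dunn_pairwise(values, groups)
      p_unc <- vapply(pair_ids, function(p) {
        dunn$p_value[dunn$group_i == as.character(p[1]) &
                       dunn$group_j == as.character(p[2])]
      }, numeric(1))
    }
  }
  out <- tibble(
    comparison = vapply(pair_ids, function(p) paste(p, collapse = "-"),
                        character(1)),
    omnibus_test = omnibus_test,
    omnibus_p = omnibus_p,
    p_uncorrected = p_unc,
    p_bonferroni = pmin(1, 3 * p_unc)
  )
  attr(out, "shapiro_p") <- setNames(sw, paste0("group", 0:2))
  class(out) <- c("group_comparison", class(out))
  out
}

#' Group-comparison table over many features
#'
#' Applies [compare_three_groups()] to each feature column and returns a
#' long summary in the style of a per-variable group table: group means
#' and SDs, the routed omnibus test and p, and the three pairwise
#' p-values with and without Bonferroni correction.
#'
#' @param features Tibble with `subject_id`, `group` and numeric feature
#'   columns.
#' @param feature_cols Character vector of columns to test (default: all
#'   numeric columns except `group`).
#' @param normality_alpha Shapiro-Wilk threshold.
#' @return Tibble, one row per feature x pairwise comparison.
#' @export
group_table <- function(features, feature_cols = NULL, normality_alpha = 0.05) {
  stopifnot(is.data.frame(features), "group" %in% names(features))
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))],
      c("group", "age", "bmi"))
  }
  purrr::map_dfr(feature_cols, function(fc) {
    v <- features[[fc]]
    ok <- !is.na(v)
    cmp <- compare_three_groups(v[ok], features$group[ok], normality_alpha)
    means <- tapply(v[ok], features$group[ok], mean)
    sds <- tapply(v[ok], features$group[ok], sd)
    dplyr::mutate(as_tibble(cmp), variable = fc,
                  mean_g0 = means[["0"]], sd_g0 = sds[["0"]],
                  mean_g1 = means[["1"]], sd_g1 = sds[["1"]],
                  mean_g2 = means[["2"]], sd_g2 = sds[["2"]],
                  .before = 1)
  })
}

#' Feature-wise agreement between processing modes
#'
#' For each feature present in both tables, correlates the minimal-PP
#' value with the clinical-PP value across subjects
#' (normality-routed, see [correlate()]). This is the analysis that shows
#' wedge-calibrated density (GV_mmAl) surviving post-processing while raw
#' GV does not.
#'
#' @param features_minimal,features_clinical Feature tibbles from
#'   [extract_features()] with matching `subject_id`.
#' @param feature_cols Columns to compare (default: shared numeric ones).
#' @return Tibble: `variable, method, estimate, p_value, strength_label, n`.
#' @export
pp_agreement <- function(features_minimal, features_clinical,
                         feature_cols = NULL) {
  joined <- dplyr::inner_join(features_minimal, features_clinical,
                              by = "subject_id",
                              suffix = c("_min", "_cli"))
  if (is.null(feature_cols)) {
    shared <- intersect(names(features_minimal), names(features_clinical))
    feature_cols <- setdiff(
      shared[vapply(features_minimal[shared], is.numeric, logical(1))],
      c("group", "age", "bmi"))
  }
  purrr::map_dfr(feature_cols, function(fc) {
    x <- joined[[paste0(fc, "_min")]]
    y <- joined[[paste0(fc, "_cli")]]
    ok <- !is.na(x) & !is.na(y)
    res <- correlate(x[ok], y[ok])
    dplyr::mutate(res[, c("method", "estimate", "p_value",
                          "strength_label", "n")],
                  variable = fc, .before = 1)
  })
}
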