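test_that("strength labels follow the closed two-decimal bins", {
  expect_equal(correlation_strength(0.00), "very weak")
  expect_equal(correlation_strength(0.19), "very weak")
  expect_equal(correlation_strength(0.20), "weak")
  expect_equal(correlation_strength(-0.39), "weak")
  expect_equal(correlation_strength(0.40), "moderate")
  expect_equal(correlation_strength(0.59), "moderate")
  expect_equal(correlation_strength(0.60), "strong")
  expect_equal(correlation_strength(-0.79), "strong")
  expect_equal(correlation_strength(0.80), "very strong")
  expect_equal(correlation_strength(1.00), "very strong")
  # every |estimate| maps to exactly one label
  labs <- vapply(seq(0, 1, by = 0.01), correlation_strength, character(1))
  expect_true(all(labs %in% c("very weak", "weak", "moderate", "strong",
                              "very strong")))
})

test_that("a perfect linear relation routes to Pearson with r = 1", {
  x <- withr::with_seed(1, rnorm(50))
  res <- correlate(x, 2 * x + 1)
  expect_equal(res$method, "pearson")
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_equal(res$strength_label, "very strong")
})

test_that("heavy-tailed data routes to Spearman", {
  res <- withr::with_seed(7, {
    x <- rnorm(100)
    y <- exp(rnorm(100) * 2) + 0.1 * x
    correlate(x, y)
  })
  expect_equal(res$method, "spearman")
  expect_lt(res$shapiro_p_y, 0.05)
})

test_that("Spearman correlation is invariant to monotone transforms", {
  res <- withr::with_seed(3, {
    x <- exp(rnorm(60))
    y <- x + exp(rnorm(60))
    list(a = correlate(x, y), b = correlate(log(x), y^3))
  })
  expect_equal(res$a$method, "spearman")
  expect_equal(res$a$estimate, res$b$estimate, tolerance = 1e-12)
})

test_that("degenerate correlations are rejected", {
  expect_error(correlate(rep(1, 10), rnorm(10)),
               class = "radbone_undefined_correlation")
  expect_error(correlate(1:3, 1:3), class = "radbone_invalid_parameter")
})

test_that("Dunn z on {1,2,3} vs {4,5,6} matches hand arithmetic", {
  # N = 6, no ties: denominator sqrt((6*7/12) * (1/3 + 1/3)) = sqrt(7/3);
  # mean rank difference = 2 - 5 = -3
  res <- dunn_pairwise(c(1, 2, 3, 4, 5, 6), c("a", "a", "a", "b", "b", "b"))
  z_hand <- -3 / sqrt(3.5 * (2 / 3))
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  expect_gt(res$p_value, 0.04) # |z| just under 1.96: not significant at n = 3
})

test_that("Dunn z is antisymmetric under label swap", {
  vals <- withr::with_seed(11, rnorm(30))
  grp <- rep(c("a", "b", "c"), each = 10)
  swapped <- c(a = "b", b = "a", c = "c")[grp]
  z1 <- dunn_pairwise(vals, grp)
  z2 <- dunn_pairwise(vals, swapped)
  expect_equal(z1$z[z1$group_i == "a" & z1$group_j == "b"],
               -z2$z[z2$group_i == "a" & z2$group_j == "b"],
               tolerance = 1e-12)
})

test_that("the tie correction shrinks the Dunn denominator", {
  vals <- c(1, 1, 1, 2, 2, 3, 3, 3, 4, 5, 5, 6)
  grp <- rep(c("a", "b", "c"), each = 4)
  N <- length(vals)
  t_sizes <- table(vals)
  tie_term <- sum(t_sizes^3 - t_sizes) / (12 * (N - 1))
  expect_gt(tie_term, 0)
  res_tied <- dunn_pairwise(vals, grp)
  # recompute without the tie correction: |z| must be smaller
  rk <- rank(vals)
  mr <- tapply(rk, grp, mean)
  z_uncorr <- (mr[["a"]] - mr[["b"]]) / sqrt((N * (N + 1) / 12) * (2 / 4))
  z_corr <- res_tied$z[res_tied$group_i == "a" & res_tied$group_j == "b"]
  expect_gt(abs(z_corr), abs(z_uncorr))
  expect_error(dunn_pairwise(rep(1, 9), rep(c("a", "b", "c"), 3)),
               class = "radbone_invalid_parameter")
})

test_that("normal groups route to ANOVA, skewed to Kruskal-Wallis", {
  res <- withr::with_seed(5, {
    v_norm <- rnorm(60)
    v_skew <- exp(rnorm(60) * 1.5)
    g <- rep(0:2, each = 20)
    list(a = compare_three_groups(v_norm, g),
         k = compare_three_groups(v_skew, g))
  })
  expect_equal(unique(res$a$omnibus_test), "anova")
  expect_equal(unique(res$k$omnibus_test), "kruskal_wallis")
  expect_equal(res$a$comparison, c("0-1", "0-2", "1-2"))
  expect_true(all(res$a$p_bonferroni >= res$a$p_uncorrected))
  expect_true(all(res$k$p_bonferroni <= 1))
  expect_equal(res$k$p_bonferroni, pmin(1, 3 * res$k$p_uncorrected))
})

test_that("constant input takes the rank-based route with p = 1", {
  res <- compare_three_groups(rep(5, 30), rep(0:2, each = 10))
  expect_equal(unique(res$omnibus_test), "kruskal_wallis")
  expect_equal(unique(res$omnibus_p), 1)
  expect_equal(res$p_uncorrected, rep(1, 3))
})

test_that("groups separated by 3 SD are all pairwise significant", {
  res <- withr::with_seed(9, {
    v <- rnorm(60) + rep(c(0, 3, 6), each = 20)
    compare_three_groups(v, rep(0:2, each = 20))
  })
  expect_true(all(res$p_bonferroni < 0.05))
  expect_lt(unique(res$omnibus_p), 0.001)
})

test_that("group_table and pp_agreement summarize feature tibbles", {
  feats <- withr::with_seed(13, tibble::tibble(
    subject_id = sprintf("S%02d", 1:30),
    group = rep(0:2, each = 10),
    f1 = rnorm(30) + rep(c(0, 1, 2), each = 10),
    f2 = rnorm(30)))
  gt <- group_table(feats, c("f1", "f2"))
  expect_equal(nrow(gt), 6)
  expect_true(all(c("variable", "mean_g0", "omnibus_p") %in% names(gt)))
  feats_b <- feats
  feats_b$f1 <- feats$f1 + withr::with_seed(14, rnorm(30, sd = 0.1))
  pa <- pp_agreement(feats, feats_b, c("f1", "f2"))
  expect_equal(nrow(pa), 2)
  expect_gt(pa$estimate[pa$variable == "f1"], 0.9)
})
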