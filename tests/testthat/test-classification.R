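make_xy <- function(n = 40, p = 3, beta = c(1, -1, 0.5), seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    eta <- X %*% beta[seq_len(p)]
    y <- rbinom(n, 1, plogis(eta))
    list(X = X, y = y)
  })
}

test_that("a huge penalty shrinks all slopes to zero with prevalence intercept", {
  d <- make_xy(seed = 2)
  fit <- fit_elastic_net_logistic(d$X, d$y, alpha = 0.5, lambda = 1e6)
  expect_equal(unname(fit$coefficients), rep(0, 3))
  expect_equal(fit$n_nonzero, 0)
  p_hat <- mean(d$y)
  expect_equal(fit$intercept, qlogis(p_hat), tolerance = 1e-6)
})

test_that("the unpenalized fit matches an independent Newton (glm) oracle", {
  d <- make_xy(n = 40, seed = 3)
  cfg <- enet_config(tol = 1e-12)
  fit <- fit_elastic_net_logistic(d$X, d$y, alpha = 1, lambda = 0, config = cfg)
  oracle <- glm(d$y ~ d$X, family = binomial())
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)[-1]),
               tolerance = 1e-4)
})

test_that("lasso at moderate lambda zeroes noise features more than informative ones", {
  res <- withr::with_seed(4, {
    n <- 80
    X <- matrix(rnorm(n * 22), n, 22,
                dimnames = list(NULL, paste0("f", 1:22)))
    y <- rbinom(n, 1, plogis(1.5 * X[, 1] - 1.5 * X[, 2]))
    fit_elastic_net_logistic(X, y, alpha = 1, lambda = 0.05)
  })
  informative <- res$coefficients[1:2]
  noise <- res$coefficients[3:22]
  expect_true(all(informative != 0))
  expect_gt(mean(noise == 0), 0.5)
})

test_that("n_nonzero is nonincreasing in lambda along the lasso path", {
  d <- make_xy(n = 60, p = 10, beta = c(2, -2, 1, rep(0, 7)), seed = 5)
  lams <- seq(0.001, 0.15, by = 0.009)
  nz <- vapply(lams, function(l) {
    fit_elastic_net_logistic(d$X, d$y, alpha = 1, lambda = l)$n_nonzero
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("DeLong AUC equals the brute-force Mann-Whitney count", {
  for (s in 1:200) {
    d <- withr::with_seed(s, {
      n <- sample(10:40, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
      scores <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
      list(scores = scores, labels = labels)
    })
    roc <- delong_roc(d$scores, d$labels)
    expect_equal(roc$auc, brute_auc(d$scores, d$labels), tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 and sign reversal mirrors it", {
  roc <- delong_roc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1)
  s <- withr::with_seed(8, rnorm(40))
  y <- withr::with_seed(9, rbinom(40, 1, 0.5))
  a <- delong_roc(s, y)
  b <- delong_roc(-s, y)
  expect_equal(b$auc, 1 - a$auc, tolerance = 1e-12)
  expect_equal(b$ci_low, 1 - a$ci_high, tolerance = 1e-9)
  expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
  expect_error(delong_roc(s, rep(1, 40)), class = "radbone_invalid_parameter")
})

test_that("DeLong CI width shrinks with sample size", {
  width <- vapply(c(50, 500), function(n) {
    d <- withr::with_seed(n, {
      y <- rbinom(n, 1, 0.5)
      list(s = rnorm(n) + y, y = y)
    })
    roc <- delong_roc(d$s, d$y)
    roc$ci_high - roc$ci_low
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("the hyperparameter grids contain the published selected values", {
  cfg <- enet_config()
  expect_true(any(abs(cfg$lambda_grid - 0.118) < 1e-12))
  expect_true(any(abs(cfg$lambda_grid - 0.037) < 1e-12))
  expect_equal(which(abs(cfg$lambda_grid - 0.037) < 1e-12), 5L)
  expect_equal(which(abs(cfg$lambda_grid - 0.118) < 1e-12), 14L)
  expect_true(any(abs(cfg$alpha_grid - 1) < 1e-12))
  expect_true(any(abs(cfg$alpha_grid - 0.8) < 1e-12))
  expect_length(cfg$alpha_grid, 19)
  expect_length(cfg$lambda_grid, 17)
})

test_that("LOOCV on label noise shows no optimism leak", {
  # single noise datasets scatter widely (pooled LOOCV probabilities are
  # mildly pessimistic under the null), so average over replicates
  aucs <- vapply(1:3, function(rep) {
    d <- withr::with_seed(10 + rep, {
      X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("f", 1:8)))
      list(X = X, y = rbinom(60, 1, 0.5))
    })
    loocv_grid_search(d$X, d$y,
                      enet_config(alpha_grid = 1,
                                  lambda_grid = seq(0.001, 0.15, 0.018)))$roc$auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("LOOCV recovers signal and is invariant to feature rescaling", {
  d <- withr::with_seed(12, {
    X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(50, 1, plogis(2 * X[, 1] - 2 * X[, 2]))
    list(X = X, y = y)
  })
  cfg <- enet_config(alpha_grid = c(0.5, 1),
                     lambda_grid = c(0.001, 0.037, 0.118))
  cv1 <- loocv_grid_search(d$X, d$y, cfg)
  expect_gt(cv1$roc$auc, 0.7)
  X2 <- d$X
  X2[, 1] <- X2[, 1] * 1000 # positive rescaling of one column
  cv2 <- loocv_grid_search(X2, d$y, cfg)
  expect_equal(cv2$best_alpha, cv1$best_alpha)
  expect_equal(cv2$best_lambda, cv1$best_lambda)
  expect_equal(cv2$roc$auc, cv1$roc$auc, tolerance = 1e-6)
})

test_that("missing features are median-imputed inside training folds", {
  d <- withr::with_seed(14, {
    X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rbinom(40, 1, plogis(2 * X[, 1]))
    X[sample(40, 5), 3] <- NA
    list(X = X, y = y)
  })
  cv <- loocv_grid_search(d$X, d$y,
                          enet_config(alpha_grid = 1,
                                      lambda_grid = c(0.001, 0.037)))
  expect_equal(nrow(cv$oof), 40)
  expect_false(anyNA(cv$oof$probability))
})
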