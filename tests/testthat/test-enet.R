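test_that("soft thresholding follows its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  z <- c(-2.5, -0.3, 0, 0.3, 2.5)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(z, 1), c(-1.5, 0, 0, 0, 1.5))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("the penalized objective has the expected special values", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(0:1, each = 5)
  # null model on balanced labels: average -loglik is log 2, penalty 0
  expect_equal(penalized_objective(0, rep(0, 4), X, y, lambda = 3, alpha = 0.7),
               log(2))
  # lambda = 0: objective is the plain average negative log-likelihood
  b <- c(0.5, -1, 0, 2)
  eta <- drop(1 + X %*% b)
  nll <- mean(log1p(exp(eta)) - y * eta)
  expect_equal(penalized_objective(1, b, X, y, 0, 0.5), nll, tolerance = 1e-10)
  # pure l1 arithmetic: one nonzero coefficient 2.0 at lambda 0.1 adds 0.2
  b1 <- c(0, 2, 0, 0)
  expect_equal(penalized_objective(0, b1, X, y, 0.1, 1) -
                 penalized_objective(0, b1, X, y, 0, 1), 0.2)
  expect_error(penalized_objective(0, rep(0, 4), X, c(y[-1], 2), 1, 0.5), "0/1")
})

test_that("the lambda path starts at the null-model threshold", {
  d <- make_logistic_data(40, 12, seed = 2)
  lam <- lambda_path(d$X, d$y, alpha = 1)
  expect_length(lam, 100)
  expect_true(all(diff(lam) < 0))
  expect_equal(lambda_path(d$X, d$y, alpha = 1, n_lambda = 1), lam[1])
  # KKT at the top of the path: the lasso fit is the null model there
  fit <- fit_enet(d$X, d$y, enet_config(alpha = 1))
  expect_true(all(fit$beta[, 1] == 0))
  expect_equal(fit$beta0[1], qlogis(mean(d$y)), tolerance = 1e-6)
  # and the very next lambda already admits a nonzero coefficient
  expect_gt(sum(fit$beta[, 2] != 0), 0)
  expect_error(lambda_path(d$X, rep(2, 40), 0.5), "0/1")
  expect_error(lambda_path(d$X, rep(1L, 40), 0.5), "constant")
})

test_that("the ridge path floor keeps lambda_max finite at alpha = 0", {
  d <- make_logistic_data(30, 8, seed = 3)
  lam0 <- lambda_path(d$X, d$y, alpha = 0)
  lam1 <- lambda_path(d$X, d$y, alpha = 1)
  expect_equal(lam0[1], lam1[1] / 0.001, tolerance = 1e-10)
})

test_that("deep in the path the fit matches unpenalized logistic regression", {
  d <- make_logistic_data(40, 5, seed = 4)
  lam <- exp(seq(log(0.5), log(1e-6), length.out = 60))
  fit <- fit_enet(d$X, d$y, enet_config(alpha = 0.5, tol = 1e-12,
                                        standardize = FALSE), lambda = lam)
  ml <- glm(d$y ~ d$X, family = binomial)
  expect_equal(unname(c(fit$beta0[60], fit$beta[, 60])),
               unname(coef(ml)), tolerance = 1e-3)
})

test_that("coordinate descent agrees with a proximal-gradient oracle", {
  cases <- expand.grid(alpha = c(0.25, 0.5, 1), lambda = c(0.05, 0.15),
                       seed = c(10, 20, 30))
  for (i in seq_len(nrow(cases))) {
    a <- cases$alpha[i]; lam <- cases$lambda[i]
    d <- make_logistic_data(30, 8, seed = cases$seed[i])
    path <- exp(seq(log(0.6), log(lam), length.out = 15))
    fit <- fit_enet(d$X, d$y, enet_config(alpha = a, tol = 1e-13,
                                          standardize = FALSE), lambda = path)
    oracle <- prox_grad_enet(d$X, d$y, lam, a)
    expect_equal(fit$beta[, 15], oracle$beta, tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(fit$beta0[15], oracle$beta0, tolerance = 1e-4)
  }
})

test_that("KKT conditions hold at convergence", {
  for (a in c(0.5, 1)) {
    d <- make_logistic_data(50, 30, seed = 5)
    fit <- fit_enet(d$X, d$y, enet_config(alpha = a, tol = 1e-12,
                                          standardize = FALSE))
    for (idx in c(20, 50, 90)) {
      viol <- kkt_violation(fit$beta0[idx], fit$beta[, idx], d$X, d$y,
                            fit$lambda_path[idx], a)
      expect_lt(viol[1], 1e-4)   # coordinate stationarity / subgradient bound
      expect_lt(viol[2], 1e-4)   # intercept score
    }
  }
})

test_that("the path cross-checks against glmnet at matched lambdas", {
  d <- make_logistic_data(80, 25, seed = 6)
  fit <- fit_enet(d$X, d$y, enet_config(alpha = 0.5, tol = 1e-12))
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0.5,
                      lambda = fit$lambda_path, thresh = 1e-14, maxit = 1e7)
  for (i in c(10, 40, 70)) {
    gb <- as.numeric(coef(g, s = fit$lambda_path[i], exact = TRUE,
                          x = d$X, y = d$y, thresh = 1e-14))
    expect_lt(max(abs(c(fit$beta0[i], unname(fit$beta[, i])) - gb)), 5e-4)
    expect_equal(unname(fit$beta[, i] != 0), gb[-1] != 0)
  }
})

test_that("the penalized objective is non-increasing over solver iterations", {
  d <- make_logistic_data(40, 15, seed = 7)
  for (a in c(0, 0.5, 1)) {
    fit <- fit_enet(d$X, d$y, enet_config(alpha = a, standardize = FALSE),
                    trace = TRUE)
    # IRLS re-approximation is not a strict descent step; any increase must
    # stay at the order of the convergence tolerance
    for (tr in fit$obj_trace) {
      if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-6))
    }
  }
})

test_that("ridge keeps every coefficient nonzero; lasso stays below n", {
  ds <- simulate_dataset(scenario_spec(10, seed = 51))
  y01 <- as.integer(ds$labels == 2)
  ridge <- fit_enet(ds$values, y01, enet_config(alpha = 0))
  expect_true(all(ridge$beta[, 50] != 0))
  expect_true(all(selected_set(ridge, lambda = ridge$lambda_path[50])))

  lasso <- fit_enet(ds$values, y01, enet_config(alpha = 1))
  nnz <- colSums(lasso$beta != 0)
  expect_true(all(nnz <= nrow(ds$values)))
  expect_equal(nnz[1], 0)
  # support grows weakly from the empty set at the top of the path
  expect_true(all(nnz >= 0) && nnz[length(nnz)] > 0)
})

test_that("cross-validation is deterministic and the one-SE rule is conservative", {
  d <- make_logistic_data(60, 40, seed = 8)
  cfg <- enet_config(alpha = 0.5, seed = 99)
  cv1 <- cv_enet(d$X, d$y, cfg)
  cv2 <- cv_enet(d$X, d$y, cfg)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$lambda_chosen, cv2$lambda_chosen)
  expect_identical(selected_set(cv1), selected_set(cv2))

  cfg_min <- enet_config(alpha = 0.5, seed = 99, lambda_rule = "min")
  cv_min <- cv_enet(d$X, d$y, cfg_min)
  expect_gte(cv1$lambda_chosen, cv_min$lambda_chosen)
  expect_equal(cv_min$lambda_chosen, cv_min$lambda_path[which.min(cv_min$cv_mean)])
})

test_that("pure-noise data keeps elastic-net false selection near zero", {
  spec <- scenario_spec(20, rho = 0, deltas = c(0, 0, 0))
  res <- vapply(1:15, function(r) {
    ds <- simulate_dataset(spec, seed = child_seed(700, "null-enet", r))
    cv <- cv_enet(ds$values, as.integer(ds$labels == 2),
                  enet_config(alpha = 0.5, seed = r))
    sel <- selected_set(cv)
    c(empty = sum(sel) == 0, prop = mean(sel))
  }, numeric(2))
  # the one-SE rule frequently lands on the null model, and even when it
  # does not the selected fraction stays near the nominal 5% level
  expect_gte(mean(res["empty", ]), 0.25)
  expect_lt(mean(res["prop", ]), 0.05)
})

test_that("selection needs a chosen lambda and input coding is validated", {
  d <- make_logistic_data(30, 10, seed = 9)
  fit <- fit_enet(d$X, d$y, enet_config(alpha = 1))
  expect_error(selected_set(fit), "chosen lambda")
  expect_error(fit_enet(d$X, d$y + 1, enet_config()), "0/1")
  expect_error(fit_enet(d$X, rep(0L, 30), enet_config()), "both classes")
  expect_error(enet_config(alpha = 1.5), "\\[0, 1\\]")
  expect_error(enet_config(cv_folds = 1), ">= 2")
  expect_error(enet_config(tol = 0), "positive")
})
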