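#' Configuration for the penalized logistic fit
#'
#' Collects the tuning choices of the elastic-net penalized logistic
#' regression: the penalty split `alpha` (0 = ridge, 1 = LASSO), the length
#' and depth of the lambda path, the cross-validation layout, and solver
#' tolerances. Defaults mirror the conventional pathwise coordinate-descent
#' setup: 100 lambda values, 10 folds, binomial deviance as the CV loss, the
#' one-standard-error rule for the final lambda, standardized features, and
#' a convergence tolerance of 1e-7 on the maximum weighted squared
#' coefficient change.
#'
#' @param alpha Penalty split in `[0, 1]`.
#' @param n_lambda Number of lambda values on the path.
#' @param lambda_min_ratio Smallest/largest lambda; default 0.01 when
#'   `n < p`, 1e-4 otherwise (resolved at fit time).
#' @param cv_folds Number of cross-validation folds.
#' @param lambda_rule `"one_se"` (largest lambda within one standard error
#'   of the CV minimum; default) or `"min"`.
#' @param cv_loss `"deviance"` (binomial deviance; default) or `"class"`
#'   (misclassification error).
#' @param max_sweeps Cap on coordinate-descent sweeps per lambda.
#' @param tol Convergence tolerance (must be positive).
#' @param standardize Center and scale features to unit (population)
#'   variance before fitting; coefficients are returned on the original
#'   scale either way.
#' @param seed Integer seed for the CV fold assignment.
#' @return An object of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, n_lambda = 100L, lambda_min_ratio = NULL,
                        cv_folds = 10L, lambda_rule = c("one_se", "min"),
                        cv_loss = c("deviance", "class"),
                        max_sweeps = 1e5, tol = 1e-7,
                        standardize = TRUE, seed = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  cv_loss <- match.arg(cv_loss)
  if (length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  if (n_lambda < 1) stop("`n_lambda` must be >= 1", call. = FALSE)
  if (cv_folds < 2) stop("`cv_folds` must be >= 2", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  structure(
    list(alpha = alpha, n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio, cv_folds = as.integer(cv_folds),
         lambda_rule = lambda_rule, cv_loss = cv_loss,
         max_sweeps = as.integer(max_sweeps), tol = tol,
         standardize = isTRUE(standardize),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "enet_config"
  )
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the proximal operator of the l1 penalty
#' and the elementary update of the coordinate-descent solver.
#'
#' @param z Numeric vector.
#' @param gamma Non-negative threshold(s).
#' @return Thresholded values, same shape as `z`.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("`gamma` must be non-negative", call. = FALSE)
  sign(z) * pmax(abs(z) - gamma, 0)
}

.check_y01 <- function(y01, n) {
  if (length(y01) != n) stop("`y01` must have one entry per sample", call. = FALSE)
  if (!all(y01 %in% c(0, 1))) {
    stop("`y01` must be coded 0/1 (group 2 -> 1)", call. = FALSE)
  }
  invisible(NULL)
}

#' Elastic-net penalized logistic objective
#'
#' The minimization form of the penalized log-likelihood: average negative
#' Bernoulli log-likelihood of the linear predictor `beta0 + X beta` plus
#' `lambda * ((1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1)`. Used for
#' monotonicity checks and oracle comparisons, not inside the solver.
#'
#' @param beta0 Intercept.
#' @param beta Coefficient vector (length = number of features).
#' @param X Samples x features matrix.
#' @param y01 0/1 response (group 2 coded 1).
#' @param lambda Penalty strength.
#' @param alpha Penalty split in `[0, 1]`.
#' @return Objective value (a single number).
#' @export
#' @examples
#' X <- matrix(rnorm(20), 10, 2)
#' penalized_objective(0, c(0, 0), X, rep(0:1, 5), 0.1, 0.5)  # log(2)
penalized_objective <- function(beta0, beta, X, y01, lambda, alpha) {
  X <- as.matrix(X)
  .check_y01(y01, nrow(X))
  if (length(beta) != ncol(X)) stop("`beta` has the wrong length", call. = FALSE)
  eta <- drop(beta0 + X %*% beta)
  nll <- mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y01 * eta)
  nll + lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

# Population-sd standardization (1/n variance, matching the usual
# penalized-regression convention); constant columns get scale 1.
.standardize <- function(X) {
  m <- colMeans(X)
  s <- sqrt(colMeans(X^2) - m^2)
  s[!is.finite(s) | s <= 0] <- 1
  list(X = sweep(sweep(X, 2, m), 2, s, "/"), center = m, scale = s)
}

#' Lambda path for the elastic-net logistic fit
#'
#' The largest lambda is the smallest penalty that keeps every coefficient
#' at zero under the l1 part of the penalty:
#' `max_i |(1/n) sum_j x_ij (y_j - ybar)| / max(alpha, 0.001)` computed on
#' standardized features (the floor on `alpha` keeps the ridge path finite).
#' The path is a geometric sequence of `n_lambda` values decreasing to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param X Samples x features matrix.
#' @param y01 0/1 response; must contain both classes.
#' @param alpha Penalty split.
#' @param n_lambda Path length.
#' @param lambda_min_ratio Smallest/largest lambda; default 0.01 when
#'   `n < p`, else 1e-4.
#' @param standardize Standardize `X` before computing the gradient bound
#'   (default, matching the fit).
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X, y01, alpha, n_lambda = 100,
                        lambda_min_ratio = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  .check_y01(y01, n)
  if (length(unique(y01)) < 2) {
    stop("labels are constant: no signal to scale the path against", call. = FALSE)
  }
  if (standardize) X <- .standardize(X)$X
  ybar <- mean(y01)
  g <- abs(drop(crossprod(X, y01 - ybar))) / n
  lmax <- max(g) / max(alpha, 0.001)
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (n < ncol(X)) 0.01 else 1e-4
  }
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit the elastic-net logistic path
#'
#' Pathwise solver for the penalized logistic likelihood: for each lambda
#' from largest to smallest (warm starts), an iteratively reweighted least
#' squares outer loop builds the quadratic approximation and cyclic
#' coordinate descent with soft-thresholding solves it; the intercept is
#' unpenalized. With `standardize = TRUE` (default) the fit runs on
#' centered/unit-variance features - so the penalty applies to standardized
#' coefficients - and coefficients are returned on the original data scale.
#'
#' @param X Samples x features numeric matrix.
#' @param y01 0/1 response (group 2 coded 1); both classes must be present.
#' @param config An [enet_config()].
#' @param lambda Optional lambda sequence overriding the computed path
#'   (used for cross-validation fold fits, which share the full-data grid).
#' @param trace Record the penalized objective after each IRLS iteration
#'   (for convergence diagnostics).
#' @return An object of class `enet_fit`: `lambda_path`, `beta0` (per
#'   lambda), `beta` (features x lambdas, original scale), `converged`,
#'   `sweeps`, `alpha`, `config`, and `obj_trace` when requested. A warning
#'   is raised (and recorded in `converged`) if any lambda hits the sweep
#'   cap; the best iterate is returned.
#' @seealso [cv_enet()], [selected_set()], [lambda_path()]
#' @export
fit_enet <- function(X, y01, config = enet_config(), lambda = NULL,
                     trace = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  .check_y01(y01, n)
  if (n < 2 || p < 1) stop("need at least 2 samples and 1 feature", call. = FALSE)
  if (length(unique(y01)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  std <- if (config$standardize) {
    .standardize(X)
  } else {
    list(X = X, center = rep(0, p), scale = rep(1, p))
  }
  if (is.null(lambda)) {
    lambda <- lambda_path(std$X, y01, config$alpha, config$n_lambda,
                          config$lambda_min_ratio, standardize = FALSE)
  }
  if (any(lambda < 0) || is.unsorted(rev(lambda), strictly = length(lambda) > 1)) {
    stop("`lambda` must be a positive strictly decreasing sequence", call. = FALSE)
  }
  if (any(lambda == 0) && n <= p) {
    warning("lambda = 0 with n <= p: the unpenalized logistic fit is ",
            "ill-posed; expect instability")
  }
  res <- enet_logistic_path_cpp(std$X, as.numeric(y01), lambda, config$alpha,
                                config$tol, config$max_sweeps, trace)
  beta <- res$beta / std$scale
  beta0 <- res$beta0 - colSums(res$beta * (std$center / std$scale))
  rownames(beta) <- colnames(X)
  if (any(res$converged == 0L)) {
    warning(sum(res$converged == 0L),
            " lambda value(s) hit the sweep cap before converging")
  }
  structure(
    list(lambda_path = lambda, beta0 = beta0, beta = beta,
         converged = res$converged == 1L, sweeps = res$sweeps,
         alpha = config$alpha, config = config,
         obj_trace = if (trace) res$obj_trace else NULL,
         center = std$center, scale = std$scale,
         lambda_chosen = NULL),
    class = "enet_fit"
  )
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("elastic-net logistic path: alpha = %g, %d lambda values\n",
              x$alpha, length(x$lambda_path)))
  if (!is.null(x$lambda_chosen)) {
    cat(sprintf("  lambda chosen (%s rule): %.5g; %d feature(s) selected\n",
                x$config$lambda_rule, x$lambda_chosen, sum(selected_set(x))))
  }
  invisible(x)
}

#' Linear predictor of an elastic-net fit
#'
#' @param object An `enet_fit`.
#' @param newx Samples x features matrix on the original data scale.
#' @param ... Unused.
#' @return Matrix of linear predictors, samples x lambdas.
#' @export
predict.enet_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  sweep(newx %*% object$beta, 2, object$beta0, "+")
}

# Per-observation binomial deviance of linear predictors eta (n x L)
# against 0/1 response; saturated log-likelihood is 0.
.binomial_deviance <- function(eta, y01) {
  2 * (pmax(eta, 0) + log1p(exp(-abs(eta))) - y01 * eta)
}

.assign_folds <- function(y01, k, seed) {
  n <- length(y01)
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    f <- sample(rep_len(seq_len(k), n))
    ok <- all(vapply(seq_len(k),
                     function(j) length(unique(y01[f != j])) == 2, logical(1)))
    if (ok) {
      if (attempt > 0) {
        warning("fold assignment retried ", attempt,
                " time(s) to keep both classes in every training split")
      }
      return(f)
    }
  }
  stop("could not build cross-validation folds with both classes in every ",
       "training split after 10 attempts", call. = FALSE)
}

#' Cross-validated elastic-net logistic fit
#'
#' Fits the full-data lambda path, then refits it on each training split of
#' a seeded k-fold partition and scores the held-out samples at the common
#' lambda grid with the configured CV loss (binomial deviance by default).
#' The final lambda follows `config$lambda_rule`: `"min"` takes the lambda
#' minimizing the mean CV loss; `"one_se"` (default) takes the largest
#' lambda whose mean CV loss is within one standard error of that minimum.
#' Fold assignment is an unstratified seeded shuffle; if a training split
#' ends up one-class the shuffle is retried with a new seed (at most 10
#' times). The selected feature set is the nonzero coefficients at the
#' chosen lambda.
#'
#' @inheritParams fit_enet
#' @return An `enet_fit` with additional fields `cv_mean`, `cv_se` (per
#'   lambda), `lambda_chosen`, `index_chosen`, `folds` and `selected`.
#' @export
cv_enet <- function(X, y01, config = enet_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  .check_y01(y01, n)
  fit <- fit_enet(X, y01, config)
  lam <- fit$lambda_path
  k <- min(config$cv_folds, n)
  seed <- if (is.null(config$seed)) 1L else config$seed
  folds <- .assign_folds(y01, k, seed)

  loss <- matrix(NA_real_, nrow = k, ncol = length(lam))
  for (j in seq_len(k)) {
    tr <- folds != j
    fit_j <- fit_enet(X[tr, , drop = FALSE], y01[tr], config, lambda = lam)
    eta <- predict(fit_j, X[!tr, , drop = FALSE])
    loss[j, ] <- if (config$cv_loss == "deviance") {
      colMeans(.binomial_deviance(eta, y01[!tr]))
    } else {
      colMeans((eta > 0) != (y01[!tr] == 1))
    }
  }
  cv_mean <- colMeans(loss)
  cv_se <- apply(loss, 2, sd) / sqrt(k)
  imin <- which.min(cv_mean)
  ichosen <- if (config$lambda_rule == "one_se") {
    # path is decreasing, so the first index within one SE is the largest lambda
    which(cv_mean <= cv_mean[imin] + cv_se[imin])[1]
  } else {
    imin
  }
  fit$cv_mean <- cv_mean
  fit$cv_se <- cv_se
  fit$folds <- folds
  fit$index_chosen <- ichosen
  fit$lambda_chosen <- lam[ichosen]
  fit$selected <- selected_set(fit)
  fit
}

#' Selected features of an elastic-net fit
#'
#' Features with exactly nonzero coefficients at the chosen lambda, as
#' produced by the soft-thresholding update (no epsilon cutoff). Ridge
#' (`alpha = 0`) applies no l1 thresholding and shrinks without zeroing, so
#' it selects every feature by construction.
#'
#' @param fit An `enet_fit`.
#' @param lambda Lambda at which to read the coefficients; defaults to the
#'   cross-validated choice.
#' @return Logical vector, one entry per feature, named when `X` had column
#'   names.
#' @export
selected_set <- function(fit, lambda = fit$lambda_chosen) {
  stopifnot(inherits(fit, "enet_fit"))
  if (is.null(lambda)) {
    stop("fit has no chosen lambda; run cv_enet() or pass `lambda`",
         call. = FALSE)
  }
  idx <- which.min(abs(fit$lambda_path - lambda))
  if (fit$alpha == 0) {
    sel <- rep(TRUE, nrow(fit$beta))
    names(sel) <- rownames(fit$beta)
    sel
  } else {
    fit$beta[, idx] != 0
  }
}
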