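## l1-penalized empirical-risk minimization: grid construction, a single
## proximal-gradient (FISTA) code path for all three losses, warm-started
## paths and K-fold cross-validation for the penalty.

## intercept-only empirical-risk minimizer
intercept_only_fit <- function(data, loss) {
  y <- data$y
  ybar <- mean(y)
  switch(loss$name,
    logistic = {
      # clamp so that a single-class response gives a finite intercept
      pb <- min(max(ybar, 1 / (2 * data$n)), 1 - 1 / (2 * data$n))
      stats::qlogis(pb)
    },
    quadratic = ybar,
    huber = stats::optimize(
      function(b0) mean(loss_value(b0, y, loss)),
      interval = range(y) + c(-1, 1)
    )$minimum
  )
}

#' Penalty grid for the screening stage
#'
#' Builds a strictly decreasing, log-equispaced grid of l1 penalties.
#' The largest value \eqn{\lambda_1 = \lambda_{\max}} is the sup-norm of
#' the predictor block of the risk gradient at the intercept-only fit —
#' for a convex loss, the smallest penalty at which the penalized solution
#' has empty support (KKT condition at the null model).
#'
#' @param data An [ss_dataset()], normally standardized.
#' @param loss A [loss_spec()].
#' @param m Grid length (at least 2). Default 20.
#' @param ratio Ratio \eqn{\lambda_m / \lambda_1} in (0, 1). Default 0.01.
#' @return Numeric vector of length `m`, strictly decreasing.
#' @export
lambda_grid <- function(data, loss, m = 20L, ratio = 0.01) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (!is.numeric(m) || length(m) != 1L || m < 2) {
    stop("`m` must be an integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must lie in (0, 1).", call. = FALSE)
  }
  b0 <- intercept_only_fit(data, loss)
  g <- risk_gradient(c(b0, rep(0, data$p)), data, loss)
  lmax <- max(abs(g[-1L]))
  if (lmax <= 0) lmax <- .Machine$double.eps
  exp(seq(log(lmax), log(ratio * lmax), length.out = as.integer(m)))
}

## soft-thresholding operator
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit the l1-penalized empirical-risk minimizer at one penalty
#'
#' Minimizes \eqn{R_n(b) + \lambda \|\tilde b\|_1} (intercept unpenalized)
#' by iteratively reweighted penalized least squares: an outer step
#' forms the quadratic approximation of the loss at the current fit
#' (Newton working weights for the logistic loss, exact for the quadratic
#' loss, a true majorizer for the Huber loss), and cyclic coordinate
#' descent with active-set sweeps solves the weighted least-squares
#' subproblem. A step-halving safeguard keeps the penalized objective
#' monotone. One compiled code path serves all three losses. Convergence
#' is declared on the sup-norm of the KKT residual of the original
#' problem.
#'
#' @param data An [ss_dataset()], normally standardized.
#' @param loss A [loss_spec()].
#' @param lambda Positive penalty level.
#' @param tol KKT residual tolerance. Default `1e-7`.
#' @param max_iter Cap on coordinate-descent sweeps. Default `1e4`.
#'   Non-convergence is reported through the `converged` flag, not an
#'   error.
#' @param init Optional warm start: list with `intercept` and `beta`.
#' @return A list of class `"ss_lasso_fit"`: `intercept`, `beta` (length
#'   p, standardized scale), `support` (indices of nonzero entries, as
#'   fitted), `lambda`, `objective`, `kkt`, `iterations` (sweeps used),
#'   `converged`.
#' @export
fit_lasso <- function(data, loss, lambda, tol = 1e-7, max_iter = 1e4,
                      init = NULL) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("`lambda` must be a positive number.", call. = FALSE)
  }
  X <- data$X; y <- data$y; p <- data$p
  if (is.null(init)) {
    b0 <- intercept_only_fit(data, loss)
    bt <- rep(0, p)
  } else {
    b0 <- init$intercept
    bt <- init$beta
  }
  loss_code <- switch(loss$name, logistic = 1L, quadratic = 2L, huber = 3L)
  delta <- if (loss$name == "huber") loss$huber_delta else 0
  fit <- .cd_lasso_fit(X, y, loss_code, delta, lambda,
                       b0, bt, tol, as.integer(max_iter))
  beta <- fit$beta
  obj <- empirical_risk(c(fit$intercept, beta), data, loss) +
    lambda * sum(abs(beta))
  structure(
    list(intercept = fit$intercept, beta = beta,
         support = which(beta != 0), lambda = lambda, objective = obj,
         kkt = fit$kkt, iterations = fit$sweeps,
         converged = fit$converged, loss = loss),
    class = "ss_lasso_fit"
  )
}

#' Fit the penalized path over a penalty grid
#'
#' Applies [fit_lasso()] along a decreasing penalty grid with warm starts
#' from the previous solution.
#'
#' @inheritParams fit_lasso
#' @param lambdas Strictly decreasing positive penalty grid, e.g. from
#'   [lambda_grid()].
#' @return An object of class `"ss_lasso_path"`: `lambdas`, `intercepts`,
#'   `coefficients` (m x p matrix, standardized scale), `supports` (list
#'   of index vectors), `converged` (logical vector), `loss`.
#' @export
fit_lasso_path <- function(data, loss, lambdas, tol = 1e-7, max_iter = 1e4) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 1L || any(lambdas <= 0) ||
      (length(lambdas) > 1L && any(diff(lambdas) >= 0))) {
    stop("`lambdas` must be strictly decreasing and positive.", call. = FALSE)
  }
  m <- length(lambdas)
  coefs <- matrix(0, m, data$p, dimnames = list(NULL, colnames(data$X)))
  ints <- numeric(m)
  supports <- vector("list", m)
  conv <- logical(m)
  init <- NULL
  for (i in seq_len(m)) {
    fit <- fit_lasso(data, loss, lambdas[i], tol = tol, max_iter = max_iter,
                     init = init)
    coefs[i, ] <- fit$beta
    ints[i] <- fit$intercept
    supports[[i]] <- fit$support
    conv[i] <- fit$converged
    init <- list(intercept = fit$intercept, beta = fit$beta)
  }
  structure(
    list(lambdas = lambdas, intercepts = ints, coefficients = coefs,
         supports = supports, converged = conv, loss = loss),
    class = "ss_lasso_path"
  )
}

#' @export
print.ss_lasso_path <- function(x, ...) {
  cat("<ss_lasso_path> ", length(x$lambdas), " penalties, ",
      ncol(x$coefficients), " predictors\n", sep = "")
  df <- data.frame(lambda = signif(x$lambdas, 4),
                   df = vapply(x$supports, length, 1L),
                   converged = x$converged)
  print(utils::head(df, 20), row.names = FALSE)
  invisible(x)
}

## subset the rows of an ss_dataset without re-standardizing
dataset_rows <- function(data, idx) {
  structure(
    list(X = data$X[idx, , drop = FALSE], y = data$y[idx],
         n = length(idx), p = data$p, standardized = data$standardized,
         column_means = data$column_means, column_scales = data$column_scales),
    class = "ss_dataset"
  )
}

## seeded, y-stratified fold assignment
cv_folds <- function(y, K, seed = NULL) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  fold
}

#' Cross-validated choice of the penalty level
#'
#' Estimates held-out prediction risk per penalty by K-fold
#' cross-validation (seeded, y-stratified folds) and selects a penalty by
#' the `"min"` rule (risk minimizer) or the `"1se"` rule (the largest
#' penalty whose CV risk is within one standard error of the minimum).
#'
#' @inheritParams fit_lasso_path
#' @param K Number of folds (>= 2); `K = 10` in the reference experiments.
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed Optional integer seed controlling the fold partition; the
#'   global RNG state is preserved.
#' @return A list of class `"ss_cv"`: `lambda` (the chosen value),
#'   `index`, `cvm`, `cvse`, `lambdas`, `rule`, `folds`, `flags`.
#' @export
cv_select_lambda <- function(data, loss, lambdas, K = 10L,
                             rule = c("1se", "min"), seed = NULL,
                             tol = 1e-7, max_iter = 1e4) {
  loss <- as_loss_spec(loss)
  rule <- match.arg(rule)
  stopifnot(inherits(data, "ss_dataset"))
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be at least 2.", call. = FALSE)
  if (data$n < 2L * K) stop("need n >= 2K observations.", call. = FALSE)
  m <- length(lambdas)
  fold <- cv_folds(data$y, K, seed)
  fold_risk <- matrix(NA_real_, K, m)
  flags <- character(0)
  for (k in seq_len(K)) {
    tr <- dataset_rows(data, which(fold != k))
    te <- dataset_rows(data, which(fold == k))
    if (loss$name == "logistic" && length(unique(tr$y)) < 2L) {
      # degenerate training fold: intercept-only fit at every penalty
      flags <- c(flags, sprintf("fold %d: single response class", k))
      b0 <- intercept_only_fit(tr, loss)
      fold_risk[k, ] <- mean(loss_value(b0, te$y, loss))
      next
    }
    path <- fit_lasso_path(tr, loss, lambdas, tol = tol, max_iter = max_iter)
    eta <- sweep(te$X %*% t(path$coefficients), 2L, path$intercepts, "+")
    fold_risk[k, ] <- vapply(
      seq_len(m), function(i) mean(loss_value(eta[, i], te$y, loss)), 0
    )
  }
  cvm <- colMeans(fold_risk)
  cvse <- apply(fold_risk, 2L, stats::sd) / sqrt(K)
  i_min <- which.min(cvm)
  index <- if (rule == "min") i_min else {
    which(cvm <= cvm[i_min] + cvse[i_min])[1L]  # largest lambda within 1 SE
  }
  structure(
    list(lambda = lambdas[index], index = index, cvm = cvm, cvse = cvse,
         lambdas = lambdas, rule = rule, folds = fold, flags = flags),
    class = "ss_cv"
  )
}

#' Unpenalized empirical-risk refit on a fixed support
#'
#' Minimizes \eqn{R_n(b)} over coefficient vectors whose nonzero predictor
#' coordinates lie in `support`, plus an intercept. The logistic branch
#' uses iteratively reweighted least squares ([stats::glm.fit()]); under
#' perfect separation iteration is capped and `converged = FALSE` is
#' reported with the achieved risk. The quadratic branch is least squares;
#' the Huber branch is smooth BFGS minimization of the package's own risk.
#'
#' @param data An [ss_dataset()].
#' @param support Integer vector of predictor indices (possibly empty);
#'   must satisfy `length(support) <= n - 1`.
#' @param loss A [loss_spec()].
#' @return A list of class `"ss_refit"`: `support` (sorted), `intercept`
#'   and `coefficients` (length p with zeros off support; on the scale of
#'   `data$X`), `intercept_original` and `coefficients_original`
#'   (back-transformed when the dataset is standardized), `risk`
#'   (empirical risk at the minimizer), `converged`, `loss`.
#' @export
refit_erm <- function(data, support, loss) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  support <- sort(unique(as.integer(support)))
  if (length(support) > 0 &&
      (min(support) < 1L || max(support) > data$p)) {
    stop("`support` indices out of range.", call. = FALSE)
  }
  if (length(support) >= data$n) {
    stop("|support| >= n: the restricted minimizer is not identified.",
         call. = FALSE)
  }
  y <- data$y
  k <- length(support)
  conv <- TRUE
  if (k == 0L) {
    b0 <- intercept_only_fit(data, loss)
    bs <- numeric(0)
  } else {
    Xs <- data$X[, support, drop = FALSE]
    Z <- cbind(1, Xs)
    if (loss$name == "logistic") {
      fit <- suppressWarnings(
        stats::glm.fit(Z, y, family = stats::binomial(),
                       control = stats::glm.control(maxit = 50))
      )
      cf <- fit$coefficients
      if (anyNA(cf)) { cf[is.na(cf)] <- 0; conv <- FALSE }
      if (!isTRUE(fit$converged)) conv <- FALSE
      if (isTRUE(fit$boundary)) conv <- FALSE
      b0 <- cf[1L]; bs <- cf[-1L]
    } else if (loss$name == "quadratic") {
      fit <- stats::lm.fit(Z, y)
      cf <- fit$coefficients
      if (anyNA(cf)) { cf[is.na(cf)] <- 0; conv <- FALSE }
      b0 <- cf[1L]; bs <- cf[-1L]
    } else {
      start <- stats::lm.fit(Z, y)$coefficients
      start[is.na(start)] <- 0
      fn <- function(b) mean(loss_value(drop(Z %*% b), y, loss))
      gr <- function(b) {
        g <- loss_deriv(drop(Z %*% b), y, loss)
        drop(crossprod(Z, g)) / data$n
      }
      opt <- stats::optim(start, fn, gr, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (opt$convergence != 0) conv <- FALSE
      b0 <- opt$par[1L]; bs <- opt$par[-1L]
    }
  }
  beta <- rep(0, data$p)
  beta[support] <- bs
  risk <- empirical_risk(c(b0, beta), data, loss)
  # back-transform to the original predictor scale
  sc <- data$column_scales; mu <- data$column_means
  beta_orig <- unname(beta / sc)
  b0_orig <- b0 - sum(beta * mu / sc)
  structure(
    list(support = support, intercept = unname(b0), coefficients = beta,
         intercept_original = unname(b0_orig),
         coefficients_original = beta_orig,
         risk = risk, converged = conv, loss = loss),
    class = "ss_refit"
  )
}

#' @export
print.ss_refit <- function(x, ...) {
  cat("<ss_refit> ", x$loss$name, " loss, |support| = ",
      length(x$support), ", risk = ", format(x$risk, digits = 6),
      if (!x$converged) " (not converged)" else "", "\n", sep = "")
  invisible(x)
}
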