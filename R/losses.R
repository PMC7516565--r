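#' Loss specification for binary empirical-risk minimization
#'
#' Constructs the pointwise loss \eqn{\rho(s, y)} used by every fitting
#' routine in the package, where \eqn{s = b^T x} is the linear predictor and
#' \eqn{y \in \{0,1\}} the binary response (treated as numeric under the
#' quadratic and Huber losses).
#'
#' The three supported losses are
#' \describe{
#'   \item{logistic}{\eqn{\rho(s,y) = -ys + \log(1 + e^s)}, the negative
#'     Bernoulli log-likelihood under the logistic link; 1-Lipschitz in
#'     \eqn{s}.}
#'   \item{quadratic}{\eqn{\rho(s,y) = (y - s)^2 / 2}, ordinary least
#'     squares applied to the 0/1 response; not Lipschitz.}
#'   \item{huber}{the Huber function of the residual \eqn{r = y - s}:
#'     \eqn{r^2/2} for \eqn{|r| \le \delta} and
#'     \eqn{\delta(|r| - \delta/2)} beyond; \eqn{\delta}-Lipschitz in
#'     \eqn{s}.}
#' }
#'
#' @param name One of `"logistic"`, `"quadratic"`, `"huber"`.
#' @param huber_delta Positive transition point \eqn{\delta} of the Huber
#'   loss; ignored for the other losses. Default `0.1`.
#' @return An object of class `"loss_spec"` with elements `name`,
#'   `huber_delta` and `lipschitz_constant` (the constant \eqn{L} in
#'   \eqn{|\rho(s_1,y)-\rho(s_2,y)| \le L|s_1-s_2|}, or `Inf` for the
#'   quadratic loss, which is not Lipschitz on the real line).
#' @examples
#' loss_spec("logistic")
#' loss_spec("huber", huber_delta = 0.1)
#' @export
loss_spec <- function(name = c("logistic", "quadratic", "huber"),
                      huber_delta = 0.1) {
  name <- match.arg(name)
  if (name == "huber") {
    if (!is.numeric(huber_delta) || length(huber_delta) != 1L ||
        !is.finite(huber_delta) || huber_delta <= 0) {
      stop("`huber_delta` must be a positive finite number.", call. = FALSE)
    }
  }
  L <- switch(name, logistic = 1, huber = huber_delta, quadratic = Inf)
  structure(
    list(name = name,
         huber_delta = if (name == "huber") huber_delta else NA_real_,
         lipschitz_constant = L),
    class = "loss_spec"
  )
}

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec> ", x$name, sep = "")
  if (x$name == "huber") cat(" (delta = ", format(x$huber_delta), ")", sep = "")
  cat("\n  Lipschitz constant:",
      if (is.finite(x$lipschitz_constant)) format(x$lipschitz_constant)
      else "unbounded", "\n")
  invisible(x)
}

as_loss_spec <- function(loss) {
  if (inherits(loss, "loss_spec")) return(loss)
  if (is.character(loss) && length(loss) == 1L) return(loss_spec(loss))
  stop("`loss` must be a loss_spec or a loss name.", call. = FALSE)
}

#' Evaluate a pointwise loss
#'
#' Computes \eqn{\rho(s, y)} elementwise. The logistic branch is evaluated
#' overflow-safely as \eqn{\max(s,0) - ys + \log(1 + e^{-|s|})}.
#'
#' @param s Numeric vector of linear-predictor values.
#' @param y Numeric vector of responses (recycled against `s`); must lie in
#'   \{0,1\} for the logistic loss.
#' @param loss A [loss_spec()] (or a loss name).
#' @return Numeric vector of nonnegative loss values.
#' @examples
#' loss_value(0, 1, loss_spec("logistic"))   # log 2
#' loss_value(0, 1, loss_spec("quadratic"))  # 0.5
#' @export
loss_value <- function(s, y, loss) {
  loss <- as_loss_spec(loss)
  stopifnot(is.numeric(s), is.numeric(y))
  if (loss$name == "logistic" && !all(y %in% c(0, 1))) {
    stop("logistic loss requires y in {0, 1}.", call. = FALSE)
  }
  switch(loss$name,
    logistic = pmax(s, 0) - y * s + log1p(exp(-abs(s))),
    quadratic = (y - s)^2 / 2,
    huber = {
      r <- abs(y - s)
      d <- loss$huber_delta
      ifelse(r <= d, r^2 / 2, d * (r - d / 2))
    }
  )
}

## derivative of rho(s, y) with respect to s, vectorized
loss_deriv <- function(s, y, loss) {
  switch(loss$name,
    logistic = stats::plogis(s) - y,
    quadratic = s - y,
    huber = -pmin(pmax(y - s, -loss$huber_delta), loss$huber_delta)
  )
}

#' Assemble a modelling dataset
#'
#' Bundles a numeric design matrix and a binary response, optionally
#' standardizing each predictor column to sample mean 0 and sample standard
#' deviation 1 (the scale on which the l1 penalty is applied). Column means
#' and scales are recorded so that fitted coefficients can be reported on
#' the original scale.
#'
#' @param X Numeric matrix, n observations by p predictors, without an
#'   intercept column.
#' @param y Numeric response of length n with values in \{0,1\}.
#' @param standardize Standardize the columns of `X`? Default `TRUE`; a
#'   column that is constant (zero variance) is an error.
#' @return An object of class `"ss_dataset"`: a list with `X`, `y`, `n`,
#'   `p`, `standardized`, `column_means`, `column_scales`.
#' @examples
#' d <- ss_dataset(matrix(rnorm(40), 10, 4), rbinom(10, 1, 0.5))
#' colMeans(d$X)  # ~ 0
#' @export
ss_dataset <- function(X, y, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop("`y` must be binary with values in {0, 1}.", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 observations.", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X).", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  mu <- rep(0, p); sc <- rep(1, p)
  if (standardize) {
    mu <- colMeans(X)
    sc <- apply(X, 2L, stats::sd)
    if (any(sc < 1e-12)) {
      stop("constant predictor column(s): ",
           paste(colnames(X)[sc < 1e-12], collapse = ", "), call. = FALSE)
    }
    X <- sweep(sweep(X, 2L, mu, "-"), 2L, sc, "/")
  }
  structure(
    list(X = X, y = y, n = n, p = p, standardized = standardize,
         column_means = mu, column_scales = sc),
    class = "ss_dataset"
  )
}

#' @export
print.ss_dataset <- function(x, ...) {
  cat("<ss_dataset> n = ", x$n, ", p = ", x$p,
      if (x$standardized) ", standardized" else "", "\n", sep = "")
  invisible(x)
}

#' Empirical risk of a coefficient vector
#'
#' The sample-average loss \eqn{R_n(b) = n^{-1} \sum_i \rho(b^T x_i, y_i)}
#' where \eqn{b = (b_0, \tilde b)} carries the intercept in its first
#' component.
#'
#' @param beta Numeric vector of length p + 1, intercept first.
#' @param data An [ss_dataset()].
#' @param loss A [loss_spec()].
#' @return The scalar empirical risk.
#' @export
empirical_risk <- function(beta, data, loss) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (length(beta) != data$p + 1L) {
    stop("`beta` must have length p + 1 (intercept first).", call. = FALSE)
  }
  eta <- drop(beta[1L] + data$X %*% beta[-1L])
  mean(loss_value(eta, data$y, loss))
}

#' Gradient of the empirical risk
#'
#' Gradient of [empirical_risk()] with respect to the full coefficient
#' vector (intercept first). For the Huber loss the clipped-residual
#' subgradient is used (the loss is differentiable, so this is the
#' gradient).
#'
#' @inheritParams empirical_risk
#' @return Numeric vector of length p + 1.
#' @export
risk_gradient <- function(beta, data, loss) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (length(beta) != data$p + 1L) {
    stop("`beta` must have length p + 1 (intercept first).", call. = FALSE)
  }
  eta <- drop(beta[1L] + data$X %*% beta[-1L])
  g <- loss_deriv(eta, data$y, loss)
  unname(c(mean(g), drop(crossprod(data$X, g)) / data$n))
}
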