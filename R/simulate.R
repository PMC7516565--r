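## Benchmark simulators: binary single-index designs with AR(1)-correlated
## Gaussian predictors and response probability q_L((x_1 + x_2)^3).
## Design m1 augments the Gaussian coordinates with the monomials of the
## two signal variables up to degree three, which makes the fitted
## logistic family correctly specified with projection support {6,7,8,9}
## and coefficients (3,3,1,1); design m2 keeps raw Gaussian coordinates
## only, so the logistic fit is misspecified but, by the linear
## regressions property of the normal design, the projection is collinear
## with the generating direction (1,1) on {1,2}.

#' AR(1) correlation matrix
#'
#' @param p Dimension.
#' @param rho Correlation parameter in (-1, 1).
#' @return The p x p matrix with entries \eqn{\rho^{|i-j|}} (symmetric
#'   positive definite).
#' @export
make_sigma <- function(p, rho) {
  stopifnot(p >= 1)
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1) {
    stop("`rho` must lie in (-1, 1).", call. = FALSE)
  }
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

#' Response probability of the benchmark designs
#'
#' The cubic single-index response \eqn{q_L(u^3) = 1 / (1 + e^{-u^3})},
#' evaluated overflow-safely.
#'
#' @param u Numeric vector of index values.
#' @return Probabilities in (0, 1).
#' @export
response_prob <- function(u) {
  stats::plogis(u^3)
}

## Gaussian design draw: n x p with covariance sigma
rmvn_ar1 <- function(n, p, rho) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (rho != 0) Z <- Z %*% chol(make_sigma(p, rho))
  Z
}

sim_truth <- function(model, active_gen, beta_gen, active_proj, beta_proj,
                      correctly_specified, eta_known) {
  structure(
    list(model = model,
         active_set_generating = active_gen,
         beta_generating = beta_gen,
         active_set_projection = active_proj,
         beta_projection = beta_proj,
         correctly_specified = correctly_specified,
         eta_known = eta_known),
    class = "ss_sim_truth"
  )
}

#' Simulate the correctly specified benchmark design (m1)
#'
#' Draws \eqn{Z \sim N_p(0, \Sigma)} with \eqn{\Sigma = [\rho^{|i-j|}]}
#' and builds the predictor matrix
#' \eqn{x_1 = z_1, x_2 = z_2, x_3 = x_1^2, x_4 = x_2^2, x_5 = x_1 x_2,
#' x_6 = x_1^2 x_2, x_7 = x_1 x_2^2, x_8 = x_1^3, x_9 = x_2^3}, and
#' \eqn{x_j = z_{j-7}} for \eqn{j = 10, \ldots, p}. The response is
#' Bernoulli with success probability \eqn{q_L((x_1 + x_2)^3)}. Since
#' \eqn{(x_1 + x_2)^3 = 3x_6 + 3x_7 + x_8 + x_9} identically, the logistic
#' model is correctly specified with projection support \{6,7,8,9\} and
#' coefficients (3, 3, 1, 1).
#'
#' @param n Sample size.
#' @param p Number of predictors (>= 10).
#' @param rho AR(1) correlation parameter in (-1, 1).
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @return A list of class `"ss_sim"`: `X` (raw, unstandardized), `y`,
#'   `truth` (an `"ss_sim_truth"`), `config`.
#' @export
simulate_m1 <- function(n, p = 150L, rho = 0, seed = NULL) {
  if (p < 10L) stop("design m1 requires p >= 10.", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1).", call. = FALSE)
  out <- with_seed(seed, {
    Z <- rmvn_ar1(n, p, rho)
    X <- matrix(0, n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    X[, 1L] <- Z[, 1L]
    X[, 2L] <- Z[, 2L]
    X[, 3L] <- X[, 1L]^2
    X[, 4L] <- X[, 2L]^2
    X[, 5L] <- X[, 1L] * X[, 2L]
    X[, 6L] <- X[, 1L]^2 * X[, 2L]
    X[, 7L] <- X[, 1L] * X[, 2L]^2
    X[, 8L] <- X[, 1L]^3
    X[, 9L] <- X[, 2L]^3
    if (p > 9L) X[, 10:p] <- Z[, 3:(p - 7L)]
    y <- stats::rbinom(n, 1L, response_prob(X[, 1L] + X[, 2L]))
    list(X = X, y = y)
  })
  structure(
    list(X = out$X, y = out$y,
         truth = sim_truth("m1", c(1L, 2L), c(1, 1), 6:9, c(3, 3, 1, 1),
                           correctly_specified = TRUE, eta_known = TRUE),
         config = list(model = "m1", n = n, p = p, rho = rho, seed = seed)),
    class = "ss_sim"
  )
}

#' Simulate the misspecified benchmark design (m2)
#'
#' Raw Gaussian AR(1) predictors with the same cubic-index Bernoulli
#' response \eqn{q_L((x_1 + x_2)^3)}. The logistic family is misspecified,
#' but the multivariate normal design satisfies the linear regressions
#' condition, so the population logistic projection is \eqn{\eta (1, 1)}
#' on support \{1, 2\} for some \eqn{\eta > 0}; the scale \eqn{\eta} is
#' not known in closed form, only the direction.
#'
#' @inheritParams simulate_m1
#' @param p Number of predictors (>= 2).
#' @return A list of class `"ss_sim"`, as in [simulate_m1()].
#' @export
simulate_m2 <- function(n, p = 150L, rho = 0, seed = NULL) {
  if (p < 2L) stop("design m2 requires p >= 2.", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1).", call. = FALSE)
  out <- with_seed(seed, {
    X <- rmvn_ar1(n, p, rho)
    colnames(X) <- paste0("x", seq_len(p))
    y <- stats::rbinom(n, 1L, response_prob(X[, 1L] + X[, 2L]))
    list(X = X, y = y)
  })
  structure(
    list(X = out$X, y = out$y,
         truth = sim_truth("m2", c(1L, 2L), c(1, 1), c(1L, 2L), c(1, 1),
                           correctly_specified = FALSE, eta_known = FALSE),
         config = list(model = "m2", n = n, p = p, rho = rho, seed = seed)),
    class = "ss_sim"
  )
}

#' Simulate a benchmark design by name
#'
#' Dispatches to [simulate_m1()] or [simulate_m2()].
#'
#' @param model `"m1"` or `"m2"`.
#' @inheritParams simulate_m1
#' @export
simulate_model <- function(model = c("m1", "m2"), n, p = 150L, rho = 0,
                           seed = NULL) {
  model <- match.arg(tolower(model), c("m1", "m2"))
  switch(model,
         m1 = simulate_m1(n, p, rho, seed),
         m2 = simulate_m2(n, p, rho, seed))
}

#' @export
print.ss_sim <- function(x, ...) {
  cfg <- x$config
  cat("<ss_sim> design ", cfg$model, ": n = ", cfg$n, ", p = ", cfg$p,
      ", rho = ", cfg$rho, "\n", sep = "")
  cat("  projection support:",
      paste(x$truth$active_set_projection, collapse = " "),
      if (x$truth$correctly_specified) "(correctly specified)"
      else "(misspecified)", "\n")
  invisible(x)
}
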