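# fixtures built in code

# generic random binary-regression instance
random_instance <- function(n, p, seed, beta = NULL, standardize = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  eta <- if (is.null(beta)) rep(0, n) else drop(X %*% beta)
  y <- rbinom(n, 1, plogis(eta))
  # guard against degenerate single-class draws in tiny instances
  if (length(unique(y)) < 2L) { y[1] <- 0; y[2] <- 1 }
  ss_dataset(X, y, standardize = standardize)
}

# design with X^T X / n = I and mean-zero columns (soft-threshold oracle)
orthonormal_instance <- function(n, p, seed) {
  set.seed(seed)
  A <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(A))
  X <- sqrt(n) * Q
  y <- rbinom(n, 1, 0.5)
  if (length(unique(y)) < 2L) { y[1] <- 0; y[2] <- 1 }
  ss_dataset(X, y, standardize = FALSE)
}

all_losses <- function() {
  list(loss_spec("logistic"), loss_spec("quadratic"),
       loss_spec("huber", huber_delta = 0.1))
}
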