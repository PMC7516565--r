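## Theory diagnostics: the l1 cone around a designated support, the
## restricted eigenvalue (minimal Rayleigh quotient over the cone), and
## the separation predicate on penalized coefficient vectors.

#' Cone specification
#'
#' The cone \eqn{C_\varepsilon = \{\Delta :
#' \|\Delta_{s^c}\|_1 \le (3 + \varepsilon)\|\Delta_s\|_1\}} of vectors
#' whose mass off a designated support is controlled by the mass on it.
#'
#' @param true_support Nonempty integer vector of support indices.
#' @param p Ambient dimension.
#' @param epsilon Positive cone-opening parameter; default 1.
#' @return An object of class `"cone_spec"`.
#' @export
cone_spec <- function(true_support, p, epsilon = 1) {
  true_support <- sort(unique(as.integer(true_support)))
  if (length(true_support) == 0L) {
    stop("`true_support` must be nonempty.", call. = FALSE)
  }
  if (min(true_support) < 1L || max(true_support) > p) {
    stop("`true_support` out of range.", call. = FALSE)
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be positive.", call. = FALSE)
  }
  structure(list(true_support = true_support, p = as.integer(p),
                 epsilon = epsilon),
            class = "cone_spec")
}

#' Cone membership
#'
#' @param delta Numeric vector of length `cone$p`.
#' @param cone A [cone_spec()].
#' @return `TRUE` iff \eqn{\|\Delta_{s^c}\|_1 \le
#'   (3 + \varepsilon)\|\Delta_s\|_1}.
#' @export
in_cone <- function(delta, cone) {
  stopifnot(inherits(cone, "cone_spec"), length(delta) == cone$p)
  s <- cone$true_support
  sum(abs(delta[-s])) <= (3 + cone$epsilon) * sum(abs(delta[s]))
}

## rescale the off-support block so that delta lies in the cone; returns
## NULL when no nonzero cone point can be produced
project_into_cone <- function(delta, cone) {
  s <- cone$true_support
  on <- sum(abs(delta[s])); off <- sum(abs(delta[-s]))
  bound <- (3 + cone$epsilon) * on
  if (off > bound) {
    if (on == 0) return(NULL)
    delta[-s] <- delta[-s] * (bound / off)
  }
  if (all(delta == 0)) return(NULL)
  delta
}

#' Restricted eigenvalue over the cone (upper-bound estimate)
#'
#' Estimates \eqn{\kappa_H(\varepsilon) = \inf_{\Delta \in C_\varepsilon
#' \setminus \{0\}} \Delta^T H \Delta / \Delta^T \Delta}, the minimal
#' Rayleigh quotient of `H` restricted to the cone. The cone makes this a
#' nonconvex program, so the estimate is a seeded random search — over
#' Gaussian directions projected into the cone, cone-boundary directions,
#' and the bottom eigenvectors of `H` projected into the cone — refined by
#' projected gradient descent on the Rayleigh quotient. The result is an
#' upper bound of the true infimum (every probe is feasible).
#'
#' @param H Symmetric nonnegative-definite p x p matrix with `p <= 50`.
#' @param cone A [cone_spec()] of matching dimension.
#' @param n_samples Number of random probe directions. Default 500.
#' @param seed Optional integer seed; global RNG state preserved.
#' @return A list of class `"ss_kappa"`: `kappa` (the estimate),
#'   `direction` (a unit vector attaining it), `cone`.
#' @export
restricted_eigenvalue <- function(H, cone, n_samples = 500L, seed = NULL) {
  stopifnot(inherits(cone, "cone_spec"))
  H <- as.matrix(H)
  p <- nrow(H)
  if (p != cone$p || ncol(H) != p) stop("dimension mismatch.", call. = FALSE)
  if (p > 50L) stop("diagnostic limited to p <= 50.", call. = FALSE)
  if (max(abs(H - t(H))) > 1e-10) {
    stop("`H` must be symmetric.", call. = FALSE)
  }
  ev <- eigen(H, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("`H` must be nonnegative definite.", call. = FALSE)
  }
  quotient <- function(d) drop(crossprod(d, H %*% d)) / sum(d^2)
  s <- cone$true_support
  best <- list(q = Inf, d = NULL)
  consider <- function(d) {
    d <- project_into_cone(d, cone)
    if (is.null(d)) return(invisible(NULL))
    q <- quotient(d)
    if (q < best$q) best <<- list(q = q, d = d / sqrt(sum(d^2)))
    invisible(NULL)
  }
  with_seed(seed, {
    # bottom eigenvectors of H pushed into the cone
    for (j in rev(seq_len(p))) consider(ev$vectors[, j])
    for (i in seq_len(n_samples)) {
      d <- stats::rnorm(p)
      consider(d)
      # boundary probe: off-support mass exactly at the cone limit
      db <- d
      on <- sum(abs(db[s])); off <- sum(abs(db[-s]))
      if (on > 0 && off > 0) {
        db[-s] <- db[-s] * ((3 + cone$epsilon) * on / off)
        consider(db)
      }
    }
  })
  # local refinement: projected gradient descent on the Rayleigh quotient
  d <- best$d
  step <- 0.5
  for (it in seq_len(400L)) {
    q <- quotient(d)
    g <- 2 * (drop(H %*% d) - q * d) / sum(d^2)
    cand <- project_into_cone(d - step * g, cone)
    if (!is.null(cand)) {
      cand <- cand / sqrt(sum(cand^2))
      if (quotient(cand) < q) {
        d <- cand
        next
      }
    }
    step <- step / 2
    if (step < 1e-10) break
  }
  if (quotient(d) < best$q) best <- list(q = quotient(d), d = d)
  structure(list(kappa = best$q, direction = best$d, cone = cone),
            class = "ss_kappa")
}

#' @export
print.ss_kappa <- function(x, ...) {
  cat("<ss_kappa> upper-bound estimate of the restricted eigenvalue: ",
      format(x$kappa, digits = 6), "\n", sep = "")
  invisible(x)
}

## exact oracle for p <= 3, used by the test suite to validate the
## random-search estimator.  On the unit sphere the Rayleigh quotient is
## smooth, so its minimum over the closed cone is attained either at an
## interior critical point (an eigenvector of H lying in the cone) or on
## the cone boundary ||Delta_c||_1 = (3 + eps) ||Delta_s||_1, which for
## p = 2 is a finite set of rays and for p = 3 a handful of smooth 1-d
## segments scanned with optimize()
cone_rayleigh_scan <- function(H, cone) {
  p <- nrow(H)
  stopifnot(p <= 3L, p == cone$p)
  quotient <- function(d) drop(crossprod(d, H %*% d)) / sum(d^2)
  if (p == 1L) return(H[1L, 1L])
  best <- Inf
  ev <- eigen(H, symmetric = TRUE)
  for (j in seq_len(p)) {
    v <- ev$vectors[, j]
    if (in_cone(v, cone)) best <- min(best, ev$values[j])
  }
  s <- cone$true_support
  cc <- setdiff(seq_len(p), s)
  R <- 3 + cone$epsilon
  place <- function(vs, vc) {
    d <- numeric(p); d[s] <- vs; d[cc] <- vc; d
  }
  minimize_seg <- function(f) {
    ts <- seq(0, 1, length.out = 201L)
    vals <- vapply(ts, f, 0)
    i <- which.min(vals)
    opt <- stats::optimize(f, c(ts[max(i - 1L, 1L)], ts[min(i + 1L, 201L)]))
    min(vals[i], opt$objective)
  }
  if (length(cc) == 0L) return(min(best, min(ev$values)))
  if (p == 2L) {
    # boundary rays: on-support 1, off-support +-R
    for (sgn in c(-1, 1)) {
      best <- min(best, quotient(place(1, sgn * R)))
    }
    return(best)
  }
  if (length(s) == 1L) {
    # off-support mass on the l1 circle of radius R: 4 sign quadrants
    for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
      f <- function(t) quotient(place(1, c(s2 * R * t, s3 * R * (1 - t))))
      best <- min(best, minimize_seg(f))
    }
  } else {
    # two on-support coordinates on a quarter circle per sign pattern,
    # off-support at the boundary radius
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
      f <- function(t) {
        th <- t * pi / 2
        vs <- c(s1 * cos(th), s2 * sin(th))
        quotient(place(vs, s3 * R * sum(abs(vs))))
      }
      best <- min(best, minimize_seg(f))
    }
  }
  best
}

#' Separation predicate on a penalized coefficient vector
#'
#' Checks whether every coefficient on the designated support dominates
#' every coefficient off it in absolute value:
#' \eqn{\max_{i \in s^c} |\hat\beta_{L,i}| \le
#' \min_{i \in s} |\hat\beta_{L,i}|}. When this holds and the on-support
#' coefficients are all nonzero, the support is a prefix set of the
#' magnitude-ordered chain, hence a member of the nested candidate
#' family.
#'
#' @param beta_L Numeric coefficient vector of length p (no intercept).
#' @param s_star Nonempty proper subset of `1:p`.
#' @return Logical.
#' @examples
#' separation_holds(c(0.9, 0.8, 0.1, 0), c(1, 2))   # TRUE
#' separation_holds(c(0.9, 0.05, 0.1, 0), c(1, 2))  # FALSE
#' @export
separation_holds <- function(beta_L, s_star) {
  s_star <- sort(unique(as.integer(s_star)))
  p <- length(beta_L)
  if (length(s_star) == 0L || length(s_star) >= p ||
      min(s_star) < 1L || max(s_star) > p) {
    stop("`s_star` must be a nonempty proper subset of 1:p.", call. = FALSE)
  }
  max(abs(beta_L[-s_star])) <= min(abs(beta_L[s_star]))
}
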