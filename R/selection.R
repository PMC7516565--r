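## Second stage: order screened predictors by coefficient magnitude, build
## nested families of candidate supports, and minimize a Generalized
## Information Criterion over them.

#' Order predictors by coefficient magnitude
#'
#' Returns the indices of nonzero coefficients sorted by absolute value,
#' largest first; ties are broken toward the smaller index. This ordering
#' defines the nested chain of candidate supports.
#'
#' @param coefficients Numeric vector of length p (no intercept).
#' @return Integer vector of ordered indices (possibly empty).
#' @examples
#' order_support(c(0, 2.5, -3, 0, 1))  # 3 2 5
#' @export
order_support <- function(coefficients) {
  stopifnot(is.numeric(coefficients))
  idx <- which(coefficients != 0)
  idx[order(-abs(coefficients[idx]), idx)]
}

#' Nested support chain from an ordered index list
#'
#' Builds the chain \eqn{\emptyset, \{j_1\}, \{j_1,j_2\}, \ldots} of
#' prefix supports of an ordered index list.
#'
#' @param ordered Integer vector of distinct predictor indices, typically
#'   from [order_support()].
#' @return List of integer vectors: the empty set followed by the k prefix
#'   sets.
#' @export
build_nested_family <- function(ordered) {
  ordered <- as.integer(ordered)
  if (anyDuplicated(ordered)) {
    stop("`ordered` must not contain duplicates.", call. = FALSE)
  }
  c(list(integer(0)),
    lapply(seq_along(ordered), function(k) ordered[seq_len(k)]))
}

#' Union family of nested chains along a penalty path
#'
#' For each penalty on a fitted path, orders the nonzero coefficients and
#' forms the nested prefix chain; chains whose full support exceeds `n`
#' are dropped entirely (at such penalties the penalized and refitted
#' solutions are not unique). The merged family is the deduplicated union
#' of all chain members together with the empty set; supports larger than
#' `size_cap` are removed.
#'
#' @param path An `"ss_lasso_path"` from [fit_lasso_path()].
#' @param n Sample size used for the admissibility filter.
#' @param size_cap Largest admissible support size; defaults to `n`.
#' @return An object of class `"ss_family"`: `chains` (list of prefix
#'   chains, one per kept penalty), `source_lambdas`, `dropped_lambdas`,
#'   `merged` (deduplicated list of sorted supports, including the empty
#'   set), `size_cap`.
#' @export
build_union_family <- function(path, n, size_cap = n) {
  stopifnot(inherits(path, "ss_lasso_path"))
  keep <- vapply(path$supports, length, 1L) <= n
  chains <- list(); src <- numeric(0)
  merged <- list(integer(0))
  seen <- new.env(parent = emptyenv())
  assign("k", TRUE, envir = seen)      # the empty set, keyed with prefix
  for (i in which(keep)) {
    ordered <- order_support(path$coefficients[i, ])
    chain <- build_nested_family(ordered)
    chains[[length(chains) + 1L]] <- chain
    src <- c(src, path$lambdas[i])
    for (w in chain[-1L]) {               # per-chain empty set not re-added
      if (length(w) > size_cap) next
      key <- paste0("k", support_key(w))
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        merged[[length(merged) + 1L]] <- sort(w)
      }
    }
  }
  structure(
    list(chains = chains, source_lambdas = src,
         dropped_lambdas = path$lambdas[!keep],
         merged = merged, size_cap = size_cap),
    class = "ss_family"
  )
}

#' @export
print.ss_family <- function(x, ...) {
  cat("<ss_family> ", length(x$chains), " chains, ",
      length(x$merged), " distinct candidate supports (size cap ",
      x$size_cap, ")\n", sep = "")
  invisible(x)
}

#' Generalized Information Criterion penalty
#'
#' Constructs the per-parameter penalty factor \eqn{a_n}:
#' `"aic"` gives 2, `"bic"` gives \eqn{\log n}, `"ebic"` gives
#' \eqn{\log n + 2 d \log p}, and `"lft"` gives
#' \eqn{\log(\log n)\,\log p} (the plug-in criterion used by the LFT
#' selector).
#'
#' @param name One of `"aic"`, `"bic"`, `"ebic"`, `"lft"`.
#' @param d Positive weight of the \eqn{\log p} term (ebic only).
#'   Default 1.
#' @param count_intercept Should the model-size term count the intercept
#'   (`|w| + 1`)? Default `TRUE`, matching the grid procedures; set
#'   `FALSE` for the bare `|w|` form.
#' @return An object of class `"gic_penalty"`.
#' @export
gic_penalty <- function(name = c("bic", "aic", "ebic", "lft"), d = 1,
                        count_intercept = TRUE) {
  name <- match.arg(name)
  if (name == "ebic" && (!is.numeric(d) || length(d) != 1L || d <= 0)) {
    stop("`d` must be a positive number for the ebic penalty.", call. = FALSE)
  }
  structure(list(name = name, d = if (name == "ebic") d else NA_real_,
                 count_intercept = isTRUE(count_intercept)),
            class = "gic_penalty")
}

#' @export
print.gic_penalty <- function(x, ...) {
  cat("<gic_penalty> ", x$name, sep = "")
  if (x$name == "ebic") cat("(d = ", format(x$d), ")", sep = "")
  cat(if (x$count_intercept) ", counting intercept" else "", "\n")
  invisible(x)
}

#' Numeric value of the GIC penalty factor
#'
#' @param pen A [gic_penalty()].
#' @param n Sample size (>= 2; the lft penalty requires n >= 3 for a
#'   positive value).
#' @param p Number of predictors (>= 1).
#' @return The scalar \eqn{a_n}.
#' @export
penalty_value <- function(pen, n, p) {
  stopifnot(inherits(pen, "gic_penalty"))
  if (n < 2) stop("`n` must be at least 2.", call. = FALSE)
  if (p < 1) stop("`p` must be at least 1.", call. = FALSE)
  switch(pen$name,
    aic = 2,
    bic = log(n),
    ebic = log(n) + 2 * pen$d * log(p),
    lft = {
      if (n < 3) stop("lft penalty requires n >= 3.", call. = FALSE)
      log(log(n)) * log(p)
    }
  )
}

#' Generalized Information Criterion of one candidate support
#'
#' Refits the empirical-risk minimizer on `support` and returns
#' \eqn{n R_n(\hat\beta(w)) + a_n (|w| + 1)} (or with bare \eqn{|w|} when
#' the penalty does not count the intercept).
#'
#' @inheritParams refit_erm
#' @param pen A [gic_penalty()].
#' @return A list: `value`, `fit_term` (\eqn{n R_n}), `penalty_term`,
#'   `refit` (the [refit_erm()] result).
#' @export
gic <- function(data, support, loss, pen) {
  stopifnot(inherits(data, "ss_dataset"))
  refit <- refit_erm(data, support, loss)
  an <- penalty_value(pen, data$n, data$p)
  size <- length(refit$support) + as.integer(pen$count_intercept)
  fit_term <- data$n * refit$risk
  list(value = fit_term + an * size, fit_term = fit_term,
       penalty_term = an * size, refit = refit)
}

## minimize GIC over a list of candidate supports; deterministic
## tie-breaking toward smaller size, then lexicographic order.
## Candidates are visited in that order, so any support whose penalty
## term alone already reaches the current minimum can be skipped without
## refitting: the losses are nonnegative, hence GIC(w) >= a_n (|w|+1),
## and a tie at the bound would lose the tie-break to the incumbent.
gic_minimize <- function(data, supports, loss, pen, procedure,
                         diagnostics = character(0)) {
  ord <- support_order(supports)
  supports <- supports[ord]
  keys <- vapply(supports, support_key, "")
  dup <- duplicated(keys)
  supports <- supports[!dup]
  keys <- keys[!dup]
  an <- penalty_value(pen, data$n, data$p)
  nc <- as.integer(pen$count_intercept)
  m <- length(supports)
  values <- fit_terms <- pens <- rep(NA_real_, m)
  convs <- rep(NA, m)
  pruned <- rep(FALSE, m)
  evals <- vector("list", m)
  best <- NA_integer_; best_value <- Inf
  for (i in seq_len(m)) {
    pen_term <- an * (length(supports[[i]]) + nc)
    if (pen_term >= best_value) { pruned[i] <- TRUE; next }
    e <- gic(data, supports[[i]], loss, pen)
    evals[[i]] <- e
    values[i] <- e$value
    fit_terms[i] <- e$fit_term
    pens[i] <- pen_term
    convs[i] <- e$refit$converged
    if (e$value < best_value) { best <- i; best_value <- e$value }
  }
  refit <- evals[[best]]$refit
  if (any(!convs, na.rm = TRUE)) {
    diagnostics <- c(diagnostics, "non-converged refit(s) in GIC trace")
  }
  trace <- data.frame(
    support = keys,
    size = vapply(supports, length, 1L),
    fit_term = fit_terms,
    penalty_term = pens,
    gic = values,
    converged = convs,
    pruned = pruned,
    stringsAsFactors = FALSE
  )
  structure(
    list(selected_support = supports[[best]], refit = refit,
         gic_trace = trace, procedure = procedure, penalty = pen,
         loss = as_loss_spec(loss), diagnostics = diagnostics),
    class = "ss_selection"
  )
}

#' @export
print.ss_selection <- function(x, ...) {
  cat("<ss_selection> procedure ", x$procedure, ", ", x$loss$name,
      " loss, penalty ", x$penalty$name, "\n", sep = "")
  w <- x$selected_support
  cat("  selected support:",
      if (length(w) == 0L) "(empty)" else paste(w, collapse = " "), "\n")
  cat("  candidates examined:", nrow(x$gic_trace),
      " | minimal GIC:",
      format(min(x$gic_trace$gic, na.rm = TRUE), digits = 6), "\n")
  if (length(x$diagnostics)) {
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Screening-Selection at a single penalty
#'
#' The two-stage SS selector: fit the l1-penalized minimizer at one
#' penalty, order its nonzero coefficients by magnitude, build the nested
#' prefix chain, and return the chain member minimizing the GIC.
#'
#' @inheritParams fit_lasso
#' @param pen A [gic_penalty()].
#' @param size_cap Largest candidate support size (default
#'   `min(n - 1, n)`, i.e. `n - 1`, the identifiability limit of the
#'   refit).
#' @return An `"ss_selection"` object.
#' @export
ss_select <- function(data, loss, lambda, pen = gic_penalty("bic"),
                      size_cap = NULL, tol = 1e-7, max_iter = 1e4) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (is.null(size_cap)) size_cap <- data$n - 1L
  size_cap <- min(size_cap, data$n - 1L)
  fit <- fit_lasso(data, loss, lambda, tol = tol, max_iter = max_iter)
  diags <- character(0)
  if (!fit$converged) diags <- c(diags, "screening fit not converged")
  ordered <- order_support(fit$beta)
  chain <- build_nested_family(ordered)
  sizes <- vapply(chain, length, 1L)
  if (any(sizes > size_cap)) {
    diags <- c(diags, sprintf("chain truncated at size cap %d", size_cap))
    chain <- chain[sizes <= size_cap]
  }
  res <- gic_minimize(data, chain, loss, pen, "ss", diags)
  res$lambda <- lambda
  res$screening_fit <- fit
  res
}

#' Screening-Selection over a penalty grid (SSnet)
#'
#' Fits the penalized path over a decreasing penalty grid, merges the
#' per-penalty nested chains into one candidate family (dropping
#' penalties whose support exceeds `n`), and minimizes the GIC over the
#' merged family.
#'
#' @inheritParams ss_select
#' @param lambdas Decreasing penalty grid; `NULL` (default) builds
#'   [lambda_grid()] with `m` values and ratio `ratio`.
#' @param m,ratio Grid parameters used when `lambdas` is `NULL`.
#' @return An `"ss_selection"` object with the family attached as
#'   `$family`.
#' @export
ssnet_select <- function(data, loss, lambdas = NULL,
                         pen = gic_penalty("bic"), size_cap = NULL,
                         m = 20L, ratio = 0.01, tol = 1e-7, max_iter = 1e4) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (is.null(lambdas)) lambdas <- lambda_grid(data, loss, m, ratio)
  if (is.null(size_cap)) size_cap <- data$n
  path <- fit_lasso_path(data, loss, lambdas, tol = tol, max_iter = max_iter)
  diags <- character(0)
  if (any(!path$converged)) {
    diags <- c(diags, "screening fit(s) not converged on path")
  }
  fam <- build_union_family(path, data$n, size_cap)
  if (length(fam$dropped_lambdas) > 0) {
    diags <- c(diags,
               sprintf("%d penalties dropped by the |support| <= n filter",
                       length(fam$dropped_lambdas)))
  }
  merged <- fam$merged
  sizes <- vapply(merged, length, 1L)
  if (any(sizes > data$n - 1L)) {       # refit identifiability limit
    diags <- c(diags, "supports at size n excluded from refitting")
    merged <- merged[sizes <= data$n - 1L]
  }
  res <- gic_minimize(data, merged, loss, pen, "ssnet", diags)
  res$lambdas <- lambdas
  res$path <- path
  res$family <- fam
  res
}

#' Screening-Selection with cross-validated penalty (SSCV)
#'
#' Chooses the penalty by K-fold cross-validation with the one-standard-
#' error rule, then runs [ss_select()] at that penalty.
#'
#' @inheritParams ssnet_select
#' @inheritParams cv_select_lambda
#' @return An `"ss_selection"` object with the CV object attached as
#'   `$cv`.
#' @export
sscv_select <- function(data, loss, lambdas = NULL,
                        pen = gic_penalty("bic"), K = 10L, seed = NULL,
                        m = 20L, ratio = 0.01, tol = 1e-7, max_iter = 1e4) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (is.null(lambdas)) lambdas <- lambda_grid(data, loss, m, ratio)
  cv <- if (length(lambdas) == 1L) {
    list(lambda = lambdas, index = 1L, rule = "1se", flags = character(0))
  } else {
    cv_select_lambda(data, loss, lambdas, K = K, rule = "1se", seed = seed,
                     tol = tol, max_iter = max_iter)
  }
  res <- ss_select(data, loss, cv$lambda, pen, tol = tol,
                   max_iter = max_iter)
  res$procedure <- "sscv"
  res$cv <- cv
  if (length(cv$flags)) res$diagnostics <- c(res$diagnostics, cv$flags)
  res
}

#' Lasso plug-in GIC selection (LFT)
#'
#' The plug-in selector of the Fan–Tang type: along the penalty grid,
#' evaluate \eqn{n R_n(\hat\beta_L(\lambda)) + a_n (|{\rm supp}\,
#' \hat\beta_L(\lambda)| + 1)} with \eqn{a_n = \log(\log n)\log p},
#' using the penalized coefficients themselves (no refit), and return the
#' support of the minimizing penalized fit. Penalties with more than `n`
#' nonzero coefficients are inadmissible.
#'
#' @inheritParams ssnet_select
#' @return An `"ss_selection"`-like object; `$refit` carries the winning
#'   penalized fit's coefficients (both scales).
#' @export
lft_select <- function(data, loss, lambdas = NULL, m = 20L, ratio = 0.01,
                       tol = 1e-7, max_iter = 1e4) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (data$n < 3L) stop("lft requires n >= 3.", call. = FALSE)
  if (is.null(lambdas)) lambdas <- lambda_grid(data, loss, m, ratio)
  path <- fit_lasso_path(data, loss, lambdas, tol = tol, max_iter = max_iter)
  sizes <- vapply(path$supports, length, 1L)
  keep <- sizes <= data$n
  if (!any(keep)) {
    stop("no admissible penalty after the |support| <= n filter.",
         call. = FALSE)
  }
  an <- penalty_value(gic_penalty("lft"), data$n, data$p)
  crit <- rep(Inf, length(lambdas))
  for (i in which(keep)) {
    risk <- empirical_risk(c(path$intercepts[i], path$coefficients[i, ]),
                           data, loss)
    crit[i] <- data$n * risk + an * (sizes[i] + 1)
  }
  # tie-break toward the larger penalty (smaller index), hence the
  # sparser fit on a monotone path
  best <- which.min(crit)
  beta <- unname(path$coefficients[best, ])
  b0 <- path$intercepts[best]
  sc <- data$column_scales; mu <- data$column_means
  refit <- structure(
    list(support = which(beta != 0), intercept = b0, coefficients = beta,
         intercept_original = b0 - sum(beta * mu / sc),
         coefficients_original = unname(beta / sc),
         risk = empirical_risk(c(b0, beta), data, loss),
         converged = path$converged[best], loss = loss),
    class = "ss_refit"
  )
  trace <- data.frame(
    lambda = lambdas,
    support = vapply(path$supports, support_key, ""),
    size = sizes,
    gic = crit,
    converged = path$converged,
    stringsAsFactors = FALSE
  )
  structure(
    list(selected_support = sort(refit$support), refit = refit,
         gic_trace = trace, procedure = "lft",
         penalty = gic_penalty("lft"), loss = loss,
         lambda = lambdas[best], lambdas = lambdas, path = path,
         diagnostics = if (all(path$converged)) character(0)
                       else "screening fit(s) not converged on path"),
    class = "ss_selection"
  )
}

#' Exhaustive GIC search over small subsets
#'
#' Minimizes the GIC over all predictor subsets of size at most `kmax`.
#' Combinatorially guarded (`p <= 15`, `kmax <= 6`); intended as the
#' ground-truth oracle against which the screened selectors are checked
#' on small problems.
#'
#' @inheritParams ss_select
#' @param kmax Largest subset size searched (<= 6).
#' @return An `"ss_selection"` object.
#' @export
exhaustive_gic <- function(data, loss, pen = gic_penalty("bic"), kmax = 3L) {
  loss <- as_loss_spec(loss)
  stopifnot(inherits(data, "ss_dataset"))
  if (data$p > 15L) stop("exhaustive search requires p <= 15.", call. = FALSE)
  if (kmax > 6L) stop("exhaustive search requires kmax <= 6.", call. = FALSE)
  kmax <- min(kmax, data$p, data$n - 1L)
  supports <- list(integer(0))
  for (k in seq_len(kmax)) {
    supports <- c(supports,
                  utils::combn(data$p, k, simplify = FALSE))
  }
  gic_minimize(data, supports, loss, pen, "exhaustive")
}
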