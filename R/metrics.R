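## Selection-performance metrics and the replicated experiment runner.

#' Angle between true and estimated coefficient vectors
#'
#' Returns \eqn{\arccos |\cos \angle(\beta, \hat\beta)|} in radians, the
#' convention being that a zero-norm vector on either side gives cosine 0
#' and hence angle \eqn{\pi/2}. The absolute value makes the metric
#' direction-free; results are clamped to \eqn{[0, \pi/2]} against
#' rounding.
#'
#' @param beta_true,beta_hat Numeric vectors of equal length (intercepts
#'   excluded by the caller).
#' @return Angle in radians in \eqn{[0, \pi/2]}.
#' @examples
#' angle_metric(c(1, 1), c(2, 2))  # 0
#' angle_metric(c(1, 0), c(0, 1))  # pi / 2
#' @export
angle_metric <- function(beta_true, beta_hat) {
  stopifnot(length(beta_true) == length(beta_hat))
  n1 <- sqrt(sum(beta_true^2)); n2 <- sqrt(sum(beta_hat^2))
  cosang <- if (n1 * n2 == 0) 0 else abs(sum(beta_true * beta_hat)) / (n1 * n2)
  acos(min(max(cosang, 0), 1))
}

## length-p embedding of the projection truth
truth_beta_vector <- function(truth, p) {
  b <- rep(0, p)
  b[truth$active_set_projection] <- truth$beta_projection
  b
}

## candidate supports examined by a selection, as canonical keys
selection_family_keys <- function(sel) {
  if (!is.null(sel$family)) {
    vapply(sel$family$merged, support_key, "")
  } else {
    unique(vapply(strsplit(sel$gic_trace$support, ","), function(s) {
      support_key(as.integer(s))
    }, ""))
  }
}

#' Build a replicate record from a selection result
#'
#' Collects what the performance metrics need from one replicate: the
#' candidate family (as canonical support keys), the selected support and
#' the refit coefficient vector (original predictor scale, intercept
#' dropped).
#'
#' @param sel An `"ss_selection"` result.
#' @param truth The replicate's `"ss_sim_truth"`.
#' @param replicate Integer replicate index.
#' @return A list of class `"ss_replicate"`.
#' @export
replicate_record <- function(sel, truth, replicate = NA_integer_) {
  structure(
    list(replicate = replicate,
         family_keys = selection_family_keys(sel),
         selected_support = sort(sel$selected_support),
         beta_hat = sel$refit$coefficients_original,
         converged = sel$refit$converged,
         truth = truth),
    class = "ss_replicate"
  )
}

#' Summarize selection performance over replicates
#'
#' Computes the four replicate averages: `Pinc` (the candidate family
#' contains the projection support), `Pequal` (the selected support
#' equals it), `Psupset` (the selected support contains it) and `ANGLE`
#' (mean angle between the embedded projection coefficients and the refit
#' coefficients).
#'
#' @param records List of [replicate_record()] results sharing one truth.
#' @return A one-row data.frame with columns `L`, `ANGLE`, `Pinc`,
#'   `Pequal`, `Psupset`, `n_nonconverged`.
#' @export
summarize_replicates <- function(records) {
  if (length(records) == 0L) {
    stop("`records` must contain at least one replicate.", call. = FALSE)
  }
  truth <- records[[1L]]$truth
  star_key <- support_key(truth$active_set_projection)
  star <- sort(truth$active_set_projection)
  p <- length(records[[1L]]$beta_hat)
  beta_true <- truth_beta_vector(truth, p)
  inc <- eq <- sup <- logical(length(records))
  ang <- numeric(length(records))
  for (k in seq_along(records)) {
    r <- records[[k]]
    inc[k] <- star_key %in% r$family_keys
    eq[k] <- identical(as.integer(r$selected_support), as.integer(star))
    sup[k] <- all(star %in% r$selected_support)
    ang[k] <- angle_metric(beta_true, r$beta_hat)
  }
  data.frame(L = length(records), ANGLE = mean(ang), Pinc = mean(inc),
             Pequal = mean(eq), Psupset = mean(sup),
             n_nonconverged = sum(!vapply(records, `[[`, TRUE, "converged")))
}

## parse "bic" / "aic" / "ebic" / "ebic2" into a gic_penalty
parse_penalty <- function(x) {
  if (inherits(x, "gic_penalty")) return(x)
  x <- tolower(x)
  if (grepl("^ebic", x)) {
    d <- sub("^ebic", "", x)
    return(gic_penalty("ebic", d = if (nzchar(d)) as.numeric(d) else 1))
  }
  gic_penalty(x)
}

#' Run a replicated selection experiment
#'
#' For each cell of the grid (correlation x procedure x loss x penalty),
#' draws `L` seeded replicates of the chosen benchmark design,
#' standardizes, runs the selector, and summarizes the selection metrics.
#' Replicate `k` of cell `c` uses seed `base_seed + 10000 * c + k`, so the
#' whole table is reproducible from `base_seed`. Individual replicate
#' failures are caught and excluded; a cell losing more than 10% of its
#' replicates is flagged invalid.
#'
#' @param model `"m1"` or `"m2"`.
#' @param n,p Design dimensions.
#' @param rhos Numeric vector of AR(1) correlations.
#' @param procedures Character vector from `"ssnet"`, `"sscv"`, `"lft"`.
#' @param losses Character vector of loss names.
#' @param penalties Character vector such as `"bic"`, `"ebic1"` (ignored
#'   for `"lft"`, which carries its own penalty).
#' @param L Replicates per cell.
#' @param base_seed Integer master seed.
#' @param m,ratio,K Grid length, grid ratio and CV fold count passed to
#'   the selectors.
#' @param keep_records Also return the per-replicate records? Default
#'   `FALSE`.
#' @return A list: `summary` (one row per cell with the four metrics) and,
#'   when requested, `records`.
#' @export
run_experiment <- function(model, n, p, rhos, procedures, losses,
                           penalties, L, base_seed = 1L, m = 20L,
                           ratio = 0.01, K = 10L, keep_records = FALSE) {
  stopifnot(L >= 1)
  grid <- expand.grid(rho = rhos, procedure = procedures, loss = losses,
                      penalty = penalties, stringsAsFactors = FALSE)
  # lft ignores the GIC penalty: collapse its duplicated cells
  is_lft <- grid$procedure == "lft"
  grid$penalty[is_lft] <- "lft"
  grid <- unique(grid)
  rows <- vector("list", nrow(grid))
  all_records <- if (keep_records) vector("list", nrow(grid)) else NULL
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    pen <- if (cell$procedure == "lft") NULL else parse_penalty(cell$penalty)
    records <- list()
    failures <- 0L
    for (k in seq_len(L)) {
      seed_k <- as.integer(base_seed + 10000L * ci + k)
      rec <- tryCatch({
        sim <- simulate_model(model, n, p, cell$rho, seed = seed_k)
        sdata <- ss_dataset(sim$X, sim$y, standardize = TRUE)
        sel <- switch(cell$procedure,
          ssnet = ssnet_select(sdata, cell$loss, pen = pen, m = m,
                               ratio = ratio),
          sscv = sscv_select(sdata, cell$loss, pen = pen, K = K,
                             seed = seed_k, m = m, ratio = ratio),
          lft = lft_select(sdata, cell$loss, m = m, ratio = ratio),
          stop("unknown procedure: ", cell$procedure)
        )
        replicate_record(sel, sim$truth, k)
      }, error = function(e) {
        warning(sprintf("replicate %d of cell %d failed: %s",
                        k, ci, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(rec)) failures <- failures + 1L
      else records[[length(records) + 1L]] <- rec
    }
    summ <- summarize_replicates(records)
    rows[[ci]] <- cbind(
      data.frame(model = model, n = n, p = p, rho = cell$rho,
                 procedure = cell$procedure, loss = cell$loss,
                 penalty = cell$penalty, stringsAsFactors = FALSE),
      summ,
      data.frame(n_failed = failures, valid = failures <= 0.1 * L)
    )
    if (keep_records) all_records[[ci]] <- records
  }
  out <- list(summary = do.call(rbind, rows))
  if (keep_records) out$records <- all_records
  out
}
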