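# Per-gene, per-cell estimation of the fraction of newly synthesised reads.
#
# For each gene in each cell, the fraction pi_g of reads originating from
# newly synthesised RNA is the mixing weight of the binomial mixture. pi_g
# carries a Beta(alpha, beta) prior; the joint log-posterior over
# (log alpha, log beta, pi_g) is maximised by quasi-Newton iteration from
# the fixed initialisation log(alpha) = log(beta) = 0, pi_g = 0.5, and the
# reported point estimate is the mode of the fitted beta distribution.

#' Select the reads used for one gene-by-cell estimate
#'
#' Estimation runs only for genes with at least `min_reads` reads in the
#' cell (too few reads give unstable estimates); genes with more than `cap`
#' reads are uniformly subsampled without replacement down to `cap` to bound
#' runtime. Subsampling is reproducible: its RNG seed is derived from the
#' experiment seed and the (cell, gene) labels, so results do not depend on
#' processing order, and the caller's RNG stream is left untouched.
#'
#' @param records data.frame/data.table of per-read records for a single
#'   gene and cell, with columns `y` and `n` (others are carried along).
#' @param min_reads minimum number of reads required for estimation (default 16).
#' @param cap maximum number of reads used (default 1000).
#' @param seed experiment seed.
#' @param cell_id,gene_id labels used to derive the subsampling seed; taken
#'   from `records` when present.
#' @return A data.table of selected records with attribute `subsampled`,
#'   or `NULL` when fewer than `min_reads` records are available.
#' @export
prepare_gene_reads <- function(records, min_reads = 16L, cap = 1000L,
                               seed = 1L, cell_id = NULL, gene_id = NULL) {
  records <- data.table::as.data.table(records)
  if (nrow(records) < min_reads) return(NULL)
  cell_id <- cell_id %||% if ("cell_id" %in% names(records)) records$cell_id[1] else ""
  gene_id <- gene_id %||% if ("gene_id" %in% names(records)) records$gene_id[1] else ""
  if (nrow(records) > cap) {
    idx <- with_seed(derive_seed(seed, cell_id, gene_id),
                     sample.int(nrow(records), cap))
    out <- records[sort(idx)]
    data.table::setattr(out, "subsampled", TRUE)
  } else {
    out <- records
    data.table::setattr(out, "subsampled", FALSE)
  }
  out
}

#' Joint log-posterior of the new-read fraction and its beta hyperparameters
#'
#' `log BetaPDF(pi_g; alpha, beta) + sum_i log mixture_pmf(y_i, n_i)`, the
#' objective maximised by [fit_pi_g()]. With `alpha = beta = 1` the prior
#' term vanishes and the value is the plain mixture log-likelihood.
#'
#' @param pi_g fraction of new reads, strictly inside (0, 1).
#' @param alpha,beta positive beta hyperparameters.
#' @param y,n per-read conversion counts and convertible positions.
#' @param p_e,p_c fixed per-cell error and conversion probabilities.
#' @param w optional multiplicities for aggregated `(y, n)` pairs.
#' @return numeric scalar log-posterior density.
#' @export
joint_log_posterior <- function(pi_g, alpha, beta, y, n, p_e, p_c, w = NULL) {
  if (pi_g <= 0 || pi_g >= 1) stop("pi_g must lie strictly inside (0, 1)")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (is.null(w)) w <- rep(1, length(y))
  dbeta(pi_g, alpha, beta, log = TRUE) +
    sum(w * mixture_pmf(y, n, p_e, p_c, pi_g, log = TRUE))
}

#' Mode of a beta distribution
#'
#' `(alpha - 1) / (alpha + beta - 2)` for `alpha, beta > 1`; 1 when
#' `alpha > 1, beta < 1`; 0 when `alpha < 1, beta > 1`. The remaining
#' regions do not arise from [fit_pi_g()] in practice but are still given
#' defined values: with both parameters below 1 the density is bimodal and
#' the endpoint with the steeper blow-up (the smaller parameter) is
#' returned, 0.5 at a tie; the uniform case `alpha = beta = 1` returns 0.5.
#'
#' @param alpha,beta positive beta parameters.
#' @return the mode, a value in `[0, 1]`.
#' @export
beta_mode <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive and finite")
  if (alpha > 1 && beta < 1) return(1)
  if (alpha < 1 && beta > 1) return(0)
  if (alpha == 1 && beta == 1) return(0.5)
  if (alpha < 1 && beta < 1) {
    # bimodal: density ~ x^(alpha-1) (1-x)^(beta-1) blows up faster at the
    # endpoint whose exponent is more negative
    return(if (alpha < beta) 0 else if (beta < alpha) 1 else 0.5)
  }
  # alpha >= 1, beta >= 1, not both 1: the interior-mode formula extends
  # continuously (alpha = 1 gives 0 for beta > 1, and vice versa)
  (alpha - 1) / (alpha + beta - 2)
}

beta_region_regular <- function(alpha, beta) {
  (alpha > 1 && beta > 1) || (alpha > 1 && beta < 1) || (alpha < 1 && beta > 1)
}

#' MAP estimate of the fraction of new reads for one gene in one cell
#'
#' Maximises [joint_log_posterior()] over (log alpha, log beta, logit pi_g)
#' with BFGS from the fixed initialisation log(alpha) = log(beta) = 0 and
#' pi_g = 0.5, holding the cell's p_e and p_c fixed. The reported
#' `pi_g_mode` is [beta_mode()] of the fitted hyperparameters; `pi_g_point`
#' is the optimiser's pi_g. When the fitted hyperparameters land in a
#' region where the beta mode is degenerate at 0/1 or ill-defined (both
#' parameters at or below 1), `pi_g_mode` falls back to the argmax of the
#' joint posterior on a fine pi grid and the estimate is flagged
#' `"boundary"`; optimiser failure flags `"unreliable"` but still emits an
#' estimate.
#'
#' @param records data.frame with columns `y`, `n` (typically from
#'   [prepare_gene_reads()]).
#' @param p_e,p_c fixed per-cell probabilities from [em_fit_pc()].
#' The joint posterior is unbounded in the hyperparameters: at any fixed
#' pi_g the beta density at its own mode grows without limit as the
#' concentration alpha + beta increases, so an unconstrained maximiser
#' diverges along that ridge. The optimisation therefore bounds log(alpha)
#' and log(beta) to `[-hyper_bound, hyper_bound]`; along the ridge the
#' fitted mode tracks pi_g, so the reported estimates are insensitive to
#' the bound.
#'
#' @param reads_total total reads for the gene before subsampling (defaults
#'   to `nrow(records)`).
#' @param maxit,reltol optimiser settings (defaults 200 iterations, 1e-8).
#' @param hyper_bound bound on |log alpha| and |log beta| (default 10).
#' @param fixed_prior optional length-2 numeric `c(alpha, beta)`: hold the
#'   hyperparameters fixed and optimise pi_g alone. `c(1, 1)` gives the
#'   maximum-likelihood estimate of pi_g (uniform prior).
#' @return A one-row data.table: `cell_id`, `gene_id`, `alpha`, `beta`,
#'   `pi_g_point`, `pi_g_mode`, `reads_total`, `reads_used`, `subsampled`,
#'   `quality_flag` (`"ok"`, `"boundary"` or `"unreliable"`).
#' @export
fit_pi_g <- function(records, p_e, p_c, reads_total = nrow(records),
                     maxit = 200L, reltol = 1e-8, hyper_bound = 10,
                     fixed_prior = NULL) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) stop("no records supplied")
  agg <- records[, .(w = .N), by = .(y, n)]
  yv <- agg$y; nv <- agg$n; wv <- agg$w

  # cache the two binomial log-pmf vectors; only pi varies inside the mixture
  le <- dbinom(yv, nv, p_e, log = TRUE)
  lc <- dbinom(yv, nv, p_c, log = TRUE)
  loglik <- function(pi) sum(wv * log_sum_exp(log1p(-pi) + le, base::log(pi) + lc))

  # pi is optimised on its natural scale inside a box (the hyperparameters
  # on the log scale): a logit transform has vanishing gradients near 0/1
  # where the line search can strand the iterate
  eps <- 1e-9
  ctrl <- list(maxit = maxit, factr = reltol / .Machine$double.eps)
  if (is.null(fixed_prior)) {
    negobj <- function(theta) {
      alpha <- exp(theta[1]); beta <- exp(theta[2])
      -(dbeta(theta[3], alpha, beta, log = TRUE) + loglik(theta[3]))
    }
    fit <- tryCatch(
      stats::optim(c(0, 0, 0.5), negobj, method = "L-BFGS-B",
                   lower = c(-hyper_bound, -hyper_bound, eps),
                   upper = c(hyper_bound, hyper_bound, 1 - eps),
                   control = ctrl),
      error = function(e) NULL)
  } else {
    stopifnot(length(fixed_prior) == 2L, all(fixed_prior > 0))
    negobj <- function(theta)
      -(dbeta(theta[1], fixed_prior[1], fixed_prior[2], log = TRUE) +
          loglik(theta[1]))
    fit <- tryCatch(
      stats::optim(0.5, negobj, method = "L-BFGS-B",
                   lower = eps, upper = 1 - eps, control = ctrl),
      error = function(e) NULL)
  }

  if (is.null(fit)) {
    alpha <- fixed_prior[1] %||% 1; beta <- fixed_prior[2] %||% 1
    pi_point <- 0.5
    flag <- "unreliable"
  } else {
    if (is.null(fixed_prior)) {
      alpha <- exp(fit$par[1]); beta <- exp(fit$par[2])
      pi_point <- fit$par[3]
    } else {
      alpha <- fixed_prior[1]; beta <- fixed_prior[2]
      pi_point <- fit$par[1]
    }
    flag <- if (fit$convergence > 1) "unreliable" else "ok"
  }

  if (!is.null(fixed_prior)) {
    # prior held fixed: the posterior maximiser itself is the estimate
    mode <- pi_point
  } else if (beta_region_regular(alpha, beta)) {
    mode <- beta_mode(alpha, beta)
    if ((mode == 0 || mode == 1) && flag == "ok") flag <- "boundary"
  } else {
    # degenerate/bimodal prior region: take the posterior argmax on a grid
    grid <- seq(1e-6, 1 - 1e-6, length.out = 10001L)
    lp <- vapply(grid, function(p)
      dbeta(p, alpha, beta, log = TRUE) + loglik(p), numeric(1))
    mode <- grid[which.max(lp)]
    if (flag == "ok") flag <- "boundary"
  }

  data.table(
    cell_id = if ("cell_id" %in% names(records)) records$cell_id[1] else NA_character_,
    gene_id = if ("gene_id" %in% names(records)) records$gene_id[1] else NA_character_,
    alpha = alpha, beta = beta,
    pi_g_point = pi_point, pi_g_mode = mode,
    reads_total = as.integer(reads_total), reads_used = nrow(records),
    subsampled = isTRUE(attr(records, "subsampled")),
    quality_flag = flag
  )
}

#' Fit pi_g for every eligible gene-by-cell pair
#'
#' Applies the read filters of [prepare_gene_reads()] and then [fit_pi_g()]
#' across all (cell, gene) pairs in a record table.
#'
#' @param records data.frame with columns `cell_id`, `gene_id`, `y`, `n`.
#' @param rates list of `cell_rates` objects (or a data.frame with columns
#'   `cell_id`, `p_e`, `p_c`) supplying the per-cell probabilities.
#' @param min_reads,cap,seed see [prepare_gene_reads()].
#' @param maxit,reltol see [fit_pi_g()].
#' @return data.table of estimates, one row per estimated gene-by-cell pair.
#' @export
fit_pi_g_all <- function(records, rates, min_reads = 16L, cap = 1000L,
                         seed = 1L, maxit = 200L, reltol = 1e-8) {
  records <- data.table::as.data.table(records)
  rt <- if (is.data.frame(rates)) data.table::as.data.table(rates)
        else rbindlist(lapply(rates, function(r)
          data.table(cell_id = r$cell_id, p_e = r$p_e, p_c = r$p_c)))
  out <- vector("list", 0L)
  groups <- split(records, by = c("cell_id", "gene_id"), drop = TRUE)
  for (g in groups) {
    sel <- prepare_gene_reads(g, min_reads = min_reads, cap = cap, seed = seed)
    if (is.null(sel)) next
    cr <- rt[cell_id == g$cell_id[1]]
    if (nrow(cr) == 0L)
      stop("no fitted rates for cell ", g$cell_id[1])
    out[[length(out) + 1L]] <- fit_pi_g(
      sel, p_e = cr$p_e[1], p_c = cr$p_c[1], reads_total = nrow(g),
      maxit = maxit, reltol = reltol)
  }
  if (length(out) == 0L)
    return(data.table(cell_id = character(), gene_id = character(),
                      alpha = numeric(), beta = numeric(),
                      pi_g_point = numeric(), pi_g_mode = numeric(),
                      reads_total = integer(), reads_used = integer(),
                      subsampled = logical(), quality_flag = character()))
  rbindlist(out)
}
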