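# Per-cell error and conversion rate models.
#
# Mismatches against the reference within gene-assigned reads are summarised
# per cell in a mismatch tally (12 substitution types in gene-strand
# orientation). The background error probability p_e comes from the C>T and
# G>A substitution fractions; the conversion probability p_c of labelled
# (new) reads is fitted by EM on a two-component binomial mixture of the
# per-read conversion counts with p_e held fixed.

BASES <- c("A", "C", "G", "T")

#' Construct a per-cell mismatch tally
#'
#' A mismatch tally records, in gene-strand orientation, how many aligned
#' positions covered each reference base and how many of them were read as
#' each other base. It is the sufficient statistic for the background error
#' probability and for conversion-rate profiling by substitution type.
#'
#' @param ref character vector of reference bases (gene-strand orientation).
#' @param alt character vector of read bases at the same positions.
#' @return An object of class `mismatch_tally`: a list with `mismatch`, a
#'   4x4 matrix of counts indexed `[reference base, read base]` (diagonal =
#'   matches), and `coverage`, positions covered per reference base.
#' @export
mismatch_tally <- function(ref = character(), alt = character()) {
  keep <- ref %in% BASES & alt %in% BASES
  m <- table(factor(ref[keep], BASES), factor(alt[keep], BASES))
  m <- matrix(as.integer(m), 4, 4, dimnames = list(BASES, BASES))
  structure(list(mismatch = m, coverage = rowSums(m)),
            class = "mismatch_tally")
}

#' @export
print.mismatch_tally <- function(x, ...) {
  cat("mismatch tally (", sum(x$coverage), " positions)\n", sep = "")
  print(x$mismatch)
  invisible(x)
}

#' Combine mismatch tallies
#'
#' @param ... `mismatch_tally` objects.
#' @return A single pooled `mismatch_tally`.
#' @export
combine_tallies <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], "mismatch_tally"))
    ts <- ts[[1]]
  out <- mismatch_tally()
  for (t in ts) {
    out$mismatch <- out$mismatch + t$mismatch
    out$coverage <- out$coverage + t$coverage
  }
  out
}

#' Per-type substitution rates from a tally
#'
#' @param tally a `mismatch_tally`.
#' @return data.table with columns `ref`, `alt`, `count`, `coverage`, `rate`
#'   for the 12 substitution types; `rate = count / coverage` (NA at zero
#'   coverage).
#' @export
tally_rates <- function(tally) {
  grid <- data.table::CJ(ref = BASES, alt = BASES)[ref != alt]
  grid[, `:=`(
    count    = tally$mismatch[cbind(ref, alt)],
    coverage = tally$coverage[ref]
  )]
  grid[, rate := ifelse(coverage > 0, count / coverage, NA_real_)]
  grid[]
}

#' Estimate the background error probability of a cell
#'
#' The error probability p_e is the mean of the C>T and G>A substitution
#' fractions in the cell's gene-strand-oriented mismatch tally. These two
#' substitution types are unaffected by 4sU conversion (which produces T>C)
#' and behave like the T>C rate observed in unlabelled cells, so they measure
#' the sequencing/PCR error floor.
#'
#' @param tally a `mismatch_tally` for one cell.
#' @param floor lower bound returned when no background mismatches are
#'   observed; keeps downstream likelihoods and the signal-to-noise ratio
#'   non-degenerate. Default `1e-6`.
#' @return numeric scalar p_e.
#' @export
estimate_pe <- function(tally, floor = 1e-6) {
  cov_c <- tally$coverage[["C"]]
  cov_g <- tally$coverage[["G"]]
  if (cov_c == 0 || cov_g == 0)
    stop("no coverage of reference C and/or G positions; ",
         "relax quality filters or pool more reads before estimating p_e")
  pe <- mean(c(tally$mismatch["C", "T"] / cov_c,
               tally$mismatch["G", "A"] / cov_g))
  max(pe, floor)
}

#' Two-component binomial mixture probability mass
#'
#' Probability of observing `y` conversions among `n` convertible positions
#' in a read when the read is new with probability `pi` (conversion
#' probability `p_c`) and old otherwise (error probability `p_e`):
#' `(1 - pi) * Binom(y; n, p_e) + pi * Binom(y; n, p_c)`.
#'
#' @param y,n integer vectors, `0 <= y <= n`.
#' @param p_e,p_c,pi probabilities in `[0, 1]`.
#' @param log return log-probability (computed stably in log space).
#' @return numeric vector of (log-)probabilities.
#' @export
mixture_pmf <- function(y, n, p_e, p_c, pi, log = FALSE) {
  if (any(y < 0) || any(y > n)) stop("require 0 <= y <= n")
  stopifnot_prob(p_e, "p_e"); stopifnot_prob(p_c, "p_c")
  stopifnot_prob(pi, "pi")
  le <- dbinom(y, n, p_e, log = TRUE)
  lc <- dbinom(y, n, p_c, log = TRUE)
  if (pi == 0) lp <- le
  else if (pi == 1) lp <- lc
  else lp <- log_sum_exp(log1p(-pi) + le, base::log(pi) + lc)
  if (log) lp else exp(lp)
}

# Observed-data log-likelihood of aggregated records; w = multiplicity.
mixture_loglik <- function(y, n, w, p_e, p_c, pi) {
  sum(w * mixture_pmf(y, n, p_e, p_c, pi, log = TRUE))
}

#' Fit the conversion probability of a cell by EM
#'
#' Fits the free parameters (p_c, pi) of the two-component binomial mixture
#' to all of one cell's per-read conversion records, with the error
#' probability p_e held fixed. The E-step computes the posterior probability
#' that each read is new; the M-step sets p_c to the responsibility-weighted
#' conversion fraction and pi to the mean responsibility. All binomial terms
#' are evaluated in log space and responsibilities via log-sum-exp, so fits
#' are stable for reads with thousands of convertible positions.
#'
#' @param y,n integer vectors of per-read conversion counts and convertible
#'   positions for one cell (pooled across genes).
#' @param p_e fixed background error probability.
#' @param cell_id optional label stored in the result.
#' @param init_pc,init_pi initial values; defaults `max(2 * p_e, 0.01)` and
#'   `0.1`.
#' @param tol convergence tolerance on the log-likelihood improvement.
#' @param max_iter maximum EM iterations.
#' @return An object of class `cell_rates`: list with `cell_id`, `p_e`,
#'   `p_c`, `pi_cell`, `em_iterations`, `loglik_trace`, `converged`, and
#'   `no_signal` (TRUE when the fit collapses onto p_c = p_e).
#' @export
em_fit_pc <- function(y, n, p_e, cell_id = NA_character_,
                      init_pc = max(2 * p_e, 0.01), init_pi = 0.1,
                      tol = 1e-8, max_iter = 500L) {
  if (length(y) == 0L) stop("no records supplied")
  if (length(y) != length(n)) stop("y and n lengths differ")
  if (any(y < 0) || any(y > n)) stop("require 0 <= y <= n")
  if (all(n == 0L)) stop("all records have n = 0 convertible positions")
  stopifnot_prob(p_e, "p_e")

  # aggregate identical (y, n) pairs; the likelihood only depends on counts
  agg <- data.table(y = y, n = n)[, .(w = .N), by = .(y, n)]
  yv <- agg$y; nv <- agg$n; wv <- agg$w
  N <- sum(wv)

  p_c <- min(max(init_pc, p_e), 1)
  pi  <- min(max(init_pi, 1e-12), 1 - 1e-12)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    le <- log1p(-pi) + dbinom(yv, nv, p_e, log = TRUE)
    lc <- base::log(pi) + dbinom(yv, nv, p_c, log = TRUE)
    lmix <- log_sum_exp(le, lc)
    r <- exp(lc - lmix)                       # responsibility of the new component
    ll <- sum(wv * lmix)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    denom <- sum(wv * r * nv)
    p_c <- if (denom > 0) sum(wv * r * yv) / denom else p_e
    p_c <- max(p_c, p_e)                      # label-switching guard
    pi <- sum(wv * r) / N
    pi <- min(max(pi, 1e-12), 1 - 1e-12)
  }
  no_signal <- isTRUE(all.equal(p_c, p_e, tolerance = 1e-8))
  # with p_c clamped at p_e the two components coincide and the likelihood
  # is flat in pi: report no detectable new fraction rather than the
  # arbitrary fixed point the flat E-step leaves pi at
  if (no_signal) pi <- 0
  structure(list(
    cell_id = cell_id, p_e = p_e, p_c = p_c, pi_cell = pi,
    em_iterations = iter, loglik_trace = trace, converged = converged,
    no_signal = no_signal
  ), class = "cell_rates")
}

#' @export
print.cell_rates <- function(x, ...) {
  cat(sprintf(
    "cell_rates [%s]: p_e=%.3g p_c=%.3g pi=%.3f (%d EM iterations, %s)\n",
    x$cell_id, x$p_e, x$p_c, x$pi_cell, x$em_iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Labelling signal-to-noise ratio of a cell
#'
#' @param model a fitted `cell_rates` object.
#' @param pe_floor the p_e floor used when fitting; a p_e at the floor means
#'   no background mismatches were seen and the ratio is unreliable.
#' @return numeric `p_c / p_e`, with attribute `reliable` set to FALSE when
#'   p_e sits at the floor.
#' @export
signal_to_noise <- function(model, pe_floor = 1e-6) {
  ratio <- model$p_c / model$p_e
  attr(ratio, "reliable") <- model$p_e > pe_floor
  ratio
}
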