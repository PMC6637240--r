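# Internal helpers shared across modules.

#' @importFrom data.table data.table setDT setkey := .N .SD setnames rbindlist
#' @importFrom stats dbinom dbeta rbinom rpois rbeta runif median sd setNames
#' @importFrom utils write.table read.table head
#' @importFrom methods as
NULL

# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", "cell_id", "gene_id", "qname", "chrom", "pos", "ref", "alt", "qual_ok",
  "strand", "n", "y", "n_cells", "n_mm", "frac", "keep", "read_id",
  "reads_total", "pi_g_mode", "new", "old", "total", "gene_mean", "covered"
))

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  # both -Inf: pmax gives -Inf and exp(NaN) would propagate
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic 32-bit string hash (polynomial, mod 2^31 - 1) used to derive
# per-(cell, gene) subsampling seeds from one experiment seed, so results do
# not depend on processing order.
string_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "\r")
  string_hash(s)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")
}
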