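# Decomposition of expression into newly synthesised and pre-existing RNA.

#' Total feature-assigned fragment counts per gene and cell
#'
#' @param records conversion record table (`cell_id`, `gene_id`, one row per
#'   fragment).
#' @return data.table `cell_id`, `gene_id`, `total`.
#' @export
total_counts <- function(records) {
  data.table::as.data.table(records)[, .(total = .N), by = .(cell_id, gene_id)]
}

#' Split total counts into new and old RNA
#'
#' For every gene-by-cell pair with a fitted new-read fraction, the expected
#' new count is `pi_g_mode * total` and the old count is the remainder, so
#' `new + old = total` exactly. Pairs without an estimate (too few reads)
#' are missing (`NA`), not zero.
#'
#' @param estimates [fit_pi_g_all()] output.
#' @param totals [total_counts()] output (long: `cell_id`, `gene_id`,
#'   `total`). Every estimated pair must be present.
#' @return An object of class `conversion_matrices`: list with `genes`,
#'   `cells`, and dense matrices `total`, `new`, `old` (genes x cells;
#'   `new`/`old` are `NA` where no estimate exists).
#' @export
decompose_counts <- function(estimates, totals) {
  est <- data.table::as.data.table(estimates)
  tot <- data.table::as.data.table(totals)
  miss <- est[!tot, on = c("cell_id", "gene_id")]
  if (nrow(miss) > 0L)
    stop("estimates without a matching total count: ",
         paste(head(paste(miss$cell_id, miss$gene_id, sep = "/"), 3L),
               collapse = ", "))
  genes <- sort(unique(tot$gene_id))
  cells <- sort(unique(tot$cell_id))
  dim2 <- list(genes, cells)
  total <- matrix(0, length(genes), length(cells), dimnames = dim2)
  total[cbind(tot$gene_id, tot$cell_id)] <- tot$total
  new <- matrix(NA_real_, length(genes), length(cells), dimnames = dim2)
  if (nrow(est) > 0L) {
    idx <- cbind(est$gene_id, est$cell_id)
    new[idx] <- est$pi_g_mode * total[idx]
  }
  old <- total - new
  structure(list(genes = genes, cells = cells, total = total, new = new,
                 old = old), class = "conversion_matrices")
}

#' @export
print.conversion_matrices <- function(x, ...) {
  cat("conversion_matrices:", length(x$genes), "gene(s) x", length(x$cells),
      "cell(s);", sum(!is.na(x$new)), "estimated pair(s)\n")
  invisible(x)
}

#' Fraction of a cell's reads from newly transcribed RNA
#'
#' `sum(new) / sum(total)` over the genes of the cell that have an
#' estimate; missing when the cell has no estimated gene.
#'
#' @param ms a `conversion_matrices` object.
#' @param cells cells to evaluate (default all).
#' @return named numeric vector of fractions in `[0, 1]` (NA where
#'   undefined).
#' @export
cell_fraction_new <- function(ms, cells = ms$cells) {
  vapply(cells, function(cc) {
    est <- !is.na(ms$new[, cc])
    if (!any(est)) return(NA_real_)
    sum(ms$new[est, cc]) / sum(ms$total[est, cc])
  }, numeric(1))
}

#' Per-gene fractions of new reads and their distribution
#'
#' @param ms a `conversion_matrices` object.
#' @return list with `fractions` (data.table `cell_id`, `gene_id`,
#'   `fraction_new` over estimated pairs) and `summary` (median and
#'   quartile hinges).
#' @export
gene_fraction_new <- function(ms) {
  idx <- which(!is.na(ms$new), arr.ind = TRUE)
  fr <- data.table(
    cell_id = ms$cells[idx[, 2]],
    gene_id = ms$genes[idx[, 1]],
    fraction_new = ms$new[idx] / ms$total[idx]
  )
  s <- if (nrow(fr) > 0L) stats::quantile(fr$fraction_new, c(0.25, 0.5, 0.75))
       else rep(NA_real_, 3)
  list(fractions = fr,
       summary = c(lower_hinge = unname(s[1]), median = unname(s[2]),
                   upper_hinge = unname(s[3])))
}

#' Number of genes with detected new reads in a cell
#'
#' @param ms a `conversion_matrices` object.
#' @param cells cells to evaluate (default all).
#' @return named integer vector: genes with `new > 0` per cell.
#' @export
genes_with_new_reads <- function(ms, cells = ms$cells) {
  vapply(cells, function(cc) {
    v <- ms$new[, cc]
    sum(!is.na(v) & v > 0)
  }, integer(1))
}

#' Mean conversions per read across a set of genes
#'
#' For each gene the mean of `y` over its reads; then the mean and sample
#' (n - 1) standard deviation of those per-gene means.
#'
#' @param records conversion record table with `gene_id` and `y`.
#' @param genes optional subset of gene ids.
#' @return list with `per_gene` (data.table `gene_id`, `gene_mean`),
#'   `mean`, and `sd` (0 for a single gene).
#' @export
mean_conversions_per_read <- function(records, genes = NULL) {
  rec <- data.table::as.data.table(records)
  if (!is.null(genes)) rec <- rec[gene_id %in% genes]
  if (nrow(rec) == 0L) stop("no records for the requested gene set")
  per <- rec[, .(gene_mean = mean(y)), by = gene_id]
  list(per_gene = per,
       mean = mean(per$gene_mean),
       sd = if (nrow(per) > 1L) sd(per$gene_mean) else 0)
}

#' Export total/new/old matrices
#'
#' Writes the three matrices either as dense TSVs or as MatrixMarket files
#' with `genes.tsv` / `cells.tsv` index files. In sparse output missing
#' (unestimated) entries are written as zeros, so dense TSV is the lossless
#' format.
#'
#' @param ms a `conversion_matrices` object.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"mtx"`.
#' @return invisibly, the paths written.
#' @export
write_matrix_set <- function(ms, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (layer in c("total", "new", "old")) {
    m <- ms[[layer]]
    if (format == "tsv") {
      p <- file.path(dir, paste0(layer, ".tsv"))
      out <- data.table(gene_id = rownames(m))
      out <- cbind(out, data.table::as.data.table(m))
      write_tsv(out, p)
    } else {
      p <- file.path(dir, paste0(layer, ".mtx"))
      m0 <- m; m0[is.na(m0)] <- 0
      Matrix::writeMM(methods::as(Matrix::Matrix(m0, sparse = TRUE),
                                  "generalMatrix"), p)
    }
    paths <- c(paths, p)
  }
  if (format == "mtx") {
    write_tsv(data.table(gene_id = ms$genes), file.path(dir, "genes.tsv"))
    write_tsv(data.table(cell_id = ms$cells), file.path(dir, "cells.tsv"))
  }
  invisible(paths)
}

#' Per-cell summary table
#'
#' @param ms a `conversion_matrices` object.
#' @param rates list of `cell_rates` fits (optional).
#' @return data.table `cell_id`, `fraction_new`, `genes_with_new_reads`,
#'   and, when rates are given, `p_e`, `p_c`, `signal_to_noise`.
#' @export
cell_summary <- function(ms, rates = NULL) {
  out <- data.table(
    cell_id = ms$cells,
    fraction_new = cell_fraction_new(ms),
    genes_with_new_reads = genes_with_new_reads(ms)
  )
  if (!is.null(rates)) {
    rt <- rbindlist(lapply(rates, function(r)
      data.table(cell_id = r$cell_id, p_e = r$p_e, p_c = r$p_c,
                 signal_to_noise = as.numeric(signal_to_noise(r)))))
    out <- merge(out, rt, by = "cell_id", all.x = TRUE, sort = FALSE)
  }
  out
}
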