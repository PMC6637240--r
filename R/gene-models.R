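# Gene models from GTF annotation.

#' Load gene models from a GTF file
#'
#' Reads a GTF, keeps exon features (or, if the file has no `type` column,
#' all features), merges overlapping exon intervals per gene, and records
#' each gene's strand. Records without a defined strand are rejected with a
#' warning: conversion counting is strand-aware (reference T on plus-strand
#' genes, reference A on minus-strand genes) so an unstranded gene cannot be
#' used.
#'
#' @param gtf path to a GTF file with `gene_id` attributes.
#' @return An object of class `gene_models`: a list with `genes` (data.table
#'   `gene_id`, `chrom`, `strand`) and `exons` (a `GRanges` of merged exon
#'   intervals with a `gene_id` metadata column).
#' @export
load_gene_models <- function(gtf) {
  if (is.character(gtf)) {
    if (!file.exists(gtf)) stop("GTF file not found: ", gtf, call. = FALSE)
    lines <- readLines(gtf, warn = FALSE)
    if (!any(nzchar(lines) & !startsWith(lines, "#")))
      return(empty_gene_models())
  }
  gr <- tryCatch(rtracklayer::import(gtf, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", gtf, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L) return(empty_gene_models())
  if (is.null(gr$gene_id)) stop("GTF has no gene_id attribute")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "exon")) gr <- gr[gr$type == "exon"]
  unstranded <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) without strand rejected")
    gr <- gr[!unstranded]
  }
  if (length(gr) == 0L) return(empty_gene_models())
  by_gene <- GenomicRanges::reduce(S4Vectors::split(gr, gr$gene_id))
  exons <- unlist(by_gene, use.names = TRUE)
  exons$gene_id <- names(exons)
  names(exons) <- NULL
  genes <- data.table(
    gene_id = names(by_gene),
    chrom = vapply(as.list(by_gene), function(x)
      as.character(GenomicRanges::seqnames(x))[1], character(1)),
    strand = vapply(as.list(by_gene), function(x)
      as.character(GenomicRanges::strand(x))[1], character(1))
  )
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

empty_gene_models <- function() {
  structure(list(
    genes = data.table(gene_id = character(), chrom = character(),
                       strand = character()),
    exons = GenomicRanges::GRanges(gene_id = character())
  ), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "gene(s),", length(x$exons),
      "merged exon interval(s)\n")
  invisible(x)
}

#' Assign alignments to genes
#'
#' Each alignment is assigned to the single gene whose merged exons its
#' aligned blocks overlap; alignments overlapping no gene or more than one
#' gene (ambiguous) are unassigned. This mirrors default union-mode feature
#' counting.
#'
#' @param galn a `GAlignments` object.
#' @param models a `gene_models` object.
#' @return character vector of gene ids, `NA` for unassigned alignments.
#' @export
assign_reads_to_genes <- function(galn, models) {
  out <- rep(NA_character_, length(galn))
  if (length(galn) == 0L || length(models$exons) == 0L) return(out)
  blocks <- GenomicAlignments::grglist(galn)
  hits <- GenomicRanges::findOverlaps(blocks, models$exons, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  ht <- data.table(read = S4Vectors::queryHits(hits),
                   gene = models$exons$gene_id[S4Vectors::subjectHits(hits)])
  ht <- unique(ht)
  ng <- ht[, .(k = .N, gene = gene[1]), by = read]
  uniq <- ng[k == 1L]
  out[uniq$read] <- uniq$gene
  out
}
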