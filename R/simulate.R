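# Ground-truthed simulation of conversion data.
#
# Two levels: (y, n) read summaries drawn from the generative model the
# estimators assume, and full mini-genome fixtures (FASTA + GTF + per-cell
# SAM) whose MD tags encode exactly the planted mismatches, for end-to-end
# testing of the annotator.

#' Define the ground truth of a simulated labelling experiment
#'
#' Per-gene new-read fractions are drawn from a beta distribution; every
#' read of a gene is new with that probability, and its conversions are
#' binomial with the conversion probability `p_c` (new reads) or the error
#' probability `p_e` (old reads) over its convertible positions.
#'
#' @param n_genes number of genes.
#' @param reads_per_gene reads per gene (scalar or vector).
#' @param p_e,p_c error and conversion probabilities (defaults 0.001 and
#'   0.02, typical of a 1-h 4sU labelling at 50 uM).
#' @param pi_alpha,pi_beta beta parameters of the per-gene new-fraction
#'   distribution (defaults 2 and 6, mean 0.25).
#' @param n_mean mean convertible positions per read (default 30, about a
#'   125-bp usable read at 25% T content); per-read `n` is 1 + Poisson(n_mean - 1).
#' @param cells cell ids (default one cell).
#' @param seed experiment seed; all draws derive from it.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_genes = 200L, reads_per_gene = 200L,
                             p_e = 0.001, p_c = 0.02,
                             pi_alpha = 2, pi_beta = 6,
                             n_mean = 30, cells = "cell1", seed = 1L) {
  stopifnot_prob(p_e, "p_e"); stopifnot_prob(p_c, "p_c")
  if (any(reads_per_gene < 0)) stop("reads_per_gene must be non-negative")
  genes <- sprintf("g%04d", seq_len(n_genes))
  pi_g <- with_seed(derive_seed(seed, "pi_g"),
                    rbeta(n_genes, pi_alpha, pi_beta))
  structure(list(
    p_e = p_e, p_c = p_c,
    pi_g = setNames(pi_g, genes),
    reads_per_gene = setNames(rep_len(reads_per_gene, n_genes), genes),
    n_mean = n_mean, cells = cells, seed = seed,
    snv_positions = NULL
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "simulation_truth: %d gene(s) x %d cell(s), p_e=%g p_c=%g, mean pi_g=%.3f\n",
    length(x$pi_g), length(x$cells), x$p_e, x$p_c, mean(x$pi_g)))
  invisible(x)
}

#' Simulate per-read conversion summaries
#'
#' @param truth a [simulation_truth()].
#' @return data.table `cell_id`, `gene_id`, `read_id`, `n`, `y`, `new`
#'   (the latent label), fully reproducible from the truth's seed.
#' @export
simulate_records <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_seed(derive_seed(truth$seed, "records"), {
    out <- vector("list", length(truth$cells))
    genes <- names(truth$pi_g)
    for (ci in seq_along(truth$cells)) {
      reps <- truth$reads_per_gene
      total <- sum(reps)
      gene_id <- rep(genes, reps)
      n <- 1L + rpois(total, truth$n_mean - 1)
      new <- runif(total) < truth$pi_g[gene_id]
      y <- rbinom(total, n, ifelse(new, truth$p_c, truth$p_e))
      out[[ci]] <- data.table(
        cell_id = truth$cells[ci], gene_id = gene_id,
        read_id = sprintf("%s_r%06d", truth$cells[ci], seq_len(total)),
        n = n, y = as.integer(y), new = new)
    }
    rbindlist(out)
  })
}

# MD tag for an ungapped alignment: runs of matches interleaved with the
# reference base at each mismatch.
make_md <- function(ref, read) {
  mm <- which(ref != read)
  parts <- character()
  last <- 0L
  for (m in mm) {
    parts <- c(parts, as.character(m - last - 1L), ref[m])
    last <- m
  }
  paste0(paste(parts, collapse = ""), length(ref) - last)
}

#' Simulate a mini-genome alignment fixture
#'
#' Writes a small reference FASTA, a GTF of single-exon genes on both
#' strands, and one SAM file per cell whose reads carry exactly the planted
#' mismatches: conversions (T>C on plus-strand genes, A>G on minus-strand
#' genes) at the truth's rates, background errors (C>T and G>A at `p_e`),
#' and germline SNVs shown by every read covering them. The returned truth
#' records give the (n, y) that [annotate_cell()] must recover once the
#' SNVs are masked.
#'
#' @param truth a [simulation_truth()]; gene count and per-gene new
#'   fractions are taken from it.
#' @param dir output directory.
#' @param gene_length,gap gene and intergenic spacer lengths (bases).
#' @param read_length read length (bases).
#' @param n_snv number of planted SNV positions (placed inside genes, at
#'   convertible positions where possible so masking is exercised).
#' @return list with `fasta`, `gtf`, `sams` (named by cell), `truth_records`
#'   (data.table `cell_id`, `gene_id`, `read_id`, `n`, `y`, `new`), `snv`
#'   (data.table `chrom`, `pos`, `ref`, `alt`), and `chrom_seq`.
#' @export
simulate_fixture <- function(truth, dir, gene_length = 400L, gap = 100L,
                             read_length = 80L, n_snv = 4L) {
  stopifnot(inherits(truth, "simulation_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- names(truth$pi_g)
  n_genes <- length(genes)
  strands <- rep_len(c("+", "-"), n_genes)
  if (n_genes < 2L) stop("fixture needs at least two genes (both strands)")
  starts <- gap + (seq_len(n_genes) - 1L) * (gene_length + gap) + 1L
  ends <- starts + gene_length - 1L
  chrom <- "chrS"
  chrom_len <- ends[n_genes] + gap

  with_seed(derive_seed(truth$seed, "fixture"), {
    seq_chars <- sample(BASES, chrom_len, replace = TRUE)

    # plant SNVs at conversion-relevant positions inside genes
    snv <- data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
    if (n_snv > 0L) {
      host <- rep_len(seq_len(n_genes), n_snv)
      spos <- integer(n_snv)
      salt <- character(n_snv)
      for (k in seq_len(n_snv)) {
        g <- host[k]
        want <- if (strands[g] == "+") "T" else "A"
        cand <- starts[g]:ends[g]
        cand <- cand[seq_chars[cand] == want & !(cand %in% spos)]
        if (length(cand) == 0L) cand <- setdiff(starts[g]:ends[g], spos)
        spos[k] <- cand[sample.int(length(cand), 1L)]
        salt[k] <- if (strands[g] == "+" && seq_chars[spos[k]] == "T") "C"
                   else if (strands[g] == "-" && seq_chars[spos[k]] == "A") "G"
                   else sample(setdiff(BASES, seq_chars[spos[k]]), 1L)
      }
      snv <- data.table(chrom = chrom, pos = spos,
                        ref = seq_chars[spos], alt = salt)
    }

    sam_lines <- setNames(vector("list", length(truth$cells)), truth$cells)
    rec <- vector("list", 0L)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
    qual_str <- paste(rep("I", read_length), collapse = "")

    for (cell in truth$cells) {
      lines <- character()
      for (g in seq_len(n_genes)) {
        n_reads <- truth$reads_per_gene[g]
        if (n_reads == 0L) next
        pi_g <- truth$pi_g[g]
        conv_ref <- if (strands[g] == "+") "T" else "A"
        conv_alt <- if (strands[g] == "+") "C" else "G"
        for (r in seq_len(n_reads)) {
          start <- sample(starts[g]:(ends[g] - read_length + 1L), 1L)
          span <- start:(start + read_length - 1L)
          ref_b <- seq_chars[span]
          read_b <- ref_b
          # germline SNVs: every read shows the variant base
          hit <- match(span, snv$pos)
          read_b[!is.na(hit)] <- snv$alt[hit[!is.na(hit)]]
          is_snv <- !is.na(hit)
          conv_idx <- which(ref_b == conv_ref & !is_snv)
          is_new <- runif(1) < pi_g
          p <- if (is_new) truth$p_c else truth$p_e
          converted <- conv_idx[runif(length(conv_idx)) < p]
          read_b[converted] <- conv_alt
          # background errors: C>T and G>A in genome space on both strands
          err_c <- which(ref_b == "C" & !is_snv)
          err_c <- err_c[runif(length(err_c)) < truth$p_e]
          read_b[err_c] <- "T"
          err_g <- which(ref_b == "G" & !is_snv)
          err_g <- err_g[runif(length(err_g)) < truth$p_e]
          read_b[err_g] <- "A"
          qn <- sprintf("%s_%s_r%04d", cell, genes[g], r)
          lines <- c(lines, paste(
            qn, 0L, chrom, start, 60L, paste0(read_length, "M"),
            "*", 0L, 0L, paste(read_b, collapse = ""), qual_str,
            "NM:i:0", paste0("MD:Z:", make_md(ref_b, read_b)),
            sep = "\t"))
          rec[[length(rec) + 1L]] <- data.table(
            cell_id = cell, gene_id = genes[g], read_id = qn,
            n = length(conv_idx), y = length(converted), new = is_new)
        }
      }
      sam_lines[[cell]] <- c(header, lines)
    }

    fasta <- file.path(dir, "genome.fa")
    ref_set <- Biostrings::DNAStringSet(
      setNames(paste(seq_chars, collapse = ""), chrom))
    Biostrings::writeXStringSet(ref_set, fasta)

    gtf <- file.path(dir, "genes.gtf")
    gtf_lines <- unlist(lapply(seq_len(n_genes), function(g)
      sprintf('%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
              chrom, c("gene", "exon"), starts[g], ends[g],
              strands[g], genes[g])))
    writeLines(gtf_lines, gtf)

    sams <- setNames(file.path(dir, paste0(truth$cells, ".sam")), truth$cells)
    for (cell in truth$cells) writeLines(sam_lines[[cell]], sams[[cell]])

    list(fasta = fasta, gtf = gtf, sams = sams,
         truth_records = rbindlist(rec), snv = snv,
         chrom_seq = paste(seq_chars, collapse = ""))
  })
}
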