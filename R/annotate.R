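# Strand-aware conversion annotation of aligned reads.
#
# For every gene-assigned read the annotator counts n, the covered
# convertible reference positions (reference T for plus-strand genes,
# reference A for minus-strand genes, i.e. positions that carried a uridine
# in the transcript), and y, how many of them show the conversion-type
# mismatch (T>C, respectively A>G). Positions in the SNV mask or below the
# base-quality cutoff contribute to neither n nor y, and overlapping
# paired-end mates are collapsed so that each genomic position is counted
# once (mates that disagree on a base call void that position).

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_bases <- function(x) unname(COMP[x])

#' Load a reference genome for conversion annotation
#'
#' @param fasta path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @return named character vector of chromosome sequences (names trimmed at
#'   the first whitespace).
#' @export
load_reference <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    fasta <- Biostrings::readDNAStringSet(fasta)
  if (inherits(fasta, "DNAStringSet")) {
    out <- as.character(fasta)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(fasta) && !is.null(names(fasta))) return(fasta)
  stop("'fasta' must be a FASTA path, DNAStringSet, or named character vector")
}

#' Count conversions within one aligned read segment
#'
#' Pure counting core used by the annotator, exposed for direct use on base
#' vectors. Convertible positions are reference T (plus-strand gene) or
#' reference A (minus-strand gene) that are not masked and meet the quality
#' cutoff; conversions are those read as C, respectively G.
#'
#' @param ref,read equal-length character vectors of reference and read
#'   bases (genome orientation).
#' @param strand `"+"` or `"-"`, the strand of the assigned gene.
#' @param qual optional integer vector of base qualities.
#' @param masked integer offsets (1-based within the vectors) excluded by
#'   the SNV mask.
#' @param min_baseq minimum base quality; positions below it count toward
#'   neither `n` nor `y`.
#' @return list with `n`, `y`, and `tally` (a [mismatch_tally()] of the
#'   retained positions in gene-strand orientation).
#' @export
count_read_conversions <- function(ref, read, strand, qual = NULL,
                                   masked = integer(), min_baseq = 27L) {
  stopifnot(length(ref) == length(read), strand %in% c("+", "-"))
  keep <- ref %in% BASES & read %in% BASES
  if (!is.null(qual)) keep <- keep & qual >= min_baseq
  if (length(masked)) keep[masked] <- FALSE
  ref <- ref[keep]; read <- read[keep]
  if (strand == "-") { ref <- comp_bases(ref); read <- comp_bases(read) }
  list(n = sum(ref == "T"),
       y = sum(ref == "T" & read == "C"),
       tally = mismatch_tally(ref, read))
}

#' Merge the conversion calls of overlapping paired-end mates
#'
#' Each genomic position is counted once toward `n` and `y`; at overlap
#' positions where the mates disagree on the base call the position is
#' excluded from both (no evidence either way).
#'
#' @param mate1,mate2 data.frames with columns `pos` (genomic position of a
#'   convertible position) and `converted` (logical call at that position).
#' @return list with merged `n` and `y`.
#' @export
merge_mate_overlap <- function(mate1, mate2) {
  both <- rbind(data.table::as.data.table(mate1)[, .(pos, converted)],
                data.table::as.data.table(mate2)[, .(pos, converted)])
  merged <- both[, .(k = data.table::uniqueN(converted),
                     converted = converted[1]), by = pos][k == 1L]
  list(n = nrow(merged), y = sum(merged$converted))
}

# Reference bases at the matched positions of one read, reconstructed from
# its MD tag. `read_chars` are the read bases at those positions, in
# reference order. Returns NULL (caller skips the read) on inconsistency.
md_ref_bases <- function(md, read_chars) {
  if (is.na(md) || !nzchar(md)) return(NULL)
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  ref <- read_chars
  i <- 0L
  for (tk in toks) {
    if (grepl("^\\d+$", tk)) {
      i <- i + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      # deletion from the reference: consumes no matched read position
    } else {
      i <- i + 1L
      if (i > length(ref)) return(NULL)
      ref[i] <- toupper(tk)
    }
  }
  if (i != length(ref)) return(NULL)
  ref
}

# Read alignments for one cell and expand them to a per-aligned-position
# table. Secondary/supplementary alignments are skipped always; duplicates
# only for paired-end data. Returns list(pos = data.table(read, qname,
# gene_id, strand, chrom, pos, ref, alt, qual), fragments, feature_reads).
cell_position_table <- function(bam, models, reference = NULL,
                                cell_id = NA_character_) {
  bam <- as_bam(bam)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual"), tag = "MD",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  galn <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(galn)$MD
  flag <- S4Vectors::mcols(galn)$flag
  paired <- bitwAnd(flag, 1L) > 0L
  dup <- bitwAnd(flag, 1024L) > 0L
  keep <- !(paired & dup)              # duplicates removed for paired-end only
  galn <- galn[keep]; md <- md[keep]
  if (length(galn) == 0L)
    return(list(pos = empty_position_table(), fragments = empty_fragments(),
                feature_reads = 0L))

  gene <- assign_reads_to_genes(galn, models)
  feature_reads <- sum(!is.na(gene))
  keep <- !is.na(gene)
  galn <- galn[keep]; gene <- gene[keep]; md <- md[keep]
  if (length(galn) == 0L)
    return(list(pos = empty_position_table(), fragments = empty_fragments(),
                feature_reads = feature_reads))

  qname <- S4Vectors::mcols(galn)$qname
  strand_of <- setNames(models$genes$strand, models$genes$gene_id)
  fragments <- unique(data.table(cell_id = cell_id, read_id = qname,
                                 gene_id = gene))

  cig <- GenomicAlignments::cigar(galn)
  refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = GenomicRanges::start(galn), ops = c("M", "=", "X"))
  qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  nseg <- S4Vectors::elementNROWS(refR)
  refU <- unlist(refR); qryU <- unlist(qryR)
  segread <- rep(seq_along(galn), nseg)
  w <- GenomicRanges::width(refU)
  stopifnot(all(w == GenomicRanges::width(qryU)))
  pos <- data.table(
    read  = rep(segread, w),
    pos   = sequence(w, from = GenomicRanges::start(refU)),
    qpos  = sequence(w, from = GenomicRanges::start(qryU))
  )
  pos[, `:=`(
    qname   = qname[read],
    gene_id = gene[read],
    chrom   = as.character(GenomicRanges::seqnames(galn))[read]
  )]
  pos[, strand := strand_of[gene_id]]

  seqchar <- as.character(S4Vectors::mcols(galn)$seq)
  pos[, alt := substring(seqchar[read], qpos, qpos)]
  qint <- as(S4Vectors::mcols(galn)$qual, "IntegerList")
  qflat <- unlist(qint)
  qoff <- cumsum(c(0L, S4Vectors::elementNROWS(qint)))
  pos[, qual := qflat[qoff[read] + qpos]]

  if (!is.null(reference)) {
    reference <- load_reference(reference)
    pos[, ref := substring(reference[chrom], pos, pos), by = chrom]
  } else {
    if (all(is.na(md)))
      stop("reads carry no MD tag and no reference FASTA was supplied")
    data.table::setkey(pos, read, pos)
    refs <- vector("list", length(galn))
    bad <- logical(length(galn))
    for (i in seq_along(galn)) {
      rc <- pos[.(i)]$alt
      rb <- md_ref_bases(md[i], rc)
      if (is.null(rb)) bad[i] <- TRUE else refs[[i]] <- rb
    }
    if (any(bad))
      warning(sum(bad), " read(s) skipped: MD tag inconsistent with CIGAR")
    pos <- pos[!bad[read]]
    pos[, ref := unlist(refs[unique(read)])]
  }
  pos <- pos[ref %in% BASES & alt %in% BASES]
  list(pos = pos[, .(read, qname, gene_id, strand, chrom, pos, ref, alt, qual)],
       fragments = fragments, feature_reads = feature_reads)
}

empty_position_table <- function() {
  data.table(read = integer(), qname = character(), gene_id = character(),
             strand = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), qual = integer())
}

empty_fragments <- function() {
  data.table(cell_id = character(), read_id = character(), gene_id = character())
}

empty_records <- function() {
  data.table(cell_id = character(), gene_id = character(),
             read_id = character(), n = integer(), y = integer())
}

# Convert SAM to (sorted, indexed) BAM on the fly so plain-text alignments
# can be used directly.
as_bam <- function(path) {
  if (tools::file_ext(path) != "sam") return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Annotate the reads of one cell with conversion records
#'
#' Reads a cell's alignments, assigns reads to genes, and produces one
#' conversion record per fragment together with the cell's mismatch tally
#' and the per-position pileup used for SNV detection. See the package
#' vignette for the full set of filtering rules.
#'
#' @param bam path to a BAM or SAM file holding one cell's alignments.
#' @param models a [load_gene_models()] result.
#' @param reference reference genome ([load_reference()] input), or `NULL`
#'   to reconstruct reference bases from MD tags.
#' @param snv_mask optional SNV mask (data.frame `chrom`, `pos`, 1-based)
#'   from [detect_snv_positions()]; masked positions count toward nothing.
#' @param min_baseq minimum base quality (default 27); lower-quality
#'   positions count toward nothing.
#' @param cell_id label for this cell.
#' @return list with `records` (data.table `cell_id`, `gene_id`, `read_id`,
#'   `n`, `y`; one row per fragment), `tally` (a [mismatch_tally()]),
#'   `coverage` and `mismatches` (per-position pileup, genome orientation),
#'   and `feature_reads` (number of gene-assigned reads).
#' @export
annotate_cell <- function(bam, models, reference = NULL, snv_mask = NULL,
                          min_baseq = 27L, cell_id = NA_character_) {
  pt <- cell_position_table(bam, models, reference, cell_id = cell_id)
  pos <- pt$pos

  pos <- pos[qual >= min_baseq]

  # pileup for SNV detection (genome orientation, quality-filtered)
  coverage <- unique(pos[, .(chrom, pos)])
  mismatches <- unique(pos[ref != alt, .(chrom, pos, ref, alt)])

  if (!is.null(snv_mask) && nrow(snv_mask) > 0L) {
    mk <- data.table::as.data.table(snv_mask)[, .(chrom, pos)]
    pos <- pos[!mk, on = c("chrom", "pos")]
  }

  # fragments whose mates were assigned to different genes are dropped
  frag <- pt$fragments
  multi <- frag[, .(k = data.table::uniqueN(gene_id)), by = read_id][k > 1L]
  if (nrow(multi) > 0L) {
    warning(nrow(multi), " fragment(s) dropped: mates assigned to different genes")
    frag <- frag[!multi, on = "read_id"]
    pos <- pos[!multi, on = c(qname = "read_id")]
  }

  # count every genomic position once per fragment; discard positions where
  # overlapping mates disagree on the base call
  pos <- pos[, .(k = data.table::uniqueN(alt), ref = ref[1], alt = alt[1],
                 gene_id = gene_id[1], strand = strand[1]),
             by = .(qname, chrom, pos)][k == 1L]

  # gene-strand orientation
  pos[strand == "-", `:=`(ref = comp_bases(ref), alt = comp_bases(alt))]

  tally <- mismatch_tally(pos$ref, pos$alt)
  counts <- pos[, .(n = sum(ref == "T"),
                    y = sum(ref == "T" & alt == "C")), by = .(qname, gene_id)]
  records <- merge(frag, counts,
                   by.x = c("read_id", "gene_id"), by.y = c("qname", "gene_id"),
                   all.x = TRUE)
  records[is.na(n), `:=`(n = 0L, y = 0L)]
  records <- records[, .(cell_id, gene_id, read_id, n = as.integer(n),
                         y = as.integer(y))]
  list(records = records, tally = tally, coverage = coverage,
       mismatches = mismatches, feature_reads = pt$feature_reads)
}

#' Annotate all cells of an experiment
#'
#' @param bams character vector of BAM/SAM paths, one per cell; names are
#'   used as cell ids (default: file basename without extension).
#' @inheritParams annotate_cell
#' @return An object of class `nasc_annotation`: list with pooled `records`,
#'   per-cell `tallies`, per-cell `pileup` (coverage + mismatches), and
#'   `feature_reads` (named integer vector).
#' @export
annotate_cells <- function(bams, models, reference = NULL, snv_mask = NULL,
                           min_baseq = 27L) {
  if (is.null(names(bams)))
    names(bams) <- tools::file_path_sans_ext(basename(bams))
  per <- lapply(names(bams), function(cid)
    annotate_cell(bams[[cid]], models, reference, snv_mask,
                  min_baseq = min_baseq, cell_id = cid))
  names(per) <- names(bams)
  structure(list(
    records = rbindlist(lapply(per, `[[`, "records")),
    tallies = lapply(per, `[[`, "tally"),
    pileup = lapply(per, function(x) x[c("coverage", "mismatches")]),
    feature_reads = vapply(per, `[[`, integer(1), "feature_reads")
  ), class = "nasc_annotation")
}

#' @export
print.nasc_annotation <- function(x, ...) {
  cat("nasc_annotation:", length(x$tallies), "cell(s),",
      nrow(x$records), "fragment record(s)\n")
  invisible(x)
}

#' Detect recurrent mismatch positions (germline SNVs)
#'
#' Genomic positions at which the same mismatch recurs across many cells
#' are germline variants, not conversions, and must be excluded from
#' conversion calling. A position is masked when, among the cells covering
#' it with at least one read, the fraction showing the same mismatch
#' exceeds `cell_fraction` and at least `min_cells_covered` cells cover it.
#'
#' @param annotation a `nasc_annotation` (first-pass, unmasked) or its
#'   `pileup` list.
#' @param min_cells_covered minimum number of covering cells (default 5).
#' @param cell_fraction cell-fraction threshold, exceeded strictly
#'   (default 0.1).
#' @return data.table SNV mask with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `n_cells`, `n_mm`.
#' @export
detect_snv_positions <- function(annotation, min_cells_covered = 5L,
                                 cell_fraction = 0.1) {
  pileup <- if (inherits(annotation, "nasc_annotation")) annotation$pileup
            else annotation
  if (length(pileup) == 0L) return(empty_snv_mask())
  cov <- rbindlist(lapply(pileup, `[[`, "coverage"))
  if (nrow(cov) == 0L) return(empty_snv_mask())
  cov_cells <- cov[, .(n_cells = .N), by = .(chrom, pos)]
  mm <- rbindlist(lapply(pileup, `[[`, "mismatches"))
  if (nrow(mm) == 0L) return(empty_snv_mask())
  mm_cells <- mm[, .(n_mm = .N), by = .(chrom, pos, ref, alt)]
  j <- merge(mm_cells, cov_cells, by = c("chrom", "pos"))
  out <- j[n_cells >= min_cells_covered & n_mm / n_cells > cell_fraction]
  data.table::setkey(out, chrom, pos)
  out[]
}

empty_snv_mask <- function() {
  data.table(chrom = character(), pos = integer(), ref = character(),
             alt = character(), n_cells = integer(), n_mm = integer())
}

#' Write / read an SNV mask as a BED-like TSV
#'
#' Columns: chrom, start (0-based), end, ref, alt. Internal positions are
#' 1-based; the conversion happens here at the file boundary.
#'
#' @param mask a [detect_snv_positions()] result.
#' @param path output file.
#' @return the path (write) or the mask data.table (read).
#' @export
write_snv_mask <- function(mask, path) {
  out <- data.table(chrom = mask$chrom, start = mask$pos - 1L, end = mask$pos,
                    ref = mask$ref, alt = mask$alt)
  write_tsv(out, path)
}

#' @rdname write_snv_mask
#' @export
read_snv_mask <- function(path) {
  x <- read_tsv(path)
  data.table(chrom = as.character(x$chrom), pos = as.integer(x$end),
             ref = x$ref, alt = x$alt)
}

#' Retain cells with enough feature-mapped reads
#'
#' Cells whose number of gene-assigned reads falls below `min_reads` are
#' removed; a cell at exactly the threshold is retained. Typical thresholds
#' are 600,000 reads for Jurkat-scale experiments and 300,000 for K562.
#'
#' @param feature_reads named integer vector (or data.frame with columns
#'   `cell_id`, `feature_reads`) of gene-assigned read counts per cell.
#' @param min_reads minimum count, `>=` semantics.
#' @return character vector of retained cell ids.
#' @export
qc_filter_cells <- function(feature_reads, min_reads) {
  if (is.data.frame(feature_reads))
    feature_reads <- setNames(feature_reads$feature_reads,
                              feature_reads$cell_id)
  names(feature_reads)[feature_reads >= min_reads]
}
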