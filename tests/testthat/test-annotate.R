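test_that("conversion counting is strand-aware and mask-aware", {
  # plus-strand gene: reference T positions are convertible, T>C converts
  r <- count_read_conversions(strsplit("TTACGT", "")[[1]],
                              strsplit("CTACGT", "")[[1]], "+")
  expect_equal(r$n, 3L)
  expect_equal(r$y, 1L)

  # minus-strand gene: reference A positions, A>G converts
  r <- count_read_conversions(strsplit("ATTG", "")[[1]],
                              strsplit("GTTG", "")[[1]], "-")
  expect_equal(r$n, 1L)
  expect_equal(r$y, 1L)

  # a masked position counts toward neither n nor y
  r <- count_read_conversions(strsplit("TTACGT", "")[[1]],
                              strsplit("CTACGT", "")[[1]], "+", masked = 1L)
  expect_equal(r$n, 2L)
  expect_equal(r$y, 0L)

  # low-quality positions are excluded the same way
  r <- count_read_conversions(strsplit("TTACGT", "")[[1]],
                              strsplit("CTACGT", "")[[1]], "+",
                              qual = c(10L, rep(40L, 5)), min_baseq = 27L)
  expect_equal(r$n, 2L)
  expect_equal(r$y, 0L)
})

test_that("strand symmetry: reverse-complementing leaves (n, y) unchanged", {
  set.seed(42)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:25) {
    ref <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    read <- ref
    flip <- runif(60) < 0.1
    read[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    fwd <- count_read_conversions(ref, read, "+")
    rc <- count_read_conversions(rev(unname(comp[ref])),
                                 rev(unname(comp[read])), "-")
    expect_equal(fwd$n, rc$n)
    expect_equal(fwd$y, rc$y)
  }
})

test_that("per-type tally rates lie in [0, 1] and respect coverage", {
  set.seed(11)
  ref <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  read <- ref
  flip <- runif(500) < 0.2
  read[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
  tal <- mismatch_tally(ref, read)
  rt <- tally_rates(tal)
  expect_true(all(rt$rate >= 0 & rt$rate <= 1, na.rm = TRUE))
  expect_true(all(rt$count <= rt$coverage))
})

test_that("overlapping mates are merged without double counting", {
  # 10 + 10 convertible positions, 4 shared with consistent calls, one
  # conversion in the shared region seen by both mates
  m1 <- data.frame(pos = 1:10,  converted = c(rep(FALSE, 9), TRUE))
  m2 <- data.frame(pos = 7:16,  converted = c(rep(FALSE, 3), TRUE,
                                              rep(FALSE, 6)))
  got <- merge_mate_overlap(m1, m2)
  expect_equal(got$n, 16L)
  expect_equal(got$y, 1L)

  # disagreement at a shared position removes it entirely
  m2b <- m2; m2b$converted[4] <- FALSE
  got <- merge_mate_overlap(m1, m2b)
  expect_equal(got$n, 15L)
  expect_equal(got$y, 0L)

  # non-overlapping mates are additive
  a <- data.frame(pos = 1:5, converted = c(TRUE, rep(FALSE, 4)))
  b <- data.frame(pos = 101:107, converted = rep(FALSE, 7))
  got <- merge_mate_overlap(a, b)
  expect_equal(got$n, 12L)
  expect_equal(got$y, 1L)
})

test_that("recurrent mismatches across cells are masked as SNVs", {
  mk_pile <- function(n_cells, n_mismatched, pos = 100L) {
    lapply(seq_len(n_cells), function(i) list(
      coverage = data.table::data.table(chrom = "chr1", pos = pos),
      mismatches = if (i <= n_mismatched)
        data.table::data.table(chrom = "chr1", pos = pos, ref = "T", alt = "C")
      else
        data.table::data.table(chrom = character(), pos = integer(),
                               ref = character(), alt = character())
    ))
  }
  # mismatched in 40 of 50 covering cells at threshold 0.1 -> masked
  m <- detect_snv_positions(mk_pile(50, 40), min_cells_covered = 5,
                            cell_fraction = 0.1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 100L)
  # 1 of 50 -> below threshold
  m <- detect_snv_positions(mk_pile(50, 1), min_cells_covered = 5,
                            cell_fraction = 0.1)
  expect_equal(nrow(m), 0L)
  # covered by too few cells -> never masked
  m <- detect_snv_positions(mk_pile(2, 2), min_cells_covered = 5,
                            cell_fraction = 0.1)
  expect_equal(nrow(m), 0L)
  # empty pileup -> empty mask
  expect_equal(nrow(detect_snv_positions(list())), 0L)
})

test_that("SNV mask round-trips through the BED-like TSV", {
  mask <- data.table::data.table(chrom = "chrS", pos = c(11L, 250L),
                                 ref = c("T", "A"), alt = c("C", "G"))
  f <- tempfile(fileext = ".tsv")
  write_snv_mask(mask, f)
  back <- read_snv_mask(f)
  expect_equal(back$pos, mask$pos)   # 1-based restored from 0-based start
  expect_equal(back$ref, mask$ref)
})

test_that("cell QC keeps cells at or above the feature-read threshold", {
  counts <- c(a = 599999L, b = 600000L, c = 700000L)
  expect_setequal(qc_filter_cells(counts, 600000L), c("b", "c"))
  expect_equal(qc_filter_cells(c(k = 300000L), 300000L), "k")
  expect_equal(length(qc_filter_cells(integer(0), 600000L)), 0L)
})

test_that("annotating a simulated fixture recovers planted (y, n) exactly", {
  sf <- small_fixture()
  models <- load_gene_models(sf$fx$gtf)
  ann <- annotate_cells(sf$fx$sams, models, sf$fx$fasta, snv_mask = sf$fx$snv)
  m <- merge(ann$records, sf$fx$truth_records,
             by = c("cell_id", "gene_id", "read_id"), suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(sf$fx$truth_records))
  expect_identical(m$n, m$n.t)
  expect_identical(m$y, m$y.t)
  expect_true(all(m$y >= 0 & m$y <= m$n))
})

test_that("reference bases reconstructed from MD tags match the FASTA path", {
  sf <- small_fixture()
  models <- load_gene_models(sf$fx$gtf)
  cell <- names(sf$fx$sams)[1]
  with_ref <- annotate_cell(sf$fx$sams[[cell]], models, sf$fx$fasta,
                            cell_id = cell)
  with_md <- annotate_cell(sf$fx$sams[[cell]], models, reference = NULL,
                           cell_id = cell)
  key <- c("read_id", "gene_id")
  expect_equal(
    data.table::setkeyv(with_md$records, key),
    data.table::setkeyv(with_ref$records, key))
  expect_equal(with_md$tally$mismatch, with_ref$tally$mismatch)
})

test_that("enlarging the SNV mask never increases any record's n or y", {
  sf <- small_fixture()
  models <- load_gene_models(sf$fx$gtf)
  cell <- names(sf$fx$sams)[2]
  base <- annotate_cell(sf$fx$sams[[cell]], models, sf$fx$fasta,
                        snv_mask = sf$fx$snv, cell_id = cell)$records
  # add arbitrary extra positions to the mask
  set.seed(5)
  extra <- data.table::data.table(
    chrom = "chrS", pos = sample(1:3000, 200),
    ref = "T", alt = "C")
  bigger <- rbind(sf$fx$snv, extra)
  masked <- annotate_cell(sf$fx$sams[[cell]], models, sf$fx$fasta,
                          snv_mask = bigger, cell_id = cell)$records
  j <- merge(base, masked, by = c("cell_id", "gene_id", "read_id"),
             suffixes = c(".a", ".b"))
  expect_equal(nrow(j), nrow(base))
  expect_true(all(j$n.b <= j$n.a))
  expect_true(all(j$y.b <= j$y.a))
})
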