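# Shared in-code fixtures.

write_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, type, start, end, strand, gene_id) {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
          chrom, type, start, end, strand, gene_id)
}

# One small mini-genome fixture reused by several files (built once).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- simulation_truth(n_genes = 6L, reads_per_gene = 40L,
                                cells = paste0("c", 1:6), seed = 7L)
      cache <<- list(truth = truth,
                     fx = simulate_fixture(truth, tempfile("smallfix")))
    }
    cache
  }
})
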