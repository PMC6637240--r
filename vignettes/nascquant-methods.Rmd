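---
title: "Quantifying newly synthesised RNA in single cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying newly synthesised RNA in single cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascquant)
library(data.table)
```

## The measurement

Metabolic labelling with 4-thiouridine (4sU) marks RNA transcribed during
the labelling window: incorporated 4sU residues, after chemical alkylation,
are read by reverse transcriptase as cytosine, so newly synthesised
transcripts acquire apparent T→C mismatches against the reference genome
(A→G in genome coordinates for genes on the minus strand). Sequencing a
single cell's transcriptome therefore yields, for every read, a small count
of conversion-type mismatches whose rate differs between *new* reads
(transcribed during labelling, conversion probability $p_c$, typically a
few percent per convertible position) and *old* reads (pre-existing RNA,
where apparent conversions are sequencing/PCR errors at probability
$p_e \sim 10^{-3}$). Because $p_c$ is small and reads are short, single
conversions are unreliable labels for individual reads; the package instead
estimates, per gene and cell, the *fraction* of reads that are new, and
decomposes expression into new and old components.

## The mixture model

For a read covering $n$ convertible positions (reference T within a
plus-strand gene, reference A within a minus-strand gene) with $y$ observed
conversions,

$$P(y \mid p_e, p_c, n, \pi) \;=\; (1-\pi)\,B(y; n, p_e) \;+\;
  \pi\,B(y; n, p_c),$$

where $B$ is the binomial pmf and $\pi$ is the probability that the read is
new. `mixture_pmf()` evaluates this in log space (log-sum-exp over the two
components), which keeps likelihood sums finite for $n$ up to at least
$10^4$.

Three estimation problems sit on top of this pmf:

1. **$p_e$ per cell** (`estimate_pe()`): the mean of the C→T and G→A
   mismatch fractions in the cell's gene-strand-oriented mismatch tally.
   These substitution types cannot be produced by 4sU conversion and
   empirically match the T→C rate of unlabelled cells, so they measure the
   error floor. When a cell shows no background mismatches at all, $p_e$
   is floored at $10^{-6}$ (configurable) so that likelihoods and the
   signal-to-noise ratio $p_c/p_e$ stay defined; such cells are flagged.

2. **$p_c$ per cell** (`em_fit_pc()`): with $p_e$ fixed, the free
   parameters $(p_c, \pi_{\text{cell}})$ of the mixture are fitted by EM on
   all of the cell's reads pooled across genes. The E-step computes each
   read's responsibility of being new via log-sum-exp; the M-step sets
   $p_c = \sum_i r_i y_i / \sum_i r_i n_i$ and $\pi = \bar r$. Iteration
   stops when the log-likelihood improves by less than $10^{-8}$ (at most
   500 iterations). After every M-step $p_c$ is clamped to $\ge p_e$, which
   removes the label-switching mode; if the fit ends with $p_c = p_e$ the
   two components coincide, the likelihood is flat in $\pi$, and the cell
   is reported as having no detectable labelling signal ($\pi = 0$,
   `no_signal = TRUE`). The log-likelihood trace is stored and asserted
   non-decreasing in the test suite.

3. **$\pi_g$ per gene and cell** (`fit_pi_g()`): $\pi_g$ carries a
   $\mathrm{Beta}(\alpha, \beta)$ prior and the joint objective
   $$\log \mathrm{BetaPDF}(\pi_g; \alpha, \beta) +
     \sum_i \log P(y_i \mid p_e, p_c, n_i, \pi_g)$$
   is maximised over $(\log\alpha, \log\beta, \pi_g)$ by bounded
   quasi-Newton (L-BFGS-B) from the fixed initialisation
   $\log\alpha = \log\beta = 0$, $\pi_g = 0.5$. The reported point estimate
   is the mode of the fitted beta,
   $$\pi_{g,\text{mode}} = \frac{\alpha - 1}{\alpha + \beta - 2}
     \quad (\alpha, \beta > 1),$$
   with mode 1 when $\alpha > 1, \beta < 1$ and mode 0 when
   $\alpha < 1, \beta > 1$.

### Why the hyperparameters are bounded

The joint objective above is *improper*: for any fixed $\pi_g$, letting
$\alpha + \beta \to \infty$ with the beta mode held at $\pi_g$ makes the
prior density at $\pi_g$ grow without bound, so an unconstrained maximiser
diverges along that ridge (and, with $\alpha < 1$, the density blows up at
the boundary itself). We therefore constrain
$|\log\alpha|, |\log\beta| \le 10$. Along the ridge the fitted beta's mode
tracks $\pi_g$, so the reported estimates are insensitive to the bound's
exact value; the bound only guarantees termination at a well-defined point.
For the parameter regions where the beta mode is ill-defined (both
parameters at or below 1, a bimodal or flat prior), the estimate falls back
to the argmax of the joint posterior on a 10,001-point grid and is flagged
`"boundary"`. Optimiser failures are flagged `"unreliable"`, never dropped.

$\pi_g$ itself is optimised on its natural scale inside
$[10^{-9}, 1 - 10^{-9}]$ rather than through a logit transform: the logit
map has vanishing gradients near 0 and 1, where a line-search step that
overshoots can strand the iterate on a numerically flat plateau. With the
box parametrisation the optimiser's $\pi_g$ agrees with a brute-force
likelihood grid to well under $10^{-3}$ (asserted in the tests).

### Precision of the estimates

With a few hundred reads the likelihood determines $p_c$ to roughly
$10^{-3}$ but is nearly flat along a compensating $(p_c, \pi)$ ridge, so
mixing weights are only pinned to a few times $10^{-2}$; the test suite's
brute-force comparisons use grid resolutions chosen accordingly (step
$10^{-3}$ in $p_c$, $4 \times 10^{-2}$ in $\pi$), and additionally require
the EM optimum to be at least as good as the grid optimum in likelihood
(up to the $<0.01$-nat residual the stopping rule can leave on a flat
ridge).

## Read-level filters

Estimation for a gene×cell pair runs only with **at least 16 reads**; with
**more than 1000 reads** a uniform subsample of exactly 1000 is used to
bound runtime. Subsampling seeds derive from the experiment seed plus the
(cell, gene) labels, so every pair's subsample is reproducible regardless
of processing order, and the ambient RNG stream is left untouched.

## Conversion annotation

`annotate_cell()` turns one cell's alignments into per-fragment records
$(n, y)$ under these rules:

* Secondary and supplementary alignments are always skipped;
  duplicate-flagged reads are skipped only for paired-end data.
* A read is assigned to the single gene whose merged exons its aligned
  blocks overlap (union mode); reads overlapping zero or several genes are
  unassigned. All aligned positions of an assigned read count, including
  intronic ones — gene assignment is exonic, position counting is not.
* Convertible positions are defined on the *reference*: covered reference
  T (plus-strand gene) or A (minus-strand gene). Insertions, deletions and
  soft-clips contribute nothing.
* Positions with base quality below 27 (configurable) are excluded from
  both $n$ and $y$ — an error-rate estimate is only interpretable above a
  quality floor.
* Positions in the SNV mask are excluded from both $n$ and $y$: a masked
  site can evidence neither conversion nor non-conversion, and excluding
  it from $n$ avoids deflating per-position rates.
* In overlapping paired-end mates every genomic position is counted once;
  where the mates disagree on the base call the position is excluded
  entirely (conservative and symmetric). Mates assigned to different genes
  void the fragment.
* Reference bases come from the FASTA when supplied, otherwise they are
  reconstructed from MD tags; reads whose MD tag is inconsistent with the
  CIGAR are skipped with a warning.

### SNV masking

Germline variants look like conversions that recur in *every* cell, unlike
true conversions, which are private to a minority of reads in a minority of
cells. The pipeline runs annotation twice: the first pass builds a
per-position pileup across all cells, `detect_snv_positions()` masks every
position where the fraction of covering cells showing the same mismatch
exceeds a threshold (given at least `min_cells_covered = 5` covering
cells), and the second pass re-annotates with the mask applied. The default
cell fraction of 0.1 is calibrated for experiments with on the order of a
hundred cells, where sporadic conversions at one position stay far below
10% of cells. For small cohorts (such as the package's six-cell test
fixtures) the same logic requires a majority fraction — at six cells a
single cell's conversion already exceeds 10% — so the fixture runs use 0.5;
a variant carried by the cell line still reaches fraction 1.0.

### Cell quality control

`qc_filter_cells()` removes cells whose gene-assigned read count falls
below a threshold (kept at exactly the threshold). Typical working values
are 600,000 feature reads for Jurkat-scale experiments and 300,000 for
K562; the pipeline default is 0 (off) because the threshold is
experiment-specific and meaningless for miniature fixtures.

## Quantification

With $\hat\pi_{g,c}$ the per-pair mode estimate and $T_{g,c}$ the total
feature-assigned fragments, the decomposition is the expectation
$N_{g,c} = \hat\pi_{g,c} \, T_{g,c}$, $O_{g,c} = T_{g,c} - N_{g,c}$ — new
counts are expected values, not integers. Pairs without an estimate are
missing, not zero. Summaries: the per-cell fraction of new reads
$\sum_g N_{g,c} / \sum_g T_{g,c}$ over estimated genes, the distribution of
per-gene fractions with quartile hinges, the per-cell count of genes with
$N > 0$, and the mean±SD (sample, $n-1$ convention) of per-gene mean
conversions per read. Matrices export as dense TSV (lossless, preserves
missingness) or MatrixMarket triplets with gene/cell index files.

## The simulator

`simulate_records()` draws directly from the generative model: per-gene
$\pi_g \sim \mathrm{Beta}(2, 6)$ by default (mean 0.25, in the range of
fractions seen after tens of minutes of labelling), each read new with
probability $\pi_g$, convertible positions per read
$n \sim 1 + \mathrm{Poisson}(29)$ (about a 125-bp usable read at ~25% T
content), and $y \sim \mathrm{Binom}(n, p_c)$ or
$\mathrm{Binom}(n, p_e)$. Defaults $p_e = 10^{-3}$, $p_c = 0.02$
correspond to a standard one-hour 50 µM labelling.

`simulate_fixture()` additionally writes a concrete mini-genome — a ~10 kb
single-chromosome FASTA, single-exon genes alternating between strands, and
one SAM file per cell whose reads carry exactly the planted mismatches
(conversions, background C→T/G→A errors, and germline SNVs shown by every
covering read), with MD tags encoding the mismatches. Because every planted
mismatch is known, the annotator's output can be checked for *exact*
equality with the planted $(n, y)$ once SNVs are masked.

What the simulator does **not** model — and what passing tests therefore do
not demonstrate about real data: splicing and intron structure, non-uniform
coverage and 3′ bias, PCR duplicates, indels, base-quality variation,
UMI structure, variable 4sU incorporation efficiency across transcripts,
and cell-to-cell variation in $p_c$. Fixture results validate the
*computation*, not the chemistry.

## Pipeline and reproducibility

`run_pipeline()` executes annotate → snv-mask → re-annotate → qc → rates →
pig → quantify, writing a TSV/MTX artifact per stage and a JSON run report
(parameters, seed, package version, per-stage record counts). Reruns with
the same configuration and seed produce identical files; an `INVALID`
marker protects against consuming partially written output. The two-pass
annotation is kept literal (annotate, build mask, re-annotate) rather than
folding the mask in lazily — fidelity of the stage structure over speed.

Problem sizes in the shipped tests and acceptance script are chosen for
desk-scale runs: 200 genes × 200 reads for parameter-recovery checks
(where estimates stabilise well before this size) and 6 genes × 6 cells ×
40 reads for full-pipeline fixtures.

## Worked example

```{r example}
truth <- simulation_truth(n_genes = 40, reads_per_gene = 120,
                          p_e = 0.001, p_c = 0.02, seed = 42)
rec <- simulate_records(truth)

em <- em_fit_pc(rec$y, rec$n, p_e = truth$p_e)
em

est <- fit_pi_g_all(rec, data.frame(cell_id = "cell1", p_e = truth$p_e,
                                    p_c = em$p_c), seed = 42)
ms <- decompose_counts(est, total_counts(rec))
cell_fraction_new(ms)
cor(est$pi_g_mode, truth$pi_g[est$gene_id])
```

## Known limitations

* New counts are expectations under the fitted model; without UMIs there is
  no direct molecule counting, and amplification biases propagate into the
  fractions.
* Short labelling times push $p_c$ toward $p_e$; fits still complete but
  estimates degrade continuously and arrive increasingly flagged — the
  flags must be honoured downstream.
* $p_e$ is assumed uniform across positions within a cell; locus-specific
  error (e.g. near homopolymers) is absorbed into the SNV mask only when it
  recurs across cells.
* Genes under 16 reads in a cell are never estimated; aggregate summaries
  are conditional on the estimated gene set.
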