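# End-to-end pipeline: annotate -> SNV mask -> re-annotate -> QC -> rates
# -> per-gene new-fraction estimation -> quantification.

#' Build a pipeline configuration
#'
#' Collects the input paths, filter thresholds and seed that drive
#' [run_pipeline()]. Defaults follow the package's standard settings:
#' base quality >= 27, SNV masking at cell fraction 0.1 with >= 5 covering
#' cells, at least 16 reads per gene-by-cell estimate, subsampling cap
#' 1000 reads. The cell QC threshold (reads mapping to features) is
#' experiment-dependent — 600,000 for Jurkat-scale data, 300,000 for K562 —
#' and defaults to 0 (off) for small fixtures.
#'
#' @param bams named character vector of per-cell BAM/SAM paths.
#' @param fasta reference FASTA path (or `NULL` to rely on MD tags).
#' @param gtf gene annotation GTF path.
#' @param outdir output directory.
#' @param min_baseq,snv_cell_fraction,snv_min_cells,qc_min_reads,
#'   min_reads_per_gene,subsample_cap,pe_floor,em_tol,em_max_iter thresholds
#'   (see the stage functions).
#' @param matrix_format `"tsv"` or `"mtx"` for the exported matrices.
#' @param seed experiment seed (drives subsampling).
#' @return list of class `nasc_config`.
#' @export
nasc_config <- function(bams, fasta = NULL, gtf, outdir,
                        min_baseq = 27L, snv_cell_fraction = 0.1,
                        snv_min_cells = 5L, qc_min_reads = 0L,
                        min_reads_per_gene = 16L, subsample_cap = 1000L,
                        pe_floor = 1e-6, em_tol = 1e-8, em_max_iter = 500L,
                        matrix_format = "tsv", seed = 1L) {
  cfg <- list(bams = bams, fasta = fasta, gtf = gtf, outdir = outdir,
              min_baseq = min_baseq, snv_cell_fraction = snv_cell_fraction,
              snv_min_cells = snv_min_cells, qc_min_reads = qc_min_reads,
              min_reads_per_gene = min_reads_per_gene,
              subsample_cap = subsample_cap, pe_floor = pe_floor,
              em_tol = em_tol, em_max_iter = em_max_iter,
              matrix_format = matrix_format, seed = seed)
  num <- c("min_baseq", "snv_cell_fraction", "snv_min_cells", "qc_min_reads",
           "min_reads_per_gene", "subsample_cap", "pe_floor", "em_tol",
           "em_max_iter")
  if (any(vapply(cfg[num], function(x) !is.numeric(x) || x < 0, logical(1))))
    stop("all thresholds must be non-negative numbers")
  structure(cfg, class = "nasc_config")
}

#' Read a pipeline configuration from YAML
#'
#' A flat YAML file whose keys match the [nasc_config()] arguments; `bams`
#' may be a named map `cell_id: path` or a list of paths. Keys supplied in
#' `...` (e.g. from CLI flags) override the file.
#'
#' @param path YAML file.
#' @param ... overrides.
#' @return a `nasc_config`.
#' @export
read_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  if (!is.null(y$bams)) y$bams <- unlist(y$bams)
  do.call(nasc_config, y)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full quantification pipeline
#'
#' Executes, in order: first-pass annotation (no mask), SNV mask detection,
#' re-annotation with the mask, cell QC, per-cell rate estimation (p_e and
#' the EM fit of p_c), per-gene new-fraction estimation, and decomposition
#' into total/new/old matrices. Every stage writes its artifact under
#' `outdir` and the run finishes with a JSON report of parameters and
#' per-stage record counts. Any stage failure aborts with the stage name;
#' an `INVALID` marker is left in the output directory in that case.
#'
#' @param config a [nasc_config()].
#' @return invisibly, a list with the report and the in-memory stage
#'   results (`annotation`, `snv_mask`, `rates`, `estimates`, `matrices`,
#'   `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nasc_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outdir, "INVALID")
  file.create(marker)
  stages <- character()
  report <- list(parameters = config[setdiff(names(config), "bams")],
                 n_cells_input = length(config$bams),
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("nascquant")))
  run_stage <- function(name, expr, track = TRUE) {
    stage_log(name, "starting")
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    if (track) stages <<- c(stages, name)
    out
  }

  # input loading is error-tracked but not one of the seven pipeline stages
  models <- run_stage("load-annotation", load_gene_models(config$gtf),
                      track = FALSE)
  reference <- if (!is.null(config$fasta)) load_reference(config$fasta) else NULL

  ann1 <- run_stage("annotate", annotate_cells(
    config$bams, models, reference, snv_mask = NULL,
    min_baseq = config$min_baseq))
  report$n_records_pass1 <- nrow(ann1$records)

  mask <- run_stage("snv-mask", detect_snv_positions(
    ann1, min_cells_covered = config$snv_min_cells,
    cell_fraction = config$snv_cell_fraction))
  write_snv_mask(mask, file.path(outdir, "snv_mask.tsv"))
  report$n_snv_positions <- nrow(mask)

  ann <- run_stage("re-annotate", annotate_cells(
    config$bams, models, reference, snv_mask = mask,
    min_baseq = config$min_baseq))
  write_tsv(ann$records, file.path(outdir, "records.tsv"))
  report$n_records <- nrow(ann$records)

  keep <- run_stage("qc", qc_filter_cells(ann$feature_reads,
                                          config$qc_min_reads))
  report$n_cells_pass_qc <- length(keep)
  records <- ann$records[cell_id %in% keep]

  rates <- run_stage("rates", {
    lapply(setNames(keep, keep), function(cc) {
      pe <- estimate_pe(ann$tallies[[cc]], floor = config$pe_floor)
      rc <- records[cell_id == cc]
      em_fit_pc(rc$y, rc$n, p_e = pe, cell_id = cc,
                tol = config$em_tol, max_iter = config$em_max_iter)
    })
  })
  rates_dt <- rbindlist(lapply(rates, function(r) data.table(
    cell_id = r$cell_id, p_e = r$p_e, p_c = r$p_c, pi_cell = r$pi_cell,
    signal_to_noise = as.numeric(signal_to_noise(r, config$pe_floor)),
    converged = r$converged, iterations = r$em_iterations)))
  write_tsv(rates_dt, file.path(outdir, "rates.tsv"))

  estimates <- run_stage("pig", fit_pi_g_all(
    records, rates, min_reads = config$min_reads_per_gene,
    cap = config$subsample_cap, seed = config$seed))
  write_tsv(estimates, file.path(outdir, "pig.tsv"))
  report$n_estimates <- nrow(estimates)

  result <- run_stage("quantify", {
    totals <- total_counts(records)
    ms <- decompose_counts(estimates, totals)
    write_matrix_set(ms, file.path(outdir, "matrices"),
                     format = config$matrix_format)
    summ <- cell_summary(ms, rates)
    write_tsv(summ, file.path(outdir, "cell_summary.tsv"))
    list(matrices = ms, summary = summ)
  })

  report$stages_completed <- stages
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  file.remove(marker)
  stage_log("done", "%d stage(s) completed", length(stages))
  invisible(list(report = report, annotation = ann, snv_mask = mask,
                 rates = rates, estimates = estimates,
                 matrices = result$matrices, summary = result$summary))
}
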