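#' Pipeline configuration
#'
#' Either a simulation block (a [simulation_config()]) or paths to real data
#' tables must be supplied — exactly one of the two. Real-data paths are a
#' named list with elements `matrix_A`, `samples_A`, `matrix_B`, `samples_B`,
#' `matrix_T`, `samples_T` (TSV, see [read_expression_matrix()]).
#'
#' @param simulation A `sim_config`, or `NULL`.
#' @param data_paths Named list of TSV paths, or `NULL`.
#' @param q_threshold DE significance cut (strict `<`) on BH q-values.
#' @param ci_level Confidence level of the per-gene intervals.
#' @param margin Optional fixed [`equivalence_margin`][fixed_margin]
#'   overriding the replicate-derived one.
#' @param reference_dataset Which disease contrast supplies `disease_lfc`
#'   for classification: `"A"` (default) or `"B"`.
#' @param require_concordant Require concordant fold-change direction for
#'   the consistent set?
#' @param run_qpcr Also simulate and analyse a qPCR validation table
#'   (simulation mode only)?
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, data_paths = NULL,
                            q_threshold = 0.1, ci_level = 0.95,
                            margin = NULL, reference_dataset = c("A", "B"),
                            require_concordant = FALSE, run_qpcr = TRUE) {
  if (is.null(simulation) == is.null(data_paths)) {
    stop("configuration error: provide exactly one of `simulation` or ",
         "`data_paths`")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "sim_config"))
  if (q_threshold <= 0 || q_threshold >= 1 || ci_level <= 0 || ci_level >= 1) {
    stop("configuration error: thresholds must lie in (0, 1)")
  }
  if (!is.null(margin)) stopifnot(inherits(margin, "equivalence_margin"))
  structure(list(simulation = simulation, data_paths = data_paths,
                 q_threshold = q_threshold, ci_level = ci_level,
                 margin = margin,
                 reference_dataset = match.arg(reference_dataset),
                 require_concordant = require_concordant,
                 run_qpcr = run_qpcr),
            class = "pipeline_config")
}

read_pipeline_inputs <- function(paths) {
  need <- c("matrix_A", "samples_A", "matrix_B", "samples_B",
            "matrix_T", "samples_T")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("data_paths lacks: ", paste(miss, collapse = ", "))
  list(
    matrix_A = read_expression_matrix(paths$matrix_A, paths$samples_A),
    matrix_B = read_expression_matrix(paths$matrix_B, paths$samples_B),
    matrix_T = read_expression_matrix(paths$matrix_T, paths$samples_T),
    truth = NULL
  )
}

#' Run the signature-discovery pipeline end to end
#'
#' Stages: (optional) simulate -> average technical replicates -> moderated
#' differential expression for disease contrasts A and B and the paired
#' treatment contrast -> replicate-derived equivalence margin -> non-change
#' calls -> DE intersection, hypergeometric overlap, fold-change correlation
#' and rescued / enhanced / TKI-independent classification -> (optional)
#' qPCR validation. All intermediate tables, a JSON manifest and a
#' human-readable summary are written under `outdir` when it is given.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created); `NULL` skips writing.
#' @param verbose Log stage progress to standard error?
#' @return A list with the per-stage objects: matrices, `results_A/B/T`,
#'   `margin`, `nonchange`, `consistent`, `overlap`, `correlation`,
#'   `classification`, optional `qpcr`, and the `manifest` list.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[persistsig] ", sprintf(...))
  alpha <- 1 - config$ci_level

  if (!is.null(config$simulation)) {
    say("simulating cohort pair and treatment dataset (seed %d)",
        config$simulation$seed)
    sim <- generate_cohort_pair(config$simulation)
    sim$matrix_T <- generate_treatment_dataset(sim$truth, config$simulation)
  } else {
    say("reading input tables")
    sim <- read_pipeline_inputs(config$data_paths)
  }

  say("differential expression: disease contrasts A and B")
  avg_A <- average_technical_replicates(sim$matrix_A)
  fits_A <- fit_gene_models(avg_A, c("disease", "control"))
  results_A <- moderate_and_test(fits_A, estimate_moderation(fits_A), alpha)
  fits_B <- fit_gene_models(sim$matrix_B, c("disease", "control"))
  results_B <- moderate_and_test(fits_B, estimate_moderation(fits_B), alpha)

  say("differential expression: paired treatment contrast")
  fits_T <- fit_gene_models(sim$matrix_T, c("treated", "baseline"),
                            paired = TRUE)
  results_T <- moderate_and_test(fits_T, estimate_moderation(fits_T), alpha)

  if (is.null(config$margin)) {
    say("deriving equivalence margin from technical replicates")
    margin <- derive_margin(replicate_foldchanges(sim$matrix_A))
  } else {
    margin <- config$margin
  }
  say("margin: [%g, %g]", margin$lower, margin$upper)
  nonchange <- call_nonchanging(results_T, margin)

  say("intersecting DE sets and classifying")
  consistent <- intersect_de(results_A, results_B, config$q_threshold,
                             config$require_concordant)
  overlap <- hypergeometric_overlap(consistent$n_universe, consistent$n_A,
                                    consistent$n_B, consistent$n_overlap)
  correlation <- correlate_foldchanges(results_A, results_B)
  disease_ref <- if (config$reference_dataset == "A") results_A else results_B
  classification <- classify_genes(consistent, disease_ref, results_T,
                                   nonchange)

  out <- list(matrix_A = sim$matrix_A, matrix_B = sim$matrix_B,
              matrix_T = sim$matrix_T, truth = sim$truth,
              results_A = results_A, results_B = results_B,
              results_T = results_T, margin = margin, nonchange = nonchange,
              consistent = consistent, overlap = overlap,
              correlation = correlation, classification = classification)

  if (config$run_qpcr && !is.null(config$simulation)) {
    say("qPCR validation on simulated Ct table")
    qtab <- generate_qpcr_table(sim$truth, config$simulation)
    dct <- delta_ct(qtab)
    out$qpcr <- list(
      table = qtab,
      differential = suppressMessages(qpcr_differential(
        dct, q_threshold = config$q_threshold, alpha = alpha)),
      nonchange = qpcr_nonchange(dct)
    )
  }

  counts <- attr(classification, "counts")
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("persistsig")),
    r_version = R.version.string,
    seed = if (!is.null(config$simulation)) config$simulation$seed else NA,
    q_threshold = config$q_threshold, ci_level = config$ci_level,
    margin = c(lower = margin$lower, upper = margin$upper),
    counts = list(
      n_genes = nrow(results_A), n_de_A = consistent$n_A,
      n_de_B = consistent$n_B, n_consistent = consistent$n_overlap,
      n_nonchanging = sum(nonchange$nonchanging),
      rescued = unname(counts["rescued"]),
      enhanced = unname(counts["enhanced"]),
      tki_independent = unname(counts["tki_independent"])
    ),
    overlap_p = overlap$p_value, pearson_r = correlation$pearson_r
  )

  if (!is.null(outdir)) write_pipeline_outputs(out, config, outdir, say)
  out
}

write_pipeline_outputs <- function(out, config, outdir, say) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  say("writing outputs to %s", outdir)
  write_expression_matrix(out$matrix_A, p("matrix_A.tsv"), p("samples_A.tsv"))
  write_expression_matrix(out$matrix_B, p("matrix_B.tsv"), p("samples_B.tsv"))
  write_expression_matrix(out$matrix_T, p("matrix_T.tsv"), p("samples_T.tsv"))
  if (!is.null(out$truth)) {
    utils::write.table(out$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_contrast_result(out$results_A, p("results_A.tsv"))
  write_contrast_result(out$results_B, p("results_B.tsv"))
  write_contrast_result(out$results_T, p("results_T.tsv"))
  write_margin(out$margin, p("margin.json"))
  utils::write.table(out$nonchange, p("nonchange.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$classification, p("classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(out$overlap), p("overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$correlation, p("correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  m <- out$manifest
  writeLines(c(
    "persistsig pipeline summary",
    sprintf("genes: %d; DE in A: %d; DE in B: %d; consistent: %d",
            m$counts$n_genes, m$counts$n_de_A, m$counts$n_de_B,
            m$counts$n_consistent),
    sprintf("overlap p = %.3g; fold-change correlation r = %.3f",
            m$overlap_p, m$pearson_r),
    sprintf("margin: [%g, %g]; non-changing after treatment: %d",
            m$margin["lower"], m$margin["upper"], m$counts$n_nonchanging),
    sprintf("classification: %d rescued (%.1f%%), %d enhanced, %d TKI-independent",
            m$counts$rescued,
            100 * m$counts$rescued / max(m$counts$n_consistent, 1),
            m$counts$enhanced, m$counts$tki_independent)
  ), p("summary.txt"))
  invisible(outdir)
}
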