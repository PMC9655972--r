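#' Intersect differentially expressed gene sets across two datasets
#'
#' The consistent set contains genes significant (q below the threshold,
#' strictly) in both datasets, over the universe of genes measured in both.
#' Direction concordance is not required by default; set
#' `require_concordant = TRUE` to additionally demand matching fold-change
#' signs.
#'
#' @param results_A,results_B `contrast_result` collections sharing a gene
#'   identifier namespace.
#' @param q_threshold Significance cut on the BH q-value (strict `<`).
#' @param require_concordant Also require `sign(beta_A) == sign(beta_B)`?
#' @return A list of class `de_intersection`: `genes` (consistent gene ids),
#'   `universe`, `n_universe`, `n_A`, `n_B`, `n_overlap`, `q_threshold`.
#' @export
intersect_de <- function(results_A, results_B, q_threshold = 0.1,
                         require_concordant = FALSE) {
  universe <- intersect(results_A$gene_id, results_B$gene_id)
  if (length(universe) == 0) {
    stop("the two result sets share no gene identifiers")
  }
  a <- results_A[match(universe, results_A$gene_id), ]
  b <- results_B[match(universe, results_B$gene_id), ]
  sig_a <- a$q < q_threshold
  sig_b <- b$q < q_threshold
  both <- sig_a & sig_b
  if (require_concordant) both <- both & sign(a$beta) == sign(b$beta)
  structure(list(genes = universe[both], universe = universe,
                 n_universe = length(universe),
                 n_A = sum(sig_a), n_B = sum(sig_b), n_overlap = sum(both),
                 q_threshold = q_threshold),
            class = "de_intersection")
}

#' @export
print.de_intersection <- function(x, ...) {
  cat(sprintf(
    "de_intersection: %d/%d and %d/%d DE (q < %g), overlap %d\n",
    x$n_A, x$n_universe, x$n_B, x$n_universe, x$q_threshold, x$n_overlap))
  invisible(x)
}

#' Upper-tail hypergeometric test for gene-set overlap
#'
#' Probability of observing at least `n_overlap` shared genes when `n_B`
#' genes are drawn without replacement from a universe of `n_universe`
#' containing `n_A` marked genes. Computed through the log-scale
#' hypergeometric tail for numerical stability at genomic set sizes.
#'
#' @param n_universe Genes tested in both datasets.
#' @param n_A,n_B DE counts in the two datasets.
#' @param n_overlap Observed shared DE genes.
#' @return A list of class `overlap_test` with the counts and `p_value`.
#' @export
hypergeometric_overlap <- function(n_universe, n_A, n_B, n_overlap) {
  if (n_A > n_universe || n_B > n_universe) {
    stop("set sizes cannot exceed the universe")
  }
  lo <- max(0, n_A + n_B - n_universe)
  hi <- min(n_A, n_B)
  if (n_overlap < lo || n_overlap > hi) {
    stop("infeasible overlap ", n_overlap, ": must lie in [", lo, ", ",
         hi, "] for these set sizes")
  }
  logp <- stats::phyper(n_overlap - 1, n_A, n_universe - n_A, n_B,
                        lower.tail = FALSE, log.p = TRUE)
  structure(list(n_universe = n_universe, n_A = n_A, n_B = n_B,
                 n_overlap = n_overlap, p_value = min(1, exp(logp)),
                 log_p = logp),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: %d shared of %d/%d DE in universe %d, p = %.3g\n",
    x$n_overlap, x$n_A, x$n_B, x$n_universe, x$p_value))
  invisible(x)
}

#' Cross-dataset fold-change correlation
#'
#' Pearson correlation of the estimated log2 fold-changes over all genes
#' shared between the two result sets (not only the DE genes), with a
#' two-sided t-based p-value.
#'
#' @param results_A,results_B `contrast_result` collections.
#' @return A list with `pearson_r`, `p_value`, `n_shared`.
#' @export
correlate_foldchanges <- function(results_A, results_B) {
  shared <- intersect(results_A$gene_id, results_B$gene_id)
  if (length(shared) < 3) stop("need >= 3 shared genes")
  a <- results_A$beta[match(shared, results_A$gene_id)]
  b <- results_B$beta[match(shared, results_B$gene_id)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero fold-change variance in one dataset")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n_shared = length(shared))
}

#' Classify consistent DE genes as rescued, enhanced or TKI-independent
#'
#' Precedence: a gene called non-changing after treatment is
#' `tki_independent`; otherwise a treatment fold-change opposing the disease
#' fold-change (`disease_lfc * tki_lfc < 0`) is `rescued`; everything else
#' (same direction, or a zero treatment estimate, which has measure zero
#' under continuous data) is `enhanced`. The three labels always partition
#' the consistent set.
#'
#' @param genes Character vector of consistent DE genes
#'   (see [intersect_de()]).
#' @param disease_results `contrast_result` of the reference disease
#'   contrast (source of `disease_lfc`).
#' @param treatment_results `contrast_result` of the paired treatment
#'   contrast (source of `tki_lfc`).
#' @param nonchange `nonchange_call` collection for the treatment contrast.
#' @return A data frame of class `signature_classification`: `gene_id`,
#'   `disease_lfc`, `tki_lfc`, `label`, with a `counts` attribute
#'   (named vector over the three labels).
#' @export
classify_genes <- function(genes, disease_results, treatment_results,
                           nonchange) {
  if (inherits(genes, "de_intersection")) genes <- genes$genes
  for (nm in c("disease_results", "treatment_results", "nonchange")) {
    tab <- get(nm)
    miss <- setdiff(genes, tab$gene_id)
    if (length(miss)) {
      stop("genes missing from ", nm, ": ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
    }
  }
  d <- disease_results$beta[match(genes, disease_results$gene_id)]
  t <- treatment_results$beta[match(genes, treatment_results$gene_id)]
  nc <- nonchange$nonchanging[match(genes, nonchange$gene_id)]
  label <- ifelse(nc, "tki_independent",
                  ifelse(d * t < 0, "rescued", "enhanced"))
  counts <- c(rescued = sum(label == "rescued"),
              enhanced = sum(label == "enhanced"),
              tki_independent = sum(label == "tki_independent"))
  structure(
    data.frame(gene_id = genes, disease_lfc = d, tki_lfc = t, label = label,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("signature_classification", "data.frame"), counts = counts
  )
}

#' @export
print.signature_classification <- function(x, ...) {
  counts <- attr(x, "counts")
  n <- nrow(x)
  cat(sprintf(
    "signature_classification: %d genes — %d rescued (%.1f%%), %d enhanced, %d TKI-independent\n",
    n, counts["rescued"], 100 * counts["rescued"] / max(n, 1),
    counts["enhanced"], counts["tki_independent"]))
  invisible(x)
}
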