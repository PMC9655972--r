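#' Reference-gene normalisation of Ct values (delta Ct)
#'
#' `dCt[g, s] = Ct[g, s] - mean over reference genes of Ct[ref, s]`, computed
#' within each sample. The resulting delta-Ct values are carried forward as
#' normalised expression quantities; note the Ct scale is inverted relative
#' to expression (higher expression, lower Ct).
#'
#' @param tab A `ct_table` (see [generate_qpcr_table()] /
#'   [read_ct_table()]).
#' @param reference_genes Gene ids to normalise against; defaults to all
#'   genes whose role is `reference`. At least 2, present and finite in
#'   every sample.
#' @return A list of class `dct_table`: `dct` (test genes x samples matrix
#'   of delta-Ct values), `samples` metadata and `reference_genes`.
#' @export
delta_ct <- function(tab, reference_genes = NULL) {
  stopifnot(inherits(tab, "ct_table"))
  if (is.null(reference_genes)) {
    reference_genes <- names(tab$roles)[tab$roles == "reference"]
  }
  miss <- setdiff(reference_genes, rownames(tab$ct))
  if (length(miss)) {
    stop("reference genes absent from the Ct table: ",
         paste(miss, collapse = ", "))
  }
  if (length(reference_genes) < 2) stop("need >= 2 reference genes")
  ref <- tab$ct[reference_genes, , drop = FALSE]
  if (anyNA(ref) || any(!is.finite(ref))) {
    stop("missing or non-finite reference Ct in at least one sample")
  }
  norm <- colMeans(ref)
  test_ids <- setdiff(rownames(tab$ct), reference_genes)
  dct <- sweep(tab$ct[test_ids, , drop = FALSE], 2, norm)
  structure(list(dct = dct, samples = tab$samples,
                 reference_genes = reference_genes),
            class = "dct_table")
}

#' Cohort differential expression on delta-Ct values
#'
#' Runs the moderated two-group machinery on delta-Ct values (disease vs
#' control by default). `beta` is the delta-delta-Ct of the contrast, with
#' its confidence interval; remember that on the Ct scale a positive
#' delta-delta-Ct means *lower* expression in the test group. With fewer
#' than 50 test genes the empirical-Bayes prior is not estimable and the fit
#' falls back to the classical unmoderated t test (`d0 = 0`), with a
#' message.
#'
#' @param dct A `dct_table` from [delta_ct()].
#' @param groups Length-2 `c(test, ref)` cohort labels.
#' @param q_threshold DE call threshold on the BH q-value (strict `<`).
#' @param alpha CI level complement.
#' @return A `contrast_result` data frame with an extra logical column `de`.
#' @export
qpcr_differential <- function(dct, groups = c("disease", "control"),
                              q_threshold = 0.1, alpha = 0.05) {
  stopifnot(inherits(dct, "dct_table"))
  keep <- dct$samples$group %in% groups
  em <- expression_matrix(dct$dct[, keep, drop = FALSE],
                          dct$samples[keep, , drop = FALSE])
  fits <- fit_gene_models(em, groups = groups, paired = FALSE)
  params <- tryCatch(estimate_moderation(fits), error = function(e) {
    message("too few genes for empirical-Bayes moderation; ",
            "using the unmoderated per-gene t test")
    list(d0 = 0, s0_2 = NA_real_)
  })
  res <- moderate_and_test(fits, params, alpha = alpha)
  res$de <- res$q < q_threshold
  res
}

#' Paired delta-delta-Ct non-change call
#'
#' For each test gene, the per-patient delta-delta-Ct is the treated minus
#' the untreated delta-Ct of that patient; the gene is non-changing when the
#' per-gene median (or mean, by `center`) lies strictly inside the
#' equivalence interval, `(-0.5, 0.5)` by default.
#'
#' @param dct A `dct_table` containing paired samples.
#' @param groups Length-2 `c(treated, untreated)` condition labels.
#' @param bounds Length-2 equivalence interval on the delta-delta-Ct scale.
#' @param center Summary across patients: `median` (default) or `mean`.
#' @return A data frame of class `qpcr_call`: `gene_id`, `median_ddct`,
#'   `nonchanging`, with the per-patient delta-delta-Ct matrix attached as
#'   attribute `ddct`.
#' @export
qpcr_nonchange <- function(dct, groups = c("treated", "baseline"),
                           bounds = c(-0.5, 0.5),
                           center = c("median", "mean")) {
  stopifnot(inherits(dct, "dct_table"))
  center <- match.arg(center)
  s <- dct$samples
  i1 <- which(s$group == groups[1])
  i2 <- which(s$group == groups[2])
  p1 <- s$patient_id[i1]
  p2 <- s$patient_id[i2]
  if (!setequal(p1, p2) || anyDuplicated(p1) || anyDuplicated(p2)) {
    stop("paired analysis requires one ", groups[1], " and one ", groups[2],
         " sample per patient")
  }
  if (length(i1) < 2) {
    warning("fewer than 2 patients: the per-gene median is a single ",
            "observation")
  }
  ddct <- dct$dct[, i1, drop = FALSE] -
    dct$dct[, i2[match(p1, p2)], drop = FALSE]
  colnames(ddct) <- p1
  med <- apply(ddct, 1, if (center == "median") stats::median else mean)
  structure(
    data.frame(gene_id = rownames(ddct), median_ddct = med,
               nonchanging = med > bounds[1] & med < bounds[2],
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("qpcr_call", "data.frame"), ddct = ddct
  )
}
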