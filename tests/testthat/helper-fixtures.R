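# small in-code fixtures shared across test files

# expression matrix from a plain genes x samples matrix and group labels;
# one biological sample per column unless patient ids are given
make_em <- function(values, group, patient = NULL, rep_index = NULL) {
  n <- ncol(values)
  if (is.null(patient)) patient <- sprintf("p%02d", seq_len(n))
  if (is.null(rep_index)) rep_index <- rep(1L, n)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)), patient_id = patient,
    group = group, tech_rep_index = rep_index, stringsAsFactors = FALSE
  )
  colnames(values) <- samples$sample_id
  expression_matrix(values, samples)
}

# two-group expr_matrix from per-group value lists (one gene per row)
make_two_group_em <- function(test_values, ref_values,
                              groups = c("disease", "control")) {
  v <- cbind(test_values, ref_values)
  make_em(v, rep(groups, c(ncol(test_values), ncol(ref_values))))
}

# contrast_result stub from explicit columns (for rule-level tests)
make_results <- function(gene_id, beta = 0, q = 1, ci_lo = beta - 1,
                         ci_hi = beta + 1) {
  structure(
    data.frame(gene_id = gene_id, beta = beta, s2 = NA_real_,
               s2_post = NA_real_, df_total = NA_real_, t_mod = NA_real_,
               p = NA_real_, q = q, ci_lo = ci_lo, ci_hi = ci_hi,
               stringsAsFactors = FALSE),
    class = c("contrast_result", "data.frame")
  )
}

# brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m),
               function(i) min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- qs
  out
}

# exhaustive upper-tail hypergeometric probability via binomial coefficients
hyper_oracle <- function(n_universe, n_A, n_B, n_overlap) {
  ks <- n_overlap:min(n_A, n_B)
  sum(choose(n_A, ks) * choose(n_universe - n_A, n_B - ks)) /
    choose(n_universe, n_B)
}
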