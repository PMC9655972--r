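#' Average technical replicates
#'
#' Collapses each biological sample (a `patient_id` x `group` combination) to
#' a single column holding the per-gene arithmetic mean of its technical
#' replicates. Averaging is unbiased for balanced replicates and lets the
#' downstream per-gene fits treat columns as independent biological units.
#'
#' @param em An [expression_matrix()] whose metadata carries
#'   `tech_rep_index`.
#' @return An `expr_matrix` with one column per biological sample
#'   (`tech_rep_index` reset to 1).
#' @export
average_technical_replicates <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  key <- biological_key(em$samples)
  keys <- unique(key)
  values <- vapply(keys, function(k) {
    idx <- which(key == k)
    if (length(idx) == 0) stop("biological sample with zero replicates")
    rowMeans(em$values[, idx, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (!is.matrix(values)) {       # single-gene input
    values <- matrix(values, nrow = 1, dimnames = list(rownames(em$values)))
  }
  first <- match(keys, key)
  samples <- em$samples[first, , drop = FALSE]
  samples$tech_rep_index <- 1L
  samples$sample_id <- samples$patient_id
  rownames(samples) <- NULL
  colnames(values) <- samples$sample_id
  expression_matrix(values, samples)
}

#' Per-gene linear model fits for a two-group or paired contrast
#'
#' For an unpaired contrast, `beta` is the difference of group means
#' (`test` minus `ref`), `s2` the pooled within-group variance,
#' `stdev_unscaled = sqrt(1/n1 + 1/n2)` and `df_resid = n1 + n2 - 2`. For a
#' paired contrast, samples are matched by `patient_id`; `beta` is the mean
#' of within-patient differences, `s2` their sample variance,
#' `stdev_unscaled = sqrt(1/n_pairs)` and `df_resid = n_pairs - 1`.
#'
#' @param em An [expression_matrix()]; technical replicates should be
#'   averaged first (see [average_technical_replicates()]).
#' @param groups Length-2 character vector `c(test, ref)` naming the levels
#'   of `em$samples$group` to contrast; `beta > 0` means higher in `test`.
#' @param paired Match samples by patient (treatment designs)?
#' @return A data frame of class `gene_fit` with columns `gene_id`, `beta`,
#'   `s2`, `stdev_unscaled`, `df_resid`. Genes with zero residual variance
#'   keep `s2 = 0` (they borrow strength during moderation).
#' @export
fit_gene_models <- function(em, groups = c("disease", "control"),
                            paired = FALSE) {
  stopifnot(inherits(em, "expr_matrix"), length(groups) == 2)
  g <- em$samples$group
  i1 <- which(g == groups[1])
  i2 <- which(g == groups[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("each group needs >= 2 samples (", groups[1], ": ", length(i1),
         ", ", groups[2], ": ", length(i2), ")")
  }
  x1 <- em$values[, i1, drop = FALSE]
  x2 <- em$values[, i2, drop = FALSE]
  if (paired) {
    p1 <- em$samples$patient_id[i1]
    p2 <- em$samples$patient_id[i2]
    if (!setequal(p1, p2) || anyDuplicated(p1) || anyDuplicated(p2)) {
      stop("paired design requires one ", groups[1], " and one ", groups[2],
           " sample per patient")
    }
    d <- x1 - x2[, match(p1, p2), drop = FALSE]
    n <- ncol(d)
    beta <- rowMeans(d)
    s2 <- rowSums((d - beta)^2) / (n - 1)
    su <- sqrt(1 / n)
    df <- n - 1
  } else {
    n1 <- ncol(x1); n2 <- ncol(x2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    beta <- m1 - m2
    rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
    df <- n1 + n2 - 2
    s2 <- rss / df
    su <- sqrt(1 / n1 + 1 / n2)
  }
  structure(
    data.frame(gene_id = rownames(em$values), beta = beta, s2 = s2,
               stdev_unscaled = su, df_resid = df,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("gene_fit", "data.frame")
  )
}

# invert the trigamma function: solve trigamma(x) = y for x > 0.
# Newton iteration on the decreasing convex function, with a bisection
# fallback if an iterate leaves (0, Inf); tolerance 1e-8.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))          # trigamma(x) ~ 1/x^2 + 1/x near 0
  if (y < 1e-6) return(1 / y)               # trigamma(x) ~ 1/x for large x
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- (tri - y) / psigamma(x, 2)       # psigamma'' < 0: Newton step
    x_new <- x - dif
    if (x_new <= 0) { x_new <- x / 2 }      # bisection-style safeguard
    if (abs(x_new - x) < 1e-8 * x) return(x_new)
    x <- x_new
  }
  x
}

#' Estimate empirical-Bayes moderation hyperparameters
#'
#' Method-of-moments fit of the scaled inverse chi-square prior for gene-wise
#' residual variances, on the log scale: with
#' `e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2)`, the excess variance of
#' `e_g` over `trigamma(df_g/2)` equals `trigamma(d0/2)`, which is inverted
#' numerically (Newton, tolerance 1e-8); then
#' `s0_2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. If the variance of
#' `e_g` does not exceed its sampling component, the variances are
#' indistinguishable from homogeneous and `d0` is reported infinite with
#' `s0_2` the mean observed variance (so a constant input variance is
#' returned exactly). Estimated `d0` above 1e7 is likewise reported
#' infinite.
#'
#' @param fits A `gene_fit` collection from [fit_gene_models()].
#' @return A list of class `moderation_params` with elements `d0` (prior
#'   degrees of freedom, possibly `Inf`) and `s0_2` (prior variance).
#' @export
estimate_moderation <- function(fits) {
  ok <- fits$df_resid >= 1 & fits$s2 > 0
  if (sum(ok) < 50) {
    stop("need >= 50 genes with positive residual variance to estimate the ",
         "variance prior; with fewer genes use a pooled-variance fallback ",
         "(d0 = Inf, s0_2 = mean variance) or an unmoderated fit (d0 = 0)")
  }
  df <- fits$df_resid[ok]
  e <- log(fits$s2[ok]) - digamma(df / 2) + log(df / 2)
  n <- length(e)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > 1e7) d0 <- Inf
  } else {
    d0 <- Inf
  }
  s0_2 <- if (is.finite(d0)) {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    mean(fits$s2[ok])
  }
  structure(list(d0 = d0, s0_2 = s0_2), class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("moderation_params: d0 = %s, s0_2 = %.6g\n",
              format(x$d0), x$s0_2))
  invisible(x)
}

#' Moderated t statistics, p-values, BH q-values and confidence intervals
#'
#' Shrinks each gene's residual variance toward the prior:
#' `s2_post = (d0 * s0_2 + df_resid * s2) / (d0 + df_resid)` (the limit
#' `s0_2` when `d0` is infinite), forms the moderated t statistic
#' `beta / (sqrt(s2_post) * stdev_unscaled)` on `df_total = df_resid + d0`
#' degrees of freedom, and reports two-sided p-values, Benjamini-Hochberg
#' q-values and `(1 - alpha)` confidence intervals. `d0 = 0` reproduces the
#' classical unmoderated t test exactly.
#'
#' @param fits A `gene_fit` collection.
#' @param params A [`moderation_params`][estimate_moderation] object, or a
#'   list with `d0 = 0` for an unmoderated analysis.
#' @param alpha Confidence level complement for the CI (default 0.05: 95% CI).
#' @return A data frame of class `contrast_result` with columns `gene_id`,
#'   `beta`, `s2`, `s2_post`, `df_total`, `t_mod`, `p`, `q`, `ci_lo`,
#'   `ci_hi`.
#' @export
moderate_and_test <- function(fits, params, alpha = 0.05) {
  d0 <- params$d0
  s0_2 <- params$s0_2
  if (any(d0 + fits$df_resid <= 0)) {
    stop("d0 + df_resid must be positive")
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, nrow(fits))
    df_total <- rep(Inf, nrow(fits))
  } else if (d0 == 0) {
    s2_post <- fits$s2
    df_total <- fits$df_resid
  } else {
    s2_post <- (d0 * s0_2 + fits$df_resid * fits$s2) / (d0 + fits$df_resid)
    df_total <- fits$df_resid + d0
  }
  se <- sqrt(s2_post) * fits$stdev_unscaled
  t_mod <- ifelse(se > 0, fits$beta / se, ifelse(fits$beta == 0, 0, Inf * sign(fits$beta)))
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  half <- stats::qt(1 - alpha / 2, df_total) * se
  structure(
    data.frame(gene_id = fits$gene_id, beta = fits$beta, s2 = fits$s2,
               s2_post = s2_post, df_total = df_total, t_mod = t_mod,
               p = p, q = benjamini_hochberg(p),
               ci_lo = fits$beta - half, ci_hi = fits$beta + half,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("contrast_result", "data.frame")
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min over j >= i of p_(j) * m / j`, mapped back to the input
#' order and capped at 1. Controls the false discovery rate for independent
#' or positively dependent tests.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Write a contrast result table as TSV
#' @param res A `contrast_result` data frame.
#' @param path Output path.
#' @export
write_contrast_result <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contrast_result
#' @export
read_contrast_result <- function(path) {
  structure(utils::read.delim(path, stringsAsFactors = FALSE),
            class = c("contrast_result", "data.frame"))
}
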