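#' Pooled technical-replicate log2 fold-changes
#'
#' For every gene and every unordered pair of technical replicates within a
#' biological sample, emits both signed differences (`r_i - r_j` and
#' `r_j - r_i`), pooled across genes and samples. The symmetrisation removes
#' any dependence on the arbitrary replicate ordering, so the empirical
#' distribution is symmetric by construction and its tails measure the
#' expected fold-change between biologically identical measurements.
#'
#' @param em An [expression_matrix()] with at least one biological sample
#'   measured in >= 2 technical replicates.
#' @return Numeric vector of signed log2 differences.
#' @export
replicate_foldchanges <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  key <- biological_key(em$samples)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    for (c in seq_len(ncol(pairs))) {
      d <- em$values[, pairs[1, c]] - em$values[, pairs[2, c]]
      out[[length(out) + 1]] <- c(d, -d)
    }
  }
  if (length(out) == 0) {
    stop("no biological sample has >= 2 technical replicates")
  }
  unlist(out, use.names = FALSE)
}

# round to the nearest `unit`, halves away from zero (so -0.486 -> -0.5 and
# 0.487 -> 0.5, and a symmetric raw pair stays symmetric)
round_half_away <- function(x, unit = 0.1) {
  sign(x) * floor(abs(x) / unit + 0.5) * unit
}

#' Derive the equivalence margin from replicate fold-changes
#'
#' The raw bounds are the 2.5th and 97.5th empirical percentiles of the
#' pooled replicate differences (linear interpolation between closest ranks,
#' i.e. [stats::quantile()] type 7), mirroring the conventional two-sided 5%
#' significance convention. The reported margin rounds each bound to the
#' nearest 0.1, halves away from zero; `round = FALSE` retains the raw
#' bounds.
#'
#' @param diffs Pooled replicate log2 differences
#'   (see [replicate_foldchanges()]).
#' @param round Round bounds to the nearest 0.1?
#' @return A list of class `equivalence_margin`: `lower`, `upper`,
#'   `raw_lower`, `raw_upper`, `percentile_lo`, `percentile_hi`, `n_diffs`,
#'   `percentile_method`.
#' @export
derive_margin <- function(diffs, round = TRUE) {
  if (length(diffs) < 1000) {
    warning("fewer than 1000 replicate differences; margin percentiles ",
            "may be unstable")
  }
  raw <- stats::quantile(diffs, c(0.025, 0.975), type = 7, names = FALSE)
  if (raw[1] >= 0 || raw[2] <= 0) {
    stop("degenerate replicate distribution: raw percentile bounds (",
         signif(raw[1], 3), ", ", signif(raw[2], 3),
         ") do not straddle zero")
  }
  bounds <- if (round) round_half_away(raw, 0.1) else raw
  if (bounds[1] >= 0 || bounds[2] <= 0) {
    stop("degenerate margin: bounds (", bounds[1], ", ", bounds[2],
         ") collapse to zero width after rounding")
  }
  structure(list(lower = bounds[1], upper = bounds[2],
                 raw_lower = raw[1], raw_upper = raw[2],
                 percentile_lo = 2.5, percentile_hi = 97.5,
                 n_diffs = length(diffs),
                 percentile_method = "linear interpolation (type 7)"),
            class = "equivalence_margin")
}

#' @export
print.equivalence_margin <- function(x, ...) {
  cat(sprintf(
    "equivalence_margin: [%g, %g] (raw percentiles %.4g, %.4g; n = %d)\n",
    x$lower, x$upper, x$raw_lower, x$raw_upper, x$n_diffs))
  invisible(x)
}

#' Manually specified equivalence margin
#'
#' @param lower,upper Margin bounds (lower < 0 < upper).
#' @return An `equivalence_margin` with raw bounds equal to the given ones.
#' @export
fixed_margin <- function(lower = -0.5, upper = 0.5) {
  if (!(lower < 0 && upper > 0)) stop("need lower < 0 < upper")
  structure(list(lower = lower, upper = upper, raw_lower = lower,
                 raw_upper = upper, percentile_lo = NA, percentile_hi = NA,
                 n_diffs = NA_integer_, percentile_method = "fixed"),
            class = "equivalence_margin")
}

#' Call non-changing genes by confidence-interval containment
#'
#' A gene is non-changing when its (1 - alpha) confidence interval both
#' crosses zero and is fully contained within the equivalence margin;
#' interval endpoints exactly on a margin bound count as contained (closed
#' interval). This is the CI-containment form of an equivalence test: being
#' unable to reject zero while being able to reject any change beyond the
#' margin.
#'
#' @param results A `contrast_result` collection with 95% CIs.
#' @param margin An `equivalence_margin`.
#' @return A data frame of class `nonchange_call`: `gene_id`, `ci_lo`,
#'   `ci_hi`, `nonchanging`, with the margin attached as attribute
#'   `margin`.
#' @export
call_nonchanging <- function(results, margin) {
  stopifnot(inherits(margin, "equivalence_margin"))
  nc <- results$ci_lo <= 0 & results$ci_hi >= 0 &
    results$ci_lo >= margin$lower & results$ci_hi <= margin$upper
  structure(
    data.frame(gene_id = results$gene_id, ci_lo = results$ci_lo,
               ci_hi = results$ci_hi, nonchanging = nc,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("nonchange_call", "data.frame"), margin = margin
  )
}

#' Write an equivalence margin as JSON
#' @param margin An `equivalence_margin`.
#' @param path Output path.
#' @export
write_margin <- function(margin, path) {
  jsonlite::write_json(unclass(margin), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_margin
#' @export
read_margin <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "equivalence_margin")
}
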