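#' Expression matrix with sample metadata
#'
#' Lightweight container pairing a genes x samples matrix of log2-scale
#' intensities with a per-sample metadata table, in the style of a limma
#' expression object plus its targets frame.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). No missing values.
#' @param samples Data frame with one row per column of `values`, containing
#'   at least `sample_id`, `patient_id`, `group` (cohort `disease`/`control`
#'   or condition `baseline`/`treated`) and `tech_rep_index`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (anyNA(values)) stop("expression values must not contain missing values")
  if (is.null(rownames(values))) stop("`values` must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "group", "tech_rep_index")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("sample table rows must correspond 1:1 with value columns")
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id))) {
    stop("column names of `values` must equal samples$sample_id, in order")
  }
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d genes x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", names(table(x$samples$group)),
                  as.integer(table(x$samples$group))), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# biological sample key: one biological specimen may be measured as several
# technical replicates, distinguished only by tech_rep_index
biological_key <- function(samples) {
  paste(samples$patient_id, samples$group, sep = "\r")
}

#' Write / read an expression matrix as TSV
#'
#' The values table has `gene_id` as its first column followed by one column
#' per sample; the metadata table has one row per sample.
#'
#' @param em An [expression_matrix()] object.
#' @param values_path,samples_path Paths for the value and metadata TSVs.
#' @return `write_expression_matrix()` returns the paths invisibly;
#'   `read_expression_matrix()` returns an `expr_matrix`.
#' @export
write_expression_matrix <- function(em, values_path, samples_path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values_path, samples_path))
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(values_path, samples_path) {
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  expression_matrix(values, samples)
}
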