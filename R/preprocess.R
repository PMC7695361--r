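#' Log-CPM normalization of a count matrix
#'
#' Transforms raw counts to log2 counts-per-million with the offsets
#' used by limma's voom transformation:
#' `log2((count + 0.5) / (library_size + 1) * 1e6)`. Precision weights
#' are not computed; only the normalized values feed the downstream
#' correlation analyses.
#'
#' @param counts `OmicsMatrix` (or matrix) of nonnegative counts;
#'   every sample must have at least one nonzero count.
#' @return An object of the same kind as the input (layer preserved)
#'   holding log-CPM values.
#' @export
logcpm_normalize <- function(counts) {
  mat <- omics_values(counts)
  if (any(mat < 0)) stop("counts must be nonnegative")
  lib <- colSums(mat)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(mat)[lib == 0], collapse = ", "))
  }
  out <- log2(sweep(mat + 0.5, 2, lib + 1, "/") * 1e6)
  if (inherits(counts, "OmicsMatrix")) omics_matrix(out, counts$layer) else out
}

#' Keep the most variable features
#'
#' Retains the `ceiling(fraction * n_features)` features with the
#' largest sample variance, preserving the original feature order among
#' survivors. Ties at the cutoff variance are resolved by lexicographic
#' feature id so the result is deterministic.
#'
#' @param expr `OmicsMatrix` or matrix.
#' @param fraction Proportion of features to keep, in `(0, 1]`.
#' @return Subset of `expr` of the same class.
#' @export
variance_filter <- function(expr, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  mat <- omics_values(expr)
  n_keep <- ceiling(fraction * nrow(mat))
  v <- apply(mat, 1, stats::var)
  ord <- order(-v, rownames(mat))
  keep_ids <- rownames(mat)[ord[seq_len(n_keep)]]
  sel <- rownames(mat) %in% keep_ids
  out <- mat[sel, , drop = FALSE]
  if (inherits(expr, "OmicsMatrix")) omics_matrix(out, expr$layer) else out
}
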