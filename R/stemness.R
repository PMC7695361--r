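#' Transcriptional stemness index
#'
#' Scores each sample's similarity to a stem-cell expression signature:
#' the Spearman correlation between the signature weights and the
#' sample's expression over the genes shared by both, then min-max
#' scaled across samples to `[0, 1]` (the published mRNAsi scoring
#' procedure). Being rank-based, the raw score is invariant to any
#' strictly monotone transform of a sample's expression.
#'
#' @param expr `OmicsMatrix` or feature x sample matrix (mRNA layer).
#' @param signature Named numeric weight vector (see
#'   [read_signature_tsv()]).
#' @return Data frame with columns `sample`, `raw` (Spearman
#'   correlation) and `scaled` (min-max scaled to `[0, 1]`; all 0.5
#'   with a warning when every sample ties).
#' @export
stemness_index <- function(expr, signature) {
  mat <- omics_values(expr)
  if (ncol(mat) < 2L) stop("need at least 2 samples for min-max scaling")
  shared <- intersect(names(signature), rownames(mat))
  if (length(shared) < 2L)
    stop("only ", length(shared),
         " signature gene(s) found in the expression matrix; need >= 2")
  w <- signature[shared]
  sub <- mat[shared, , drop = FALSE]
  raw <- apply(sub, 2, function(x) {
    suppressWarnings(stats::cor(w, x, method = "spearman"))
  })
  if (all(is.na(raw))) stop("stemness correlation undefined for every sample")
  if (length(unique(raw)) == 1L)
    warning("all samples have identical stemness; scaled scores set to 0.5")
  data.frame(sample = colnames(mat), raw = unname(raw),
             scaled = minmax_scale(unname(raw)),
             stringsAsFactors = FALSE)
}

#' Write stemness scores as TSV
#' @param scores Data frame from [stemness_index()].
#' @param path Output path.
#' @export
write_stemness_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
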