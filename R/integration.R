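#' Correlate features shared by two omics layers
#'
#' Matches features and samples by id across two layers (e.g. gene
#' methylation vs mRNA expression, mRNA vs protein) and computes, per
#' shared feature, the Pearson correlation over the shared samples with
#' its two-sided Student t p-value (`df = n - 2`). Features with zero
#' variance in either layer are skipped with a message.
#'
#' @param matrix_a,matrix_b `OmicsMatrix` objects (or matrices); layer
#'   tags, when present, annotate the records.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame of correlation records: `feature`, `layer_a`,
#'   `layer_b`, `r`, `p`, `n`, `sign_class` (`"negative"`/`"positive"`).
#' @export
correlate_paired_features <- function(matrix_a, matrix_b,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- omics_values(matrix_a); b <- omics_values(matrix_b)
  layer_a <- if (inherits(matrix_a, "OmicsMatrix")) matrix_a$layer else "layerA"
  layer_b <- if (inherits(matrix_b, "OmicsMatrix")) matrix_b$layer else "layerB"
  shared_samples <- intersect(colnames(a), colnames(b))
  if (length(shared_samples) < 3L)
    stop("need at least 3 shared samples; found ", length(shared_samples))
  shared_features <- intersect(rownames(a), rownames(b))
  empty <- data.frame(feature = character(), layer_a = character(),
                      layer_b = character(), r = numeric(), p = numeric(),
                      n = integer(), sign_class = character(),
                      stringsAsFactors = FALSE)
  if (length(shared_features) == 0L) {
    warning("no shared features between layers")
    return(empty)
  }
  a <- a[shared_features, shared_samples, drop = FALSE]
  b <- b[shared_features, shared_samples, drop = FALSE]
  n <- length(shared_samples)
  sda <- apply(a, 1, stats::sd)
  sdb <- apply(b, 1, stats::sd)
  flat <- sda == 0 | sdb == 0
  if (any(flat))
    message(sum(flat), " feature(s) with zero variance skipped")
  keep <- shared_features[!flat]
  if (length(keep) == 0L) return(empty)
  if (method == "spearman") {
    a <- t(apply(a[keep, , drop = FALSE], 1, rank))
    b <- t(apply(b[keep, , drop = FALSE], 1, rank))
  } else {
    a <- a[keep, , drop = FALSE]
    b <- b[keep, , drop = FALSE]
  }
  az <- (a - rowMeans(a)) / apply(a, 1, stats::sd)
  bz <- (b - rowMeans(b)) / apply(b, 1, stats::sd)
  r <- rowSums(az * bz) / (n - 1)
  r <- pmin(1, pmax(-1, r))
  data.frame(feature = keep, layer_a = layer_a, layer_b = layer_b,
             r = unname(r), p = cor_pvalue(unname(r), n), n = n,
             sign_class = ifelse(r < 0, "negative", "positive"),
             stringsAsFactors = FALSE)
}

#' Filter correlation records on strength and significance
#'
#' Keeps records with `|r| > cor_cut` and `p < p_cut`, both strict —
#' the classical `|cor| > 0.9, P < 0.01` rule used for cross-omics
#' cascades. Optionally applies Benjamini-Hochberg correction before
#' filtering (off by default; the conventional rule uses raw p-values).
#'
#' @param records Data frame from [correlate_paired_features()].
#' @param cor_cut Absolute-correlation threshold in `(0, 1)`.
#' @param p_cut P-value threshold in `(0, 1)`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Filtered records (same columns).
#' @export
filter_significant <- function(records, cor_cut = 0.9, p_cut = 0.01,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (cor_cut <= 0 || cor_cut >= 1 || p_cut <= 0 || p_cut >= 1)
    stop("cuts must lie in (0, 1)")
  p <- if (adjust == "BH") stats::p.adjust(records$p, "BH") else records$p
  records[abs(records$r) > cor_cut & p < p_cut, , drop = FALSE]
}

#' Partition correlation records by regulatory sign
#'
#' Splits records into the negatively correlated set — for a
#' methylation-vs-expression comparison, the genes considered
#' methylation-regulated transcription genes — and the positively
#' correlated set.
#'
#' @param records (Typically significance-filtered) correlation
#'   records.
#' @return List with elements `negative` and `positive`, each a records
#'   data frame.
#' @export
classify_methylation_regulated <- function(records) {
  list(negative = records[records$sign_class == "negative", , drop = FALSE],
       positive = records[records$sign_class == "positive", , drop = FALSE])
}

#' Intersection of two gene id sets
#'
#' Deterministic (sorted) exact intersection, used e.g. to cross the
#' methylation-regulated transcription genes with the transcriptionally
#' regulated proteins.
#'
#' @param ids_a,ids_b Character vectors of feature ids.
#' @return Sorted character vector.
#' @export
triple_intersection <- function(ids_a, ids_b) {
  sort(intersect(ids_a, ids_b))
}

#' Write correlation records as TSV
#' @param records Records data frame.
#' @param path Output path.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
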