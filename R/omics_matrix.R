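#' Omics matrix container
#'
#' A feature x sample numeric matrix tagged with the omics layer it
#' carries. The methylation layer is constrained to rates in `[0, 1]`.
#' Feature and sample identifiers must be unique.
#'
#' @param values Numeric matrix with rownames (features) and colnames
#'   (samples).
#' @param layer One of `"mrna"`, `"lncrna"`, `"methylation"`,
#'   `"protein"`.
#' @return An object of class `OmicsMatrix`.
#' @export
omics_matrix <- function(values,
                         layer = c("mrna", "lncrna", "methylation", "protein")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (layer == "methylation") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("methylation values must lie in [0, 1]")
  }
  structure(list(values = values, layer = layer), class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d features x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' Extract the numeric matrix from an OmicsMatrix (or pass one through)
#' @param x An `OmicsMatrix` or a plain numeric matrix.
#' @return The underlying numeric matrix.
#' @export
omics_values <- function(x) {
  if (inherits(x, "OmicsMatrix")) x$values else as.matrix(x)
}

#' Feature and sample identifiers
#' @param x An `OmicsMatrix` or matrix.
#' @return Character vector of ids.
#' @export
features <- function(x) rownames(omics_values(x))

#' @rdname features
#' @export
samples <- function(x) colnames(omics_values(x))

#' Read / write an omics matrix as TSV
#'
#' The on-disk format is a tab-separated table whose first column holds
#' feature ids and whose header row holds sample ids. Reading is
#' gzip-transparent (via [base::connections]).
#'
#' @param path File path.
#' @param layer Layer tag for the returned object.
#' @return `read_omics_tsv()` returns an `OmicsMatrix`;
#'   `write_omics_tsv()` returns `path` invisibly.
#' @export
read_omics_tsv <- function(path, layer = "mrna") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  storage.mode(mat) <- "double"
  omics_matrix(mat, layer = layer)
}

#' @rdname read_omics_tsv
#' @param x An `OmicsMatrix` or matrix to write.
#' @export
write_omics_tsv <- function(x, path) {
  mat <- omics_values(x)
  df <- data.frame(feature = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Per-sample traits: `sample`, `age_group` ("young"/"old"), `passage`
#' (integer), and optionally `stemness` (numeric).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_phenotype_tsv
#' @param phenotype Data frame to write.
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  utils::write.table(phenotype, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Numeric encoding of phenotype traits
#'
#' Encodes age group as young = 0 / old = 1, keeps passage numeric, and
#' carries any numeric columns (e.g. stemness) through unchanged. The
#' encoding is recorded as an attribute for provenance.
#'
#' @param phenotype Phenotype data.frame with a `sample` column.
#' @return Numeric matrix, samples in rows, one column per trait.
#' @export
encode_traits <- function(phenotype) {
  stopifnot("sample" %in% names(phenotype))
  out <- list()
  if ("age_group" %in% names(phenotype)) {
    ag <- phenotype$age_group
    if (!all(ag %in% c("young", "old")))
      stop("age_group must be 'young' or 'old'")
    out$age <- ifelse(ag == "old", 1, 0)
  }
  for (col in setdiff(names(phenotype), c("sample", "age_group", "donor"))) {
    if (is.numeric(phenotype[[col]])) out[[col]] <- phenotype[[col]]
  }
  mat <- do.call(cbind, out)
  rownames(mat) <- phenotype$sample
  attr(mat, "encoding") <- c(age = "young=0, old=1")
  mat
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Empty sets are rejected, names must be unique.
#'
#' @param path GMT file path.
#' @param source Source tag attached to every set (`"GO_BP"`, `"KEGG"`,
#'   `"custom"`).
#' @return Named list of character vectors with attribute `source`
#'   (named character vector of per-set tags).
#' @export
read_gmt <- function(path, source = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) in GMT")
  attr(sets, "source") <- stats::setNames(rep(source, length(sets)), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network edge list
#'
#' Accepts 2/3-column TSV (`gene`, `gene`[, `score`]) or SIF
#' (`node` `interaction` `node`). Self-loops and duplicate undirected
#' edges are dropped so the result is a simple graph.
#'
#' @param path File path.
#' @param format `"tsv"` or `"sif"`.
#' @param min_score Optional confidence threshold; edges with score
#'   below it are dropped (TSV with a score column only).
#' @return Data frame with columns `from`, `to` and optionally `score`.
#' @export
read_network <- function(path, format = c("tsv", "sif"), min_score = NULL) {
  format <- match.arg(format)
  if (format == "sif") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    edges <- data.frame(from = df[[1]], to = df[[3]],
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    edges <- data.frame(from = df[[1]], to = df[[2]],
                        stringsAsFactors = FALSE)
    if (ncol(df) >= 3) edges$score <- as.numeric(df[[3]])
  }
  if (!is.null(min_score) && "score" %in% names(edges))
    edges <- edges[edges$score >= min_score, , drop = FALSE]
  simplify_edges(edges)
}

# canonicalize an undirected edge list: drop self-loops and duplicates,
# order endpoints lexicographically within each edge
simplify_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
  out <- edges[keep, , drop = FALSE]
  out$from <- a[keep]
  out$to <- b[keep]
  rownames(out) <- NULL
  out
}

#' @rdname read_network
#' @param edges Edge data frame (`from`, `to`[, `score`]).
#' @export
write_network_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TRRUST-style TF-target table
#'
#' Four tab-separated columns: TF, target gene, regulation mode
#' (`Activation` / `Repression` / `Unknown`), reference id. A header row
#' is optional and detected from the third column's values.
#'
#' @param path File path.
#' @return Data frame with columns `tf`, `target`, `mode`, `reference`.
#' @export
read_tf_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) > 0 &&
      !df[1, 3] %in% c("Activation", "Repression", "Unknown")) {
    df <- df[-1, , drop = FALSE]
  }
  if (ncol(df) < 4) stop("TF table needs 4 columns: tf, target, mode, reference")
  out <- data.frame(tf = df[[1]], target = df[[2]], mode = df[[3]],
                    reference = df[[4]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a stemness signature
#'
#' Two-column TSV: gene id, real-valued weight.
#'
#' @param path File path.
#' @return Named numeric vector of weights.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  w <- as.numeric(df[[2]])
  names(w) <- as.character(df[[1]])
  if (anyDuplicated(names(w))) stop("duplicate gene ids in signature")
  w
}

#' @rdname read_signature_tsv
#' @param signature Named numeric weight vector.
#' @export
write_signature_tsv <- function(signature, path) {
  utils::write.table(
    data.frame(gene = names(signature), weight = unname(signature)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
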