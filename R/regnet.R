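# cross-correlation of two feature x sample matrices over shared
# samples; returns long data.frame (regulator, target, r, p)
cross_correlate <- function(reg_mat, gene_mat) {
  shared <- intersect(colnames(reg_mat), colnames(gene_mat))
  if (length(shared) < 3L)
    stop("need at least 3 shared samples; found ", length(shared))
  a <- reg_mat[, shared, drop = FALSE]
  b <- gene_mat[, shared, drop = FALSE]
  n <- length(shared)
  r <- stats::cor(t(a), t(b))
  r[] <- pmin(1, pmax(-1, as.vector(r)))
  out <- data.frame(
    regulator = rep(rownames(a), times = ncol(r)),
    target = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), stringsAsFactors = FALSE)
  out$p <- cor_pvalue(out$r, n)
  out$n <- n
  out
}

#' Link lncRNAs to module genes by expression correlation
#'
#' Tests every candidate lncRNA against every gene of the selected
#' modules and keeps pairs passing `|r| > cor_cut` and `p < p_cut`
#' (both strict), the same rule as the cross-omics cascades.
#'
#' @param lncrna_expr `OmicsMatrix` or matrix of lncRNA expression.
#' @param module_gene_expr `OmicsMatrix` or matrix restricted to the
#'   genes of the modules under study (e.g. the most trait-correlated
#'   modules).
#' @param cor_cut,p_cut Strict thresholds (defaults 0.9 / 0.01).
#' @return Edge data frame: `regulator`, `target`, `r`, `p`, `n`,
#'   `regulator_type = "lncRNA"`.
#' @export
link_lncrna_to_modules <- function(lncrna_expr, module_gene_expr,
                                   cor_cut = 0.9, p_cut = 0.01) {
  edges <- cross_correlate(omics_values(lncrna_expr),
                           omics_values(module_gene_expr))
  edges <- edges[abs(edges$r) > cor_cut & edges$p < p_cut, , drop = FALSE]
  edges$regulator_type <- if (nrow(edges)) "lncRNA" else character(0)
  rownames(edges) <- NULL
  edges
}

#' Link transcription factors to module genes via curated pairs
#'
#' Only curated (TF, target) pairs — e.g. from a TRRUST-style table —
#' are correlation-tested (no all-vs-all screening). Pairs whose TF or
#' target is absent from the expression matrix are logged and skipped.
#' An edge survives when `|r| > cor_cut`, `p < p_cut` and the target
#' belongs to `module_genes`.
#'
#' @param tf_table Data frame with columns `tf`, `target` (see
#'   [read_tf_table()]).
#' @param expr `OmicsMatrix` or matrix holding both TFs and targets.
#' @param module_genes Character vector of genes in the selected
#'   modules.
#' @param cor_cut,p_cut Strict thresholds (defaults 0.9 / 0.01).
#' @return Edge data frame: `regulator`, `target`, `r`, `p`, `n`,
#'   `mode`, `regulator_type = "TF"`.
#' @export
link_tfs_to_modules <- function(tf_table, expr, module_genes,
                                cor_cut = 0.9, p_cut = 0.01) {
  empty <- data.frame(regulator = character(), target = character(),
                      r = numeric(), p = numeric(), n = integer(),
                      mode = character(), regulator_type = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tf_table) == 0L) return(empty)
  mat <- omics_values(expr)
  present <- tf_table$tf %in% rownames(mat) &
    tf_table$target %in% rownames(mat)
  if (any(!present))
    message(sum(!present), " curated pair(s) missing from expression matrix")
  tab <- tf_table[present & tf_table$target %in% module_genes, ,
                  drop = FALSE]
  if (nrow(tab) == 0L) return(empty)
  n <- ncol(mat)
  if (n < 3L) stop("need at least 3 samples")
  r <- vapply(seq_len(nrow(tab)), function(i)
    stats::cor(mat[tab$tf[i], ], mat[tab$target[i], ]), numeric(1))
  p <- cor_pvalue(r, n)
  keep <- abs(r) > cor_cut & p < p_cut
  out <- data.frame(regulator = tab$tf[keep], target = tab$target[keep],
                    r = r[keep], p = p[keep], n = n,
                    mode = if ("mode" %in% names(tab)) tab$mode[keep] else
                      rep("Unknown", sum(keep)),
                    regulator_type = rep("TF", sum(keep)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite regulatory network
#'
#' Combines regulator-to-gene edges with gene-to-pathway membership
#' edges taken from enrichment overlaps, then prunes regulators with no
#' surviving path to a pathway and any node left isolated. The result
#' is a tripartite graph: regulators (lncRNA/TF) -> module genes ->
#' pathways.
#'
#' @param edges Regulates edges from [link_lncrna_to_modules()] and/or
#'   [link_tfs_to_modules()] (rbind-compatible).
#' @param enrichment_rows Enrichment rows (see [enrich_modules()])
#'   computed on the same module genes.
#' @param selected_pathways Pathway (term) names to include; each must
#'   appear in `enrichment_rows`.
#' @return A `RegulatoryNetwork`: list with `graph` (igraph; vertex
#'   attribute `type` in lncRNA/TF/module_gene/pathway, edge attributes
#'   `type` = regulates/participates_in, `r`, `p`) and `counts`
#'   (regulators, genes, pathways, edges by type).
#' @export
attach_pathways <- function(edges, enrichment_rows, selected_pathways) {
  missing_pw <- setdiff(selected_pathways, enrichment_rows$term)
  if (length(missing_pw) > 0L)
    stop("selected pathway(s) absent from enrichment: ",
         paste(missing_pw, collapse = ", "))
  rows <- enrichment_rows[enrichment_rows$term %in% selected_pathways, ,
                          drop = FALSE]
  gene_pw <- unique(do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    genes <- strsplit(rows$overlap_genes[i], ",", fixed = TRUE)[[1L]]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) return(NULL)
    data.frame(gene = genes, pathway = rows$term[i],
               stringsAsFactors = FALSE)
  })))
  if (is.null(gene_pw))
    gene_pw <- data.frame(gene = character(), pathway = character())
  pw_genes <- unique(gene_pw$gene)
  # prune regulators whose targets never reach a pathway
  keep_edge <- edges$target %in% pw_genes
  reg_keep <- unique(edges$regulator[keep_edge])
  edges <- edges[edges$regulator %in% reg_keep & keep_edge, , drop = FALSE]
  gene_keep <- unique(edges$target)
  gene_pw <- gene_pw[gene_pw$gene %in% gene_keep, , drop = FALSE]
  pw_keep <- sort(unique(gene_pw$pathway))

  reg_type <- tapply(edges$regulator_type, edges$regulator, `[[`, 1L)
  verts <- rbind(
    data.frame(name = sort(unique(edges$regulator)),
               type = unname(reg_type[sort(unique(edges$regulator))]),
               stringsAsFactors = FALSE),
    data.frame(name = sort(gene_keep), type = "module_gene",
               stringsAsFactors = FALSE),
    data.frame(name = pw_keep, type = "pathway", stringsAsFactors = FALSE))
  # a regulator may itself be a module gene (a TF inside a module);
  # it keeps a single node with its regulator type taking precedence
  verts <- verts[!duplicated(verts$name), , drop = FALSE]
  e1 <- data.frame(from = edges$regulator, to = edges$target,
                   type = "regulates", r = edges$r, p = edges$p,
                   stringsAsFactors = FALSE)
  e1 <- e1[!duplicated(paste(e1$from, e1$to)), , drop = FALSE]
  e2 <- data.frame(from = gene_pw$gene, to = gene_pw$pathway,
                   type = "participates_in", r = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
  ed <- rbind(e1, e2)
  ed <- ed[order(ed$type, ed$from, ed$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
  counts <- list(
    n_regulators = sum(verts$type %in% c("lncRNA", "TF")),
    n_lncrna = sum(verts$type == "lncRNA"),
    n_tf = sum(verts$type == "TF"),
    n_genes = sum(verts$type == "module_gene"),
    n_pathways = sum(verts$type == "pathway"),
    n_regulates = nrow(e1),
    n_participates = nrow(e2))
  structure(list(graph = g, counts = counts), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "RegulatoryNetwork: %d regulators (%d lncRNA, %d TF) -> %d genes -> %d pathways; %d regulates + %d participates_in edges\n",
    n_regulators, n_lncrna, n_tf, n_genes, n_pathways, n_regulates,
    n_participates)))
  invisible(x)
}

#' Correlate per-sample pathway scores across omics layers
#'
#' Given pathway x sample score matrices for two or more layers (e.g.
#' GSVA-style scores on methylation, mRNA, lncRNA, protein profiles),
#' computes per pathway the Pearson correlation between the layer score
#' profiles with its t p-value, for every layer pair.
#'
#' @param score_matrices Named list of pathway x sample matrices.
#' @return Data frame: `pathway`, `layer_a`, `layer_b`, `r`, `p`, `n`.
#' @export
pathway_layer_correlation <- function(score_matrices) {
  if (length(score_matrices) < 2L) stop("need scores for at least 2 layers")
  layers <- names(score_matrices)
  out <- list()
  for (i in seq_len(length(layers) - 1L)) {
    for (j in seq(i + 1L, length(layers))) {
      a <- score_matrices[[i]]; b <- score_matrices[[j]]
      pws <- intersect(rownames(a), rownames(b))
      smp <- intersect(colnames(a), colnames(b))
      if (length(smp) < 3L)
        stop("fewer than 3 shared samples between layers ",
             layers[i], " and ", layers[j])
      for (pw in pws) {
        x <- a[pw, smp]; y <- b[pw, smp]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        r <- stats::cor(x, y)
        out[[length(out) + 1L]] <- data.frame(
          pathway = pw, layer_a = layers[i], layer_b = layers[j],
          r = r, p = cor_pvalue(r, length(smp)), n = length(smp),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(pathway = character(), layer_a = character(),
                      layer_b = character(), r = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a regulatory network
#'
#' Writes the network in a Cytoscape-compatible format with nodes and
#' edges in sorted order so identical networks give byte-identical
#' files. GraphML round-trips node/edge attributes; SIF and edge-TSV
#' carry the edge relation types.
#'
#' @param net `RegulatoryNetwork` (or bare igraph).
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  g <- if (inherits(net, "RegulatoryNetwork")) net$graph else net
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed) > 0L) ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  if (format == "sif") {
    rel <- if ("type" %in% names(ed) && nrow(ed) > 0L) ed$type else
      rep("interacts", nrow(ed))
    writeLines(c("#source\tinteraction\ttarget",
                 sprintf("%s\t%s\t%s", ed$from, rel, ed$to)), path)
  } else if (format == "tsv") {
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return igraph graph.
#' @export
import_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ed <- data.frame(from = vapply(parts, `[[`, "", 1L),
                     type = vapply(parts, `[[`, "", 2L),
                     to = vapply(parts, `[[`, "", 3L),
                     stringsAsFactors = FALSE)
    return(igraph::graph_from_data_frame(ed[, c("from", "to", "type")],
                                         directed = TRUE))
  }
  ed <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = TRUE)
}

#' JSON summary of a regulatory network
#' @param net `RegulatoryNetwork`.
#' @param path Output path.
#' @export
write_network_summary <- function(net, path) {
  jsonlite::write_json(net$counts, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
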