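#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` term
#' genes when `m` module genes are sampled without replacement from a
#' universe of `U` genes of which `K` belong to the term. The term is
#' restricted to the universe before testing.
#'
#' @param module_genes Character vector, must be a subset of
#'   `universe`.
#' @param term_genes Character vector (restricted to `universe`).
#' @param universe Character vector of all testable genes.
#' @param module Optional module name for the output row.
#' @param term Optional term name for the output row.
#' @return One-row data frame: `module`, `term`, `k` (overlap), `m`
#'   (module size), `K` (term size in universe), `U` (universe size),
#'   `p`, `overlap_genes` (comma-joined, sorted).
#' @export
ora_test <- function(module_genes, term_genes, universe,
                     module = "module", term = "term") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    stop("module genes must be a subset of the universe")
  term_genes <- intersect(unique(term_genes), universe)
  overlap <- sort(intersect(module_genes, term_genes))
  k <- length(overlap); m <- length(module_genes)
  K <- length(term_genes); U <- length(universe)
  p <- stats::phyper(k - 1L, K, U - K, m, lower.tail = FALSE)
  data.frame(module = module, term = term, k = k, m = m, K = K, U = U,
             p = p, overlap_genes = paste(overlap, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Over-representation of gene sets in every module
#'
#' Runs [ora_test()] for each non-grey module against each gene set,
#' with the universe equal to all features of the analysed expression
#' matrix, and keeps rows below the source-appropriate raw p cutoff
#' (GO: 0.01, KEGG: 0.05, custom: `p_cut_kegg`). Rows are sorted by
#' `(module, p)`.
#'
#' @param assignment `ModuleAssignment` or named label vector.
#' @param sets Named list of gene sets (see [read_gmt()]); an optional
#'   `source` attribute tags each set `GO_BP` / `KEGG` / `custom`.
#' @param universe Character vector of all analysed features.
#' @param p_cut_go,p_cut_kegg Raw p-value cutoffs per source.
#' @return Data frame of enrichment rows (possibly empty).
#' @export
enrich_modules <- function(assignment, sets, universe,
                           p_cut_go = 0.01, p_cut_kegg = 0.05) {
  labels <- if (inherits(assignment, "ModuleAssignment"))
    assignment$labels else assignment
  labels <- labels[names(labels) %in% universe]
  mods <- setdiff(sort(unique(labels)), "grey")
  src <- attr(sets, "source")
  if (is.null(src))
    src <- stats::setNames(rep("custom", length(sets)), names(sets))
  rows <- list()
  for (m in mods) {
    genes <- names(labels)[labels == m]
    for (s in names(sets)) {
      row <- ora_test(genes, sets[[s]], universe, module = m, term = s)
      row$source <- unname(src[s])
      cut <- if (identical(row$source, "GO_BP")) p_cut_go else p_cut_kegg
      if (row$k > 0L && row$p < cut) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(module = character(), term = character(),
                      k = integer(), m = integer(), K = integer(),
                      U = integer(), p = numeric(),
                      overlap_genes = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$module, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two gene memberships
#'
#' Chance-corrected agreement of two indicator vectors over a common
#' gene universe.
#'
#' @param members_a,members_b Character vectors of genes.
#' @param universe Character vector over which membership is compared.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_similarity <- function(members_a, members_b, universe) {
  ina <- universe %in% members_a
  inb <- universe %in% members_b
  n <- length(universe)
  a <- sum(ina & inb); b <- sum(ina & !inb)
  c_ <- sum(!ina & inb); d <- sum(!ina & !inb)
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Kappa similarity network over enriched terms
#'
#' Connects enriched terms whose overlapping-gene memberships agree
#' beyond `kappa_cut` (Cohen's kappa over the union of all enriched
#' genes), the construction ClueGO uses to group redundant terms.
#'
#' @param rows Enrichment rows from [enrich_modules()] (>= 2 rows).
#' @param kappa_cut Kappa threshold for an edge (default 0.4, the
#'   conventional ClueGO setting).
#' @return [igraph] graph; vertices carry `term`, `module`, `p`
#'   attributes, edges carry `kappa`.
#' @export
term_similarity_network <- function(rows, kappa_cut = 0.4) {
  if (nrow(rows) < 2L) stop("need at least 2 enrichment rows")
  memb <- strsplit(rows$overlap_genes, ",", fixed = TRUE)
  universe <- sort(unique(unlist(memb)))
  vid <- paste(rows$module, rows$term, sep = "|")
  edges <- list()
  for (i in seq_len(nrow(rows) - 1L)) {
    for (j in seq(i + 1L, nrow(rows))) {
      kp <- kappa_similarity(memb[[i]], memb[[j]], universe)
      if (kp > kappa_cut)
        edges[[length(edges) + 1L]] <- data.frame(
          from = vid[i], to = vid[j], kappa = kp,
          stringsAsFactors = FALSE)
    }
  }
  verts <- data.frame(name = vid, term = rows$term, module = rows$module,
                      p = rows$p, stringsAsFactors = FALSE)
  ed <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), kappa = numeric())
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

# single-sample rank-weighted enrichment walk; x = one sample's
# expression (named), set = gene ids; tau weights the rank statistic
ssgsea_walk <- function(x, in_set, tau) {
  n <- length(x)
  ord <- order(-x, names(x))          # descending, ties by feature id
  rank_stat <- (n:1)                   # top gene gets n
  inside <- in_set[ord]
  w <- rank_stat^tau
  p_in <- cumsum(ifelse(inside, w, 0)) / sum(w[inside])
  n_out <- n - sum(inside)
  p_out <- if (n_out == 0L) rep(0, n) else cumsum(!inside) / n_out
  dev <- p_in - p_out
  dev[which.max(abs(dev))]
}

#' Per-sample gene-set activity scores
#'
#' Single-sample rank-weighted enrichment in the ssGSEA family: per
#' sample, genes are ranked by decreasing expression (ties broken by
#' feature id); walking down the ranked list, in-set genes accumulate
#' weight `rank^tau` (normalised) and out-set genes a constant penalty;
#' the score is the maximum-deviation statistic of the walk. Scores are
#' rank-based, hence invariant under strictly monotone per-sample
#' transforms of expression.
#'
#' @param expr `OmicsMatrix` or matrix.
#' @param sets Named list of gene sets.
#' @param tau Rank-weight exponent (default 0.25).
#' @return set x sample numeric matrix; sets with fewer than 2 genes in
#'   the matrix are skipped with a warning.
#' @export
gene_set_score <- function(expr, sets, tau = 0.25) {
  mat <- omics_values(expr)
  usable <- vapply(sets, function(s)
    sum(rownames(mat) %in% s) >= 2L, logical(1))
  if (any(!usable))
    warning("skipping set(s) with < 2 matched genes: ",
            paste(names(sets)[!usable], collapse = ", "))
  sets <- sets[usable]
  if (length(sets) == 0L)
    return(matrix(numeric(), nrow = 0, ncol = ncol(mat),
                  dimnames = list(NULL, colnames(mat))))
  in_sets <- lapply(sets, function(s) rownames(mat) %in% s)
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(mat),
                dimnames = list(names(sets), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    x <- stats::setNames(mat[, j], rownames(mat))
    for (i in seq_along(sets)) {
      out[i, j] <- ssgsea_walk(x, in_sets[[i]], tau)
    }
  }
  out
}
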