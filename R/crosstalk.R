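#' Count interaction edges between module pairs
#'
#' For every unordered pair of distinct modules, the number of network
#' edges with one endpoint in each. Grey (unassigned) genes and edges
#' touching genes absent from the assignment are ignored (a message
#' reports how many).
#'
#' @param network Edge data frame (`from`, `to`[, `score`]), an
#'   undirected simple graph over gene ids.
#' @param assignment `ModuleAssignment` or named label vector.
#' @return Data frame with columns `module_a`, `module_b` (sorted so
#'   `module_a < module_b`) and `observed`, covering every module pair
#'   including zero counts.
#' @export
count_between_module_edges <- function(network, assignment) {
  labels <- if (inherits(assignment, "ModuleAssignment"))
    assignment$labels else assignment
  labels <- labels[labels != "grey"]
  mods <- sort(unique(labels))
  if (length(mods) < 2L)
    stop("assignment must cover at least 2 non-grey modules")
  pairs <- utils::combn(mods, 2L)
  out <- data.frame(module_a = pairs[1L, ], module_b = pairs[2L, ],
                    observed = 0L, stringsAsFactors = FALSE)
  if (nrow(network) == 0L) {
    warning("empty network; all between-module counts are 0")
    return(out)
  }
  la <- labels[network$from]
  lb <- labels[network$to]
  dropped <- is.na(la) | is.na(lb)
  if (any(dropped))
    message(sum(dropped), " edge(s) touching unassigned genes ignored")
  keep <- !dropped & la != lb
  if (any(keep)) {
    key <- paste(pmin(la[keep], lb[keep]), pmax(la[keep], lb[keep]),
                 sep = "\r")
    tab <- table(key)
    outkey <- paste(out$module_a, out$module_b, sep = "\r")
    hit <- match(outkey, names(tab))
    out$observed <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  out
}

#' Permutation test for module crosstalk
#'
#' Tests, for every module pair, whether the observed number of
#' between-module interaction edges exceeds what random module
#' assignments produce. The null permutes module labels across assigned
#' genes (module sizes preserved, network fixed); for each pair,
#' `n` counts permutations whose between-module edge count is strictly
#' greater than the observed one and `p = n / N`. A pair is significant
#' when `p < 0.05` (strict) and its observed count is positive; pairs
#' with an observed count of zero are flagged degenerate and never
#' called significant.
#'
#' @param network Edge data frame (`from`, `to`[, `score`]).
#' @param assignment `ModuleAssignment` or named label vector.
#' @param N Number of permutations (default 1000).
#' @param seed Integer seed for the permutation generator.
#' @param null `"label"` (default; module-label permutation) or
#'   `"rewire"` (degree-preserving edge rewiring via
#'   [igraph::keeping_degseq()]; much slower).
#' @param alpha Significance level (default 0.05, strict `<`).
#' @param min_score Optional edge-confidence threshold applied before
#'   testing.
#' @return Data frame with columns `module_a`, `module_b`, `observed`,
#'   `n`, `N`, `p`, `significant`, `degenerate`.
#' @export
crosstalk_test <- function(network, assignment, N = 1000L, seed = 1L,
                           null = c("label", "rewire"), alpha = 0.05,
                           min_score = NULL) {
  null <- match.arg(null)
  if (N < 1L) stop("'N' must be >= 1")
  labels <- if (inherits(assignment, "ModuleAssignment"))
    assignment$labels else assignment
  labels <- labels[labels != "grey"]
  mods <- sort(unique(labels))
  if (length(mods) < 2L) {
    return(data.frame(module_a = character(), module_b = character(),
                      observed = integer(), n = integer(), N = integer(),
                      p = numeric(), significant = logical(),
                      degenerate = logical(), stringsAsFactors = FALSE))
  }
  if (!is.null(min_score) && "score" %in% names(network))
    network <- network[network$score >= min_score, , drop = FALSE]

  obs <- count_between_module_edges(network, labels)
  K <- length(mods)
  pair_index <- function(la, lb) {
    ia <- match(la, mods); ib <- match(lb, mods)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    (lo - 1L) * K + hi
  }
  obs_key <- pair_index(obs$module_a, obs$module_b)
  obs_counts <- obs$observed

  genes <- names(labels)
  lab_int <- match(labels, mods)
  in_net <- network$from %in% genes & network$to %in% genes
  e1 <- match(network$from[in_net], genes)
  e2 <- match(network$to[in_net], genes)

  exceed <- integer(nrow(obs))
  set.seed(seed)
  if (null == "label") {
    for (b in seq_len(N)) {
      pl <- lab_int[sample.int(length(lab_int))]
      l1 <- pl[e1]; l2 <- pl[e2]
      keep <- l1 != l2
      key <- (pmin(l1[keep], l2[keep]) - 1L) * K + pmax(l1[keep], l2[keep])
      counts <- tabulate(key, nbins = K * K)
      exceed <- exceed + (counts[obs_key] > obs_counts)
    }
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = genes[e1], to = genes[e2]), directed = FALSE,
      vertices = genes)
    for (b in seq_len(N)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * length(e1)))
      ed <- igraph::as_data_frame(gr, what = "edges")
      l1 <- lab_int[match(ed$from, genes)]
      l2 <- lab_int[match(ed$to, genes)]
      keep <- l1 != l2
      key <- (pmin(l1[keep], l2[keep]) - 1L) * K + pmax(l1[keep], l2[keep])
      counts <- tabulate(key, nbins = K * K)
      exceed <- exceed + (counts[obs_key] > obs_counts)
    }
  }
  out <- obs
  out$n <- exceed
  out$N <- as.integer(N)
  out$p <- exceed / N
  out$degenerate <- out$observed == 0L
  out$significant <- out$p < alpha & !out$degenerate
  out
}

#' Export significant crosstalk pairs as SIF
#'
#' One line per significant module pair:
#' `module_a<TAB>crosstalk<TAB>module_b`, sorted for reproducibility.
#'
#' @param result Data frame from [crosstalk_test()].
#' @param path Output path.
#' @export
write_crosstalk_sif <- function(result, path) {
  sig <- result[result$significant, , drop = FALSE]
  sig <- sig[order(sig$module_a, sig$module_b), , drop = FALSE]
  lines <- sprintf("%s\tcrosstalk\t%s", sig$module_a, sig$module_b)
  writeLines(lines, path)
  invisible(path)
}
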