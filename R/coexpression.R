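#' Soft-thresholded co-expression adjacency
#'
#' Pearson correlations across samples raised to the soft-threshold
#' power: unsigned `|r|^power`, signed `((1 + r)/2)^power`.
#'
#' @param expr `OmicsMatrix` or feature x sample matrix, >= 3 samples.
#' @param power Soft-threshold exponent, >= 1.
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return Symmetric adjacency matrix with unit diagonal, entries in
#'   `[0, 1]`, dimnames = feature ids.
#' @export
adjacency_matrix <- function(expr, power, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  mat <- omics_values(expr)
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  if (power < 1) stop("'power' must be >= 1")
  sdv <- apply(mat, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance feature(s): ",
         paste(utils::head(rownames(mat)[sdv == 0], 5), collapse = ", "))
  }
  r <- stats::cor(t(mat))
  adj <- if (mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  adj[adj > 1] <- 1
  diag(adj) <- 1
  adj
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Connectivity `k_i = sum_{j != i} a_ij` is binned into 10 equal-width
#' bins; empty bins (and bins with nonpositive mean connectivity or
#' zero frequency) are dropped; the fit is the R-squared of the
#' regression of `log10(frequency)` on `log10(mean connectivity)`
#' over the remaining bins. The regression slope is attached as
#' attribute `"slope"` (scale-free networks give a negative slope).
#'
#' @param adjacency Symmetric adjacency matrix with unit diagonal.
#' @param nbins Number of equal-width connectivity bins.
#' @return R-squared in `[0, 1]` with attribute `slope`; degenerate
#'   inputs (constant connectivity, fewer than 2 usable bins) return 0
#'   with a warning.
#' @export
scale_free_fit <- function(adjacency, nbins = 10L) {
  k <- rowSums(adjacency) - diag(adjacency)
  if (diff(range(k)) == 0) {
    warning("all connectivities equal; scale-free fit undefined")
    return(structure(0, slope = NA_real_))
  }
  bins <- cut(k, breaks = nbins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  meank <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & meank > 0
  if (sum(ok) < 2L) {
    warning("fewer than 2 usable connectivity bins; scale-free fit undefined")
    return(structure(0, slope = NA_real_))
  }
  x <- log10(meank[ok])
  y <- log10(freq[ok])
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxx == 0 || syy == 0) {
    warning("degenerate binned connectivity; scale-free fit undefined")
    return(structure(0, slope = NA_real_))
  }
  structure(sxy^2 / (sxx * syy), slope = sxy / sxx)
}

#' Choose the soft-threshold power
#'
#' Scans candidate powers and returns the smallest one whose scale-free
#' topology fit reaches `r2_cut`; if none qualifies the power with the
#' best fit is returned and the scan is flagged.
#'
#' @param expr `OmicsMatrix` or matrix.
#' @param powers Candidate integer powers (default 1..30).
#' @param r2_cut Scale-free fit threshold (default 0.8).
#' @param mode Adjacency mode, see [adjacency_matrix()].
#' @return List with elements `power` (the choice), `scan` (data frame
#'   of `power`, `scale_free_r2`, `slope`, `mean_connectivity`) and
#'   `flagged` (`TRUE` when no power reached `r2_cut`).
#' @export
pick_soft_threshold <- function(expr, powers = 1:30, r2_cut = 0.8,
                                mode = c("unsigned", "signed")) {
  if (length(powers) == 0L) stop("'powers' must be nonempty")
  mode <- match.arg(mode)
  mat <- omics_values(expr)
  sdv <- apply(mat, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance feature(s): ",
         paste(utils::head(rownames(mat)[sdv == 0], 5), collapse = ", "))
  }
  r <- stats::cor(t(mat))
  base <- if (mode == "unsigned") abs(r) else (1 + r) / 2
  scan <- data.frame(power = powers, scale_free_r2 = NA_real_,
                     slope = NA_real_, mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    adj <- base^powers[i]
    diag(adj) <- 1
    fit <- suppressWarnings(scale_free_fit(adj))
    scan$scale_free_r2[i] <- as.numeric(fit)
    scan$slope[i] <- attr(fit, "slope")
    scan$mean_connectivity[i] <- mean(rowSums(adj) - 1)
  }
  choose_power_from_scan(scan, r2_cut)
}

#' Apply the power-selection rule to a completed scan
#'
#' Returns the smallest power whose scale-free fit reaches `r2_cut`;
#' when none qualifies, the power with the best fit is returned and the
#' result is flagged.
#'
#' @param scan Data frame with columns `power` and `scale_free_r2`.
#' @param r2_cut Fit threshold.
#' @return List with `power`, `scan`, `flagged`.
#' @export
choose_power_from_scan <- function(scan, r2_cut = 0.8) {
  qualifying <- which(scan$scale_free_r2 >= r2_cut)
  if (length(qualifying) > 0L) {
    list(power = scan$power[qualifying[1L]], scan = scan, flagged = FALSE)
  } else {
    list(power = scan$power[which.max(scan$scale_free_r2)], scan = scan,
         flagged = TRUE)
  }
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{j != i} a_ij`;
#' the diagonal is 1. High overlap means two genes share neighbours as
#' well as being directly connected; `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param adjacency Symmetric matrix, entries in `[0, 1]`, unit
#'   diagonal.
#' @return Symmetric TOM matrix with entries in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0) || any(a > 1 + 1e-12)) stop("adjacency entries must lie in [0, 1]")
  if (any(abs(diag(a) - 1) > 1e-12)) stop("adjacency diagonal must be 1")
  n <- nrow(a)
  k <- rowSums(a) - 1
  # sum over all u of a_iu a_uj includes u=i and u=j, each contributing a_ij
  L <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# fixed color palette for module naming, ordered by module size rank
module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
    "lightsteelblue1", "yellowgreen", "sienna3", "skyblue3", "plum1",
    "orangered4", "mediumpurple3")
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut statically at `cut_quantile` of the maximum merge
#' height. Clusters smaller than `min_module_size` are relabelled
#' `"grey"` (unassigned); the rest are named by size rank from a fixed
#' colour list.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_quantile Static cut height as a fraction of the maximum
#'   merge height (default 0.75; TOM dissimilarities saturate near 1,
#'   so cuts close to 1 absorb unrelated genes into clusters).
#' @return A `ModuleAssignment`: list with `labels` (named character
#'   vector, feature -> module), `eigengenes` (`NULL` until computed
#'   from expression), `dendrogram` (the `hclust` object).
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_quantile = 0.75) {
  ids <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    warning("fewer features than min_module_size; everything is grey")
    labels <- stats::setNames(rep("grey", nrow(tom)), ids)
    return(structure(list(labels = labels, eigengenes = NULL,
                          dendrogram = NULL),
                     class = "ModuleAssignment"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- cut_quantile * max(hc$height)
  raw <- stats::cutree(hc, h = cut_h)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  # name clusters by decreasing size; ties broken by cluster index
  big <- big[order(-sizes[big], as.integer(big))]
  palette <- module_colors()
  nm <- if (length(big) <= length(palette)) palette[seq_along(big)] else
    c(palette, paste0("module", seq_len(length(big) - length(palette))))
  lookup <- stats::setNames(nm[seq_along(big)], big)
  labels <- ifelse(as.character(raw) %in% big,
                   lookup[as.character(raw)], "grey")
  labels <- stats::setNames(unname(labels), ids)
  structure(list(labels = labels, eigengenes = NULL, dendrogram = hc),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("ModuleAssignment:", sum(names(tab) != "grey"), "modules,",
      sum(x$labels == "grey"), "unassigned (grey) of",
      length(x$labels), "features\n")
  print(tab)
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the standardized member submatrix,
#' scaled to unit variance. The sign is chosen so the eigengene
#' correlates nonnegatively with the mean standardized member profile,
#' making it a summary of the module's typical expression.
#'
#' @param expr `OmicsMatrix` or matrix containing the members.
#' @param member_ids Feature ids of the module members.
#' @return Named per-sample numeric vector with attribute
#'   `"var_explained"` (fraction of member variance captured).
#' @export
module_eigengene <- function(expr, member_ids) {
  mat <- omics_values(expr)
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  missing <- setdiff(member_ids, rownames(mat))
  if (length(missing) > 0L)
    stop("member id(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- mat[member_ids, , drop = FALSE]
  z <- standardize_rows(sub)
  sv <- svd(z)
  me <- sv$v[, 1L]
  mean_profile <- colMeans(z)
  s <- sum((me - mean(me)) * (mean_profile - mean(mean_profile)))
  if (s < 0) me <- -me
  me <- me / stats::sd(me)
  names(me) <- colnames(mat)
  attr(me, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  me
}

#' Eigengenes for every module of an assignment
#'
#' @param expr `OmicsMatrix` or matrix.
#' @param assignment `ModuleAssignment`.
#' @return sample x module matrix of eigengene profiles (grey
#'   excluded), and the assignment with its `eigengenes` slot filled if
#'   `update = TRUE`.
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- setdiff(sort(unique(assignment$labels)), "grey")
  if (length(mods) == 0L) return(NULL)
  mes <- vapply(mods, function(m) {
    module_eigengene(expr, names(assignment$labels)[assignment$labels == m])
  }, numeric(ncol(omics_values(expr))))
  colnames(mes) <- mods
  rownames(mes) <- colnames(omics_values(expr))
  mes
}

#' Merge modules with similar eigengenes
#'
#' Repeatedly merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor(ME_a, ME_b)` falls below `cut_height`,
#' recomputing eigengenes after each merge, until no pair qualifies.
#' The merged module keeps the larger module's name (ties: the
#' lexicographically smaller name). Grey is never merged.
#'
#' @param expr `OmicsMatrix` or matrix.
#' @param assignment `ModuleAssignment`.
#' @param cut_height Dissimilarity threshold (default 0.25,
#'   i.e. eigengene correlation > 0.75 merges).
#' @return Updated `ModuleAssignment` with `eigengenes` filled.
#' @export
merge_close_modules <- function(expr, assignment, cut_height = 0.25) {
  labels <- assignment$labels
  repeat {
    mods <- setdiff(sort(unique(labels)), "grey")
    if (length(mods) < 2L) break
    tmp <- assignment
    tmp$labels <- labels
    mes <- module_eigengenes(expr, tmp)
    d <- 1 - stats::cor(mes)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    if (d[idx[1L], idx[2L]] >= cut_height) break
    a <- mods[idx[1L]]; b <- mods[idx[2L]]
    na <- sum(labels == a); nb <- sum(labels == b)
    keep <- if (na > nb) a else if (nb > na) b else min(a, b)
    drop <- if (keep == a) b else a
    labels[labels == drop] <- keep
  }
  assignment$labels <- labels
  assignment$eigengenes <- module_eigengenes(expr, assignment)
  assignment
}

#' Module-trait correlation table
#'
#' Pearson correlation of each module eigengene with each numeric
#' trait, with the two-sided Student t p-value on `n - 2` degrees of
#' freedom. Raw p-values are reported (no multiplicity correction).
#'
#' @param eigengenes sample x module matrix (e.g. from
#'   [module_eigengenes()]).
#' @param traits sample x trait numeric matrix (e.g. from
#'   [encode_traits()]); rows are matched to the eigengene rows by
#'   name when both are named.
#' @return Data frame with columns `module`, `trait`, `r`, `p`,
#'   `flagged` (`TRUE` for constant traits, where `r` is undefined and
#'   `p = 1`).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits)) && !is.null(rownames(eigengenes)))
    traits <- traits[rownames(eigengenes), , drop = FALSE]
  n <- nrow(eigengenes)
  if (n < 3L) stop("need at least 3 samples")
  out <- expand.grid(module = colnames(eigengenes),
                     trait = colnames(traits),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_; out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    tv <- traits[, out$trait[i]]
    if (stats::sd(tv) == 0) {
      out$flagged[i] <- TRUE
      out$p[i] <- 1
      next
    }
    r <- stats::cor(eigengenes[, out$module[i]], tv)
    out$r[i] <- r
    out$p[i] <- cor_pvalue(r, n)
  }
  out
}
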