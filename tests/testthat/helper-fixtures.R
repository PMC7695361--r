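# shared fixtures, all built in code

test_cohort <- function(seed = 1L, n_samples = 12L, ...) {
  generate_cohort(cohort_config(n_samples = n_samples, seed = seed, ...))
}

# deterministic random feature x sample matrix with ids
rand_expr <- function(n_genes, n_samples, seed = 1L, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, sd = sd), nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# two-sided p-value for Pearson r by numeric integration of the t
# density (independent of pt-based implementation paths)
t_tail_oracle <- function(r, n) {
  df <- n - 2
  tstat <- abs(r) * sqrt(df / (1 - r^2))
  2 * stats::integrate(function(u) stats::dt(u, df = df),
                       lower = tstat, upper = Inf,
                       rel.tol = 1e-12)$value
}

# brute-force topological overlap via explicit O(n^3) loops
tom_bruteforce <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) L <- L + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      out[i, j] <- (L + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# random valid adjacency (symmetric, [0,1], unit diagonal)
rand_adjacency <- function(n, seed = 1L) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

# hypergeometric upper tail by exhaustive enumeration of all
# m-subsets of the universe (usable for universes up to ~12)
ora_enumeration_oracle <- function(U, K, m, k) {
  universe <- seq_len(U)
  term <- seq_len(K)
  draws <- utils::combn(U, m)
  hits <- apply(draws, 2, function(d) sum(d %in% term) >= k)
  mean(hits)
}

# explicit step-by-step rank-weighted enrichment walk for one sample
gss_walk_oracle <- function(x, set_genes, tau) {
  n <- length(x)
  ord <- names(x)[order(-x, names(x))]
  inside <- ord %in% set_genes
  rstat <- n:1
  w_in <- sum((rstat^tau)[inside])
  p_in <- 0; p_out <- 0; best <- 0
  n_out <- n - sum(inside)
  for (i in seq_len(n)) {
    if (inside[i]) p_in <- p_in + rstat[i]^tau / w_in
    else p_out <- p_out + 1 / n_out
    if (abs(p_in - p_out) > abs(best)) best <- p_in - p_out
  }
  best
}
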