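test_that("adjacency reproduces closed forms and the direct formula", {
  x <- rand_expr(8, 6, seed = 1)
  x <- rbind(x, dup = x[1, ])
  expect_equal(adjacency_matrix(x, power = 4)["g001", "dup"], 1)

  a1 <- adjacency_matrix(x, power = 1)
  expect_equal(a1, abs(cor(t(x))), tolerance = 1e-12)

  # beta = 6 against an elementwise oracle computed pair by pair
  a6 <- adjacency_matrix(x[1:8, ], power = 6)
  for (i in 1:7) for (j in (i + 1):8) {
    xi <- x[i, ]; xj <- x[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(a6[i, j], abs(r)^6, tolerance = 1e-12)
  }
  expect_true(isSymmetric(a6))
  expect_equal(unname(diag(a6)), rep(1, 8))
})

test_that("raising the power never increases off-diagonal adjacency", {
  x <- rand_expr(12, 8, seed = 7)
  prev <- adjacency_matrix(x, power = 1)
  for (pw in c(2, 4, 8, 16)) {
    cur <- adjacency_matrix(x, power = pw)
    off <- upper.tri(cur)
    expect_true(all(cur[off] <= prev[off] + 1e-15))
    prev <- cur
  }
})

test_that("adjacency rejects zero-variance features by name", {
  x <- rand_expr(4, 5, seed = 2)
  x["g002", ] <- 3
  expect_error(adjacency_matrix(x, 6), "g002")
})

test_that("scale-free fit is exact on a constructed power-law graph", {
  # blocks of identical-connectivity nodes with frequency = 60 / k,
  # so binned log10(freq) is exactly linear in log10(k) with slope -1
  ks <- 1:5
  sizes <- 60 / ks
  blocks <- lapply(seq_along(ks), function(b) {
    n <- sizes[b]
    w <- ks[b] / (n - 1)
    a <- matrix(w, n, n)
    diag(a) <- 1
    a
  })
  n_tot <- sum(sizes)
  adj <- matrix(0, n_tot, n_tot)
  at <- 0
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    adj[idx, idx] <- b
    at <- at + nrow(b)
  }
  fit <- scale_free_fit(adj)
  expect_equal(as.numeric(fit), 1, tolerance = 1e-10)
  expect_equal(attr(fit, "slope"), -1, tolerance = 1e-10)
})

test_that("scale-free fit degenerates to zero with a warning", {
  a <- matrix(0.4, 6, 6); diag(a) <- 1
  expect_warning(fit <- scale_free_fit(a), "equal")
  expect_equal(as.numeric(fit), 0)
})

test_that("scale-free fit matches explicit normal equations on random graphs", {
  for (seed in 1:5) {
    a <- rand_adjacency(30, seed = seed)
    fit <- suppressWarnings(scale_free_fit(a))
    k <- rowSums(a) - 1
    bins <- cut(k, breaks = 10, include.lowest = TRUE)
    freq <- tapply(k, bins, length)
    meank <- tapply(k, bins, mean)
    ok <- !is.na(freq) & freq > 0 & meank > 0
    x <- log10(meank[ok]); y <- log10(freq[ok])
    # least squares via explicit normal equations
    sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
    beta <- sxy / sxx
    resid <- y - mean(y) - beta * (x - mean(x))
    r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
    expect_equal(as.numeric(fit), r2, tolerance = 1e-10)
  }
})

test_that("power selection takes the smallest qualifying power", {
  scan <- data.frame(power = 1:3, scale_free_r2 = c(0.5, 0.81, 0.9))
  sel <- choose_power_from_scan(scan, 0.8)
  expect_equal(sel$power, 2)
  expect_false(sel$flagged)
})

test_that("power selection falls back to the best fit when none qualifies", {
  scan <- data.frame(power = 1:4, scale_free_r2 = c(0.1, 0.6, 0.75, 0.4))
  sel <- choose_power_from_scan(scan, 0.8)
  expect_equal(sel$power, 3)
  expect_true(sel$flagged)
})

test_that("pick_soft_threshold agrees with an exhaustive independent scan", {
  co <- test_cohort(seed = 4)
  expr <- variance_filter(co$mrna, 0.3)
  powers <- 1:10
  pick <- pick_soft_threshold(expr, powers = powers)
  r2s <- vapply(powers, function(pw) {
    as.numeric(suppressWarnings(
      scale_free_fit(adjacency_matrix(expr, pw))))
  }, numeric(1))
  qual <- which(r2s >= 0.8)
  oracle <- if (length(qual)) powers[qual[1]] else powers[which.max(r2s)]
  expect_equal(pick$power, oracle)
  expect_equal(pick$scan$scale_free_r2, r2s, tolerance = 1e-12)
})

test_that("topological overlap matches closed forms", {
  ones <- matrix(1, 3, 3)
  expect_equal(topological_overlap(ones)[1, 2], 1)

  # two genes with no shared neighbours and no direct link overlap 0
  a <- diag(4)
  a[1, 3] <- a[3, 1] <- 0.5
  a[2, 4] <- a[4, 2] <- 0.5
  expect_equal(topological_overlap(a)[1, 2], 0)
})

test_that("topological overlap equals O(n^3) brute force", {
  for (seed in 1:3) {
    a <- rand_adjacency(10, seed = seed)
    expect_equal(topological_overlap(a), tom_bruteforce(a),
                 tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(c(1, .2, .3, 1), 2, 2)),
               "symmetric")
})

test_that("block-diagonal TOM yields exactly the planted blocks", {
  a <- matrix(0, 100, 100)
  a[1:50, 1:50] <- 1
  a[51:100, 51:100] <- 1
  dimnames(a) <- list(paste0("g", 1:100), paste0("g", 1:100))
  asn <- detect_modules(topological_overlap(a), min_module_size = 30)
  expect_equal(length(setdiff(unique(asn$labels), "grey")), 2)
  expect_equal(sum(asn$labels == "grey"), 0)
  expect_equal(length(unique(asn$labels[1:50])), 1)
  expect_equal(length(unique(asn$labels[51:100])), 1)
})

test_that("too-few features leaves everything grey with a warning", {
  a <- rand_adjacency(20, seed = 1)
  expect_warning(asn <- detect_modules(topological_overlap(a),
                                       min_module_size = 30), "grey")
  expect_true(all(asn$labels == "grey"))
})

test_that("module eigengene is the standardized profile for rank-1 modules", {
  set.seed(9)
  v <- rnorm(8)
  x <- outer(runif(20, 0.5, 2), v) + matrix(rnorm(160, sd = 0), nrow = 20)
  dimnames(x) <- list(paste0("g", 1:20), paste0("s", 1:8))
  me <- module_eigengene(x, rownames(x))
  expect_equal(sd(me), 1)
  expect_equal(abs(cor(me, v)), 1, tolerance = 1e-10)
  expect_gt(cor(me, v), 0)  # sign follows the (positive-loading) mean
  expect_equal(attr(me, "var_explained"), 1, tolerance = 1e-10)
})

test_that("eigengene explained variance matches an independent SVD", {
  x <- rand_expr(30, 8, seed = 11)
  me <- module_eigengene(x, rownames(x))
  z <- t(scale(t(x)))
  d <- svd(z)$d
  expect_equal(attr(me, "var_explained"), d[1]^2 / sum(d^2),
               tolerance = 1e-10)
  # no member's standardized profile explains more variance
  best_member <- max(vapply(seq_len(nrow(z)), function(i) {
    proj <- as.numeric(z %*% z[i, ]) / sqrt(sum(z[i, ]^2))
    sum(proj^2) / sum(z^2)
  }, numeric(1)))
  expect_gte(attr(me, "var_explained") + 1e-12, best_member)
  expect_error(module_eigengene(x, c("g001", "nope")), "nope")
})

test_that("modules with identical eigengenes merge; orthogonal ones do not", {
  set.seed(13)
  f1 <- rnorm(10)
  f2 <- resid(lm(rnorm(10) ~ f1))  # orthogonal to f1
  mk <- function(f, n, prefix) {
    x <- outer(runif(n, 0.8, 1.2), f)
    rownames(x) <- paste0(prefix, seq_len(n))
    x
  }
  x <- rbind(mk(f1, 40, "a"), mk(f1, 35, "b"), mk(f2, 30, "c"))
  colnames(x) <- paste0("s", 1:10)
  labels <- setNames(rep(c("alpha", "beta", "gamma"), c(40, 35, 30)),
                     rownames(x))
  asn <- structure(list(labels = labels, eigengenes = NULL,
                        dendrogram = NULL), class = "ModuleAssignment")
  merged <- merge_close_modules(x, asn, cut_height = 0.25)
  mods <- setdiff(unique(merged$labels), "grey")
  expect_equal(length(mods), 2)
  # identical-factor modules collapsed into the larger one's name
  expect_true(all(merged$labels[1:75] == "alpha"))
  expect_true(all(merged$labels[76:105] == "gamma"))
  # after convergence no remaining pair is below the cut
  d <- 1 - cor(merged$eigengenes)
  expect_true(all(d[upper.tri(d)] >= 0.25))
})

test_that("chain merging reaches the exhaustive fixed point", {
  set.seed(17)
  base <- rnorm(12)
  mk <- function(f, n, prefix) {
    x <- outer(runif(n, 0.9, 1.1), f)
    rownames(x) <- paste0(prefix, seq_len(n))
    x
  }
  fA <- base
  fB <- 0.95 * base + sqrt(1 - 0.95^2) * resid(lm(rnorm(12) ~ base))
  fC <- 0.95 * fB + 0.1 * resid(lm(rnorm(12) ~ base + fB))
  x <- rbind(mk(fA, 40, "a"), mk(fB, 35, "b"), mk(fC, 30, "c"))
  colnames(x) <- paste0("s", 1:12)
  labels <- setNames(rep(c("A", "B", "C"), c(40, 35, 30)), rownames(x))
  asn <- structure(list(labels = labels, eigengenes = NULL,
                        dendrogram = NULL), class = "ModuleAssignment")
  merged <- merge_close_modules(x, asn, cut_height = 0.25)
  # all three factors are mutually ~0.9 correlated: single fixed point
  expect_equal(length(setdiff(unique(merged$labels), "grey")), 1)
})

test_that("module-trait correlations carry exact t p-values", {
  set.seed(19)
  trait <- c(1, 2, 3, 4, 5, 6)
  orth <- resid(lm(rnorm(6) ~ trait))
  eig <- cbind(self = scale(trait)[, 1], orth = scale(orth)[, 1])
  rownames(eig) <- paste0("s", 1:6)
  traits <- cbind(t1 = trait, const = rep(2, 6))
  rownames(traits) <- rownames(eig)
  mt <- module_trait_correlation(eig, traits)

  self_row <- mt[mt$module == "self" & mt$trait == "t1", ]
  expect_equal(self_row$r, 1, tolerance = 1e-12)
  expect_lt(self_row$p, 1e-12)

  orth_row <- mt[mt$module == "orth" & mt$trait == "t1", ]
  expect_equal(orth_row$r, 0, tolerance = 1e-12)
  expect_equal(orth_row$p, 1, tolerance = 1e-12)

  const_rows <- mt[mt$trait == "const", ]
  expect_true(all(const_rows$flagged))
  expect_true(all(const_rows$p == 1))
})

test_that("the t p-value at r = 0.9, n = 6 matches numeric integration", {
  expect_equal(cor_pvalue(0.9, 6), t_tail_oracle(0.9, 6),
               tolerance = 1e-10)
  expect_equal(cor_pvalue(-0.55, 8), t_tail_oracle(-0.55, 8),
               tolerance = 1e-10)
})
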