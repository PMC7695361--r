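test_that("the same seed reproduces the cohort bit for bit", {
  a <- test_cohort(seed = 5)
  b <- test_cohort(seed = 5)
  expect_identical(a, b)
  c <- test_cohort(seed = 6)
  expect_false(identical(a$mrna$values, c$mrna$values))
})

test_that("noiseless module genes are perfectly correlated within modules", {
  co <- test_cohort(seed = 2, noise_sd = 0)
  lab <- co$truth$modules
  for (m in paste0("M", 1:4)) {
    x <- co$mrna$values[names(lab)[lab == m][1:10], ]
    r <- cor(t(x))
    expect_equal(unname(r[upper.tri(r)]), rep(1, sum(upper.tri(r))),
                 tolerance = 1e-10)
  }
})

test_that("planted methylation pairs survive the correlation filter", {
  co <- test_cohort(seed = 3, n_samples = 6)
  planted <- co$truth$planted_pairs$methylation_mrna$feature
  expect_length(planted, 50)
  r <- vapply(planted, function(g)
    cor(co$methylation$values[g, ], co$mrna$values[g, ]), numeric(1))
  expect_true(all(r < 0))
  expect_gte(mean(abs(r) > 0.917), 0.8)
})

test_that("planted protein pairs are positively correlated with their mRNA", {
  co <- test_cohort(seed = 3)
  planted <- co$truth$planted_pairs$mrna_protein$feature
  r <- vapply(planted, function(g)
    cor(co$protein$values[g, ], co$mrna$values[g, ]), numeric(1))
  expect_true(all(r > 0.9))
})

test_that("methylation stays within [0, 1] and stemness tracks design", {
  for (seed in 1:3) {
    co <- test_cohort(seed = seed)
    expect_true(all(co$methylation$values >= 0 &
                      co$methylation$values <= 1))
    ph <- co$phenotype
    # stemness decreases with passage within each donor group
    for (g in c("young", "old")) {
      sub <- ph[ph$age_group == g, ]
      expect_lt(cor(sub$passage, sub$stemness), 0)
    }
    expect_lt(mean(ph$stemness[ph$age_group == "old"]),
              mean(ph$stemness[ph$age_group == "young"]))
  }
})

test_that("within-module correlation exceeds between-module correlation", {
  co <- test_cohort(seed = 8)
  lab <- co$truth$modules
  r <- cor(t(co$mrna$values[lab != "grey", ]))
  l <- lab[lab != "grey"]
  same <- outer(l, l, "==") & upper.tri(r)
  diff <- !outer(l, l, "==") & upper.tri(r)
  expect_gt(mean(abs(r[same])), mean(abs(r[diff])))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_samples = 2), "n_samples")
  expect_error(cohort_config(module_sizes = c(400L, 300L),
                             module_traits = c("age", "none"),
                             trait_coupling = c(0.9, 0)),
               "module_sizes")
  expect_error(cohort_config(planted_r = 0.8), "planted_r")
})

test_that("background network hits its expected edge count and is simple", {
  co <- test_cohort(seed = 1, n_genes = 100L,
                    module_sizes = c(30L, 30L),
                    module_traits = c("age", "passage"),
                    trait_coupling = c(0.9, 0.9),
                    coupling_pairs = 10L, lnc_coupling_pairs = 5L,
                    n_methylated = 50L, n_proteins = 30L,
                    n_lncrnas = 30L, n_tfs = 2L,
                    n_signature_genes = 10L,
                    n_lncrna_regulators = 2L)
  genes <- names(co$truth$modules)
  edges <- generate_background_network(genes, mean_degree = 1,
                                       truth = co$truth, seed = 2)
  # 4950 pairs at p = 1/99: expectation 50, sd ~ 7
  expect_gt(nrow(edges), 22)
  expect_lt(nrow(edges), 78)
  expect_true(all(edges$from != edges$to))
  expect_false(any(duplicated(paste(edges$from, edges$to))))
  expect_identical(edges,
                   generate_background_network(genes, 1, truth = co$truth,
                                               seed = 2))
  expect_error(generate_background_network(c(genes, "XX"), 1,
                                           truth = co$truth, seed = 1),
               "unknown")
})

test_that("enrichment multiplies the planted pair's edge probability", {
  co <- test_cohort(seed = 4)
  genes <- names(co$truth$modules)
  lab <- co$truth$modules
  between <- function(edges) {
    sum((lab[edges$from] == "M1" & lab[edges$to] == "M2") |
          (lab[edges$from] == "M2" & lab[edges$to] == "M1"))
  }
  flat <- generate_background_network(genes, 8, 1, co$truth, seed = 5)
  rich <- generate_background_network(genes, 8, 3, co$truth, seed = 5)
  expect_gt(between(rich), 2 * between(flat))
})

test_that("regulator tables honour their contracts", {
  co <- test_cohort(seed = 6)
  truth <- co$truth

  empty <- generate_regulator_tables(truth, n_tfs = 0L,
                                     n_lncrna_regulators = 0L, seed = 1)
  expect_equal(nrow(empty$tf_table), 0)
  expect_length(empty$lncrna_ids, 0)

  expect_error(generate_regulator_tables(truth, n_tfs = 1L,
                                         targets_per_regulator = 1000L,
                                         seed = 1),
               "targets_per_regulator")

  # planted TF rows live inside the TF's own module
  tab <- truth$tf_table
  expect_true(all(truth$modules[tab$tf] == truth$modules[tab$target]))
  expect_true(all(tab$mode %in% c("Activation", "Repression", "Unknown")))
})

test_that("a noiseless cohort gives TF-target correlations of one", {
  co <- test_cohort(seed = 7, noise_sd = 0)
  tab <- co$truth$tf_table
  r <- vapply(seq_len(nrow(tab)), function(i)
    cor(co$mrna$values[tab$tf[i], ], co$mrna$values[tab$target[i], ]),
    numeric(1))
  expect_equal(abs(r), rep(1, nrow(tab)), tolerance = 1e-10)
})

test_that("written cohorts round-trip through the pipeline readers", {
  co <- test_cohort(seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_omics_tsv(file.path(dir, "mrna.tsv"), "mrna")
  expect_equal(back$values, co$mrna$values, tolerance = 1e-12)
  ph <- read_phenotype_tsv(file.path(dir, "phenotype.tsv"))
  expect_equal(ph$sample, co$phenotype$sample)
  sig <- read_signature_tsv(file.path(dir, "signature.tsv"))
  expect_equal(sig, co$signature, tolerance = 1e-12)
  tf <- read_tf_table(file.path(dir, "tf_targets.tsv"))
  expect_equal(tf$tf, co$truth$tf_table$tf)
})
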