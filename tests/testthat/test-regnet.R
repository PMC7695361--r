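test_that("an lncRNA identical to a module gene links with r = 1", {
  genes <- rand_expr(5, 8, seed = 1)
  lnc <- genes[1, , drop = FALSE]
  rownames(lnc) <- "lnc1"
  edges <- link_lncrna_to_modules(lnc, genes)
  hit <- edges[edges$regulator == "lnc1" & edges$target == "g001", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$r, 1)
  expect_equal(hit$regulator_type, "lncRNA")
})

test_that("planted lncRNA regulators are recovered with high sensitivity", {
  co <- test_cohort(seed = 5)
  regs <- co$truth$regulators
  lnc_regs <- regs[regs$type == "lncRNA", ]
  mod_genes <- names(co$truth$modules)[co$truth$modules %in%
                                         unique(lnc_regs$module)]
  edges <- link_lncrna_to_modules(
    co$lncrna$values[lnc_regs$regulator, , drop = FALSE],
    co$mrna$values[mod_genes, , drop = FALSE])
  # a regulator counts as recovered when linked to its own module
  recovered <- vapply(seq_len(nrow(lnc_regs)), function(i) {
    targets <- edges$target[edges$regulator == lnc_regs$regulator[i]]
    any(co$truth$modules[targets] == lnc_regs$module[i])
  }, logical(1))
  expect_gte(mean(recovered), 0.8)
})

test_that("TF linkage tests only curated pairs and applies both cuts", {
  set.seed(51)
  f <- rnorm(8)
  x <- rbind(tf1 = f + rnorm(8, sd = 0.01),
             hit = f + rnorm(8, sd = 0.01),
             miss = rnorm(8),
             offmod = f)
  colnames(x) <- paste0("s", 1:8)
  tab <- data.frame(tf = c("tf1", "tf1", "tf1", "ghost"),
                    target = c("hit", "miss", "offmod", "hit"),
                    mode = "Activation", reference = "r1")
  edges <- suppressMessages(
    link_tfs_to_modules(tab, x, module_genes = c("hit", "miss")))
  expect_equal(edges$target, "hit")      # miss fails cuts, offmod not in module
  expect_equal(edges$regulator, "tf1")   # ghost logged as missing
  expect_true(abs(edges$r) > 0.9 & edges$p < 0.01)

  empty <- link_tfs_to_modules(tab[0, ], x, module_genes = "hit")
  expect_equal(nrow(empty), 0)
})

test_that("a minimal chain becomes a 3-node, 2-edge tripartite graph", {
  edges <- data.frame(regulator = "lnc1", target = "geneA", r = 0.95,
                      p = 1e-4, regulator_type = "lncRNA")
  enr <- data.frame(module = "blue", term = "pathway1", k = 1, m = 10,
                    K = 5, U = 100, p = 0.001, overlap_genes = "geneA",
                    source = "KEGG")
  net <- attach_pathways(edges, enr, "pathway1")
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_equal(net$counts$n_regulators, 1)
  expect_equal(net$counts$n_pathways, 1)
  expect_error(attach_pathways(edges, enr, "missing_pathway"), "missing")
})

test_that("regulators with no path to a pathway are pruned", {
  edges <- data.frame(
    regulator = c("lnc1", "lnc2"), target = c("geneA", "geneB"),
    r = c(0.95, 0.93), p = c(1e-4, 1e-4), regulator_type = "lncRNA")
  enr <- data.frame(module = "blue", term = "pw", k = 1, m = 10, K = 5,
                    U = 100, p = 0.001, overlap_genes = "geneA",
                    source = "KEGG")
  net <- attach_pathways(edges, enr, "pw")
  expect_false("lnc2" %in% igraph::V(net$graph)$name)
  expect_false("geneB" %in% igraph::V(net$graph)$name)
  # tripartite constraint: regulates edges go regulator -> gene,
  # participates edges gene -> pathway
  ed <- igraph::as_data_frame(net$graph)
  types <- setNames(igraph::V(net$graph)$type, igraph::V(net$graph)$name)
  reg <- ed[ed$type == "regulates", ]
  expect_true(all(types[reg$from] %in% c("lncRNA", "TF")))
  expect_true(all(types[reg$to] == "module_gene"))
  par <- ed[ed$type == "participates_in", ]
  expect_true(all(types[par$from] == "module_gene"))
  expect_true(all(types[par$to] == "pathway"))
})

test_that("network exports round-trip and are deterministic", {
  edges <- data.frame(
    regulator = c("lnc1", "tf1"), target = c("geneA", "geneA"),
    r = c(0.95, -0.92), p = c(1e-4, 2e-4),
    regulator_type = c("lncRNA", "TF"))
  enr <- data.frame(module = "blue", term = "pw", k = 1, m = 10, K = 5,
                    U = 100, p = 0.001, overlap_genes = "geneA",
                    source = "KEGG")
  net <- attach_pathways(edges, enr, "pw")

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), 1 + 3)  # header + 2 regulates + 1 participates
  back <- import_network(sif, "sif")
  expect_equal(igraph::vcount(back), igraph::vcount(net$graph))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  rt <- import_network(gml, "graphml")
  expect_setequal(igraph::V(rt)$name, igraph::V(net$graph)$name)
  expect_setequal(igraph::V(rt)$type, igraph::V(net$graph)$type)
  expect_equal(igraph::ecount(rt), igraph::ecount(net$graph))
  ed1 <- igraph::as_data_frame(rt); ed2 <- igraph::as_data_frame(net$graph)
  expect_equal(ed1[order(ed1$from, ed1$to), c("from", "to", "type")],
               ed2[order(ed2$from, ed2$to), c("from", "to", "type")],
               ignore_attr = TRUE)

  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml2, "graphml")
  expect_identical(readLines(gml), readLines(gml2))
  expect_error(export_network(net, sif, "dot"), "arg")

  # empty network still writes a valid header-only SIF
  emptyg <- igraph::make_empty_graph()
  sif0 <- withr::local_tempfile(fileext = ".sif")
  export_network(emptyg, sif0, "sif")
  expect_equal(readLines(sif0), "#source\tinteraction\ttarget")
})

test_that("pathway scores correlate across layers as the oracle says", {
  sc <- matrix(rnorm(12), 3, 4,
               dimnames = list(paste0("pw", 1:3), paste0("s", 1:4)))
  same <- pathway_layer_correlation(list(mrna = sc, protein = sc))
  expect_equal(same$r, rep(1, 3), tolerance = 1e-12)

  other <- matrix(rnorm(12), 3, 4, dimnames = dimnames(sc))
  res <- pathway_layer_correlation(list(mrna = sc, protein = other))
  for (i in seq_len(nrow(res))) {
    x <- sc[res$pathway[i], ]; y <- other[res$pathway[i], ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r[i], r, tolerance = 1e-12)
    expect_equal(res$p[i], t_tail_oracle(r, 4), tolerance = 1e-9)
  }
  expect_error(pathway_layer_correlation(list(a = sc)), "2 layers")
  expect_error(pathway_layer_correlation(list(a = sc[, 1:2],
                                              b = sc[, 1:2])),
               "shared samples")
})
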