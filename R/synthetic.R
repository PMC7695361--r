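#' Configuration for a synthetic multi-omics cohort
#'
#' Describes a passage-series stem-cell cohort: two donor age groups
#' sampled at increasing culture passages, with planted co-expression
#' modules coupled to the age / passage / stemness traits, planted
#' methylation-expression anticorrelated gene pairs, planted
#' mRNA-protein correlated pairs, a planted stemness signature, and
#' planted lncRNA/TF regulators of the modules. The seed fully
#' determines the generated cohort.
#'
#' @param n_samples Number of samples (>= 3); laid out as two donor
#'   groups x passages 3/6/10 (replicated when more than 6).
#' @param n_genes,n_lncrnas,n_proteins,n_methylated Feature counts per
#'   layer.
#' @param module_sizes Integer vector of planted module sizes (their
#'   sum must not exceed `n_genes`).
#' @param module_traits Trait coupled to each module: `"age"`,
#'   `"passage"`, `"stemness"` or `"none"`.
#' @param trait_coupling Per-module target correlation between the
#'   module's latent factor and its trait, in `[-1, 1]`.
#' @param coupling_pairs Number of planted methylation<->mRNA
#'   anticorrelated genes and of planted mRNA<->protein correlated
#'   genes.
#' @param lnc_coupling_pairs Planted methylation<->lncRNA
#'   anticorrelated pairs.
#' @param n_triple Genes planted in both cascades (methylation-mRNA
#'   and mRNA-protein), the expected triple-intersection hits.
#' @param planted_r Target |correlation| for planted pairs, in
#'   `(0.9, 1]` so planted pairs can survive the `|cor| > 0.9` filter.
#' @param noise_sd Expression noise standard deviation around the
#'   module factors (the factors themselves have unit variance).
#' @param n_signature_genes Genes carrying the planted stemness
#'   signature.
#' @param n_tfs,n_lncrna_regulators,targets_per_regulator Planted
#'   regulator counts for the regulatory-network stage.
#' @param crosstalk_pairs List of length-2 integer vectors naming
#'   module index pairs designated as crosstalking (used by
#'   [generate_background_network()]).
#' @param seed Integer seed.
#' @return A `CohortConfig` list (validated).
#' @export
cohort_config <- function(n_samples = 6L,
                          n_genes = 600L,
                          n_lncrnas = 100L,
                          n_proteins = 150L,
                          n_methylated = 200L,
                          module_sizes = c(100L, 80L, 60L, 50L),
                          module_traits = c("age", "passage", "stemness",
                                            "none"),
                          trait_coupling = c(0.9, 0.9, 1, 0),
                          coupling_pairs = 50L,
                          lnc_coupling_pairs = 10L,
                          n_triple = 1L,
                          planted_r = 0.98,
                          noise_sd = 0.3,
                          n_signature_genes = 100L,
                          n_tfs = 8L,
                          n_lncrna_regulators = 8L,
                          targets_per_regulator = 5L,
                          crosstalk_pairs = list(c(1L, 2L)),
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_lncrnas = as.integer(n_lncrnas),
              n_proteins = as.integer(n_proteins),
              n_methylated = as.integer(n_methylated),
              module_sizes = as.integer(module_sizes),
              module_traits = module_traits,
              trait_coupling = trait_coupling,
              coupling_pairs = as.integer(coupling_pairs),
              lnc_coupling_pairs = as.integer(lnc_coupling_pairs),
              n_triple = as.integer(n_triple),
              planted_r = planted_r, noise_sd = noise_sd,
              n_signature_genes = as.integer(n_signature_genes),
              n_tfs = as.integer(n_tfs),
              n_lncrna_regulators = as.integer(n_lncrna_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              crosstalk_pairs = crosstalk_pairs,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "CohortConfig")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_samples < 3L)
    stop("n_samples must be >= 3 (correlation p-values need n - 2 > 0)")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (length(cfg$module_traits) != length(cfg$module_sizes) ||
      length(cfg$trait_coupling) != length(cfg$module_sizes))
    stop("module_traits and trait_coupling must match module_sizes in length")
  if (!all(cfg$module_traits %in% c("age", "passage", "stemness", "none")))
    stop("module_traits must be age/passage/stemness/none")
  if (any(abs(cfg$trait_coupling) > 1))
    stop("trait_coupling must lie in [-1, 1]")
  if (cfg$planted_r <= 0.9 || cfg$planted_r > 1)
    stop("planted_r must lie in (0.9, 1]")
  n_bg <- cfg$n_genes - sum(cfg$module_sizes)
  need <- 2L * cfg$coupling_pairs
  if (!"stemness" %in% cfg$module_traits) need <- need + cfg$n_signature_genes
  if (n_bg < need)
    stop("not enough background genes (", n_bg, ") for signature and ",
         "planted pairs (need ", need, ")")
  if (cfg$n_methylated < cfg$coupling_pairs + cfg$lnc_coupling_pairs)
    stop("n_methylated too small for the planted pairs")
  if (cfg$n_proteins < cfg$coupling_pairs)
    stop("n_proteins too small for the planted pairs")
  if (cfg$n_lncrnas < cfg$lnc_coupling_pairs + cfg$n_lncrna_regulators)
    stop("n_lncrnas too small for planted pairs and regulators")
  invisible(cfg)
}

# sample layout: two donor groups x passages 3/6/10, replicated as needed
build_phenotype <- function(n_samples) {
  half <- ceiling(n_samples / 2)
  donor <- c(rep("young", half), rep("old", n_samples - half))
  passage <- c(rep(c(3L, 6L, 10L), length.out = half),
               rep(c(3L, 6L, 10L), length.out = n_samples - half))
  id <- sprintf("%s_P%d_r%d", ifelse(donor == "young", "Y", "O"), passage,
                stats::ave(seq_len(n_samples),
                           paste(donor, passage), FUN = seq_along))
  data.frame(sample = id, age_group = donor, passage = passage,
             stringsAsFactors = FALSE)
}

# mix a unit-variance noise vector into a standardized trait so the
# population correlation with the trait equals rho
couple_to_trait <- function(trait, rho, noise) {
  z <- if (stats::sd(trait) == 0) rep(0, length(trait)) else
    as.numeric(scale(trait))
  rho * z + sqrt(1 - rho^2) * noise
}

# residualize a noise vector against a basis (traits + earlier factors)
# and rescale to unit sample variance, so module factors carry no
# chance in-sample correlation beyond their trait coupling; with more
# basis vectors than samples the raw vector is returned
orthogonal_noise <- function(eps, basis) {
  if (length(basis) > 0L) {
    X <- cbind(1, do.call(cbind, basis))
    if (ncol(X) < length(eps)) {
      eps <- stats::resid(stats::lm.fit(X, eps))
    }
  }
  s <- stats::sd(eps)
  if (s < 1e-10) return(eps)
  as.numeric(scale(eps))
}

#' Generate a synthetic multi-omics cohort with ground truth
#'
#' Module genes follow a latent-factor model: each module has a
#' per-sample factor coupled to its trait, and members are positive
#' affine transforms of the factor plus Gaussian noise, so
#' within-module correlations are high and between-module correlations
#' are near zero. Background genes are independent noise. Planted
#' methylation values are a linear-decreasing transform of the paired
#' gene's expression plus noise, clipped to `[0, 1]`; planted proteins
#' are increasing transforms of their mRNAs. The phenotype table
#' carries a planted stemness covariate that decreases with passage and
#' is lower in the old donor group, and a planted stemness signature
#' is expressed over dedicated genes.
#'
#' @param config A `CohortConfig` from [cohort_config()].
#' @return List with elements `mrna`, `lncrna`, `methylation`,
#'   `protein` (each an `OmicsMatrix`), `phenotype` (data frame with
#'   planted `stemness` column), `signature` (named weight vector) and
#'   `truth` (a `GroundTruth` list: `modules`, `module_traits`,
#'   `factors`, `planted_pairs`, `triple_genes`, `stemness`,
#'   `signature`, `regulators`, `tf_table`, `crosstalk_pairs`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  ns <- config$n_samples
  pheno <- build_phenotype(ns)
  smp <- pheno$sample

  # planted stemness: decreasing in passage, lower for the old donor
  stemness <- 1 - 0.06 * pheno$passage - 0.25 * (pheno$age_group == "old") +
    stats::rnorm(ns, sd = 0.03)
  pheno$stemness <- stemness
  traits <- list(age = as.numeric(pheno$age_group == "old"),
                 passage = as.numeric(pheno$passage),
                 stemness = stemness,
                 none = rep(0, ns))

  n_mod <- length(config$module_sizes)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  modules <- stats::setNames(rep("grey", config$n_genes), gene_ids)
  factors <- matrix(0, nrow = n_mod, ncol = ns,
                    dimnames = list(paste0("M", seq_len(n_mod)), smp))
  # background genes: independent noise, less variable than module
  # genes so a variance filter behaves as it does on real profiles
  expr <- matrix(stats::rnorm(config$n_genes * ns, sd = 0.7),
                 nrow = config$n_genes,
                 dimnames = list(gene_ids, smp))
  loadings <- stats::setNames(rep(NA_real_, config$n_genes), gene_ids)
  trait_basis <- lapply(traits[c("age", "passage", "stemness")],
                        function(t) as.numeric(scale(t)))
  factor_basis <- list()
  offset <- 0L
  for (m in seq_len(n_mod)) {
    size <- config$module_sizes[m]
    idx <- offset + seq_len(size)
    offset <- offset + size
    eps <- orthogonal_noise(stats::rnorm(ns),
                            c(trait_basis, factor_basis))
    f <- couple_to_trait(traits[[config$module_traits[m]]],
                         config$trait_coupling[m], eps)
    factor_basis[[m]] <- eps
    factors[m, ] <- f
    modules[idx] <- paste0("M", m)
    load <- stats::runif(size, 0.7, 1.3)
    loadings[idx] <- load
    noise <- matrix(stats::rnorm(size * ns, sd = config$noise_sd),
                    nrow = size)
    expr[idx, ] <- outer(load, f) + noise
  }

  # background gene blocks: methylation-paired and protein-paired genes
  bg <- gene_ids[modules == "grey"]
  meth_genes <- bg[seq_len(config$coupling_pairs)]
  prot_fresh <- bg[config$coupling_pairs +
                     seq_len(config$coupling_pairs - config$n_triple)]
  triple_genes <- meth_genes[seq_len(config$n_triple)]
  prot_genes <- c(triple_genes, prot_fresh)

  # planted stemness signature: the stemness-coupled module's genes
  # weighted by their factor loadings (a stemness program is itself a
  # co-expressed module); with no stemness-coupled module, a dedicated
  # block of background genes carries the signature instead
  z_stem <- as.numeric(scale(stemness))
  stem_mod <- which(config$module_traits == "stemness")
  if (length(stem_mod) > 0L) {
    m <- stem_mod[1L]
    sig_genes <- gene_ids[modules == paste0("M", m)]
    signature <- stats::setNames(loadings[sig_genes], sig_genes)
  } else {
    sig_genes <- bg[2L * config$coupling_pairs - config$n_triple +
                      seq_len(config$n_signature_genes)]
    w <- stats::runif(config$n_signature_genes, 0.5, 2)
    expr[sig_genes, ] <- outer(w, z_stem) +
      matrix(stats::rnorm(config$n_signature_genes * ns,
                          sd = config$noise_sd),
             nrow = config$n_signature_genes)
    modules[sig_genes] <- "signature"
    signature <- stats::setNames(w, sig_genes)
  }

  mrna <- omics_matrix(expr, "mrna")

  # methylation: planted pairs are decreasing transforms of expression
  meth_lnc_ids <- sprintf("LNC%04d", seq_len(config$lnc_coupling_pairs))
  other_meth <- setdiff(gene_ids, meth_genes)
  n_other <- config$n_methylated - config$coupling_pairs -
    config$lnc_coupling_pairs
  meth_ids <- c(meth_genes, meth_lnc_ids,
                sample(other_meth, n_other))
  meth <- matrix(stats::runif(length(meth_ids) * ns, 0.1, 0.9),
                 nrow = length(meth_ids),
                 dimnames = list(meth_ids, smp))
  slope <- 0.12
  sig_noise <- slope * sqrt(1 / config$planted_r^2 - 1)
  plant_meth <- function(x) {
    z <- as.numeric(scale(x))
    pmin(1, pmax(0, 0.5 - slope * z + stats::rnorm(ns, sd = sig_noise)))
  }
  for (g in meth_genes) meth[g, ] <- plant_meth(expr[g, ])

  # lncRNA: planted regulators track module factors; planted
  # methylation-coupled lncRNAs get anticorrelated methylation rows
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrnas))
  lnc <- matrix(stats::rnorm(config$n_lncrnas * ns), nrow = config$n_lncrnas,
                dimnames = list(lnc_ids, smp))
  for (g in meth_lnc_ids) meth[g, ] <- plant_meth(lnc[g, ])

  regs <- generate_regulator_tables(
    truth = list(modules = modules, factors = factors),
    n_tfs = config$n_tfs,
    n_lncrna_regulators = config$n_lncrna_regulators,
    targets_per_regulator = config$targets_per_regulator,
    noise_sd = config$noise_sd, sample_ids = smp)
  if (length(regs$lncrna_ids) > 0L) {
    # regulator profiles replace the last plain lncRNAs
    slot <- config$n_lncrnas - length(regs$lncrna_ids) +
      seq_along(regs$lncrna_ids)
    rownames(lnc)[slot] <- regs$lncrna_ids
    lnc[slot, ] <- regs$lncrna_profiles
  }
  lncrna <- omics_matrix(lnc, "lncrna")
  methylation <- omics_matrix(meth, "methylation")

  # protein: planted pairs are increasing transforms of their mRNA
  other_prot <- setdiff(gene_ids, prot_genes)
  prot_ids <- c(prot_genes,
                sample(other_prot, config$n_proteins - length(prot_genes)))
  prot <- matrix(stats::rnorm(length(prot_ids) * ns), nrow = length(prot_ids),
                 dimnames = list(prot_ids, smp))
  for (g in prot_genes) {
    x <- expr[g, ]
    sn <- stats::sd(x) * sqrt(1 / config$planted_r^2 - 1)
    prot[g, ] <- 0.5 + x + stats::rnorm(ns, sd = sn)
  }
  protein <- omics_matrix(prot, "protein")

  truth <- list(
    modules = modules,
    module_traits = stats::setNames(config$module_traits,
                                    rownames(factors)),
    factors = factors,
    planted_pairs = list(
      methylation_mrna = data.frame(feature = meth_genes,
                                    sign = "negative",
                                    stringsAsFactors = FALSE),
      methylation_lncrna = data.frame(feature = meth_lnc_ids,
                                      sign = "negative",
                                      stringsAsFactors = FALSE),
      mrna_protein = data.frame(feature = prot_genes, sign = "positive",
                                stringsAsFactors = FALSE)),
    triple_genes = triple_genes,
    stemness = stats::setNames(stemness, smp),
    signature = signature,
    regulators = regs$regulators,
    tf_table = regs$tf_table,
    crosstalk_pairs = config$crosstalk_pairs)

  list(mrna = mrna, lncrna = lncrna, methylation = methylation,
       protein = protein, phenotype = pheno, signature = signature,
       truth = truth)
}

#' Generate a background gene-gene interaction network
#'
#' Erdos-Renyi-style random graph over the supplied gene ids with edge
#' probability `mean_degree / (n - 1)`, multiplied by
#' `intra_module_enrichment` for gene pairs whose modules form a
#' designated crosstalking pair in the ground truth. The result is an
#' undirected simple graph (no self-loops, no duplicates).
#'
#' @param genes Character vector of gene ids.
#' @param mean_degree Target mean degree (>= 1 recommended; must be
#'   positive).
#' @param intra_module_enrichment Multiplier (>= 0) on the edge
#'   probability between crosstalking module pairs; 1 = no enrichment.
#' @param truth `GroundTruth` list with `modules` (named labels) and
#'   `crosstalk_pairs` (list of module-index pairs); every gene in
#'   `genes` must be known to the truth.
#' @param seed Integer seed.
#' @return Edge data frame (`from`, `to`).
#' @export
generate_background_network <- function(genes, mean_degree,
                                        intra_module_enrichment = 1,
                                        truth, seed = 1L) {
  if (mean_degree <= 0) stop("mean_degree must be positive")
  unknown <- setdiff(genes, names(truth$modules))
  if (length(unknown) > 0L)
    stop("gene id(s) unknown to ground truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  set.seed(seed)
  n <- length(genes)
  p_base <- mean_degree / (n - 1)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- rep(p_base, nrow(idx))
  if (intra_module_enrichment != 1 && length(truth$crosstalk_pairs) > 0L) {
    lab <- truth$modules[genes]
    la <- lab[idx[, 1L]]; lb <- lab[idx[, 2L]]
    for (cp in truth$crosstalk_pairs) {
      ma <- paste0("M", cp[1L]); mb <- paste0("M", cp[2L])
      hit <- (la == ma & lb == mb) | (la == mb & lb == ma)
      p[hit] <- p[hit] * intra_module_enrichment
    }
  }
  p <- pmin(p, 1)
  keep <- stats::runif(nrow(idx)) < p
  edges <- data.frame(from = genes[idx[keep, 1L]],
                      to = genes[idx[keep, 2L]],
                      stringsAsFactors = FALSE)
  simplify_edges(edges)
}

#' Generate planted regulator tables and profiles
#'
#' TFs are drawn from the module genes and assigned curated-style
#' target rows within their module (so TF-target expression
#' correlations are high by construction); lncRNA regulators receive
#' expression profiles equal to their target module's latent factor
#' plus noise.
#'
#' @param truth `GroundTruth` list with `modules` (named labels over
#'   genes) and `factors` (module x sample matrix).
#' @param n_tfs Number of TFs to plant (0 gives an empty table).
#' @param n_lncrna_regulators Number of planted lncRNA regulators.
#' @param targets_per_regulator Curated targets per TF (must not
#'   exceed module size minus one).
#' @param noise_sd Noise around lncRNA regulator profiles.
#' @param seed Optional seed; omit when called from
#'   [generate_cohort()], which manages the RNG stream.
#' @param sample_ids Sample ids for the regulator profiles (defaults
#'   to the columns of `truth$factors`).
#' @return List: `tf_table` (columns `tf`, `target`, `mode`,
#'   `reference`), `lncrna_ids`, `lncrna_profiles` (regulator x sample
#'   matrix), `regulators` (data frame `regulator`, `type`, `module`).
#' @export
generate_regulator_tables <- function(truth, n_tfs = 8L,
                                      n_lncrna_regulators = 8L,
                                      targets_per_regulator = 5L,
                                      noise_sd = 0.1, seed = NULL,
                                      sample_ids = colnames(truth$factors)) {
  if (!is.null(seed)) set.seed(seed)
  mods <- rownames(truth$factors)
  mod_genes <- split(names(truth$modules), truth$modules)
  mod_genes <- mod_genes[intersect(mods, names(mod_genes))]
  if (length(mod_genes) == 0L) stop("ground truth has no module genes")
  sizes <- lengths(mod_genes)
  if (targets_per_regulator > max(sizes) - 1L)
    stop("targets_per_regulator exceeds available module genes")

  tf_rows <- list()
  tf_regs <- character(0); tf_mods <- character(0)
  if (n_tfs > 0L) {
    host <- rep(names(mod_genes), length.out = n_tfs)
    for (i in seq_len(n_tfs)) {
      m <- host[i]
      if (targets_per_regulator > sizes[[m]] - 1L)
        stop("targets_per_regulator exceeds module ", m, " size")
      tf <- sample(mod_genes[[m]], 1L)
      targets <- sample(setdiff(mod_genes[[m]], tf), targets_per_regulator)
      tf_rows[[i]] <- data.frame(
        tf = tf, target = targets,
        mode = sample(c("Activation", "Repression", "Unknown"),
                      targets_per_regulator, replace = TRUE),
        reference = sprintf("SYN%04d", i), stringsAsFactors = FALSE)
      tf_regs <- c(tf_regs, tf); tf_mods <- c(tf_mods, m)
    }
  }
  tf_table <- if (length(tf_rows) > 0L) do.call(rbind, tf_rows) else
    data.frame(tf = character(), target = character(), mode = character(),
               reference = character(), stringsAsFactors = FALSE)

  lnc_ids <- character(0); lnc_mods <- character(0)
  profiles <- NULL
  if (n_lncrna_regulators > 0L) {
    host <- rep(names(mod_genes), length.out = n_lncrna_regulators)
    lnc_ids <- sprintf("LNCREG%03d", seq_len(n_lncrna_regulators))
    lnc_mods <- host
    profiles <- t(vapply(host, function(m) {
      truth$factors[m, ] + stats::rnorm(ncol(truth$factors), sd = noise_sd)
    }, numeric(ncol(truth$factors))))
    rownames(profiles) <- lnc_ids
    colnames(profiles) <- sample_ids
  }
  regulators <- rbind(
    data.frame(regulator = tf_regs, type = rep("TF", length(tf_regs)),
               module = tf_mods, stringsAsFactors = FALSE),
    data.frame(regulator = lnc_ids,
               type = rep("lncRNA", length(lnc_ids)),
               module = lnc_mods, stringsAsFactors = FALSE))
  list(tf_table = tf_table, lncrna_ids = lnc_ids,
       lncrna_profiles = profiles, regulators = regulators)
}

#' Generate synthetic gene sets aligned with planted modules
#'
#' One set per planted module (a sampled fraction of the module's
#' genes plus random background genes) plus a number of purely random
#' sets, tagged half `GO_BP` / half `KEGG` so both enrichment cutoffs
#' are exercised.
#'
#' @param truth `GroundTruth` list (needs `modules`).
#' @param n_random Number of random decoy sets.
#' @param member_fraction Fraction of each module planted into its set.
#' @param set_size Size of the random sets.
#' @param seed Integer seed.
#' @return Named list of gene sets with a `source` attribute.
#' @export
generate_gene_sets <- function(truth, n_random = 10L,
                               member_fraction = 0.6, set_size = 40L,
                               seed = 1L) {
  set.seed(seed)
  genes <- names(truth$modules)
  mods <- setdiff(sort(unique(truth$modules)), "grey")
  sets <- list()
  for (m in mods) {
    mg <- genes[truth$modules == m]
    core <- sample(mg, max(2L, round(member_fraction * length(mg))))
    pad <- sample(setdiff(genes, mg), round(0.2 * length(core)))
    sets[[paste0("SET_", m)]] <- sort(unique(c(core, pad)))
  }
  for (i in seq_len(n_random)) {
    sets[[sprintf("SET_RANDOM%02d", i)]] <-
      sort(sample(genes, min(set_size, length(genes))))
  }
  src <- rep(c("GO_BP", "KEGG"), length.out = length(sets))
  attr(sets, "source") <- stats::setNames(src, names(sets))
  sets
}

#' Write a synthetic cohort to disk in pipeline input formats
#'
#' Emits the same TSV/GMT/edge-list formats the pipeline reads, so a
#' synthetic cohort is indistinguishable from real inputs; the ground
#' truth is saved as JSON alongside.
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_tsv(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_omics_tsv(cohort$lncrna, file.path(dir, "lncrna.tsv"))
  write_omics_tsv(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_omics_tsv(cohort$protein, file.path(dir, "protein.tsv"))
  write_phenotype_tsv(cohort$phenotype, file.path(dir, "phenotype.tsv"))
  write_signature_tsv(cohort$signature, file.path(dir, "signature.tsv"))
  utils::write.table(cohort$truth$tf_table,
                     file.path(dir, "tf_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- cohort$truth
  truth$factors <- NULL  # matrices are regenerable from the seed
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
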