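#' Default pipeline configuration
#'
#' Builds a validated `PipelineConfig` list. With `demo = TRUE` no
#' input paths are needed: a synthetic cohort is generated into the
#' output directory and then analysed end-to-end.
#'
#' @param output_dir Artifact directory.
#' @param inputs Named list of input paths (`mrna`, `lncrna`,
#'   `methylation`, `protein`, `phenotype`, `signature`, `network`,
#'   `gene_sets`, `tf_table`); ignored in demo mode.
#' @param demo Generate and analyse a synthetic cohort.
#' @param seed Master seed; every random stage derives its own seed
#'   from it.
#' @param counts Whether the mRNA/lncRNA inputs are raw counts needing
#'   log-CPM normalization (synthetic cohorts emit normalized values).
#' @param params Stage parameters overriding the defaults
#'   (`variance_fraction`, `powers`, `r2_cut`, `min_module_size`,
#'   `cut_quantile`, `merge_cut`, `cor_cut`, `p_cut`, `n_permutations`,
#'   `kappa_cut`, `tau`, `mean_degree`, `enrichment_factor`).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(output_dir, inputs = list(), demo = FALSE,
                            seed = 1L, counts = FALSE, params = list()) {
  defaults <- list(variance_fraction = 0.2, powers = 1:20, r2_cut = 0.8,
                   power = 12L, min_module_size = 30L, cut_quantile = 0.75,
                   merge_cut = 0.25, cor_cut = 0.9, p_cut = 0.01,
                   n_permutations = 1000L, kappa_cut = 0.4, tau = 0.25,
                   mean_degree = 8, enrichment_factor = 3)
  # the scaled-down demo cohort plants modules over ~half its genes, so
  # the conventional top-20% variance filter would truncate them; the
  # demo keeps the top half instead unless told otherwise
  if (demo && !"variance_fraction" %in% names(params))
    defaults$variance_fraction <- 0.5
  params <- utils::modifyList(defaults, params)
  cfg <- list(output_dir = output_dir, inputs = inputs, demo = demo,
              seed = as.integer(seed), counts = counts, params = params)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file path.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$output_dir)) stop("config must set output_dir")
  if (is.null(raw$seed)) stop("config must set an explicit seed")
  pipeline_config(output_dir = raw$output_dir,
                  inputs = if (is.null(raw$inputs)) list() else raw$inputs,
                  demo = isTRUE(raw$demo), seed = raw$seed,
                  counts = isTRUE(raw$counts),
                  params = if (is.null(raw$params)) list() else raw$params)
}

#' Validate pipeline inputs
#'
#' Report-only checks: sample-id agreement between every omics layer
#' and the phenotype table, duplicate feature/sample ids, methylation
#' range, and count integrality/nonnegativity where counts are
#' declared. The run itself decides what to do with violations.
#'
#' @param layers Named list of `OmicsMatrix` objects.
#' @param phenotype Phenotype data frame with a `sample` column.
#' @param counts Whether the mrna/lncrna layers are declared raw
#'   counts.
#' @return Data frame with columns `layer` and `violation` (zero rows
#'   when everything is clean).
#' @export
validate_inputs <- function(layers, phenotype, counts = FALSE) {
  bad <- list()
  note <- function(layer, msg)
    bad[[length(bad) + 1L]] <<- data.frame(layer = layer, violation = msg,
                                           stringsAsFactors = FALSE)
  pheno_samples <- phenotype$sample
  if (anyDuplicated(pheno_samples))
    note("phenotype", "duplicate sample ids")
  for (nm in names(layers)) {
    mat <- omics_values(layers[[nm]])
    if (anyDuplicated(rownames(mat))) note(nm, "duplicate feature ids")
    if (anyDuplicated(colnames(mat))) note(nm, "duplicate sample ids")
    extra <- setdiff(colnames(mat), pheno_samples)
    if (length(extra) > 0L)
      note(nm, paste("sample(s) missing from phenotype:",
                     paste(extra, collapse = ",")))
    if (nm == "methylation" &&
        (min(mat) < 0 || max(mat) > 1))
      note(nm, "methylation values outside [0, 1]")
    if (counts && nm %in% c("mrna", "lncrna")) {
      if (any(mat < 0)) note(nm, "negative counts")
      if (any(mat != round(mat))) note(nm, "non-integer counts")
    }
  }
  if (length(bad) == 0L)
    return(data.frame(layer = character(), violation = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

# run one stage with manifest-based resumption: skip when every output
# exists and the stored parameter hash is unchanged
run_stage <- function(name, manifest, stage_params, outputs, fun, log) {
  hash <- config_hash(stage_params)
  prior <- manifest$stages[[name]]
  if (!is.null(prior) && identical(prior$hash, hash) &&
      all(file.exists(outputs))) {
    log(sprintf("[%s] up to date, skipped", name))
    prior$skipped <- TRUE
    manifest$stages[[name]] <- prior
    return(list(manifest = manifest, value = NULL, skipped = TRUE))
  }
  t0 <- Sys.time()
  value <- tryCatch(fun(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  manifest$stages[[name]] <- list(
    hash = hash, outputs = outputs, skipped = FALSE,
    seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
  log(sprintf("[%s] done (%.2fs)", name,
              manifest$stages[[name]]$seconds))
  list(manifest = manifest, value = value, skipped = FALSE)
}

#' Run the full multi-omics pipeline
#'
#' Stage order: (demo cohort generation) -> normalize -> variance
#' filter -> stemness -> co-expression network (power scan, TOM,
#' modules, merge) -> module-trait correlation -> crosstalk ->
#' enrichment -> cross-omics correlation cascade -> per-sample pathway
#' scoring -> regulatory network. Every stage writes TSV/SIF/GraphML
#' artifacts plus a JSON run manifest with parameters, seeds and row
#' counts; a rerun with an unchanged configuration skips completed
#' stages.
#'
#' @param config `PipelineConfig` from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The output directory, invisibly; the manifest is at
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  p <- config$params
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else
    function(msg) message(msg)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  else list(package = "stemomics",
            version = as.character(utils::packageVersion("stemomics")),
            seed = config$seed, stages = list())
  save_manifest <- function()
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

  # --- inputs -------------------------------------------------------
  if (config$demo) {
    sim_dir <- file.path(out, "cohort")
    st <- run_stage("simulate", manifest, list(seed = config$seed),
                    file.path(sim_dir, "mrna.tsv"), function() {
      cohort <- generate_cohort(cohort_config(n_samples = 12L,
                                              seed = config$seed))
      write_cohort(cohort, sim_dir)
      sets <- generate_gene_sets(cohort$truth, seed = config$seed + 1L)
      write_gmt(sets, file.path(sim_dir, "gene_sets.gmt"))
      net <- generate_background_network(
        names(cohort$truth$modules), mean_degree = p$mean_degree,
        intra_module_enrichment = p$enrichment_factor,
        truth = cohort$truth, seed = config$seed + 2L)
      write_network_tsv(net, file.path(sim_dir, "network.tsv"))
      TRUE
    }, log)
    manifest <- st$manifest
    config$inputs <- list(
      mrna = file.path(sim_dir, "mrna.tsv"),
      lncrna = file.path(sim_dir, "lncrna.tsv"),
      methylation = file.path(sim_dir, "methylation.tsv"),
      protein = file.path(sim_dir, "protein.tsv"),
      phenotype = file.path(sim_dir, "phenotype.tsv"),
      signature = file.path(sim_dir, "signature.tsv"),
      network = file.path(sim_dir, "network.tsv"),
      gene_sets = file.path(sim_dir, "gene_sets.gmt"),
      tf_table = file.path(sim_dir, "tf_targets.tsv"))
  }
  ins <- config$inputs
  needed <- c("mrna", "lncrna", "methylation", "protein", "phenotype",
              "signature", "network", "gene_sets", "tf_table")
  missing <- setdiff(needed, names(ins))
  if (length(missing) > 0L)
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  for (f in unlist(ins)) if (!file.exists(f)) stop("input not found: ", f)

  mrna <- read_omics_tsv(ins$mrna, "mrna")
  lncrna <- read_omics_tsv(ins$lncrna, "lncrna")
  methylation <- read_omics_tsv(ins$methylation, "methylation")
  protein <- read_omics_tsv(ins$protein, "protein")
  phenotype <- read_phenotype_tsv(ins$phenotype)
  signature <- read_signature_tsv(ins$signature)
  network <- read_network(ins$network)
  sets <- read_gmt(ins$gene_sets)
  tf_table <- read_tf_table(ins$tf_table)

  report <- validate_inputs(list(mrna = mrna, lncrna = lncrna,
                                 methylation = methylation,
                                 protein = protein),
                            phenotype, counts = config$counts)
  utils::write.table(report, file.path(out, "validation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(report) > 0L)
    stop("input validation failed; see ", file.path(out, "validation.tsv"))

  # --- normalize + filter ------------------------------------------
  if (config$counts) {
    mrna <- logcpm_normalize(mrna)
    lncrna <- logcpm_normalize(lncrna)
  }
  st <- run_stage("variance_filter", manifest,
                  list(fraction = p$variance_fraction),
                  file.path(out, "expr_filtered.tsv"), function() {
    filtered <- variance_filter(mrna, p$variance_fraction)
    write_omics_tsv(filtered, file.path(out, "expr_filtered.tsv"))
    filtered
  }, log)
  manifest <- st$manifest
  filtered <- read_omics_tsv(file.path(out, "expr_filtered.tsv"), "mrna")

  # --- stemness -----------------------------------------------------
  st <- run_stage("stemness", manifest, list(), file.path(out, "stemness.tsv"),
                  function() {
    scores <- stemness_index(mrna, signature)
    write_stemness_tsv(scores, file.path(out, "stemness.tsv"))
    scores
  }, log)
  manifest <- st$manifest
  scores <- utils::read.delim(file.path(out, "stemness.tsv"))
  phenotype$stemness <- scores$scaled[match(phenotype$sample, scores$sample)]

  # --- co-expression network ---------------------------------------
  st <- run_stage("coexpression", manifest,
                  p[c("powers", "r2_cut", "power", "min_module_size",
                      "cut_quantile", "merge_cut")],
                  file.path(out, c("modules.tsv", "eigengenes.tsv",
                                   "power_scan.tsv")), function() {
    pick <- pick_soft_threshold(filtered, powers = p$powers,
                                r2_cut = p$r2_cut)
    utils::write.table(pick$scan, file.path(out, "power_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    power <- if (is.null(p$power)) pick$power else p$power
    adj <- adjacency_matrix(filtered, power)
    tom <- topological_overlap(adj)
    assignment <- detect_modules(tom, min_module_size = p$min_module_size,
                                 cut_quantile = p$cut_quantile)
    assignment <- merge_close_modules(filtered, assignment,
                                      cut_height = p$merge_cut)
    utils::write.table(
      data.frame(feature = names(assignment$labels),
                 module = unname(assignment$labels)),
      file.path(out, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(sample = rownames(assignment$eigengenes),
                 assignment$eigengenes, check.names = FALSE),
      file.path(out, "eigengenes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(power = power, scan_power = pick$power, flagged = pick$flagged)
  }, log)
  manifest <- st$manifest
  mod_df <- utils::read.delim(file.path(out, "modules.tsv"))
  labels <- stats::setNames(mod_df$module, mod_df$feature)
  assignment <- structure(list(labels = labels, eigengenes = NULL,
                               dendrogram = NULL),
                          class = "ModuleAssignment")
  eg <- utils::read.delim(file.path(out, "eigengenes.tsv"),
                          check.names = FALSE)
  eigengenes <- as.matrix(eg[, -1, drop = FALSE])
  rownames(eigengenes) <- eg$sample
  assignment$eigengenes <- eigengenes

  # --- module-trait correlation ------------------------------------
  traits <- encode_traits(phenotype)
  st <- run_stage("module_trait", manifest, list(),
                  file.path(out, "module_trait.tsv"), function() {
    mt <- module_trait_correlation(eigengenes, traits)
    utils::write.table(mt, file.path(out, "module_trait.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mt
  }, log)
  manifest <- st$manifest
  mt <- utils::read.delim(file.path(out, "module_trait.tsv"))

  # --- crosstalk ----------------------------------------------------
  st <- run_stage("crosstalk", manifest,
                  list(N = p$n_permutations, seed = config$seed + 10L),
                  file.path(out, "crosstalk.tsv"), function() {
    ct <- crosstalk_test(network, assignment, N = p$n_permutations,
                         seed = config$seed + 10L)
    utils::write.table(ct, file.path(out, "crosstalk.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_crosstalk_sif(ct, file.path(out, "crosstalk_significant.sif"))
    ct
  }, log)
  manifest <- st$manifest

  # --- enrichment ---------------------------------------------------
  st <- run_stage("enrichment", manifest, list(kappa_cut = p$kappa_cut),
                  file.path(out, "enrichment.tsv"), function() {
    rows <- enrich_modules(assignment, sets, universe = features(filtered))
    utils::write.table(rows, file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(rows) >= 2L) {
      tg <- term_similarity_network(rows, kappa_cut = p$kappa_cut)
      export_network(tg, file.path(out, "term_network.graphml"),
                     format = "graphml")
    }
    rows
  }, log)
  manifest <- st$manifest
  enr <- utils::read.delim(file.path(out, "enrichment.tsv"),
                           colClasses = c(overlap_genes = "character"))

  # --- cross-omics cascade -----------------------------------------
  st <- run_stage("integration", manifest,
                  list(cor_cut = p$cor_cut, p_cut = p$p_cut),
                  file.path(out, c("meth_mrna.tsv", "meth_lncrna.tsv",
                                   "mrna_protein.tsv",
                                   "triple_intersection.txt")), function() {
    mm <- correlate_paired_features(methylation, mrna)
    ml <- correlate_paired_features(methylation, lncrna)
    mp <- correlate_paired_features(mrna, protein)
    mm_sig <- filter_significant(mm, p$cor_cut, p$p_cut)
    ml_sig <- filter_significant(ml, p$cor_cut, p$p_cut)
    mp_sig <- filter_significant(mp, p$cor_cut, p$p_cut)
    write_records_tsv(mm_sig, file.path(out, "meth_mrna.tsv"))
    write_records_tsv(ml_sig, file.path(out, "meth_lncrna.tsv"))
    write_records_tsv(mp_sig, file.path(out, "mrna_protein.tsv"))
    meth_reg <- classify_methylation_regulated(mm_sig)$negative
    tri <- triple_intersection(meth_reg$feature, mp_sig$feature)
    writeLines(tri, file.path(out, "triple_intersection.txt"))
    TRUE
  }, log)
  manifest <- st$manifest

  # --- per-sample pathway scores -----------------------------------
  st <- run_stage("pathway_scores", manifest, list(tau = p$tau),
                  file.path(out, "pathway_scores_mrna.tsv"), function() {
    layer_scores <- list()
    for (nm in c("mrna", "lncrna", "methylation", "protein")) {
      x <- switch(nm, mrna = mrna, lncrna = lncrna,
                  methylation = methylation, protein = protein)
      sc <- suppressWarnings(gene_set_score(x, sets, tau = p$tau))
      layer_scores[[nm]] <- sc
      utils::write.table(
        data.frame(set = rownames(sc), sc, check.names = FALSE),
        file.path(out, paste0("pathway_scores_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pl <- pathway_layer_correlation(layer_scores)
    utils::write.table(pl, file.path(out, "pathway_layer_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, log)
  manifest <- st$manifest

  # --- regulatory network ------------------------------------------
  st <- run_stage("regnet", manifest,
                  list(cor_cut = p$cor_cut, p_cut = p$p_cut),
                  file.path(out, "regnet.graphml"), function() {
    # most trait-correlated module per trait (ties: smaller p, name)
    mt_ok <- mt[!mt$flagged & !is.na(mt$r), , drop = FALSE]
    sel <- unique(unlist(lapply(split(mt_ok, mt_ok$trait), function(d) {
      d <- d[order(-abs(d$r), d$p, d$module), , drop = FALSE]
      d$module[1L]
    })))
    mod_genes <- names(labels)[labels %in% sel]
    gene_expr <- omics_values(filtered)[mod_genes, , drop = FALSE]
    lnc_edges <- link_lncrna_to_modules(lncrna, gene_expr,
                                        cor_cut = p$cor_cut,
                                        p_cut = p$p_cut)
    tf_edges <- link_tfs_to_modules(tf_table, mrna, mod_genes,
                                    cor_cut = p$cor_cut, p_cut = p$p_cut)
    edges <- rbind(lnc_edges[, c("regulator", "target", "r", "p",
                                 "regulator_type")],
                   tf_edges[, c("regulator", "target", "r", "p",
                                "regulator_type")])
    enr_sel <- enr[enr$module %in% sel, , drop = FALSE]
    if (nrow(edges) > 0L && nrow(enr_sel) > 0L) {
      net <- attach_pathways(edges, enr_sel,
                             selected_pathways = unique(enr_sel$term))
      export_network(net, file.path(out, "regnet.graphml"), "graphml")
      export_network(net, file.path(out, "regnet.sif"), "sif")
      write_network_summary(net, file.path(out, "regnet_summary.json"))
    } else {
      writeLines(character(0), file.path(out, "regnet.graphml"))
      jsonlite::write_json(list(n_regulators = 0, n_genes = 0,
                                n_pathways = 0),
                           file.path(out, "regnet_summary.json"),
                           auto_unbox = TRUE)
    }
    TRUE
  }, log)
  manifest <- st$manifest

  save_manifest()
  invisible(out)
}
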