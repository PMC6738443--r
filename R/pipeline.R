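#' Default pipeline configuration
#'
#' Returns the full nested parameter list the pipeline runs with; pass a
#' partial list (or a YAML file of the same shape) to [run_pipeline()] to
#' override any subset. Exactly one of `simulation` (generator settings) or
#' `inputs` (paths to expression/labels/edges/regulators/gene_sets files)
#' provides the data.
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    simulation = list(),    # sim_config() arguments; NULL when inputs given
    inputs = NULL,          # list(expression=, labels=, edges=, regulators=, gene_sets=)
    de = list(alpha = 0.05, top_k = 100, moderated = TRUE),
    gsea = list(n_perm = 1000, nom_p = 0.05, weight_exponent = 1),
    network = list(min_score = 0.4, top_n = 10),
    modules = list(penalty = 2, min_size = 3, min_density = 0.5,
                   merge_threshold = 0.8),
    enrichment = list(go_p = 0.01, go_q = 0.01, kegg_p = 0.05, kegg_q = 0.2),
    regulators = list(min_score = 0.5, min_quantity = 2, alpha = 0.01,
                      corr_alpha = 0.05),
    validation = list(alpha = 0.05))
}

validate_config <- function(cfg) {
  bad <- function(field) abort(paste0("invalid config field `", field,
                                      "`: must lie in (0, 1]"),
                               class = "modregnet_config_error")
  probs <- list("de.alpha" = cfg$de$alpha, "gsea.nom_p" = cfg$gsea$nom_p,
                "regulators.alpha" = cfg$regulators$alpha,
                "regulators.corr_alpha" = cfg$regulators$corr_alpha,
                "validation.alpha" = cfg$validation$alpha)
  for (f in names(probs))
    if (!is.numeric(probs[[f]]) || probs[[f]] <= 0 || probs[[f]] > 1) bad(f)
  if (!is.null(cfg$inputs) && length(cfg$simulation))
    abort("config must provide either `inputs` or `simulation`, not both",
          class = "modregnet_config_error")
  invisible(cfg)
}

merge_config <- function(user) {
  if (is.character(user) && length(user) == 1) user <- yaml::read_yaml(user)
  cfg <- utils::modifyList(default_config(), user %||% list())
  validate_config(cfg)
  if (!is.null(cfg$inputs)) cfg$simulation <- list()
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)),
          class = "modregnet_stage_error"))
}

join_genes <- function(x) vapply(x, paste, character(1), collapse = ",")

#' Run the whole module-discovery pipeline
#'
#' Executes, in order: data simulation (or loading), quantile normalization,
#' differential expression and top-DEG clustering, GSEA, DEG network
#' construction and W-score hub ranking, cohesive module mining, module
#' over-representation, regulator-module association with the TF correlation
#' filter, the integrated regulator-gene-pathway network, and validation of
#' hub genes and module TFs in a second cohort (simulated from the same
#' planted truth when the data are simulated) with ROC curves. Every stage's
#' result is written as a plain-text table under `outdir`, and a JSON
#' manifest records the configuration, seed and an MD5 checksum of every
#' output file; a rerun with the same manifest reproduces every file
#' bit-for-bit.
#'
#' @param config partial configuration list (or path to a YAML file); see
#'   [default_config()].
#' @param outdir output directory.
#' @param seed integer master seed; drives the generator, GSEA permutations
#'   and the validation cohort.
#' @return invisibly, the manifest list (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), outdir, seed = 1L) {
  cfg <- merge_config(config)
  seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  written <- character()
  emit <- function(tbl, f) {
    readr::write_tsv(tbl, out(f))
    written <<- c(written, f)
  }

  # -- data ------------------------------------------------------------
  simulated <- is.null(cfg$inputs)
  data <- run_stage("data", {
    if (simulated) {
      sim_cfg <- do.call(sim_config, modifyList(cfg$simulation, list(seed = seed)))
      simulate_study(sim_cfg)
    } else {
      list(expression = read_expression(cfg$inputs$expression),
           labels = read_labels(cfg$inputs$labels),
           edges = read_edges(cfg$inputs$edges),
           regulators = read_regulators(cfg$inputs$regulators),
           gene_sets = read_gmt(cfg$inputs$gene_sets),
           truth = NULL)
    }
  })

  # -- normalization & differential expression -------------------------
  normalized <- run_stage("normalize", quantile_normalize(data$expression))
  emit(normalized, "normalized.tsv")
  fit <- run_stage("de", fit_differential(normalized, data$labels,
                                          moderated = cfg$de$moderated))
  de_tab <- tidy(fit, alpha = cfg$de$alpha)
  emit(de_tab, "de_results.tsv")
  degs <- run_stage("de", select_degs(fit, alpha = cfg$de$alpha))
  clust <- run_stage("cluster", top_deg_cluster(fit, normalized,
                                                k = cfg$de$top_k,
                                                alpha = cfg$de$alpha))
  emit(tibble(gene_id = clust$genes), "top_deg_selection.tsv")

  # -- GSEA -------------------------------------------------------------
  gsea <- run_stage("gsea", gsea_test(normalized, data$labels, data$gene_sets,
                                      n_perm = cfg$gsea$n_perm,
                                      weight_exponent = cfg$gsea$weight_exponent,
                                      seed = seed + 101L))
  emit(gsea |> mutate(leading_edge = join_genes(.data$leading_edge),
                      significant = .data$nom_p < cfg$gsea$nom_p),
       "gsea.tsv")

  # -- network & hubs ---------------------------------------------------
  network <- run_stage("network",
                       build_network(degs, data$edges,
                                     min_score = cfg$network$min_score))
  emit(network$nodes, "network_nodes.tsv")
  write_network(network, out("network.sif"), "sif")
  write_network(network, out("network.graphml"), "graphml")
  written <- c(written, "network.sif", "network.graphml")
  hubs <- run_stage("network", rank_hubs(network, top_n = cfg$network$top_n))
  emit(hubs, "hub_genes.tsv")

  # -- modules ----------------------------------------------------------
  modules <- run_stage("modules", detect_modules(
    network, penalty = cfg$modules$penalty, min_size = cfg$modules$min_size,
    min_density = cfg$modules$min_density,
    merge_threshold = cfg$modules$merge_threshold))
  emit(as_tibble(modules) |> mutate(members = join_genes(.data$members)),
       "modules.tsv")
  if (nrow(modules)) emit(tidy(modules), "module_membership.tsv")

  # -- enrichment -------------------------------------------------------
  enr <- run_stage("enrichment", enrich_modules(
    modules, data$gene_sets,
    go_p = cfg$enrichment$go_p, go_q = cfg$enrichment$go_q,
    kegg_p = cfg$enrichment$kegg_p, kegg_q = cfg$enrichment$kegg_q))
  emit(if (nrow(enr)) mutate(enr, overlap_genes = join_genes(.data$overlap_genes))
       else enr, "enrichment.tsv")

  # -- regulators -------------------------------------------------------
  reg <- run_stage("regulators", filter_regulators(
    data$regulators, min_score = cfg$regulators$min_score))
  assoc <- run_stage("regulators", associate_regulators(
    modules, reg, background = network$nodes$gene_id,
    min_quantity = cfg$regulators$min_quantity, alpha = cfg$regulators$alpha))
  emit(assoc, "regulator_associations.tsv")
  sig_tfs <- assoc |>
    filter(.data$significant, .data$regulator_class == "TF") |>
    pull("regulator_id") |> unique()
  sig_tfs <- intersect(sig_tfs, normalized$gene_id)
  correlations <- bind_rows(map(sig_tfs, function(tf) {
    targets <- reg |> filter(.data$regulator_id == tf) |> pull("target")
    tf_target_correlation(normalized, tf, targets,
                          alpha = cfg$regulators$corr_alpha)
  }))
  if (nrow(correlations)) emit(correlations, "tf_correlations.tsv")
  integrated <- run_stage("regulators", build_integrated_network(
    assoc, modules, correlations = if (nrow(correlations)) correlations,
    enrichments = enr, de = de_tab))
  emit(integrated$nodes, "integrated_nodes.tsv")
  emit(integrated$edges, "integrated_edges.tsv")
  if (nrow(integrated$edges)) {
    write_network(integrated, out("integrated.sif"), "sif")
    written <- c(written, "integrated.sif")
  }

  # -- validation -------------------------------------------------------
  panel <- unique(c(hubs$gene_id, sig_tfs))
  val <- run_stage("validation", {
    if (simulated) {
      vcfg <- do.call(sim_config, modifyList(
        cfg$simulation,
        list(seed = seed + 7L, n_case = 40L, n_control = 30L)))
      vdat <- simulate_expression(vcfg, truth = data$truth)
      vexpr <- quantile_normalize(vdat$expression)
      list(genes = validate_genes(vexpr, vdat$labels, panel, de_tab,
                                  alpha = cfg$validation$alpha),
           roc_discovery = roc_table(normalized, data$labels, panel),
           roc_validation = roc_table(vexpr, vdat$labels, panel))
    } else {
      list(genes = tibble(), roc_discovery = roc_table(normalized, data$labels, panel),
           roc_validation = tibble())
    }
  })
  if (nrow(val$genes)) emit(val$genes, "validation.tsv")
  emit(val$roc_discovery, "roc_discovery.tsv")
  if (nrow(val$roc_validation)) emit(val$roc_validation, "roc_validation.tsv")

  # -- manifest ---------------------------------------------------------
  files <- out(written)
  manifest <- list(
    package = "modregnet",
    version = as.character(utils::packageVersion("modregnet")),
    seed = seed, config = cfg, simulated = simulated,
    counts = list(n_degs = nrow(degs),
                  n_degs_up = sum(degs$direction == "up"),
                  n_degs_down = sum(degs$direction == "down"),
                  n_network_nodes = nrow(network$nodes),
                  n_network_edges = nrow(network$edges),
                  n_modules = nrow(modules),
                  n_module_genes = length(unique(unlist(modules$members))),
                  n_significant_associations = sum(assoc$significant),
                  n_significant_gsea = sum(gsea$nom_p < cfg$gsea$nom_p)),
    outputs = as.list(setNames(unname(tools::md5sum(files)), written)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  inform(sprintf("pipeline complete: %d DEGs, %d modules, %d significant regulator pairs",
                 nrow(degs), nrow(modules), sum(assoc$significant)))
  invisible(manifest)
}

#' Re-run a pipeline from its manifest
#'
#' Reads the configuration and seed recorded in a manifest and re-executes
#' [run_pipeline()]; with the same package version the outputs are
#' bit-identical to the recorded checksums.
#'
#' @param manifest_path path to a `manifest.json` written by [run_pipeline()].
#' @param outdir output directory (defaults to the manifest's directory).
#' @return invisibly, the new manifest.
#' @export
rerun_pipeline <- function(manifest_path, outdir = dirname(manifest_path)) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  if (!is.null(cfg$simulation))
    cfg$simulation <- as.list(cfg$simulation)
  run_pipeline(cfg, outdir = outdir, seed = man$seed)
}
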