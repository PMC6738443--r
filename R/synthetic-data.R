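#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the package is exercised under: a
#' small two-group microarray-like cohort (7 cases vs 6 controls, log2
#' intensities around 7), 10% of genes differentially expressed with a 2
#' log2-unit shift, five cohesive interaction modules planted among the DE
#' genes, and a mix of planted and null regulators.
#'
#' @param n_genes number of genes.
#' @param n_case,n_control samples per condition (each >= 2).
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param effect_size absolute log2 shift applied to DE genes in cases.
#' @param noise_sd residual noise standard deviation (log2 units).
#' @param n_modules number of planted interaction modules.
#' @param module_size_range length-2 integer range of module sizes.
#' @param module_overlap genes shared between consecutive planted modules
#'   (0 = disjoint modules, the default).
#' @param p_in,p_out within-module / background edge probabilities.
#' @param n_regulators total regulators (one planted per module, rest null).
#' @param targets_per_regulator targets listed per regulator.
#' @param module_targets_per_regulator planted targets inside a planted
#'   regulator's module (the "q" guaranteeing the quantity > 2 rule can fire).
#' @param n_gene_sets total gene sets (one planted per module, rest null).
#' @param term_size_range length-2 range of gene-set sizes.
#' @param term_module_coverage fraction of a module a planted term must cover.
#' @param seed integer seed; fixes every downstream draw.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000, n_case = 7, n_control = 6,
                       de_fraction = 0.1, effect_size = 2, noise_sd = 0.5,
                       n_modules = 5, module_size_range = c(8, 12),
                       module_overlap = 0,
                       p_in = 0.9, p_out = 0.01,
                       n_regulators = 20, targets_per_regulator = 30,
                       module_targets_per_regulator = 5,
                       n_gene_sets = 30, term_size_range = c(15, 200),
                       term_module_coverage = 0.6,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control), de_fraction = de_fraction,
              effect_size = effect_size, noise_sd = noise_sd,
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              module_overlap = as.integer(module_overlap),
              p_in = p_in, p_out = p_out,
              n_regulators = as.integer(n_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              module_targets_per_regulator = as.integer(module_targets_per_regulator),
              n_gene_sets = as.integer(n_gene_sets),
              term_size_range = as.integer(term_size_range),
              term_module_coverage = term_module_coverage,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) abort(paste0("invalid `", field, "`: ", why),
                                    class = "modregnet_config_error")
  if (cfg$n_genes < 10) bad("n_genes", "need at least 10 genes")
  if (cfg$n_case < 2) bad("n_case", "need at least 2 case samples")
  if (cfg$n_control < 2) bad("n_control", "need at least 2 control samples")
  for (f in c("de_fraction", "p_in", "p_out", "term_module_coverage"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must lie in [0, 1]")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be nonnegative")
  if (length(cfg$module_size_range) != 2 ||
      cfg$module_size_range[1] > cfg$module_size_range[2] ||
      cfg$module_size_range[1] < 3)
    bad("module_size_range", "must be an increasing pair with minimum >= 3")
  need <- cfg$n_modules * cfg$module_size_range[2]
  if (need > cfg$n_genes)
    bad("module_size_range", "planted modules do not fit within n_genes")
  if (cfg$targets_per_regulator > cfg$n_genes)
    bad("targets_per_regulator", "exceeds n_genes")
  if (cfg$module_targets_per_regulator > cfg$module_size_range[1])
    bad("module_targets_per_regulator", "exceeds the smallest module size")
  if (length(cfg$term_size_range) != 2 ||
      cfg$term_size_range[1] > cfg$term_size_range[2])
    bad("term_size_range", "must be an increasing pair")
  invisible(cfg)
}

gene_ids_for <- function(n) sprintf("g%0*d", nchar(n), seq_len(n))

empty_truth <- function() {
  structure(list(de_genes_up = character(), de_genes_down = character(),
                 modules = list(), regulator_targets = integer(),
                 enriched_terms = integer()),
            class = "synthetic_truth")
}

#' Simulate a case-control expression matrix with planted DE genes
#'
#' Baseline per-gene means are drawn from N(7, 1) on the log2 scale
#' (microarray-like intensities); planted DE genes are shifted by
#' `+effect_size` (up) or `-effect_size` (down) in case samples only, and
#' i.i.d. N(0, noise_sd) noise is added throughout.
#'
#' @param config a [sim_config()].
#' @param truth optionally, an existing truth object whose `de_genes_up` /
#'   `de_genes_down` are reused (for simulating an independent validation
#'   cohort that shares the discovery cohort's planted effects).
#' @return list with `expression` (tibble, gene_id + sample columns),
#'   `labels` (sample_id, condition) and `truth`.
#' @export
simulate_expression <- function(config, truth = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- gene_ids_for(config$n_genes)
  samples <- c(sprintf("case_%02d", seq_len(config$n_case)),
               sprintf("ctrl_%02d", seq_len(config$n_control)))
  labels <- tibble(sample_id = samples,
                   condition = rep(c("case", "control"),
                                   c(config$n_case, config$n_control)))

  if (is.null(truth)) {
    truth <- empty_truth()
    n_de <- round(config$n_genes * config$de_fraction)
    de <- resample(genes, n_de)
    n_up <- ceiling(n_de / 2)
    truth$de_genes_up <- sort(de[seq_len(n_up)])
    truth$de_genes_down <- sort(de[setdiff(seq_len(n_de), seq_len(n_up))])
  } else {
    truth$de_genes_up <- intersect(truth$de_genes_up, genes)
    truth$de_genes_down <- intersect(truth$de_genes_down, genes)
  }

  baseline <- rnorm(config$n_genes, mean = 7, sd = 1)
  mat <- matrix(baseline, nrow = config$n_genes, ncol = length(samples),
                dimnames = list(genes, samples))
  shift <- setNames(numeric(config$n_genes), genes)
  shift[truth$de_genes_up] <- config$effect_size
  shift[truth$de_genes_down] <- -config$effect_size
  mat[, labels$condition == "case"] <-
    mat[, labels$condition == "case"] + shift
  mat <- mat + matrix(rnorm(length(mat), sd = config$noise_sd),
                      nrow = nrow(mat))
  list(expression = as_expr_tibble(mat), labels = labels, truth = truth)
}

# map flat upper-triangle indices (ordered by second endpoint, then first)
# back to (i, j) pairs, i < j
index_to_pair <- function(idx, n) {
  cum <- c(0, cumsum(seq_len(n) - 1))
  j <- findInterval(idx - 0.5, cum) # j-1 values of cum are < idx
  i <- idx - cum[j]
  cbind(i, j + 0L)
}

#' Simulate a scored interaction network with planted cohesive modules
#'
#' Planted-partition graph: node pairs inside a planted module are connected
#' with probability `p_in` and carry scores Uniform(0.7, 1); all other pairs
#' are connected with probability `p_out` with scores Uniform(0.15, 0.7).
#' Module members are drawn preferentially from the planted DE genes so that
#' a network restricted to detected DEGs retains the planted modules.
#'
#' @param config a [sim_config()].
#' @param gene_ids character vector of node ids.
#' @param truth truth object; planted DE genes guide module placement and the
#'   planted modules are appended to it.
#' @return list with `edges` (tibble gene_a, gene_b, score) and `truth`.
#' @export
simulate_interactions <- function(config, gene_ids, truth = empty_truth()) {
  validate_sim_config(config)
  if (!length(gene_ids)) abort("gene_ids must be nonempty")
  set.seed(config$seed + 1L)
  n <- length(gene_ids)
  sizes <- resample(seq(config$module_size_range[1], config$module_size_range[2]),
                    config$n_modules, replace = TRUE)
  if (sum(sizes) - config$module_overlap * (config$n_modules - 1) > n)
    abort("invalid `module_size_range`: planted modules do not fit within n_genes",
          class = "modregnet_config_error")

  # place modules among DE genes first, then the rest
  pool <- c(resample(intersect(c(truth$de_genes_up, truth$de_genes_down), gene_ids)),
            resample(setdiff(gene_ids, c(truth$de_genes_up, truth$de_genes_down))))
  modules <- vector("list", config$n_modules)
  used <- 0
  for (m in seq_len(config$n_modules)) {
    carry <- if (m > 1 && config$module_overlap > 0)
      utils::tail(modules[[m - 1]], config$module_overlap) else character()
    fresh <- pool[used + seq_len(sizes[m] - length(carry))]
    used <- used + sizes[m] - length(carry)
    modules[[m]] <- sort(c(carry, fresh))
  }
  truth$modules <- modules

  member_idx <- lapply(modules, match, gene_ids)
  in_module_pair <- new.env(parent = emptyenv())
  edges_a <- integer(); edges_b <- integer(); scores <- numeric()
  for (idx in member_idx) {
    prs <- t(utils::combn(sort(idx), 2))
    keep <- runif(nrow(prs)) < config$p_in
    for (r in seq_len(nrow(prs)))
      assign(paste(prs[r, 1], prs[r, 2]), TRUE, envir = in_module_pair)
    edges_a <- c(edges_a, prs[keep, 1]); edges_b <- c(edges_b, prs[keep, 2])
    scores <- c(scores, runif(sum(keep), 0.7, 1))
  }
  m_all <- n * (n - 1) / 2
  n_bg <- stats::rbinom(1, m_all, config$p_out)
  if (n_bg > 0) {
    bg <- index_to_pair(sample.int(m_all, n_bg), n)
    inside <- vapply(seq_len(nrow(bg)), function(r)
      !is.null(in_module_pair[[paste(bg[r, 1], bg[r, 2])]]), logical(1))
    bg <- bg[!inside, , drop = FALSE]
    edges_a <- c(edges_a, bg[, 1]); edges_b <- c(edges_b, bg[, 2])
    scores <- c(scores, runif(nrow(bg), 0.15, 0.7))
  }
  edges <- tibble(gene_a = gene_ids[edges_a], gene_b = gene_ids[edges_b],
                  score = scores) |>
    mutate(tmp_a = pmin(.data$gene_a, .data$gene_b),
           tmp_b = pmax(.data$gene_a, .data$gene_b)) |>
    select(gene_a = "tmp_a", gene_b = "tmp_b", "score") |>
    arrange(.data$gene_a, .data$gene_b)
  list(edges = edges, truth = truth)
}

#' Simulate regulator-target tables with planted module-targeting regulators
#'
#' One planted regulator per planted module (classes alternate ncRNA / TF;
#' planted TFs are module member genes so their expression is observable),
#' each guaranteed `module_targets_per_regulator` targets inside its module
#' plus uniform decoys; remaining regulators are null with fully random
#' targets. Planted module-target rows carry scores Uniform(0.5, 1) so they
#' survive the score >= 0.5 filter; all other rows Uniform(0, 1).
#'
#' @param config a [sim_config()].
#' @param truth truth object holding the planted modules.
#' @param gene_ids all candidate target genes.
#' @return list with `regulators` (tibble regulator_id, class, target, score)
#'   and the augmented `truth`.
#' @export
simulate_regulators <- function(config, truth, gene_ids) {
  validate_sim_config(config)
  if (config$targets_per_regulator > length(gene_ids))
    abort("invalid `targets_per_regulator`: exceeds the number of genes",
          class = "modregnet_config_error")
  if (!length(truth$modules)) abort("truth carries no planted modules")
  set.seed(config$seed + 2L)
  q <- config$module_targets_per_regulator
  rows <- list()
  planted <- integer()
  n_planted <- min(config$n_modules, config$n_regulators)
  for (m in seq_len(n_planted)) {
    cls <- if (m %% 2 == 1) "ncRNA" else "TF"
    members <- truth$modules[[m]]
    if (cls == "TF") {
      reg_id <- members[1]
      members <- setdiff(members, reg_id)
    } else {
      reg_id <- sprintf("miR_%02d", m)
    }
    core <- resample(members, min(q, length(members)))
    decoys <- resample(setdiff(gene_ids, c(core, reg_id)),
                       max(config$targets_per_regulator - length(core), 0))
    rows[[length(rows) + 1]] <- tibble(
      regulator_id = reg_id, class = cls, target = c(core, decoys),
      score = c(runif(length(core), 0.5, 1), runif(length(decoys))))
    planted[reg_id] <- m
  }
  for (r in seq_len(config$n_regulators - n_planted)) {
    cls <- if (r %% 2 == 1) "ncRNA" else "TF"
    reg_id <- if (cls == "ncRNA") sprintf("lnc_%02d", r) else
      resample(setdiff(gene_ids, unlist(truth$modules)), 1)
    targets <- resample(setdiff(gene_ids, reg_id), config$targets_per_regulator)
    rows[[length(rows) + 1]] <- tibble(regulator_id = reg_id, class = cls,
                                       target = targets,
                                       score = runif(length(targets)))
  }
  truth$regulator_targets <- planted
  list(regulators = bind_rows(rows), truth = truth)
}

#' Simulate a gene-set collection with planted module-enriched terms
#'
#' One planted term per module covering at least `term_module_coverage` of the
#' module's genes, padded with random genes to a size drawn from
#' `term_size_range`; remaining terms are random. Planted terms get category
#' "BP"; null terms alternate "BP" and "pathway".
#'
#' @inheritParams simulate_regulators
#' @return list with `gene_sets` (a gene-set collection tibble: term_id,
#'   term_name, category, genes list-column) and the augmented `truth`.
#' @export
simulate_gene_sets <- function(config, truth, gene_ids) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  # clamp set sizes to the genome when it is smaller than the stated range
  hi <- min(config$term_size_range[2], length(gene_ids))
  lo <- min(config$term_size_range[1], hi)
  rows <- list()
  enriched <- integer()
  for (m in seq_along(truth$modules)) {
    members <- truth$modules[[m]]
    core <- resample(members, ceiling(config$term_module_coverage * length(members)))
    size <- resample(seq(max(lo, length(core)), hi), 1)
    fill <- resample(setdiff(gene_ids, core), size - length(core))
    id <- sprintf("TERM_P%02d", m)
    rows[[length(rows) + 1]] <- tibble(
      term_id = id, term_name = sprintf("planted module %d process", m),
      category = "BP", genes = list(sort(c(core, fill))))
    enriched[id] <- m
  }
  n_null <- max(config$n_gene_sets - length(truth$modules), 0)
  for (t in seq_len(n_null)) {
    size <- resample(seq(lo, hi), 1)
    rows[[length(rows) + 1]] <- tibble(
      term_id = sprintf("TERM_N%02d", t),
      term_name = sprintf("null set %d", t),
      category = if (t %% 2 == 1) "BP" else "pathway",
      genes = list(sort(resample(gene_ids, size))))
  }
  truth$enriched_terms <- enriched
  list(gene_sets = bind_rows(rows), truth = truth)
}

#' Simulate a full synthetic study
#'
#' Runs all four generators in order with sub-seeds derived from
#' `config$seed`, so a fixed seed fixes every table bit-for-bit.
#'
#' @param config a [sim_config()].
#' @return a `sim_study` list: expression, labels, edges, regulators,
#'   gene_sets, truth, config.
#' @export
simulate_study <- function(config = sim_config()) {
  ex <- simulate_expression(config)
  net <- simulate_interactions(config, ex$expression$gene_id, ex$truth)
  reg <- simulate_regulators(config, net$truth, ex$expression$gene_id)
  gs <- simulate_gene_sets(config, reg$truth, ex$expression$gene_id)
  structure(list(expression = ex$expression, labels = ex$labels,
                 edges = net$edges, regulators = reg$regulators,
                 gene_sets = gs$gene_sets, truth = gs$truth, config = config),
            class = "sim_study")
}

#' Write a simulated study to plain-text files
#'
#' Expression, labels, edges and regulators as TSV, gene sets as GMT, truth
#' as JSON.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, a named vector of the written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             edges = file.path(dir, "edges.tsv"),
             regulators = file.path(dir, "regulators.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  readr::write_tsv(study$expression, paths["expression"])
  readr::write_tsv(study$labels, paths["labels"])
  readr::write_tsv(study$edges, paths["edges"])
  readr::write_tsv(study$regulators, paths["regulators"])
  write_gmt(study$gene_sets, paths["gene_sets"])
  jsonlite::write_json(
    list(de_genes_up = study$truth$de_genes_up,
         de_genes_down = study$truth$de_genes_down,
         modules = study$truth$modules,
         regulator_targets = as.list(study$truth$regulator_targets),
         enriched_terms = as.list(study$truth$enriched_terms)),
    paths["truth"], auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}
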