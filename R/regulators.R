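#' Filter a regulator-target table by interaction score
#'
#' Keeps rows with score >= `min_score` (boundary inclusive) and collapses
#' duplicate (regulator, target) pairs to the highest-scoring row.
#'
#' @param regulators tibble (regulator_id, class, target, score).
#' @param min_score minimum interaction score retained.
#' @return filtered tibble.
#' @export
filter_regulators <- function(regulators, min_score = 0.5) {
  if (!"score" %in% names(regulators))
    abort("regulator table has no `score` column")
  regulators |>
    filter(.data$score >= min_score) |>
    group_by(.data$regulator_id, .data$target) |>
    slice(which.max(.data$score)) |>
    ungroup()
}

#' Associate regulators with modules by hypergeometric overlap
#'
#' For each (regulator, module) pair: the overlap ("quantity") between the
#' regulator's in-background targets and the module's in-background members
#' is scored with the hypergeometric upper tail over the background
#' universe. A pair is significant when quantity > `min_quantity` (strictly;
#' i.e. at least `min_quantity + 1` shared genes) and p < `alpha`.
#'
#' @param modules a `module_set`.
#' @param regulators (filtered) regulator-target tibble.
#' @param background character vector of eligible target genes; typically
#'   the interaction-network genes.
#' @param min_quantity strict lower bound on the overlap count (default 2,
#'   i.e. quantity must exceed 2).
#' @param alpha hypergeometric p-value threshold.
#' @return tibble (regulator_id, regulator_class, module_id, quantity,
#'   p_value, significant).
#' @export
associate_regulators <- function(modules, regulators, background,
                                 min_quantity = 2, alpha = 0.01) {
  if (!length(background)) abort("background universe is empty")
  background <- unique(background)
  N <- length(background)
  reg_split <- regulators |>
    group_by(.data$regulator_id) |>
    summarise(class = .data$class[1],
              targets = list(intersect(unique(.data$target), background)))
  empty <- map_int(reg_split$targets, length) == 0
  if (any(empty)) {
    inform(sprintf("%d regulator(s) with no in-background targets skipped", sum(empty)))
    reg_split <- reg_split[!empty, ]
  }
  mod_members <- map(modules$members, intersect, background)
  rows <- pmap(reg_split, function(regulator_id, class, targets) {
    K <- length(targets)
    tibble(regulator_id = regulator_id, regulator_class = class,
           module_id = modules$module_id,
           quantity = map_int(mod_members, ~ length(intersect(targets, .x))),
           n = map_int(mod_members, length), K = K)
  })
  bind_rows(rows) |>
    filter(.data$n > 0) |>
    mutate(p_value = hypergeom_p(.data$quantity, .data$K, .data$n, N),
           significant = .data$quantity > min_quantity & .data$p_value < alpha) |>
    select("regulator_id", "regulator_class", "module_id", "quantity",
           "p_value", "significant") |>
    arrange(desc(.data$significant), .data$p_value)
}

#' Correlate a transcription factor with its target genes
#'
#' Pearson correlation across all samples with a two-sided p-value from the
#' t transform on n - 2 degrees of freedom; a pair is kept when p < `alpha`.
#' Zero-variance profiles yield an undefined r and are flagged, not kept.
#'
#' @param expr expression tibble containing the TF and targets.
#' @param tf_id TF gene id.
#' @param targets character vector of target gene ids.
#' @param alpha correlation significance threshold.
#' @return tibble (tf_id, target, r, p_value, kept, reason).
#' @export
tf_target_correlation <- function(expr, tf_id, targets, alpha = 0.05) {
  mat <- as_expr_matrix(expr)
  if (!tf_id %in% rownames(mat)) abort(paste0("TF not in expression matrix: ", tf_id))
  if (ncol(mat) < 3) abort("correlation needs at least 3 samples")
  x <- mat[tf_id, ]
  n <- length(x)
  present <- targets %in% rownames(mat)
  rows <- map(targets[present], function(tg) {
    y <- mat[tg, ]
    if (sd(x) == 0 || sd(y) == 0)
      return(tibble(tf_id = tf_id, target = tg, r = NA_real_,
                    p_value = NA_real_, kept = FALSE, reason = "zero variance"))
    r <- cor(x, y)
    p <- if (abs(r) >= 1) .Machine$double.xmin else
      2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
    tibble(tf_id = tf_id, target = tg, r = r, p_value = p,
           kept = p < alpha, reason = NA_character_)
  })
  absent <- map(targets[!present], ~ tibble(
    tf_id = tf_id, target = .x, r = NA_real_, p_value = NA_real_,
    kept = FALSE, reason = "not measured"))
  bind_rows(c(rows, absent))
}

#' Build the integrated regulator-gene-pathway network
#'
#' Expands every significant regulator-module association into regulator ->
#' gene edges over the module's members (TF edges additionally require a
#' kept expression correlation for that pair), and every retained enrichment
#' record into gene -> term edges over its overlap genes. Gene nodes carry
#' the differential-expression direction.
#'
#' @param associations output of [associate_regulators()].
#' @param modules the `module_set` the associations refer to.
#' @param correlations output of [tf_target_correlation()] (rows for every
#'   TF under consideration), or NULL to skip the TF correlation filter.
#' @param enrichments output of [enrich_modules()] (may be empty).
#' @param de per-gene table with gene_id and direction (see [tidy.deg_fit()]).
#' @return an `integrated_network`: list of `nodes` (id, type, direction)
#'   and `edges` (from, to, edge_type, module_id).
#' @export
build_integrated_network <- function(associations, modules, correlations = NULL,
                                     enrichments = NULL, de = NULL) {
  sig <- filter(associations, .data$significant)
  member_of <- setNames(modules$members, modules$module_id)
  reg_edges <- pmap(sig, function(regulator_id, regulator_class, module_id, ...) {
    genes <- setdiff(member_of[[module_id]], regulator_id)
    if (regulator_class == "TF" && !is.null(correlations)) {
      ok <- correlations |>
        filter(.data$tf_id == regulator_id, .data$kept) |> pull("target")
      genes <- intersect(genes, ok)
    }
    if (!length(genes)) return(NULL)
    tibble(from = regulator_id, to = genes,
           edge_type = paste0(regulator_class, "-gene"), module_id = module_id)
  }) |> bind_rows()
  path_edges <- if (!is.null(enrichments) && nrow(enrichments)) {
    enrichments |>
      filter(.data$category == "pathway") |>
      pmap(function(module_id, term_id, overlap_genes, ...)
        tibble(from = overlap_genes, to = term_id,
               edge_type = "gene-pathway", module_id = module_id)) |>
      bind_rows()
  } else tibble()
  edges <- bind_rows(reg_edges, path_edges)
  if (!nrow(edges)) {
    return(structure(list(nodes = tibble(id = character(), type = character(),
                                         direction = character()),
                          edges = edges), class = "integrated_network"))
  }
  reg_class <- setNames(sig$regulator_class, sig$regulator_id)
  node_ids <- unique(c(edges$from, edges$to))
  nodes <- tibble(id = node_ids) |>
    mutate(type = dplyr::case_when(
      .data$id %in% names(reg_class) ~ unname(reg_class[.data$id]),
      .data$id %in% edges$to[edges$edge_type == "gene-pathway"] ~ "pathway",
      .default = "gene"))
  if (!is.null(de))
    nodes <- left_join(nodes, select(de, id = "gene_id", "direction"), by = "id")
  else nodes$direction <- NA_character_
  structure(list(nodes = nodes, edges = edges), class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf("<integrated_network> %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(names(table(x$nodes$type)), table(x$nodes$type),
                    sep = ":", collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
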