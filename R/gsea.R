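#' Rank genes by the signal-to-noise metric
#'
#' The classic GSEA ranking statistic: (mean_case - mean_control) /
#' (sd_case + sd_control), with each group sd floored at
#' max(0.2 * |group mean|, 0.2) for stability on low-variance genes. Genes
#' are returned in descending metric order with ties broken by gene id.
#'
#' @param expr expression tibble.
#' @param labels label tibble.
#' @return tibble (gene_id, metric), descending.
#' @export
rank_genes <- function(expr, labels) {
  mat <- as_expr_matrix(expr)
  check_labels(labels, colnames(mat))
  is_case <- labels$condition[match(colnames(mat), labels$sample_id)] == "case"
  metric <- signal_to_noise(mat, is_case)
  tibble(gene_id = rownames(mat), metric = metric) |>
    arrange(desc(.data$metric), .data$gene_id)
}

signal_to_noise <- function(mat, is_case) {
  g1 <- mat[, is_case, drop = FALSE]; g0 <- mat[, !is_case, drop = FALSE]
  m1 <- rowMeans(g1); m0 <- rowMeans(g0)
  s1 <- sqrt(rowSums((g1 - m1)^2) / (ncol(g1) - 1))
  s0 <- sqrt(rowSums((g0 - m0)^2) / (ncol(g0) - 1))
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s0 <- pmax(s0, 0.2 * abs(m0), 0.2)
  unname((m1 - m0) / (s1 + s0))
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; at members of `gene_set` the running sum rises by
#' the gene's |metric|^`weight_exponent` share, at non-members it falls by
#' 1/(N - N_hit). The enrichment score is the running sum's maximum deviation
#' from zero (signed); the leading edge collects the member genes at or
#' before (after, for negative scores) the extremum.
#'
#' @param ranked tibble from [rank_genes()] (gene_id, metric, already sorted).
#' @param gene_set character vector of member genes.
#' @param weight_exponent weight on |metric| (1 = classic weighted GSEA,
#'   0 = unweighted Kolmogorov-Smirnov form).
#' @return list(es, running_sum, leading_edge, n_hits).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  hit <- ranked$gene_id %in% gene_set
  n <- length(hit); nh <- sum(hit)
  if (nh == 0) {
    warn("gene set shares no genes with the ranked list; skipped")
    return(NULL)
  }
  if (nh == n) {
    # every position a hit: the sum climbs to exactly 1
    w <- abs(ranked$metric)^weight_exponent
    if (sum(w) == 0) w <- rep(1, n)
    running <- cumsum(w / sum(w))
    return(list(es = 1, running_sum = running,
                leading_edge = ranked$gene_id, n_hits = nh))
  }
  w <- abs(ranked$metric)^weight_exponent
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1  # all-zero metrics: fall back to equal weights
  step <- ifelse(hit, w / sum(w), -1 / (n - nh))
  running <- cumsum(step)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) ranked$gene_id[hit & seq_len(n) <= i_max]
             else ranked$gene_id[hit & seq_len(n) >= i_max]
  list(es = es, running_sum = running, leading_edge = leading, n_hits = nh)
}

# add-one-corrected permutation p against same-sign null scores: with k of s
# same-sign nulls at least as extreme, p = (1 + k) / (1 + s), never exactly 0
nom_p_same_sign <- function(es, nulls) {
  same <- if (es >= 0) nulls >= 0 else nulls < 0
  (1 + sum(same & abs(nulls) >= abs(es))) / (1 + sum(same))
}

#' Gene-set enrichment analysis with permutation p-values
#'
#' Computes the enrichment score of every gene set against the case/control
#' signal-to-noise ranking, then a nominal permutation p-value: the null ES
#' distribution comes from relabeling phenotypes (recomputing the ranking
#' each time), or from size-matched random gene sets when the cohort admits
#' fewer distinct relabelings than `n_perm` (or on request). The p-value uses
#' the add-one correction restricted to same-sign nulls, so it is never 0.
#'
#' @param expr expression tibble.
#' @param labels label tibble.
#' @param gene_sets gene-set collection tibble (see [read_gmt()]).
#' @param n_perm permutations (>= 10).
#' @param mode "auto" (phenotype, falling back to gene_set), "phenotype", or
#'   "gene_set".
#' @param weight_exponent see [enrichment_score()].
#' @param seed integer seed for the permutations.
#' @return a `gsea_result` tibble: term_id, category, n_hits, es, nom_p,
#'   n_perm_used, leading_edge (list-column).
#' @export
gsea_test <- function(expr, labels, gene_sets, n_perm = 1000,
                      mode = c("auto", "phenotype", "gene_set"),
                      weight_exponent = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 10) abort("n_perm must be at least 10")
  mat <- as_expr_matrix(expr)
  check_labels(labels, colnames(mat))
  is_case <- labels$condition[match(colnames(mat), labels$sample_id)] == "case"
  n_distinct_perm <- choose(ncol(mat), sum(is_case))
  if (mode %in% c("auto", "phenotype") && n_distinct_perm < n_perm) {
    inform(sprintf(
      "only %d distinct phenotype permutations (< n_perm = %d); using gene_set mode",
      n_distinct_perm, n_perm))
    mode <- "gene_set"
  } else if (mode == "auto") {
    mode <- "phenotype"
  }

  observed <- rank_genes(expr, labels)
  obs <- map(gene_sets$genes, ~ suppressWarnings(
    enrichment_score(observed, .x, weight_exponent)))
  keep <- !map_lgl(obs, is.null)
  if (!all(keep))
    inform(sprintf("%d gene set(s) disjoint from the ranked list; skipped",
                   sum(!keep)))
  gene_sets <- gene_sets[keep, ]; obs <- obs[keep]

  set.seed(seed)
  n_sets <- nrow(gene_sets)
  null_es <- matrix(NA_real_, nrow = n_perm, ncol = n_sets)
  if (mode == "phenotype") {
    for (p in seq_len(n_perm)) {
      perm_case <- seq_along(is_case) %in% sample(length(is_case), sum(is_case))
      metric <- signal_to_noise(mat, perm_case)
      ord <- order(-metric, rownames(mat))
      ranked_p <- tibble(gene_id = rownames(mat)[ord], metric = metric[ord])
      null_es[p, ] <- map_dbl(gene_sets$genes, ~
        enrichment_score(ranked_p, .x, weight_exponent)$es)
    }
  } else {
    universe <- observed$gene_id
    for (s in seq_len(n_sets)) {
      size <- obs[[s]]$n_hits
      null_es[, s] <- vapply(seq_len(n_perm), function(p)
        enrichment_score(observed, resample(universe, size),
                         weight_exponent)$es, numeric(1))
    }
  }

  nom_p <- vapply(seq_len(n_sets), function(s)
    nom_p_same_sign(obs[[s]]$es, null_es[, s]), numeric(1))

  structure(
    tibble(term_id = gene_sets$term_id, category = gene_sets$category,
           n_hits = map_int(obs, ~ .x$n_hits),
           es = map_dbl(obs, ~ .x$es), nom_p = nom_p,
           n_perm_used = n_perm, mode = mode,
           leading_edge = map(obs, ~ .x$leading_edge)),
    class = c("gsea_result", class(tibble())))
}
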