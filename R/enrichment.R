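#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of at least k hits
#' when drawing n genes from a universe of N containing K annotated ones.
#' Vectorized; computed via [stats::phyper()] (stable log-space tails).
#'
#' @param k observed overlap.
#' @param K annotated (term / target) genes in the universe.
#' @param n drawn genes (module size in the universe).
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & N >= 0 & k <= n & n <= N & K <= N &
    k <= pmin(K, n) + 0 # k cannot exceed either margin
  if (!all(ok)) abort("inconsistent hypergeometric counts: need 0 <= k <= min(K, n), n <= N, K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Module over-representation against a gene-set collection
#'
#' One hypergeometric upper-tail test per (module, term) pair with nonzero
#' overlap; BH adjustment is applied within each module and category (GO
#' categories separately; the pathway collection on its own); records must
#' clear their category's p and q cutoffs to be reported. GO-style
#' categories (BP/CC/MF) use `go_p`/`go_q`; "pathway" uses
#' `kegg_p`/`kegg_q`.
#'
#' @param modules a `module_set` (or tibble with module_id + members list).
#' @param gene_sets gene-set collection tibble.
#' @param background universe of genes; default: every gene annotated to at
#'   least one set in the collection.
#' @param go_p,go_q cutoffs for GO categories.
#' @param kegg_p,kegg_q cutoffs for the pathway category.
#' @return tibble of enrichment records (module_id, term_id, term_name,
#'   category, k, K, n, N, p_value, q_value, overlap_genes), sorted by
#'   p-value within module.
#' @export
enrich_modules <- function(modules, gene_sets, background = NULL,
                           go_p = 0.01, go_q = 0.01,
                           kegg_p = 0.05, kegg_q = 0.2) {
  if (is.null(background)) background <- unique(unlist(gene_sets$genes))
  if (!length(background)) abort("background universe is empty")
  N <- length(background)
  term_genes <- map(gene_sets$genes, intersect, background)
  skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(modules))) {
    mod_bg <- intersect(modules$members[[i]], background)
    n <- length(mod_bg)
    if (!n) next
    for (j in seq_len(nrow(gene_sets))) {
      ov <- intersect(mod_bg, term_genes[[j]])
      if (!length(ov)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1]] <- tibble(
        module_id = modules$module_id[i],
        term_id = gene_sets$term_id[j], term_name = gene_sets$term_name[j],
        category = gene_sets$category[j],
        k = length(ov), K = length(term_genes[[j]]), n = n, N = N,
        p_value = hypergeom_p(length(ov), length(term_genes[[j]]), n, N),
        overlap_genes = list(sort(ov)))
    }
  }
  if (skipped) inform(sprintf("%d (module, term) pairs with zero overlap not tested", skipped))
  if (!length(rows)) return(tibble())
  bind_rows(rows) |>
    group_by(.data$module_id, .data$category) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    mutate(p_cut = if_else(.data$category == "pathway", kegg_p, go_p),
           q_cut = if_else(.data$category == "pathway", kegg_q, go_q)) |>
    filter(.data$p_value < .data$p_cut, .data$q_value < .data$q_cut) |>
    select(-"p_cut", -"q_cut") |>
    arrange(.data$module_id, .data$p_value)
}
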