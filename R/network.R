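#' Build the score-weighted DEG interaction network
#'
#' Restricts a scored edge list to pairs where both genes are differentially
#' expressed and the interaction score clears `min_score` (0.4, the usual
#' medium-confidence convention, by default). Duplicate A-B/B-A rows collapse
#' to the maximum score; self-loops are dropped; genes left without any edge
#' are dropped with a message. Nodes carry logFC, p-value, unweighted degree
#' and the W hub score.
#'
#' @param degs DEG table with gene_id, logFC, p_value (e.g. [select_degs()]).
#' @param edges edge tibble (gene_a, gene_b, score).
#' @param min_score minimum interaction score kept.
#' @return a `deg_network`: list of `nodes` and `edges` tibbles.
#' @export
build_network <- function(degs, edges, min_score = 0.4) {
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edges)))
    abort(paste0("edge table must have columns: ", paste(need, collapse = ", ")))
  deg_ids <- unique(degs$gene_id)
  n_in <- nrow(edges)
  edges <- edges |>
    filter(.data$gene_a != .data$gene_b,
           .data$gene_a %in% deg_ids, .data$gene_b %in% deg_ids,
           .data$score >= min_score) |>
    mutate(a = pmin(.data$gene_a, .data$gene_b),
           b = pmax(.data$gene_a, .data$gene_b))
  edges <- if (nrow(edges)) {
    edges |>
      group_by(.data$a, .data$b) |>
      summarise(score = max(.data$score), .groups = "drop") |>
      select(gene_a = "a", gene_b = "b", "score") |>
      arrange(.data$gene_a, .data$gene_b)
  } else {
    tibble(gene_a = character(), gene_b = character(), score = numeric())
  }
  if (n_in - nrow(edges) > 0)
    inform(sprintf("kept %d of %d edges (DEG endpoints, score >= %s, deduplicated)",
                   nrow(edges), n_in, format(min_score)))
  connected <- union(edges$gene_a, edges$gene_b)
  dropped <- setdiff(deg_ids, connected)
  if (length(dropped))
    inform(sprintf("dropped %d isolated DEG(s)", length(dropped)))
  deg_counts <- table(c(edges$gene_a, edges$gene_b))
  nodes <- degs |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    filter(.data$gene_id %in% connected) |>
    mutate(degree = as.integer(deg_counts[.data$gene_id]),
           w_score = w_score(.data$logFC, .data$p_value, .data$degree)) |>
    select("gene_id", "logFC", "p_value", "degree", "w_score") |>
    arrange(.data$gene_id)
  structure(list(nodes = nodes, edges = edges), class = "deg_network")
}

#' @export
print.deg_network <- function(x, ...) {
  cat(sprintf("<deg_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(head(x$nodes))
  invisible(x)
}

#' @method tidy deg_network
#' @export
tidy.deg_network <- function(x, ...) x$nodes

#' @method glance deg_network
#' @export
glance.deg_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         mean_degree = mean(x$nodes$degree),
         max_w = max(x$nodes$w_score))
}

#' The W hub score
#'
#' W = |logFC| * (-log10 p) * degree: a node is hub-like when it is strongly
#' and confidently differentially expressed and highly connected. Vectorized.
#' Nonpositive p-values are floored at the smallest positive double, with a
#' warning.
#'
#' @param logFC log2 fold change.
#' @param p_value differential-expression p-value in (0, 1].
#' @param degree node degree (incident edge count).
#' @return numeric W >= 0; 0 exactly when p = 1, logFC = 0 or degree = 0.
#' @export
w_score <- function(logFC, p_value, degree) {
  if (any(p_value <= 0)) {
    warn("p_value <= 0 floored at the smallest positive double")
    p_value <- pmax(p_value, .Machine$double.xmin)
  }
  if (any(degree < 0)) abort("degree must be nonnegative")
  abs(logFC) * (-log10(p_value)) * degree
}

#' Rank hub genes by W
#'
#' Descending W; ties broken by degree (descending) then gene id, so the
#' ranking is deterministic.
#'
#' @param network a `deg_network`.
#' @param top_n hubs to return.
#' @return tibble of the top `top_n` node rows.
#' @export
rank_hubs <- function(network, top_n = 10) {
  if (!nrow(network$nodes)) abort("network has no nodes")
  network$nodes |>
    arrange(desc(.data$w_score), desc(.data$degree), .data$gene_id) |>
    head(top_n)
}

#' Convert / export a network
#'
#' @param network a `deg_network` (or an integrated network; any list with
#'   nodes/edges tibbles whose first two edge columns are endpoints).
#' @return `as_igraph()`: an igraph object with node and edge attributes.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' @rdname as_igraph
#' @param path output path.
#' @param format "sif" (tab-separated source / interaction / target) or
#'   "graphml".
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    e <- network$edges
    writeLines(paste(e[[1]], "interacts", e[[2]], sep = "\t"), path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}
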