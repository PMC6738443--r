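# adjacency-list view of a network, used by the miner
mod_graph <- function(x) {
  if (inherits(x, "mod_graph")) return(x)
  edges <- if (inherits(x, "deg_network")) x$edges else x
  if (!all(c("gene_a", "gene_b") %in% names(edges)))
    abort("need a deg_network or an edge table with gene_a/gene_b")
  w <- if ("score" %in% names(edges)) edges$score else
       if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  nodes <- sort(union(edges$gene_a, edges$gene_b))
  if (inherits(x, "deg_network")) nodes <- sort(union(nodes, x$nodes$gene_id))
  adj <- setNames(vector("list", length(nodes)), nodes)
  both <- c(edges$gene_a, edges$gene_b)
  other <- c(edges$gene_b, edges$gene_a)
  ww <- c(w, w)
  idx <- split(seq_along(both), both)
  for (nd in names(idx))
    adj[[nd]] <- setNames(ww[idx[[nd]]], other[idx[[nd]]])
  structure(list(adj = adj, nodes = nodes,
                 strength = vapply(adj, function(a) sum(a %||% 0), numeric(1)),
                 degree = vapply(adj, length, integer(1))),
            class = "mod_graph")
}

#' Cohesiveness of a vertex set
#'
#' The ClusterONE objective f(V) = w_in / (w_in + w_bound + penalty): the
#' total internal edge weight over internal plus boundary weight plus a
#' penalty term that damps tiny sets. f is in [0, 1] and reaches 1 only for a
#' fully internal (isolated) set at penalty 0.
#'
#' @param network a `deg_network` or an edge tibble (gene_a, gene_b, score).
#' @param members nonempty character vector of member nodes.
#' @param penalty nonnegative penalty weight (ClusterONE convention: 2).
#' @return scalar cohesiveness.
#' @export
cohesiveness <- function(network, members, penalty = 2) {
  if (!length(members)) abort("members must be nonempty")
  g <- mod_graph(network)
  if (!all(members %in% g$nodes)) abort("members must be nodes of the network")
  inside <- g$nodes %in% members
  names(inside) <- g$nodes
  w_in <- 0; w_bound <- 0
  for (v in members) {
    a <- g$adj[[v]]
    if (is.null(a)) next
    int <- inside[names(a)]
    w_in <- w_in + sum(a[int])
    w_bound <- w_bound + sum(a[!int])
  }
  w_in <- w_in / 2 # each internal edge visited from both ends
  if (w_in + w_bound + penalty == 0) return(0)
  w_in / (w_in + w_bound + penalty)
}

#' Grow one cohesive module from a seed node
#'
#' Greedy local search on f(V): from {seed}, repeatedly apply the single
#' node addition (an outside node adjacent to V) or removal (an inside node)
#' that most increases cohesiveness, until no move improves it. Ties are
#' broken toward the lexicographically smallest node id, so growth is
#' deterministic. Every accepted step strictly increases f.
#'
#' @inheritParams cohesiveness
#' @param seed_node starting node id.
#' @return list(members, cohesiveness, size).
#' @export
grow_module <- function(network, seed_node, penalty = 2) {
  g <- mod_graph(network)
  if (!seed_node %in% g$nodes) abort("seed_node is not in the network")
  eps <- 1e-12
  in_v <- setNames(logical(length(g$nodes)), g$nodes)
  in_v[seed_node] <- TRUE
  # s_v[u] = total edge weight between u and the current set V
  s_v <- setNames(numeric(length(g$nodes)), g$nodes)
  a <- g$adj[[seed_node]]
  if (!is.null(a)) s_v[names(a)] <- a
  w_in <- 0; w_bound <- g$strength[[seed_node]]
  f <- function(wi, wb) if (wi + wb + penalty == 0) 0 else wi / (wi + wb + penalty)
  f_cur <- f(w_in, w_bound)

  repeat {
    adds <- names(which(!in_v & s_v > 0))
    rems <- if (sum(in_v) > 1) names(which(in_v)) else character()
    if (!length(adds) && !length(rems)) break
    cand <- character(); new_f <- numeric(); kind <- character()
    if (length(adds)) {
      wi <- w_in + s_v[adds]
      wb <- w_bound - s_v[adds] + (g$strength[adds] - s_v[adds])
      cand <- c(cand, adds); new_f <- c(new_f, wi / (wi + wb + penalty))
      kind <- c(kind, rep("add", length(adds)))
    }
    if (length(rems)) {
      wi <- w_in - s_v[rems]
      wb <- w_bound + s_v[rems] - (g$strength[rems] - s_v[rems])
      cand <- c(cand, rems); new_f <- c(new_f, wi / (wi + wb + penalty))
      kind <- c(kind, rep("remove", length(rems)))
    }
    best <- max(new_f)
    if (best <= f_cur + eps) break
    pick <- which(new_f >= best - eps)
    pick <- pick[order(cand[pick])][1] # lexicographic tie-break
    node <- cand[pick]
    nb <- g$adj[[node]]
    if (kind[pick] == "add") {
      w_in <- w_in + s_v[[node]]
      w_bound <- w_bound - s_v[[node]] + (g$strength[[node]] - s_v[[node]])
      in_v[node] <- TRUE
      if (!is.null(nb)) s_v[names(nb)] <- s_v[names(nb)] + nb
    } else {
      w_in <- w_in - s_v[[node]]
      w_bound <- w_bound + s_v[[node]] - (g$strength[[node]] - s_v[[node]])
      in_v[node] <- FALSE
      if (!is.null(nb)) s_v[names(nb)] <- s_v[names(nb)] - nb
    }
    f_new <- f(w_in, w_bound)
    stopifnot(f_new > f_cur) # accepted moves must strictly improve f
    f_cur <- f_new
  }
  members <- sort(names(which(in_v)))
  list(members = members, cohesiveness = f_cur, size = length(members))
}

#' Pairwise module overlap score
#'
#' The match coefficient omega(A, B) = |A n B|^2 / (|A| |B|); 1 for identical
#' sets, 0 for disjoint ones. Used to merge near-duplicate modules.
#'
#' @param a,b character vectors.
#' @return scalar in [0, 1].
#' @export
overlap_score <- function(a, b) {
  length(intersect(a, b))^2 / (length(unique(a)) * length(unique(b)))
}

internal_density <- function(g, members) {
  if (length(members) < 2) return(0)
  inside <- setNames(g$nodes %in% members, g$nodes)
  n_int <- sum(vapply(members, function(v) {
    a <- g$adj[[v]]
    if (is.null(a)) 0L else sum(inside[names(a)])
  }, integer(1))) / 2
  n_int / choose(length(members), 2)
}

#' Detect overlapping cohesive modules
#'
#' ClusterONE-style mining: grow a module greedily ([grow_module()]) from
#' each node in descending degree order that is not yet covered by an earlier
#' module; discard candidates smaller than `min_size` or with internal
#' (unweighted) edge density below `min_density`; then repeatedly merge the
#' pair with the largest overlap score >= `merge_threshold` (the union is
#' rescored) until no pair qualifies.
#'
#' @inheritParams cohesiveness
#' @param min_size smallest module reported.
#' @param min_density minimum internal edge density.
#' @param merge_threshold overlap score at or above which modules merge.
#' @return a `module_set` tibble: module_id, size, density, cohesiveness,
#'   members (list-column), sorted by cohesiveness descending.
#' @export
detect_modules <- function(network, penalty = 2, min_size = 3,
                           min_density = 0.5, merge_threshold = 0.8) {
  g <- mod_graph(network)
  if (!length(g$nodes)) abort("network has no nodes")
  seeds <- g$nodes[order(-g$degree, g$nodes)]
  keep <- function(m) m$size >= min_size &&
    internal_density(g, m$members) >= min_density
  covered <- character()
  mods <- list()
  for (s in seeds) {
    if (s %in% covered) next
    m <- grow_module(g, s, penalty)
    if (keep(m)) {
      # only reported modules claim coverage; a rejected growth (e.g. a
      # sparse blob absorbed from a background hub) consumes just its seed,
      # so genuine modules behind it still get grown
      covered <- union(covered, m$members)
      mods[[length(mods) + 1]] <- m
    } else {
      covered <- union(covered, s)
    }
  }
  # merge highly overlapping modules to a fixpoint
  repeat {
    if (length(mods) < 2) break
    best <- c(0, 0); best_w <- -Inf
    for (i in seq_len(length(mods) - 1)) for (j in seq(i + 1, length(mods))) {
      w <- overlap_score(mods[[i]]$members, mods[[j]]$members)
      if (w > best_w) { best_w <- w; best <- c(i, j) }
    }
    if (best_w < merge_threshold) break
    u <- sort(union(mods[[best[1]]]$members, mods[[best[2]]]$members))
    mods[[best[1]]] <- list(members = u,
                            cohesiveness = cohesiveness(g, u, penalty),
                            size = length(u))
    mods[[best[2]]] <- NULL
  }
  mods <- purrr::keep(mods, keep)
  out <- tibble(
    members = map(mods, "members"),
    size = map_int(mods, "size"),
    density = map_dbl(mods, ~ internal_density(g, .x$members)),
    cohesiveness = map_dbl(mods, "cohesiveness")) |>
    arrange(desc(.data$cohesiveness), desc(.data$size)) |>
    mutate(module_id = sprintf("M%02d", row_number())) |>
    select("module_id", "size", "density", "cohesiveness", "members")
  structure(out, class = c("module_set", class(tibble())))
}

#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble(n_modules = nrow(x), n_genes = length(unique(unlist(x$members))),
         mean_size = mean(x$size), mean_cohesiveness = mean(x$cohesiveness))
}

#' Flat module membership table
#'
#' @param x a `module_set`.
#' @param ... unused.
#' @return tibble (module_id, gene_id), one row per membership.
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  tidyr::unnest(select(as_tibble(x), "module_id", gene_id = "members"),
                "gene_id")
}
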