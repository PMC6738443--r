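#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same distribution of values: the
#' per-rank cross-sample means. Delegates to [limma::normalizeQuantiles()],
#' the standard microarray route. Idempotent; gene and sample ids are
#' preserved.
#'
#' @param expr expression tibble (gene_id + one column per sample).
#' @return expression tibble of the same shape.
#' @export
quantile_normalize <- function(expr) {
  mat <- as_expr_matrix(expr)
  if (ncol(mat) < 2) abort("quantile normalization needs at least 2 samples")
  as_expr_tibble(limma::normalizeQuantiles(mat))
}

#' Differential expression with a moderated t statistic
#'
#' Fits the case-vs-control contrast per gene. With `moderated = TRUE`
#' (default) the per-gene variances are shrunk toward a common prior by
#' empirical Bayes ([limma::lmFit()] + [limma::eBayes()]), giving the
#' moderated t with `df_residual + df_prior` degrees of freedom; this keeps
#' statistics finite even for near-constant genes. With `moderated = FALSE`
#' the ordinary pooled two-sample t is computed (the prior-df-to-zero limit),
#' useful as a closed-form reference. logFC is case minus control in log2
#' units. p-values are two-sided; BH adjustment spans all genes.
#'
#' @param expr expression tibble.
#' @param labels label tibble (sample_id, condition in case/control).
#' @param moderated shrink variances via empirical Bayes?
#' @return a `deg_fit` object; see [tidy.deg_fit()].
#' @export
fit_differential <- function(expr, labels, moderated = TRUE) {
  mat <- as_expr_matrix(expr)
  check_labels(labels, colnames(mat))
  labels <- labels[match(colnames(mat), labels$sample_id), ]
  is_case <- labels$condition == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 + n0 < 3) abort("zero residual degrees of freedom: need n_case + n_control >= 3")

  if (moderated) {
    design <- cbind(intercept = 1, case = as.numeric(is_case))
    fit <- limma::eBayes(limma::lmFit(mat, design))
    tab <- tibble(gene_id = rownames(mat),
                  logFC = unname(fit$coefficients[, "case"]),
                  t = unname(fit$t[, "case"]),
                  p_value = unname(fit$p.value[, "case"]),
                  adj_p = unname(p.adjust(fit$p.value[, "case"], method = "BH")))
    df_prior <- fit$df.prior; s2_prior <- fit$s2.prior
    df_residual <- unname(fit$df.residual[1])
  } else {
    m1 <- rowMeans(mat[, is_case, drop = FALSE])
    m0 <- rowMeans(mat[, !is_case, drop = FALSE])
    v1 <- apply(mat[, is_case, drop = FALSE], 1, stats::var)
    v0 <- apply(mat[, !is_case, drop = FALSE], 1, stats::var)
    df_residual <- n1 + n0 - 2
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df_residual
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    t_stat <- (m1 - m0) / se
    t_stat[se == 0 & m1 == m0] <- 0
    p <- 2 * pt(-abs(t_stat), df_residual)
    p <- pmax(p, .Machine$double.xmin)
    tab <- tibble(gene_id = rownames(mat), logFC = unname(m1 - m0),
                  t = unname(t_stat), p_value = unname(p),
                  adj_p = unname(p.adjust(p, method = "BH")))
    df_prior <- 0; s2_prior <- NA_real_
  }
  structure(list(table = tab, moderated = moderated,
                 df_residual = df_residual, df_prior = df_prior,
                 s2_prior = s2_prior, n_case = n1, n_control = n0),
            class = "deg_fit")
}

#' @export
print.deg_fit <- function(x, ...) {
  cat(sprintf("<deg_fit> %d genes, %d case vs %d control, %s t (df = %s)\n",
              nrow(x$table), x$n_case, x$n_control,
              if (x$moderated) "moderated" else "ordinary",
              format(x$df_residual + x$df_prior, digits = 4)))
  print(head(x$table))
  invisible(x)
}

#' Tidy and summarize a differential-expression fit
#'
#' `tidy()` returns the per-gene table with a `direction` call (up / down /
#' ns) at the unadjusted `alpha`; `glance()` one row of fit-level summaries.
#'
#' @param x a `deg_fit`.
#' @param alpha unadjusted p-value threshold for the direction call.
#' @param ... unused.
#' @method tidy deg_fit
#' @export
tidy.deg_fit <- function(x, alpha = 0.05, ...) {
  mutate(x$table, direction = dplyr::case_when(
    .data$p_value < alpha & .data$logFC > 0 ~ "up",
    .data$p_value < alpha & .data$logFC < 0 ~ "down",
    .default = "ns"))
}

#' @rdname tidy.deg_fit
#' @method glance deg_fit
#' @export
glance.deg_fit <- function(x, alpha = 0.05, ...) {
  d <- tidy(x, alpha = alpha)
  tibble(n_genes = nrow(d), n_up = sum(d$direction == "up"),
         n_down = sum(d$direction == "down"),
         df_residual = x$df_residual, df_prior = x$df_prior,
         moderated = x$moderated)
}

#' Call differentially expressed genes
#'
#' Partitions genes by the unadjusted p-value threshold and the sign of
#' logFC, following the common practice for small cohorts where an FDR
#' threshold can be too conservative.
#'
#' @param fit a `deg_fit` (or an already-tidied per-gene tibble).
#' @param alpha unadjusted p-value threshold.
#' @return tibble of significant genes (gene_id, logFC, t, p_value, adj_p,
#'   direction), logFC-magnitude sorted within direction.
#' @export
select_degs <- function(fit, alpha = 0.05) {
  d <- if (inherits(fit, "deg_fit")) tidy(fit, alpha = alpha) else
    mutate(fit, direction = dplyr::case_when(
      .data$p_value < alpha & .data$logFC > 0 ~ "up",
      .data$p_value < alpha & .data$logFC < 0 ~ "down",
      .default = "ns"))
  out <- d |> filter(.data$direction != "ns") |>
    arrange(.data$direction, desc(abs(.data$logFC)))
  inform(sprintf("%d DEGs at p < %s: %d up, %d down",
                 nrow(out), format(alpha), sum(out$direction == "up"),
                 sum(out$direction == "down")))
  out
}

#' Two-way hierarchical clustering of the top differentially expressed genes
#'
#' Selects the `k` most up- and `k` most down-regulated significant genes
#' (ranked by logFC magnitude) and clusters both genes and samples
#' agglomeratively with Euclidean distance and average linkage.
#'
#' @param fit a `deg_fit`.
#' @param expr the expression tibble the fit came from.
#' @param k genes to take per direction (all available, with a warning, if
#'   fewer exist).
#' @param alpha significance threshold for eligibility.
#' @return a `deg_cluster` list: `genes` (selected ids), `gene_order` and
#'   `sample_order` (dendrogram leaf orders), and the two `hclust` trees.
#' @export
top_deg_cluster <- function(fit, expr, k = 100, alpha = 0.05) {
  d <- tidy(fit, alpha = alpha)
  up <- d |> filter(.data$direction == "up") |> arrange(desc(.data$logFC))
  down <- d |> filter(.data$direction == "down") |> arrange(.data$logFC)
  if (nrow(up) == 0 && nrow(down) == 0) {
    warn("no significant genes; empty selection")
    return(structure(list(genes = character(), gene_order = character(),
                          sample_order = character(), gene_tree = NULL,
                          sample_tree = NULL), class = "deg_cluster"))
  }
  if (nrow(up) < k || nrow(down) < k)
    warn(sprintf("fewer than k = %d DEGs in a direction (%d up, %d down); taking all",
                 k, nrow(up), nrow(down)))
  genes <- c(head(up$gene_id, k), head(down$gene_id, k))
  mat <- as_expr_matrix(expr)[genes, , drop = FALSE]
  gene_tree <- hclust(dist(mat), method = "average")
  sample_tree <- hclust(dist(t(mat)), method = "average")
  structure(list(genes = genes,
                 gene_order = rownames(mat)[gene_tree$order],
                 sample_order = colnames(mat)[sample_tree$order],
                 gene_tree = gene_tree, sample_tree = sample_tree),
            class = "deg_cluster")
}
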