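#' Validate gene panels in an independent cohort
#'
#' Re-tests a list of genes (hub genes, TFs) in a second expression set with
#' the same moderated t contrast used in discovery, and flags each gene as
#' consistent when it is significant at `alpha` with the same direction of
#' change as in the reference. Genes absent from the validation matrix are
#' reported untestable.
#'
#' @param expr validation expression tibble.
#' @param labels validation label tibble.
#' @param genes character vector of genes to validate.
#' @param reference reference directions: named character vector ("up" /
#'   "down") or a tibble with gene_id and direction.
#' @param alpha unadjusted significance threshold.
#' @param moderated use the moderated t (default) or the ordinary pooled t.
#' @return tibble (gene_id, logFC, p_value, reference_direction, tested,
#'   consistent).
#' @export
validate_genes <- function(expr, labels, genes, reference, alpha = 0.05,
                           moderated = TRUE) {
  if (!length(genes)) abort("gene list is empty")
  if (is.data.frame(reference))
    reference <- setNames(reference$direction, reference$gene_id)
  fit <- fit_differential(expr, labels, moderated = moderated)
  tab <- fit$table
  tibble(gene_id = genes) |>
    left_join(select(tab, "gene_id", "logFC", "p_value"), by = "gene_id") |>
    mutate(reference_direction = unname(reference[.data$gene_id]),
           tested = !is.na(.data$p_value),
           consistent = .data$tested & .data$p_value < alpha &
             if_else(.data$reference_direction == "up",
                     .data$logFC > 0, .data$logFC < 0))
}

#' ROC curve and AUC for one gene
#'
#' Scores samples by expression with the fixed orientation "higher value
#' predicts case". The AUC is the Mann-Whitney rank statistic U / (n_case *
#' n_control) with ties counted 1/2, which equals the trapezoidal area under
#' the threshold-sweep curve; an AUC below 0.5 is reported as-is unless
#' `auto_direction = TRUE`, which applies the max(auc, 1 - auc) convention.
#'
#' @param values numeric per-sample scores (expression of one gene).
#' @param labels per-sample condition ("case"/"control"), or a label tibble
#'   when `values` is named by sample id.
#' @param auto_direction report max(auc, 1 - auc)?
#' @return a `roc_result`: auc, n_case, n_control, curve (fpr, tpr,
#'   threshold tibble).
#' @export
roc_auc <- function(values, labels, auto_direction = FALSE) {
  if (is.data.frame(labels)) {
    labels <- labels$condition[match(names(values), labels$sample_id)]
  }
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) abort("both conditions must be present")
  if (auto_direction) {
    r <- roc_auc(values, ifelse(is_case, "case", "control"))
    if (r$auc < 0.5) r <- roc_auc(-values, ifelse(is_case, "case", "control"))
    return(r)
  }
  rk <- rank(values) # average ranks: ties count 1/2
  auc <- (sum(rk[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # threshold sweep, one step per distinct value, descending
  thr <- sort(unique(values), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(values >= t & is_case), numeric(1))
  fp <- vapply(thr, function(t) sum(values >= t & !is_case), numeric(1))
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fp / n0),
                  tpr = c(0, tp / n1))
  structure(list(auc = auc, n_case = n1, n_control = n0, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d case vs %d control)\n",
              x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_case = x$n_case, n_control = x$n_control)
}

#' Per-gene AUC table
#'
#' @param expr expression tibble.
#' @param labels label tibble.
#' @param genes genes to score (default: all).
#' @param auto_direction see [roc_auc()].
#' @return tibble (gene_id, auc, n_case, n_control).
#' @export
roc_table <- function(expr, labels, genes = NULL, auto_direction = FALSE) {
  mat <- as_expr_matrix(expr)
  genes <- genes %||% rownames(mat)
  genes <- intersect(genes, rownames(mat))
  cond <- labels$condition[match(colnames(mat), labels$sample_id)]
  bind_rows(map(genes, function(g) {
    r <- roc_auc(mat[g, ], cond, auto_direction = auto_direction)
    tibble(gene_id = g, auc = r$auc, n_case = r$n_case, n_control = r$n_control)
  }))
}
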