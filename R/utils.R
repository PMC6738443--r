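# Internal conventions:
#   expression table  : tibble, first column `gene_id`, one numeric column per sample
#   label table       : tibble with `sample_id`, `condition` in {"case","control"}

as_expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (!is.numeric(m)) abort("expression columns must be numeric")
  rownames(m) <- expr$gene_id
  m
}

as_expr_tibble <- function(mat) {
  tibble(gene_id = rownames(mat)) |> bind_cols(as_tibble(mat))
}

check_labels <- function(labels, sample_ids = NULL) {
  if (!is.data.frame(labels) || !all(c("sample_id", "condition") %in% names(labels)))
    abort("labels must be a data frame with columns sample_id and condition")
  bad <- setdiff(unique(labels$condition), c("case", "control"))
  if (length(bad))
    abort(paste0("condition must be 'case' or 'control'; found: ",
                 paste(bad, collapse = ", ")))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, labels$sample_id)
    if (length(missing))
      abort(paste0("samples missing from labels: ", paste(head(missing, 5), collapse = ", ")))
  }
  tab <- table(labels$condition)
  if (length(tab) < 2 || any(tab < 2))
    abort("both conditions must be present with at least 2 samples each")
  invisible(labels)
}

group_ids <- function(labels) {
  list(case    = labels$sample_id[labels$condition == "case"],
       control = labels$sample_id[labels$condition == "control"])
}

# canonical undirected pair key (lexicographically ordered endpoints)
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

`%||%` <- rlang::`%||%`

# sample() that never auto-expands a length-1 vector into 1:x
resample <- function(x, size = length(x), ...) x[sample.int(length(x), size, ...)]
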