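#' Read an expression matrix, labels, edge or regulator table from TSV
#'
#' `read_expression()` drops genes with any missing value (with a message
#' giving the count) and enforces unique gene and sample ids.
#'
#' @param path file path.
#' @return a tibble in the package's respective table shape.
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(expr)[1] != "gene_id") names(expr)[1] <- "gene_id"
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene ids in expression table")
  complete <- stats::complete.cases(expr)
  if (any(!complete)) {
    inform(sprintf("dropped %d gene(s) with missing values", sum(!complete)))
    expr <- expr[complete, ]
  }
  expr
}

#' @rdname read_expression
#' @export
read_labels <- function(path) {
  labels <- readr::read_tsv(path, show_col_types = FALSE)
  check_labels(labels)
  labels
}

#' @rdname read_expression
#' @export
read_edges <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edges)))
    abort(paste0("edge table must have columns: ", paste(need, collapse = ", ")))
  edges
}

#' @rdname read_expression
#' @export
read_regulators <- function(path) {
  reg <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("regulator_id", "class", "target", "score")
  if (!all(need %in% names(reg)))
    abort(paste0("regulator table must have columns: ", paste(need, collapse = ", ")))
  reg
}

#' Read and write gene-set collections in GMT format
#'
#' GMT is the tab-separated gene-set format: set name, description, then the
#' member genes. The description field stores the category (BP/CC/MF/pathway)
#' so collections round-trip. Reading of memberships is delegated to
#' [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return `read_gmt()`: a gene-set collection tibble (term_id, term_name,
#'   category, genes list-column).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(fields, function(f) f[2], character(1))
  names(desc) <- vapply(fields, function(f) f[1], character(1))
  meta <- strsplit(unname(desc[names(sets)]), "|", fixed = TRUE)
  tibble(term_id = names(sets),
         term_name = vapply(meta, function(m) if (length(m) > 1) m[2] else m[1],
                            character(1)),
         category = vapply(meta, function(m) m[1], character(1)),
         genes = unname(sets))
}

#' @rdname read_gmt
#' @param collection a gene-set collection tibble.
#' @export
write_gmt <- function(collection, path) {
  lines <- pmap(collection, function(term_id, term_name, category, genes, ...)
    paste(c(term_id, paste(category, term_name, sep = "|"), genes),
          collapse = "\t"))
  writeLines(unlist(lines), path)
  invisible(path)
}
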