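#' Gene expression matrix with sample roles and batch labels
#'
#' The central data container of the package: a genes x samples matrix of
#' log2-scale expression values, together with a role (`"patient"` or
#' `"cell-line"`) and a batch label for every sample. All clustering and
#' batch-correction steps operate on this container; deconvolution converts
#' to the linear scale internally.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values are log2-scale and
#'   must be finite.
#' @param role Character vector, one entry per sample, typically
#'   `"patient"` or `"cell-line"`.
#' @param batch Character vector, one batch label per sample.
#' @return An object of class `expr_mat`: a list with elements `values`,
#'   `role` and `batch` (the latter two named by sample id).
#' @export
expression_matrix <- function(values, role, batch) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_bad_arg("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(rownames(values) == ""))
    stop_bad_arg("every gene must have a non-missing id (rownames)")
  if (is.null(colnames(values)))
    stop_bad_arg("samples must have ids (colnames)")
  if (!all(is.finite(values)))
    stop_bad_arg("expression values must be finite")
  n <- ncol(values)
  if (length(role) == 1L) role <- rep(role, n)
  if (length(batch) == 1L) batch <- rep(batch, n)
  if (length(role) != n || length(batch) != n || anyNA(role) || anyNA(batch))
    stop_bad_arg("role and batch must be defined for every sample")
  role <- stats::setNames(as.character(role), colnames(values))
  batch <- stats::setNames(as.character(batch), colnames(values))
  structure(list(values = values, role = role, batch = batch),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expr_mat: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  roles:  ", paste(sprintf("%s (%d)", names(table(x$role)),
                                  table(x$role)), collapse = ", "), "\n")
  cat("  batches:", paste(sprintf("%s (%d)", names(table(x$batch)),
                                  table(x$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

# Coerce expr_mat or plain matrix to a values matrix.
expr_values <- function(x) {
  if (inherits(x, "expr_mat")) x$values
  else if (is.matrix(x)) x
  else stop_bad_arg("expected an `expr_mat` or a numeric matrix")
}

#' Combine expression matrices by shared genes
#'
#' Column-binds two `expr_mat` objects on the intersection of their gene
#' ids, preserving roles and batches. Used to integrate purified patient
#' profiles with a cell-line panel prior to batch correction.
#'
#' @param x,y `expr_mat` objects.
#' @return An `expr_mat` over the shared genes.
#' @export
combine_expression <- function(x, y) {
  stopifnot(inherits(x, "expr_mat"), inherits(y, "expr_mat"))
  genes <- intersect(rownames(x$values), rownames(y$values))
  if (length(genes) == 0L) stop_bad_arg("no shared genes to combine on")
  if (any(colnames(y$values) %in% colnames(x$values)))
    stop_bad_arg("duplicate sample ids between the two matrices")
  expression_matrix(cbind(x$values[genes, , drop = FALSE],
                          y$values[genes, , drop = FALSE]),
                    role = c(x$role, y$role),
                    batch = c(x$batch, y$batch))
}

#' Read and write expression matrices as TSV
#'
#' The on-disk format is a genes x samples TSV (first column `gene`, header
#' row of sample ids) plus a sidecar TSV holding per-sample role and batch.
#'
#' @param x An `expr_mat`.
#' @param path Path of the expression TSV; the sidecar is written next to it
#'   with suffix `_samples.tsv` unless `meta_path` is given.
#' @param meta_path Optional explicit path for the sample sidecar.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expr_mat`.
#' @export
write_expression_tsv <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  meta_path <- meta_path %||% paste0(sub("\\.tsv$", "", path), "_samples.tsv")
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(x$values), role = unname(x$role),
                     batch = unname(x$batch), stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, meta_path = NULL) {
  meta_path <- meta_path %||% paste0(sub("\\.tsv$", "", path), "_samples.tsv")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- meta[match(colnames(values), meta$sample), ]
  expression_matrix(values, role = meta$role, batch = meta$batch)
}

#' Read and write marker gene sets in GMT format
#'
#' @param path Path to a GMT file.
#' @param sets Named list of character vectors of gene ids.
#' @param description Description field written for each set.
#' @return `read_gmt` returns a named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
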