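# Tumor purification of bulk expression: build a cell-type signature
# matrix, estimate per-sample cell-type fractions by non-negative least
# squares, and invert the mixture to obtain tumor-only expression profiles.
# This is a documented NNLS purification surrogate for reference-based
# deconvolution platforms; it returns per-sample purified profiles only.

#' Cell-type signature matrix
#'
#' @param values Non-negative numeric matrix, genes x cell types, on the
#'   linear scale, with gene ids as rownames and type labels as colnames.
#' @param tumor_types Character vector of column labels that are tumor
#'   (sub)types; the remaining columns are non-tumor cell types. At least
#'   one column must be a tumor type.
#' @return An object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, tumor_types) {
  if (!is.matrix(values) || any(values < 0))
    stop_bad_arg("signature values must be a non-negative matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_bad_arg("signature matrix needs gene and type names")
  if (!all(tumor_types %in% colnames(values)) || length(tumor_types) == 0L)
    stop_bad_arg("`tumor_types` must name at least one signature column")
  if (qr(values)$rank < ncol(values))
    warning("signature matrix is column-rank deficient; ",
            "fractions may not be identifiable")
  structure(list(values = values, tumor_types = tumor_types),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d genes x %d types (%d tumor)\n",
              nrow(x$values), ncol(x$values), length(x$tumor_types)))
  invisible(x)
}

#' Build a signature matrix from labeled single-cell-like profiles
#'
#' Computes per-type mean linear expression and restricts it to the union
#' of the top `n_markers_per_type` genes per type, ranked by the
#' fold-change of that type's mean over the maximum of the other types'
#' means.
#'
#' @param profiles An [expression_matrix()] (log2 scale) of single-cell-like
#'   reference profiles, or a plain log2 matrix.
#' @param types Character vector assigning a cell type to every profile.
#' @param n_markers_per_type Number of marker genes retained per type.
#' @param tumor_types Which type labels are tumor (sub)types.
#' @return A [signature_matrix()] on the linear scale, restricted to the
#'   marker-gene union.
#' @export
build_signature_matrix <- function(profiles, types, n_markers_per_type = 50,
                                   tumor_types) {
  m <- expr_values(profiles)
  if (length(types) != ncol(m))
    stop_bad_arg("`types` must label every profile")
  tt <- table(types)
  if (length(tt) < 2L) stop_bad_arg("need at least 2 cell types")
  if (any(tt < 3L))
    stop_bad_arg("every type needs >= 3 profiles; short: ",
                 paste(names(tt)[tt < 3L], collapse = ", "))
  type_levels <- sort(unique(types))  # invariant to profile order
  lin_means <- vapply(type_levels, function(ty) {
    rowMeans(2^m[, types == ty, drop = FALSE] - 1)
  }, numeric(nrow(m)))
  rownames(lin_means) <- rownames(m)
  eps <- 1e-8
  markers <- unique(unlist(lapply(seq_along(type_levels), function(j) {
    fc <- (lin_means[, j] + eps) /
      (apply(lin_means[, -j, drop = FALSE], 1, max) + eps)
    rownames(m)[utils::head(order(-fc), n_markers_per_type)]
  })))
  signature_matrix(lin_means[markers, , drop = FALSE], tumor_types)
}

#' Estimate per-sample cell-type fractions by non-negative least squares
#'
#' Fits each bulk sample (converted to the linear scale) onto the signature
#' columns by NNLS over the gene intersection, then normalizes the
#' coefficients to sum to one. Samples whose NNLS fit is degenerate (all
#' coefficients zero) are returned as `NA` rows with a warning.
#'
#' @param bulk An [expression_matrix()] (log2 scale) or log2 matrix.
#' @param signature A [signature_matrix()].
#' @return Matrix of fractions, samples x cell types; rows sum to 1.
#' @export
estimate_fractions <- function(bulk, signature) {
  stopifnot(inherits(signature, "signature_matrix"))
  b <- expr_values(bulk)
  genes <- intersect(rownames(b), rownames(signature$values))
  if (length(genes) == 0L)
    stop_bad_arg("no shared genes between bulk and signature")
  message(sprintf("estimate_fractions: using %d shared genes", length(genes)))
  S <- signature$values[genes, , drop = FALSE]
  blin <- 2^b[genes, , drop = FALSE] - 1
  out <- matrix(NA_real_, ncol(b), ncol(S),
                dimnames = list(colnames(b), colnames(S)))
  degenerate <- character(0)
  for (j in seq_len(ncol(b))) {
    y <- blin[, j]
    if (all(y == 0)) stop_bad_arg("all-zero bulk sample: ", colnames(b)[j])
    x <- pracma::lsqnonneg(S, y)$x
    if (sum(x) <= 0) {
      degenerate <- c(degenerate, colnames(b)[j])
    } else {
      out[j, ] <- x / sum(x)
    }
  }
  if (length(degenerate))
    warning("degenerate NNLS fit (all-zero coefficients) for: ",
            paste(degenerate, collapse = ", "))
  out
}

#' Impute tumor-only expression from bulk profiles
#'
#' Inverts the linear mixture per sample: the non-tumor contribution
#' implied by the estimated fractions is subtracted from the linear-scale
#' bulk, negative residuals are clipped to zero, the result is divided by
#' the tumor fraction and returned as log2(x + 1). Samples with tumor
#' fraction below `min_tumor_fraction` are excluded with a warning (tiny
#' denominators would amplify noise); excluded ids are attached as the
#' `excluded` attribute.
#'
#' @param bulk An [expression_matrix()] (log2) or log2 matrix.
#' @param signature A [signature_matrix()].
#' @param fractions Fraction matrix from [estimate_fractions()].
#' @param min_tumor_fraction Minimum tumor fraction for a sample to be
#'   purified (default 0.2).
#' @return An [expression_matrix()] of purified tumor profiles (role
#'   `"patient"`, batch `"patient"`) over the genes shared with the
#'   signature.
#' @export
impute_tumor_expression <- function(bulk, signature, fractions,
                                    min_tumor_fraction = 0.2) {
  stopifnot(inherits(signature, "signature_matrix"))
  b <- expr_values(bulk)
  if (!all(colnames(b) %in% rownames(fractions)))
    stop_bad_arg("fractions must be available for every sample")
  genes <- intersect(rownames(b), rownames(signature$values))
  S <- signature$values[genes, , drop = FALSE]
  nontumor <- setdiff(colnames(S), signature$tumor_types)
  f_tumor <- rowSums(fractions[colnames(b), signature$tumor_types,
                               drop = FALSE])
  keep <- !is.na(f_tumor) & f_tumor >= min_tumor_fraction & f_tumor > 0
  if (any(!keep))
    warning(sum(!keep), " sample(s) excluded for tumor fraction < ",
            min_tumor_fraction, ": ",
            paste(colnames(b)[!keep], collapse = ", "))
  if (!any(keep)) stop_bad_arg("no samples pass the tumor-fraction filter")

  blin <- 2^b[genes, keep, drop = FALSE] - 1
  contam <- S[, nontumor, drop = FALSE] %*%
    t(fractions[colnames(b)[keep], nontumor, drop = FALSE])
  tumor_lin <- pmax(blin - contam, 0) /
    rep(f_tumor[keep], each = length(genes))
  values <- log2(tumor_lin + 1)
  role <- if (inherits(bulk, "expr_mat")) bulk$role[keep] else "patient"
  out <- expression_matrix(values, role = role, batch = "patient")
  attr(out, "excluded") <- colnames(b)[!keep]
  out
}
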