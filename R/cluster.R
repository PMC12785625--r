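# Integration and clustering: empirical-Bayes batch correction, variable
# gene selection over patient samples, Ward agglomerative clustering,
# primary-cluster cuts, representative cell-line assignment and marker
# signature scores.

#' Empirical-Bayes batch correction (ComBat)
#'
#' Removes per-gene batch location/scale effects by the standard parametric
#' empirical-Bayes scheme (standardize per gene, estimate per-batch
#' location/scale, shrink toward batch-level priors, adjust and
#' back-transform), as implemented in \code{sva::ComBat}. With a single
#' batch the input is returned unchanged. Genes with zero pooled variance
#' cannot be standardized and are passed through unchanged (a message
#' reports how many).
#'
#' @param x An [expression_matrix()] (log2 scale).
#' @param batch Optional batch labels; defaults to `x$batch`.
#' @return An [expression_matrix()] with batch-adjusted values.
#' @export
combat_correct <- function(x, batch = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  batch <- batch %||% x$batch
  if (length(batch) != ncol(x$values))
    stop_bad_arg("`batch` must label every sample")
  if (length(unique(batch)) < 2L) return(x)
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop_bad_arg("every batch needs >= 2 samples; short: ",
                 paste(names(sizes)[sizes < 2L], collapse = ", "))
  v <- row_vars(x$values)
  flat <- v <= 1e-12
  if (any(flat))
    message(sum(flat), " zero-variance gene(s) passed through uncorrected")
  values <- x$values
  if (any(!flat)) {
    corrected <- suppressMessages(
      sva::ComBat(dat = values[!flat, , drop = FALSE], batch = batch))
    values[!flat, ] <- corrected
  }
  expression_matrix(values, role = x$role, batch = x$batch)
}

#' Select the most variable genes among patient samples
#'
#' Ranks genes by variance computed over patient-role samples only and
#' returns the top `k` gene ids (in the original gene order of the matrix).
#' Ties are broken by input gene order; `k` is capped at the gene count.
#'
#' @param x An [expression_matrix()] containing at least one sample with
#'   role `"patient"`.
#' @param k Number of genes to keep (default 5000).
#' @return Character vector of selected gene ids.
#' @export
select_variable_genes <- function(x, k = 5000) {
  stopifnot(inherits(x, "expr_mat"))
  if (k <= 0) stop_bad_arg("`k` must be positive")
  pat <- x$values[, x$role == "patient", drop = FALSE]
  if (ncol(pat) == 0L) stop_bad_arg("no patient-role samples in the matrix")
  v <- row_vars(pat)
  k <- min(k, nrow(pat))
  idx <- sort(order(-v)[seq_len(k)])  # order() is stable: ties by gene order
  rownames(x$values)[idx]
}

#' Ward agglomerative clustering
#'
#' Hierarchical clustering of samples (columns) by Ward's minimum-variance
#' method on Euclidean distances over log2 expression, via the
#' Lance-Williams recurrence (`hclust`, method `ward.D2`). Merge heights
#' are reported as the increase in within-cluster sum of squares
#' (delta-SSE) of each merge; for two singletons at Euclidean distance `d`
#' this is `d^2 / 2`.
#'
#' @param x An [expression_matrix()] or a genes x samples matrix.
#' @param genes Optional gene subset to cluster on (e.g. from
#'   [select_variable_genes()]).
#' @return An object of class `ward_dendrogram`: list with the underlying
#'   `hclust` object, the `merge` table, per-merge `height` (delta-SSE) and
#'   leaf `labels`.
#' @export
ward_cluster <- function(x, genes = NULL) {
  m <- expr_values(x)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 2L) stop_bad_arg("need at least 2 samples to cluster")
  if (!all(is.finite(m))) stop_bad_arg("non-finite values in the matrix")
  hc <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  structure(list(hclust = hc, merge = hc$merge,
                 height = hc$height^2 / 2, labels = hc$labels,
                 n = ncol(m)),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat(sprintf("ward_dendrogram: %d leaves, %d merges (delta-SSE heights)\n",
              x$n, length(x$height)))
  invisible(x)
}

#' Cut a Ward dendrogram into k primary clusters
#'
#' Removes the `k - 1` highest merges, yielding exactly `k` clusters.
#' Labels are 1..k in order of first appearance along the sample order.
#'
#' @param dendrogram A [ward_cluster()] result.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector: sample -> cluster id.
#' @export
cut_primary_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "ward_dendrogram"))
  if (k < 1 || k > dendrogram$n)
    stop_bad_arg("`k` must be between 1 and the number of leaves")
  raw <- stats::cutree(dendrogram$hclust, k = k)
  relabeled <- match(raw, unique(raw))
  stats::setNames(as.integer(relabeled), names(raw))
}

#' Assign a representative cell line to each patient cluster
#'
#' Within each cluster, among the cell-line members not on the exclusion
#' list, picks the line with minimum Euclidean distance to the cluster's
#' patient centroid. Clusters with no eligible line are marked
#' unrepresented; excluded-but-present lines are reported.
#'
#' @param clusters Named cluster labels from [cut_primary_clusters()].
#' @param x The clustered [expression_matrix()] (roles identify cell lines).
#' @param excludable_lines Cell lines that may not be used (e.g. lines
#'   requiring special culture conditions).
#' @param genes Optional gene subset (use the clustering gene set).
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (the input labels) and `representatives` (data frame per cluster:
#'   representative line or `NA`, member counts, excluded lines present).
#' @export
assign_representatives <- function(clusters, x, excludable_lines = character(),
                                   genes = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  m <- x$values
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  m <- m[, names(clusters), drop = FALSE]
  role <- x$role[names(clusters)]
  ks <- sort(unique(clusters))
  reps <- do.call(rbind, lapply(ks, function(k) {
    members <- names(clusters)[clusters == k]
    patients <- members[role[members] == "patient"]
    lines <- members[role[members] == "cell-line"]
    eligible <- setdiff(lines, excludable_lines)
    excluded_present <- intersect(lines, excludable_lines)
    rep_line <- NA_character_
    if (length(eligible)) {
      centroid <- if (length(patients))
        rowMeans(m[, patients, drop = FALSE]) else
        rowMeans(m[, members, drop = FALSE])
      d <- vapply(eligible, function(l) sqrt(sum((m[, l] - centroid)^2)),
                  numeric(1))
      rep_line <- eligible[which.min(d)]
    }
    data.frame(cluster = k, representative = rep_line,
               n_patients = length(patients), n_cell_lines = length(lines),
               excluded_present = paste(excluded_present, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  structure(list(cluster = clusters, representatives = reps),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d clusters\n",
              length(x$cluster), nrow(x$representatives)))
  print(x$representatives, row.names = FALSE)
  invisible(x)
}

#' Marker-set signature score
#'
#' Per-sample mean of per-gene z-scores over a marker set; genes are
#' standardized across all samples with a variance floor of 1e-8 (genes
#' that are constant across samples contribute a z-score of 0).
#'
#' @param x An [expression_matrix()] or log2 matrix.
#' @param markers Character vector of marker gene ids (e.g. one GMT entry);
#'   at least one must be present in the matrix.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(x, markers) {
  m <- expr_values(x)
  markers <- intersect(markers, rownames(m))
  if (length(markers) == 0L)
    stop_bad_arg("no marker genes overlap the expression matrix")
  sub <- m[markers, , drop = FALSE]
  mu <- rowMeans(sub)
  sd <- sqrt(pmax(row_vars(sub), 1e-8))
  z <- (sub - mu) / sd
  z[row_vars(sub) <= 1e-8, ] <- 0
  colMeans(z)
}

#' Export a Ward dendrogram as Newick
#'
#' Writes the dendrogram with delta-SSE merge heights as branch lengths.
#'
#' @param dendrogram A [ward_cluster()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "ward_dendrogram"))
  hc <- dendrogram$hclust
  hc$height <- dendrogram$height
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
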