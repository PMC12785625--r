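# Independent brute-force oracles, deliberately written without reference
# to the implementations they check.

# Exhaustive Ward clustering: at every step recompute the increase in
# within-cluster sum of squares for every cluster pair and merge the
# minimum. `x`: samples in rows. Returns merge heights and the partition
# (list of leaf-index sets) after each merge.
ward_oracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  partitions <- list()
  delta_sse <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE])
    cb <- colMeans(x[b, , drop = FALSE])
    (length(a) * length(b)) / (length(a) + length(b)) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- delta_sse(clusters[[i]], clusters[[j]])
      if (d < best[1]) best <- c(d, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(sort(merged)))
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Partition trace of an hclust-style merge table, in the same canonical
# form as ward_oracle().
merge_partitions <- function(merge, n) {
  partitions <- vector("list", nrow(merge))
  tops <- lapply(seq_len(n), identity)   # current top-level groups
  ids <- -seq_len(n)                     # hclust id of each group
  for (s in seq_len(nrow(merge))) {
    ia <- which(ids == merge[s, 1]); ib <- which(ids == merge[s, 2])
    newg <- sort(c(tops[[ia]], tops[[ib]]))
    tops <- c(tops[-c(ia, ib)], list(newg))
    ids <- c(ids[-c(ia, ib)], s)
    partitions[[s]] <- lapply(tops, sort)
  }
  partitions
}

canonical_partition <- function(p) {
  keys <- vapply(p, function(g) paste(g, collapse = ","), character(1))
  sort(keys)
}

# Full-enumeration Mann-Whitney: p-value over all C(n+m, n) group
# assignments of the pooled sample.
mw_enum_oracle <- function(x, y, alternative = "two.sided") {
  pool <- c(x, y)
  n <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + sum(outer(a, b, "==")) / 2
  U <- u_stat(x, y)
  combos <- utils::combn(length(pool), n)
  us <- apply(combos, 2, function(ii) u_stat(pool[ii], pool[-ii]))
  p_less <- mean(us <= U)
  p_greater <- mean(us >= U)
  switch(alternative,
         less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}
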