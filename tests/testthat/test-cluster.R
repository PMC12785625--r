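test_that("a single batch passes through batch correction unchanged", {
  set.seed(1)
  v <- matrix(rnorm(50 * 10, 6), 50, 10,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10)))
  x <- expression_matrix(v, role = "patient", batch = "one")
  expect_equal(combat_correct(x)$values, v, tolerance = 1e-10)
})

test_that("a known +2 location shift is removed by batch correction", {
  set.seed(7)
  g <- 200; n <- 50
  base <- runif(g, 4, 8)
  v <- base + matrix(rnorm(g * 2 * n, 0, 0.1), g, 2 * n)
  v[, (n + 1):(2 * n)] <- v[, (n + 1):(2 * n)] + 2
  dimnames(v) <- list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:(2 * n)))
  x <- expression_matrix(v, role = "patient",
                         batch = rep(c("a", "b"), each = n))
  cx <- suppressMessages(combat_correct(x))
  d <- rowMeans(cx$values[, 1:n]) - rowMeans(cx$values[, (n + 1):(2 * n)])
  expect_lt(max(abs(d)), 0.05)
})

test_that("batch correction preserves per-gene pooled means (round trip)", {
  set.seed(8)
  g <- 150; n <- 40
  base <- runif(g, 4, 8)
  v <- base + matrix(rnorm(g * 2 * n, 0, 0.001), g, 2 * n)
  v[, (n + 1):(2 * n)] <- v[, (n + 1):(2 * n)] + 2
  dimnames(v) <- list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:(2 * n)))
  x <- expression_matrix(v, role = "patient",
                         batch = rep(c("a", "b"), each = n))
  cx <- suppressMessages(combat_correct(x))
  expect_lt(max(abs(rowMeans(cx$values) - rowMeans(v))), 1e-6)
})

test_that("batch correction rejects singleton batches and tolerates flat genes", {
  set.seed(2)
  v <- matrix(rnorm(30 * 9, 5), 30, 9,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:9)))
  v[1, ] <- 3  # zero-variance gene
  x <- expression_matrix(v, role = "patient",
                         batch = c(rep("a", 4), rep("b", 4), "c"))
  expect_error(combat_correct(x), ">= 2 samples")
  x2 <- expression_matrix(v[, 1:8], role = "patient",
                          batch = rep(c("a", "b"), each = 4))
  expect_message(cx <- combat_correct(x2), "zero-variance")
  expect_equal(unname(cx$values[1, ]), rep(3, 8))
})

test_that("variable-gene selection uses patient samples only", {
  set.seed(3)
  g <- 40
  v <- matrix(rnorm(g * 8, 6, 1), g, 8,
              dimnames = list(sprintf("g%02d", 1:g), sprintf("s%02d", 1:8)))
  # gene 1: constant across patients (cols 1-5), wildly variable across lines
  v[1, 1:5] <- 5
  v[1, 6:8] <- c(0, 10, 20)
  x <- expression_matrix(v, role = c(rep("patient", 5), rep("cell-line", 3)),
                         batch = "b")
  sel <- select_variable_genes(x, k = g - 1)
  expect_false("g01" %in% sel)            # never selected before any other
  expect_equal(select_variable_genes(x, k = 100), rownames(v))  # cap, order
  expect_error(select_variable_genes(x, k = 0), "positive")
})

test_that("the default variable-gene filter keeps exactly 5000 of 20000 genes", {
  set.seed(4)
  v <- matrix(rnorm(20000 * 10), 20000, 10,
              dimnames = list(sprintf("g%05d", 1:20000),
                              sprintf("s%02d", 1:10)))
  x <- expression_matrix(v, role = "patient", batch = "b")
  expect_length(select_variable_genes(x, k = 5000), 5000L)
})

test_that("two singletons merge at delta-SSE = squared distance / 2", {
  v <- matrix(c(0, 0, 2, 0), 2, 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  d <- ward_cluster(v)
  expect_equal(d$height, 2)  # distance 2 -> d^2/2
})

test_that("duplicated samples merge first at height zero", {
  set.seed(5)
  v <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(sprintf("f%02d", 1:10), c("a", "b", "c", "a2")))
  v[, "a2"] <- v[, "a"]
  d <- ward_cluster(v)
  expect_equal(d$height[1], 0)
  first <- sort(d$merge[1, ])
  expect_true(all(first < 0))
  expect_setequal(d$labels[-first], c("a", "a2"))
  v[1, 1] <- NA
  expect_error(ward_cluster(v), "non-finite")
})

test_that("Ward merges match the exhaustive delta-SSE oracle", {
  for (s in 1:4) {
    set.seed(100 + s)
    n <- sample(6:10, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    rownames(x) <- sprintf("s%02d", seq_len(n))
    d <- ward_cluster(t(x))
    oracle <- ward_oracle(x)
    expect_equal(d$height, oracle$heights, tolerance = 1e-10)
    got <- merge_partitions(d$merge, n)
    for (step in seq_len(n - 1))
      expect_identical(canonical_partition(got[[step]]),
                       canonical_partition(oracle$partitions[[step]]))
  }
})

test_that("cluster cuts behave at the extremes and relabel by appearance", {
  set.seed(6)
  v <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%d", 1:6)))
  d <- ward_cluster(v)
  expect_equal(unname(cut_primary_clusters(d, 6)), 1:6)
  expect_equal(unname(cut_primary_clusters(d, 1)), rep(1L, 6))
  expect_error(cut_primary_clusters(d, 7), "between 1")
  cl <- cut_primary_clusters(d, 3)
  expect_equal(cl[["s1"]], 1L)  # first sample defines cluster 1
  expect_equal(sort(unique(cl)), 1:3)
})

test_that("representatives minimize distance to the patient centroid and honor exclusions", {
  # cluster 1: two patients around 0 plus lines near (0) and (3)
  v <- cbind(p1 = c(0, 0), p2 = c(0.2, -0.2), near = c(0.3, 0),
             far = c(3, 0), lonely = c(10, 10))
  rownames(v) <- c("f1", "f2")
  x <- expression_matrix(v, role = c("patient", "patient", "cell-line",
                                     "cell-line", "cell-line"),
                         batch = "b")
  cl <- stats::setNames(c(1L, 1L, 1L, 1L, 2L), colnames(v))
  a <- assign_representatives(cl, x)
  expect_equal(a$representatives$representative, c("near", "lonely"))
  # excluding the closest line falls back to the next one
  a2 <- assign_representatives(cl, x, excludable_lines = "near")
  expect_equal(a2$representatives$representative[1], "far")
  expect_equal(a2$representatives$excluded_present[1], "near")
  # a cluster whose only line is excluded is unrepresented
  a3 <- assign_representatives(cl, x,
                               excludable_lines = c("near", "far", "lonely"))
  expect_true(all(is.na(a3$representatives$representative)))
})

test_that("signature scores follow z-score arithmetic", {
  v <- matrix(c(1, 4, 2, 5, 3, 6), 2, 3,
              dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  sc <- signature_score(v, c("m1", "m2"))
  expect_equal(unname(sc["s3"]), 1)   # every marker at mean + 1 sd
  expect_equal(unname(sc["s2"]), 0)
  flat <- matrix(5, 3, 4, dimnames = list(c("m1", "m2", "x"),
                                          sprintf("s%d", 1:4)))
  expect_equal(unname(signature_score(flat, c("m1", "m2"))), rep(0, 4))
  expect_error(signature_score(v, "absent"), "overlap")
})

test_that("dendrograms export as Newick with delta-SSE branch lengths", {
  set.seed(9)
  v <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(sprintf("f%d", 1:5), c("a", "b", "c", "d")))
  d <- ward_cluster(v)
  path <- tempfile(fileext = ".nwk")
  export_newick(d, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("a", "b", "c", "d"))
})
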