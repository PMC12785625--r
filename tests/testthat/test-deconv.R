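make_profiles <- function(base, types, noise = 0, seed = 1) {
  # 3 noiseless replicates per type profile (log2)
  set.seed(seed)
  vals <- vapply(seq_along(types), function(i)
    base[[types[i]]] + rnorm(length(base[[types[i]]]), 0, noise),
    numeric(length(base[[1]])))
  rownames(vals) <- names(base[[1]])
  colnames(vals) <- sprintf("c%02d", seq_along(types))
  vals
}

test_that("signature building reproduces noiseless type means on their markers", {
  cfg <- test_config()
  base <- list(sub1 = cfg$subtypes$sub1$base_profile,
               sub2 = cfg$subtypes$sub2$base_profile)
  types <- rep(c("sub1", "sub2"), each = 3)
  prof <- make_profiles(base, types)
  sig <- build_signature_matrix(prof, types, n_markers_per_type = 10,
                                tumor_types = c("sub1", "sub2"))
  expect_lte(nrow(sig$values), 20)
  mk <- cfg$subtypes$sub1$marker_genes
  expect_true(all(mk %in% rownames(sig$values)))
  expect_equal(sig$values[mk, "sub1"],
               2^cfg$subtypes$sub1$base_profile[mk] - 1, tolerance = 1e-9)
})

test_that("signature building is invariant to profile order and validates groups", {
  cfg <- test_config()
  base <- list(sub1 = cfg$subtypes$sub1$base_profile,
               sub2 = cfg$subtypes$sub2$base_profile)
  types <- rep(c("sub1", "sub2"), each = 3)
  prof <- make_profiles(base, types, noise = 0.1)
  perm <- c(4, 1, 5, 2, 6, 3)
  s1 <- build_signature_matrix(prof, types, 10, tumor_types = "sub1")
  s2 <- build_signature_matrix(prof[, perm], types[perm], 10,
                               tumor_types = "sub1")
  expect_equal(s1$values[sort(rownames(s1$values)), ],
               s2$values[sort(rownames(s2$values)), ])
  expect_error(build_signature_matrix(prof[, 1:4], types[1:4], 10, "sub1"),
               ">= 3 profiles")
  expect_error(build_signature_matrix(prof[, 1:3], types[1:3], 10, "sub1"),
               "2 cell types")
})

test_that("NNLS recovers exact fractions from noiseless mixtures", {
  cfg <- test_config(n_patients = 1, noise_sd = 0, tumor_fraction = 0.6,
                     subtype_probs = c(sub1 = 1, sub2 = 0))
  co <- generate_cohort(cfg)
  fr <- suppressMessages(estimate_fractions(co$bulk, co$signatures))
  expect_equal(unname(fr[1, c("sub1", "stroma")]), c(0.6, 0.4),
               tolerance = 1e-8)
  expect_equal(unname(fr[1, c("sub2")]), 0, tolerance = 1e-8)
})

test_that("50 random noiseless mixtures are recovered below 1e-6", {
  cfg <- test_config()
  co <- generate_cohort(cfg)
  sig <- co$signatures$values
  set.seed(99)
  w <- matrix(rgamma(50 * 3, 1), 50, 3)
  w <- w / rowSums(w)
  bulk <- log2(sig %*% t(w) + 1)
  colnames(bulk) <- sprintf("m%02d", 1:50)
  fr <- suppressMessages(estimate_fractions(bulk, co$signatures))
  expect_lt(max(abs(fr - w)), 1e-6)
})

test_that("fractions are invariant to positive scaling of a bulk sample", {
  cfg <- test_config()
  co <- generate_cohort(cfg)
  sig <- co$signatures$values
  mix <- 0.3 * sig[, "sub1"] + 0.5 * sig[, "sub2"] + 0.2 * sig[, "stroma"]
  bulk <- cbind(s1 = log2(mix + 1), s2 = log2(7.3 * mix + 1))
  fr <- suppressMessages(estimate_fractions(bulk, co$signatures))
  expect_equal(fr["s1", ], fr["s2", ], tolerance = 1e-8)
})

test_that("degenerate and invalid bulk samples are flagged", {
  cfg <- test_config(n_genes = 30)
  co <- generate_cohort(test_config(n_genes = 30, n_patients = 1))
  zero <- matrix(0, 30, 1,
                 dimnames = list(rownames(co$signatures$values), "z"))
  expect_error(suppressMessages(estimate_fractions(zero, co$signatures)),
               "all-zero")
  expect_error(suppressMessages(
    estimate_fractions(matrix(1, 3, 1, dimnames = list(c("x1", "x2", "x3"),
                                                       "s")),
                       co$signatures)),
    "no shared genes")
})

test_that("pure tumor samples are returned unchanged by imputation", {
  cfg <- test_config(n_patients = 4, noise_sd = 0, tumor_fraction = 1)
  co <- generate_cohort(cfg)
  fr <- suppressMessages(estimate_fractions(co$bulk, co$signatures))
  pur <- impute_tumor_expression(co$bulk, co$signatures, fr)
  expect_equal(pur$values, co$bulk$values, tolerance = 1e-6)
})

test_that("imputation algebraically inverts a noiseless two-type mixture", {
  cfg <- test_config(n_patients = 6, noise_sd = 0, tumor_fraction = 0.55,
                     subtype_probs = c(sub1 = 0, sub2 = 1))
  co <- generate_cohort(cfg)
  fr <- suppressMessages(estimate_fractions(co$bulk, co$signatures))
  pur <- impute_tumor_expression(co$bulk, co$signatures, fr)
  target <- cfg$subtypes$sub2$base_profile
  for (j in seq_len(ncol(pur$values)))
    expect_equal(unname(pur$values[, j]), unname(target), tolerance = 1e-6)
})

test_that("negative residuals are clipped to zero before the log transform", {
  sig <- signature_matrix(
    matrix(c(10, 2, 5, 8), 2, 2,
           dimnames = list(c("gA", "gB"), c("tumor", "stroma"))),
    tumor_types = "tumor")
  # bulk below the stromal contribution on gA -> negative residual
  bulk <- matrix(log2(c(1, 6) + 1), 2, 1,
                 dimnames = list(c("gA", "gB"), "s1"))
  fr <- matrix(c(0.5, 0.5), 1, 2,
               dimnames = list("s1", c("tumor", "stroma")))
  pur <- impute_tumor_expression(bulk, sig, fr)
  expect_equal(unname(pur$values["gA", 1]), 0)
  expect_equal(unname(pur$values["gB", 1]), log2((6 - 0.5 * 8) / 0.5 + 1))
})

test_that("low-purity samples are excluded with a warning", {
  cfg <- test_config(n_patients = 3, noise_sd = 0, tumor_fraction = 0.1)
  co <- generate_cohort(cfg)
  fr <- suppressMessages(estimate_fractions(co$bulk, co$signatures))
  expect_warning(
    expect_error(impute_tumor_expression(co$bulk, co$signatures, fr),
                 "tumor-fraction filter"),
    "excluded")
})

test_that("fraction error grows monotonically with measurement noise", {
  rmse_at <- function(noise_sd) {
    errs <- vapply(1:10, function(s) {
      cfg <- test_config(n_patients = 10, noise_sd = noise_sd, seed = s)
      co <- generate_cohort(cfg)
      fr <- suppressMessages(estimate_fractions(co$bulk, co$signatures))
      truth <- as.matrix(co$truth[, colnames(fr)])
      sqrt(mean((fr - truth)^2))
    }, numeric(1))
    mean(errs)
  }
  rmse <- vapply(c(0, 0.1, 0.25, 0.5), rmse_at, numeric(1))
  expect_true(all(diff(rmse) > 0))
})
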