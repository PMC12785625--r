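test_that("a pure, noiseless one-subtype patient reproduces the base profile", {
  cfg <- test_config(n_patients = 3, noise_sd = 0, tumor_fraction = 1,
                     subtype_probs = c(sub1 = 1, sub2 = 0))
  co <- generate_cohort(cfg)
  prof <- cfg$subtypes$sub1$base_profile
  for (j in 1:3)
    expect_equal(unname(co$bulk$values[, j]), unname(prof), tolerance = 1e-12)
  expect_true(all(co$truth$subtype == "sub1"))
})

test_that("noiseless bulk equals the fraction-weighted linear mixture, gene by gene", {
  cfg <- test_config(n_patients = 5, noise_sd = 0, tumor_fraction = 0.6,
                     subtype_probs = c(sub1 = 1, sub2 = 0))
  co <- generate_cohort(cfg)
  sig <- co$signatures$values
  expected <- log2(0.6 * sig[, "sub1"] + 0.4 * sig[, "stroma"] + 1)
  for (j in 1:5)
    expect_equal(unname(co$bulk$values[, j]), unname(expected),
                 tolerance = 1e-12)
  # truth records the fractions
  expect_equal(co$truth$sub1, rep(0.6, 5))
  expect_equal(co$truth$stroma, rep(0.4, 5))
})

test_that("the unstratified preset generates a 208-patient cohort", {
  co <- generate_cohort(hetmix_preset("unstratified-CRPC", seed = 1)$config)
  expect_equal(ncol(co$bulk$values), 208L)
  expect_true(all(co$bulk$role == "patient"))
})

test_that("cohort generation is deterministic given the seed and validates input", {
  cfg <- test_config(seed = 11)
  expect_identical(generate_cohort(cfg)$bulk$values,
                   generate_cohort(cfg)$bulk$values)
  expect_error(test_config(tumor_fraction = 0), "tumor fraction")
  # gene universe must be able to hold the markers
  base <- test_gene_universe(15)
  st <- subtype_spec("s", names(base)[1:10], base, 24)
  expect_error(
    cohort_config(list(s = st), list(), n_patients = 2,
                  subtype_probs = c(s = 1), tumor_fraction = 1),
    NA)  # 15 >= 10 markers is fine
  expect_error(subtype_spec("s", c("nope"), base, 24), "gene universe")
})

test_that("identity batch leaves cell-line profiles at their subtype profile", {
  cfg <- test_config(noise_sd = 0, batch_shift = 0, batch_scale = 1)
  panel <- generate_cell_line_panel(cfg)
  expect_equal(unname(panel$values[, "sub1_line"]),
               unname(cfg$subtypes$sub1$base_profile), tolerance = 1e-12)
  expect_true(all(panel$role == "cell-line"))
  expect_true(all(panel$batch == "cell-line"))
})

test_that("a constant +2 batch shift moves cell lines by 2 log2 units", {
  cfg <- test_config(noise_sd = 0, batch_shift = 2)
  panel <- generate_cell_line_panel(cfg)
  diff <- panel$values[, "sub2_line"] - cfg$subtypes$sub2$base_profile
  expect_equal(unname(diff), rep(2, cfg$n_genes), tolerance = 1e-12)
})

test_that("unknown subtype in the panel is rejected", {
  cfg <- test_config()
  cfg$cell_lines$subtype[1] <- "mystery"
  expect_error(generate_cell_line_panel(cfg), "unknown subtype")
})

test_that("resistant derivatives stay closer to their parent than any other subtype", {
  p <- hetmix_preset("taxane-resistant-CRPC", seed = 5)
  panel <- generate_cell_line_panel(p$config)
  m <- panel$values
  profs <- vapply(p$config$subtypes, `[[`, numeric(p$config$n_genes),
                  "base_profile")
  inter <- min(dist(t(profs)))
  for (l in c("DU145", "22RV1", "R1D567")) {
    d_parent <- sqrt(sum((m[, paste0("doceR_", l)] -
                            m[, paste0("doceS_", l)])^2))
    expect_lt(d_parent, inter)
  }
})

test_that("monotherapy tables obey the Hill law at the grid boundaries", {
  cfg <- test_config()
  grid <- c(0, 0.5, 1, 2, 5, 10, 50, 100)
  tbl <- generate_monotherapy_table(cfg$subtypes, conc_grid = grid)
  expect_equal(nrow(tbl), 2 * 2 * 8)  # 2 lines x 2 drugs x 8 concentrations
  expect_true(all(tbl$viability >= 0 & tbl$viability <= 1))
  expect_true(all(tbl$viability[tbl$concentration == 0] == 1))
  # Hill midpoint with full efficacy
  st <- list(s = subtype_spec("s", character(0), test_gene_universe(20), 24,
                              list(d = list(ic50 = 2, hill = 1.3, emax = 1))))
  mid <- generate_monotherapy_table(st, conc_grid = c(0, 2), drugs = "d")
  expect_equal(mid$viability[mid$concentration == 2], 0.5)
  expect_error(generate_monotherapy_table(cfg$subtypes, conc_grid = c(-1, 2)),
               ">= 0")
})

test_that("three lines x two drugs over an 8-point grid gives 48 in-range rows", {
  cfg <- test_config()
  lines <- data.frame(line = c("a", "b", "c"),
                      subtype = c("sub1", "sub2", "sub1"),
                      stringsAsFactors = FALSE)
  tbl <- generate_monotherapy_table(cfg$subtypes, conc_grid = 2^(0:7),
                                    lines = lines, noise_sd = 0.1, seed = 4)
  expect_equal(nrow(tbl), 48L)
  expect_true(all(tbl$viability >= 0 & tbl$viability <= 1))
})

test_that("vehicle growth doubles every doubling time at low density", {
  g <- growth_params(doubling_time = c(a = 24, b = 48), capacity = 1e9)
  obs <- generate_growth_experiment(g, c(a = 100, b = 100),
                                    list(vehicle = list()),
                                    n_replicates = 2, noise_sdlog = 0,
                                    duration = 96, seed = 1)
  ratio <- obs$area_end / obs$area_start
  expect_equal(ratio[obs$channel == "a"], rep(2^(96 / 24), 2),
               tolerance = 0.01)
  expect_equal(ratio[obs$channel == "b"], rep(2^(96 / 48), 2),
               tolerance = 0.01)
})

test_that("growth experiments honor replicate counts and are seed-deterministic", {
  g <- growth_params(doubling_time = c(a = 24, b = 48),
                     dose_response = list(
                       a = list(d = list(ic50 = 1, hill = 2, emax = 1)),
                       b = list(d = list(ic50 = 1, hill = 2, emax = 1))))
  tr <- list(vehicle = list(), treated = list(d = 1))
  obs1 <- generate_growth_experiment(g, c(a = 500, b = 500), tr,
                                     n_replicates = 6, seed = 42)
  obs2 <- generate_growth_experiment(g, c(a = 500, b = 500), tr,
                                     n_replicates = 6, seed = 42)
  expect_identical(obs1, obs2)
  expect_equal(sum(obs1$condition == "vehicle" & obs1$channel == "a"), 6L)
  expect_error(generate_growth_experiment(g, c(a = 0, b = 0), tr, seed = 1),
               "positive total")
  expect_error(generate_growth_experiment(g, c(a = 10, b = 10), tr,
                                          n_replicates = 0, seed = 1),
               "n_replicates")
})
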