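# Small deterministic generator configurations and hand-built fixtures used
# across the test files. The baseline profile is a deterministic ramp so
# expectations can be computed exactly.

test_gene_universe <- function(n_genes = 120) {
  stats::setNames(seq(5, 7, length.out = n_genes),
                  sprintf("t%03d", seq_len(n_genes)))
}

# Two tumor subtypes with complementary drug sensitivities plus one stromal
# contaminant. Marker blocks of 10 genes at +2 log2.
test_config <- function(n_patients = 12, n_genes = 120, noise_sd = 0,
                        tumor_fraction = c(5, 2), subtype_probs = NULL,
                        batch_shift = 0, batch_scale = 1,
                        cell_lines = NULL, seed = 1L, ...) {
  base <- test_gene_universe(n_genes)
  genes <- names(base)
  mk <- function(i) genes[((i - 1) * 10 + 1):(i * 10)]
  bump <- function(i) { p <- base; p[mk(i)] <- p[mk(i)] + 2; p }
  dr <- function(a_ic50, b_ic50)
    list(drg_a = list(ic50 = a_ic50, hill = 2, emax = 0.95),
         drg_b = list(ic50 = b_ic50, hill = 2, emax = 0.95))
  subtypes <- list(
    sub1 = subtype_spec("sub1", mk(1), bump(1), doubling_time = 24,
                        dose_response = dr(1, 1000)),
    sub2 = subtype_spec("sub2", mk(2), bump(2), doubling_time = 48,
                        dose_response = dr(1000, 1)))
  cohort_config(
    subtypes = subtypes,
    nontumor_profiles = list(stroma = bump(3)),
    n_patients = n_patients,
    subtype_probs = subtype_probs %||% c(sub1 = 0.5, sub2 = 0.5),
    tumor_fraction = tumor_fraction, noise_sd = noise_sd,
    batch_shift = batch_shift, batch_scale = batch_scale,
    cell_lines = cell_lines, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built monotherapy table from a named list
# drug -> conc -> named viability vector.
mono_table <- function(entries) {
  rows <- list()
  for (d in names(entries)) for (cc in names(entries[[d]])) {
    v <- entries[[d]][[cc]]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = names(v), drug = d, concentration = as.numeric(cc),
      viability = unname(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Well observations for evaluate_combo with explicit per-line medians and a
# deterministic replicate spread.
make_obs <- function(medians, n_rep = 6, spread = 0.02) {
  # medians: list(condition -> named per-line normalized growth);
  # start areas fixed at 100.
  rows <- list()
  offs <- seq(-spread, spread, length.out = n_rep)
  for (cond in names(medians)) for (l in names(medians[[cond]])) {
    for (r in seq_len(n_rep)) {
      ng <- medians[[cond]][[l]] * (1 + offs[r])
      rows[[length(rows) + 1L]] <- data.frame(
        well = sprintf("%s_r%d", cond, r), condition = cond, replicate = r,
        channel = l, area_start = 100, area_end = 100 * ng,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
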