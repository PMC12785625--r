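# End-to-end workflows: (1) representative cell-line selection --
# synthetic cohort -> tumor purification -> integration + batch correction
# -> variable genes -> Ward clustering -> cluster cut -> representative
# assignment; (2) combination evaluation -- monotherapy table -> IDA
# ranking -> co-culture simulation -> efficacy report. Both are
# deterministic given the preset seed.

#' Run the representative-selection pipeline
#'
#' Executes the full selection workflow on a scenario preset: generate the
#' bulk cohort and cell-line panel, estimate cell-type fractions and impute
#' tumor-only patient profiles, integrate with the panel, batch-correct,
#' select the most variable genes among patients, cluster with Ward's
#' method, cut the primary clusters and assign a representative cell line
#' to each. AR/NEPC marker signature scores are attached per cluster.
#'
#' @param preset A preset object from [hetmix_preset()], or a preset name
#'   (then built with `seed`).
#' @param seed Master seed (used only when `preset` is a name).
#' @param k Number of primary clusters (default 4).
#' @param n_variable_genes Variable-gene filter size (default 5000, capped
#'   at the gene universe).
#' @param min_tumor_fraction Purity threshold for [impute_tumor_expression()].
#' @param out_dir Optional output directory; when given, writes the Newick
#'   dendrogram, assignment/score/fraction CSVs, the marker GMT and a JSON
#'   manifest. Reruns with the same preset are bit-identical.
#' @return A list of class `selection_result`: the cluster `assignment`,
#'   the `dendrogram`, per-sample `scores`, estimated `fractions`, the
#'   ground `truth`, selected `genes` and the `manifest`.
#' @export
run_selection_pipeline <- function(preset = "unstratified-CRPC", seed = 1L,
                                   k = 4, n_variable_genes = 5000,
                                   min_tumor_fraction = 0.2,
                                   out_dir = NULL) {
  if (is.character(preset)) preset <- hetmix_preset(preset, seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("synthgen", generate_cohort(preset$config))
  panel <- stage("synthgen", generate_cell_line_panel(preset$config))
  # fractions are estimated on the marker-gene signature (cell types are
  # identifiable there); imputation then uses the full-transcriptome
  # signature
  sig_markers <- if (is.null(preset$deconv_genes)) cohort$signatures else
    signature_matrix(
      cohort$signatures$values[preset$deconv_genes, , drop = FALSE],
      cohort$signatures$tumor_types)
  fractions <- stage("deconv", suppressMessages(
    estimate_fractions(cohort$bulk, sig_markers)))
  purified <- stage("deconv", impute_tumor_expression(
    cohort$bulk, cohort$signatures, fractions,
    min_tumor_fraction = min_tumor_fraction))
  combined <- stage("integrate", combine_expression(purified, panel))
  corrected <- stage("combat", suppressMessages(combat_correct(combined)))
  genes <- stage("variable_genes",
                 select_variable_genes(corrected, n_variable_genes))
  dend <- stage("ward", ward_cluster(corrected, genes))
  clusters <- stage("cut", cut_primary_clusters(dend, k))
  assignment <- stage("representatives", assign_representatives(
    clusters, corrected, excludable_lines = preset$excluded_lines,
    genes = genes))

  scores <- vapply(preset$marker_sets, function(ms)
    signature_score(corrected, ms), numeric(ncol(corrected$values)))
  reps <- assignment$representatives
  for (s in colnames(scores)) {
    reps[[paste0("mean_", s)]] <- vapply(reps$cluster, function(kk)
      mean(scores[names(clusters)[clusters == kk], s]), numeric(1))
  }
  assignment$representatives <- reps

  manifest <- list(
    preset = preset$name, seed = preset$seed, k = k,
    n_variable_genes = length(genes),
    n_patients = sum(corrected$role == "patient"),
    n_cell_lines = sum(corrected$role == "cell-line"),
    n_excluded_low_purity = length(attr(purified, "excluded")),
    n_clusters = nrow(reps),
    n_represented = sum(!is.na(reps$representative)),
    representatives = stats::setNames(reps$representative,
                                      paste0("cluster_", reps$cluster)),
    excluded_lines = preset$excluded_lines,
    package_version = as.character(utils::packageVersion("hetmix")))

  result <- structure(list(assignment = assignment, dendrogram = dend,
                           scores = scores, fractions = fractions,
                           truth = cohort$truth, genes = genes,
                           corrected = corrected, manifest = manifest),
                      class = "selection_result")
  if (!is.null(out_dir)) write_selection_result(result, out_dir)
  result
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d clusters (%d represented), %d patients\n",
              x$manifest$n_clusters, x$manifest$n_represented,
              x$manifest$n_patients))
  print(x$assignment$representatives, row.names = FALSE, digits = 3)
  invisible(x)
}

write_selection_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  export_newick(result$dendrogram, file.path(out_dir, "dendrogram.nwk"))
  utils::write.csv(data.frame(sample = names(result$assignment$cluster),
                              cluster = unname(result$assignment$cluster)),
                   file.path(out_dir, "assignment.csv"), row.names = FALSE)
  utils::write.csv(result$assignment$representatives,
                   file.path(out_dir, "representatives.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(result$scores),
                              result$scores, check.names = FALSE),
                   file.path(out_dir, "signature_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(result$fractions),
                              result$fractions, check.names = FALSE),
                   file.path(out_dir, "fractions.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# Growth parameters for a set of panel lines under a preset.
preset_growth_params <- function(preset, lines,
                                 combo_model = "ida_min",
                                 synergy_strength = 8) {
  cl <- preset$config$cell_lines
  idx <- match(lines, cl$line)
  if (anyNA(idx)) stop_bad_arg("unknown line(s): ",
                               paste(lines[is.na(idx)], collapse = ", "))
  subtypes <- cl$subtype[idx]
  td <- stats::setNames(vapply(subtypes, function(st)
    preset$config$subtypes[[st]]$doubling_time, numeric(1)), lines)
  rfac <- with_substream(preset$seed, "resistance_factors",
                         stats::setNames(10^stats::runif(length(lines), 1, 2),
                                         lines))
  dose_response <- lapply(stats::setNames(seq_along(lines), lines),
                          function(i) {
    dr <- preset$config$subtypes[[subtypes[i]]]$dose_response
    if (isTRUE(cl$resistant[idx[i]]) && "docetaxel" %in% names(dr))
      dr$docetaxel$ic50 <- dr$docetaxel$ic50 * rfac[lines[i]]
    dr
  })
  growth_params(doubling_time = td,
                cell_area = stats::setNames(
                  seq(1, 1.4, length.out = length(lines)), lines),
                capacity = 5e6, combo_model = combo_model,
                synergy_strength = synergy_strength,
                dose_response = dose_response)
}

#' Run the combination-evaluation pipeline
#'
#' Builds a monotherapy viability table for the preset's cell-line panel,
#' ranks all partner drugs against the anchor by IDA score, simulates a
#' mixed-cell growth experiment for the top-ranked (or configured)
#' combination in the representative mixture, and evaluates the efficacy
#' report including the mixture-versus-aggregated comparison and the
#' cluster-level collateral-sensitivity diagnostic.
#'
#' @param preset Preset object or name (see [hetmix_preset()]).
#' @param seed Master seed (used only when `preset` is a name).
#' @param representatives Lines to co-culture; default the preset's mixture
#'   line set (e.g. the represented lines of a selection run).
#' @param combo Optional explicit combination: list with `drugA`, `concA`,
#'   `drugB`, `concB`; default anchor + top-ranked partner at the preset
#'   partner dose.
#' @param combo_model Within-line interaction model for the simulation
#'   (default `"ida_min"`; see [growth_params()]).
#' @param n_replicates Wells per condition (default 6 technical replicates).
#' @param mono_noise_sd Bounded multiplicative noise of the monotherapy
#'   table.
#' @param out_dir Optional output directory for the JSON report and the
#'   ranking CSV.
#' @return A list of class `evaluation_result`: the `ranking`, the chosen
#'   `combo`, the well `observations`, the efficacy `report` and the
#'   `collateral` diagnostic.
#' @export
run_combo_evaluation <- function(preset = "unstratified-CRPC", seed = 1L,
                                 representatives = NULL, combo = NULL,
                                 combo_model = "ida_min",
                                 n_replicates = 6, mono_noise_sd = 0.02,
                                 out_dir = NULL) {
  if (is.character(preset)) preset <- hetmix_preset(preset, seed = seed)
  lines <- representatives %||% preset$mixture_lines
  specs <- preset$config$subtypes

  ranking <- NULL
  if (is.null(combo)) {
    tbl <- suppressMessages(generate_monotherapy_table(
      specs, conc_grid = preset$conc_grid, drugs = preset$drugs,
      lines = preset$config$cell_lines, noise_sd = mono_noise_sd,
      conc_cap = preset$conc_cap, seed = substream_seed(preset$seed, "mono")))
    ranking <- suppressMessages(
      rank_combos(tbl, preset$anchor$drug, preset$anchor$conc))
    partner <- ranking$partner[1]
    combo <- list(drugA = preset$anchor$drug, concA = preset$anchor$conc,
                  drugB = partner,
                  concB = unname(preset$partner_dose[partner] %||%
                                   ranking$partner_conc[1]))
    if (is.na(combo$concB)) combo$concB <- ranking$partner_conc[1]
  }

  growth <- preset_growth_params(preset, lines, combo_model = combo_model)
  ratio <- seeding_ratio(growth$doubling_time)
  seeding <- ratio * (preset$seeding_cells / sum(ratio))
  treatments <- list(
    vehicle = list(),
    mono_a = stats::setNames(list(combo$concA), combo$drugA),
    mono_b = stats::setNames(list(combo$concB), combo$drugB),
    combo = stats::setNames(list(combo$concA, combo$concB),
                            c(combo$drugA, combo$drugB)))
  obs <- generate_growth_experiment(
    growth, seeding, treatments, n_replicates = n_replicates,
    noise_sdlog = preset$noise_sdlog, duration = preset$duration,
    seed = substream_seed(preset$seed, "experiment"))
  report <- evaluate_combo(obs)

  # cluster-level (per-lineage) predicted efficacy of the two drugs
  eff <- vapply(c(A = "drugA", B = "drugB"), function(role) {
    drug <- combo[[role]]
    conc <- combo[[if (role == "drugA") "concA" else "concB"]]
    vapply(specs, function(st) {
      p <- st$dose_response[[drug]]
      1 - hill_viability(conc, p$ic50, p$hill, p$emax)
    }, numeric(1))
  }, numeric(length(specs)))
  collateral <- suppressWarnings(collateral_sensitivity(eff[, "A"],
                                                        eff[, "B"]))

  result <- structure(list(ranking = ranking, combo = combo,
                           observations = obs, report = report,
                           collateral = collateral,
                           lines = lines, preset = preset$name,
                           seed = preset$seed),
                      class = "evaluation_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(ranking))
      utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(preset = preset$name, seed = preset$seed, combo = combo,
           lines = lines,
           mixture = result$report$mixture[c("medians", "best_mono", "p")],
           aggregated = result$report$aggregated[c("medians", "p")],
           per_line = result$report$per_line,
           verdicts = result$report$verdicts[
             c("combo_superior_in_mixture", "combo_superior_in_aggregate")],
           collateral = collateral),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result (%s): %s %g + %s %g in [%s]\n",
              x$preset, x$combo$drugA, x$combo$concA, x$combo$drugB,
              x$combo$concB, paste(x$lines, collapse = ", ")))
  cat(sprintf("  collateral sensitivity: rho = %s (%s)\n",
              format(x$collateral$rho, digits = 3), x$collateral$verdict))
  print(x$report)
  invisible(x)
}
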