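# Synthetic-data generators: patient cohorts, cell-line panels, monotherapy
# screens and co-culture growth experiments with the statistical structure
# the downstream pipeline assumes (latent tumor subtypes with marker genes,
# stromal/immune contamination, cell-line batch effects, Hill dose-response,
# replicate-level observation noise). Everything is driven by one master
# seed through named substreams so modules are testable in isolation.

#' Specification of a latent tumor subtype
#'
#' @param name Subtype label.
#' @param marker_genes Character vector of marker gene ids (must be a subset
#'   of the gene universe defined by `base_profile`).
#' @param base_profile Named numeric vector of per-gene mean log2 expression
#'   over the full gene universe.
#' @param doubling_time Doubling time in hours (> 0) of the cell line(s)
#'   modeling this subtype.
#' @param dose_response Named list `drug -> list(ic50, hill, emax)`.
#' @return An object of class `subtype_spec`.
#' @export
subtype_spec <- function(name, marker_genes, base_profile, doubling_time,
                         dose_response = list()) {
  if (is.null(names(base_profile)))
    stop_bad_arg("`base_profile` must be named by gene id")
  if (!all(marker_genes %in% names(base_profile)))
    stop_bad_arg("marker genes must belong to the gene universe")
  if (doubling_time <= 0) stop_bad_arg("`doubling_time` must be > 0")
  for (p in dose_response) {
    if (p$emax < 0 || p$emax > 1) stop_bad_arg("emax must be in [0, 1]")
    if (p$ic50 <= 0 || p$hill <= 0) stop_bad_arg("ic50 and hill must be > 0")
  }
  structure(list(name = name, marker_genes = marker_genes,
                 base_profile = base_profile,
                 doubling_time = doubling_time,
                 dose_response = dose_response),
            class = "subtype_spec")
}

#' Configuration of a synthetic patient cohort
#'
#' Defines the generative model for bulk tumor expression: each patient has
#' one dominant latent subtype, a tumor purity drawn from a Beta
#' distribution (or fixed), and the remaining fraction split among
#' non-tumor (stromal/immune) cell types. Expression is mixed on the linear
#' scale, log2(x+1)-transformed, and measurement noise is added in log2
#' space. Cell-line samples additionally receive a per-gene location/scale
#' batch distortion.
#'
#' @param subtypes Named list of [subtype_spec()] objects sharing one gene
#'   universe.
#' @param nontumor_profiles Named list of per-gene mean log2 expression for
#'   the non-tumor cell types (same gene universe).
#' @param n_patients Number of patient samples.
#' @param subtype_probs Per-subtype probability that a patient's dominant
#'   subtype is that subtype; must sum to 1.
#' @param tumor_fraction Either a length-2 vector of Beta shape parameters
#'   (default `c(5, 2)`) or a fixed fraction in `(0, 1]`.
#' @param noise_sd Measurement noise sd in log2 units (>= 0).
#' @param batch_shift,batch_scale Per-gene location/scale distortion applied
#'   to cell-line samples in log2 space (scalar or per-gene vector).
#' @param cell_lines Data frame with columns `line`, `subtype`, and
#'   optionally `excluded` (logical; line unavailable for the mixed model)
#'   and `resistant` (logical; a drug-resistant derivative).
#' @param resistance_sets Named list `subtype -> gene ids` perturbed in
#'   resistant derivatives of that subtype's lines.
#' @param resistance_shift Log2 shift applied to resistance-set genes in
#'   resistant lines.
#' @param seed Master integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(subtypes, nontumor_profiles, n_patients,
                          subtype_probs, tumor_fraction = c(5, 2),
                          noise_sd = 0.25, batch_shift = 0, batch_scale = 1,
                          cell_lines = NULL, resistance_sets = list(),
                          resistance_shift = 1, seed = 1L) {
  if (is.null(names(subtypes)) || !all(vapply(subtypes, inherits,
                                              logical(1), "subtype_spec")))
    stop_bad_arg("`subtypes` must be a named list of subtype_spec objects")
  genes <- names(subtypes[[1]]$base_profile)
  for (s in subtypes)
    if (!identical(names(s$base_profile), genes))
      stop_bad_arg("all subtypes must share one gene universe")
  for (p in nontumor_profiles)
    if (!identical(names(p), genes))
      stop_bad_arg("non-tumor profiles must share the gene universe")
  if (abs(sum(subtype_probs) - 1) > 1e-8)
    stop_bad_arg("`subtype_probs` must sum to 1")
  if (!all(names(subtypes) %in% names(subtype_probs)))
    stop_bad_arg("`subtype_probs` must cover every subtype")
  n_markers <- length(unique(unlist(lapply(subtypes, `[[`, "marker_genes"))))
  if (length(genes) < n_markers)
    stop_bad_arg("gene universe smaller than the marker-gene union")
  if (length(tumor_fraction) == 1L &&
      (tumor_fraction <= 0 || tumor_fraction > 1))
    stop_bad_arg("fixed tumor fraction must be in (0, 1]")
  if (noise_sd < 0) stop_bad_arg("`noise_sd` must be >= 0")
  if (is.null(cell_lines))
    cell_lines <- data.frame(line = paste0(names(subtypes), "_line"),
                             subtype = names(subtypes),
                             stringsAsFactors = FALSE)
  if (is.null(cell_lines$excluded)) cell_lines$excluded <- FALSE
  if (is.null(cell_lines$resistant)) cell_lines$resistant <- FALSE
  if (!all(cell_lines$subtype %in% names(subtypes)))
    stop_bad_arg("cell line refers to an unknown subtype")
  structure(list(subtypes = subtypes,
                 nontumor_profiles = nontumor_profiles,
                 genes = genes, n_genes = length(genes),
                 n_patients = as.integer(n_patients),
                 subtype_probs = subtype_probs[names(subtypes)],
                 tumor_fraction = tumor_fraction,
                 noise_sd = noise_sd,
                 batch_shift = batch_shift, batch_scale = batch_scale,
                 cell_lines = cell_lines,
                 resistance_sets = resistance_sets,
                 resistance_shift = resistance_shift,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Linear-scale signature column for a log2 profile.
lin <- function(log2_profile) 2^log2_profile - 1

#' Generate a synthetic bulk-expression cohort
#'
#' Draws, for each patient, a dominant tumor subtype and cell-type
#' fractions, mixes the corresponding linear-scale reference profiles, and
#' returns the log2-transformed bulk matrix together with the ground truth
#' and the cell-type signature matrix used for mixing.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `bulk` (an [expression_matrix()] with role
#'   `"patient"`), `truth` (data frame: sample, dominant subtype, per-type
#'   fractions), and `signatures` (a [signature_matrix()] on the linear
#'   scale).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  types <- c(names(config$subtypes), names(config$nontumor_profiles))
  sig <- vapply(c(lapply(config$subtypes, `[[`, "base_profile"),
                  config$nontumor_profiles),
                lin, numeric(config$n_genes))
  rownames(sig) <- config$genes
  signatures <- signature_matrix(sig, tumor_types = names(config$subtypes))

  n <- config$n_patients
  res <- with_substream(config$seed, "cohort", {
    dominant <- sample(names(config$subtypes), n, replace = TRUE,
                       prob = config$subtype_probs)
    f_tumor <- if (length(config$tumor_fraction) == 2L)
      stats::rbeta(n, config$tumor_fraction[1], config$tumor_fraction[2])
    else rep(config$tumor_fraction, n)
    if (any(f_tumor <= 0)) stop_bad_arg("tumor fraction must be positive")
    k_nt <- length(config$nontumor_profiles)
    nt_frac <- matrix(0, n, k_nt,
                      dimnames = list(NULL, names(config$nontumor_profiles)))
    if (k_nt > 0L) {
      w <- matrix(stats::rgamma(n * k_nt, shape = 2), n, k_nt)
      nt_frac <- (w / rowSums(w)) * (1 - f_tumor)
      colnames(nt_frac) <- names(config$nontumor_profiles)
    }
    noise <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                    config$n_genes, n)
    list(dominant = dominant, f_tumor = f_tumor, nt_frac = nt_frac,
         noise = noise)
  })

  frac <- matrix(0, n, length(types), dimnames = list(NULL, types))
  frac[cbind(seq_len(n), match(res$dominant, types))] <- res$f_tumor
  if (ncol(res$nt_frac) > 0L)
    frac[, colnames(res$nt_frac)] <- res$nt_frac

  bulk_lin <- sig %*% t(frac)
  values <- log2(bulk_lin + 1) + res$noise
  ids <- sprintf("P%03d", seq_len(n))
  colnames(values) <- ids
  rownames(values) <- config$genes
  rownames(frac) <- ids

  truth <- data.frame(sample = ids, subtype = res$dominant,
                      frac, check.names = FALSE, stringsAsFactors = FALSE)
  list(bulk = expression_matrix(values, role = "patient", batch = "patient"),
       truth = truth, signatures = signatures)
}

#' Generate a synthetic cell-line expression panel
#'
#' Each cell line's log2 profile is its subtype's base profile, optionally
#' perturbed on a subtype-specific resistance gene set (for resistant
#' derivatives, emulating drug-resistant clones whose transcriptomes remain
#' close to their parent), then distorted by the per-gene batch shift/scale
#' and measurement noise. Samples carry role `"cell-line"` and batch
#' `"cell-line"`.
#'
#' @param config A [cohort_config()]; the panel composition comes from
#'   `config$cell_lines`.
#' @return An [expression_matrix()].
#' @export
generate_cell_line_panel <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cl <- config$cell_lines
  shift <- rep(config$batch_shift, length.out = config$n_genes)
  scale <- rep(config$batch_scale, length.out = config$n_genes)
  values <- with_substream(config$seed, "panel", {
    vapply(seq_len(nrow(cl)), function(i) {
      st <- config$subtypes[[cl$subtype[i]]]
      if (is.null(st)) stop_bad_arg("unknown subtype: ", cl$subtype[i])
      prof <- st$base_profile
      if (isTRUE(cl$resistant[i])) {
        rset <- config$resistance_sets[[cl$subtype[i]]]
        if (!is.null(rset))
          prof[rset] <- prof[rset] + config$resistance_shift
      }
      prof * scale + shift +
        stats::rnorm(config$n_genes, 0, config$noise_sd)
    }, numeric(config$n_genes))
  })
  colnames(values) <- cl$line
  rownames(values) <- config$genes
  expression_matrix(values, role = "cell-line", batch = "cell-line")
}

#' Generate a synthetic monotherapy viability table
#'
#' Evaluates each line's Hill dose-response over a concentration grid,
#' optionally adding bounded multiplicative noise, and clamps viabilities to
#' `[0, 1]`. Resistant lines have the resisted drug's IC50 multiplied by a
#' per-line factor drawn log-uniformly from `resistance_factor_range`,
#' emulating derivatives with 10-100x greater IC50s than their parents.
#'
#' @param specs Named list of [subtype_spec()] objects carrying the per-drug
#'   Hill parameters.
#' @param conc_grid Non-negative, ascending concentration grid shared by all
#'   drugs.
#' @param drugs Drugs to tabulate (default: all drugs of the first spec).
#' @param lines Data frame with columns `line`, `subtype` and optionally
#'   `resistant`; default one line per spec, named after the subtype.
#' @param noise_sd Half-width of the bounded multiplicative viability noise
#'   (0 = noiseless).
#' @param resisted_drug Drug whose IC50 is inflated in resistant lines.
#' @param resistance_factor_range Log-uniform range of the IC50 inflation.
#' @param conc_cap Named per-drug maximum allowed (clinically sustainable)
#'   concentration, stored as the `conc_cap` attribute; defaults to
#'   `max(conc_grid)` for every drug.
#' @param seed Integer seed.
#' @return Data frame with columns `cell_line`, `drug`, `concentration`,
#'   `viability` and attribute `conc_cap`.
#' @export
generate_monotherapy_table <- function(specs, conc_grid, drugs = NULL,
                                       lines = NULL, noise_sd = 0,
                                       resisted_drug = "docetaxel",
                                       resistance_factor_range = c(10, 100),
                                       conc_cap = NULL, seed = 1L) {
  if (any(conc_grid < 0)) stop_bad_arg("concentrations must be >= 0")
  if (is.unsorted(conc_grid)) stop_bad_arg("`conc_grid` must be ascending")
  drugs <- drugs %||% names(specs[[1]]$dose_response)
  if (is.null(lines))
    lines <- data.frame(line = names(specs), subtype = names(specs),
                        stringsAsFactors = FALSE)
  if (is.null(lines$resistant)) lines$resistant <- FALSE
  conc_cap <- conc_cap %||%
    stats::setNames(rep(max(conc_grid), length(drugs)), drugs)

  rows <- with_substream(seed, "monotherapy", {
    rfac <- stats::setNames(
      10^stats::runif(nrow(lines), log10(resistance_factor_range[1]),
                      log10(resistance_factor_range[2])), lines$line)
    out <- list()
    for (i in seq_len(nrow(lines))) {
      st <- specs[[lines$subtype[i]]]
      if (is.null(st)) stop_bad_arg("unknown subtype: ", lines$subtype[i])
      for (d in drugs) {
        p <- st$dose_response[[d]]
        if (is.null(p))
          stop_bad_arg("spec '", lines$subtype[i], "' lacks drug '", d, "'")
        ic50 <- p$ic50
        if (isTRUE(lines$resistant[i]) && d == resisted_drug)
          ic50 <- ic50 * rfac[lines$line[i]]
        v <- hill_viability(conc_grid, ic50, p$hill, p$emax)
        if (noise_sd > 0)
          v <- v * (1 + stats::runif(length(v), -noise_sd, noise_sd))
        out[[length(out) + 1L]] <- data.frame(
          cell_line = lines$line[i], drug = d, concentration = conc_grid,
          viability = pmin(pmax(v, 0), 1), stringsAsFactors = FALSE)
      }
    }
    out
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  attr(tbl, "conc_cap") <- conc_cap
  tbl
}

#' Generate a synthetic co-culture growth experiment
#'
#' Simulates the deterministic mixture trajectory for each treatment
#' condition, converts cell counts to per-channel imaging areas via the
#' per-line cell-area constants, and applies independent multiplicative
#' lognormal well noise to the areas recorded at treatment start and after
#' `duration` hours (default 5 days).
#'
#' @param growth A [growth_params()] object.
#' @param seeding Named vector of seeded cell counts per line.
#' @param treatments Named list `condition -> named list(drug = conc)`; use
#'   an empty list for the vehicle condition.
#' @param n_replicates Technical replicates (wells) per condition (>= 1).
#' @param noise_sdlog Lognormal sd of the per-well, per-channel area noise.
#' @param duration,dt Passed to [simulate_mixture()].
#' @param seed Integer seed; identical seeds give identical observations.
#' @return Data frame of well observations with columns `well`,
#'   `condition`, `replicate`, `channel`, `area_start`, `area_end`.
#' @export
generate_growth_experiment <- function(growth, seeding, treatments,
                                       n_replicates = 6, noise_sdlog = 0.1,
                                       duration = 120, dt = 1, seed = 1L) {
  if (n_replicates < 1) stop_bad_arg("`n_replicates` must be >= 1")
  if (length(treatments) == 0L || is.null(names(treatments)))
    stop_bad_arg("`treatments` must be a named list of conditions")
  lines <- names(growth$doubling_time)
  obs <- lapply(names(treatments), function(cond) {
    traj <- simulate_mixture(growth, seeding, treatments[[cond]],
                             duration = duration, dt = dt)
    n0 <- traj[1, lines]
    n1 <- traj[nrow(traj), lines]
    a0 <- n0 * growth$cell_area
    a1 <- n1 * growth$cell_area
    with_substream(seed, paste0("wells:", cond), {
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        e0 <- exp(stats::rnorm(length(lines), 0, noise_sdlog))
        e1 <- exp(stats::rnorm(length(lines), 0, noise_sdlog))
        data.frame(well = sprintf("%s_r%d", cond, r), condition = cond,
                   replicate = r, channel = lines,
                   area_start = unname(a0 * e0),
                   area_end = unname(a1 * e1),
                   stringsAsFactors = FALSE)
      }))
    })
  })
  out <- do.call(rbind, obs)
  rownames(out) <- NULL
  out
}
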