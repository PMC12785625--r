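# Built-in synthetic scenario presets. The unstratified preset emulates a
# CRPC-like cohort with four latent lineages -- an AR-negative
# adenocarcinoma, an AR-plus-variant lineage, a variant-only lineage and a
# neuroendocrine-like (NEPC) lineage whose only matching cell line cannot
# be co-cultured and is therefore excludable -- plus stromal and immune
# contamination. The taxane-resistant preset adds docetaxel-resistant
# derivative lines whose transcriptomes are bounded perturbations of their
# parents (lineage-specific resistance programs) and whose docetaxel IC50s
# are 10-100x the parental values.

crpc_subtype_names <- c("AR_negative", "AR_variant", "ARv_only", "NEPC_like")

# Hill parameters (ic50 in nM) per drug and subtype. Sensitivities are
# complementary by construction: docetaxel hits the AR-variant lineages,
# daporinad the AR-negative and NEPC-like lineages, the variant-only
# lineage responds to both; selumetinib is selective for the AR-variant
# lineage; cabazitaxel and vinorelbine are moderately pan-active;
# paclitaxel mirrors docetaxel; dasatinib and the inert control are weak.
crpc_drug_panel <- function() {
  ic50 <- list(
    docetaxel     = c(AR_negative = 400, AR_variant = 2,   ARv_only = 3,
                      NEPC_like = 300),
    daporinad     = c(AR_negative = 2.2, AR_variant = 900, ARv_only = 3.5,
                      NEPC_like = 2.5),
    selumetinib   = c(AR_negative = 600, AR_variant = 2,   ARv_only = 600,
                      NEPC_like = 600),
    cabazitaxel   = c(AR_negative = 7,   AR_variant = 7,   ARv_only = 7,
                      NEPC_like = 7),
    vinorelbine   = c(AR_negative = 7,   AR_variant = 7,   ARv_only = 7,
                      NEPC_like = 7),
    paclitaxel    = c(AR_negative = 400, AR_variant = 2,   ARv_only = 3,
                      NEPC_like = 300),
    dasatinib     = c(AR_negative = 50,  AR_variant = 50,  ARv_only = 50,
                      NEPC_like = 50),
    inert_control = c(AR_negative = 50,  AR_variant = 50,  ARv_only = 50,
                      NEPC_like = 50))
  emax <- c(docetaxel = 0.95, daporinad = 0.95, selumetinib = 0.95,
            cabazitaxel = 0.95, vinorelbine = 0.95, paclitaxel = 0.95,
            dasatinib = 0.4, inert_control = 0.05)
  lapply(stats::setNames(nm = crpc_subtype_names), function(st) {
    lapply(stats::setNames(nm = names(ic50)), function(d) {
      list(ic50 = unname(ic50[[d]][st]), hill = 2, emax = unname(emax[[d]]))
    })
  })
}

#' Built-in synthetic scenario presets
#'
#' Constructs the full configuration of one of the two study scenarios: the
#' unstratified cohort (208 patients, four latent lineages, one candidate
#' cell line each, the NEPC-like line excludable) or the taxane-resistant
#' cohort (79 taxane-exposed patients, parental and docetaxel-resistant
#' clone pairs for three lineages). Gene universe: 2000 genes with 100
#' disjoint marker genes per cell type (4 tumor lineages + stroma + immune)
#' at a 2-log2 (4-fold) marker elevation, measurement noise 0.25 log2,
#' tumor purity ~ Beta(5, 2), and a per-gene cell-line batch distortion.
#'
#' @param name Preset name: `"unstratified-CRPC"` or
#'   `"taxane-resistant-CRPC"`.
#' @param seed Master seed driving every random draw of the scenario.
#' @param n_patients Cohort size override (defaults: 208 unstratified, 79
#'   taxane-resistant).
#' @param n_genes Gene universe size (default 2000).
#' @return A list with the [cohort_config()] (`$config`), drug/concentration
#'   settings for combination ranking and evaluation, the mixture line set,
#'   excludable lines, and AR/NEPC marker sets.
#' @export
hetmix_preset <- function(name = c("unstratified-CRPC",
                                   "taxane-resistant-CRPC"),
                          seed = 1L, n_patients = NULL, n_genes = 2000) {
  name <- match.arg(name)
  n_markers <- 200
  genes <- sprintf("g%04d", seq_len(n_genes))
  stopifnot(n_genes >= 6 * n_markers + 3 * 40)

  base <- with_substream(seed, "universe",
                         stats::setNames(stats::runif(n_genes, 4, 8), genes))
  block <- function(i) genes[((i - 1) * n_markers + 1):(i * n_markers)]
  marker_lfc <- 2
  drug_panel <- crpc_drug_panel()
  doubling <- c(AR_negative = 28, AR_variant = 56, ARv_only = 56,
                NEPC_like = 42)
  subtypes <- lapply(seq_along(crpc_subtype_names), function(i) {
    st <- crpc_subtype_names[i]
    prof <- base
    prof[block(i)] <- prof[block(i)] + marker_lfc
    subtype_spec(st, marker_genes = block(i), base_profile = prof,
                 doubling_time = doubling[[st]],
                 dose_response = drug_panel[[st]])
  })
  names(subtypes) <- crpc_subtype_names
  nontumor <- lapply(c(stroma = 5, immune = 6), function(i) {
    prof <- base
    prof[block(i)] <- prof[block(i)] + marker_lfc
    prof
  })

  # lineage-specific resistance programs (NAMPT/PI3K-like, MEK/ERK-like),
  # outside the marker blocks
  r0 <- 6 * n_markers
  resistance_sets <- list(AR_negative = genes[(r0 + 1):(r0 + 40)],
                          AR_variant = genes[(r0 + 41):(r0 + 80)],
                          ARv_only = genes[(r0 + 81):(r0 + 120)])

  batch_shift <- with_substream(seed, "batch",
                                stats::rnorm(n_genes, 0.8, 0.3))

  if (name == "unstratified-CRPC") {
    n_patients <- n_patients %||% 208L
    cell_lines <- data.frame(
      line = c("DU145_like", "22RV1_like", "R1D567_like", "H660_like"),
      subtype = crpc_subtype_names,
      excluded = c(FALSE, FALSE, FALSE, TRUE),
      resistant = FALSE, stringsAsFactors = FALSE)
    mixture_lines <- c("DU145_like", "22RV1_like", "R1D567_like")
  } else {
    n_patients <- n_patients %||% 79L
    parents <- c("doceS_DU145", "doceS_22RV1", "doceS_R1D567")
    resistant <- c("doceR_DU145", "doceR_22RV1", "doceR_R1D567")
    cell_lines <- data.frame(
      line = c(parents, resistant, "H660_like"),
      subtype = c(rep(crpc_subtype_names[1:3], 2), "NEPC_like"),
      excluded = c(rep(FALSE, 6), TRUE),
      resistant = c(rep(FALSE, 3), rep(TRUE, 3), FALSE),
      stringsAsFactors = FALSE)
    mixture_lines <- resistant
  }

  config <- cohort_config(
    subtypes = subtypes, nontumor_profiles = nontumor,
    n_patients = n_patients,
    subtype_probs = c(AR_negative = 0.3, AR_variant = 0.3,
                      ARv_only = 0.25, NEPC_like = 0.15),
    tumor_fraction = c(5, 2), noise_sd = 0.25,
    batch_shift = batch_shift, batch_scale = 1,
    cell_lines = cell_lines, resistance_sets = resistance_sets,
    resistance_shift = 1, seed = seed)

  conc_grid <- c(0.5, 1, 3, 5, 10, 30, 60, 100)
  drugs <- names(drug_panel[[1]])
  anchor <- if (name == "unstratified-CRPC")
    list(drug = "docetaxel", conc = 3) else
    list(drug = "selumetinib", conc = 5)

  list(name = name, seed = seed, config = config,
       drugs = drugs, conc_grid = conc_grid,
       conc_cap = stats::setNames(rep(100, length(drugs)), drugs),
       anchor = anchor,
       partner_dose = c(daporinad = 5, selumetinib = 5, vinorelbine = 3,
                        cabazitaxel = 3, docetaxel = 3, dasatinib = 5,
                        inert_control = 5, paclitaxel = 3),
       mixture_lines = mixture_lines,
       excluded_lines = cell_lines$line[cell_lines$excluded],
       deconv_genes = genes[seq_len(6 * n_markers)],
       marker_sets = list(
         AR_signature = subtypes$AR_variant$marker_genes,
         NEPC_signature = subtypes$NEPC_like$marker_genes),
       seeding_cells = 50000, duration = 120, noise_sdlog = 0.1)
}

#' Synthetic expression-to-AUC screening scenario with planted
#' resistant-selective drugs
#'
#' Builds a training panel of cell lines with iid log2 expression and
#' per-drug AUC responses generated from sparse linear models, plus
#' docetaxel-sensitive/-resistant clone profiles for two lineages. Each
#' lineage upregulates its own resistance gene program in the resistant
#' clone, and one planted drug per lineage has negative AUC coefficients on
#' exactly that program (a MEK-inhibitor-like drug for the first lineage,
#' an NAMPT-inhibitor-like drug for the second), so the resistant clone is
#' truly more sensitive to the planted drug. Decoy drugs act through
#' unrelated genes.
#'
#' @param seed Integer seed.
#' @param n_train Training panel size (default 100 lines).
#' @param n_genes Gene count (default 300).
#' @param n_decoys Number of decoy drugs (default 8).
#' @param n_reps Replicate expression draws per clone (default 5).
#' @param rep_sd Per-gene sd of the replicate draws (default 0.1).
#' @return List with `x_train` (genes x lines, log2), `auc` (drugs x
#'   lines), per-lineage clone replicate matrices (`clones`), and the
#'   planted drug per lineage (`planted`).
#' @export
generate_resistance_screen <- function(seed = 1L, n_train = 100,
                                       n_genes = 300, n_decoys = 8,
                                       n_reps = 5, rep_sd = 0.1) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  sets <- list(`22RV1` = genes[1:30], DU145 = genes[31:60])
  planted <- c(`22RV1` = "MEK_inhibitor", DU145 = "NAMPT_inhibitor")
  with_substream(seed, "screen", {
    x_train <- matrix(stats::rnorm(n_genes * n_train, 6, 1), n_genes,
                      n_train, dimnames = list(genes,
                                               sprintf("CCL%03d",
                                                       seq_len(n_train))))
    beta <- matrix(0, n_genes, 2 + n_decoys,
                   dimnames = list(genes,
                                   c(planted,
                                     sprintf("decoy_%02d",
                                             seq_len(n_decoys)))))
    beta[sets$`22RV1`, "MEK_inhibitor"] <- -0.02
    beta[sets$DU145, "NAMPT_inhibitor"] <- -0.02
    for (j in seq_len(n_decoys)) {
      idx <- sample(61:n_genes, 10)
      beta[idx, 2 + j] <- stats::rnorm(10, 0, 0.02)
    }
    auc <- t(beta) %*% (x_train - 6) / 1 + 0.7 +
      matrix(stats::rnorm(ncol(beta) * n_train, 0, 0.02), ncol(beta),
             n_train)
    clones <- lapply(names(sets), function(lg) {
      prof <- 6 + stats::rnorm(n_genes, 0, 0.3)
      names(prof) <- genes
      res_prof <- prof
      res_prof[sets[[lg]]] <- res_prof[sets[[lg]]] + 1.5
      draw <- function(p, tag) {
        m <- vapply(seq_len(n_reps), function(r)
          p + stats::rnorm(n_genes, 0, rep_sd), numeric(n_genes))
        dimnames(m) <- list(genes, sprintf("%s_%s_r%d", lg, tag,
                                           seq_len(n_reps)))
        m
      }
      list(sensitive = draw(prof, "S"), resistant = draw(res_prof, "R"))
    })
    names(clones) <- names(sets)
    list(x_train = x_train, auc = auc, clones = clones, planted = planted,
         resistance_sets = sets)
  })
}

#' Run a differential-sensitivity screen over a drug panel
#'
#' For every drug, fits an expression-to-AUC ridge model on the training
#' panel ([fit_and_predict()]), predicts the AUC of each sensitive and
#' resistant replicate profile, and contrasts the groups with
#' [differential_sensitivity()].
#'
#' @param x_train Training expression (genes x lines).
#' @param auc Drug x line matrix of training AUCs.
#' @param x_sensitive,x_resistant Replicate expression profiles of the
#'   sensitive and resistant clones (genes x replicates).
#' @param seed Seed for the cross-validation fold assignments.
#' @return The [differential_sensitivity()] table, one row per drug, sorted
#'   by the signed t statistic (most resistant-selective first).
#' @export
run_sensitivity_screen <- function(x_train, auc, x_sensitive, x_resistant,
                                   seed = 1L) {
  drugs <- rownames(auc)
  preds <- lapply(drugs, function(d) {
    fp <- fit_and_predict(x_train, auc[d, ],
                          cbind(x_sensitive, x_resistant),
                          seed = substream_seed(seed, paste0("cv:", d)))
    fp$predictions
  })
  pred_s <- do.call(rbind, lapply(preds, `[`, seq_len(ncol(x_sensitive))))
  pred_r <- do.call(rbind, lapply(preds, function(p)
    p[ncol(x_sensitive) + seq_len(ncol(x_resistant))]))
  rownames(pred_s) <- rownames(pred_r) <- drugs
  out <- differential_sensitivity(pred_s, pred_r)
  out[order(out$t), ]
}
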