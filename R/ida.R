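# Independent drug action (IDA) combination scoring: under IDA each tumor
# (cell line) benefits from the single most effective drug in the
# combination, so the predicted per-line combo viability is the minimum of
# the monotherapy viabilities. The combo score is the mean-viability gain
# of the combo over the best single agent across the line panel.

# Pull per-line viabilities for one (drug, conc) from a monotherapy table.
mono_viability <- function(table, drug, conc, tol = 1e-9) {
  sel <- table$drug == drug & abs(table$concentration - conc) < tol
  stats::setNames(table$viability[sel], table$cell_line[sel])
}

#' IDA combination efficacy score
#'
#' For every cell line with measurements for both (drug, concentration)
#' pairs, the predicted combination viability is
#' `min(v(A, cA), v(B, cB))`. The best monotherapy is the single
#' (drug, conc) of the pair with the lower mean viability across the shared
#' lines, and the score is
#' `mean(best mono viability) - mean(combo viability)`, which is always
#' `>= 0`; higher scores predict greater combination efficacy in a
#' heterogeneous population.
#'
#' @param table Monotherapy table: data frame with columns `cell_line`,
#'   `drug`, `concentration`, `viability` (in `[0, 1]`).
#' @param drugA,drugB Drug identifiers.
#' @param concA,concB Tested concentrations.
#' @return An object of class `combo_prediction`: list with the per-line
#'   viabilities, the mean combo viability, the best-mono choice and the
#'   `score`.
#' @export
ida_combo_score <- function(table, drugA, drugB, concA, concB) {
  vA <- mono_viability(table, drugA, concA)
  vB <- mono_viability(table, drugB, concB)
  shared <- intersect(names(vA), names(vB))
  dropped <- length(union(names(vA), names(vB))) - length(shared)
  if (dropped > 0)
    message(dropped, " line(s) lacking one measurement dropped")
  if (length(shared) == 0L)
    stop_bad_arg("no cell line has measurements for both drugs")
  vA <- vA[shared]; vB <- vB[shared]
  v_combo <- pmin(vA, vB)
  means <- c(A = mean(vA), B = mean(vB))
  best <- if (means["A"] <= means["B"]) {
    list(drug = drugA, conc = concA, mean_viability = unname(means["A"]))
  } else {
    list(drug = drugB, conc = concB, mean_viability = unname(means["B"]))
  }
  structure(list(drugA = drugA, drugB = drugB, concA = concA, concB = concB,
                 per_line = data.frame(line = shared, vA = unname(vA),
                                       vB = unname(vB),
                                       v_combo = unname(v_combo),
                                       stringsAsFactors = FALSE),
                 mean_combo = mean(v_combo), best_mono = best,
                 score = best$mean_viability - mean(v_combo),
                 n_lines = length(shared)),
            class = "combo_prediction")
}

#' @export
print.combo_prediction <- function(x, ...) {
  cat(sprintf("combo %s (%g) + %s (%g): score %.4f over %d lines\n",
              x$drugA, x$concA, x$drugB, x$concB, x$score, x$n_lines))
  cat(sprintf("  best mono: %s @ %g (mean viability %.3f); combo mean %.3f\n",
              x$best_mono$drug, x$best_mono$conc,
              x$best_mono$mean_viability, x$mean_combo))
  invisible(x)
}

#' Rank partner drugs for an anchor drug by IDA score
#'
#' For each partner drug, evaluates the IDA score against the anchor (at a
#' fixed anchor concentration) over the partner's tested concentrations up
#' to its maximum allowed (clinically sustainable) concentration, and
#' records the maximum. Partners are ranked in decreasing score order, ties
#' broken lexicographically by drug id.
#'
#' @param table Monotherapy table (see [ida_combo_score()]); its `conc_cap`
#'   attribute, if present, supplies per-drug concentration caps.
#' @param anchor_drug Anchor drug id.
#' @param anchor_conc Fixed anchor concentration.
#' @param partners Partner drug ids (default: all other drugs in the table).
#' @param conc_caps Named per-drug maximum allowed concentration; partners
#'   without a cap use their full tested grid.
#' @return Data frame with one row per partner: `anchor`, `partner`,
#'   `anchor_conc`, `partner_conc` (the maximizing concentration), `score`,
#'   `n_lines`, sorted by decreasing score.
#' @export
rank_combos <- function(table, anchor_drug, anchor_conc, partners = NULL,
                        conc_caps = attr(table, "conc_cap")) {
  partners <- partners %||% setdiff(unique(table$drug), anchor_drug)
  if (length(partners) == 0L) stop_bad_arg("empty partner set")
  rows <- lapply(sort(partners), function(p) {
    grid <- sort(unique(table$concentration[table$drug == p]))
    if (!is.null(conc_caps) && p %in% names(conc_caps))
      grid <- grid[grid <= conc_caps[[p]]]
    if (length(grid) == 0L) return(NULL)
    preds <- lapply(grid, function(cc)
      ida_combo_score(table, anchor_drug, p, anchor_conc, cc))
    scores <- vapply(preds, `[[`, numeric(1), "score")
    i <- which.max(scores)
    data.frame(anchor = anchor_drug, partner = p,
               anchor_conc = anchor_conc, partner_conc = grid[i],
               score = scores[i], n_lines = preds[[i]]$n_lines,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$partner), ]
  rownames(out) <- NULL
  out
}

#' Collateral-sensitivity diagnostic across patient clusters
#'
#' Spearman rank correlation of two drugs' per-cluster predicted
#' efficacies. A negative correlation (the clusters responding least to one
#' drug respond most to the other) is the collateral-sensitivity pattern
#' that makes IDA combinations effective in heterogeneous cohorts.
#'
#' @param eff_a,eff_b Per-cluster mean predicted efficacies for the two
#'   drugs (same cluster order, length >= 3).
#' @return List with `rho` (Spearman correlation), and `verdict`:
#'   `"collateral"` (rho < 0), `"redundant"` (rho >= 0) or `"undefined"`
#'   (constant input).
#' @export
collateral_sensitivity <- function(eff_a, eff_b) {
  if (length(eff_a) != length(eff_b) || length(eff_a) < 3L)
    stop_bad_arg("need per-cluster efficacies for >= 3 clusters")
  if (stats::sd(eff_a) == 0 || stats::sd(eff_b) == 0) {
    warning("constant efficacy vector: correlation undefined")
    return(list(rho = NA_real_, verdict = "undefined"))
  }
  rho <- stats::cor(eff_a, eff_b, method = "spearman")
  list(rho = rho, verdict = if (rho < 0) "collateral" else "redundant")
}
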