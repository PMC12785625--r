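# Well-level efficacy readouts: normalized growth areas, mixture
# proliferation, exact/approximate Mann-Whitney U tests, Bliss independence
# synergy, and the mixture-versus-aggregated combination verdict.

#' Normalized growth area per well and channel
#'
#' Divides each channel's area at the treatment endpoint by its area at the
#' treatment start, normalizing for differences in seeding density across
#' wells.
#'
#' @param obs Well observations: data frame with columns `well`,
#'   `condition`, `replicate`, `channel`, `area_start`, `area_end`.
#' @return The input with an added `norm_growth` column.
#' @export
normalized_growth_area <- function(obs) {
  need <- c("well", "condition", "replicate", "channel",
            "area_start", "area_end")
  if (!all(need %in% names(obs)))
    stop_bad_arg("observations need columns: ", paste(need, collapse = ", "))
  bad <- obs$area_start <= 0
  if (any(bad))
    stop_bad_arg("zero or negative start area in well/channel: ",
                 paste(sprintf("%s/%s", obs$well[bad], obs$channel[bad]),
                       collapse = ", "))
  obs$norm_growth <- obs$area_end / obs$area_start
  obs
}

#' Mixture proliferation per well
#'
#' Sums the channel-normalized growth ratios within each well, treating the
#' co-culture as one composite tumor.
#'
#' @param norm Output of [normalized_growth_area()].
#' @return Data frame with one row per well: `well`, `condition`,
#'   `replicate`, `proliferation`.
#' @export
mixture_proliferation <- function(norm) {
  if (is.null(norm$norm_growth))
    stop_bad_arg("run normalized_growth_area() first")
  channels <- sort(unique(norm$channel))
  by_well <- split(norm, norm$well)
  rows <- lapply(by_well, function(w) {
    if (!setequal(w$channel, channels))
      stop_bad_arg("well ", w$well[1], " is missing channel(s): ",
                   paste(setdiff(channels, w$channel), collapse = ", "))
    data.frame(well = w$well[1], condition = w$condition[1],
               replicate = w$replicate[1],
               proliferation = sum(w$norm_growth),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$replicate), ]
}

#' Mann-Whitney U test
#'
#' Rank-sum test with `U = #\{(i, j): x_i > y_j\} + #ties / 2`. For small
#' samples (`n, m <= 8`) without ties, p-values come from the exact null
#' distribution of U; otherwise a normal approximation with tie and
#' continuity corrections is used. Two-sided p-values double the smaller
#' tail (capped at 1).
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` (x tends smaller)
#'   or `"greater"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   default chooses automatically.
#' @return List with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop_bad_arg("both samples must be non-empty")
  n <- length(x); m <- length(y)
  cmp <- outer(x, y, ">")
  ties <- outer(x, y, "==")
  U <- sum(cmp) + sum(ties) / 2
  has_ties <- any(duplicated(c(x, y)))
  use_exact <- exact %||% (n <= 8 && m <= 8 && !has_ties)
  if (use_exact && has_ties) use_exact <- FALSE

  if (use_exact) {
    p_less <- stats::pwilcox(U, n, m)
    p_greater <- 1 - stats::pwilcox(U - 1, n, m)
    p <- switch(alternative,
                less = p_less,
                greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    return(list(U = U, p = p, method = "exact"))
  }

  N <- n + m
  tie_counts <- table(c(x, y))
  tie_term <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
  sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
  z <- U - n * m / 2
  # continuity correction toward the alternative, as in the classical
  # normal approximation; a centered statistic gives p = 1 two-sided
  p <- switch(alternative,
              less = stats::pnorm((z + 0.5) / sigma),
              greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
              two.sided = {
                zc <- (z - sign(z) * 0.5) / sigma
                min(1, 2 * (if (z > 0) stats::pnorm(zc, lower.tail = FALSE)
                            else stats::pnorm(zc)))
              })
  list(U = U, p = p, method = "normal")
}

#' Bliss independence synergy score
#'
#' Given inhibition fractions of the two single agents and the combination,
#' the score is the observed combination inhibition minus the Bliss
#' expectation `eA + eB - eA * eB`. Positive scores indicate synergy,
#' values near zero independence, negative scores antagonism.
#'
#' @param e_a,e_b,e_ab Inhibition fractions in `[0, 1]` (values within
#'   `tol` outside are clipped; larger violations are errors).
#' @param tol Clipping tolerance (default 1e-8).
#' @return The Bliss synergy score.
#' @export
bliss_synergy <- function(e_a, e_b, e_ab, tol = 1e-8) {
  clip01 <- function(e, nm) {
    if (any(e < -tol | e > 1 + tol))
      stop_bad_arg("`", nm, "` must be an inhibition fraction in [0, 1]")
    pmin(pmax(e, 0), 1)
  }
  e_a <- clip01(e_a, "e_a"); e_b <- clip01(e_b, "e_b")
  e_ab <- clip01(e_ab, "e_ab")
  e_ab - (e_a + e_b - e_a * e_b)
}

#' Evaluate a drug combination from well observations
#'
#' Computes the complete readout of one mixed-cell combination experiment
#' with conditions vehicle / monotherapy A / monotherapy B / combination:
#'
#' * per-line tests of the combination against that line's best
#'   monotherapy (the dashed-line reference: lower median normalized
#'   growth within the line), plus a per-line Bliss synergy score from
#'   vehicle-relative median inhibitions;
#' * the mixture-level test: combination versus the best monotherapy by
#'   median mixture proliferation;
#' * the aggregated analysis mimicking common pharmacological practice:
#'   per-line normalized ratios pooled across lines per condition, then the
#'   same comparison on the pooled values;
#' * verdict booleans at level `alpha`.
#'
#' @param obs Well observations (see [normalized_growth_area()]) covering
#'   all four conditions with >= 5 replicates each.
#' @param conditions Named character vector mapping the roles `vehicle`,
#'   `mono_a`, `mono_b`, `combo` to condition labels in `obs`.
#' @param alpha Significance level (default 0.05); tests are two-sided with
#'   no multiplicity correction within the experiment.
#' @return An object of class `efficacy_report`.
#' @export
evaluate_combo <- function(obs,
                           conditions = c(vehicle = "vehicle",
                                          mono_a = "mono_a",
                                          mono_b = "mono_b",
                                          combo = "combo"),
                           alpha = 0.05) {
  need <- c("vehicle", "mono_a", "mono_b", "combo")
  if (!all(need %in% names(conditions)))
    stop_bad_arg("`conditions` must name: ", paste(need, collapse = ", "))
  missing_cond <- setdiff(conditions[need], unique(obs$condition))
  if (length(missing_cond))
    stop_bad_arg("missing condition(s) in the observations: ",
                 paste(missing_cond, collapse = ", "))
  norm <- normalized_growth_area(obs)
  norm <- norm[norm$condition %in% conditions[need], ]
  reps <- tapply(norm$well, norm$condition,
                 function(w) length(unique(w)))
  if (any(reps < 5))
    stop_bad_arg("need >= 5 replicates per condition; short: ",
                 paste(names(reps)[reps < 5], collapse = ", "))
  mix <- mixture_proliferation(norm)

  prolif <- function(cond) mix$proliferation[mix$condition == cond]
  med_mix <- vapply(conditions[need], function(cc) stats::median(prolif(cc)),
                    numeric(1))
  names(med_mix) <- need
  best_role <- if (med_mix["mono_a"] <= med_mix["mono_b"]) "mono_a" else
    "mono_b"
  best_cond <- conditions[[best_role]]

  mix_test <- mann_whitney_u(prolif(conditions[["combo"]]),
                             prolif(best_cond))
  mixture <- list(medians = med_mix, best_mono = best_cond,
                  best_mono_role = best_role,
                  U = mix_test$U, p = mix_test$p)

  pooled <- function(cond) norm$norm_growth[norm$condition == cond]
  agg_test <- mann_whitney_u(pooled(conditions[["combo"]]),
                             pooled(best_cond))
  aggregated <- list(
    medians = vapply(conditions[need],
                     function(cc) stats::median(pooled(cc)), numeric(1)),
    best_mono = best_cond, U = agg_test$U, p = agg_test$p)
  names(aggregated$medians) <- need

  lines <- sort(unique(norm$channel))
  per_line <- do.call(rbind, lapply(lines, function(l) {
    g <- function(cond) norm$norm_growth[norm$condition == cond &
                                           norm$channel == l]
    med <- vapply(conditions[need], function(cc) stats::median(g(cc)),
                  numeric(1))
    names(med) <- need
    line_best <- if (med["mono_a"] <= med["mono_b"]) "mono_a" else "mono_b"
    tst <- mann_whitney_u(g(conditions[["combo"]]),
                          g(conditions[[line_best]]))
    inhib <- function(role) min(max(1 - med[role] / med["vehicle"], 0), 1)
    bliss <- bliss_synergy(inhib("mono_a"), inhib("mono_b"), inhib("combo"))
    data.frame(line = l, median_vehicle = med[["vehicle"]],
               median_mono_a = med[["mono_a"]],
               median_mono_b = med[["mono_b"]],
               median_combo = med[["combo"]],
               best_mono = conditions[[line_best]],
               p_combo_vs_best = tst$p, bliss_score = bliss,
               stringsAsFactors = FALSE)
  }))
  rownames(per_line) <- NULL

  verdicts <- list(
    combo_superior_in_mixture = unname(
      mix_test$p < alpha && med_mix["combo"] < med_mix[best_role]),
    combo_superior_in_aggregate = unname(
      agg_test$p < alpha &&
        aggregated$medians["combo"] < aggregated$medians[best_role]),
    per_line_synergy = stats::setNames(
      per_line$p_combo_vs_best < alpha &
        per_line$median_combo < pmin(per_line$median_mono_a,
                                     per_line$median_mono_b) &
        per_line$bliss_score > 0,
      per_line$line))

  structure(list(per_line = per_line, mixture = mixture,
                 aggregated = aggregated, verdicts = verdicts,
                 alpha = alpha, conditions = conditions),
            class = "efficacy_report")
}

#' @export
print.efficacy_report <- function(x, ...) {
  cat("efficacy_report\n")
  cat(sprintf("  mixture: best mono = %s, combo p = %.4g -> superior: %s\n",
              x$mixture$best_mono, x$mixture$p,
              x$verdicts$combo_superior_in_mixture))
  cat(sprintf("  aggregated: combo p = %.4g -> superior: %s\n",
              x$aggregated$p, x$verdicts$combo_superior_in_aggregate))
  print(x$per_line, row.names = FALSE, digits = 3)
  invisible(x)
}
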