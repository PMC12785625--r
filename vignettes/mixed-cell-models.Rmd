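---
title: "Mixed-cell models of inter-patient tumor heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-cell models of inter-patient tumor heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Preclinical drug testing is usually carried out one model at a time, and
per-model responses are then aggregated. Combinations whose benefit comes
from *independent drug action* (IDA) — each drug rescuing the subset of
patients or tumor subtypes sensitive to it — look unremarkable in any single
model and are diluted away by aggregation, yet they are exactly the
combinations expected to help a heterogeneous cohort. `hetmix` implements a
computational counterpart of a mixed-cell modeling workflow for this
problem, using castration-resistant prostate cancer (CRPC) as the motivating
disease:

1. **Match cell lines to patient tumor clusters.** Bulk patient expression
   is purified to tumor-only profiles, integrated with cell-line profiles,
   batch-corrected, and clustered; each patient cluster is assigned the
   transcriptomically closest cell line.
2. **Nominate combinations under IDA.** Monotherapy viability tables over a
   cell-line panel are scanned for partner drugs whose sensitivity profile
   complements an anchor drug.
3. **Evaluate combinations in the mixture.** Co-cultures of the
   representative lines are simulated (or measured) well by well, and the
   combination is judged at the *mixture* level — alongside the
   conventional aggregated analysis that the mixture analysis is designed
   to improve upon.

Everything runs on a seeded synthetic generator, so the full pipeline is
testable end to end without downloads.

# The synthetic cohort generator

Each patient carries one dominant latent tumor subtype. The built-in CRPC
scenario uses four: an AR-negative adenocarcinoma lineage, an
AR-plus-variant lineage, a variant-only lineage, and a neuroendocrine-like
(NEPC) lineage. Expression is generated per sample as a linear-scale
mixture

\[
b_{gs} = f_s\, T_{g,k(s)} + \sum_{j \in \text{non-tumor}} f_{js}\, N_{gj},
\]

then transformed to `log2(x + 1)`, after which Gaussian measurement noise
is added in log2 space. Mixing is linear because transcript abundances add;
clustering happens in log space because that is where RNA-seq distances are
taken. Defaults, chosen once to give separable but non-trivial structure:

* gene universe 2,000 genes; 200 disjoint marker genes per cell type
  (4 tumor lineages + stroma + immune) elevated by 2 log2 units (4-fold).
  A sizable informative fraction of the transcriptome mirrors real tumor
  data, where lineage programs span thousands of genes; it also keeps the
  cluster signal above the noise that purification re-amplifies (below).
* tumor purity \(f_s \sim \mathrm{Beta}(5, 2)\) (mean 0.71), non-tumor mass
  split between stroma and immune by a symmetric Dirichlet draw;
* measurement noise 0.25 log2 units;
* cell lines get a per-gene batch distortion (location ~ N(0.8, 0.3),
  scale 1) plus the same measurement noise;
* cohort sizes 208 (unstratified scenario) and 79 (taxane-resistant
  scenario); the taxane scenario adds docetaxel-resistant (doceR)
  derivatives whose profiles differ from their parents only on a
  40-gene lineage-specific resistance program (+1 log2) — a perturbation
  deliberately smaller than any inter-lineage distance — and whose
  docetaxel IC50s are inflated 10–100x (log-uniform).

All randomness flows from one master seed through named substreams
(`cohort`, `panel`, `monotherapy`, `wells:<condition>`, ...), so each
module is reproducible in isolation and identical configurations are
bit-identical.

What the generator does *not* emulate: gene–gene correlation beyond the
block structure, count-level sampling noise, isoform effects, or
real cell-line compendium distributions. Green tests therefore certify the pipeline's
logic and its statistical behavior under the stated model, not performance
on real RNA-seq.

# Tumor purification

`estimate_fractions()` fits each bulk sample (linear scale) onto the
columns of a cell-type signature matrix by non-negative least squares and
normalizes the coefficients to sum to one; `impute_tumor_expression()`
inverts the mixture,

\[
\hat T_{gs} = \max\!\big(0,\; b_{gs} - \textstyle\sum_{j \ne \text{tumor}}
\hat f_{js} S_{gj}\big) \,/\, \hat f_{\text{tumor},s},
\]

returned as `log2(x + 1)`. This is a deliberately simple, documented
surrogate for reference-based deconvolution platforms: the clustering
pipeline needs tumor-purified profiles, not bit-compatibility with any
particular tool. Two numerical choices matter:

* **Fractions are estimated on marker genes only.** Whole-transcriptome
  signature columns are nearly collinear (cell types share most of their
  baseline), which makes NNLS fractions unstable; restricting the fit to
  the marker union makes types identifiable, exactly as signature matrices
  for deconvolution tools are built from differentially expressed genes.
  Imputation then uses the full-gene signature.
* **`min_tumor_fraction = 0.2`.** Division by \(\hat f\) amplifies
  measurement noise by \(1/f\); samples below 20% estimated purity are
  excluded with a warning rather than purified into noise.

Noiseless mixtures are recovered to machine precision (tested to 1e-6 over
random fractions); fraction error grows monotonically with the noise level;
and scaling a bulk sample by any positive constant leaves fractions
unchanged.

# Integration, batch correction, clustering

`combat_correct()` wraps the standard parametric empirical-Bayes
location/scale adjustment (ComBat from the sva package). Genes with zero
pooled variance cannot be standardized and pass through unchanged. Because
empirical-Bayes shrinkage leaves a residual of \((1-w)(\hat\gamma_g -
\bar\gamma)\) in each batch mean, exact removal of a known shift and exact
pooled-mean preservation hold in the low-noise limit; the tests check a +2
shift at within-batch noise 0.1 (residual < 0.05) and the pooled-mean round
trip at noise 0.001 (< 1e-6).

`select_variable_genes()` ranks genes by variance *across patient samples
only* — cell-line-only variability must not drive the feature set — with
ties broken by input order and `k` capped at the gene count. The default
`k = 5000` follows the clustering protocol the pipeline emulates; on the
2,000-gene synthetic universe the cap makes the filter a no-op, which is
intentional (the filter's behavior is tested separately on a 20,000-gene
matrix).

`ward_cluster()` performs Ward minimum-variance clustering on Euclidean
distances over log2 expression via the Lance–Williams recurrence
(`hclust`, `ward.D2`). Merge heights are reported as the *increase in
within-cluster sum of squares* (delta-SSE, `h^2/2` in `ward.D2` units), and
the full merge sequence is verified against a brute-force oracle that
recomputes every pairwise delta-SSE at every step for instances up to 12
leaves. The primary-cluster cut removes the k−1 highest merges; `k = 4` is
the default because both emulated scenarios are built around four lineages,
and the cut is a parameter rather than a discovery procedure (the number of
"primary" clusters on a dendrogram is a judgment call, not an output).

`assign_representatives()` operationalizes what is usually a manual step in such a
workflow: within each cluster, the non-excluded cell line closest
(Euclidean, on the clustering genes) to the cluster's patient centroid is
selected; clusters whose only line is excludable (the NEPC-like H660
analog, which cannot be co-cultured) are reported as unrepresented.
Signature scores (`signature_score()`) are mean marker z-scores with a
1e-8 variance floor, so constant genes contribute zero rather than NaN.

# IDA combination scoring

For a combination (A at dose a, B at dose b) over a shared line panel,

\[
\text{score} = \overline{v}_{\text{best mono}} - \overline{\min(v_A, v_B)},
\]

where the best mono is the single (drug, dose) with the lower mean
viability across the panel. The min rule is the IDA assumption itself: each
line benefits only from the drug it is more sensitive to. The score is
non-negative by construction, zero for self- or inert pairings, and isolated
behind one function so an alternative form can be swapped in.
`rank_combos()` maximizes the score over each partner's tested
concentrations up to its per-drug cap (the clinically sustainable plasma
concentration, a config input since such caps are drug-specific clinical
data), and ranks partners with lexicographic tie-breaking.
`collateral_sensitivity()` reports the Spearman correlation of two drugs'
per-cluster efficacies; a negative value is the collateral pattern that
makes IDA combinations work cohort-wide.

# Co-culture simulation

`simulate_mixture()` grows each line under a shared carrying capacity:

\[
N_i(t + dt) = N_i(t)\, e^{\, r_i\, g(v_i)\, dt\, (1 - \sum_j N_j / K)},
\qquad r_i = \ln 2 / T_{d,i},\; g(v) = 2v - 1 .
\]

The single multiplier \(g\) reproduces both cytostatic (v = 0.5, stasis)
and cytotoxic (v < 0.5, decline) phenotypes without a separate death term.
Seeding follows `seeding_ratio()` — counts proportional to doubling times
with half-up rounding (so doubling times of 14:28:28 h give a 1:2:2 seed),
50,000 cells/well total by default. K defaults to 5e6 cells/well: large
enough that subpopulations couple only weakly, since the co-culture
interaction strength is not quantified by the data the simulator emulates.
Halving `dt` moves day-5 counts by < 0.5% at defaults.

Within-line multi-drug viability is configurable: `ida_min` (no
within-line interaction), `bliss` (product), or `synergy`. The third model
exists for a structural reason: with exponential kinetics the measured
growth-inhibition Bliss score of a product-viability combo is
\(e^{-a(2 - v_A - v_B)} - e^{-a(1 - v_A v_B)} < 0\) for all
\(v_A, v_B < 1\) — a Bliss-independent *viability* model can never produce
positive Bliss scores on *growth* readouts. Emulating an empirically
synergistic combination therefore requires super-Bliss potency:
`v = vA*vB*(1 - s*(1-vA)*(1-vB))` with strength `s` (default 8), which
leaves an inert partner exactly neutral and reduces to the product at
`s = 0`. The interaction term applies only when two or more drugs are
co-applied.

# Efficacy readouts

`normalized_growth_area()` divides each channel's endpoint area by its
start area (normalizing seeding differences); `mixture_proliferation()`
sums the per-channel ratios within a well, treating the co-culture as one
composite tumor. `mann_whitney_u()` uses the exact U distribution for
n, m ≤ 8 without ties (U = #{x > y} + ties/2, two-sided by doubling the
smaller tail) and a tie- and continuity-corrected normal approximation
otherwise; the exact branch is verified against full enumeration of all
C(n+m, n) arrangements. Six replicates per condition is the default —
comfortably above the usual minimum of five for rank-sum testing.

`evaluate_combo()` assembles the full verdict at `alpha = 0.05`, two-sided,
with no multiplicity correction within one experiment (raw p-values are the
convention for these readouts):

* **Mixture level**: combo vs the best monotherapy, where "best" is the
  mono with lower *median* mixture proliferation (median rather than mean,
  for robustness with 6 replicates; the choice is ours to make and is
  isolated here).
* **Aggregated analysis**: the per-line normalized ratios are pooled across
  lines per condition — not per-line means — and the same test is run on
  the pooled values. Pooling raw ratios reproduces the between-line
  variance inflation that makes complementary combinations invisible to
  the conventional analysis.
* **Per line**: combo vs that line's best mono (the "dashed line" of a
  per-line growth figure), plus a Bliss score computed from
  vehicle-relative median inhibitions clipped to [0, 1].

A combination is `combo_superior_in_mixture` when the mixture-level test is
significant *and* the combo median is lower. Under the complementary
scenario (line 1 sensitive to A only, line 2 to B only, line 3 to both,
IDA-min within line), the mixture verdict fires while the aggregated one
does not in ≥ 90% of seeded runs, and under an inert partner the
mixture-level false-positive rate stays at the nominal level (≤ 7% at
alpha 0.05 over 200 runs). Both rates are recomputed by
`scripts/acceptance.R`.

# Drug-sensitivity imputation

`fit_and_predict()` regresses dose-response AUC (lower = more sensitive) on
standardized gene expression with a ridge penalty chosen by 5-fold
cross-validation over a log grid; gene means/sds come from the training
panel only and are re-applied to new profiles. A planted linear model is
recovered with held-out R² > 0.99; permuted responses predict nothing.
`differential_sensitivity()` contrasts predicted AUCs of sensitive vs
resistant clones with a Student t test per drug, signing the statistic as
mean(resistant) − mean(sensitive) so negative values flag
"resistant-selective" drugs, and adds Benjamini–Hochberg adjustment across
the panel (hundreds of drugs are screened simultaneously; raw p-values are
reported alongside). Replicate variation for the t test comes from
replicate expression draws of each clone profile — point predictions have
no sampling variance of their own, so the screen exposes this resampling
explicitly rather than hiding it.

# Scenario presets and problem sizes

`hetmix_preset()` pins the two study scenarios (drug panel with
complementary Hill dose-responses, concentration grid 0.5–100 nM with
per-drug caps at 100 nM, anchor docetaxel at 3 nM for the unstratified
scenario and selumetinib at 5 nM for the taxane-resistant one, partner
doses at low, far-below-IC50 values such as daporinad 5 nM). Doubling
times (28/56/56/42 h) reproduce the 1:2:2 seeding ratio of the three
co-cultured lines; absolute values are synthetic presets, configurable,
since only the ratio is constrained by the workflow being emulated.

The test suite and the acceptance script use the presets at full cohort
size (208/79 patients, 2,000 genes) and 10-seed replication for the
structural claims, 100 seeds for the mixture-vs-aggregate power contrast,
and 200 seeds for the null false-positive rate; a selection run takes a
couple of seconds and the whole acceptance script about a minute on one
CPU.

# Known limitations

* The purification surrogate performs no empirical-Bayes shrinkage, no
  per-gene "high-resolution" imputation, and no batch handling of its own
  (batch effects are handled downstream by ComBat).
* The IDA score is a mean-viability gap, not a survival/hazard analysis;
  dose-response curves are consumed as viability tables, never fitted from
  raw screens.
* The simulator is well-mixed and static-dose: no spatial structure, no
  pharmacokinetics, no resistance evolution over the 5-day horizon.
* `k = 4` and the AR/NEPC marker sets are inputs, not discoveries; with
  different marker GMTs the signature scores change accordingly.
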