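#' Hill dose-response viability
#'
#' Fractional viability of a cell population exposed to a drug at
#' concentration `conc`, under a Hill (log-logistic) law:
#' \deqn{v(c) = 1 - E_{max} \frac{c^h}{c^h + IC_{50}^h}}
#' so that `v(0) = 1`, `v(ic50) = 1 - emax/2` and `v(Inf) = 1 - emax`.
#'
#' @param conc Non-negative concentration(s); vectorized.
#' @param ic50 Half-maximal concentration, > 0.
#' @param hill Hill slope, > 0.
#' @param emax Maximal effect, fraction in `[0, 1]`.
#' @return Viability in `[1 - emax, 1]`, same length as `conc`.
#' @export
hill_viability <- function(conc, ic50, hill, emax) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_bad_arg("`conc` must be non-negative and finite")
  if (ic50 <= 0) stop_bad_arg("`ic50` must be > 0")
  if (hill <= 0) stop_bad_arg("`hill` must be > 0")
  if (emax < 0 || emax > 1) stop_bad_arg("`emax` must be in [0, 1]")
  ch <- conc^hill
  1 - emax * ch / (ch + ic50^hill)
}

#' Seeding ratio from doubling times
#'
#' Integer seeding ratio proportional to relative doubling times, so that
#' slower-growing lines are seeded in larger numbers and all lines occupy a
#' comparable share of the mixture after unperturbed growth. Each entry is
#' `round(Td_i / min(Td))` with half-up rounding and a floor of 1.
#'
#' @param doubling_times Positive doubling times in hours, optionally named.
#' @return Integer vector of the same length (and names).
#' @examples
#' seeding_ratio(c(14, 28, 28)) # 1:2:2
#' @export
seeding_ratio <- function(doubling_times) {
  if (any(!is.finite(doubling_times)) || any(doubling_times <= 0))
    stop_bad_arg("doubling times must be positive and finite")
  x <- doubling_times / min(doubling_times)
  r <- pmax(1L, as.integer(floor(x + 0.5)))  # half-up, not banker's rounding
  stats::setNames(r, names(doubling_times))
}

#' Growth parameters for a mixed-cell co-culture
#'
#' @param doubling_time Named numeric vector of per-line doubling times
#'   (hours, > 0); names are the line (channel) labels.
#' @param cell_area Per-line area per cell, used to convert simulated counts
#'   to imaging areas. Scalar or named vector; arbitrary units.
#' @param capacity Shared carrying capacity (cells/well). Large values give
#'   near-exponential growth; the default couples subpopulations weakly.
#' @param combo_model Within-line model combining the viabilities of
#'   simultaneously applied drugs: `"ida_min"` (minimum; no within-line
#'   interaction), `"bliss"` (product; Bliss-independent), or `"synergy"`
#'   (product with a potency boost, see Details).
#' @param synergy_strength Strength `s` of the potency boost when
#'   `combo_model = "synergy"`:
#'   `v = max(0, vA * vB * (1 - s * (1 - vA) * (1 - vB)))`. An inert partner
#'   (`v = 1`) leaves the other drug's effect unchanged.
#' @param dose_response Nested named list `line -> drug -> list(ic50, hill,
#'   emax)` giving each line's Hill parameters per drug.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(doubling_time, cell_area = 1, capacity = 5e6,
                          combo_model = c("ida_min", "bliss", "synergy"),
                          synergy_strength = 8, dose_response = list()) {
  combo_model <- match.arg(combo_model)
  if (is.null(names(doubling_time)))
    stop_bad_arg("`doubling_time` must be named by line")
  if (any(doubling_time <= 0)) stop_bad_arg("doubling times must be > 0")
  lines <- names(doubling_time)
  if (length(cell_area) == 1L)
    cell_area <- stats::setNames(rep(cell_area, length(lines)), lines)
  if (!all(lines %in% names(cell_area)))
    stop_bad_arg("`cell_area` must cover every line")
  structure(list(doubling_time = doubling_time,
                 cell_area = cell_area[lines],
                 capacity = capacity,
                 combo_model = combo_model,
                 synergy_strength = synergy_strength,
                 dose_response = dose_response),
            class = "growth_params")
}

# Combined within-line viability of a treatment (list of drug = conc).
combined_viability <- function(growth, line, treatment) {
  if (length(treatment) == 0L) return(1)
  dr <- growth$dose_response[[line]]
  vs <- vapply(names(treatment), function(drug) {
    p <- dr[[drug]]
    if (is.null(p))
      stop_bad_arg("missing dose-response parameters for line '", line,
                   "', drug '", drug, "'")
    hill_viability(treatment[[drug]], p$ic50, p$hill, p$emax)
  }, numeric(1))
  v <- switch(growth$combo_model,
              ida_min = min(vs),
              bliss = prod(vs),
              # potency boost beyond Bliss independence; the interaction
              # term only exists when >= 2 drugs are co-applied
              synergy = if (length(vs) < 2L) prod(vs) else
                prod(vs) * (1 - growth$synergy_strength * prod(1 - vs)))
  min(max(v, 0), 1)
}

#' Simulate drug-treated growth of a mixed-cell culture
#'
#' Shared-capacity logistic growth of co-cultured subpopulations under a
#' static drug treatment. Each line `i` is updated as
#' \deqn{N_i(t + dt) = N_i(t)\, e^{r_i\, g(v_i)\, dt\, (1 - \sum_j N_j / K)}}
#' with intrinsic rate `r_i = ln 2 / Td_i` and drug-effect multiplier
#' `g(v) = 2v - 1`, so a combined viability of 0.5 is cytostatic and
#' viabilities below 0.5 are cytotoxic. The combined viability of a
#' multi-drug treatment follows the configured within-line combo model.
#'
#' @param growth A [growth_params()] object.
#' @param seeding Named vector of initial cell counts per line (all lines in
#'   `growth`, total > 0 and below capacity).
#' @param treatment Named list/vector `drug = concentration`; empty for
#'   vehicle.
#' @param duration Total simulated time in hours (> 0). Default 120 h
#'   (5 days of exposure).
#' @param dt Integration step in hours; must satisfy `0 < dt <= duration`.
#' @return Numeric matrix of cell counts, time points (hours) in rows
#'   (rownames), lines in columns.
#' @export
simulate_mixture <- function(growth, seeding, treatment = list(),
                             duration = 120, dt = 1) {
  stopifnot(inherits(growth, "growth_params"))
  if (dt <= 0 || dt > duration)
    stop_bad_arg("`dt` must satisfy 0 < dt <= duration")
  lines <- names(growth$doubling_time)
  if (length(seeding) == 0L || sum(seeding) <= 0)
    stop_bad_arg("mixture seeding must be non-empty with positive total")
  if (!all(lines %in% names(seeding)))
    stop_bad_arg("`seeding` must cover every line in `growth`")
  seeding <- seeding[lines]
  if (growth$capacity <= sum(seeding))
    stop_bad_arg("carrying capacity must exceed total seeding")
  treatment <- as.list(treatment)
  if (length(treatment) && any(unlist(treatment) < 0))
    stop_bad_arg("treatment doses must be >= 0")

  v <- vapply(lines, function(l) combined_viability(growth, l, treatment),
              numeric(1))
  g <- 2 * v - 1
  r <- log(2) / growth$doubling_time

  steps <- c(rep(dt, floor(duration / dt)),
             if (duration %% dt > 1e-12) duration %% dt)
  times <- cumsum(c(0, steps))
  out <- matrix(NA_real_, nrow = length(times), ncol = length(lines),
                dimnames = list(format(times, trim = TRUE), lines))
  n <- seeding
  out[1, ] <- n
  for (i in seq_along(steps)) {
    crowd <- 1 - sum(n) / growth$capacity
    n <- n * exp(r * g * steps[i] * crowd)
    out[i + 1L, ] <- n
  }
  attr(out, "times") <- times
  attr(out, "viability") <- v
  out
}
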