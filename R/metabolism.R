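#' Metabolic parameter set (cross-inhibited Michaelis-Menten consumption)
#'
#' Defaults are the published consumption-rate fit for EMT6/Ro spheroid
#' cells; glucose and oxygen uptake are Michaelis-Menten in their own
#' substrate with a maximal rate that is down-regulated by the other
#' substrate (cells consume less glucose when well oxygenated and less
#' oxygen when glucose-rich).  Rates are expressed per unit cell volume
#' (mM/h for a fully occupied tissue element); per-cell rates in mol/cell/s
#' are obtained via [rate_mmh_to_molcells()] with the 2700 um^3 reference
#' cell volume.
#'
#' @param k_G_G glucose half-saturation for glucose uptake (mM).
#' @param k_G_O2 oxygen half-saturation entering the glucose maximal rate (mM).
#' @param q_G_min,q_G_max glucose uptake bounds (mM/h).
#' @param k_O2_O2 oxygen half-saturation for oxygen uptake (mM).
#' @param k_O2_G glucose half-saturation entering the oxygen maximal rate (mM).
#' @param q_O2_min,q_O2_max oxygen uptake bounds (mM/h).
#' @param G_crit glucose concentration below which no ATP is produced (mM).
#' @param atp_per_glycolysis ATP yield per glucose through glycolysis.
#' @param atp_per_O2 ATP yield per O2 through oxidative phosphorylation
#'   (17/3: 17 ATP per pyruvate, 3 O2 per pyruvate; 18 ATP is the
#'   shuttle-dependent alternative, set `atp_per_pyruvate = 18`).
#' @param atp_per_pyruvate convenience: 17 (default) or 18; sets
#'   `atp_per_O2 = atp_per_pyruvate / 3`.
#' @param lactate_per_glucose lactate yield per anaerobically used glucose.
#' @param cell_volume reference cell volume (um^3).
#' @return object of class `metabolic_params`.
#' @export
metabolic_params <- function(k_G_G = 0.068, k_G_O2 = 0.031,
                             q_G_min = 186.67, q_G_max = 706.67,
                             k_O2_O2 = 0.031, k_O2_G = 0.100,
                             q_O2_min = 120.00, q_O2_max = 306.66,
                             G_crit = 0.01,
                             atp_per_glycolysis = 2,
                             atp_per_pyruvate = 17,
                             atp_per_O2 = atp_per_pyruvate / 3,
                             lactate_per_glucose = 2,
                             cell_volume = 2700) {
  p <- list(k_G_G = k_G_G, k_G_O2 = k_G_O2, q_G_min = q_G_min,
            q_G_max = q_G_max, k_O2_O2 = k_O2_O2, k_O2_G = k_O2_G,
            q_O2_min = q_O2_min, q_O2_max = q_O2_max, G_crit = G_crit,
            atp_per_glycolysis = atp_per_glycolysis, atp_per_O2 = atp_per_O2,
            lactate_per_glucose = lactate_per_glucose,
            cell_volume = cell_volume)
  rates <- unlist(p[c("k_G_G", "k_G_O2", "q_G_min", "q_G_max", "k_O2_O2",
                      "k_O2_G", "q_O2_min", "q_O2_max", "G_crit")])
  if (any(rates <= 0)) stop("all kinetic constants must be positive")
  if (q_G_min >= q_G_max || q_O2_min >= q_O2_max)
    stop("q_min must be smaller than q_max")
  if (cell_volume <= 0) stop("cell_volume must be positive")
  structure(p, class = "metabolic_params")
}

check_conc <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(vals[[nm]] < 0, na.rm = TRUE))
      stop("negative concentration: ", nm)
}

#' Glucose and oxygen uptake rates
#'
#' `glucose_uptake()` evaluates
#' `q_G = V_G_max(O) * G / (G + k_G_G)` with the cross-inhibited maximal
#' rate `V_G_max = q_G_max * (1 - (1 - q_G_min/q_G_max) * O / (O + k_G_O2))`;
#' `oxygen_uptake()` is symmetric with the roles of G and O exchanged.
#' Both are vectorized over concentrations (mM) and return mM/h.
#'
#' @param G,O glucose and oxygen concentrations (mM), non-negative.
#' @param params a [metabolic_params()] object.
#' @export
glucose_uptake <- function(G, O, params = metabolic_params()) {
  check_conc(G = G, O = O)
  vmax <- params$q_G_max *
    (1 - (1 - params$q_G_min / params$q_G_max) * O / (O + params$k_G_O2))
  vmax * G / (G + params$k_G_G)
}

#' @rdname glucose_uptake
#' @export
oxygen_uptake <- function(G, O, params = metabolic_params()) {
  check_conc(G = G, O = O)
  vmax <- params$q_O2_max *
    (1 - (1 - params$q_O2_min / params$q_O2_max) * G / (G + params$k_O2_G))
  vmax * O / (O + params$k_O2_O2)
}

#' ATP production rate
#'
#' `p_ATP = 2 q_G + (17/3) q_O2` (mM/h): two ATP per glucose from
#' glycolysis plus 17 ATP per pyruvate (3 O2 per pyruvate) from the citric
#' acid cycle and oxidative phosphorylation.  Below the critical glucose
#' concentration `G_crit` no pyruvate is available and no ATP is produced.
#'
#' @inheritParams glucose_uptake
#' @export
atp_production <- function(G, O, params = metabolic_params()) {
  check_conc(G = G, O = O)
  p <- params$atp_per_glycolysis * glucose_uptake(G, O, params) +
    params$atp_per_O2 * oxygen_uptake(G, O, params)
  p[G <= params$G_crit] <- 0
  p
}

#' Lactate production rate
#'
#' Glucose metabolized aerobically consumes 6 O2 per glucose, so the
#' aerobic glucose flux is `q_O2 / 6` and the anaerobic remainder
#' `q_G - q_O2 / 6` is fermented, yielding two lactate per glucose:
#' `p_L = max(0, 2 q_G - q_O2 / 3)` (mM/h).
#'
#' @inheritParams glucose_uptake
#' @export
lactate_production <- function(G, O, params = metabolic_params()) {
  qg <- glucose_uptake(G, O, params)
  qo <- oxygen_uptake(G, O, params)
  pmax(0, params$lactate_per_glucose * (qg - qo / 6))
}

#' Fraction of consumed glucose fully oxidized
#'
#' `q_O2 / (6 q_G)`, clamped to \[0, 1\]: the share of the glucose uptake that
#' passes through the Krebs cycle (the complement is the Warburg-like
#' anaerobic share).  Undefined at `q_G = 0`.
#'
#' @inheritParams glucose_uptake
#' @export
aerobic_glucose_fraction <- function(G, O, params = metabolic_params()) {
  qg <- glucose_uptake(G, O, params)
  if (any(qg == 0))
    stop("aerobic glucose fraction undefined where q_G = 0")
  pmin(1, pmax(0, oxygen_uptake(G, O, params) / (6 * qg)))
}

#' Convert rates between mM/h (per cell volume) and mol/cell/s
#'
#' A rate of 1 mM/h in a cell of volume V um^3 corresponds to
#' `1e-3 mol/L * V * 1e-15 L / 3600 s` per cell; for the 2700 um^3 reference
#' volume, 1 mol/cell/s = 13.33e17 mM/h.
#'
#' @param rate rate to convert (vectorized).
#' @param cell_volume cell volume in um^3 (> 0).
#' @return converted rate.
#' @export
rate_mmh_to_molcells <- function(rate, cell_volume = 2700) {
  if (any(cell_volume <= 0)) stop("cell_volume must be positive")
  rate * 1e-3 * cell_volume * 1e-15 / 3600
}

#' @rdname rate_mmh_to_molcells
#' @export
rate_molcells_to_mmh <- function(rate, cell_volume = 2700) {
  if (any(cell_volume <= 0)) stop("cell_volume must be positive")
  rate * 3600 / (1e-3 * cell_volume * 1e-15)
}

#' Tabulate the metabolic response surface
#'
#' Evaluates uptake, ATP and lactate production and the aerobic glucose
#' fraction on a (G, O) grid; one row per concentration pair.  Useful for
#' exporting the metabolism surfaces as CSV.
#'
#' @param G_values,O_values concentration grids (mM).
#' @inheritParams glucose_uptake
#' @return data.frame with columns G, O, q_G, q_O2, p_ATP, p_L,
#'   aerobic_fraction.
#' @export
uptake_surface <- function(G_values, O_values, params = metabolic_params()) {
  g <- expand.grid(G = G_values, O = O_values)
  qg <- glucose_uptake(g$G, g$O, params)
  data.frame(
    G = g$G, O = g$O,
    q_G = qg,
    q_O2 = oxygen_uptake(g$G, g$O, params),
    p_ATP = atp_production(g$G, g$O, params),
    p_L = lactate_production(g$G, g$O, params),
    aerobic_fraction = ifelse(qg > 0,
                              pmin(1, oxygen_uptake(g$G, g$O, params) /
                                     (6 * pmax(qg, .Machine$double.xmin))),
                              NA_real_))
}
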