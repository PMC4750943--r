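#' Heaviside step function, H(x) = 1 for x >= 0
#' @param x numeric.
#' @export
heaviside <- function(x) as.numeric(x >= 0)

#' Growth-control model specification (variants 1-4)
#'
#' Bundles the thresholds and maximal rates of the four nested growth
#' control hypotheses:
#' \describe{
#'   \item{variant 1}{division/death gated by the glucose-oxygen product
#'     against `p_oxyglc`;}
#'   \item{variant 2}{gated by the ATP production rate against
#'     `p_ATP_min` = 900 mM/h;}
#'   \item{variant 3}{variant 2 plus lactate-induced death through a Hill
#'     response, half-maximal at `L_max` = 20 mM;}
#'   \item{variant 4}{variant 3 plus waste/hypoxia effects: cycling speed is
#'     halved per adverse flag (waste above `W_max`, oxygen below `O_min`)
#'     and a cell exposed for more than `n_exp_max` cell cycles becomes
#'     permanently quiescent at its next division.}
#' }
#'
#' @param variant integer 1-4.
#' @param dL pushing range (sites) in the cycle-entry probability
#'   `exp(-L/dL)`.
#' @param ECM_min minimal ECM level (dimensionless intensity) required for
#'   cycle entry.
#' @param p_oxyglc glucose-oxygen product threshold (mM^2), variant 1.  Not
#'   printed in the source material; calibrated (see vignette).
#' @param p_ATP_min ATP production threshold (mM/h), variants 2-4.
#' @param L_max lactate concentration of half-maximal death rate (mM).
#' @param hill_n Hill coefficient of the lactate death response.
#' @param W_max waste exposure threshold (dimensionless), variant 4.
#' @param O_min hypoxia threshold (mM), variant 4.
#' @param n_exp_max exposure tolerance (cell cycles), variant 4.
#' @param k_div_max maximal division rate 1/tau (1/h).
#' @param k_nec_max maximal death rate (1/h).
#' @param knec_combination how ATP-starvation death and lactate death
#'   combine in variants 3-4: `"noisy_or"` (default; hazards combine as
#'   independent risks, so starvation alone still kills at L = 0) or
#'   `"product"` (the literal multiplicative form, kept for comparison).
#' @param exposure_clock `"nominal"` (default): exposure accrues at the
#'   nominal cycle rate 1/tau, i.e. in cell-cycle units; `"local"`: accrues
#'   at the cell's current division rate.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(variant = 4L, dL = 2, ECM_min = 0.003,
                       p_oxyglc = 1.0, p_ATP_min = 900,
                       L_max = 20, hill_n = 2L,
                       W_max = 1.5e-4, O_min = 0.07, n_exp_max = 8,
                       k_div_max = 1 / 24, k_nec_max = 0.1,
                       knec_combination = c("noisy_or", "product"),
                       exposure_clock = c("nominal", "local")) {
  variant <- as.integer(variant)
  if (!variant %in% 1:4) stop("variant must be 1, 2, 3 or 4")
  if (hill_n < 1) stop("hill_n must be >= 1")
  thr <- c(dL = dL, ECM_min = ECM_min, p_oxyglc = p_oxyglc,
           p_ATP_min = p_ATP_min, L_max = L_max, W_max = W_max,
           O_min = O_min, n_exp_max = n_exp_max, k_div_max = k_div_max,
           k_nec_max = k_nec_max)
  if (any(thr < 0)) stop("thresholds and rates must be non-negative")
  structure(list(variant = variant, dL = dL, ECM_min = ECM_min,
                 p_oxyglc = p_oxyglc, p_ATP_min = p_ATP_min, L_max = L_max,
                 hill_n = as.integer(hill_n), W_max = W_max, O_min = O_min,
                 n_exp_max = n_exp_max, k_div_max = k_div_max,
                 k_nec_max = k_nec_max,
                 knec_combination = match.arg(knec_combination),
                 exposure_clock = match.arg(exposure_clock)),
            class = "model_spec")
}

#' Local concentrations seen by a cell
#'
#' Plain container for the interpolated field values at one or more
#' positions; all concentrations non-negative, ECM in \[0, 1\].
#' @param G,O,L glucose, oxygen, lactate (mM).
#' @param ECM extracellular matrix (dimensionless intensity).
#' @param W waste (dimensionless).
#' @export
local_concentrations <- function(G, O, L = 0, ECM = 0, W = 0) {
  n <- max(lengths(list(G, O, L, ECM, W)))
  out <- data.frame(G = rep_len(G, n), O = rep_len(O, n),
                    L = rep_len(L, n), ECM = rep_len(ECM, n),
                    W = rep_len(W, n))
  if (any(out < 0)) stop("concentrations must be non-negative")
  if (any(out$ECM > 1)) stop("ECM must lie in [0, 1]")
  class(out) <- c("local_concentrations", "data.frame")
  out
}

#' Probability of (re-)entering the cell cycle at division
#'
#' `p_div = exp(-L / dL) * H(ECM - ECM_min)`, with the additional factor
#' `H(n_exp_max - n_exp)` for variant 4 (a cell past its exposure tolerance
#' never cycles again).  `L` is the hop distance to the closest free lattice
#' site (Inf allowed: probability 0), so cells deep inside the spheroid,
#' which would have to push many neighbors to grow, rarely keep cycling --
#' the stochastic form of mechanical contact inhibition.
#'
#' @param L_dist hop distance to the closest free site (>= 0, Inf allowed).
#' @param ECM local ECM level.
#' @param n_exp accumulated exposure (cell cycles), variant 4.
#' @param spec a [model_spec()].
#' @return probability in \[0, 1\]; vectorized.
#' @export
p_div <- function(L_dist, ECM, n_exp = 0, spec = model_spec()) {
  if (any(L_dist < 0)) stop("L_dist must be non-negative")
  p <- exp(-L_dist / spec$dL) * heaviside(ECM - spec$ECM_min)
  # exposure at or beyond the tolerance blocks cycle entry permanently
  if (spec$variant == 4L) p <- p * as.numeric(n_exp < spec$n_exp_max)
  p
}

#' Division and death rates of the model variants
#'
#' `k_div()`: variant 1 gates the maximal rate by
#' `H(G*O - p_oxyglc)`; variants 2-4 by `H(p_ATP - p_ATP_min)`; variant 4
#' additionally halves the rate per adverse flag
#' (`1 - 0.5 H(W - W_max)` and `1 - 0.5 H(O_min - O)`, quartering when both
#' hold).
#'
#' `k_nec()`: variant 1 `k_nec_max * H(p_oxyglc - G*O)`; variant 2
#' `k_nec_max * H(p_ATP_min - p_ATP)`; variants 3-4 combine ATP-starvation
#' death with the lactate Hill response
#' `hill(L) = L^n / (L_max^n + L^n)` as independent hazards
#' (`H + hill - H*hill`, default) or as the literal product.
#'
#' @param local a [local_concentrations()] (or data.frame with columns
#'   G, O, L, ECM, W).
#' @param p_ATP ATP production rate (mM/h) at the same positions.
#' @param spec a [model_spec()].
#' @return rate in 1/h; vectorized.
#' @export
k_div <- function(local, p_ATP, spec = model_spec()) {
  k <- if (spec$variant == 1L) {
    spec$k_div_max * heaviside(local$G * local$O - spec$p_oxyglc)
  } else {
    spec$k_div_max * heaviside(p_ATP - spec$p_ATP_min)
  }
  if (spec$variant == 4L) {
    k <- k * (1 - 0.5 * heaviside(local$W - spec$W_max)) *
      (1 - 0.5 * heaviside(spec$O_min - local$O))
  }
  k
}

#' @rdname k_div
#' @export
k_nec <- function(local, p_ATP, spec = model_spec()) {
  if (spec$variant == 1L)
    return(spec$k_nec_max * heaviside(spec$p_oxyglc - local$G * local$O))
  h_atp <- heaviside(spec$p_ATP_min - p_ATP)
  if (spec$variant == 2L) return(spec$k_nec_max * h_atp)
  hill <- local$L^spec$hill_n / (spec$L_max^spec$hill_n +
                                 local$L^spec$hill_n)
  comb <- if (spec$knec_combination == "noisy_or")
    h_atp + hill - h_atp * hill
  else
    h_atp * hill
  spec$k_nec_max * comb
}

#' Update the waste/hypoxia exposure counter
#'
#' Implements the cumulative exposure integral of the waste-quiescence
#' mechanism: while the local waste exceeds `W_max` or the local oxygen is
#' below `O_min`, exposure accrues; once `n_exp >= n_exp_max` (cell cycles)
#' the cell is barred from re-entering the cycle at its next division (see
#' [p_div()]).  Exposure never decreases.  With the default `"nominal"`
#' clock the accrual rate is `1/tau` (one unit per nominal cell cycle);
#' with `"local"` it is the cell's current division rate `k_div_local`.
#'
#' @param n_exp current exposure (cell cycles).
#' @param W,O local waste and oxygen.
#' @param elapsed elapsed time (h).
#' @param spec a [model_spec()].
#' @param tau expected cell-cycle time (h).
#' @param k_div_local the cell's current division rate (1/h), used by the
#'   `"local"` clock.
#' @return updated exposure; vectorized.
#' @export
update_exposure <- function(n_exp, W, O, elapsed, spec = model_spec(),
                            tau = 1 / spec$k_div_max,
                            k_div_local = NULL) {
  if (any(elapsed < 0)) stop("elapsed must be non-negative")
  flag <- 1 - heaviside(spec$W_max - W) * heaviside(O - spec$O_min)
  rate <- if (spec$exposure_clock == "local" && !is.null(k_div_local))
    k_div_local
  else
    1 / tau
  n_exp + flag * rate * elapsed
}
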