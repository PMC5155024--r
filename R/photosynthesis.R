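#' Bulk attenuation coefficient of the culture
#'
#' Beer-Lambert attenuation coefficient of the algal suspension, modelled as
#' a background medium term plus a chlorophyll-specific term, the standard
#' oceanographic treatment: `k = k_background + k_chl * [Chl]` with the
#' chlorophyll concentration in mg Chl m^-3 derived from the C-biomass
#' concentration and the cellular Chl:C ratio.
#'
#' @param tc_conc C-biomass concentration, g C m^-3 (>= 0).
#' @param chlc Cellular Chl:C mass ratio, g Chl (g C)^-1 (>= 0).
#' @param k_background Attenuation of the medium itself, m^-1 (default 0.1).
#' @param k_chl Chl-specific attenuation, m^2 (mg Chl)^-1 (default 0.012).
#' @return Attenuation coefficient, m^-1.
#' @examples
#' attenuation_coefficient(500, 0.02) # 0.1 + 0.012 * 10000 = 120.1
#' @export
attenuation_coefficient <- function(tc_conc, chlc, k_background = 0.1,
                                    k_chl = 0.012) {
  if (any(tc_conc < 0) || any(chlc < 0)) {
    abort("`tc_conc` and `chlc` must be >= 0.")
  }
  if (any(k_background < 0) || any(k_chl < 0)) {
    abort("attenuation parameters must be >= 0.")
  }
  chl_mg_m3 <- tc_conc * chlc * 1000
  k_background + k_chl * chl_mg_m3
}

#' Depth-integrated Smith photosynthesis
#'
#' Depth average over the optical path `tau` of the Smith
#' photosynthesis-irradiance curve `P(E) = Pqm * y / sqrt(1 + y^2)` (with
#' `y = E * alpha * ChlC / Pqm`) under Beer-Lambert light decay
#' `E(z) = E_avg * exp(-k z)`. The average has the closed form
#'
#'   `PS = Pqm / (k tau) * (asinh(x) - asinh(x * exp(-k tau)))`
#'
#' where `x = E_avg * alpha * ChlC / Pqm` is the dimensionless surface light
#' saturation. `asinh` is used rather than the raw `log(y + sqrt(1 + y^2))`
#' primitive to avoid cancellation at small arguments. For optically thin
#' cultures (`k tau -> 0`) the analytic limit is the surface Smith value
#' `Pqm * x / sqrt(1 + x^2)`.
#'
#' @param e_avg Panel-face-averaged photon flux density,
#'   umol photons m^-2 s^-1 (>= 0).
#' @param chlc Cellular Chl:C mass ratio, g Chl (g C)^-1.
#' @param alpha Photosynthetic efficiency at E = 0,
#'   g C (g Chl)^-1 d^-1 per (umol photons m^-2 s^-1) (> 0).
#' @param pqm Absolute maximum C-specific photosynthesis rate,
#'   g C (g C)^-1 d^-1 (> 0).
#' @param k Attenuation coefficient, m^-1 (>= 0).
#' @param tau Optical half-depth, m (> 0): half the panel width when both
#'   faces are lit.
#' @return Depth-averaged C-specific gross photosynthesis rate,
#'   g C (g C)^-1 d^-1, in `[0, pqm]`. Vectorised over its arguments.
#' @examples
#' depth_integrated_ps(e_avg = 400, chlc = 0.02, alpha = 0.2, pqm = 2,
#'                     k = 100, tau = 0.025)
#' @export
depth_integrated_ps <- function(e_avg, chlc, alpha, pqm, k, tau) {
  if (any(e_avg < 0) || any(chlc < 0) || any(k < 0) || any(tau < 0)) {
    abort("irradiance, pigment and optical arguments must be >= 0.")
  }
  if (any(alpha <= 0) || any(pqm <= 0)) {
    abort("`alpha` and `pqm` must be > 0.")
  }
  x <- e_avg * alpha * chlc / pqm
  ktau <- k * tau
  thin <- ktau < 1e-7
  out <- numeric(length(x + ktau))
  x <- rep_len(x, length(out))
  ktau <- rep_len(ktau, length(out))
  pqm <- rep_len(pqm, length(out))
  out[thin] <- pqm[thin] * x[thin] / sqrt(1 + x[thin]^2)
  if (any(!thin)) {
    xt <- x[!thin]
    kt <- ktau[!thin]
    out[!thin] <- pqm[!thin] / kt * (asinh(xt) - asinh(xt * exp(-kt)))
  }
  out
}

#' Net C-specific growth potential from gross photosynthesis
#'
#' Offsets gross depth-averaged photosynthesis by respiration. The result
#' can be negative: in the dark the basal respiration term drains biomass
#' carbon overnight.
#'
#' @param ps Gross C-specific photosynthesis, g C (g C)^-1 d^-1 (>= 0).
#' @param resp Respiration rate, g C (g C)^-1 d^-1 (>= 0); see
#'   [respiration_rate()].
#' @return Net C-specific rate `ps - resp`, g C (g C)^-1 d^-1.
#' @export
net_c_specific_growth <- function(ps, resp) {
  if (any(ps < 0) || any(resp < 0)) abort("`ps` and `resp` must be >= 0.")
  ps - resp
}

#' Respiration rate
#'
#' Basal plus growth-proportional respiration, the standard decomposition
#' for this model family: `R = r_basal + zeta * PS`. `r_basal` is the dark
#' maintenance cost; `zeta` is the metabolic cost per unit of gross C
#' fixation.
#'
#' @param ps Gross C-specific photosynthesis, g C (g C)^-1 d^-1.
#' @param r_basal Basal respiration, d^-1 (default 0.03).
#' @param zeta Cost-of-growth fraction, dimensionless (default 0.2).
#' @return Respiration rate, g C (g C)^-1 d^-1.
#' @export
respiration_rate <- function(ps, r_basal = 0.03, zeta = 0.2) {
  if (any(ps < 0)) abort("`ps` must be >= 0.")
  r_basal + zeta * ps
}

#' Maximum photosynthesis rate consistent with the current growth ceiling
#'
#' Closure coupling the Smith-curve ceiling `Pqm` to the
#' temperature-dependent maximum growth rate: `Pqm` is set so that fully
#' light-saturated photosynthesis, net of respiration, can just support
#' `mu_m`, i.e. `Pqm = (mu_m + r_basal) / (1 - zeta)`. Recomputed at every
#' time step as `mu_m` tracks the seasonal temperature proxy.
#'
#' @param mu_m Current maximum growth rate, d^-1.
#' @param r_basal Basal respiration, d^-1.
#' @param zeta Cost-of-growth fraction.
#' @return `Pqm`, g C (g C)^-1 d^-1.
#' @export
pqm_from_mu <- function(mu_m, r_basal = 0.03, zeta = 0.2) {
  if (any(zeta >= 1)) abort("`zeta` must be < 1.")
  (mu_m + r_basal) / (1 - zeta)
}
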