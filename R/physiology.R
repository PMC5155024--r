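#' Physiological parameter set for the algal growth model
#'
#' Bundles the strain physiology used by [step_physiology()] and
#' [run_simulation()]. Defaults are a generic parameterisation of a
#' *Nannochloropsis*-like marine eustigmatophyte; all values are overridable
#' from the `strain` section of a run configuration and should be treated as
#' calibratable rather than strain truths.
#'
#' The `variant` selects the stoichiometric sophistication of the model:
#' \describe{
#'   \item{`"CNPCHL"`}{fully acclimative: variable N:C and P:C quotas plus
#'     dynamic photoacclimative Chl:C (the default).}
#'   \item{`"CNCHL"`}{variable N:C and dynamic Chl:C; P:C held at its
#'     replete value (P never limits).}
#'   \item{`"CN"`}{variable N:C only; Chl:C held constant at `chlc_fixed`.}
#'   \item{`"FIXED"`}{fixed Redfield stoichiometry (N:C 0.176, P:C
#'     0.024 g g C^-1), constant Chl:C, and a constant storage fraction
#'     `cexc_fixed` imposed a priori.}
#' }
#'
#' @param mu_winter,mu_summer Seasonal endpoints of the maximum growth rate
#'   mu_m, d^-1. The seasonal temperature proxy interpolates sinusoidally
#'   between them (see [seasonal_mu_max()]).
#' @param phase_day Day of year of the annual mu_m minimum (mid-winter).
#' @param ncmin,ncmax N:C quota bounds, g N (g C)^-1.
#' @param pcmin,pcmax P:C quota bounds, g P (g C)^-1.
#' @param kq_n,kq_p Curvature constants of the normalised quota curve.
#' @param vmax_n,vmax_p Maximum C-specific uptake rates, g N (or P)
#'   (g C)^-1 d^-1.
#' @param ks_n,ks_p Uptake half-saturation constants, g m^-3.
#' @param chlc_m Maximum attainable Chl:C, g Chl (g C)^-1.
#' @param chlc_min Floor on Chl:C under saturating light.
#' @param chlc_fixed Constant Chl:C used by the `CN` and `FIXED` variants.
#' @param rho_chl First-order Chl:C relaxation rate towards its
#'   photoacclimation target, d^-1.
#' @param alpha Photosynthetic efficiency at E = 0, g C (g Chl)^-1 d^-1 per
#'   (umol photons m^-2 s^-1). An effective engineering constant absorbing
#'   spectral and photon-unit conversions; fitted, not measured.
#' @param r_basal,zeta Respiration parameters, see [respiration_rate()].
#' @param cexc_base,cexc_max Endpoints of the linear map from N:C quota to
#'   the C-storage fraction of biomass (see [storage_fraction()]).
#' @param rho_cexc First-order relaxation rate of the realised storage
#'   fraction towards its quota-determined target, d^-1. Storage pools
#'   build and burn over days, not time steps; the finite rate damps
#'   within-harvest-cycle swings of the feedstock fraction.
#' @param cexc_fixed Constant storage fraction for the `FIXED` variant.
#' @param nc_fixed,pc_fixed Redfield mass ratios used by `FIXED`.
#' @param variant One of `"CNPCHL"`, `"CNCHL"`, `"CN"`, `"FIXED"`.
#' @param force_replete Logical; if `TRUE` the quotas are pinned at their
#'   maxima and nutrient bookkeeping is skipped. A validation mode that
#'   reduces every variant to the same light-limited model.
#' @return A list of class `pbr_physiology`.
#' @export
physiology_params <- function(mu_winter = 1.04, mu_summer = 1.5,
                              phase_day = 15,
                              ncmin = 0.05, ncmax = 0.20,
                              pcmin = 0.005, pcmax = 0.03,
                              kq_n = 2, kq_p = 0.1,
                              vmax_n = 0.30, vmax_p = 0.05,
                              ks_n = 0.14, ks_p = 0.03,
                              chlc_m = 0.033, chlc_min = 0.002,
                              chlc_fixed = 0.02, rho_chl = 1,
                              alpha = 0.47, r_basal = 0.03, zeta = 0.2,
                              cexc_base = 0.26, cexc_max = 0.40,
                              rho_cexc = 0.37, cexc_fixed = 0.33,
                              nc_fixed = 0.176, pc_fixed = 0.024,
                              variant = "CNPCHL", force_replete = FALSE) {
  p <- as.list(environment())
  physiology_validate(p)
}

physiology_validate <- function(p) {
  if (!(p$variant %in% c("CNPCHL", "CNCHL", "CN", "FIXED"))) {
    abort("`variant` must be one of CNPCHL, CNCHL, CN, FIXED.")
  }
  if (!(p$ncmin > 0 && p$ncmin < p$ncmax)) abort("need 0 < ncmin < ncmax.")
  if (!(p$pcmin > 0 && p$pcmin < p$pcmax)) abort("need 0 < pcmin < pcmax.")
  if (p$chlc_m <= 0) abort("`chlc_m` must be > 0.")
  if (!(p$mu_summer >= p$mu_winter && p$mu_winter > 0)) {
    abort("need mu_summer >= mu_winter > 0.")
  }
  if (p$zeta < 0 || p$zeta >= 1) abort("`zeta` must lie in [0, 1).")
  class(p) <- "pbr_physiology"
  p
}

variant_flags <- function(variant) {
  switch(variant,
    CNPCHL = list(quota_n = TRUE, quota_p = TRUE, chl_dyn = TRUE, fixed = FALSE),
    CNCHL  = list(quota_n = TRUE, quota_p = FALSE, chl_dyn = TRUE, fixed = FALSE),
    CN     = list(quota_n = TRUE, quota_p = FALSE, chl_dyn = FALSE, fixed = FALSE),
    FIXED  = list(quota_n = FALSE, quota_p = FALSE, chl_dyn = FALSE, fixed = TRUE),
    abort("unknown variant")
  )
}

#' Instantaneous culture state
#'
#' Constructs the state vector advanced by [step_physiology()]. All
#' concentrations are per m^3 of culture (g m^-3, equivalent to mg L^-1);
#' quotas are intensive mass ratios; `hc`/`hexc` are cumulative harvested
#' masses in grams for the whole array.
#'
#' @param tc C-biomass concentration, g C m^-3.
#' @param nc,pc Cellular N:C and P:C quotas, g (g C)^-1.
#' @param chlc Chl:C ratio, g Chl (g C)^-1.
#' @param cexc C-storage fraction of biomass (carbohydrate + lipid), 0..1.
#' @param din_n,din_a Dissolved nitrate-N and ammonium-N, g N m^-3.
#' @param dip Dissolved phosphate-P, g P m^-3.
#' @param dic Dissolved inorganic carbon, g C m^-3 (a large, non-limiting
#'   reservoir debited for bookkeeping only).
#' @param hc,hexc Cumulative harvested biomass C and storage C, g.
#' @return A list of class `pbr_state`.
#' @export
algal_state <- function(tc = 200, nc = 0.15, pc = 0.02, chlc = 0.02,
                        cexc = 0.29, din_n = 61.6, din_a = 0, dip = 5.5,
                        dic = 25000, hc = 0, hexc = 0) {
  s <- list(tc = tc, nc = nc, pc = pc, chlc = chlc, cexc = cexc,
            din_n = din_n, din_a = din_a, dip = dip, dic = dic,
            hc = hc, hexc = hexc)
  bad <- names(s)[vapply(s, function(v) !is.finite(v) || v < 0, logical(1))]
  if (length(bad)) abort(paste0("state fields must be finite and >= 0: ",
                                paste(bad, collapse = ", ")))
  if (s$hexc > s$hc + 1e-12) abort("`hexc` cannot exceed `hc`.")
  class(s) <- "pbr_state"
  s
}

#' Normalised quota limitation curve
#'
#' Maps an internal nutrient quota onto a growth-limitation factor in
#' `[0, 1]`: `f = (1 + kq) (q - qmin) / ((q - qmin) + kq (qmax - qmin))`.
#' `f` is 0 at the subsistence quota, 1 at the replete quota, and its
#' curvature is set by `kq` (small `kq` gives a near-step Droop-like
#' response). Values outside the quota bounds are clamped with a warning.
#'
#' @param q Current quota, g (g C)^-1.
#' @param qmin,qmax Quota bounds.
#' @param kq Dimensionless curvature constant (> 0).
#' @return Limitation factor in `[0, 1]`.
#' @examples
#' quota_limitation(0.125, 0.05, 0.20, kq = 1) # midpoint, kq = 1 -> 2/3
#' @export
quota_limitation <- function(q, qmin, qmax, kq) {
  if (any(q < qmin - 1e-12) || any(q > qmax + 1e-12)) {
    warn("quota outside [qmin, qmax]; clamping.",
         .frequency = "once", .frequency_id = "pbrsim_quota_clamp")
  }
  q <- pmin(pmax(q, qmin), qmax)
  qn <- (q - qmin) / (qmax - qmin)
  (1 + kq) * qn / (qn + kq)
}

#' Quota-regulated Michaelis-Menten nutrient uptake
#'
#' C-specific transport rate with substrate saturation and a linear
#' feedback shutdown as the internal quota fills:
#' `V = vmax * s / (s + ks) * max(0, (qmax - q) / (qmax - qmin))`.
#'
#' @param s External substrate concentration, g m^-3.
#' @param vmax Maximum C-specific uptake, g (g C)^-1 d^-1.
#' @param ks Half-saturation constant, g m^-3.
#' @param q Current quota; `qmin`, `qmax` its bounds.
#' @param qmin,qmax Quota bounds.
#' @return Uptake rate, g (g C)^-1 d^-1.
#' @export
nutrient_uptake <- function(s, vmax, ks, q, qmin, qmax) {
  if (any(s < 0)) abort("substrate `s` must be >= 0.")
  vmax * (s / (s + ks)) * pmax(0, (qmax - q) / (qmax - qmin))
}

#' Partition nitrogen demand between ammonium and nitrate
#'
#' Ammonium is energetically cheaper and is consumed first, up to demand;
#' nitrate supplies the remainder. Total never exceeds either the demand or
#' the availability. `din_n`, `din_a` and `demand` must share units (both
#' as masses, or both as rates over the same interval).
#'
#' @param din_n,din_a Available nitrate-N and ammonium-N.
#' @param demand Nitrogen demand.
#' @return Named numeric vector `c(uptake_n = , uptake_a = )`.
#' @export
ammonium_preference <- function(din_n, din_a, demand) {
  if (demand < 0) abort("`demand` must be >= 0.")
  take_a <- min(din_a, demand)
  take_n <- min(din_n, demand - take_a)
  c(uptake_n = take_n, uptake_a = take_a)
}

#' Realised growth rate under the threshold (Liebig) law
#'
#' Combines the light-driven net photosynthesis with the quota limitation
#' factors: `mu = min(ps_net, mu_m * f_N, mu_m * f_P)`. Variants drop the
#' limitation terms they hold fixed; `FIXED` uses `min(ps_net, mu_m)`, with
#' uptake locked to Redfield demand inside [step_physiology()] but no
#' nutrient-status feedback on growth. `mu` can be negative at night when
#' dark respiration exceeds zero photosynthesis.
#'
#' @param state An [algal_state()].
#' @param params A [physiology_params()].
#' @param ps_net Net C-specific photosynthesis, g C (g C)^-1 d^-1.
#' @param mu_m Current temperature-adjusted maximum growth rate, d^-1
#'   (defaults to the summer endpoint).
#' @return Growth rate, d^-1.
#' @export
growth_rate <- function(state, params, ps_net, mu_m = params$mu_summer) {
  fl <- variant_flags(params$variant)
  f_n <- if (fl$quota_n && !params$force_replete) {
    quota_limitation(state$nc, params$ncmin, params$ncmax, params$kq_n)
  } else 1
  f_p <- if (fl$quota_p && !params$force_replete) {
    quota_limitation(state$pc, params$pcmin, params$pcmax, params$kq_p)
  } else 1
  min(ps_net, mu_m * f_n, mu_m * f_p)
}

#' Photoacclimative Chl:C dynamics
#'
#' The cellular pigment target rises under light limitation and falls under
#' N stress or saturating light:
#' `chlc* = max(chlc_min, chlc_m * f_N * (1 - ps_achieved / ps_lightsat))`,
#' where `ps_achieved / ps_lightsat` measures the degree of light
#' saturation. Chl:C relaxes first-order towards the target at rate
#' `rho_chl` and is clipped to `[chlc_min, chlc_m]`. The `CN` and `FIXED`
#' variants return the configured constant Chl:C unchanged.
#'
#' @param state An [algal_state()].
#' @param params A [physiology_params()].
#' @param ps_achieved Realised gross photosynthesis, g C (g C)^-1 d^-1.
#' @param ps_lightsat Fully light-saturated rate (the `Pqm` ceiling).
#' @param dt Time step, days.
#' @return Updated Chl:C ratio.
#' @export
chl_dynamics <- function(state, params, ps_achieved, ps_lightsat, dt) {
  fl <- variant_flags(params$variant)
  if (!fl$chl_dyn) return(state$chlc)
  f_n <- if (fl$quota_n && !params$force_replete) {
    quota_limitation(state$nc, params$ncmin, params$ncmax, params$kq_n)
  } else 1
  sat <- if (ps_lightsat > 0) min(1, ps_achieved / ps_lightsat) else 0
  target <- max(params$chlc_min, params$chlc_m * f_n * (1 - sat))
  chlc <- state$chlc + params$rho_chl * (target - state$chlc) * dt
  min(max(chlc, params$chlc_min), params$chlc_m)
}

#' C-storage fraction of biomass from N status
#'
#' The proportion of biomass carbon held as C-rich storage products
#' (carbohydrate + lipid) increases linearly as the N:C quota falls away
#' from its replete value:
#' `cexc* = cexc_base + (cexc_max - cexc_base) * (ncmax - nc) / (ncmax - ncmin)`.
#' This is the *target* composition; inside [step_physiology()] the realised
#' storage fraction relaxes towards it first-order at rate `rho_cexc`.
#' The `FIXED` variant returns the constant `cexc_fixed`.
#'
#' @param nc N:C quota, g N (g C)^-1.
#' @param params A [physiology_params()].
#' @return Storage fraction in `[cexc_base, cexc_max]`.
#' @export
storage_fraction <- function(nc, params) {
  if (variant_flags(params$variant)$fixed) {
    return(rep_len(params$cexc_fixed, length(nc)))
  }
  nc <- pmin(pmax(nc, params$ncmin), params$ncmax)
  frac <- (params$ncmax - nc) / (params$ncmax - params$ncmin)
  params$cexc_base + (params$cexc_max - params$cexc_base) * frac
}

#' Advance the culture state by one time step
#'
#' One forward-Euler step of the coupled physiology at fixed irradiance:
#' computes the attenuation coefficient, depth-integrated gross
#' photosynthesis, respiration, quota-limited growth, regulated N and P
#' uptake (ammonium before nitrate), photoacclimative Chl:C relaxation and
#' the storage fraction, then updates all pools. The discretisation is
#' conservative: cellular element pools are advanced as extensive
#' quantities, so dissolved + cellular N (and P) is preserved to rounding
#' error over any number of steps; DIC is debited by net fixation.
#' Quota-bound overshoots (e.g. dark respiration concentrating N:C above
#' `ncmax`) are clipped with the excess remineralised to the ammonium pool,
#' preserving the element ledgers.
#'
#' @param state An [algal_state()].
#' @param params A [physiology_params()].
#' @param light List or one-row data frame with `e0` and `e_avg_panel`
#'   (umol photons m^-2 s^-1), as produced by [irradiance_calendar()].
#' @param optics List with `k_background`, `k_chl` and `tau_m` (optical
#'   half-depth, m).
#' @param dt Time step, days (> 0).
#' @param mu_m Current maximum growth rate, d^-1; defaults to the summer
#'   endpoint. Supply [seasonal_mu_max()] output for seasonal runs.
#' @return The advanced `pbr_state`, with a `diag` attribute carrying the
#'   step diagnostics (`ps`, `resp`, `mu`, `k`, `f_n`, `f_p`, `fixed_c`,
#'   `resp_c`, `uptake_n`, `uptake_p`), per-m^3 masses where extensive.
#' @export
step_physiology <- function(state, params, light, optics, dt,
                            mu_m = params$mu_summer) {
  if (dt <= 0) abort("`dt` must be > 0.")
  fl <- variant_flags(params$variant)
  e_avg <- light$e_avg_panel %||% light$e_avg
  if (is.null(e_avg)) abort("`light` must carry `e_avg_panel`.")

  tc <- state$tc; nc <- state$nc; pc <- state$pc; chlc <- state$chlc
  din_n <- state$din_n; din_a <- state$din_a; dip <- state$dip

  pqm <- pqm_from_mu(mu_m, params$r_basal, params$zeta)
  k <- attenuation_coefficient(tc, chlc, optics$k_background, optics$k_chl)
  ps <- depth_integrated_ps(e_avg, chlc, params$alpha, pqm, k, optics$tau_m)
  resp <- respiration_rate(ps, params$r_basal, params$zeta)
  ps_net <- ps - resp

  f_n <- if (fl$quota_n && !params$force_replete) {
    quota_limitation(nc, params$ncmin, params$ncmax, params$kq_n)
  } else 1
  f_p <- if (fl$quota_p && !params$force_replete) {
    quota_limitation(pc, params$pcmin, params$pcmax, params$kq_p)
  } else 1
  mu <- min(ps_net, mu_m * f_n, mu_m * f_p)

  up_n <- c(uptake_n = 0, uptake_a = 0)
  up_p <- 0

  makeup_n <- makeup_p <- 0
  if (fl$fixed) {
    # Fixed-stoichiometry description: growth is light/temperature-limited
    # only. Uptake is locked to Redfield demand and debited from the pools,
    # but the description carries no nutrient-status feedback, so once the
    # pools run dry the shortfall is met by an implicit make-up supply that
    # is recorded in the ledger. Ignoring nutrient exhaustion is the
    # characteristic naivety of this variant.
    tc2 <- tc * (1 + mu * dt)
    if (!params$force_replete) {
      if (mu > 0) {
        need_n <- mu * tc * dt * params$nc_fixed
        up_n <- ammonium_preference(din_n, din_a, need_n)
        makeup_n <- need_n - sum(up_n)
        need_p <- mu * tc * dt * params$pc_fixed
        up_p <- min(dip, need_p)
        makeup_p <- need_p - up_p
        din_n <- din_n - up_n[["uptake_n"]]
        din_a <- din_a - up_n[["uptake_a"]]
        dip <- dip - up_p
      } else {
        # dark C loss at fixed stoichiometry remineralises N and P
        rel <- (tc - tc2)
        din_a <- din_a + rel * params$nc_fixed
        dip <- dip + rel * params$pc_fixed
        up_n <- c(uptake_n = 0, uptake_a = -rel * params$nc_fixed)
        up_p <- -rel * params$pc_fixed
      }
    }
    nc2 <- params$nc_fixed
    pc2 <- params$pc_fixed
  } else {
    tc2 <- tc * (1 + mu * dt)
    if (tc2 <= 0) tc2 <- 1e-9
    if (!params$force_replete) {
      stot <- din_n + din_a
      v_n <- nutrient_uptake(stot, params$vmax_n, params$ks_n,
                             nc, params$ncmin, params$ncmax)
      up_n <- ammonium_preference(din_n, din_a, v_n * tc * dt)
      v_p <- nutrient_uptake(dip, params$vmax_p, params$ks_p,
                             pc, params$pcmin, params$pcmax)
      up_p <- min(dip, v_p * tc * dt)

      cn2 <- nc * tc + sum(up_n)
      cp2 <- pc * tc + up_p
      din_n <- din_n - up_n[["uptake_n"]]
      din_a <- din_a - up_n[["uptake_a"]]
      dip <- dip - up_p

      nc2 <- cn2 / tc2
      pc2 <- cp2 / tc2
      # clip quota overshoot back to the dissolved pools (remineralisation)
      if (nc2 > params$ncmax) {
        din_a <- din_a + (nc2 - params$ncmax) * tc2
        nc2 <- params$ncmax
      }
      if (nc2 < params$ncmin) {
        grab <- min(din_n + din_a, (params$ncmin - nc2) * tc2)
        take <- ammonium_preference(din_n, din_a, grab)
        din_n <- din_n - take[["uptake_n"]]
        din_a <- din_a - take[["uptake_a"]]
        nc2 <- nc2 + grab / tc2
      }
      if (pc2 > params$pcmax) {
        dip <- dip + (pc2 - params$pcmax) * tc2
        pc2 <- params$pcmax
      }
      if (pc2 < params$pcmin) {
        grab <- min(dip, (params$pcmin - pc2) * tc2)
        dip <- dip - grab
        pc2 <- pc2 + grab / tc2
      }
    } else {
      nc2 <- params$ncmax
      pc2 <- params$pcmax
    }
  }

  fixed_c <- (mu + resp) * tc * dt # gross fixation consistent with realised mu
  resp_c <- resp * tc * dt
  dic2 <- state$dic - (fixed_c - resp_c)

  chlc2 <- chl_dynamics(state, params, ps, pqm, dt)
  cexc2 <- if (fl$fixed) params$cexc_fixed else {
    state$cexc + params$rho_cexc * (storage_fraction(nc2, params) - state$cexc) * dt
  }

  out <- state
  out$tc <- tc2; out$nc <- nc2; out$pc <- pc2
  out$chlc <- chlc2; out$cexc <- cexc2
  out$din_n <- max(din_n, 0); out$din_a <- max(din_a, 0)
  out$dip <- max(dip, 0); out$dic <- dic2
  attr(out, "diag") <- list(ps = ps, resp = resp, mu = mu, k = k,
                            f_n = f_n, f_p = f_p,
                            fixed_c = fixed_c, resp_c = resp_c,
                            uptake_n = sum(up_n), uptake_p = up_p,
                            makeup_n = makeup_n, makeup_p = makeup_p)
  out
}

# Internal fast scalar stepper used by the Euler production loop.
# Mirrors step_physiology() arithmetic exactly (the test-suite asserts
# equivalence); parameters are hoisted into the closure so the per-step
# cost is plain scalar arithmetic.
# State vector layout: tc, nc, pc, chlc, din_n, din_a, dip, dic, cexc.
# Returns c(state'[1:8], cexc', ps, resp, mu, k, fixed_c, resp_c, makeup_n,
# makeup_p).
make_stepper <- function(params, optics) {
  fl <- variant_flags(params$variant)
  force_replete <- params$force_replete
  quota_n <- fl$quota_n && !force_replete
  quota_p <- fl$quota_p && !force_replete
  chl_dyn <- fl$chl_dyn
  fixed <- fl$fixed
  ncmin <- params$ncmin; ncmax <- params$ncmax; dnc <- ncmax - ncmin
  pcmin <- params$pcmin; pcmax <- params$pcmax; dpc <- pcmax - pcmin
  kq_n <- params$kq_n; kq_p <- params$kq_p
  vmax_n <- params$vmax_n; vmax_p <- params$vmax_p
  ks_n <- params$ks_n; ks_p <- params$ks_p
  chlc_m <- params$chlc_m; chlc_min <- params$chlc_min
  rho_chl <- params$rho_chl
  alpha <- params$alpha; r_basal <- params$r_basal; zeta <- params$zeta
  cexc_base <- params$cexc_base
  cexc_span <- params$cexc_max - params$cexc_base
  rho_cexc <- params$rho_cexc
  cexc_fixed <- params$cexc_fixed
  nc_fixed <- params$nc_fixed; pc_fixed <- params$pc_fixed
  k_bg <- optics$k_background; k_chl <- optics$k_chl; tau <- optics$tau_m

  function(st, e_avg, mu_m, dt) {
    tc <- st[1]; nc <- st[2]; pc <- st[3]; chlc <- st[4]
    din_n <- st[5]; din_a <- st[6]; dip <- st[7]; dic <- st[8]
    cexc <- st[9]

    pqm <- (mu_m + r_basal) / (1 - zeta)
    k <- k_bg + k_chl * tc * chlc * 1000
    ktau <- k * tau
    x <- e_avg * alpha * chlc / pqm
    ps <- if (ktau < 1e-7) pqm * x / sqrt(1 + x * x)
          else pqm / ktau * (asinh(x) - asinh(x * exp(-ktau)))
    resp <- r_basal + zeta * ps
    ps_net <- ps - resp

    f_n <- if (quota_n) {
      qn <- (min(max(nc, ncmin), ncmax) - ncmin) / dnc
      (1 + kq_n) * qn / (qn + kq_n)
    } else 1
    f_p <- if (quota_p) {
      qp <- (min(max(pc, pcmin), pcmax) - pcmin) / dpc
      (1 + kq_p) * qp / (qp + kq_p)
    } else 1
    mu <- min(ps_net, mu_m * f_n, mu_m * f_p)

    makeup_n <- makeup_p <- 0
    if (fixed) {
      # no nutrient-status feedback: pools debited, shortfall made up
      tc2 <- tc * (1 + mu * dt)
      if (!force_replete) {
        if (mu > 0) {
          need_n <- mu * tc * dt * nc_fixed
          take_a <- min(din_a, need_n)
          take_n <- min(din_n, need_n - take_a)
          makeup_n <- need_n - take_a - take_n
          need_p <- mu * tc * dt * pc_fixed
          up_p <- min(dip, need_p)
          makeup_p <- need_p - up_p
          din_n <- din_n - take_n; din_a <- din_a - take_a; dip <- dip - up_p
        } else {
          rel <- tc - tc2
          din_a <- din_a + rel * nc_fixed
          dip <- dip + rel * pc_fixed
        }
      }
      nc2 <- nc_fixed; pc2 <- pc_fixed
    } else {
      tc2 <- tc * (1 + mu * dt)
      if (tc2 <= 0) tc2 <- 1e-9
      if (!force_replete) {
        stot <- din_n + din_a
        v_n <- vmax_n * (stot / (stot + ks_n)) * max(0, (ncmax - nc) / dnc)
        want <- v_n * tc * dt
        take_a <- min(din_a, want)
        take_n <- min(din_n, want - take_a)
        v_p <- vmax_p * (dip / (dip + ks_p)) * max(0, (pcmax - pc) / dpc)
        up_p <- min(dip, v_p * tc * dt)

        cn2 <- nc * tc + take_a + take_n
        cp2 <- pc * tc + up_p
        din_n <- din_n - take_n; din_a <- din_a - take_a; dip <- dip - up_p
        nc2 <- cn2 / tc2
        pc2 <- cp2 / tc2
        if (nc2 > ncmax) { din_a <- din_a + (nc2 - ncmax) * tc2; nc2 <- ncmax }
        if (nc2 < ncmin) {
          grab <- min(din_n + din_a, (ncmin - nc2) * tc2)
          ga <- min(din_a, grab); gn <- min(din_n, grab - ga)
          din_n <- din_n - gn; din_a <- din_a - ga
          nc2 <- nc2 + grab / tc2
        }
        if (pc2 > pcmax) { dip <- dip + (pc2 - pcmax) * tc2; pc2 <- pcmax }
        if (pc2 < pcmin) {
          grab <- min(dip, (pcmin - pc2) * tc2)
          dip <- dip - grab
          pc2 <- pc2 + grab / tc2
        }
      } else {
        nc2 <- ncmax; pc2 <- pcmax
      }
    }

    fixed_c <- (mu + resp) * tc * dt
    resp_c <- resp * tc * dt
    dic2 <- dic - (fixed_c - resp_c)

    chlc2 <- if (chl_dyn) {
      sat <- if (pqm > 0) min(1, ps / pqm) else 0
      target <- max(chlc_min, chlc_m * f_n * (1 - sat))
      min(max(chlc + rho_chl * (target - chlc) * dt, chlc_min), chlc_m)
    } else chlc
    cexc2 <- if (fixed) cexc_fixed else {
      tgt <- cexc_base + cexc_span * (ncmax - min(max(nc2, ncmin), ncmax)) / dnc
      cexc + rho_cexc * (tgt - cexc) * dt
    }

    c(tc2, nc2, pc2, chlc2,
      if (din_n < 0) 0 else din_n, if (din_a < 0) 0 else din_a,
      if (dip < 0) 0 else dip, dic2,
      cexc2, ps, resp, mu, k, fixed_c, resp_c, makeup_n, makeup_p)
  }
}
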