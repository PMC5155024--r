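#' Seasonal maximum growth rate
#'
#' Temperature enters the model only as a multiplier on the maximum growth
#' rate mu_m: a sinusoid between the mid-winter and mid-summer endpoints,
#' `mu_m(d) = mu_winter + (mu_summer - mu_winter) * (1 - cos(2 pi (d - phase_day)/365)) / 2`.
#' With the default endpoints (1.04 and 1.5 d^-1) the implied Q10 over a
#' ~5 degC seasonal swing is about 2; no explicit temperature state is
#' carried.
#'
#' @param day_of_year Integer day of year, 1..365. Vectorised.
#' @param mu_winter,mu_summer Seasonal mu_m endpoints, d^-1.
#' @param phase_day Day of year of the annual minimum (default 15).
#' @return mu_m, d^-1.
#' @examples
#' seasonal_mu_max(c(15, 15 + 182))
#' @export
seasonal_mu_max <- function(day_of_year, mu_winter = 1.04, mu_summer = 1.5,
                            phase_day = 15) {
  if (any(day_of_year < 1) || any(day_of_year > 365)) {
    abort("`day_of_year` must lie in 1..365.")
  }
  if (!(mu_summer >= mu_winter && mu_winter > 0)) {
    abort("need mu_summer >= mu_winter > 0.")
  }
  mu_winter + (mu_summer - mu_winter) *
    (1 - cos(2 * pi * (day_of_year - phase_day) / 365)) / 2
}

#' Harvest and dilution event
#'
#' Removes a fraction `dil` of the culture volume and replaces it with
#' fresh medium. Harvested biomass C and storage C are credited to the
#' cumulative `hc`/`hexc` ledgers; the dissolved pools relax towards the
#' medium concentrations in the replaced fraction; the intensive quotas
#' (N:C, P:C, Chl:C, storage fraction) are unchanged. A washout guard never
#' lets the biomass concentration fall below the inoculum floor: the
#' effective exchanged fraction is reduced accordingly.
#'
#' @param state An [algal_state()].
#' @param plan Operation plan: list with `dil` (fraction 0..1), `nut_n`,
#'   `nut_p` (medium refill concentrations, g m^-3), optionally
#'   `inoculum_floor` (g C m^-3, default 10) and `dic_refill`
#'   (default 25000 g C m^-3).
#' @param volume Culture volume, m^3.
#' @return The post-harvest `pbr_state`; an `event` attribute carries the
#'   removed masses (g) and the effective exchanged fraction.
#' @examples
#' s <- algal_state(tc = 600, cexc = 0.35)
#' h <- harvest_event(s, list(dil = 0.3, nut_n = 61.6, nut_p = 5.5), 0.242)
#' h$hc # 43.56 g
#' @export
harvest_event <- function(state, plan, volume) {
  dil <- plan$dil
  if (is.null(dil) || dil < 0 || dil > 1) abort("`dil` must lie in [0, 1].")
  floor_tc <- plan$inoculum_floor %||% 10
  f <- if (state$tc > floor_tc) min(dil, 1 - floor_tc / state$tc) else 0

  removed_c <- f * state$tc * volume
  removed_storage <- removed_c * state$cexc
  removed_cell_n <- f * state$nc * state$tc * volume
  removed_cell_p <- f * state$pc * state$tc * volume
  removed_din <- f * (state$din_n + state$din_a) * volume
  removed_dip <- f * state$dip * volume

  out <- state
  out$tc <- (1 - f) * state$tc
  out$din_n <- (1 - f) * state$din_n + f * (plan$nut_n %||% 0)
  out$din_a <- (1 - f) * state$din_a
  out$dip <- (1 - f) * state$dip + f * (plan$nut_p %||% 0)
  out$dic <- (1 - f) * state$dic + f * (plan$dic_refill %||% 25000)
  out$hc <- state$hc + removed_c
  out$hexc <- state$hexc + removed_storage
  attr(out, "event") <- list(
    frac = f,
    removed_c_g = removed_c,
    removed_storage_g = removed_storage,
    removed_n_g = removed_cell_n + removed_din,
    removed_p_g = removed_cell_p + removed_dip,
    refill_n_g = f * (plan$nut_n %||% 0) * volume,
    refill_p_g = f * (plan$nut_p %||% 0) * volume
  )
  out
}

#' Run a coupled reactor simulation
#'
#' Steps the coupled irradiance-photosynthesis-physiology system forward at
#' a fixed step (default 11.25 min) over the configured span, firing
#' harvest/dilution events at local midnight of each scheduled day, and
#' records the full trajectory plus a harvest ledger. See [pbr_config()]
#' for the configuration schema and defaults.
#'
#' @param config A [pbr_config()], a nested list with the same sections, or
#'   a path to a YAML run configuration (see [load_config()]).
#' @param method Integration scheme: `"euler"` (the production default,
#'   matching the system-dynamics heritage of the model) or `"rk4"` (a
#'   classical Runge-Kutta reference mode used for numerical verification).
#' @return An object of class `pbr_sim`: a list with
#'   \describe{
#'     \item{trajectory}{tibble, one row per step (`time_d`, light, state,
#'       rates).}
#'     \item{ledger}{tibble of harvest events (`time_d`, `harvested_c_g`,
#'       `harvested_storage_g`, `frac`).}
#'     \item{accounting}{whole-run mass accounting (g): gross fixed C,
#'       respired C, nutrient refills and removals, initial/final standing
#'       stocks.}
#'     \item{config, volume_m3, footprint_m2}{run metadata.}
#'   }
#' @examples
#' \donttest{
#' sim <- run_simulation(pbr_config(operation = list(sim_days = 10)))
#' glance(sim)
#' }
#' @export
run_simulation <- function(config = pbr_config(), method = NULL) {
  cfg <- as_pbr_config(config)
  geom <- panel_geometry_validate(cfg$geometry)
  params <- do.call(physiology_params, cfg$strain)
  optics <- list(
    k_background = cfg$optics$k_background,
    k_chl = cfg$optics$k_chl,
    tau_m = cfg$optics$tau_m %||% geom$tau_m
  )
  op <- cfg$operation
  method <- method %||% cfg$integrator$method %||% "euler"
  if (!method %in% c("euler", "rk4")) abort("`method` must be euler or rk4.")

  dt_min <- cfg$integrator$dt_min
  dt <- dt_min / 1440
  n_per_day <- as.integer(round(1440 / dt_min))
  n_steps <- op$sim_days * n_per_day
  volume <- geom$volume_m3
  dil <- op$dil %||% default_dilution(op$harvest_interval_d)
  plan <- list(dil = dil, nut_n = op$nut_n, nut_p = op$nut_p,
               inoculum_floor = op$inoculum_floor %||% 10,
               dic_refill = cfg$initial$dic)
  cont_d <- op$continuous_dilution %||% 0

  # precompute forcing at step starts (and half-steps for rk4)
  res <- if (method == "rk4") 2L else 1L
  t_grid <- seq(0, by = dt / res, length.out = n_steps * res + 1)
  doy_grid <- ((op$start_day - 1 + floor(t_grid)) %% 365) + 1
  if ((cfg$site$light %||% "diel") == "constant") {
    e0_grid <- rep_len(cfg$site$constant_pfd %||% 500, length(t_grid))
  } else {
    lambda <- cfg$site$clearness
    if (length(lambda) == 1) lambda <- rep(lambda, 12)
    e0_grid <- surface_irradiance(cfg$site$latitude_deg, doy_grid,
                                  (t_grid %% 1) * 24,
                                  lambda[month_of_day(doy_grid)],
                                  cfg$site$solar_constant_pfd %||% 2500)
  }
  ratio <- panel_shading_ratio(geom$height_m, geom$separation_m)
  eavg_grid <- e0_grid * ratio
  mum_grid <- seasonal_mu_max(doy_grid, params$mu_winter, params$mu_summer,
                              params$phase_day)

  state <- do.call(algal_state, cfg$initial[setdiff(names(cfg$initial), "dic_refill")])

  cols <- c("time_d", "e0", "e_avg", "tc", "nc", "pc", "chlc", "cexc",
            "din_n", "din_a", "dip", "dic", "ps", "resp", "mu", "mu_m", "k")
  traj <- matrix(NA_real_, nrow = n_steps + 1, ncol = length(cols),
                 dimnames = list(NULL, cols))
  traj[1, ] <- c(0, NA, NA, state$tc, state$nc, state$pc, state$chlc,
                 state$cexc, state$din_n, state$din_a, state$dip, state$dic,
                 NA, NA, NA, NA, NA)

  max_ev <- op$sim_days + 2L
  ev_t <- numeric(max_ev); ev_c <- numeric(max_ev)
  ev_x <- numeric(max_ev); ev_f <- numeric(max_ev)
  n_ev <- 0L

  acc <- list(fixed_c_g = 0, resp_c_g = 0,
              refill_n_g = 0, refill_p_g = 0,
              harvested_n_g = 0, harvested_p_g = 0,
              initial = state)

  interval <- op$harvest_interval_d
  if (interval < 1) abort("`harvest_interval_d` must be >= 1.")
  stepper <- make_stepper(params, optics)

  # scalar working copies of state and accounting for the hot loop
  tc <- state$tc; nc <- state$nc; pc <- state$pc; chlc <- state$chlc
  din_n <- state$din_n; din_a <- state$din_a; dip <- state$dip
  dic <- state$dic; cexc <- state$cexc
  hc <- state$hc; hexc <- state$hexc
  fixed_c_g <- resp_c_g <- refill_n_g <- refill_p_g <- 0
  harvested_n_g <- harvested_p_g <- makeup_n_g <- makeup_p_g <- 0
  nut_n <- plan$nut_n; nut_p <- plan$nut_p
  floor_tc <- plan$inoculum_floor; dic_refill <- plan$dic_refill

  # mirrors harvest_event() on the scalar state (asserted equivalent in tests)
  do_harvest <- function(frac, t, record = TRUE) {
    f <- if (tc > floor_tc) min(frac, 1 - floor_tc / tc) else 0
    removed_c <- f * tc * volume
    if (record) {
      n_ev <<- n_ev + 1L
      ev_t[n_ev] <<- t; ev_c[n_ev] <<- removed_c
      ev_x[n_ev] <<- removed_c * cexc; ev_f[n_ev] <<- f
    }
    hc <<- hc + removed_c
    hexc <<- hexc + removed_c * cexc
    harvested_n_g <<- harvested_n_g + f * (nc * tc + din_n + din_a) * volume
    harvested_p_g <<- harvested_p_g + f * (pc * tc + dip) * volume
    refill_n_g <<- refill_n_g + f * nut_n * volume
    refill_p_g <<- refill_p_g + f * nut_p * volume
    tc <<- (1 - f) * tc
    din_n <<- (1 - f) * din_n + f * nut_n
    din_a <<- (1 - f) * din_a
    dip <<- (1 - f) * dip + f * nut_p
    dic <<- (1 - f) * dic + f * dic_refill
    invisible(NULL)
  }

  use_rk4 <- method == "rk4"
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    if (i > 1 && (i - 1) %% n_per_day == 0) {
      day_idx <- as.integer(round(t))
      if (day_idx %% interval == 0) do_harvest(dil, t)
    }
    if (cont_d > 0) do_harvest(cont_d * dt, t, record = FALSE)

    gi <- (i - 1) * res + 1
    mu_m_i <- mum_grid[gi]
    if (!use_rk4) {
      sv <- stepper(c(tc, nc, pc, chlc, din_n, din_a, dip, dic, cexc),
                    eavg_grid[gi], mu_m_i, dt)
    } else {
      st_l <- list(tc = tc, nc = nc, pc = pc, chlc = chlc, cexc = cexc,
                   din_n = din_n, din_a = din_a, dip = dip, dic = dic)
      stepped <- rk4_step(st_l, params, optics, dt, mu_m_i,
                          eavg_grid[gi:(gi + 2)])
      s2 <- stepped$state
      dg <- stepped$diag
      sv <- c(s2$tc, s2$nc, s2$pc, s2$chlc, s2$din_n, s2$din_a, s2$dip,
              s2$dic, s2$cexc, dg$ps, dg$resp, dg$mu, dg$k,
              dg$fixed_c, dg$resp_c, 0, 0)
    }
    tc <- sv[1]; nc <- sv[2]; pc <- sv[3]; chlc <- sv[4]
    din_n <- sv[5]; din_a <- sv[6]; dip <- sv[7]; dic <- sv[8]; cexc <- sv[9]
    fixed_c_g <- fixed_c_g + sv[14] * volume
    resp_c_g <- resp_c_g + sv[15] * volume
    makeup_n_g <- makeup_n_g + sv[16] * volume
    makeup_p_g <- makeup_p_g + sv[17] * volume
    if (!is.finite(tc) || !is.finite(nc)) {
      abort(paste0("non-finite state at t = ", signif(t, 6), " d; ",
                   "last tc = ", signif(traj[i, "tc"], 6)))
    }
    traj[i + 1, ] <- c(t + dt, e0_grid[gi], eavg_grid[gi], tc, nc, pc, chlc,
                       cexc, din_n, din_a, dip, dic,
                       sv[10], sv[11], sv[12], mu_m_i, sv[13])
  }
  # terminal midnight event (end of the final scheduled day)
  if (op$sim_days > 0 && op$sim_days %% interval == 0) {
    do_harvest(dil, op$sim_days)
  }
  acc$fixed_c_g <- fixed_c_g; acc$resp_c_g <- resp_c_g
  acc$refill_n_g <- refill_n_g; acc$refill_p_g <- refill_p_g
  acc$harvested_n_g <- harvested_n_g; acc$harvested_p_g <- harvested_p_g
  acc$makeup_n_g <- makeup_n_g; acc$makeup_p_g <- makeup_p_g
  acc$final <- algal_state(tc = tc, nc = nc, pc = pc, chlc = chlc,
                           cexc = cexc, din_n = din_n, din_a = din_a,
                           dip = dip, dic = max(dic, 0), hc = hc, hexc = hexc)

  out <- list(
    trajectory = tibble::as_tibble(as.data.frame(traj)),
    ledger = tibble::tibble(time_d = ev_t[seq_len(n_ev)],
                            harvested_c_g = ev_c[seq_len(n_ev)],
                            harvested_storage_g = ev_x[seq_len(n_ev)],
                            frac = ev_f[seq_len(n_ev)]),
    accounting = acc,
    config = cfg,
    method = method,
    volume_m3 = volume,
    footprint_m2 = geom$footprint_m2
  )
  class(out) <- "pbr_sim"
  out
}

# one classical RK4 step on the extensive state vector; eavg3 holds the
# panel-average PFD at (t, t + dt/2, t + dt)
rk4_step <- function(state, params, optics, dt, mu_m, eavg3) {
  y <- c(tc = state$tc, cn = state$nc * state$tc, cp = state$pc * state$tc,
         chlc = state$chlc, din_n = state$din_n, din_a = state$din_a,
         dip = state$dip, dic = state$dic)
  k1 <- physiology_derivs(y, params, optics, mu_m, eavg3[1])
  k2 <- physiology_derivs(y + dt / 2 * k1$dy, params, optics, mu_m, eavg3[2])
  k3 <- physiology_derivs(y + dt / 2 * k2$dy, params, optics, mu_m, eavg3[2])
  k4 <- physiology_derivs(y + dt * k3$dy, params, optics, mu_m, eavg3[3])
  y2 <- y + dt / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)

  out <- state
  out$tc <- max(y2[["tc"]], 1e-9)
  nc2 <- y2[["cn"]] / out$tc
  pc2 <- y2[["cp"]] / out$tc
  din_a2 <- y2[["din_a"]]
  dip2 <- y2[["dip"]]
  if (nc2 > params$ncmax) { din_a2 <- din_a2 + (nc2 - params$ncmax) * out$tc; nc2 <- params$ncmax }
  if (pc2 > params$pcmax) { dip2 <- dip2 + (pc2 - params$pcmax) * out$tc; pc2 <- params$pcmax }
  out$nc <- nc2; out$pc <- pc2
  out$chlc <- min(max(y2[["chlc"]], params$chlc_min), params$chlc_m)
  out$din_n <- max(y2[["din_n"]], 0)
  out$din_a <- max(din_a2, 0)
  out$dip <- max(dip2, 0)
  out$dic <- y2[["dic"]]
  out$cexc <- if (variant_flags(params$variant)$fixed) params$cexc_fixed else {
    state$cexc + params$rho_cexc * (storage_fraction(out$nc, params) - state$cexc) * dt
  }
  list(state = out,
       diag = list(ps = k1$ps, resp = k1$resp, mu = k1$mu, k = k1$k,
                   fixed_c = (k1$mu + k1$resp) * state$tc * dt,
                   resp_c = k1$resp * state$tc * dt))
}

# instantaneous derivatives of the extensive state vector (quota model)
physiology_derivs <- function(y, params, optics, mu_m, e_avg) {
  fl <- variant_flags(params$variant)
  tc <- max(y[["tc"]], 1e-12)
  nc <- min(max(y[["cn"]] / tc, params$ncmin), params$ncmax)
  pc <- min(max(y[["cp"]] / tc, params$pcmin), params$pcmax)
  chlc <- min(max(y[["chlc"]], params$chlc_min), params$chlc_m)

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

  if (params$force_replete || fl$fixed) {
    v_tot <- 0; take_a_rate <- 0; take_n_rate <- 0; v_p <- 0
    if (fl$fixed && !params$force_replete) {
      avail <- y[["din_n"]] + y[["din_a"]]
      v_tot <- max(mu, 0) * params$nc_fixed * (avail > 0)
      take_a_rate <- min(v_tot, (y[["din_a"]] > 0) * v_tot)
      take_n_rate <- v_tot - take_a_rate
      v_p <- max(mu, 0) * params$pc_fixed * (y[["dip"]] > 0)
    }
  } else {
    stot <- max(y[["din_n"]], 0) + max(y[["din_a"]], 0)
    v_tot <- nutrient_uptake(stot, params$vmax_n, params$ks_n,
                             nc, params$ncmin, params$ncmax)
    share_a <- if (stot > 0) max(y[["din_a"]], 0) / stot else 0
    take_a_rate <- v_tot * share_a
    take_n_rate <- v_tot * (1 - share_a)
    v_p <- nutrient_uptake(max(y[["dip"]], 0), params$vmax_p, params$ks_p,
                           pc, params$pcmin, params$pcmax)
  }

  sat <- if (pqm > 0) min(1, ps / pqm) else 0
  target <- max(params$chlc_min, params$chlc_m * f_n * (1 - sat))
  dchlc <- if (fl$chl_dyn) params$rho_chl * (target - chlc) else 0

  dy <- c(tc = mu * tc,
          cn = v_tot * tc,
          cp = v_p * tc,
          chlc = dchlc,
          din_n = -take_n_rate * tc,
          din_a = -take_a_rate * tc,
          dip = -v_p * tc,
          dic = -mu * tc)
  list(dy = dy, ps = ps, resp = resp, mu = mu, k = k)
}

#' @export
print.pbr_sim <- function(x, ...) {
  cfg <- x$config
  cat("<pbr_sim> ", cfg$operation$sim_days, "-day run, variant ",
      cfg$strain$variant %||% "CNPCHL", ", harvest every ",
      cfg$operation$harvest_interval_d, " d (", x$method, ")\n", sep = "")
  g <- glance(x)
  cat(sprintf("  mean VP %.1f mg C L-1 d-1 | peak VP %.1f | mean AXP %.2f g C m-2 d-1\n",
              g$mean_vp, g$peak_vp, g$mean_axp))
  invisible(x)
}
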