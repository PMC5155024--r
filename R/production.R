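#' Mean volumetric production over a window
#'
#' Harvested biomass carbon per culture volume per day, the headline
#' volumetric production statistic: `VP = sum(harvested C in window) /
#' (volume * window length)`. Internally g C m^-3 d^-1, reported as the
#' numerically identical mg C L^-1 d^-1.
#'
#' @param sim A `pbr_sim` from [run_simulation()].
#' @param window Numeric length-2 `c(t0, t1)` in days; events with
#'   `t0 < time_d <= t1` are counted. Default: the whole run.
#' @return Mean VP, mg C L^-1 d^-1.
#' @export
volumetric_production <- function(sim, window = NULL) {
  w <- production_window(sim, window)
  got <- dplyr::filter(sim$ledger, .data$time_d > w[1], .data$time_d <= w[2])
  sum(got$harvested_c_g) / (sim$volume_m3 * (w[2] - w[1]))
}

#' Mean areal feedstock production over a window
#'
#' Harvested C-rich storage (the biofuel feedstock proxy) per ground
#' footprint per day: `AXP = sum(harvested storage C) / (footprint * window
#' length)`, in g C m^-2 d^-1. The footprint convention is ground area per
#' panel `(width + separation) * length`, giving a volume-to-area factor of
#' `w h / (w + s)` (0.07 m for the default geometry).
#'
#' @inheritParams volumetric_production
#' @return Mean AXP, g C m^-2 d^-1.
#' @export
areal_feedstock_production <- function(sim, window = NULL) {
  w <- production_window(sim, window)
  got <- dplyr::filter(sim$ledger, .data$time_d > w[1], .data$time_d <= w[2])
  sum(got$harvested_storage_g) / (sim$footprint_m2 * (w[2] - w[1]))
}

production_window <- function(sim, window) {
  span <- sim$config$operation$sim_days
  if (is.null(window)) window <- c(0, span)
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be c(t0, t1) with t1 > t0.")
  }
  if (window[1] < 0 || window[2] > span) abort("`window` outside the run span.")
  window
}

#' Daily production series
#'
#' Net biomass (and storage) carbon produced per day: the change in
#' standing stock across the day plus anything harvested during it. For
#' daily harvesting this tracks the harvest yields; for longer intervals it
#' is the instantaneous daily production whose within-cycle swing grows
#' with the harvest interval.
#'
#' @param sim A `pbr_sim`.
#' @return A tibble with one row per simulated day: `day`, `day_of_year`,
#'   `month`, `vp` (mg C L^-1 d^-1), `axp` (g C m^-2 d^-1), `mean_e_avg`,
#'   `mean_mu`, `mean_nc`, `mean_cexc`.
#' @export
daily_production <- function(sim) {
  tr <- sim$trajectory
  n_per_day <- sum(tr$time_d > 0 & tr$time_d <= 1)
  days <- sim$config$operation$sim_days
  start_day <- sim$config$operation$start_day %||% 1
  v2a <- sim$volume_m3 / sim$footprint_m2

  idx <- seq(1, nrow(tr), by = n_per_day) # rows at integer days
  tc_bnd <- tr$tc[idx]
  storage_bnd <- (tr$tc * tr$cexc)[idx]
  harv <- sim$ledger
  hv_c <- hv_x <- numeric(days)
  if (nrow(harv)) {
    # an event at midnight t = d is removed from the stock during day d + 1;
    # the terminal event (t = sim_days) removes stock already counted as the
    # final day's standing increase, so it is excluded here
    day_bin <- floor(harv$time_d) + 1
    keep <- day_bin <= days
    hv_c <- as.numeric(tapply(harv$harvested_c_g[keep],
                              factor(day_bin[keep], levels = seq_len(days)), sum))
    hv_x <- as.numeric(tapply(harv$harvested_storage_g[keep],
                              factor(day_bin[keep], levels = seq_len(days)), sum))
    hv_c[is.na(hv_c)] <- 0
    hv_x[is.na(hv_x)] <- 0
  }
  # production during day d = delta standing over (d-1, d] + removals
  # from events at midnight d-1 (the start of day d)
  dprod_c <- diff(tc_bnd) + hv_c / sim$volume_m3
  dprod_x <- diff(storage_bnd) + hv_x / sim$volume_m3

  day <- seq_len(days)
  doy <- ((start_day - 1 + day - 1) %% 365) + 1
  step_day <- pmin(floor(tr$time_d[-1] - 1e-9) + 1, days)
  by_day <- function(v) as.numeric(tapply(v, step_day, mean))
  tibble::tibble(
    day = day,
    day_of_year = as.integer(doy),
    month = as.integer(month_of_day(doy)),
    vp = dprod_c,
    axp = dprod_x * v2a,
    mean_e_avg = by_day(tr$e_avg[-1]),
    mean_mu = by_day(tr$mu[-1]),
    mean_nc = by_day(tr$nc[-1]),
    mean_cexc = by_day(tr$cexc[-1])
  )
}

#' Monthly production summary
#'
#' Calendar-month means of the daily production series and the panel-face
#' irradiance, the aggregation used for month-by-month model/data
#' comparisons.
#'
#' @param sim A `pbr_sim` spanning at least one month.
#' @return A tibble with `month`, `n_days`, `mean_vp`, `mean_axp`,
#'   `mean_e_avg`.
#' @export
monthly_summary <- function(sim) {
  dp <- daily_production(sim)
  dplyr::group_by(dp, month = .data$month) |>
    dplyr::summarise(n_days = dplyr::n(),
                     mean_vp = mean(.data$vp),
                     mean_axp = mean(.data$axp),
                     mean_e_avg = mean(.data$mean_e_avg),
                     .groups = "drop")
}

#' @describeIn run_simulation `tidy()` returns the step-level trajectory as
#'   a tibble.
#' @param x A `pbr_sim` object.
#' @param ... Unused.
#' @export
tidy.pbr_sim <- function(x, ...) {
  x$trajectory
}

#' @describeIn run_simulation `glance()` returns a one-row summary with the
#'   headline production statistics (mean/peak VP and AXP, harvested
#'   totals, mean physiological state).
#' @export
glance.pbr_sim <- function(x, ...) {
  dp <- daily_production(x)
  tibble::tibble(
    sim_days = x$config$operation$sim_days,
    variant = x$config$strain$variant %||% "CNPCHL",
    harvest_interval_d = x$config$operation$harvest_interval_d,
    dil = x$config$operation$dil %||%
      default_dilution(x$config$operation$harvest_interval_d),
    mean_vp = volumetric_production(x),
    peak_vp = max(dp$vp),
    mean_axp = areal_feedstock_production(x),
    peak_axp = max(dp$axp),
    harvested_c_g = x$accounting$final$hc,
    harvested_storage_g = x$accounting$final$hexc,
    mean_tc = mean(x$trajectory$tc),
    mean_nc = mean(x$trajectory$nc),
    mean_cexc = mean(x$trajectory$cexc)
  )
}

#' @describeIn run_simulation `autoplot()` shows the daily VP and AXP
#'   series with monthly means overlaid.
#' @param object A `pbr_sim` object.
#' @export
autoplot.pbr_sim <- function(object, ...) {
  dp <- daily_production(object) |>
    dplyr::select("day", "vp", "axp") |>
    tidyr::pivot_longer(c("vp", "axp"), names_to = "metric") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      vp = "VP (mg C L⁻¹ d⁻¹)",
      axp = "AXP (g C m⁻² d⁻¹)"))
  ggplot2::ggplot(dp, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "simulation day", y = NULL,
                  title = "Daily volumetric and areal feedstock production") +
    ggplot2::theme_minimal()
}

#' Plot the light field of a run
#'
#' Daily mean overhead and panel-face-averaged PFD over the simulation.
#'
#' @param sim A `pbr_sim`.
#' @return A ggplot object.
#' @export
plot_irradiance <- function(sim) {
  tr <- sim$trajectory |>
    dplyr::filter(!is.na(.data$e0)) |>
    dplyr::mutate(day = floor(.data$time_d - 1e-9) + 1) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(e0 = mean(.data$e0), e_avg = mean(.data$e_avg),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("e0", "e_avg"), names_to = "series")
  ggplot2::ggplot(tr, ggplot2::aes(.data$day, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulation day",
                  y = "PFD (µmol photons m⁻² s⁻¹)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
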