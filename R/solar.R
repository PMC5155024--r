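#' Solar declination angle
#'
#' Cooper-style approximation of the solar declination for a 365-day
#' calendar (leap days ignored): `delta = -23.45 deg * cos(2*pi*(day + 10)/365)`.
#' Adequate for the monthly-average irradiance fitting this package targets.
#'
#' @param day_of_year Integer day of year, 1..365. Vectorised.
#' @return Declination in radians, bounded by +/- 23.45 degrees.
#' @examples
#' solar_declination(172) # near the summer solstice, ~ +0.409 rad
#' @export
solar_declination <- function(day_of_year) {
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1) || any(day_of_year > 365)) {
    abort("`day_of_year` must lie in 1..365.")
  }
  -(23.45 * pi / 180) * cos(2 * pi * (day_of_year + 10) / 365)
}

#' Instantaneous overhead surface irradiance
#'
#' Photon flux density reaching the top of the panel array from the solar
#' cycle: `E0 = SC * (sin(phi) sin(delta) - cos(phi) cos(delta) cos(theta)) * Lambda`,
#' clamped at zero when the sun is below the horizon. The diel angle is
#' `theta = 2*pi*hour/24` with `hour` counted from local solar midnight, so
#' the expression peaks at solar noon. `SC` is the solar constant expressed
#' directly as a PAR photon flux; only the product `SC * Lambda` is
#' identified when the clearness index is calibrated against measured PFD.
#'
#' @param latitude_deg Latitude in degrees north (-90..90).
#' @param day_of_year Integer day of year, 1..365.
#' @param hour Decimal hour of local solar time; wrapped modulo 24.
#' @param clearness Dimensionless clearness index Lambda in `[0, 1]`: the
#'   fraction of extraterrestrial sunlight penetrating the atmosphere on an
#'   average day.
#' @param solar_constant_pfd Solar constant as PAR photon flux density,
#'   umol photons m^-2 s^-1 (default 2500).
#' @return Photon flux density, umol photons m^-2 s^-1 (>= 0). Vectorised
#'   over `day_of_year` and `hour`.
#' @examples
#' # solar noon at 40 N on the vernal equinox under Lambda = 0.7
#' surface_irradiance(40, 80, 12, 0.7)
#' @export
surface_irradiance <- function(latitude_deg, day_of_year, hour, clearness,
                               solar_constant_pfd = 2500) {
  if (any(abs(latitude_deg) > 90)) abort("`latitude_deg` must lie within +/-90.")
  if (any(clearness < 0 | clearness > 1)) abort("`clearness` must lie in [0, 1].")
  phi <- latitude_deg * pi / 180
  delta <- solar_declination(day_of_year)
  theta <- 2 * pi * (hour %% 24) / 24
  pmax(0, solar_constant_pfd * (sin(phi) * sin(delta) -
                                  cos(phi) * cos(delta) * cos(theta)) * clearness)
}

#' Angle of sky visible between neighbouring panels
#'
#' For vertical panels separated by `s`, a point a depth `z` below the top
#' of the panel sees an unobstructed wedge of sky of angle
#' `beta = 2 * atan(s / (2 z))`. At the panel top (`z = 0`) the whole sky
#' from horizon to horizon is visible and `beta = pi` (taken as the limit,
#' not an error).
#'
#' @param z Depth below the panel top, m (>= 0). Vectorised.
#' @param s Panel separation, m (> 0).
#' @return Angle in radians, in `(0, pi]`, monotone decreasing in `z`.
#' @export
shading_angle <- function(z, s) {
  if (any(z < 0)) abort("`z` must be >= 0.")
  if (any(s <= 0)) abort("`s` must be > 0.")
  # pi/2 - atan(2z/s) is the numerically safe form of atan(s/2z) at z = 0
  2 * (pi / 2 - atan(2 * z / s))
}

#' Irradiance on a panel face at a given depth below the top
#'
#' The overhead flux is scaled by the fraction of visible sky:
#' `E(z) = E0 * beta(z) / pi`.
#'
#' @param e0 Overhead photon flux density, umol photons m^-2 s^-1 (>= 0).
#' @param z Depth below the panel top, m.
#' @param s Panel separation, m.
#' @return Photon flux density in `[0, e0]`.
#' @export
panel_irradiance_at_height <- function(e0, z, s) {
  if (any(e0 < 0)) abort("`e0` must be >= 0.")
  e0 * shading_angle(z, s) / pi
}

#' Fraction of overhead irradiance reaching an average point on a panel face
#'
#' Height-average of the shading profile, in closed form:
#' `ratio = (1 / (pi h)) * (s/2 * log(1 + (2h/s)^2) + 2 h * atan(s / (2h)))`.
#' Depends only on the ratio `s/h`; tends to 1 as `s/h -> Inf` (no shading)
#' and to 0 as `s -> 0` (full occlusion).
#'
#' @param height_m Panel height `h`, m (> 0).
#' @param separation_m Panel separation `s`, m (> 0).
#' @return Dimensionless ratio in `(0, 1)`.
#' @export
panel_shading_ratio <- function(height_m, separation_m) {
  if (any(height_m <= 0) || any(separation_m <= 0)) {
    abort("panel `height_m` and `separation_m` must be > 0.")
  }
  h <- height_m
  s <- separation_m
  (0.5 * s * log(1 + (2 * h / s)^2) + 2 * h * atan(s / (2 * h))) / (pi * h)
}

#' Average irradiance over a shaded vertical panel face
#'
#' Closed-form height average of [panel_irradiance_at_height()] from the top
#' of the panel to its base. Equals `e0 * panel_shading_ratio(h, s)`.
#'
#' @param e0 Overhead photon flux density, umol photons m^-2 s^-1.
#' @param geom A panel geometry, see [panel_geometry()].
#' @return Panel-face-averaged photon flux density in `[0, e0]`.
#' @examples
#' g <- panel_geometry()
#' average_panel_irradiance(1000, g) # ~ 397 for the default geometry
#' @export
average_panel_irradiance <- function(e0, geom) {
  geom <- panel_geometry_validate(geom)
  e0 * panel_shading_ratio(geom$height_m, geom$separation_m)
}

#' Flat-panel array geometry
#'
#' Describes one repeating unit of a vertical flat-panel array. The optical
#' half-depth `tau` used for Beer-Lambert attenuation defaults to half the
#' panel width (both faces are illuminated equally). The ground footprint of
#' a panel is `(width + separation) * length`, so the volume-to-footprint
#' conversion factor is `width * height / (width + separation)` metres.
#'
#' @param height_m Panel height, m.
#' @param width_m Panel width (optical path), m.
#' @param length_m Panel length, m.
#' @param separation_m Gap between neighbouring panels, m.
#' @param n_panels Number of panels in the array (>= 1).
#' @return A list of class `pbr_geometry` with the fields above plus the
#'   derived `tau_m`, `volume_m3` (per array), `footprint_m2` (per array).
#' @examples
#' panel_geometry() # the 0.05 x 0.28 x 17.3 m reference panel, 0.15 m apart
#' @export
panel_geometry <- function(height_m = 0.28, width_m = 0.05, length_m = 17.3,
                           separation_m = 0.15, n_panels = 1) {
  g <- list(height_m = height_m, width_m = width_m, length_m = length_m,
            separation_m = separation_m, n_panels = n_panels)
  panel_geometry_validate(g)
}

panel_geometry_validate <- function(g) {
  stopifnot(is.list(g))
  need <- c("height_m", "width_m", "length_m", "separation_m")
  for (f in need) {
    if (is.null(g[[f]]) || !is.finite(g[[f]]) || g[[f]] <= 0) {
      abort(paste0("geometry field `", f, "` must be a positive number."))
    }
  }
  g$n_panels <- g$n_panels %||% 1
  if (g$n_panels < 1) abort("`n_panels` must be >= 1.")
  g$tau_m <- g$tau_m %||% (g$width_m / 2)
  g$volume_m3 <- g$width_m * g$height_m * g$length_m * g$n_panels
  g$footprint_m2 <- (g$width_m + g$separation_m) * g$length_m * g$n_panels
  class(g) <- "pbr_geometry"
  g
}

#' Irradiance calendar for a site and panel geometry
#'
#' Evaluates the solar model on a regular time grid and averages each
#' overhead value over the shaded panel face. Months follow a fixed 365-day
#' calendar; the monthly clearness index is applied by calendar month of the
#' simulated day.
#'
#' @param site Site description: list with `latitude_deg`, `clearness`
#'   (length 12, one Lambda per month), `solar_constant_pfd`.
#' @param geom Panel geometry from [panel_geometry()].
#' @param days Number of days to tabulate (default 365).
#' @param dt_min Time step, minutes; must divide 1440 (default 11.25).
#' @param start_day Day of year of the first simulated day (default 1).
#' @return A tibble with one row per step: `time_d` (decimal days from the
#'   start), `day_of_year`, `month`, `hour`, `e0` and `e_avg_panel`
#'   (umol photons m^-2 s^-1).
#' @examples
#' cal <- irradiance_calendar(list(latitude_deg = 40, clearness = rep(0.7, 12)),
#'                            panel_geometry(), days = 2)
#' dplyr::summarise(cal, peak = max(e0))
#' @export
irradiance_calendar <- function(site, geom = panel_geometry(), days = 365,
                                dt_min = 11.25, start_day = 1) {
  lambda <- site$clearness
  if (length(lambda) == 1) lambda <- rep(lambda, 12)
  if (length(lambda) != 12) abort("site `clearness` must have 1 or 12 values.")
  sc <- site$solar_constant_pfd %||% 2500
  if (1440 %% dt_min != 0) abort("`dt_min` must divide 1440.")
  geom <- panel_geometry_validate(geom)

  n_per_day <- as.integer(round(1440 / dt_min))
  time_d <- seq(0, days - dt_min / 1440, by = dt_min / 1440)
  doy <- ((start_day - 1 + floor(time_d)) %% 365) + 1
  hour <- (time_d %% 1) * 24
  month <- month_of_day(doy)
  e0 <- surface_irradiance(site$latitude_deg, doy, hour, lambda[month], sc)
  tibble::tibble(
    time_d = time_d,
    day_of_year = as.integer(doy),
    month = as.integer(month),
    hour = hour,
    e0 = e0,
    e_avg_panel = e0 * panel_shading_ratio(geom$height_m, geom$separation_m)
  )
}

# month index (1..12) of a 365-day calendar day-of-year
month_of_day <- function(doy) {
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(doy - 1, c(0, ends[-12]))
}

#' Monthly mean panel irradiance
#'
#' Convenience summary of [irradiance_calendar()]: the 24-h mean
#' panel-face-averaged PFD for each calendar month.
#'
#' @inheritParams irradiance_calendar
#' @return A tibble with `month`, `mean_e0`, `mean_e_avg`.
#' @export
monthly_mean_irradiance <- function(site, geom = panel_geometry(),
                                    dt_min = 11.25) {
  irradiance_calendar(site, geom, days = 365, dt_min = dt_min) |>
    dplyr::group_by(month = .data$month) |>
    dplyr::summarise(mean_e0 = mean(.data$e0),
                     mean_e_avg = mean(.data$e_avg_panel),
                     .groups = "drop")
}
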