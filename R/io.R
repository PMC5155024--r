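#' Write a simulation trajectory to CSV
#'
#' One row per time step with an ISO-8601 timestamp in local solar time
#' (the nominal non-leap year 2001 carries the day-of-year; no timezone
#' database is involved) alongside the numeric state and rate columns.
#' Round-trips through [read_trajectory()] to full double precision.
#'
#' @param sim A `pbr_sim` from [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  tr <- sim$trajectory
  if (!nrow(tr)) abort("empty trajectory.")
  start_day <- sim$config$operation$start_day %||% 1
  secs <- round((start_day - 1 + tr$time_d) * 86400)
  stamp <- as.POSIXct(secs, origin = "2001-01-01", tz = "UTC")
  out <- dplyr::mutate(tr,
                       timestamp_iso = format(stamp, "%Y-%m-%dT%H:%M:%S"),
                       .before = 1)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return A tibble with the same columns (timestamp parsed as character;
#'   all numeric columns restored).
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(timestamp_iso = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Write the full output set of a run
#'
#' Writes `trajectory.csv`, `ledger.csv` and `monthly.csv` plus a
#' `metadata.yaml` sidecar (configuration hash, resolved configuration,
#' package version, integration method) sufficient to reproduce the run.
#'
#' @param sim A `pbr_sim`.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed to record in the sidecar (the simulator itself
#'   is deterministic; calibration seeds belong here).
#' @return `dir`, invisibly.
#' @export
write_simulation_outputs <- function(sim, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(sim, file.path(dir, "trajectory.csv"))
  readr::write_csv(sim$ledger, file.path(dir, "ledger.csv"), progress = FALSE)
  readr::write_csv(monthly_summary(sim), file.path(dir, "monthly.csv"),
                   progress = FALSE)
  meta <- list(
    package = "pbrsim",
    version = as.character(utils::packageVersion("pbrsim")),
    method = sim$method,
    config_hash = rlang::hash(unclass(sim$config)),
    seed = seed,
    config = unclass(sim$config)
  )
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Deterministic reference fixtures for tests and calibration demos
#'
#' Generates, purely in code, the small synthetic inputs the test-suite and
#' calibration examples need: (a) a 12-month table of panel-average PFD
#' targets produced from a known clearness calendar drawn uniformly in
#' 0.55..0.8, (b) a fast 10-day run configuration (1,280 steps at the
#' default step size), and (c) synthetic monthly VP/AXP targets from a
#' known 31-day run of that configuration. Everything is a deterministic
#' function of `seed`; the global RNG state is untouched.
#'
#' @param seed Integer seed.
#' @return A list with `lambda_true` (the generating clearness calendar),
#'   `irradiance_targets` (tibble: month, target_pfd), `ci_config`
#'   (a `pbr_config`), and `production_targets` (tibble: month, target_vp,
#'   target_axp).
#' @export
make_reference_fixtures <- function(seed = 1) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)

  lambda_true <- round(runif(12, 0.55, 0.8), 3)
  site <- list(latitude_deg = 40, clearness = lambda_true,
               solar_constant_pfd = 2500)
  mm <- monthly_mean_irradiance(site, panel_geometry())
  irradiance_targets <- tibble::tibble(month = mm$month,
                                       target_pfd = mm$mean_e_avg)

  ci_config <- pbr_config(site = list(clearness = lambda_true),
                          operation = list(sim_days = 10))

  month_cfg <- pbr_config(site = list(clearness = lambda_true),
                          operation = list(sim_days = 31))
  ms <- monthly_summary(run_simulation(month_cfg))
  production_targets <- tibble::tibble(month = ms$month,
                                       target_vp = ms$mean_vp,
                                       target_axp = ms$mean_axp)

  list(lambda_true = lambda_true,
       irradiance_targets = irradiance_targets,
       ci_config = ci_config,
       production_targets = production_targets)
}
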