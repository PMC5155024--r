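# shared fixtures: small fast configurations built in code

fast_config <- function(days = 10, ...) {
  pbr_config(operation = modifyList(list(sim_days = days), list(...)))
}

# constant-light chemostat configuration (no diel cycle, continuous dilution)
chemostat_config <- function(days = 40, rate = 0.3, pfd = 600) {
  pbr_config(
    site = list(light = "constant", constant_pfd = pfd),
    operation = list(sim_days = days, harvest_interval_d = days + 1,
                     continuous_dilution = rate, dil = 0),
    initial = list(tc = 100)
  )
}

# trapezoid quadrature on a fixed grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# element ledgers of a finished run; all residuals should vanish
ledger_residuals <- function(sim) {
  a <- sim$accounting
  v <- sim$volume_m3
  dC <- (a$final$tc - a$initial$tc) * v
  c_res <- a$fixed_c_g - a$resp_c_g - dC - a$final$hc
  n0 <- (a$initial$din_n + a$initial$din_a + a$initial$nc * a$initial$tc) * v
  n1 <- (a$final$din_n + a$final$din_a + a$final$nc * a$final$tc) * v
  n_res <- n1 - n0 - a$refill_n_g - (a$makeup_n_g %||% 0) + a$harvested_n_g
  p0 <- (a$initial$dip + a$initial$pc * a$initial$tc) * v
  p1 <- (a$final$dip + a$final$pc * a$final$tc) * v
  p_res <- p1 - p0 - a$refill_p_g - (a$makeup_p_g %||% 0) + a$harvested_p_g
  scale <- c(a$fixed_c_g, a$refill_n_g + n0, a$refill_p_g + p0)
  c(C = c_res, N = n_res, P = p_res) / pmax(scale, 1e-9)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
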