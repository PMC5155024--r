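#' Define a calibration problem
#'
#' A bounded derivative-free estimation problem: free parameters with
#' finite bounds, a prediction function, and targets. The objective
#' minimised by [random_search()] is the sum of squared relative errors
#' `sum(((pred - target)/target)^2)` over the named targets.
#'
#' @param lower,upper Named numeric vectors of identical names: the bounds
#'   of each free parameter.
#' @param predict_fn Function taking a named parameter vector and returning
#'   named predictions covering every target name. May signal an error for
#'   an infeasible candidate; the candidate is then rejected (objective
#'   `+Inf`).
#' @param targets Named numeric vector of non-zero target values.
#' @return A list of class `pbr_problem`.
#' @export
calibration_problem <- function(lower, upper, predict_fn, targets) {
  if (!length(lower) || is.null(names(lower)) ||
      !identical(names(lower), names(upper))) {
    abort("`lower` and `upper` must be named identically.")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper <= lower)) {
    abort("bounds must be finite with upper > lower.")
  }
  if (!length(targets) || is.null(names(targets)) || any(targets == 0)) {
    abort("`targets` must be a named numeric vector with non-zero values.")
  }
  structure(list(lower = lower, upper = upper, predict_fn = predict_fn,
                 targets = targets),
            class = "pbr_problem")
}

#' Calibration objective: sum of squared relative errors
#'
#' Evaluates the problem's prediction function at a candidate parameter
#' vector and scores it against the targets. A failed simulation yields
#' `+Inf` (candidate rejected), so the search is robust to infeasible
#' corners of the box.
#'
#' @param params Named candidate vector within the problem bounds.
#' @param problem A [calibration_problem()].
#' @return Non-negative scalar; 0 iff every prediction equals its target.
#' @export
objective <- function(params, problem) {
  if (any(params < problem$lower - 1e-12) ||
      any(params > problem$upper + 1e-12)) {
    abort("`params` outside the problem bounds.")
  }
  pred <- tryCatch(problem$predict_fn(params), error = function(e) NULL)
  if (is.null(pred)) return(Inf)
  miss <- setdiff(names(problem$targets), names(pred))
  if (length(miss)) {
    abort(paste0("prediction is missing target: ", miss[1]))
  }
  pred <- pred[names(problem$targets)]
  if (any(!is.finite(pred))) return(Inf)
  sum(((pred - problem$targets) / problem$targets)^2)
}

#' Adaptive random search over a bounded parameter box
#'
#' A simple stochastic optimiser in the spirit of the parameter-tuning
#' tools used with system-dynamics models: the first candidate is sampled
#' uniformly in the box; subsequent candidates perturb the running best
#' with a Gaussian step whose scale expands on success and shrinks on
#' failure (a (1+1)-style scheme), with occasional uniform restarts to
#' escape local basins. Fully deterministic given `seed`; the global RNG
#' state is left untouched.
#'
#' @param problem A [calibration_problem()].
#' @param n_iter Number of objective evaluations (>= 1).
#' @param seed Integer seed driving all randomness.
#' @param sigma0 Initial Gaussian step scale as a fraction of each
#'   parameter range (default 0.25).
#' @param restart_prob Probability of a uniform restart draw (default 0.05).
#' @return An object of class `pbr_calibration`: list with `par` (best
#'   parameters), `objective` (best score), `trace` (tibble of
#'   `iter`, `objective`, `best`), `n_eval`, `seed`. The running best in
#'   `trace$best` is non-increasing.
#' @examples
#' pr <- calibration_problem(c(a = 0), c(a = 1),
#'                           function(p) c(y = p[["a"]]^2), c(y = 0.25))
#' fit <- random_search(pr, 200, seed = 1)
#' fit$par
#' @export
random_search <- function(problem, n_iter, seed, sigma0 = 0.25,
                          restart_prob = 0.05) {
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  stopifnot(inherits(problem, "pbr_problem"))
  lower <- problem$lower
  upper <- problem$upper
  range <- upper - lower
  d <- length(lower)

  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  sigma <- sigma0
  best <- NULL
  best_obj <- Inf
  obj_trace <- best_trace <- numeric(n_iter)

  for (i in seq_len(n_iter)) {
    if (i == 1 || runif(1) < restart_prob) {
      cand <- lower + runif(d) * range
    } else {
      cand <- best + rnorm(d) * sigma * range
      cand <- pmin(pmax(cand, lower), upper)
    }
    names(cand) <- names(lower)
    o <- objective(cand, problem)
    if (o < best_obj) {
      best <- cand
      best_obj <- o
      sigma <- min(sigma * 1.6, 1)
    } else {
      sigma <- max(sigma * 0.96, 1e-4)
    }
    obj_trace[i] <- o
    best_trace[i] <- best_obj
  }

  structure(list(par = best, objective = best_obj,
                 trace = tibble::tibble(iter = seq_len(n_iter),
                                        objective = obj_trace,
                                        best = best_trace),
                 n_eval = n_iter, seed = seed),
            class = "pbr_calibration")
}

#' Check fitted clearness indices against the plausible envelope
#'
#' `TRUE` iff every fitted clearness parameter in a calibration result lies
#' inside the plausible atmospheric envelope (by default 0.45..0.8, the
#' typical range of monthly clearness indices).
#'
#' @param result A `pbr_calibration` (or a named parameter vector).
#' @param lower,upper Envelope bounds.
#' @param pattern Regular expression selecting the clearness parameters by
#'   name (default `"^clearness"`).
#' @return Logical scalar.
#' @export
tuned_clearness_check <- function(result, lower = 0.45, upper = 0.8,
                                  pattern = "^clearness") {
  par <- if (inherits(result, "pbr_calibration")) result$par else result
  lam <- par[grepl(pattern, names(par))]
  if (!length(lam)) abort("no clearness parameters found in the result.")
  all(lam >= lower & lam <= upper)
}

#' Monthly-irradiance calibration problem for the clearness calendar
#'
#' Builds a [calibration_problem()] whose free parameters are the 12
#' monthly clearness indices (`clearness_1` .. `clearness_12`) and whose
#' targets are monthly mean panel-face PFD values. Because the irradiance
#' model is linear in the clearness index, predictions are evaluated from
#' a precomputed unit-clearness calendar, making each objective evaluation
#' cheap.
#'
#' @param targets Tibble with columns `month` (1..12) and `target_pfd`
#'   (monthly mean panel-average PFD, umol photons m^-2 s^-1).
#' @param site Site list (latitude, solar constant); clearness is ignored.
#' @param geom A [panel_geometry()].
#' @param bounds Length-2 numeric bounds for every monthly index
#'   (default `c(0.45, 0.8)`).
#' @param dt_min Calendar resolution used for the monthly means.
#' @return A `pbr_problem`.
#' @export
clearness_problem <- function(targets, site = list(latitude_deg = 40),
                              geom = panel_geometry(),
                              bounds = c(0.45, 0.8), dt_min = 11.25) {
  stopifnot(all(c("month", "target_pfd") %in% names(targets)))
  site$clearness <- rep(1, 12)
  unit <- monthly_mean_irradiance(site, geom, dt_min = dt_min)
  a <- unit$mean_e_avg[match(1:12, unit$month)]
  nm <- paste0("clearness_", targets$month)
  tv <- setNames(targets$target_pfd, nm)
  months <- targets$month
  calibration_problem(
    lower = setNames(rep(bounds[1], length(nm)), nm),
    upper = setNames(rep(bounds[2], length(nm)), nm),
    predict_fn = function(p) setNames(p * a[months], nm),
    targets = tv
  )
}

#' Production calibration problem over configuration fields
#'
#' Builds a [calibration_problem()] whose free parameters are arbitrary
#' scalar fields of a run configuration (addressed as `"section.key"`,
#' e.g. `"operation.dil"`, `"strain.chlc_m"`) and whose targets are
#' whole-run production statistics from [glance()] (`mean_vp`, `peak_vp`,
#' `mean_axp`, `peak_axp`). Each objective evaluation is one full
#' simulation of `base_config`.
#'
#' @param base_config A [pbr_config()] to perturb.
#' @param free Named list: `"section.key" = c(lower, upper)`.
#' @param targets Named numeric vector over glance statistics.
#' @return A `pbr_problem`.
#' @export
production_problem <- function(base_config, free, targets) {
  base_config <- as_pbr_config(base_config)
  paths <- strsplit(names(free), ".", fixed = TRUE)
  if (any(lengths(paths) != 2)) abort("free parameter names must be 'section.key'.")
  lo <- vapply(free, `[`, numeric(1), 1)
  hi <- vapply(free, `[`, numeric(1), 2)
  predict_fn <- function(p) {
    cfg <- unclass(base_config)
    for (j in seq_along(p)) {
      cfg[[paths[[j]][1]]][[paths[[j]][2]]] <- unname(p[j])
    }
    g <- glance(run_simulation(validate_config(cfg)))
    unlist(g[intersect(names(g), names(targets))])
  }
  calibration_problem(setNames(lo, names(free)), setNames(hi, names(free)),
                      predict_fn, targets)
}

#' @describeIn random_search `tidy()` returns one row per fitted parameter
#'   with its bounds.
#' @param x A `pbr_calibration`.
#' @param ... Unused.
#' @export
tidy.pbr_calibration <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @describeIn random_search `glance()` returns a one-row fit summary.
#' @export
glance.pbr_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_eval = x$n_eval, seed = x$seed,
                 n_par = length(x$par))
}

#' @describeIn random_search `autoplot()` shows the running-best objective
#'   trace on a log scale.
#' @param object A `pbr_calibration`.
#' @export
autoplot.pbr_calibration <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$iter, .data$best)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "evaluation", y = "best objective (relative SSE)") +
    ggplot2::theme_minimal()
}

#' @export
print.pbr_calibration <- function(x, ...) {
  cat("<pbr_calibration> ", x$n_eval, " evaluations, seed ", x$seed,
      ", objective ", signif(x$objective, 4), "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}
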