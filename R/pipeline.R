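#' Calibrated parameters of the reference injury strain field
#'
#' The depth-decaying maximum shear strain field that stands in for an
#' external injurious-compression solve: superficial strain saturates the
#' damage function and the deep plateau yields partial damage.  Values are
#' frozen by the shipped calibration run; the field is a calibrated
#' stand-in, not a published strain solution.
#'
#' @return List with \code{surface_peak}, \code{deep_plateau},
#'   \code{decay_depth}.
#' @export
reference_strain_parameters <- function() {
  list(surface_peak = 2.0, deep_plateau = 0.44, decay_depth = 0.27)
}

#' Assemble a reference run configuration
#'
#' Bundles every choice of a pipeline run: mode, domain resolution, strain
#' source, damage parameters, kinetic registry, horizon and solver step.
#' Control mode forces zero cell damage regardless of the strain source.
#'
#' @param mode \code{"injury"} or \code{"control"}.
#' @param width,thickness,nx,nz domain geometry (see
#'   \code{\link{build_domain}}).
#' @param lesion optional lesion polygon.
#' @param strain_source \code{"parametric"} (default),
#'   \code{"surrogate"}, or \code{"file"}.
#' @param strain for \code{"parametric"}: list with \code{surface_peak},
#'   \code{deep_plateau}, \code{decay_depth},
#'   \code{lateral_noise_sd}; for \code{"surrogate"}: list with
#'   \code{axial_stretch}, \code{mode}; for \code{"file"}: list with
#'   \code{path}.
#' @param k_INJ,eps_dmg_init,eps_dmg_max,C_cell_healthy damage-function
#'   parameters (see \code{\link{damage_parameters}}).
#' @param params a \code{kinetic_parameters} object.
#' @param horizon simulated duration (s, default 12 days).
#' @param dt macro time step (s).
#' @param seed integer seed for any stochastic strain option.
#' @param checkpoints optional checkpoint times (s).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(mode = c("injury", "control"),
                       width = 3e-3, thickness = 1e-3, nx = 61, nz = 21,
                       lesion = NULL,
                       strain_source = c("parametric", "surrogate", "file"),
                       strain = reference_strain_parameters(),
                       k_INJ = 0.35, eps_dmg_init = 0.4, eps_dmg_max = 1.5,
                       C_cell_healthy = 1e14,
                       params = kinetic_parameters(),
                       horizon = 12 * 86400, dt = 300, seed = 1L,
                       checkpoints = NULL) {
  mode <- match.arg(mode)
  strain_source <- match.arg(strain_source)
  structure(list(mode = mode, width = width, thickness = thickness,
                 nx = nx, nz = nz, lesion = lesion,
                 strain_source = strain_source, strain = strain,
                 k_INJ = k_INJ, eps_dmg_init = eps_dmg_init,
                 eps_dmg_max = eps_dmg_max,
                 C_cell_healthy = C_cell_healthy,
                 params = params, horizon = horizon, dt = dt,
                 seed = as.integer(seed), checkpoints = checkpoints),
            class = "run_config")
}

strain_field_from_config <- function(config, domain) {
  s <- config$strain
  switch(config$strain_source,
    parametric = parametric_strain_field(
      domain, s$surface_peak, s$deep_plateau, s$decay_depth,
      lateral_noise_sd = if (is.null(s$lateral_noise_sd)) 0
                         else s$lateral_noise_sd,
      seed = config$seed),
    surrogate = max_shear(homogeneous_strain_surrogate(
      domain, s$axial_stretch,
      mode = if (is.null(s$mode)) "incompressible-unconfined" else s$mode)),
    file = load_strain_field(s$path, domain))
}

#' Execute the full reference pipeline
#'
#' Runs mechanics (strain field) -> cell damage -> reaction-diffusion
#' simulation -> summary metrics for one configuration, and returns the
#' simulation result together with the bulk day-12 loss, the day-0 and
#' normalized day-12 depth profiles, and a provenance manifest (parameter
#' table with provenance tags, seed, mode, strain source).
#'
#' @param config a \code{run_config}.
#' @return List with \code{result} (a \code{simulation_result}),
#'   \code{metrics} (bulk loss and profiles) and \code{provenance}.
#' @export
run_reference <- function(config) {
  stopifnot(inherits(config, "run_config"))
  missing_par <- names(config$params)[!vapply(config$params, is.finite,
                                              logical(1))]
  if (length(missing_par))
    stop("configuration error: missing parameter(s): ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  domain <- build_domain(config$width, config$thickness, config$nx,
                         config$nz, config$lesion)
  dp <- damage_parameters(eps_dmg_init = config$eps_dmg_init,
                          eps_dmg_max = config$eps_dmg_max,
                          k_INJ = config$k_INJ,
                          C_cell_healthy = config$C_cell_healthy)
  damage <- NULL
  eps <- NULL
  if (config$mode == "injury") {
    eps <- strain_field_from_config(config, domain)
    damage <- damage_field(eps, dp)
  }
  res <- simulate_explant(domain, damage, config$params,
                          horizon = config$horizon,
                          checkpoints = config$checkpoints, dt = config$dt)
  day0 <- depth_profile(res, 0)
  day12 <- depth_profile(res, config$horizon, normalize_to = day0)
  metrics <- list(
    bulk_loss_pct = bulk_percent_change(res, 0, config$horizon),
    day0_profile = day0,
    day12_profile = day12
  )
  prov <- list(parameters = as.data.frame(config$params),
               mode = config$mode, seed = config$seed,
               strain_source = if (config$mode == "injury")
                 config$strain_source else "none (control)",
               strain = config$strain,
               k_INJ = config$k_INJ, eps_dmg_max = config$eps_dmg_max)
  defaults <- prov$parameters$name[prov$parameters$provenance == "default"]
  if (length(defaults))
    message("note: default-provenance parameters in use: ",
            paste(defaults, collapse = ", "))
  list(result = res, metrics = metrics, provenance = prov)
}

#' Deterministic calibration of free parameters
#'
#' Minimizes the squared mismatch between simulated and target summary
#' quantities (bulk day-12 loss and, optionally, the normalized day-12
#' depth profile) over a named set of free parameters using
#' derivative-free Nelder-Mead search in log-parameter space (golden
#' section for a single parameter).  Parameters tagged \code{"paper"} in
#' the registry are locked and refuse calibration.  The search is
#' deterministic: fixed start, fixed iteration budget.
#'
#' @param targets list with any of \code{bulk_loss_pct} (numeric) and
#'   \code{day12_profile} (a \code{depth_profile} in percent-of-day-0
#'   units).
#' @param free character vector of free parameter names (kinetic registry
#'   entries or \code{"k_INJ"} / \code{"eps_dmg_max"}).
#' @param config base \code{run_config}; free parameters start from their
#'   values here.
#' @param maxit iteration budget of the optimizer.
#' @param residual_tol calibration fails (no frozen registry returned)
#'   when the achieved root-mean-square residual exceeds this.
#' @return List with the calibrated \code{config}, the frozen
#'   \code{params} registry, the achieved \code{residual} and the
#'   optimizer trace; or, on failure, an object of class
#'   \code{calibration_failure}.
#' @export
calibrate <- function(targets, free, config, maxit = 60,
                      residual_tol = Inf) {
  stopifnot(inherits(config, "run_config"))
  if (length(free) == 0) {
    return(list(config = config, params = config$params, residual = NA_real_,
                evaluations = 0))
  }
  prov <- attr(config$params, "provenance")
  locked <- free[free %in% names(prov)][
    prov[free[free %in% names(prov)]] == "paper"]
  if (length(locked))
    stop("configuration error: parameter(s) tagged 'paper' are locked: ",
         paste(locked, collapse = ", "), call. = FALSE)

  start <- vapply(free, function(p) reference_value_of(config, p),
                  numeric(1))
  if (any(start <= 0))
    stop("configuration error: free parameters must start positive for ",
         "log-space search", call. = FALSE)
  n_eval <- 0
  objective <- function(logv) {
    cfg <- config
    for (i in seq_along(free))
      cfg <- override_parameter(cfg, free[i], exp(logv[i]))
    out <- tryCatch(run_reference(cfg), error = function(e) NULL)
    n_eval <<- n_eval + 1
    if (is.null(out)) return(1e6)
    err <- 0
    nres <- 0
    if (!is.null(targets$bulk_loss_pct)) {
      err <- err + (out$metrics$bulk_loss_pct - targets$bulk_loss_pct)^2
      nres <- nres + 1
    }
    if (!is.null(targets$day12_profile)) {
      ref <- targets$day12_profile
      m <- stats::approx(out$metrics$day12_profile$depth,
                         out$metrics$day12_profile$value,
                         xout = ref$depth, rule = 2)$y
      err <- err + sum((m - ref$value)^2)
      nres <- nres + nrow(ref)
    }
    err / max(nres, 1)
  }

  if (length(free) == 1) {
    opt <- stats::optimize(objective,
                           interval = log(start) + c(-3, 3), tol = 1e-8)
    best <- opt$minimum; val <- opt$objective
  } else {
    opt <- stats::optim(log(start), objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    best <- opt$par; val <- opt$value
  }
  residual <- sqrt(val)
  cfg <- config
  for (i in seq_along(free))
    cfg <- override_parameter(cfg, free[i], exp(best[i]))
  if (residual > residual_tol) {
    return(structure(list(residual = residual, free = free,
                          values = exp(best), evaluations = n_eval),
                     class = "calibration_failure"))
  }
  list(config = cfg, params = cfg$params, residual = residual,
       values = stats::setNames(exp(best), free), evaluations = n_eval)
}
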