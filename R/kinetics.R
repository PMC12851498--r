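#' @name kinetics
#' @title Species and reaction kinetics of the degradation network
#' @description
#' The biochemical state carries six diffusible/immobile species --- intact
#' collagen (\code{col}), degraded collagen (\code{cold}), intact aggrecan
#' (\code{agg}), degraded aggrecan (\code{aggd}), MMP (\code{mmp}) and
#' aggrecanase (\code{aga}) --- plus two stimulus variables (\code{S_mmp},
#' \code{S_aga}) that delay protease release after cell damage.  All
#' concentrations are in mol m^-3 and time is in seconds (12 days =
#' 1,036,800 s).
NULL

#' Species ordering used throughout the solver
#' @export
SPECIES <- c("col", "cold", "agg", "aggd", "mmp", "aga", "S_mmp", "S_aga")

# FTIR absorption-unit to molar scaling for collagen: the depth-mean of the
# initial collagen polynomial divided by this factor equals 0.2 mol m^-3.
COLLAGEN_MOLAR_SCALE <- 46.2276

# FCD (mEq ml^-1) to aggrecan molarity: 502.5 / (2 * 2.5 * 1000).
FCD_TO_AGGRECAN <- 502.5 / (2 * 2.5 * 1000)

#' Depth polynomials for initial composition
#'
#' Degree-6 polynomials in normalized depth z (0 = articular surface,
#' 1 = bottom) describing the initial depth-wise collagen content (FTIR
#' absorption units) and fixed charge density (mEq ml^-1) of young bovine
#' cartilage explants.
#'
#' @return List with coefficient vectors \code{col} and \code{fcd}
#'   (constant term first) and evaluator functions \code{c_col0(z)},
#'   \code{c_fcd0(z)}.
#' @export
depth_polynomials <- function() {
  col <- c(8.782, -47.9, 247.8, -363.4, 22.9, 328.6, -187.1)
  fcd <- c(0.03, 1.1, -5.8, 14.9, -21.0, 15.2, -4.4)
  evalp <- function(coef) {
    force(coef)
    function(z) {
      if (any(z < -1e-12 | z > 1 + 1e-12))
        stop("input error: depth polynomial evaluated outside [0, 1]",
             call. = FALSE)
      out <- 0
      for (k in rev(seq_along(coef))) out <- out * z + coef[k]
      out
    }
  }
  list(col = col, fcd = fcd, c_col0 = evalp(col), c_fcd0 = evalp(fcd))
}

#' Initial collagen concentration field
#'
#' Scales the depth-wise collagen polynomial (absorption units) to molarity
#' so that the depth mean is 0.2 mol m^-3; the field is laterally
#' homogeneous.
#'
#' @param domain a \code{cart_domain}.
#' @param polys output of \code{\link{depth_polynomials}}.
#' @return Per-node collagen concentration (mol m^-3).
#' @export
initial_collagen <- function(domain, polys = depth_polynomials()) {
  stopifnot(inherits(domain, "cart_domain"))
  c0 <- polys$c_col0(domain$depth) / COLLAGEN_MOLAR_SCALE
  c0[domain$lesion_mask] <- 0
  c0
}

#' Initial aggrecan concentration field
#'
#' Converts the depth-wise fixed charge density (mEq ml^-1) to aggrecan
#' molarity with the factor 502.5 / (2 x 2.5 x 1000) = 0.1005 per
#' mEq ml^-1.  Negative polynomial values (possible near the surface for
#' perturbed coefficients) are clamped to zero with a warning.
#'
#' @inheritParams initial_collagen
#' @return Per-node aggrecan concentration (mol m^-3).
#' @export
initial_aggrecan <- function(domain, polys = depth_polynomials()) {
  stopifnot(inherits(domain, "cart_domain"))
  fcd <- polys$c_fcd0(domain$depth)
  if (any(fcd < 0)) {
    warning("negative fixed charge density clamped to 0")
    fcd <- pmax(fcd, 0)
  }
  agg <- fcd * FCD_TO_AGGRECAN
  agg[domain$lesion_mask] <- 0
  agg
}

#' Kinetic parameter registry
#'
#' Every rate, threshold and transport constant of the degradation network,
#' with units and a provenance tag (\code{"paper"} for values fixed from
#' the source experiments/reference kinetics, \code{"default"} for
#' literature-lineage defaults, \code{"calibrated"} for values frozen by
#' the shipped calibration run).  Any value can be overridden by name.
#'
#' @param ... named numeric overrides, e.g. \code{k_INJ_rate = ...}.
#' @param hill_direction direction of the aggrecan Hill modulation of MMP
#'   activity: \code{"increasing"} (default; the factor grows with total
#'   aggrecan) or \code{"decreasing"} (reciprocal protection variant).
#' @return Object of class \code{kinetic_parameters}: a named numeric list
#'   with \code{units} and \code{provenance} attributes.
#' @export
kinetic_parameters <- function(..., hill_direction = c("increasing",
                                                       "decreasing")) {
  hill_direction <- match.arg(hill_direction)
  def <- list(
    #           value        units              provenance
    D_mmp   = c(1e-14,       "m2 s-1",          "calibrated"),
    D_aga   = c(1e-14,       "m2 s-1",          "default"),
    D_agg   = c(1e-13,       "m2 s-1",          "default"),
    D_aggd  = c(1e-12,       "m2 s-1",          "default"),
    D_cold  = c(1e-12,       "m2 s-1",          "default"),
    alpha_mmp = c(3e-6,      "s-1",             "calibrated"),
    alpha_aga = c(3e-6,      "s-1",             "default"),
    k_mmp   = c(0.35e-21,    "mol",             "paper"),
    k_aga   = c(0.35e-21,    "mol",             "default"),
    k_rate_mmp = c(3.6e-5,   "s-1",             "paper"),
    k_rate_aga = c(3.6e-5,   "s-1",             "default"),
    k_mmp_cold = c(2e-4,     "m3 mol-1 s-1",    "calibrated"),
    n_R_cold = c(10,         "1",               "default"),
    k_mmp_catalytic = c(1.5, "s-1",             "paper"),
    K_m_mmp = c(0.15,        "mol m-3",         "calibrated"),
    k_basal = c(2.032433e-7, "s-1",             "calibrated"),
    k_act   = c(3e-5,        "mol m-3",         "paper"),
    n_hill  = c(2,           "1",               "default"),
    k_aga_catalytic = c(1.5, "s-1",             "default"),
    K_m_aga = c(0.15,        "mol m-3",         "default"),
    h_agg   = c(1e-9,        "m s-1",           "default"),
    h_aggd  = c(1e-8,        "m s-1",           "default"),
    h_mmp   = c(1e-11,       "m s-1",           "calibrated")
  )
  vals <- lapply(def, function(v) as.numeric(v[1]))
  units <- vapply(def, function(v) v[2], character(1))
  prov <- vapply(def, function(v) v[3], character(1))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(vals))
    if (length(bad))
      stop("configuration error: unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(over)) {
      vals[[nm]] <- as.numeric(over[[nm]])
      prov[[nm]] <- "calibrated"
    }
  }
  if (any(unlist(vals) < 0))
    stop("configuration error: kinetic parameters must be non-negative",
         call. = FALSE)
  for (nm in c("K_m_mmp", "K_m_aga", "k_act", "n_hill"))
    if (vals[[nm]] <= 0)
      stop(sprintf("configuration error: %s must be positive", nm),
           call. = FALSE)
  structure(vals, units = units, provenance = prov,
            hill_direction = hill_direction, class = "kinetic_parameters")
}

#' Override one registry entry
#'
#' @param params a \code{kinetic_parameters} object.
#' @param name parameter name.
#' @param value new numeric value (provenance becomes \code{"calibrated"}).
#' @return Modified \code{kinetic_parameters}.
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (!name %in% names(params))
    stop("configuration error: unknown parameter ", name, call. = FALSE)
  params[[name]] <- as.numeric(value)
  prov <- attr(params, "provenance")
  prov[[name]] <- "calibrated"
  attr(params, "provenance") <- prov
  params
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.kinetic_parameters <- function(x, ...) {
  data.frame(name = names(x), value = unlist(x, use.names = FALSE),
             units = unname(attr(x, "units")),
             provenance = unname(attr(x, "provenance")),
             stringsAsFactors = FALSE)
}

#' Read / write the parameter registry as flat CSV
#'
#' The registry round-trips through a four-column CSV
#' (\code{name, value, units, provenance}).
#'
#' @param path CSV path.
#' @param params a \code{kinetic_parameters} object (for writing).
#' @return \code{read_parameter_registry} returns a
#'   \code{kinetic_parameters} object.
#' @export
read_parameter_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "value")
  if (!all(need %in% names(df)))
    stop("format error: registry CSV needs 'name' and 'value' columns",
         call. = FALSE)
  args <- as.list(df$value)
  names(args) <- df$name
  p <- do.call(kinetic_parameters, args)
  if ("provenance" %in% names(df)) {
    prov <- attr(p, "provenance")
    prov[df$name] <- df$provenance
    attr(p, "provenance") <- prov
  }
  p
}

#' @rdname read_parameter_registry
#' @export
write_parameter_registry <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

# ---- reaction terms (pure, vectorized over nodes) -------------------------

#' First-order delayed stimulus rate
#'
#' \code{dS/dt = alpha * (k * C_cell_damaged - S)}.  With constant forcing
#' from damaged cells the stimulus relaxes exponentially toward
#' \code{k * C_cell_damaged} with time constant \code{1 / alpha},
#' producing the delayed onset of protease release.
#'
#' @param S current stimulus (mol m^-3).
#' @param C_cell_damaged damaged-cell concentration (cells m^-3).
#' @param alpha rate constant (s^-1).
#' @param k protease amount released per damaged cell (mol).
#' @return dS/dt (mol m^-3 s^-1).
#' @export
stimulus_rate <- function(S, C_cell_damaged, alpha, k) {
  alpha * (k * C_cell_damaged - S)
}

#' Reaction part of the MMP balance
#'
#' Production from the stimulus minus consumption by binding to degraded
#' collagen: \code{k_rate_mmp * S_mmp - k_mmp_cold * C_mmp * C_cold *
#' n_R_cold}.  The binding-site count \code{n_R_cold} enters as a linear
#' multiplier.
#'
#' @param S_mmp,C_mmp,C_cold per-node concentrations (mol m^-3).
#' @param params a \code{kinetic_parameters} object.
#' @return Reaction rate of MMP (mol m^-3 s^-1).
#' @export
mmp_rate <- function(S_mmp, C_mmp, C_cold, params) {
  params$k_rate_mmp * S_mmp -
    params$k_mmp_cold * C_mmp * C_cold * params$n_R_cold
}

#' Hill-type aggrecan modulation of MMP activity
#'
#' \code{f = 1 / (1 + (x / k_act)^(-n))} with \code{x = C_agg + C_aggd}
#' (direction \code{"increasing"}: the factor is 1/2 at \code{x = k_act},
#' tends to 1 at high total aggrecan and to 0 at zero).  The
#' \code{"decreasing"} variant uses the reciprocal Hill form
#' \code{1 / (1 + (x / k_act)^n)} in which aggrecan shields collagen.
#'
#' @param C_agg,C_aggd intact and degraded aggrecan (mol m^-3).
#' @param k_act total-aggrecan concentration at half-maximal activity.
#' @param n_hill Hill coefficient (> 0).
#' @param direction \code{"increasing"} (default) or \code{"decreasing"}.
#' @return Modulation factor in [0, 1].
#' @export
agg_protection <- function(C_agg, C_aggd, k_act = 3e-5, n_hill = 2,
                           direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is.finite(k_act) || k_act <= 0)
    stop("configuration error: k_act must be positive", call. = FALSE)
  x <- C_agg + C_aggd
  if (any(x < 0)) stop("input error: negative aggrecan", call. = FALSE)
  r <- (x / k_act)^n_hill
  if (direction == "increasing") r / (1 + r) else 1 / (1 + r)
}

#' Reaction part of the intact collagen balance
#'
#' Michaelis-Menten cleavage by MMP, modulated by the aggrecan Hill factor,
#' plus first-order basal loss:
#' \code{-f_protect * k_mmp_catalytic * C_mmp * C_col / (C_col + K_m_mmp)
#' - k_basal * C_col}.  Always non-positive; with no MMP this reduces to
#' the basal decay of the free-swelling control.
#'
#' @param C_col,C_mmp per-node concentrations (mol m^-3).
#' @param f_protect aggrecan modulation factor in [0, 1].
#' @param params a \code{kinetic_parameters} object.
#' @return Reaction rate of intact collagen (mol m^-3 s^-1).
#' @export
collagen_rate <- function(C_col, C_mmp, f_protect, params) {
  -f_protect * params$k_mmp_catalytic * C_mmp *
    C_col / (C_col + params$K_m_mmp) - params$k_basal * C_col
}

#' Reaction part of the degraded collagen balance
#'
#' Gains what the enzymatic term removes from intact collagen and is
#' consumed by MMP binding; basal loss is not routed here (it reflects
#' culture conditions, not enzymatic cleavage), so in a closed system with
#' basal loss and binding off \code{C_col + C_cold} is conserved.
#'
#' @inheritParams collagen_rate
#' @param C_cold degraded collagen (mol m^-3).
#' @return Reaction rate of degraded collagen (mol m^-3 s^-1).
#' @export
degraded_collagen_rate <- function(C_col, C_cold, C_mmp, f_protect, params) {
  f_protect * params$k_mmp_catalytic * C_mmp *
    C_col / (C_col + params$K_m_mmp) -
    params$k_mmp_cold * C_mmp * C_cold * params$n_R_cold
}

#' Reaction rates of the aggrecanase / aggrecan subsystem
#'
#' Aggrecanase is produced from its stimulus
#' (\code{k_rate_aga * S_aga}); intact aggrecan is cleaved with
#' Michaelis-Menten kinetics
#' (\code{k_aga_catalytic * C_aga * C_agg / (C_agg + K_m_aga)}) and the
#' degraded pool gains exactly what the intact pool loses, so
#' \code{C_agg + C_aggd} is conserved under reactions alone.
#'
#' @param C_aga,C_agg,C_aggd,S_aga per-node concentrations (mol m^-3).
#' @param params a \code{kinetic_parameters} object.
#' @return List with components \code{d_aga}, \code{d_agg}, \code{d_aggd}.
#' @export
aggrecan_system_rates <- function(C_aga, C_agg, C_aggd, S_aga, params) {
  cleave <- params$k_aga_catalytic * C_aga * C_agg / (C_agg + params$K_m_aga)
  list(d_aga = params$k_rate_aga * S_aga,
       d_agg = -cleave,
       d_aggd = cleave)
}

#' All reaction rates for the coupled state
#'
#' Evaluates every reaction term of the network at once.  Diffusion is
#' handled separately by the solver; lesion nodes are expected to be zeroed
#' by the caller.
#'
#' @param state named list (or environment) of per-node vectors for every
#'   entry of \code{\link{SPECIES}}.
#' @param C_cell_damaged per-node damaged-cell concentration (cells m^-3).
#' @param params a \code{kinetic_parameters} object.
#' @return Named list of per-node derivative vectors, one per species.
#' @export
reaction_rates <- function(state, C_cell_damaged, params) {
  # rates are defined on the non-negative orthant; trial states from an
  # adaptive integrator may dip below zero and are projected back, which
  # keeps sink terms from turning into spurious sources
  state <- lapply(state, function(v) pmax(v, 0))
  fp <- agg_protection(state$agg, state$aggd, params$k_act, params$n_hill,
                       direction = attr(params, "hill_direction"))
  agg_sys <- aggrecan_system_rates(state$aga, state$agg, state$aggd,
                                   state$S_aga, params)
  list(
    col = collagen_rate(state$col, state$mmp, fp, params),
    cold = degraded_collagen_rate(state$col, state$cold, state$mmp, fp,
                                  params),
    agg = agg_sys$d_agg,
    aggd = agg_sys$d_aggd,
    mmp = mmp_rate(state$S_mmp, state$mmp, state$cold, params),
    aga = agg_sys$d_aga,
    S_mmp = stimulus_rate(state$S_mmp, C_cell_damaged, params$alpha_mmp,
                          params$k_mmp),
    S_aga = stimulus_rate(state$S_aga, C_cell_damaged, params$alpha_aga,
                          params$k_aga)
  )
}

# ---- dimensional audit ----------------------------------------------------

# parse "m3 mol-1 s-1" style unit strings into exponent vectors
unit_dim <- function(u) {
  dims <- c(m = 0, s = 0, mol = 0)
  u <- trimws(u)
  if (u == "1" || u == "") return(dims)
  for (tok in strsplit(u, "\\s+")[[1]]) {
    m <- regmatches(tok, regexec("^([A-Za-z]+)(-?[0-9]+)?$", tok))[[1]]
    if (length(m) == 0)
      stop("format error: cannot parse unit token '", tok, "'", call. = FALSE)
    base <- m[2]
    expo <- if (m[3] == "") 1L else as.integer(m[3])
    if (!base %in% names(dims))
      stop("format error: unknown unit base '", base, "'", call. = FALSE)
    dims[base] <- dims[base] + expo
  }
  dims
}

#' Dimensional audit of every reaction term
#'
#' Checks symbolically, from the units recorded in the registry, that each
#' term of each rate expression reduces to mol m^-3 s^-1 (and each boundary
#' flux to mol m^-2 s^-1).  Concentrations contribute mol m^-3, the
#' damaged-cell density m^-3, and the Laplacian of a concentration
#' mol m^-5.
#'
#' @param params a \code{kinetic_parameters} object.
#' @return \code{TRUE} invisibly; stops with the offending term otherwise.
#' @export
audit_units <- function(params = kinetic_parameters()) {
  u <- attr(params, "units")
  conc <- c(m = -3, s = 0, mol = 1)
  cell <- c(m = -3, s = 0, mol = 0)
  lap <- c(m = -5, s = 0, mol = 1)
  rate <- c(m = -3, s = -1, mol = 1)
  flux <- c(m = -2, s = -1, mol = 1)
  terms <- list(
    stimulus_production = list(u["alpha_mmp"], u["k_mmp"], list(cell)),
    stimulus_relaxation = list(u["alpha_mmp"], list(conc)),
    mmp_production = list(u["k_rate_mmp"], list(conc)),
    mmp_binding = list(u["k_mmp_cold"], list(conc), list(conc),
                       u["n_R_cold"]),
    collagen_cleavage = list(u["k_mmp_catalytic"], list(conc)),
    collagen_basal = list(u["k_basal"], list(conc)),
    aggrecan_cleavage = list(u["k_aga_catalytic"], list(conc)),
    aggrecanase_production = list(u["k_rate_aga"], list(conc))
  )
  diffusion <- list(
    mmp_diffusion = list(u["D_mmp"], list(lap)),
    aga_diffusion = list(u["D_aga"], list(lap)),
    agg_diffusion = list(u["D_agg"], list(lap)),
    aggd_diffusion = list(u["D_aggd"], list(lap)),
    cold_diffusion = list(u["D_cold"], list(lap))
  )
  fluxes <- list(
    robin_agg = list(u["h_agg"], list(conc)),
    robin_aggd = list(u["h_aggd"], list(conc)),
    robin_mmp = list(u["h_mmp"], list(conc))
  )
  # Michaelis ratios and the Hill factor are dimensionless by construction:
  # check their ingredients share the concentration dimension.
  for (nm in c("K_m_mmp", "K_m_aga", "k_act"))
    if (!identical(unit_dim(u[[nm]]), conc))
      stop("unit audit failed: ", nm, " is not a concentration",
           call. = FALSE)
  dim_of <- function(factors) {
    total <- c(m = 0, s = 0, mol = 0)
    for (f in factors) {
      total <- total + if (is.list(f)) f[[1]] else unit_dim(f)
    }
    total
  }
  for (nm in names(terms))
    if (!identical(dim_of(terms[[nm]]), rate))
      stop("unit audit failed: term '", nm,
           "' does not reduce to mol m-3 s-1", call. = FALSE)
  for (nm in names(diffusion))
    if (!identical(dim_of(diffusion[[nm]]), rate))
      stop("unit audit failed: term '", nm,
           "' does not reduce to mol m-3 s-1", call. = FALSE)
  for (nm in names(fluxes))
    if (!identical(dim_of(fluxes[[nm]]), flux))
      stop("unit audit failed: flux '", nm,
           "' does not reduce to mol m-2 s-1", call. = FALSE)
  invisible(TRUE)
}
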