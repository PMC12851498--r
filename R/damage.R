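#' Parameters of the strain-threshold cell-damage function
#'
#' Cells begin to be damaged once the maximum shear strain exceeds
#' \code{eps_dmg_init} (reference 0.4, i.e. 40 %) and the damaged fraction
#' saturates at \code{eps_dmg_max} (reference 1.5).  \code{k_INJ} caps the
#' maximum fraction of healthy cells that can turn damaged (reference
#' 0.35), and \code{C_cell_healthy} is the spatially homogeneous healthy
#' chondrocyte density (cells per cubic metre).
#'
#' @param eps_dmg_init strain threshold where damage starts (dimensionless).
#' @param eps_dmg_max strain at which the damaged fraction saturates.
#' @param k_INJ maximum damaged fraction in [0, 1].
#' @param C_cell_healthy healthy cell density (cells m^-3).
#' @param branch intermediate branch of the damage function:
#'   \code{"concave"} (default) uses
#'   \code{(eps_max / eps) * (eps - eps_init) / (eps_max - eps_init)};
#'   \code{"convex"} uses \code{(eps / eps_max) * ...} normalised to reach
#'   1 at \code{eps_dmg_max}.  Both are continuous at the two thresholds.
#' @return An object of class \code{damage_parameters}.
#' @export
damage_parameters <- function(eps_dmg_init = 0.4, eps_dmg_max = 1.5,
                              k_INJ = 0.35, C_cell_healthy = 1e14,
                              branch = c("concave", "convex")) {
  branch <- match.arg(branch)
  if (!(eps_dmg_init > 0 && eps_dmg_init < eps_dmg_max))
    stop("configuration error: need 0 < eps_dmg_init < eps_dmg_max",
         call. = FALSE)
  if (k_INJ < 0 || k_INJ > 1)
    stop("configuration error: k_INJ must lie in [0, 1]", call. = FALSE)
  if (C_cell_healthy <= 0)
    stop("configuration error: C_cell_healthy must be positive",
         call. = FALSE)
  structure(list(eps_dmg_init = eps_dmg_init, eps_dmg_max = eps_dmg_max,
                 k_INJ = k_INJ, C_cell_healthy = C_cell_healthy,
                 branch = branch),
            class = "damage_parameters")
}

#' Fraction of damaged cells as a function of maximum shear strain
#'
#' Stepwise nonlinear damage function: 0 below \code{eps_dmg_init}, 1 at or
#' above \code{eps_dmg_max}, and a continuous increasing branch in between
#' (concave by default).
#'
#' @param eps per-node maximum shear strain (>= 0).
#' @param params a \code{damage_parameters} object.
#' @return Per-node damaged fraction in [0, 1].
#' @export
damage_fraction <- function(eps, params = damage_parameters()) {
  stopifnot(inherits(params, "damage_parameters"))
  if (any(!is.finite(eps)) || any(eps < 0))
    stop("input error: maximum shear strain must be finite and >= 0",
         call. = FALSE)
  e0 <- params$eps_dmg_init
  e1 <- params$eps_dmg_max
  f <- numeric(length(eps))
  mid <- eps > e0 & eps < e1
  if (params$branch == "concave") {
    f[mid] <- (e1 / eps[mid]) * (eps[mid] - e0) / (e1 - e0)
  } else {
    # convex alternative; also 0 at e0 and 1 at e1
    f[mid] <- (eps[mid] / e1) * (eps[mid] - e0) / (e1 - e0)
  }
  f[eps >= e1] <- 1
  pmin(pmax(f, 0), 1)
}

#' Damaged-cell concentration
#'
#' \code{C_cell_damaged = k_INJ * f_dmg * C_cell_healthy}; the attainable
#' maximum is \code{k_INJ * C_cell_healthy} (35 % of healthy cells at the
#' reference \code{k_INJ}).
#'
#' @param f_dmg per-node damaged fraction in [0, 1].
#' @param params a \code{damage_parameters} object.
#' @return Per-node damaged-cell concentration (cells m^-3).
#' @export
damaged_cell_concentration <- function(f_dmg, params = damage_parameters()) {
  stopifnot(inherits(params, "damage_parameters"))
  if (any(f_dmg < 0 | f_dmg > 1))
    stop("input error: f_dmg must lie in [0, 1]", call. = FALSE)
  params$k_INJ * f_dmg * params$C_cell_healthy
}

#' Full damage field from a strain field
#'
#' Convenience wrapper mapping a maximum shear strain field to the damaged
#' fraction and damaged-cell concentration in one step.  The damage field
#' is computed once from the peak-compression strain snapshot and held
#' constant over the simulated culture period.
#'
#' @param eps per-node maximum shear strain.
#' @param params a \code{damage_parameters} object.
#' @return List with components \code{f_dmg} and \code{C_cell_damaged}.
#' @export
damage_field <- function(eps, params = damage_parameters()) {
  f <- damage_fraction(eps, params)
  list(f_dmg = f, C_cell_damaged = damaged_cell_concentration(f, params))
}
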