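#' Default boundary conditions for the explant culture
#'
#' Encodes the culture-bath exchange of the explant: zero flux across the
#' bottom surface for every species; Robin (mass-transfer) conditions for
#' intact aggrecan, degraded aggrecan and MMP through the top and lateral
#' surfaces with bath concentration 0; Dirichlet zero-concentration
#' conditions for degraded collagen and aggrecanase on the same surfaces.
#' Lesion faces inherit the top-surface condition per species, so the
#' lesion void communicates with the bath.  Intact collagen and the two
#' stimulus variables do not diffuse.
#'
#' @param params a \code{kinetic_parameters} object supplying the Robin
#'   mass-transfer coefficients \code{h_agg}, \code{h_aggd}, \code{h_mmp}.
#' @return Named list (per species) of per-face-label conditions, each a
#'   list with \code{type} in \code{"zero-flux"}, \code{"robin"},
#'   \code{"dirichlet"} and, for Robin, the coefficient \code{h} (m s^-1).
#' @export
boundary_conditions <- function(params = kinetic_parameters()) {
  zf <- list(type = "zero-flux")
  dir0 <- list(type = "dirichlet")
  robin <- function(h) list(type = "robin", h = h)
  faces <- function(top, bottom, lateral, lesion = top)
    list(top = top, bottom = bottom, lateral = lateral, lesion = lesion)
  list(
    col  = faces(zf, zf, zf),
    cold = faces(dir0, zf, dir0),
    agg  = faces(robin(params$h_agg), zf, robin(params$h_agg)),
    aggd = faces(robin(params$h_aggd), zf, robin(params$h_aggd)),
    mmp  = faces(robin(params$h_mmp), zf, robin(params$h_mmp)),
    aga  = faces(dir0, zf, dir0),
    S_mmp = faces(zf, zf, zf),
    S_aga = faces(zf, zf, zf)
  )
}

#' Sparse diffusion operator with mixed boundary conditions
#'
#' Builds the finite-volume 5-point Laplacian \code{L} on the structured
#' grid such that the diffusive contribution to \code{dC/dt} is
#' \code{L %*% C}.  Zero-flux faces drop out of the flux balance, Robin
#' faces add a surface sink \code{-h C / w} (w the half- or full-cell
#' width), and Dirichlet faces pin boundary nodes at zero concentration
#' (their rows are cleared and the nodes are reported for clamping).
#' Faces exposed by the lesion mask apply the \code{lesion} condition with
#' a ghost value at the half-cell face.
#'
#' @param domain a \code{cart_domain}.
#' @param D diffusivity (m^2 s^-1, >= 0).
#' @param bc per-face-label condition list for one species, as one element
#'   of \code{\link{boundary_conditions}}.
#' @return List with the sparse operator \code{L} (dgCMatrix) and the
#'   integer vector \code{dirichlet} of pinned node indices.
#' @export
diffusion_operator <- function(domain, D, bc) {
  stopifnot(inherits(domain, "cart_domain"))
  if (D < 0) stop("configuration error: negative diffusivity", call. = FALSE)
  need <- c("top", "bottom", "lateral", "lesion")
  if (!all(need %in% names(bc)))
    stop("configuration error: unlabeled face in boundary condition set",
         call. = FALSE)
  nx <- domain$nx; nz <- domain$nz; n <- domain$n_nodes
  dx <- domain$dx; dz <- domain$dz
  live <- !domain$lesion_mask
  wx <- rep(domain$dx, nx); wx[c(1, nx)] <- dx / 2
  wz <- rep(domain$dz, nz); wz[c(1, nz)] <- dz / 2
  node_wx <- rep(wx, each = nz)
  node_wz <- rep(wz, times = nx)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  # interior faces along x: node i=(ix,iz), j=(ix+1,iz)
  iz_all <- rep(seq_len(nz), times = nx - 1)
  ix_all <- rep(seq_len(nx - 1), each = nz)
  i <- (ix_all - 1L) * nz + iz_all
  j <- i + nz
  ok <- live[i] & live[j]
  ci <- D / (dx * node_wx[i[ok]])
  cj <- D / (dx * node_wx[j[ok]])
  add(i[ok], j[ok], ci); add(i[ok], i[ok], -ci)
  add(j[ok], i[ok], cj); add(j[ok], j[ok], -cj)

  # interior faces along z: node i=(ix,iz), j=(ix,iz+1)
  iz_all <- rep(seq_len(nz - 1), times = nx)
  ix_all <- rep(seq_len(nx), each = nz - 1)
  i <- (ix_all - 1L) * nz + iz_all
  j <- i + 1L
  ok <- live[i] & live[j]
  ci <- D / (dz * node_wz[i[ok]])
  cj <- D / (dz * node_wz[j[ok]])
  add(i[ok], j[ok], ci); add(i[ok], i[ok], -ci)
  add(j[ok], i[ok], cj); add(j[ok], j[ok], -cj)

  dirichlet <- integer(0)
  fc <- domain$faces
  for (r in seq_len(nrow(fc))) {
    k <- fc$node[r]
    if (!live[k]) next
    cond <- bc[[fc$label[r]]]
    along_x <- fc$side[r] %in% c("left", "right")
    w <- if (along_x) node_wx[k] else node_wz[k]
    h_cell <- if (along_x) dx else dz
    outer_face <- !(fc$label[r] == "lesion")
    if (cond$type == "zero-flux") {
      # no flux: nothing to add
    } else if (cond$type == "robin") {
      add(k, k, -cond$h / w)
    } else if (cond$type == "dirichlet") {
      if (outer_face) {
        dirichlet <- c(dirichlet, k)
      } else {
        # ghost value 0 at the half-cell lesion face
        add(k, k, -2 * D / (h_cell * w))
      }
    } else {
      stop("configuration error: unknown boundary condition type '",
           cond$type, "'", call. = FALSE)
    }
  }

  L <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  dirichlet <- sort(unique(dirichlet))
  if (length(dirichlet)) L[dirichlet, ] <- 0
  list(L = L, dirichlet = dirichlet)
}

split_state <- function(y, n) {
  st <- vector("list", length(SPECIES))
  names(st) <- SPECIES
  for (s in seq_along(SPECIES)) st[[s]] <- y[((s - 1) * n + 1):(s * n)]
  st
}

#' Integrate the coupled reaction-diffusion system
#'
#' Advances the six species and two stimulus variables from the standard
#' initial state (depth-wise collagen and aggrecan, everything else zero)
#' over the culture horizon using Strang operator splitting: an implicit
#' (backward Euler) half-step of diffusion per diffusible species, an
#' adaptive explicit reaction step over all nodes at once
#' (\code{deSolve}, Dormand-Prince 4(5)), and a second diffusion
#' half-step.  The implicit diffusion solve preserves non-negativity;
#' reaction overshoot below zero is clipped with the clipped mass logged
#' and bounded.
#'
#' @param domain a \code{cart_domain}.
#' @param damage damage field as returned by \code{\link{damage_field}}
#'   (a list with \code{C_cell_damaged}), or \code{NULL} for the
#'   free-swelling control (no damaged cells).
#' @param params a \code{kinetic_parameters} object.
#' @param bcs boundary condition set, see
#'   \code{\link{boundary_conditions}}.
#' @param horizon simulated duration in seconds (default 12 days).
#' @param checkpoints times (s) at which to store the state; snapped to
#'   the macro-step grid.  Defaults to daily checkpoints plus the horizon.
#' @param dt macro time step in seconds (default 300).
#' @param rtol,atol relative/absolute tolerance of the reaction
#'   integrator.
#' @param max_clip_frac hard error threshold on cumulative clipped
#'   negative mass, relative to the largest total mass seen per species.
#' @return Object of class \code{simulation_result}: \code{times},
#'   \code{states} (list of per-species vectors per checkpoint),
#'   \code{domain}, \code{params}, and \code{diagnostics}.
#' @export
simulate_explant <- function(domain, damage = NULL,
                             params = kinetic_parameters(),
                             bcs = boundary_conditions(params),
                             horizon = 12 * 86400, checkpoints = NULL,
                             dt = 300, rtol = 1e-6, atol = 1e-15,
                             max_clip_frac = 1e-9) {
  stopifnot(inherits(domain, "cart_domain"),
            inherits(params, "kinetic_parameters"))
  n <- domain$n_nodes
  Cdmg <- if (is.null(damage)) rep(0, n) else damage$C_cell_damaged
  if (length(Cdmg) != n)
    stop("input error: damage field length does not match the domain",
         call. = FALSE)
  Cdmg[domain$lesion_mask] <- 0

  # initial state
  st <- list(col = initial_collagen(domain), cold = rep(0, n),
             agg = initial_aggrecan(domain), aggd = rep(0, n),
             mmp = rep(0, n), aga = rep(0, n),
             S_mmp = rep(0, n), S_aga = rep(0, n))

  diffusivity <- c(col = 0, cold = params$D_cold, agg = params$D_agg,
                   aggd = params$D_aggd, mmp = params$D_mmp,
                   aga = params$D_aga, S_mmp = 0, S_aga = 0)
  diffusive <- names(diffusivity)[diffusivity > 0]

  n_steps <- ceiling(horizon / dt)
  dt <- horizon / n_steps  # exact horizon

  # implicit Euler half-step factorizations, one per diffusive species
  solvers <- list()
  for (s in diffusive) {
    op <- diffusion_operator(domain, diffusivity[[s]], bcs[[s]])
    A <- Matrix::Diagonal(n) - (dt / 2) * op$L
    solvers[[s]] <- list(fac = Matrix::lu(A), dirichlet = op$dirichlet)
  }

  if (is.null(checkpoints))
    checkpoints <- unique(c(seq(0, horizon, by = 86400), horizon))
  checkpoints <- sort(unique(pmin(pmax(checkpoints, 0), horizon)))
  ck_steps <- unique(round(checkpoints / dt))
  ck_times <- ck_steps * dt

  lesion <- domain$lesion_mask
  clip_mass <- stats::setNames(numeric(length(SPECIES)), SPECIES)
  mass_seen <- vapply(st, function(v) sum(domain$weights * v), numeric(1))
  mass_seen <- pmax(mass_seen, 0)
  # reference scale for the clipped-mass guard: species that start empty
  # (enzymes, degradation products) are measured against the total initial
  # inventory of the run rather than their own (zero) initial mass
  mass_scale <- max(sum(mass_seen), .Machine$double.xmin)

  react_fun <- function(t, y, parms) {
    sv <- split_state(y, n)
    r <- reaction_rates(sv, Cdmg, params)
    list(unlist(r, use.names = FALSE))
  }

  apply_diffusion <- function(st) {
    for (s in diffusive) {
      sol <- solvers[[s]]
      v <- Matrix::solve(sol$fac, st[[s]])
      v <- as.numeric(v)
      if (length(sol$dirichlet)) v[sol$dirichlet] <- 0
      v[lesion] <- 0
      st[[s]] <- v
    }
    st
  }

  clip_negatives <- function(st) {
    for (s in SPECIES) {
      v <- st[[s]]
      neg <- v < 0
      if (any(neg)) {
        clip_mass[[s]] <<- clip_mass[[s]] - sum(domain$weights[neg] * v[neg])
        v[neg] <- 0
        st[[s]] <- v
      }
    }
    st
  }

  states <- list(); times <- numeric(0)
  store <- function(step, st) {
    if (step %in% ck_steps) {
      states[[length(states) + 1]] <<- st
      times <<- c(times, step * dt)
    }
  }
  store(0, st)

  # fastest local reaction time scale, used to cap the explicit substep
  # (the MMP / degraded-collagen binding pair is the stiffest coupling)
  stiffness_scale <- function(st) {
    params$k_mmp_cold * params$n_R_cold * max(st$mmp + st$cold) +
      max(params$alpha_mmp, params$alpha_aga) +
      params$k_mmp_catalytic * max(st$mmp) / params$K_m_mmp +
      params$k_aga_catalytic * max(st$aga) / params$K_m_aga
  }

  prev_max <- rep(Inf, 3)
  for (step in seq_len(n_steps)) {
    st <- apply_diffusion(st)
    y <- unlist(st, use.names = FALSE)
    hmax <- min(dt, 1 / max(stiffness_scale(st), 1 / dt))
    out <- deSolve::ode(y = y, times = c(0, dt), func = react_fun,
                        parms = NULL, method = "ode45", hmax = hmax,
                        rtol = rtol, atol = atol)
    st <- split_state(as.numeric(out[nrow(out), -1]), n)
    names(st) <- SPECIES
    st <- apply_diffusion(st)
    st <- clip_negatives(st)

    cur_max <- max(vapply(st, function(v) max(abs(v)), numeric(1)))
    if (!is.finite(cur_max))
      stop("solver error: non-finite state at t = ", step * dt, " s",
           call. = FALSE)
    # divergence guard: sustained growth of the state magnitude
    prev_max <- c(prev_max[-1], cur_max)
    if (all(diff(prev_max) > 0) && cur_max > 1e6)
      stop("solver error: residual growth over 3 consecutive steps",
           call. = FALSE)
    mass_now <- vapply(st, function(v) sum(domain$weights * v), numeric(1))
    mass_seen <- pmax(mass_seen, mass_now)
    bad <- clip_mass > max_clip_frac * mass_scale
    if (any(bad))
      stop("solver error: clipped negative mass beyond tolerance for ",
           paste(SPECIES[bad], collapse = ", "), call. = FALSE)
    store(step, st)
  }

  structure(list(
    times = times, states = states, domain = domain, params = params,
    damage = damage,
    diagnostics = list(n_steps = n_steps, dt = dt,
                       clipped_mass = clip_mass,
                       max_mass = mass_seen)
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "simulation_result: %d checkpoints over %.2f days, %d x %d grid\n",
    length(x$times), max(x$times) / 86400, x$domain$nx, x$domain$nz))
  invisible(x)
}

#' Extract one species field at a checkpoint
#'
#' @param result a \code{simulation_result}.
#' @param species one of \code{\link{SPECIES}}.
#' @param time checkpoint time in seconds (matched within half a macro
#'   step).
#' @return Per-node numeric vector.
#' @export
species_field <- function(result, species, time) {
  stopifnot(inherits(result, "simulation_result"))
  species <- match.arg(species, SPECIES)
  i <- which.min(abs(result$times - time))
  if (abs(result$times[i] - time) > result$diagnostics$dt / 2 + 1e-9)
    stop("input error: no checkpoint near t = ", time, " s", call. = FALSE)
  result$states[[i]][[species]]
}

#' Grid and time-step refinement study
#'
#' Re-runs a reference configuration on successively refined grids and
#' time steps and reports the change in day-12 bulk collagen loss between
#' successive refinements.  The run is flagged non-convergent when the
#' last refinement still changes the bulk loss by more than
#' \code{threshold} percentage points.
#'
#' @param config a \code{run_config} (see \code{\link{run_config}}).
#' @param grid_factors multipliers applied to the cell counts, coarsest
#'   first (1 = the configured grid).
#' @param dt_factors multipliers applied to the macro step.
#' @param threshold convergence threshold in percentage points.
#' @return List with the bulk-loss table per refinement, the successive
#'   deltas, and the \code{converged} flag.
#' @export
convergence_study <- function(config, grid_factors = c(1, 2),
                              dt_factors = c(1, 0.5), threshold = 0.5) {
  runs <- data.frame(grid_factor = numeric(0), dt_factor = numeric(0),
                     nx = integer(0), nz = integer(0),
                     bulk_loss_pct = numeric(0))
  for (i in seq_along(grid_factors)) {
    g <- grid_factors[i]
    f <- dt_factors[min(i, length(dt_factors))]
    cfg <- config
    cfg$nx <- as.integer((config$nx - 1) * g + 1)
    cfg$nz <- as.integer((config$nz - 1) * g + 1)
    cfg$dt <- config$dt * f
    res <- run_reference(cfg)
    runs <- rbind(runs, data.frame(grid_factor = g, dt_factor = f,
                                   nx = cfg$nx, nz = cfg$nz,
                                   bulk_loss_pct = res$metrics$bulk_loss_pct))
  }
  deltas <- abs(diff(runs$bulk_loss_pct))
  list(runs = runs, deltas = deltas,
       converged = length(deltas) == 0 || deltas[length(deltas)] <= threshold)
}
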