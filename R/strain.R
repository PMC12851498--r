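#' Maximum shear strain from principal Green-Lagrange strains
#'
#' The scalar damage driver is the largest pairwise difference of the three
#' principal Green-Lagrange strains,
#' \code{max(|e1 - e2|, |e1 - e3|, |e2 - e3|)}, evaluated per node.
#'
#' @param principal_strains numeric matrix with one row per node and three
#'   columns of principal Green-Lagrange strains (dimensionless), or a
#'   length-3 vector for a single evaluation.
#' @return Numeric vector of per-node maximum shear strain (>= 0).
#' @export
max_shear <- function(principal_strains) {
  if (is.null(dim(principal_strains)))
    principal_strains <- matrix(principal_strains, nrow = 1)
  if (ncol(principal_strains) != 3)
    stop("input error: three principal strains per node required",
         call. = FALSE)
  if (!all(is.finite(principal_strains)))
    stop("input error: non-finite principal strains", call. = FALSE)
  e1 <- principal_strains[, 1]
  e2 <- principal_strains[, 2]
  e3 <- principal_strains[, 3]
  pmax(abs(e1 - e2), abs(e1 - e3), abs(e2 - e3))
}

#' Homogeneous-deformation strain surrogate
#'
#' Produces a spatially uniform principal Green-Lagrange strain field for a
#' prescribed axial stretch, standing in for a finite-element solve of the
#' unconfined compression.  Two incompressible kinematic modes are offered:
#' \describe{
#'   \item{incompressible-unconfined}{lateral stretch
#'     \code{axial_stretch^(-1/2)} in both lateral directions,}
#'   \item{plane-strain-incompressible}{in-plane lateral stretch
#'     \code{1 / axial_stretch}, zero out-of-plane strain.}
#' }
#' Green-Lagrange strain per axis is \code{(lambda^2 - 1) / 2}; the product
#' of the stretches is 1 (volume preserved).
#'
#' @param domain a \code{cart_domain}.
#' @param axial_stretch axial stretch ratio in (0, 1); 0.5 corresponds to
#'   50 % compression.
#' @param mode kinematic mode, see above.
#' @return Matrix \code{n_nodes x 3} of principal Green-Lagrange strains.
#' @export
homogeneous_strain_surrogate <- function(domain, axial_stretch,
                                         mode = c("incompressible-unconfined",
                                                  "plane-strain-incompressible")) {
  stopifnot(inherits(domain, "cart_domain"))
  mode <- match.arg(mode)
  if (!is.finite(axial_stretch) || axial_stretch <= 0 || axial_stretch >= 1)
    stop("input error: axial_stretch must lie strictly between 0 and 1",
         call. = FALSE)
  gl <- function(lambda) (lambda^2 - 1) / 2
  if (mode == "incompressible-unconfined") {
    lam_lat <- axial_stretch^(-0.5)
    e <- c(gl(lam_lat), gl(lam_lat), gl(axial_stretch))
  } else {
    lam_lat <- 1 / axial_stretch
    e <- c(gl(lam_lat), 0, gl(axial_stretch))
  }
  matrix(rep(e, each = domain$n_nodes), ncol = 3)
}

#' Parametric depth-decaying maximum shear strain field
#'
#' Generates a maximum shear strain field that peaks at the articular
#' surface and decays exponentially with normalized depth,
#' \code{eps(depth) = plateau + (peak - plateau) * exp(-depth / decay)},
#' optionally perturbed per node by multiplicative lognormal noise with
#' median 1.  This emulates the depth-varying strain output of an external
#' injurious-compression solve, with superficial strain high enough to
#' saturate the damage function and a partial-damage plateau at depth.
#'
#' @param domain a \code{cart_domain}.
#' @param surface_peak strain at depth 0 (>= deep_plateau).
#' @param deep_plateau asymptotic strain at depth (>= 0).
#' @param decay_depth decay constant in normalized depth units (> 0).
#' @param lateral_noise_sd standard deviation of log-strain noise (>= 0);
#'   0 gives a laterally constant field.
#' @param seed integer seed making the noise reproducible.
#' @return Numeric vector of per-node maximum shear strain.
#' @export
parametric_strain_field <- function(domain, surface_peak, deep_plateau,
                                    decay_depth, lateral_noise_sd = 0,
                                    seed = 1L) {
  stopifnot(inherits(domain, "cart_domain"))
  if (!is.finite(surface_peak) || !is.finite(deep_plateau) ||
      surface_peak < deep_plateau || deep_plateau < 0)
    stop("input error: need surface_peak >= deep_plateau >= 0", call. = FALSE)
  if (!is.finite(decay_depth) || decay_depth <= 0)
    stop("input error: decay_depth must be positive", call. = FALSE)
  if (lateral_noise_sd < 0)
    stop("input error: negative noise sd", call. = FALSE)
  eps <- deep_plateau + (surface_peak - deep_plateau) *
    exp(-domain$depth / decay_depth)
  if (lateral_noise_sd > 0) {
    eps <- eps * with_seed(seed, stats::rlnorm(domain$n_nodes,
                                               meanlog = 0,
                                               sdlog = lateral_noise_sd))
  }
  eps[domain$lesion_mask] <- 0
  eps
}

# Run code under a local RNG seed without disturbing the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Load a strain field from a delimited file
#'
#' Reads either a per-node table matching the domain grid exactly or a
#' scattered table that is mapped to the nearest grid node (unassigned
#' nodes are filled from their nearest assigned node).  Columns:
#' \code{x, z, eps} for a scalar maximum shear field or
#' \code{x, z, ep1, ep2, ep3} for principal strains (reduced with
#' \code{\link{max_shear}}).
#'
#' @param path CSV file path.
#' @param domain a \code{cart_domain}.
#' @return Per-node maximum shear strain vector.
#' @export
load_strain_field <- function(path, domain) {
  stopifnot(inherits(domain, "cart_domain"))
  tab <- utils::read.csv(path)
  if (ncol(tab) == 3) {
    vals <- tab[, 3]
  } else if (ncol(tab) == 5) {
    vals <- max_shear(as.matrix(tab[, 3:5]))
  } else {
    stop(sprintf("format error: expected 3 or 5 columns, found %d", ncol(tab)),
         call. = FALSE)
  }
  if (any(!is.finite(vals)) || any(!is.finite(as.matrix(tab[, 1:2]))))
    stop("input error: non-finite entries in strain file", call. = FALSE)

  if (nrow(tab) == domain$n_nodes) {
    # exact grid: match rows to nodes by coordinates
    key <- order(round(tab[, 1], 12), round(tab[, 2], 12))
    dom_key <- order(round(domain$node_x, 12), round(domain$node_z, 12))
    eps <- numeric(domain$n_nodes)
    eps[dom_key] <- vals[key]
    # verify the coordinates actually coincide
    if (max(abs(tab[key, 1] - domain$node_x[dom_key])) > domain$dx / 2 ||
        max(abs(tab[key, 2] - domain$node_z[dom_key])) > domain$dz / 2)
      stop("format error: node coordinates do not match the domain grid",
           call. = FALSE)
    return(eps)
  }

  # scattered points: nearest-node assignment, then nearest-neighbour fill
  eps <- rep(NA_real_, domain$n_nodes)
  ix <- pmin(pmax(round(tab[, 1] / domain$dx), 0), domain$nx - 1) + 1
  iz <- pmin(pmax(round(tab[, 2] / domain$dz), 0), domain$nz - 1) + 1
  node <- (ix - 1) * domain$nz + iz
  # later points overwrite earlier ones at the same node
  eps[node] <- vals
  un <- which(is.na(eps))
  as_ <- which(!is.na(eps))
  if (length(as_) == 0)
    stop("input error: no points map onto the grid", call. = FALSE)
  for (k in un) {
    d2 <- (domain$node_x[as_] - domain$node_x[k])^2 +
      (domain$node_z[as_] - domain$node_z[k])^2
    eps[k] <- eps[as_[which.min(d2)]]
  }
  eps
}
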