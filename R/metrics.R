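#' Bulk percent change of collagen between two checkpoints
#'
#' \code{100 * (1 - <C_col(t1)> / <C_col(t0)>)} with \code{< >} the
#' area-weighted average over non-lesion nodes.
#'
#' @param result a \code{simulation_result}.
#' @param t0,t1 checkpoint times in seconds (\code{t0 < t1}).
#' @return Percent decrease (positive = loss).
#' @export
bulk_percent_change <- function(result, t0 = 0,
                                t1 = max(result$times)) {
  stopifnot(inherits(result, "simulation_result"))
  if (t0 >= t1) stop("input error: need t0 < t1", call. = FALSE)
  w <- result$domain$weights
  c0 <- species_field(result, "col", t0)
  c1 <- species_field(result, "col", t1)
  100 * (1 - sum(w * c1) / sum(w * c0))
}

#' Depth-wise collagen profile at a checkpoint
#'
#' Averages the collagen field laterally (quadrature-weighted, lesion
#' nodes excluded) within an optional region of interest, one bin per grid
#' depth row.  With \code{normalize_to} the profile is expressed as
#' percent of the supplied day-0 profile.
#'
#' @param result a \code{simulation_result}.
#' @param time checkpoint time (s).
#' @param roi optional \code{roi_spec}; default spans the full width.
#' @param normalize_to optional reference \code{depth_profile} (same depth
#'   bins) for percent-remaining normalization.
#' @param species species to profile (default intact collagen).
#' @return A \code{depth_profile}: data frame with columns \code{depth}
#'   and \code{value}.
#' @export
depth_profile <- function(result, time, roi = NULL, normalize_to = NULL,
                          species = "col") {
  stopifnot(inherits(result, "simulation_result"))
  dom <- result$domain
  field <- species_field(result, species, time)
  mask <- if (is.null(roi)) !dom$lesion_mask else roi_depth_mask(dom, roi)
  if (!any(mask)) stop("input error: empty ROI", call. = FALSE)
  wx <- rep(c(dom$dx / 2, rep(dom$dx, dom$nx - 2), dom$dx / 2), each = dom$nz)
  val <- numeric(dom$nz)
  for (iz in seq_len(dom$nz)) {
    rows <- seq(iz, dom$n_nodes, by = dom$nz)
    sel <- rows[mask[rows]]
    if (length(sel) == 0) { val[iz] <- NA_real_; next }
    val[iz] <- sum(wx[sel] * field[sel]) / sum(wx[sel])
  }
  out <- data.frame(depth = dom$z / dom$thickness, value = val)
  if (!is.null(normalize_to)) {
    ref <- stats::approx(normalize_to$depth, normalize_to$value,
                         xout = out$depth, rule = 2)$y
    out$value <- 100 * out$value / ref
  }
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Compare a model profile with a banded reference profile
#'
#' Re-bins the model profile onto the reference depth bins by linear
#' interpolation, flags each bin as inside/outside the reference band,
#' and reports the fraction of depth inside the band plus the RMSE against
#' the reference mean.  Sub-ranges of normalized depth can be assessed
#' separately via \code{depth_ranges}.
#'
#' @param model a \code{depth_profile}.
#' @param reference a \code{depth_profile} with \code{band_low} and
#'   \code{band_high} columns.
#' @param depth_ranges optional named list of 2-vectors (depth intervals)
#'   over which to report the inside-band fraction separately.
#' @return List with the per-bin table, \code{fraction_inside},
#'   \code{rmse}, and (if requested) per-range inside fractions.
#' @export
profile_agreement <- function(model, reference, depth_ranges = NULL) {
  if (is.null(reference$band_low) || is.null(reference$band_high))
    stop("input error: reference profile lacks confidence bands",
         call. = FALSE)
  lo <- max(min(model$depth), min(reference$depth))
  hi <- min(max(model$depth), max(reference$depth))
  if (lo >= hi)
    stop("input error: non-overlapping depth supports", call. = FALSE)
  keep <- reference$depth >= lo - 1e-12 & reference$depth <= hi + 1e-12
  ref <- reference[keep, ]
  m <- stats::approx(model$depth, model$value, xout = ref$depth)$y
  inside <- m >= ref$band_low & m <= ref$band_high
  tab <- data.frame(depth = ref$depth, model = m, reference = ref$value,
                    band_low = ref$band_low, band_high = ref$band_high,
                    inside = inside)
  out <- list(table = tab,
              fraction_inside = mean(inside),
              rmse = sqrt(mean((m - ref$value)^2)))
  if (!is.null(depth_ranges)) {
    out$ranges <- vapply(depth_ranges, function(rg) {
      sel <- tab$depth >= rg[1] - 1e-12 & tab$depth <= rg[2] + 1e-12
      if (!any(sel)) return(NA_real_)
      mean(tab$inside[sel])
    }, numeric(1))
  }
  out
}

#' One-at-a-time sensitivity sweep specification
#'
#' @param parameter name of a kinetic registry entry, or one of the damage
#'   parameters \code{"k_INJ"}, \code{"eps_dmg_max"}.
#' @param values numeric values to sweep (must include the reference
#'   value of the base configuration).
#' @return Object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(parameter, values) {
  known <- c(names(kinetic_parameters()), "k_INJ", "eps_dmg_max")
  if (!parameter %in% known)
    stop("configuration error: unknown sweep parameter '", parameter, "'",
         call. = FALSE)
  structure(list(parameter = parameter, values = values),
            class = "sweep_spec")
}

#' Run a one-at-a-time parameter sweep
#'
#' Runs one full simulation per value of the swept parameter with all
#' other parameters held at the base configuration, and records the day-12
#' bulk collagen loss, its delta against the reference value's run, and
#' the normalized day-12 depth profile.  A failing member run is recorded
#' and the sweep continues.
#'
#' @param spec a \code{sweep_spec}.
#' @param config base \code{run_config} (the reference run).
#' @return List with a tidy results table (\code{parameter, value,
#'   bulk_loss_pct, delta_vs_reference}) and the list of day-12 profiles.
#' @export
run_sweep <- function(spec, config) {
  stopifnot(inherits(spec, "sweep_spec"))
  tab <- data.frame(parameter = character(0), value = numeric(0),
                    bulk_loss_pct = numeric(0))
  profiles <- list()
  for (v in spec$values) {
    cfg <- override_parameter(config, spec$parameter, v)
    res <- tryCatch(run_reference(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      tab <- rbind(tab, data.frame(parameter = spec$parameter, value = v,
                                   bulk_loss_pct = NA_real_))
      profiles[[length(profiles) + 1]] <- NULL
      next
    }
    tab <- rbind(tab, data.frame(parameter = spec$parameter, value = v,
                                 bulk_loss_pct = res$metrics$bulk_loss_pct))
    profiles[[length(profiles) + 1]] <- res$metrics$day12_profile
  }
  ref_value <- reference_value_of(config, spec$parameter)
  iref <- which.min(abs(tab$value - ref_value))
  tab$delta_vs_reference <- tab$bulk_loss_pct - tab$bulk_loss_pct[iref]
  list(table = tab, profiles = profiles, reference_value = ref_value)
}

override_parameter <- function(config, parameter, value) {
  if (parameter %in% c("k_INJ", "eps_dmg_max")) {
    config[[parameter]] <- value
  } else {
    config$params <- set_param(config$params, parameter, value)
  }
  config
}

reference_value_of <- function(config, parameter) {
  if (parameter %in% c("k_INJ", "eps_dmg_max")) config[[parameter]]
  else config$params[[parameter]]
}

#' Parameter value lists of the shipped sensitivity study
#'
#' The six swept parameters with their value lists (reference value in the
#' middle; the half-maximal-activity concentration \code{k_act} also
#' carries a 100-fold variant because its +/-50 % band has no visible
#' effect at the aggrecan concentrations of this tissue).
#'
#' @return Named list of numeric value vectors.
#' @export
sensitivity_value_table <- function() {
  list(
    k_INJ = c(0.2, 0.35, 0.5),
    eps_dmg_max = c(1.0, 1.5, 2.0),
    k_rate_mmp = c(1.8e-5, 3.6e-5, 5.3e-5),
    k_act = c(1.5e-5, 3e-5, 4.5e-5, 300e-5),
    k_mmp = c(0.17e-21, 0.35e-21, 0.52e-21),
    k_mmp_catalytic = c(0.75, 1.5, 2.25)
  )
}

#' Run every sweep of the sensitivity study
#'
#' @param config base \code{run_config}.
#' @param parameters subset of parameter names to sweep (default all six).
#' @return Named list of \code{\link{run_sweep}} outputs.
#' @export
run_all_sweeps <- function(config,
                           parameters = names(sensitivity_value_table())) {
  vt <- sensitivity_value_table()
  out <- list()
  for (p in parameters)
    out[[p]] <- run_sweep(sweep_spec(p, vt[[p]]), config)
  out
}
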