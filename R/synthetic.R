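#' Configuration of the synthetic-data generator
#'
#' Fixes everything the synthetic fixtures need: the RNG seed, the
#' FTIR-like pixel size, multiplicative noise levels, per-group sample
#' counts matching the emulated explant experiment (control day 0 n = 18,
#' day 12 n = 21; injury day 0 n = 18, day 12 n = 6) and the per-group
#' depth-wise mean percent-loss curves.  The default loss curves are a
#' uniform ~20 % for the day-12 control and a superficially weighted
#' curve with ~35 % bulk loss for the day-12 injury group; the noise
#' levels are invented fixture defaults, not estimates of the experiment.
#'
#' @param seed integer seed fixing all randomness.
#' @param pixel_size pixel edge of the synthetic collagen maps (m).
#' @param lateral_noise_sd sd of the lognormal lateral pixel noise.
#' @param between_sample_sd sd of the lognormal per-sample scale factor.
#' @param depth_noise_sd sd (relative to the mean) of additive per-depth
#'   noise within a sample.
#' @param group_sizes named counts per (group, day).
#' @param injury_loss list with \code{surface}, \code{deep} and
#'   \code{decay} defining the injury day-12 loss curve
#'   \code{loss(d) = deep + (surface - deep) exp(-d / decay)} (fractions).
#' @param control_loss uniform day-12 control loss fraction.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L, pixel_size = 5.5e-6,
                         lateral_noise_sd = 0.10,
                         between_sample_sd = 0.15,
                         depth_noise_sd = 0.05,
                         group_sizes = c(control_day0 = 18, control_day12 = 21,
                                         injury_day0 = 18, injury_day12 = 6),
                         injury_loss = list(surface = 0.53, deep = 0.26,
                                            decay = 0.33),
                         control_loss = 0.20) {
  if (any(group_sizes < 1))
    stop("configuration error: group sizes must be >= 1", call. = FALSE)
  if (lateral_noise_sd < 0 || between_sample_sd < 0 || depth_noise_sd < 0)
    stop("configuration error: noise sds must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 lateral_noise_sd = lateral_noise_sd,
                 between_sample_sd = between_sample_sd,
                 depth_noise_sd = depth_noise_sd,
                 group_sizes = group_sizes,
                 injury_loss = injury_loss,
                 control_loss = control_loss),
            class = "synth_config")
}

#' Mean remaining-collagen curve of a synthetic group (percent of day 0)
#'
#' @param config a \code{synth_config}.
#' @param group one of \code{"control_day0"}, \code{"control_day12"},
#'   \code{"injury_day0"}, \code{"injury_day12"}.
#' @param depth normalized depth values.
#' @return Percent remaining at each depth.
#' @export
synth_mean_curve <- function(config, group, depth) {
  loss <- switch(group,
    control_day0 = rep(0, length(depth)),
    injury_day0 = rep(0, length(depth)),
    control_day12 = rep(config$control_loss, length(depth)),
    injury_day12 = with(config$injury_loss,
                        deep + (surface - deep) * exp(-depth / decay)),
    stop("input error: unknown group '", group, "'", call. = FALSE))
  100 * (1 - loss)
}

#' Synthetic FTIR-like collagen map
#'
#' Generates a pixel map of collagen content in absorption units over the
#' explant cross-section at the configured pixel size: each pixel is the
#' depth polynomial value at its depth times lognormal lateral noise with
#' median 1.  Pixels inside an optional lesion polygon are zeroed.
#' Deterministic for a given config seed.
#'
#' @param config a \code{synth_config}.
#' @param domain a \code{cart_domain} providing the physical extent.
#' @param lesion optional lesion polygon (matrix of x, z vertices in m).
#' @return List with pixel centre vectors \code{x}, \code{z} and the map
#'   matrix (rows = depth pixels, columns = lateral pixels).
#' @export
synth_collagen_map <- function(config, domain, lesion = NULL) {
  stopifnot(inherits(config, "synth_config"),
            inherits(domain, "cart_domain"))
  px <- config$pixel_size
  x <- seq(px / 2, domain$width - px / 2, by = px)
  z <- seq(px / 2, domain$thickness - px / 2, by = px)
  polys <- depth_polynomials()
  base <- polys$c_col0(z / domain$thickness)
  map <- matrix(rep(base, times = length(x)), nrow = length(z))
  if (config$lateral_noise_sd > 0) {
    noise <- with_seed(config$seed,
                       stats::rlnorm(length(map), 0, config$lateral_noise_sd))
    map <- map * matrix(noise, nrow = length(z))
  }
  if (!is.null(lesion)) {
    poly <- validate_lesion_polygon(lesion, domain$width, domain$thickness)
    gx <- rep(x, each = length(z))
    gz <- rep(z, times = length(x))
    inside <- pracma::inpolygon(gx, gz, poly[, 1], poly[, 2],
                                boundary = FALSE)
    map[matrix(inside, nrow = length(z))] <- 0
  }
  list(x = x, z = z, map = map)
}

#' Synthetic group-level depth profiles with 95 percent confidence bands
#'
#' Simulates per-sample depth-wise remaining-collagen curves for each
#' group as the group's mean curve times a per-sample lognormal factor,
#' plus per-depth noise, and returns the empirical mean with normal-theory
#' 95 % confidence bands per depth bin.  These banded profiles emulate
#' the statistical shape of experimental group summaries and serve as
#' reference profiles for \code{\link{profile_agreement}}.
#'
#' @param config a \code{synth_config}.
#' @param depth normalized depth bin centres (default 21 bins over [0,1]).
#' @param type \code{"empirical"} (default) simulates the group samples
#'   and returns the empirical mean with bands from the sample standard
#'   deviation; \code{"population"} returns the configured mean curve
#'   with deterministic normal-theory bands built from the configured
#'   noise levels — the expected band of the emulated experiment, free
#'   of re-draw noise in the reference itself.
#' @return Named list of \code{depth_profile} data frames (columns
#'   \code{depth}, \code{value}, \code{band_low}, \code{band_high},
#'   percent-of-day-0 units).
#' @export
synth_group_profiles <- function(config,
                                 depth = seq(0, 1, length.out = 21),
                                 type = c("empirical", "population")) {
  stopifnot(inherits(config, "synth_config"))
  type <- match.arg(type)
  groups <- names(config$group_sizes)
  if (type == "population") {
    rel_sd <- sqrt(config$between_sample_sd^2 + config$depth_noise_sd^2)
    out <- list()
    for (g in groups) {
      n <- config$group_sizes[[g]]
      mu <- synth_mean_curve(config, g, depth)
      half <- 1.96 * rel_sd * mu / sqrt(n)
      prof <- data.frame(depth = depth, value = mu,
                         band_low = mu - half, band_high = mu + half)
      class(prof) <- c("depth_profile", "data.frame")
      out[[g]] <- prof
    }
    return(out)
  }
  with_seed(config$seed, {
    out <- list()
    for (g in groups) {
      n <- config$group_sizes[[g]]
      mu <- synth_mean_curve(config, g, depth)
      samples <- matrix(NA_real_, nrow = n, ncol = length(depth))
      for (i in seq_len(n)) {
        scale_i <- stats::rlnorm(1, 0, config$between_sample_sd)
        noise <- stats::rnorm(length(depth), 0, config$depth_noise_sd * mu)
        samples[i, ] <- mu * scale_i + noise
      }
      m <- colMeans(samples)
      if (n >= 2) {
        half <- 1.96 * apply(samples, 2, stats::sd) / sqrt(n)
      } else {
        warning("group size < 2: confidence bands undefined for ", g)
        half <- rep(NA_real_, length(depth))
      }
      prof <- data.frame(depth = depth, value = m,
                         band_low = m - half, band_high = m + half)
      class(prof) <- c("depth_profile", "data.frame")
      out[[g]] <- prof
    }
    out
  })
}

#' Fixture suite of maximum shear strain fields
#'
#' Emits four strain fields spanning the damage function's branches:
#' (a) a sub-threshold uniform field (0.3, zero damage), (b) a saturating
#' uniform field (2.0, full damage), (c) the reference depth-decaying
#' field, and (d) a laterally perturbed variant of (c).
#'
#' @param config a \code{synth_config}.
#' @param domain a \code{cart_domain}.
#' @return Named list of per-node strain vectors
#'   (\code{sub_threshold}, \code{saturating}, \code{reference},
#'   \code{lateral_perturbed}).
#' @export
synth_strain_suite <- function(config, domain) {
  stopifnot(inherits(config, "synth_config"),
            inherits(domain, "cart_domain"))
  ref <- reference_strain_parameters()
  list(
    sub_threshold = rep(0.3, domain$n_nodes),
    saturating = rep(2.0, domain$n_nodes),
    reference = parametric_strain_field(domain, ref$surface_peak,
                                        ref$deep_plateau, ref$decay_depth,
                                        0, config$seed),
    lateral_perturbed = parametric_strain_field(domain, ref$surface_peak,
                                                ref$deep_plateau,
                                                ref$decay_depth,
                                                0.10, config$seed)
  )
}

#' Parametric triangular lesion notch
#'
#' An apex-down triangular notch cut into the top surface, standing in for
#' a segmented histological lesion geometry.
#'
#' @param x_center lateral position of the notch centre (m).
#' @param depth notch depth from the surface (m).
#' @param width notch opening width at the surface (m).
#' @return A 3 x 2 vertex matrix usable as a lesion polygon.
#' @export
lesion_notch <- function(x_center = 1.5e-3, depth = 0.4e-3,
                         width = 0.2e-3) {
  matrix(c(x_center - width / 2, 0,
           x_center + width / 2, 0,
           x_center, depth),
         ncol = 2, byrow = TRUE)
}
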