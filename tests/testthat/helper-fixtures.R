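# shared cheap fixtures: small grids and fast solver settings keep the
# suite quick while exercising the same code paths as the reference runs

tiny_domain <- function() build_domain(3e-3, 1e-3, 7, 5)

tiny_config <- function(mode = "control", ...) {
  run_config(mode = mode, nx = 7, nz = 5, dt = 7200, ...)
}

coarse_config <- function(mode = "injury", dt = 600, ...) {
  run_config(mode = mode, nx = 31, nz = 21, dt = dt, ...)
}

# all-faces zero-flux boundary set for conservation checks
zero_flux_bcs <- function() {
  zf <- list(type = "zero-flux")
  faces <- list(top = zf, bottom = zf, lateral = zf, lesion = zf)
  stats::setNames(rep(list(faces), length(SPECIES)), SPECIES)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
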