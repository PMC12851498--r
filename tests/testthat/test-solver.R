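test_that("diffusion operator annihilates constants under zero flux", {
  dom <- tiny_domain()
  zf <- zero_flux_bcs()[["mmp"]]
  op <- diffusion_operator(dom, 1e-11, zf)
  out <- as.numeric(op$L %*% rep(3, dom$n_nodes))
  expect_lt(max(abs(out)), 1e-15)
  expect_length(op$dirichlet, 0)
})

test_that("discrete Laplacian of a linear profile vanishes in the interior", {
  dom <- build_domain(3e-3, 1e-3, 9, 7)
  bc <- list(top = list(type = "dirichlet"), bottom = list(type = "dirichlet"),
             lateral = list(type = "zero-flux"),
             lesion = list(type = "zero-flux"))
  op <- diffusion_operator(dom, 1e-11, bc)
  v <- dom$node_z / dom$thickness
  out <- as.numeric(op$L %*% v)
  interior <- dom$node_z > 0 & dom$node_z < dom$thickness
  expect_equal(out[interior], rep(0, sum(interior)), tolerance = 1e-12)
  # top and bottom rows are pinned
  expect_setequal(op$dirichlet,
                  which(dom$node_z %in% range(dom$z)))
})

test_that("Robin exchange with an empty bath drains to the zero steady state", {
  # 1D column: Robin at the top, zero flux at the bottom, no source
  dom <- build_domain(3e-3, 1e-3, 3, 9)
  bc <- list(top = list(type = "robin", h = 1e-7),
             bottom = list(type = "zero-flux"),
             lateral = list(type = "zero-flux"),
             lesion = list(type = "zero-flux"))
  op <- diffusion_operator(dom, 1e-10, bc)
  n <- dom$n_nodes
  A <- Matrix::Diagonal(n) - 5e4 * op$L
  v <- rep(1, n)
  for (i in 1:400) v <- as.numeric(Matrix::solve(A, v))
  expect_lt(max(abs(v)), 1e-6)
})

test_that("unlabeled faces and bad conditions are rejected", {
  dom <- tiny_domain()
  expect_error(diffusion_operator(dom, 1e-11, list(top = list(type = "zero-flux"))),
               "unlabeled face")
  bc <- zero_flux_bcs()[["mmp"]]
  bc$top <- list(type = "mystery")
  expect_error(diffusion_operator(dom, 1e-11, bc), "unknown boundary")
  expect_error(diffusion_operator(dom, -1, zero_flux_bcs()[["mmp"]]),
               "negative diffusivity")
})

test_that("zero damage with zero basal loss is a fixed point", {
  dom <- tiny_domain()
  p <- kinetic_parameters(k_basal = 0)
  res <- simulate_explant(dom, NULL, p, horizon = 86400, dt = 7200)
  c0 <- species_field(res, "col", 0)
  c1 <- species_field(res, "col", 86400)
  expect_equal(c1, c0, tolerance = 1e-12)
  # aggrecan only moves by diffusion/Robin exchange; everything else stays 0
  for (s in c("cold", "mmp", "aga", "S_mmp", "S_aga"))
    expect_equal(max(abs(species_field(res, s, 86400))), 0)
})

test_that("basal-only control run matches the exponential oracle everywhere", {
  dom <- build_domain(3e-3, 1e-3, 9, 7)
  p <- kinetic_parameters()
  res <- simulate_explant(dom, NULL, p, horizon = 12 * 86400, dt = 3600)
  c0 <- species_field(res, "col", 0)
  c1 <- species_field(res, "col", 12 * 86400)
  loss <- 100 * (1 - c1 / c0)
  expect_true(all(abs(loss - 19.0) < 0.1))
})

test_that("pure diffusion under all-faces zero flux conserves mass", {
  dom <- tiny_domain()
  p <- kinetic_parameters(k_basal = 0)
  res <- simulate_explant(dom, NULL, p, bcs = zero_flux_bcs(),
                          horizon = 86400, dt = 3600)
  for (s in c("col", "agg")) {
    m0 <- sum(dom$weights * species_field(res, s, 0))
    m1 <- sum(dom$weights * species_field(res, s, 86400))
    expect_lt(abs(m1 - m0) / m0, 1e-10)
  }
})

test_that("reaction-only runs conserve the two mass pairs", {
  dom <- tiny_domain()
  # diffusion off entirely; basal and binding off so col + cold and
  # agg + aggd are linear invariants of the reactions
  p <- kinetic_parameters(k_basal = 0, k_mmp_cold = 0, D_mmp = 0,
                          D_aga = 0, D_agg = 0, D_aggd = 0, D_cold = 0)
  eps <- rep(2, dom$n_nodes)
  res <- simulate_explant(dom, damage_field(eps), p,
                          bcs = zero_flux_bcs(), horizon = 2 * 86400,
                          dt = 3600)
  w <- dom$weights
  pair <- function(t, a, b)
    sum(w * (species_field(res, a, t) + species_field(res, b, t)))
  expect_lt(abs(pair(2 * 86400, "col", "cold") - pair(0, "col", "cold")) /
              pair(0, "col", "cold"), 1e-10)
  expect_lt(abs(pair(2 * 86400, "agg", "aggd") - pair(0, "agg", "aggd")) /
              pair(0, "agg", "aggd"), 1e-10)
  # and the reactions actually ran
  expect_gt(max(species_field(res, "mmp", 2 * 86400)), 0)
  expect_gt(max(species_field(res, "cold", 2 * 86400)), 0)
})

test_that("every stored state is non-negative in an injury run", {
  dom <- build_domain(3e-3, 1e-3, 9, 7)
  eps <- parametric_strain_field(dom, 2.0, 0.44, 0.27, 0, 1)
  res <- simulate_explant(dom, damage_field(eps), kinetic_parameters(),
                          horizon = 3 * 86400, dt = 3600)
  for (st in res$states)
    for (s in SPECIES)
      expect_true(all(st[[s]] >= 0))
  expect_true(all(diff(res$times) > 0))
  expect_equal(res$times[1], 0)
})

test_that("repeated runs are bit-identical", {
  dom <- tiny_domain()
  eps <- parametric_strain_field(dom, 2.0, 0.44, 0.27, 0.1, 5)
  a <- simulate_explant(dom, damage_field(eps), kinetic_parameters(),
                        horizon = 86400, dt = 7200)
  b <- simulate_explant(dom, damage_field(eps), kinetic_parameters(),
                        horizon = 86400, dt = 7200)
  expect_identical(a$states, b$states)
})

test_that("mismatched damage fields are rejected", {
  dom <- tiny_domain()
  expect_error(simulate_explant(dom, list(C_cell_damaged = 1:3),
                                kinetic_parameters()),
               "does not match")
})

test_that("lesion nodes carry no species mass", {
  dom <- build_domain(3e-3, 1e-3, 13, 9, lesion = lesion_notch())
  expect_gt(sum(dom$lesion_mask), 0)
  eps <- parametric_strain_field(dom, 2.0, 0.44, 0.27, 0, 1)
  res <- simulate_explant(dom, damage_field(eps), kinetic_parameters(),
                          horizon = 86400, dt = 3600)
  st <- res$states[[length(res$states)]]
  for (s in SPECIES)
    expect_equal(max(abs(st[[s]][dom$lesion_mask])), 0)
  # peri-lesion collagen is still positive
  expect_gt(min(st$col[!dom$lesion_mask]), 0)
})
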