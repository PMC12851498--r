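test_that("maximum shear is the largest pairwise principal difference", {
  expect_equal(max_shear(c(0.5, 0.2, -0.375)), 0.875)
  expect_equal(max_shear(c(1.5, 0, -0.375)), 1.875)
  expect_equal(max_shear(c(0.3, 0.3, 0.3)), 0)
  expect_error(max_shear(c(1, NA, 0)), "non-finite")
  expect_error(max_shear(matrix(1, 2, 2)), "three principal strains")
})

test_that("maximum shear matches brute force and ignores permutation order", {
  set.seed(42)
  e <- matrix(stats::runif(300, -0.5, 2), ncol = 3)
  brute <- apply(e, 1, function(v) {
    max(abs(outer(v, v, "-")))
  })
  expect_equal(max_shear(e), brute)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1)))
    expect_equal(max_shear(e[, perm]), max_shear(e))
})

test_that("homogeneous surrogates give closed-form kinematics", {
  dom <- tiny_domain()
  e <- homogeneous_strain_surrogate(dom, 0.5, "incompressible-unconfined")
  expect_equal(dim(e), c(dom$n_nodes, 3))
  expect_equal(unique(e[, 3]), -0.375)
  expect_equal(unique(e[, 1]), 0.5)
  expect_equal(unique(max_shear(e)), 0.875)
  ep <- homogeneous_strain_surrogate(dom, 0.5, "plane-strain-incompressible")
  expect_equal(unique(ep[, 1]), 1.5)
  expect_equal(unique(ep[, 2]), 0)
  expect_equal(unique(max_shear(ep)), 1.875)
  expect_error(homogeneous_strain_surrogate(dom, 1.0), "input error")
  expect_error(homogeneous_strain_surrogate(dom, 0), "input error")
})

test_that("homogeneous surrogates preserve volume", {
  dom <- tiny_domain()
  for (lam in c(0.3, 0.5, 0.8)) {
    e <- homogeneous_strain_surrogate(dom, lam, "incompressible-unconfined")
    stretches <- sqrt(2 * e[1, ] + 1)
    expect_lt(abs(prod(stretches) - 1), 1e-12)
    ep <- homogeneous_strain_surrogate(dom, lam, "plane-strain-incompressible")
    expect_lt(abs(prod(sqrt(2 * ep[1, ] + 1)) - 1), 1e-12)
  }
})

test_that("parametric strain field follows the stated depth law", {
  dom <- build_domain(3e-3, 1e-3, 7, 21)
  eps <- parametric_strain_field(dom, 1.2, 0.5, 0.15, 0, 1)
  surf <- eps[dom$depth == 0]
  bot <- eps[dom$depth == 1]
  expect_equal(unique(surf), 1.2)
  expect_equal(unique(bot), 0.5 + 0.7 * exp(-1 / 0.15), tolerance = 1e-12)
  # laterally constant without noise
  m <- matrix(eps, nrow = dom$nz)
  expect_equal(m[, 1], m[, 7])
  expect_error(parametric_strain_field(dom, 0.5, 1.2, 0.15), "surface_peak")
  expect_error(parametric_strain_field(dom, 1.2, 0.5, 0), "decay_depth")
})

test_that("parametric strain noise is reproducible by seed", {
  dom <- tiny_domain()
  a <- parametric_strain_field(dom, 1.2, 0.5, 0.15, 0.1, 7)
  b <- parametric_strain_field(dom, 1.2, 0.5, 0.15, 0.1, 7)
  c <- parametric_strain_field(dom, 1.2, 0.5, 0.15, 0.1, 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # lognormal noise: median 1, so the field median tracks the noiseless law
  expect_gt(min(a), 0)
})

test_that("strain fields load from grid-matched CSV", {
  dom <- tiny_domain()
  eps <- parametric_strain_field(dom, 1.2, 0.5, 0.15, 0, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  ord <- sample(dom$n_nodes)  # row order must not matter
  utils::write.csv(data.frame(x = dom$node_x[ord], z = dom$node_z[ord],
                              eps = eps[ord]), path, row.names = FALSE)
  expect_equal(load_strain_field(path, dom), eps)
})

test_that("principal-strain CSV reduces through max_shear", {
  dom <- tiny_domain()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = dom$node_x, z = dom$node_z,
                              ep1 = 0.5, ep2 = 0.2, ep3 = -0.375),
                   path, row.names = FALSE)
  expect_equal(load_strain_field(path, dom), rep(0.875, dom$n_nodes))
})

test_that("scattered strain tables map to nearest nodes with fill", {
  dom <- build_domain(3e-3, 1e-3, 7, 5)
  set.seed(3)
  pts <- data.frame(x = stats::runif(40, 0, 3e-3),
                    z = stats::runif(40, 0, 1e-3))
  pts$eps <- 0.5 + pts$x * 100
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pts, path, row.names = FALSE)
  got <- load_strain_field(path, dom)
  # brute-force oracle: nearest scattered point per assigned node wins last;
  # here check the property that every node value is one of the inputs and
  # nodes coinciding with a point's nearest grid node match that point
  expect_true(all(vapply(got, function(v) min(abs(v - pts$eps)), 1) < 1e-12))
  ix <- pmin(pmax(round(pts$x / dom$dx), 0), dom$nx - 1) + 1
  iz <- pmin(pmax(round(pts$z / dom$dz), 0), dom$nz - 1) + 1
  node <- (ix - 1) * dom$nz + iz
  last <- !duplicated(node, fromLast = TRUE)
  expect_equal(got[node[last]], pts$eps[last], tolerance = 1e-12)
})

test_that("NaN strain entries are rejected", {
  dom <- tiny_domain()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = dom$node_x, z = dom$node_z,
                              eps = c(NA, rep(1, dom$n_nodes - 1))),
                   path, row.names = FALSE)
  expect_error(load_strain_field(path, dom), "input error")
})
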