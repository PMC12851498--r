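test_that("initial collagen matches the scaled depth polynomial", {
  dom <- build_domain(3e-3, 1e-3, 7, 21)
  c0 <- initial_collagen(dom)
  surf <- unique(round(c0[dom$depth == 0], 10))
  bot <- unique(round(c0[dom$depth == 1], 10))
  expect_equal(surf, round(8.782 / 46.2276, 10))
  expect_equal(surf, 0.19, tolerance = 1e-3)
  expect_equal(bot, 0.2094, tolerance = 1e-3)
  # laterally homogeneous
  expect_equal(matrix(c0, dom$nz)[, 1], matrix(c0, dom$nz)[, 7])
})

test_that("depth-mean initial collagen is 0.2 mol m-3", {
  polys <- depth_polynomials()
  mean_c <- stats::integrate(function(z) polys$c_col0(z), 0, 1,
                             rel.tol = 1e-10)$value / 46.2276
  expect_equal(mean_c, 0.2, tolerance = 0.01)
  expect_equal(mean_c, 0.1990, tolerance = 1e-3)
})

test_that("initial aggrecan converts fixed charge density to molarity", {
  dom <- build_domain(3e-3, 1e-3, 7, 21)
  a0 <- initial_aggrecan(dom)
  expect_equal(unique(round(a0[dom$depth == 0], 12)),
               round(0.03 * 0.1005, 12))
  polys <- depth_polynomials()
  mean_a <- stats::integrate(function(z) polys$c_fcd0(z), 0, 1,
                             rel.tol = 1e-10)$value * 0.1005
  expect_equal(mean_a, 7.68e-3, tolerance = 1e-3)
})

test_that("stimulus dynamics follow the first-order delay closed form", {
  p <- kinetic_parameters()
  # fixed point
  S_star <- p$k_mmp * 3.5e13
  expect_equal(stimulus_rate(S_star, 3.5e13, p$alpha_mmp, p$k_mmp), 0)
  # closed form vs numeric integration oracle
  alpha <- 1e-4
  oracle <- deSolve::ode(c(S = 0), seq(0, 1 / alpha, length.out = 5),
                         function(t, y, parms)
                           list(stimulus_rate(y, 3.5e13, alpha, p$k_mmp)),
                         NULL, method = "ode45", rtol = 1e-10, atol = 1e-20)
  S_end <- oracle[nrow(oracle), 2]
  expect_equal(unname(S_end), S_star * (1 - exp(-1)), tolerance = 1e-6)
  # pure decay from s0 when no damaged cells
  s0 <- 2e-9
  expect_equal(
    unname(deSolve::ode(c(S = s0), c(0, 2 / alpha),
                 function(t, y, parms) list(stimulus_rate(y, 0, alpha, 0)),
                 NULL, method = "ode45", rtol = 1e-10,
                 atol = 1e-20)[2, 2]),
    s0 * exp(-2), tolerance = 1e-6)
})

test_that("MMP reaction balance is production minus binding", {
  p <- kinetic_parameters(k_rate_mmp = 3.6e-5)
  expect_equal(mmp_rate(0, 1e-8, 0, p), 0)
  expect_equal(mmp_rate(1.2e-8, 0, 0, p), 4.32e-13)
  # linearity in the production constant
  p2 <- set_param(p, "k_rate_mmp", 7.2e-5)
  expect_equal(mmp_rate(1.2e-8, 0, 0, p2), 2 * mmp_rate(1.2e-8, 0, 0, p))
  # binding sink sign
  expect_lt(mmp_rate(0, 1e-8, 1e-6, p), 0)
})

test_that("aggrecan Hill factor has the printed shape", {
  expect_equal(agg_protection(3e-5, 0), 0.5)
  expect_equal(agg_protection(1.5e-5, 1.5e-5), 0.5)
  expect_equal(agg_protection(2.56 * 3e-5, 0), 1 / (1 + 2.56^-2),
               tolerance = 1e-12)
  expect_equal(agg_protection(2.56 * 3e-5, 0), 0.868, tolerance = 1e-3)
  expect_equal(agg_protection(0, 0), 0)
  expect_equal(agg_protection(1, 0), 1, tolerance = 1e-8)
  # strictly increasing in total aggrecan
  x <- seq(0, 5e-4, length.out = 50)
  expect_true(all(diff(agg_protection(x, 0)) > 0))
  # reciprocal variant decreases
  expect_true(all(diff(agg_protection(x, 0,
                                      direction = "decreasing")) < 0))
  expect_error(agg_protection(1e-5, 0, k_act = 0), "configuration error")
})

test_that("collagen rate reduces to basal decay without MMP", {
  p <- kinetic_parameters()
  expect_equal(collagen_rate(0.2, 0, 1, p), -p$k_basal * 0.2)
  # 12-day pure basal decay: 19.0 % loss
  ratio <- exp(-2.032433e-7 * 1.0368e6)
  expect_equal(100 * (1 - ratio), 19.0, tolerance = 0.05)
  # saturated Michaelis-Menten limit
  p2 <- kinetic_parameters(k_basal = 0)
  expect_equal(collagen_rate(1e3, 1e-7, 1, p2),
               -p2$k_mmp_catalytic * 1e-7, tolerance = 1e-3)
  expect_lte(collagen_rate(0.2, 1e-7, 0.5, p), 0)
})

test_that("enzymatic transfer conserves collagen mass in a closed node", {
  p <- kinetic_parameters(k_basal = 0, k_mmp_cold = 0)
  expect_equal(degraded_collagen_rate(0.2, 0.01, 0, 1, p), 0)
  st <- list(col = 0.2, cold = 0.01, agg = 5e-3, aggd = 0, mmp = 1e-7,
             aga = 0, S_mmp = 0, S_aga = 0)
  r <- reaction_rates(st, 0, p)
  expect_equal(r$col + r$cold, 0, tolerance = 1e-22)
  expect_equal(r$agg + r$aggd, 0, tolerance = 1e-22)
  # with binding on, degraded collagen decays once production stops
  pb <- kinetic_parameters(k_basal = 0, k_mmp_cold = 1e-2)
  traj <- deSolve::ode(c(cold = 1e-4), c(0, 1e5),
                       function(t, y, parms)
                         list(degraded_collagen_rate(0, y, 1e-7, 1, pb)),
                       NULL, method = "ode45")
  expect_lt(traj[2, 2], 1e-4)
  expect_gt(traj[2, 2], 0)
})

test_that("aggrecanase subsystem conserves total aggrecan under reactions", {
  p <- kinetic_parameters()
  r0 <- aggrecan_system_rates(0, 5e-3, 0, 0, p)
  expect_equal(unlist(r0), c(d_aga = 0, d_agg = 0, d_aggd = 0))
  r <- aggrecan_system_rates(1e-8, 5e-3, 1e-4, 2e-9, p)
  expect_equal(r$d_agg + r$d_aggd, 0)
  expect_equal(r$d_aga, p$k_rate_aga * 2e-9)
  # Michaelis-Menten decay of aggrecan under constant aggrecanase
  aga <- 1e-7
  traj <- deSolve::ode(c(agg = 5e-3), seq(0, 5e5, length.out = 3),
                       function(t, y, parms) {
                         rr <- aggrecan_system_rates(aga, y, 0, 0, p)
                         list(rr$d_agg)
                       }, NULL, method = "ode45", rtol = 1e-10)
  expect_true(all(diff(traj[, 2]) < 0))
  # independent oracle: exact implicit solution of MM decay
  # Km*log(a0/a) + (a0 - a) = k*aga*t
  a_end <- traj[3, 2]
  lhs <- p$K_m_aga * log(5e-3 / a_end) + (5e-3 - a_end)
  expect_equal(unname(lhs), p$k_aga_catalytic * aga * 5e5, tolerance = 1e-6)
})

test_that("the unseeded state is a fixed point apart from basal decay", {
  p <- kinetic_parameters()
  n <- 4
  zero <- rep(0, n)
  st <- list(col = rep(0.2, n), cold = zero, agg = rep(5e-3, n),
             aggd = zero, mmp = zero, aga = zero, S_mmp = zero,
             S_aga = zero)
  r <- reaction_rates(st, zero, p)
  expect_equal(r$col, rep(-p$k_basal * 0.2, n))
  for (s in setdiff(SPECIES, "col"))
    expect_equal(r[[s]], zero)
})

test_that("rates on the boundary of the positive orthant are outgoing-free", {
  p <- kinetic_parameters()
  set.seed(11)
  for (i in 1:25) {
    st <- list(col = stats::runif(1, 0, 0.25), cold = stats::runif(1, 0, 1e-4),
               agg = stats::runif(1, 0, 1e-2), aggd = stats::runif(1, 0, 1e-3),
               mmp = stats::runif(1, 0, 1e-6), aga = stats::runif(1, 0, 1e-7),
               S_mmp = stats::runif(1, 0, 1e-8), S_aga = stats::runif(1, 0, 1e-8))
    # zero one species at a time; its rate must be >= 0
    for (s in setdiff(SPECIES, "col")) {
      st2 <- st; st2[[s]] <- 0
      r <- reaction_rates(st2, 1e13, p)
      expect_gte(r[[s]], 0)
    }
  }
})

test_that("registry validates, prints, and round-trips through CSV", {
  p <- kinetic_parameters()
  expect_error(kinetic_parameters(bogus = 1), "unknown parameter")
  expect_error(kinetic_parameters(K_m_mmp = 0), "must be positive")
  expect_error(kinetic_parameters(D_mmp = -1), "non-negative")
  p2 <- set_param(p, "k_mmp_cold", 1e-3)
  expect_equal(p2$k_mmp_cold, 1e-3)
  expect_equal(attr(p2, "provenance")[["k_mmp_cold"]], "calibrated")
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_registry(p, path)
  back <- read_parameter_registry(path)
  expect_equal(unclass(back)[names(p)], unclass(p)[names(p)])
  expect_identical(attr(back, "provenance"), attr(p, "provenance"))
})

test_that("shipped frozen registry equals the in-code defaults", {
  path <- system.file("extdata", "params_reference.csv",
                      package = "cartdegen")
  expect_true(nzchar(path))
  frozen <- read_parameter_registry(path)
  p <- kinetic_parameters()
  expect_equal(unclass(frozen)[names(p)], unclass(p)[names(p)])
})

test_that("every rate term passes the dimensional audit", {
  expect_true(audit_units(kinetic_parameters()))
  # a corrupted unit is caught
  p <- kinetic_parameters()
  u <- attr(p, "units"); u[["k_rate_mmp"]] <- "m s-1"
  attr(p, "units") <- u
  expect_error(audit_units(p), "unit audit failed")
})
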