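test_that("Muller-Brown deepest minimum matches the grid+Newton oracle", {
  mb <- muller_brown()
  oracle <- oracle_stationary_2d(mb, c(-1.8, 1.2), c(-0.5, 2.2), n = 40,
                                 kind = "minimum")
  expect_gte(length(oracle), 3)        # the three known MB minima
  deepest <- oracle[[1]]
  expect_lt(max(abs(deepest$x - c(-0.558, 1.442))), 1e-2)
  r <- minimize(mb, c(0, 1.5), tol = 1e-9, with_hessian = FALSE)
  expect_true(r$converged)
  expect_lt(max(abs(r$x - deepest$x)), 1e-6)
  expect_lt(abs(r$energy - deepest$energy), 1e-8)
})

test_that("fixture surface gradients match finite differences", {
  surfaces <- list(muller_brown(), model_azo_internal())
  pts <- list(list(c(0.3, 0.8), c(-0.7, 1.4), c(0.5, 0.1)),
              list(c(37, 120, 131), c(90, 128, 128), c(170, 150, 118)))
  for (k in seq_along(surfaces)) {
    for (x in pts[[k]]) {
      for (state in c("s0", "t1")) {
        ev <- surface_eval(surfaces[[k]], x)
        g_an <- if (state == "s0") ev$g_s0 else ev$g_t1
        g_fd <- surface_fd_gradient(surfaces[[k]], x, state)
        expect_lt(max(abs(g_an - g_fd)) / max(abs(g_fd), 1), 1e-5)
      }
    }
  }
  # toy Cartesian surface at random thermally perturbed geometries
  surf <- toy_surface()
  set.seed(11)
  for (k in 1:20) {
    x <- as_coord_vector(surf$reference(sample(c("cis", "trans"), 1))) +
      rnorm(surf$dimensionality, sd = 0.05)
    ev <- surface_eval(surf, x)
    g_fd <- surface_fd_gradient(surf, x, "s0")
    expect_lt(max(abs(ev$g_s0 - g_fd)) / max(abs(g_fd)), 1e-4)
    g_fdt <- surface_fd_gradient(surf, x, "t1")
    expect_lt(max(abs(ev$g_t1 - g_fdt)) / max(abs(g_fdt)), 1e-4)
  }
})

test_that("gradient at the located minimum is numerically zero", {
  mb <- muller_brown()
  r <- minimize(mb, c(0, 1.5), tol = 1e-9, with_hessian = FALSE)
  expect_lt(max(abs(surface_eval(mb, r$x)$g_s0)), 1e-8)
})

test_that("azo model has the triplet topology of the two-state picture", {
  ms <- model_azo_internal()
  # T1 below S0 at the perpendicular geometry
  ev90 <- surface_eval(ms, c(90, 120, 120))
  expect_lt(ev90$e_t1 - ev90$e_s0, 0)
  # T1 above S0 at both planar endpoints (isomerization completes on S0)
  ev0 <- surface_eval(ms, c(0, 115, 115))
  ev180 <- surface_eval(ms, c(180, 115, 115))
  expect_gt(ev0$e_t1 - ev0$e_s0, 0)
  expect_gt(ev180$e_t1 - ev180$e_s0, 0)
})

test_that("minimum seam energy lies below the rotational saddle energy", {
  ms <- model_azo_internal()
  sc <- relaxed_scan(ms, c(0, 115, 115), "omega", seq(0, 180, 10))
  ts <- evf_saddle(ms, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-8)
  expect_true(ts$converged)
  # seam = {omega = 70} and {omega = 105} planes; minimize S0 on each
  e_seam <- vapply(c(70, 105), function(w) {
    r <- minimize(ms, c(w, 120, 120), tol = 1e-8, mask = c(2L, 3L),
                  with_hessian = FALSE)
    r$energy
  }, numeric(1))
  expect_lt(min(e_seam), ts$energy)
  expect_lt(max(e_seam), ts$energy)
})

test_that("seam crossings along the rotation path sit at 70 and 105 deg", {
  ms <- model_azo_internal()
  # scan the gap along the relaxed rotation path
  # grid offset so no point lands exactly on a zero of the gap
  sc <- relaxed_scan(ms, c(0, 115, 115), "omega", seq(51, 129, 2.5))
  gaps <- vapply(sc$reports, function(r) {
    ev <- surface_eval(ms, r$x); ev$e_t1 - ev$e_s0
  }, numeric(1))
  sgn <- sign(gaps)
  flips <- which(diff(sgn) != 0)
  expect_length(flips, 2)
  w_flip <- sc$grid[flips]
  expect_true(w_flip[1] > 60 && w_flip[1] < 80)
  expect_true(w_flip[2] > 95 && w_flip[2] < 115)
})

test_that("calibrated rotational barrier from cis is locked at ~29", {
  ms <- model_azo_internal()
  cis <- minimize(ms, c(0, 115, 115), tol = 1e-8, with_hessian = FALSE)
  sc <- relaxed_scan(ms, cis$x, "omega", seq(0, 180, 10))
  ts <- evf_saddle(ms, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-8)
  expect_true(ts$converged)
  expect_equal(ts$energy - cis$energy, 29.0, tolerance = 0.01)
})

test_that("toy Cartesian references have the constructed geometry", {
  surf <- toy_surface()
  mt <- measure_cnnc(surf$reference("trans"))
  expect_lt(abs(abs(mt$omega) - 180), 2)
  mc <- measure_cnnc(surf$reference("cis"))
  expect_lt(abs(mc$omega), 2)
  # cis is metastable: higher S0 energy than trans
  e_cis <- surface_eval(surf, as_coord_vector(surf$reference("cis")))$e_s0
  e_trans <- surface_eval(surf,
                          as_coord_vector(surf$reference("trans")))$e_s0
  expect_gt(e_cis - e_trans, 0)
})

test_that("toy Cartesian energy is invariant under rigid-body motion", {
  surf <- toy_surface()
  x <- as_coord_vector(surf$reference("cis"))
  e0 <- surface_eval(surf, x)$e_s0
  set.seed(5)
  for (k in 1:6) {
    R <- random_rotation()
    p <- matrix(x, ncol = 3, byrow = TRUE) %*% R
    p <- p + matrix(rnorm(3), nrow(p), 3, byrow = TRUE)
    expect_lt(abs(surface_eval(surf, as.numeric(t(p)))$e_s0 - e0), 1e-9)
  }
})

test_that("invalid toy sizes are rejected; valid sizes work", {
  expect_error(toy_azo_cartesian(0), "n_ring_atoms")
  expect_error(toy_azo_cartesian(4), "n_ring_atoms")
  s2 <- toy_azo_cartesian(2)
  expect_equal(s2$dimensionality, 3L * 8L)
  expect_lt(max(abs(surface_eval(s2, as_coord_vector(s2$reference("cis")))$g_s0 -
                      surface_fd_gradient(s2, as_coord_vector(s2$reference("cis"))))),
            1e-4)
})

test_that("surface contract rejects wrong coordinate lengths", {
  mb <- muller_brown()
  expect_error(surface_eval(mb, c(1, 2, 3)), "dimensionality")
})
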