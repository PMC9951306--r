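test_that("single harmonic oscillator frequency matches the closed form", {
  k <- 600; m <- 12.011
  ho <- two_state_surface("ho", 1L, "internal", function(x)
    list(e_s0 = 0.5 * k * x[1]^2, g_s0 = k * x[1], e_t1 = 500, g_t1 = 0),
    masses = m)
  r <- minimize(ho, 0.1, tol = 1e-10)
  va <- vibrational_analysis(ho, r, "minimum")
  kc <- azo_constants
  nu_cf <- sqrt(k * kc$J_per_kcal / kc$NA_avogadro * 1e20 /
                  (m * kc$amu_kg)) / (2 * pi * kc$c)
  expect_equal(va$frequencies, nu_cf, tolerance = 1e-6)
})

test_that("TS projection removes exactly the imaginary mode", {
  surf <- toy_surface()
  sc <- relaxed_scan(surf, toy_cis_min()$x, "omega", seq(0, 180, 20),
                     tol = 1e-5)
  m0 <- cartesian_driving_constraint(surf, "omega", 0)$grad(
    sc$reports[[sc$ts_guess_index]]$x)
  ts <- evf_saddle(surf, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-6,
                   trust = 0.05, mode0 = m0)
  expect_true(ts$converged)
  raw <- vibrational_analysis(surf, ts, "minimum")
  expect_equal(raw$n_imaginary, 1L)
  proj <- vibrational_analysis(surf, ts, "ts_projected")
  expect_equal(proj$n_imaginary, 0L)
  expect_equal(length(proj$frequencies), length(raw$frequencies) - 1L)
})

test_that("rigid-body projection leaves tiny residuals at toy minima", {
  surf <- toy_surface()
  r <- minimize(surf, toy_cis_min()$x, tol = 1e-6)
  va <- vibrational_analysis(surf, r, "minimum")
  expect_equal(length(va$projected_residual), 6L)
  expect_lt(max(va$projected_residual), 1e-2)
  expect_equal(length(va$frequencies), surf$dimensionality - 6L)
  expect_equal(va$n_imaginary, 0L)
})

test_that("vibrational analysis refuses non-converged reports", {
  surf <- toy_surface()
  bad <- minimize(surf, as_coord_vector(surf$reference("cis")),
                  tol = 1e-9, max_steps = 1L)
  expect_error(vibrational_analysis(surf, bad), "converged")
})

test_that("single-mode vibrational entropy matches the closed form", {
  nu <- 1000; Tt <- 298.15
  th <- thermo_from_frequencies(nu, 0, Tt, qh_cutoff = 0)
  kc <- azo_constants
  x <- kc$h * kc$c * nu / (kc$kB * Tt)
  S_cf <- kc$R_gas * (x / expm1(x) - log(-expm1(-x)))
  expect_equal(th$S, S_cf, tolerance = 1e-9)
  # G = H - T S identity
  expect_equal(th$G, th$H - Tt * th$S / kc$J_per_kcal,
               tolerance = 1e-10)
  # ZPE = h c nu / 2 per mode
  expect_equal(th$zpe,
               kc$h * kc$c * nu / 2 * kc$NA_avogadro / kc$J_per_kcal,
               tolerance = 1e-12)
})

test_that("qh_cutoff = 0 reproduces the pure harmonic result exactly", {
  freqs <- c(40, 90, 500, 1500)
  th0 <- thermo_from_frequencies(freqs, 0, qh_cutoff = 0)
  kc <- azo_constants
  x <- kc$h * kc$c * freqs / (kc$kB * 298.15)
  S_cf <- sum(kc$R_gas * (x / expm1(x) - log(-expm1(-x))))
  expect_identical(th0$S, S_cf)
})

test_that("raising the quasiharmonic cutoff never increases entropy", {
  freqs <- c(20, 60, 110, 400, 900)
  S <- vapply(c(0, 50, 100, 200), function(qc)
    thermo_from_frequencies(freqs, 0, qh_cutoff = qc)$S, numeric(1))
  expect_true(all(diff(S) <= 1e-12))
})

test_that("imaginary frequencies are excluded from thermal sums", {
  th <- thermo_from_frequencies(c(-500, 800), 10, qh_cutoff = 0)
  ref <- thermo_from_frequencies(800, 10, qh_cutoff = 0)
  expect_equal(th$n_imaginary, 1L)
  expect_equal(th$S, ref$S)
  expect_equal(th$zpe, ref$zpe)
})

test_that("vibrational entropy approaches the classical limit at low frequency", {
  kc <- azo_constants
  Tt <- 298.15
  for (nu in c(5, 1, 0.2)) {
    th <- thermo_from_frequencies(nu, 0, Tt, qh_cutoff = 0)
    x <- kc$h * kc$c * nu / (kc$kB * Tt)
    S_classical <- kc$R_gas * (1 - log(x))
    expect_lt(abs(th$S - S_classical) / S_classical, x)
  }
})

test_that("negative temperature is rejected", {
  expect_error(thermo_from_frequencies(100, 0, T = -5), "positive")
})

test_that("ensemble free energy follows the Boltzmann closed forms", {
  kc <- azo_constants
  RT <- kc$R_gas * 298.15 / kc$J_per_kcal
  # single member: identity
  expect_equal(ensemble_free_energy(5.0), 5.0)
  # m equal members: G - RT ln m
  expect_equal(ensemble_free_energy(rep(2, 4)), 2 - RT * log(4),
               tolerance = 1e-12)
  # dominance: one member 10 kcal/mol below the rest
  expect_equal(ensemble_free_energy(c(1, 11, 11, 11)), 1,
               tolerance = 1e-4)
})

test_that("ensemble free energy checks temperatures", {
  a <- thermo_from_frequencies(500, 0, T = 298.15)
  b <- thermo_from_frequencies(500, 0, T = 310)
  expect_error(ensemble_free_energy(list(a, b), T = 298.15), "mixed")
  expect_equal(ensemble_free_energy(list(a), T = 298.15), a$G)
  expect_error(ensemble_free_energy(list(), 298.15), "empty")
})

test_that("free-energy differences ignore the electronic-energy zero", {
  freqs1 <- c(120, 340, 900)
  freqs2 <- c(80, 410, 1100)
  d0 <- thermo_from_frequencies(freqs2, 7)$G -
    thermo_from_frequencies(freqs1, 2)$G
  shift <- 1234.5
  d1 <- thermo_from_frequencies(freqs2, 7 + shift)$G -
    thermo_from_frequencies(freqs1, 2 + shift)$G
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("seam-projected MECP thermochemistry drops one mode", {
  surf <- toy_surface()
  sc <- relaxed_scan(surf, toy_cis_min()$x, "omega", seq(0, 180, 20),
                     tol = 1e-5)
  m0 <- cartesian_driving_constraint(surf, "omega", 0)$grad(
    sc$reports[[sc$ts_guess_index]]$x)
  ts <- evf_saddle(surf, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-6,
                   trust = 0.05, mode0 = m0)
  path <- irc(surf, ts, step_size = 0.2, max_points = 500, tol = 1e-3)
  seeds <- c(locate_seam_crossings(path$forward),
             locate_seam_crossings(path$backward))
  expect_gte(length(seeds), 1)
  m <- mecp_optimize(surf, seeds[[1]]$x, tol_gap = 1e-5, tol_grad = 1e-4)
  expect_true(m$converged)
  va <- vibrational_analysis(surf, m, "mecp_seam_projected")
  expect_equal(length(va$frequencies), surf$dimensionality - 7L)
  expect_equal(va$n_imaginary, 0L)
})
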