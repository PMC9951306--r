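# 1-D double well V = x^4 - 2 x^2 embedded as a two-state surface
.double_well <- function() {
  two_state_surface("double_well", 1L, "internal", function(x)
    list(e_s0 = x[1]^4 - 2 * x[1]^2, g_s0 = 4 * x[1]^3 - 4 * x[1],
         e_t1 = 500, g_t1 = 0))
}

.quad_bowl <- function(A = diag(c(2, 5))) {
  two_state_surface("bowl", 2L, "internal", function(x)
    list(e_s0 = 0.5 * sum(x * (A %*% x)), g_s0 = as.numeric(A %*% x),
         e_t1 = 500, g_t1 = c(0, 0)))
}

test_that("minimization of a quadratic bowl reaches the origin", {
  r <- minimize(.quad_bowl(), c(3, -4), tol = 1e-8)
  expect_true(r$converged)
  expect_lt(max(abs(r$x)), 1e-7)
  expect_lt(abs(r$energy), 1e-12)
  expect_equal(r$n_imaginary, 0L)
})

test_that("starting exactly at a minimum converges immediately", {
  r <- minimize(.quad_bowl(), c(0, 0), tol = 1e-8, with_hessian = FALSE)
  expect_true(r$converged)
  expect_lte(r$n_steps, 1L)
  expect_equal(r$x, c(0, 0))
})

test_that("non-convergence returns a flagged partial report, no error", {
  r <- minimize(.quad_bowl(), c(3, -4), tol = 1e-8, max_steps = 2L,
                with_hessian = FALSE)
  expect_false(r$converged)
  expect_equal(r$reason, "step_limit")
})

test_that("hessian_fd recovers a known quadratic form and is symmetric", {
  A <- matrix(c(4, 1, 1, 3), 2, 2)
  H <- hessian_fd(.quad_bowl(A), c(0.3, -0.2))
  expect_lt(max(abs(H - A)) / max(abs(A)), 1e-6)
  expect_identical(H, t(H))
})

test_that("hessian_fd matches analytic Muller-Brown second derivatives", {
  mb <- muller_brown()
  # closed-form Hessian of the four-Gaussian sum (independent oracle)
  p <- mb$params$scale
  A <- c(-200, -100, -170, 15) * p
  a <- c(-1, -1, -6.5, 0.7); b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1); y0 <- c(0, 0.5, 1.5, 1)
  mb_hess <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    term <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    u <- 2 * a * dx + b * dy
    v <- b * dx + 2 * cc * dy
    hxx <- sum(term * (u^2 + 2 * a))
    hxy <- sum(term * (u * v + b))
    hyy <- sum(term * (v^2 + 2 * cc))
    matrix(c(hxx, hxy, hxy, hyy), 2, 2)
  }
  set.seed(3)
  for (k in 1:5) {
    x <- c(runif(1, -1.5, 1), runif(1, -0.2, 2))
    Ha <- mb_hess(x)
    Hn <- hessian_fd(mb, x, step = 1e-4)
    expect_lt(max(abs(Hn - Ha)) / max(abs(Ha)), 1e-4)
  }
})

test_that("relaxed scan of the 1-D double well peaks at the grid point nearest 0", {
  dw <- .double_well()
  grid <- seq(-1.2, 1.2, length.out = 25)
  sc <- relaxed_scan(dw, -1.2, 1, grid)
  expect_equal(sc$ts_guess_index, which.min(abs(grid)))
})

test_that("omega scan of the azo model peaks near 90 degrees", {
  ms <- model_azo_internal()
  sc <- relaxed_scan(ms, c(0, 115, 115), "omega", seq(0, 180, 10))
  expect_lt(abs(sc$grid[sc$ts_guess_index] - 90), 11)
})

test_that("alpha scan of the azo model peaks near 180 degrees", {
  ms <- model_azo_internal()
  sc <- relaxed_scan(ms, c(0, 115, 115), "alpha", seq(115, 180, 5))
  expect_lt(abs(sc$grid[sc$ts_guess_index] - 180), 6)
})

test_that("scan constraint is satisfied to 0.1 degree on Cartesian surfaces", {
  surf <- toy_surface()
  sc <- relaxed_scan(surf, toy_cis_min()$x, "omega", seq(0, 60, 20),
                     tol = 1e-5)
  for (k in seq_along(sc$grid)) {
    g <- from_coord_vector(sc$reports[[k]]$x, surf$reference("cis"))
    d <- (measure_cnnc(g)$omega - sc$grid[k] + 180) %% 360 - 180
    expect_lt(abs(d), 0.1)
  }
})

test_that("EVF refines the double-well barrier to the exact saddle", {
  dw <- .double_well()
  ts <- evf_saddle(dw, 0.3, tol = 1e-10)
  expect_true(ts$converged)
  expect_lt(abs(ts$x), 1e-8)
  expect_lt(abs(ts$energy), 1e-12)
  expect_equal(ts$n_imaginary, 1L)
})

test_that("EVF finds the Muller-Brown saddle located by the oracle", {
  mb <- muller_brown()
  oracle <- oracle_stationary_2d(mb, c(-1.2, 0.6), c(0, 1.8), n = 30,
                                 kind = "saddle")
  expect_gte(length(oracle), 1)
  # the saddle between the two lower minima, near (-0.822, 0.624)
  d <- vapply(oracle, function(s)
    sum((s$x - c(-0.822, 0.624))^2), numeric(1))
  sad <- oracle[[which.min(d)]]
  ts <- evf_saddle(mb, c(-0.7, 0.6), tol = 1e-9, trust = 0.05)
  expect_true(ts$converged)
  expect_lt(max(abs(ts$x - sad$x)), 1e-5)
  expect_lt(abs(ts$energy - sad$energy), 1e-5)
})

test_that("EVF on the azo rotation barrier has exactly one imaginary mode", {
  ms <- model_azo_internal()
  sc <- relaxed_scan(ms, c(0, 115, 115), "omega", seq(0, 180, 10))
  ts <- evf_saddle(ms, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-8)
  expect_true(ts$converged)
  expect_equal(ts$n_imaginary, 1L)
  # fine-grid relaxed-scan oracle for the saddle omega
  scf <- relaxed_scan(ms, c(80, 125, 125), "omega", seq(80, 95, 0.25))
  w_oracle <- scf$grid[scf$ts_guess_index]
  expect_lt(abs(ts$x[1] - w_oracle), 5)
})

test_that("EVF walking into a minimum reports failure with a reason", {
  ts <- evf_saddle(.quad_bowl(), c(0.4, 0.4), tol = 1e-8, max_steps = 60)
  expect_false(ts$converged)
  expect_true(ts$reason %in%
                c("converged_to_minimum", "step_limit"))
})

test_that("IRC from the double-well saddle reaches both minima at +-1", {
  dw <- .double_well()
  ts <- evf_saddle(dw, 0.3, tol = 1e-10)
  path <- irc(dw, ts, step_size = 0.01, max_points = 2000, tol = 1e-8)
  ends <- sort(c(tail(attr(path$forward, "coords")[, 1], 1),
                 tail(attr(path$backward, "coords")[, 1], 1)))
  expect_equal(ends, c(-1, 1), tolerance = 1e-4)
})

test_that("IRC energies are monotonically non-increasing per branch", {
  ms <- model_azo_internal()
  sc <- relaxed_scan(ms, c(0, 115, 115), "omega", seq(0, 180, 10))
  ts <- evf_saddle(ms, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-8)
  path <- irc(ms, ts, step_size = 0.5, max_points = 2000, tol = 1e-6)
  expect_true(all(diff(path$forward$e_s0) <= 1e-8))
  expect_true(all(diff(path$backward$e_s0) <= 1e-8))
  expect_true(all(diff(path$forward$arc_length) > 0))
  # endpoints at the cis and trans basins
  w_ends <- sort(abs(c(tail(attr(path$forward, "coords")[, 1], 1),
                       tail(attr(path$backward, "coords")[, 1], 1))))
  expect_lt(w_ends[1], 5)
  expect_gt(w_ends[2], 175)
})

test_that("Muller-Brown IRC connects the saddle to its two minima", {
  mb <- muller_brown()
  ts <- evf_saddle(mb, c(-0.7, 0.6), tol = 1e-9, trust = 0.05)
  path <- irc(mb, ts, step_size = 0.01, max_points = 4000, tol = 1e-7)
  mins <- oracle_stationary_2d(mb, c(-1.8, 1.2), c(-0.5, 2.2), n = 40,
                               kind = "minimum")
  e1 <- tail(attr(path$forward, "coords"), 1)
  e2 <- tail(attr(path$backward, "coords"), 1)
  d_to_min <- function(e) min(vapply(mins, function(m)
    sqrt(sum((m$x - e)^2)), numeric(1)))
  expect_lt(d_to_min(as.numeric(e1)), 1e-3)
  expect_lt(d_to_min(as.numeric(e2)), 1e-3)
  # no singlet-triplet crossing anywhere on a single-state fixture
  expect_length(locate_seam_crossings(path$forward), 0)
})

test_that("seam crossing detection finds sign changes by interpolation", {
  gaps <- c(2, 1, -1, -2, -1, 1)
  df <- data.frame(arc_length = 1:6, e_s0 = 0, e_t1 = gaps, gap = gaps)
  attr(df, "coords") <- matrix(1:6, ncol = 1)
  seeds <- locate_seam_crossings(df)
  expect_length(seeds, 2)
  expect_equal(seeds[[1]]$arc_length, 2.5)    # halfway between 2 and 3
  expect_equal(seeds[[2]]$arc_length, 5.5)
  # all-positive gap -> no crossing
  df2 <- df; df2$gap <- abs(gaps) + 1
  expect_length(locate_seam_crossings(df2), 0)
  # exact zero returned as-is
  df3 <- df; df3$gap <- c(1, 0, 1, 1, 1, 1)
  s3 <- locate_seam_crossings(df3)
  expect_length(s3, 1)
  expect_equal(s3[[1]]$gap, 0)
})

test_that("IRC through the rotational saddle yields crossings at 70/105", {
  ms <- model_azo_internal()
  sc <- relaxed_scan(ms, c(0, 115, 115), "omega", seq(0, 180, 10))
  ts <- evf_saddle(ms, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-8)
  path <- irc(ms, ts, step_size = 0.5, max_points = 2000, tol = 1e-6)
  seeds <- c(locate_seam_crossings(path$forward),
             locate_seam_crossings(path$backward))
  expect_length(seeds, 2)
  ws <- sort(vapply(seeds, function(s) s$x[1], numeric(1)))
  expect_true(ws[1] > 60 && ws[1] < 80)
  expect_true(ws[2] > 95 && ws[2] < 115)
})

test_that("MECP of two paraboloids lands at the algebraic solution", {
  tp <- two_state_surface("tp", 2L, "internal", function(x)
    list(e_s0 = x[1]^2 + x[2]^2, g_s0 = c(2 * x[1], 2 * x[2]),
         e_t1 = (x[1] - 2)^2 + x[2]^2 + 1,
         g_t1 = c(2 * (x[1] - 2), 2 * x[2])))
  m <- mecp_optimize(tp, c(1, 0.5), tol_gap = 1e-6, tol_grad = 1e-6)
  expect_true(m$converged)
  expect_lt(max(abs(m$x - c(1.25, 0))), 1e-5)
  expect_lt(abs(m$e_s0 - 1.5625), 1e-6)
  expect_lt(abs(m$gap), 1e-6)
})

test_that("converged MECPs satisfy gap and projected-gradient conditions", {
  ms <- model_azo_internal()
  sc <- relaxed_scan(ms, c(0, 115, 115), "omega", seq(0, 180, 10))
  ts <- evf_saddle(ms, sc$reports[[sc$ts_guess_index]]$x, tol = 1e-8)
  path <- irc(ms, ts, step_size = 0.5, max_points = 2000, tol = 1e-6)
  seeds <- c(locate_seam_crossings(path$forward),
             locate_seam_crossings(path$backward))
  for (s in seeds) {
    m <- mecp_optimize(ms, s$x, tol_gap = 1e-6, tol_grad = 1e-6)
    expect_true(m$converged)
    expect_lt(abs(m$e_s0 - m$e_t1), 1e-6)
    # first-order condition: mean gradient projected off ghat_diff
    dg <- m$g_diff / sqrt(sum(m$g_diff^2))
    gm <- (m$g_s0 + m$g_t1) / 2
    gproj <- gm - sum(gm * dg) * dg
    expect_lt(max(abs(gproj)), 1e-6)
    # crossing point below the rotational saddle
    expect_lt(m$e_s0, ts$energy)
  }
})

test_that("IRC refuses saddle reports without one imaginary mode", {
  r <- minimize(.quad_bowl(), c(1, 1), tol = 1e-8)
  expect_error(irc(.quad_bowl(), r), "exactly one imaginary")
})
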