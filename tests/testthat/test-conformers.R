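test_that("torsion enumeration matches an exhaustive-grid oracle count", {
  surf <- toy_surface()
  # TS-region structure with the core frozen; one free cap torsion per
  # side, each under a 2-fold potential -> the oracle counts the basins
  ts_guess <- from_coord_vector(toy_cis_min()$x, surf$reference("cis"),
                                tag = "guess")
  cs <- generate_ts_conformers(surf, ts_guess, n_target = 0, seed = 1)
  # oracle: constrained minimization from a dense 36-point grid of one
  # cap torsion (the other held at its reference), counting distinct
  # outcomes by the same RMSD criterion
  p0 <- ts_guess$coords
  core <- surf$core
  axis <- p0[core[["N1"]], ] - p0[core[["C1"]], ]
  n <- surf$dimensionality
  core_coords <- unlist(lapply(core, function(a) (a - 1) * 3 + 1:3))
  mask <- setdiff(seq_len(n), core_coords)
  outcomes <- list()
  for (ang in seq(0, 350, 10)) {
    p <- azokin:::.rotate_atoms(p0, surf$side_atoms[[1]],
                                p0[core[["C1"]], ], axis, ang)
    r <- minimize(surf, as.numeric(t(p)), tol = 1e-5, mask = mask,
                  with_hessian = FALSE)
    if (!r$converged) next
    # grid points at exact torsion maxima relax onto the ridge; a true
    # conformer must be a constrained minimum (no negative curvature in
    # the free block)
    Hf <- hessian_fd(surf, r$x)[mask, mask]
    if (min(eigen(Hf, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-4) next
    g <- from_coord_vector(r$x, ts_guess)
    dup <- any(vapply(outcomes, function(o)
      heavy_atom_rmsd(o, g) < 0.25, logical(1)))
    if (!dup) outcomes[[length(outcomes) + 1L]] <- g
  }
  # enumeration explores both sides; the oracle only side 1, so compare
  # against the side-1 slice: conformers sharing side-2 positions
  side2_ref <- ts_guess$coords[surf$side_atoms[[2]], , drop = FALSE]
  side1_variants <- Filter(function(cf)
    max(abs(cf$coords[surf$side_atoms[[2]], ] - side2_ref)) < 0.2,
    cs$conformers)
  expect_equal(length(side1_variants), length(outcomes))
  expect_lte(length(cs$conformers), 9)   # 3 x 3 enumeration ceiling
})

test_that("frozen-core conformers preserve the core coordinates exactly", {
  surf <- toy_surface()
  ts_guess <- from_coord_vector(toy_cis_min()$x, surf$reference("cis"))
  mc0 <- measure_cnnc(ts_guess)
  cs <- generate_ts_conformers(surf, ts_guess, n_target = 4, seed = 7)
  expect_gte(length(cs$conformers), 1)
  for (cf in cs$conformers) {
    mc <- measure_cnnc(cf)
    expect_lt(abs(mc$omega - mc0$omega), 0.1)
    expect_lt(abs(mc$alpha - mc0$alpha), 0.1)
    expect_lt(abs(mc$alpha_prime - mc0$alpha_prime), 0.1)
  }
  expect_false(is.unsorted(cs$energies))
})

test_that("duplicates are removed keeping the lower-energy member", {
  surf <- toy_surface()
  g <- from_coord_vector(toy_cis_min()$x, surf$reference("cis"))
  set <- structure(list(conformers = list(g, g),
                        energies = c(2.0, 1.0),
                        provenance = "perturbation_sampling",
                        discovery = 1:2),
                   class = "azo_conformers")
  dd <- dedup_conformers(set)
  expect_length(dd$conformers, 1)
  expect_equal(dd$energies, 1.0)
})

test_that("dedup is idempotent", {
  surf <- toy_surface()
  ts_guess <- from_coord_vector(toy_cis_min()$x, surf$reference("cis"))
  cs <- generate_ts_conformers(surf, ts_guess, n_target = 4, seed = 3)
  dd <- dedup_conformers(cs)
  expect_equal(length(dd$conformers), length(cs$conformers))
  expect_equal(dd$energies, cs$energies)
})

test_that("conformer generation is deterministic for a fixed seed", {
  surf <- toy_surface()
  ts_guess <- from_coord_vector(toy_cis_min()$x, surf$reference("cis"))
  c1 <- generate_ts_conformers(surf, ts_guess, n_target = 3, seed = 11)
  c2 <- generate_ts_conformers(surf, ts_guess, n_target = 3, seed = 11)
  expect_equal(c1$energies, c2$energies)
  expect_equal(lapply(c1$conformers, `[[`, "coords"),
               lapply(c2$conformers, `[[`, "coords"))
})

test_that("select_lowest keeps the n smallest with stable tie-breaks", {
  surf <- toy_surface()
  g <- from_coord_vector(toy_cis_min()$x, surf$reference("cis"))
  mk <- function(E, disc) structure(
    list(conformers = rep(list(g), length(E)), energies = E,
         provenance = "torsion_enumeration", discovery = disc),
    class = "azo_conformers")
  s8 <- mk(c(5, 3, 8, 1, 7, 2, 6, 4), 1:8)
  expect_equal(select_lowest(s8, 5)$energies, c(1, 2, 3, 4, 5))
  # fewer members than requested -> all returned
  s3 <- mk(c(3, 1, 2), 1:3)
  expect_equal(select_lowest(s3, 5)$energies, c(1, 2, 3))
  # ties break by discovery order, giving a total order
  st <- mk(c(2, 1, 1, 2), 1:4)
  sel <- select_lowest(st, 4)
  expect_equal(sel$discovery, c(2L, 3L, 1L, 4L))
  expect_error(select_lowest(mk(numeric(0), integer(0)), 5), "empty")
})

test_that("at most 20 TS optimizations are scheduled for 4 mechanisms", {
  # 4 mechanisms x select_lowest(n = 5) caps the EVF workload
  n_sched <- 0
  for (mech in mechanism_labels()) {
    fake <- structure(list(conformers = as.list(1:8), energies = 1:8,
                           provenance = "torsion_enumeration",
                           discovery = 1:8),
                      class = "azo_conformers")
    n_sched <- n_sched + length(select_lowest(fake, 5)$conformers)
  }
  expect_lte(n_sched, 20)
})

test_that("superposed RMSD is zero for rigid copies", {
  g <- toy_surface()$reference("cis")
  g2 <- g
  R <- random_rotation()
  g2$coords <- g$coords %*% R + matrix(c(1, -2, 0.5), nrow(g$coords), 3,
                                       byrow = TRUE)
  expect_lt(heavy_atom_rmsd(g, g2), 1e-10)
})
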