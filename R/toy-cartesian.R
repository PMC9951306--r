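#' Toy Cartesian azo force field
#'
#' A full-dimensional (3N) Cartesian embedding of the analytic two-state
#' azo model: harmonic bonds and angles hold a C-N=N-C core plus one to
#' three "ring" cap atoms per side together, a small 2-fold torsion acts
#' on the first cap torsion of each side (so conformer machinery has
#' distinct wells to find), and the two-state torsional/bending energy of
#' [model_azo_internal()] is evaluated on the (omega, alpha, alpha')
#' internal coordinates computed from the core Cartesians, with gradients
#' propagated by the chain rule. This gives the eigenvector-following,
#' IRC, MECP, Hessian and thermochemistry code paths a cheap but honest
#' 3N-dimensional testbed.
#'
#' Coordinate vectors are flattened atom-major: (x1, y1, z1, x2, ...).
#'
#' @param n_ring_atoms cap atoms per side, 1, 2 or 3 (6-10 atoms total).
#' @param params overrides forwarded to [model_azo_internal()].
#' @return a `two_state_surface` (Cartesian) with extra fields: `core`,
#'   `elements`, `masses`, `n_ring`, `side_atoms` (list of the movable
#'   cap-atom indices per side), `cap_torsions` (atom quadruples carrying
#'   the 2-fold torsion), and `reference(tag, omega)` generating
#'   deterministic "cis" / "trans" starting geometries.
#' @export
toy_azo_cartesian <- function(n_ring_atoms = 1L, params = list()) {
  n_ring_atoms <- as.integer(n_ring_atoms)
  if (!n_ring_atoms %in% 1:3)
    stop("configuration error: n_ring_atoms must be 1, 2 or 3")
  # torsional terms are gated by sin^4 of the CNN angles so the energy
  # stays C2-smooth when the core passes through collinearity at the
  # inversion transition state; b_rot is recalibrated for the gated
  # variant so the relaxed rotation barrier from cis stays ~29 kcal/mol
  model <- model_azo_internal(utils::modifyList(
    list(eps_gate = TRUE, b_rot = 94.2), params))
  natoms <- 4L + 2L * n_ring_atoms
  elements <- c("C", "N", "N", "C", rep("C", 2L * n_ring_atoms))
  masses <- atomic_mass(elements)
  core <- c(C1 = 1L, N1 = 2L, N2 = 3L, C2 = 4L)
  side1 <- if (n_ring_atoms > 0) 4L + seq_len(n_ring_atoms) else integer(0)
  side2 <- 4L + n_ring_atoms + seq_len(n_ring_atoms)

  # force-field terms
  kb <- 300; ka <- 60; kt <- 2.0
  bonds <- rbind(
    c(1, 2, 1.43), c(2, 3, 1.25), c(3, 4, 1.43))
  for (r in side1) bonds <- rbind(bonds, c(1, r, 1.50))
  for (r in side2) bonds <- rbind(bonds, c(4, r, 1.50))
  angles <- NULL                       # (i, j, k, theta0_deg), vertex j
  for (r in side1) angles <- rbind(angles, c(r, 1, 2, 120))
  for (r in side2) angles <- rbind(angles, c(r, 4, 3, 120))
  if (n_ring_atoms > 1) {
    for (s in list(c(1L, side1), c(4L, side2))) {
      ctr <- s[1]; caps <- s[-1]
      cmb <- utils::combn(caps, 2)
      for (k in seq_len(ncol(cmb)))
        angles <- rbind(angles, c(cmb[1, k], ctr, cmb[2, k], 110))
    }
  }
  cap_torsions <- rbind(c(side1[1], 1, 2, 3), c(side2[1], 4, 3, 2))

  get_p <- function(x) matrix(x, ncol = 3, byrow = TRUE)

  evaluate <- function(x) {
    p <- get_p(x)
    e <- 0
    grad <- matrix(0, natoms, 3)
    # bonds
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]; r0 <- bonds[b, 3]
      d <- p[j, ] - p[i, ]
      r <- sqrt(sum(d^2))
      e <- e + kb * (r - r0)^2
      f <- 2 * kb * (r - r0) * d / r
      grad[j, ] <- grad[j, ] + f
      grad[i, ] <- grad[i, ] - f
    }
    # angles (harmonic in radians)
    if (!is.null(angles)) for (a in seq_len(nrow(angles))) {
      i <- angles[a, 1]; j <- angles[a, 2]; k <- angles[a, 3]
      th <- .bond_angle(p[i, ], p[j, ], p[k, ]) * pi / 180
      th0 <- angles[a, 4] * pi / 180
      e <- e + ka * (th - th0)^2
      ga <- .angle_grad(p[i, ], p[j, ], p[k, ]) * pi / 180
      coefa <- 2 * ka * (th - th0)
      grad[i, ] <- grad[i, ] + coefa * ga[1, ]
      grad[j, ] <- grad[j, ] + coefa * ga[2, ]
      grad[k, ] <- grad[k, ] + coefa * ga[3, ]
    }
    # core internals first (the CNN-angle gates reuse them)
    cp <- p[core, , drop = FALSE]
    w <- .dihedral(cp[1, ], cp[2, ], cp[3, ], cp[4, ])
    al <- .bond_angle(cp[1, ], cp[2, ], cp[3, ])
    alp <- .bond_angle(cp[2, ], cp[3, ], cp[4, ])
    gal <- .angle_grad(cp[1, ], cp[2, ], cp[3, ])
    galp <- .angle_grad(cp[2, ], cp[3, ], cp[4, ])
    collinear <- !is.finite(w)
    gw <- if (collinear) matrix(0, 4, 3)
          else .dihedral_grad(cp[1, ], cp[2, ], cp[3, ], cp[4, ])
    d2r <- pi / 180
    a0 <- model$params$alpha0 * d2r
    # 2-fold cap torsions, gated by sin^2(CNN)/sin^2(a0) of their side
    for (t in seq_len(nrow(cap_torsions))) {
      q <- cap_torsions[t, ]
      ang <- if (t == 1) al else alp
      s4 <- sin(a0)^4
      gate <- sin(ang * d2r)^4 / s4
      dgate <- 4 * sin(ang * d2r)^3 * cos(ang * d2r) / s4 * d2r # per degree
      gang <- if (t == 1) gal else galp
      gang_atoms <- if (t == 1) core[1:3] else core[2:4]
      phi <- .dihedral(p[q[1], ], p[q[2], ], p[q[3], ], p[q[4], ]) * d2r
      if (!is.finite(phi)) next                       # gate is 0 here
      vt <- kt * (1 - cos(2 * phi)) / 2
      e <- e + gate * vt
      gd <- .dihedral_grad(p[q[1], ], p[q[2], ], p[q[3], ], p[q[4], ]) * d2r
      coeft <- gate * kt * sin(2 * phi)
      for (a in 1:4) grad[q[a], ] <- grad[q[a], ] + coeft * gd[a, ]
      for (a in 1:3) grad[gang_atoms[a], ] <- grad[gang_atoms[a], ] +
        dgate * vt * gang[a, ]
    }
    # two-state internal model on the core (omega-terms are gated inside
    # the model, so the collinear limit w -> anything is consistent)
    mev <- model$evaluate(c(if (collinear) 0 else w, al, alp))
    g_int_s0 <- matrix(0, natoms, 3)
    for (a in 1:4) g_int_s0[core[a], ] <- g_int_s0[core[a], ] +
      mev$g_s0[1] * gw[a, ]
    for (a in 1:3) {
      g_int_s0[core[a], ] <- g_int_s0[core[a], ] + mev$g_s0[2] * gal[a, ]
      g_int_s0[core[a + 1], ] <- g_int_s0[core[a + 1], ] +
        mev$g_s0[3] * galp[a, ]
    }
    e_s0 <- e + mev$e_s0
    g_s0 <- grad + g_int_s0
    # triplet: gap term depends on omega only
    dgap_dw <- mev$g_t1[1] - mev$g_s0[1]
    g_t1 <- g_s0
    for (a in 1:4) g_t1[core[a], ] <- g_t1[core[a], ] + dgap_dw * gw[a, ]
    list(e_s0 = e_s0, g_s0 = as.numeric(t(g_s0)),
         e_t1 = e + mev$e_t1, g_t1 = as.numeric(t(g_t1)),
         gap_s0s1 = mev$gap_s0s1)
  }

  reference <- function(tag = c("cis", "trans"), omega = NULL) {
    tag <- match.arg(tag)
    if (is.null(omega)) omega <- if (tag == "cis") 0 else 180
    a0 <- model$params$alpha0
    p <- matrix(0, natoms, 3)
    p[2, ] <- c(0, 0, 0)                              # N1
    p[3, ] <- c(0, 0, 1.25)                           # N2
    d2r <- pi / 180
    p[1, ] <- p[2, ] + 1.43 * c(sin(a0 * d2r), 0, cos(a0 * d2r))  # C1
    # C2 placed by NERF so dihedral C1-N1-N2-C2 = omega
    p[4, ] <- .place_atom(p[1, ], p[2, ], p[3, ], 1.43, a0, omega)
    for (k in seq_along(side1))
      p[side1[k], ] <- .place_atom(p[3, ], p[2, ], p[1, ], 1.50, 120,
                                   c(0, 120, -120)[k])
    for (k in seq_along(side2))
      p[side2[k], ] <- .place_atom(p[2, ], p[3, ], p[4, ], 1.50, 120,
                                   c(0, 120, -120)[k])
    geometry(elements, p, core = core, tag = tag)
  }

  two_state_surface(
    name = sprintf("toy_azo_cartesian_%d", n_ring_atoms),
    dimensionality = 3L * natoms, coordinate_kind = "cartesian",
    evaluate = evaluate,
    params = c(model$params, list(n_ring_atoms = n_ring_atoms,
                                  k_bond = kb, k_angle = ka, k_tors = kt)),
    elements = elements, masses = masses,
    core = core, n_ring = n_ring_atoms,
    side_atoms = list(side1, side2),
    cap_torsions = cap_torsions,
    reference = reference)
}

# NERF placement: new atom D at distance r from C, angle(D,C,B) = ang
# degrees, dihedral(D,C,B,A) = dih degrees (measured as .dihedral(A,B,C,D))
.place_atom <- function(pA, pB, pC, r, ang, dih) {
  d2r <- pi / 180
  ang <- ang * d2r; dih <- dih * d2r
  bc <- pC - pB; bc <- bc / sqrt(sum(bc^2))
  ab <- pB - pA
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- r * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  pC + d2[1] * bc + d2[2] * m + d2[3] * n
}

# helpers between geometry objects and flat coordinate vectors
#' Flatten a geometry to a surface coordinate vector (atom-major)
#' @param geom an `azo_geometry`
#' @return numeric vector (x1, y1, z1, x2, ...)
#' @export
as_coord_vector <- function(geom) as.numeric(t(geom$coords))

#' Rebuild a geometry from a flat coordinate vector
#' @param x coordinate vector
#' @param template `azo_geometry` supplying elements/core/charge
#' @param tag optional new tag
#' @return an `azo_geometry`
#' @export
from_coord_vector <- function(x, template, tag = template$tag) {
  geometry(template$elements, matrix(x, ncol = 3, byrow = TRUE),
           core = template$core, charge = template$charge, tag = tag,
           check = FALSE)
}
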