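#' @title Transition-state-region conformer generation
#' @description Generates, deduplicates and ranks conformers around a TS
#'   guess with the four C-N=N-C core atoms frozen in place, mirroring a
#'   conformational search with fixed CNNC atoms. Candidates come from
#'   systematic enumeration of non-core rotatable torsions at 120-degree
#'   increments plus seeded random perturbation, each followed by
#'   constrained minimization on the surface.
#' @name conformers
NULL

# Kabsch-superposed RMSD between two coordinate matrices (same atom order)
.kabsch_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' Heavy-atom RMSD after optimal superposition
#' @param g1,g2 `azo_geometry` objects with identical element lists.
#' @return RMSD in angstrom.
#' @export
heavy_atom_rmsd <- function(g1, g2) {
  if (!identical(g1$elements, g2$elements))
    stop("geometries must share the same element list")
  keep <- g1$elements != "H"
  .kabsch_rmsd(g1$coords[keep, , drop = FALSE],
               g2$coords[keep, , drop = FALSE])
}

# rotate the given atoms about the axis through `origin` with direction
# `axis` by `angle_deg` (Rodrigues)
.rotate_atoms <- function(coords, atoms, origin, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  for (a in atoms) {
    v <- coords[a, ] - origin
    coords[a, ] <- origin + v * cos(th) + .cross3(k, v) * sin(th) +
      k * sum(k * v) * (1 - cos(th))
  }
  coords
}

.conformer_set <- function(conformers, energies, provenance, discovery) {
  structure(list(conformers = conformers, energies = energies,
                 provenance = provenance, discovery = discovery),
            class = "azo_conformers")
}

#' @export
print.azo_conformers <- function(x, ...) {
  cat(sprintf("<azo_conformers> %d member(s), E in [%.4f, %.4f] kcal/mol\n",
              length(x$conformers),
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Deduplicate a conformer set by superposed RMSD
#'
#' Pairs closer than `rmsd_thr` keep only the lower-energy member (ties
#' break to the earlier discovery index). Idempotent. Members are
#' returned sorted by energy ascending.
#'
#' @param set an `azo_conformers` set.
#' @param rmsd_thr heavy-atom RMSD threshold in angstrom (default 0.25).
#' @return a deduplicated, energy-sorted `azo_conformers`.
#' @export
dedup_conformers <- function(set, rmsd_thr = 0.25) {
  n <- length(set$conformers)
  if (n <= 1) return(set)
  ord <- order(set$energies, set$discovery)
  keep <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in keep) {
      if (heavy_atom_rmsd(set$conformers[[i]], set$conformers[[j]]) <
          rmsd_thr) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  .conformer_set(set$conformers[keep], set$energies[keep],
                 set$provenance, set$discovery[keep])
}

#' Generate TS-region conformers with the CNNC core frozen
#'
#' Candidate structures are built by (a) systematic rotation of each
#' side's substituent atoms about its C-N axis in 120-degree increments
#' and (b) seeded Gaussian perturbation of all non-core atoms. Every
#' candidate is then minimized on the surface with the four core atoms'
#' positions frozen, so the core internal coordinates (omega, alpha,
#' alpha') are preserved exactly. The result is deduplicated by
#' superposed heavy-atom RMSD (lower energy wins) and sorted by energy.
#' Deterministic for a fixed seed.
#'
#' @param surface a Cartesian `two_state_surface` with `core` and
#'   `side_atoms` fields (e.g. [toy_azo_cartesian()]).
#' @param ts_guess an `azo_geometry` (or flat coordinate vector) of the
#'   TS guess.
#' @param n_target number of random-perturbation candidates (default 8).
#' @param seed RNG seed for the perturbation slice.
#' @param state electronic state minimized on.
#' @param freeze_core freeze the four core atoms (default TRUE; FALSE
#'   reuses the machinery for plain minimum conformer searches).
#' @param rmsd_thr deduplication threshold, angstrom.
#' @param perturb_sd Gaussian displacement scale, angstrom (default 0.15).
#' @param tol minimizer tolerance.
#' @return an `azo_conformers` set, energies ascending.
#' @export
generate_ts_conformers <- function(surface, ts_guess, n_target = 8L,
                                   seed = 1L, state = "s0",
                                   freeze_core = TRUE, rmsd_thr = 0.25,
                                   perturb_sd = 0.15, tol = 1e-5) {
  if (inherits(ts_guess, "azo_geometry")) {
    template <- ts_guess
    x0 <- as_coord_vector(ts_guess)
  } else {
    x0 <- as.numeric(ts_guess)
    template <- geometry(surface$elements,
                         matrix(x0, ncol = 3, byrow = TRUE),
                         core = surface$core, check = FALSE)
  }
  n <- surface$dimensionality
  core_idx <- surface$core
  core_coords <- unlist(lapply(core_idx, function(a) (a - 1) * 3 + 1:3))
  mask <- if (freeze_core) setdiff(seq_len(n), core_coords) else seq_len(n)
  p0 <- matrix(x0, ncol = 3, byrow = TRUE)

  # (a) torsion enumeration: each side's substituents about its C-N axis
  starts <- list(p0)
  sides <- surface$side_atoms
  if (!is.null(sides)) {
    axes <- list(
      list(origin = p0[core_idx[["C1"]], ],
           axis = p0[core_idx[["N1"]], ] - p0[core_idx[["C1"]], ]),
      list(origin = p0[core_idx[["C2"]], ],
           axis = p0[core_idx[["N2"]], ] - p0[core_idx[["C2"]], ]))
    grid <- expand.grid(rep(list(c(0, 120, 240)), length(sides)))
    starts <- lapply(seq_len(nrow(grid)), function(k) {
      p <- p0
      for (s in seq_along(sides)) {
        ang <- grid[k, s]
        if (ang != 0 && length(sides[[s]]))
          p <- .rotate_atoms(p, sides[[s]], axes[[s]]$origin,
                             axes[[s]]$axis, ang)
      }
      p
    })
  }
  prov <- rep("torsion_enumeration", length(starts))

  # (b) seeded random perturbation of the movable atoms
  if (n_target > 0) {
    set.seed(seed)
    move_atoms <- if (freeze_core) setdiff(seq_len(n %/% 3), core_idx)
                  else seq_len(n %/% 3)
    for (k in seq_len(n_target)) {
      p <- p0
      p[move_atoms, ] <- p[move_atoms, ] +
        matrix(stats::rnorm(3 * length(move_atoms), sd = perturb_sd),
               ncol = 3)
      starts[[length(starts) + 1L]] <- p
    }
    prov <- c(prov, rep("perturbation_sampling", n_target))
  }

  confs <- list(); energies <- numeric(0); provs <- character(0)
  for (k in seq_along(starts)) {
    r <- minimize(surface, as.numeric(t(starts[[k]])), state = state,
                  tol = tol, mask = mask, with_hessian = FALSE)
    if (!r$converged) next
    confs[[length(confs) + 1L]] <-
      from_coord_vector(r$x, template, tag = template$tag)
    energies <- c(energies, r$energy)
    provs <- c(provs, prov[k])
  }
  set <- .conformer_set(confs, energies,
                        provenance = unique(provs),
                        discovery = seq_along(confs))
  dedup_conformers(set, rmsd_thr)
}

#' Select the lowest-energy conformers
#'
#' First `min(n, size)` members by energy; stable order with ties broken
#' by the earlier discovery index.
#'
#' @param set an `azo_conformers` set.
#' @param n number to keep (default 5).
#' @return an `azo_conformers` subset.
#' @export
select_lowest <- function(set, n = 5L) {
  if (length(set$conformers) == 0) stop("empty conformer set")
  ord <- order(set$energies, set$discovery)
  keep <- ord[seq_len(min(n, length(ord)))]
  .conformer_set(set$conformers[keep], set$energies[keep],
                 set$provenance, set$discovery[keep])
}
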