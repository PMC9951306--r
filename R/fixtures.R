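#' @title Labeled fixture datasets from the toy surface
#' @description Samples labeled geometries (energies, forces, gaps) from
#'   an analytic Cartesian surface for training and evaluating the
#'   neural potential: base frames are taken along the relaxed rotation
#'   pathway (so the rotation barrier region is represented) and
#'   thermally displaced. Everything is deterministic for a fixed seed.
#' @name fixtures
NULL

#' Relaxed base frames along the rotation pathway
#'
#' Constrained-minimizes the surface at a grid of CNNC dihedrals,
#' warm-started from the cis reference; used as sampling centers.
#'
#' @param surface a Cartesian `two_state_surface` with a `reference`
#'   generator (e.g. [toy_azo_cartesian()]).
#' @param omega_grid dihedral grid, degrees.
#' @return list of list(x, omega) base frames.
#' @export
toy_base_frames <- function(surface, omega_grid = seq(0, 180, 15)) {
  x0 <- as_coord_vector(surface$reference("cis"))
  sc <- relaxed_scan(surface, x0, "omega", omega_grid, tol = 1e-5)
  lapply(seq_along(omega_grid), function(k)
    list(x = sc$reports[[k]]$x, omega = omega_grid[k]))
}

#' Sample a labeled dataset from an analytic surface
#'
#' Draws geometries by Gaussian displacement of pathway base frames and
#' labels them with the surface's energies and forces. Gap labels are
#' attached only to samples whose base frame lies near the cis or trans
#' end (within `gap_window` degrees of 0 or 180), emulating a gap head
#' trained on near-equilibrium structures only.
#'
#' @param surface a Cartesian `two_state_surface`.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param displacement_sd Gaussian displacement per coordinate, angstrom
#'   (default 0.03, the thermal scale of the stiff bond modes,
#'   sqrt(kT/k)).
#' @param base_frames optional precomputed [toy_base_frames()] output.
#' @param gap_window degrees from the planar endpoints within which gap
#'   labels are kept.
#' @return list of labeled records (elements, coords, e_s0, f_s0, e_t1,
#'   f_t1, gap, omega_base).
#' @export
sample_toy_dataset <- function(surface, n, seed = 1L,
                               displacement_sd = 0.03,
                               base_frames = NULL, gap_window = 20) {
  if (is.null(base_frames)) base_frames <- toy_base_frames(surface)
  elements <- surface$elements
  natom <- length(elements)
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    bf <- base_frames[[sample.int(length(base_frames), 1)]]
    x <- bf$x + stats::rnorm(3 * natom, sd = displacement_sd)
    ev <- surface_eval(surface, x)
    near_eq <- min(abs(bf$omega), abs(180 - abs(bf$omega))) <= gap_window
    list(elements = elements,
         coords = matrix(x, ncol = 3, byrow = TRUE),
         e_s0 = ev$e_s0,
         f_s0 = -matrix(ev$g_s0, ncol = 3, byrow = TRUE),
         e_t1 = ev$e_t1,
         f_t1 = -matrix(ev$g_t1, ncol = 3, byrow = TRUE),
         gap = if (near_eq) ev$gap_s0s1 else NA_real_,
         omega_base = bf$omega)
  })
}

#' Held-out S0 energy mean absolute error of an ensemble
#'
#' @param ensemble an `azo_ensemble`.
#' @param records labeled evaluation records.
#' @param keep_fraction evaluate only the `keep_fraction` of records
#'   with the lowest ensemble uncertainty (1 keeps all).
#' @return MAE in kcal/mol.
#' @export
energy_mae <- function(ensemble, records, keep_fraction = 1) {
  pred <- predict_ensemble(ensemble, records, forces = FALSE)
  err <- abs(pred$e_s0_mean -
               vapply(records, `[[`, numeric(1), "e_s0"))
  if (keep_fraction < 1) {
    n_keep <- max(1L, floor(length(err) * keep_fraction))
    keep <- order(pred$e_s0_std)[seq_len(n_keep)]
    err <- err[keep]
  }
  mean(err)
}

#' Held-out S0 force mean absolute error of an ensemble
#' @param ensemble an `azo_ensemble`.
#' @param records labeled evaluation records.
#' @return MAE in kcal/mol/angstrom.
#' @export
force_mae <- function(ensemble, records) {
  pred <- predict_ensemble(ensemble, records, forces = TRUE)
  errs <- vapply(seq_along(records), function(m)
    mean(abs(pred$forces_s0_mean[[m]] - records[[m]]$f_s0)), numeric(1))
  mean(errs)
}

#' Active-learning loop on an analytic surface
#'
#' Starting from an initial labeled dataset, repeatedly trains an
#' ensemble, selects new pool geometries by mixed
#' uncertainty/random/energy sampling, labels them with the surface (the
#' stand-in for new quantum-chemistry calculations), and retrains.
#'
#' @param surface labeling surface.
#' @param dataset initial labeled records.
#' @param pool unlabeled candidate records.
#' @param config a [potential_config()].
#' @param rounds selection/retraining rounds (default 2).
#' @param n_add labels added per round (default 200).
#' @param fractions selection mix, see [select_active_learning()].
#' @param eval_set held-out labeled records tracked across rounds.
#' @return list with `ensemble` (final), `mae` (held-out S0 energy MAE
#'   after round 0..rounds), `n_train` (dataset sizes).
#' @export
active_learn <- function(surface, dataset, pool, config, rounds = 2L,
                         n_add = 200L,
                         fractions = c(uncertainty = 0.5, random = 0.25,
                                       energy = 0.25),
                         eval_set) {
  label <- function(rec) {
    x <- as.numeric(t(rec$coords))
    ev <- surface_eval(surface, x)
    rec$e_s0 <- ev$e_s0
    rec$f_s0 <- -matrix(ev$g_s0, ncol = 3, byrow = TRUE)
    rec$e_t1 <- ev$e_t1
    rec$f_t1 <- -matrix(ev$g_t1, ncol = 3, byrow = TRUE)
    if (is.null(rec$gap)) rec$gap <- NA_real_
    rec
  }
  ens <- train_ensemble(dataset, config)
  mae <- energy_mae(ens, eval_set)
  n_train <- length(dataset)
  for (r in seq_len(rounds)) {
    sel <- select_active_learning(pool, ens, min(n_add, length(pool)),
                                  fractions, seed = config$seed + 100L + r)
    dataset <- c(dataset, lapply(pool[sel], label))
    pool <- pool[-sel]
    ens <- train_ensemble(dataset, config)
    mae <- c(mae, energy_mae(ens, eval_set))
    n_train <- c(n_train, length(dataset))
  }
  list(ensemble = ens, mae = mae, n_train = n_train)
}
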