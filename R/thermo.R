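#' @title Harmonic / quasiharmonic thermochemistry
#' @description Vibrational analysis on stationary reports (with
#'   rigid-body, transition-mode, or seam-normal projection) and ideal-gas
#'   rigid-rotor-harmonic-oscillator thermochemistry with a quasiharmonic
#'   entropy floor, plus Boltzmann aggregation over conformer ensembles.
#' @name thermo
NULL

# eigenvalue (kcal/mol / unit^2 / amu) -> signed wavenumber (cm^-1);
# negative output marks an imaginary mode
.eig_to_wavenumber <- function(lam) {
  k <- azo_constants
  w2 <- lam * k$J_per_kcal / k$NA_avogadro * 1e20 / k$amu_kg  # 1/s^2
  sign(lam) * sqrt(abs(w2)) / (2 * pi * k$c)
}

# orthonormalized mass-weighted rigid-body vectors (3 translations +
# 3 rotations; 5 for linear) at geometry `coords` with masses `m`
.rigid_body_basis <- function(coords, m) {
  n <- nrow(coords)
  sm <- sqrt(rep(m, each = 3))
  com <- colSums(coords * m) / sum(m)
  r <- sweep(coords, 2, com)
  vecs <- matrix(0, 3 * n, 6)
  for (d in 1:3) {                      # translations
    v <- matrix(0, n, 3); v[, d] <- 1
    vecs[, d] <- as.numeric(t(v)) * sm
  }
  for (d in 1:3) {                      # rotations about principal axes
    e <- c(0, 0, 0); e[d] <- 1
    v <- t(apply(r, 1, function(ri) .cross3(e, ri)))
    vecs[, 3 + d] <- as.numeric(t(v)) * sm
  }
  q <- qr(vecs)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

#' Vibrational analysis of a stationary report
#'
#' Diagonalizes the mass-weighted Hessian stored on the report. For
#' Cartesian surfaces the six rigid-body modes (five for linear systems)
#' are projected out first. `treatment = "ts_projected"` additionally
#' projects the imaginary (transition) mode before thermochemistry;
#' `"mecp_seam_projected"` projects the normalized mass-weighted
#' gradient-difference direction, the seam normal, which plays the role
#' of the reaction coordinate at a crossing point.
#'
#' @param surface the `two_state_surface` the report was computed on.
#' @param report a converged `azo_stationary` report carrying a Hessian.
#' @param treatment "minimum", "ts_projected" or "mecp_seam_projected".
#' @return list with `frequencies` (cm^-1, imaginary negative, projected
#'   modes removed), `projected_residual` (cm^-1 magnitudes of the
#'   removed modes; near zero when projection is clean), `n_imaginary`,
#'   and `treatment`.
#' @export
vibrational_analysis <- function(surface, report,
                                 treatment = c("minimum", "ts_projected",
                                               "mecp_seam_projected")) {
  treatment <- match.arg(treatment)
  if (!isTRUE(report$converged))
    stop("vibrational analysis requires a converged stationary report")
  if (is.null(report$hessian)) stop("report carries no Hessian")
  m3 <- .coord_masses(surface)
  sm <- sqrt(m3)
  Hmw <- report$hessian / outer(sm, sm)
  proj <- NULL
  if (surface$coordinate_kind == "cartesian") {
    coords <- matrix(report$x, ncol = 3, byrow = TRUE)
    proj <- .rigid_body_basis(coords, surface$masses)
  }
  if (treatment == "mecp_seam_projected") {
    if (is.null(report$g_diff))
      stop("seam projection needs the gradient difference on the report")
    seam <- report$g_diff / sm
    seam <- seam / sqrt(sum(seam^2))
    proj <- cbind(proj, seam)
  }
  apply_proj <- function(H, basis) {
    if (is.null(basis)) return(H)
    q <- qr(basis)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    P <- diag(nrow(H)) - Q %*% t(Q)
    P %*% H %*% P
  }
  Hp <- apply_proj(Hmw, proj)
  if (treatment == "ts_projected") {
    ed0 <- eigen(Hp, symmetric = TRUE)
    ts_mode <- ed0$vectors[, which.min(ed0$values)]
    proj <- cbind(proj, ts_mode)
    Hp <- apply_proj(Hmw, proj)
  }
  n_proj <- if (is.null(proj)) 0L else qr(proj)$rank
  ed <- eigen(Hp, symmetric = TRUE)
  freqs <- .eig_to_wavenumber(ed$values)
  ord <- order(abs(ed$values))
  removed <- ord[seq_len(n_proj)]
  list(frequencies = sort(if (n_proj) freqs[-removed] else freqs),
       projected_residual = abs(freqs[removed]),
       n_imaginary = sum(freqs[setdiff(seq_along(freqs), removed)] < 0),
       treatment = treatment)
}

#' RRHO thermochemistry from frequencies
#'
#' Ideal-gas rigid-rotor-harmonic-oscillator enthalpy, entropy and free
#' energy. Real frequencies below the quasiharmonic cutoff are floored to
#' the cutoff for the entropy term only; imaginary frequencies are
#' excluded from the thermal sums. Translational and rotational
#' contributions (1 atm, symmetry number 1) are included when a geometry
#' with masses is supplied, and omitted -- with the summary flagged --
#' for low-dimensional model surfaces.
#'
#' @param frequencies wavenumbers in cm^-1, imaginary as negative.
#' @param electronic_energy electronic energy, kcal/mol.
#' @param T temperature, K.
#' @param qh_cutoff quasiharmonic entropy floor, cm^-1 (default 100;
#'   0 recovers the pure harmonic result).
#' @param geom optional `azo_geometry` enabling translation/rotation terms.
#' @param treatment label propagated into the summary.
#' @return an `azo_thermo` summary: T, electronic_energy, zpe, H
#'   (kcal/mol), S (J/(mol K)), G = H - T S (kcal/mol), frequencies,
#'   n_imaginary, treatment, qh_cutoff, includes_trans_rot.
#' @export
thermo_from_frequencies <- function(frequencies, electronic_energy,
                                    T = 298.15, qh_cutoff = 100,
                                    geom = NULL, treatment = "minimum") {
  if (T <= 0) stop("temperature must be positive")
  k <- azo_constants
  real <- frequencies[frequencies > 0]
  n_imag <- sum(frequencies < 0)
  xs <- function(nu) k$h * k$c * nu / (k$kB * T)
  zpe <- sum(k$h * k$c * real / 2) * k$NA_avogadro / k$J_per_kcal
  x <- xs(real)
  h_vib_J <- sum(k$R_gas * T * x / expm1(x))
  nu_s <- pmax(real, qh_cutoff)
  xq <- xs(nu_s)
  s_vib <- sum(k$R_gas * (xq / expm1(xq) - log(-expm1(-xq))))
  h_tr_J <- 0; s_tr <- 0
  includes_tr <- FALSE
  if (!is.null(geom)) {
    includes_tr <- TRUE
    m <- atomic_mass(geom$elements)
    M <- sum(m) * k$amu_kg
    # translation (Sackur-Tetrode, 1 atm) + pV term in the enthalpy
    p0 <- 101325
    q_tr <- (2 * pi * M * k$kB * T / k$h^2)^1.5 * k$kB * T / p0
    s_tr <- k$R_gas * (log(q_tr) + 2.5)
    h_tr_J <- 2.5 * k$R_gas * T + 1.5 * k$R_gas * T   # trans + rot, + pV in trans
    # rotation: principal moments from the inertia tensor, sigma = 1
    com <- colSums(geom$coords * m) / sum(m)
    r <- sweep(geom$coords, 2, com) * 1e-10
    mkg <- m * k$amu_kg
    I <- matrix(0, 3, 3)
    for (a in seq_along(mkg)) {
      ra <- r[a, ]
      I <- I + mkg[a] * (sum(ra^2) * diag(3) - outer(ra, ra))
    }
    mom <- sort(eigen(I, symmetric = TRUE)$values)
    if (mom[1] / mom[3] < 1e-8) {       # linear
      B <- k$hbar^2 / (2 * mom[3])
      s_tr <- s_tr + k$R_gas * (log(k$kB * T / B) + 1)
      h_tr_J <- h_tr_J - 0.5 * k$R_gas * T
    } else {
      q_rot <- sqrt(pi * prod(2 * k$kB * T / k$hbar^2 * mom)) / 2
      s_tr <- s_tr + k$R_gas * (log(q_rot) + 1.5)
    }
  }
  H <- electronic_energy + zpe + (h_vib_J + h_tr_J) / k$J_per_kcal
  S <- s_vib + s_tr
  G <- H - T * S / k$J_per_kcal
  structure(list(T = T, electronic_energy = electronic_energy, zpe = zpe,
                 H = H, S = S, G = G, frequencies = frequencies,
                 n_imaginary = n_imag, treatment = treatment,
                 qh_cutoff = qh_cutoff, includes_trans_rot = includes_tr),
            class = "azo_thermo")
}

#' @export
print.azo_thermo <- function(x, ...) {
  cat(sprintf(
    "<azo_thermo> T=%.2fK E=%.4f ZPE=%.4f H=%.4f S=%.3f G=%.4f (%s)%s\n",
    x$T, x$electronic_energy, x$zpe, x$H, x$S, x$G, x$treatment,
    if (!x$includes_trans_rot) " [no trans/rot]" else ""))
  invisible(x)
}

#' Boltzmann ensemble free energy
#'
#' Aggregates conformer free energies as
#' G_ens = -RT ln sum_i exp(-G_i / RT), evaluated stably via
#' log-sum-exp. All members must share the same temperature.
#'
#' @param members list of `azo_thermo` summaries (or a numeric vector of
#'   free energies in kcal/mol).
#' @param T temperature, K (checked against the members).
#' @return ensemble free energy, kcal/mol.
#' @export
ensemble_free_energy <- function(members, T = 298.15) {
  if (length(members) == 0) stop("empty ensemble")
  if (is.list(members)) {
    Ts <- vapply(members, `[[`, numeric(1), "T")
    if (any(abs(Ts - T) > 1e-9))
      stop("mixed temperatures in ensemble")
    G <- vapply(members, `[[`, numeric(1), "G")
  } else {
    G <- as.numeric(members)
  }
  RT <- azo_constants$R_gas * T / azo_constants$J_per_kcal
  gmin <- min(G)
  gmin - RT * log(sum(exp(-(G - gmin) / RT)))
}
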