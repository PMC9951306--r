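#' Two-state potential-energy surface contract
#'
#' A `two_state_surface` bundles a deterministic evaluator that returns,
#' for a coordinate vector, the singlet ground-state (S0) energy and
#' gradient, the lowest triplet (T1) energy and gradient, and optionally a
#' vertical S0/S1 excitation gap. Energies are in kcal/mol; gradients in
#' kcal/mol per angstrom (Cartesian surfaces) or per coordinate unit
#' (low-dimensional model surfaces).
#'
#' @param name surface name.
#' @param dimensionality number of coordinates.
#' @param coordinate_kind "internal" or "cartesian".
#' @param evaluate function(x) returning a list with e_s0, g_s0, e_t1,
#'   g_t1 and optionally gap_s0s1.
#' @param params named list of surface parameters, kept for provenance.
#' @param elements,masses for Cartesian surfaces: element symbols and
#'   atomic masses (amu) of the atoms, in coordinate order.
#' @param ... additional fields stored on the surface (e.g. reference
#'   geometry generators).
#' @return an object of class `two_state_surface`.
#' @export
two_state_surface <- function(name, dimensionality, coordinate_kind,
                              evaluate, params = list(), elements = NULL,
                              masses = NULL, ...) {
  stopifnot(is.function(evaluate), dimensionality >= 1)
  structure(
    list(name = name, dimensionality = as.integer(dimensionality),
         coordinate_kind = match.arg(coordinate_kind,
                                     c("internal", "cartesian")),
         evaluate = evaluate, params = params,
         elements = elements, masses = masses, ...),
    class = "two_state_surface")
}

#' @export
print.two_state_surface <- function(x, ...) {
  cat(sprintf("<two_state_surface> %s: %d %s coordinate(s)\n",
              x$name, x$dimensionality, x$coordinate_kind))
  invisible(x)
}

#' Evaluate a surface
#'
#' @param surface a `two_state_surface`.
#' @param x coordinate vector.
#' @return list with e_s0, g_s0, e_t1, g_t1, gap_s0s1 (NA when the
#'   surface defines no S0/S1 gap).
#' @export
surface_eval <- function(surface, x) {
  x <- as.numeric(x)
  if (length(x) != surface$dimensionality)
    stop(sprintf("coordinate length %d != surface dimensionality %d",
                 length(x), surface$dimensionality))
  ev <- surface$evaluate(x)
  if (is.null(ev$gap_s0s1)) ev$gap_s0s1 <- NA_real_
  ev
}

# convenience accessors for a single electronic state
.state_energy <- function(ev, state) {
  if (state == "s0") ev$e_s0 else ev$e_t1
}
.state_gradient <- function(ev, state) {
  if (state == "s0") ev$g_s0 else ev$g_t1
}

#' Finite-difference gradient of a surface (testing aid)
#' @param surface a `two_state_surface`.
#' @param x coordinate vector.
#' @param state "s0" or "t1".
#' @param step central-difference step.
#' @return numeric gradient vector.
#' @export
surface_fd_gradient <- function(surface, x, state = "s0", step = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + step
    xm <- x; xm[i] <- xm[i] - step
    (.state_energy(surface_eval(surface, xp), state) -
       .state_energy(surface_eval(surface, xm), state)) / (2 * step)
  }, numeric(1))
}

# --- Muller-Brown fixture ---------------------------------------------------

#' Muller-Brown benchmark surface
#'
#' The standard four-Gaussian 2-D surface used to exercise minimizers,
#' saddle search, and IRC integration. The published parameterization is
#' scaled by 0.1 so that well depths and barriers land on a kcal/mol-like
#' scale. The triplet channel is a flat constant +500 kcal/mol, far above
#' S0 everywhere, so crossing detection correctly reports no crossing.
#'
#' @param scale energy scale factor (default 0.1).
#' @return a `two_state_surface` with 2 internal coordinates.
#' @export
muller_brown <- function(scale = 0.1) {
  A <- c(-200, -100, -170, 15) * scale
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  evaluate <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    term <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    e <- sum(term)
    gx <- sum(term * (2 * a * dx + b * dy))
    gy <- sum(term * (b * dx + 2 * cc * dy))
    list(e_s0 = e, g_s0 = c(gx, gy), e_t1 = 500, g_t1 = c(0, 0))
  }
  two_state_surface("muller_brown", 2L, "internal", evaluate,
                    params = list(scale = scale))
}

# --- analytic azo model surface ---------------------------------------------

# default parameters of the 3-coordinate azo model; barrier-defining
# b_rot is calibrated (see model_azo_internal docs) and locked by tests
.azo_model_defaults <- list(
  alpha0 = 115,    # equilibrium CNN angle, degrees
  k_bend = 150,    # bend stiffness, kcal/mol per (cos a - cos a0)^2
  de_ct = 12,      # cis-trans electronic energy difference, kcal/mol
  b_rot = 43.7,    # torsional barrier parameter, kcal/mol (calibrated so
                   # the relaxed rotational barrier from cis is ~29)
  eps_tors = 1.0,  # residual torsion at collinear CNN, kcal/mol
  s_gap = 34,      # singlet-triplet gap scale, kcal/mol
  omega_x1 = 70,   # first seam crossing along the rotation path, degrees
  omega_x2 = 105,  # second seam crossing, degrees
  gap_vert0 = 65,  # vertical S0/S1 gap at trans, kcal/mol
  gap_vert_amp = 8, # cis-trans modulation of the vertical gap, kcal/mol
  eps_gate = FALSE, # gate the residual torsion by g(a) g(a') (Cartesian)
  k_anis = 260,    # out-of-plane bend anisotropy near CNN collinearity:
                   # makes the inversion apex a proper index-1 saddle
                   # (in-plane bend reactive, out-of-plane bend stiff),
                   # mimicking the conjugation penalty of real azo dyes
  m_anis = 30      # sharpness of the collinearity window
)

#' Analytic two-state azo photoswitch model surface
#'
#' A 3-coordinate (omega, alpha, alpha'; all in degrees) analytic
#' two-state surface with the qualitative topology of the azobenzene
#' S0/T1 pair: S0 minima at omega = 0 (cis, metastable) and omega = 180
#' (trans, energy zero up to a small residual), a rotational barrier near
#' |omega| = 90, inversion saddles at alpha (or alpha') = 180, and a T1
#' state that dips below S0 in a window around omega = 90 so that the two
#' S0/T1 seam crossings along the rotation path sit at omega = 70 and
#' 105 degrees with crossing energies below the S0 rotational saddle.
#'
#' The torsional barrier parameter is calibrated so the relaxed S0
#' rotational barrier measured from the cis minimum is about 29 kcal/mol,
#' the azobenzene scale, purely so downstream thermochemistry and rate
#' code runs at realistic magnitudes.
#'
#' Functional form (angles in radians internally): with
#' g(a) = sin^2(a)/sin^2(a0), U(a) = k_bend (cos a - cos a0)^2,
#' \deqn{E_{S0} = [B sin^2 w + \Delta E_{ct} (1+\cos w)/2] g(a) g(a') +
#'   U(a) + U(a') + \epsilon (1-\cos w)/2}
#' \deqn{E_{T1} = E_{S0} + s (\cos w - \cos w_{X1})(\cos w - \cos w_{X2})}
#' The T1-S0 gap depends only on omega, so the seam planes are exactly
#' omega = +/- 70 and +/- 105 degrees.
#'
#' @param params optional named list overriding the calibrated defaults.
#' @return a `two_state_surface` with coordinates (omega, alpha,
#'   alpha_prime) in degrees.
#' @export
model_azo_internal <- function(params = list()) {
  p <- utils::modifyList(.azo_model_defaults, params)
  d2r <- pi / 180
  a0 <- p$alpha0 * d2r
  sin2a0 <- sin(a0)^2
  cosa0 <- cos(a0)
  c1 <- cos(p$omega_x1 * d2r)
  c2 <- cos(p$omega_x2 * d2r)
  gate <- isTRUE(p$eps_gate)
  evaluate <- function(x) {
    w <- x[1] * d2r; a <- x[2] * d2r; ap <- x[3] * d2r
    sw <- sin(w); cw <- cos(w)
    sa <- sin(a); ca <- cos(a)
    sap <- sin(ap); cap <- cos(ap)
    Tt <- p$b_rot * sw^2 + p$de_ct * (1 + cw) / 2
    dT <- 2 * p$b_rot * sw * cw - p$de_ct * sw / 2
    g_a <- sa^2 / sin2a0;  dg_a <- 2 * sa * ca / sin2a0
    g_ap <- sap^2 / sin2a0; dg_ap <- 2 * sap * cap / sin2a0
    U_a <- p$k_bend * (ca - cosa0)^2
    dU_a <- -2 * p$k_bend * (ca - cosa0) * sa
    U_ap <- p$k_bend * (cap - cosa0)^2
    dU_ap <- -2 * p$k_bend * (cap - cosa0) * sap
    # the residual torsion is gated by g(a) g(a') on Cartesian
    # embeddings, where omega ceases to exist at CNN collinearity
    # torsion-bracket gate: on Cartesian embeddings the gate is squared
    # ((g_a g_ap)^2 ~ sin^4), which keeps the energy C2-smooth through
    # the CNN collinearity of the inversion saddle
    if (gate) {
      G <- (g_a * g_ap)^2
      dGda <- 2 * g_a * dg_a * g_ap^2
      dGdap <- 2 * g_a^2 * g_ap * dg_ap
    } else {
      G <- g_a * g_ap
      dGda <- dg_a * g_ap
      dGdap <- g_a * dg_ap
    }
    eps_w <- p$eps_tors * (1 - cw) / 2
    e0 <- Tt * G + U_a + U_ap + (if (gate) eps_w * G else eps_w)
    dw <- dT * G + p$eps_tors * sw / 2 * (if (gate) G else 1)
    da <- Tt * dGda + dU_a + (if (gate) eps_w * dGda else 0)
    dap <- Tt * dGdap + dU_ap + (if (gate) eps_w * dGdap else 0)
    # out-of-plane bend anisotropy near either CNN collinearity; the
    # sin^2(w) sin^2(a) sin^2(a') product is a smooth function of the
    # Cartesian frame (out-of-plane displacement squared), so the term
    # stays regular at both collinear apexes
    if (p$k_anis != 0) {
      win_a <- ((1 - ca) / 2)^p$m_anis
      dwin_a <- p$m_anis * ((1 - ca) / 2)^(p$m_anis - 1) * sa / 2
      win_ap <- ((1 - cap) / 2)^p$m_anis
      dwin_ap <- p$m_anis * ((1 - cap) / 2)^(p$m_anis - 1) * sap / 2
      W <- win_a + win_ap
      B1 <- sa^2; B2 <- sap^2
      e0 <- e0 + p$k_anis * sw^2 * B1 * B2 * W
      dw <- dw + p$k_anis * 2 * sw * cw * B1 * B2 * W
      da <- da + p$k_anis * sw^2 * B2 * (2 * sa * ca * W + B1 * dwin_a)
      dap <- dap + p$k_anis * sw^2 * B1 * (2 * sap * cap * W + B2 * dwin_ap)
    }
    # triplet gap depends on omega only
    gapT <- p$s_gap * (cw - c1) * (cw - c2)
    dgapT <- -p$s_gap * sw * ((cw - c2) + (cw - c1))
    # gradients converted to per-degree
    g_s0 <- c(dw, da, dap) * d2r
    list(e_s0 = e0, g_s0 = g_s0,
         e_t1 = e0 + gapT, g_t1 = g_s0 + c(dgapT, 0, 0) * d2r,
         gap_s0s1 = p$gap_vert0 + p$gap_vert_amp * (1 + cw) / 2)
  }
  two_state_surface("model_azo_internal", 3L, "internal", evaluate,
                    params = p)
}
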