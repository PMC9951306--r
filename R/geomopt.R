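#' @title Stationary-point machinery on two-state surfaces
#' @description Minimization, constrained relaxed scans, finite-difference
#'   Hessians, eigenvector-following saddle refinement, IRC integration,
#'   seam-crossing detection and MECP optimization. All operations work on
#'   any [two_state_surface()], internal-coordinate or Cartesian.
#' @name geomopt
NULL

# per-coordinate mass vector: atomic masses repeated x,y,z for Cartesian
# surfaces; for internal-coordinate surfaces either explicit per-
# coordinate masses or unit masses
.coord_masses <- function(surface) {
  if (is.null(surface$masses)) return(rep(1, surface$dimensionality))
  if (surface$coordinate_kind == "cartesian")
    rep(surface$masses, each = 3L)
  else
    rep(surface$masses, length.out = surface$dimensionality)
}

.new_report <- function(x, energy, grad, hessian = NULL, eigenvalues = NULL,
                        n_imaginary = NA_integer_, converged = FALSE,
                        n_steps = 0L, kind = "minimum", state = "s0",
                        reason = NULL, extra = list()) {
  r <- c(list(x = as.numeric(x), energy = energy,
              gradient_norm = max(abs(grad)), gradient = as.numeric(grad),
              hessian = hessian, eigenvalues = eigenvalues,
              n_imaginary = n_imaginary, converged = converged,
              n_steps = n_steps, kind = kind, state = state,
              reason = reason), extra)
  class(r) <- "azo_stationary"
  r
}

#' @export
print.azo_stationary <- function(x, ...) {
  cat(sprintf(
    "<azo_stationary> kind=%s state=%s E=%.6f max|g|=%.2e n_imag=%s %s (%d steps)%s\n",
    x$kind, x$state, x$energy, x$gradient_norm,
    ifelse(is.na(x$n_imaginary), "?", x$n_imaginary),
    if (isTRUE(x$converged)) "converged" else "NOT converged", x$n_steps,
    if (!is.null(x$reason)) paste0(" [", x$reason, "]") else ""))
  invisible(x)
}

# count eigenvalues that are imaginary modes: below -thr on a scale set by
# the largest curvature (rigid-body/projected modes hover at ~0)
.count_imaginary <- function(eigenvalues, rel = 1e-6, abs_floor = 1e-5) {
  thr <- max(abs_floor, rel * max(abs(eigenvalues), 1))
  sum(eigenvalues < -thr)
}

#' Finite-difference Hessian from analytic gradients
#'
#' Central differences of the surface's analytic gradient, symmetrized as
#' (H + t(H))/2.
#'
#' @param surface a `two_state_surface`.
#' @param x coordinate vector.
#' @param state "s0" or "t1".
#' @param step finite-difference step (default 1e-3).
#' @return symmetric dim x dim matrix.
#' @export
hessian_fd <- function(surface, x, state = "s0", step = 1e-3) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- xp[i] + step
    xm <- x; xm[i] <- xm[i] - step
    gp <- .state_gradient(surface_eval(surface, xp), state)
    gm <- .state_gradient(surface_eval(surface, xm), state)
    H[i, ] <- (gp - gm) / (2 * step)
  }
  (H + t(H)) / 2
}

# mass-weighted Hessian eigenvalues (units kcal/mol/A^2/amu for Cartesian)
.mw_eigen <- function(H, masses3) {
  sm <- sqrt(masses3)
  Hmw <- H / outer(sm, sm)
  eigen(Hmw, symmetric = TRUE)
}

# --- constraint helpers -----------------------------------------------------

# A constraint is a list(value = function(x), grad = function(x),
# target = scalar, wrap = logical) on one scalar internal coordinate.
# Satisfy the constraint by Newton correction along its gradient and
# project gradients off it (Lagrange projection).
.constraint_residual <- function(con, x) {
  v <- con$value(x) - con$target
  if (isTRUE(con$wrap)) {  # periodic (dihedral, degrees)
    v <- (v + 180) %% 360 - 180
  }
  v
}

.constraint_correct <- function(con, x, tol = 1e-8, max_iter = 50) {
  for (k in seq_len(max_iter)) {
    r <- .constraint_residual(con, x)
    if (!is.finite(r)) break            # degenerate coordinate: leave x
    if (abs(r) < tol) break
    gc_ <- con$grad(x)
    if (!all(is.finite(gc_)) || sum(gc_^2) < 1e-20) break
    x <- x - gc_ * r / sum(gc_^2)
  }
  x
}

.project_off <- function(g, gc_) {
  ghat <- gc_ / sqrt(sum(gc_^2))
  g - sum(g * ghat) * ghat
}

# --- minimization -----------------------------------------------------------

#' Minimize a surface on one electronic state
#'
#' Quasi-Newton (BFGS with backtracking line search) descent; converged
#' when the largest absolute (projected) gradient component drops below
#' `tol`. Supports frozen coordinates (`mask`) and a single scalar
#' internal-coordinate constraint enforced by Newton correction plus
#' Lagrange gradient projection. Never throws on non-convergence: the
#' partial report carries `converged = FALSE`.
#'
#' @param surface a `two_state_surface`.
#' @param x0 starting coordinates.
#' @param state "s0" or "t1".
#' @param tol convergence threshold on max abs gradient component
#'   (default 1e-4 kcal/mol per coordinate unit).
#' @param max_steps iteration cap.
#' @param mask optional integer vector of coordinate indices allowed to
#'   move (all others frozen).
#' @param constraint optional constraint list (value/grad/target/wrap).
#' @param with_hessian if TRUE (default) attach the Hessian, its
#'   (mass-weighted, for Cartesian surfaces) eigenvalues and the imaginary
#'   count to the report.
#' @param newton_polish enable the finite-difference-Hessian Newton
#'   polish near convergence (default TRUE; turn off for surfaces whose
#'   evaluations are expensive, e.g. learned potentials).
#' @return an `azo_stationary` report with kind "minimum".
#' @export
minimize <- function(surface, x0, state = "s0", tol = 1e-4, max_steps = 2000L,
                     mask = NULL, constraint = NULL, with_hessian = TRUE,
                     newton_polish = TRUE) {
  x <- as.numeric(x0)
  n <- length(x)
  free <- if (is.null(mask)) seq_len(n) else sort(unique(as.integer(mask)))
  eff_grad <- function(x, g) {
    ge <- numeric(n)
    ge[free] <- g[free]
    if (!is.null(constraint)) {
      gc_ <- numeric(n)
      gc_[free] <- constraint$grad(x)[free]
      if (sum(gc_^2) > 0) ge <- .project_off(ge, gc_)
    }
    ge
  }
  if (!is.null(constraint)) x <- .constraint_correct(constraint, x)
  ev <- surface_eval(surface, x)
  e <- .state_energy(ev, state)
  g <- eff_grad(x, .state_gradient(ev, state))
  scale0 <- 1 / max(1, max(abs(g)))   # conservative until curvature known
  Binv <- diag(n) * scale0
  scaled <- FALSE
  steps <- 0L
  next_polish <- 0L
  converged <- max(abs(g)) < tol
  while (!converged && steps < max_steps) {
    p <- -as.numeric(Binv %*% g)
    if (sum(p * g) > -1e-14) {          # reset on non-descent direction
      Binv <- diag(n) * scale0; scaled <- FALSE; p <- -g * scale0
    }
    plen <- sqrt(sum(p^2))
    if (plen > 0.5) p <- p * 0.5 / plen
    alpha <- 1
    ok <- FALSE
    repeat {
      xn <- x + alpha * p
      if (!is.null(constraint)) xn <- .constraint_correct(constraint, xn)
      evn <- surface_eval(surface, xn)
      en <- .state_energy(evn, state)
      if (is.finite(en) && en <= e + 1e-4 * alpha * sum(g * p)) {
        ok <- TRUE; break
      }
      alpha <- alpha / 2
      if (alpha < 1e-10) { xn <- x; evn <- ev; en <- e; break }
    }
    if (!ok && scaled) {                # stuck: drop curvature model
      Binv <- diag(n) * scale0; scaled <- FALSE
      steps <- steps + 1L
      next
    }
    gn <- eff_grad(xn, .state_gradient(evn, state))
    sdx <- xn - x; ydg <- gn - g
    sy <- sum(sdx * ydg)
    if (sy > 1e-12) {
      if (!scaled) {                    # Nocedal-Wright H0 rescaling
        Binv <- diag(n) * sy / sum(ydg^2)
        scaled <- TRUE
      }
      rho <- 1 / sy                     # BFGS inverse update
      V <- diag(n) - rho * outer(sdx, ydg)
      Binv <- V %*% Binv %*% t(V) + rho * outer(sdx, sdx)
    }
    x <- xn; e <- en; g <- gn; ev <- evn
    steps <- steps + 1L
    converged <- max(abs(g)) < tol
    # quadratic-convergence polish once BFGS is in the basin: Newton (or
    # KKT-projected Newton under a constraint) on the free coordinates
    if (newton_polish && !converged && max(abs(g)) < 1e3 * tol &&
        steps > 5 && steps >= next_polish) {
      next_polish <- steps + 50L
      pol <- .newton_polish(surface, x, state, tol, free, constraint)
      if (pol$converged) {
        x <- pol$x; e <- pol$e; g <- eff_grad(x, pol$g_full)
        steps <- steps + pol$n_steps
        converged <- TRUE
        break
      }
    }
  }
  hess <- NULL; eigvals <- NULL; n_imag <- NA_integer_
  if (with_hessian) {
    hess <- hessian_fd(surface, x, state)
    eigvals <- .mw_eigen(hess, .coord_masses(surface))$values
    # frozen/constrained optimizations: imaginary count refers to the
    # full Hessian and is informational only
    n_imag <- .count_imaginary(eigvals)
  }
  .new_report(x, e, g, hess, eigvals, n_imag, converged, steps,
              kind = "minimum", state = state,
              reason = if (!converged) "step_limit" else NULL)
}

# Newton (KKT-projected under a scalar constraint) polish on the free
# coordinates; safeguarded by a Levenberg shift and step halving
.newton_polish <- function(surface, x, state, tol, free, constraint,
                           max_iter = 25L) {
  n <- length(x)
  eff <- function(x, g) {
    ge <- numeric(n); ge[free] <- g[free]
    if (!is.null(constraint)) {
      gc_ <- numeric(n); gc_[free] <- constraint$grad(x)[free]
      if (sum(gc_^2) > 0) ge <- .project_off(ge, gc_)
    }
    ge
  }
  for (it in seq_len(max_iter)) {
    ev <- surface_eval(surface, x)
    g_full <- .state_gradient(ev, state)
    ge <- eff(x, g_full)
    if (max(abs(ge)) < tol)
      return(list(converged = TRUE, x = x,
                  e = .state_energy(ev, state), g_full = g_full,
                  n_steps = it - 1L))
    H <- hessian_fd(surface, x, state)
    Hf <- H[free, free, drop = FALSE]
    gf <- ge[free]
    if (!is.null(constraint)) {        # restrict to the constraint tangent
      gc_ <- constraint$grad(x)[free]
      nc <- sqrt(sum(gc_^2))
      if (nc > 0) {
        ch <- gc_ / nc
        P <- diag(length(free)) - outer(ch, ch)
        Hf <- P %*% Hf %*% P
      }
    }
    # descend only along well-conditioned positive-curvature directions;
    # rigid-body null modes and ridge modes (scan structures may sit on
    # symmetric ridges, refined later by EVF) are left untouched
    ed <- eigen(Hf, symmetric = TRUE)
    keep <- ed$values > 1e-4
    if (!any(keep)) return(list(converged = FALSE))
    gt <- as.numeric(t(ed$vectors[, keep, drop = FALSE]) %*% gf)
    d <- -as.numeric(ed$vectors[, keep, drop = FALSE] %*%
                       (gt / ed$values[keep]))
    step <- numeric(n); step[free] <- d
    if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
    xn <- x + step
    if (!is.null(constraint)) xn <- .constraint_correct(constraint, xn)
    x <- xn
  }
  ev <- surface_eval(surface, x)
  g_full <- .state_gradient(ev, state)
  ge <- eff(x, g_full)
  list(converged = max(abs(ge)) < tol, x = x,
       e = .state_energy(ev, state), g_full = g_full, n_steps = max_iter)
}

# --- relaxed scan -----------------------------------------------------------

#' Relaxed scan along a driving coordinate
#'
#' At each grid value the driving coordinate is constrained (satisfied to
#' 0.1 degrees for internal drives) and all remaining coordinates are
#' minimized; each point warm-starts from the previous. The
#' highest-energy point is tagged as the transition-state guess (ties
#' break to the lower grid value). Non-converged points are flagged in
#' their report and the scan continues.
#'
#' @param surface a `two_state_surface`.
#' @param x0 starting coordinates (relaxed at the first grid value).
#' @param driving for internal surfaces a coordinate index or one of
#'   "omega", "alpha", "alpha_prime"; for Cartesian surfaces one of those
#'   names (resolved through the surface's core mapping) or a constraint
#'   list.
#' @param grid numeric vector of driving-coordinate values.
#' @param state electronic state.
#' @param tol minimizer tolerance per point.
#' @param mask optional free-coordinate mask (on top of the constraint).
#' @param newton_polish,max_steps forwarded to [minimize()].
#' @return list with `reports` (one `azo_stationary` per grid point),
#'   `energies`, `grid`, and `ts_guess_index`.
#' @export
relaxed_scan <- function(surface, x0, driving, grid, state = "s0",
                         tol = 1e-4, mask = NULL, newton_polish = TRUE,
                         max_steps = 2000L) {
  n <- surface$dimensionality
  internal_names <- c(omega = 1L, alpha = 2L, alpha_prime = 3L)
  make_con <- NULL
  if (is.list(driving)) {
    make_con <- function(v) { driving$target <- v; driving }
  } else if (surface$coordinate_kind == "internal") {
    idx <- if (is.character(driving)) internal_names[[driving]]
           else as.integer(driving)
    if (is.na(idx) || idx < 1 || idx > n) stop("invalid driving coordinate")
    wrap <- is.character(driving) && driving == "omega"
    make_con <- function(v) {
      list(value = function(x) x[idx],
           grad = function(x) { g <- numeric(n); g[idx] <- 1; g },
           target = v, wrap = wrap)
    }
  } else {
    if (!is.character(driving) || is.null(surface$core))
      stop("Cartesian scans need a named driving coordinate and a core mapping")
    make_con <- function(v) cartesian_driving_constraint(surface, driving, v)
  }
  x <- as.numeric(x0)
  reports <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    con <- make_con(grid[k])
    rep_k <- minimize(surface, x, state, tol, max_steps = max_steps,
                      mask = mask, constraint = con,
                      with_hessian = FALSE, newton_polish = newton_polish)
    rep_k$driving_value <- grid[k]
    reports[[k]] <- rep_k
    x <- rep_k$x
  }
  energies <- vapply(reports, `[[`, numeric(1), "energy")
  list(reports = reports, energies = energies, grid = grid,
       ts_guess_index = which.max(energies))   # which.max takes first tie
}

#' Constraint on an internal coordinate of a Cartesian surface
#'
#' Builds a scalar constraint (value, analytic gradient) on omega, alpha
#' or alpha_prime of the azo core of a Cartesian surface, for Lagrange
#' projection during scans.
#'
#' @param surface Cartesian `two_state_surface` carrying a `core` field.
#' @param which "omega", "alpha" or "alpha_prime".
#' @param target target value in degrees.
#' @return constraint list usable by [minimize()] and [relaxed_scan()].
#' @export
cartesian_driving_constraint <- function(surface, which, target) {
  core <- surface$core
  n <- surface$dimensionality
  if (which == "omega") {
    idx <- core[c("C1", "N1", "N2", "C2")]
    list(value = function(x) {
           p <- matrix(x, ncol = 3, byrow = TRUE)
           .dihedral(p[idx[1], ], p[idx[2], ], p[idx[3], ], p[idx[4], ])
         },
         grad = function(x) {
           p <- matrix(x, ncol = 3, byrow = TRUE)
           gd <- .dihedral_grad(p[idx[1], ], p[idx[2], ], p[idx[3], ],
                                p[idx[4], ])
           g <- numeric(n)
           for (a in 1:4) g[(idx[a] - 1) * 3 + 1:3] <- gd[a, ]
           g
         },
         target = target, wrap = TRUE)
  } else {
    idx <- if (which == "alpha") core[c("C1", "N1", "N2")]
           else core[c("N1", "N2", "C2")]
    list(value = function(x) {
           p <- matrix(x, ncol = 3, byrow = TRUE)
           .bond_angle(p[idx[1], ], p[idx[2], ], p[idx[3], ])
         },
         grad = function(x) {
           p <- matrix(x, ncol = 3, byrow = TRUE)
           ga <- .angle_grad(p[idx[1], ], p[idx[2], ], p[idx[3], ])
           g <- numeric(n)
           for (a in 1:3) g[(idx[a] - 1) * 3 + 1:3] <- ga[a, ]
           g
         },
         target = target, wrap = FALSE)
  }
}

# --- eigenvector following --------------------------------------------------

#' Eigenvector-following saddle refinement (P-RFO)
#'
#' Partitioned rational-function step: energy is maximized along the
#' lowest-eigenvalue Hessian mode and minimized along all others, with an
#' adaptive trust radius. A converged report has exactly one imaginary
#' mode; convergence onto a minimum or a higher-index point returns
#' `converged = FALSE` with a reason code, never an exception.
#'
#' @param surface a `two_state_surface`.
#' @param x0 starting point (typically the relaxed-scan maximum).
#' @param state electronic state.
#' @param tol max abs gradient component at convergence.
#' @param max_steps iteration cap.
#' @param trust initial trust radius (coordinate units).
#' @param mode0 optional initial direction for the uphill mode (e.g. the
#'   scan driving direction); the eigenvector with the largest overlap is
#'   followed. Defaults to the lowest-eigenvalue mode.
#' @return an `azo_stationary` report with kind "saddle".
#' @export
evf_saddle <- function(surface, x0, state = "s0", tol = 1e-4,
                       max_steps = 200L, trust = 0.1, mode0 = NULL) {
  x <- as.numeric(x0)
  n <- length(x)
  trust_max <- 4 * trust
  ev <- surface_eval(surface, x)
  e <- .state_energy(ev, state)
  g <- .state_gradient(ev, state)
  steps <- 0L
  mode_prev <- if (is.null(mode0)) NULL
               else mode0 / sqrt(sum(mode0^2))   # followed uphill mode
  while (max(abs(g)) >= tol && steps < max_steps) {
    H <- hessian_fd(surface, x, state)
    ed <- eigen(H, symmetric = TRUE)
    lam <- ed$values; V <- ed$vectors
    # follow the mode with the largest overlap with the previous uphill
    # mode; first iteration takes the lowest-eigenvalue mode
    im <- if (is.null(mode_prev)) which.min(lam)
          else which.max(abs(as.numeric(t(V) %*% mode_prev)))
    mode_prev <- V[, im]
    gt <- as.numeric(t(V) %*% g)
    # uphill RFO shift along the followed mode
    l1 <- lam[im]; g1 <- gt[im]
    lp <- 0.5 * (l1 + sqrt(l1^2 + 4 * g1^2))
    st <- numeric(n)
    st[im] <- if (abs(l1 - lp) > 1e-12) -g1 / (l1 - lp) else 0
    # soft modes (rigid-body null modes, flat ridge directions) carry
    # only numerical noise: keep them frozen
    soft <- max(1e-4, 1e-6 * max(abs(lam)))
    rest <- setdiff(which(abs(lam) > soft), im)
    if (length(rest)) {
      gr <- gt[rest]; lr <- lam[rest]
      ln <- 0.5 * (min(lr) - sqrt(min(lr)^2 + 4 * sum(gr^2)))
      ln <- min(ln, 0)
      st[rest] <- -gr / (lr - ln + 1e-12)
    }
    slen <- sqrt(sum(st^2))
    if (slen > trust) st <- st * trust / slen
    dx <- as.numeric(V %*% st)
    pred <- sum(g * dx) + 0.5 * sum(dx * as.numeric(H %*% dx))
    xn <- x + dx
    evn <- surface_eval(surface, xn)
    en <- .state_energy(evn, state)
    gn <- .state_gradient(evn, state)
    ratio <- if (abs(pred) > 1e-14) (en - e) / pred else 1
    accept <- is.finite(en) && all(is.finite(gn)) &&
      (ratio > 0 || abs(en - e) < 1e-10)
    if (accept) {
      x <- xn; ev <- evn; e <- en; g <- gn
      if (ratio > 0.75 && ratio < 1.25) trust <- min(trust * 1.25, trust_max)
      else if (ratio < 0.25 || ratio > 3) trust <- max(trust / 2, 1e-8)
    } else {
      trust <- trust / 2
      if (trust < 1e-10) break
    }
    steps <- steps + 1L
  }
  H <- hessian_fd(surface, x, state)
  eigvals <- .mw_eigen(H, .coord_masses(surface))$values
  n_imag <- .count_imaginary(eigvals)
  grad_ok <- max(abs(g)) < tol
  converged <- grad_ok && n_imag == 1L
  reason <- if (!grad_ok) "step_limit"
            else if (n_imag == 0L) "converged_to_minimum"
            else if (n_imag > 1L) "higher_index_saddle"
            else NULL
  .new_report(x, e, g, H, eigvals, n_imag, converged, steps,
              kind = "saddle", state = state, reason = reason)
}

# --- intrinsic reaction coordinate ------------------------------------------

#' Intrinsic reaction coordinate from a saddle
#'
#' Displaces +/- along the imaginary mode, then follows damped
#' steepest-descent (Euler with energy-monotone step halving) in
#' mass-weighted coordinates until the gradient drops below the minimizer
#' tolerance. S0 and T1 energies and their gap are recorded at every
#' point, which is what downstream seam-crossing detection consumes.
#'
#' @param surface a `two_state_surface`.
#' @param saddle_report converged saddle report with one imaginary mode.
#' @param state descending electronic state.
#' @param step_size Euler step in mass-weighted units (default 0.05).
#' @param max_points cap on path points per branch.
#' @param tol gradient convergence threshold at the endpoints.
#' @return list with `forward` and `backward`, each a data.frame of path
#'   points (arc_length, e_s0, e_t1, gap) with coordinates in
#'   `attr(.,"coords")` (one row per point); `truncated` flags per branch.
#' @export
irc <- function(surface, saddle_report, state = "s0", step_size = 0.05,
                max_points = 600L, tol = 1e-4) {
  if (is.na(saddle_report$n_imaginary) || saddle_report$n_imaginary != 1L)
    stop("IRC requires a saddle report with exactly one imaginary mode")
  m3 <- .coord_masses(surface)
  sm <- sqrt(m3)
  edec <- .mw_eigen(saddle_report$hessian, m3)
  mode_mw <- edec$vectors[, which.min(edec$values)]
  x_saddle <- saddle_report$x

  run_branch <- function(direction) {
    # initial displacement along the imaginary mode (mass-weighted)
    q <- x_saddle * sm + direction * step_size * mode_mw
    pts_x <- list(); arc <- numeric(0); es0 <- numeric(0); et1 <- numeric(0)
    s_cum <- step_size
    truncated <- FALSE
    h <- step_size
    k <- 0L
    repeat {
      x <- q / sm
      ev <- surface_eval(surface, x)
      eg <- .state_gradient(ev, state)
      e <- .state_energy(ev, state)
      k <- k + 1L
      pts_x[[k]] <- x; arc[k] <- s_cum
      es0[k] <- ev$e_s0; et1[k] <- ev$e_t1
      if (max(abs(eg)) < tol) break
      if (k >= max_points) { truncated <- TRUE; break }
      g_mw <- eg / sm
      ghat <- g_mw / sqrt(sum(g_mw^2))
      # damped Euler: halve the step until the energy does not increase
      h_try <- h
      repeat {
        qn <- q - h_try * ghat
        en <- .state_energy(surface_eval(surface, qn / sm), state)
        if (en <= e + 1e-12 || h_try < 1e-8) break
        h_try <- h_try / 2
      }
      q <- qn
      s_cum <- s_cum + h_try
      h <- min(step_size, h_try * 2)
    }
    coords <- do.call(rbind, pts_x)
    df <- data.frame(arc_length = arc, e_s0 = es0, e_t1 = et1,
                     gap = et1 - es0)
    attr(df, "coords") <- coords
    attr(df, "truncated") <- truncated
    df
  }
  fwd <- run_branch(+1)
  bwd <- run_branch(-1)
  list(forward = fwd, backward = bwd,
       saddle = list(x = x_saddle, e_s0 = surface_eval(surface, x_saddle)$e_s0))
}

#' Locate singlet-triplet seam crossings along a path
#'
#' Every sign change of the S0/T1 gap between consecutive path points
#' yields a crossing seed by linear interpolation in arc length;
#' zero-gap points are returned as-is. Seeds are ordered by arc length.
#'
#' @param path data.frame of path points with columns arc_length and gap
#'   and coordinates in `attr(path, "coords")`.
#' @return list of seeds, each list(x, arc_length, gap); empty when the
#'   gap never changes sign.
#' @export
locate_seam_crossings <- function(path) {
  if (is.null(path) || nrow(path) == 0) return(list())
  gap <- path$gap
  if (any(!is.finite(gap))) stop("path gap contains non-finite values")
  coords <- attr(path, "coords")
  seeds <- list()
  for (i in seq_len(nrow(path))) {
    if (gap[i] == 0) {
      seeds[[length(seeds) + 1L]] <-
        list(x = coords[i, ], arc_length = path$arc_length[i], gap = 0)
    } else if (i > 1 && sign(gap[i]) != sign(gap[i - 1]) &&
               gap[i - 1] != 0) {
      f <- abs(gap[i - 1]) / (abs(gap[i - 1]) + abs(gap[i]))
      xi <- coords[i - 1, ] + f * (coords[i, ] - coords[i - 1, ])
      si <- path$arc_length[i - 1] +
        f * (path$arc_length[i] - path$arc_length[i - 1])
      seeds[[length(seeds) + 1L]] <- list(x = xi, arc_length = si,
                                          gap = NA_real_)
    }
  }
  if (length(seeds) > 1) {
    ord <- order(vapply(seeds, `[[`, numeric(1), "arc_length"))
    seeds <- seeds[ord]
  }
  seeds
}

# --- minimum-energy crossing point ------------------------------------------

#' Minimum-energy crossing point optimization
#'
#' Gradient-projection MECP search: the effective gradient is
#' (e_s0 - e_t1) * ghat_diff + P g_mean, where ghat_diff is the
#' normalized gradient-difference vector and P projects onto its
#' orthogonal complement. Converged when |gap| < tol_gap and the largest
#' component of the projected mean gradient is below tol_grad. The report
#' stores both states' gradients at the solution; its Hessian is the
#' state-averaged Hessian (the smooth function whose seam-restricted
#' minimum the MECP is), which downstream seam-projected thermochemistry
#' consumes.
#'
#' @param surface a `two_state_surface`.
#' @param x0 starting point near the seam.
#' @param tol_gap gap tolerance, kcal/mol (default 1e-4).
#' @param tol_grad projected-gradient tolerance (default 1e-4).
#' @param max_steps iteration cap.
#' @return an `azo_stationary` report with kind "mecp" and extra fields
#'   g_s0, g_t1, g_diff, e_s0, e_t1.
#' @export
mecp_optimize <- function(surface, x0, tol_gap = 1e-4, tol_grad = 1e-4,
                          max_steps = 3000L) {
  x <- as.numeric(x0)
  comp <- function(x) {
    ev <- surface_eval(surface, x)
    dg <- ev$g_s0 - ev$g_t1
    nd <- sqrt(sum(dg^2))
    if (nd < 1e-14) stop("degenerate seam: gradient difference vanishes")
    ghat <- dg / nd
    gmean <- (ev$g_s0 + ev$g_t1) / 2
    gproj <- gmean - sum(gmean * ghat) * ghat
    geff <- (ev$e_s0 - ev$e_t1) * ghat + gproj
    list(ev = ev, ghat = ghat, gproj = gproj, geff = geff,
         gap = ev$e_s0 - ev$e_t1,
         merit = (ev$e_s0 - ev$e_t1)^2 + sum(gproj^2))
  }
  cc <- comp(x)
  alpha <- 0.05
  steps <- 0L
  next_polish <- 40L
  # mean-energy surface + gap-as-constraint view for Newton acceleration
  mean_surface <- two_state_surface(
    "mecp_mean", surface$dimensionality, surface$coordinate_kind,
    function(z) {
      ev <- surface$evaluate(z)
      list(e_s0 = (ev$e_s0 + ev$e_t1) / 2,
           g_s0 = (ev$g_s0 + ev$g_t1) / 2, e_t1 = 0,
           g_t1 = numeric(length(ev$g_s0)))
    }, elements = surface$elements, masses = surface$masses)
  gap_constraint <- list(
    value = function(z) { ev <- surface_eval(surface, z); ev$e_s0 - ev$e_t1 },
    grad = function(z) { ev <- surface_eval(surface, z); ev$g_s0 - ev$g_t1 },
    target = 0, wrap = FALSE)
  done <- function(cc) abs(cc$gap) < tol_gap && max(abs(cc$gproj)) < tol_grad
  while (!done(cc) && steps < max_steps) {
    xn <- x - alpha * cc$geff
    ccn <- tryCatch(comp(xn), error = function(e) NULL)
    if (!is.null(ccn) && is.finite(ccn$merit) && ccn$merit <= cc$merit) {
      x <- xn; cc <- ccn
      alpha <- min(alpha * 1.2, 1)
    } else {
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    steps <- steps + 1L
    if (!done(cc) && steps >= next_polish && abs(cc$gap) < 1) {
      next_polish <- steps + 100L
      pol <- .newton_polish(mean_surface, x, "s0", tol_grad / 2,
                            seq_along(x), gap_constraint)
      if (isTRUE(pol$converged)) {
        ccp <- tryCatch(comp(pol$x), error = function(e) NULL)
        if (!is.null(ccp) && ccp$merit <= cc$merit + 1e-12) {
          x <- pol$x; cc <- ccp
        }
      }
    }
  }
  converged <- abs(cc$gap) < tol_gap && max(abs(cc$gproj)) < tol_grad
  Hs0 <- hessian_fd(surface, x, "s0")
  Ht1 <- hessian_fd(surface, x, "t1")
  H <- (Hs0 + Ht1) / 2
  eigvals <- .mw_eigen(H, .coord_masses(surface))$values
  .new_report(x, cc$ev$e_s0, cc$gproj, H, eigvals,
              .count_imaginary(eigvals), converged, steps,
              kind = "mecp", state = "seam",
              reason = if (!converged) "step_limit" else NULL,
              extra = list(e_s0 = cc$ev$e_s0, e_t1 = cc$ev$e_t1,
                           gap = cc$gap, g_s0 = cc$ev$g_s0,
                           g_t1 = cc$ev$g_t1,
                           g_diff = cc$ev$g_s0 - cc$ev$g_t1))
}
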