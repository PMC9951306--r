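#' @title Barrier workflow orchestration
#' @description Runs the full thermal-isomerization workflow on a
#'   molecule + surface: cis/trans optimization, four mechanism scans
#'   (two rotations, two inversions), TS-region conformer search,
#'   eigenvector-following refinement, filters, IRC verification,
#'   singlet-triplet crossings and MECP refinement on the rotational
#'   channels, conformer-ensemble thermochemistry, and both Eyring and
#'   intersystem-crossing rate theories side by side.
#' @name pipeline
NULL

#' Workflow configuration
#'
#' @param temperature run temperature, K.
#' @param H_SO spin-orbit coupling constant, cm^-1 (default 20, the
#'   azo-compound value; the n-pi* character of the triplet makes it
#'   about 20x the typical planar-aromatic coupling).
#' @param seed RNG seed controlling every stochastic step.
#' @param n_conformers conformers kept per mechanism (default 5, so at
#'   most 20 TS optimizations across the four mechanisms).
#' @param n_perturb random-perturbation candidates per conformer search.
#' @param scan_step relaxed-scan step, degrees.
#' @param tol_opt,tol_ts minimizer / saddle gradient tolerances.
#' @param tol_gap,tol_grad MECP convergence tolerances.
#' @param qh_cutoff quasiharmonic entropy floor, cm^-1.
#' @param rmsd_thr conformer deduplication threshold, angstrom.
#' @param irc_step,irc_max_points IRC integrator controls.
#' @param classify_tol mechanism classification tolerance, degrees.
#' @return an `azo_config` list.
#' @export
azo_config <- function(temperature = 298.15, H_SO = 20, seed = 1L,
                       n_conformers = 5L, n_perturb = 6L, scan_step = 15,
                       tol_opt = 1e-5, tol_ts = 1e-6, tol_gap = 1e-5,
                       tol_grad = 1e-4, qh_cutoff = 100, rmsd_thr = 0.25,
                       irc_step = 0.15, irc_max_points = 800L,
                       classify_tol = 25) {
  cfg <- list(temperature = temperature, H_SO = H_SO, seed = as.integer(seed),
              n_conformers = as.integer(n_conformers),
              n_perturb = as.integer(n_perturb), scan_step = scan_step,
              tol_opt = tol_opt, tol_ts = tol_ts, tol_gap = tol_gap,
              tol_grad = tol_grad, qh_cutoff = qh_cutoff,
              rmsd_thr = rmsd_thr, irc_step = irc_step,
              irc_max_points = as.integer(irc_max_points),
              classify_tol = classify_tol)
  class(cfg) <- "azo_config"
  cfg
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' The four mechanism labels
#' @return character vector of the four channels.
#' @export
mechanism_labels <- function() {
  c("rotation_plus", "rotation_minus", "inversion_alpha",
    "inversion_alpha_prime")
}

#' Classify a transition state by its core coordinates
#'
#' Rotation first: |omega| within `tol_omega` of 90 degrees is a
#' rotational TS (the sign of omega picks the plus/minus channel); this
#' groups inversion-assisted rotation, which also sits near |omega| = 90,
#' with rotation. Otherwise alpha (then alpha') within `tol_alpha` of
#' 180 classifies the two inversion channels.
#'
#' @param mc list with omega, alpha, alpha_prime (degrees), e.g. from
#'   [measure_cnnc()].
#' @param tol_omega,tol_alpha classification tolerances, degrees.
#' @return one of [mechanism_labels()].
#' @export
classify_mechanism <- function(mc, tol_omega = 25, tol_alpha = 25) {
  if (is.finite(mc$omega) && abs(abs(mc$omega) - 90) <= tol_omega)
    return(if (mc$omega >= 0) "rotation_plus" else "rotation_minus")
  if (abs(mc$alpha - 180) <= tol_alpha) return("inversion_alpha")
  if (abs(mc$alpha_prime - 180) <= tol_alpha)
    return("inversion_alpha_prime")
  stop(sprintf(
    "unclassified transition state: omega=%.1f alpha=%.1f alpha_prime=%.1f",
    mc$omega, mc$alpha, mc$alpha_prime))
}

# core internal coordinates of a surface point
.mech_coords <- function(surface, x) {
  if (surface$coordinate_kind == "internal") {
    list(omega = x[1], alpha = x[2], alpha_prime = x[3],
         omega_defined = TRUE)
  } else {
    g <- geometry(surface$elements, matrix(x, ncol = 3, byrow = TRUE),
                  core = surface$core, check = FALSE)
    measure_cnnc(g)
  }
}

.start_coords <- function(surface, tag) {
  if (!is.null(surface$reference))
    return(as_coord_vector(surface$reference(tag)))
  a0 <- surface$params$alpha0
  if (is.null(a0)) a0 <- 115
  c(if (tag == "cis") 0 else 180, a0, a0)
}

#' Filter TS and MECP candidates
#'
#' A TS candidate is accepted only if its refinement converged, it has
#' exactly one imaginary frequency, and its IRC endpoints classify (by
#' CNNC dihedral) as one cis-like (|omega| < 60) and one trans-like
#' (|omega| > 120) structure. An MECP candidate is accepted only if its
#' optimization converged with the gap and projected gradient below
#' tolerance. Filtering never throws; every rejection carries a
#' machine-readable reason code.
#'
#' @param candidates list of candidate entries; a TS entry has fields
#'   `report` (azo_stationary) and `endpoint_omegas` (length-2 numeric or
#'   NULL); an MECP entry has `report` with kind "mecp".
#' @return list with `accepted` and `rejected` (each entries augmented
#'   with `reason` for rejections).
#' @export
apply_filters <- function(candidates) {
  accepted <- list(); rejected <- list()
  for (cand in candidates) {
    rep_ <- cand$report
    reason <- NULL
    if (identical(rep_$kind, "mecp")) {
      if (!isTRUE(rep_$converged)) reason <- "mecp_not_converged"
    } else {
      if (!isTRUE(rep_$converged)) {
        reason <- "ts_not_converged"
      } else if (is.na(rep_$n_imaginary) || rep_$n_imaginary != 1L) {
        reason <- "imaginary_count"
      } else if (!is.null(cand$endpoint_omegas)) {
        w <- abs(cand$endpoint_omegas)
        cis_like <- w < 60
        trans_like <- w > 120
        if (!(any(cis_like) && any(trans_like) &&
              any(cis_like != trans_like)))
          reason <- "irc_endpoints"
      }
    }
    if (is.null(reason)) {
      accepted[[length(accepted) + 1L]] <- cand
    } else {
      cand$reason <- reason
      rejected[[length(rejected) + 1L]] <- cand
    }
  }
  list(accepted = accepted, rejected = rejected)
}

# thermochemistry for one stationary report on a surface
.thermo_of <- function(surface, report, treatment, cfg) {
  va <- vibrational_analysis(surface, report, treatment)
  geom <- if (surface$coordinate_kind == "cartesian")
    geometry(surface$elements, matrix(report$x, ncol = 3, byrow = TRUE),
             check = FALSE)
  else NULL
  thermo_from_frequencies(va$frequencies, report$energy,
                          T = cfg$temperature, qh_cutoff = cfg$qh_cutoff,
                          geom = geom, treatment = treatment)
}

#' Run the full barrier workflow
#'
#' Executes, deterministically for a fixed seed: (1) cis and trans
#' minimization with conformer ensembles; (2) four relaxed scans (omega
#' to +180, omega to -180, alpha to 180, alpha' to 180) from the cis
#' minimum, each yielding a TS guess; (3) a fixed-core conformer search
#' per guess, keeping the `n_conformers` lowest, each refined by
#' eigenvector following (at most 4 x 5 = 20 TS optimizations); (4)
#' imaginary-frequency / convergence / IRC-endpoint filters; (5) for the
#' lowest-free-energy accepted TS of each rotational channel, the two
#' singlet-triplet crossings on its IRC, each refined to an MECP
#' (inversion channels are spin-allowed all the way and get Eyring rates
#' only); (6) quasiharmonic thermochemistry for all accepted species;
#' (7) Eyring rates per mechanism from ensemble activation free
#' energies, and ISC rates per rotational channel from the cis-side
#' MECP; (8) an assembled report with both theories side by side.
#'
#' @param structure optional `azo_geometry` cis starting structure;
#'   defaults to the surface's own cis reference.
#' @param surface a `two_state_surface`.
#' @param config an [azo_config()].
#' @return an `azo_barrier_report`.
#' @export
run_barrier_workflow <- function(structure = NULL, surface,
                                 config = azo_config()) {
  cfg <- config
  T_ <- cfg$temperature
  cart <- surface$coordinate_kind == "cartesian"
  failures <- list()
  note_fail <- function(stage, mech, msg)
    failures[[length(failures) + 1L]] <<-
      list(stage = stage, mechanism = mech, reason = msg)

  # (1) minima + conformer ensembles -----------------------------------
  x_cis0 <- if (!is.null(structure)) as_coord_vector(structure)
            else .start_coords(surface, "cis")
  x_trans0 <- .start_coords(surface, "trans")
  min_cis <- minimize(surface, x_cis0, tol = cfg$tol_opt)
  min_trans <- minimize(surface, x_trans0, tol = cfg$tol_opt)
  if (!min_cis$converged || !min_trans$converged)
    stop("workflow failed: cis/trans minimization did not converge")
  min_ensemble <- function(rep_, tag, seed_off) {
    members <- list(rep_)
    if (cart) {
      gg <- geometry(surface$elements,
                     matrix(rep_$x, ncol = 3, byrow = TRUE),
                     core = surface$core, tag = tag, check = FALSE)
      cs <- generate_ts_conformers(surface, gg, n_target = cfg$n_perturb,
                                   seed = cfg$seed + seed_off,
                                   freeze_core = FALSE,
                                   rmsd_thr = cfg$rmsd_thr,
                                   tol = cfg$tol_opt)
      cs <- select_lowest(cs, cfg$n_conformers)
      members <- lapply(cs$conformers, function(cf)
        minimize(surface, as_coord_vector(cf), tol = cfg$tol_opt))
      members <- Filter(function(m) m$converged, members)
      if (!length(members)) members <- list(rep_)
    }
    thermos <- lapply(members, .thermo_of, surface = surface,
                      treatment = "minimum", cfg = cfg)
    list(members = members, thermos = thermos,
         G_ens = ensemble_free_energy(thermos, T_),
         best = which.min(vapply(thermos, `[[`, numeric(1), "G")))
  }
  cis_ens <- min_ensemble(min_cis, "cis", 11L)
  trans_ens <- min_ensemble(min_trans, "trans", 12L)
  mc_cis <- .mech_coords(surface, min_cis$x)

  # (2) four relaxed scans ---------------------------------------------
  w0 <- mc_cis$omega
  scan_specs <- list(
    rotation_plus = list(driving = "omega",
                         grid = seq(w0, 180, by = cfg$scan_step)),
    rotation_minus = list(driving = "omega",
                          grid = seq(w0, -180, by = -cfg$scan_step)),
    inversion_alpha = list(driving = "alpha",
                           grid = seq(mc_cis$alpha, 180,
                                      by = cfg$scan_step)),
    inversion_alpha_prime = list(driving = "alpha_prime",
                                 grid = seq(mc_cis$alpha_prime, 180,
                                            by = cfg$scan_step)))
  ts_candidates <- list()
  n_ts_opt <- 0L
  for (mech in names(scan_specs)) {
    spec <- scan_specs[[mech]]
    sc <- tryCatch(
      relaxed_scan(surface, min_cis$x, spec$driving, spec$grid,
                   tol = cfg$tol_opt),
      error = function(e) { note_fail("scan", mech,
                                      conditionMessage(e)); NULL })
    if (is.null(sc)) next
    guess_x <- sc$reports[[sc$ts_guess_index]]$x

    # (3) conformers + EVF
    if (cart) {
      gg <- geometry(surface$elements,
                     matrix(guess_x, ncol = 3, byrow = TRUE),
                     core = surface$core, tag = mech, check = FALSE)
      cs <- tryCatch(
        generate_ts_conformers(surface, gg, n_target = cfg$n_perturb,
                               seed = cfg$seed + match(mech,
                                                       names(scan_specs)),
                               rmsd_thr = cfg$rmsd_thr, tol = cfg$tol_opt),
        error = function(e) { note_fail("conformers", mech,
                                        conditionMessage(e)); NULL })
      if (is.null(cs)) next
      cs <- select_lowest(cs, cfg$n_conformers)
      starts <- lapply(cs$conformers, as_coord_vector)
    } else {
      starts <- list(guess_x)
    }
    for (x0 in starts) {
      n_ts_opt <- n_ts_opt + 1L
      mode0 <- if (cart)
        cartesian_driving_constraint(surface, spec$driving, 0)$grad(x0)
      else {
        v <- numeric(surface$dimensionality)
        v[c(omega = 1L, alpha = 2L, alpha_prime = 3L)[[spec$driving]]] <- 1
        v
      }
      ts <- evf_saddle(surface, x0, tol = cfg$tol_ts, trust = 0.05,
                       mode0 = mode0)
      mc <- .mech_coords(surface, ts$x)
      label <- tryCatch(
        classify_mechanism(mc, cfg$classify_tol, cfg$classify_tol),
        error = function(e) NA_character_)
      epo <- NULL
      if (isTRUE(ts$converged) && identical(ts$n_imaginary, 1L)) {
        path <- irc(surface, ts, step_size = cfg$irc_step,
                    max_points = cfg$irc_max_points, tol = cfg$tol_opt * 10)
        epo <- c(.mech_coords(surface,
                   attr(path$forward, "coords")[nrow(path$forward), ])$omega,
                 .mech_coords(surface,
                   attr(path$backward, "coords")[nrow(path$backward), ])$omega)
      } else {
        path <- NULL
      }
      ts_candidates[[length(ts_candidates) + 1L]] <-
        list(mechanism = if (is.na(label)) mech else label,
             scan_channel = mech, report = ts,
             endpoint_omegas = epo, irc_path = path)
    }
  }

  # (4) filters ---------------------------------------------------------
  filt <- apply_filters(ts_candidates)
  accepted <- filt$accepted

  # (6,7) thermochemistry + per-mechanism results -----------------------
  mech_results <- list()
  for (mech in mechanism_labels()) {
    idx <- which(vapply(accepted, `[[`, character(1), "mechanism") == mech)
    if (!length(idx)) {
      note_fail("mechanism", mech, "no accepted transition state")
      next
    }
    thermos <- lapply(accepted[idx], function(cand)
      .thermo_of(surface, cand$report, "ts_projected", cfg))
    G_ts <- ensemble_free_energy(thermos, T_)
    Gs <- vapply(thermos, `[[`, numeric(1), "G")
    best <- idx[which.min(Gs)]
    dG <- G_ts - cis_ens$G_ens
    mech_results[[mech]] <- list(
      mechanism = mech, n_conformer_ts = length(idx),
      ts_report = accepted[[best]]$report,
      ts_thermo = thermos[[which.min(Gs)]],
      ts_coords = .mech_coords(surface, accepted[[best]]$report$x),
      G_ts_ensemble = G_ts, dG_dagger = dG,
      k_eyring = eyring_rate(dG, T_),
      best_candidate = accepted[[best]])
  }

  # (5) MECPs on rotational channels ------------------------------------
  for (mech in c("rotation_plus", "rotation_minus")) {
    mr <- mech_results[[mech]]
    if (is.null(mr)) next
    path <- mr$best_candidate$irc_path
    seeds <- c(locate_seam_crossings(path$forward),
               locate_seam_crossings(path$backward))
    if (length(seeds) < 2) {
      note_fail("crossings", mech,
                sprintf("expected 2 seam crossings, found %d",
                        length(seeds)))
      next
    }
    mecps <- lapply(seeds, function(s)
      mecp_optimize(surface, s$x, tol_gap = cfg$tol_gap,
                    tol_grad = cfg$tol_grad))
    mfilt <- apply_filters(lapply(mecps, function(m) list(report = m)))
    if (length(mfilt$accepted) < 2) {
      note_fail("mecp", mech, "MECP optimization not converged")
      next
    }
    mecps <- lapply(mfilt$accepted, `[[`, "report")
    womega <- vapply(mecps, function(m)
      abs(.mech_coords(surface, m$x)$omega), numeric(1))
    cis_side <- mecps[[which.min(womega)]]
    trans_side <- mecps[[which.max(womega)]]
    th_x <- .thermo_of(surface, cis_side, "mecp_seam_projected", cfg)
    dG_X <- th_x$G - cis_ens$G_ens
    m3 <- .coord_masses(surface)
    dF <- sqrt(sum((cis_side$g_diff / sqrt(m3))^2))
    kpref <- isc_prefactor(cfg$H_SO, dF, mu = 1, T = T_)
    k_isc_v <- isc_rate(kpref, dG_X, T_)
    S_cis <- cis_ens$thermos[[cis_ens$best]]$S
    dS_X <- th_x$S - S_cis
    mech_results[[mech]]$isc <- list(
      mecp_cis_side = cis_side, mecp_trans_side = trans_side,
      mecp_thermo = th_x,
      omega_cis_side = .mech_coords(surface, cis_side$x)$omega,
      omega_trans_side = .mech_coords(surface, trans_side$x)$omega,
      dG_X = dG_X, dF = dF, k_isc_prefactor = kpref, k_isc = k_isc_v,
      dG_eff = effective_activation(k_isc_v, T_),
      dS_X = dS_X,
      dS_eff = effective_entropy(dS_X, kpref, T_),
      half_life_isc = half_life(k_isc_v))
  }

  # (8) assemble ---------------------------------------------------------
  dG_rxn <- cis_ens$G_ens - trans_ens$G_ens
  ey <- vapply(mech_results, function(m) m$dG_dagger, numeric(1))
  winner_eyring <- if (length(ey)) names(which.min(ey)) else NA_character_
  isc_ks <- vapply(mech_results, function(m)
    if (is.null(m$isc)) NA_real_ else m$isc$k_isc, numeric(1))
  winner_isc <- if (any(!is.na(isc_ks)))
    names(which.max(replace(isc_ks, is.na(isc_ks), -Inf)))
  else NA_character_
  lam <- list(cis = NA_real_, trans = NA_real_)
  gap_cis <- surface_eval(surface, min_cis$x)$gap_s0s1
  gap_trans <- surface_eval(surface, min_trans$x)$gap_s0s1
  if (is.finite(gap_cis)) lam$cis <- gap_wavelength(gap_cis)
  if (is.finite(gap_trans)) lam$trans <- gap_wavelength(gap_trans)

  structure(list(
    tag = if (!is.null(structure)) structure$tag else surface$name,
    surface = surface$name, config = cfg,
    config_hash = .config_hash(cfg), seed = cfg$seed,
    temperature = T_,
    cis = list(report = min_cis, thermos = cis_ens$thermos,
               G_ensemble = cis_ens$G_ens,
               coords = .mech_coords(surface, min_cis$x)),
    trans = list(report = min_trans, thermos = trans_ens$thermos,
                 G_ensemble = trans_ens$G_ens,
                 coords = .mech_coords(surface, min_trans$x)),
    dG_rxn = dG_rxn,
    mechanisms = mech_results,
    winner_eyring = winner_eyring, winner_isc = winner_isc,
    n_ts_optimizations = n_ts_opt,
    filters = list(n_accepted = length(filt$accepted),
                   n_rejected = length(filt$rejected),
                   rejected_reasons = vapply(filt$rejected, `[[`,
                                             character(1), "reason")),
    lambda = lam,
    failures = failures,
    version = tryCatch(as.character(utils::packageVersion("azokin")),
                       error = function(e) "dev")),
    class = "azo_barrier_report")
}

#' @export
print.azo_barrier_report <- function(x, ...) {
  cat(sprintf("<azo_barrier_report> %s on %s at %.2f K\n", x$tag,
              x$surface, x$temperature))
  cat(sprintf("  dG_rxn (G_cis - G_trans) = %.3f kcal/mol\n", x$dG_rxn))
  for (m in x$mechanisms) {
    cat(sprintf("  %-22s dG+ = %6.2f  k_eyring = %.3e 1/s  t1/2 = %.3e s\n",
                m$mechanism, m$dG_dagger, m$k_eyring,
                half_life(m$k_eyring)))
    if (!is.null(m$isc))
      cat(sprintf(
        "  %-22s dG_X = %6.2f  k_ISC = %.3e 1/s  dG_eff = %6.2f  dS_eff = %7.2f J/(mol K)\n",
        "", m$isc$dG_X, m$isc$k_isc, m$isc$dG_eff, m$isc$dS_eff))
  }
  cat(sprintf("  winner: eyring=%s isc=%s; %d TS optimizations; filters %d/%d accepted\n",
              x$winner_eyring, x$winner_isc, x$n_ts_optimizations,
              x$filters$n_accepted,
              x$filters$n_accepted + x$filters$n_rejected))
  invisible(x)
}

#' Serialize a barrier report to JSON
#'
#' @param report an `azo_barrier_report`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
barrier_report_json <- function(report, path = NULL) {
  strip <- function(m) {
    out <- list(mechanism = m$mechanism,
                n_conformer_ts = m$n_conformer_ts,
                dG_dagger = m$dG_dagger, k_eyring = m$k_eyring,
                half_life_eyring = half_life(m$k_eyring),
                ts_energy = m$ts_report$energy,
                ts_coords = m$ts_coords[c("omega", "alpha", "alpha_prime")],
                ts_n_imaginary = m$ts_report$n_imaginary)
    if (!is.null(m$isc))
      out$isc <- m$isc[c("omega_cis_side", "omega_trans_side", "dG_X",
                         "dF", "k_isc_prefactor", "k_isc", "dG_eff",
                         "dS_X", "dS_eff", "half_life_isc")]
    out
  }
  obj <- list(
    tag = report$tag, surface = report$surface,
    temperature = report$temperature, seed = report$seed,
    config_hash = report$config_hash, version = report$version,
    dG_rxn = report$dG_rxn,
    G_cis_ensemble = report$cis$G_ensemble,
    G_trans_ensemble = report$trans$G_ensemble,
    mechanisms = lapply(report$mechanisms, strip),
    winner_eyring = report$winner_eyring,
    winner_isc = report$winner_isc,
    n_ts_optimizations = report$n_ts_optimizations,
    filters = report$filters,
    lambda_cis_nm = report$lambda$cis,
    lambda_trans_nm = report$lambda$trans,
    failures = report$failures)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' One-row CSV summary of a barrier report
#'
#' @param report an `azo_barrier_report`.
#' @param path optional output path; appends a header + row.
#' @return data.frame with one row.
#' @export
barrier_report_csv <- function(report, path = NULL) {
  getm <- function(mech, field, sub = NULL) {
    m <- report$mechanisms[[mech]]
    if (is.null(m)) return(NA_real_)
    if (is.null(sub)) m[[field]]
    else if (is.null(m$isc)) NA_real_ else m$isc[[field]]
  }
  rot <- c("rotation_plus", "rotation_minus")
  inv <- c("inversion_alpha", "inversion_alpha_prime")
  dg_rot <- suppressWarnings(min(vapply(rot, getm, numeric(1),
                                        field = "dG_dagger"), na.rm = TRUE))
  dg_inv <- suppressWarnings(min(vapply(inv, getm, numeric(1),
                                        field = "dG_dagger"), na.rm = TRUE))
  isc_of <- function(f) {
    v <- vapply(rot, getm, numeric(1), field = f, sub = "isc")
    if (all(is.na(v))) NA_real_ else v[which.min(v)]
  }
  df <- data.frame(
    tag = report$tag, T_K = report$temperature,
    dG_dagger_rot = dg_rot, dG_dagger_inv = dg_inv,
    dG_X = isc_of("dG_X"), dG_eff = isc_of("dG_eff"),
    dS_eff = isc_of("dS_eff"),
    k_eyring_best = if (!is.na(report$winner_eyring))
      report$mechanisms[[report$winner_eyring]]$k_eyring else NA_real_,
    k_isc_best = if (!is.na(report$winner_isc))
      report$mechanisms[[report$winner_isc]]$isc$k_isc else NA_real_,
    dG_rxn = report$dG_rxn,
    lambda_cis_nm = report$lambda$cis,
    lambda_trans_nm = report$lambda$trans,
    n_accepted = report$filters$n_accepted,
    n_rejected = report$filters$n_rejected,
    stringsAsFactors = FALSE)
  df$half_life_eyring_s <- if (!is.na(df$k_eyring_best))
    half_life(df$k_eyring_best) else NA_real_
  df$half_life_isc_s <- if (!is.na(df$k_isc_best))
    half_life(df$k_isc_best) else NA_real_
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
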