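#' @title Miniature equivariant message-passing potential
#' @description A small invariant/equivariant neural interatomic
#'   potential with separate S0-energy, T1-energy and S0/S1-gap heads
#'   over a shared message-passing trunk, trained on energies, forces and
#'   gaps. Atoms carry scalar features and (within each interaction)
#'   vector features built from pair orientations; all readout quantities
#'   are invariant, so predicted energies are exactly invariant under
#'   rotation, translation and atom permutation and forces (obtained by
#'   differentiating the energy with respect to coordinates) transform
#'   equivariantly. Three-member ensembles provide a disagreement-based
#'   uncertainty, which drives active learning.
#' @name mlpot
NULL

#' Potential configuration
#'
#' @param feature_width scalar feature width per atom (default 64).
#' @param n_interactions message-passing rounds (default 3).
#' @param cutoff radial cutoff, angstrom (default 5).
#' @param n_rbf radial basis functions (default 16).
#' @param learning_rate Adam step size.
#' @param batch_size molecules per minibatch.
#' @param max_epochs training epochs.
#' @param seed base RNG seed (member m trains with seed + m - 1).
#' @param loss_weights named vector, weights of the energy / force / gap
#'   mean-squared-error terms (default 1, 10, 1).
#' @return a `potential_config` list.
#' @export
potential_config <- function(feature_width = 64L, n_interactions = 3L,
                             cutoff = 5.0, n_rbf = 16L,
                             learning_rate = 5e-3, batch_size = 32L,
                             max_epochs = 200L, seed = 1L,
                             loss_weights = c(energy = 1, force = 10,
                                              gap = 1)) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (n_interactions < 1) stop("need at least one interaction block")
  structure(list(feature_width = as.integer(feature_width),
                 n_interactions = as.integer(n_interactions),
                 cutoff = cutoff, n_rbf = as.integer(n_rbf),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 loss_weights = loss_weights),
            class = "potential_config")
}

# --- parameters -------------------------------------------------------------

.init_params <- function(config, n_elem, seed) {
  set.seed(seed)
  F_ <- config$feature_width; R_ <- config$n_rbf
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)),
                                nr, nc)
  layers <- lapply(seq_len(config$n_interactions), function(t)
    list(W1 = rn(R_, F_), W2 = rn(F_, F_), W3 = rn(R_, F_),
         W4 = rn(F_, F_), b = numeric(F_)))
  list(emb = rn(n_elem, F_) * sqrt(n_elem),   # O(1) initial features
       layers = layers,
       A1 = rn(F_, F_), a1 = numeric(F_), a2 = rn(F_, 3))
}

.flatten_params <- function(p) {
  unlist(list(p$emb, lapply(p$layers, unlist), p$A1, p$a1, p$a2),
         use.names = FALSE)
}

.unflatten_params <- function(v, like) {
  pos <- 0L
  take <- function(x) {
    n <- length(x)
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
  }
  like$emb <- take(like$emb)
  like$layers <- lapply(like$layers, function(L) lapply(L, take))
  like$A1 <- take(like$A1); like$a1 <- take(like$a1); like$a2 <- take(like$a2)
  like
}

# --- batch assembly ---------------------------------------------------------

# records: list of list(elements, coords, ...); vocab: element symbols
.make_batch <- function(records, vocab) {
  nat <- vapply(records, function(r) length(r$elements), integer(1))
  off <- cumsum(c(0L, nat[-length(nat)]))
  Z <- unlist(lapply(records, function(r) {
    z <- match(r$elements, vocab)
    if (anyNA(z))
      stop("unseen element(s): ",
           paste(unique(r$elements[is.na(z)]), collapse = ", "))
    z
  }))
  pos <- do.call(rbind, lapply(records, `[[`, "coords"))
  mol <- rep(seq_along(records), nat)
  pi_ <- integer(0); pj <- integer(0)
  for (m in seq_along(records)) {
    n <- nat[m]
    if (n < 2) next
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$i != idx$j, ]
    pi_ <- c(pi_, idx$i + off[m]); pj <- c(pj, idx$j + off[m])
  }
  np <- length(pi_)
  out <- list(Z = Z, pos = pos, mol = mol, i = pi_, j = pj,
              n_atoms = length(Z), n_mol = length(records), nat = nat,
              Ai = NULL, Aj = NULL, Amol = NULL)
  if (np >= 20000L) {   # sparse incidence matrices pay off on big batches
    out$Ai <- Matrix::sparseMatrix(i = pi_, j = seq_len(np), x = 1,
                                   dims = c(length(Z), np))
    out$Aj <- Matrix::sparseMatrix(i = pj, j = seq_len(np), x = 1,
                                   dims = c(length(Z), np))
    out$Amol <- Matrix::sparseMatrix(i = mol, j = seq_along(mol), x = 1,
                                     dims = c(length(records), length(Z)))
  }
  out
}

.rowsum_to <- function(x, group, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# scatter-add (hot path): base rowsum for small batches (S4 dispatch on
# sparse matrices costs more than the arithmetic there), sparse matrix
# multiply for large training batches
.scatter <- function(A, x, group, n) {
  if (is.null(A) || length(group) < 20000L) {
    out <- matrix(0, n, ncol(x))
    rs <- rowsum(x, group)
    out[as.integer(rownames(rs)), ] <- rs
    out
  } else {
    as.matrix(A %*% x)
  }
}

# --- forward / backward -----------------------------------------------------

.forward <- function(params, config, batch, pos = batch$pos) {
  F_ <- config$feature_width; R_ <- config$n_rbf; rc <- config$cutoff
  i <- batch$i; j <- batch$j; n <- batch$n_atoms
  rvec <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  r <- sqrt(rowSums(rvec^2))
  rhat <- rvec / r
  mu <- seq(0, rc, length.out = R_)
  gam <- 1 / (2 * (rc / (R_ - 1))^2)
  dr_mu <- outer(r, mu, "-")
  gauss <- exp(-gam * dr_mu^2)
  inside <- r < rc
  fc <- ifelse(inside, 0.5 * (1 + cos(pi * r / rc)), 0)
  B <- gauss * fc
  s <- params$emb[batch$Z, , drop = FALSE]
  caches <- vector("list", config$n_interactions)
  for (t in seq_len(config$n_interactions)) {
    L <- params$layers[[t]]
    Filt <- B %*% L$W1
    m <- .scatter(batch$Ai, Filt * s[j, , drop = FALSE], i, n)
    FiltV <- B %*% L$W3
    Vmsg <- FiltV * s[j, , drop = FALSE]
    V <- lapply(1:3, function(d) .scatter(batch$Ai, Vmsg * rhat[, d], i, n))
    q <- V[[1]]^2 + V[[2]]^2 + V[[3]]^2
    ds <- tanh(sweep(m %*% L$W2 + q %*% L$W4, 2, L$b, "+"))
    caches[[t]] <- list(s_in = s, Filt = Filt, FiltV = FiltV, V = V,
                        q = q, m = m, ds = ds)
    s <- s + ds
  }
  pre_r <- sweep(s %*% params$A1, 2, params$a1, "+")
  h <- tanh(pre_r)
  e_atom <- h %*% params$a2
  E_raw <- .scatter(batch$Amol, e_atom, batch$mol, batch$n_mol)
  list(E_raw = E_raw, s_out = s, h = h, caches = caches,
       B = B, gauss = gauss, fc = fc, r = r, rhat = rhat,
       mu = mu, gam = gam, inside = inside, dr_mu = dr_mu)
}

# GE: n_mol x 3 adjoint of E_raw. Returns parameter gradients (same
# structure as params) and gpos (n_atoms x 3).
.backward <- function(params, config, batch, fw, GE) {
  i <- batch$i; j <- batch$j; n <- batch$n_atoms
  g_e_atom <- GE[batch$mol, , drop = FALSE]
  g <- list(emb = matrix(0, nrow(params$emb), ncol(params$emb)),
            layers = NULL, A1 = NULL, a1 = NULL, a2 = NULL)
  g$a2 <- crossprod(fw$h, g_e_atom)
  g_h <- g_e_atom %*% t(params$a2)
  g_pre <- g_h * (1 - fw$h^2)
  g$A1 <- crossprod(fw$s_out, g_pre)
  g$a1 <- colSums(g_pre)
  gs <- g_pre %*% t(params$A1)
  gB <- matrix(0, length(fw$r), config$n_rbf)
  g_rhat <- matrix(0, length(fw$r), 3)
  glayers <- vector("list", config$n_interactions)
  for (t in rev(seq_len(config$n_interactions))) {
    L <- params$layers[[t]]
    cc <- fw$caches[[t]]
    ga <- gs * (1 - cc$ds^2)
    gW2 <- crossprod(cc$m, ga)
    gW4 <- crossprod(cc$q, ga)
    gb <- colSums(ga)
    gm <- ga %*% t(L$W2)
    gq <- ga %*% t(L$W4)
    s_j <- cc$s_in[j, , drop = FALSE]
    # vector channel
    Vmsg <- cc$FiltV * s_j
    gVmsg <- matrix(0, length(fw$r), config$feature_width)
    for (d in 1:3) {
      gVd <- 2 * cc$V[[d]] * gq
      gVd_p <- gVd[i, , drop = FALSE]
      gVmsg <- gVmsg + gVd_p * fw$rhat[, d]
      g_rhat[, d] <- g_rhat[, d] + rowSums(gVd_p * Vmsg)
    }
    gFiltV <- gVmsg * s_j
    gW3 <- crossprod(fw$B, gFiltV)
    gB <- gB + gFiltV %*% t(L$W3)
    gs_nb <- gVmsg * cc$FiltV
    # scalar channel
    gMsg <- gm[i, , drop = FALSE]
    gFilt <- gMsg * s_j
    gW1 <- crossprod(fw$B, gFilt)
    gB <- gB + gFilt %*% t(L$W1)
    gs_nb <- gs_nb + gMsg * cc$Filt
    gs <- gs + .scatter(batch$Aj, gs_nb, j, n)
    glayers[[t]] <- list(W1 = gW1, W2 = gW2, W3 = gW3, W4 = gW4, b = gb)
  }
  g$layers <- glayers
  g$emb <- .rowsum_to(gs, batch$Z, nrow(params$emb))
  # coordinates
  dgauss <- fw$gauss * (-2 * fw$gam * fw$dr_mu)
  dfc <- ifelse(fw$inside, -0.5 * pi / config$cutoff *
                  sin(pi * fw$r / config$cutoff), 0)
  dBdr <- dgauss * fw$fc + fw$gauss * dfc
  g_r <- rowSums(gB * dBdr)
  dot_rh <- rowSums(g_rhat * fw$rhat)
  g_rvec <- g_rhat / fw$r - fw$rhat * (dot_rh / fw$r) + g_r * fw$rhat
  gpos <- .scatter(batch$Aj, g_rvec, j, n) - .scatter(batch$Ai, g_rvec, i, n)
  list(params = g, gpos = gpos)
}

# --- model container --------------------------------------------------------

#' Build an untrained potential
#'
#' Initializes a potential for a given element vocabulary. Atomic
#' features start from the element identity only; `n_interactions`
#' rounds of message passing mix distance (radial basis) and orientation
#' (unit-vector) information within the cutoff; per-atom energies are
#' read out and summed to molecular energies for each of the three
#' heads. Forces follow by differentiating the energy with respect to
#' coordinates (reverse-mode, exact).
#'
#' @param config a [potential_config()].
#' @param vocab character vector of element symbols the model knows.
#' @param seed RNG seed for weight initialization.
#' @return an `azo_potential`.
#' @export
build_model <- function(config, vocab, seed = config$seed) {
  norm <- list(eref = matrix(0, length(vocab), 3,
                             dimnames = list(vocab, NULL)),
               sigma = c(1, 1, 1))
  structure(list(config = config, vocab = vocab,
                 params = .init_params(config, length(vocab), seed),
                 norm = norm, seed = seed, history = NULL),
            class = "azo_potential")
}

#' @export
print.azo_potential <- function(x, ...) {
  cat(sprintf("<azo_potential> width=%d interactions=%d cutoff=%.1fA vocab=%s%s\n",
              x$config$feature_width, x$config$n_interactions,
              x$config$cutoff, paste(x$vocab, collapse = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# physical-scale predictions for a list of records
.predict_model <- function(model, records, forces = TRUE,
                           forces_t1 = TRUE) {
  batch <- .make_batch(records, model$vocab)
  fw <- .forward(model$params, model$config, batch)
  refs <- apply(model$norm$eref, 2, function(col)
    as.numeric(rowsum(col[batch$Z], batch$mol)))
  refs <- matrix(refs, ncol = 3)
  E <- sweep(fw$E_raw, 2, model$norm$sigma, "*") + refs
  out <- list(e_s0 = E[, 1], e_t1 = E[, 2], gap = E[, 3])
  if (forces) {
    nm <- batch$n_mol
    for (hd in if (forces_t1) 1:2 else 1L) {
      GE <- matrix(0, nm, 3); GE[, hd] <- 1
      bw <- .backward(model$params, model$config, batch, fw, GE)
      Fm <- -model$norm$sigma[hd] * bw$gpos
      out[[c("forces_s0", "forces_t1")[hd]]] <-
        lapply(seq_len(nm), function(m) Fm[batch$mol == m, , drop = FALSE])
    }
  }
  out
}

# --- training ---------------------------------------------------------------

# loss and parameter gradient on one minibatch of records; labels are
# fields e_s0, e_t1, gap (may be NA), f_s0, f_t1 on each record
.loss_grad <- function(model, records, eps_dir = 1e-4) {
  cfg <- model$config
  w <- cfg$loss_weights
  batch <- .make_batch(records, model$vocab)
  fw <- .forward(model$params, cfg, batch)
  nm <- batch$n_mol
  refs <- apply(model$norm$eref, 2, function(col)
    as.numeric(rowsum(col[batch$Z], batch$mol)))
  refs <- matrix(refs, ncol = 3)
  sig <- model$norm$sigma
  E <- sweep(fw$E_raw, 2, sig, "*") + refs
  lab <- cbind(vapply(records, `[[`, numeric(1), "e_s0"),
               vapply(records, `[[`, numeric(1), "e_t1"),
               vapply(records, function(r)
                 if (is.null(r$gap) || is.na(r$gap)) NA_real_ else r$gap,
                 numeric(1)))
  res <- E - lab
  has_gap <- !is.na(lab[, 3])
  loss <- w[["energy"]] * (mean(res[, 1]^2) + mean(res[, 2]^2))
  GE <- cbind(2 * w[["energy"]] * sig[1] * res[, 1] / nm,
              2 * w[["energy"]] * sig[2] * res[, 2] / nm,
              0)
  if (any(has_gap)) {
    ng <- sum(has_gap)
    loss <- loss + w[["gap"]] * mean(res[has_gap, 3]^2)
    GE[, 3] <- ifelse(has_gap, 2 * w[["gap"]] * sig[3] * res[, 3] / ng, 0)
    GE[is.na(GE[, 3]), 3] <- 0
  }
  bw <- .backward(model$params, cfg, batch, fw, GE)
  gflat <- .flatten_params(bw$params)
  # force terms via the directional-derivative identity:
  # dLf/dtheta = -sigma^2/(2 eps) [dEraw/dtheta(x + eps w) -
  #                                dEraw/dtheta(x - eps w)],
  # with w the (detached) scaled force residual
  ntot3 <- 3 * batch$n_atoms
  for (hd in 1:2) {
    key <- c("f_s0", "f_t1")[hd]
    Flab <- do.call(rbind, lapply(records, `[[`, key))
    GEh <- matrix(0, nm, 3); GEh[, hd] <- 1
    bwF <- .backward(model$params, cfg, batch, fw, GEh)
    Fhat <- -sig[hd] * bwF$gpos
    resF <- Fhat - Flab
    loss <- loss + w[["force"]] * sum(resF^2) / ntot3
    wdir <- 2 * w[["force"]] * resF / ntot3
    scl <- max(abs(wdir), 1e-12)
    eps <- eps_dir / scl
    # one-sided directional difference; the base parameter gradient of
    # this head is bwF's own parameter gradient
    fw2 <- .forward(model$params, cfg, batch,
                    pos = batch$pos + eps * wdir)
    bw2 <- .backward(model$params, cfg, batch, fw2, GEh)
    gflat <- gflat - sig[hd] / eps *
      (.flatten_params(bw2$params) - .flatten_params(bwF$params))
  }
  list(loss = as.numeric(loss), grad = gflat)
}

# least-squares per-element reference energies and residual scales
.fit_norm <- function(records, vocab) {
  X <- t(vapply(records, function(r)
    vapply(vocab, function(e) sum(r$elements == e), numeric(1)),
    numeric(length(vocab))))
  X <- matrix(X, ncol = length(vocab))
  eref <- matrix(0, length(vocab), 3, dimnames = list(vocab, NULL))
  sigma <- c(1, 1, 1)
  labs <- list(vapply(records, `[[`, numeric(1), "e_s0"),
               vapply(records, `[[`, numeric(1), "e_t1"),
               vapply(records, function(r)
                 if (is.null(r$gap) || is.na(r$gap)) NA_real_ else r$gap,
                 numeric(1)))
  for (hd in 1:3) {
    y <- labs[[hd]]
    ok <- !is.na(y)
    if (!any(ok)) next
    A <- crossprod(X[ok, , drop = FALSE]) + 1e-8 * diag(length(vocab))
    beta <- solve(A, crossprod(X[ok, , drop = FALSE], y[ok]))
    eref[, hd] <- beta
    resid <- y[ok] - X[ok, , drop = FALSE] %*% beta
    sigma[hd] <- max(stats::sd(resid), 1e-3)
  }
  list(eref = eref, sigma = sigma)
}

#' Train one potential on a labeled dataset
#'
#' Adam on the weighted sum of energy, force and gap mean-squared
#' errors. Gap labels may be missing (NA) on individual records; they
#' simply drop out of the gap term. Deterministic for a fixed seed.
#'
#' @param model an `azo_potential` from [build_model()].
#' @param dataset list of records: elements, coords, e_s0, e_t1, f_s0,
#'   f_t1 (n x 3 matrices, kcal/mol/angstrom), gap (or NA).
#' @param verbose print the loss every few epochs.
#' @return the trained `azo_potential` with a `history` data.frame.
#' @export
train_model <- function(model, dataset, verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  cfg <- model$config
  model$norm <- .fit_norm(dataset, model$vocab)
  set.seed(model$seed)
  theta <- .flatten_params(model$params)
  mt <- vt <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  it <- 0L
  hist_epoch <- integer(0); hist_loss <- numeric(0)
  nb <- max(1L, length(dataset) %/% cfg$batch_size)
  base_lr <- cfg$learning_rate
  for (epoch in seq_len(cfg$max_epochs)) {
    # step decay: x0.3 at 60% and 85% of the schedule
    lr <- base_lr * if (epoch > 0.85 * cfg$max_epochs) 0.09
                    else if (epoch > 0.6 * cfg$max_epochs) 0.3 else 1
    perm <- sample.int(length(dataset))
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- perm[seq.int(bi, length(dataset), by = nb)]
      lg <- .loss_grad(model, dataset[idx])
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", epoch,
             " (batch ", bi, "); try a smaller learning rate")
      it <- it + 1L
      mt <- b1 * mt + (1 - b1) * lg$grad
      vt <- b2 * vt + (1 - b2) * lg$grad^2
      mh <- mt / (1 - b1^it); vh <- vt / (1 - b2^it)
      theta <- theta - lr * mh / (sqrt(vh) + epsA)
      model$params <- .unflatten_params(theta, model$params)
      ep_loss <- ep_loss + lg$loss / nb
    }
    hist_epoch <- c(hist_epoch, epoch); hist_loss <- c(hist_loss, ep_loss)
    if (verbose && (epoch %% 10 == 0 || epoch == 1))
      message(sprintf("epoch %3d  loss %.6f", epoch, ep_loss))
  }
  model$history <- data.frame(epoch = hist_epoch, loss = hist_loss)
  model
}

#' Train a potential ensemble
#'
#' Trains `n_members` models that differ only by their initialization /
#' shuffling seed (seed, seed+1, ...), the standard recipe for
#' disagreement-based uncertainty.
#'
#' @param dataset labeled records (see [train_model()]).
#' @param config a [potential_config()].
#' @param n_members ensemble size (default 3).
#' @param vocab element vocabulary; defaults to the elements present.
#' @param verbose print training progress.
#' @return an `azo_ensemble`.
#' @export
train_ensemble <- function(dataset, config, n_members = 3L, vocab = NULL,
                           verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  if (is.null(vocab))
    vocab <- sort(unique(unlist(lapply(dataset, `[[`, "elements"))))
  members <- lapply(seq_len(n_members), function(m) {
    mod <- build_model(config, vocab, seed = config$seed + m - 1L)
    mod$seed <- config$seed + m - 1L
    train_model(mod, dataset, verbose = verbose)
  })
  structure(list(members = members, config = config, vocab = vocab),
            class = "azo_ensemble")
}

#' @export
print.azo_ensemble <- function(x, ...) {
  cat(sprintf("<azo_ensemble> %d members, width=%d\n",
              length(x$members), x$config$feature_width))
  invisible(x)
}

#' Ensemble prediction with disagreement uncertainty
#'
#' Averages member predictions; the uncertainty is the population
#' standard deviation of the member S0 energies (energy disagreement
#' only). Deterministic.
#'
#' @param ensemble an `azo_ensemble`.
#' @param geoms one `azo_geometry` or a list of them (or records with
#'   elements/coords).
#' @param forces also return mean forces (default TRUE).
#' @return list with e_s0_mean, e_t1_mean, gap_mean, e_s0_std (one entry
#'   per geometry), forces_s0_mean / forces_t1_mean (lists of n x 3
#'   matrices), and per-member values in `members`.
#' @export
predict_ensemble <- function(ensemble, geoms, forces = TRUE,
                             forces_t1 = TRUE) {
  if (inherits(geoms, "azo_geometry") ||
      (!is.null(geoms$elements) && !is.null(geoms$coords)))
    geoms <- list(geoms)
  per <- lapply(ensemble$members, .predict_model, records = geoms,
                forces = forces, forces_t1 = forces_t1)
  es0 <- do.call(cbind, lapply(per, `[[`, "e_s0"))
  et1 <- do.call(cbind, lapply(per, `[[`, "e_t1"))
  gp <- do.call(cbind, lapply(per, `[[`, "gap"))
  M <- length(per)
  out <- list(e_s0_mean = rowMeans(es0), e_t1_mean = rowMeans(et1),
              gap_mean = rowMeans(gp),
              e_s0_std = sqrt(pmax(rowMeans(es0^2) - rowMeans(es0)^2, 0)),
              members = per)
  if (forces) {
    avg_forces <- function(key) {
      lapply(seq_along(geoms), function(m) {
        Reduce(`+`, lapply(per, function(p) p[[key]][[m]])) / M
      })
    }
    out$forces_s0_mean <- avg_forces("forces_s0")
    if (forces_t1) out$forces_t1_mean <- avg_forces("forces_t1")
  }
  out
}

# --- checkpointing and dataset i/o ------------------------------------------

#' Save / load an ensemble checkpoint
#'
#' The checkpoint is a self-describing archive holding the
#' configuration, element vocabulary, normalization statistics and all
#' member weights; reloading reproduces predictions bit-identically.
#'
#' @param ensemble an `azo_ensemble`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `azo_ensemble`.
#' @export
save_checkpoint <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "azo_ensemble")) stop("not an ensemble checkpoint")
  x
}

#' Write / read a labeled dataset as JSON-lines
#'
#' One JSON object per line with fields elements, coords, e_s0, f_s0,
#' e_t1, f_t1, gap.
#'
#' @param dataset list of labeled records.
#' @param path file path.
#' @return `read_dataset_jsonl` returns the list of records.
#' @export
write_dataset_jsonl <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in dataset) {
    writeLines(jsonlite::toJSON(
      list(elements = r$elements, coords = r$coords, e_s0 = r$e_s0,
           f_s0 = r$f_s0, e_t1 = r$e_t1, f_t1 = r$f_t1,
           gap = if (is.null(r$gap)) NA else r$gap),
      auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_dataset_jsonl
#' @export
read_dataset_jsonl <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    x$coords <- matrix(x$coords, ncol = 3)
    x$f_s0 <- matrix(x$f_s0, ncol = 3)
    x$f_t1 <- matrix(x$f_t1, ncol = 3)
    if (is.null(x$gap)) x$gap <- NA_real_
    x
  })
}

# --- active learning --------------------------------------------------------

#' Active-learning selection from a geometry pool
#'
#' Splits the selection into an uncertainty slice (largest ensemble
#' disagreement first), an energy slice (Boltzmann-weighted sampling of
#' the predicted S0 energies at `sel_temperature`), and a uniform random
#' slice, with no duplicates across slices. Deterministic given the
#' seed. Selecting the whole pool returns the whole pool regardless of
#' the fractions.
#'
#' @param pool list of geometries/records.
#' @param ensemble trained `azo_ensemble` scoring the pool.
#' @param n_select number to select.
#' @param fractions named numeric (uncertainty, random, energy) summing
#'   to 1.
#' @param seed RNG seed.
#' @param sel_temperature Boltzmann temperature for the energy slice, K.
#' @return integer indices into `pool`, uncertainty slice first.
#' @export
select_active_learning <- function(pool, ensemble, n_select,
                                   fractions = c(uncertainty = 0.5,
                                                 random = 0.25,
                                                 energy = 0.25),
                                   seed = 1L, sel_temperature = 1000) {
  if (length(pool) == 0) stop("empty pool")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (n_select > length(pool)) stop("n_select exceeds pool size")
  if (n_select == length(pool)) return(seq_along(pool))
  pred <- predict_ensemble(ensemble, pool, forces = FALSE)
  set.seed(seed)
  n_unc <- round(n_select * fractions[["uncertainty"]])
  n_en <- round(n_select * fractions[["energy"]])
  n_rnd <- n_select - n_unc - n_en
  taken <- integer(0)
  if (n_unc > 0)
    taken <- order(pred$e_s0_std, decreasing = TRUE)[seq_len(n_unc)]
  if (n_en > 0) {
    rem <- setdiff(seq_along(pool), taken)
    RT <- azo_constants$R_gas * sel_temperature / azo_constants$J_per_kcal
    e <- pred$e_s0_mean[rem]
    wgt <- exp(-(e - min(e)) / RT)
    taken <- c(taken, rem[sample.int(length(rem), n_en, prob = wgt)])
  }
  if (n_rnd > 0) {
    rem <- setdiff(seq_along(pool), taken)
    taken <- c(taken, rem[sample.int(length(rem), n_rnd)])
  }
  taken
}

# --- ML potential as a two-state surface ------------------------------------

#' Wrap a trained ensemble as a two-state surface
#'
#' Exposes the ensemble-mean S0/T1 energies, analytic mean forces and
#' the gap head as a Cartesian [two_state_surface()], so the saddle
#' search, IRC, MECP and thermochemistry machinery runs unchanged on the
#' learned potential.
#'
#' With `uncertainty_penalty > 0` the S0 energy (and its gradient) is
#' augmented by kappa times the ensemble disagreement, E + kappa * sd.
#' Inside the training distribution the disagreement is small and the
#' surface is essentially the mean; outside it the penalty walls off the
#' extrapolation holes that unconstrained optimizers otherwise fall
#' into. This is the standard uncertainty-aware trick for geometry
#' optimization on learned potentials; report energies from an
#' unpenalized surface at the converged geometries.
#'
#' @param ensemble a trained `azo_ensemble`.
#' @param template an `azo_geometry` fixing elements, core and atom
#'   order.
#' @param uncertainty_penalty kappa, the weight of the ensemble standard
#'   deviation added to the S0 energy (default 0: plain mean surface).
#' @param t1 when FALSE, skip the T1 force evaluation (the T1 energy is
#'   still reported with a zero gradient); single-state optimizations on
#'   the learned surface run about a third faster.
#' @return a `two_state_surface`.
#' @export
ml_surface <- function(ensemble, template, uncertainty_penalty = 0,
                       t1 = TRUE) {
  elements <- template$elements
  kappa <- uncertainty_penalty
  M <- length(ensemble$members)
  # the pair/group structure depends only on the element list: build it
  # once and reuse across evaluations
  batch0 <- .make_batch(list(list(elements = elements,
                                  coords = template$coords)),
                        ensemble$vocab)
  refs <- vapply(ensemble$members, function(mod)
    colSums(mod$norm$eref[batch0$Z, , drop = FALSE]), numeric(3))
  evaluate <- function(x) {
    pos <- matrix(x, ncol = 3, byrow = TRUE)
    ei <- numeric(M); ti <- numeric(M); gpi <- numeric(M)
    gi <- vector("list", M)
    gt <- 0
    for (m in seq_len(M)) {
      mod <- ensemble$members[[m]]
      fw <- .forward(mod$params, mod$config, batch0, pos = pos)
      sig <- mod$norm$sigma
      ei[m] <- sig[1] * fw$E_raw[1, 1] + refs[1, m]
      ti[m] <- sig[2] * fw$E_raw[1, 2] + refs[2, m]
      gpi[m] <- sig[3] * fw$E_raw[1, 3] + refs[3, m]
      GE <- matrix(c(1, 0, 0), 1, 3)
      bw <- .backward(mod$params, mod$config, batch0, fw, GE)
      gi[[m]] <- sig[1] * as.numeric(t(bw$gpos))
      if (t1) {
        GEt <- matrix(c(0, 1, 0), 1, 3)
        bwt <- .backward(mod$params, mod$config, batch0, fw, GEt)
        gt <- gt + sig[2] * as.numeric(t(bwt$gpos)) / M
      }
    }
    e_s0 <- mean(ei)
    g_s0 <- Reduce(`+`, gi) / M
    if (kappa > 0 && M > 1) {
      sd_ <- sqrt(max(mean(ei^2) - mean(ei)^2, 0))
      if (sd_ > 1e-10) {
        dsd <- (Reduce(`+`, Map(`*`, gi, ei)) / M - e_s0 * g_s0) / sd_
        e_s0 <- e_s0 + kappa * sd_
        g_s0 <- g_s0 + kappa * dsd
      }
    }
    list(e_s0 = e_s0, g_s0 = g_s0,
         e_t1 = mean(ti),
         g_t1 = if (t1) gt else numeric(3L * length(elements)),
         gap_s0s1 = mean(gpi))
  }
  two_state_surface(name = "ml_ensemble",
                    dimensionality = 3L * length(elements),
                    coordinate_kind = "cartesian", evaluate = evaluate,
                    params = list(n_members = M,
                                  uncertainty_penalty = kappa),
                    elements = elements, masses = atomic_mass(elements),
                    core = template$core)
}
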