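# shared fixtures, built lazily once per test run

.fix <- new.env()

toy_surface <- function() {
  if (is.null(.fix$toy)) .fix$toy <- toy_azo_cartesian(1)
  .fix$toy
}

toy_cis_min <- function() {
  if (is.null(.fix$cis)) {
    .fix$cis <- minimize(toy_surface(),
                         as_coord_vector(toy_surface()$reference("cis")),
                         tol = 1e-5, with_hessian = FALSE)
  }
  .fix$cis
}

# dense-grid + Newton-polish oracle for stationary points of 2-D
# surfaces; independent of the package optimizers (plain Newton on the
# analytic gradient with finite-difference Hessians)
oracle_stationary_2d <- function(surface, xlim, ylim, n = 60,
                                 kind = c("minimum", "saddle")) {
  kind <- match.arg(kind)
  pts <- expand.grid(x = seq(xlim[1], xlim[2], length.out = n),
                     y = seq(ylim[1], ylim[2], length.out = n))
  found <- list()
  for (k in seq_len(nrow(pts))) {
    x <- as.numeric(pts[k, ])
    for (it in 1:60) {
      ev <- surface_eval(surface, x)
      if (max(abs(ev$g_s0)) < 1e-11) break
      H <- hessian_fd(surface, x, step = 1e-5)
      step <- tryCatch(-solve(H, ev$g_s0), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      if (sqrt(sum(step^2)) > 0.3) step <- step * 0.3 / sqrt(sum(step^2))
      x <- x + step
    }
    ev <- surface_eval(surface, x)
    if (max(abs(ev$g_s0)) > 1e-9) next
    if (x[1] < xlim[1] - 0.5 || x[1] > xlim[2] + 0.5 ||
        x[2] < ylim[1] - 0.5 || x[2] > ylim[2] + 0.5) next
    lam <- eigen(hessian_fd(surface, x, step = 1e-5),
                 symmetric = TRUE, only.values = TRUE)$values
    n_neg <- sum(lam < -1e-8)
    want <- if (kind == "minimum") 0L else 1L
    if (n_neg != want) next
    dup <- any(vapply(found, function(f)
      sqrt(sum((f$x - x)^2)) < 1e-4, logical(1)))
    if (!dup) found[[length(found) + 1L]] <-
      list(x = x, energy = ev$e_s0)
  }
  found[order(vapply(found, `[[`, numeric(1), "energy"))]
}

# random labeled records on the toy surface without touching the scans
quick_toy_records <- function(n, seed = 1, sd_ = 0.04) {
  surf <- toy_surface()
  set.seed(seed)
  base <- list(as_coord_vector(surf$reference("cis")),
               as_coord_vector(surf$reference("trans")))
  lapply(seq_len(n), function(k) {
    x <- base[[1 + k %% 2]] + rnorm(surf$dimensionality, sd = sd_)
    ev <- surface_eval(surf, x)
    list(elements = surf$elements,
         coords = matrix(x, ncol = 3, byrow = TRUE),
         e_s0 = ev$e_s0,
         f_s0 = -matrix(ev$g_s0, ncol = 3, byrow = TRUE),
         e_t1 = ev$e_t1,
         f_t1 = -matrix(ev$g_t1, ncol = 3, byrow = TRUE),
         gap = ev$gap_s0s1)
  })
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

model_report <- function() {
  if (is.null(.fix$model_report)) {
    .fix$model_report <- run_barrier_workflow(
      surface = model_azo_internal(),
      config = azo_config(scan_step = 10))
  }
  .fix$model_report
}
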