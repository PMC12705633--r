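# Reconstruction drivers.
#
# All gradient-based variants minimize Phi(lambda) = -L(lambda) + beta R(lambda)
# under one sign convention: g is the gradient of Phi, the search direction is
# s = P g (preconditioned), and the update is lambda <- lambda - alpha s. One
# iteration costs exactly one forward projection (of the search direction, also
# reused for the incremental sinogram update) and one back projection (inside
# the gradient); the expectation sinogram is refreshed by a full forward
# projection every `refresh_every` iterations to bound floating-point drift of
# the incremental update.
#
# Variants: PCG (filter + conjugate directions), PG (filter only), DCG
# (diagonal preconditioner + conjugate), DG (diagonal only), plus a BSREM
# comparator (subset-based, nonnegativity-constrained, relaxed).

#' Quadratic step size
#'
#' `alpha = <s|g> / (<f | 1/max(ybar, b) | f> + beta <s|H_rdp|s>)`: the exact
#' line minimizer of the local quadratic model built from the expected
#' tomographic curvature plus the prior curvature along the direction. If the
#' full denominator is nonpositive (the RDP is non-convex), the likelihood-only
#' curvature is used; if that is also nonpositive the step is degenerate and an
#' error is raised.
#'
#' @param s search direction image.
#' @param f forward projection of `s` (attenuation included).
#' @param g objective gradient image.
#' @param weights per-LOR curvature weights `1/max(ybar, b)` (see
#'   [hessian_weights()]).
#' @param lam current image (point at which the prior curvature is evaluated).
#' @param rdp an [rdp_params()]; its `beta` scales the prior term.
#' @return Positive scalar step whenever `<s|g> > 0`.
#' @export
step_size <- function(s, f, g, weights, lam, rdp) {
  num <- sum(s * g)
  den_lik <- sum(f * f * weights)
  den <- den_lik
  if (rdp$beta > 0) den <- den + rdp$beta * rdp_bilinear(lam, s, rdp)
  if (den <= 0) den <- den_lik                 # RDP non-convexity guard
  if (den <= 0) stop("degenerate step: nonpositive curvature along direction")
  num / den
}

#' Configure a reconstruction run
#'
#' @param algorithm one of `"PCG"`, `"PG"`, `"DCG"`, `"DG"`, `"BSREM"`.
#' @param n_iter number of iterations (epochs for BSREM).
#' @param beta prior strength (stored into `rdp`).
#' @param rdp an [rdp_params()]; `eps = NULL` is resolved from the
#'   initialization at run time.
#' @param constrain_nonneg truncate negative values to zero after each update
#'   (the constrained variant; costs one extra forward projection per
#'   iteration to re-synchronize the expectation).
#' @param osem_subiters,osem_subsets OSEM initialization settings.
#' @param bsrem_subsets subset count for BSREM (5 to 9).
#' @param refresh_every refresh the incremental expectation by a full forward
#'   projection every this many iterations.
#' @param grad_tol optional relative gradient-norm stopping tolerance (stop
#'   when `|g| < grad_tol * |g_initial|`).
#' @param seed optional integer seed (the gradient algorithms are
#'   deterministic; kept for interface uniformity).
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(algorithm = c("PCG", "PG", "DCG", "DG", "BSREM"),
                         n_iter = 10L, beta = 0, rdp = rdp_params(),
                         constrain_nonneg = FALSE,
                         osem_subiters = 14L, osem_subsets = 2L,
                         bsrem_subsets = 7L, refresh_every = 20L,
                         grad_tol = NULL, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (n_iter < 0L) stop("n_iter must be >= 0")
  if (algorithm == "BSREM" && (bsrem_subsets < 5L || bsrem_subsets > 9L))
    stop("BSREM subset count must be between 5 and 9")
  rdp$beta <- beta
  structure(list(algorithm = algorithm, n_iter = as.integer(n_iter),
                 beta = beta, rdp = rdp,
                 constrain_nonneg = isTRUE(constrain_nonneg),
                 osem_subiters = as.integer(osem_subiters),
                 osem_subsets = as.integer(osem_subsets),
                 bsrem_subsets = as.integer(bsrem_subsets),
                 refresh_every = as.integer(refresh_every),
                 grad_tol = grad_tol, seed = seed),
            class = "recon_config")
}

#' Run a reconstruction
#'
#' Full pipeline for one algorithm: OSEM initialization, frozen preconditioner
#' (eta at the initialization, apodized ramp filter for the PCG/PG variants),
#' then the iteration loop with Polak-Ribiere conjugation (PCG/DCG), quadratic
#' step sizes, incremental expectation updates, and per-iteration metric
#' logging. Deterministic given the inputs.
#'
#' @param data list with elements `y`, `a`, `b` (e.g. from
#'   [simulate_acquisition()]).
#' @param geom a [pet_geometry()].
#' @param cfg a [recon_config()].
#' @param init optional initialization image (default: OSEM per `cfg`).
#' @param ref optional reference image for RMSE/VOI metrics.
#' @param mask logical whole-object mask for metrics and parameter resolution
#'   (default: voxels where the OSEM initialization exceeds 10% of its mean).
#' @param vois optional named list of logical VOI masks.
#' @return List of class `pet_recon` with elements `image`, `trace`
#'   (data.frame), `ybar` (final expectation sinogram), `eta`, `precond`,
#'   `config`, `mask`, `rdp`.
#' @export
run_reconstruction <- function(data, geom, cfg, init = NULL, ref = NULL,
                               mask = NULL, vois = list()) {
  stopifnot(inherits(cfg, "recon_config"))
  if (cfg$algorithm == "BSREM")
    return(bsrem_run(data, geom, cfg, init = init, ref = ref,
                     mask = mask, vois = vois))
  y <- data$y; a <- data$a; b <- data$b
  lam <- if (is.null(init))
    osem_initialize(y, a, b, geom, cfg$osem_subiters, cfg$osem_subsets)
  else as_image(init, geom)
  if (is.null(mask)) mask <- lam > 0.1 * mean(lam)
  rdp <- resolve_rdp_eps(cfg$rdp, lam, mask)
  bg_mean <- if (!is.null(ref)) mean(ref[mask]) else NA_real_

  ybar <- make_expectation(lam, geom, a = a, b = b, count = FALSE)
  state <- likelihood_state(y, ybar, b, a, geom)
  eta <- compute_eta(state, rdp, lam, count = FALSE)
  use_filter <- cfg$algorithm %in% c("PCG", "PG")
  filt <- if (use_filter) build_filter(geom, use_tof = geom$n_tof > 1L) else NULL
  pre <- preconditioner_state(eta, filter = filt, mask = mask)
  conjugate <- cfg$algorithm %in% c("PCG", "DCG")

  trace <- new_trace(names(vois))
  projection_counts_reset()
  g_prev <- NULL; pg_prev <- NULL; dir_prev <- NULL
  g0_norm <- NULL
  converged <- FALSE
  gnorm <- NA_real_
  for (k in seq_len(cfg$n_iter)) {
    state$ybar <- ybar
    g <- grad_modified(state)
    if (rdp$beta > 0) g <- g + rdp$beta * rdp_grad(lam, rdp)
    gnorm <- sqrt(sum(g^2))
    if (is.null(g0_norm)) g0_norm <- gnorm
    if (!is.null(cfg$grad_tol) && gnorm < cfg$grad_tol * g0_norm) {
      converged <- TRUE
      break
    }
    s <- precond_apply(g, pre)
    if (conjugate && k > 1L) {
      gamma_k <- pr_coefficient(s, g, g_prev, pg_prev)
      dir <- s + gamma_k * dir_prev
      if (sum(dir * g) <= 0) dir <- s       # restart on non-descent direction
    } else {
      dir <- s
    }
    f <- forward_project(dir, geom, a = a)
    w <- hessian_weights(state)
    alpha <- step_size(dir, f, g, w, lam, rdp)
    lam <- lam - alpha * dir
    ybar <- ybar - alpha * f
    if (cfg$constrain_nonneg) {
      lam <- pmax(lam, 0)
      ybar <- make_expectation(lam, geom, a = a, b = b)
    } else if (k %% cfg$refresh_every == 0L) {
      ybar <- make_expectation(lam, geom, a = a, b = b)
    }
    if (any(!is.finite(lam)))
      stop("numerical failure: nonfinite values in the image update at iteration ", k)
    state$ybar <- ybar
    obj <- neg_loglik(state) + if (rdp$beta > 0) rdp$beta * rdp_value(lam, rdp) else 0
    met <- compute_metrics(lam, ref, mask, vois, bg_mean)
    trace <- trace_row(trace, k, k, obj, gnorm, met$rmse,
                       projection_counts(), met$voi)
    g_prev <- g; pg_prev <- s; dir_prev <- dir
  }
  structure(list(image = lam, trace = trace, ybar = ybar, eta = eta,
                 precond = pre, config = cfg, mask = mask, rdp = rdp,
                 converged = converged, final_grad_norm = gnorm,
                 initial_grad_norm = g0_norm),
            class = "pet_recon")
}

# Polak-Ribiere conjugation coefficient in its preconditioned form, with the
# nonnegativity clamp (restart): the denominator pairs the previous
# preconditioned gradient with the previous gradient.
pr_coefficient <- function(s, g, g_prev, pg_prev) {
  den <- sum(pg_prev * g_prev)
  if (den <= 0) return(0)
  max(sum(s * (g - g_prev)) / den, 0)
}

#' BSREM comparator reconstruction
#'
#' Block sequential regularized EM (De Pierro-Yamagishi type): relaxed,
#' subset-scaled gradient steps preconditioned by `lambda / sensitivity`, with
#' small-value thresholding after each sub-iteration (values below the
#' threshold are reset to it), which makes the iterates strictly positive —
#' the constrained comparator to the unconstrained gradient variants.
#' Relaxation `alpha_n = 1 / (1 + 0.1 n)` over epochs `n`; metrics are logged
#' once per sub-iteration at fractional epochs.
#'
#' @inheritParams run_reconstruction
#' @return A `pet_recon` list (see [run_reconstruction()]).
#' @export
bsrem_run <- function(data, geom, cfg, init = NULL, ref = NULL,
                      mask = NULL, vois = list()) {
  y <- data$y; a <- data$a; b <- data$b
  lam <- if (is.null(init))
    osem_initialize(y, a, b, geom, cfg$osem_subiters, cfg$osem_subsets)
  else as_image(init, geom)
  if (is.null(mask)) mask <- lam > 0.1 * mean(lam)
  rdp <- resolve_rdp_eps(cfg$rdp, lam, mask)
  bg_mean <- if (!is.null(ref)) mean(ref[mask]) else NA_real_
  nsub <- cfg$bsrem_subsets
  angle_sets <- lapply(seq_len(nsub), function(m) seq(m, geom$n_angles, by = nsub))
  has_tof <- length(dim(y)) == 4L
  ones <- if (has_tof) array(1, c(sinogram_dim(geom, FALSE), geom$n_tof))
          else array(1, sinogram_dim(geom, FALSE))
  sens <- back_project(ones, geom, a = a, count = FALSE)
  tau <- 1e-6 * mean(lam[mask])
  lam <- pmax(lam, tau)
  tiny <- .Machine$double.xmin
  trace <- new_trace(names(vois))
  projection_counts_reset()
  it <- 0L
  for (n in seq_len(cfg$n_iter)) {
    alpha_n <- 1 / (1 + 0.1 * (n - 1))
    for (m in seq_len(nsub)) {
      it <- it + 1L
      ang <- angle_sets[[m]]
      ysub <- if (has_tof) y[, ang, , , drop = FALSE] else y[, ang, , drop = FALSE]
      bsub <- if (has_tof) b[, ang, , , drop = FALSE] else b[, ang, , drop = FALSE]
      ybar <- forward_project(lam, geom, a = a, angles = ang) + bsub
      ratio <- (ybar - ysub) / pmax(ybar, tiny)
      gsub <- nsub * back_project(ratio, geom, a = a, angles = ang)
      if (rdp$beta > 0) gsub <- gsub + rdp$beta * rdp_grad(lam, rdp)
      prec <- ifelse(sens > 0, pmax(lam, tau) / sens, 0)
      lam <- lam - alpha_n * prec * gsub
      lam <- pmax(lam, tau)
      met <- compute_metrics(lam, ref, mask, vois, bg_mean)
      trace <- trace_row(trace, it, it / nsub, NA_real_, sqrt(sum(gsub^2)),
                         met$rmse, projection_counts(), met$voi)
    }
  }
  structure(list(image = lam, trace = trace, ybar = NULL, eta = NULL,
                 precond = NULL, config = cfg, mask = mask, rdp = rdp),
            class = "pet_recon")
}
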