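# Smooth relative difference prior (RDP), defined for possibly-negative
# activity values:
#
#   M = sum_j sum_{xi in N_j} k_j k_xi (l_j - l_xi)^2 /
#         sqrt(l_j^2 + l_xi^2 + gamma^2 (l_j - l_xi)^2 + eps^2)
#
# The square-root denominator makes the pair term smooth everywhere (eps > 0)
# and well defined for negative values, while keeping the defining RDP
# behavior: for |l| >> eps the penalty scales linearly with activity times the
# squared *relative* difference, so hot regions are not over-smoothed, and
# edges with contrast above ~gamma are preserved. gamma controls edge
# preservation, eps the scale below which the penalty acts like a quadratic.
#
# Analytic gradient and Hessian are implemented in closed form for general
# gamma (obtained by differentiating the pair term symbolically); the
# double-sum runs over ordered pairs, so each unordered neighbor pair
# contributes twice.

#' Parameters of the relative difference prior
#'
#' @param beta global penalty strength (multiplies the prior in the objective).
#' @param gamma edge-preservation parameter (default 2; edges with contrast
#'   above about `gamma` are preserved rather than smoothed).
#' @param eps smoothing constant in activity units; if `NULL` it is resolved at
#'   reconstruction time as `1e-3 *` the mean initialization activity inside
#'   the object mask.
#' @param k_weights optional image-shaped array of positive per-voxel weights
#'   `k_j` (default 1 everywhere).
#' @param neighborhood `"8+axial"` (default: the 8 in-plane neighbors plus the
#'   2 axial ones), `"4+axial"`, or an integer matrix of lattice offsets with
#'   columns (dx, dy, dz); the offset set must be symmetric (contain -o for
#'   every o).
#' @return An object of class `rdp_params`.
#' @export
rdp_params <- function(beta = 0, gamma = 2, eps = NULL, k_weights = NULL,
                       neighborhood = "8+axial") {
  if (beta < 0) stop("beta must be nonnegative")
  if (!is.null(eps) && eps <= 0) stop("eps must be positive")
  if (!is.null(k_weights) && any(k_weights <= 0))
    stop("k_weights must be positive")
  offs <- neighborhood_offsets(neighborhood)
  structure(list(beta = beta, gamma = gamma, eps = eps,
                 k_weights = k_weights, offsets = offs),
            class = "rdp_params")
}

neighborhood_offsets <- function(spec) {
  if (is.matrix(spec)) {
    offs <- spec
  } else {
    offs <- switch(spec,
      "8+axial" = {
        g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0))
        rbind(g[!(g[, 1] == 0 & g[, 2] == 0), , drop = FALSE],
              c(0, 0, 1), c(0, 0, -1))
      },
      "4+axial" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                        c(0, 0, 1), c(0, 0, -1)),
      stop("unknown neighborhood spec: ", spec))
  }
  storage.mode(offs) <- "integer"
  if (ncol(offs) != 3L) stop("offsets must have 3 columns (dx, dy, dz)")
  key <- apply(offs, 1, paste, collapse = ",")
  neg <- apply(-offs, 1, paste, collapse = ",")
  if (!setequal(key, neg)) stop("neighborhood must be symmetric")
  if (any(key == "0,0,0")) stop("neighborhood must not contain the zero offset")
  unname(offs)
}

# eps resolution used by the optimizers: 1e-3 x mean init activity in mask
resolve_rdp_eps <- function(params, init, mask = NULL) {
  if (!is.null(params$eps)) return(params)
  v <- if (is.null(mask)) init[init > 0] else init[mask]
  m <- mean(abs(v))
  if (!is.finite(m) || m <= 0) m <- 1
  params$eps <- 1e-3 * m
  params
}

# pair-term kernels; u, v vectors, gamma/eps scalars ------------------------

rdp_pair_value <- function(u, v, gamma, eps) {
  d <- u - v
  d^2 / sqrt(u^2 + v^2 + gamma^2 * d^2 + eps^2)
}

rdp_pair_grad <- function(u, v, gamma, eps) {
  d <- u - v
  D <- u^2 + v^2 + gamma^2 * d^2 + eps^2
  d * (2 * eps^2 + gamma^2 * d^2 + u^2 + u * v + 2 * v^2) / D^1.5
}

rdp_pair_huu <- function(u, v, gamma, eps) {
  d <- u - v
  D <- u^2 + v^2 + gamma^2 * d^2 + eps^2
  (2 * eps^4 - eps^2 * (gamma^2 * d^2 + u^2 - 6 * u * v - 3 * v^2) -
     2 * gamma^2 * v^2 * d^2 + v^2 * (u^2 + 6 * u * v + v^2)) / D^2.5
}

rdp_pair_huv <- function(u, v, gamma, eps) {
  d <- u - v
  D <- u^2 + v^2 + gamma^2 * d^2 + eps^2
  (-2 * eps^4 + eps^2 * gamma^2 * d^2 - 2 * eps^2 * (u + v)^2 +
     2 * gamma^2 * u * v * d^2 - u * v * (u^2 + 6 * u * v + v^2)) / D^2.5
}

# loop over symmetric offsets, handing the aligned (u, v, k_u, k_v, source
# index region) blocks to `fun`, which accumulates into the closure
offset_sweep <- function(img, params, fun) {
  d <- dim(img)
  k <- params$k_weights
  for (r in seq_len(nrow(params$offsets))) {
    o <- params$offsets[r, ]
    xr <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
    yr <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
    zr <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
    if (o[1] > d[1] - 1L || -o[1] > d[1] - 1L ||
        o[2] > d[2] - 1L || -o[2] > d[2] - 1L ||
        o[3] > d[3] - 1L || -o[3] > d[3] - 1L) next
    u <- as.vector(img[xr, yr, zr])
    v <- as.vector(img[xr + o[1], yr + o[2], zr + o[3]])
    kk <- if (is.null(k)) 1 else
      as.vector(k[xr, yr, zr]) * as.vector(k[xr + o[1], yr + o[2], zr + o[3]])
    fun(u, v, kk, xr, yr, zr, o)
  }
}

#' Relative difference prior value
#'
#' The double sum over ordered neighbor pairs of the smooth RDP pair term.
#' Zero if and only if the image is constant; always nonnegative.
#'
#' @param img image-shaped activity array (negatives allowed).
#' @param params an [rdp_params()] with `eps` set.
#' @return Nonnegative scalar.
#' @export
rdp_value <- function(img, params) {
  img <- if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
  acc <- 0
  offset_sweep(img, params, function(u, v, kk, xr, yr, zr, o) {
    acc <<- acc + sum(kk * rdp_pair_value(u, v, params$gamma, params$eps))
  })
  acc
}

#' Relative difference prior gradient
#'
#' Analytic gradient of [rdp_value()]; closed form for any `gamma`. Each
#' unordered pair contributes twice (once per orientation of the double sum).
#'
#' @inheritParams rdp_value
#' @return Image-shaped gradient array; zero on constant images.
#' @export
rdp_grad <- function(img, params) {
  was_mat <- is.matrix(img)
  img <- if (was_mat) array(img, c(dim(img), 1L)) else img
  g <- array(0, dim(img))
  offset_sweep(img, params, function(u, v, kk, xr, yr, zr, o) {
    g[xr, yr, zr] <<- g[xr, yr, zr] +
      2 * kk * rdp_pair_grad(u, v, params$gamma, params$eps)
  })
  if (was_mat) g[, , 1] else g
}

#' Diagonal of the relative difference prior Hessian
#'
#' Per-voxel second derivative `d^2 M / d lambda_j^2`, summed over the
#' neighborhood, in closed form. This enters the diagonal component of the
#' preconditioner. Note the RDP is non-convex: individual diagonal entries can
#' be negative for unfavorable local configurations.
#'
#' @inheritParams rdp_value
#' @return Image-shaped array of diagonal Hessian entries.
#' @export
rdp_hess_diag <- function(img, params) {
  was_mat <- is.matrix(img)
  img <- if (was_mat) array(img, c(dim(img), 1L)) else img
  h <- array(0, dim(img))
  offset_sweep(img, params, function(u, v, kk, xr, yr, zr, o) {
    h[xr, yr, zr] <<- h[xr, yr, zr] +
      2 * kk * rdp_pair_huu(u, v, params$gamma, params$eps)
  })
  if (was_mat) h[, , 1] else h
}

#' Bilinear form of the relative difference prior Hessian
#'
#' `<s | H_rdp | s>` assembled from the analytic diagonal and pairwise
#' off-diagonal second derivatives; this is the prior's curvature along a
#' search direction, used by the quadratic step size. May be negative (the
#' RDP is non-convex); the optimizer guards the step-size denominator.
#'
#' @inheritParams rdp_value
#' @param s image-shaped direction array.
#' @return Scalar `<s|H|s>`.
#' @export
rdp_bilinear <- function(img, s, params) {
  img <- if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
  s <- if (is.matrix(s)) array(s, c(dim(s), 1L)) else s
  if (!all(dim(s) == dim(img))) stop("direction shape must match image")
  acc <- 0
  offset_sweep(img, params, function(u, v, kk, xr, yr, zr, o) {
    su <- as.vector(s[xr, yr, zr])
    sv <- as.vector(s[xr + o[1], yr + o[2], zr + o[3]])
    acc <<- acc + 2 * sum(kk * (rdp_pair_huu(u, v, params$gamma, params$eps) * su^2 +
                                  rdp_pair_huv(u, v, params$gamma, params$eps) * su * sv))
  })
  acc
}
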