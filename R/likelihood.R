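# Poisson likelihood for emission data, in the unconstrained formulation:
# the image may go negative, and the only constraint kept is the sinogram-space
# one, implemented by clamping the gradient/curvature denominator at the
# background expectation b: ratio terms use max(ybar, b) instead of ybar.
# Inside the support (ybar >> b) this is exactly the Poisson gradient; in
# background bins it keeps the expected curvature of the exact likelihood while
# letting the voxel values fluctuate around zero.

#' Bundle the per-LOR quantities entering the likelihood
#'
#' A light container for the measured counts `y`, current expectation `ybar`,
#' background `b` and attenuation factors `a`, with the shape/validity checks
#' applied once.
#'
#' @param y counts sinogram (nonnegative; integer for measured data, but
#'   non-integer expectations are accepted for noiseless experiments).
#' @param ybar current expected-counts sinogram (same shape as `y`).
#' @param b background (scatter + randoms) expectation sinogram, nonnegative.
#' @param a attenuation factor sinogram (non-TOF shape), values in (0, 1].
#' @param geom a [pet_geometry()].
#' @return An object of class `pet_likelihood`.
#' @export
likelihood_state <- function(y, ybar, b, a, geom) {
  check_sinogram(y, geom, "y")
  if (any(y < 0)) stop("y must contain nonnegative counts")
  if (!all(dim(ybar) == dim(y))) stop("ybar shape must match y")
  if (!all(dim(b) == dim(y))) stop("b shape must match y")
  if (any(b < 0)) stop("b must be nonnegative")
  check_a_dims(a, sinogram_dim(geom, tof = FALSE))
  if (any(a <= 0) || any(a > 1)) stop("attenuation factors must lie in (0, 1]")
  structure(list(y = y, ybar = ybar, b = b, a = a, geom = geom),
            class = "pet_likelihood")
}

# reporting floor for ybar <= 0 (the optimizer itself never uses the objective
# value, only gradients; this just keeps the monitored number finite)
ybar_floor <- function(b) 1e-12 * max(mean(b), .Machine$double.eps)

#' Poisson negative log-likelihood
#'
#' `sum_i ybar_i - y_i log(ybar_i)` (up to the data-only constant). Because
#' the unconstrained iterates may drive `ybar` nonpositive in background bins,
#' the evaluation clamps `ybar` at a tiny positive floor; the value is used for
#' monitoring only.
#'
#' @param state a [likelihood_state()].
#' @return Finite scalar.
#' @export
neg_loglik <- function(state) {
  yb <- pmax(state$ybar, ybar_floor(state$b))
  lg <- ifelse(state$y > 0, state$y * log(yb), 0)
  sum(yb - lg)
}

#' Modified (unconstrained) Poisson likelihood gradient
#'
#' Gradient of the negative log-likelihood with the denominator clamped at the
#' background: back-projection of `(ybar - y) / max(ybar, b)`. Wherever
#' `ybar >= b` (every LOR crossing the object) this is bit-identical to the
#' exact Poisson gradient; the clamp only acts in background bins, where it
#' preserves the expected curvature without constraining the image. The clamp
#' uses `b` itself, never a deflated `alpha * b`, which would bias the solution.
#'
#' @param state a [likelihood_state()].
#' @param count logical, passed to the back-projector's counter.
#' @return Image-shaped gradient of the negative log-likelihood (the descent
#'   direction is its negative).
#' @export
grad_modified <- function(state, count = TRUE) {
  den <- pmax(state$ybar, state$b)
  bad <- den <= 0 & state$y > 0
  if (any(bad))
    stop("numerical degeneracy: max(ybar, b) = 0 in ", sum(bad),
         " bins with y > 0")
  ratio <- ifelse(den > 0, (state$ybar - state$y) / den, 0)
  back_project(ratio, state$geom, a = state$a, count = count)
}

#' Expected-curvature weights of the Poisson likelihood
#'
#' Per-LOR weights `1 / max(ybar, b)` — the expectation of `y / ybar^2` under
#' the Poisson model, with the same background clamp as the gradient. These
#' weights enter the quadratic step size and the diagonal preconditioner
#' component. Bins where `max(ybar, b) = 0` and `y = 0` carry no information
#' and get weight 0; such a bin with `y > 0` is an error.
#'
#' @param state a [likelihood_state()].
#' @return Sinogram of nonnegative weights.
#' @export
hessian_weights <- function(state) {
  den <- pmax(state$ybar, state$b)
  bad <- den <= 0 & state$y > 0
  if (any(bad))
    stop("numerical degeneracy: max(ybar, b) = 0 in ", sum(bad),
         " bins with y > 0")
  ifelse(den > 0, 1 / den, 0)
}
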