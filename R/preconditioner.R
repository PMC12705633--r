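# Mixed diagonal-circulant preconditioner.
#
# The Hessian of the MAP objective is approximated as D^-2 (x) C where D^-2 is
# its expected diagonal at the initialization ("eta") and C is the (roughly
# shift-invariant, per-slice 2D) tomographic response sum_i c_ij c_ixi, whose
# inverse acts like a ramp (|f|) filter. The preconditioner applies
#
#   s = D F^-1 T F D g,   D = diag(1/sqrt(eta)),
#
# with T a band-limited, Hamming-apodized ramp filter in the in-plane spatial
# frequencies (optionally damped by the TOF kernel). With T = 1 this reduces
# to the pure diagonal scaling D D g = g / eta. Both eta and T are computed
# once at initialization and frozen for all iterations — the Poisson Hessian
# is approximately constant given a reasonable starting image.

#' Diagonal curvature image eta for the preconditioner
#'
#' Expected diagonal of the MAP objective Hessian at the initialization:
#' the back-projection `sum_i a_i^2 c_ij / max(ybar_i, b_i)` (using the
#' approximations `sum_i a_i^2 c_ij^2 ~ sum_i a_i^2 c_ij`, exact for a binary
#' projector footprint, and `E(y/ybar^2) = 1/ybar`) plus `beta` times the
#' analytic diagonal of the prior Hessian at the initialization image. Because
#' it is a back-projection of smooth per-LOR weights, eta is intrinsically a
#' low-frequency image.
#'
#' @param state a [likelihood_state()] evaluated at the initialization image
#'   (its `ybar` must be the initial expectation).
#' @param rdp an [rdp_params()] with `eps` resolved; its `beta` scales the
#'   prior term.
#' @param init_img initialization image at which the prior curvature is taken.
#' @param kernel projector kernel (the `"binary"` variant makes the
#'   `c^2 ~ c` approximation exact; used by oracle tests).
#' @param count logical; whether the back-projection increments the counter.
#' @return Image-shaped array `eta` (not yet floored; see
#'   [preconditioner_state()]).
#' @export
compute_eta <- function(state, rdp, init_img, kernel = "joseph", count = FALSE) {
  w <- hessian_weights(state)
  eta <- back_project(state$a * w, state$geom, a = state$a,
                      kernel = kernel, count = count)
  if (rdp$beta > 0)
    eta <- eta + rdp$beta * rdp_hess_diag(init_img, rdp)
  eta
}

#' Apodized 2D ramp filter for the circulant preconditioner component
#'
#' Built by the fixed recipe: (1) discrete band-limited ramp (Ram-Lak) impulse
#' response `h[0] = 1/(4 dx^2)`, `h[n odd] = -1/(pi n dx)^2`, `h[n even] = 0`,
#' length the next power of two >= `2 n_radial`; (2) if `use_tof`, multiply the
#' impulse response by the TOF kernel `exp(-x^2 / (4 sigma^2))` in the spatial
#' domain; (3) Fourier transform; (4) multiply by the Hamming window with
#' cutoff at the Nyquist frequency `fmax = 1/(2 dx)` (the window
#' `0.54 - 0.46 cos(.)` over the symmetric frequency axis, i.e.
#' `0.54 + 0.46 cos(pi f / fmax)` on `[0, fmax]`: 1 at DC, 0.08 at Nyquist);
#' (5) interpolate radially (linear in `|f|`) onto the 2D
#' FFT grid of a slice, zero beyond `fmax`. The same 2D filter is applied to
#' all slices. The overall scale is left unnormalized — the quadratic step
#' size absorbs any global scaling of the search direction.
#'
#' @param geom a [pet_geometry()].
#' @param use_tof logical; damp the ramp by the TOF kernel (requires
#'   `geom$n_tof > 1`).
#' @param interp radial interpolation scheme, `"linear"` (default) or
#'   `"spline"`.
#' @return List with `filter2d` (nx-by-ny matrix of nonnegative responses on
#'   the wrapped FFT frequency grid), and the 1D profile (`f`, `t1d`) for
#'   inspection/export.
#' @export
build_filter <- function(geom, use_tof = FALSE, interp = c("linear", "spline")) {
  interp <- match.arg(interp)
  if (use_tof && geom$n_tof <= 1L)
    stop("use_tof requires a TOF geometry (n_tof > 1)")
  dx <- geom$pixel_size
  L <- 2^ceiling(log2(2 * geom$n_radial))
  # impulse response in natural circular order: index k=0..L-1 holds offset
  # n = k for k < L/2 and n = k - L for k >= L/2
  n <- ifelse(seq_len(L) - 1 < L / 2, seq_len(L) - 1, seq_len(L) - 1 - L)
  h <- numeric(L)
  h[n == 0] <- 1 / (4 * dx^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd] * dx)^2
  if (use_tof) h <- h * exp(-(n * dx)^2 / (4 * geom$tof_sigma^2))
  H <- Re(stats::fft(h)) * dx          # ~continuous transform; scale immaterial
  H <- pmax(H, 0)
  fmax <- 1 / (2 * dx)
  f <- (0:(L / 2)) / (L * dx)
  t1d <- H[1:(L / 2 + 1)]
  # Hamming apodization with cutoff at Nyquist: the window 0.54 - 0.46 cos(.)
  # taken over the full symmetric frequency axis [-fmax, fmax] peaks at DC and
  # falls to 0.08 at |f| = fmax, i.e. 0.54 + 0.46 cos(pi f / fmax) on [0, fmax]
  t1d <- t1d * (0.54 + 0.46 * cos(pi * f / fmax))
  # radial interpolation onto the wrapped 2D FFT grid
  fx <- fft_freq(geom$nx, dx)
  fy <- fft_freq(geom$ny, dx)
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  t2d <- if (interp == "linear") {
    stats::approx(f, t1d, xout = pmin(fr, fmax), rule = 2)$y
  } else {
    stats::spline(f, t1d, xout = pmin(fr, fmax))$y
  }
  t2d <- pmax(t2d, 0)
  t2d[fr > fmax] <- 0
  dim(t2d) <- dim(fr)
  list(filter2d = t2d, f = f, t1d = t1d)
}

# wrapped FFT frequencies in cycles/mm for an n-point axis with spacing dx
fft_freq <- function(n, dx) {
  k <- seq_len(n) - 1
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * dx)
}

#' Assemble the frozen preconditioner state
#'
#' Floors `eta` at its 1st percentile over the support mask (back-projected
#' curvature is ~0 outside the scanned object, which would otherwise blow up
#' `D = eta^(-1/2)`), takes `d = 1/sqrt(eta)`, and stores the 2D filter. With
#' `filter = NULL` the operator is the pure diagonal `g / eta` (the DCG/DG
#' variants).
#'
#' @param eta image-shaped curvature array from [compute_eta()].
#' @param filter result of [build_filter()], or `NULL` for diagonal-only.
#' @param mask optional logical support mask used for the percentile floor
#'   (default: voxels where `eta > 0`).
#' @return Object of class `pet_preconditioner`.
#' @export
preconditioner_state <- function(eta, filter = NULL, mask = NULL) {
  if (is.null(mask)) mask <- eta > 0
  vals <- eta[mask]
  if (length(vals) == 0 || stats::quantile(vals, 0.01) <= 0)
    stop("degenerate initialization: nonpositive curvature inside the support")
  floor_val <- stats::quantile(vals, 0.01, names = FALSE)
  eta_f <- pmax(eta, floor_val)
  structure(list(eta = eta, d_values = 1 / sqrt(eta_f),
                 filter2d = if (is.null(filter)) NULL else filter$filter2d),
            class = "pet_preconditioner")
}

#' Apply the preconditioner to a gradient image
#'
#' Per slice: multiply by `d`, 2D FFT, multiply by the filter, inverse FFT,
#' real part, multiply by `d` again (`s = D F^-1 T F D g`). The operator is
#' linear, symmetric (D diagonal, T real and even on the FFT grid) and
#' positive semidefinite (T >= 0, D > 0). Without a filter it is `g / eta`.
#'
#' @param g image-shaped gradient array.
#' @param state a [preconditioner_state()].
#' @return Image-shaped preconditioned direction.
#' @export
precond_apply <- function(g, state) {
  was_mat <- is.matrix(g)
  if (was_mat) g <- array(g, c(dim(g), 1L))
  if (!all(dim(g) == dim(state$d_values)))
    stop("gradient shape does not match preconditioner state")
  if (is.null(state$filter2d)) {
    out <- state$d_values^2 * g
  } else {
    out <- array(0, dim(g))
    for (sl in seq_len(dim(g)[3])) {
      tmp <- state$d_values[, , sl] * g[, , sl]
      Ff <- stats::fft(tmp) * state$filter2d
      out[, , sl] <- state$d_values[, , sl] *
        Re(stats::fft(Ff, inverse = TRUE)) / length(tmp)
    }
  }
  if (was_mat) out[, , 1] else out
}
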