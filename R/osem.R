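# OSEM initialization: ordered-subsets EM with angle-interleaved subsets.
# Multiplicative updates keep the image nonnegative; the result seeds the
# gradient-based reconstructions (default: 14 sub-iterations over 2 subsets,
# i.e. 7 passes over the data).

#' OSEM reconstruction (used as the initializer)
#'
#' Standard ordered-subsets expectation maximization on angle-interleaved
#' subsets: `lambda <- lambda / sens_m * back_m(a y / ybar)` with
#' `ybar = fwd_m(lambda) a + b`. Deterministic; voxels with zero subset
#' sensitivity are left untouched.
#'
#' @param y counts sinogram.
#' @param a attenuation factor sinogram (non-TOF shape).
#' @param b background sinogram (same shape as `y`).
#' @param geom a [pet_geometry()].
#' @param subiters total number of sub-iterations (default 14).
#' @param subsets number of angle-interleaved subsets (default 2).
#' @param init optional starting image (default: uniform 1).
#' @return Nonnegative activity image.
#' @export
osem_initialize <- function(y, a, b, geom, subiters = 14L, subsets = 2L,
                            init = NULL) {
  check_sinogram(y, geom, "y")
  subsets <- as.integer(subsets); subiters <- as.integer(subiters)
  if (subsets < 1L || subiters < 1L) stop("subiters and subsets must be >= 1")
  lam <- if (is.null(init)) array(1, image_dim(geom)) else as_image(init, geom)
  angle_sets <- lapply(seq_len(subsets), function(m) seq(m, geom$n_angles, by = subsets))
  has_tof <- length(dim(y)) == 4L
  ones <- if (has_tof) array(1, c(sinogram_dim(geom, FALSE), geom$n_tof))
          else array(1, sinogram_dim(geom, FALSE))
  sens <- lapply(angle_sets, function(ang) {
    s1 <- if (has_tof) ones[, ang, , , drop = FALSE] else ones[, ang, , drop = FALSE]
    back_project(s1, geom, a = a, angles = ang)
  })
  tiny <- .Machine$double.xmin
  for (it in seq_len(subiters)) {
    m <- (it - 1L) %% subsets + 1L
    ang <- angle_sets[[m]]
    ybar <- forward_project(lam, geom, a = a, angles = ang)
    bsub <- if (has_tof) b[, ang, , , drop = FALSE] else b[, ang, , drop = FALSE]
    ysub <- if (has_tof) y[, ang, , , drop = FALSE] else y[, ang, , drop = FALSE]
    ybar <- ybar + bsub
    ratio <- ifelse(ybar > 0, ysub / pmax(ybar, tiny), 0)
    upd <- back_project(ratio, geom, a = a, angles = ang)
    ok <- sens[[m]] > 0
    lam[ok] <- lam[ok] / sens[[m]][ok] * upd[ok]
  }
  lam
}
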