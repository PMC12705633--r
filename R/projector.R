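# Sparse-matrix projector for the toy parallel-beam model.
#
# The 2D (per-slice) system matrix is assembled once per geometry with
# Joseph's method: rays are traced per view angle, stepping along the
# dominant axis one pixel row/column at a time and linearly interpolating
# between the two nearest pixels in the other direction; each sample carries
# a length weight pixel_size / |dominant direction cosine| (mm), so forward
# projections are line integrals in mm. Backprojection is the exact
# transpose, which guarantees an adjoint pair to machine precision.
#
# For TOF geometries one sparse matrix per TOF bin is stored; the entry for
# pixel j in TOF bin m carries the Gaussian weight exp(-(t - t_m)^2/(2 sigma^2))
# (3-sigma truncated, renormalized over bins), where t is the signed position
# of the sample along the ray. Renormalization makes the TOF bins an exact
# partition of the non-TOF line integral.

.proj_cache <- new.env(parent = emptyenv())
.proj_counts <- new.env(parent = emptyenv())
.proj_counts$forward <- 0L
.proj_counts$back <- 0L

#' Reset the instrumented projection counters
#'
#' The package counts every forward and back projection executed (including
#' those inside OSEM, eta computation and scheduled expectation refreshes),
#' which makes the per-iteration projection budget of the optimizers testable.
#' @return Invisibly, the counters before the reset.
#' @export
projection_counts_reset <- function() {
  old <- projection_counts()
  .proj_counts$forward <- 0L
  .proj_counts$back <- 0L
  invisible(old)
}

#' Read the instrumented projection counters
#' @return Named integer vector with elements `forward` and `back`.
#' @export
projection_counts <- function() {
  c(forward = .proj_counts$forward, back = .proj_counts$back)
}

geom_key <- function(geom, kernel) {
  paste(kernel, geom$nx, geom$ny, geom$n_radial, geom$n_angles,
        format(geom$pixel_size, digits = 15), geom$n_tof,
        if (is.null(geom$tof_sigma)) 0 else format(geom$tof_sigma, digits = 15),
        sep = "|")
}

# Build the per-slice system matrix (list of sparse matrices, one per TOF bin).
# kernel = "joseph" (length-weighted linear interpolation, default) or
# "binary" (nearest radial sample, unit weights; used by dense-oracle tests
# where sum(c^2) must equal sum(c) exactly).
build_system_matrix <- function(geom, kernel = c("joseph", "binary")) {
  kernel <- match.arg(kernel)
  key <- geom_key(geom, kernel)
  hit <- .proj_cache[[key]]
  if (!is.null(hit)) return(hit)

  nx <- geom$nx; ny <- geom$ny; px <- geom$pixel_size
  nr <- geom$n_radial; na <- geom$n_angles
  xc <- (seq_len(nx) - (nx + 1) / 2) * px
  yc <- (seq_len(ny) - (ny + 1) / 2) * px
  rho <- (seq_len(nr) - (nr + 1) / 2) * px
  theta <- (seq_len(na) - 1) * pi / na

  ii <- vector("list", na); jj <- vector("list", na)
  ww <- vector("list", na); tt <- vector("list", na)
  for (ang in seq_len(na)) {
    cth <- cos(theta[ang]); sth <- sin(theta[ang])
    if (abs(cth) >= abs(sth)) {
      # step along y (columns); interpolate across rows (x)
      # ray point: p = rho*(c,s) + l*(-s,c); at y = yc[j]: l = (y - rho*s)/c
      l <- outer(rho, yc, function(r, y) (y - r * sth) / cth)   # nr x ny
      x <- outer(rho, yc, function(r, y) r * cth - ((y - r * sth) / cth) * sth)
      fi <- x / px + (nx + 1) / 2
      stepdim <- ny; wf <- px / abs(cth)
      colbase <- matrix(rep((seq_len(ny) - 1L) * nx, each = nr), nr, ny)
      along_rows <- TRUE
    } else {
      l <- outer(rho, xc, function(r, x) (r * cth - x) / sth)   # nr x nx
      y <- outer(rho, xc, function(r, x) r * sth + ((r * cth - x) / sth) * cth)
      fi <- y / px + (ny + 1) / 2
      stepdim <- nx; wf <- px / abs(sth)
      colbase <- NULL
      along_rows <- FALSE
    }
    rowidx <- matrix(rep(seq_len(nr), stepdim), nr, stepdim) + (ang - 1L) * nr
    if (kernel == "joseph") {
      i0 <- floor(fi); fr <- fi - i0
      # two entries per sample
      idx1 <- i0; w1 <- (1 - fr) * wf
      idx2 <- i0 + 1; w2 <- fr * wf
      mk <- function(idx, w) {
        nmax <- if (along_rows) nx else ny
        keep <- idx >= 1 & idx <= nmax & w > 0
        if (!any(keep)) return(NULL)
        colj <- if (along_rows) {
          idx[keep] + colbase[keep]
        } else {
          # stepping along x: row index is the step, col index interpolated
          srow <- matrix(rep(seq_len(nx), each = nr), nr, nx)
          srow[keep] + (idx[keep] - 1L) * nx
        }
        list(i = rowidx[keep], j = colj, w = w[keep], t = l[keep])
      }
      e1 <- mk(idx1, w1); e2 <- mk(idx2, w2)
      ii[[ang]] <- c(e1$i, e2$i); jj[[ang]] <- c(e1$j, e2$j)
      ww[[ang]] <- c(e1$w, e2$w); tt[[ang]] <- c(e1$t, e2$t)
    } else {
      idx <- round(fi)
      nmax <- if (along_rows) nx else ny
      keep <- idx >= 1 & idx <= nmax
      colj <- if (along_rows) {
        idx[keep] + colbase[keep]
      } else {
        srow <- matrix(rep(seq_len(nx), each = nr), nr, nx)
        srow[keep] + (idx[keep] - 1L) * nx
      }
      ii[[ang]] <- rowidx[keep]; jj[[ang]] <- colj
      ww[[ang]] <- rep(1, sum(keep)); tt[[ang]] <- l[keep]
    }
  }
  i <- unlist(ii); j <- unlist(jj); w <- unlist(ww); tl <- unlist(tt)
  nlor <- nr * na; npix <- nx * ny

  mats <- if (geom$n_tof > 1L) {
    sig <- geom$tof_sigma
    centers <- (seq_len(geom$n_tof) - (geom$n_tof + 1) / 2) * tof_bin_width(geom)
    wm <- vapply(centers, function(tc) {
      d <- tl - tc
      out <- exp(-d^2 / (2 * sig^2))
      out[abs(d) > 3 * sig] <- 0
      out
    }, numeric(length(tl)))
    tot <- rowSums(wm)
    # samples outside every truncated kernel go to the nearest bin so that the
    # TOF marginalization stays exact
    lost <- tot <= 0
    if (any(lost)) {
      nb <- max.col(-abs(outer(tl[lost], centers, "-")), ties.method = "first")
      wm[lost, ] <- 0
      wm[cbind(which(lost), nb)] <- 1
      tot[lost] <- 1
    }
    wm <- wm / tot
    lapply(seq_len(geom$n_tof), function(m) {
      keep <- wm[, m] > 0
      Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep] * wm[keep, m],
                           dims = c(nlor, npix))
    })
  } else {
    list(Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(nlor, npix)))
  }
  .proj_cache[[key]] <- mats
  mats
}

# TOF bin width in mm: FWHM of the Gaussian TOF kernel
tof_bin_width <- function(geom) 2 * sqrt(2 * log(2)) * geom$tof_sigma

lor_rows <- function(geom, angles) {
  as.vector(outer(seq_len(geom$n_radial), (angles - 1L) * geom$n_radial, "+"))
}

#' Forward project an activity image
#'
#' Computes per-LOR line integrals `sum_j a_i c_ij lambda_j` of an activity
#' image through the parallel-beam system, optionally multiplied by
#' attenuation factors `a`. For TOF geometries each line integral is
#' distributed over TOF bins with truncated Gaussian weights that sum to one,
#' so summing the TOF output over its last dimension recovers the non-TOF
#' projection. The background term `b` is *not* added here; see
#' [make_expectation()].
#'
#' @param img activity image, array `(nx, ny, n_slices)` (a matrix is accepted
#'   for single-slice geometries). Negative values are allowed.
#' @param geom a [pet_geometry()].
#' @param a optional attenuation-factor sinogram (non-TOF shape); applied
#'   multiplicatively per LOR (constant across TOF bins).
#' @param angles optional integer subset of view angles (used by subset
#'   algorithms); output then has `length(angles)` in the angle dimension.
#' @param kernel projector kernel, `"joseph"` or `"binary"`.
#' @param count logical; whether the call increments the projection counter.
#' @return Sinogram array `(n_radial, n_angles, n_slices[, n_tof])`.
#' @export
forward_project <- function(img, geom, a = NULL, angles = NULL,
                            kernel = "joseph", count = TRUE) {
  img <- as_image(img, geom)
  mats <- build_system_matrix(geom, kernel)
  X <- matrix(img, nrow = geom$nx * geom$ny)
  rows <- if (is.null(angles)) NULL else lor_rows(geom, angles)
  nang <- if (is.null(angles)) geom$n_angles else length(angles)
  out <- vapply(mats, function(A) {
    if (!is.null(rows)) A <- A[rows, , drop = FALSE]
    as.matrix(A %*% X)
  }, matrix(0, geom$n_radial * nang, geom$n_slices))
  dim(out) <- c(geom$n_radial, nang, geom$n_slices, length(mats))
  if (!is.null(a)) {
    asub <- if (is.null(angles)) a else a[, angles, , drop = FALSE]
    check_a_dims(asub, c(geom$n_radial, nang, geom$n_slices))
    out <- out * as.vector(asub)  # recycles over the TOF dimension
  }
  if (length(mats) == 1L) dim(out) <- dim(out)[1:3]
  if (count) .proj_counts$forward <- .proj_counts$forward + 1L
  out
}

check_a_dims <- function(a, d3) {
  if (!is.array(a) || length(dim(a)) != 3L || !all(dim(a) == d3))
    stop("attenuation sinogram shape does not match geometry (non-TOF shape expected)")
  invisible(TRUE)
}

#' Back project a sinogram (exact adjoint of the forward projector)
#'
#' Computes `sum_i a_i c_ij s_i` per voxel. Because projection is a stored
#' sparse matrix, the adjoint identity `<Ax, s> == <x, A's>` holds to machine
#' precision. TOF sinograms are summed over TOF bins with the same Gaussian
#' weights used by [forward_project()].
#'
#' @inheritParams forward_project
#' @param s sinogram array (with or without TOF dimension).
#' @return Activity-image array `(nx, ny, n_slices)`.
#' @export
back_project <- function(s, geom, a = NULL, angles = NULL,
                         kernel = "joseph", count = TRUE) {
  mats <- build_system_matrix(geom, kernel)
  nang <- if (is.null(angles)) geom$n_angles else length(angles)
  dexp <- c(geom$n_radial, nang, geom$n_slices)
  ds <- dim(s)
  has_tof <- length(ds) == 4L
  if (!(length(ds) %in% c(3L, 4L)) || !all(ds[1:3] == dexp))
    stop("sinogram shape does not match geometry/angle subset")
  if (has_tof && ds[4L] != length(mats))
    stop("sinogram TOF dimension does not match geometry")
  if (!has_tof && length(mats) > 1L)  # adjoint of the TOF-marginalized forward
    s <- array(rep(as.vector(s), length(mats)), dim = c(dexp, length(mats)))
  if (!is.null(a)) {
    asub <- if (is.null(angles)) a else a[, angles, , drop = FALSE]
    check_a_dims(asub, dexp)
    s <- s * as.vector(asub)
  }
  rows <- if (is.null(angles)) NULL else lor_rows(geom, angles)
  acc <- matrix(0, geom$nx * geom$ny, geom$n_slices)
  for (m in seq_along(mats)) {
    A <- mats[[m]]
    if (!is.null(rows)) A <- A[rows, , drop = FALSE]
    sm <- if (length(dim(s)) == 4L) s[, , , m, drop = FALSE] else s
    acc <- acc + as.matrix(Matrix::crossprod(A, matrix(sm, nrow = nrow(A))))
  }
  if (count) .proj_counts$back <- .proj_counts$back + 1L
  array(acc, dim = image_dim(geom))
}

#' Attenuation factor sinogram from a linear attenuation map
#'
#' `a_i = exp(-integral of mu along LOR i)`, the probability that both
#' annihilation photons escape unattenuated. The factor is independent of the
#' emission position along the LOR, hence constant across TOF bins; the
#' returned sinogram has no TOF dimension.
#'
#' @param mu linear attenuation map in 1/mm, image-shaped, nonnegative.
#' @param geom a [pet_geometry()].
#' @return Sinogram array of factors in (0, 1].
#' @export
attenuation_factors <- function(mu, geom) {
  mu <- as_image(mu, geom)
  if (any(mu < 0)) stop("attenuation coefficients must be nonnegative")
  li <- forward_project(mu, geom, count = FALSE)
  if (length(dim(li)) == 4L) li <- rowSums(li, dims = 3L)  # TOF marginal
  exp(-li)
}

#' Expected counts sinogram
#'
#' The Poisson forward model `ybar = sum_j a_i c_ij lambda_j + b_i`.
#'
#' @inheritParams forward_project
#' @param b additive background (scatter + randoms) sinogram, same shape as
#'   the projection output.
#' @return Sinogram of expected counts.
#' @export
make_expectation <- function(img, geom, a = NULL, b = NULL, count = TRUE) {
  ybar <- forward_project(img, geom, a = a, count = count)
  if (!is.null(b)) {
    if (!all(dim(b) == dim(ybar))) stop("background sinogram shape mismatch")
    ybar <- ybar + b
  }
  ybar
}
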