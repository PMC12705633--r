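#' Scanner geometry for the toy parallel-beam PET model
#'
#' Describes a per-slice 2D parallel-beam acquisition: the image lattice, the
#' sinogram sampling (radial bins and view angles over \[0, pi)), and optional
#' time-of-flight (TOF) binning. Radial bins are centered on the image grid and
#' the coordinate origin sits at the volume center, so the system is (up to
#' discretization) shift-invariant in-plane -- the assumption behind the
#' circulant part of the preconditioner.
#'
#' @param nx,ny image lattice size in pixels (in-plane).
#' @param n_radial number of radial sinogram bins; must be >= `nx` and `ny`.
#' @param n_angles number of view angles, uniformly sampled on \[0, pi).
#' @param n_slices number of axial slices (direct planes only; no oblique rays).
#' @param pixel_size in-plane pixel size in mm (isotropic; also the radial bin
#'   spacing and the axial voxel size).
#' @param n_tof number of TOF bins; 1 means non-TOF. Must be odd when > 1.
#' @param tof_sigma spatial TOF resolution sigma in mm (required when
#'   `n_tof > 1`).
#' @return An object of class `pet_geometry`.
#' @examples
#' geom <- pet_geometry(nx = 32, ny = 32, n_radial = 32, n_angles = 16)
#' @export
pet_geometry <- function(nx, ny = nx, n_radial = nx, n_angles,
                         n_slices = 1L, pixel_size = 2,
                         n_tof = 1L, tof_sigma = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  n_radial <- as.integer(n_radial); n_angles <- as.integer(n_angles)
  n_slices <- as.integer(n_slices); n_tof <- as.integer(n_tof)
  if (n_radial < max(nx, ny))
    stop("n_radial must be at least the image width in pixels")
  if (n_angles < 1L) stop("n_angles must be >= 1")
  if (n_slices < 1L) stop("n_slices must be >= 1")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (n_tof > 1L) {
    if (n_tof %% 2L == 0L) stop("n_tof must be odd when > 1")
    if (is.null(tof_sigma) || tof_sigma <= 0)
      stop("tof_sigma must be a positive length in mm when n_tof > 1")
  } else {
    tof_sigma <- NULL
  }
  structure(
    list(nx = nx, ny = ny, n_radial = n_radial, n_angles = n_angles,
         n_slices = n_slices, pixel_size = pixel_size,
         n_tof = n_tof, tof_sigma = tof_sigma),
    class = "pet_geometry")
}

#' @exportS3Method base::print
print.pet_geometry <- function(x, ...) {
  cat(sprintf("pet_geometry: %dx%dx%d image @ %.3g mm, %d radial x %d angles",
              x$nx, x$ny, x$n_slices, x$pixel_size, x$n_radial, x$n_angles))
  if (x$n_tof > 1L)
    cat(sprintf(", %d TOF bins (sigma %.3g mm)", x$n_tof, x$tof_sigma))
  cat("\n")
  invisible(x)
}

#' Dimensions of a sinogram for a geometry
#'
#' @param geom a [pet_geometry()].
#' @param tof logical; include the TOF dimension (only if `geom$n_tof > 1`).
#' @return Integer vector `(n_radial, n_angles, n_slices[, n_tof])`.
#' @export
sinogram_dim <- function(geom, tof = geom$n_tof > 1L) {
  d <- c(geom$n_radial, geom$n_angles, geom$n_slices)
  if (tof && geom$n_tof > 1L) d <- c(d, geom$n_tof)
  d
}

#' Dimensions of the image lattice for a geometry
#' @param geom a [pet_geometry()].
#' @return Integer vector `(nx, ny, n_slices)`.
#' @export
image_dim <- function(geom) c(geom$nx, geom$ny, geom$n_slices)

# internal: coerce a 2D slice input to the canonical 3D image array
as_image <- function(x, geom) {
  d <- image_dim(geom)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || !all(dim(x) == d))
    stop("image shape does not match geometry (expected ",
         paste(d, collapse = "x"), ")")
  x
}

check_sinogram <- function(s, geom, what = "sinogram") {
  dn <- sinogram_dim(geom, tof = FALSE)
  dt <- sinogram_dim(geom, tof = TRUE)
  if (!is.array(s)) stop(what, " must be an array")
  ds <- dim(s)
  if (length(ds) == length(dn) && all(ds == dn)) return("notof")
  if (geom$n_tof > 1L && length(ds) == length(dt) && all(ds == dt)) return("tof")
  stop(what, " shape does not match geometry")
}
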