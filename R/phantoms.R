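# Digital phantoms and seeded acquisition simulation.
#
# Three procedurally generated phantom families emulate the benchmark
# conditions the reconstruction algorithms are meant to face:
#  - nema_like: image-quality phantom — a uniform cylinder background with six
#    spheres (diameters 10, 13, 17, 22, 28, 37 mm) at a configurable
#    sphere:background contrast (10:1 default; 4:1 for the low-contrast
#    variant; 0 = cold).
#  - brain_like: procedural gray/white-matter-like pattern at 4:1
#    gray:white contrast with cold ventricle-like inserts.
#  - thorax_like: body ellipse with low-attenuation lung fields, a
#    high-attenuation spine, and an irregular hot lesion; its attenuation
#    factors span >= 2 orders of magnitude across LORs.
# Water-equivalent attenuation (0.0096/mm) fills the object; bone-like
# regions use 0.0172/mm, lung-like 0.0024/mm.

MU_WATER <- 0.0096   # 1/mm at 511 keV
MU_BONE  <- 0.0172
MU_LUNG  <- 0.0024

#' Specify a synthetic phantom and acquisition
#'
#' @param kind `"nema_like"`, `"brain_like"` or `"thorax_like"`.
#' @param fov_mm field of view in mm (default 256; 500 for `thorax_like`).
#' @param background_activity activity of the background compartment
#'   (arbitrary units; rescaled by the count budget at simulation time).
#' @param inserts data.frame with columns `cx`, `cy` (center, mm), `diameter`
#'   (mm) and `contrast` (activity ratio to background; 0 = cold). `NULL`
#'   selects the family default.
#' @param total_counts expected total prompt counts (trues + background).
#' @param scatter_fraction fraction of prompts carried by the uniform
#'   background sinogram `b` (in `[0, 1)`).
#' @param seed integer seed for the Poisson sampling.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("nema_like", "brain_like", "thorax_like"),
                         fov_mm = NULL, background_activity = 1,
                         inserts = NULL, total_counts = 5e6,
                         scatter_fraction = 0.2, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(fov_mm)) fov_mm <- if (kind == "thorax_like") 500 else 256
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must be in [0, 1)")
  if (total_counts <= 0) stop("total_counts must be positive")
  if (is.null(inserts) && kind == "nema_like") {
    diam <- c(10, 13, 17, 22, 28, 37)
    angs <- (seq_along(diam) - 1) * pi / 3
    inserts <- data.frame(cx = 57.2 * cos(angs), cy = 57.2 * sin(angs),
                          diameter = diam, contrast = 10)
  }
  if (!is.null(inserts)) {
    if (any(inserts$diameter <= 0)) stop("insert diameters must be positive")
    if (any(inserts$contrast < 0)) stop("insert contrast must be >= 0")
  }
  structure(list(kind = kind, fov_mm = fov_mm,
                 background_activity = background_activity,
                 inserts = inserts, total_counts = total_counts,
                 scatter_fraction = scatter_fraction, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default geometry for a phantom spec
#'
#' 128x128 single-slice grid covering the field of view (2 mm pixels at the
#' default 256 mm FOV), 128 radial bins, 96 view angles.
#'
#' @param spec a [phantom_spec()].
#' @param nx image size in pixels.
#' @param n_angles number of view angles.
#' @param n_slices axial slices.
#' @param n_tof,tof_sigma TOF settings (see [pet_geometry()]).
#' @return A [pet_geometry()].
#' @export
default_geometry <- function(spec, nx = 128L, n_angles = 96L, n_slices = 1L,
                             n_tof = 1L, tof_sigma = NULL) {
  pet_geometry(nx = nx, ny = nx, n_radial = nx, n_angles = n_angles,
               n_slices = n_slices, pixel_size = spec$fov_mm / nx,
               n_tof = n_tof, tof_sigma = tof_sigma)
}

grid_coords <- function(geom) {
  list(x = (seq_len(geom$nx) - (geom$nx + 1) / 2) * geom$pixel_size,
       y = (seq_len(geom$ny) - (geom$ny + 1) / 2) * geom$pixel_size)
}

disc_mask <- function(geom, cx, cy, radius) {
  gc <- grid_coords(geom)
  outer(gc$x, gc$y, function(x, y) (x - cx)^2 + (y - cy)^2 <= radius^2)
}

ellipse_mask <- function(geom, cx, cy, rx, ry) {
  gc <- grid_coords(geom)
  outer(gc$x, gc$y, function(x, y) ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1)
}

erode1 <- function(m) {
  # 4-neighborhood erosion by one voxel, per slice; masks that erosion would
  # empty (inserts a voxel or two across) are returned unchanged
  n1 <- nrow(m); n2 <- ncol(m)
  sh <- function(dr, dc) {
    p <- matrix(FALSE, n1, n2)
    rs <- max(1, 1 + dr):min(n1, n1 + dr); cs <- max(1, 1 + dc):min(n2, n2 + dc)
    p[rs, cs] <- m[rs - dr, cs - dc]
    p
  }
  out <- m & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1)
  if (!any(out)) m else out
}

rep_slices <- function(m, n_slices) array(m, c(dim(m), n_slices))

#' Rasterize a phantom
#'
#' Builds the activity image, linear attenuation map and VOI set for a
#' [phantom_spec()] on a given geometry. VOI masks are eroded by one voxel
#' from the insert boundary to reduce partial-volume contamination; the
#' returned set also contains `background` (object minus all inserts, eroded)
#' and `whole_object`.
#'
#' @param spec a [phantom_spec()].
#' @param geom a [pet_geometry()] (default [default_geometry()]).
#' @return List with `activity`, `mu`, `vois` (named list of logical arrays),
#'   and `mask` (whole-object logical array).
#' @export
make_phantom <- function(spec, geom = default_geometry(spec)) {
  gc <- grid_coords(geom)
  half <- spec$fov_mm / 2
  act2 <- matrix(0, geom$nx, geom$ny)
  mu2 <- matrix(0, geom$nx, geom$ny)
  vois2 <- list()
  bg <- spec$background_activity
  if (spec$kind == "nema_like") {
    body_r <- 0.4 * spec$fov_mm
    body <- disc_mask(geom, 0, 0, body_r)
    act2[body] <- bg
    mu2[body] <- MU_WATER
    if (!is.null(spec$inserts)) {
      for (r in seq_len(nrow(spec$inserts))) {
        ins <- spec$inserts[r, ]
        if (abs(ins$cx) + ins$diameter / 2 > half ||
            abs(ins$cy) + ins$diameter / 2 > half)
          stop("insert outside the field of view")
        m <- disc_mask(geom, ins$cx, ins$cy, ins$diameter / 2)
        act2[m] <- bg * ins$contrast
        vois2[[sprintf("sphere_%02.0fmm", ins$diameter)]] <- erode1(m)
      }
    }
    object <- body
  } else if (spec$kind == "brain_like") {
    outer_r <- 0.36 * spec$fov_mm
    skull <- disc_mask(geom, 0, 0, outer_r)
    # cortical ribbon: radius modulated by angular folds
    th <- outer(gc$x, gc$y, function(x, y) atan2(y, x))
    rr <- outer(gc$x, gc$y, function(x, y) sqrt(x^2 + y^2))
    rim <- outer_r * (0.78 + 0.06 * cos(7 * th))
    gray <- skull & (rr >= rim)
    white <- skull & !gray
    act2[white] <- bg
    act2[gray] <- 4 * bg
    vent_l <- ellipse_mask(geom, -0.05 * spec$fov_mm, 0.03 * spec$fov_mm,
                           0.045 * spec$fov_mm, 0.09 * spec$fov_mm)
    vent_r <- ellipse_mask(geom, 0.05 * spec$fov_mm, 0.03 * spec$fov_mm,
                           0.045 * spec$fov_mm, 0.09 * spec$fov_mm)
    act2[vent_l | vent_r] <- 0
    mu2[skull] <- MU_WATER
    vois2$gray_matter <- erode1(gray & rr <= outer_r * 0.97)
    vois2$ventricles <- erode1(vent_l | vent_r)
    object <- skull
  } else { # thorax_like
    # adult-thorax-scale water ellipse: the widest lung-free chord is about
    # 0.96 x fov of water, so attenuation factors reach ~1% as in an abdomen
    body <- ellipse_mask(geom, 0, 0, 0.48 * spec$fov_mm, 0.36 * spec$fov_mm)
    lung_l <- ellipse_mask(geom, -0.17 * spec$fov_mm, 0.15 * spec$fov_mm,
                           0.12 * spec$fov_mm, 0.13 * spec$fov_mm)
    lung_r <- ellipse_mask(geom, 0.17 * spec$fov_mm, 0.15 * spec$fov_mm,
                           0.12 * spec$fov_mm, 0.13 * spec$fov_mm)
    spine <- disc_mask(geom, 0, -0.24 * spec$fov_mm, 0.04 * spec$fov_mm)
    act2[body] <- bg
    act2[lung_l | lung_r] <- 0.25 * bg
    mu2[body] <- MU_WATER
    mu2[lung_l | lung_r] <- MU_LUNG
    mu2[spine] <- MU_BONE
    # irregular hot lesion near the right lung border
    th <- outer(gc$x, gc$y, function(x, y) atan2(y - 0.1 * spec$fov_mm,
                                                 x - 0.08 * spec$fov_mm))
    rr <- outer(gc$x, gc$y, function(x, y)
      sqrt((x - 0.08 * spec$fov_mm)^2 + (y - 0.1 * spec$fov_mm)^2))
    lesion <- rr <= 0.035 * spec$fov_mm * (1 + 0.3 * cos(3 * th))
    act2[lesion] <- 6 * bg
    vois2$lesion <- erode1(lesion)
    vois2$lung <- erode1(lung_l)
    object <- body
  }
  ns <- geom$n_slices
  # coarse grids can erode a small insert away entirely; fall back to the raw
  # mask there, and drop inserts that do not rasterize at all
  vois2 <- Filter(any, vois2)
  vois <- lapply(vois2, rep_slices, n_slices = ns)
  inside <- object & !Reduce(`|`, c(list(matrix(FALSE, geom$nx, geom$ny)), vois2))
  vois$background <- rep_slices(erode1(inside), ns)
  vois$whole_object <- rep_slices(object, ns)
  list(activity = rep_slices(act2, ns), mu = rep_slices(mu2, ns),
       vois = vois, mask = rep_slices(object, ns))
}

#' Simulate a PET acquisition of a phantom
#'
#' Computes attenuation factors from the phantom's mu-map, scales the
#' noiseless attenuated projection so that trues carry
#' `(1 - scatter_fraction) * total_counts` and the spatially uniform
#' background sinogram `b` carries `scatter_fraction * total_counts` (so the
#' total expectation sums to `total_counts`), then draws `y ~ Poisson(ybar)`
#' with the spec's seed. The returned `truth` image is rescaled by the same
#' factor and is directly comparable to reconstructions.
#'
#' @param phantom output of [make_phantom()].
#' @param geom the [pet_geometry()] used to rasterize the phantom.
#' @param spec the [phantom_spec()] (count budget and seed).
#' @return List of class `pet_data`: `y`, `a`, `b`, `truth`, `ybar`
#'   (noise-free expectation), `scale`.
#' @export
simulate_acquisition <- function(phantom, geom, spec) {
  a <- attenuation_factors(phantom$mu, geom)
  raw <- forward_project(phantom$activity, geom, a = a, count = FALSE)
  tot_raw <- sum(raw)
  if (tot_raw <= 0) stop("phantom has no activity in the field of view")
  scale <- (1 - spec$scatter_fraction) * spec$total_counts / tot_raw
  ybar_true <- raw * scale
  b <- array(spec$scatter_fraction * spec$total_counts / length(raw), dim(raw))
  ybar <- ybar_true + b
  set.seed(spec$seed)
  y <- array(stats::rpois(length(ybar), as.vector(ybar)), dim(ybar))
  list(y = y, a = a, b = b, truth = phantom$activity * scale,
       ybar = ybar, scale = scale)
}

#' Thin a measured sinogram to a fraction of its counts
#'
#' Exact Poisson thinning by binomial subsampling: each recorded event is
#' kept independently with probability `fraction` (reproducing low-count
#' re-processing of an acquisition). The background expectation is scaled by
#' the same fraction.
#'
#' @param data a `pet_data` list (see [simulate_acquisition()]).
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return A `pet_data` list with thinned `y`, scaled `b`, `ybar`, `truth`.
#' @export
thin_counts <- function(data, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  set.seed(as.integer(seed))
  y2 <- array(stats::rbinom(length(data$y), as.integer(data$y), fraction),
              dim(data$y))
  out <- data
  out$y <- y2
  out$b <- data$b * fraction
  out$ybar <- data$ybar * fraction
  out$truth <- data$truth * fraction
  out
}
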