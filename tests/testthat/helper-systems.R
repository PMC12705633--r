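# Shared fixtures, all built in code.

# dense system matrix assembled column-by-column by projecting unit voxels:
# the independent oracle for every projector-based computation
dense_system_matrix <- function(geom, a = NULL, kernel = "joseph") {
  npix <- geom$nx * geom$ny * geom$n_slices
  cols <- lapply(seq_len(npix), function(j) {
    e <- array(0, image_dim(geom))
    e[j] <- 1
    as.vector(forward_project(e, geom, a = a, kernel = kernel, count = FALSE))
  })
  do.call(cbind, cols)
}

tiny_geom <- function(nx = 8, n_angles = 4, ...) {
  pet_geometry(nx = nx, ny = nx, n_radial = nx, n_angles = n_angles,
               pixel_size = 2, ...)
}

# a small reproducible emission problem on an n x n grid
tiny_problem <- function(nx = 16, n_angles = 8, seed = 42, b_level = 0.5) {
  geom <- tiny_geom(nx, n_angles)
  set.seed(seed)
  img <- array(0, image_dim(geom))
  cx <- (seq_len(nx) - (nx + 1) / 2)
  disc <- outer(cx, cx, function(x, y) x^2 + y^2 <= (0.4 * nx)^2)
  img[, , 1][disc] <- 2
  img[, , 1][outer(cx, cx, function(x, y) (x - 1)^2 + y^2 <= 2)] <- 6
  mu <- array(0, image_dim(geom))
  mu[, , 1][disc] <- 0.0096
  a <- attenuation_factors(mu, geom)
  ybar_t <- forward_project(img, geom, a = a, count = FALSE)
  b <- array(b_level * mean(ybar_t), dim(ybar_t))
  ybar <- ybar_t + b
  y <- array(rpois(length(ybar), as.vector(ybar)), dim(ybar))
  list(geom = geom, truth = img, mu = mu, a = a, b = b, ybar = ybar, y = y,
       mask = array(disc, image_dim(geom)))
}

rel_err <- function(x, y) abs(x - y) / max(abs(y), .Machine$double.eps)

# central-difference gradient of a scalar function of an image
numeric_grad <- function(fn, img, h) {
  g <- array(0, dim(img))
  for (j in seq_along(img)) {
    ip <- img; ip[j] <- ip[j] + h
    im <- img; im[j] <- im[j] - h
    g[j] <- (fn(ip) - fn(im)) / (2 * h)
  }
  g
}
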