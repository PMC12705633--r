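# step size, conjugation, OSEM, the iteration loop contracts, and BSREM.

quad_problem <- function(nx = 16, n_angles = 8, seed = 41, bg = 50) {
  # background-dominated Poisson problem: max(ybar, b) = b everywhere, so the
  # objective is exactly quadratic with Hessian A' diag(a^2/b) A
  geom <- tiny_geom(nx, n_angles)
  set.seed(seed)
  truth <- array(0, image_dim(geom))
  cx <- (seq_len(nx) - (nx + 1) / 2)
  truth[, , 1][outer(cx, cx, function(x, y) x^2 + y^2 <= (0.4 * nx)^2)] <- 2
  mu <- array(0, image_dim(geom)); mu[truth > 0] <- 0.0096
  a <- attenuation_factors(mu, geom)
  fwd <- forward_project(truth, geom, a = a, count = FALSE)
  b <- array(bg * mean(fwd), dim(fwd))
  ybar <- fwd + b
  y <- array(rpois(length(ybar), as.vector(ybar)), dim(ybar))
  list(geom = geom, truth = truth, a = a, b = b, y = y, ybar = ybar)
}

neg_quad_problem <- function(nx = 8, n_angles = 16, seed = 41) {
  # nonpositive trues keep ybar <= b, so the background clamp is active in
  # every bin and the modified objective is exactly quadratic:
  # H = A' diag(a^2 / b) A with constant weights
  geom <- tiny_geom(nx, n_angles)
  set.seed(seed)
  truth <- array(0, image_dim(geom))
  cx <- (seq_len(nx) - (nx + 1) / 2)
  truth[, , 1][outer(cx, cx, function(x, y) x^2 + y^2 <= (0.4 * nx)^2)] <- -2
  a <- array(0.9, sinogram_dim(geom))
  fwd <- forward_project(truth, geom, a = a, count = FALSE)
  b <- array(3 * max(abs(fwd)), dim(fwd))
  y <- b + fwd                        # noiseless; y > 0
  list(geom = geom, truth = truth, a = a, b = b, y = y)
}

test_that("the quadratic step size is the exact line minimizer on a quadratic", {
  q <- neg_quad_problem()
  geom <- q$geom
  lam0 <- array(0, image_dim(geom))   # ybar = b exactly: clamp active
  st <- likelihood_state(q$y, make_expectation(lam0, geom, a = q$a, b = q$b,
                                               count = FALSE),
                         q$b, q$a, geom)
  g <- grad_modified(st, count = FALSE)
  set.seed(42)
  s <- array(rnorm(prod(image_dim(geom))), image_dim(geom))
  f <- forward_project(s, geom, a = q$a, count = FALSE)
  w <- hessian_weights(st)
  alpha <- step_size(s, f, g, w, lam0, rdp_params(eps = 1))
  # dense oracle: alpha = <s,g> / <s, H s> with H = A' diag(a^2/b) A
  A <- dense_system_matrix(geom)
  H <- t(A) %*% (as.vector(q$a)^2 / as.vector(q$b) * A)
  alpha_oracle <- sum(s * g) / drop(t(c(s)) %*% H %*% c(s))
  expect_equal(alpha, alpha_oracle, tolerance = 1e-10)
})

test_that("with beta = 0 the step denominator is likelihood-only, and matches a line search", {
  q <- quad_problem(seed = 43, bg = 0.5)
  q$y <- q$ybar                       # noiseless, well-conditioned
  geom <- q$geom
  lam0 <- 0.98 * q$truth
  ybar0 <- make_expectation(lam0, geom, a = q$a, b = q$b, count = FALSE)
  st <- likelihood_state(q$y, ybar0, q$b, q$a, geom)
  g <- grad_modified(st, count = FALSE)
  s <- g
  f <- forward_project(s, geom, a = q$a, count = FALSE)
  w <- hessian_weights(st)
  alpha <- step_size(s, f, g, w, lam0, rdp_params(eps = 1))
  expect_equal(alpha, sum(s * g) / sum(f * f * w), tolerance = 1e-14)
  # golden-section oracle on the true objective along -s
  phi <- function(t) {
    st2 <- likelihood_state(q$y, ybar0 - t * f, q$b, q$a, geom)
    neg_loglik(st2)
  }
  opt <- optimize(phi, c(0, 10 * alpha), tol = 1e-10)
  expect_equal(alpha, opt$minimum, tolerance = 0.05)
})

test_that("an exact-inverse preconditioner solves a quadratic in one Newton step", {
  q <- neg_quad_problem(nx = 8, n_angles = 16, seed = 44)
  geom <- q$geom
  A <- dense_system_matrix(geom)
  W <- as.vector(q$a)^2 / as.vector(q$b)
  H <- t(A) %*% (W * A)
  lam <- array(0, image_dim(geom))              # ybar = b: clamp active
  st <- likelihood_state(q$y, make_expectation(lam, geom, a = q$a, b = q$b,
                                               count = FALSE),
                         q$b, q$a, geom)
  g <- grad_modified(st, count = FALSE)
  s <- array(solve(H, c(g)), dim(g))            # P = H^{-1}: Newton direction
  f <- forward_project(s, geom, a = q$a, count = FALSE)
  alpha <- step_size(s, f, g, hessian_weights(st), lam, rdp_params(eps = 1))
  expect_equal(alpha, 1, tolerance = 1e-8)
  lam1 <- lam - alpha * s                       # = truth: the exact minimizer
  st1 <- likelihood_state(q$y, make_expectation(lam1, geom, a = q$a, b = q$b,
                                                count = FALSE),
                          q$b, q$a, geom)
  g1 <- grad_modified(st1, count = FALSE)
  expect_lt(sqrt(sum(g1^2)) / sqrt(sum(g^2)), 1e-8)
})

test_that("the Polak-Ribiere coefficient is clamped at zero", {
  d <- c(4, 4, 1)
  set.seed(45)
  g_prev <- array(rnorm(prod(d)), d)
  pg_prev <- g_prev                      # positive denominator
  s <- array(rnorm(prod(d)), d)
  # craft a gradient change with negative inner product against s
  g <- g_prev - 2 * s * sum(s * s)
  expect_lt(sum(s * (g - g_prev)), 0)
  expect_identical(petprecon:::pr_coefficient(s, g, g_prev, pg_prev), 0)
  # positive case reproduces the ratio
  g2 <- g_prev + s
  expect_equal(petprecon:::pr_coefficient(s, g2, g_prev, pg_prev),
               sum(s * (g2 - g_prev)) / sum(pg_prev * g_prev))
  # nonpositive denominator also restarts
  expect_identical(petprecon:::pr_coefficient(s, g2, g_prev, -pg_prev), 0)
})

test_that("OSEM initialization is nonnegative and recovers a uniform disc", {
  geom <- tiny_geom(16, 8)
  truth <- array(0, image_dim(geom))
  cx <- (1:16 - 8.5)
  disc <- outer(cx, cx, function(x, y) x^2 + y^2 <= 6^2)
  truth[, , 1][disc] <- 5
  a <- array(1, sinogram_dim(geom))
  y <- forward_project(truth, geom, a = a, count = FALSE)   # noiseless, b = 0
  b <- array(0, dim(y))
  lam <- osem_initialize(y, a, b, geom, subiters = 14, subsets = 2)
  expect_true(all(lam >= 0))
  interior <- disc & outer(cx, cx, function(x, y) x^2 + y^2 <= 4.5^2)
  expect_equal(mean(lam[, , 1][interior]), 5, tolerance = 0.02)
})

test_that("one 1-subset OSEM iteration is the classical MLEM update", {
  p <- tiny_problem(8, 4, seed = 46)
  geom <- p$geom
  lam0 <- array(1, image_dim(geom))
  lam1 <- osem_initialize(p$y, p$a, p$b, geom, subiters = 1, subsets = 1,
                          init = lam0)
  # hand-coded MLEM oracle
  sens <- back_project(array(1, sinogram_dim(geom)), geom, a = p$a, count = FALSE)
  ybar <- forward_project(lam0, geom, a = p$a, count = FALSE) + p$b
  upd <- back_project(p$y / ybar, geom, a = p$a, count = FALSE)
  oracle <- lam0
  oracle[sens > 0] <- lam0[sens > 0] * upd[sens > 0] / sens[sens > 0]
  expect_equal(lam1, oracle, tolerance = 1e-12)
})

test_that("zero-iteration runs return the initialization unchanged", {
  p <- tiny_problem(8, 4, seed = 47)
  init <- array(1, image_dim(p$geom))
  for (alg in c("PCG", "PG", "DCG", "DG")) {
    cfg <- recon_config(alg, n_iter = 0, beta = 0, rdp = rdp_params(eps = 1))
    rec <- run_reconstruction(list(y = p$y, a = p$a, b = p$b), p$geom, cfg,
                              init = init, mask = p$mask)
    expect_identical(rec$image, init)
  }
})

test_that("the first PCG iteration equals the PG iteration", {
  p <- tiny_problem(16, 8, seed = 48)
  data <- list(y = p$y, a = p$a, b = p$b)
  r1 <- run_reconstruction(data, p$geom,
                           recon_config("PCG", n_iter = 1, beta = 0.01,
                                        rdp = rdp_params(eps = 0.1)),
                           init = array(1, image_dim(p$geom)), mask = p$mask)
  r2 <- run_reconstruction(data, p$geom,
                           recon_config("PG", n_iter = 1, beta = 0.01,
                                        rdp = rdp_params(eps = 0.1)),
                           init = array(1, image_dim(p$geom)), mask = p$mask)
  expect_identical(r1$image, r2$image)
})

test_that("each gradient iteration uses exactly one forward and one back projection", {
  p <- tiny_problem(16, 8, seed = 49)
  data <- list(y = p$y, a = p$a, b = p$b)
  for (alg in c("PCG", "PG", "DCG", "DG")) {
    cfg <- recon_config(alg, n_iter = 15, beta = 0.01,
                        rdp = rdp_params(eps = 0.1), refresh_every = 1000L)
    rec <- run_reconstruction(data, p$geom, cfg,
                              init = array(1, image_dim(p$geom)), mask = p$mask)
    expect_equal(diff(rec$trace$forward_projections), rep(1, 14))
    expect_equal(diff(rec$trace$back_projections), rep(1, 14))
  }
  # a scheduled expectation refresh costs one extra (logged) forward projection
  cfg <- recon_config("PCG", n_iter = 15, beta = 0.01,
                      rdp = rdp_params(eps = 0.1), refresh_every = 5L)
  rec <- run_reconstruction(data, p$geom, cfg,
                            init = array(1, image_dim(p$geom)), mask = p$mask)
  fp <- diff(rec$trace$forward_projections)
  expect_equal(sum(fp == 2), 3)          # refreshes logged at iterations 5, 10, 15
  expect_equal(diff(rec$trace$back_projections), rep(1, 14))
})

test_that("the incremental expectation stays consistent with the image", {
  p <- tiny_problem(16, 8, seed = 50)
  data <- list(y = p$y, a = p$a, b = p$b)
  cfg <- recon_config("PCG", n_iter = 25, beta = 0.01,
                      rdp = rdp_params(eps = 0.1))
  rec <- run_reconstruction(data, p$geom, cfg,
                            init = array(1, image_dim(p$geom)), mask = p$mask)
  exact <- make_expectation(rec$image, p$geom, a = p$a, b = p$b, count = FALSE)
  expect_lt(sqrt(sum((rec$ybar - exact)^2)) / sqrt(sum(exact^2)), 1e-8)
})

test_that("diagonal-preconditioned descent converges on a noiseless problem", {
  # strictly positive activity everywhere (no empty air voxels with vanishing
  # sensitivity-weighted curvature), so the monitored gradient norm must fall
  # below 1e-6 of its initial value
  nx <- 12
  geom <- tiny_geom(nx, 8)
  cx <- (seq_len(nx) - (nx + 1) / 2)
  truth <- array(2 + 0.5 * sin(outer(cx, cx, "+")), image_dim(geom))
  mu <- array(0.0096, image_dim(geom))
  a <- attenuation_factors(mu, geom)
  fwd <- forward_project(truth, geom, a = a, count = FALSE)
  b <- array(mean(fwd), dim(fwd))
  y <- fwd + b                           # exactly noiseless
  cfg <- recon_config("DG", n_iter = 12000L, beta = 0,
                      rdp = rdp_params(eps = 1), grad_tol = 1e-6)
  rec <- run_reconstruction(list(y = y, a = a, b = b), geom, cfg,
                            init = array(1, image_dim(geom)),
                            mask = array(TRUE, image_dim(geom)))
  expect_true(rec$converged)
  expect_lt(rec$final_grad_norm, 1e-6 * rec$initial_grad_norm)
})

test_that("negativity truncation keeps the constrained run nonnegative", {
  p <- tiny_problem(16, 8, seed = 52)
  data <- list(y = p$y, a = p$a, b = p$b)
  cfg <- recon_config("DG", n_iter = 30, beta = 0.01,
                      rdp = rdp_params(eps = 0.1), constrain_nonneg = TRUE)
  rec <- run_reconstruction(data, p$geom, cfg,
                            init = array(1, image_dim(p$geom)), mask = p$mask)
  expect_true(all(rec$image >= 0))
  # the unconstrained run of the same problem does go negative
  cfg_u <- recon_config("DG", n_iter = 30, beta = 0.01,
                        rdp = rdp_params(eps = 0.1))
  rec_u <- run_reconstruction(data, p$geom, cfg_u,
                              init = array(1, image_dim(p$geom)), mask = p$mask)
  expect_true(any(rec_u$image < 0))
})

test_that("BSREM stays positive, walks disjoint subsets, and tracks epochs", {
  p <- tiny_problem(16, 8, seed = 53)
  data <- list(y = p$y, a = p$a, b = p$b)
  cfg <- recon_config("BSREM", n_iter = 4, beta = 0.001,
                      rdp = rdp_params(eps = 0.1), bsrem_subsets = 8L)
  rec <- run_reconstruction(data, p$geom, cfg, init = NULL, mask = p$mask)
  expect_true(all(rec$image > 0))
  expect_equal(nrow(rec$trace), 4 * 8)
  expect_equal(rec$trace$epoch, (1:32) / 8)
  # disjoint angle subsets covering all views exactly once
  sets <- lapply(1:8, function(m) seq(m, p$geom$n_angles, by = 8))
  expect_equal(sort(unlist(sets)), seq_len(p$geom$n_angles))
  expect_error(recon_config("BSREM", bsrem_subsets = 4L), "between 5 and 9")
})

test_that("BSREM approaches the unconstrained hot-region activity at high counts", {
  # high-count, noise-free data: constrained and unconstrained optima agree in
  # hot regions, so a long BSREM run must approach the unconstrained reference
  q <- quad_problem(nx = 16, n_angles = 8, seed = 54, bg = 0.2)
  y <- round(q$ybar * 1e3) / 1  # high-count integer-like scaling
  data <- list(y = y, a = q$a, b = q$b * 1e3)
  hot <- q$truth > 0
  ref_cfg <- recon_config("PCG", n_iter = 150, beta = 0,
                          rdp = rdp_params(eps = 1))
  ref <- run_reconstruction(data, q$geom, ref_cfg, mask = hot)
  cfg <- recon_config("BSREM", n_iter = 40, beta = 0,
                      rdp = rdp_params(eps = 1), bsrem_subsets = 8L)
  rec <- run_reconstruction(data, q$geom, cfg, mask = hot)
  expect_lt(abs(voi_error(rec$image, ref$image, hot)), 0.02)
})
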