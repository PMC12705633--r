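# Benchmark driver: phantom -> simulate -> initialize -> reference ->
# reconstruct (all variants, three beta levels) -> metrics -> report files.

#' Pilot rule for the mid prior strength
#'
#' Chooses `beta_mid` so that the prior contributes about 10% of the
#' likelihood curvature trace at the initialization:
#' `beta_mid = 0.1 * sum(eta_lik[mask]) / sum(max(H_rdp_diag, 0)[mask])`.
#' The low/high levels of a sweep are `beta_mid / 3` and `3 * beta_mid`.
#'
#' @param data a `pet_data` list.
#' @param geom a [pet_geometry()].
#' @param init initialization image (e.g. from [osem_initialize()]).
#' @param mask logical object mask.
#' @param rdp an [rdp_params()] (its `eps` is resolved from `init` if unset).
#' @return Positive scalar `beta_mid`.
#' @export
beta_mid_pilot <- function(data, geom, init, mask, rdp = rdp_params()) {
  rdp <- resolve_rdp_eps(rdp, init, mask)
  ybar <- make_expectation(init, geom, a = data$a, b = data$b, count = FALSE)
  state <- likelihood_state(data$y, ybar, data$b, data$a, geom)
  rdp0 <- rdp; rdp0$beta <- 0
  eta_lik <- compute_eta(state, rdp0, init, count = FALSE)
  hprior <- pmax(rdp_hess_diag(init, rdp), 0)
  tr_prior <- sum(hprior[mask])
  if (tr_prior <= 0) stop("prior curvature trace is zero at the initialization")
  0.1 * sum(eta_lik[mask]) / tr_prior
}

#' Generate the default benchmark problem
#'
#' Phantom, geometry, simulated data, OSEM initialization, resolved RDP
#' parameters and the pilot `beta_mid` in one call — the shared setup for the
#' convergence experiments.
#'
#' @param spec a [phantom_spec()].
#' @param geom a [pet_geometry()].
#' @param osem_subiters,osem_subsets OSEM initialization settings.
#' @return List with `phantom`, `data`, `init`, `mask`, `vois`, `rdp`,
#'   `beta_mid`, `geom`, `spec`.
#' @export
benchmark_problem <- function(spec = phantom_spec("nema_like"),
                              geom = default_geometry(spec),
                              osem_subiters = 14L, osem_subsets = 2L) {
  ph <- make_phantom(spec, geom)
  data <- simulate_acquisition(ph, geom, spec)
  init <- osem_initialize(data$y, data$a, data$b, geom,
                          osem_subiters, osem_subsets)
  mask <- ph$mask
  rdp <- resolve_rdp_eps(rdp_params(), init, mask)
  beta_mid <- beta_mid_pilot(data, geom, init, mask, rdp)
  list(phantom = ph, data = data, init = init, mask = mask,
       vois = ph$vois, rdp = rdp, beta_mid = beta_mid,
       geom = geom, spec = spec)
}

#' Converged reference reconstruction
#'
#' Long unconstrained DG run with gradient-norm stopping (relative tolerance
#' `1e-7`), used as the reference image for all convergence metrics.
#'
#' @param prob a [benchmark_problem()].
#' @param beta prior strength for the reference.
#' @param max_iter iteration cap.
#' @param grad_tol relative gradient-norm stopping tolerance.
#' @param constrain_nonneg reference variant with negativity truncation.
#' @return A `pet_recon`.
#' @export
reference_reconstruction <- function(prob, beta, max_iter = 3000L,
                                     grad_tol = 1e-7,
                                     constrain_nonneg = FALSE) {
  cfg <- recon_config("DG", n_iter = max_iter, beta = beta, rdp = prob$rdp,
                      constrain_nonneg = constrain_nonneg,
                      grad_tol = grad_tol)
  run_reconstruction(prob$data, prob$geom, cfg, init = prob$init,
                     mask = prob$mask)
}

#' Run the full benchmark suite
#'
#' For each requested beta level (low = mid/3, mid, high = 3*mid), builds a
#' converged DG reference and runs every requested algorithm against it,
#' collecting per-iteration traces and a summary table of
#' constrained-vs-unconstrained agreement (whole-object RMSE and min/max VOI
#' absolute error). Fully deterministic given the spec seed.
#'
#' @param prob a [benchmark_problem()].
#' @param algorithms character vector of algorithm names.
#' @param n_iter iterations per algorithm (epochs for BSREM).
#' @param beta_levels named numeric vector of beta values; default the
#'   low/mid/high triple from the pilot rule.
#' @param ref_iter iteration cap for the reference runs.
#' @param out_dir optional directory; when given, traces (CSV), volumes
#'   (NIfTI) and the summary table are written there.
#' @return List with `traces` (named list of data.frames), `summary`
#'   (data.frame), `references`, `beta_levels`.
#' @export
run_benchmark <- function(prob,
                          algorithms = c("PCG", "PG", "DCG", "DG", "BSREM"),
                          n_iter = 20L, beta_levels = NULL, ref_iter = 3000L,
                          out_dir = NULL) {
  if (is.null(beta_levels))
    beta_levels <- c(low = prob$beta_mid / 3, mid = prob$beta_mid,
                     high = 3 * prob$beta_mid)
  traces <- list(); refs <- list()
  summary_rows <- list()
  for (lev in names(beta_levels)) {
    beta <- beta_levels[[lev]]
    ref <- reference_reconstruction(prob, beta, max_iter = ref_iter)
    refs[[lev]] <- ref
    for (alg in algorithms) {
      cfg <- recon_config(alg, n_iter = n_iter, beta = beta, rdp = prob$rdp)
      rec <- run_reconstruction(prob$data, prob$geom, cfg, init = prob$init,
                                ref = ref$image, mask = prob$mask,
                                vois = prob$vois)
      key <- paste(alg, lev, sep = "_")
      traces[[key]] <- rec$trace
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_trace(rec$trace, file.path(out_dir, paste0("trace_", key, ".csv")))
        write_volume(rec$image, file.path(out_dir, paste0("image_", key, ".nii.gz")),
                     prob$geom)
      }
    }
    # constrained vs unconstrained agreement at this beta
    refc <- reference_reconstruction(prob, beta, max_iter = ref_iter,
                                     constrain_nonneg = TRUE)
    voi_ae <- vapply(prob$vois[!names(prob$vois) %in% "whole_object"],
                     function(v) abs(as.numeric(
                       voi_error(refc$image, ref$image, v,
                                 bg_mean = mean(ref$image[prob$mask])))),
                     numeric(1))
    summary_rows[[lev]] <- data.frame(
      phantom = prob$spec$kind, beta_level = lev, beta = beta,
      rmse_constr_vs_unconstr = rmse(refc$image, ref$image, prob$mask),
      min_voi_ae_pct = 100 * min(voi_ae), max_voi_ae_pct = 100 * max(voi_ae))
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  list(traces = traces, summary = summary, references = refs,
       beta_levels = beta_levels)
}

#' Plot convergence traces
#'
#' VOI error or RMSE versus epoch (log-x), one line per algorithm/beta trace.
#'
#' @param traces named list of trace data.frames (see [run_benchmark()]).
#' @param metric trace column to plot (e.g. `"rmse"` or a `voi_*` column).
#' @param path optional output file (PNG/PDF via [ggplot2::ggsave()]).
#' @return The ggplot object, invisibly.
#' @export
plot_convergence <- function(traces, metric = "rmse", path = NULL) {
  df <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    if (!metric %in% names(tr)) return(NULL)
    data.frame(run = nm, epoch = tr$epoch, value = abs(tr[[metric]]))
  }))
  if (is.null(df) || nrow(df) == 0) stop("metric not found in any trace")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = value, colour = run)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "epoch", y = paste0("|", metric, "|")) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 5)
  invisible(p)
}

#' Canned convergence study on the default image-quality phantom
#'
#' The package's standard experiment: simulate the default NEMA-IQ-like
#' acquisition (128x128 grid, 2 mm pixels, 10:1 sphere contrast, 20% uniform
#' background fraction, 5e6 expected prompts), OSEM-initialize, build a
#' converged unconstrained reference (long PCG run with gradient-norm
#' monitoring -- the fastest-converging variant is used to generate the
#' reference), run the four gradient variants and BSREM against it, and run
#' the constrained-vs-unconstrained comparison with the diagonal-preconditioned
#' gradient algorithm. Deterministic given `seed`.
#'
#' @param seed integer seed for the Poisson data.
#' @param n_iter iterations for the compared algorithms (epochs for BSREM).
#' @param ref_iter iteration cap for the converged reference run.
#' @param t3_iter iterations for each arm of the constrained-vs-unconstrained
#'   comparison.
#' @param algorithms gradient variants to trace.
#' @param include_bsrem logical; also run the BSREM comparator.
#' @param constrained_pair logical; run the constrained-vs-unconstrained pair.
#' @return List with the problem (`prob`), the reference run (`reference`),
#'   per-algorithm `traces`, and scalars `voi10_at` (percent |VOI error| of
#'   the 10 mm sphere per iteration), `rmse_constr_unconstr` (percent, or NA
#'   if not run).
#' @export
run_convergence_study <- function(seed = 1L, n_iter = 20L, ref_iter = 600L,
                                  t3_iter = 1500L,
                                  algorithms = c("PCG", "PG", "DCG", "DG"),
                                  include_bsrem = TRUE,
                                  constrained_pair = TRUE) {
  spec <- phantom_spec("nema_like", total_counts = 5e6, scatter_fraction = 0.2,
                       seed = seed)
  geom <- default_geometry(spec)
  prob <- benchmark_problem(spec, geom)
  beta <- prob$beta_mid
  ref_cfg <- recon_config("PCG", n_iter = ref_iter, beta = beta,
                          rdp = prob$rdp, grad_tol = 1e-7)
  reference <- run_reconstruction(prob$data, geom, ref_cfg, init = prob$init,
                                  mask = prob$mask)
  traces <- list()
  for (alg in algorithms) {
    cfg <- recon_config(alg, n_iter = n_iter, beta = beta, rdp = prob$rdp)
    rec <- run_reconstruction(prob$data, geom, cfg, init = prob$init,
                              ref = reference$image, mask = prob$mask,
                              vois = prob$vois)
    traces[[alg]] <- rec$trace
  }
  if (include_bsrem) {
    cfg <- recon_config("BSREM", n_iter = n_iter, beta = beta, rdp = prob$rdp)
    rec <- run_reconstruction(prob$data, geom, cfg, init = prob$init,
                              ref = reference$image, mask = prob$mask,
                              vois = prob$vois)
    traces$BSREM <- rec$trace
  }
  voi10_at <- if ("PCG" %in% names(traces))
    100 * abs(traces$PCG$voi_sphere_10mm) else numeric()
  rmse_cu <- NA_real_
  if (constrained_pair) {
    cfg_u <- recon_config("DG", n_iter = t3_iter, beta = beta, rdp = prob$rdp)
    cfg_c <- recon_config("DG", n_iter = t3_iter, beta = beta, rdp = prob$rdp,
                          constrain_nonneg = TRUE)
    rec_u <- run_reconstruction(prob$data, geom, cfg_u, init = prob$init,
                                mask = prob$mask)
    rec_c <- run_reconstruction(prob$data, geom, cfg_c, init = prob$init,
                                mask = prob$mask)
    rmse_cu <- rmse(rec_c$image, rec_u$image, prob$mask)
  }
  list(prob = prob, reference = reference, traces = traces,
       voi10_at = voi10_at, rmse_constr_unconstr = rmse_cu)
}
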