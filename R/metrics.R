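# Convergence metrics: normalized whole-object RMSE and per-VOI relative
# errors, recorded per iteration (fractional epochs for subset algorithms).

#' Normalized root mean squared error (percent)
#'
#' RMSE between `x` and `ref` over `mask`, normalized to the mean of `ref`
#' inside the mask and expressed in percent:
#' `100 * sqrt(mean((x - ref)^2)) / mean(ref)`.
#'
#' @param x,ref image-shaped arrays.
#' @param mask logical image-shaped mask (nonempty).
#' @return Scalar percent value.
#' @export
rmse <- function(x, ref, mask) {
  if (!any(mask)) stop("mask must be nonempty")
  100 * sqrt(mean((x[mask] - ref[mask])^2)) / mean(ref[mask])
}

#' Relative error of the mean activity within a VOI
#'
#' `sum(x in VOI) / sum(ref in VOI) - 1`. For (near-)cold VOIs whose reference
#' sum is below a floor of `1e-6 * bg_mean * n_voxels`, the ratio is
#' meaningless; the function then reports the absolute difference normalized
#' by `bg_mean * n_voxels` and flags the value with attribute
#' `cold_guard = TRUE`.
#'
#' @param x,ref image-shaped arrays.
#' @param voi logical VOI mask (nonempty).
#' @param bg_mean background mean used by the cold-VOI guard (e.g. the mean of
#'   `ref` over the whole-object mask); defaults to `mean(abs(ref[voi]))`
#'   which disables the guard in ordinary use.
#' @return Scalar relative error (unitless; multiply by 100 for percent).
#' @export
voi_error <- function(x, ref, voi, bg_mean = NULL) {
  if (!any(voi)) stop("VOI mask must be nonempty")
  sref <- sum(ref[voi])
  if (is.null(bg_mean)) bg_mean <- mean(abs(ref[voi]))
  floor_val <- 1e-6 * abs(bg_mean) * sum(voi)
  if (abs(sref) < floor_val) {
    out <- (sum(x[voi]) - sref) / (abs(bg_mean) * sum(voi))
    attr(out, "cold_guard") <- TRUE
    return(out)
  }
  sum(x[voi]) / sref - 1
}

new_trace <- function(voi_names = character()) {
  cols <- c("iteration", "epoch", "objective", "grad_norm", "rmse",
            "forward_projections", "back_projections",
            if (length(voi_names)) paste0("voi_", voi_names))
  df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
  names(df) <- cols
  df
}

trace_row <- function(trace, iteration, epoch, objective, grad_norm,
                      rmse_val, counts, voi_vals = numeric()) {
  trace[nrow(trace) + 1L, ] <- c(iteration, epoch, objective, grad_norm,
                                 rmse_val, counts[["forward"]],
                                 counts[["back"]], unlist(voi_vals))
  trace
}

compute_metrics <- function(img, ref, mask, vois, bg_mean) {
  if (is.null(ref)) return(list(rmse = NA_real_, voi = lapply(vois, function(v) NA_real_)))
  list(rmse = rmse(img, ref, mask),
       voi = lapply(vois, function(v) as.numeric(voi_error(img, ref, v, bg_mean))))
}
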