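# Persistence helpers: volumes as NIfTI (RNifti), sinograms as serialized
# array archives, convergence traces as CSV, configuration as YAML.

#' Write an activity/attenuation volume as NIfTI
#'
#' @param img image-shaped array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geom a [pet_geometry()] providing the voxel size.
#' @return The path, invisibly.
#' @export
write_volume <- function(img, path, geom) {
  RNifti::writeNifti(RNifti::asNifti(img, pixdim = rep(geom$pixel_size, 3)),
                     path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  a <- as.array(arr)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  a
}

#' Write a sinogram (or any array) as a compressed archive
#' @param s array.
#' @param path output path (`.rds`).
#' @return The path, invisibly.
#' @export
write_sinogram <- function(s, path) {
  saveRDS(s, path, compress = "gzip")
  invisible(path)
}

#' Read a sinogram archive written by [write_sinogram()]
#' @param path input path.
#' @return The stored array.
#' @export
read_sinogram <- function(path) readRDS(path)

#' Write a convergence trace as CSV
#' @param trace data.frame trace from a `pet_recon`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a geometry/phantom configuration from YAML
#'
#' Recognized top-level blocks: `geometry` (arguments of [pet_geometry()])
#' and `phantom` (arguments of [phantom_spec()]).
#'
#' @param path YAML file path.
#' @return List with elements `geometry` (or `NULL`) and `phantom` (or `NULL`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(geometry = NULL, phantom = NULL)
  if (!is.null(cfg$geometry)) out$geometry <- do.call(pet_geometry, cfg$geometry)
  if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    if (!is.null(ph$inserts)) ph$inserts <- as.data.frame(do.call(rbind, lapply(ph$inserts, as.data.frame)))
    out$phantom <- do.call(phantom_spec, ph)
  }
  out
}
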