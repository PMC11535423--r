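# File I/O: multi-page TIFF stacks (16-bit, with the intensity scale recorded
# in a YAML sidecar), label-mask TIFFs, CSV tables, and YAML parameter echoes.

sidecar_path <- function(path) paste0(path, ".yml")

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are quantized to 16 bits after division by a scale factor
#' (their maximum); the scale and the physical voxel sizes are recorded in a
#' YAML sidecar next to the TIFF so [read_stack_tiff()] restores the original
#' floating-point values (up to quantization).
#'
#' @param stack an [image_stack]
#' @param path output TIFF path (z-major pages)
#' @return invisibly, the sidecar path
#' @export
write_stack_tiff <- function(stack, path) {
  assert_stack(stack)
  a <- stack$intensities
  scale <- max(a, 0)
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(a)[1]), function(z) pmin(pmax(a[z, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(intensity_scale = scale,
                        voxel_size_z = stack$voxel_size_z,
                        pixel_size_xy = stack$pixel_size_xy),
                   sidecar_path(path))
  invisible(sidecar_path(path))
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF path; a YAML sidecar written by [write_stack_tiff()] is
#'   used for the intensity scale and voxel sizes when present
#' @param voxel_size_z,pixel_size_xy voxel sizes, um; override/supply when no
#'   sidecar exists
#' @return an [image_stack]
#' @export
read_stack_tiff <- function(path, voxel_size_z = NULL, pixel_size_xy = NULL) {
  meta <- list(intensity_scale = 1, voxel_size_z = 0.240, pixel_size_xy = 0.103)
  if (file.exists(sidecar_path(path))) {
    meta <- utils::modifyList(meta, yaml::read_yaml(sidecar_path(path)))
  }
  if (!is.null(voxel_size_z)) meta$voxel_size_z <- voxel_size_z
  if (!is.null(pixel_size_xy)) meta$pixel_size_xy <- pixel_size_xy
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  dm <- c(length(pages), dim(pages[[1]]))
  a <- array(0, dm)
  for (z in seq_len(dm[1])) a[z, , ] <- pages[[z]] / 65535 * meta$intensity_scale
  image_stack(a, meta$voxel_size_z, meta$pixel_size_xy)
}

#' Write a 2D label mask as a 16-bit TIFF
#'
#' @param labels integer matrix `[y, x]`; 0 is background; labels must be
#'   below 65536
#' @param path output path
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 2D label mask from a 16-bit TIFF
#'
#' @param path TIFF path
#' @return integer matrix `[y, x]`
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Save a simulated smFISH dataset to disk
#'
#' Writes the stack (multi-page TIFF + sidecar), the cell and nuclei label
#' masks, the ground-truth spot table (CSV), and the simulation parameters
#' (YAML) into a directory.
#'
#' @param sim result of [generate_smfish_stack()]
#' @param dir output directory (created if needed)
#' @param params the [stack_sim_params] used (echoed to `params.yml`)
#' @return invisibly, the directory
#' @export
save_smfish_simulation <- function(sim, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack_tiff(sim$stack, file.path(dir, "stack.tif"))
  write_label_tiff(sim$cell_labels, file.path(dir, "cells.tif"))
  write_label_tiff(sim$nuclei_labels, file.path(dir, "nuclei.tif"))
  utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (!is.null(params)) {
    yaml::write_yaml(unclass(params), file.path(dir, "params.yml"))
  }
  invisible(dir)
}

#' Write a spot table and per-cell counts to CSV
#'
#' @param spots a `spot_table` from [call_spots()]
#' @param cell_labels the cell label matrix (for zero-count cells)
#' @param path spots CSV path; counts go to `<path base>_counts.csv`
#' @return invisibly, the counts path
#' @export
write_spot_table <- function(spots, cell_labels, path) {
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE)
  counts_path <- sub("(\\.[^.]+)?$", "_counts\\1", path)
  if (counts_path == path) counts_path <- paste0(path, "_counts.csv")
  utils::write.csv(spot_counts(spots, cell_labels), counts_path,
                   row.names = FALSE)
  invisible(counts_path)
}
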