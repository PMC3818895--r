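#' Persist per-slice binary masks as single-channel TIFF files
#'
#' Writes one 8-bit grayscale TIFF per slice (0 = background, 255 =
#' foreground), numbered `mask_0001.tif`, ...
#'
#' @param masks list of logical matrices (z order).
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_masks <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    paths[i] <- file.path(dir, sprintf("mask_%04d.tif", i))
    tiff::writeTIFF(masks[[i]] * 1, paths[i], bits.per.sample = 8)
  }
  invisible(paths)
}

#' Read masks written by [write_masks()]
#' @param dir directory holding `mask_*.tif`.
#' @return list of logical matrices.
#' @export
read_masks <- function(dir) {
  files <- sort(list.files(dir, pattern = "^mask_\\d+\\.tif$",
                           full.names = TRUE))
  lapply(files, function(f) tiff::readTIFF(f) > 0.5)
}

#' Persist a voxel volume as a multi-page TIFF
#'
#' Label volumes are scaled into \[0, 1\] by the maximum label so the TIFF
#' stays 8-bit; binary volumes write as 0/255.
#'
#' @param volume a `voxel_volume`, or a raw logical/integer 3D array.
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
write_volume_tiff <- function(volume, path) {
  grid <- if (inherits(volume, "voxel_volume")) volume$grid else volume
  top <- max(1, max(grid))
  pages <- lapply(seq_len(dim(grid)[3]), function(z) grid[, , z] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Persist an extracted nucleus table as CSV
#'
#' @param nuclei a `nucleus_set` from [extract_nuclei_3d()] (or its
#'   `records` data.frame).
#' @param path output CSV path.
#' @param ki67 optional marker label (`"pos"`/`"neg"`) written as a column.
#' @return invisibly, `path`.
#' @export
write_nuclei <- function(nuclei, path, ki67 = NA_character_) {
  rec <- if (inherits(nuclei, "nucleus_set")) nuclei$records else nuclei
  rec$ki67 <- ki67
  utils::write.csv(rec[, c("id", "ki67", "compartment", "x", "y", "z",
                           "voxel_count", "slice_span")],
                   path, row.names = FALSE)
  invisible(path)
}
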