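#' Ordered stack of RGB section images
#'
#' Container for an ordered series of serial-section images with physical
#' calibration. Images are numeric arrays `ny x nx x 3` on \[0, 1\]; list
#' order is physical z order.
#'
#' @param images list of RGB arrays, all of identical dimensions.
#' @param pixel_size_um in-plane pixel edge in micrometers.
#' @param slice_thickness_um section thickness (z voxel depth) in micrometers.
#' @param true_transforms optional list of per-slice [rigid_transform()]s
#'   applied during synthetic rendering (ground truth for recovery tests).
#' @return object of class `section_stack`.
#' @export
section_stack <- function(images, pixel_size_um, slice_thickness_um,
                          true_transforms = NULL) {
  stopifnot(length(images) >= 1, pixel_size_um > 0, slice_thickness_um > 0)
  d <- dim(images[[1]])
  for (i in seq_along(images))
    if (!all(dim(images[[i]]) == d))
      stop(sprintf("slice %d has mismatching dimensions", i))
  structure(list(images = images,
                 pixel_size_um = pixel_size_um,
                 slice_thickness_um = slice_thickness_um,
                 true_transforms = true_transforms),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("section_stack: %d slices of %d x %d px, %.3g um/px, %.3g um thick\n",
              length(x$images), d[2], d[1], x$pixel_size_um,
              x$slice_thickness_um))
  invisible(x)
}

#' Write a section stack as numbered 8-bit RGB TIFF files
#'
#' Writes `slice_0001.tif`, ... plus a plain-text metadata sidecar
#' (`stack_meta.txt`: pixel size, slice thickness) and, when ground-truth
#' transforms are present, `true_transforms.csv`.
#'
#' @param stack a [section_stack()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written image paths.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$images))
  for (i in seq_along(stack$images)) {
    paths[i] <- file.path(dir, sprintf("slice_%04d.tif", i))
    img <- pmin(pmax(stack$images[[i]], 0), 1)
    tiff::writeTIFF(img, paths[i], bits.per.sample = 8)
  }
  writeLines(c(sprintf("pixel_size_um\t%.6g", stack$pixel_size_um),
               sprintf("slice_thickness_um\t%.6g", stack$slice_thickness_um),
               sprintf("n_slices\t%d", length(stack$images))),
             file.path(dir, "stack_meta.txt"))
  if (!is.null(stack$true_transforms)) {
    tt <- stack$true_transforms
    df <- data.frame(slice_index = seq_along(tt),
                     tx = vapply(tt, `[[`, numeric(1), "tx"),
                     ty = vapply(tt, `[[`, numeric(1), "ty"),
                     theta_deg = vapply(tt, `[[`, numeric(1), "theta"),
                     center_x = vapply(tt, function(t) t$center[1], numeric(1)),
                     center_y = vapply(tt, function(t) t$center[2], numeric(1)))
    utils::write.csv(df, file.path(dir, "true_transforms.csv"),
                     row.names = FALSE)
  }
  invisible(paths)
}

#' Read a section stack written by [write_stack()]
#'
#' @param dir directory holding `slice_*.tif` and `stack_meta.txt`.
#' @return a [section_stack()].
#' @export
read_stack <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "stack_meta.txt"), header = FALSE,
                            col.names = c("key", "value"))
  val <- function(k) as.numeric(meta$value[meta$key == k])
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.tif$",
                           full.names = TRUE))
  imgs <- lapply(files, tiff::readTIFF)
  tt <- NULL
  tpath <- file.path(dir, "true_transforms.csv")
  if (file.exists(tpath)) {
    df <- utils::read.csv(tpath)
    tt <- lapply(seq_len(nrow(df)), function(i)
      rigid_transform(df$tx[i], df$ty[i], df$theta_deg[i],
                      c(df$center_x[i], df$center_y[i])))
  }
  section_stack(imgs, val("pixel_size_um"), val("slice_thickness_um"), tt)
}

#' Persist composed registration transforms as CSV
#' @param transforms list of [rigid_transform()]s.
#' @param path output CSV path.
#' @export
write_transforms <- function(transforms, path) {
  df <- data.frame(slice_index = seq_along(transforms),
                   tx = vapply(transforms, `[[`, numeric(1), "tx"),
                   ty = vapply(transforms, `[[`, numeric(1), "ty"),
                   theta_deg = vapply(transforms, `[[`, numeric(1), "theta"),
                   center_x = vapply(transforms, function(t) t$center[1], numeric(1)),
                   center_y = vapply(transforms, function(t) t$center[2], numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
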