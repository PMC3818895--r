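#' Anisotropic voxel volumes from per-slice masks
#'
#' The stack is assembled with no resampling in z: the z voxel depth is
#' fixed at the physical slice thickness (anisotropic voxels,
#' `dx = dy != dz`). Physical volume of any region is voxel count times
#' `dx * dy * dz`.
#'
#' @name volume_builder
NULL

#' In-plane circular core footprint
#'
#' @param ny,nx grid dimensions in pixels.
#' @param diameter_px core diameter in pixels.
#' @param center `(cx, cy)`; default grid center.
#' @return logical `ny x nx` matrix, TRUE inside the disk.
#' @export
core_disk <- function(ny, nx, diameter_px, center = c((nx + 1) / 2, (ny + 1) / 2)) {
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  (X - center[1])^2 + (Y - center[2])^2 <= (diameter_px / 2)^2
}

#' Stack per-slice masks into a voxel volume
#'
#' @param masks list of logical matrices (z order), all of the same shape.
#' @param voxel_dims_um `(dx, dy, dz)` voxel edges in micrometers; `dz` is
#'   the slice thickness.
#' @return object of class `voxel_volume`: list with logical 3D `grid`
#'   (`ny x nx x nz`), `voxel_dims_um`, and `core_mask` (set by
#'   [apply_core_cylinder()]; initially the full plane).
#' @export
stack_to_volume <- function(masks, voxel_dims_um) {
  stopifnot(length(masks) >= 2, length(voxel_dims_um) == 3,
            all(voxel_dims_um > 0))
  d <- dim(masks[[1]])
  for (i in seq_along(masks))
    if (!all(dim(masks[[i]]) == d))
      stop(sprintf("slice %d has mismatching shape", i))
  grid <- array(FALSE, c(d[1], d[2], length(masks)))
  for (i in seq_along(masks)) grid[, , i] <- masks[[i]]
  structure(list(grid = grid,
                 voxel_dims_um = as.numeric(voxel_dims_um),
                 core_mask = matrix(TRUE, d[1], d[2])),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("voxel_volume: %d x %d x %d voxels of %.3g x %.3g x %.3g um, %d foreground\n",
              d[2], d[1], d[3], x$voxel_dims_um[1], x$voxel_dims_um[2],
              x$voxel_dims_um[3], sum(x$grid)))
  invisible(x)
}

#' Restrict a volume to the circular tissue core
#'
#' Voxels outside the in-plane core disk are cleared on every slice and the
#' disk footprint is recorded as `core_mask`. The analyzed total tissue
#' volume is defined as disk area times stack height.
#'
#' @param volume a `voxel_volume`.
#' @param core_diameter_um core diameter in micrometers.
#' @param center optional in-plane disk center `(cx, cy)` in pixels.
#' @return the clipped `voxel_volume` with `core_mask` and
#'   `core_diameter_um` set.
#' @export
apply_core_cylinder <- function(volume, core_diameter_um, center = NULL) {
  d <- dim(volume$grid)
  dx <- volume$voxel_dims_um[1]
  dpx <- core_diameter_um / dx
  if (dpx > max(d[1], d[2]) + 1e-9)
    stop("core diameter exceeds the grid extent")
  disk <- if (is.null(center)) core_disk(d[1], d[2], dpx)
          else core_disk(d[1], d[2], dpx, center)
  if (!any(disk)) stop("degenerate core: no in-core pixel")
  grid <- volume$grid
  grid[!array(disk, d)] <- FALSE
  volume$grid <- grid
  volume$core_mask <- disk
  volume$core_diameter_um <- core_diameter_um
  volume
}

#' Physical volume of the core cylinder
#'
#' Digital total tissue volume: in-core pixel count times pixel area times
#' stack height. With an analytically circular field the continuous
#' counterpart is `pi (d/2)^2 * n_slices * dz`.
#'
#' @param volume a `voxel_volume` after [apply_core_cylinder()].
#' @return volume in cubic millimeters.
#' @export
core_volume_mm3 <- function(volume) {
  v <- volume$voxel_dims_um
  sum(volume$core_mask) * v[1] * v[2] * v[3] * dim(volume$grid)[3] / 1e9
}

#' Extract 3D nucleus objects with the two-consecutive-slice noise filter
#'
#' Labels 26-connected components of a candidate nucleus volume and deletes
#' every component confined to a single image plane: objects assigned as
#' nuclei must be connected between at least two consecutive sections, and
#' single-plane signals with no corresponding object in an adjacent section
#' are noise. Survivors are assigned a compartment by majority voxel
#' overlap with the parenchyma volume (ties go to parenchyma, the
#' biologically intended assignment for nuclei inside CK+ cytoplasm).
#'
#' Ki67-negative candidates are holes in the parenchyma and by definition
#' lie inside it; pass `compartment = "parenchyma"` for those.
#'
#' @param nucleus_volume logical 3D array of candidate voxels.
#' @param parenchyma_volume logical 3D array (same shape).
#' @param compartment `"auto"` (majority overlap vote) or a fixed
#'   compartment label.
#' @return object of class `nucleus_set`: list with `records` (data.frame:
#'   id, compartment, x, y, z centroid voxel coords, voxel_count,
#'   slice_span) and `mask` (the surviving voxels).
#' @export
extract_nuclei_3d <- function(nucleus_volume, parenchyma_volume,
                              compartment = c("auto", "parenchyma", "stroma")) {
  compartment <- match.arg(compartment)
  if (!all(dim(nucleus_volume) == dim(parenchyma_volume)))
    stop("volumes must be congruent")
  lab <- label_components(nucleus_volume, 26)
  n <- attr(lab, "n_components")
  empty <- data.frame(id = integer(0), compartment = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      voxel_count = integer(0), slice_span = integer(0))
  if (n == 0)
    return(structure(list(records = empty, mask = nucleus_volume & FALSE),
                     class = "nucleus_set"))
  d <- dim(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  z <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  rem <- (idx - 1L) %% (d[1] * d[2])
  x <- rem %/% d[1] + 1L
  y <- rem %% d[1] + 1L
  span <- vapply(split(z, l), function(v) length(unique(v)), integer(1))
  ids <- as.integer(names(span))
  keep_ids <- ids[span >= 2L]
  if (length(keep_ids) == 0)
    return(structure(list(records = empty, mask = nucleus_volume & FALSE),
                     class = "nucleus_set"))
  keep <- l %in% keep_ids
  l2 <- l[keep]
  par_hit <- parenchyma_volume[idx][keep]
  agg <- function(v) vapply(split(v, l2), mean, numeric(1))
  cx <- agg(x[keep]); cy <- agg(y[keep]); cz <- agg(z[keep])
  vc <- vapply(split(l2, l2), length, integer(1))
  frac_par <- agg(par_hit)
  comp <- if (compartment == "auto")
    ifelse(frac_par >= 0.5, "parenchyma", "stroma") else rep(compartment, length(vc))
  rec <- data.frame(id = seq_along(vc),
                    compartment = comp,
                    x = cx, y = cy, z = cz,
                    voxel_count = as.integer(vc),
                    slice_span = as.integer(span[as.character(sort(unique(l2)))]),
                    row.names = NULL)
  # order of split() groups is sorted label order; align all columns to it
  mask <- array(FALSE, d)
  mask[idx[keep]] <- TRUE
  structure(list(records = rec, mask = mask), class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("nucleus_set: %d nuclei (%d parenchymal, %d stromal)\n",
              nrow(x$records), sum(x$records$compartment == "parenchyma"),
              sum(x$records$compartment == "stroma")))
  invisible(x)
}
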