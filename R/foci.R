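#' Discohesive cancer foci: detection and per-focus morphometry
#'
#' A discohesive cancer focus is a cancer cell or clump that has detached
#' from the main tumor mass and is completely surrounded by stroma in 3D.
#' Any parenchyma component in contact with the outer surfaces of the image
#' stack (top or bottom image plane, or the lateral circularly-cut core
#' margin) cannot be shown to be detached within the analyzed volume and is
#' excluded from the focus pool; the bulk tumor mass is by construction in
#' that excluded set. Every remaining interior component is necessarily
#' enclosed by stroma within the analyzed volume.
#'
#' @name foci_morphometry
NULL

#' Partition parenchyma components into bulk / foci / boundary-excluded
#'
#' 26-connected components of the in-core parenchyma volume are classified
#' by boundary contact: a component touches the boundary when any of its
#' voxels lies in the first or last slice, on the image border, or
#' 8-adjacent in-plane to an out-of-core pixel. The largest
#' boundary-touching component is reported as the bulk tumor; other
#' boundary-touching components are excluded; all interior components are
#' discohesive focus candidates.
#'
#' @param volume a `voxel_volume` of binary parenchyma after
#'   [apply_core_cylinder()].
#' @return object of class `component_partition`: list with `labels`
#'   (integer 3D array), `bulk_ids`, `focus_ids`, `boundary_excluded_ids`,
#'   `sizes` (voxel counts per component).
#' @export
partition_components <- function(volume) {
  grid <- volume$grid
  d <- dim(grid)
  lab <- label_components(grid, 26)
  n <- attr(lab, "n_components")
  if (n == 0)
    return(structure(list(labels = lab, bulk_ids = integer(0),
                          focus_ids = integer(0),
                          boundary_excluded_ids = integer(0),
                          sizes = integer(0)),
                     class = "component_partition"))
  sizes <- label_sizes(lab)
  # lateral contact band: in-core pixels 8-adjacent to out-of-core space
  # (or on the image border)
  core <- volume$core_mask
  out <- !core
  band <- core & (.dilate2d8(out) | .border2d(d[1], d[2]))
  touching <- unique(c(lab[, , 1], lab[, , d[3]],
                       lab[array(band, d)]))
  touching <- sort(touching[touching > 0])
  interior <- setdiff(seq_len(n), touching)
  bulk <- if (length(touching)) touching[which.max(sizes[touching])] else integer(0)
  structure(list(labels = lab,
                 bulk_ids = bulk,
                 focus_ids = interior,
                 boundary_excluded_ids = setdiff(touching, bulk),
                 sizes = sizes),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  cat(sprintf("component_partition: %d components (%d bulk, %d foci, %d boundary-excluded)\n",
              length(x$sizes), length(x$bulk_ids), length(x$focus_ids),
              length(x$boundary_excluded_ids)))
  invisible(x)
}

# 8-neighbourhood binary dilation of a 2D mask
.dilate2d8 <- function(m) {
  d <- dim(m)
  out <- m
  for (oy in -1:1) for (ox in -1:1) {
    if (oy == 0 && ox == 0) next
    ys <- seq_len(d[1]) + oy; xs <- seq_len(d[2]) + ox
    oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]
    out[oky, okx] <- out[oky, okx] | m[ys[oky], xs[okx]]
  }
  out
}

.border2d <- function(ny, nx) {
  b <- matrix(FALSE, ny, nx)
  b[1, ] <- TRUE; b[ny, ] <- TRUE; b[, 1] <- TRUE; b[, nx] <- TRUE
  b
}

# one-voxel 26-neighbourhood dilation restricted to a subarray
.dilate3d26 <- function(m) {
  d <- dim(m)
  out <- m
  for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
    if (oy == 0 && ox == 0 && oz == 0) next
    ys <- seq_len(d[1]) + oy; xs <- seq_len(d[2]) + ox; zs <- seq_len(d[3]) + oz
    oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    out[oky, okx, okz] <- out[oky, okx, okz] | m[ys[oky], xs[okx], zs[okz]]
  }
  out
}

#' Validate detachment of each focus by one-voxel dilation
#'
#' The dilation half of the dilation/shrinkage continuity test: each focus
#' is dilated by one voxel (26-neighbourhood); the detachment flag is TRUE
#' iff the dilated envelope intersects no other parenchyma component. A
#' FALSE flag marks a focus lying diagonally one voxel from other
#' parenchyma - already 26-disconnected, hence still counted - as QC
#' metadata only, never a reclassification.
#'
#' @param partition a `component_partition`.
#' @return named logical vector over `partition$focus_ids`.
#' @export
validate_detachment <- function(partition) {
  lab <- partition$labels
  d <- dim(lab)
  out <- logical(length(partition$focus_ids))
  names(out) <- partition$focus_ids
  for (i in seq_along(partition$focus_ids)) {
    id <- partition$focus_ids[i]
    idx <- which(lab == id, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - 2L, 1L)
    hi <- pmin(apply(idx, 2, max) + 2L, d)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dil <- .dilate3d26(sub == id)
    out[i] <- !any(dil & sub != id & sub > 0L)
  }
  out
}

#' Equivalent sphere diameter
#'
#' Diameter of the sphere with the same volume: `d = (6 V / pi)^(1/3)`.
#'
#' @param volume_um3 volume(s) in cubic micrometers.
#' @return diameter(s) in micrometers.
#' @export
equivalent_diameter <- function(volume_um3) (6 * volume_um3 / pi)^(1 / 3)

#' Per-focus statistics
#'
#' For every discohesive focus: voxel count, physical volume, equivalent
#' sphere diameter, Ki67-positive and Ki67-negative nucleus counts (a
#' nucleus belongs to the focus whose component contains its centroid
#' voxel), centroid, and the detachment QC flag.
#'
#' @param partition a `component_partition`.
#' @param voxel_dims_um `(dx, dy, dz)` in micrometers.
#' @param ki67_pos,ki67_neg `nucleus_set` objects (or their `records`
#'   data.frames) from [extract_nuclei_3d()]; may be NULL.
#' @param detachment optional result of [validate_detachment()]; computed
#'   when missing.
#' @return data.frame with one row per focus: id, voxel_count, volume_um3,
#'   equivalent_diameter_um, n_ki67_pos, n_ki67_neg, x, y, z,
#'   detachment_confirmed.
#' @export
focus_stats <- function(partition, voxel_dims_um,
                        ki67_pos = NULL, ki67_neg = NULL,
                        detachment = NULL) {
  ids <- partition$focus_ids
  voxvol <- prod(voxel_dims_um)
  if (is.null(detachment)) detachment <- validate_detachment(partition)
  count_in <- function(nuc) {
    if (is.null(nuc)) return(rep(0L, length(ids)))
    rec <- if (inherits(nuc, "nucleus_set")) nuc$records else nuc
    if (nrow(rec) == 0) return(rep(0L, length(ids)))
    d <- dim(partition$labels)
    xi <- pmin(pmax(round(rec$x), 1), d[2])
    yi <- pmin(pmax(round(rec$y), 1), d[1])
    zi <- pmin(pmax(round(rec$z), 1), d[3])
    lb <- partition$labels[cbind(yi, xi, zi)]
    vapply(ids, function(k) sum(lb == k), integer(1))
  }
  vox <- if (length(ids)) partition$sizes[ids] else integer(0)
  cent <- t(vapply(ids, function(k) {
    w <- which(partition$labels == k, arr.ind = TRUE)
    c(mean(w[, 2]), mean(w[, 1]), mean(w[, 3]))
  }, numeric(3)))
  if (length(ids) == 0) cent <- matrix(numeric(0), 0, 3)
  data.frame(id = ids,
             voxel_count = as.integer(vox),
             volume_um3 = vox * voxvol,
             equivalent_diameter_um = equivalent_diameter(vox * voxvol),
             n_ki67_pos = count_in(ki67_pos),
             n_ki67_neg = count_in(ki67_neg),
             x = cent[, 1], y = cent[, 2], z = cent[, 3],
             detachment_confirmed = as.logical(detachment[as.character(ids)]),
             row.names = NULL)
}

#' Size-class labels for the focus size distribution
#' @export
focus_size_bins <- function() {
  c("<16", "16-20", "21-25", "26-30", "31-35", "36-40", "41-45", "46-50",
    "51-200", ">200")
}

#' Bin focus equivalent diameters into the standard size classes
#'
#' Each diameter is rounded to the nearest integer micrometer and binned
#' into contiguous integer classes `<16`, `16-20`, `21-25`, ..., `46-50`,
#' `51-200`, `>200` (rounding first resolves the apparent 1-um gaps between
#' printed class labels).
#'
#' @param diameters_um numeric vector of equivalent diameters.
#' @return named integer vector of counts over [focus_size_bins()]; sums to
#'   `length(diameters_um)`.
#' @export
size_histogram <- function(diameters_um) {
  r <- round(diameters_um)
  breaks <- c(16, 21, 26, 31, 36, 41, 46, 51, 201)
  bin <- findInterval(r, breaks) + 1L
  counts <- tabulate(bin, nbins = 10L)
  names(counts) <- focus_size_bins()
  counts
}
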