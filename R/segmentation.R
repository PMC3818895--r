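#' Stain-channel segmentation of registered sections
#'
#' Converts per-slice concentration maps (from [unmix()]) into binary masks:
#' CK-positive tumor parenchyma from the DAB channel, Ki67-positive nucleus
#' candidates from the SG channel, Ki67-negative nucleus candidates as open
#' spaces circumscribed by CK-positive cytoplasm, and stroma by subtraction
#' from the tissue footprint.
#'
#' Thresholds default to a single Otsu threshold computed on the pooled
#' in-core histogram of the whole stack, applied to every slice: one global
#' threshold prevents slice-to-slice segmentation flicker that would corrupt
#' 3D continuity. Per-slice thresholding is available via `policy`.
#'
#' @name segmentation
NULL

#' Otsu threshold of a value sample
#'
#' Maximizes between-class variance on a fixed-bin histogram of the pooled
#' values.
#'
#' @param values numeric vector (pooled map values).
#' @param n_bins histogram resolution (default 256).
#' @return threshold on the value scale; values strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no values to threshold")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(pmax(floor((values - lo) / (hi - lo) * n_bins) + 1, 1),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  lo + k / n_bins * (hi - lo)
}

# resolve a threshold per the policy for a list of per-slice maps
.resolve_threshold <- function(maps, tissue, policy, n_bins = 256) {
  if (is.numeric(policy)) return(rep(policy, length(maps)))
  policy <- match.arg(policy, c("pooled_otsu", "per_slice_otsu"))
  if (policy == "pooled_otsu") {
    pooled <- unlist(lapply(maps, function(m) m[tissue]))
    rep(otsu_threshold(pooled, n_bins), length(maps))
  } else {
    vapply(maps, function(m) otsu_threshold(m[tissue], n_bins), numeric(1))
  }
}

# drop 8-connected in-plane objects smaller than min_px
.remove_small_2d <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask, 8)
  sz <- label_sizes(lab)
  keep <- which(sz >= min_px)
  array(lab %in% keep, dim(mask))
}

#' Default minimum in-plane object size
#'
#' Area in pixels of a 2 um-radius disk at the given pixel size; anything
#' smaller than a sub-nuclear speck is treated as noise.
#'
#' @param pixel_size_um pixel edge in micrometers.
#' @return integer pixel count.
#' @export
default_min_object_px <- function(pixel_size_um) {
  max(1L, as.integer(round(pi * (2 / pixel_size_um)^2)))
}

#' Segment CK-positive tumor parenchyma from the DAB channel
#'
#' Thresholds the DAB concentration maps (pooled-Otsu by default) and
#' removes in-plane objects smaller than `min_object_px`. In-plane holes are
#' deliberately NOT filled: they are the Ki67-negative nucleus candidates.
#'
#' @param dab_maps list of per-slice DAB concentration matrices.
#' @param tissue logical in-plane tissue (core disk) mask.
#' @param policy `"pooled_otsu"` (default), `"per_slice_otsu"`, or a fixed
#'   numeric threshold.
#' @param min_object_px minimum in-plane object area in pixels.
#' @return list of logical masks, one per slice, restricted to `tissue`;
#'   attribute `threshold` records the threshold(s) used.
#' @export
segment_parenchyma <- function(dab_maps, tissue,
                               policy = "pooled_otsu",
                               min_object_px = 1L) {
  if (!any(tissue)) {
    warning("empty tissue region; returning empty masks")
    return(lapply(dab_maps, function(m) array(FALSE, dim(m))))
  }
  thr <- .resolve_threshold(dab_maps, tissue, policy)
  masks <- lapply(seq_along(dab_maps), function(i)
    .remove_small_2d((dab_maps[[i]] > thr[i]) & tissue, min_object_px))
  attr(masks, "threshold") <- thr
  masks
}

#' Segment Ki67-positive nucleus candidates from the SG channel
#'
#' Same policy as [segment_parenchyma()], on the SG concentration channel;
#' no hole logic.
#'
#' @inheritParams segment_parenchyma
#' @param sg_maps list of per-slice SG concentration matrices.
#' @return list of logical masks with attribute `threshold`.
#' @export
segment_ki67 <- function(sg_maps, tissue,
                         policy = "pooled_otsu",
                         min_object_px = 1L) {
  segment_parenchyma(sg_maps, tissue, policy, min_object_px)
}

#' Detect Ki67-negative nucleus candidates as holes in the parenchyma
#'
#' Ki67-negative nuclei leave unstained open spaces fully circumscribed by
#' CK-positive cytoplasm. In-plane holes are background components
#' (4-connectivity) not connected to the slice border through background,
#' kept when their area lies within `area_bounds_um2`.
#'
#' @param parenchyma_mask logical in-plane parenchyma mask.
#' @param pixel_size_um pixel edge in micrometers.
#' @param area_bounds_um2 inclusive area bounds in square micrometers
#'   (default 10-150, covering nuclei at ~1 um/px).
#' @return logical mask of candidate pixels.
#' @export
detect_negative_nuclei <- function(parenchyma_mask, pixel_size_um,
                                   area_bounds_um2 = c(10, 150)) {
  bg <- !parenchyma_mask
  lab <- label_components(bg, 4)
  d <- dim(lab)
  border_labels <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  border_labels <- border_labels[border_labels > 0]
  sz <- label_sizes(lab)
  px_area <- pixel_size_um^2
  ok <- which(sz * px_area >= area_bounds_um2[1] &
              sz * px_area <= area_bounds_um2[2])
  ok <- setdiff(ok, border_labels)
  array(lab %in% ok, d)
}

#' Stroma mask by subtraction
#'
#' The stroma is everything in the tissue footprint that is not tumor
#' parenchyma; voxelwise `tissue AND NOT parenchyma`.
#'
#' @param tissue logical tissue mask (2D or 3D).
#' @param parenchyma logical parenchyma mask, must be contained in `tissue`.
#' @return logical mask of the same shape.
#' @export
stroma_mask <- function(tissue, parenchyma) {
  if (!all(dim(tissue) == dim(parenchyma)))
    stop("tissue and parenchyma must share dimensions")
  if (any(parenchyma & !tissue))
    stop("parenchyma must be contained in tissue")
  tissue & !parenchyma
}
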