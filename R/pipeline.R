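#' Full reconstruction and morphometry pipeline for one section stack
#'
#' Runs the complete chain on a [section_stack()]: rigid registration (from
#' the middle reference slice), Beer-Lambert optical-density conversion and
#' colour deconvolution, pooled-Otsu segmentation of CK+ parenchyma and
#' Ki67+ nuclei, hole-based Ki67- candidate detection, anisotropic volume
#' assembly restricted to the core cylinder, the two-consecutive-slice
#' nucleus filter, discohesive-focus partition with boundary exclusion and
#' detachment QC, and the case-level morphometry record.
#'
#' @param stack a [section_stack()].
#' @param core_diameter_um analyzed core-cylinder diameter; default 90% of
#'   the in-plane extent.
#' @param case_id,invasion_mode,depth_mm case metadata passed through to
#'   the morphometry record (the invasion mode is user-supplied, never
#'   inferred).
#' @param stain a [stain_model()].
#' @param register run rigid stack registration first (default TRUE; set
#'   FALSE for already-aligned stacks).
#' @param reg_opts options for [estimate_rigid()].
#' @param threshold_policy `"pooled_otsu"` (default), `"per_slice_otsu"`,
#'   or a fixed numeric threshold, applied to both chromogen channels.
#' @param min_object_px minimum in-plane object area in pixels; default
#'   [default_min_object_px()] at the stack's pixel size.
#' @param area_bounds_um2 Ki67- candidate hole area bounds.
#' @return object of class `tumor3d`: list with `record` (one-row
#'   morphometry data.frame), `foci` (per-focus table), `size_histogram`,
#'   `partition`, `nuclei_pos`, `nuclei_neg`, `parenchyma` (voxel_volume),
#'   `transforms` (composed registration transforms or NULL), `thresholds`.
#' @export
analyze_stack <- function(stack,
                          core_diameter_um = NULL,
                          case_id = "case",
                          invasion_mode = NA_character_,
                          depth_mm = NA_real_,
                          stain = stain_model(),
                          register = TRUE,
                          reg_opts = list(),
                          threshold_policy = "pooled_otsu",
                          min_object_px = NULL,
                          area_bounds_um2 = c(10, 150)) {
  dx <- stack$pixel_size_um
  dz <- stack$slice_thickness_um
  d <- dim(stack$images[[1]])
  if (is.null(core_diameter_um))
    core_diameter_um <- 0.9 * min(d[1], d[2]) * dx
  if (is.null(min_object_px)) min_object_px <- default_min_object_px(dx)

  transforms <- NULL
  imgs <- stack$images
  if (register && length(imgs) >= 2) {
    reg <- register_stack(stack, fill = 1, opts = reg_opts)
    imgs <- reg$stack$images
    transforms <- reg$transforms
  }

  tissue <- core_disk(d[1], d[2], core_diameter_um / dx)
  dab_maps <- vector("list", length(imgs))
  sg_maps <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    conc <- unmix(rgb_to_od(imgs[[i]], stain$I0), stain)
    dab_maps[[i]] <- conc$dab
    sg_maps[[i]] <- conc$sg
  }

  par_masks <- segment_parenchyma(dab_maps, tissue, threshold_policy,
                                  min_object_px)
  ki_masks <- segment_ki67(sg_maps, tissue, threshold_policy, min_object_px)
  neg_masks <- lapply(par_masks, detect_negative_nuclei, pixel_size_um = dx,
                      area_bounds_um2 = area_bounds_um2)

  vd <- c(dx, dx, dz)
  par_vol <- apply_core_cylinder(stack_to_volume(par_masks, vd),
                                 core_diameter_um)
  ki_vol <- apply_core_cylinder(stack_to_volume(ki_masks, vd),
                                core_diameter_um)
  neg_vol <- apply_core_cylinder(stack_to_volume(neg_masks, vd),
                                 core_diameter_um)

  nuclei_pos <- extract_nuclei_3d(ki_vol$grid, par_vol$grid, "auto")
  nuclei_neg <- extract_nuclei_3d(neg_vol$grid, par_vol$grid, "parenchyma")

  partition <- partition_components(par_vol)
  detachment <- validate_detachment(partition)
  foci <- focus_stats(partition, vd, nuclei_pos, nuclei_neg, detachment)
  record <- case_morphometry(par_vol, partition, foci, nuclei_pos,
                             case_id = case_id,
                             invasion_mode = invasion_mode,
                             depth_mm = depth_mm)
  structure(list(record = record,
                 foci = foci,
                 size_histogram = size_histogram(foci$equivalent_diameter_um),
                 partition = partition,
                 nuclei_pos = nuclei_pos,
                 nuclei_neg = nuclei_neg,
                 parenchyma = par_vol,
                 transforms = transforms,
                 thresholds = list(dab = attr(par_masks, "threshold"),
                                   sg = attr(ki_masks, "threshold"))),
            class = "tumor3d")
}

#' @export
print.tumor3d <- function(x, ...) {
  r <- x$record
  cat(sprintf("tumor3d case '%s' (%s):\n", r$case_id, r$invasion_mode))
  cat(sprintf("  tissue %.3g mm3, parenchyma %.3g mm3 (%.1f%%)\n",
              r$v_total_mm3, r$v_parenchyma_mm3, r$parenchyma_pct))
  cat(sprintf("  border S = %.3g mm2, S/Vp = %.1f 1/mm\n",
              r$border_area_mm2, r$s_over_vp_mm_inv))
  cat(sprintf("  Ki67+ in parenchyma: %d (%.1f x10^4/mm3)\n",
              r$n_ki67_parenchyma, r$ki67_density_1e4_per_mm3))
  cat(sprintf("  discohesive foci: %d (%.3g%% of Vp)\n",
              r$n_foci, r$foci_volume_pct))
  invisible(x)
}

#' @export
summary.tumor3d <- function(object, ...) {
  print(object)
  cat("\nFocus size distribution:\n")
  print(object$size_histogram)
  if (nrow(object$foci)) {
    cat("\nPer-focus table (first rows):\n")
    print(utils::head(object$foci, 10))
  }
  invisible(object)
}

#' Plot one slice of a reconstruction
#'
#' Shows the parenchyma mask of a slice with discohesive-focus voxels
#' highlighted.
#'
#' @param x a `tumor3d` object.
#' @param slice slice index (default middle).
#' @param ... ignored.
#' @export
plot.tumor3d <- function(x, slice = NULL, ...) {
  d <- dim(x$parenchyma$grid)
  if (is.null(slice)) slice <- (d[3] + 1) %/% 2
  lab <- x$partition$labels[, , slice]
  img <- matrix(0, d[1], d[2])
  img[lab > 0] <- 1
  img[array(lab %in% x$partition$focus_ids, dim(lab))] <- 2
  graphics::image(t(img[rev(seq_len(d[1])), ]),
                  col = c("white", "grey40", "red"), axes = FALSE,
                  main = sprintf("%s, slice %d (red = discohesive foci)",
                                 x$record$case_id, slice))
  invisible(x)
}
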