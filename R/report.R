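#' Case-level morphometry and report tables
#'
#' Case statistics mirror the standard 3D morphometry panel: total tissue
#' volume, tumor parenchyma volume `Vp` (and percent), parenchymal-stromal
#' border area `S`, the shape-complexity index `S/Vp`, Ki67-positive nucleus
#' counts and density, and discohesive focus counts and volume fraction.
#'
#' @name morphometry_report
NULL

#' Parenchymal-stromal border area by voxel-face counting
#'
#' The border is delineated as a plane one voxel in width: every voxel face
#' separating a parenchyma voxel from a stroma voxel is counted with its
#' physical face area (x-normal faces `dy*dz`, y-normal `dx*dz`, z-normal
#' `dx*dy`). Faces against out-of-core or out-of-stack space are NOT part
#' of the parenchyma-stroma border and are not counted. Face counting
#' overestimates a smooth surface by a known factor of about 1.5; this
#' cancels in relative comparisons between cases processed identically.
#'
#' @param parenchyma,stroma congruent, disjoint logical 3D arrays.
#' @param voxel_dims_um `(dx, dy, dz)` in micrometers.
#' @return border area in square millimeters.
#' @export
border_area <- function(parenchyma, stroma, voxel_dims_um) {
  if (!all(dim(parenchyma) == dim(stroma)))
    stop("volumes must be congruent")
  if (any(parenchyma & stroma))
    stop("parenchyma and stroma must be disjoint")
  d <- dim(parenchyma)
  dx <- voxel_dims_um[1]; dy <- voxel_dims_um[2]; dz <- voxel_dims_um[3]
  pairs_along <- function(a, b, axis) {
    n <- d[axis]
    if (n < 2) return(0L)
    i1 <- seq_len(n - 1); i2 <- i1 + 1L
    if (axis == 1) {
      sum(a[i1, , , drop = FALSE] & b[i2, , , drop = FALSE]) +
        sum(b[i1, , , drop = FALSE] & a[i2, , , drop = FALSE])
    } else if (axis == 2) {
      sum(a[, i1, , drop = FALSE] & b[, i2, , drop = FALSE]) +
        sum(b[, i1, , drop = FALSE] & a[, i2, , drop = FALSE])
    } else {
      sum(a[, , i1, drop = FALSE] & b[, , i2, drop = FALSE]) +
        sum(b[, , i1, drop = FALSE] & a[, , i2, drop = FALSE])
    }
  }
  n_y <- pairs_along(parenchyma, stroma, 1)   # y-normal faces
  n_x <- pairs_along(parenchyma, stroma, 2)   # x-normal faces
  n_z <- pairs_along(parenchyma, stroma, 3)   # z-normal faces
  (n_x * dy * dz + n_y * dx * dz + n_z * dx * dy) / 1e6
}

#' Depth-of-invasion class
#'
#' Shallow: depth < 3 mm; intermediate: 3 <= depth <= 5 mm; deep:
#' depth > 5 mm; `NA` depth maps to class `"NA"`.
#'
#' @param depth_mm numeric depth(s) in millimeters (NA allowed).
#' @return character vector in `{"shallow","intermediate","deep","NA"}`.
#' @export
depth_class <- function(depth_mm) {
  if (any(!is.na(depth_mm) & depth_mm < 0)) stop("depth must be non-negative")
  ifelse(is.na(depth_mm), "NA",
         ifelse(depth_mm < 3, "shallow",
                ifelse(depth_mm <= 5, "intermediate", "deep")))
}

#' Case-level morphometry record
#'
#' Assembles the full per-case panel from the upstream pipeline outputs.
#' When `Vp = 0`, ratio quantities (`parenchyma_pct` aside) are reported as
#' `NA` (undefined), never as zero.
#'
#' @param parenchyma_volume `voxel_volume` of in-core binary parenchyma
#'   (after [apply_core_cylinder()]).
#' @param partition a `component_partition` of that volume.
#' @param foci data.frame from [focus_stats()].
#' @param ki67_pos `nucleus_set` of Ki67-positive nuclei (or NULL).
#' @param case_id case label.
#' @param invasion_mode one of `"PB"`, `"TSC"`, `"DS"`, `"SF"` (pass-through
#'   metadata; the mode is not inferred).
#' @param depth_mm depth of invasion in mm, or NA.
#' @return one-row data.frame (a MorphometryRecord): case_id, invasion_mode,
#'   depth_mm, depth_class, v_total_mm3, v_parenchyma_mm3, v_stroma_mm3,
#'   parenchyma_pct, border_area_mm2, s_over_vp_mm_inv, n_ki67_parenchyma,
#'   ki67_density_1e4_per_mm3, n_foci, foci_volume_pct.
#' @export
case_morphometry <- function(parenchyma_volume, partition, foci,
                             ki67_pos = NULL, case_id = "case",
                             invasion_mode = NA_character_,
                             depth_mm = NA_real_) {
  v <- parenchyma_volume$voxel_dims_um
  voxvol <- prod(v)
  d <- dim(parenchyma_volume$grid)
  core3d <- array(parenchyma_volume$core_mask, d)
  v_total <- sum(parenchyma_volume$core_mask) * voxvol * d[3] / 1e9
  n_par <- sum(parenchyma_volume$grid)
  v_p <- n_par * voxvol / 1e9
  stroma <- core3d & !parenchyma_volume$grid
  v_s <- sum(stroma) * voxvol / 1e9
  S <- border_area(parenchyma_volume$grid, stroma, v)
  n_pos <- if (is.null(ki67_pos)) NA_integer_ else {
    rec <- if (inherits(ki67_pos, "nucleus_set")) ki67_pos$records else ki67_pos
    sum(rec$compartment == "parenchyma")
  }
  foci_vol <- if (nrow(foci)) sum(foci$volume_um3) / 1e9 else 0
  data.frame(case_id = case_id,
             invasion_mode = invasion_mode,
             depth_mm = depth_mm,
             depth_class = depth_class(depth_mm),
             v_total_mm3 = v_total,
             v_parenchyma_mm3 = v_p,
             v_stroma_mm3 = v_s,
             parenchyma_pct = if (v_total > 0) 100 * v_p / v_total else NA_real_,
             border_area_mm2 = S,
             s_over_vp_mm_inv = if (v_p > 0) S / v_p else NA_real_,
             n_ki67_parenchyma = n_pos,
             ki67_density_1e4_per_mm3 = if (v_p > 0 && !is.na(n_pos))
               n_pos / v_p / 1e4 else NA_real_,
             n_foci = nrow(foci),
             foci_volume_pct = if (v_p > 0) 100 * foci_vol / v_p else NA_real_,
             stringsAsFactors = FALSE)
}

#' Group summaries (mean and sample SD)
#'
#' @param records data.frame of morphometry records.
#' @param value column name to summarize (default `"s_over_vp_mm_inv"`).
#' @param group grouping column (default `"invasion_mode"`).
#' @return data.frame with group, n, mean, sd (sample SD, n-1 denominator;
#'   NA for n < 2).
#' @export
group_summary <- function(records, value = "s_over_vp_mm_inv",
                          group = "invasion_mode") {
  g <- records[[group]]
  v <- records[[value]]
  out <- do.call(rbind, lapply(split(v, g), function(x) {
    x <- x[!is.na(x)]
    data.frame(n = length(x), mean = mean(x),
               sd = if (length(x) >= 2) stats::sd(x) else NA_real_)
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

#' Write report tables
#'
#' Writes `cases.csv` (case metadata pass-through), `morphometry.csv` (one
#' row per case at printed precision: volumes 2 decimals, border area and
#' ratios 1 decimal), per-case `foci_<case>.csv` tables, a
#' `size_histogram.csv` (size classes x cases plus a Total row and column),
#' and a `manifest.txt` run manifest.
#'
#' @param records data.frame of [case_morphometry()] rows.
#' @param foci_tables named list of [focus_stats()] data.frames per case.
#' @param out_dir output directory (created if missing).
#' @param config optional named list echoed into the manifest.
#' @return invisibly, the output directory.
#' @export
write_reports <- function(records, foci_tables = list(), out_dir,
                          config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta_cols <- intersect(c("case_id", "invasion_mode", "depth_mm",
                           "depth_class"), names(records))
  utils::write.csv(records[, meta_cols, drop = FALSE],
                   file.path(out_dir, "cases.csv"), row.names = FALSE)
  fmt <- records
  for (col in intersect(c("v_total_mm3", "v_parenchyma_mm3", "v_stroma_mm3"),
                        names(fmt)))
    fmt[[col]] <- round(fmt[[col]], 2)
  for (col in intersect(c("parenchyma_pct", "border_area_mm2",
                          "s_over_vp_mm_inv", "ki67_density_1e4_per_mm3",
                          "foci_volume_pct"), names(fmt)))
    fmt[[col]] <- round(fmt[[col]], 1)
  utils::write.csv(fmt, file.path(out_dir, "morphometry.csv"),
                   row.names = FALSE)
  for (nm in names(foci_tables))
    utils::write.csv(foci_tables[[nm]],
                     file.path(out_dir, sprintf("foci_%s.csv", nm)),
                     row.names = FALSE)
  if (length(foci_tables)) {
    hist_mat <- vapply(foci_tables, function(tb)
      size_histogram(tb$equivalent_diameter_um), integer(10))
    if (is.null(dim(hist_mat))) hist_mat <- matrix(hist_mat, ncol = 1)
    hist_df <- data.frame(size_um = focus_size_bins(), hist_mat,
                          Total = rowSums(hist_mat), check.names = FALSE)
    hist_df <- rbind(hist_df,
                     c(size_um = "Total",
                       as.list(colSums(hist_df[, -1, drop = FALSE]))))
    utils::write.csv(hist_df, file.path(out_dir, "size_histogram.csv"),
                     row.names = FALSE)
  }
  manifest <- c(sprintf("tumor3d version\t%s",
                        as.character(utils::packageVersion("tumor3d"))),
                sprintf("R version\t%s", R.version.string),
                sprintf("written\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                vapply(names(config), function(k)
                  sprintf("%s\t%s", k, paste(format(config[[k]]),
                                             collapse = " ")),
                  character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
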