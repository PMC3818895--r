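#' Reference 14-case invasion-front morphometry series
#'
#' Published 3D morphometry measurements of tissue cores from the deep
#' invasion front of 14 early-stage oral tongue squamous cell carcinomas
#' (cases A-N), bundled for consistency checking of derived quantities.
#' Columns: case metadata (invasion mode, depth of invasion, occult
#' metastasis status), total reconstructed tissue volume, segmented tumor
#' parenchyma volume `Vp` with its printed percent of total,
#' parenchymal-stromal border area `S`, the printed `S/Vp` ratio, the count
#' of Ki67-positive nuclei in cancer cells with the printed density
#' (x10^4/mm^3), and the discohesive-focus count with its printed percent
#' of `Vp`.
#'
#' Values are reproduced at their printed precision; derived columns
#' (percentages, ratios, densities) can be recomputed from the others with
#' [check_reference_consistency()], which flags case C as internally
#' inconsistent.
#'
#' @return data.frame with one row per case.
#' @export
reference_cases <- function() {
  data.frame(
    case_id = LETTERS[1:14],
    invasion_mode = c("DS", "PB", "PB", "PB", "TSC", "PB", "TSC", "PB",
                      "TSC", "TSC", "SF", "DS", "DS", "SF"),
    depth_mm = c(1.9, 2.4, 2.5, 2.6, 2.8, 2.9, 3.3, 3.5, 3.6, 4.6,
                 7.0, 7.6, 10.6, NA),
    occult_metastasis = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                          TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    v_total_mm3 = c(2.88, 2.86, 2.95, 2.91, 2.74, 2.58, 2.94, 2.19, 2.91,
                    2.59, 2.39, 2.73, 2.74, 2.91),
    v_parenchyma_mm3 = c(0.19, 0.96, 0.56, 0.37, 0.47, 0.43, 0.20, 0.92,
                         0.49, 0.11, 0.031, 0.11, 0.19, 0.032),
    parenchyma_pct = c(6.6, 33.6, 21.4, 12.7, 17.2, 16.7, 6.8, 42.0, 16.8,
                       4.2, 1.3, 4.0, 6.9, 1.1),
    border_area_mm2 = c(17.2, 48.3, 61.4, 30.9, 18.3, 31.3, 27.2, 81.8,
                        24.4, 11.2, 3.8, 18.4, 28.8, 27.2),
    s_over_vp_mm_inv = c(90.5, 50.3, 97.5, 83.5, 38.9, 72.8, 136.0, 88.9,
                         49.8, 101.8, 122.6, 167.3, 151.6, 850.0),
    n_ki67_parenchyma = c(20805, 221803, 61896, 47913, 23702, 108234,
                          29009, 88303, 80410, 18435, 4193, 35156, 45217,
                          9751),
    ki67_density_1e4_per_mm3 = c(10.9, 23.1, 9.8, 12.9, 5.0, 25.1, 14.5,
                                 9.6, 16.4, 16.8, 13.5, 32.0, 23.8, 30.5),
    n_foci = c(65L, 2L, 30L, 53L, 19L, 116L, 76L, 19L, 7L, 36L, 117L,
               232L, 159L, 35L),
    foci_volume_pct = c(2.83, 0.0010, 0.060, 0.0089, 0.44, 0.26, 0.59,
                        0.024, 0.088, 0.33, 27.1, 3.76, 8.34, 1.69),
    stringsAsFactors = FALSE)
}

#' Reference discohesive-focus size distribution
#'
#' Counts of discohesive cancer foci per equivalent-sphere-diameter size
#' class and case for the reference 14-case series (966 foci in total).
#'
#' @return data.frame: `size_um` class labels (as in [focus_size_bins()])
#'   by case columns A-N.
#' @export
reference_focus_sizes <- function() {
  m <- rbind(
    c(4, 0, 0, 12, 1, 13, 4, 2, 0, 2, 1, 17, 18, 1),
    c(32, 1, 0, 29, 12, 73, 33, 5, 0, 13, 15, 80, 63, 23),
    c(18, 1, 13, 8, 3, 21, 14, 7, 0, 10, 21, 54, 32, 5),
    c(5, 0, 12, 2, 1, 4, 10, 3, 1, 7, 23, 33, 19, 2),
    c(3, 0, 4, 1, 0, 1, 5, 1, 2, 2, 12, 22, 8, 1),
    c(0, 0, 1, 0, 1, 2, 2, 0, 0, 1, 11, 9, 3, 0),
    c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0, 10, 6, 7, 1),
    c(1, 0, 0, 1, 1, 1, 7, 0, 3, 1, 21, 11, 8, 2),
    c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 0, 1, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  df <- data.frame(size_um = focus_size_bins(), m, stringsAsFactors = FALSE)
  names(df)[-1] <- LETTERS[1:14]
  df
}

#' Largest analyzed reference focus: nucleus composition
#'
#' The single largest discohesive focus analyzed in the reference series:
#' Ki67-positive and Ki67-negative nucleus counts.
#'
#' @return list with `n_ki67_pos`, `n_ki67_neg`.
#' @export
reference_largest_focus <- function() {
  list(n_ki67_pos = 277L, n_ki67_neg = 1015L)
}

#' Internal-consistency check of the reference morphometry table
#'
#' Recomputes every derivable column of [reference_cases()] from the
#' measured columns at printed precision: `parenchyma_pct` from `Vp` and
#' `V_total`, `s_over_vp_mm_inv` from `S` and `Vp`, and the Ki67 density
#' from the count and `Vp`. A row passes when each recomputed value agrees
#' with the printed one to within the final printed digit (|diff| <= 0.1
#' for one-decimal columns). Case C fails: its printed `Vp` (0.56) is
#' irreconcilable with its printed percent, `S/Vp` and density, which all
#' imply `Vp` near 0.63.
#'
#' @param tol agreement tolerance on one-decimal columns (default 0.1, the
#'   final printed digit).
#' @return data.frame per case: recomputed values, per-column agreement
#'   flags, and overall `consistent`.
#' @export
check_reference_consistency <- function(tol = 0.1) {
  rc <- reference_cases()
  pct_re <- round(100 * rc$v_parenchyma_mm3 / rc$v_total_mm3, 1)
  sv_re <- round(rc$border_area_mm2 / rc$v_parenchyma_mm3, 1)
  dens_re <- round(rc$n_ki67_parenchyma / rc$v_parenchyma_mm3 / 1e4, 1)
  eps <- 1e-9
  ok_pct <- abs(pct_re - rc$parenchyma_pct) <= tol + eps
  ok_sv <- abs(sv_re - rc$s_over_vp_mm_inv) <= tol + eps
  ok_dens <- abs(dens_re - rc$ki67_density_1e4_per_mm3) <= tol + eps
  data.frame(case_id = rc$case_id,
             parenchyma_pct_recomputed = pct_re,
             s_over_vp_recomputed = sv_re,
             ki67_density_recomputed = dens_re,
             ok_parenchyma_pct = ok_pct,
             ok_s_over_vp = ok_sv,
             ok_ki67_density = ok_dens,
             consistent = ok_pct & ok_sv & ok_dens,
             stringsAsFactors = FALSE)
}
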