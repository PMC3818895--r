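#' Two-chromogen brightfield stain model
#'
#' Beer-Lambert model of a double-immunostained section: transmitted
#' intensity per RGB channel is `I = I0 * 10^-(c' V)` where `c` holds the
#' per-pixel stain concentrations and the rows of `V` are unit optical
#' density vectors. Row 1 is DAB (brown; marks CK-positive carcinoma
#' cytoplasm), row 2 is Vector SG (blue-gray; marks Ki67-positive nuclei),
#' row 3 a residual channel completing the basis.
#'
#' The DAB vector is the published Ruifrok-Johnston vector. SG has no
#' canonical published vector; the default is the normalized blue-gray
#' direction (0.60, 0.55, 0.58), with the residual taken orthogonal to both.
#' Only rendering/unmixing self-consistency depends on the exact SG choice.
#'
#' @param I0 per-channel incident (blank slide) intensity on \[0, 1\].
#' @param od_dab,od_sg optical-density direction vectors (normalized
#'   internally).
#' @param amplitude list of typical stain concentrations per structure:
#'   `dab` for CK+ cytoplasm, `sg` for Ki67+ nuclei.
#' @return object of class `stain_model` with the 3x3 unit-row matrix `M`.
#' @export
stain_model <- function(I0 = c(1, 1, 1),
                        od_dab = c(0.26814753, 0.57031375, 0.77642715),
                        od_sg = c(0.60, 0.55, 0.58),
                        amplitude = list(dab = 1.0, sg = 1.0)) {
  stopifnot(all(I0 > 0), length(od_dab) == 3, length(od_sg) == 3)
  nrm <- function(v) v / sqrt(sum(v^2))
  v1 <- nrm(od_dab)
  v2 <- nrm(od_sg)
  v3 <- nrm(c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1]))
  M <- rbind(dab = v1, sg = v2, residual = v3)
  if (abs(det(M)) < 1e-8) stop("stain vectors are collinear; matrix singular")
  structure(list(I0 = I0, M = M, amplitude = amplitude),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("stain_model (rows = unit OD vectors):\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Convert an RGB image to optical density
#'
#' Beer-Lambert inversion `OD_c = -log10(max(I_c, eps) / I0_c)`, clamped at
#' zero (a pixel brighter than the blank slide carries no stain).
#'
#' @param image RGB array on \[0, 1\].
#' @param I0 per-channel incident intensity (all > 0).
#' @param eps floor applied to intensities before the log (default 1/255,
#'   one 8-bit quantization step).
#' @return array of the same shape holding per-channel OD.
#' @export
rgb_to_od <- function(image, I0 = c(1, 1, 1), eps = 1 / 255) {
  stopifnot(all(I0 > 0))
  od <- array(0, dim(image))
  for (k in 1:3)
    od[, , k] <- pmax(-log10(pmax(image[, , k], eps) / I0[k]), 0)
  od
}

#' Unmix an OD image into per-stain concentration maps
#'
#' Ruifrok-Johnston colour deconvolution: per pixel, solve `od = c' M` for
#' the concentration vector `c`, where the rows of `M` are the unit stain OD
#' vectors. Negative concentrations are clamped to zero unless
#' `clamp = FALSE`.
#'
#' @param od OD array (`ny x nx x 3`), e.g. from [rgb_to_od()].
#' @param stain a [stain_model()] (or a bare 3x3 unit-row matrix).
#' @param clamp clamp negative concentrations at 0 (default TRUE).
#' @return list of three `ny x nx` maps: `dab`, `sg`, `residual`.
#' @export
unmix <- function(od, stain, clamp = TRUE) {
  M <- if (inherits(stain, "stain_model")) stain$M else stain
  if (abs(det(M)) < 1e-12) stop("stain matrix is singular")
  d <- dim(od)
  odm <- matrix(od, ncol = 3)
  conc <- odm %*% solve(M)
  if (clamp) conc[conc < 0] <- 0
  list(dab = matrix(conc[, 1], d[1], d[2]),
       sg = matrix(conc[, 2], d[1], d[2]),
       residual = matrix(conc[, 3], d[1], d[2]))
}

# transmitted RGB for concentration maps c_dab, c_sg (matrices)
compose_rgb <- function(c_dab, c_sg, stain) {
  d <- dim(c_dab)
  out <- array(0, c(d[1], d[2], 3))
  for (k in 1:3) {
    od_k <- c_dab * stain$M[1, k] + c_sg * stain$M[2, k]
    out[, , k] <- stain$I0[k] * 10^(-od_k)
  }
  out
}
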