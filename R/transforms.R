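#' Rigid 2D transforms
#'
#' A rigid transform maps a point `p = (x, y)` (1-based pixel-center
#' coordinates, x along columns, y along rows) to
#' `R(theta) (p - center) + center + (tx, ty)`, i.e. rotation about `center`
#' followed by translation. No scaling or shear: the linear part always has
#' determinant 1.
#'
#' @param tx,ty translation in pixels.
#' @param theta rotation in degrees (counter-clockwise in x-right/y-down
#'   pixel coordinates).
#' @param center length-2 rotation center `(cx, cy)` in pixel coordinates.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, theta = 0, center = c(0, 0)) {
  stopifnot(length(center) == 2, is.finite(tx), is.finite(ty), is.finite(theta))
  structure(list(tx = tx, ty = ty, theta = theta,
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: t = (%.3f, %.3f) px, theta = %.4f deg, center = (%.1f, %.1f)\n",
              x$tx, x$ty, x$theta, x$center[1], x$center[2]))
  invisible(x)
}

# 2x2 rotation matrix for theta degrees
.rot2 <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# full affine form: p' = A p + b
transform_matrix <- function(T) {
  A <- .rot2(T$theta)
  b <- T$center + c(T$tx, T$ty) - A %*% T$center
  list(A = A, b = as.numeric(b))
}

# back to parameter form for a given rotation center
transform_from_matrix <- function(A, b, center = c(0, 0)) {
  theta <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  t <- as.numeric(b) - center + as.numeric(A %*% center)
  rigid_transform(tx = t[1], ty = t[2], theta = theta, center = center)
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `B` first, then `A` (`A %then% B` in
#' function-composition order, `compose_transforms(A, B) = A o B`).
#'
#' @param A,B `rigid_transform` objects.
#' @param center rotation center for the parameterization of the result.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(A, B, center = A$center) {
  Ma <- transform_matrix(A); Mb <- transform_matrix(B)
  R <- Ma$A %*% Mb$A
  b <- as.numeric(Ma$A %*% Mb$b) + Ma$b
  transform_from_matrix(R, b, center)
}

#' Invert a rigid transform
#'
#' @param T a `rigid_transform`.
#' @return The inverse `rigid_transform` (same rotation center).
#' @export
invert_transform <- function(T) {
  M <- transform_matrix(T)
  Ri <- t(M$A)                      # inverse of a rotation
  bi <- -as.numeric(Ri %*% M$b)
  transform_from_matrix(Ri, bi, T$center)
}

#' Displacement between two rigid transforms
#'
#' Measures how far `A` is from `B` as the residual transform `A o B^-1`:
#' its rotation angle and the displacement it induces at a reference point
#' (typically the image center).
#'
#' @param A,B `rigid_transform` objects.
#' @param at point at which the displacement is evaluated.
#' @return list with `dtheta` (degrees) and `dpx` (Euclidean pixels at `at`).
#' @export
transform_delta <- function(A, B, at = A$center) {
  D <- compose_transforms(A, invert_transform(B), center = at)
  M <- transform_matrix(D)
  p <- as.numeric(M$A %*% at) + M$b
  list(dtheta = abs(D$theta), dpx = sqrt(sum((p - at)^2)))
}

#' Apply a rigid transform to an image
#'
#' Resamples `image` so that the output, in the fixed frame, shows the input
#' mapped through `T`: `out(q) = image(T^-1 q)`. Intensity images use
#' bilinear interpolation; masks should use nearest-neighbour so they stay
#' binary. Out-of-frame samples are filled with `fill`.
#'
#' @param image 2D matrix or 3-channel array (rows = y, cols = x).
#' @param T a `rigid_transform` mapping input coordinates onto output
#'   coordinates.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param fill value for samples falling outside the input frame.
#' @return Array of the same shape as `image`.
#' @export
apply_transform <- function(image, T, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  d <- dim(image)
  ny <- d[1]; nx <- d[2]
  Ti <- invert_transform(T)
  M <- transform_matrix(Ti)
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  xs <- M$A[1, 1] * X + M$A[1, 2] * Y + M$b[1]
  ys <- M$A[2, 1] * X + M$A[2, 2] * Y + M$b[2]

  sample_plane <- function(img) {
    if (interp == "nearest") {
      xi <- round(xs); yi <- round(ys)
      ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
      out <- matrix(fill, ny, nx)
      idx <- (pmin(pmax(xi, 1), nx) - 1) * ny + pmin(pmax(yi, 1), ny)
      v <- img[idx]
      out[ok] <- v[ok]
      out
    } else {
      ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
      x0 <- pmin(floor(xs), nx - 1); y0 <- pmin(floor(ys), ny - 1)
      fx <- xs - x0;  fy <- ys - y0
      x0c <- pmin(pmax(x0, 1), nx - 1); y0c <- pmin(pmax(y0, 1), ny - 1)
      i00 <- (x0c - 1) * ny + y0c
      v <- (1 - fx) * (1 - fy) * img[i00] +
           fx * (1 - fy) * img[i00 + ny] +
           (1 - fx) * fy * img[i00 + 1] +
           fx * fy * img[i00 + ny + 1]
      out <- matrix(fill, ny, nx)
      out[ok] <- v[ok]
      out
    }
  }

  if (length(d) == 2) {
    st <- is.logical(image)
    img <- if (st) (image * 1) else image
    out <- sample_plane(img)
    if (st) out <- out > 0.5
    out
  } else {
    out <- array(fill, d)
    for (k in seq_len(d[3])) out[, , k] <- sample_plane(image[, , k])
    out
  }
}
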