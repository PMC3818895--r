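#' Rigid registration of serial-section images
#'
#' Sections cut from a tissue core land on the glass with arbitrary shifts
#' and small rotations. Alignment is restricted to rigid motion (translation
#' plus rotation, no stretching or shearing): affine or deformable warps
#' degrade serial-section stacks by letting per-slice distortions accumulate.
#' Similarity is evaluated on the luminance channel, since both chromogens
#' (DAB and SG) darken luminance.
#'
#' @name registration
NULL

#' Luminance (mean of RGB) of an image
#' @param image 2D matrix (returned as-is) or 3-channel array.
#' @return 2D matrix.
#' @export
luminance <- function(image) {
  if (length(dim(image)) == 2) return(image)
  (image[, , 1] + image[, , 2] + image[, , 3]) / 3
}

# block-mean downsample by integer factor
.downsample <- function(img, s) {
  if (s == 1) return(img)
  d <- dim(img)
  ny <- (d[1] %/% s) * s; nx <- (d[2] %/% s) * s
  img <- img[seq_len(ny), seq_len(nx)]
  a <- array(img, c(s, ny %/% s, s, nx %/% s))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# translation by circular FFT cross-correlation; returns (tx, ty, score)
.fft_translation <- function(fixed, moving) {
  Ff <- stats::fft(fixed)
  Fm <- stats::fft(moving)
  C <- Re(stats::fft(Ff * Conj(Fm), inverse = TRUE))
  i <- which.max(C)
  ny <- nrow(fixed); nx <- ncol(fixed)
  iy <- (i - 1) %% ny; ix <- (i - 1) %/% ny
  if (iy > ny / 2) iy <- iy - ny
  if (ix > nx / 2) ix <- ix - nx
  denom <- sqrt(sum(fixed^2) * sum(moving^2))
  list(tx = ix, ty = iy, score = if (denom > 0) max(C) / denom / length(C) else 0)
}

# centroids of small compact blobs in a foreground mask: the features used
# by the correspondence ("fine") refinement stage. Elongated cross-sections
# (oblique cuts of cords or projections, whose centroids drift laterally
# from section to section) are rejected by a compactness filter: area over
# the circumscribed circle must be disk-like.
.blob_centroids <- function(fg, area_px, min_compact = 0.5, w = NULL) {
  if (!any(fg)) return(matrix(numeric(0), 0, 2))
  lab <- label_components(fg, 8)
  sz <- label_sizes(lab)
  keep <- which(sz >= area_px[1] & sz <= area_px[2])
  if (!length(keep)) return(matrix(numeric(0), 0, 2))
  idx <- which(lab > 0)
  l <- lab[idx]
  x <- (idx - 1) %/% nrow(fg) + 1
  y <- (idx - 1) %% nrow(fg) + 1
  wv <- if (is.null(w)) rep(1, length(idx)) else pmax(w[idx], 1e-8)
  ok <- l %in% keep
  wsum <- tapply(wv[ok], l[ok], sum)
  cx <- tapply(x[ok] * wv[ok], l[ok], sum) / wsum
  cy <- tapply(y[ok] * wv[ok], l[ok], sum) / wsum
  r2max <- vapply(seq_along(cx), function(i) {
    sel <- l[ok] == as.integer(names(cx)[i])
    max((x[ok][sel] - cx[i])^2 + (y[ok][sel] - cy[i])^2)
  }, numeric(1))
  area <- sz[as.integer(names(cx))]
  compact <- area / pmax(pi * (sqrt(r2max) + 0.5)^2, 1)
  round_enough <- compact >= min_compact
  cbind(cx[round_enough], cy[round_enough])
}

.transform_points <- function(T, pts) {
  M <- transform_matrix(T)
  t(M$A %*% t(pts)) + rep(M$b, each = nrow(pts))
}

# one mutual-nearest-neighbour Procrustes update of T (moving -> fixed).
# The translation correction is always applied in full (the matched-centroid
# shift is precise even for two matches). The rotation correction competes
# with the rotation already estimated from image correlation: with few
# matches a point-based angle is high-variance, so it is shrunk by
# lambda = m / (m + n0) (m = match count) - a precision-weighted blend that
# trusts points only as their number grows. Fewer than 4 matches apply the
# translation only; fewer than 2 leave T unchanged.
.procrustes_update <- function(T, fixed_pts, moving_pts, gate, center,
                               n0 = 12) {
  if (nrow(fixed_pts) < 2 || nrow(moving_pts) < 2) return(T)
  B <- .transform_points(T, moving_pts)
  d2 <- outer(fixed_pts[, 1], B[, 1], "-")^2 +
    outer(fixed_pts[, 2], B[, 2], "-")^2
  ja <- apply(d2, 1, which.min)
  jb <- apply(d2, 2, which.min)
  m <- which(jb[ja] == seq_len(nrow(fixed_pts)) &
               d2[cbind(seq_len(nrow(fixed_pts)), ja)] < gate^2)
  if (length(m) < 2) return(T)
  X <- fixed_pts[m, , drop = FALSE]
  Y <- B[ja[m], , drop = FALSE]
  xb <- colMeans(X); yb <- colMeans(Y)
  ang <- 0
  if (length(m) >= 4) {
    H <- t(Y - rep(yb, each = nrow(Y))) %*% (X - rep(xb, each = nrow(X)))
    sv <- svd(H)
    R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
    lambda <- if (n0 <= 0) 1 else length(m) / (length(m) + n0)
    ang <- atan2(R[2, 1], R[1, 1]) * lambda
  }
  Rd <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  D <- transform_from_matrix(Rd, xb - as.numeric(Rd %*% yb), center)
  compose_transforms(D, T, center)
}

.ncc <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 16) return(-1)
  va <- a[ok]; vb <- b[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(-1)
  stats::cor(va, vb)
}

#' Estimate the rigid transform aligning one section onto another
#'
#' Two-stage ("rough and fine") search for the rigid transform mapping
#' `moving` onto `fixed`, maximizing normalized cross-correlation: a coarse
#' stage scans candidate rotations on a block-averaged pyramid level with
#' Fourier cross-correlation for the translation at each angle, then a
#' Nelder-Mead refinement of `(tx, ty, theta)` at full resolution.
#'
#' After the intensity refinement, a correspondence stage sharpens the
#' estimate: centroids of small compact blobs (nuclei and small structure
#' cross-sections, which recur at identical positions on consecutive
#' sections) are matched mutually-nearest-neighbour within a shrinking gate
#' and a closed-form rigid Procrustes fit is applied. This suppresses the
#' bias that gradual structural change between consecutive sections imprints
#' on a pure correlation optimum. When RGB images are given, blob features
#' are taken both from dark luminance objects and from the unmixed SG
#' channel, so Ki67+ nuclei embedded in dark CK+ parenchyma still serve as
#' anchors.
#'
#' @param fixed,moving grayscale matrices or RGB arrays (similarity is
#'   computed on luminance) of identical dimensions.
#' @param opts list of options: `max_rot` (degrees scanned, default 4),
#'   `rot_step` (coarse angular step, default 1), `min_size` (pyramid level
#'   minimum edge, default 96), `refine` (logical, default TRUE), `icp`
#'   (run the blob-correspondence stage, default TRUE), `icp_gates`
#'   (match gates in px, default 2.5, 1.5, 1.2), `icp_area_px` (blob area
#'   band, default 5-100), `icp_lum` (luminance below which a pixel is
#'   object, default 0.85), `icp_sg` (SG concentration above which a pixel
#'   is a nucleus footprint, default 0.15), `stain` (a [stain_model()] used
#'   to unmix RGB inputs for SG features).
#' @return A [rigid_transform()] `T` such that `apply_transform(moving, T)`
#'   superimposes on `fixed`.
#' @export
estimate_rigid <- function(fixed, moving, opts = list()) {
  o <- .reg_opts(opts)
  f <- luminance(fixed); m <- luminance(moving)
  if (!all(dim(f) == dim(m))) stop("fixed and moving must share dimensions")
  if (stats::sd(f) == 0 || stats::sd(m) == 0) stop("no registrable content")
  f0 <- f - mean(f); m0 <- m - mean(m)
  ny <- nrow(f); nx <- ncol(f)
  center <- c((nx + 1) / 2, (ny + 1) / 2)

  s <- 1
  while (min(ny, nx) / (2 * s) >= o$min_size) s <- 2 * s
  fd <- .downsample(f0, s); md <- .downsample(m0, s)
  cd <- c((ncol(fd) + 1) / 2, (nrow(fd) + 1) / 2)

  angles <- seq(-o$max_rot, o$max_rot, by = o$rot_step)
  best <- list(score = -Inf, tx = 0, ty = 0, theta = 0)
  for (a in angles) {
    mr <- if (a == 0) md else
      apply_transform(md, rigid_transform(0, 0, a, cd), "bilinear", fill = 0)
    tr <- .fft_translation(fd, mr)
    if (tr$score > best$score)
      best <- list(score = tr$score, tx = tr$tx * s, ty = tr$ty * s, theta = a)
  }

  T0 <- rigid_transform(best$tx, best$ty, best$theta, center)
  if (!o$refine) return(T0)

  obj <- function(p) {
    Tp <- rigid_transform(p[1], p[2], p[3], center)
    -.ncc(f0, apply_transform(m0, Tp, "bilinear", fill = NA))
  }
  fit <- stats::optim(c(best$tx, best$ty, best$theta), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8))
  T1 <- rigid_transform(fit$par[1], fit$par[2], fit$par[3], center)
  if (!o$icp) return(T1)

  fp <- .slice_features(fixed, o)
  mp <- .slice_features(moving, o)
  for (gate in o$icp_gates)
    T1 <- .procrustes_update(T1, fp, mp, gate, center, n0 = o$icp_n0)
  T1
}

# blob features of one slice, with intensity-weighted (sub-pixel) centroids:
# dark luminance objects and/or, for RGB input, SG-channel nucleus
# footprints. Nuclei are the preferred fiducials: they are point-like,
# biologically stationary markers recurring on consecutive sections.
.slice_features <- function(image, o, channels = "both") {
  pts <- matrix(numeric(0), 0, 2)
  if (channels %in% c("both", "lum")) {
    g <- luminance(image)
    pts <- rbind(pts, .blob_centroids(g < o$icp_lum, o$icp_area_px,
                                      w = pmax(o$icp_lum - g, 0)))
  }
  if (channels %in% c("both", "sg") && length(dim(image)) == 3) {
    stain <- if (is.null(o$stain)) stain_model() else o$stain
    sg <- unmix(rgb_to_od(image, stain$I0), stain)$sg
    pts <- rbind(pts, .blob_centroids(sg > o$icp_sg, o$icp_area_px, w = sg))
  }
  pts
}

# shared option defaults for the estimator and the stack chain
.reg_opts <- function(opts) {
  utils::modifyList(list(max_rot = 4, rot_step = 1, min_size = 96,
                         refine = TRUE, icp = TRUE,
                         icp_gates = c(2.5, 1.5, 1.2),
                         icp_area_px = c(5, 100), icp_lum = 0.85,
                         icp_sg = 0.15, stain = NULL, icp_n0 = 0,
                         chain_refine = TRUE, chain_sweeps = 1,
                         chain_n0 = Inf), opts)
}

#' Register a full section stack
#'
#' Estimates neighbour-to-neighbour rigid transforms and composes them
#' outward from a reference slice (default: the middle slice, which halves
#' worst-case error accumulation compared to anchoring at the first slice).
#'
#' Pure chain composition accumulates the small content-induced bias of
#' each pairwise estimate as a random walk. To suppress it, the chain is
#' refined against an anchor map: nucleus-footprint centroids (SG channel,
#' intensity-weighted for sub-pixel precision) of the two previously placed
#' slices, mapped into the reference frame, re-anchor each newly placed
#' slice by a gated translation correction (rotation is left to the
#' pairwise estimates, whose point stage already fixes it; re-rotating
#' against sparse anchor maps would add jitter). Because every nucleus
#' spans two to three consecutive sections, this adds reliable lag-2 ties
#' that a plain chain lacks. A final symmetric sweep re-anchors each slice
#' against both neighbours. Every slice is resampled exactly once with its
#' composed transform.
#'
#' @param stack a [section_stack()].
#' @param reference index of the reference slice (default middle).
#' @param fill background fill for resampled out-of-frame pixels (default 1,
#'   i.e. blank-slide white on the \[0, 1\] intensity scale).
#' @param opts options forwarded to [estimate_rigid()]; additionally
#'   `chain_refine` (default TRUE) and `chain_sweeps` (default 1).
#' @return list with `stack` (aligned [section_stack()]), `transforms`
#'   (composed per-slice [rigid_transform()]s into the reference frame) and
#'   `pairwise` (neighbour transforms).
#' @export
register_stack <- function(stack, reference = NULL, fill = 1, opts = list()) {
  imgs <- stack$images
  n <- length(imgs)
  if (n < 2) stop("need at least 2 slices to register")
  if (is.null(reference)) reference <- (n + 1) %/% 2
  o <- .reg_opts(opts)
  pairwise <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    pairwise[[i]] <- tryCatch(
      estimate_rigid(imgs[[i]], imgs[[i + 1]], opts),
      error = function(e) stop(sprintf(
        "registration failed between slices %d and %d: %s", i, i + 1,
        conditionMessage(e)), call. = FALSE))
  }
  d <- dim(imgs[[1]])
  center <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  rgb <- length(d) == 3
  feats <- if (o$chain_refine)
    lapply(imgs, .slice_features, o = o, channels = if (rgb) "sg" else "lum")
  else NULL
  composed <- vector("list", n)
  composed[[reference]] <- rigid_transform(0, 0, 0, center)
  anchor_refine <- function(T, j, sources) {
    if (is.null(feats) || nrow(feats[[j]]) == 0) return(T)
    A <- do.call(rbind, lapply(sources, function(k)
      if (nrow(feats[[k]])) .transform_points(composed[[k]], feats[[k]])
      else NULL))
    if (is.null(A)) return(T)
    for (gate in o$icp_gates)
      T <- .procrustes_update(T, A, feats[[j]], gate, center, n0 = o$chain_n0)
    T
  }
  if (reference < n)
    for (j in (reference + 1):n) {
      T0 <- compose_transforms(composed[[j - 1]], pairwise[[j - 1]], center)
      composed[[j]] <- anchor_refine(T0, j, intersect(c(j - 1, j - 2), reference:n))
    }
  if (reference > 1)
    for (j in (reference - 1):1) {
      T0 <- compose_transforms(composed[[j + 1]],
                               invert_transform(pairwise[[j]]), center)
      composed[[j]] <- anchor_refine(T0, j, intersect(c(j + 1, j + 2), 1:reference))
    }
  if (o$chain_refine && o$chain_sweeps > 0)
    for (sweep in seq_len(o$chain_sweeps))
      for (j in order(abs(seq_len(n) - reference)))
        if (j != reference)
          composed[[j]] <- anchor_refine(composed[[j]], j,
                                         setdiff(max(1, j - 2):min(n, j + 2), j))
  aligned <- lapply(seq_len(n), function(j)
    apply_transform(imgs[[j]], composed[[j]], "bilinear", fill = fill))
  out <- stack
  out$images <- aligned
  list(stack = out, transforms = composed, pairwise = pairwise)
}

#' Mean absolute difference between adjacent slices
#'
#' Browsing-smoothness proxy: a well-aligned stack changes little between
#' neighbouring sections.
#'
#' @param stack a [section_stack()].
#' @return mean over slice pairs of the per-pixel mean absolute luminance
#'   difference.
#' @export
stack_roughness <- function(stack) {
  g <- lapply(stack$images, luminance)
  mean(vapply(seq_len(length(g) - 1), function(i)
    mean(abs(g[[i]] - g[[i + 1]])), numeric(1)))
}
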