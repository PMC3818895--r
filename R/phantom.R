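#' Synthetic invasion-front phantoms
#'
#' Ground-truth 3D phantoms of the four canonical invasion architectures of
#' oral tongue squamous cell carcinoma, rendered into misaligned, noisy,
#' double-chromogen RGB serial sections. Every downstream stage
#' (registration, stain separation, volume assembly, focus morphometry) is
#' testable against the voxel-level truth without any external data.
#'
#' Archetypes: `PB` (pushing and bulky: one large blob with short
#' finger-like projections), `TSC` (trabecular: interconnected cords forming
#' one connected honeycomb), `DS` (diffuse spreading: a compact mass plus
#' many small detached foci), `SF` (special forms: a few thin tortuous
#' strands).
#'
#' @name synthetic_data
NULL

#' Phantom specification
#'
#' @param mode invasion-architecture archetype: `"PB"`, `"TSC"`, `"DS"` or
#'   `"SF"`.
#' @param grid voxel grid `(nx, ny, nz)`; the default 512 x 512 x 40 is a
#'   desk-scale reduction of a full 3-mm-core acquisition (which is also
#'   supported, just not the default).
#' @param pixel_size_um in-plane pixel edge (default 0.92).
#' @param slice_thickness_um section thickness (default 4).
#' @param core_diameter_um tissue-core diameter; default 90% of the
#'   in-plane grid extent (the full-scale value is 3000).
#' @param focus_plan list of `c(equivalent_diameter_um, count)` pairs of
#'   detached foci to plant.
#' @param min_focus_separation_vox minimum voxel gap between a planted
#'   focus and any other parenchyma (default 2, which guarantees
#'   26-disconnection and a clean one-voxel-dilation detachment test).
#' @param focus_margin_px minimum in-plane distance (pixels) between a
#'   planted focus and the lateral core margin; marginal foci would be
#'   boundary-excluded by the analysis anyway.
#' @param nuclei list: `parenchyma_density_per_mm3`,
#'   `stroma_density_per_mm3` (Ki67+ only; the model has no counterstain,
#'   so Ki67- stromal nuclei are unobservable and are not generated),
#'   `ki67_fraction` (of parenchymal nuclei), `nucleus_radius_um`.
#' @param misalignment `c(max_shift_px, max_rotation_deg)` per-slice rigid
#'   mounting error bounds.
#' @param noise_sd Gaussian intensity noise SD on the \[0, 1\] scale.
#' @param seed integer RNG seed. Independent streams are derived for
#'   geometry, foci, nuclei, misalignment and noise, so e.g. changing
#'   `noise_sd` never changes the geometry.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(mode = c("PB", "TSC", "DS", "SF"),
                         grid = c(512, 512, 40),
                         pixel_size_um = 0.92,
                         slice_thickness_um = 4,
                         core_diameter_um = NULL,
                         focus_plan = list(c(18, 4), c(22, 3), c(28, 2), c(40, 1)),
                         min_focus_separation_vox = 2,
                         focus_margin_px = 16,
                         nuclei = list(),
                         misalignment = c(8, 2),
                         noise_sd = 0.02,
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(grid) == 3, all(grid >= 4),
            pixel_size_um > 0, slice_thickness_um > 0,
            noise_sd >= 0, length(misalignment) == 2, all(misalignment >= 0))
  if (is.null(core_diameter_um))
    core_diameter_um <- 0.9 * min(grid[1], grid[2]) * pixel_size_um
  if (core_diameter_um > min(grid[1], grid[2]) * pixel_size_um + 1e-9)
    stop("grid physical extent must cover the core diameter")
  nuc <- utils::modifyList(list(parenchyma_density_per_mm3 = 2e5,
                                stroma_density_per_mm3 = 2e5,
                                ki67_fraction = 0.5,
                                nucleus_radius_um = 3.5), nuclei)
  stopifnot(nuc$parenchyma_density_per_mm3 >= 0,
            nuc$stroma_density_per_mm3 >= 0,
            nuc$ki67_fraction >= 0, nuc$ki67_fraction <= 1,
            nuc$nucleus_radius_um > 0)
  for (fp in focus_plan) {
    stopifnot(length(fp) == 2, fp[2] >= 0)
    if (fp[1] < 2 * max(pixel_size_um, slice_thickness_um))
      stop(sprintf("focus diameter %.1f um is below 2 voxels", fp[1]))
  }
  structure(list(mode = mode, grid = as.integer(grid),
                 pixel_size_um = pixel_size_um,
                 slice_thickness_um = slice_thickness_um,
                 core_diameter_um = core_diameter_um,
                 focus_plan = focus_plan,
                 min_focus_separation_vox = min_focus_separation_vox,
                 focus_margin_px = focus_margin_px,
                 nuclei = nuc,
                 misalignment = as.numeric(misalignment),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: mode %s, grid %d x %d x %d, %.3g um/px, core %.0f um, seed %d\n",
              x$mode, x$grid[1], x$grid[2], x$grid[3], x$pixel_size_um,
              x$core_diameter_um, x$seed))
  invisible(x)
}

# ---- voxel stamping helpers (arrays are [ny, nx, nz]) ----

# stamp a physical sphere (ellipsoid in voxel units) of radius r_um
.stamp_ellipsoid <- function(mask, cx, cy, cz, r_um, dx, dz, value = TRUE) {
  d <- dim(mask)
  rx <- r_um / dx; rz <- r_um / dz
  xs <- max(1, floor(cx - rx)):min(d[2], ceiling(cx + rx))
  ys <- max(1, floor(cy - rx)):min(d[1], ceiling(cy + rx))
  zs <- max(1, floor(cz - rz)):min(d[3], ceiling(cz + rz))
  if (!length(xs) || !length(ys) || !length(zs)) return(mask)
  qy <- ((ys - cy) / rx)^2
  qx <- ((xs - cx) / rx)^2
  qxy <- outer(qy, qx, "+")
  for (z in zs) {
    inside <- qxy + ((z - cz) / rz)^2 <= 1
    sub <- mask[ys, xs, z]
    sub[inside] <- value
    mask[ys, xs, z] <- sub
  }
  mask
}

# list of voxel indices (linear) of an ellipsoid, for overlap tests
.ellipsoid_hits <- function(d, cx, cy, cz, rx, rz) {
  xs <- max(1, floor(cx - rx)):min(d[2], ceiling(cx + rx))
  ys <- max(1, floor(cy - rx)):min(d[1], ceiling(cy + rx))
  zs <- max(1, floor(cz - rz)):min(d[3], ceiling(cz + rz))
  qy <- ((ys - cy) / rx)^2
  qx <- ((xs - cx) / rx)^2
  qxy <- outer(qy, qx, "+")
  out <- integer(0)
  plane <- d[1] * d[2]
  for (z in zs) {
    inside <- which(qxy + ((z - cz) / rz)^2 <= 1, arr.ind = TRUE)
    if (nrow(inside))
      out <- c(out, (z - 1L) * plane + (xs[inside[, 2]] - 1L) * d[1] +
                 ys[inside[, 1]])
  }
  out
}

# tube between two voxel-space points, radius r_um
.stamp_tube <- function(mask, p0, p1, r_um, dx, dz) {
  step <- max(0.5, min(r_um / dx, r_um / dz) / 2)
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2, ceiling(len / step))
  for (t in seq(0, 1, length.out = n)) {
    p <- p0 + t * (p1 - p0)
    mask <- .stamp_ellipsoid(mask, p[1], p[2], p[3], r_um, dx, dz)
  }
  mask
}

# separable binary box erosion, half-widths (rx px in-plane, rz slices)
.erode_box <- function(mask, rx, rz) {
  shift_and <- function(m, axis, k) {
    d <- dim(m)
    out <- array(FALSE, d)
    idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_dst <- idx_src
    src <- idx_src[[axis]] + k
    ok <- src >= 1 & src <= d[axis]
    idx_src[[axis]] <- src[ok]
    idx_dst[[axis]] <- which(ok)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- mask
  for (axis in 1:3) {
    r <- if (axis == 3) rz else rx
    if (r < 1) next
    acc <- out
    for (k in seq_len(r)) {
      acc <- acc & shift_and(out, axis, k) & shift_and(out, axis, -k)
    }
    out <- acc
  }
  out
}

# ---- archetype bulk geometries ----

.bulk_pb <- function(d, dx, dz, fingers = TRUE) {
  nx <- d[2]; ny <- d[1]; nz <- d[3]
  mask <- array(FALSE, d)
  cx <- nx / 2 + stats::runif(1, -0.02, 0.02) * nx
  cy <- ny / 2 + stats::runif(1, -0.02, 0.02) * ny
  rx <- (if (fingers) 0.26 else 0.22) * min(nx, ny)
  rz <- 0.60 * nz
  zc <- 1 - 0.12 * nz
  # dome: ellipsoid anchored through the first slice
  qy <- ((seq_len(ny) - cy) / rx)^2
  qx <- ((seq_len(nx) - cx) / rx)^2
  qxy <- outer(qy, qx, "+")
  for (z in seq_len(nz)) {
    q <- ((z - zc) / rz)^2
    mask[, , z] <- qxy + q <= 1
  }
  if (fingers) {
    nf <- 8
    for (i in seq_len(nf)) {
      phi <- stats::runif(1, 0, 2 * pi)
      u <- stats::runif(1, 0.45, 0.8)          # depth fraction on the dome
      zs <- zc + rz * u
      rs <- rx * sqrt(max(0, 1 - u^2))
      p0 <- c(cx + 0.85 * rs * cos(phi), cy + 0.85 * rs * sin(phi), zs)
      out_dir <- c(cos(phi), sin(phi))
      p1 <- p0 + c(out_dir * stats::runif(1, 8, 16),
                   stats::runif(1, 2, 4))
      p1[3] <- min(p1[3], nz - 1)
      mask <- .stamp_tube(mask, p0, p1, 5, dx, dz)
    }
  }
  mask
}

.bulk_tsc <- function(d, dx, dz) {
  nx <- d[2]; ny <- d[1]; nz <- d[3]
  mask <- array(FALSE, d)
  sp <- max(24, round(40 / dx * 0.92))
  gx <- max(2, floor(0.58 * nx / sp)); gy <- max(2, floor(0.58 * ny / sp))
  spz <- max(3, round(nz / 4)); gz <- max(2, floor(0.8 * nz / spz))
  nodes <- array(0, c(gy, gx, gz, 3))
  for (iy in seq_len(gy)) for (ix in seq_len(gx)) for (iz in seq_len(gz)) {
    nodes[iy, ix, iz, ] <- c(
      nx / 2 + (ix - (gx + 1) / 2) * sp + stats::runif(1, -0.2, 0.2) * sp,
      ny / 2 + (iy - (gy + 1) / 2) * sp + stats::runif(1, -0.2, 0.2) * sp,
      1 + (iz - 1) * spz + stats::runif(1, 0, 0.3) * spz)
  }
  r_cord <- 6
  node_id <- function(iy, ix, iz) (iz - 1) * gy * gx + (ix - 1) * gy + iy
  parent <- seq_len(gy * gx * gz)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list()
  for (iy in seq_len(gy)) for (ix in seq_len(gx)) for (iz in seq_len(gz)) {
    for (nb in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      jy <- iy + nb[1]; jx <- ix + nb[2]; jz <- iz + nb[3]
      if (jy > gy || jx > gx || jz > gz) next
      if (stats::runif(1) < 0.75)
        edges[[length(edges) + 1]] <- c(iy, ix, iz, jy, jx, jz)
    }
  }
  for (e in edges) {
    a <- find(node_id(e[1], e[2], e[3])); b <- find(node_id(e[4], e[5], e[6]))
    if (a != b) parent[a] <- b
    mask <- .stamp_tube(mask, nodes[e[1], e[2], e[3], ],
                        nodes[e[4], e[5], e[6], ], r_cord, dx, dz)
  }
  # connect any remaining pieces along a deterministic chain of grid lines
  roots <- unique(vapply(seq_len(gy * gx * gz), find, numeric(1)))
  if (length(roots) > 1) {
    for (iz in seq_len(gz)) for (ix in seq_len(gx)) for (iy in seq_len(gy)) {
      if (iy < gy) {
        a <- find(node_id(iy, ix, iz)); b <- find(node_id(iy + 1, ix, iz))
        if (a != b) {
          parent[a] <- b
          mask <- .stamp_tube(mask, nodes[iy, ix, iz, ],
                              nodes[iy + 1, ix, iz, ], r_cord, dx, dz)
        }
      }
      if (ix < gx) {
        a <- find(node_id(iy, ix, iz)); b <- find(node_id(iy, ix + 1, iz))
        if (a != b) {
          parent[a] <- b
          mask <- .stamp_tube(mask, nodes[iy, ix, iz, ],
                              nodes[iy, ix + 1, iz, ], r_cord, dx, dz)
        }
      }
      if (iz < gz) {
        a <- find(node_id(iy, ix, iz)); b <- find(node_id(iy, ix, iz + 1))
        if (a != b) {
          parent[a] <- b
          mask <- .stamp_tube(mask, nodes[iy, ix, iz, ],
                              nodes[iy, ix, iz + 1, ], r_cord, dx, dz)
        }
      }
    }
  }
  # anchor the honeycomb through the first slice
  for (ix in seq_len(gx)) for (iy in seq_len(gy)) {
    p <- nodes[iy, ix, 1, ]
    mask <- .stamp_tube(mask, p, c(p[1], p[2], 1), r_cord, dx, dz)
  }
  mask
}

.bulk_sf <- function(d, dx, dz) {
  nx <- d[2]; ny <- d[1]; nz <- d[3]
  mask <- array(FALSE, d)
  for (s in 1:3) {
    p <- c(nx / 2 + stats::runif(1, -0.15, 0.15) * nx,
           ny / 2 + stats::runif(1, -0.15, 0.15) * ny, 1)
    vel <- c(stats::runif(1, -2, 2), stats::runif(1, -2, 2))
    while (p[3] < nz) {
      vel <- 0.7 * vel + stats::rnorm(2, 0, 2.5)
      q <- p + c(vel, 1)
      q[1] <- min(max(q[1], 0.2 * nx), 0.8 * nx)
      q[2] <- min(max(q[2], 0.2 * ny), 0.8 * ny)
      mask <- .stamp_tube(mask, p, q, 5.5, dx, dz)
      p <- q
    }
  }
  mask
}

# ---- phantom construction ----

#' Build a ground-truth phantom volume
#'
#' Generates the archetype bulk geometry, plants detached foci meeting the
#' separation constraints, samples nuclei, and computes the truth
#' morphometry report directly from the noiseless voxels.
#'
#' Nucleus placement uses Poisson counts at the stated densities with a
#' hard-core rejection (minimum center distance of one nucleus diameter
#' plus 1 um) so rendered nuclei stay resolvable as distinct objects;
#' Ki67-negative nuclei are placed inside the in-plane-eroded parenchyma so
#' their unstained holes are fully circumscribed by CK+ cytoplasm.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `ground_truth`: list with `parenchyma` (logical
#'   `ny x nx x nz` array), `focus_label` (integer array, 0 = bulk or
#'   background, k = planted focus k), `nucleus_table`, `core_mask`,
#'   `voxel_dims_um`, `spec`, and `truth_report` (see
#'   [truth_morphometry()]).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
  d <- c(ny, nx, nz)
  dx <- spec$pixel_size_um; dz <- spec$slice_thickness_um
  core <- core_disk(ny, nx, spec$core_diameter_um / dx)
  core3d <- array(core, d)

  set.seed(spec$seed + 101L)
  bulk <- switch(spec$mode,
                 PB = .bulk_pb(d, dx, dz, fingers = TRUE),
                 DS = .bulk_pb(d, dx, dz, fingers = FALSE),
                 TSC = .bulk_tsc(d, dx, dz),
                 SF = .bulk_sf(d, dx, dz))
  bulk <- bulk & core3d

  # ---- plant detached foci ----
  set.seed(spec$seed + 102L)
  parenchyma <- bulk
  focus_label <- array(0L, d)
  sep <- spec$min_focus_separation_vox
  core_r <- spec$core_diameter_um / dx / 2
  ccx <- (nx + 1) / 2; ccy <- (ny + 1) / 2
  plan <- spec$focus_plan[order(-vapply(spec$focus_plan, `[`, numeric(1), 1))]
  k <- 0L
  for (fp in plan) {
    diam <- fp[1]
    for (j in seq_len(fp[2])) {
      rx <- diam / 2 / dx; rz <- diam / 2 / dz
      rmax <- core_r - spec$focus_margin_px - rx
      zlo <- 1.6 + rz; zhi <- nz - 0.6 - rz
      if (rmax <= 0 || zhi <= zlo)
        stop(sprintf("focus plan unsatisfiable: focus %d (diameter %.1f um) cannot fit the grid",
                     k + 1L, diam))
      placed <- FALSE
      for (try in seq_len(1000)) {
        rr <- sqrt(stats::runif(1)) * rmax
        phi <- stats::runif(1, 0, 2 * pi)
        cx <- ccx + rr * cos(phi); cy <- ccy + rr * sin(phi)
        cz <- stats::runif(1, zlo, zhi)
        guard <- .ellipsoid_hits(d, cx, cy, cz, rx + sep, rz + sep)
        if (any(parenchyma[guard])) next
        hits <- .ellipsoid_hits(d, cx, cy, cz, rx, rz)
        parenchyma[hits] <- TRUE
        k <- k + 1L
        focus_label[hits] <- k
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("focus plan unsatisfiable: cannot place focus %d (diameter %.1f um) after 1000 attempts",
                     k + 1L, diam))
    }
  }

  # ---- nuclei ----
  # Poisson counts at the stated densities, with a class-aware hard core:
  # within a marker class, two nuclei must either be separated in-plane by
  # more than the sum of their footprint radii plus two pixels, or in z by
  # enough slabs that their section footprints can never become 26-adjacent.
  # Across classes a plain spherical hard core suffices. This keeps every
  # rendered nucleus resolvable as one connected object, so object counting
  # equals nucleus counting on the truth (the method itself never splits
  # touching nuclei; the phantom is built so it does not have to).
  # Nuclei are sampled from the eroded interior of their compartment so
  # each lies wholly inside it.
  set.seed(spec$seed + 103L)
  voxvol_mm3 <- dx * dx * dz / 1e9
  r_um <- spec$nuclei$nucleus_radius_um
  v_p <- sum(parenchyma) * voxvol_mm3
  stroma3d <- core3d & !parenchyma
  v_s <- sum(stroma3d) * voxvol_mm3
  er_xy <- as.integer(ceiling(r_um / dx) + 1L)
  ero_par_idx <- which(.erode_box(parenchyma, er_xy, 1L))
  ero_str_idx <- which(.erode_box(stroma3d, er_xy, 1L))

  n_pos_par <- stats::rpois(1, spec$nuclei$parenchyma_density_per_mm3 *
                              spec$nuclei$ki67_fraction * v_p)
  n_neg_par <- stats::rpois(1, spec$nuclei$parenchyma_density_per_mm3 *
                              (1 - spec$nuclei$ki67_fraction) * v_p)
  n_pos_str <- stats::rpois(1, spec$nuclei$stroma_density_per_mm3 * v_s)

  placed_um <- matrix(numeric(0), 0, 3)
  placed_cls <- character(0)
  min_xy <- 2 * r_um + 2 * dx          # in-plane exclusion, same class
  min_z <- 2 * r_um + 1.5 * dz         # axial exclusion, same class
  min_3d2 <- (2 * r_um + 1)^2          # spherical exclusion, across classes
  to_um <- function(p) c(p[1] * dx, p[2] * dx, p[3] * dz)
  place_batch <- function(n, pool, compartment, ki67) {
    if (n == 0 || length(pool) == 0) return(NULL)
    plane <- d[1] * d[2]
    rows <- vector("list", n)
    got <- 0
    for (i in seq_len(n)) {
      for (try in seq_len(120)) {
        v <- pool[sample.int(length(pool), 1)]
        z <- (v - 1L) %/% plane + 1L
        rem <- (v - 1L) %% plane
        x <- rem %/% d[1] + 1L
        y <- rem %% d[1] + 1L
        p <- c(x, y, z) + stats::runif(3, -0.5, 0.5)
        pu <- to_um(p)
        if (nrow(placed_um) > 0) {
          dxy <- sqrt((placed_um[, 1] - pu[1])^2 + (placed_um[, 2] - pu[2])^2)
          dzv <- abs(placed_um[, 3] - pu[3])
          same <- placed_cls == ki67
          if (any(same & dxy < min_xy & dzv < min_z)) next
          if (any(!same & dxy^2 + dzv^2 < min_3d2)) next
        }
        placed_um <<- rbind(placed_um, pu)
        placed_cls <<- c(placed_cls, ki67)
        got <- got + 1
        rows[[got]] <- data.frame(x = p[1], y = p[2], z = p[3],
                                  radius_um = r_um,
                                  compartment = compartment, ki67 = ki67)
        break
      }
    }
    if (got == 0) NULL else do.call(rbind, rows[seq_len(got)])
  }
  tabs <- list(place_batch(n_pos_par, ero_par_idx, "parenchyma", "pos"),
               place_batch(n_neg_par, ero_par_idx, "parenchyma", "neg"),
               place_batch(n_pos_str, ero_str_idx, "stroma", "pos"))
  nucleus_table <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  if (is.null(nucleus_table))
    nucleus_table <- data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), radius_um = numeric(0),
                                compartment = character(0),
                                ki67 = character(0))
  nucleus_table <- cbind(id = seq_len(nrow(nucleus_table)), nucleus_table)
  rownames(nucleus_table) <- NULL

  # observable CK+ cytoplasm: parenchyma minus the unstained holes that
  # Ki67-negative nuclei leave on each section slab (this is what the DAB
  # channel can show, and hence what digital Vp measures)
  cytoplasm <- .carve_holes(parenchyma, nucleus_table, dx, dz)

  gt <- structure(list(parenchyma = parenchyma,
                       cytoplasm = cytoplasm,
                       focus_label = focus_label,
                       nucleus_table = nucleus_table,
                       core_mask = core,
                       core_diameter_um = spec$core_diameter_um,
                       voxel_dims_um = c(dx, dx, dz),
                       spec = spec),
                  class = "ground_truth")
  gt$truth_report <- truth_morphometry(gt)
  gt
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$parenchyma)
  cat(sprintf("ground_truth (%s): %d x %d x %d voxels, %d planted foci, %d nuclei\n",
              x$spec$mode, d[2], d[1], d[3], max(x$focus_label),
              nrow(x$nucleus_table)))
  invisible(x)
}

#' Slab footprint of a spherical nucleus on a section
#'
#' A section is a 4-um slab, not a plane: the in-plane footprint of a
#' nucleus on slice `k` is the projection of the intersection of its sphere
#' with the slab, a disk of radius `sqrt(r^2 - dzmin^2)` where `dzmin` is
#' the axial distance from the nucleus center to the slab. With the default
#' 7-um nuclei and 4-um slices every nucleus spans at least two consecutive
#' sections, as the noise filter presumes.
#'
#' @param z_center nucleus z in continuous voxel coordinates (voxel `k`
#'   spans `[k - 0.5, k + 0.5]`).
#' @param slice integer slice index.
#' @param radius_um nucleus radius.
#' @param dz_um slice thickness.
#' @return footprint radius in micrometers, or 0 when the sphere misses the
#'   slab.
#' @export
nucleus_footprint_um <- function(z_center, slice, radius_um, dz_um) {
  z_um <- (z_center - 0.5) * dz_um
  lo <- (slice - 1) * dz_um; hi <- slice * dz_um
  dzmin <- pmax(0, lo - z_um, z_um - hi)
  sqrt(pmax(radius_um^2 - dzmin^2, 0))
}

# carve per-slab Ki67-negative nucleus holes out of a parenchyma volume
.carve_holes <- function(parenchyma, nucleus_table, dx, dz) {
  out <- parenchyma
  neg <- nucleus_table[nucleus_table$ki67 == "neg", , drop = FALSE]
  if (!nrow(neg)) return(out)
  for (z in seq_len(dim(parenchyma)[3])) {
    fr <- nucleus_footprint_um(neg$z, z, neg$radius_um, dz)
    hit <- which(fr > 0)
    if (!length(hit)) next
    sl <- out[, , z]
    for (i in hit) sl <- .stamp_disk(sl, neg$x[i], neg$y[i], fr[i] / dx, FALSE)
    out[, , z] <- sl
  }
  out
}

# stamp a disk value into a matrix
.stamp_disk <- function(mat, cx, cy, r_px, value) {
  d <- dim(mat)
  xs <- max(1, floor(cx - r_px)):min(d[2], ceiling(cx + r_px))
  ys <- max(1, floor(cy - r_px)):min(d[1], ceiling(cy + r_px))
  if (!length(xs) || !length(ys)) return(mat)
  inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r_px^2
  sub <- mat[ys, xs, drop = FALSE]
  sub[inside] <- value
  mat[ys, xs] <- sub
  mat
}

#' Render a phantom into misaligned, noisy RGB serial sections
#'
#' Per slice, the DAB concentration is the parenchyma occupancy (with
#' Ki67-negative nuclei carved out as unstained holes in the cytoplasm) and
#' the SG concentration is the Ki67-positive nucleus footprint; transmitted
#' RGB follows Beer-Lambert through the [stain_model()]. Each slice is then
#' displaced by a seeded random rigid transform within the misalignment
#' bounds and Gaussian noise is added and clipped to \[0, 1\]. Stroma is
#' unstained and renders at background intensity.
#'
#' @param gt a `ground_truth` from [build_phantom()].
#' @param stain a [stain_model()].
#' @param misalignment `c(max_shift_px, max_rotation_deg)`; default from
#'   the phantom spec.
#' @param noise_sd intensity noise SD; default from the spec.
#' @param seed RNG seed; default from the spec (independent sub-streams for
#'   misalignment and noise).
#' @return a [section_stack()] with `true_transforms` recorded.
#' @export
render_stack <- function(gt, stain = stain_model(),
                         misalignment = gt$spec$misalignment,
                         noise_sd = gt$spec$noise_sd,
                         seed = gt$spec$seed) {
  d <- dim(gt$parenchyma)
  nz <- d[3]
  dx <- gt$voxel_dims_um[1]; dz <- gt$voxel_dims_um[3]
  center <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  nt <- gt$nucleus_table
  pos <- nt[nt$ki67 == "pos", , drop = FALSE]
  neg <- nt[nt$ki67 == "neg", , drop = FALSE]

  set.seed(seed + 1L)
  transforms <- lapply(seq_len(nz), function(z)
    rigid_transform(stats::runif(1, -misalignment[1], misalignment[1]),
                    stats::runif(1, -misalignment[1], misalignment[1]),
                    stats::runif(1, -misalignment[2], misalignment[2]),
                    center))

  set.seed(seed + 2L)
  images <- vector("list", nz)
  for (z in seq_len(nz)) {
    # cytoplasm already has Ki67-negative holes carved out per slab
    c_dab <- stain$amplitude$dab * (gt$cytoplasm[, , z] * 1)
    c_sg <- matrix(0, d[1], d[2])
    if (nrow(pos)) {
      fr <- nucleus_footprint_um(pos$z, z, pos$radius_um, dz)
      for (i in which(fr > 0))
        c_sg <- .stamp_disk(c_sg, pos$x[i], pos$y[i], fr[i] / dx,
                            stain$amplitude$sg)
    }
    rgb <- compose_rgb(c_dab, c_sg, stain)
    out <- array(0, dim(rgb))
    for (kk in 1:3)
      out[, , kk] <- apply_transform(rgb[, , kk], transforms[[z]],
                                     "bilinear", fill = stain$I0[kk])
    if (noise_sd > 0)
      out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
    images[[z]] <- pmin(pmax(out, 0), 1)
  }
  section_stack(images, dx, dz, true_transforms = transforms)
}

#' Morphometry computed directly from noiseless voxel truth
#'
#' Runs the focus partition and case morphometry on the ground-truth
#' observable cytoplasm mask (parenchyma with Ki67-negative nucleus holes,
#' i.e. what CK staining can show and what digital morphometry measures)
#' and the true nucleus table, bypassing rendering and segmentation.
#' Serves as the recovery oracle for the full pipeline.
#'
#' @param gt a `ground_truth`.
#' @return list with `record` (the [case_morphometry()] row), `foci` (the
#'   [focus_stats()] table) and `partition`.
#' @export
truth_morphometry <- function(gt) {
  d <- dim(gt$parenchyma)
  vol <- structure(list(grid = gt$cytoplasm,
                        voxel_dims_um = gt$voxel_dims_um,
                        core_mask = gt$core_mask,
                        core_diameter_um = gt$core_diameter_um),
                   class = "voxel_volume")
  partition <- partition_components(vol)
  nt <- gt$nucleus_table
  pos <- nt[nt$ki67 == "pos", , drop = FALSE]
  neg <- nt[nt$ki67 == "neg", , drop = FALSE]
  foci <- focus_stats(partition, gt$voxel_dims_um, pos, neg)
  record <- case_morphometry(vol, partition, foci, ki67_pos = pos,
                             case_id = "truth",
                             invasion_mode = gt$spec$mode)
  list(record = record, foci = foci, partition = partition)
}
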