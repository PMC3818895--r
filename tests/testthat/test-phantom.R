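test_that("phantom spec validates physical and statistical parameters", {
  expect_s3_class(fx_spec(), "phantom_spec")
  expect_error(phantom_spec("PB", grid = c(64, 64, 10), core_diameter_um = 1e4),
               "core diameter")
  expect_error(phantom_spec("PB", focus_plan = list(c(5, 1))), "below 2 voxels")
  expect_error(phantom_spec("PB", nuclei = list(ki67_fraction = 1.5)))
  expect_error(phantom_spec("PB", nuclei = list(parenchyma_density_per_mm3 = -1)))
})

test_that("identical spec and seed give bit-identical phantom and rendering", {
  a <- build_phantom(fx_spec())
  b <- build_phantom(fx_spec())
  expect_identical(a$parenchyma, b$parenchyma)
  expect_identical(a$focus_label, b$focus_label)
  expect_identical(a$nucleus_table, b$nucleus_table)
  sa <- render_stack(a)
  sb <- render_stack(b)
  expect_identical(sa$images, sb$images)
  expect_identical(sa$true_transforms, sb$true_transforms)
})

test_that("planted foci match the plan and are 26-disconnected from bulk", {
  gt <- fx_gt()
  expect_equal(max(gt$focus_label), 3)
  lab <- gt$focus_label
  d <- dim(lab)
  for (k in 1:3) {
    idx <- which(lab == k, arr.ind = TRUE)
    # every voxel Chebyshev-adjacent to a focus voxel is focus-k or empty
    for (i in seq_len(nrow(idx))) {
      ys <- max(1, idx[i, 1] - 1):min(d[1], idx[i, 1] + 1)
      xs <- max(1, idx[i, 2] - 1):min(d[2], idx[i, 2] + 1)
      zs <- max(1, idx[i, 3] - 1):min(d[3], idx[i, 3] + 1)
      nb_par <- gt$parenchyma[ys, xs, zs]
      nb_lab <- lab[ys, xs, zs]
      expect_true(all(!nb_par | nb_lab == k))
    }
  }
  # strictly interior: never in first/last slice, always strictly in-core
  foci_idx <- which(lab > 0, arr.ind = TRUE)
  expect_true(all(foci_idx[, 3] > 1 & foci_idx[, 3] < d[3]))
  expect_true(all(gt$core_mask[foci_idx[, 1:2]]))
  # and clear of the lateral margin: the whole in-plane 8-neighbourhood is in-core
  for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1),
                 c(1, -1), c(-1, 1)))
    expect_true(all(gt$core_mask[cbind(foci_idx[, 1] + o[1],
                                       foci_idx[, 2] + o[2])]))
})

test_that("unsatisfiable focus plans fail with the offending focus named", {
  expect_error(
    build_phantom(phantom_spec("PB", grid = c(80, 80, 10),
                               focus_plan = list(c(40, 2)), seed = 1)),
    "unsatisfiable.*diameter 40")
})

test_that("zero parenchyma nucleus density leaves only stromal nuclei", {
  spec <- phantom_spec("DS", grid = c(96, 96, 12), focus_plan = list(),
                       nuclei = list(parenchyma_density_per_mm3 = 0),
                       seed = 3)
  gt <- build_phantom(spec)
  expect_true(all(gt$nucleus_table$compartment == "stroma"))
  expect_true(all(gt$nucleus_table$ki67 == "pos"))
})

test_that("PB bulk is a single connected component (independent labeling oracle)", {
  gt <- fx_gt()
  bulk <- gt$parenchyma & (gt$focus_label == 0)
  lab <- oracle_label(bulk, 26)
  expect_equal(attr(lab, "n_components"), 1)
  rec <- gt$truth_report$record
  expect_gt(rec$parenchyma_pct, 0)
  expect_lt(rec$parenchyma_pct, 100)
})

test_that("every archetype anchors its bulk through the first slice", {
  for (mode in c("PB", "TSC", "DS", "SF")) {
    spec <- phantom_spec(mode, grid = c(96, 96, 12), focus_plan = list(),
                         seed = 5)
    gt <- build_phantom(spec)
    expect_gt(sum(gt$parenchyma[, , 1]), 0)
  }
})

test_that("parenchyma and stroma voxels partition the in-core tissue exactly", {
  gt <- fx_gt()
  d <- dim(gt$parenchyma)
  core3d <- array(gt$core_mask, d)
  stroma <- core3d & !gt$parenchyma
  expect_identical(sum(gt$parenchyma) + sum(stroma), sum(gt$core_mask) * d[3])
  expect_false(any(gt$parenchyma & !core3d))
})

test_that("nucleus table respects compartment and marker invariants", {
  gt <- fx_gt()
  nt <- gt$nucleus_table
  expect_true(all(nt$ki67[nt$compartment == "stroma"] == "pos"))
  # Ki67-negative nuclei lie inside parenchyma
  neg <- nt[nt$ki67 == "neg", ]
  if (nrow(neg) > 0) {
    at <- cbind(round(neg$y), round(neg$x), round(neg$z))
    expect_true(all(gt$parenchyma[at]))
  }
})

test_that("rendering honours the blank-slide and identity-transform cases", {
  spec <- phantom_spec("SF", grid = c(64, 64, 6), focus_plan = list(),
                       nuclei = list(parenchyma_density_per_mm3 = 0,
                                     stroma_density_per_mm3 = 0),
                       seed = 2)
  gt <- build_phantom(spec)
  gt$parenchyma[] <- FALSE
  gt$cytoplasm[] <- FALSE
  st <- render_stack(gt, misalignment = c(0, 0), noise_sd = 0)
  stain <- stain_model()
  for (im in st$images)
    for (k in 1:3) expect_equal(max(abs(im[, , k] - stain$I0[k])), 0)
  expect_true(all(vapply(st$true_transforms, function(T)
    T$tx == 0 && T$ty == 0 && T$theta == 0, logical(1))))
})

test_that("noise changes pixels but never the geometry stream", {
  spec <- fx_spec()
  a <- render_stack(build_phantom(spec), noise_sd = 0)
  b <- render_stack(build_phantom(spec), noise_sd = 0.05)
  expect_identical(a$true_transforms, b$true_transforms)
  expect_false(identical(a$images[[1]], b$images[[1]]))
})

test_that("a rendered pure-DAB pixel has OD collinear with the DAB stain vector", {
  gt <- fx_gt()
  st <- fx_stack0()
  stain <- stain_model()
  z <- 6
  # a cytoplasm pixel without any Ki67+ footprint: pure DAB
  nt <- gt$nucleus_table
  pos <- nt[nt$ki67 == "pos", ]
  sl <- gt$cytoplasm[, , z]
  cand <- which(sl, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(pos)))
    keep <- keep & (abs(cand[, 2] - pos$x[i]) > 6 | abs(cand[, 1] - pos$y[i]) > 6)
  px <- cand[which(keep)[1], ]
  od <- -log10(pmax(st$images[[z]][px[1], px[2], ], 1 / 255) / stain$I0)
  cosine <- sum(od * stain$M[1, ]) / sqrt(sum(od^2) * sum(stain$M[1, ]^2))
  expect_gt(cosine, 0.999)
})

test_that("truth morphometry reports planted foci and voxel arithmetic", {
  gt <- fx_gt()
  tr <- gt$truth_report
  expect_equal(nrow(tr$foci), 3)
  expect_equal(tr$record$n_foci, 3)
  # one 10-voxel bar: volume = count x voxel volume
  bar <- matrix(FALSE, 8, 12)
  bar[4, 2:11] <- TRUE
  vol <- stack_to_volume(list(bar & FALSE, bar, bar & FALSE), c(1, 1, 4))
  expect_equal(sum(vol$grid) * prod(vol$voxel_dims_um), 40)
})

test_that("stack TIFF round trip preserves images and calibration", {
  st <- fx_stack0()
  sub <- section_stack(st$images[1:3], st$pixel_size_um,
                       st$slice_thickness_um, st$true_transforms[1:3])
  dir <- file.path(tempdir(), "tumor3d-stack-test")
  write_stack(sub, dir)
  back <- read_stack(dir)
  expect_equal(length(back$images), 3)
  expect_equal(back$pixel_size_um, sub$pixel_size_um)
  expect_equal(back$slice_thickness_um, sub$slice_thickness_um)
  # 8-bit quantization: half-step accuracy
  expect_lt(max(abs(back$images[[2]] - sub$images[[2]])), 1 / 255)
  expect_equal(back$true_transforms[[2]]$tx, sub$true_transforms[[2]]$tx)
})
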