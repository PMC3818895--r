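test_that("optical density follows Beer-Lambert closed forms", {
  I0 <- c(0.95, 0.9, 1)
  img <- array(0, c(2, 2, 3))
  for (k in 1:3) img[, , k] <- I0[k]
  expect_equal(rgb_to_od(img, I0), array(0, c(2, 2, 3)))
  img[1, 1, 2] <- I0[2] / 10
  od <- rgb_to_od(img, I0)
  expect_equal(od[1, 1, 2], 1)
  # brighter than blank clamps at zero, never negative
  img[2, 2, 3] <- 1.2 * I0[3]
  expect_equal(rgb_to_od(img, I0)[2, 2, 3], 0)
})

test_that("unmixing inverts composition to machine precision (matrix oracle)", {
  stain <- stain_model()
  set.seed(9)
  c1 <- matrix(runif(600, 0, 1.5), 20, 30)
  c2 <- matrix(runif(600, 0, 1.5), 20, 30)
  odm <- cbind(as.numeric(c1), as.numeric(c2), 0) %*% stain$M
  od <- array(0, c(20, 30, 3))
  for (k in 1:3) od[, , k] <- matrix(odm[, k], 20, 30)
  conc <- unmix(od, stain, clamp = FALSE)
  expect_lt(max(abs(conc$dab - c1)), 1e-9)
  expect_lt(max(abs(conc$sg - c2)), 1e-9)
  expect_lt(max(abs(conc$residual)), 1e-9)
  # independent oracle: solve() per pixel
  oracle <- t(solve(t(stain$M), t(odm)))
  expect_lt(max(abs(oracle[, 1] - as.numeric(conc$dab))), 1e-9)
  # OD equal to one stain row gives a unit pulse on that stain
  od1 <- array(rep(stain$M[2, ], each = 4), c(2, 2, 3))
  u <- unmix(od1, stain)
  expect_equal(u$sg, matrix(1, 2, 2), tolerance = 1e-12)
  expect_equal(u$dab, matrix(0, 2, 2), tolerance = 1e-12)
  expect_error(unmix(od, matrix(1, 3, 3)), "singular")
})

test_that("pooled Otsu matches a brute-force between-class-variance oracle", {
  set.seed(4)
  vals <- c(rnorm(4000, 0.1, 0.02), rnorm(1000, 1, 0.05))
  thr <- otsu_threshold(vals)
  oracle <- oracle_otsu(vals)
  # same split of the sample
  expect_identical(vals > thr, vals > oracle)
  # two-level map with equal areas: mask is exactly the high level
  m <- matrix(c(rep(0.1, 50), rep(1, 50)), 10, 10)
  masks <- segment_parenchyma(list(m), matrix(TRUE, 10, 10))
  expect_identical(masks[[1]], m == 1)
})

test_that("parenchyma segmentation recovers phantom cytoplasm at zero noise", {
  gt <- fx_gt()
  res <- fx_res0()
  expect_gt(dice(res$parenchyma$grid, gt$cytoplasm), 0.95)
  # all-zero map segments to empty
  z <- matrix(0, 8, 8)
  expect_warning(m0 <- segment_parenchyma(list(z), matrix(FALSE, 8, 8)),
                 "empty tissue")
  expect_false(any(m0[[1]]))
})

test_that("cytoplasm recovery stays strong at default noise on all archetypes", {
  for (mode in c("PB", "TSC", "DS", "SF")) {
    spec <- phantom_spec(mode, grid = c(112, 112, 24),
                         focus_plan = list(c(18, 2)), seed = 31)
    gt <- build_phantom(spec)
    for (ns in c(0, gt$spec$noise_sd)) {
      st <- render_stack(gt, misalignment = c(0, 0), noise_sd = ns)
      res <- analyze_stack(st, core_diameter_um = gt$core_diameter_um,
                           register = FALSE)
      d <- dice(res$parenchyma$grid, gt$cytoplasm)
      if (ns == 0) expect_gt(d, 0.95) else expect_gt(d, 0.85)
    }
  }
})

test_that("Ki67+ segmentation covers true positive nucleus centroids", {
  gt <- fx_gt()
  res <- fx_res0()
  nt <- gt$nucleus_table
  pos <- nt[nt$ki67 == "pos", ]
  lab <- res$nuclei_pos$mask
  covered <- mean(lab[cbind(pmin(pmax(round(pos$y), 1), 112),
                            pmin(pmax(round(pos$x), 1), 112),
                            pmin(pmax(round(pos$z), 1), 18))])
  expect_gte(covered, 0.9)
})

test_that("negative-nucleus holes are detected per slice near truth", {
  gt <- fx_gt()
  res <- fx_res0()
  # 3D object count equals the true Ki67- count at zero noise
  expect_equal(nrow(res$nuclei_neg$records),
               sum(gt$nucleus_table$ki67 == "neg"))
  # constructed cases: solid disk has no candidates; one hole -> one candidate
  disk <- core_disk(40, 40, 30)
  expect_false(any(detect_negative_nuclei(disk, 0.92)))
  holed <- disk & !core_disk(40, 40, 6)
  cand <- detect_negative_nuclei(holed, 0.92)
  expect_equal(attr(label_components(cand, 8), "n_components"), 1)
  # bounds: an oversized hole is not a nucleus candidate
  big_hole <- disk & !core_disk(40, 40, 16)
  expect_false(any(detect_negative_nuclei(big_hole, 0.92)))
})

test_that("stroma is the exact set complement of parenchyma in tissue", {
  tissue <- core_disk(24, 24, 20)
  par <- tissue & core_disk(24, 24, 10)
  s <- stroma_mask(tissue, par)
  expect_identical(s | par, tissue)
  expect_false(any(s & par))
  expect_identical(stroma_mask(tissue, tissue), tissue & FALSE)
  expect_identical(stroma_mask(tissue, tissue & FALSE), tissue)
  expect_error(stroma_mask(par, tissue), "contained in tissue")
})

test_that("segmentation is invariant to a global intensity rescaling", {
  gt <- fx_gt()
  st <- fx_stack0()
  stain <- stain_model()
  s <- 0.8
  tissue <- core_disk(112, 112, gt$core_diameter_um / 0.92)
  maps1 <- lapply(st$images[5:8], function(im)
    unmix(rgb_to_od(im, stain$I0), stain)$dab)
  maps2 <- lapply(st$images[5:8], function(im)
    unmix(rgb_to_od(im * s, stain$I0 * s), stain)$dab)
  m1 <- segment_parenchyma(maps1, tissue)
  m2 <- segment_parenchyma(maps2, tissue)
  expect_identical(m1[1:4], m2[1:4])
})
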