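test_that("border area counts anisotropic faces exactly (hand counts)", {
  # a 1x1x4 um voxel alone in a stroma sea exposes 18 um^2
  d <- c(7, 7, 5)
  par <- array(FALSE, d)
  par[4, 4, 3] <- TRUE
  core <- matrix(TRUE, 7, 7)
  str <- array(core, d) & !par
  expect_equal(border_area(par, str, c(1, 1, 4)) * 1e6, 18)
  # two x-adjacent voxels share one 4 um^2 face: 2*18 - 2*4 = 28
  par[4, 5, 3] <- TRUE
  str <- array(core, d) & !par
  expect_equal(border_area(par, str, c(1, 1, 4)) * 1e6, 28)
  # faces against out-of-stack space are not counted
  par2 <- array(FALSE, d)
  par2[4, 4, 1] <- TRUE                   # voxel on the first slice
  str2 <- array(core, d) & !par2
  expect_equal(border_area(par2, str2, c(1, 1, 4)) * 1e6, 18 - 1)
  expect_error(border_area(par, par, c(1, 1, 4)), "disjoint")
})

test_that("border area agrees with a brute-force face-walking oracle", {
  set.seed(8)
  par <- array(runif(6 * 6 * 4) < 0.4, c(6, 6, 4))
  str <- !par
  vd <- c(0.92, 0.92, 4)
  expect_equal(border_area(par, str, vd) * 1e6,
               oracle_border_area_um2(par, str, vd))
})

test_that("digital-ball face-count area overestimates 4*pi*r^2 by ~1.5", {
  b <- digital_ball(20)
  ratio <- border_area(b, !b, c(1, 1, 1)) * 1e6 / (4 * pi * 20^2)
  expect_gte(ratio, 1.4)
  expect_lte(ratio, 1.6)
})

test_that("case morphometry fills the record with consistent ratios", {
  res <- fx_res0()
  r <- res$record
  expect_equal(r$v_parenchyma_mm3 + r$v_stroma_mm3, r$v_total_mm3,
               tolerance = 1e-12)
  expect_equal(r$parenchyma_pct, 100 * r$v_parenchyma_mm3 / r$v_total_mm3)
  expect_equal(r$s_over_vp_mm_inv, r$border_area_mm2 / r$v_parenchyma_mm3)
  expect_equal(r$ki67_density_1e4_per_mm3,
               r$n_ki67_parenchyma / r$v_parenchyma_mm3 / 1e4)
  expect_equal(r$foci_volume_pct,
               100 * sum(res$foci$volume_um3) / 1e9 / r$v_parenchyma_mm3)
})

test_that("empty parenchyma yields zero volumes and undefined ratios", {
  g <- array(FALSE, c(16, 16, 4))
  v <- apply_core_cylinder(
    stack_to_volume(lapply(1:4, function(z) g[, , z]), c(1, 1, 4)), 14)
  p <- partition_components(v)
  fs <- focus_stats(p, c(1, 1, 4))
  rec <- case_morphometry(v, p, fs)
  expect_equal(rec$v_parenchyma_mm3, 0)
  expect_equal(rec$n_foci, 0)
  expect_true(is.na(rec$s_over_vp_mm_inv))
  expect_true(is.na(rec$foci_volume_pct))
})

test_that("group summaries reproduce the published S/Vp means and SDs", {
  gs <- group_summary(reference_cases())
  get <- function(g, col) gs[gs$group == g, col]
  expect_equal(round(get("PB", "mean"), 1), 78.6)
  expect_equal(round(get("PB", "sd"), 1), 18.2)
  expect_equal(round(get("TSC", "mean"), 1), 81.6)
  expect_equal(round(get("TSC", "sd"), 1), 45.5)
  expect_lte(abs(get("DS", "mean") - 136.4), 0.1)
  expect_equal(round(get("DS", "sd"), 1), 40.6)
  expect_equal(get("PB", "n"), 5)
  expect_equal(get("TSC", "n"), 4)
  expect_equal(get("DS", "n"), 3)
  # a single-member group has an undefined SD
  one <- group_summary(data.frame(invasion_mode = "X", s_over_vp_mm_inv = 7))
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sd))
})

test_that("depth classes follow the strict <3 / 3-5 / >5 mm boundaries", {
  expect_equal(depth_class(2.9), "shallow")
  expect_equal(depth_class(3.0), "intermediate")
  expect_equal(depth_class(3.5), "intermediate")
  expect_equal(depth_class(5.0), "intermediate")
  expect_equal(depth_class(5.1), "deep")
  expect_equal(depth_class(NA), "NA")
  expect_error(depth_class(-1), "non-negative")
})

test_that("report writer emits consistent CSV tables and a manifest", {
  res <- fx_res0()
  rec <- res$record
  rec$case_id <- "P1"
  rec$invasion_mode <- "PB"
  rec$depth_mm <- 2.4
  rec$depth_class <- depth_class(2.4)
  out <- file.path(tempdir(), "tumor3d-report-test")
  write_reports(rec, list(P1 = res$foci), out, config = list(seed = 7))
  morph <- read.csv(file.path(out, "morphometry.csv"))
  expect_equal(morph$v_total_mm3, round(rec$v_total_mm3, 2))
  expect_equal(morph$s_over_vp_mm_inv, round(rec$s_over_vp_mm_inv, 1))
  hist <- read.csv(file.path(out, "size_histogram.csv"), check.names = FALSE)
  expect_equal(nrow(hist), 11)            # 10 bins + totals row
  body <- hist[1:10, ]
  expect_equal(as.integer(hist$P1[11]), sum(as.integer(body$P1)))
  expect_equal(as.integer(body$Total), as.integer(body$P1))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  # empty record list: header-only tables
  out2 <- file.path(tempdir(), "tumor3d-report-empty")
  write_reports(rec[0, ], list(), out2)
  expect_equal(nrow(read.csv(file.path(out2, "morphometry.csv"))), 0)
})

test_that("masks, volumes and nucleus tables persist to disk and read back", {
  res <- fx_res0()
  m <- lapply(1:3, function(z) res$parenchyma$grid[, , z])
  dir <- file.path(tempdir(), "tumor3d-io-test")
  write_masks(m, dir)
  back <- read_masks(dir)
  expect_identical(back, m)
  vpath <- file.path(dir, "labels.tif")
  write_volume_tiff(res$parenchyma, vpath)
  expect_true(file.exists(vpath))
  npath <- file.path(dir, "nuclei.csv")
  write_nuclei(res$nuclei_pos, npath, ki67 = "pos")
  df <- read.csv(npath)
  expect_equal(nrow(df), nrow(res$nuclei_pos$records))
  expect_true(all(df$slice_span >= 2))
})
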