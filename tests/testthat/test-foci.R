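# helper: wrap a logical grid as an in-core voxel_volume
as_vol <- function(grid, vd = c(1, 1, 4), core_diameter = NULL) {
  v <- stack_to_volume(lapply(seq_len(dim(grid)[3]), function(z) grid[, , z]),
                       vd)
  if (!is.null(core_diameter)) v <- apply_core_cylinder(v, core_diameter)
  v
}

test_that("partition separates bulk, interior foci and boundary contacts", {
  g <- array(FALSE, c(30, 30, 10))
  g[10:20, 10:20, 1:4] <- TRUE            # blob touching the bottom plane
  g[24:26, 24:26, 6:7] <- TRUE            # interior sphere-ish focus
  p <- partition_components(as_vol(g))
  expect_equal(length(p$bulk_ids), 1)
  expect_equal(length(p$focus_ids), 1)
  expect_equal(length(p$boundary_excluded_ids), 0)
  # disjoint cover of all components
  all_ids <- sort(c(p$bulk_ids, p$focus_ids, p$boundary_excluded_ids))
  expect_equal(all_ids, seq_along(p$sizes))

  # a component touching the lateral core margin by one voxel is excluded
  g2 <- array(FALSE, c(30, 30, 10))
  g2[14:16, 27:29, 4:6] <- TRUE           # touches the rim of a 28-px core
  g2[14:16, 14:16, 4:6] <- TRUE           # interior control
  v2 <- as_vol(g2, core_diameter = 28)
  p2 <- partition_components(v2)
  expect_equal(length(p2$focus_ids), 1)
  expect_equal(length(p2$bulk_ids) + length(p2$boundary_excluded_ids), 1)
  # empty parenchyma: empty partition
  p0 <- partition_components(as_vol(array(FALSE, c(8, 8, 3))))
  expect_equal(length(p0$sizes), 0)
})

test_that("adding an interior detached component never decreases foci count", {
  g <- array(FALSE, c(30, 30, 10))
  g[10:20, 10:20, 1:4] <- TRUE
  n0 <- length(partition_components(as_vol(g))$focus_ids)
  g[5:7, 22:24, 6:7] <- TRUE
  n1 <- length(partition_components(as_vol(g))$focus_ids)
  g[24:26, 5:7, 7:8] <- TRUE
  n2 <- length(partition_components(as_vol(g))$focus_ids)
  expect_equal(c(n0, n1, n2), c(0, 1, 2))
})

test_that("detachment flag is true for separated foci and never reclassifies", {
  gt <- fx_gt()
  p <- gt$truth_report$partition
  flags <- validate_detachment(p)
  expect_true(all(flags))
  # a focus one empty voxel from bulk diagonally: still 26-disconnected,
  # dilation test confirms detachment, and it stays counted
  g <- array(FALSE, c(20, 20, 8))
  g[5:10, 5:10, 1:3] <- TRUE
  g[12, 12, 5] <- TRUE                    # Chebyshev distance 2 from bulk
  g[12:13, 12:13, 5:6] <- TRUE
  p2 <- partition_components(as_vol(g))
  expect_equal(length(p2$focus_ids), 1)
  expect_true(all(validate_detachment(p2)))
})

test_that("equivalent sphere diameter follows the closed form", {
  expect_equal(equivalent_diameter(4188.79), 20, tolerance = 1e-4)
  expect_equal(equivalent_diameter(0.92 * 0.92 * 4),
               (6 * 3.3856 / pi)^(1 / 3))
  expect_equal(round(equivalent_diameter(0.92 * 0.92 * 4), 2), 1.86)
  # digital ball: equivalent diameter within 1 voxel of 2r for r >= 5
  for (r in c(5, 8, 12, 20)) {
    b <- digital_ball(r)
    d <- equivalent_diameter(sum(b))
    expect_lt(abs(d - 2 * r), 1)
  }
})

test_that("per-focus statistics count nuclei by centroid membership", {
  g <- array(FALSE, c(24, 24, 10))
  g[4:10, 4:10, 1:3] <- TRUE              # bulk at bottom plane
  g[14:18, 14:18, 5:7] <- TRUE            # focus
  v <- as_vol(g, vd = c(0.92, 0.92, 4))
  p <- partition_components(v)
  pos <- data.frame(x = c(16, 5), y = c(16, 5), z = c(6, 2),
                    compartment = "parenchyma")
  neg <- data.frame(x = c(15, 17), y = c(15.2, 16), z = c(5.4, 6.6),
                    compartment = "parenchyma")
  fs <- focus_stats(p, c(0.92, 0.92, 4), pos, neg)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$n_ki67_pos, 1)          # the bulk nucleus is not in the focus
  expect_equal(fs$n_ki67_neg, 2)
  expect_equal(fs$volume_um3, fs$voxel_count * 0.92 * 0.92 * 4)
  expect_equal(fs$equivalent_diameter_um,
               (6 * fs$volume_um3 / pi)^(1 / 3))
  expect_true(fs$detachment_confirmed)
})

test_that("size histogram rounds then bins into the standard classes", {
  h <- size_histogram(c(15.4, 20.4, 20.6, 25.4, 50.4, 50.6, 200.4, 201.6))
  expect_equal(sum(h), 8)
  expect_equal(unname(h["<16"]), 1)       # 15.4 -> 15
  expect_equal(unname(h["16-20"]), 1)     # 20.4 -> 20
  expect_equal(unname(h["21-25"]), 2)     # 20.6 -> 21, 25.4 -> 25
  expect_equal(unname(h["46-50"]), 1)     # 50.4 -> 50
  expect_equal(unname(h["51-200"]), 2)    # 50.6 -> 51, 200.4 -> 200
  expect_equal(unname(h[">200"]), 1)      # 201.6 -> 202
  # partition identity on the fixture
  res <- fx_res0()
  expect_equal(sum(res$size_histogram), nrow(res$foci))
})

test_that("planted focus count and sizes are recovered exactly at zero noise", {
  gt <- fx_gt()
  res <- fx_res0()
  expect_equal(res$record$n_foci, max(gt$focus_label))
  # recovered equivalent diameters near the planted 18 um
  expect_true(all(abs(res$foci$equivalent_diameter_um - 18) < 2.5))
})
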