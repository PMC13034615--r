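test_that("equivolume depth matches the closed form and beats equidistant on the shell", {
  rib <- fx_depth_shell()
  dv <- compute_depth(rib$seg, "equivolume")
  de <- compute_depth(rib$seg, "equidistant")
  gm <- which(!is.na(rib$depth_truth))
  truth <- as.numeric(rib$depth_truth)[gm]
  err_v <- abs(as.numeric(dv)[gm] - truth)
  err_e <- abs(as.numeric(de)[gm] - truth)
  expect_lt(max(err_v), 0.03)
  # the curvature correction must do something: the equidistant metric shows
  # its known curvature bias
  expect_lt(mean(err_v), mean(err_e))
  # spec'd mid-shell example: r = 11 -> alpha ~ 23/44
  r <- as.numeric(rib$radius)[gm]
  mid <- abs(r - 11) < 0.1
  expect_equal(mean(as.numeric(dv)[gm][mid]), 23 / 44, tolerance = 0.03)
  # boundary contract
  expect_lt(mean(as.numeric(dv)[gm][r > 11.9]), 0.1)
  expect_gt(mean(as.numeric(dv)[gm][r < 10.1]), 0.9)
})

test_that("equivolume reduces to equidistant on the flat slab", {
  sl <- fx_slab()
  de <- compute_depth(sl$seg, "equidistant")
  gm <- which(!is.na(sl$depth_truth))
  expect_lt(max(abs(as.numeric(sl$depth)[gm] - as.numeric(de)[gm])), 0.02)
  expect_lt(max(abs(as.numeric(sl$depth)[gm] -
                      as.numeric(sl$depth_truth)[gm])), 0.02)
})

test_that("layer bins partition gray matter with the stated index rule", {
  sl <- fx_slab()
  l3 <- bin_layers(sl$depth, 3)
  gm <- which(!is.na(sl$depth))
  expect_true(all(!is.na(as.numeric(l3)[gm])))
  expect_true(all(is.na(as.numeric(l3)[-gm])))
  expect_true(all(as.numeric(l3)[gm] %in% 1:3))
  # index rule: ceil(alpha * n), clamped
  d <- vol3d(array(c(0.5, 0, 1, NA), dim = c(4, 1, 1)), 1)
  l <- bin_layers(d, 3)
  expect_equal(as.numeric(l)[1:3], c(2, 1, 3))
  l11 <- bin_layers(d, 11)
  expect_equal(as.numeric(l11)[2:3], c(1, 11))
  # near-equal occupancy for uniform depth values
  tab <- table(as.numeric(bin_layers(sl$depth, 11))[gm])
  expect_equal(length(tab), 11L)
  expect_lte(max(tab) / min(tab), 1.2)
})

test_that("geodesic distances match collinear, diagonal and Dijkstra oracles", {
  # straight corridor of 0.5 mm voxels
  m <- array(FALSE, dim = c(12, 3, 3)); m[1:11, 2, 2] <- TRUE
  g <- geodesic_distance(m, c(1, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(g[11, 2, 2], 5)
  # diagonal neighbour at unit voxels
  m2 <- array(TRUE, dim = c(2, 2, 2))
  g2 <- geodesic_distance(m2, c(1, 1, 1), c(1, 1, 1))
  expect_equal(g2[2, 2, 2], sqrt(3))
  # L-shaped corridor around a notch equals the independent Dijkstra
  mL <- array(FALSE, dim = c(7, 7, 3))
  mL[1:7, 1, 2] <- TRUE; mL[7, 1:7, 2] <- TRUE
  gL <- geodesic_distance(mL, c(1, 1, 2), c(1, 1, 1))
  oL <- dijkstra_oracle(mL, c(1, 1, 2), c(1, 1, 1))
  expect_equal(as.numeric(gL)[which(mL)], oL[which(mL)])
  # random masks, anisotropic voxels: exact agreement with the oracle
  set.seed(99)
  h <- c(0.7, 0.7, 1.3)
  for (i in 1:5) {
    mm <- array(stats::runif(6 * 6 * 4) < 0.7, dim = c(6, 6, 4))
    mm[3, 3, 2] <- TRUE
    gg <- geodesic_distance(mm, c(3, 3, 2), h)
    oo <- dijkstra_oracle(mm, c(3, 3, 2), h)
    sel <- which(mm)
    expect_equal(as.numeric(gg)[sel], oo[sel], tolerance = 1e-12)
  }
  expect_error(geodesic_distance(m, c(12, 2, 2), c(0.5, 0.5, 0.5)),
               "outside the mask")
  # geodesic >= Euclidean everywhere
  sel <- which(mL)
  pos <- vasomap:::voxel_coords_mm(vasomap:::linear_to_triple(sel, dim(mL)),
                                   c(1, 1, 1))
  eu <- sqrt(rowSums(sweep(pos, 2, pos[1, ])^2))
  expect_true(all(as.numeric(gL)[sel] >= eu - 1e-9))
})

test_that("geodesic disks cover the expected arc and degenerate radii behave", {
  rib <- fx_depth_shell()
  depth <- compute_depth(rib$seg)
  d <- dim(depth)
  # seed at mid-depth, mid-angle
  gm_idx <- which(!is.na(depth))
  r <- as.numeric(rib$radius)[gm_idx]
  th <- as.numeric(rib$theta)[gm_idx]
  seed_i <- gm_idx[which.min(abs(r - 11) + abs(th - pi / 4))]
  seed <- as.integer(vasomap:::linear_to_triple(seed_i, d))
  disk <- make_disk(depth, seed, radius_mm = 6)
  di <- which(as.logical(disk))
  expect_gt(length(di), 0)
  # arc reach: geodesic radius 6 mm at mid-depth r~11 spans ~ +-31 deg
  thd <- as.numeric(rib$theta)[di] * 180 / pi
  expect_equal(max(thd) - min(thd), 2 * (6 / 11) * 180 / pi, tolerance = 8)
  # disk spans all depths over its patch
  expect_gt(max(as.numeric(depth)[di]), 0.9)
  expect_lt(min(as.numeric(depth)[di]), 0.1)
  # huge radius covers the whole connected gray matter
  all_disk <- make_disk(depth, seed, radius_mm = 1e3)
  expect_equal(sort(which(as.logical(all_disk))), sort(gm_idx))
  expect_error(make_disk(depth, c(1, 1, 1)), "not in gray matter")
})

test_that("Euclidean distance bins are half-open 2 mm bins within the mask", {
  m <- array(TRUE, dim = c(31, 1, 1))
  mv <- vol3d(array(1, dim = dim(m)), 1) > 0
  attr(mv, "voxel_mm") <- c(1, 1, 1)
  bins <- euclidean_distance_bins(structure(m, voxel_mm = c(1, 1, 1)),
                                  c(1, 1, 1))
  v <- as.numeric(bins)
  # voxel 5 is 4.0 mm away -> bin 3 ([4,6)); voxel 4 is 3 mm -> bin 2
  expect_equal(v[4], 2)
  expect_equal(v[5], 3)
  # 14 mm and beyond unassigned (half-open upper edge)
  expect_true(all(is.na(v[15:31])))
  expect_equal(sort(unique(stats::na.omit(v))), 1:7)
  expect_error(
    euclidean_distance_bins(structure(array(FALSE, dim = c(2, 2, 2)),
                                      voxel_mm = c(1, 1, 1)), c(1, 1, 1)),
    "outside the mask")
})

test_that("depth increases monotonically along sampled columns", {
  sl <- fx_slab()
  d <- dim(sl$depth)
  # slab columns are vertical: depth decreases with k (CSF above)
  gmz <- which(!is.na(sl$depth[10, 10, ]))
  expect_true(all(diff(as.numeric(sl$depth[10, 10, gmz])) < 0))
  rib <- fx_depth_shell()
  dv <- compute_depth(rib$seg)
  col <- column_field(dv)
  # step from a mid voxel along its column direction: depth must increase
  gm_idx <- which(!is.na(dv))
  set.seed(4)
  for (i in sample(gm_idx, 25)) {
    trip <- as.integer(vasomap:::linear_to_triple(i, dim(dv)))
    dir <- col[trip[1], trip[2], trip[3], ]
    if (anyNA(dir)) next
    p <- vasomap:::voxel_coords_mm(matrix(trip, 1), attr(dv, "voxel_mm")) +
      0.6 * dir
    vi <- floor(p / attr(dv, "voxel_mm")) + 1
    if (any(vi < 1) || any(vi > dim(dv))) next
    nxt <- dv[vi[1], vi[2], vi[3]]
    if (!is.na(nxt))
      expect_gte(nxt, dv[trip[1], trip[2], trip[3]] - 0.05)
  }
})
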