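test_that("ribbon truth depth follows the closed-form annulus solution", {
  rib <- fx_depth_shell()
  gm <- which(!is.na(rib$depth_truth))
  r <- as.numeric(rib$radius)[gm]
  expect_equal(as.numeric(rib$depth_truth)[gm],
               (12^2 - r^2) / (12^2 - 10^2), tolerance = 1e-12)
  # a mid-shell voxel at r = 11 carries alpha = 23/44
  mid <- gm[abs(r - 11) < 1e-6]
  if (length(mid))
    expect_equal(as.numeric(rib$depth_truth)[mid[1]], 23 / 44)
  # boundary values
  expect_true(all(as.numeric(rib$depth_truth)[gm][r > 11.99] < 0.01))
  expect_true(all(as.numeric(rib$depth_truth)[gm][r < 10.01] > 0.99))
  # closed form vs a numerical equal-volume binning of the annulus
  rr <- seq(10, 12, length.out = 20001)
  vol <- cumsum(rr * c(0, diff(rr)))           # ~ integral of r dr
  alpha_num <- 1 - vol / vol[length(vol)]
  i <- findInterval(r, rr)
  expect_lt(max(abs(as.numeric(rib$depth_truth)[gm] - alpha_num[i])), 1e-3)
})

test_that("ribbon segmentation uses the four-code convention and rejects bad geometry", {
  rib <- fx_depth_shell()
  expect_true(all(as.numeric(rib$seg) %in% 0:3))
  expect_error(build_ribbon(phantom_spec(shape = c(10, 10, 5), voxel_mm = 0.5)),
               "exceeds the domain")
  expect_error(phantom_spec(r_inner_mm = 12, r_outer_mm = 10), "r_inner")
})

test_that("digit painting respects profiles, truth bins and amplitude zeroing", {
  spec <- phantom_spec(seed = 2)
  rib <- build_ribbon(spec)
  truth <- paint_digits(rib, spec)
  a <- as.numeric(truth$amp_bold$D3)
  al <- as.numeric(truth$depth_truth)
  gm <- which(!is.na(a))
  # nonzero amplitude only in gray matter
  expect_true(all(which(!is.na(a) & a != 0) %in% which(rib$seg == 2L)))
  # linear-to-surface: amplitude at the patch centre decreases with depth
  pk <- truth$peak_voxel$D3
  ctr <- gm[order(-a[gm])[1:30]]
  expect_lt(stats::cor(al[ctr], a[ctr]), 0)
  # default triphasic contract: A1 strictly decreasing, A2 strictly
  # increasing over bins 3..7
  tri <- default_triphasic()
  expect_true(all(diff(tri$A1[3:7]) < 0))
  expect_true(all(diff(tri$A2[3:7]) > 0))
  # zero amplitudes give identically zero maps
  spec0 <- phantom_spec(bold_amp_max = 0, bold_amp_floor = 0,
                        cbv_amp_max = 0, cbv_amp_floor = 0, seed = 2)
  truth0 <- paint_digits(build_ribbon(spec0), spec0)
  expect_true(all(as.numeric(truth0$amp_bold$D2)[gm] == 0))
  # distance bins are the half-open 2 mm bins from the peak voxel
  b <- as.numeric(truth$dist_bin$D3)
  h <- attr(truth$seg, "voxel_mm")
  pk_mm <- vasomap:::voxel_coords_mm(matrix(pk, 1), h)
  mm <- vasomap:::voxel_coords_mm(
    vasomap:::linear_to_triple(gm, dim(truth$seg)), h)
  dist <- sqrt(rowSums(sweep(mm, 2, as.numeric(pk_mm))^2))
  expect_equal(b[gm][dist < 13.9], floor(dist[dist < 13.9] / 2) + 1)
  expect_true(all(is.na(b[gm][dist >= 14])))
})

test_that("simulated runs are seed-reproducible and obey the signal model", {
  spec <- suppressWarnings(phantom_spec(shape = c(29, 29, 13), voxel_mm = 0.5,
                                        n_blocks_per_digit = 2, seed = 3))
  rib <- build_ribbon(spec)
  truth <- paint_digits(rib, spec)
  des <- make_stim_design(spec, 1)
  r1 <- simulate_run(truth, des, spec, seed = 9)
  r2 <- simulate_run(truth, des, spec, seed = 9)
  r3 <- simulate_run(truth, des, spec, seed = 10)
  expect_identical(as.numeric(r1$interleaved), as.numeric(r2$interleaved))
  expect_false(identical(as.numeric(r1$interleaved), as.numeric(r3$interleaved)))

  # zero noise, zero amplitude: flat baselines
  spec0 <- suppressWarnings(phantom_spec(shape = c(29, 29, 13), voxel_mm = 0.5,
                        n_blocks_per_digit = 2, bold_amp_max = 0,
                        bold_amp_floor = 0, cbv_amp_max = 0, cbv_amp_floor = 0,
                        triphasic = transform(default_triphasic(),
                                              A1 = 0, A2 = 0, A3 = 0),
                        noise_sd_bold = 0, noise_sd_nulled = 0, seed = 3))
  truth0 <- paint_digits(build_ribbon(spec0), spec0)
  r0 <- simulate_run(truth0, make_stim_design(spec0, 1), spec0, seed = 1)
  expect_equal(range(as.numeric(r0$bold)), c(1000, 1000))
  expect_equal(range(as.numeric(r0$nulled)), c(800, 800))

  # multiplicative model: nulled / bold recovers (1 - v) exactly
  spec_v <- suppressWarnings(phantom_spec(shape = c(29, 29, 13), voxel_mm = 0.5,
                        n_blocks_per_digit = 2, noise_sd_bold = 0,
                        noise_sd_nulled = 0, seed = 3))
  truth_v <- paint_digits(build_ribbon(spec_v), spec_v)
  rv <- simulate_run(truth_v, make_stim_design(spec_v, 1), spec_v, seed = 1)
  ratio <- as.numeric(rv$nulled) / as.numeric(rv$bold) * 1000 / 800
  expect_true(all(ratio <= 1 + 1e-12))
  expect_lt(min(ratio), 1 - 0.005)   # CBV response present somewhere
})

test_that("stimulation designs are block-structured without digit repeats", {
  spec <- phantom_spec(seed = 21)
  for (r in 1:3) {
    des <- make_stim_design(spec, r)
    expect_equal(nrow(des), 12L)
    expect_equal(sort(unique(des$trial_type)), c("D2", "D3", "D4"))
    expect_true(all(table(des$trial_type) == 4L))
    expect_true(all(diff(des$onset) == 60))
    expect_true(all(des$trial_type[-1] != des$trial_type[-12]))
  }
})

test_that("slab phantom has uniform depth planes with known values", {
  sl <- build_slab()
  expect_true(all(as.numeric(sl$seg) %in% 0:3))
  gm <- which(!is.na(sl$depth_truth))
  vals <- sort(unique(round(as.numeric(sl$depth_truth)[gm], 10)))
  expect_equal(vals, (2 * (1:11) - 1) / 22)
})
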