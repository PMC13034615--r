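test_that("interleaved splitting separates contrasts and validates parity", {
  x <- array(0, dim = c(1, 1, 1, 8))
  x[1, 1, 1, ] <- c(10, 100, 11, 101, 12, 102, 13, 103)  # n0 b0 n1 b1 ...
  run <- series4d(x, 1, tr_s = 1.925, contrast = "nulled")
  parts <- split_interleaved(run)
  expect_equal(as.numeric(parts$nulled[1, 1, 1, ]), c(10, 11, 12, 13))
  expect_equal(as.numeric(parts$bold[1, 1, 1, ]), c(100, 101, 102, 103))
  expect_equal(series_tr(parts$nulled), 3.85)
  expect_equal(series_t0(parts$bold), 1.925)
  odd <- series4d(array(1, dim = c(1, 1, 1, 7)), 1, tr_s = 1, contrast = "nulled")
  expect_error(split_interleaved(odd), "odd number")
})

test_that("non-steady-state volumes are replaced by volumes four to six", {
  s <- series_from_vec(c(1, 2, 3, 4, 5, 6, 7))
  out <- replace_nonsteady(s)
  expect_equal(as.numeric(out[1, 1, 1, ]), c(4, 5, 6, 4, 5, 6, 7))
  steady <- series_from_vec(c(4, 5, 6, 4, 5, 6, 7))
  expect_equal(as.numeric(replace_nonsteady(steady)),
               as.numeric(steady))
  expect_error(replace_nonsteady(series_from_vec(1:5)), "at least 6")
})

test_that("temporal upsampling is exact on polynomials and keeps originals", {
  # constant
  cst <- upsample_temporal(series_from_vec(rep(3, 10), tr = 2))
  expect_equal(as.numeric(cst), rep(3, 20))
  expect_equal(series_tr(cst), 1)
  # linear ramp: midpoints exactly between
  ramp <- upsample_temporal(series_from_vec(0:9, tr = 2))
  expect_equal(as.numeric(ramp)[2], 0.5)
  expect_equal(as.numeric(ramp)[11], 5)
  # degree-7 polynomial at an interior midpoint
  f <- function(t) (t / 5)^7 - 3 * (t / 5)^3 + 2
  s <- series_from_vec(f(0:23), tr = 2)
  up <- upsample_temporal(s, 2)
  expect_equal(up[1, 1, 1, 22], f(10.5), tolerance = 1e-9)
  expect_equal(as.numeric(up)[seq(1, 47, 2)], f(0:23))
  expect_error(upsample_temporal(series_from_vec(1:7)), "at least 8")
})

test_that("nulled/BOLD alignment follows the declared platform convention", {
  nulled <- series_from_vec(c(1, 2, 3), contrast = "nulled")
  bold <- series_from_vec(c(10, 20, 30), contrast = "bold", t0 = 1)
  vb <- align_nulled_bold(nulled, bold, "VB17")
  expect_equal(as.numeric(vb$nulled), c(1, 1, 2))
  expect_equal(dim(vb$nulled)[4], dim(vb$bold)[4])
  ve <- align_nulled_bold(nulled, bold, "VE")
  expect_equal(as.numeric(ve$bold), c(10, 10, 20))
  no <- align_nulled_bold(nulled, bold, "none")
  expect_equal(as.numeric(no$bold), c(10, 20, 30))
  expect_equal(series_t0(no$bold), series_t0(nulled))
  empty <- series4d(array(0, dim = c(1, 1, 1, 1)), 1, tr_s = 1,
                    contrast = "nulled")
  expect_error(align_nulled_bold(empty[, , , 0, drop = FALSE], bold),
               regexp = ".")
})

test_that("dynamic division recovers the ratio and guards small denominators", {
  v <- c(1, 0.98, 0.95, 1)
  b <- c(1000, 990, 1010, 1000)
  nulled <- series_from_vec(v * b, contrast = "nulled")
  bold <- series_from_vec(b, contrast = "bold")
  vaso <- bold_correct(nulled, bold)
  expect_equal(as.numeric(vaso), v, tolerance = 1e-12)
  expect_equal(series_contrast(vaso), "vaso")
  # nulled == bold -> ratio 1
  same <- bold_correct(bold, bold)
  expect_true(all(as.numeric(same) == 1))
  # zero denominator masked, no error
  b0 <- series_from_vec(c(1000, 0, 1000, 1000), contrast = "bold")
  out <- bold_correct(nulled, b0)
  expect_true(is.na(as.numeric(out)[2]))
  expect_true(all(!is.na(as.numeric(out)[-2])))
})

test_that("T1-weighted EPI is the inverse variation coefficient", {
  n2 <- series_from_vec(c(1, 3), contrast = "nulled")
  t1 <- compute_t1w_epi(n2, n2)          # concatenated 1,3,1,3
  expect_equal(t1[1, 1, 1], 2 / stats::sd(c(1, 3, 1, 3)))
  # scale invariance
  n2c <- series_from_vec(5 * c(1, 3), contrast = "nulled")
  expect_equal(compute_t1w_epi(n2c, n2c)[1, 1, 1], t1[1, 1, 1])
  # zero variance masked
  flat <- series_from_vec(rep(2, 4), contrast = "nulled")
  expect_true(is.na(compute_t1w_epi(flat, flat)[1, 1, 1]))
})

test_that("tSNR approaches mean/sd for long Gaussian series", {
  set.seed(1)
  mu <- 100; sigma <- 5
  s <- series_from_vec(stats::rnorm(10000, mu, sigma))
  expect_equal(compute_tsnr(s)[1, 1, 1], mu / sigma, tolerance = 0.05)
  # constant voxel masked
  expect_true(is.na(compute_tsnr(series_from_vec(rep(7, 20)))[1, 1, 1]))
  # linear trend removed by default
  tr <- series_from_vec(mu + 0.5 * (1:2000) + stats::rnorm(2000, 0, sigma))
  expect_gt(compute_tsnr(tr)[1, 1, 1], 10)
})

test_that("framewise displacement combines translations and scaled rotations", {
  m <- tibble::tibble(tx = c(0, 0.1, 0.1, 0.1), ty = c(0, 0.1, 0.1, 0.1),
                      tz = c(0, 0.1, 0.1, 0.1), rx = c(0, 0, 0.001, 0.001),
                      ry = 0, rz = 0)
  fd <- framewise_displacement(m)
  expect_equal(fd$fd_mm, c(0, 0.3, 0.05, 0))
  expect_true(all(framewise_displacement(
    tibble::tibble(a = rep(1, 5), b = 1, c = 1, d = 1, e = 1, f = 1))$fd_mm == 0))
  expect_error(framewise_displacement(m[, 1:4]), "6")
})

test_that("decimation inverts upsampling on the original sample grid", {
  s <- series_from_vec(stats::rnorm(20), tr = 3.85)
  up <- upsample_temporal(s, 2)
  down <- decimate_temporal(up, 2)
  expect_equal(as.numeric(down), as.numeric(s))
  expect_equal(series_tr(down), 3.85)
})

test_that("preprocessing is scale-consistent", {
  run <- fx_noiseless_study()$runs[[1]]$interleaved
  small <- series4d(array(run[1:8, 1:8, 1:4, 1:40], dim = c(8, 8, 4, 40)),
                    attr(run, "voxel_mm"), tr_s = series_tr(run),
                    contrast = "nulled")
  scaled <- series4d(3 * array(small, dim = dim(small)),
                     attr(run, "voxel_mm"), tr_s = series_tr(run),
                     contrast = "nulled")
  p1 <- preprocess_run(small, platform = "none")
  p2 <- preprocess_run(scaled, platform = "none")
  expect_equal(as.numeric(p2$vaso), as.numeric(p1$vaso), tolerance = 1e-12)
  expect_equal(as.numeric(p2$qc$tsnr_bold), as.numeric(p1$qc$tsnr_bold),
               tolerance = 1e-12)
  expect_equal(as.numeric(p2$qc$t1w_epi), as.numeric(p1$qc$t1w_epi),
               tolerance = 1e-12)
})
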