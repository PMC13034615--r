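test_that("gamma response has the stated shape, mean lag and mode", {
  # mean k*theta = 6 and sd sqrt(k)*theta = 3 imply theta = 1.5, k = 4
  h <- make_hrf(0.01)
  t <- seq(0, 32, by = 0.01)
  expect_equal(sum(t * h) / sum(h), 6, tolerance = 0.05)
  expect_equal(t[which.max(h)], 4.5, tolerance = 0.02)  # mode (k-1)*theta
  expect_equal(max(h), 1)
  # the sampled kernel at the analysis TR keeps the mean lag
  h2 <- make_hrf(1.925)
  t2 <- seq(0, 32, by = 1.925)
  expect_equal(sum(t2 * h2) / sum(h2), 6, tolerance = 0.25)
})

test_that("design matrices carry conditions, drift, motion and spikes", {
  des <- tibble::tibble(trial_type = c("D2", "D3"), onset = c(20, 80),
                        duration = 30)
  set.seed(31)
  mot <- tibble::tibble(tx = stats::rnorm(150, 0, 0.01),
                        ty = stats::rnorm(150, 0, 0.01),
                        tz = stats::rnorm(150, 0, 0.01),
                        rx = stats::rnorm(150, 0, 1e-4),
                        ry = stats::rnorm(150, 0, 1e-4),
                        rz = stats::rnorm(150, 0, 1e-4),
                        outlier = seq_len(150) == 7)
  X <- build_design(des, n_vol = 150, tr_s = 2, motion = mot)
  expect_equal(X$conditions, c("D2", "D3"))
  # 300 s at 0.01 Hz -> floor(2 * 300 * 0.01) = 6 cosines
  expect_equal(sum(grepl("^drift_", colnames(X$X))), 6L)
  expect_true("spike_7" %in% colnames(X$X))
  expect_equal(which(X$X[, "spike_7"] == 1), 7L)
  # no events in a condition column -> zeros
  des0 <- tibble::tibble(trial_type = "D2", onset = 1000, duration = 30)
  X0 <- build_design(des0, n_vol = 50, tr_s = 2)
  expect_true(all(X0$X[, "D2"] == 0))
  # collinear columns rejected
  mot_bad <- mot
  mot_bad$ty <- mot_bad$tx
  expect_error(build_design(des, n_vol = 150, tr_s = 2, motion = mot_bad),
               "rank deficient")
})

test_that("OLS betas match a brute-force normal-equations solve", {
  set.seed(8)
  for (i in 1:3) {
    n <- 40
    X <- cbind(1, stats::rnorm(n), stats::rnorm(n))
    Y <- X %*% c(2, -1, 0.5) + stats::rnorm(n, 0, 0.3)
    s <- series_from_vec(as.numeric(Y))
    dsn <- structure(list(X = X, conditions = "c1", tr_s = 1,
                          frame_times = seq_len(n)), class = "vaso_design")
    colnames(dsn$X) <- c("c1", "i", "x")
    maps <- fit_glm(s, dsn, list(contrast("c1", c(c1 = 1))))
    bf <- solve(t(X) %*% X, t(X) %*% Y)
    expect_equal(maps[[1]]$beta[1, 1, 1], bf[1], tolerance = 1e-10)
  }
})

test_that("t statistics convert to well-known normal quantiles", {
  expect_equal(vasomap:::t_to_z(2.042, 30), 1.96, tolerance = 0.005)
  expect_equal(vasomap:::t_to_z(-2.042, 30), -1.96, tolerance = 0.005)
  expect_equal(vasomap:::t_to_z(0, 10), 0)
  # perfect fit: capped at |z| = 40, not infinite
  s <- series_from_vec(c(rep(0, 10), rep(1, 10)))
  X <- cbind(cond = c(rep(0, 10), rep(1, 10)), intercept = 1)
  dsn <- structure(list(X = X, conditions = "cond", tr_s = 1,
                        frame_times = 1:20), class = "vaso_design")
  maps <- fit_glm(s, dsn, list(contrast("cond", c(cond = 1))))
  expect_equal(maps[[1]]$beta[1, 1, 1], 1, tolerance = 1e-10)
  expect_lte(abs(maps[[1]]$z[1, 1, 1]), 40)
})

test_that("fixed effects combine runs by inverse variance", {
  mk <- function(beta, var) {
    v <- function(x) vol3d(array(x, dim = c(2, 1, 1)), 1)
    structure(list(name = "c", beta = v(beta), var = v(var),
                   t = v(beta / sqrt(var)), z = v(beta / sqrt(var)), df = 100),
              class = "vaso_statmap")
  }
  a <- mk(c(2, 1), c(0.25, 1))
  fe <- fixed_effects(list(a, a))
  # two identical runs: combined z = sqrt(2) x single-run z (normal reference)
  expect_equal(as.numeric(fe$z), sqrt(2) * as.numeric(a$beta) /
                 sqrt(as.numeric(a$var)), tolerance = 1e-10)
  expect_equal(as.numeric(fe$var), as.numeric(a$var) / 2)
  # single run: identity
  expect_identical(fixed_effects(list(a)), a)
  # masked voxels excluded from the sums
  b <- mk(c(NA, 1), c(NA, 1))
  fe2 <- fixed_effects(list(a, b))
  expect_equal(fe2$beta[1, 1, 1], 2)      # only run a contributes
  expect_equal(fe2$var[2, 1, 1], 0.5)
  other <- mk(c(1, 1), c(1, 1))
  other$beta <- vol3d(array(1, dim = c(3, 1, 1)), 1)
  expect_error(fixed_effects(list(a, other)), "same grid")
})

test_that("FDR thresholding matches brute-force step-up enumeration", {
  # spec'd example: thresholds are q*k/m = 1/3000, 2/3000, 3/3000
  expect_equal(fdr_threshold(c(0.0001, 0.0002, 0.5), q = 0.001),
               c(TRUE, TRUE, FALSE))
  expect_false(any(fdr_threshold(rep(1, 20), 0.001)))
  expect_true(all(fdr_threshold(rep(0, 20), 0.001)))
  set.seed(123)
  for (i in 1:100) {
    p <- stats::runif(sample(5:60, 1))^sample(1:3, 1)
    q <- sample(c(0.001, 0.01, 0.05, 0.2), 1)
    expect_identical(fdr_threshold(p, q), bh_oracle(p, q))
  }
})

test_that("null calibration: false-positive rate near the nominal level", {
  maps <- fx_null_fit()
  z <- as.numeric(maps$D2$z)
  z <- z[!is.na(z)]
  expect_gte(length(z), 1e4)
  rate <- mean(abs(z) > stats::qnorm(0.975))
  se <- sqrt(0.05 * 0.95 / length(z))
  expect_lt(abs(rate - 0.05), 3 * se)
})
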