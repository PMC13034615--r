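test_that("cleaning removes trends and reports percent change of the run mean", {
  # pure linear ramp -> identically zero percent change
  ramp <- series_from_vec(100 + 0.3 * (1:50))
  expect_equal(as.numeric(clean_timeseries(ramp)), rep(0, 50),
               tolerance = 1e-10)
  # constant -> zero
  expect_equal(as.numeric(clean_timeseries(series_from_vec(rep(5, 30)))),
               rep(0, 30), tolerance = 1e-12)
  # mean * (1 + 0.02 * boxcar): plateau recovered near +2 percent (small
  # detrending bias allowed)
  box <- c(rep(0, 30), rep(1, 20), rep(0, 30))
  s <- series_from_vec(500 * (1 + 0.02 * box))
  out <- as.numeric(clean_timeseries(s))
  plateau <- mean(out[35:48]) - mean(out[c(1:25, 60:80)])
  expect_equal(plateau, 2, tolerance = 0.1)
  # zero-mean voxel masked
  z <- series_from_vec(rep(0, 20))
  expect_true(all(is.na(as.numeric(clean_timeseries(z)))))
})

test_that("event-related averages slice the stated window with trial bookkeeping", {
  # single-voxel compartment, two conditions
  n <- 300
  tr <- 1
  sig <- numeric(n)
  onsets <- c(50, 150)
  for (o in onsets) sig[(o + 1):(o + 10)] <- 1   # boxcar after onset
  s <- series4d(array(rep(sig, each = 2), dim = c(2, 1, 1, n)), 1, tr_s = tr,
                contrast = "bold")
  layers <- vol3d(array(c(1, 1), dim = c(2, 1, 1)), 1)
  regions <- vol3d(array(c(1, 1), dim = c(2, 1, 1)), 1)
  comp <- make_compartments(layers, regions)
  des <- tibble::tibble(trial_type = "D2", onset = onsets, duration = 10)
  era <- extract_era(s, des, comp, window = c(-15, 70))
  expect_equal(sort(unique(era$trials$t_vol)), -15:70)
  expect_equal(nrow(era$summary), 86L)
  expect_equal(era$n_dropped, 0L)
  m <- era$summary$mean[era$summary$t_vol %in% 0:9]
  expect_true(all(m == 1))
  expect_true(all(era$summary$mean[era$summary$t_vol %in% 11:40] == 0))
  expect_true(all(era$summary$mean[era$summary$t_vol < 0] == 0))
  # identical trials -> zero confidence interval
  expect_true(all(era$summary$ci == 0))
  # a late onset whose window leaves the run is dropped and counted
  des2 <- tibble::tibble(trial_type = "D2", onset = c(50, 280), duration = 10)
  era2 <- extract_era(s, des2, comp)
  expect_equal(era2$n_dropped, 1L)
  expect_equal(unique(era2$summary$n_trials), 1L)
  # early onset without the full pre-window is dropped too
  des3 <- tibble::tibble(trial_type = "D2", onset = 5, duration = 10)
  expect_error(extract_era(s, des3, comp), "beyond the run")
})

test_that("triphasic features find the constructed extrema with stated conventions", {
  tr <- 1.925
  t_vol <- -15:70
  t_s <- t_vol * tr
  # triangular bump peaking at volume 5, trough at volume 12, post peak at
  # volume 20 (4 volumes after the offset volume 15.58 -> within the window)
  y <- numeric(86)
  y[t_vol == 5] <- 1
  y[t_vol %in% 4:6] <- c(0.5, 1, 0.5)
  y[t_vol == 12] <- -1
  y[t_vol == 20] <- 0.8
  s <- tibble::tibble(condition = "pooled", region = 1, layer = 1,
                      t_vol = t_vol, t_s = t_s, n_trials = 5, ci = 0, mean = y)
  era <- structure(list(summary = s, trials = NULL, tr_s = tr,
                        window = c(-15, 70)), class = "vaso_era")
  fe <- extract_triphasic(era, stim_on_s = 30, post_window_vol = 8)
  expect_equal(fe$ttp_initial_s, 5 * tr)
  expect_equal(fe$amp_initial_pct, 1)
  expect_equal(fe$ttp_trough_s, 12 * tr)
  expect_equal(fe$amp_trough_pct, -1)
  # post-stimulus time measured from stimulus offset
  expect_equal(fe$ttp_post_s, 20 * tr - 30)
  expect_equal(fe$amp_post_pct, 0.8)
  # invariant orderings
  expect_lte(fe$ttp_initial_s, fe$ttp_trough_s)
  expect_lte(fe$ttp_initial_s, 30)
  expect_lte(fe$ttp_post_s, 8 * tr)
  # window too short -> error
  s_short <- s[s$t_vol <= 18, ]
  era_short <- structure(list(summary = s_short, tr_s = tr,
                              window = c(-15, 18)), class = "vaso_era")
  expect_error(extract_triphasic(era_short), "too short")
})

test_that("pooling weights digits by their trial counts", {
  mk_era <- function(cond, value, trials) {
    tt <- tidyr::crossing(trial = seq_len(trials), t_vol = 0:25,
                          region = c(3, 4), layer = 1)
    tt$condition <- cond
    tt$t_s <- tt$t_vol * 1.925
    tt$compartment <- tt$region
    tt$value <- value
    e <- structure(list(trials = tt, n_dropped = 0L, tr_s = 1.925,
                        window = c(0, 25)), class = "vaso_era")
    e$summary <- vasomap:::summarise_era(e)
    e
  }
  eras <- list(D2 = mk_era("D2", 1, 2), D3 = mk_era("D3", 4, 1),
               D4 = mk_era("D4", 1, 1))
  pooled <- pool_over_digits(eras)
  # (2 trials x 1 + 1 x 4 + 1 x 1) / 4 = 1.75
  expect_true(all(pooled$summary$mean == 1.75))
  expect_true(all(pooled$summary$n_trials == 4L))
  expect_equal(unique(pooled$summary$condition), "pooled")
  # identical tables pool to themselves
  same <- list(D2 = mk_era("D2", 2, 2), D3 = mk_era("D3", 2, 2),
               D4 = mk_era("D4", 2, 2))
  expect_true(all(pool_over_digits(same)$summary$mean == 2))
  # disjoint bins cannot be pooled
  e_off <- mk_era("D3", 1, 1)
  e_off$trials$region <- e_off$trials$region + 10
  expect_error(pool_over_digits(list(D2 = mk_era("D2", 1, 1), D3 = e_off)),
               "share no distance bins")
})

test_that("noiseless pipeline recovers injected sustained amplitudes", {
  # compartments built on the truth patches themselves (their response to
  # the preferred digit is purely the injected sustained amplitude; ROI
  # compartments would also average surround voxels whose plateau response
  # is the triphasic trough)
  study <- fx_noiseless_study()
  res <- fx_noiseless_analysis()
  clean <- clean_timeseries(
    preprocess_run(study$runs[[1]]$interleaved, study$runs[[1]]$motion,
                   platform = "none")$bold,
    study$runs[[1]]$motion)
  for (i in seq_along(res$digits)) {
    dg <- res$digits[i]
    patch <- vasomap:::vol_like(
      as.numeric(!is.na(study$truth$patch_mask[[dg]]) &
                   study$truth$patch_mask[[dg]] > 0), res$depth)
    comp <- make_compartments(res$layers_era, patch)
    era <- extract_era(clean, study$designs[[1]], comp)
    s <- era$summary[era$summary$condition == dg, ]
    for (lay in 1:3) {
      sel <- which(as.logical(patch > 0) & as.numeric(res$layers_era) == lay)
      inj <- mean(as.numeric(study$truth$amp_bold[[dg]])[sel])
      cell <- s[s$layer == lay, ]
      # percent change is taken against the run mean, which includes the
      # activation, so the injected amplitude is plateau minus the
      # immediately pre-stimulus level
      plateau <- mean(cell$mean[cell$t_s >= 15 & cell$t_s <= 28]) -
        mean(cell$mean[cell$t_s >= -10 & cell$t_s <= -2])
      expect_equal(plateau, inj, tolerance = 0.05 * inj + 0.02)
    }
  }
})

test_that("zero-noise triphasic features match the injected parameters on the grid", {
  res <- fx_noiseless_analysis()
  tri <- default_triphasic()
  fe <- res$features
  tr <- res$era_pooled$tr_s
  for (b in 3:7) {
    row <- fe[fe$region == b & fe$layer == 2, ]
    expect_equal(row$ttp_initial_s, tri$t1[b], tolerance = tr + 1e-9)
    expect_equal(row$ttp_trough_s, tri$t2[b], tolerance = tr + 1e-9)
    if (tri$A3[b] > 0)
      expect_equal(row$ttp_post_s, tri$t3[b], tolerance = tr + 1e-9)
  }
  mid <- fe[fe$layer == 2 & fe$region >= 3, ]
  expect_true(all(diff(mid$amp_initial_pct) < 0))      # A1 decreasing
  expect_true(all(diff(mid$amp_trough_pct) < 0))       # trough more negative
})
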