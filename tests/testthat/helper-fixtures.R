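# Shared fixtures, computed lazily and cached for the whole test run.
# The heavy ones (full phantom studies) are built once and reused by the
# module tests and the acceptance suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# fine-grid quarter-cylinder shell for depth validation (few slices: the
# geometry is axially invariant)
fx_depth_shell <- function() fixture("depth_shell", function() {
  spec <- suppressWarnings(phantom_spec(shape = c(71, 71, 5), voxel_mm = 0.2,
                                        seed = 1))
  build_ribbon(spec)
})

fx_slab <- function() fixture("slab", function() {
  sl <- build_slab()
  sl$depth <- compute_depth(sl$seg)
  sl$column <- column_field(sl$depth)
  sl
})

# noiseless single-run study at the default phantom geometry
fx_noiseless_study <- function() fixture("noiseless_study", function() {
  # no outlier volumes either: censoring a plateau sample is correct pipeline
  # behaviour but would contaminate the discretisation-error invariants
  spec <- phantom_spec(n_runs = 1, noise_sd_bold = 0, noise_sd_nulled = 0,
                       n_motion_spikes = 0, seed = 5)
  simulate_study(spec)
})

fx_noiseless_analysis <- function() fixture("noiseless_analysis", function() {
  analyze_study(fx_noiseless_study())
})

# the default study conditions: 3 runs x 4 repetitions per digit, default
# noise and amplitudes
fx_default_study <- function() fixture("default_study", function() {
  simulate_study(phantom_spec(seed = 42))
})

fx_default_analysis <- function() fixture("default_analysis", function() {
  analyze_study(fx_default_study())
})

# small all-null phantom (no injected response anywhere) for calibration
fx_null_fit <- function() fixture("null_fit", function() {
  tri0 <- default_triphasic()
  tri0$A1 <- tri0$A2 <- tri0$A3 <- 0
  spec <- suppressWarnings(phantom_spec(
    shape = c(29, 29, 13), voxel_mm = 0.5, n_runs = 1,
    n_blocks_per_digit = 2, bold_amp_max = 0, bold_amp_floor = 0,
    cbv_amp_max = 0, cbv_amp_floor = 0, triphasic = tri0, seed = 11))
  study <- simulate_study(spec)
  pre <- preprocess_run(study$runs[[1]]$interleaved, study$runs[[1]]$motion,
                        platform = "none")
  ser <- decimate_temporal(pre$bold, 2)
  mot <- vasomap:::motion_to_pairs(study$runs[[1]]$motion)
  X <- build_design(study$designs[[1]], n_vol = dim(ser)[4],
                    tr_s = series_tr(ser), t0_s = series_t0(ser),
                    motion = mot)
  fit_glm(ser, X, digit_contrasts(type = "vs_rest"))
})

# tiny series constructors --------------------------------------------------

series_from_vec <- function(x, tr = 1, contrast = "bold", t0 = 0) {
  series4d(array(x, dim = c(1, 1, 1, length(x))), 1, tr_s = tr,
           contrast = contrast, t0_s = t0)
}

# independent O(n^2) Dijkstra on a 26-connected voxel mask graph
dijkstra_oracle <- function(mask, seed_trip, voxel_mm) {
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  pos <- vasomap:::voxel_coords_mm(vasomap:::linear_to_triple(idx, d), voxel_mm)
  trip <- vasomap:::linear_to_triple(idx, d)
  dist <- rep(Inf, n)
  start <- which(idx == vasomap:::triple_to_linear(matrix(seed_trip, 1), d))
  dist[start] <- 0
  visited <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(visited, Inf, dist))
    if (!is.finite(dist[u])) break
    visited[u] <- TRUE
    dd <- abs(sweep(trip, 2, trip[u, ]))
    nb <- which(!visited & dd[, 1] <= 1 & dd[, 2] <= 1 & dd[, 3] <= 1)
    if (!length(nb)) next
    w <- sqrt(rowSums(sweep(pos[nb, , drop = FALSE], 2, pos[u, ])^2))
    better <- dist[u] + w < dist[nb]
    dist[nb[better]] <- dist[u] + w[better]
  }
  out <- array(NA_real_, dim = d)
  out[idx] <- dist
  out
}

# brute-force Benjamini-Hochberg step-up enumeration
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= q * seq_len(m) / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
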