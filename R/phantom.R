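#' Specification of the synthetic cortical phantom
#'
#' Collects every parameter of the synthetic ground-truth phantom: a curved
#' gray-matter ribbon (quarter-cylinder shell, so the equivolume depth has an
#' exact closed form), three adjacent digit patches with block-design
#' responses, a BOLD laminar amplitude profile increasing toward the surface,
#' a CBV profile peaking at mid-depth, distance-dependent triphasic surround
#' responses, and an interleaved nulled/not-nulled acquisition with
#' multiplicative BOLD contamination of the nulled series.
#'
#' Defaults emulate the acquisition and stimulation conditions of the
#' somatosensory digit-mapping protocol the pipeline targets: pair repetition
#' time 3.85 s, 30 s on/off vibrotactile blocks, three digits (D2--D4), and
#' 3 runs x 4 repetitions = 12 repetitions per digit.
#'
#' @param shape Domain size in voxels, length 3.
#' @param voxel_mm Voxel size in mm (scalar or length 3). The default is
#'   anisotropic with the fine axes spanning the plane that contains the
#'   cortical-depth direction and the coarse axis along the gyrus, mirroring
#'   acquisitions that optimise resolution perpendicular to the cortical
#'   bank at the cost of slice thickness.
#' @param r_inner_mm,r_outer_mm Inner (white-matter) and outer (pial) radius
#'   of the gray-matter shell in mm; must satisfy `r_inner_mm < r_outer_mm`.
#' @param csf_mm Thickness of the cerebrospinal-fluid shell outside the pial
#'   surface, mm.
#' @param digit_centers_deg Angular positions (degrees) of the three digit
#'   patch centres on the shell.
#' @param patch_fwhm_mm Tangential full width at half maximum of each digit
#'   patch, mm.
#' @param bold_profile,cbv_profile Laminar amplitude profile tags:
#'   `"linear_to_surface"` (amplitude grows linearly from the white-matter
#'   boundary to the pial surface, emulating the draining-vein bias of BOLD)
#'   and `"mid_depth_peak"` (unimodal peak near mid-depth, emulating
#'   microvascular CBV).
#' @param bold_amp_max,bold_amp_floor Peak-of-patch BOLD sustained response in
#'   percent signal change at the pial surface and at the white-matter
#'   boundary; the default 2:1 superficial-to-deep gradient matches the
#'   laminar z-score profiles typically reported for BOLD digit responses.
#' @param cbv_amp_max,cbv_amp_floor Same for the CBV (blood-volume) response
#'   `v(t)`, percent.
#' @param triphasic Tibble of per-distance-bin triphasic parameters, see
#'   [default_triphasic()]. Trough amplitude `A2` is stored as a magnitude.
#' @param pair_tr_s Pair repetition time (time between same-contrast volumes),
#'   seconds.
#' @param block_on_s,block_off_s Stimulation block on/off duration, seconds.
#' @param n_blocks_per_digit Stimulation blocks per digit per run.
#' @param n_runs Number of runs.
#' @param lead_off_s Initial rest before the first block, seconds.
#' @param tail_off_s Rest appended after the last block so that full
#'   post-stimulus event windows fit inside the run, seconds.
#' @param baseline_bold,baseline_nulled Baseline signal levels `B0`, `N0`
#'   (arbitrary units).
#' @param noise_sd_bold,noise_sd_nulled Gaussian noise standard deviation per
#'   volume for each contrast (same units as the baselines). Defaults give a
#'   BOLD temporal SNR of about 65 and a BOLD-corrected VASO tSNR near 19 —
#'   both above the >10 quality bar for sub-millimetre fMRI, with the usual
#'   large BOLD-over-VASO advantage — and are calibrated so that the weakest
#'   injected condition (the deep patch edge at half the deep-layer
#'   amplitude) remains detectable at the winner-take-all threshold with 12
#'   repetitions per digit.
#' @param ar1 Lag-one autocorrelation of the noise (0 = white, the default).
#' @param n_motion_spikes Motion outlier volumes injected per run.
#' @param seed Integer seed controlling every random element.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 48, 26),
                         voxel_mm = c(0.3, 0.3, 1.2),
                         r_inner_mm = 10, r_outer_mm = 12, csf_mm = 2,
                         digit_centers_deg = c(25, 45, 65),
                         patch_fwhm_mm = 3,
                         bold_profile = "linear_to_surface",
                         cbv_profile = "mid_depth_peak",
                         bold_amp_max = 4, bold_amp_floor = 2,
                         cbv_amp_max = 2, cbv_amp_floor = 0.5,
                         triphasic = default_triphasic(),
                         pair_tr_s = 3.85,
                         block_on_s = 30, block_off_s = 30,
                         n_blocks_per_digit = 4, n_runs = 3,
                         lead_off_s = 30, tail_off_s = 75,
                         baseline_bold = 1000, baseline_nulled = 800,
                         noise_sd_bold = 15, noise_sd_nulled = 40,
                         ar1 = 0, n_motion_spikes = 1,
                         seed = 42) {
  voxel_mm <- if (length(voxel_mm) == 1L) rep(voxel_mm, 3L) else as.numeric(voxel_mm)
  stopifnot(length(shape) == 3L, all(shape >= 2), all(voxel_mm > 0),
            length(digit_centers_deg) == 3L,
            pair_tr_s > 0, block_on_s > 0, block_off_s > 0,
            n_blocks_per_digit >= 1, n_runs >= 1)
  if (!(r_inner_mm < r_outer_mm))
    stop("phantom geometry: r_inner_mm must be < r_outer_mm", call. = FALSE)
  stopifnot(is.data.frame(triphasic),
            all(c("bin", "A1", "t1", "A2", "t2", "A3", "t3") %in% names(triphasic)))
  amps <- unlist(triphasic[c("A1", "A2", "A3")])
  if (any(!is.finite(amps))) stop("triphasic amplitudes must be finite", call. = FALSE)
  if (any(triphasic$A2 < 0))
    stop("trough amplitude A2 is stored as a magnitude and must be >= 0", call. = FALSE)
  if (min(diff(sort(digit_centers_deg))) * pi / 180 *
      (r_inner_mm + r_outer_mm) / 2 < patch_fwhm_mm)
    warning("digit patch centres closer than one FWHM; truth patches may overlap")
  spec <- list(shape = as.integer(shape), voxel_mm = voxel_mm,
               r_inner_mm = r_inner_mm, r_outer_mm = r_outer_mm, csf_mm = csf_mm,
               digit_centers_deg = digit_centers_deg, patch_fwhm_mm = patch_fwhm_mm,
               bold_profile = bold_profile, cbv_profile = cbv_profile,
               bold_amp_max = bold_amp_max, bold_amp_floor = bold_amp_floor,
               cbv_amp_max = cbv_amp_max, cbv_amp_floor = cbv_amp_floor,
               triphasic = tibble::as_tibble(triphasic),
               pair_tr_s = pair_tr_s, block_on_s = block_on_s,
               block_off_s = block_off_s,
               n_blocks_per_digit = n_blocks_per_digit, n_runs = n_runs,
               lead_off_s = lead_off_s, tail_off_s = tail_off_s,
               baseline_bold = baseline_bold, baseline_nulled = baseline_nulled,
               noise_sd_bold = noise_sd_bold, noise_sd_nulled = noise_sd_nulled,
               ar1 = ar1, n_motion_spikes = n_motion_spikes, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Default distance-resolved triphasic surround parameters
#'
#' Amplitudes (percent signal change) and extremum times (seconds) of the
#' three phases of the surround response injected by the phantom, per 2 mm
#' Euclidean distance bin from a digit patch centre. Bins 1--2 (0--4 mm) are
#' the patch itself and carry no extra triphasic component; from bin 3
#' outwards the initial-peak amplitude `A1` decreases and the trough magnitude
#' `A2` increases with distance, the initial-peak and trough latencies
#' shorten, and a post-stimulus peak (`A3`, latency `t3` measured from
#' stimulus offset) appears from bin 4 (>6 mm) outwards — the qualitative
#' ordering reported for distance-resolved somatosensory responses.
#'
#' @return A tibble with columns `bin, A1, t1, A2, t2, A3, t3`.
#' @export
default_triphasic <- function() {
  tibble::tibble(
    bin = 1:7,
    A1  = c(0, 0, 0.50, 0.40, 0.30, 0.20, 0.10),
    t1  = c(0, 0, 10,    9,    8,    7,    6),
    A2  = c(0, 0, 0.10, 0.20, 0.30, 0.40, 0.50),
    t2  = c(0, 0, 25,   24,   23,   22,   21),
    A3  = c(0, 0, 0,    0.20, 0.25, 0.25, 0.25),
    t3  = c(0, 0, 0,    4,    5,    6,    7))
}

# closed-form equivolume depth on an annulus: fraction of shell volume between
# radius r and the pial radius r_p, relative to the full shell volume.
annulus_equivolume <- function(r, r_w, r_p) {
  pmin(1, pmax(0, (r_p^2 - r^2) / (r_p^2 - r_w^2)))
}

#' Build the quarter-cylinder ribbon phantom segmentation
#'
#' Constructs a tissue segmentation (0 background, 1 white matter, 2 gray
#' matter, 3 CSF) in which gray matter is a quarter-cylinder shell
#' `r_inner <= r < r_outer` around the domain corner, white matter fills the
#' inside and a CSF shell the outside. Because the geometry is an annulus,
#' the equivolume depth of every gray-matter voxel is known in closed form:
#' `alpha(r) = (r_p^2 - r^2) / (r_p^2 - r_w^2)`, 0 at the pial surface and 1
#' at the white-matter boundary — the analytic ground truth against which the
#' numerical depth estimator is validated.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `seg` (label [vol3d()]), `depth_truth`
#'   ([vol3d()], `NA` outside gray matter), `radius` (vol3d of cylinder radius
#'   per voxel, mm) and `theta` (angle, radians).
#' @export
build_ribbon <- function(spec) {
  d <- spec$shape; h <- spec$voxel_mm
  extent_xy <- c(d[1] * h[1], d[2] * h[2])
  if (spec$r_outer_mm + spec$csf_mm > min(extent_xy))
    stop("phantom geometry: shell (r_outer + csf) exceeds the domain", call. = FALSE)
  cx <- (seq_len(d[1]) - 0.5) * h[1]
  cy <- (seq_len(d[2]) - 0.5) * h[2]
  r2d <- sqrt(outer(cx^2, cy^2, `+`))        # cylinder axis along z
  th2d <- atan2(rep(cy, each = d[1]), rep(cx, times = d[2]))
  lab2d <- matrix(0L, d[1], d[2])
  lab2d[r2d < spec$r_inner_mm] <- 1L
  lab2d[r2d >= spec$r_inner_mm & r2d < spec$r_outer_mm] <- 2L
  lab2d[r2d >= spec$r_outer_mm & r2d < spec$r_outer_mm + spec$csf_mm] <- 3L
  labels <- array(lab2d, dim = d)
  radius <- array(r2d, dim = d)
  theta <- array(th2d, dim = d)
  depth <- array(NA_real_, dim = d)
  gm <- labels == 2L
  depth[gm] <- annulus_equivolume(radius[gm], spec$r_inner_mm, spec$r_outer_mm)
  seg <- vol3d(labels, h)
  list(seg = seg,
       depth_truth = structure(vol3d(depth, h), metric = "equivolume"),
       radius = vol3d(radius, h), theta = vol3d(theta, h))
}

#' Build a flat-slab phantom segmentation
#'
#' Zero-curvature variant of [build_ribbon()]: gray matter is a stack of
#' `gm_planes` axial planes with white matter below and CSF above. In this
#' limit equivolume and equidistant depth coincide, which makes the slab the
#' discriminating fixture for the curvature correction, and columns are
#' exactly vertical, which makes per-layer voxel counts analytic. The default
#' 11 gray-matter planes give exactly one plane per layer when 11 layers are
#' used.
#'
#' @param shape Domain size in voxels (z must cover `gm_planes` plus margins).
#' @param voxel_mm Voxel size, mm.
#' @param gm_planes Number of gray-matter planes along z.
#' @param wm_planes Number of white-matter planes below gray matter.
#' @return As [build_ribbon()] (without `radius`/`theta`).
#' @export
build_slab <- function(shape = c(20, 20, 19), voxel_mm = 0.5,
                       gm_planes = 11, wm_planes = 4) {
  h <- if (length(voxel_mm) == 1L) rep(voxel_mm, 3L) else voxel_mm
  d <- as.integer(shape)
  if (wm_planes + gm_planes >= d[3])
    stop("slab does not fit in the domain along z", call. = FALSE)
  labels <- array(0L, dim = d)
  labels[, , seq_len(wm_planes)] <- 1L
  gm_idx <- wm_planes + seq_len(gm_planes)
  labels[, , gm_idx] <- 2L
  labels[, , (wm_planes + gm_planes + 1L):d[3]] <- 3L
  depth <- array(NA_real_, dim = d)
  # depth 0 at the pial (CSF) side: plane centres at (2m-1)/(2*gm_planes)
  for (m in seq_len(gm_planes))
    depth[, , gm_idx[gm_planes - m + 1L]] <- (2 * m - 1) / (2 * gm_planes)
  list(seg = vol3d(labels, h),
       depth_truth = structure(vol3d(depth, h), metric = "equivolume"))
}

# peak-normalised gamma-shaped bump with mode `m` (s) and sd `s` (s)
gamma_bump <- function(t, m, s) {
  theta <- (-m + sqrt(m^2 + 4 * s^2)) / 2
  k <- 1 + m / theta
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::dgamma(t[pos], shape = k, scale = theta) /
    stats::dgamma(m, shape = k, scale = theta)
  out
}

# the three-phase surround kernel, evaluated in percent signal change.
# Widths (sd) of the three gamma components are fixed generator constants.
triphasic_kernel <- function(t, A1, t1, A2, t2, A3, t3, on_s) {
  y <- numeric(length(t))
  if (A1 > 0) y <- y + A1 * gamma_bump(t, t1, 3)
  if (A2 > 0) y <- y - A2 * gamma_bump(t, t2, 6)
  if (A3 > 0) y <- y + A3 * gamma_bump(t - on_s, t3, 3)
  y
}

laminar_profile <- function(alpha, tag, amp_max, amp_floor) {
  switch(tag,
         linear_to_surface = amp_floor + (amp_max - amp_floor) * (1 - alpha),
         mid_depth_peak = amp_floor + (amp_max - amp_floor) *
           exp(-(alpha - 0.5)^2 / (2 * 0.15^2)),
         stop("unknown laminar profile tag: ", tag, call. = FALSE))
}

#' Paint digit patches and surround truth onto the ribbon
#'
#' Assigns each of the three digits a sustained-response amplitude map
#' (tangential Gaussian patch times a laminar depth profile, separately for
#' the BOLD and the CBV contrast) and every gray-matter voxel a set of
#' triphasic surround parameters per digit, indexed by its 2 mm Euclidean
#' distance bin from that digit's patch centre.
#'
#' @param ribbon Result of [build_ribbon()].
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth` list: `seg`, `depth_truth`, `amp_bold` /
#'   `amp_cbv` (named lists of per-digit [vol3d()] amplitude maps, percent),
#'   `dist_bin` (per-digit vol3d of distance-bin index 1..7, `NA` beyond
#'   14 mm or outside gray matter), `patch_mask` (per-digit truth patches,
#'   amplitude >= half maximum), `peak_voxel` (per-digit index triple of the
#'   amplitude maximum), `triphasic_truth` (tibble digit x bin x layer) and
#'   `digits`.
#' @export
paint_digits <- function(ribbon, spec) {
  seg <- ribbon$seg
  d <- dim(seg); h <- voxel_mm(seg)
  gm <- which(seg == 2L)
  if (!length(gm)) stop("segmentation has no gray matter", call. = FALSE)
  alpha <- as.numeric(ribbon$depth_truth)[gm]
  r <- as.numeric(ribbon$radius)[gm]
  th <- as.numeric(ribbon$theta)[gm]
  trip <- linear_to_triple(gm, d)
  zmm <- (trip[, 3L] - 0.5) * h[3]
  z_mid <- d[3] * h[3] / 2
  r_mid <- (spec$r_inner_mm + spec$r_outer_mm) / 2
  sigma <- spec$patch_fwhm_mm / (2 * sqrt(2 * log(2)))
  digits <- c("D2", "D3", "D4")
  amp_bold <- amp_cbv <- dist_bin <- patch_mask <- list()
  peak_voxel <- list()
  prof_b <- laminar_profile(alpha, spec$bold_profile,
                            spec$bold_amp_max, spec$bold_amp_floor)
  prof_v <- laminar_profile(alpha, spec$cbv_profile,
                            spec$cbv_amp_max, spec$cbv_amp_floor)
  gm_mm <- voxel_coords_mm(trip, h)
  for (i in seq_along(digits)) {
    th0 <- spec$digit_centers_deg[i] * pi / 180
    # tangential distance on the shell: arc along the circumference + axial
    tang2 <- (r * (th - th0))^2 + (zmm - z_mid)^2
    w <- exp(-tang2 / (2 * sigma^2))
    ab <- prof_b * w
    av <- prof_v * w
    amp_bold[[i]] <- fill_gm(ab, gm, d, h)
    amp_cbv[[i]] <- fill_gm(av, gm, d, h)
    patch_mask[[i]] <- fill_gm(w >= 0.5, gm, d, h)
    pk <- gm[which.max(ab)]       # ties: which.max takes the lowest index
    peak_voxel[[i]] <- as.integer(linear_to_triple(pk, d))
    pk_mm <- voxel_coords_mm(linear_to_triple(pk, d), h)
    dist <- sqrt(rowSums(sweep(gm_mm, 2L, as.numeric(pk_mm), `-`)^2))
    bin <- ifelse(dist < 14, floor(dist / 2) + 1, NA_real_)
    dist_bin[[i]] <- fill_gm(bin, gm, d, h)
  }
  names(amp_bold) <- names(amp_cbv) <- names(dist_bin) <-
    names(patch_mask) <- names(peak_voxel) <- digits
  overlap <- sum(patch_mask$D2 & patch_mask$D3, na.rm = TRUE) +
    sum(patch_mask$D3 & patch_mask$D4, na.rm = TRUE) +
    sum(patch_mask$D2 & patch_mask$D4, na.rm = TRUE)
  if (overlap > 0)
    warning(sprintf("digit truth patches overlap in %d voxels", overlap))
  tri <- tidyr::crossing(digit = digits, spec$triphasic)
  tri <- tidyr::crossing(tri, layer = c("superficial", "middle", "deep"))
  truth <- list(seg = seg, depth_truth = ribbon$depth_truth,
                amp_bold = amp_bold, amp_cbv = amp_cbv,
                dist_bin = dist_bin, patch_mask = patch_mask,
                peak_voxel = peak_voxel, triphasic_truth = tri,
                patch_overlap_voxels = overlap, digits = digits)
  class(truth) <- "phantom_truth"
  truth
}

fill_gm <- function(values, gm_idx, d, h) {
  a <- array(NA_real_, dim = d)
  a[gm_idx] <- as.numeric(values)
  vol3d(a, h)
}

#' Pseudo-randomised block-design stimulation schedule
#'
#' One 30 s on / 30 s off block design per run with `n_blocks_per_digit`
#' blocks per digit, digit order shuffled under the constraint that the same
#' digit is never stimulated twice in a row.
#'
#' @param spec A [phantom_spec()].
#' @param run Run number (enters the shuffling seed).
#' @return A tibble with columns `trial_type`, `onset`, `duration` (seconds)
#'   and attribute `run_duration_s`.
#' @export
make_stim_design <- function(spec, run = 1L) {
  digits <- c("D2", "D3", "D4")
  n <- spec$n_blocks_per_digit
  seq_ok <- function(x) all(x[-1] != x[-length(x)])
  set.seed(spec$seed + 1000L * run)
  repeat {
    order <- sample(rep(digits, n))
    if (seq_ok(order)) break
  }
  cyc <- spec$block_on_s + spec$block_off_s
  onsets <- spec$lead_off_s + (seq_along(order) - 1) * cyc
  run_duration <- spec$lead_off_s + length(order) * cyc + spec$tail_off_s
  design <- tibble::tibble(trial_type = order, onset = onsets,
                           duration = spec$block_on_s)
  stopifnot(all(diff(design$onset) >= design$duration[-nrow(design)]))
  attr(design, "run_duration_s") <- run_duration
  design
}

# unit sustained response: block regressor convolved with the canonical gamma
# response, normalised so a 30 s block plateaus at 1. Returned as a function
# of time (s) via a fine lookup grid.
sustained_unit <- function(onsets, on_s, t_max) {
  dt <- 0.05
  tg <- seq(0, t_max + 32, by = dt)
  box <- rowSums(vapply(onsets, function(o) as.numeric(tg >= o & tg < o + on_s),
                        numeric(length(tg))))
  h <- make_hrf(dt)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tg)] * dt
  one <- stats::convolve(as.numeric(tg >= 0 & tg < on_s), rev(h),
                         type = "open")[seq_along(tg)] * dt
  conv <- conv / max(one)
  function(t) {
    i <- pmin(pmax(round(t / dt) + 1, 1), length(tg))
    conv[i]
  }
}

triphasic_unit <- function(onsets, pars, on_s) {
  # force the promises: the caller reuses these variable names across loop
  # iterations
  onsets <- as.numeric(onsets); pars <- as.list(pars); on_s <- as.numeric(on_s)
  function(t) {
    y <- numeric(length(t))
    for (o in onsets)
      y <- y + triphasic_kernel(t - o, pars$A1, pars$t1, pars$A2, pars$t2,
                                pars$A3, pars$t3, on_s)
    y
  }
}

#' Simulate one interleaved nulled/not-nulled run
#'
#' Generates the voxelwise signal model: `bold(t) = B0 (1 + b(t)) + e` and
#' `nulled(t) = N0 (1 - v(t)) (1 + b(t)) + e`, where `b(t)` sums the
#' BOLD-weighted sustained responses and the distance-binned triphasic
#' surround responses of the three digits (in fractional units) and `v(t)`
#' the CBV-weighted sustained responses. The multiplicative construction
#' means exact division of nulled by BOLD recovers `(1 - v(t))` — the model
#' assumption behind dynamic-division BOLD correction. Both members of a
#' pair carry the signal content of the pair time (the within-pair
#' acquisition offset of half a pair is recorded as series metadata only),
#' so the division identity holds exactly; see the methods vignette for why
#' this is the appropriate ground-truth condition. The two contrasts are
#' returned both separately and interleaved.
#'
#' @param truth A [paint_digits()] result.
#' @param design A [make_stim_design()] tibble.
#' @param spec The [phantom_spec()].
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @return List with `interleaved`, `nulled`, `bold` ([series4d()]),
#'   `motion` (tibble, one row per interleaved volume) and `n_pairs`.
#' @export
simulate_run <- function(truth, design, spec, seed = spec$seed) {
  d <- dim(truth$seg); h <- voxel_mm(truth$seg)
  nvox <- prod(d)
  run_s <- attr(design, "run_duration_s")
  n_pairs <- ceiling(run_s / spec$pair_tr_s)
  t_nulled <- (seq_len(n_pairs) - 1) * spec$pair_tr_s
  t_bold <- t_nulled + spec$pair_tr_s / 2
  digits <- truth$digits

  # shared unit time courses (columns) and voxel loading matrices (sparse-ish)
  cols_b <- list(); loads_b <- list()
  cols_v <- list(); loads_v <- list()
  t_max <- max(t_bold)
  for (dg in digits) {
    ons <- design$onset[design$trial_type == dg]
    if (!length(ons)) next
    u <- sustained_unit(ons, spec$block_on_s, t_max)
    amp_b <- as.numeric(truth$amp_bold[[dg]]); amp_b[is.na(amp_b)] <- 0
    amp_v <- as.numeric(truth$amp_cbv[[dg]]); amp_v[is.na(amp_v)] <- 0
    cols_b[[length(cols_b) + 1L]] <- u
    loads_b[[length(loads_b) + 1L]] <- amp_b / 100
    cols_v[[length(cols_v) + 1L]] <- u
    loads_v[[length(loads_v) + 1L]] <- amp_v / 100
    bins <- as.numeric(truth$dist_bin[[dg]])
    for (b in unique(stats::na.omit(bins))) {
      pars <- spec$triphasic[spec$triphasic$bin == b, ]
      if (!nrow(pars) || (pars$A1 == 0 && pars$A2 == 0 && pars$A3 == 0)) next
      ind <- as.numeric(!is.na(bins) & bins == b & as.numeric(truth$seg) == 2)
      cols_b[[length(cols_b) + 1L]] <- triphasic_unit(ons, pars, spec$block_on_s)
      loads_b[[length(loads_b) + 1L]] <- ind / 100
    }
  }
  eval_frac <- function(cols, loads, times) {
    out <- matrix(0, nvox, length(times))
    for (i in seq_along(cols)) {
      tc <- cols[[i]](times)
      nz <- loads[[i]] != 0
      out[nz, ] <- out[nz, ] + tcrossprod(loads[[i]][nz], tc)
    }
    out
  }
  # signal content is evaluated at the pair time for BOTH members: the
  # within-pair acquisition offset is carried as series metadata only, so
  # that dynamic division is exactly invertible (the ground-truth condition
  # the BOLD correction assumes)
  b_at_null <- eval_frac(cols_b, loads_b, t_nulled)
  b_at_bold <- b_at_null
  v_at_null <- eval_frac(cols_v, loads_v, t_nulled)

  set.seed(seed)
  noise <- function(sd) {
    e <- matrix(stats::rnorm(nvox * n_pairs, 0, sd), nvox, n_pairs)
    if (spec$ar1 > 0)
      e <- t(apply(e, 1L, function(x)
        as.numeric(stats::filter(x, spec$ar1, method = "recursive")))) *
        sqrt(1 - spec$ar1^2)
    e
  }
  bold_m <- spec$baseline_bold * (1 + b_at_bold) + noise(spec$noise_sd_bold)
  null_m <- spec$baseline_nulled * (1 - v_at_null) * (1 + b_at_null) +
    noise(spec$noise_sd_nulled)

  inter <- matrix(0, nvox, 2L * n_pairs)
  inter[, seq(1L, 2L * n_pairs, by = 2L)] <- null_m
  inter[, seq(2L, 2L * n_pairs, by = 2L)] <- bold_m
  mk <- function(m, tr, contrast, t0)
    series4d(array(m, dim = c(d, ncol(m))), h, tr_s = tr, contrast = contrast,
             t0_s = t0)
  motion <- simulate_motion(2L * n_pairs, spec, seed)
  list(interleaved = mk(inter, spec$pair_tr_s / 2, "nulled", 0),
       nulled = mk(null_m, spec$pair_tr_s, "nulled", 0),
       bold = mk(bold_m, spec$pair_tr_s, "bold", spec$pair_tr_s / 2),
       motion = motion, n_pairs = n_pairs)
}

# nuisance-only motion: white jitter around a stable head position plus a
# few large transient outliers. Motion never displaces the images; it exists
# to exercise the confound and framewise-displacement machinery. The jitter
# is deliberately serially uncorrelated: a temporally smooth random trace has
# so few effective degrees of freedom that regressing it out absorbs a
# noticeable fraction of any block response purely by chance — an artifact
# of synthetic nuisance traces that would contaminate every ground-truth
# recovery invariant (the methods vignette quantifies this as a limitation).
simulate_motion <- function(n_vol, spec, seed) {
  set.seed(seed + 7L)
  walk <- function(sd) stats::rnorm(n_vol, 0, 3 * sd)
  m <- tibble::tibble(
    trans_x = walk(0.004), trans_y = walk(0.004), trans_z = walk(0.004),
    rot_x = walk(8e-5), rot_y = walk(8e-5), rot_z = walk(8e-5))
  spikes <- integer(0)
  if (spec$n_motion_spikes > 0) {
    spikes <- sample(seq(5L, n_vol - 2L), spec$n_motion_spikes)
    # transient excursions (the head returns): a persistent step would act
    # as a strong low-frequency regressor and soak up task variance
    for (s in spikes) m$trans_x[s] <- m$trans_x[s] + 0.9
  }
  m$outlier <- seq_len(n_vol) %in% spikes
  m
}

#' Simulate a complete phantom study
#'
#' Builds the ribbon, paints the digit truth and simulates all runs of the
#' study design (default three runs of four repetitions per digit).
#'
#' @param spec A [phantom_spec()].
#' @return List with `spec`, `truth`, `designs` (list of tibbles), `runs`
#'   (list of [simulate_run()] results).
#' @export
simulate_study <- function(spec = phantom_spec()) {
  ribbon <- build_ribbon(spec)
  truth <- paint_digits(ribbon, spec)
  designs <- lapply(seq_len(spec$n_runs), function(r) make_stim_design(spec, r))
  runs <- lapply(seq_len(spec$n_runs), function(r) {
    sim <- simulate_run(truth, designs[[r]], spec, seed = spec$seed + r)
    # the separated contrasts are recoverable from the interleaved stack;
    # dropping them keeps multi-run studies within a small memory footprint
    out <- sim[c("interleaved", "motion", "n_pairs")]
    rm(sim); gc(FALSE)
    out
  })
  list(spec = spec, truth = truth, designs = designs, runs = runs)
}
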