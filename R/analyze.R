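#' Acquisition protocol constants
#'
#' The acquisition and stimulation protocol the pipeline (and the phantom's
#' defaults) target: an interleaved blood-nulled/not-nulled 3D-EPI slab of 22
#' slices of 1.29 mm at 0.75 mm in-plane, pair repetition time 3850 ms, 30 s
#' on/off vibrotactile blocks, up to 3 runs of 4 repetitions per digit, and
#' the study-level motion bookkeeping (9198 acquired volumes of which 30
#' exceeded the in-plane voxel size in framewise displacement).
#'
#' @return A named list of protocol constants.
#' @export
acquisition_protocol <- function() {
  list(n_slices = 22L, slice_mm = 1.29, inplane_mm = 0.75,
       pair_tr_s = 3.85, block_on_s = 30, block_off_s = 30,
       n_runs = 3L, reps_per_run = 4L,
       distance_edges_mm = seq(0, 14, by = 2),
       post_window_vol = 8L,
       era_window_vol = c(-15L, 70L),
       n_volumes_total = 9198L, n_fd_over_voxel = 30L,
       highpass_hz = 0.01, fdr_q = 0.001,
       disk_radius_mm = 12, cylinder_radius_mm = 0.45,
       hrf_mean_s = 6, hrf_sd_s = 3, upsample_factor = 2L)
}

#' Derived protocol arithmetic
#'
#' Quantities that follow from the protocol constants: slab coverage in the
#' slice direction, the effective (upsampled) sampling interval, the duration
#' of the 8-volume post-stimulus window, the number of distance bins, the
#' percentage of motion-affected volumes and the repetitions per digit.
#'
#' @param p Protocol list, default [acquisition_protocol()].
#' @return A one-row tibble.
#' @export
protocol_summary <- function(p = acquisition_protocol()) {
  eff_tr <- p$pair_tr_s / p$upsample_factor
  tibble::tibble(
    slab_coverage_mm = p$n_slices * p$slice_mm,
    effective_tr_s = eff_tr,
    post_window_s = p$post_window_vol * eff_tr,
    n_distance_bins = length(p$distance_edges_mm) - 1L,
    fd_exceed_pct = 100 * p$n_fd_over_voxel / p$n_volumes_total,
    reps_per_digit = p$n_runs * p$reps_per_run)
}

#' Flip the sign of a statistical map
#'
#' The BOLD-corrected VASO signal *decreases* when cerebral blood volume
#' increases, so its activation betas and z-scores are negative for a
#' positive response; this helper inverts them so that activation is
#' positive, the convention used for all reported VASO maps.
#'
#' @param m A `vaso_statmap`.
#' @return The map with `beta`, `t`, `z` negated.
#' @export
invert_statmap <- function(m) {
  for (f in c("beta", "t", "z")) {
    v <- m[[f]]
    m[[f]] <- vol3d(array(-as.numeric(v), dim = dim(v)), attr(v, "voxel_mm"))
  }
  m
}

#' Mean z-score per cortical layer
#'
#' @param statmap A `vaso_statmap`.
#' @param layers Layer [vol3d()] from [bin_layers()].
#' @param mask Optional logical [vol3d()] restriction (e.g. a digit ROI).
#' @return Tibble with `layer` (1 = most superficial), `n_voxels`, `mean_z`.
#' @export
profile_by_layer <- function(statmap, layers, mask = NULL) {
  z <- as.numeric(statmap$z)
  lay <- as.numeric(layers)
  keep <- !is.na(z) & !is.na(lay)
  if (!is.null(mask)) keep <- keep & array(as.logical(mask), dim = dim(layers))
  tibble::tibble(layer = lay[keep], z = z[keep]) |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(n_voxels = dplyr::n(), mean_z = mean(.data$z),
                     .groups = "drop") |>
    dplyr::arrange(.data$layer)
}

# collapse a per-interleaved-volume motion table to the pair grid: parameter
# means over the two members, outlier if either member is flagged
motion_to_pairs <- function(motion) {
  n <- nrow(motion)
  pair <- rep(seq_len(ceiling(n / 2)), each = 2L)[seq_len(n)]
  m <- as.data.frame(motion)[, 1:6]
  out <- tibble::as_tibble(rowsum(as.matrix(m), pair) / as.numeric(table(pair)))
  if ("outlier" %in% names(motion))
    out$outlier <- as.logical(tapply(motion$outlier, pair, any))
  out
}

# seed for the geodesic disk: gray-matter voxel with the largest summed
# digit-versus-rest evidence, emulating a disk centred on the digit region
choose_disk_seed <- function(statmaps_vs_rest, gm_mask) {
  zsum <- Reduce(`+`, lapply(statmaps_vs_rest, function(m) {
    z <- as.numeric(m$z); z[!is.finite(z)] <- 0; z
  }))
  d <- dim(statmaps_vs_rest[[1L]]$z)
  zsum[!array(as.logical(gm_mask), dim = d)] <- NA_real_
  as.integer(linear_to_triple(which.max(zsum), d))
}

#' Run the full analysis on a simulated (or loaded) study
#'
#' Chains every stage of the pipeline on a study object as produced by
#' [simulate_study()]: per-run preprocessing (split, steady-state
#' replacement, upsample, align, dynamic division), voxelwise GLMs for BOLD
#' and VASO with winner-take-all and versus-rest contrasts, fixed-effects
#' combination across runs, equivolume depth and layers, geodesic disk,
#' five-step digit ROI construction, laminar z profiles (11 layers),
#' event-related averages in 3-layer compartments for digit ROIs and
#' distance bins, digit-pooled distance ERAs, and triphasic feature
#' extraction.
#'
#' @param study List with `spec`, `truth` (segmentation at least), `designs`,
#'   `runs` (each with `interleaved` and `motion`).
#' @param q FDR level for ROI construction.
#' @param disk_radius_mm Geodesic disk radius.
#' @param cylinder_radius_mm UVD cylinder radius.
#' @param n_layers_profile,n_layers_era Layer counts for profiles and ERAs.
#' @param invert_vaso Flip VASO statistics so activation is positive.
#' @param guard Division guard for [bold_correct()].
#' @param platform Nulled/BOLD alignment convention; the phantom's pairs are
#'   simultaneous, hence `"none"` (see [align_nulled_bold()]).
#' @param distance_mask Population for the Euclidean distance bins: all of
#'   gray matter (default, the distance-bin definition) or gray matter
#'   restricted to the geodesic disk (the conservative variant for data whose
#'   segmentation is trustworthy only near the disk).
#' @return A `vaso_analysis` list; see the elements in the examples of the
#'   package vignette.
#' @export
analyze_study <- function(study, q = 0.001, disk_radius_mm = 12,
                          cylinder_radius_mm = 0.45,
                          n_layers_profile = 11L, n_layers_era = 3L,
                          invert_vaso = TRUE, guard = 0.05,
                          platform = "none",
                          distance_mask = c("gm", "disk")) {
  distance_mask <- match.arg(distance_mask)
  spec <- study$spec
  seg <- study$truth$seg
  digits <- study$truth$digits %||% c("D2", "D3", "D4")
  gm <- vol_like(seg == 2L, seg)

  # --- per-run preprocessing + GLM (sequential: one run's series in memory
  # at a time; only statistics, the cleaned BOLD series and small QC maps
  # are retained) -----------------------------------------------------------
  cons <- c(digit_contrasts(digits, "vs_others"), digit_contrasts(digits, "vs_rest"))
  names(cons) <- c(paste0(digits, "_vs_others"), paste0(digits, "_vs_rest"))
  n_runs <- length(study$runs)
  maps_bold_runs <- maps_vaso_runs <- clean_bold <- qc <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    motion <- study$runs[[r]]$motion
    pre <- preprocess_run(study$runs[[r]]$interleaved, motion,
                          guard = guard, platform = platform)
    fit_run <- function(series) {
      # the GLM sees the pair-grid samples: interpolated volumes add no
      # information but correlate the noise (see decimate_temporal)
      series <- decimate_temporal(series, 2L)
      mot <- motion_to_pairs(motion)
      X <- build_design(study$designs[[r]], n_vol = n_volumes(series),
                        tr_s = series_tr(series), t0_s = series_t0(series),
                        motion = mot)
      fit_glm(series, X, cons)
    }
    maps_bold_runs[[r]] <- fit_run(pre$bold)
    maps_vaso_runs[[r]] <- fit_run(pre$vaso)
    clean_bold[[r]] <- clean_timeseries(pre$bold, motion)
    qc[[r]] <- pre$qc
    rm(pre); gc(FALSE)
  }
  combine <- function(runs_maps)
    lapply(stats::setNames(names(cons), names(cons)), function(nm)
      fixed_effects(lapply(runs_maps, `[[`, nm)))
  maps_bold <- combine(maps_bold_runs)
  maps_vaso <- combine(maps_vaso_runs)
  rm(maps_bold_runs, maps_vaso_runs)
  if (invert_vaso) maps_vaso <- lapply(maps_vaso, invert_statmap)

  # --- geometry ----------------------------------------------------------
  depth <- compute_depth(seg, metric = "equivolume")
  column <- column_field(depth)
  layers_profile <- bin_layers(depth, n_layers_profile)
  layers_era <- bin_layers(depth, n_layers_era)
  seed <- choose_disk_seed(maps_bold[paste0(digits, "_vs_rest")], gm)
  disk <- make_disk(depth, seed, radius_mm = disk_radius_mm)

  # --- digit ROIs (winner-take-all, BOLD) --------------------------------
  rois <- build_digit_rois(
    stats::setNames(maps_bold[paste0(digits, "_vs_others")], digits),
    disk, depth, column, q = q, cylinder_radius_mm = cylinder_radius_mm)

  # --- laminar z profiles in the preferred-digit ROI ---------------------
  profiles <- dplyr::bind_rows(lapply(digits, function(dg) {
    dplyr::bind_rows(
      dplyr::mutate(profile_by_layer(maps_bold[[paste0(dg, "_vs_rest")]],
                                     layers_profile, rois$masks[[dg]]),
                    contrast = "bold", digit = dg),
      dplyr::mutate(profile_by_layer(maps_vaso[[paste0(dg, "_vs_rest")]],
                                     layers_profile, rois$masks[[dg]]),
                    contrast = "vaso", digit = dg))
  }))

  # --- peak voxels and distance bins -------------------------------------
  disk_gm <- vol_like(as.logical(disk) & !is.na(depth), seg)
  bin_mask <- if (distance_mask == "gm") gm else disk_gm
  peaks <- lapply(stats::setNames(digits, digits), function(dg) {
    pk <- find_peak_voxel(maps_bold[[paste0(dg, "_vs_rest")]], gm)
    # if bins are restricted to the disk and the global gray-matter peak
    # falls outside it, fall back to the within-disk peak
    if (!bin_mask[pk[1L], pk[2L], pk[3L]])
      pk <- find_peak_voxel(maps_bold[[paste0(dg, "_vs_rest")]], bin_mask)
    pk
  })
  dist_bins <- lapply(peaks, function(pk)
    euclidean_distance_bins(bin_mask, pk))

  # --- event-related averages --------------------------------------------
  comp_roi <- make_compartments(layers_era, rois$labels)
  era_roi <- combine_eras(lapply(seq_along(clean_bold), function(r)
    extract_era(clean_bold[[r]], study$designs[[r]], comp_roi)))
  era_dist <- lapply(stats::setNames(digits, digits), function(dg) {
    comp <- make_compartments(layers_era, dist_bins[[dg]])
    combine_eras(lapply(seq_along(clean_bold), function(r)
      extract_era(clean_bold[[r]], study$designs[[r]], comp)))
  })
  era_pooled <- pool_over_digits(era_dist)
  features <- extract_triphasic(era_pooled, stim_on_s = spec$block_on_s)

  structure(list(qc = qc, maps_bold = maps_bold, maps_vaso = maps_vaso,
                 depth = depth, column = column,
                 layers_profile = layers_profile, layers_era = layers_era,
                 disk = disk, disk_seed = seed, rois = rois,
                 profiles = profiles, peaks = peaks, dist_bins = dist_bins,
                 era_roi = era_roi, era_dist = era_dist,
                 era_pooled = era_pooled, features = features,
                 digits = digits),
            class = "vaso_analysis")
}

#' @export
print.vaso_analysis <- function(x, ...) {
  cat("<vaso_analysis>\n  digits:", paste(x$digits, collapse = ", "), "\n")
  print(x$rois$summary)
  invisible(x)
}

#' Tidy a statistical map into a voxel table
#'
#' @param x A `vaso_statmap`.
#' @param ... Passed to [tidy.vol3d()].
#' @return Tibble of voxels with `beta`, `t`, `z` columns.
#' @method tidy vaso_statmap
#' @export
tidy.vaso_statmap <- function(x, ...) {
  tb <- tidy.vol3d(x$z, ...)
  names(tb)[names(tb) == "value"] <- "z"
  tb$beta <- as.numeric(x$beta)[triple_to_linear(cbind(tb$i, tb$j, tb$k),
                                                 dim(x$z))]
  tb
}

#' @method glance vaso_statmap
#' @export
glance.vaso_statmap <- function(x, ...) {
  z <- as.numeric(x$z)
  tibble::tibble(contrast = x$name, df = x$df,
                 n_voxels = sum(!is.na(z)),
                 max_z = max(z, na.rm = TRUE),
                 n_sig_unc05 = sum(abs(z) > stats::qnorm(0.975), na.rm = TRUE))
}

#' Plot event-related averages
#'
#' One line per region (digit ROI or distance bin), faceted by layer, with
#' the across-trial 95% confidence ribbon and the stimulation period shaded.
#'
#' @param object A `vaso_era`.
#' @param stim_on_s Stimulation duration for the shaded band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vaso_era
#' @export
autoplot.vaso_era <- function(object, stim_on_s = 30, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$t_s, y = .data$mean,
                                  colour = factor(.data$region),
                                  fill = factor(.data$region))) +
    ggplot2::annotate("rect", xmin = 0, xmax = stim_on_s, ymin = -Inf,
                      ymax = Inf, alpha = 0.1) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$ci,
                                      ymax = .data$mean + .data$ci),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(.data$layer ~ .data$condition) +
    ggplot2::labs(x = "time from onset (s)", y = "signal change (%)",
                  colour = "region", fill = "region")
}

#' Plot laminar activation profiles
#'
#' @param profiles The `profiles` tibble of a [analyze_study()] result.
#' @return A ggplot object: mean z against layer (1 = superficial), per
#'   digit and contrast.
#' @export
plot_layer_profile <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$layer, y = .data$mean_z,
                                         colour = .data$digit)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$contrast, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "layer (1 = superficial)", y = "mean z")
}
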