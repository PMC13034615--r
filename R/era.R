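#' Detrend, denoise and convert a series to percent signal change
#'
#' Removes, per voxel, a linear trend, the (optional) six motion parameters
#' and one spike regressor per flagged outlier volume by ordinary least
#' squares, then expresses the residual as percent signal change with
#' respect to the voxelwise mean of the *original* series:
#' `100 * residual / mean`.
#'
#' @param series A [series4d()].
#' @param motion Optional motion tibble (6 parameter columns, optional
#'   logical `outlier`), one row per volume of `series`.
#' @return A [series4d()] in percent signal change; voxels with zero mean or
#'   missing time points are `NA`.
#' @export
clean_timeseries <- function(series, motion = NULL) {
  n <- n_volumes(series)
  X <- cbind(1, seq_len(n))
  if (!is.null(motion)) {
    mm <- as.matrix(as.data.frame(motion)[, 1:6])
    stopifnot(nrow(mm) == n)
    X <- cbind(X, scale(mm, center = TRUE, scale = FALSE))
    if ("outlier" %in% names(motion) && any(motion$outlier))
      for (i in which(motion$outlier)) {
        v <- numeric(n); v[i] <- 1; X <- cbind(X, v)
      }
  }
  Y <- t(series_matrix(series))                # time x voxel
  ok <- colSums(!is.finite(Y)) == 0L
  mu <- colMeans(Y)
  out <- matrix(NA_real_, nrow(Y), ncol(Y))
  okv <- ok & abs(mu) > .Machine$double.eps
  if (any(okv)) {
    Yk <- Y[, okv, drop = FALSE]
    B <- solve(crossprod(X), crossprod(X, Yk))
    resid <- Yk - X %*% B
    out[, okv] <- 100 * sweep(resid, 2L, mu[okv], `/`)
  }
  series_from_matrix(t(out), series)
}

#' Compartment labels from layers crossed with regions
#'
#' Builds the (region x layer) compartments over which event-related
#' averages are computed: e.g. 3 digit ROIs x 3 layer bins, or 7 distance
#' bins x 3 layer bins.
#'
#' @param layers Integer layer [vol3d()] from [bin_layers()].
#' @param regions Integer region [vol3d()] (digit ROI labels or distance-bin
#'   indices), `NA`/0 outside.
#' @param region_names Optional names for the region levels.
#' @return A list `lookup` (tibble compartment/region/layer) and `comp`
#'   (integer vol3d of compartment ids).
#' @export
make_compartments <- function(layers, regions, region_names = NULL) {
  d <- dim(layers)
  lay <- as.numeric(layers)
  reg <- as.numeric(regions)
  reg[!is.na(reg) & reg == 0] <- NA_real_
  ok <- !is.na(lay) & !is.na(reg)
  rl <- sort(unique(reg[ok])); ll <- sort(unique(lay[ok]))
  lookup <- tidyr::crossing(region = rl, layer = ll)
  lookup$compartment <- seq_len(nrow(lookup))
  comp <- array(NA_real_, dim = d)
  key <- match(paste(reg[ok], lay[ok]), paste(lookup$region, lookup$layer))
  comp[ok] <- lookup$compartment[key]
  if (!is.null(region_names))
    lookup$region_name <- region_names[lookup$region]
  list(lookup = lookup, comp = vol_like(comp, layers))
}

#' Event-related averages in layer-by-region compartments
#'
#' Averages the cleaned (percent-signal-change) time course over the voxels
#' of every compartment, slices a window of 15 volumes before to 70 volumes
#' after each stimulation onset (86 samples), and summarises across trials
#' with a t-based 95% confidence interval. Trials whose window would extend
#' beyond the run are dropped and counted.
#'
#' @param cleaned A percent-signal-change [series4d()] from
#'   [clean_timeseries()].
#' @param design Stimulation tibble (`trial_type`, `onset`, `duration`).
#' @param compartments Result of [make_compartments()].
#' @param window Window in volumes relative to onset, default `c(-15, 70)`
#'   inclusive.
#' @return A `vaso_era` object: `trials` (tibble condition/region/layer/
#'   trial/t_vol/t_s/value), `summary` (mean, ci half-width, n per cell),
#'   `n_dropped`, `tr_s`, `window`.
#' @export
extract_era <- function(cleaned, design, compartments, window = c(-15, 70)) {
  tr <- series_tr(cleaned); t0 <- series_t0(cleaned)
  n <- n_volumes(cleaned)
  look <- compartments$lookup
  comp <- as.numeric(compartments$comp)
  sel <- which(!is.na(comp))
  if (!length(sel)) stop("no voxels in any compartment", call. = FALSE)
  m <- series_matrix(cleaned)[sel, , drop = FALSE]
  grp <- comp[sel]
  # voxels that are NA at any time point cannot contribute
  good <- rowSums(!is.finite(m)) == 0L
  m <- m[good, , drop = FALSE]; grp <- grp[good]
  traces <- rowsum(m, grp) / as.numeric(table(grp))   # compartment x time
  comp_ids <- as.integer(rownames(traces))
  win <- window[1]:window[2]
  rows <- list(); n_dropped <- 0L
  for (ci in seq_len(nrow(design))) {
    onset_vol <- round((design$onset[ci] - t0) / tr)   # 0-based volume index
    iv <- onset_vol + win
    if (iv[1] < 0 || iv[length(iv)] > n - 1L) { n_dropped <- n_dropped + 1L; next }
    vals <- traces[, iv + 1L, drop = FALSE]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      condition = design$trial_type[ci],
      compartment = rep(comp_ids, times = length(win)),
      trial = ci,
      t_vol = rep(win, each = length(comp_ids)),
      value = as.numeric(vals))
  }
  if (!length(rows))
    stop("every trial window extends beyond the run; nothing to average",
         call. = FALSE)
  trials <- dplyr::left_join(dplyr::bind_rows(rows), look, by = "compartment")
  trials$t_s <- trials$t_vol * tr
  era <- structure(list(trials = trials, n_dropped = n_dropped,
                        tr_s = tr, window = window),
                   class = "vaso_era")
  era$summary <- summarise_era(era)
  era
}

summarise_era <- function(era) {
  dplyr::summarise(
    dplyr::group_by(era$trials, .data$condition, .data$region, .data$layer,
                    .data$t_vol, .data$t_s),
    n_trials = dplyr::n(),
    ci = ifelse(.data$n_trials >= 2,
                stats::qt(0.975, pmax(.data$n_trials - 1, 1)) *
                  stats::sd(.data$value) / sqrt(.data$n_trials), NA_real_),
    mean = mean(.data$value), .groups = "drop")
}

#' Merge event-related averages across runs
#'
#' Concatenates the per-trial slices of several runs (same compartments) and
#' recomputes the across-trial summary.
#'
#' @param eras List of `vaso_era` objects.
#' @return A combined `vaso_era`.
#' @export
combine_eras <- function(eras) {
  stopifnot(length(eras) >= 1L)
  tr <- eras[[1L]]$tr_s
  trials <- dplyr::bind_rows(lapply(seq_along(eras), function(i) {
    tt <- eras[[i]]$trials
    tt$trial <- paste0("run", i, "_", tt$trial)
    tt
  }))
  out <- structure(list(trials = trials,
                        n_dropped = sum(vapply(eras, `[[`, 0L, "n_dropped")),
                        tr_s = tr, window = eras[[1L]]$window),
                   class = "vaso_era")
  out$summary <- summarise_era(out)
  out
}

#' Pool event-related averages over the stimulated digits
#'
#' For a distance-bin analysis each digit contributes the response to its
#' *own* stimulation within its *own* distance map; pooling collapses these
#' over the three digits, weighting each digit by its number of trials
#' (i.e. a plain mean over all contributing trials).
#'
#' @param eras Named list of `vaso_era`, one per digit, whose regions are
#'   that digit's distance bins.
#' @param conditions Character vector: the condition to keep from each era
#'   (defaults to the names of `eras`).
#' @return A pooled `vaso_era` with condition `"pooled"`.
#' @export
pool_over_digits <- function(eras, conditions = names(eras)) {
  stopifnot(length(eras) == length(conditions))
  kept <- lapply(seq_along(eras), function(i) {
    tt <- eras[[i]]$trials
    tt <- tt[tt$condition == conditions[i], ]
    tt$trial <- paste0(conditions[i], "_", tt$trial)
    tt$condition <- "pooled"
    tt
  })
  bins <- lapply(kept, function(tt) sort(unique(tt$region)))
  if (!length(Reduce(intersect, bins)))
    stop("digit ERAs share no distance bins; cannot pool", call. = FALSE)
  out <- structure(list(trials = dplyr::bind_rows(kept),
                        n_dropped = sum(vapply(eras, `[[`, 0L, "n_dropped")),
                        tr_s = eras[[1L]]$tr_s, window = eras[[1L]]$window),
                   class = "vaso_era")
  out$summary <- summarise_era(out)
  out
}

#' @export
print.vaso_era <- function(x, ...) {
  cat(sprintf("<vaso_era> %d compartments x %d time points, tr = %.4g s, %d dropped trial(s)\n",
              length(unique(x$trials$compartment %||% paste(x$trials$region, x$trials$layer))),
              diff(x$window) + 1L, x$tr_s, x$n_dropped))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy an event-related average
#'
#' @param x A `vaso_era`.
#' @param ... Unused.
#' @return The summary tibble (condition, region, layer, t_vol, t_s, mean,
#'   ci, n_trials).
#' @method tidy vaso_era
#' @export
tidy.vaso_era <- function(x, ...) x$summary

#' Extract triphasic response features
#'
#' From the across-trial mean trace of every (condition, region, layer)
#' cell: the *initial peak* is the highest deflection within the stimulation
#' period, the *trough* the lowest deflection after the initial peak and
#' before the end of stimulation, and the *post-stimulus peak* the highest
#' deflection within `post_window_vol` volumes (default 8, about 15.4 s at a
#' 1.925 s effective sampling interval) after stimulus offset. Times to peak
#' are reported in seconds relative to stimulus onset for the first two
#' phases and relative to stimulus offset for the post-stimulus peak; ties
#' resolve to the earliest time.
#'
#' @param era A `vaso_era`.
#' @param stim_on_s Stimulation duration, seconds (default 30).
#' @param post_window_vol Post-stimulus search window in volumes (default 8).
#' @return A tibble with one row per cell and columns `ttp_initial_s`,
#'   `amp_initial_pct`, `ttp_trough_s`, `amp_trough_pct`, `ttp_post_s`,
#'   `amp_post_pct`.
#' @export
extract_triphasic <- function(era, stim_on_s = 30, post_window_vol = 8L) {
  s <- era$summary
  tr <- era$tr_s
  need_max <- ceiling(stim_on_s / tr) + post_window_vol
  if (max(s$t_vol) < need_max)
    stop("event-related window too short for the post-stimulus search window",
         call. = FALSE)
  one <- function(df) {
    df <- df[order(df$t_vol), ]
    stim <- df[df$t_vol >= 0 & df$t_s <= stim_on_s + 1e-9, ]
    i1 <- which.max(stim$mean)
    post_all <- df[df$t_s > stim_on_s, ]
    post <- post_all[seq_len(min(post_window_vol, nrow(post_all))), ]
    tr_seg <- stim[stim$t_vol > stim$t_vol[i1], ]
    if (!nrow(tr_seg)) tr_seg <- stim[i1, ]   # degenerate: peak at stim end
    i2 <- which.min(tr_seg$mean)
    i3 <- which.max(post$mean)
    tibble::tibble(
      ttp_initial_s = stim$t_s[i1], amp_initial_pct = stim$mean[i1],
      ttp_trough_s = tr_seg$t_s[i2], amp_trough_pct = tr_seg$mean[i2],
      ttp_post_s = post$t_s[i3] - stim_on_s, amp_post_pct = post$mean[i3])
  }
  out <- dplyr::group_modify(
    dplyr::group_by(s, .data$condition, .data$region, .data$layer),
    function(df, key) one(df))
  dplyr::ungroup(out)
}
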