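#' Split an interleaved nulled/not-nulled run into its two contrasts
#'
#' Interleaved acquisitions store blood-nulled and not-nulled (BOLD) volumes
#' alternately, nulled first. The two contrasts are separated and processed
#' independently; each output series carries the pair repetition time and the
#' not-nulled series an acquisition offset of half a pair.
#'
#' @param run Interleaved [series4d()] with an even number of volumes.
#' @return List `nulled`, `bold` of equal length.
#' @export
split_interleaved <- function(run) {
  n <- n_volumes(run)
  if (n %% 2L != 0L)
    stop(sprintf("interleaved run has an odd number of volumes (%d)", n),
         call. = FALSE)
  tr_pair <- 2 * series_tr(run)
  m <- series_matrix(run)
  odd <- seq(1L, n, by = 2L)
  list(nulled = series_from_matrix(m[, odd, drop = FALSE], run,
                                   tr_s = tr_pair, contrast = "nulled",
                                   t0_s = series_t0(run)),
       bold = series_from_matrix(m[, odd + 1L, drop = FALSE], run,
                                 tr_s = tr_pair, contrast = "bold",
                                 t0_s = series_t0(run) + series_tr(run)))
}

#' Replace non-steady-state volumes
#'
#' The first three volumes of a run are acquired before the longitudinal
#' magnetisation reaches steady state; they are replaced by copies of volumes
#' four to six.
#'
#' @param s A [series4d()] with at least 6 volumes.
#' @return The series with volumes 1--3 replaced.
#' @export
replace_nonsteady <- function(s) {
  if (n_volumes(s) < 6L)
    stop("need at least 6 volumes to replace the non-steady-state volumes",
         call. = FALSE)
  m <- series_matrix(s)
  m[, 1:3] <- m[, 4:6]
  series_from_matrix(m, s)
}

# Lagrange interpolation weights for the points `xs` evaluated at `x`
lagrange_weights <- function(xs, x) {
  n <- length(xs)
  w <- numeric(n)
  for (i in seq_len(n)) {
    others <- xs[-i]
    w[i] <- prod((x - others) / (xs[i] - others))
  }
  w
}

#' Temporal upsampling by piecewise 7th-order polynomial interpolation
#'
#' Inserts `factor - 1` interpolated volumes between consecutive samples.
#' Each new time point is evaluated with the Lagrange polynomial through the
#' 8 nearest original samples (4 on each side), so the operator reproduces
#' polynomials up to degree 7 exactly at interior points; near the series
#' edges the window shrinks symmetrically and the order degrades gracefully.
#' Original sample times are copied through unchanged.
#'
#' @param s A [series4d()] with at least 8 volumes.
#' @param factor Integer upsampling factor (>= 2).
#' @return A [series4d()] of `factor` times the length with `tr_s / factor`.
#' @export
upsample_temporal <- function(s, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 2L)
  n <- n_volumes(s)
  if (n < 8L)
    stop("temporal upsampling needs at least 8 volumes", call. = FALSE)
  n_out <- factor * n
  # weight matrix W (n x n_out): out = data %*% W
  W <- matrix(0, n, n_out)
  for (j in seq_len(n_out)) {
    t <- (j - 1) / factor               # in units of the input TR, 0-based
    if (abs(t - round(t)) < 1e-12 && round(t) < n) {
      W[round(t) + 1L, j] <- 1
      next
    }
    m <- floor(t)
    half <- max(1L, min(m + 1L, n - 1L - m, 4L)) # symmetric shrink at edges
    idx <- (m - half + 1L):(m + half)            # 0-based sample indices
    idx <- idx - max(0L, max(idx) - (n - 1L))    # trailing midpoint: shift
    idx <- idx + max(0L, -min(idx))              # window into range
    W[idx + 1L, j] <- lagrange_weights(idx, t)
  }
  out <- series_matrix(s) %*% W
  series_from_matrix(out, s, tr_s = series_tr(s) / factor)
}

#' Temporally align the nulled to the not-nulled series
#'
#' After upsampling both contrasts to a common sampling interval, one
#' contrast still leads the other by half a pair. Following the convention
#' of the VB17 sequence platform, the first nulled volume is duplicated and
#' the series truncated to the not-nulled length; for the VE platform
#' convention (`platform = "VE"`) the first not-nulled volume is duplicated
#' instead. `platform = "none"` applies no shift and simply harmonises the
#' time metadata — the right choice for pair-simultaneous data such as the
#' synthetic phantom, whose two contrasts carry the signal content of the
#' same pair time.
#'
#' @param nulled,bold [series4d()] objects on the same sampling interval.
#' @param platform `"VB17"` (default), `"VE"`, or `"none"`.
#' @return List `nulled`, `bold` of equal length on a common grid.
#' @export
align_nulled_bold <- function(nulled, bold, platform = c("VB17", "VE", "none")) {
  platform <- match.arg(platform)
  if (n_volumes(nulled) < 1L || n_volumes(bold) < 1L)
    stop("cannot align empty series", call. = FALSE)
  if (abs(series_tr(nulled) - series_tr(bold)) > 1e-9)
    stop("nulled and bold series must share the sampling interval", call. = FALSE)
  shift_dup <- function(s, len, t0) {
    m <- series_matrix(s)
    m <- cbind(m[, 1L], m)[, seq_len(len), drop = FALSE]
    # the duplicated series now lives on the other contrast's time grid
    series_from_matrix(m, s, t0_s = t0)
  }
  if (platform == "VB17") {
    out <- list(nulled = shift_dup(nulled, n_volumes(bold), series_t0(bold)),
                bold = bold)
  } else if (platform == "VE") {
    out <- list(nulled = nulled,
                bold = shift_dup(bold, n_volumes(nulled), series_t0(nulled)))
  } else {
    if (n_volumes(nulled) != n_volumes(bold))
      stop("pair-simultaneous alignment needs equal-length series",
           call. = FALSE)
    m <- series_matrix(bold)
    out <- list(nulled = nulled,
                bold = series_from_matrix(m, bold, t0_s = series_t0(nulled)))
  }
  if (n_volumes(out$nulled) != n_volumes(out$bold))
    stop("nulled and bold lengths differ after alignment", call. = FALSE)
  out
}

#' Keep every `factor`-th volume of a series
#'
#' Inverse of temporal upsampling: selects volumes `phase, phase + factor,
#' ...` (1-based) and rescales the repetition time. The voxelwise GLM is fit
#' on the decimated (pair-grid) series because interpolated volumes carry no
#' independent information but induce strong temporal autocorrelation, which
#' would make ordinary-least-squares statistics anticonservative.
#'
#' @param s A [series4d()].
#' @param factor Decimation factor (default 2).
#' @param phase 1-based index of the first retained volume.
#' @return A [series4d()] with `tr_s * factor`.
#' @export
decimate_temporal <- function(s, factor = 2L, phase = 1L) {
  n <- n_volumes(s)
  stopifnot(factor >= 1L, phase >= 1L, phase <= n)
  keep <- seq(phase, n, by = factor)
  m <- series_matrix(s)[, keep, drop = FALSE]
  series_from_matrix(m, s, tr_s = series_tr(s) * factor,
                     t0_s = series_t0(s) + (phase - 1L) * series_tr(s))
}

#' Dynamic division: BOLD-correct the nulled series
#'
#' The blood-nulled series carries a multiplicative BOLD contamination;
#' dividing it volume-by-volume by the not-nulled series removes it, yielding
#' the BOLD-corrected VASO time course. Voxel-time points where the
#' not-nulled signal falls below `guard` times its voxelwise run mean are set
#' to `NA` instead of producing unstable ratios.
#'
#' @param nulled,bold Aligned, equal-length [series4d()] on one grid.
#' @param guard Fraction of the voxelwise mean |bold| below which the ratio
#'   is masked (default 0.05).
#' @return A [series4d()] with contrast `"vaso"`.
#' @export
bold_correct <- function(nulled, bold, guard = 0.05) {
  if (!all(dim(nulled) == dim(bold)) ||
      any(abs(voxel_mm(nulled) - voxel_mm(bold)) > 1e-9))
    stop("nulled and bold series are not on the same grid", call. = FALSE)
  nm <- series_matrix(nulled)
  bm <- series_matrix(bold)
  thr <- guard * rowMeans(abs(bm))
  bad <- abs(bm) < pmax(thr, .Machine$double.eps)
  out <- nm / bm
  out[bad] <- NA_real_
  series_from_matrix(out, nulled, contrast = "vaso")
}

#' T1-weighted EPI image from the inverse variation coefficient
#'
#' The inversion-recovery nature of the acquisition gives the concatenated
#' nulled + not-nulled time course a strong T1 contrast: its voxelwise mean
#' divided by its (sample) standard deviation yields an anatomical-contrast
#' image in the native functional space, used for registration and QC.
#'
#' @param nulled,bold [series4d()] on the same grid.
#' @return A [vol3d()]; voxels with zero temporal variance are `NA`.
#' @export
compute_t1w_epi <- function(nulled, bold) {
  if (!all(dim(nulled)[1:3] == dim(bold)[1:3]))
    stop("series are not on the same grid", call. = FALSE)
  m <- cbind(series_matrix(nulled), series_matrix(bold))
  mu <- rowMeans(m)
  n <- ncol(m)
  sd <- sqrt(pmax(rowSums(m^2) - n * mu^2, 0) / (n - 1L))
  out <- mu / sd
  out[sd == 0] <- NA_real_
  vol_like(out, nulled)
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by the temporal standard deviation of the
#' residuals after (by default) removing a linear trend. Voxels with zero
#' residual variance are masked `NA`.
#'
#' @param s A [series4d()] with at least 2 volumes.
#' @param detrend Remove a linear trend before computing the standard
#'   deviation (default `TRUE`).
#' @return A [vol3d()] tSNR map.
#' @export
compute_tsnr <- function(s, detrend = TRUE) {
  n <- n_volumes(s)
  stopifnot(n >= 2L)
  m <- series_matrix(s)
  mu <- rowMeans(m)
  if (detrend) {
    X <- cbind(1, seq_len(n))
    m <- m - tcrossprod(m %*% X %*% solve(crossprod(X)), X)
  }
  sd <- sqrt(rowSums((m - rowMeans(m))^2) / (n - 1L))
  out <- mu / sd
  # numerically zero variance (constant voxels) is masked, not infinite
  out[sd <= 1e-10 * (abs(mu) + 1)] <- NA_real_
  vol_like(out, s)
}

#' Framewise displacement from a motion-parameter trace
#'
#' Scalar per-volume head-motion summary: the sum of absolute differences of
#' the three translations (mm) plus `head_radius_mm` times the sum of
#' absolute differences of the three rotations (radians), i.e. rotations are
#' converted to arc length on a sphere of the given radius. The first volume
#' has no predecessor and is assigned 0. Outlier volumes are flagged where FD
#' exceeds the 75th percentile plus 1.5 times the interquartile range of the
#' run (the boxplot fence used by common motion-outlier tools), or a fixed
#' threshold if `threshold_mm` is given.
#'
#' @param motion Tibble/data frame whose first six numeric columns are three
#'   translations (mm) and three rotations (radians), one row per volume.
#' @param head_radius_mm Sphere radius for the rotation term (default 50).
#' @param threshold_mm Optional fixed outlier threshold in mm.
#' @return A tibble with columns `volume`, `fd_mm`, `outlier`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50,
                                   threshold_mm = NULL) {
  motion <- as.data.frame(motion)
  if (ncol(motion) < 6L)
    stop("motion trace must have 6 finite numeric parameters per volume",
         call. = FALSE)
  m <- as.matrix(motion[, 1:6])
  if (!is.numeric(m) || anyNA(m))
    stop("motion trace must have 6 finite numeric parameters per volume",
         call. = FALSE)
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  thr <- if (is.null(threshold_mm)) {
    q <- stats::quantile(fd, c(0.25, 0.75), names = FALSE)
    q[2] + 1.5 * (q[2] - q[1])
  } else threshold_mm
  tibble::tibble(volume = seq_along(fd), fd_mm = fd, outlier = fd > thr)
}

#' Preprocess one interleaved run into aligned BOLD and VASO series
#'
#' Chains the standard preprocessing: contrast separation, steady-state
#' volume replacement per contrast, temporal upsampling by 2,
#' nulled/BOLD alignment and dynamic-division BOLD correction; also computes
#' tSNR maps for all three contrasts, the T1-weighted EPI image and the
#' framewise-displacement trace.
#'
#' @param run Interleaved [series4d()].
#' @param motion Optional motion tibble (6 parameters per interleaved
#'   volume).
#' @param upsample_factor Temporal upsampling factor, default 2.
#' @param guard Division guard passed to [bold_correct()].
#' @param platform Alignment convention, see [align_nulled_bold()].
#' @return List with `bold`, `vaso`, `nulled` (aligned series), `qc` (list of
#'   tSNR maps, `t1w_epi`, `fd` tibble, `n_fd_outliers`).
#' @export
preprocess_run <- function(run, motion = NULL, upsample_factor = 2L,
                           guard = 0.05, platform = "VB17") {
  parts <- split_interleaved(run)
  parts <- lapply(parts, replace_nonsteady)
  t1w <- compute_t1w_epi(parts$nulled, parts$bold)
  nulled_up <- upsample_temporal(parts$nulled, upsample_factor)
  bold_up <- upsample_temporal(parts$bold, upsample_factor)
  aligned <- align_nulled_bold(nulled_up, bold_up, platform = platform)
  vaso <- bold_correct(aligned$nulled, aligned$bold, guard = guard)
  fd <- NULL; n_out <- NA_integer_
  if (!is.null(motion)) {
    fd <- framewise_displacement(motion)
    n_out <- sum(fd$outlier)
  }
  qc <- list(tsnr_nulled = compute_tsnr(parts$nulled),
             tsnr_bold = compute_tsnr(parts$bold),
             tsnr_vaso = compute_tsnr(vaso),
             t1w_epi = t1w, fd = fd, n_fd_outliers = n_out)
  list(bold = aligned$bold, vaso = vaso, nulled = aligned$nulled, qc = qc)
}
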