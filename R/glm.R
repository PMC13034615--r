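#' Canonical gamma haemodynamic response kernel
#'
#' Gamma-density response with mean lag 6 s and standard deviation 3 s (so
#' shape `k = 4`, scale `theta = 1.5`, mode at 4.5 s), sampled at the
#' repetition time, truncated at 32 s and peak-normalised.
#'
#' @param tr_s Sampling interval, seconds.
#' @param mean_lag_s Mean of the gamma density, seconds (default 6).
#' @param sd_s Standard deviation, seconds (default 3).
#' @param duration_s Truncation, seconds (default 32).
#' @return Numeric kernel sampled at `0, tr_s, 2 tr_s, ...`, max 1.
#' @export
make_hrf <- function(tr_s, mean_lag_s = 6, sd_s = 3, duration_s = 32) {
  stopifnot(mean_lag_s > 0, sd_s > 0, tr_s > 0)
  theta <- sd_s^2 / mean_lag_s
  k <- mean_lag_s / theta
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = k, scale = theta)
  h / max(h)
}

#' Build a GLM design matrix
#'
#' One regressor per stimulation condition (block boxcar convolved with the
#' gamma response, plateau-normalised so the betas are on the scale of the
#' fractional plateau response), an intercept, a discrete-cosine drift basis
#' implementing the high-pass filter (all cosines with frequency below
#' `highpass_hz`; their number is `floor(2 * duration * highpass_hz)`),
#' demeaned motion parameters, and one unit spike column per flagged outlier
#' volume.
#'
#' @param design Stimulation tibble with `trial_type`, `onset`, `duration`
#'   (seconds).
#' @param n_vol Number of analysed volumes.
#' @param tr_s Repetition time of the analysed series, seconds.
#' @param t0_s Acquisition time of the first volume, seconds.
#' @param motion Optional motion tibble (first six columns are the
#'   parameters, optional logical `outlier` column), one row per analysed
#'   volume.
#' @param highpass_hz High-pass cutoff, Hz (default 0.01).
#' @param hrf_mean_s,hrf_sd_s Gamma response parameters.
#' @return A list of class `vaso_design`: `X` (matrix), `conditions` (names
#'   of condition columns), `tr_s`, `frame_times`.
#' @export
build_design <- function(design, n_vol, tr_s, t0_s = 0, motion = NULL,
                         highpass_hz = 0.01, hrf_mean_s = 6, hrf_sd_s = 3) {
  frame_times <- t0_s + (seq_len(n_vol) - 1) * tr_s
  conds <- sort(unique(design$trial_type))
  # convolve on a fine grid so fractional-TR onsets are honoured
  dt <- tr_s / 16
  tg <- seq(0, max(frame_times) + 32, by = dt)
  hrf <- make_hrf(dt, hrf_mean_s, hrf_sd_s)
  one_block <- stats::convolve(
    as.numeric(tg >= 0 & tg < design$duration[1]), rev(hrf),
    type = "open")[seq_along(tg)]
  plateau <- max(one_block)
  cond_cols <- vapply(conds, function(cc) {
    ons <- design$onset[design$trial_type == cc]
    dur <- design$duration[design$trial_type == cc]
    box <- numeric(length(tg))
    for (i in seq_along(ons)) box <- box + (tg >= ons[i] & tg < ons[i] + dur[i])
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tg)] / plateau
    conv[pmin(pmax(round(frame_times / dt) + 1, 1), length(tg))]
  }, numeric(n_vol))
  duration <- n_vol * tr_s
  n_dct <- max(0L, floor(2 * duration * highpass_hz))
  dct <- NULL
  if (n_dct > 0) {
    tt <- seq_len(n_vol) - 0.5
    dct <- vapply(seq_len(n_dct), function(k)
      cos(pi * k * tt / n_vol), numeric(n_vol))
    colnames(dct) <- paste0("drift_", seq_len(n_dct))
  }
  mot <- spikes <- NULL
  if (!is.null(motion)) {
    mm <- as.matrix(as.data.frame(motion)[, 1:6])
    stopifnot(nrow(mm) == n_vol)
    mot <- scale(mm, center = TRUE, scale = FALSE)
    colnames(mot) <- paste0("motion_", 1:6)
    if ("outlier" %in% names(motion) && any(motion$outlier)) {
      out_idx <- which(motion$outlier)
      spikes <- vapply(out_idx, function(i) {
        v <- numeric(n_vol); v[i] <- 1; v
      }, numeric(n_vol))
      colnames(spikes) <- paste0("spike_", out_idx)
    }
  }
  X <- cbind(cond_cols, intercept = 1, dct, mot, spikes)
  colnames(X)[seq_along(conds)] <- conds
  # a condition without events keeps its (all-zero) column so the contrast
  # interface stays stable; the rank check applies to the nonzero columns
  nz <- colSums(X != 0) > 0
  qrX <- qr(X[, nz, drop = FALSE])
  if (qrX$rank < sum(nz)) {
    dropped <- colnames(X)[nz][qrX$pivot[(qrX$rank + 1L):sum(nz)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, conditions = conds, tr_s = tr_s,
                 frame_times = frame_times),
            class = "vaso_design")
}

#' Define a contrast over condition regressors
#'
#' @param name Contrast label.
#' @param weights Named numeric vector of weights over condition regressors,
#'   e.g. `c(D2 = 1, D3 = -0.5, D4 = -0.5)` for the winner-take-all
#'   digit-versus-other-digits contrast, or `c(D2 = 1)` for digit-versus-rest.
#' @return A `vaso_contrast` list.
#' @export
contrast <- function(name, weights) {
  if (!length(weights) || all(weights == 0) || any(!is.finite(weights)))
    stop("contrast weights must be finite with at least one nonzero",
         call. = FALSE)
  structure(list(name = name, weights = weights), class = "vaso_contrast")
}

#' Winner-take-all and versus-rest contrasts for a digit set
#'
#' @param digits Condition names (default `D2, D3, D4`).
#' @param type `"vs_others"`: each digit against the mean of the other
#'   digits (weights `+1, -1/(n-1)...`); `"vs_rest"`: each digit alone.
#' @return Named list of [contrast()] objects.
#' @export
digit_contrasts <- function(digits = c("D2", "D3", "D4"),
                            type = c("vs_others", "vs_rest")) {
  type <- match.arg(type)
  out <- lapply(digits, function(dg) {
    if (type == "vs_others") {
      w <- stats::setNames(rep(-1 / (length(digits) - 1), length(digits)), digits)
      w[dg] <- 1
      contrast(paste0(dg, "_vs_others"), w)
    } else {
      contrast(paste0(dg, "_vs_rest"), stats::setNames(1, dg))
    }
  })
  stats::setNames(out, digits)
}

#' Voxelwise ordinary-least-squares GLM with contrast z-maps
#'
#' Fits the design to every voxel time course by OLS and evaluates each
#' contrast: `t = c'b / sqrt(c' (X'X)^-1 c * sigma^2)` with
#' `df = n - rank(X)`, mapped to a z-score through the t-distribution
#' quantile transform. Numerically perfect fits are capped at `|z| = 40`,
#' and the residual variance is floored at the square of the single-precision
#' relative accuracy of the voxel's signal level (`1.2e-7` times its RMS):
#' acquired data carry at most float32 information, so variance below that
#' floor is numerically meaningless and would otherwise let vanishing
#' effects dominate the FDR step on noise-free synthetic data.
#' Voxels with any missing time point or zero temporal variance are masked.
#'
#' @param series A [series4d()].
#' @param design A `vaso_design` from [build_design()].
#' @param contrasts List of [contrast()] objects.
#' @param z_cap Cap on |z| (default 40).
#' @param var_floor_rel Relative variance floor (default `1.2e-7`, float32
#'   epsilon).
#' @return A named list of `vaso_statmap` objects, one per contrast, each
#'   with [vol3d()] fields `beta`, `var`, `t`, `z` and scalar `df`.
#' @export
fit_glm <- function(series, design, contrasts, z_cap = 40,
                    var_floor_rel = 1.2e-7) {
  X <- design$X
  n <- nrow(X)
  if (n_volumes(series) != n)
    stop("series length does not match the design matrix", call. = FALSE)
  Y <- t(series_matrix(series))              # time x voxel
  ok <- colSums(!is.finite(Y)) == 0L
  mu0 <- colMeans(Y)
  ss <- colSums(Y^2)
  ok[ok] <- (ss - n * mu0^2)[ok] > 0
  nzc <- colSums(X != 0) > 0         # event-free condition columns drop out
  Xf <- X[, nzc, drop = FALSE]
  XtXinv_f <- chol2inv(chol(crossprod(Xf)))
  Bf <- XtXinv_f %*% crossprod(Xf, Y[, ok, drop = FALSE])
  B <- matrix(0, ncol(X), ncol(Bf))
  B[nzc, ] <- Bf
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[nzc, nzc] <- XtXinv_f
  resid <- Y[, ok, drop = FALSE] - Xf %*% Bf
  df <- n - qr(Xf)$rank
  sigma2 <- colSums(resid^2) / df
  rms <- sqrt(colMeans(Y[, ok, drop = FALSE]^2))
  sigma2 <- pmax(sigma2, (var_floor_rel * rms)^2)
  out <- lapply(contrasts, function(ct) {
    cvec <- numeric(ncol(X))
    names(cvec) <- colnames(X)
    cvec[names(ct$weights)] <- ct$weights
    cb <- drop(crossprod(cvec, B))
    cvar <- drop(crossprod(cvec, XtXinv %*% cvec)) * sigma2
    tt <- cb / sqrt(cvar)
    tt[cvar == 0] <- sign(cb[cvar == 0]) * Inf
    z <- t_to_z(tt, df)
    z <- pmin(pmax(z, -z_cap), z_cap)
    mk <- function(v) {
      full <- rep(NA_real_, length(ok)); full[ok] <- v
      vol_like(full, series)
    }
    structure(list(name = ct$name, beta = mk(cb), var = mk(cvar),
                   t = mk(tt), z = mk(z), df = df),
              class = "vaso_statmap")
  })
  stats::setNames(out, vapply(contrasts, `[[`, "", "name"))
}

# numerically stable t -> standard normal quantile transform
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  neg <- !is.na(t) & t < 0
  z[pos] <- -stats::qnorm(stats::pt(t[pos], df, lower.tail = FALSE,
                                    log.p = TRUE), log.p = TRUE)
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, lower.tail = TRUE,
                                   log.p = TRUE), log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

#' @export
print.vaso_statmap <- function(x, ...) {
  cat(sprintf("<vaso_statmap> %s: df = %s, max |z| = %.2f\n", x$name,
              format(x$df), max(abs(x$z), na.rm = TRUE)))
  invisible(x)
}

#' Fixed-effects combination of per-run statistical maps
#'
#' Combines runs by inverse-variance weighting of the contrast estimates:
#' `b = sum(b_i / v_i) / sum(1 / v_i)`, `v = 1 / sum(1 / v_i)`, with the
#' combined z recomputed from `b / sqrt(v)` against the standard normal.
#' Masked (non-finite) voxels of a run are excluded from its sums.
#'
#' @param maps List of `vaso_statmap` objects for the same contrast and grid.
#' @param z_cap Cap on |z|.
#' @return A combined `vaso_statmap` (with `df = Inf`, normal reference).
#' @export
fixed_effects <- function(maps, z_cap = 40) {
  stopifnot(length(maps) >= 1L)
  if (length(maps) == 1L) return(maps[[1L]])
  d <- dim(maps[[1L]]$beta)
  for (m in maps)
    if (!all(dim(m$beta) == d))
      stop("statistical maps are not on the same grid", call. = FALSE)
  wsum <- array(0, dim = d); bwsum <- array(0, dim = d)
  any_ok <- array(FALSE, dim = d)
  for (m in maps) {
    w <- 1 / as.numeric(m$var)
    ok <- is.finite(w) & w > 0 & is.finite(as.numeric(m$beta))
    w[!ok] <- 0
    b <- as.numeric(m$beta); b[!ok] <- 0
    wsum <- wsum + w
    bwsum <- bwsum + w * b
    any_ok <- any_ok | ok
  }
  beta <- bwsum / wsum
  var <- 1 / wsum
  beta[!any_ok] <- NA_real_
  var[!any_ok] <- NA_real_
  z <- beta / sqrt(var)
  z <- pmin(pmax(z, -z_cap), z_cap)
  tmpl <- maps[[1L]]$beta
  structure(list(name = maps[[1L]]$name,
                 beta = vol_like(beta, tmpl), var = vol_like(var, tmpl),
                 t = vol_like(z, tmpl), z = vol_like(z, tmpl), df = Inf),
            class = "vaso_statmap")
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up false-discovery-rate control at level `q` over a stated voxel
#' population (typically gray matter within the geodesic disk).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, never
#'   rejected).
#' @param q FDR level, default 0.001.
#' @return Logical rejection vector of the same length.
#' @export
fdr_threshold <- function(p, q = 0.001) {
  if (!length(p)) return(logical(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH") <= q
  out
}

#' Convert z-scores to p-values
#'
#' @param z Numeric z-scores.
#' @param sided `"two"` (default) or `"one"` (positive tail; the
#'   winner-take-all contrast direction is positive for the preferred digit).
#' @return p-values.
#' @export
z_to_p <- function(z, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (sided == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
}
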