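#' Scalar volume on an axis-aligned voxel lattice
#'
#' `vol3d()` wraps a 3D numeric array together with its voxel size in mm and an
#' optional contrast tag. All spatial operations in the package (depth
#' estimation, distance mapping, ROI construction) work on this container.
#' Voxel indices are 1-based in R; the centre of voxel `(i, j, k)` sits at
#' physical position `((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz)` mm.
#'
#' @param data 3D numeric array.
#' @param voxel_mm Numeric length-3 vector of voxel edge lengths in mm.
#' @param contrast Optional contrast tag, one of `"nulled"`, `"bold"`,
#'   `"vaso"`, or `NULL` for non-functional volumes.
#' @return An object of class `vol3d`: the array with `voxel_mm` and
#'   `contrast` attributes.
#' @export
vol3d <- function(data, voxel_mm, contrast = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be 3 positive numbers", call. = FALSE)
  if (!is.null(contrast))
    contrast <- match.arg(contrast, c("nulled", "bold", "vaso"))
  structure(data, voxel_mm = voxel_mm, contrast = contrast, class = "vol3d")
}

#' Time series of volumes (4D lattice)
#'
#' A 4D array `(x, y, z, t)` with voxel size, repetition time between
#' consecutive stored volumes (`tr_s`), a contrast tag and the acquisition
#' offset of the first volume (`t0_s`). For interleaved nulled/not-nulled
#' acquisitions `tr_s` of the interleaved stack is the volume-to-volume time;
#' after [split_interleaved()] each contrast carries the pair repetition time.
#'
#' @param data 4D numeric array, time last.
#' @param voxel_mm Voxel size in mm (length 3, or scalar for isotropic).
#' @param tr_s Time between consecutive volumes of this series, seconds.
#' @param contrast `"nulled"`, `"bold"` or `"vaso"`.
#' @param t0_s Acquisition time of the first volume, seconds.
#' @return An object of class `series4d`.
#' @export
series4d <- function(data, voxel_mm, tr_s, contrast = c("nulled", "bold", "vaso"),
                     t0_s = 0) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array", call. = FALSE)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a single positive number", call. = FALSE)
  contrast <- match.arg(contrast)
  structure(data, voxel_mm = voxel_mm, tr_s = tr_s, contrast = contrast,
            t0_s = t0_s, class = "series4d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels @ %s mm%s\n",
              paste(dim(x), collapse = " x "),
              paste(signif(attr(x, "voxel_mm"), 4), collapse = " x "),
              if (is.null(attr(x, "contrast"))) "" else
                paste0(" [", attr(x, "contrast"), "]")))
  invisible(x)
}

#' @export
print.series4d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<series4d> %s voxels x %d volumes, tr = %.4g s, t0 = %.4g s [%s]\n",
              paste(d[1:3], collapse = " x "), d[4], attr(x, "tr_s"),
              attr(x, "t0_s"), attr(x, "contrast")))
  invisible(x)
}

n_volumes <- function(s) dim(s)[4L]

voxel_mm <- function(x) attr(x, "voxel_mm")

#' Number of volumes, repetition time and contrast of a series
#'
#' Small accessors used throughout the pipeline.
#' @param s A [series4d()].
#' @return `series_tr()` the repetition time in seconds; `series_contrast()`
#'   the contrast tag; `series_t0()` the first-volume offset in seconds.
#' @export
series_tr <- function(s) attr(s, "tr_s")

#' @rdname series_tr
#' @export
series_contrast <- function(s) attr(s, "contrast")

#' @rdname series_tr
#' @export
series_t0 <- function(s) attr(s, "t0_s")

# voxel x time matrix view of a series (copies)
series_matrix <- function(s) {
  d <- dim(s)
  matrix(as.numeric(s), prod(d[1:3]), d[4L])
}

# rebuild a series from a voxel x time matrix using `like` for metadata
series_from_matrix <- function(m, like, tr_s = series_tr(like),
                               contrast = series_contrast(like),
                               t0_s = series_t0(like)) {
  d <- dim(like)
  series4d(array(m, dim = c(d[1:3], ncol(m))), voxel_mm(like),
           tr_s = tr_s, contrast = contrast, t0_s = t0_s)
}

vol_like <- function(values, like, contrast = NULL) {
  d <- if (inherits(like, "series4d")) dim(like)[1:3] else dim(like)
  vol3d(array(values, dim = d), voxel_mm(like), contrast = contrast)
}

# physical centre coordinates (mm) of a set of 1-based voxel index triples
voxel_coords_mm <- function(idx, voxel_mm) {
  idx <- matrix(idx, ncol = 3L)
  sweep(idx - 0.5, 2L, voxel_mm, `*`)
}

# linear index <-> (i,j,k) triples for dimension `d`
linear_to_triple <- function(lin, d) {
  lin0 <- lin - 1L
  i <- lin0 %% d[1L]
  j <- (lin0 %/% d[1L]) %% d[2L]
  k <- lin0 %/% (d[1L] * d[2L])
  cbind(i, j, k) + 1L
}

triple_to_linear <- function(trip, d) {
  trip <- matrix(trip, ncol = 3L)
  (trip[, 3L] - 1L) * d[1L] * d[2L] + (trip[, 2L] - 1L) * d[1L] + trip[, 1L]
}

# the 26-neighbourhood offsets (excluding the origin)
offsets26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Tidy a volume into a tibble of voxel records
#'
#' Returns one row per (finite, by default non-zero-maskable) voxel with its
#' index triple, physical position in mm and value — the bridge from the
#' lattice containers into tidyverse workflows.
#'
#' @param x A [vol3d()].
#' @param drop_na Drop voxels with `NA` value (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `i, j, k, x_mm, y_mm, z_mm, value`.
#' @importFrom generics tidy
#' @method tidy vol3d
#' @export
tidy.vol3d <- function(x, drop_na = TRUE, ...) {
  d <- dim(x)
  keep <- if (drop_na) which(!is.na(x)) else seq_len(prod(d))
  trip <- linear_to_triple(keep, d)
  mm <- voxel_coords_mm(trip, voxel_mm(x))
  tibble::tibble(i = trip[, 1L], j = trip[, 2L], k = trip[, 3L],
                 x_mm = mm[, 1L], y_mm = mm[, 2L], z_mm = mm[, 3L],
                 value = as.numeric(x[keep]))
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
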