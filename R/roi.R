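#' Largest 26-connected component of a binary mask
#'
#' Ties between equal-sized components are broken deterministically in favour
#' of the component containing the smallest linear voxel index.
#'
#' @param mask Logical [vol3d()].
#' @return Logical [vol3d()] containing only the largest component; an empty
#'   input returns an empty mask with a warning.
#' @export
largest_cluster <- function(mask) {
  d <- dim(mask); h <- attr(mask, "voxel_mm")
  m <- array(as.logical(mask), dim = d)
  if (!any(m)) {
    warning("largest_cluster: empty input mask")
    return(vol3d(array(FALSE, dim = d), h))
  }
  mg <- mask_graph(m, h)
  comp <- igraph::components(mg$graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest linear index among members decides
    first_idx <- vapply(best, function(cc)
      min(mg$idx[comp$membership == cc]), numeric(1))
    best <- best[which.min(first_idx)]
  }
  out <- array(FALSE, dim = d)
  out[mg$idx[comp$membership == best]] <- TRUE
  vol3d(out, h)
}

#' Columnar max-propagation across cortical depth (UVD filter)
#'
#' For every gray-matter voxel of the disk, a thin cylinder (default radius
#' 0.45 mm) is placed along the local column direction spanning the full
#' cortical depth, and the voxel receives the maximum input value found
#' within its cylinder. Applied to a binarised activation map this propagates
#' any active voxel across all depths of its column, so that a similar number
#' of voxels is included at every depth level.
#'
#' @param input Numeric/logical [vol3d()] (values to propagate), `NA`/0
#'   outside the mask of interest.
#' @param disk Logical [vol3d()]: the gray-matter disk over which cylinders
#'   are placed.
#' @param depth Depth [vol3d()] (defines gray matter).
#' @param column Column direction field from [column_field()].
#' @param radius_mm Cylinder radius, default 0.45.
#' @param step_frac Line sampling step as a fraction of the smallest voxel
#'   edge, default 0.25.
#' @param max_extent_mm Half-length bound of the column line, default 6.
#' @return [vol3d()] of propagated values on `disk`; voxels with an undefined
#'   column direction are skipped and counted in attribute `n_skipped`.
#' @export
uvd_filter_max <- function(input, disk, depth, column, radius_mm = 0.45,
                           step_frac = 0.25, max_extent_mm = 6) {
  d <- dim(depth); h <- voxel_mm(depth)
  gm <- !is.na(depth)
  dk <- array(as.logical(disk), dim = d) & gm
  vals <- array(as.numeric(input), dim = d)
  vals[is.na(vals)] <- 0
  idx <- which(dk)
  out <- array(NA_real_, dim = d)
  if (!length(idx)) return(vol3d(out, h))
  trips <- linear_to_triple(idx, d)
  mm <- voxel_coords_mm(trips, h)
  cvec <- matrix(NA_real_, length(idx), 3L)
  for (ax in 1:3) cvec[, ax] <- column[, , , ax][idx]
  step <- step_frac * min(h)
  s_grid <- seq(-max_extent_mm, max_extent_mm, by = step)
  offs27 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  n_skipped <- 0L
  for (v in seq_along(idx)) {
    dir <- cvec[v, ]
    if (anyNA(dir)) { n_skipped <- n_skipped + 1L; next }
    p0 <- mm[v, ]
    # walk outward in both directions until the line leaves gray matter
    keep_s <- logical(length(s_grid))
    zero_i <- which.min(abs(s_grid))
    for (dir_sign in c(-1L, 1L)) {
      ii <- if (dir_sign > 0) zero_i:length(s_grid) else zero_i:1
      for (si in ii) {
        p <- p0 + s_grid[si] * dir
        vi <- floor(p / h) + 1L
        if (any(vi < 1L) || any(vi > d)) break
        if (!gm[vi[1L], vi[2L], vi[3L]]) break
        keep_s[si] <- TRUE
      }
    }
    s_in <- s_grid[keep_s]
    if (!length(s_in)) s_in <- 0
    pts <- sweep(outer(s_in, dir), 2L, p0, `+`)
    line_vox <- unique(floor(sweep(pts, 2L, h, `/`)) + 1L)
    # candidate voxels: the column voxels plus their immediate neighbours
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(offs27)), function(oi)
      sweep(line_vox, 2L, as.integer(offs27[oi, ]), `+`))))
    okc <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
      cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[okc, , drop = FALSE]
    lin <- triple_to_linear(cand, d)
    lin <- lin[gm[lin]]
    if (!length(lin)) { out[idx[v]] <- vals[idx[v]]; next }
    cmm <- voxel_coords_mm(linear_to_triple(lin, d), h)
    rel <- sweep(cmm, 2L, p0, `-`)
    proj <- drop(rel %*% dir)
    perp2 <- rowSums(rel^2) - proj^2
    smin <- min(s_in) - step / 2; smax <- max(s_in) + step / 2
    inside <- perp2 <= radius_mm^2 + 1e-12 & proj >= smin & proj <= smax
    sel <- lin[inside]
    out[idx[v]] <- if (length(sel)) max(vals[sel]) else vals[idx[v]]
  }
  structure(vol3d(out, h), n_skipped = n_skipped)
}

#' Peak activation voxel within gray matter
#'
#' @param statmap A `vaso_statmap` (its `z` field is maximised).
#' @param gm_mask Logical [vol3d()] restricting the search.
#' @return Voxel index triple (1-based). Ties in z (which occur when several
#'   voxels reach the numerical z cap) are resolved by the larger contrast
#'   estimate, then by the lowest linear index, so the choice is
#'   deterministic. Errors if no finite z exists in the mask.
#' @export
find_peak_voxel <- function(statmap, gm_mask) {
  d <- dim(statmap$z)
  z <- as.numeric(statmap$z)
  z[!array(as.logical(gm_mask), dim = d)] <- NA_real_
  if (all(is.na(z)))
    stop("no finite z-scores within the search mask", call. = FALSE)
  zmax <- max(z, na.rm = TRUE)
  at_max <- which(!is.na(z) & z == zmax)
  if (length(at_max) > 1L) {
    beta <- as.numeric(statmap$beta)[at_max]
    at_max <- at_max[beta == max(beta, na.rm = TRUE)]
  }
  as.integer(linear_to_triple(at_max[1L], d))
}

#' Five-step winner-take-all digit ROI construction
#'
#' Implements the digit ROI procedure: (1) normalised cortical depth is given
#' by `depth`; (2--3) each digit's winner-take-all z-map
#' (digit > other digits) is FDR-thresholded at `q` over the gray matter of
#' the geodesic disk, binarised and intersected with the disk; (4) the
#' largest 26-connected cluster is propagated across cortical depth with the
#' columnar max filter ([uvd_filter_max()]); (5) voxels belonging to more
#' than one digit ROI are removed from all of them. Every filtering step is
#' recorded in the provenance.
#'
#' @param statmaps Named list of `vaso_statmap` (one per digit,
#'   digit-versus-others contrast) on one grid.
#' @param disk Logical disk [vol3d()] from [make_disk()].
#' @param depth Depth [vol3d()].
#' @param column Column field from [column_field()].
#' @param q FDR level (default 0.001).
#' @param sided Sidedness of the z-to-p conversion for FDR (default two).
#' @param cylinder_radius_mm UVD cylinder radius (default 0.45).
#' @return A `vaso_roiset`: `labels` (integer vol3d, 1..n digits), `masks`
#'   (named list of logical vol3d), `summary` tibble (digit, voxel count,
#'   volume mm^3), `provenance` list.
#' @export
build_digit_rois <- function(statmaps, disk, depth, column, q = 0.001,
                             sided = "two", cylinder_radius_mm = 0.45) {
  d <- dim(depth); h <- voxel_mm(depth)
  gm <- !is.na(depth)
  dk <- array(as.logical(disk), dim = d) & gm
  pop <- which(dk)
  digits <- names(statmaps)
  masks <- list()
  prov <- list(q = q, sided = sided, cylinder_radius_mm = cylinder_radius_mm,
               population_voxels = length(pop), steps = list())
  for (dg in digits) {
    z <- as.numeric(statmaps[[dg]]$z)[pop]
    p <- z_to_p(z, sided = sided)
    # the binarised digit map is an activation map: only the positive
    # contrast direction enters, whatever the sidedness of the p-values
    sig <- fdr_threshold(p, q = q) & !is.na(z) & z > 0
    binmask <- array(FALSE, dim = d)
    binmask[pop[sig]] <- TRUE
    n_sig <- sum(sig)
    if (n_sig == 0L) {
      warning(sprintf("digit %s: no suprathreshold voxels; empty ROI", dg))
      masks[[dg]] <- vol3d(binmask, h)
      prov$steps[[dg]] <- list(n_suprathreshold = 0L, n_largest_cluster = 0L,
                               n_propagated = 0L)
      next
    }
    clus <- largest_cluster(vol3d(binmask, h))
    propagated <- uvd_filter_max(clus, vol3d(dk, h), depth, column,
                                 radius_mm = cylinder_radius_mm)
    roi <- array(FALSE, dim = d)
    roi[which(!is.na(propagated) & propagated > 0)] <- TRUE
    masks[[dg]] <- vol3d(roi, h)
    prov$steps[[dg]] <- list(n_suprathreshold = n_sig,
                             n_largest_cluster = sum(clus),
                             n_propagated = sum(roi),
                             n_skipped_columns = attr(propagated, "n_skipped"))
  }
  # step 5: remove voxels claimed by multiple digit ROIs
  counts <- Reduce(`+`, lapply(masks, function(m) array(as.numeric(m), dim = d)))
  shared <- counts > 1
  prov$n_overlap_removed <- sum(shared)
  labels <- array(0L, dim = d)
  for (i in seq_along(digits)) {
    m <- array(as.logical(masks[[i]]), dim = d) & !shared
    masks[[i]] <- vol3d(m, h)
    labels[m] <- i
  }
  names(masks) <- digits
  vox_mm3 <- prod(h)
  summary <- tibble::tibble(
    digit = digits,
    n_voxels = vapply(masks, function(m) sum(m), integer(1)),
    volume_mm3 = vapply(masks, function(m) sum(m) * vox_mm3, numeric(1)))
  structure(list(labels = vol3d(labels, h), masks = masks,
                 summary = summary, provenance = prov),
            class = "vaso_roiset")
}

#' @export
print.vaso_roiset <- function(x, ...) {
  cat("<vaso_roiset>\n")
  print(x$summary)
  cat(sprintf("overlap voxels removed: %d\n", x$provenance$n_overlap_removed))
  invisible(x)
}

#' @importFrom generics glance
#' @method glance vaso_roiset
#' @export
glance.vaso_roiset <- function(x, ...) {
  tibble::tibble(n_digits = nrow(x$summary),
                 total_voxels = sum(x$summary$n_voxels),
                 total_volume_mm3 = sum(x$summary$volume_mm3),
                 overlap_removed = x$provenance$n_overlap_removed)
}
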