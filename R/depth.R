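# ---- small lattice helpers ---------------------------------------------

# shift a 3D array by an integer offset, padding with NA
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) { src[[ax]] <- seq_len(d[ax] - o); dst[[ax]] <- src[[ax]] + o }
    else { src[[ax]] <- seq(1 - o, d[ax]); dst[[ax]] <- src[[ax]] + o }
    if (abs(o) >= d[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

# minimum Euclidean distance from each row of `from` to the point set `to`
# (both in mm), chunked so the cross-distance matrix stays small
nn_min_dist <- function(from, to, chunk = 1024L) {
  n <- nrow(from)
  out <- numeric(n)
  to2 <- rowSums(to^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    f <- from[idx, , drop = FALSE]
    d2 <- outer(rowSums(f^2), to2, `+`) - 2 * tcrossprod(f, to)
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

# Distance from points to a voxelised surface given by boundary face
# midpoints. The raw nearest-face-point distance carries the staircase bias
# of the rasterised surface; instead, each face point gets a local tangent
# plane (centroid and smallest principal component of the face points within
# `rho`), and the point-to-plane distance to the plane of the nearest face
# point is used. The centroid averages the staircase onto the underlying
# smooth surface.
surface_distance <- function(points, faces, rho) {
  nf <- nrow(faces)
  centr <- faces
  normal <- matrix(NA_real_, nf, 3L)
  f2 <- rowSums(faces^2)
  chunk <- 512L
  for (start in seq(1L, nf, by = chunk)) {
    ii <- start:min(start + chunk - 1L, nf)
    d2 <- outer(rowSums(faces[ii, , drop = FALSE]^2), f2, `+`) -
      2 * tcrossprod(faces[ii, , drop = FALSE], faces)
    for (w in seq_along(ii)) {
      nb <- faces[d2[w, ] <= rho^2, , drop = FALSE]
      if (nrow(nb) >= 4L) {
        c0 <- colMeans(nb)
        ev <- eigen(stats::cov(nb), symmetric = TRUE)
        centr[ii[w], ] <- c0
        normal[ii[w], ] <- ev$vectors[, 3L]
      }
    }
  }
  nn <- nn_index(points, faces)
  have_plane <- !is.na(normal[nn, 1L])
  rel <- points - centr[nn, , drop = FALSE]
  d_plane <- abs(rowSums(rel * normal[nn, , drop = FALSE]))
  d_point <- sqrt(rowSums((points - faces[nn, , drop = FALSE])^2))
  ifelse(have_plane, d_plane, d_point)
}

# masked gradient of a scalar field: central differences where both
# neighbours are defined, one-sided otherwise, 0 where isolated
masked_gradient <- function(a, voxel_mm) {
  d <- dim(a)
  g <- array(0, dim = c(d, 3L))
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    fwd <- shift_array(a, -off)   # value at +1 along ax
    bwd <- shift_array(a, off)    # value at -1 along ax
    h <- voxel_mm[ax]
    cen <- (fwd - bwd) / (2 * h)
    one_f <- (fwd - a) / h
    one_b <- (a - bwd) / h
    res <- cen
    res[is.na(res)] <- one_f[is.na(res)]
    res[is.na(res)] <- one_b[is.na(res)]
    res[is.na(res)] <- 0
    res[is.na(a)] <- NA_real_
    g[, , , ax] <- res
  }
  g
}

# Gaussian smoothing of a masked field over the mask only
masked_smooth <- function(a, voxel_mm, sigma_vox = 1, radius = 2L) {
  d <- dim(a)
  acc <- array(0, dim = d)
  wacc <- array(0, dim = d)
  offs <- as.matrix(expand.grid(-radius:radius, -radius:radius, -radius:radius))
  w <- exp(-rowSums(offs^2) / (2 * sigma_vox^2))
  for (i in seq_len(nrow(offs))) {
    s <- shift_array(a, offs[i, ])
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + w[i] * s[ok]
    wacc[ok] <- wacc[ok] + w[i]
  }
  out <- acc / wacc
  out[is.na(a)] <- NA_real_
  out
}

# Local weighted quadratic fits of one or more fields sharing a common
# defined-voxel mask. For every defined voxel, fits
#   v(x) ~ a + b'x + x'Cx   (x = offset from the voxel centre, mm)
# over the Gaussian-weighted defined neighbourhood, returning the smoothed
# value `a`, the gradient `b` and the Hessian (2C). A quadratic fit is exact
# for polynomial fields up to degree 2 even when the window is cut by the
# mask, which removes the boundary bias a plain masked smoothing would have.
local_quadfit <- function(fields, voxel_mm, sigma_vox = 1.25, radius = 2L) {
  if (!is.list(fields)) fields <- list(fields)
  d <- dim(fields[[1L]])
  def <- !is.na(fields[[1L]])
  defN <- array(as.numeric(def), dim = d)
  offs <- as.matrix(expand.grid(-radius:radius, -radius:radius, -radius:radius))
  w_off <- exp(-rowSums(offs^2) / (2 * sigma_vox^2))
  # polynomial basis of the offset (constant per shift)
  poly <- function(o) {
    x <- o[1] * voxel_mm[1]; y <- o[2] * voxel_mm[2]; z <- o[3] * voxel_mm[3]
    c(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
  }
  nb <- 10L
  # unique entries of M = sum w u u': upper triangle, 55 terms
  ut <- which(upper.tri(matrix(0, nb, nb), diag = TRUE))
  M <- vector("list", length(ut))
  for (i in seq_along(ut)) M[[i]] <- array(0, dim = d)
  rhs <- lapply(fields, function(f)
    lapply(seq_len(nb), function(i) array(0, dim = d)))
  for (s in seq_len(nrow(offs))) {
    o <- offs[s, ]
    ind <- shift_array(defN, -o)          # 1 where the neighbour is defined
    ind[is.na(ind)] <- 0
    if (!any(ind > 0)) next
    u <- poly(o)
    w <- w_off[s]
    uu <- tcrossprod(u)[ut]
    for (i in seq_along(ut))
      M[[i]] <- M[[i]] + (w * uu[i]) * ind
    for (fi in seq_along(fields)) {
      v <- shift_array(fields[[fi]], -o)
      v[is.na(v)] <- 0
      for (bi in seq_len(nb))
        rhs[[fi]][[bi]] <- rhs[[fi]][[bi]] + (w * u[bi]) * (v * ind)
    }
  }
  idx <- which(def)
  Mm <- vapply(M, function(a) a[idx], numeric(length(idx)))
  Rm <- lapply(rhs, function(r)
    vapply(r, function(a) a[idx], numeric(length(idx))))
  tmpl <- matrix(0, nb, nb)
  out <- lapply(fields, function(f)
    list(value = array(NA_real_, dim = d),
         grad = array(NA_real_, dim = c(d, 3L)),
         hess = vector("list", length(idx))))
  coefs <- lapply(fields, function(f) matrix(NA_real_, length(idx), nb))
  for (v in seq_along(idx)) {
    Mv <- tmpl
    Mv[upper.tri(Mv, diag = TRUE)] <- Mm[v, ]
    Mv <- Mv + t(Mv) - diag(diag(Mv))
    ch <- tryCatch(chol(Mv), error = function(e) NULL)
    for (fi in seq_along(fields)) {
      if (is.null(ch)) {
        cf <- c(fields[[fi]][idx[v]], rep(0, nb - 1L))   # degenerate window
      } else {
        cf <- backsolve(ch, forwardsolve(t(ch), Rm[[fi]][v, ]))
      }
      coefs[[fi]][v, ] <- cf
    }
  }
  for (fi in seq_along(fields)) {
    cf <- coefs[[fi]]
    out[[fi]]$value[idx] <- cf[, 1L]
    for (ax in 1:3) {
      g <- array(NA_real_, dim = d)
      g[idx] <- cf[, 1L + ax]
      out[[fi]]$grad[, , , ax] <- g
    }
    out[[fi]]$hess_coef <- cf[, 5:10, drop = FALSE]   # xx,yy,zz,xy,xz,yz
  }
  c(out, list(idx = idx))
}

# mm coordinates of the midpoints of faces between `from_label` voxels and
# `to_label` voxels (6-neighbourhood)
boundary_face_points <- function(seg, from_label, to_label) {
  d <- dim(seg); h <- voxel_mm(seg)
  a <- array(as.numeric(seg), dim = d)
  pts <- list()
  axes <- diag(3L)
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    off <- sgn * axes[ax, ]
    nb <- shift_array(a, -off)   # neighbour value at +off
    sel <- which(a == from_label & !is.na(nb) & nb == to_label)
    if (!length(sel)) next
    trip <- linear_to_triple(sel, d)
    mm <- voxel_coords_mm(trip, h)
    mm[, ax] <- mm[, ax] + sgn * h[ax] / 2
    nrm <- matrix(0, nrow(mm), 3L)
    nrm[, ax] <- sgn
    pts[[length(pts) + 1L]] <- cbind(mm, nrm)
  }
  if (!length(pts)) {
    out <- matrix(numeric(0), 0L, 3L)
    attr(out, "outward") <- matrix(numeric(0), 0L, 3L)
    return(out)
  }
  all <- do.call(rbind, pts)
  out <- all[, 1:3, drop = FALSE]
  # lattice hint of the outward direction (from `from_label` toward
  # `to_label`), used to orient fitted surface normals
  attr(out, "outward") <- all[, 4:6, drop = FALSE]
  out
}

# Curvature of a voxelised boundary surface at each face point: fit a local
# quadric w = b0 + b1 u + b2 v + b3 u^2 + b4 uv + b5 v^2 in the tangent
# frame (PCA of the face points within `rho`, normal oriented along the
# outward lattice hint) and read the divergence of the outward normal field
# at the surface, c = -(2 b3 + 2 b5). Positive c means the surface bends
# around a centre on the inner (gray/white) side, as on a gyral crown seen
# from the pial surface. A second pass averages c over the same
# neighbourhoods, since boundary curvature varies on scales much larger than
# a voxel.
face_curvature <- function(faces, rho) {
  outward <- attr(faces, "outward")
  nf <- nrow(faces)
  cvec <- rep(NA_real_, nf)
  f2 <- rowSums(faces^2)
  chunk <- 512L
  nbrs <- vector("list", nf)
  for (start in seq(1L, nf, by = chunk)) {
    ii <- start:min(start + chunk - 1L, nf)
    d2 <- outer(rowSums(faces[ii, , drop = FALSE]^2), f2, `+`) -
      2 * tcrossprod(faces[ii, , drop = FALSE], faces)
    for (w in seq_along(ii)) {
      sel <- which(d2[w, ] <= rho^2)
      nbrs[[ii[w]]] <- sel
      nb <- faces[sel, , drop = FALSE]
      if (nrow(nb) < 8L) next
      c0 <- colMeans(nb)
      ev <- eigen(stats::cov(nb), symmetric = TRUE)
      n3 <- ev$vectors[, 3L]
      if (sum(n3 * outward[ii[w], ]) < 0) n3 <- -n3
      rel <- sweep(nb, 2L, c0)
      u <- rel %*% ev$vectors[, 1L]
      v <- rel %*% ev$vectors[, 2L]
      wv <- rel %*% n3
      X <- cbind(1, u, v, u^2, u * v, v^2)
      fit <- tryCatch(solve(crossprod(X), crossprod(X, wv)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      cvec[ii[w]] <- -2 * (fit[4L] + fit[6L])
    }
  }
  # neighbourhood mean of the per-face estimates
  csm <- vapply(seq_len(nf), function(i) {
    vals <- cvec[nbrs[[i]]]
    if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
  }, numeric(1))
  csm
}

# ---- cortical depth -----------------------------------------------------

#' Normalised cortical depth of gray-matter voxels
#'
#' Computes a per-voxel depth coordinate in `[0, 1]` (0 at the pial/CSF
#' boundary, 1 at the white-matter boundary) from a tissue segmentation.
#'
#' The *equidistant* metric is `d_csf / (d_csf + d_wm)`, where the two terms
#' are distances from the voxel centre to locally fitted tangent planes of
#' the gray/CSF and gray/white boundary surfaces (plane fitting averages the
#' staircase of the rasterised boundary onto the underlying smooth surface).
#' The *equivolume* metric (the default) corrects the equidistant estimate
#' for local curvature so that equal depth increments enclose equal tissue
#' volume: the divergence `c` of the pial surface normal — the local
#' curvature of the depth level sets — is estimated by quadric fits to the
#' pial face points, propagated to the voxel as `c / (1 - c * d_csf)`, and
#' the annulus (locally cylindrical) equal-volume reparameterisation is
#' applied in closed form. Flat cortex (voxel curvature below `kappa_min`)
#' reduces to the equidistant solution.
#'
#' @param seg Label [vol3d()] with codes 0 background, 1 white matter,
#'   2 gray matter, 3 CSF.
#' @param metric `"equivolume"` (default) or `"equidistant"`.
#' @param sigma_vox Width (voxels) of the local quadratic fits that denoise
#'   the boundary-distance fields.
#' @param kappa_min Curvature magnitude (1/mm) below which the cortex is
#'   treated as flat.
#' @return A depth [vol3d()], `NA` outside gray matter, with attribute
#'   `metric`.
#' @export
compute_depth <- function(seg, metric = c("equivolume", "equidistant"),
                          sigma_vox = 1, kappa_min = 0.02) {
  metric <- match.arg(metric)
  d <- dim(seg); h <- voxel_mm(seg)
  gm_idx <- which(seg == 2L)
  if (!length(gm_idx)) stop("segmentation has no gray matter", call. = FALSE)
  csf_faces <- boundary_face_points(seg, 2L, 3L)
  wm_faces <- boundary_face_points(seg, 2L, 1L)
  if (!nrow(csf_faces) || !nrow(wm_faces))
    stop("gray matter has no CSF or no white-matter boundary", call. = FALSE)
  gm_mm <- voxel_coords_mm(linear_to_triple(gm_idx, d), h)
  rho <- 3 * mean(h)
  d_csf_raw <- surface_distance(gm_mm, csf_faces, rho)
  d_wm_raw <- surface_distance(gm_mm, wm_faces, rho)
  dc_field <- array(NA_real_, dim = d); dc_field[gm_idx] <- d_csf_raw
  dw_field <- array(NA_real_, dim = d); dw_field[gm_idx] <- d_wm_raw
  # polish the staircase noise of the face-point distances with local
  # quadratic fits (exact on smooth distance fields, no boundary bias)
  fits <- local_quadfit(list(dc_field, dw_field), h, sigma_vox = sigma_vox)
  d_csf <- pmax(fits[[1L]]$value[gm_idx], 0)
  d_wm <- pmax(fits[[2L]]$value[gm_idx], 0)
  alpha_d <- pmin(1, pmax(0, d_csf / (d_csf + d_wm)))
  depth <- array(NA_real_, dim = d)
  depth[gm_idx] <- alpha_d
  if (metric == "equidistant")
    return(structure(vol3d(depth, h), metric = "equidistant"))

  # curvature of the pial surface from local quadric fits to its face
  # points, propagated inward: a voxel at distance dC below a surface patch
  # with normal divergence c sits at signed curvature c / (1 - c * dC)
  # quadric window: wide enough (in mm) to average several staircase
  # periods, independent of resolution, but never below 6 voxels
  cface <- face_curvature(csf_faces, rho = max(6 * mean(h), 2.4))
  cvox <- cface[nn_index(gm_mm, csf_faces)]
  kappa <- cvox / (1 - cvox * d_csf)

  alpha_v <- alpha_d
  curved <- which(is.finite(kappa) & abs(kappa) >= kappa_min)
  cc <- cvox[curved]
  dC <- d_csf[curved]; dW <- d_wm[curved]
  R <- 1 / abs(cc)
  pos <- cc > 0                      # centre of curvature on the WM side
  s <- ifelse(pos, R - dC, R + dC)   # voxel's distance from that centre
  r_w <- ifelse(pos, s - dW, s + dW)
  av <- ifelse(pos,
               (R^2 - s^2) / (R^2 - r_w^2),
               (s^2 - R^2) / (r_w^2 - R^2))
  ok <- s > 0 & (!pos | r_w > 0)
  alpha_v[curved[ok]] <- av[ok]
  depth[gm_idx] <- pmin(1, pmax(0, alpha_v))
  structure(vol3d(depth, h), metric = "equivolume")
}

#' Bin cortical depth into equal-width layers
#'
#' Layer index `ceiling(depth * n_bins)` clamped to `[1, n_bins]`; bin 1 is
#' the most superficial (smallest depth). The bins partition gray matter
#' exactly.
#'
#' @param depth A depth [vol3d()] from [compute_depth()].
#' @param n_bins Number of layers (>= 2); the pipeline uses 11 for laminar
#'   profiles and 3 for event-related averages.
#' @return An integer layer [vol3d()], `NA` outside gray matter.
#' @export
bin_layers <- function(depth, n_bins) {
  stopifnot(n_bins >= 2L)
  lab <- ceiling(as.numeric(depth) * n_bins)
  lab <- pmin(pmax(lab, 1L), as.integer(n_bins))
  structure(vol_like(lab, depth), n_bins = as.integer(n_bins))
}

#' Column direction field
#'
#' Unit vector along increasing cortical depth at every gray-matter voxel
#' (the local "cortical column" direction), obtained from the smoothed
#' gradient of the depth map.
#'
#' @param depth A depth [vol3d()].
#' @param sigma_vox Gradient smoothing in voxels.
#' @return A 4D array `(x, y, z, 3)` of unit vectors, `NA` where undefined.
#' @export
column_field <- function(depth, sigma_vox = 1) {
  h <- voxel_mm(depth)
  g <- masked_gradient(array(as.numeric(depth), dim = dim(depth)), h)
  for (ax in 1:3) g[, , , ax] <- masked_smooth(g[, , , ax], h, sigma_vox)
  nrm <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
  nrm[nrm < 1e-9] <- NA_real_
  for (ax in 1:3) g[, , , ax] <- g[, , , ax] / nrm
  attr(g, "voxel_mm") <- h
  g
}

# ---- distances ----------------------------------------------------------

# igraph over the 26-connected voxel graph of a logical mask; vertex i maps
# to the i-th TRUE voxel (in linear-index order)
mask_graph <- function(mask, voxel_mm) {
  d <- dim(mask)
  idx <- which(mask)
  map <- array(NA_integer_, dim = d)
  map[idx] <- seq_along(idx)
  offs <- offsets26()
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]                     # 13 unique directions
  from <- integer(0); to <- integer(0); w <- numeric(0)
  mnum <- array(as.numeric(mask), dim = d)
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    nb <- shift_array(array(as.numeric(map), dim = d), -off)
    sel <- which(mask & !is.na(nb))
    if (!length(sel)) next
    from <- c(from, map[sel])
    to <- c(to, as.integer(nb[sel]))
    w <- c(w, rep(sqrt(sum((off * voxel_mm)^2)), length(sel)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  list(graph = g, idx = idx, map = map)
}

#' Geodesic distance through a gray-matter mask
#'
#' Shortest-path distance (mm) from a seed voxel through the 26-connected
#' voxel graph of the mask, with edge lengths equal to the physical
#' centre-to-centre distance (anisotropic voxel sizes respected). This is the
#' along-cortex distance used for geodesic disks; unreachable voxels are
#' `Inf`.
#'
#' @param mask Logical [vol3d()] (or 3D array with `voxel_mm` attr).
#' @param seed Voxel index triple (1-based) inside the mask.
#' @param voxel_mm Voxel size, taken from `mask` when absent.
#' @return A [vol3d()] of distances, `NA` outside the mask.
#' @export
geodesic_distance <- function(mask, seed, voxel_mm = attr(mask, "voxel_mm")) {
  d <- dim(mask)
  m <- array(as.logical(mask), dim = d)
  seed_lin <- triple_to_linear(matrix(as.integer(seed), 1L), d)
  if (!m[seed_lin]) stop("seed voxel is outside the mask", call. = FALSE)
  mg <- mask_graph(m, voxel_mm)
  dist <- igraph::distances(mg$graph, v = mg$map[seed_lin],
                            algorithm = "dijkstra")[1L, ]
  out <- array(NA_real_, dim = d)
  out[mg$idx] <- dist
  vol3d(out, voxel_mm)
}

#' Geodesic gray-matter disk
#'
#' Flattens the ribbon onto its mid-depth shell (depth in `[0.4, 0.6]`),
#' computes geodesic distances within that shell from the seed's nearest
#' mid-depth voxel, and selects all gray-matter voxels whose foot point on
#' the shell (nearest mid-depth voxel) lies within `radius_mm`. The disk
#' therefore spans all depths over the selected cortical patch, which is what
#' restricts ROI construction to a region of cortex rather than a Euclidean
#' ball.
#'
#' @param depth Depth [vol3d()] (defines gray matter as its non-`NA` set).
#' @param seed Gray-matter voxel index triple.
#' @param radius_mm Along-cortex disk radius, default 12.
#' @param shell Depth interval defining the mid-depth shell.
#' @return Logical [vol3d()] disk mask.
#' @export
make_disk <- function(depth, seed, radius_mm = 12, shell = c(0.4, 0.6)) {
  d <- dim(depth); h <- voxel_mm(depth)
  gm <- !is.na(depth)
  seed_lin <- triple_to_linear(matrix(as.integer(seed), 1L), d)
  if (!gm[seed_lin]) stop("seed voxel is not in gray matter", call. = FALSE)
  sh <- gm & !is.na(depth) & depth >= shell[1] & depth <= shell[2]
  sh_idx <- which(sh)
  if (!length(sh_idx))
    stop("mid-depth shell is empty; cannot build a disk", call. = FALSE)
  sh_mm <- voxel_coords_mm(linear_to_triple(sh_idx, d), h)
  seed_mm <- voxel_coords_mm(linear_to_triple(seed_lin, d), h)
  near <- which.min(rowSums(sweep(sh_mm, 2L, as.numeric(seed_mm), `-`)^2))
  # along-cortex distance: geodesic through the full gray-matter graph (the
  # thin mid-depth band alone can disconnect at coarse voxel sizes), read
  # off at the shell voxels
  geod <- geodesic_distance(gm, linear_to_triple(sh_idx[near], d), h)
  gd <- as.numeric(geod)[sh_idx]
  if (all(!is.finite(gd)))
    stop("seed is not connectable to the mid-depth shell", call. = FALSE)
  # foot point of every GM voxel = nearest mid-depth voxel
  gm_idx <- which(gm)
  gm_mm <- voxel_coords_mm(linear_to_triple(gm_idx, d), h)
  foot <- nn_index(gm_mm, sh_mm)
  inside <- is.finite(gd[foot]) & gd[foot] <= radius_mm
  out <- array(FALSE, dim = d)
  out[gm_idx[inside]] <- TRUE
  vol3d(out, h)
}

# index of the nearest row of `to` for each row of `from` (chunked)
nn_index <- function(from, to, chunk = 1024L) {
  n <- nrow(from)
  out <- integer(n)
  to2 <- rowSums(to^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    f <- from[idx, , drop = FALSE]
    d2 <- outer(rowSums(f^2), to2, `+`) - 2 * tcrossprod(f, to)
    out[idx] <- apply(d2, 1L, which.min)
  }
  out
}

#' Euclidean distance bins from a peak voxel
#'
#' Straight-line distance (mm) from the peak voxel centre to every voxel in
#' the mask, cut into half-open bins `[e1, e2), [e2, e3), ...` — by default
#' the seven 2 mm bins from 0 to 14 mm used for distance-resolved response
#' profiles. Distances at or beyond the last edge are unassigned.
#'
#' @param mask Logical [vol3d()] (gray matter, possibly restricted to a
#'   disk).
#' @param peak Voxel index triple of the activation peak, inside the mask.
#' @param edges Bin edges in mm, default `seq(0, 14, 2)`.
#' @return Integer bin [vol3d()] (1-based), `NA` outside the mask or beyond
#'   the last edge, with attribute `edges`.
#' @export
euclidean_distance_bins <- function(mask, peak, edges = seq(0, 14, by = 2)) {
  d <- dim(mask); h <- attr(mask, "voxel_mm")
  m <- array(as.logical(mask), dim = d)
  peak_lin <- triple_to_linear(matrix(as.integer(peak), 1L), d)
  if (!m[peak_lin]) stop("peak voxel is outside the mask", call. = FALSE)
  idx <- which(m)
  mm <- voxel_coords_mm(linear_to_triple(idx, d), h)
  pk <- as.numeric(voxel_coords_mm(linear_to_triple(peak_lin, d), h))
  dist <- sqrt(rowSums(sweep(mm, 2L, pk, `-`)^2))
  bin <- findInterval(dist, edges, rightmost.closed = FALSE)
  bin[bin < 1L | bin >= length(edges)] <- NA_integer_
  out <- array(NA_real_, dim = d)
  out[idx] <- bin
  structure(vol3d(out, h), edges = edges)
}
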