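# Automatic lesion delineation: slice-wise fuzzy c-means inside an
# operator seed box on the CE-T1 channel, 3D connected-component cleanup,
# hole filling, and affine mapping of the mask onto the second modality.

#' Co-registered two-modality volume pair
#'
#' @param t1c,t2 3D intensity arrays (CE-T1-like and T2-like channels).
#' @param spacing mm per axis (length 3).
#' @param affine_t1c,affine_t2 4x4 voxel-to-world transforms (0-based voxel
#'   indices); default diagonal spacing.
#' @return object of class `volume_pair`.
#' @export
volume_pair <- function(t1c, t2, spacing, affine_t1c = NULL,
                        affine_t2 = NULL) {
  stopifnot(length(dim(t1c)) == 3, length(dim(t2)) == 3,
            length(spacing) == 3, all(spacing > 0))
  if (is.null(affine_t1c)) affine_t1c <- diag(c(spacing, 1))
  if (is.null(affine_t2)) affine_t2 <- diag(c(spacing, 1))
  for (a in list(affine_t1c, affine_t2))
    if (abs(det(a)) < 1e-12)
      stop_radscore("affine must be invertible", "radscore_spec_error")
  structure(list(t1c = t1c, t2 = t2, spacing = as.double(spacing),
                 affine_t1c = affine_t1c, affine_t2 = affine_t2),
            class = "volume_pair")
}

#' Binary tumor mask on a stated grid
#'
#' @param mask logical (or 0/1) 3D array.
#' @param spacing mm per axis.
#' @param affine 4x4 voxel-to-world transform of the grid the mask indexes.
#' @return object of class `tumor_mask`.
#' @export
tumor_mask <- function(mask, spacing, affine = NULL) {
  stopifnot(length(dim(mask)) == 3)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(mask = array(as.logical(mask), dim = dim(mask)),
                 spacing = as.double(spacing), affine = affine),
            class = "tumor_mask")
}

#' Operator seed box
#'
#' The in-plane rectangle and slice range an operator would place around
#' the lesion on the CE-T1 volume.
#'
#' @param x_range,y_range in-plane voxel index ranges (1-based, inclusive,
#'   length 2).
#' @param slices first and last axial slice containing the lesion (1-based,
#'   length 2).
#' @return object of class `seed_box`.
#' @export
seed_box <- function(x_range, y_range, slices) {
  stopifnot(length(x_range) == 2, length(y_range) == 2, length(slices) == 2)
  if (slices[1] > slices[2] || x_range[1] > x_range[2] ||
      y_range[1] > y_range[2])
    stop_radscore("seed box ranges must be increasing", "radscore_spec_error")
  structure(list(x_range = as.integer(x_range), y_range = as.integer(y_range),
                 slices = as.integer(slices)), class = "seed_box")
}

# Seed box from a truth mask: bounding box padded in-plane (emulates the
# operator's rectangle).
seed_box_from_mask <- function(mask, pad = 4L) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  seed_box(
    x_range = c(max(1L, min(idx[, 1]) - pad), min(d[1], max(idx[, 1]) + pad)),
    y_range = c(max(1L, min(idx[, 2]) - pad), min(d[2], max(idx[, 2]) + pad)),
    slices = range(idx[, 3]))
}

#' Fuzzy c-means clustering of 1D intensities
#'
#' Standard FCM fixed point: memberships `u_ik` proportional to
#' `(1/|x_i - c_k|)^(2/(m-1))` row-normalized to one, centroids the
#' membership^m-weighted means, alternated until the largest centroid move
#' falls below `tol` times the data range (relative tolerance, so the
#' clustering is invariant to affine intensity rescaling) or `max_iter`.
#'
#' @param values numeric vector; needs at least `n_clusters` distinct
#'   values.
#' @param n_clusters number of clusters.
#' @param fuzziness exponent m > 1.
#' @param tol relative centroid-change tolerance.
#' @param max_iter iteration cap.
#' @param init `"quantile"` (deterministic centroid init at the
#'   `(k - 0.5)/K` intensity quantiles) or `"random"`.
#' @param seed used only for `init = "random"`.
#' @return list with `memberships` (n x K, rows sum to 1), `centroids`,
#'   `objective` (per-iteration value of the FCM objective, non-increasing),
#'   `iterations`, `converged`.
#' @export
fcm_cluster <- function(values, n_clusters = 2, fuzziness = 2, tol = 1e-5,
                        max_iter = 200, init = c("quantile", "random"),
                        seed = NULL) {
  init <- match.arg(init)
  values <- as.double(values)
  n <- length(values)
  stopifnot(n >= 1, n_clusters >= 1, fuzziness > 1)
  rng <- diff(range(values))
  if (n_clusters == 1) {
    return(list(memberships = matrix(1, n, 1), centroids = mean(values),
                objective = sum((values - mean(values))^2), iterations = 0L,
                converged = TRUE))
  }
  if (rng == 0)
    stop_radscore("all values identical: degenerate input for FCM",
                  "radscore_degenerate_error")
  if (length(unique(values)) < n_clusters)
    stop_radscore("need at least n_clusters distinct values",
                  "radscore_degenerate_error")
  centroids <- if (init == "quantile") {
    quantile(values, probs = (seq_len(n_clusters) - 0.5) / n_clusters,
             names = FALSE)
  } else {
    with_seed(seed, sample(unique(values), n_clusters))
  }
  expo <- 2 / (fuzziness - 1)
  memberships_for <- function(cent) {
    d <- abs(outer(values, cent, "-"))
    u <- matrix(0, n, n_clusters)
    zero <- d < .Machine$double.eps
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      z <- zero[has_zero, , drop = FALSE]
      u[has_zero, ] <- z / rowSums(z)
    }
    if (any(!has_zero)) {
      w <- d[!has_zero, , drop = FALSE]^(-expo)
      u[!has_zero, ] <- w / rowSums(w)
    }
    u
  }
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    u <- memberships_for(centroids)
    um <- u^fuzziness
    objective <- c(objective,
                   sum(um * abs(outer(values, centroids, "-"))^2))
    new_c <- colSums(um * values) / colSums(um)
    moved <- max(abs(new_c - centroids))
    centroids <- new_c
    if (moved < tol * rng) { converged <- TRUE; break }
  }
  list(memberships = memberships_for(centroids), centroids = centroids,
       objective = objective, iterations = iter, converged = converged)
}

# Fill background cavities not connected to the array border;
# `connectivity` is the background connectivity (6 in 3D, 4 per slice).
fill_holes3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  labs <- cc_label3d(as.integer(bg), d, 6L, FALSE)
  labs <- array(labs, dim = d)
  border <- unique(c(labs[1, , ], labs[d[1], , ], labs[, 1, ],
                     labs[, d[2], ], labs[, , 1], labs[, , d[3]]))
  border <- setdiff(border, 0L)
  mask | (bg & !(labs %in% border))
}

fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[3])) {
    sl <- mask[, , z, drop = FALSE]
    d2 <- c(d[1], d[2], 1L)
    bg <- !sl
    labs <- array(cc_label3d(as.integer(bg), d2, 6L, FALSE), dim = d2)
    border <- setdiff(unique(c(labs[1, , 1], labs[d[1], , 1],
                               labs[, 1, 1], labs[, d[2], 1])), 0L)
    mask[, , z] <- sl | (bg & !(labs %in% border))
  }
  mask
}

#' Segment the lesion on the CE-T1 channel
#'
#' Runs two-cluster FCM on each axial slice inside the seed box, assigns
#' voxels whose membership in the brighter cluster exceeds 0.5, stacks the
#' slices, keeps the largest 26-connected 3D component, and fills enclosed
#' holes (3D, then per-slice 2D for thick-slice grids).  The result is
#' invariant to positive affine rescaling of the input intensities.
#'
#' @param pair a [volume_pair()].
#' @param box a [seed_box()].
#' @param fuzziness,tol,max_iter FCM parameters (see [fcm_cluster()]).
#' @param min_membership tumor-membership binarization threshold.
#' @return a [tumor_mask()] on the CE-T1 grid.
#' @export
segment_volume <- function(pair, box, fuzziness = 2, tol = 1e-5,
                           max_iter = 200, min_membership = 0.5) {
  stopifnot(inherits(pair, "volume_pair"), inherits(box, "seed_box"))
  d <- dim(pair$t1c)
  if (box$x_range[2] > d[1] || box$y_range[2] > d[2] || box$slices[2] > d[3])
    stop_radscore("seed box exceeds the volume grid", "radscore_spec_error")
  seg <- array(FALSE, dim = d)
  xr <- box$x_range[1]:box$x_range[2]
  yr <- box$y_range[1]:box$y_range[2]
  for (z in box$slices[1]:box$slices[2]) {
    vals <- as.vector(pair$t1c[xr, yr, z])
    if (diff(range(vals)) == 0) next
    fc <- fcm_cluster(vals, n_clusters = 2, fuzziness = fuzziness,
                      tol = tol, max_iter = max_iter)
    tumor_k <- which.max(fc$centroids)
    seg[xr, yr, z] <- fc$memberships[, tumor_k] > min_membership
  }
  if (!any(seg))
    stop_radscore("segmentation produced an empty mask",
                  "radscore_segmentation_error")
  labs <- array(cc_label3d(as.integer(seg), d, 26L, FALSE), dim = d)
  counts <- tabulate(labs[labs > 0])
  seg <- labs == which.max(counts)
  seg <- fill_holes3d(seg)
  seg <- fill_holes_slicewise(seg)
  tumor_mask(seg, spacing = pair$spacing, affine = pair$affine_t1c)
}

# Trilinear interpolation of a 3D array at 0-based voxel coordinates;
# points outside the grid contribute zero.
interp3 <- function(arr, x, y, z) {
  d <- dim(arr)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(length(x))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) fx else 1 - fx) *
         (if (dy == 1) fy else 1 - fy) *
         (if (dz == 1) fz else 1 - fz)
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    ok <- w > 0 & xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] &
      zi >= 0 & zi < d[3]
    if (any(ok)) {
      idx <- 1 + xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok])
      out[ok] <- out[ok] + w[ok] * arr[idx]
    }
  }
  out
}

#' Map a tumor mask onto another grid through affine transforms
#'
#' Resamples the mask through `inv(affine_src) %*% affine_dst` with linear
#' interpolation and re-binarizes at 0.5.
#'
#' @param mask a [tumor_mask()] on the source grid.
#' @param affine_src,affine_dst 4x4 voxel-to-world transforms.
#' @param dst_shape voxels per axis of the destination grid.
#' @return a [tumor_mask()] on the destination grid.
#' @export
map_mask <- function(mask, affine_src, affine_dst, dst_shape) {
  stopifnot(inherits(mask, "tumor_mask"))
  for (a in list(affine_src, affine_dst))
    if (abs(det(a)) < 1e-12)
      stop_radscore("affine must be invertible", "radscore_spec_error")
  dst_shape <- as.integer(dst_shape)
  tm <- solve(affine_src) %*% affine_dst
  g <- expand.grid(i = 0:(dst_shape[1] - 1), j = 0:(dst_shape[2] - 1),
                   k = 0:(dst_shape[3] - 1))
  src <- tm %*% rbind(g$i, g$j, g$k, 1)
  vals <- interp3(array(as.double(mask$mask), dim = dim(mask$mask)),
                  src[1, ], src[2, ], src[3, ])
  out <- array(vals >= 0.5, dim = dst_shape)
  if (!any(out))
    stop_radscore("mapped mask is empty", "radscore_segmentation_error")
  spacing_dst <- sqrt(colSums(affine_dst[1:3, 1:3]^2))
  tumor_mask(out, spacing = spacing_dst, affine = affine_dst)
}
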