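# First-order feature block: 14 shape descriptors + 18 intensity
# statistics.  Shape uses a marching-tetrahedra surface mesh (compiled) for
# mesh volume / surface area and principal-component axis lengths on
# physical voxel coordinates.  Degenerate-moment convention: skewness and
# kurtosis of a constant region are reported as 0.

#' First-order intensity statistics (18)
#'
#' @param values numeric vector of in-mask intensities.
#' @param levels discretized levels of the same voxels (for entropy /
#'   uniformity); defaults to a 32-bin discretization of `values`.
#' @param voxel_volume physical volume of one voxel in mm^3.
#' @return named numeric vector of 18 features.
#' @export
intensity_features <- function(values, levels = NULL, voxel_volume = 1) {
  if (length(values) == 0)
    stop_radscore("empty mask", "radscore_degenerate_error")
  if (is.null(levels)) levels <- discretize(values, 32)
  np <- length(values)
  p <- tabulate(levels) / np
  p <- p[p > 0]
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  robust <- values[values >= q[1] & values <= q[5]]
  c(Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(values),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = diff(range(values)),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    Kurtosis = if (m2 == 0) 0 else m4 / m2^2,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Separable Gaussian smoothing of a 3D array (zero padding at the border),
# sigma in voxels per axis.  Used to anti-alias the binary mask before
# isosurface extraction: meshing the raw binary staircase overestimates
# surface area by ~25% on spheres, while the 0.5 level set of the smoothed
# indicator tracks the true surface to a few percent.
gauss_smooth3 <- function(arr, sigma = 1) {
  sigma <- rep_len(sigma, 3)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-((-r):r)^2 / (2 * sigma[ax]^2))
    k <- k / sum(k)
    d <- dim(arr)
    out <- array(0, dim = d)
    for (s in (-r):r) {
      w <- k[s + r + 1]
      src_lo <- max(1, 1 + s); src_hi <- min(d[ax], d[ax] + s)
      if (src_lo > src_hi) next
      dst_lo <- max(1, 1 - s); dst_hi <- min(d[ax], d[ax] - s)
      idx_src <- src_lo:src_hi; idx_dst <- dst_lo:dst_hi
      if (ax == 1) out[idx_dst, , ] <- out[idx_dst, , ] +
          w * arr[idx_src, , ]
      else if (ax == 2) out[, idx_dst, ] <- out[, idx_dst, ] +
          w * arr[, idx_src, ]
      else out[, , idx_dst] <- out[, , idx_dst] + w * arr[, , idx_src]
    }
    arr <- out
  }
  arr
}

# Mesh volume and surface area of a mask: marching tetrahedra on the
# Gaussian-smoothed indicator (falls back to the raw binary field for
# masks too small to survive smoothing).
mask_mesh_stats <- function(mask, spacing, sigma = 0.8) {
  d <- dim(mask)
  sm <- gauss_smooth3(array(as.double(mask), dim = d), sigma)
  if (max(sm) < 0.5 + 1e-9)
    sm <- array(as.double(mask), dim = d)
  mesh_stats_field(sm, d, as.double(spacing), 0.5)
}

# Boundary voxels: in-mask with at least one 6-neighbour outside the mask
# or outside the grid.
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  interior <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  mask & !interior
}

max_pairwise <- function(pts) {
  if (nrow(pts) < 2) return(0)
  max(dist(pts))
}

#' Shape descriptors (14)
#'
#' Mesh volume and surface area come from a marching-tetrahedra
#' triangulation of the mask at iso-level 0.5; axis lengths are
#' `4 * sqrt(eigenvalue)` of the physical-coordinate covariance.
#'
#' @param mask logical 3D array.
#' @param spacing mm per axis.
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing) {
  if (!any(mask)) stop_radscore("empty mask", "radscore_degenerate_error")
  d <- dim(mask)
  ms <- mask_mesh_stats(mask, spacing)
  vol_mesh <- ms[1]; area <- ms[2]
  np <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  phys <- sweep(idx - 1, 2, spacing, "*")
  bidx <- which(boundary_voxels(mask), arr.ind = TRUE)
  bphys <- sweep(bidx - 1, 2, spacing, "*")
  max2d <- function(plane_axes, slice_axis) {
    m <- 0
    for (s in unique(bidx[, slice_axis])) {
      pts <- bphys[bidx[, slice_axis] == s, plane_axes, drop = FALSE]
      m <- max(m, max_pairwise(pts))
    }
    m
  }
  ctr <- colMeans(phys)
  cc <- sweep(phys, 2, ctr)
  ev <- eigen(crossprod(cc) / np, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  c(MeshVolume = vol_mesh,
    VoxelVolume = np * prod(spacing),
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol_mesh,
    Sphericity = (36 * pi * vol_mesh^2)^(1 / 3) / area,
    Maximum3DDiameter = max_pairwise(bphys),
    Maximum2DDiameterSlice = max2d(c(1, 2), 3),
    Maximum2DDiameterColumn = max2d(c(1, 3), 2),
    Maximum2DDiameterRow = max2d(c(2, 3), 1),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] == 0) 1 else sqrt(ev[2] / ev[1]),
    Flatness = if (ev[1] == 0) 1 else sqrt(ev[3] / ev[1]))
}

#' Combined first-order block (32 = 14 shape + 18 intensity)
#'
#' @param values in-mask intensities.
#' @param mask logical 3D array the values came from.
#' @param spacing mm per axis.
#' @param levels optional discretized levels for entropy / uniformity.
#' @return named numeric vector of 32 features (`shape_*`, `firstorder_*`).
#' @export
base_features <- function(values, mask, spacing, levels = NULL) {
  sh <- shape_features(mask, spacing)
  fo <- intensity_features(values, levels = levels,
                           voxel_volume = prod(spacing))
  c(setNames(sh, paste0("shape_", names(sh))),
    setNames(fo, paste0("firstorder_", names(fo))))
}
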