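# Fixed-bin-count gray-level discretization.  Bin-count (rather than
# bin-width) discretization makes every downstream texture feature
# invariant to positive affine rescaling of the input intensities, which
# matters when pooling scanners with different intensity scales.

#' Discretize in-mask intensities to 1..n_bins
#'
#' `level = floor((x - min) / (max - min) * n_bins) + 1`, with `x = max`
#' assigned `n_bins`; a constant region maps to level 1.
#'
#' @param values numeric vector of in-mask intensities.
#' @param n_bins number of gray levels (>= 2).
#' @return integer vector of levels in `1..n_bins`.
#' @export
discretize <- function(values, n_bins = 32) {
  stopifnot(n_bins >= 2)
  if (length(values) == 0)
    stop_radscore("empty mask: nothing to discretize",
                  "radscore_degenerate_error")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  lev <- floor((values - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  lev[lev > n_bins] <- as.integer(n_bins)
  as.integer(lev)
}

# Discretize a masked volume: integer array with 0 outside the mask and
# levels 1..n_bins inside.
discretize_volume <- function(volume, mask, n_bins = 32) {
  lev <- array(0L, dim = dim(volume))
  lev[mask] <- discretize(volume[mask], n_bins)
  lev
}

# The 13 unique 3D direction offsets (half of the 26-neighbourhood).
direction_offsets_3d <- function(distance = 1L) {
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  keep <- apply(offs, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0
  })
  offs <- offs[keep, , drop = FALSE]
  storage.mode(offs) <- "integer"
  offs * as.integer(distance)
}
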