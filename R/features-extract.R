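# Per-patient feature vector assembly: 107 features per modality
# (14 shape + 18 first-order intensity + 24 GLCM + 16 GLRLM + 16 GLSZM +
# 5 NGTDM + 14 GLDM), computed on each of the two modalities for 214 in
# total.  Ordering and names are fixed across runs.

#' Feature-extraction configuration
#'
#' @param n_bins gray levels for fixed-bin-count discretization.
#' @param distance GLCM offset length in voxels.
#' @param gldm_alpha GLDM level-difference tolerance.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(n_bins = 32, distance = 1, gldm_alpha = 0) {
  structure(list(n_bins = n_bins, distance = distance,
                 gldm_alpha = gldm_alpha), class = "feature_config")
}

#' Extract the 107 features of one modality
#'
#' @param volume 3D intensity array.
#' @param mask logical 3D array on the same grid.
#' @param spacing mm per axis.
#' @param prefix name prefix, e.g. `"T1"` or `"T2"`.
#' @param config a [feature_config()].
#' @return named numeric vector of length 107.
#' @export
extract_modality_features <- function(volume, mask, spacing, prefix = "T1",
                                      config = feature_config()) {
  stopifnot(all(dim(volume) == dim(mask)))
  if (!any(mask)) stop_radscore("empty mask", "radscore_degenerate_error")
  values <- volume[mask]
  lev_vec <- discretize(values, config$n_bins)
  lev <- array(0L, dim = dim(volume))
  lev[mask] <- lev_vec
  ng <- config$n_bins
  glcm <- glcm_features(lev, ng, distance = config$distance)
  glrlm <- glrlm_features(lev, ng)
  glszm <- glszm_features(lev, ng)
  ngtdm <- ngtdm_features(lev, ng)
  gldm <- gldm_features(lev, ng, alpha = config$gldm_alpha)
  out <- c(base_features(values, mask, spacing, levels = lev_vec),
           setNames(glcm, paste0("glcm_", names(glcm))),
           setNames(glrlm, paste0("glrlm_", names(glrlm))),
           setNames(glszm, paste0("glszm_", names(glszm))),
           setNames(ngtdm, paste0("ngtdm_", names(ngtdm))),
           setNames(gldm, paste0("gldm_", names(gldm))))
  setNames(out, paste0(prefix, "_", names(out)))
}

#' Extract the full 214-value two-modality feature vector
#'
#' @param pair a [volume_pair()].
#' @param mask_t1c a [tumor_mask()] on the CE-T1 grid.
#' @param mask_t2 a [tumor_mask()] on the T2 grid; when `NULL` the CE-T1
#'   mask is mapped through the stored affines (identity grids reuse it
#'   directly).
#' @param config a [feature_config()].
#' @return named numeric vector of length 214 (`T1_*` block then `T2_*`
#'   block).
#' @export
extract_feature_vector <- function(pair, mask_t1c, mask_t2 = NULL,
                                   config = feature_config()) {
  stopifnot(inherits(pair, "volume_pair"), inherits(mask_t1c, "tumor_mask"))
  if (is.null(mask_t2)) {
    same_grid <- all(dim(pair$t1c) == dim(pair$t2)) &&
      max(abs(pair$affine_t1c - pair$affine_t2)) < 1e-9
    mask_t2 <- if (same_grid) mask_t1c else
      map_mask(mask_t1c, pair$affine_t1c, pair$affine_t2, dim(pair$t2))
  }
  c(extract_modality_features(pair$t1c, mask_t1c$mask, pair$spacing,
                              prefix = "T1", config = config),
    extract_modality_features(pair$t2, mask_t2$mask, mask_t2$spacing,
                              prefix = "T2", config = config))
}
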