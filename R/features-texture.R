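# Texture feature families on a discretized volume: GLCM, GLRLM, GLSZM,
# NGTDM, GLDM.  Matrix accumulation lives in compiled code; the feature
# formulas follow the de-facto standard definitions used by reference
# radiomics software.  GLCMs are symmetric; GLCM and GLRLM are computed per
# direction over the 13 unique 3D offsets and feature values averaged;
# GLSZM zones and GLDM dependences use the 26-neighbourhood.

EPS <- .Machine$double.eps

# ---- GLCM ------------------------------------------------------------

glcm_features_from_p <- function(P) {
  ng <- nrow(P)
  i <- seq_len(ng)
  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sigx <- sqrt(sum((i - mux)^2 * px)); sigy <- sqrt(sum((i - muy)^2 * py))
  # sum / difference distributions
  ks <- 2:(2 * ng)
  ps <- vapply(ks, function(k) sum(P[ii + jj == k]), 0)
  kd <- 0:(ng - 1)
  pd <- vapply(kd, function(k) sum(P[abs(ii - jj) == k]), 0)
  da <- sum(kd * pd)
  hxy <- -sum(P * log2(P + EPS))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxpy + EPS))
  hxy2 <- -sum(pxpy * log2(pxpy + EPS))
  hx <- -sum(px * log2(px + EPS)); hy <- -sum(py * log2(py + EPS))
  present <- px > 0
  mcc <- if (sum(present) <= 1) 1 else {
    Pp <- P[present, present, drop = FALSE]
    A <- Pp / rowSums(Pp)
    B <- sweep(Pp, 2, colSums(Pp), "/")
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  c(Autocorrelation = sum(ii * jj * P),
    JointAverage = mux,
    ClusterProminence = sum((ii + jj - mux - muy)^4 * P),
    ClusterShade = sum((ii + jj - mux - muy)^3 * P),
    ClusterTendency = sum((ii + jj - mux - muy)^2 * P),
    Contrast = sum((ii - jj)^2 * P),
    Correlation = if (sigx * sigy == 0) 1 else
      (sum(ii * jj * P) - mux * muy) / (sigx * sigy),
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * log2(pd + EPS)),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(P / (1 + abs(ii - jj))),
    Idm = sum(P / (1 + (ii - jj)^2)),
    Idmn = sum(P / (1 + ((ii - jj) / ng)^2)),
    Idn = sum(P / (1 + abs(ii - jj) / ng)),
    Imc1 = if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy),
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(P[ii != jj] / ((ii - jj)[ii != jj])^2),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps * log2(ps + EPS)),
    SumSquares = sum((ii - mux)^2 * P))
}

#' Gray-level co-occurrence features (24)
#'
#' Symmetric GLCM per direction, normalized to a probability table;
#' features computed per direction and averaged over directions with at
#' least one valid voxel pair.
#'
#' @param levels integer 3D array; 0 outside the mask, levels `1..n_levels`
#'   inside.
#' @param n_levels number of gray levels of the discretization.
#' @param distance offset length in voxels.
#' @param offsets integer matrix of direction offsets (rows); default the
#'   13 unique 3D directions.
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(levels, n_levels, distance = 1, offsets = NULL) {
  if (is.null(offsets)) offsets <- direction_offsets_3d(distance)
  counts <- glcm_counts(as.integer(levels), dim(levels), as.integer(n_levels),
                        offsets)
  nd <- dim(counts)[3]
  acc <- NULL; nvalid <- 0
  for (d in seq_len(nd)) {
    m <- counts[, , d]
    tot <- sum(m)
    if (tot == 0) next
    f <- glcm_features_from_p(m / tot)
    acc <- if (is.null(acc)) f else acc + f
    nvalid <- nvalid + 1
  }
  if (nvalid == 0)
    stop_radscore("no valid voxel pairs for GLCM", "radscore_degenerate_error")
  acc / nvalid
}

# ---- GLRLM -----------------------------------------------------------

glrlm_features_from_counts <- function(R, n_voxels) {
  ng <- nrow(R); nl <- ncol(R)
  gi <- seq_len(ng); jl <- seq_len(nl)
  nr <- sum(R)
  p <- R / nr
  rg <- rowSums(R); rl <- colSums(R)
  pg <- rg / nr; pl <- rl / nr
  mug <- sum(gi * pg); mul <- sum(jl * pl)
  c(ShortRunEmphasis = sum(rl / jl^2) / nr,
    LongRunEmphasis = sum(rl * jl^2) / nr,
    GrayLevelNonUniformity = sum(rg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rg^2) / nr^2,
    RunLengthNonUniformity = sum(rl^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / nr^2,
    RunPercentage = nr / n_voxels,
    GrayLevelVariance = sum(pg * (gi - mug)^2),
    RunVariance = sum(pl * (jl - mul)^2),
    RunEntropy = -sum(p * log2(p + EPS)),
    LowGrayLevelRunEmphasis = sum(rg / gi^2) / nr,
    HighGrayLevelRunEmphasis = sum(rg * gi^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / outer(gi^2, jl^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * outer(gi^2, 1 / jl^2)) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * outer(1 / gi^2, jl^2)) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * outer(gi^2, jl^2)) / nr)
}

#' Gray-level run-length features (16), averaged over 13 directions
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels, n_levels, offsets = NULL) {
  if (is.null(offsets)) offsets <- direction_offsets_3d(1L)
  n_voxels <- sum(levels > 0)
  if (n_voxels == 0)
    stop_radscore("empty mask", "radscore_degenerate_error")
  counts <- glrlm_counts(as.integer(levels), dim(levels),
                         as.integer(n_levels), offsets)
  nd <- dim(counts)[3]
  acc <- NULL
  for (d in seq_len(nd)) {
    f <- glrlm_features_from_counts(counts[, , d, drop = TRUE], n_voxels)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nd
}

# ---- GLSZM -----------------------------------------------------------

#' Gray-level size-zone features (16)
#'
#' Zones are maximal 26-connected sets of equal gray level.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(levels, n_levels) {
  n_voxels <- sum(levels > 0)
  if (n_voxels == 0)
    stop_radscore("empty mask", "radscore_degenerate_error")
  labs <- cc_label3d(as.integer(levels), dim(levels), 26L, TRUE)
  nz <- max(labs)
  first <- match(seq_len(nz), labs)
  g <- as.integer(levels)[first]          # zone gray level
  s <- tabulate(labs[labs > 0], nbins = nz)  # zone size
  ng_counts <- tabulate(g, nbins = n_levels)
  ns_counts <- tabulate(s)
  pg <- ng_counts / nz
  gi <- seq_len(n_levels)
  mug <- sum(gi * pg)
  psz <- tabulate(match(s, sort(unique(s))), nbins = length(unique(s))) / nz
  szs <- sort(unique(s))
  mus <- sum(szs * psz)
  pzone <- as.vector(table(paste(g, s))) / nz
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(ng_counts^2) / nz,
    GrayLevelNonUniformityNormalized = sum(ng_counts^2) / nz^2,
    SizeZoneNonUniformity = sum(ns_counts^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ns_counts^2) / nz^2,
    ZonePercentage = nz / n_voxels,
    GrayLevelVariance = sum(pg * (gi - mug)^2),
    ZoneVariance = sum(psz * (szs - mus)^2),
    ZoneEntropy = -sum(pzone * log2(pzone + EPS)),
    LowGrayLevelZoneEmphasis = mean(1 / g^2),
    HighGrayLevelZoneEmphasis = mean(g^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (g^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(g^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / g^2),
    LargeAreaHighGrayLevelEmphasis = mean(g^2 * s^2))
}

# ---- NGTDM -----------------------------------------------------------

#' Neighbourhood gray-tone difference features (5)
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(levels, n_levels) {
  nv <- sum(levels > 0)
  if (nv == 0) stop_radscore("empty mask", "radscore_degenerate_error")
  st <- ngtdm_stats(as.integer(levels), dim(levels), as.integer(n_levels))
  n_i <- st[, 1]; s_i <- st[, 2]
  p_i <- n_i / nv
  pres <- which(p_i > 0)
  ngp <- length(pres)
  i <- seq_len(n_levels)
  sum_ps <- sum(p_i * s_i)
  coarseness <- if (sum_ps == 0) 1e6 else 1 / sum_ps
  if (ngp > 1) {
    pij <- outer(p_i[pres], p_i[pres])
    dij <- outer(i[pres], i[pres], "-")
    contrast <- sum(pij * dij^2) / (ngp * (ngp - 1)) * sum(s_i) / nv
    ipi <- i[pres] * p_i[pres]
    denom_b <- sum(abs(outer(ipi, ipi, "-")))
    busyness <- if (denom_b == 0) 0 else sum_ps / denom_b
    num_c <- abs(dij) * (outer(p_i[pres] * s_i[pres], p_i[pres] * s_i[pres],
                               "+")) / outer(p_i[pres], p_i[pres], "+")
    complexity <- sum(num_c) / nv
    strength <- if (sum(s_i) == 0) 0 else
      sum(outer(p_i[pres], p_i[pres], "+") * dij^2) / sum(s_i)
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

# ---- GLDM ------------------------------------------------------------

#' Gray-level dependence features (14)
#'
#' The dependence size of a voxel is 1 + the number of 26-neighbours whose
#' level differs from the centre by at most `alpha` (the centre counts, so
#' sizes start at 1).
#'
#' @inheritParams glcm_features
#' @param alpha level-difference tolerance for dependence.
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, n_levels, alpha = 0) {
  nv <- sum(levels > 0)
  if (nv == 0) stop_radscore("empty mask", "radscore_degenerate_error")
  D <- gldm_counts(as.integer(levels), dim(levels), as.integer(n_levels),
                   as.integer(alpha))
  ng <- nrow(D); ndep <- ncol(D)
  gi <- seq_len(ng); jd <- seq_len(ndep)
  nz <- sum(D)
  p <- D / nz
  dg <- rowSums(D); dd <- colSums(D)
  pg <- dg / nz; pd <- dd / nz
  mug <- sum(gi * pg); mud <- sum(jd * pd)
  c(SmallDependenceEmphasis = sum(dd / jd^2) / nz,
    LargeDependenceEmphasis = sum(dd * jd^2) / nz,
    GrayLevelNonUniformity = sum(dg^2) / nz,
    DependenceNonUniformity = sum(dd^2) / nz,
    DependenceNonUniformityNormalized = sum(dd^2) / nz^2,
    GrayLevelVariance = sum(pg * (gi - mug)^2),
    DependenceVariance = sum(pd * (jd - mud)^2),
    DependenceEntropy = -sum(p * log2(p + EPS)),
    LowGrayLevelEmphasis = sum(dg / gi^2) / nz,
    HighGrayLevelEmphasis = sum(dg * gi^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(D / outer(gi^2, jd^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(D * outer(gi^2, 1 / jd^2)) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(D * outer(1 / gi^2, jd^2)) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(D * outer(gi^2, jd^2)) / nz)
}

#' Texture features for one matrix family
#'
#' Dispatcher over the run-length, neighbourhood gray-tone difference and
#' gray-level dependence families.
#'
#' @inheritParams glcm_features
#' @param family one of `"GLRLM"`, `"NGTDM"`, `"GLDM"`.
#' @param ... passed to the family function.
#' @return named numeric vector (16 / 5 / 14 values).
#' @export
texture_family_features <- function(levels, n_levels,
                                    family = c("GLRLM", "NGTDM", "GLDM"),
                                    ...) {
  if (!family[1] %in% c("GLRLM", "NGTDM", "GLDM"))
    stop_radscore(paste0("unknown texture family: ", family[1]),
                  "radscore_spec_error")
  switch(family[1],
         GLRLM = glrlm_features(levels, n_levels, ...),
         NGTDM = ngtdm_features(levels, n_levels),
         GLDM = gldm_features(levels, n_levels, ...))
}
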