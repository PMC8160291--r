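# Radiomic feature extraction: discretization, worked toy examples, shape
# accuracy on analytic solids, degenerate conventions, and full-vector
# structural contracts.

test_that("fixed-bin-count discretization follows the stated formula", {
  expect_equal(discretize(c(0, 0.5, 1), 2), c(1L, 2L, 2L))
  expect_equal(discretize(rep(3.7, 10), 8), rep(1L, 10))
  x <- rnorm(200)
  expect_identical(discretize(x, 16), discretize(2.5 * x + 7, 16))
  expect_error(discretize(numeric(0), 4), class = "radscore_degenerate_error")
})

test_that("GLCM worked example and degenerate cases", {
  # 1D image [1,1,1,2], distance 1, single direction, symmetric:
  # p(1,1)=2/3, p(1,2)=p(2,1)=1/6, marginal means 7/6, shade = 2/27
  g <- glcm_features(lat1d(c(1, 1, 1, 2)), 2,
                     offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(g["ClusterShade"]), 2 / 27, tolerance = 1e-12)
  expect_equal(unname(g["ClusterProminence"]),
               (2 - 7 / 3)^4 * 2 / 3 + (3 - 7 / 3)^4 * 1 / 3,
               tolerance = 1e-12)
  # constant image: single cell at (1,1); shade and prominence vanish
  gc <- glcm_features(array(1L, dim = c(3, 3, 2)), 4)
  expect_equal(unname(gc["ClusterShade"]), 0)
  expect_equal(unname(gc["ClusterProminence"]), 0)
  # single voxel: no pairs at all
  expect_error(glcm_features(lat1d(1), 2), class = "radscore_degenerate_error")
})

test_that("GLCM probability tables normalize and symmetric tables have zero shade", {
  lev <- random_lattice(c(6, 6, 3), 5, seed = 3)
  counts <- radscore:::glcm_counts(as.integer(lev), dim(lev), 5L,
                                   radscore:::direction_offsets_3d(1))
  for (d in seq_len(dim(counts)[3])) {
    M <- counts[, , d]
    expect_true(all(M == t(M)))
    expect_gt(sum(M), 0)
  }
  # a table symmetric about its marginal mean: uniform over all cells
  P <- matrix(1 / 16, 4, 4)
  expect_equal(unname(o_glcm_feats(P)["ClusterShade"]), 0, tolerance = 1e-12)
})

test_that("GLSZM worked examples", {
  expect_equal(unname(glszm_features(array(2L, dim = c(3, 3, 3)),
                                     2)["GrayLevelNonUniformity"]), 1)
  z <- array(c(1L, 1L, 2L, 3L), dim = c(2, 2, 1))
  expect_equal(unname(glszm_features(z, 3)["GrayLevelNonUniformity"]), 1)
  expect_equal(unname(glszm_features(lat1d(c(1, 2, 1, 2)),
                                     2)["GrayLevelNonUniformity"]), 2)
})

test_that("GLRLM handles a constant region without division errors", {
  f <- glrlm_features(array(1L, dim = c(4, 4, 2)), 3)
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["GrayLevelNonUniformityNormalized"]), 1)
})

test_that("texture families are well-defined functions of the lattice", {
  lev <- random_lattice(c(7, 6, 3), 4, seed = 9)
  for (fam in c("GLRLM", "NGTDM", "GLDM")) {
    a <- texture_family_features(lev, 4, fam)
    b <- texture_family_features(lev + 0L, 4, fam)  # fresh copy
    expect_identical(a, b)
  }
  expect_error(texture_family_features(lev, 4, "BOGUS"),
               class = "radscore_spec_error")
})

test_that("first-order degenerate conventions and unit geometry", {
  f <- intensity_features(rep(5, 20))
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Skewness"]), 0)
  expect_equal(unname(f["Kurtosis"]), 0)
  m <- array(FALSE, dim = c(3, 3, 3)); m[2, 2, 2] <- TRUE
  sh <- shape_features(m, c(1, 1, 1))
  expect_equal(unname(sh["VoxelVolume"]), 1)
})

test_that("sphericity is within 5% of the analytic ellipsoid value", {
  dd <- c(21L, 17L, 15L)
  cx <- (0:20) - 10; cy <- (0:16) - 8; cz <- (0:14) - 7
  m <- array(outer(outer(cx^2 / 64, cy^2 / 36, "+"), cz^2 / 25, "+") <= 1, dd)
  sh <- shape_features(m, c(1, 1, 1))
  a <- 8; b <- 6; cc <- 5; p <- 1.6075  # Thomsen surface approximation
  area <- 4 * pi * ((a^p * b^p + a^p * cc^p + b^p * cc^p) / 3)^(1 / p)
  vol <- 4 / 3 * pi * a * b * cc
  sph <- (36 * pi * vol^2)^(1 / 3) / area
  expect_equal(unname(sh["Sphericity"]), sph, tolerance = 0.05)
  expect_equal(unname(sh["Elongation"]), 6 / 8, tolerance = 0.05)
  expect_equal(unname(sh["Flatness"]), 5 / 8, tolerance = 0.05)
})

test_that("full vector: length, symmetry, determinism, texture rescale invariance", {
  ph <- generate_phantom_pair(small_spec(), 1, 42)
  fv <- extract_feature_vector(ph$pair, ph$mask)
  expect_length(fv, 214)
  expect_true(all(is.finite(fv)))
  expect_false(any(duplicated(names(fv))))
  expect_equal(sum(startsWith(names(fv), "T1_")), 107)
  # identical volumes in both channels: T1 block equals T2 block
  pair2 <- volume_pair(ph$pair$t1c, ph$pair$t1c, ph$pair$spacing)
  fv2 <- extract_feature_vector(pair2, ph$mask)
  expect_equal(unname(fv2[1:107]), unname(fv2[108:214]))
  # bit-identical on repeat
  expect_identical(fv, extract_feature_vector(ph$pair, ph$mask))
  # positive affine intensity rescaling leaves every discretization-based
  # feature unchanged (shape trivially; raw-intensity statistics scale)
  pair3 <- volume_pair(3 * ph$pair$t1c + 50, 3 * ph$pair$t2 + 50,
                       ph$pair$spacing)
  fv3 <- extract_feature_vector(pair3, ph$mask)
  textural <- grepl("_(glcm|glrlm|glszm|ngtdm|gldm)_", names(fv)) |
    grepl("(Entropy|Uniformity)$", names(fv)) | grepl("_shape_", names(fv))
  expect_equal(fv[textural], fv3[textural], tolerance = 1e-10)
})
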