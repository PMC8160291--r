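# FCM clustering, slice-wise segmentation with 3D post-processing, and
# affine mask mapping.

test_that("FCM separates two well-defined clusters", {
  fc <- fcm_cluster(c(0, 0, 0, 10, 10, 10), n_clusters = 2)
  expect_equal(sort(fc$centroids), c(0, 10), tolerance = 1e-3)
  top <- apply(fc$memberships, 1, max)
  expect_true(all(top > 0.99))
})

test_that("FCM degenerate and single-cluster contracts", {
  fc1 <- fcm_cluster(c(1, 2, 3, 10), n_clusters = 1)
  expect_equal(fc1$centroids, 4)
  expect_true(all(fc1$memberships == 1))
  expect_error(fcm_cluster(rep(2, 6), 2), class = "radscore_degenerate_error")
  expect_error(fcm_cluster(c(1, 1, 2, 2), 3),
               class = "radscore_degenerate_error")
})

test_that("FCM objective is non-increasing across iterations", {
  for (s in 1:5) {
    set.seed(s)
    vals <- c(rnorm(40, 0, 2), rnorm(40, 6, 2), rnorm(20, 12, 1))
    fc <- fcm_cluster(vals, n_clusters = 3, tol = 1e-9, max_iter = 300)
    expect_true(all(diff(fc$objective) <= 1e-8 * max(fc$objective)))
  }
})

test_that("segmentation recovers the phantom lesion (Dice >= 0.90)", {
  ph <- generate_phantom_pair(phantom_spec(), 0, 12)
  box <- radscore:::seed_box_from_mask(ph$mask$mask, pad = 4)
  seg <- segment_volume(ph$pair, box)
  expect_gte(mask_dice(seg$mask, ph$mask$mask), 0.90)
  # single connected component after post-processing
  labs <- radscore:::cc_label3d(as.integer(seg$mask), dim(seg$mask), 26L,
                                FALSE)
  expect_equal(max(labs), 1L)
})

test_that("segmentation is invariant to positive affine intensity rescaling", {
  ph <- generate_phantom_pair(small_spec(), 0, 21)
  box <- radscore:::seed_box_from_mask(ph$mask$mask, pad = 3)
  seg1 <- segment_volume(ph$pair, box)
  pair2 <- volume_pair(3.7 * ph$pair$t1c + 120, ph$pair$t2, ph$pair$spacing)
  seg2 <- segment_volume(pair2, box)
  expect_identical(seg1$mask, seg2$mask)
})

test_that("post-processing fills holes and keeps the largest component", {
  d <- c(12L, 12L, 5L)
  vol <- array(10, dim = d)
  vol[3:9, 3:9, 2:4] <- 100      # big blob
  vol[6, 6, 3] <- 10             # interior dark voxel -> hole to fill
  vol[11, 11, 3] <- 100          # scattered bright voxel
  pair <- volume_pair(vol, vol, c(1, 1, 1))
  seg <- segment_volume(pair, seed_box(c(1, 12), c(1, 12), c(1, 5)))
  expect_true(seg$mask[6, 6, 3])
  expect_false(seg$mask[11, 11, 3])
})

test_that("map_mask: identity, integer translation, rotation", {
  ph <- generate_phantom_pair(small_spec(), 0, 31)
  m <- ph$mask
  eye <- diag(4)
  out <- map_mask(m, eye, eye, dim(m$mask))
  expect_identical(out$mask, m$mask)
  # pure integer-voxel translation
  tr <- diag(4); tr[1:3, 4] <- c(2, -1, 1)
  shifted <- map_mask(m, eye, tr, dim(m$mask))
  d <- dim(m$mask)
  manual <- array(FALSE, d)
  manual[1:(d[1] - 2), 2:d[2], 1:(d[3] - 1)] <-
    m$mask[3:d[1], 1:(d[2] - 1), 2:d[3]]
  expect_identical(shifted$mask, manual)
  # 90-degree in-plane rotation about the grid centre of an asymmetric mask
  am <- array(FALSE, dim = c(15L, 15L, 3L))
  am[3:9, 5:7, 2] <- TRUE; am[3:5, 8:11, 2] <- TRUE
  amask <- tumor_mask(am, c(1, 1, 1))
  ctr <- c(7, 7, 1)
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(0, 1, -1, 0), 2)
  tc <- diag(4); tc[1:3, 4] <- ctr
  tcinv <- diag(4); tcinv[1:3, 4] <- -ctr
  aff_dst <- tc %*% rot %*% tcinv
  rotated <- map_mask(amask, diag(4), aff_dst, dim(am))
  expect_lte(abs(sum(rotated$mask) - sum(am)) / sum(am), 0.02)
  # centroid maps through the transform within half a voxel
  cvox <- colMeans(which(am, arr.ind = TRUE)) - 1
  crot <- colMeans(which(rotated$mask, arr.ind = TRUE)) - 1
  expected <- solve(aff_dst) %*% c(cvox, 1)
  expect_lt(max(abs(crot - expected[1:3])), 0.5)
})

test_that("map_mask round-trips rigid transforms (>= 95% recovered)", {
  ph <- generate_phantom_pair(phantom_spec(), 0, 17)
  m <- ph$mask
  th <- 10 * pi / 180
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot[1:3, 4] <- c(0.4, -0.7, 0.2)
  fwd <- map_mask(m, diag(c(m$spacing, 1)), diag(c(m$spacing, 1)) %*% rot,
                  dim(m$mask))
  back <- map_mask(fwd, diag(c(m$spacing, 1)) %*% rot,
                   diag(c(m$spacing, 1)), dim(m$mask))
  recovered <- sum(back$mask & m$mask) / sum(m$mask)
  expect_gte(recovered, 0.95)
})

test_that("empty results raise stage-appropriate errors", {
  vol <- array(0, dim = c(8, 8, 3)); vol[1, 1, 1] <- 1
  m <- tumor_mask(array(c(TRUE, rep(FALSE, 8 * 8 * 3 - 1)), c(8, 8, 3)),
                  c(1, 1, 1))
  tr <- diag(4); tr[1, 4] <- 100   # shift far outside
  expect_error(map_mask(m, diag(4), tr, dim(m$mask)),
               class = "radscore_segmentation_error")
})
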