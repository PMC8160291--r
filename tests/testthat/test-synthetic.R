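# Synthetic cohort generator: geometry, determinism, planted texture
# effects, outcome-model closed forms, calibration, and distributional
# properties.

test_that("truth mask matches an independently discretized ellipsoid", {
  spec <- phantom_spec(grid_shape = c(32, 32, 10), voxel_spacing = c(1, 1, 5),
                       tumor_radius = 10)
  ph <- generate_phantom_pair(spec, 0, 1)
  # independent recount by explicit loop over voxel centres
  cnt <- 0
  ctr <- spec$tumor_center * spec$voxel_spacing
  for (k in 1:10) for (j in 1:32) for (i in 1:32) {
    p <- (c(i, j, k) - 1) * spec$voxel_spacing - ctr
    if (sum(p^2) <= 100) cnt <- cnt + 1
  }
  expect_equal(sum(ph$mask$mask), cnt)
})

test_that("tumor outside the grid is rejected with a geometry error", {
  expect_error(phantom_spec(grid_shape = c(10, 10, 4), tumor_radius = 30),
               class = "radscore_geometry_error")
})

test_that("same seed gives bit-identical phantoms", {
  spec <- small_spec()
  a <- generate_phantom_pair(spec, 1, 99)
  b <- generate_phantom_pair(spec, 1, 99)
  expect_identical(a$pair$t1c, b$pair$t1c)
  expect_identical(a$pair$t2, b$pair$t2)
  expect_identical(a$latent_texture, b$latent_texture)
  expect_false(identical(a$pair$t1c,
                         generate_phantom_pair(spec, 1, 100)$pair$t1c))
})

test_that("class skewness difference shows in tumor-voxel sample skewness", {
  spec <- small_spec(texture_skewness = c(0, 1.5), latent_jitter = 0)
  sk <- vapply(1:50, function(s) {
    p1 <- generate_phantom_pair(spec, 1, s)
    p0 <- generate_phantom_pair(spec, 0, 1000 + s)
    c(skew_sample(p1$pair$t1c[p1$mask$mask]),
      skew_sample(p0$pair$t1c[p0$mask$mask]))
  }, c(0, 0))
  expect_gt(mean(sk[1, ]) - mean(sk[2, ]), 0)
  expect_gt(mean(sk[1, ]), 0.2)  # planted positive asymmetry
})

test_that("zero hazard never produces events and follow-up is the censor draw", {
  p <- outcome_params(baseline_hazard = 0, beta_bone = 0, beta_adc = 0,
                      beta_texture = 0)
  for (s in 1:5) {
    oc <- simulate_outcome(0, list(bone_invasion = 1, adc_value = 0.5), p, s)
    expect_equal(oc$event, 0L)
    expect_gte(oc$followup_time, 14)
    expect_lte(oc$followup_time, 149)
  }
})

test_that("event frequency matches the exponential/fixed-censoring closed form", {
  lambda <- 0.01; cwin <- 60
  p <- outcome_params(baseline_hazard = lambda, beta_bone = 0, beta_adc = 0,
                      beta_texture = 0, censor_window = c(cwin, cwin),
                      latent_center = 0, latent_scale = 1)
  ev <- vapply(1:10000, function(s)
    simulate_outcome(0, list(bone_invasion = 0, adc_value = 1), p,
                     s)$event, 0L)
  expect_equal(mean(ev), 1 - exp(-lambda * cwin), tolerance = 0.035)
})

test_that("event times are exchangeable with an inverse-CDF exponential sampler", {
  lambda <- 0.02
  p <- outcome_params(baseline_hazard = lambda, beta_bone = 0, beta_adc = 0,
                      beta_texture = 0, censor_window = c(1e6, 1e6 + 1),
                      latent_center = 0, latent_scale = 1)
  sim <- vapply(1:10000, function(s)
    simulate_outcome(0, list(bone_invasion = 0, adc_value = 1), p,
                     s)$followup_time, 0)
  set.seed(424242)
  ref <- -log(runif(10000)) / lambda
  ks <- suppressWarnings(stats::ks.test(sim, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort generation is deterministic and validates inputs", {
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  generate_cohort(10, spec = small_spec(), seed = 5, out_dir = d1)
  generate_cohort(10, spec = small_spec(), seed = 5, out_dir = d2)
  expect_identical(readLines(file.path(d1, "covariates.csv")),
                   readLines(file.path(d2, "covariates.csv")))
  # covariate table identical whether or not volumes are materialized
  light <- generate_cohort(10, spec = small_spec(), seed = 5)
  expect_equal(light$covariates,
               read.csv(file.path(d1, "covariates.csv"),
                        stringsAsFactors = FALSE),
               tolerance = 1e-9)
  expect_error(generate_cohort(1), class = "radscore_spec_error")
})

test_that("default calibration yields the stated event prevalence", {
  co <- generate_cohort(2000, seed = 314)
  expect_lt(abs(mean(co$covariates$event) - 0.148), 0.03)
  # follow-up range respects the censor window
  expect_gte(min(co$covariates$followup_time), 0)
  expect_lte(max(co$covariates$followup_time), 149)
})

test_that("increasing beta_texture strengthens the latent-event association", {
  cors <- vapply(c(0.2, 0.9, 1.8), function(bt) {
    co <- generate_cohort(5000, params = outcome_params(beta_texture = bt),
                          seed = 2718)
    cor(co$covariates$latent_texture, co$covariates$event)
  }, 0)
  expect_true(all(diff(cors) > 0))
})
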