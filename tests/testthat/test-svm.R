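# Gaussian-kernel SVM: standardization, dual solver against closed forms,
# the printed score equation, cross-validation, and sequential forward
# selection.

test_that("standardize centers and scales with training parameters only", {
  set.seed(1)
  tr <- matrix(rnorm(60, 5, 3), 20, 3)
  ap <- matrix(rnorm(15, 5, 3), 5, 3)
  st <- standardize(tr, ap)
  expect_equal(unname(colMeans(st$train)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(st$train, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(standardize(tr, matrix(colMeans(tr), 1))$apply),
               matrix(0, 1, 3), tolerance = 1e-12)
  trc <- cbind(tr, 7)  # constant column
  expect_warning(stc <- standardize(trc), "zero-variance")
  expect_true(all(stc$train[, 4] == 0))
})

test_that("two symmetric points match the closed-form dual solution", {
  a <- c(0.7, -0.3)
  X <- rbind(a, -a); y <- c(1, -1)
  m <- train_svm(X, y, C = 100, tol = 1e-10)
  K12 <- exp(-sum((2 * a)^2))
  alpha_true <- 1 / (1 - K12)   # from the 2x2 dual system, interior optimum
  expect_equal(unname(m$weights), rep(alpha_true, 2), tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-6)
  # f(x) = alpha * (G(x1,x) - G(x2,x)); check at x = x1
  expect_equal(svm_score(m, a), alpha_true * (1 - K12), tolerance = 1e-6)
})

test_that("separable clusters reach training accuracy 1 and KKT holds", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  y <- rep(c(1, -1), each = 20)
  st <- standardize(X)
  m <- train_svm(st$train, y, C = 1)
  expect_equal(mean(sign(svm_score(m, st$train)) == y), 1)
  expect_true(all(m$alpha >= 0 & m$alpha <= 1 + 1e-12))
  expect_lt(abs(sum(m$alpha * y)), 1e-8)
  expect_error(train_svm(X, rep(1, 40)), class = "radscore_degenerate_error")
})

test_that("svm_score equals the printed kernel expansion", {
  # N = 1, w = 0.5, y = +1, b = 0.1, x = x1 -> 0.5 * e^0 + 0.1
  m <- structure(list(support_vectors = matrix(c(1, 2), 1), weights = 0.5,
                      labels = 1, bias = 0.1), class = "svm_model")
  expect_equal(svm_score(m, c(1, 2)), 0.6, tolerance = 1e-12)
  # far from every support vector the kernel vanishes: score -> b
  expect_equal(svm_score(m, c(100, 100)), 0.1, tolerance = 1e-12)
  # random 5-SV model equals a term-by-term hand expansion
  set.seed(11)
  sv <- matrix(rnorm(15), 5, 3)
  w <- runif(5); yl <- c(1, -1, 1, 1, -1); b <- 0.3
  m5 <- structure(list(support_vectors = sv, weights = w, labels = yl,
                       bias = b), class = "svm_model")
  x <- rnorm(3)
  hand <- b
  for (n in 1:5)
    hand <- hand + w[n] * yl[n] * exp(-sum((sv[n, ] - x)^2))
  expect_equal(svm_score(m5, x), hand, tolerance = 1e-12)
  # bounded by sum of weights plus bias
  for (s in 1:10) {
    xx <- rnorm(3, sd = 3)
    expect_lte(abs(svm_score(m5, xx)), sum(w) + abs(b))
  }
  expect_error(svm_score(m5, c(1, 2)), class = "radscore_spec_error")
})

test_that("cv_objective: determinism, separable, permutation null", {
  set.seed(3)
  n <- 40
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(y * 3 + rnorm(n, sd = 0.3), rnorm(n))
  expect_equal(cv_objective(X, y, 1, seed = 5), 1)
  expect_identical(cv_objective(X, y, 1:2, seed = 9),
                   cv_objective(X, y, 1:2, seed = 9))
  # label permutation: accuracy near chance averaged over 100 repeats
  set.seed(10)
  yp <- y[sample.int(n)]
  obj <- cv_objective(X, yp, 1:2, n_repeats = 100, seed = 77)
  expect_lt(abs(obj - 0.5), 0.1)
  expect_error(cv_objective(X, y, integer(0)), class = "radscore_spec_error")
})

test_that("fold assignment is stratified within one sample", {
  set.seed(2)
  y <- c(rep(1, 23), rep(-1, 57))[sample.int(80)]
  fold <- radscore:::stratified_folds(y, 10, 4)
  for (f in 1:10) {
    expect_lte(abs(sum(y[fold == f] == 1) - 23 / 10), 1)
    expect_lte(abs(sum(y[fold == f] == -1) - 57 / 10), 1)
  }
})

test_that("compiled SFS candidate path equals the reference cv_objective", {
  set.seed(6)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- sign(X[, 2] + rnorm(50, sd = 0.8))
  fold <- radscore:::stratified_folds(y, 10, radscore:::derive_seed(3, 1))
  fast <- radscore:::sfs_candidate_objective(X, y, fold, integer(0), 1:6,
                                             1, 1e-3, 2000L, 0L)
  slow <- vapply(1:6, function(j) cv_objective(X, y, j, seed = 3), 0)
  # identical folds and solver; summation-order rounding may flip at most
  # a borderline sample on signal-free candidates
  expect_lt(max(abs(as.numeric(fast) - slow)), 1 / 50 + 1e-12)
  fast2 <- radscore:::sfs_candidate_objective(X, y, fold, 2L,
                                              c(1L, 3L, 4L), 1, 1e-3, 2000L, 0L)
  slow2 <- vapply(c(1, 3, 4), function(j)
    cv_objective(X, y, c(2, j), seed = 3), 0)
  expect_lt(max(abs(as.numeric(fast2) - slow2)), 1 / 50 + 1e-12)
  # AUC metric: pooled out-of-fold rank AUC agrees with the R path
  fauc <- radscore:::sfs_candidate_objective(X, y, fold, integer(0), 1:6,
                                             1, 1e-3, 2000L, 1L)
  sauc <- vapply(1:6, function(j)
    cv_objective(X, y, j, seed = 3, metric = "auc"), 0)
  expect_lt(max(abs(as.numeric(fauc) - sauc)), 0.03)
})

test_that("forward selection: one-step case, noise termination, trace", {
  set.seed(8)
  n <- 40
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(y * 2 + rnorm(n, sd = 0.5), rnorm(n))
  sel <- sequential_forward_selection(X, y, seed = 2, max_features = 2)
  expect_equal(sel$selected[1], 1L)
  expect_true(all(diff(sel$trace$objective) >= 0))
  # all-noise features: terminates at or below the cap, near-chance CV
  Xn <- matrix(rnorm(n * 6), n, 6)
  seln <- sequential_forward_selection(Xn, y, seed = 2, max_features = 4)
  expect_lte(length(seln$selected), 4)
  final_obj <- cv_objective(Xn, y, seln$selected, seed = 2)
  expect_lt(final_obj, 0.85)
  # model predicts on raw features end to end
  sc <- predict(sel$model, X)
  expect_length(sc, n)
  expect_gt(rank_auc <- radscore:::rank_auc(sc, y), 0.9)
})
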