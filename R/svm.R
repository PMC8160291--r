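# Gaussian-kernel soft-margin SVM with the unit-width kernel
# G(x_n, x) = exp(-||x_n - x||^2) and the decision value
# f(x) = sum_n w_n y_n G(x_n, x) + b used as a per-patient risk score.
# Features are z-scored with training-set parameters first, which is what
# makes the fixed unit kernel width meaningful.  The dual is solved by a
# compiled SMO solver.

#' Z-score standardization learned on training data
#'
#' @param train_matrix numeric matrix (rows = samples).
#' @param apply_matrix optional matrix transformed with the training
#'   parameters only.
#' @return list with `train`, `apply` (or NULL), `center`, `scale`;
#'   zero-variance features get scale 1 with a warning.
#' @export
standardize <- function(train_matrix, apply_matrix = NULL) {
  train_matrix <- as.matrix(train_matrix)
  if (nrow(train_matrix) < 2)
    stop_radscore("standardize needs >= 2 training rows",
                  "radscore_spec_error")
  center <- colMeans(train_matrix)
  scale <- apply(train_matrix, 2, sd)
  if (any(scale == 0)) {
    warning("zero-variance feature(s): scale forced to 1")
    scale[scale == 0] <- 1
  }
  tr <- sweep(sweep(train_matrix, 2, center), 2, scale, "/")
  ap <- if (!is.null(apply_matrix)) {
    apply_matrix <- matrix(as.double(as.matrix(apply_matrix)),
                           ncol = ncol(train_matrix))
    sweep(sweep(apply_matrix, 2, center), 2, scale, "/")
  }
  list(train = tr, apply = ap, center = center, scale = scale)
}

rbf_kernel <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0))
}

#' Train a Gaussian-kernel SVM
#'
#' Solves the soft-margin dual with kernel `exp(-||u - v||^2)` (unit
#' width; standardize features first).  Support vectors are the rows with
#' positive dual coefficient; the bias comes from margin vectors.
#'
#' @param X standardized feature matrix (rows = samples).
#' @param y labels in -1/+1.
#' @param C box constraint.
#' @param tol KKT violation tolerance of the solver.
#' @param max_iter solver pass cap.
#' @return object of class `svm_model` with `support_vectors`, `weights`
#'   (dual coefficients), `labels`, `bias`, `C`, and slots for
#'   `selected_features` / `standardization` filled by higher-level
#'   fitting.
#' @export
train_svm <- function(X, y, C = 1, tol = 1e-3, max_iter = 2000) {
  X <- as.matrix(X)
  y <- as.double(y)
  if (!all(y %in% c(-1, 1)))
    stop_radscore("labels must be -1/+1", "radscore_spec_error")
  if (length(unique(y)) < 2)
    stop_radscore("single-class input: cannot train an SVM",
                  "radscore_degenerate_error")
  if (anyNA(X)) stop_radscore("missing values in features",
                              "radscore_spec_error")
  K <- rbf_kernel(X)
  fit <- smo_train(K, y, C, tol, as.integer(max_iter))
  alpha <- fit$alpha
  sv <- alpha > 1e-12
  structure(list(support_vectors = X[sv, , drop = FALSE],
                 weights = alpha[sv], labels = y[sv], bias = fit$b,
                 alpha = alpha, C = C, converged = fit$converged,
                 selected_features = NULL, standardization = NULL),
            class = "svm_model")
}

#' Kernel-expansion SVM score
#'
#' Returns exactly `sum_n w_n y_n exp(-||x_n - x||^2) + b` for each row of
#' `x` (already standardized, restricted to the model's features).
#'
#' @param model an `svm_model`.
#' @param x numeric vector (one sample) or matrix (rows = samples).
#' @return numeric vector of scores.
#' @export
svm_score <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$support_vectors))
    stop_radscore("feature dimension mismatch", "radscore_spec_error")
  G <- rbf_kernel(x, model$support_vectors)
  as.vector(G %*% (model$weights * model$labels)) + model$bias
}

#' Predict risk scores from raw (unstandardized) feature rows
#'
#' Applies the model's stored feature selection and standardization, then
#' [svm_score()].
#'
#' @param object an `svm_model` fitted by [fit_svm_model()] or
#'   [sequential_forward_selection()].
#' @param newdata numeric matrix or data frame of raw features.
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$selected_features))
    newdata <- newdata[, object$selected_features, drop = FALSE]
  if (!is.null(object$standardization)) {
    st <- object$standardization
    newdata <- sweep(sweep(newdata, 2, st$center), 2, st$scale, "/")
  }
  svm_score(object, newdata)
}

# Fit on raw features: standardize, train, remember the transform.
#' Fit a Gaussian-kernel SVM on raw features
#'
#' @param X raw feature matrix.
#' @param y labels in -1/+1.
#' @param features column indices to use (stored in the model).
#' @param C box constraint.
#' @return an `svm_model` carrying selection and standardization.
#' @export
fit_svm_model <- function(X, y, features = seq_len(ncol(X)), C = 1) {
  X <- as.matrix(X)
  Xs <- X[, features, drop = FALSE]
  st <- suppressWarnings(standardize(Xs))
  model <- train_svm(st$train, y, C = C)
  model$selected_features <- features
  model$standardization <- list(center = st$center, scale = st$scale)
  model
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so per-fold class counts differ from balance by at most one.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

rank_auc <- function(scores, labels) {
  pos <- labels > 0
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cross-validated performance of a feature subset
#'
#' Stratified k-fold CV of the Gaussian-kernel SVM on the given feature
#' subset, averaged over `n_repeats` independent fold assignments.
#' Deterministic given `seed`.
#'
#' @param X raw feature matrix.
#' @param y labels in -1/+1.
#' @param feature_subset column indices.
#' @param k_folds folds (each class must have >= 2 members).
#' @param n_repeats repeated random fold assignments.
#' @param seed integer seed.
#' @param metric `"accuracy"` (sign agreement) or `"auc"` (rank AUC of the
#'   pooled out-of-fold scores).
#' @param C box constraint.
#' @return mean CV performance (scalar).
#' @export
cv_objective <- function(X, y, feature_subset, k_folds = 10, n_repeats = 1,
                         seed = 1, metric = c("accuracy", "auc"), C = 1) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (length(feature_subset) == 0)
    stop_radscore("empty feature subset", "radscore_spec_error")
  if (min(table(y)) < 2)
    stop_radscore("each class needs >= 2 members for stratified CV",
                  "radscore_spec_error")
  Xs <- X[, feature_subset, drop = FALSE]
  perf <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, k_folds, derive_seed(seed, r))
    scores <- numeric(length(y))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      st <- suppressWarnings(standardize(Xs[tr, , drop = FALSE],
                                         Xs[!tr, , drop = FALSE]))
      model <- train_svm(st$train, y[tr], C = C)
      scores[!tr] <- svm_score(model, st$apply)
    }
    perf[r] <- if (metric == "accuracy") mean((scores > 0) == (y > 0))
               else rank_auc(scores, y)
  }
  mean(perf)
}

#' Cross-validated per-patient SVM scores
#'
#' Out-of-fold scores: each patient is scored by a model not trained on
#' that patient (averaged over `n_repeats` fold assignments).
#'
#' @inheritParams cv_objective
#' @param features column indices to use.
#' @return numeric vector of scores, one per row of `X`.
#' @export
cv_scores <- function(X, y, features, k_folds = 10, n_repeats = 1, seed = 1,
                      C = 1) {
  X <- as.matrix(X)
  Xs <- X[, features, drop = FALSE]
  acc <- matrix(0, nrow(X), n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, k_folds, derive_seed(seed, r))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      st <- suppressWarnings(standardize(Xs[tr, , drop = FALSE],
                                         Xs[!tr, , drop = FALSE]))
      model <- train_svm(st$train, y[tr], C = C)
      acc[!tr, r] <- svm_score(model, st$apply)
    }
  }
  rowMeans(acc)
}

#' Sequential forward feature selection under CV
#'
#' Greedy forward selection: at each iteration every remaining candidate is
#' scored by [cv_objective()] on identical folds and the best is added;
#' selection stops when the best improvement falls below `min_improve`
#' (default 1e-6) or `max_features` is reached.  Ties break toward the
#' lower feature index.  The returned model is refit on all data with the
#' selected subset.
#'
#' @inheritParams cv_objective
#' @param max_features selection cap (default 4).
#' @param min_improve termination threshold on the CV objective.
#' @return list with `selected` (ordered indices), `trace` (per-iteration
#'   data frame: chosen feature, objective), `candidate_scores`
#'   (per-iteration named vectors), and `model` (an `svm_model` refit on
#'   all data).
#' @export
sequential_forward_selection <- function(X, y, k_folds = 10, n_repeats = 1,
                                         seed = 1, max_features = 4,
                                         min_improve = 1e-6,
                                         metric = c("accuracy", "auc"),
                                         C = 1) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2)
    stop_radscore("need >= 2 candidate features", "radscore_spec_error")
  selected <- integer(0)
  current <- if (metric == "accuracy") max(table(y)) / length(y) else 0.5
  trace <- data.frame(iteration = integer(0), feature = integer(0),
                      objective = numeric(0))
  cand_scores <- list()
  repeat {
    remaining <- setdiff(seq_len(p), selected)
    if (length(remaining) == 0 || length(selected) >= max_features) break
    # compiled fast path; identical folds, standardization and solver
    # settings as cv_objective (equivalence is under test)
    acc <- numeric(length(remaining))
    for (r in seq_len(n_repeats)) {
      fold <- stratified_folds(y, k_folds, derive_seed(seed, r))
      acc <- acc + sfs_candidate_objective(
        X, as.double(y), as.integer(fold), as.integer(selected),
        as.integer(remaining), C, 1e-3, 2000L,
        if (metric == "auc") 1L else 0L)
    }
    objs <- acc / n_repeats
    names(objs) <- colnames(X)[remaining] %||% as.character(remaining)
    best <- which.max(objs)  # first maximum = lowest index tie-break
    cand_scores[[length(cand_scores) + 1]] <- objs
    if (objs[best] - current < min_improve) break
    selected <- c(selected, remaining[best])
    current <- objs[best]
    trace <- rbind(trace, data.frame(iteration = length(selected),
                                     feature = remaining[best],
                                     objective = current))
  }
  if (length(selected) == 0) {
    # no candidate improves on the empty set; keep the single best so a
    # model exists, but record the empty-improvement trace
    selected <- which.max(cand_scores[[1]])
  }
  model <- fit_svm_model(X, y, features = selected, C = C)
  list(selected = selected, trace = trace, candidate_scores = cand_scores,
       model = model)
}
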