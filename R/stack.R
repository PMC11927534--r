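#' Out-of-fold meta-features for stacking
#'
#' For each base learner, class-probability predictions are generated
#' out-of-fold under stratified cross-validation, so no row is ever
#' predicted by a model trained on it; the per-learner probability
#' blocks are concatenated column-wise.
#'
#' @param train a `feature_table`.
#' @param learners base-learner names.
#' @param hyperparams optional per-learner hyperparameter lists.
#' @param n_folds folds (default 5).
#' @param seed seed fixing folds and fits.
#' @return n x (K * B) matrix with columns `learner.class`, plus a
#'   `"folds"` attribute with the fold assignment used.
#' @export
oof_meta_features <- function(train, learners, hyperparams = NULL,
                              n_folds = 5, seed = 1) {
  stopifnot(inherits(train, "feature_table"))
  if (n_folds < 2) stop("n_folds must be >= 2")
  pool <- candidate_pool(learners)
  y <- train$y
  classes <- levels(y)
  fold <- stratified_folds(y, n_folds, seed)
  meta <- matrix(0, length(y), length(classes) * length(pool))
  colnames(meta) <- as.vector(outer(classes, names(pool),
                                    function(k, b) paste(b, k, sep = ".")))
  for (b in seq_along(pool)) {
    spec <- pool[[b]]
    params <- .merge_params(spec, hyperparams[[names(pool)[b]]])
    cols <- (b - 1L) * length(classes) + seq_along(classes)
    for (f in seq_len(n_folds)) {
      te <- fold == f
      set.seed(seed + 1000L * b + f)
      m <- spec$fit(train$x[!te, , drop = FALSE], droplevels(y[!te]),
                    params)
      meta[te, cols] <- spec$prob(m, train$x[te, , drop = FALSE],
                                  classes)
    }
  }
  attr(meta, "folds") <- fold
  meta
}

#' Extract base-learner weights from the meta-learner
#'
#' Per base learner, the mean absolute meta-learner coefficient over
#' its probability columns and over classes, normalized to sum to one.
#' These weights express the relative importance of each base learner
#' in the ensemble's decision and drive the weighted Shapley
#' aggregation.
#'
#' @param meta a fitted `nnet::multinom` meta-learner, or a coefficient
#'   matrix whose first column is the intercept followed by the
#'   `n_bases * n_classes` probability-column coefficients.
#' @param n_bases number of base learners.
#' @param n_classes number of classes.
#' @return Numeric weight vector (length `n_bases`, non-negative,
#'   summing to 1).
#' @export
extract_base_weights <- function(meta, n_bases, n_classes) {
  cf <- if (is.matrix(meta)) meta else
    tryCatch(stats::coef(meta), error = function(e) NULL)
  if (is.null(cf)) return(rep(1 / n_bases, n_bases))
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  cf <- cf[, -1, drop = FALSE]                    # drop intercept
  if (ncol(cf) != n_bases * n_classes)
    stop("meta coefficient shape mismatch")
  w <- vapply(seq_len(n_bases), function(b) {
    cols <- (b - 1L) * n_classes + seq_len(n_classes)
    mean(abs(cf[, cols]))
  }, numeric(1))
  if (sum(w) <= 0) return(rep(1 / n_bases, n_bases))
  w / sum(w)
}

#' Fit a stacking ensemble (optionally tuned by hybrid DE)
#'
#' The central fitting function. Base learners are fitted on the full
#' training data; a multinomial-logistic meta-learner is fitted on
#' their out-of-fold class probabilities; per-base weights are
#' extracted from the meta-learner's coefficients. With
#' `optimize = TRUE` the base-learner hyperparameters are first tuned
#' by [hde_optimize()] against the stack's cross-validated accuracy
#' ([cv_fitness()]).
#'
#' @param x a `feature_table`, or a numeric feature matrix.
#' @param y class labels (ignored when `x` is a `feature_table`).
#' @param learners base-learner names (default the diversity-selected
#'   trio `LR`, `DT`, `MLP`).
#' @param hyperparams optional per-learner hyperparameter lists; when
#'   `optimize = TRUE` these are replaced by the tuned values.
#' @param n_folds folds for the out-of-fold meta-features.
#' @param seed seed fixing folds and fits.
#' @param optimize tune hyperparameters with the hybrid DE optimizer.
#' @param control an [hde_control()] for the optimizer.
#' @param fitness_folds folds for the optimizer's CV objective.
#' @return An object of class `hde_stack` with elements `base_models`,
#'   `learners`, `hyperparams`, `meta`, `base_weights`, `classes`,
#'   `n_folds`, `seed`, and (when optimized) `hde`.
#' @seealso [predict.hde_stack()], [ensemble_size_sweep()],
#'   [stack_shap()]
#' @export
hde_stack <- function(x, y = NULL, learners = c("LR", "DT", "MLP"),
                      hyperparams = NULL, n_folds = 5, seed = 1,
                      optimize = FALSE, control = hde_control(),
                      fitness_folds = n_folds) {
  train <- if (inherits(x, "feature_table")) x else feature_table(x, y)
  if (length(learners) < 1) stop("at least one base learner required")
  if (min(table(train$y)) < n_folds)
    stop("a training class has fewer samples than n_folds")
  hde_res <- NULL
  if (optimize) {
    space <- joint_param_space(learners)
    obj <- function(params)
      cv_fitness(train, learners, split_joint_params(params, learners),
                 n_folds = fitness_folds, seed = seed)
    hde_res <- hde_optimize(obj, space, control)
    hyperparams <- split_joint_params(hde_res$best_params, learners)
  }
  pool <- candidate_pool(learners)
  classes <- levels(train$y)
  meta_x <- oof_meta_features(train, learners, hyperparams, n_folds,
                              seed)
  base_models <- vector("list", length(pool))
  names(base_models) <- names(pool)
  used <- vector("list", length(pool))
  names(used) <- names(pool)
  for (b in seq_along(pool)) {
    params <- .merge_params(pool[[b]], hyperparams[[names(pool)[b]]])
    set.seed(seed + 77L * b)
    base_models[[b]] <- pool[[b]]$fit(train$x, train$y, params)
    used[[b]] <- params
  }
  md <- as.data.frame(meta_x)
  names(md) <- paste0("M", seq_len(ncol(md)))
  md$.y <- train$y
  meta <- nnet::multinom(.y ~ ., md, trace = FALSE, decay = 1e-3,
                         maxit = 300, MaxNWts = 1e5)
  w <- extract_base_weights(meta, length(pool), length(classes))
  names(w) <- names(pool)
  structure(list(base_models = base_models, learners = learners,
                 hyperparams = used, meta = meta,
                 base_weights = w, classes = classes,
                 n_folds = n_folds, seed = seed, hde = hde_res,
                 n_features = ncol(train$x),
                 feature_names = colnames(train$x)),
            class = "hde_stack")
}

# joint space over several learners, parameter names prefixed
joint_param_space <- function(learners) {
  pool <- candidate_pool(learners)
  parts <- list()
  for (b in names(pool))
    for (pn in names(pool[[b]]$space))
      parts[[paste(b, pn, sep = ".")]] <- pool[[b]]$space[[pn]]
  do.call(param_space, parts)
}

split_joint_params <- function(params, learners) {
  out <- stats::setNames(vector("list", length(learners)), learners)
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    out[[parts[1]]][[parts[2]]] <- params[[nm]]
  }
  out
}

#' Cross-validated fitness of a stack configuration
#'
#' Mean stratified-CV accuracy of the stacking ensemble under given
#' hyperparameters — the objective maximized by the DE optimizer.
#' Folds and fits are seeded, so the objective is deterministic for a
#' given seed.
#'
#' @param train a `feature_table`.
#' @param learners base-learner names.
#' @param hyperparams per-learner hyperparameter lists.
#' @param n_folds outer CV folds.
#' @param seed seed.
#' @return Scalar in `[0, 1]`.
#' @export
cv_fitness <- function(train, learners, hyperparams = NULL,
                       n_folds = 5, seed = 1) {
  stopifnot(inherits(train, "feature_table"))
  fold <- stratified_folds(train$y, n_folds, seed + 500L)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    fit <- hde_stack(ft_subset_rows(train, which(!te)),
                     learners = learners, hyperparams = hyperparams,
                     n_folds = min(3, n_folds), seed = seed)
    pr <- predict(fit, train$x[te, , drop = FALSE])
    acc[f] <- mean(as.character(pr) ==
                     as.character(train$y[te]))
  }
  mean(acc)
}

#' Predict from a fitted stacking ensemble
#'
#' @param object an `hde_stack`.
#' @param newdata feature matrix or `feature_table` with the training
#'   feature layout.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return Factor of predicted classes, or a probability matrix.
#' @export
predict.hde_stack <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_table")) newdata$x else
    as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("newdata has ", ncol(x), " features; expected ",
         object$n_features)
  meta_x <- stack_meta_features(object, x)
  md <- as.data.frame(meta_x)
  names(md) <- paste0("M", seq_len(ncol(md)))
  p <- stats::predict(object$meta, md, type = "probs")
  if (is.null(dim(p)) && length(object$classes) == 2)
    p <- cbind(1 - p, p)
  if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

# base-learner probability blocks for new data
stack_meta_features <- function(object, x) {
  pool <- candidate_pool(object$learners)
  K <- length(object$classes)
  meta <- matrix(0, nrow(x), K * length(pool))
  for (b in seq_along(pool))
    meta[, (b - 1L) * K + seq_len(K)] <-
      pool[[b]]$prob(object$base_models[[b]], x, object$classes)
  meta
}

#' @export
print.hde_stack <- function(x, ...) {
  cat("<hde_stack>", length(x$learners), "base learners:",
      paste(x$learners, collapse = ", "), "\n")
  cat("  base weights:",
      paste(sprintf("%s=%.3f", x$learners, x$base_weights),
            collapse = ", "), "\n")
  if (!is.null(x$hde))
    cat(sprintf("  tuned by HDE: CV fitness %.4f\n",
                x$hde$best_fitness))
  invisible(x)
}

#' @export
summary.hde_stack <- function(object, ...) {
  cat("Stacking ensemble over", length(object$classes), "classes\n")
  print(object)
  cat("  hyperparameters:\n")
  for (b in object$learners) {
    pp <- object$hyperparams[[b]]
    pp <- pp[!vapply(pp, is.null, logical(1))]
    cat(sprintf("    %s: %s\n", b,
                paste(sprintf("%s=%.4g", names(pp),
                              unlist(pp)), collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.hde_stack <- function(object, ...) object$base_weights

#' Ensemble-size sweep
#'
#' Builds the stack from the top-K candidates of a diversity ranking
#' for each K in `K_range` and evaluates accuracy / macro precision /
#' recall / F1 on a test set, tracing how ensemble performance first
#' rises and then falls as weaker or redundant learners join.
#'
#' @param report a [diversity_report()].
#' @param train,test `feature_table`s.
#' @param K_range sizes to evaluate (default `1..M`).
#' @param n_folds,seed passed to [hde_stack()].
#' @return data.frame with one row per K: `K`, `learners`, and the
#'   four test metrics (percent).
#' @export
ensemble_size_sweep <- function(report, train, test,
                                K_range = seq_len(nrow(report$ranking)),
                                n_folds = 5, seed = 1) {
  out <- data.frame()
  for (K in K_range) {
    sel <- select_base_learners(report, K)
    fit <- hde_stack(train, learners = sel, n_folds = n_folds,
                     seed = seed)
    pm <- performance_metrics(predict(fit, test$x), test$y)
    out <- rbind(out, data.frame(K = K,
                                 learners = paste(sel, collapse = "+"),
                                 t(pm)))
  }
  out
}
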