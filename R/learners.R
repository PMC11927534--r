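# Candidate classifier pool. Each learner exposes a hyperparameter
# space, defaults, a fit function and a class-probability predictor
# returning columns ordered by the factor levels of the training
# labels. Fits are deterministic given the caller's RNG state.

.as_learn_df <- function(x) {
  d <- as.data.frame(x)
  names(d) <- paste0("V", seq_len(ncol(d)))
  d
}

# reorder/complete a probability matrix to the full class set
.prob_fix <- function(p, classes, n) {
  if (is.null(dim(p))) p <- matrix(p, nrow = n)
  out <- matrix(0, n, length(classes),
                dimnames = list(NULL, classes))
  cn <- colnames(p)
  if (is.null(cn) && ncol(p) == length(classes)) cn <- classes
  keep <- intersect(cn, classes)
  out[, keep] <- p[, match(keep, cn), drop = FALSE]
  out
}

# deterministic RBF bandwidth: median heuristic on at most 200 rows
.median_sigma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 200) round(seq(1, n, length.out = 200)) else seq_len(n)
  d2 <- stats::dist(x[idx, , drop = FALSE])^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 else 1 / m
}

#' The candidate base-learner pool
#'
#' Six standard classifiers — multinomial logistic regression (LR),
#' decision tree (DT), RBF support vector machine (SVM), k-nearest
#' neighbours (KNN), Gaussian process (GP) and a single-hidden-layer
#' perceptron (MLP) — with bounded, log-scaled-where-conventional
#' hyperparameter spaces for the DE optimizer.
#'
#' @param learners which learners to include.
#' @return Named list; each element has `space` (a [param_space()]),
#'   `defaults`, `fit(x, y, params)` and `prob(model, x, classes)`.
#' @export
candidate_pool <- function(learners = c("LR", "DT", "SVM", "KNN",
                                        "GP", "MLP")) {
  pool <- list(
    LR = list(
      space = param_space(decay = p_num(1e-4, 1e1, "log")),
      defaults = list(decay = 1e-3),
      fit = function(x, y, params) {
        d <- .as_learn_df(x); d$.y <- y
        nnet::multinom(.y ~ ., d, trace = FALSE, decay = params$decay,
                       maxit = 200, MaxNWts = 1e5)
      },
      prob = function(m, x, classes) {
        p <- stats::predict(m, .as_learn_df(x), type = "probs")
        if (is.null(dim(p))) {
          if (length(m$lev) == 2) {
            # binary: vector of P(second level)
            p <- cbind(1 - p, p)
            colnames(p) <- m$lev
          } else {
            # single row: named vector over classes
            p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
          }
        }
        .prob_fix(p, classes, nrow(x))
      }),
    DT = list(
      space = param_space(max_depth = p_int(2, 20),
                          cp = p_num(1e-4, 1e-1, "log")),
      defaults = list(max_depth = 10, cp = 1e-3),
      fit = function(x, y, params) {
        d <- .as_learn_df(x); d$.y <- y
        rpart::rpart(.y ~ ., d, method = "class",
                     control = rpart::rpart.control(
                       maxdepth = params$max_depth, cp = params$cp,
                       xval = 0))
      },
      prob = function(m, x, classes)
        .prob_fix(stats::predict(m, .as_learn_df(x)), classes, nrow(x))),
    SVM = list(
      space = param_space(cost = p_num(1e-2, 1e2, "log"),
                          gamma = p_num(1e-4, 1e1, "log")),
      defaults = list(cost = 1, gamma = NULL),
      fit = function(x, y, params) {
        g <- params$gamma
        if (is.null(g)) g <- 1 / ncol(x)
        d <- .as_learn_df(x); d$.y <- y
        e1071::svm(.y ~ ., d, cost = params$cost, gamma = g,
                   kernel = "radial", probability = TRUE)
      },
      prob = function(m, x, classes) {
        pr <- stats::predict(m, .as_learn_df(x), probability = TRUE)
        .prob_fix(attr(pr, "probabilities"), classes, nrow(x))
      }),
    KNN = list(
      space = param_space(k = p_int(1, 30)),
      defaults = list(k = 5),
      fit = function(x, y, params) {
        k <- min(params$k, length(y) - 1)
        caret::knn3(as.matrix(x), y, k = k)
      },
      prob = function(m, x, classes)
        .prob_fix(stats::predict(m, as.matrix(x), type = "prob"),
                  classes, nrow(x))),
    GP = list(
      space = param_space(sigma = p_num(1e-3, 1e1, "log")),
      defaults = list(sigma = NULL),
      fit = function(x, y, params) {
        s <- params$sigma
        if (is.null(s)) s <- .median_sigma(as.matrix(x))
        kernlab::gausspr(as.matrix(x), y, kernel = "rbfdot",
                         kpar = list(sigma = s))
      },
      prob = function(m, x, classes) {
        # multiclass probability coupling is unreliable in this GP
        # implementation; use one-hot of the class predictions (the
        # stated convention for learners without probability output)
        cl <- as.character(kernlab::predict(m, as.matrix(x)))
        p <- matrix(0, nrow(x), length(classes),
                    dimnames = list(NULL, classes))
        p[cbind(seq_len(nrow(x)), match(cl, classes))] <- 1
        p
      }),
    MLP = list(
      space = param_space(size = p_int(8, 64),
                          decay = p_num(1e-5, 1e-1, "log")),
      defaults = list(size = 32, decay = 1e-3),
      fit = function(x, y, params) {
        m <- nnet::nnet(as.matrix(x), one_hot(y), size = params$size,
                        decay = params$decay, softmax = TRUE,
                        maxit = 150, trace = FALSE, MaxNWts = 1e5)
        m$.classes <- levels(y)
        m
      },
      prob = function(m, x, classes) {
        p <- stats::predict(m, as.matrix(x))
        colnames(p) <- m$.classes
        .prob_fix(p, classes, nrow(x))
      }))
  unknown <- setdiff(learners, names(pool))
  if (length(unknown))
    stop("unknown learner(s): ", paste(unknown, collapse = ", "))
  pool[learners]
}

# fill missing hyperparameters with the pool defaults
.merge_params <- function(spec, params) {
  out <- spec$defaults
  for (nm in names(params)) out[[nm]] <- params[[nm]]
  out
}

#' Out-of-fold candidate evaluation
#'
#' Fits each candidate on stratified cross-validation folds and
#' collects its out-of-fold predicted labels, the input to
#' [diversity_report()].
#'
#' @param train a `feature_table`.
#' @param learners candidate names (see [candidate_pool()]).
#' @param hyperparams optional named list (per learner) of
#'   hyperparameter overrides.
#' @param n_folds folds (default 5).
#' @param seed seed fixing folds and fits.
#' @return Named list of out-of-fold prediction vectors.
#' @export
evaluate_candidates <- function(train, learners = c("LR", "DT", "SVM",
                                                    "KNN", "GP", "MLP"),
                                hyperparams = NULL, n_folds = 5,
                                seed = 1) {
  stopifnot(inherits(train, "feature_table"))
  pool <- candidate_pool(learners)
  y <- train$y
  classes <- levels(y)
  fold <- stratified_folds(y, n_folds, seed)
  preds <- lapply(pool, function(.) character(length(y)))
  for (b in seq_along(pool)) {
    spec <- pool[[b]]
    params <- .merge_params(spec, hyperparams[[names(pool)[b]]])
    for (f in seq_len(n_folds)) {
      te <- fold == f
      set.seed(seed + 1000L * b + f)
      m <- spec$fit(train$x[!te, , drop = FALSE], droplevels(y[!te]),
                    params)
      p <- spec$prob(m, train$x[te, , drop = FALSE], classes)
      preds[[b]][te] <- classes[max.col(p, ties.method = "first")]
    }
  }
  names(preds) <- names(pool)
  preds
}
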