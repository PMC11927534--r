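# Internal PLS machinery shared by the band selectors. The inner model
# throughout is PLS regression on one-hot class indicators, the
# standard chemometric device for driving RMSECV-based wavelength
# selection in a classification setting.

one_hot <- function(y) {
  y <- as.factor(y)
  m <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, paste0("c", seq_len(nlevels(y)))))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

# Fit PLS and return the regression coefficient matrix (p x q) at the
# largest usable number of components.
pls_coef <- function(x, y01, ncomp = 5) {
  x <- as.matrix(x)
  keep <- apply(x, 2, stats::sd) > 1e-12
  ncomp <- max(1, min(ncomp, sum(keep), nrow(x) - 1))
  B <- matrix(0, ncol(x), ncol(y01))
  if (sum(keep) == 0) return(B)
  xs <- x[, keep, drop = FALSE]
  if (sum(keep) < 3) {
    # tiny subsets: full-rank PLS equals MLR, and the PLS backend
    # needs at least 3 columns
    cf <- stats::lm.fit(cbind(1, xs), y01)$coefficients
    cf[is.na(cf)] <- 0
    B[keep, ] <- cf[-1, , drop = FALSE]
    return(B)
  }
  colnames(xs) <- paste0("V", seq_len(ncol(xs)))
  fit <- mixOmics::pls(xs, y01, ncomp = ncomp, mode = "regression")
  pr <- stats::predict(fit, xs[1, , drop = FALSE])
  B[keep, ] <- pr$B.hat[, , ncomp]
  B
}

pls_predict_new <- function(x_tr, y01_tr, x_te, ncomp = 5) {
  keep <- apply(x_tr, 2, stats::sd) > 1e-12
  if (sum(keep) == 0)
    return(matrix(colMeans(y01_tr), nrow(x_te), ncol(y01_tr),
                  byrow = TRUE))
  ncomp <- max(1, min(ncomp, sum(keep), nrow(x_tr) - 1))
  xs <- x_tr[, keep, drop = FALSE]
  if (sum(keep) < 3) {
    cf <- stats::lm.fit(cbind(1, xs), y01_tr)$coefficients
    cf[is.na(cf)] <- 0
    return(cbind(1, x_te[, keep, drop = FALSE]) %*% cf)
  }
  colnames(xs) <- paste0("V", seq_len(ncol(xs)))
  xt <- x_te[, keep, drop = FALSE]
  colnames(xt) <- colnames(xs)
  fit <- mixOmics::pls(xs, y01_tr, ncomp = ncomp, mode = "regression")
  stats::predict(fit, xt)$predict[, , ncomp]
}

# 5-fold root-mean-square error of cross-validation of the inner PLS.
rmsecv_pls <- function(x, y01, ncomp = 5, n_folds = 5, seed = 1) {
  x <- as.matrix(x)
  set.seed(seed)
  fold <- rep_len(seq_len(n_folds), nrow(x))[sample(nrow(x))]
  se <- 0
  for (f in seq_len(n_folds)) {
    te <- fold == f
    pr <- pls_predict_new(x[!te, , drop = FALSE], y01[!te, , drop = FALSE],
                          x[te, , drop = FALSE], ncomp)
    se <- se + sum((pr - y01[te, , drop = FALSE])^2)
  }
  sqrt(se / length(y01))
}

selection_result <- function(method, indices, score_trace, params,
                             feature_names = NULL) {
  structure(list(method = method, indices = as.integer(indices),
                 score_trace = score_trace, params = params,
                 feature_names = feature_names),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d features selected\n",
              x$method, length(x$indices)))
  invisible(x)
}

#' Successive projections algorithm (SPA) for wavelength selection
#'
#' Forward selection by vector projection: starting from a candidate
#' band, each step adds the band whose projection onto the orthogonal
#' complement of the already-selected set has maximal norm, yielding a
#' minimally collinear chain. Chain prefixes are scored by the RMSE of
#' a multiple linear regression on one-hot labels over a held-out
#' validation split, and the (start, size) pair with minimal RMSE wins.
#'
#' @param x samples x bands matrix.
#' @param y class labels.
#' @param n_max maximum chain length.
#' @param n_starts number of starting bands tried (the bands of largest
#'   norm after autoscaling); `NULL` tries every band.
#' @param val_frac validation fraction for the inner scoring model.
#' @param seed seed for the validation split.
#' @return A `selection_result`; `score_trace` holds the per-size RMSE
#'   of the winning chain.
#' @export
spa_select <- function(x, y, n_max = 20, n_starts = 30, val_frac = 0.3,
                       seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (n_max < 1 || n_max > p) stop("n_max must be in [1, bands]")
  y01 <- one_hot(y)
  # autoscale so projection norms are comparable across bands
  mu <- colMeans(x); sdev <- apply(x, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu, `-`), 2, sdev, `/`)
  norms0 <- sqrt(colSums(xs^2))
  starts <- order(norms0, decreasing = TRUE)
  if (!is.null(n_starts)) starts <- starts[seq_len(min(n_starts, p))]
  starts <- starts[norms0[starts] > 1e-10]
  set.seed(seed)
  n <- nrow(x)
  val <- sample(n, max(1, round(val_frac * n)))
  tr <- setdiff(seq_len(n), val)
  best <- list(rmse = Inf, chain = integer(0), k = 0, trace = NULL)
  for (s0 in starts) {
    res <- xs
    chain <- integer(0)
    avail <- rep(TRUE, p)
    j <- s0
    for (step in seq_len(min(n_max, p))) {
      chain <- c(chain, j)
      avail[j] <- FALSE
      u <- res[, j]
      uu <- sum(u^2)
      if (uu < 1e-12) break
      proj <- as.numeric(crossprod(res, u)) / uu
      res <- res - outer(u, proj)
      res[, !avail] <- 0
      nn <- sqrt(colSums(res^2))
      if (step == min(n_max, p) || max(nn) < 1e-8) break
      j <- which.max(nn)
    }
    rmse_k <- vapply(seq_along(chain), function(k) {
      sel <- chain[seq_len(k)]
      fit <- stats::lm.fit(cbind(1, x[tr, sel, drop = FALSE]), y01[tr, ])
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      pr <- cbind(1, x[val, sel, drop = FALSE]) %*% cf
      sqrt(mean((pr - y01[val, , drop = FALSE])^2))
    }, numeric(1))
    k <- which.min(rmse_k)
    if (rmse_k[k] < best$rmse)
      best <- list(rmse = rmse_k[k], chain = chain, k = k,
                   trace = rmse_k)
  }
  if (best$k == 0) stop("SPA found no usable band chain")
  selection_result("SPA", best$chain[seq_len(best$k)], best$trace,
                   list(n_max = n_max, n_starts = n_starts,
                        val_frac = val_frac, seed = seed))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo wavelength selection: at each sampling an inner PLS is
#' fitted on a random row subset, bands are ranked by absolute
#' regression coefficient, the retained fraction shrinks along a
#' two-constant exponential decay fixed by its endpoints (all bands at
#' the first sampling, two at the last), and adaptive reweighted
#' sampling draws the surviving set. The subset with minimal 5-fold
#' RMSECV wins.
#'
#' @inheritParams spa_select
#' @param n_mc number of Monte-Carlo samplings (>= 2).
#' @param ncomp inner PLS components.
#' @param n_folds folds for the RMSECV criterion.
#' @return A `selection_result`; `score_trace` is the per-sampling
#'   RMSECV, with `n_retained` giving the retained-count schedule.
#' @export
cars_select <- function(x, y, n_mc = 50, ncomp = 5, n_folds = 5,
                        seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (n_mc < 2) stop("n_mc must be >= 2")
  y01 <- one_hot(y)
  n <- nrow(x)
  # exponential decay through (1, 1) and (n_mc, 2/p)
  kdec <- log(p / 2) / (n_mc - 1)
  ratio <- exp(kdec) * exp(-kdec * seq_len(n_mc))
  set.seed(seed)
  retained <- seq_len(p)
  sets <- vector("list", n_mc)
  rmse <- rep(NA_real_, n_mc)
  n_ret <- integer(n_mc)
  for (i in seq_len(n_mc)) {
    rows <- sample(n, max(2, round(0.8 * n)))
    B <- pls_coef(x[rows, retained, drop = FALSE], y01[rows, ], ncomp)
    w <- rowSums(abs(B))
    n_keep <- min(length(retained), max(2, round(ratio[i] * p)))
    top <- retained[order(w, decreasing = TRUE)[seq_len(n_keep)]]
    w_top <- w[match(top, retained)]
    if (sum(w_top) <= 0) w_top <- rep(1, length(top))
    retained <- sort(unique(sample(top, n_keep, replace = TRUE,
                                   prob = w_top)))
    n_ret[i] <- n_keep
    sets[[i]] <- retained
    rmse[i] <- rmsecv_pls(x[, retained, drop = FALSE], y01, ncomp,
                          n_folds, seed = seed + i)
    if (length(retained) < 2) break
  }
  done <- which(!is.na(rmse))
  ibest <- done[which.min(rmse[done])]
  selection_result("CARS", sets[[ibest]], rmse[done],
                   list(n_mc = n_mc, ncomp = ncomp, seed = seed,
                        n_retained = n_ret[done], best_iter = ibest))
}

#' Bootstrap soft shrinkage (BOSS) wavelength selection
#'
#' Iteratively: draw sub-models by weighted bootstrap sampling of the
#' surviving bands, fit an inner PLS per sub-model on a row bootstrap,
#' score it on the out-of-bag rows, accumulate the normalized absolute
#' coefficients of the best sub-models into soft weights (bands absent
#' from every retained sub-model shrink to zero and drop out), and
#' record the 5-fold RMSECV of the iteration's best sub-model. The
#' bands of the minimal-RMSECV iteration are returned.
#'
#' @inheritParams cars_select
#' @param n_boot sub-models per iteration (>= 2).
#' @param max_iter iteration cap.
#' @return A `selection_result`; `score_trace` is the per-iteration
#'   RMSECV with its argmin in `params$best_iter`; `params$weights`
#'   holds the final soft weights (non-negative, summing to one).
#' @export
boss_select <- function(x, y, n_boot = 30, ncomp = 5, n_folds = 5,
                        seed = 1, max_iter = 20) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (n_boot < 2) stop("n_boot must be >= 2")
  y01 <- one_hot(y)
  n <- nrow(x)
  set.seed(seed)
  w <- rep(1 / p, p)
  rmse <- numeric(0)
  sets <- list()
  w_trace <- list()
  for (it in seq_len(max_iter)) {
    pool <- which(w > 0)
    if (length(pool) < 2) break
    sub_rmse <- rep(Inf, n_boot)
    sub_vars <- vector("list", n_boot)
    sub_B <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      vars <- sort(unique(sample(pool, length(pool), replace = TRUE,
                                 prob = w[pool])))
      rows <- sample(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(rows))
      if (length(oob) < 2) oob <- seq_len(n)
      B <- pls_coef(x[rows, vars, drop = FALSE], y01[rows, ], ncomp)
      pr <- pls_predict_new(x[rows, vars, drop = FALSE], y01[rows, ],
                            x[oob, vars, drop = FALSE], ncomp)
      sub_rmse[b] <- sqrt(mean((pr - y01[oob, , drop = FALSE])^2))
      sub_vars[[b]] <- vars
      sub_B[[b]] <- B
    }
    keep <- order(sub_rmse)[seq_len(max(1, floor(n_boot / 10)))]
    w_new <- rep(0, p)
    for (b in keep) {
      ab <- rowSums(abs(sub_B[[b]]))
      if (sum(ab) > 0) w_new[sub_vars[[b]]] <- w_new[sub_vars[[b]]] +
          ab / sum(ab)
    }
    if (sum(w_new) <= 0) break
    w <- w_new / sum(w_new)
    bb <- keep[1]
    sets[[it]] <- sub_vars[[bb]]
    rmse[it] <- rmsecv_pls(x[, sub_vars[[bb]], drop = FALSE], y01,
                           ncomp, n_folds, seed = seed + it)
    w_trace[[it]] <- w
  }
  if (length(rmse) == 0) stop("BOSS produced no usable iteration")
  ibest <- which.min(rmse)
  selection_result("BOSS", sets[[ibest]], rmse,
                   list(n_boot = n_boot, ncomp = ncomp, seed = seed,
                        best_iter = ibest, weights = w_trace,
                        final_weights = w))
}

#' Morphological feature selection (MI / RFE / SFM)
#'
#' Thin wrappers over standard selectors: mutual-information ranking
#' (equal-frequency discretization), recursive feature elimination with
#' a multinomial-logistic importance backend, and tree-importance
#' (Gini) thresholding via a random forest, each returning the top `k`
#' features.
#'
#' @param ft a `feature_table`.
#' @param method one of `"MI"`, `"RFE"`, `"SFM"`.
#' @param k number of features to keep (default 15).
#' @param seed seed (used by SFM's forest and RFE's fits).
#' @return A `selection_result` with `k` indices ordered by importance.
#' @export
morph_select <- function(ft, method = c("MI", "RFE", "SFM"), k = 15,
                         seed = 1) {
  method <- match.arg(method)
  x <- ft$x; y <- ft$y
  if (k > ncol(x)) stop("k exceeds the number of features")
  idx <- switch(method,
    MI = {
      mi <- apply(x, 2, mutual_information, y = y)
      order(mi, decreasing = TRUE)[seq_len(k)]
    },
    RFE = rfe_multinom(x, y, k, seed),
    SFM = {
      set.seed(seed)
      rf <- randomForest::randomForest(x, y, ntree = 300)
      imp <- rf$importance[, "MeanDecreaseGini"]
      order(imp, decreasing = TRUE)[seq_len(k)]
    })
  selection_result(method, idx, numeric(0), list(k = k, seed = seed),
                   feature_names = colnames(x)[idx])
}

# Mutual information between a continuous feature and a class label via
# equal-frequency discretization of the feature.
mutual_information <- function(x, y, n_bins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(0)
  xb <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(xb, y)
  pj <- tab / sum(tab)
  pr <- rowSums(pj); pc <- colSums(pj)
  e <- outer(pr, pc)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / e[nz]))
}

# Recursive feature elimination: standardized multinomial-logistic fits,
# importance = mean absolute coefficient per feature, dropping the
# worst ~20% of survivors each round until k remain.
rfe_multinom <- function(x, y, k, seed = 1) {
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, colMeans(x), `-`), 2, sdev, `/`)
  remaining <- seq_len(ncol(x))
  set.seed(seed)
  while (length(remaining) > k) {
    d <- data.frame(xs[, remaining, drop = FALSE], .y = y)
    names(d) <- c(paste0("V", remaining), ".y")
    fit <- nnet::multinom(.y ~ ., d, trace = FALSE, decay = 1e-3,
                          MaxNWts = 1e5, maxit = 120)
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
    imp <- colMeans(abs(cf[, -1, drop = FALSE]))
    n_drop <- min(length(remaining) - k,
                  max(1, floor(0.2 * length(remaining))))
    remaining <- remaining[order(imp,
                                 decreasing = TRUE)][seq_len(length(remaining) - n_drop)]
  }
  # order survivors by a final fit's importance
  d <- data.frame(xs[, remaining, drop = FALSE], .y = y)
  names(d) <- c(paste0("V", remaining), ".y")
  fit <- nnet::multinom(.y ~ ., d, trace = FALSE, decay = 1e-3,
                        MaxNWts = 1e5, maxit = 120)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  imp <- colMeans(abs(cf[, -1, drop = FALSE]))
  remaining[order(imp, decreasing = TRUE)]
}
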