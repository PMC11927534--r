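# Shapley-value attribution for arbitrary probability-output models.
# Coalition values are interventional: features outside the coalition
# are marginalized over a background sample. Two estimators:
#   exact    — full subset enumeration (2^p coalitions), for small p;
#   sampling — permutation telescoping: for each sampled feature
#              ordering the marginal contributions telescope from the
#              background mean to f(x), so additivity (local accuracy)
#              is exact by construction in both modes.

#' Shapley values for a prediction function
#'
#' @param predict_fun function mapping a feature matrix to an
#'   n x C output matrix (e.g. class probabilities).
#' @param X samples to explain (matrix, rows = samples).
#' @param background background feature matrix used to marginalize
#'   absent features (typically a k-means summary of training data).
#' @param n_perm permutations per sample for the sampling estimator.
#' @param exact force exact enumeration (`TRUE`/`FALSE`); default
#'   enumerates when `ncol(X) <= 10`.
#' @param seed seed for the permutation draws.
#' @return Object of class `shap_values`: list with `values`
#'   (array samples x features x outputs), `base_values` (length-C
#'   expected output over the background), `method`.
#' @export
shap_values <- function(predict_fun, X, background, n_perm = 20,
                        exact = NULL, seed = 1) {
  X <- as.matrix(X); background <- as.matrix(background)
  if (nrow(background) < 1) stop("background must be non-empty")
  p <- ncol(X)
  if (is.null(exact)) exact <- p <= 10
  out0 <- predict_fun(background)
  if (is.null(dim(out0))) out0 <- matrix(out0, nrow(background))
  C <- ncol(out0)
  base <- colMeans(out0)
  vals <- array(0, dim = c(nrow(X), p, C),
                dimnames = list(NULL, colnames(X), colnames(out0)))
  nb <- nrow(background)
  if (exact) {
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
    sizes <- rowSums(subsets)
    # Shapley kernel weight s!(p-1-s)!/p! for coalitions S not
    # containing the feature (|S| <= p-1); the full set never enters
    wgt <- numeric(length(sizes))
    ok <- sizes <= p - 1
    wgt[ok] <- factorial(sizes[ok]) * factorial(p - 1 - sizes[ok]) /
      factorial(p)
    for (i in seq_len(nrow(X))) {
      # coalition values v(S) for every S
      big <- background[rep(seq_len(nb), nrow(subsets)), , drop = FALSE]
      for (s in seq_len(nrow(subsets))) {
        rows <- (s - 1L) * nb + seq_len(nb)
        on <- subsets[s, ]
        if (any(on))
          big[rows, on] <- matrix(X[i, on], nb, sum(on), byrow = TRUE)
      }
      pr <- predict_fun(big)
      if (is.null(dim(pr))) pr <- matrix(pr, nrow(big))
      v <- rowsum(pr, rep(seq_len(nrow(subsets)), each = nb)) / nb
      code <- as.integer(subsets %*% 2^(seq_len(p) - 1))
      vmap <- v[order(code), , drop = FALSE]       # v by bitmask + 1
      for (j in seq_len(p)) {
        without <- which(!subsets[, j])
        wcode <- code[without]
        dv <- vmap[wcode + 2^(j - 1) + 1L, , drop = FALSE] -
          vmap[wcode + 1L, , drop = FALSE]
        vals[i, j, ] <- colSums(dv * wgt[without])
      }
    }
  } else {
    set.seed(seed)
    for (i in seq_len(nrow(X))) {
      phi <- matrix(0, p, C)
      for (r in seq_len(n_perm)) {
        ord <- sample.int(p)
        # stacked cumulative replacements: block k has the first k
        # features of the ordering set to x
        big <- background[rep(seq_len(nb), p + 1L), , drop = FALSE]
        for (k in seq_len(p)) {
          rows <- k * nb + seq_len(nb)
          on <- ord[seq_len(k)]
          big[rows, on] <- matrix(X[i, on], nb, k, byrow = TRUE)
        }
        pr <- predict_fun(big)
        if (is.null(dim(pr))) pr <- matrix(pr, nrow(big))
        v <- rowsum(pr, rep(seq_len(p + 1L), each = nb)) / nb
        phi[ord, ] <- phi[ord, ] + (v[-1, , drop = FALSE] -
                                      v[-(p + 1L), , drop = FALSE])
      }
      vals[i, , ] <- phi / n_perm
    }
  }
  structure(list(values = vals, base_values = base,
                 method = if (exact) "exact" else "sampling"),
            class = "shap_values")
}

#' Weighted aggregation of per-base-learner SHAP tensors
#'
#' The ensemble explanation is the base-weight mixture of the
#' per-learner explanations: `phi = sum_b w_b phi_b` and
#' `base = sum_b w_b base_b`. Aggregation is linear in every tensor,
#' and local accuracy carries over to the weight-mixture surrogate of
#' the stack.
#'
#' @param tensors list of `shap_values` objects (shape-aligned).
#' @param weights non-negative weights summing to 1, one per tensor.
#' @return A `shap_values` object with the aggregated tensor.
#' @export
aggregate_shap <- function(tensors, weights) {
  if (length(tensors) != length(weights))
    stop("one weight per tensor required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  d <- dim(tensors[[1]]$values)
  vals <- array(0, dim = d, dimnames = dimnames(tensors[[1]]$values))
  base <- rep(0, d[3])
  for (b in seq_along(tensors)) {
    if (!identical(dim(tensors[[b]]$values), d))
      stop("tensor shape mismatch")
    vals <- vals + weights[b] * tensors[[b]]$values
    base <- base + weights[b] * tensors[[b]]$base_values
  }
  structure(list(values = vals, base_values = base,
                 method = "aggregated"), class = "shap_values")
}

#' Weighted SHAP explanation of a stacking ensemble
#'
#' Computes per-base-learner Shapley values on the class-probability
#' outputs, multiplies each learner's tensor by its meta-learner
#' weight and sums them — the explanation of the weight-mixture
#' surrogate of the stack.
#'
#' @param object a fitted [hde_stack()].
#' @param X samples to explain (matrix or `feature_table`).
#' @param background background data (matrix or `feature_table`);
#'   summarized to at most `bg_size` rows by k-means.
#' @param bg_size background summary size (default 50).
#' @param n_perm,exact,seed passed to [shap_values()].
#' @return Object of class `shap_explanation`: the aggregated
#'   `shap_values` plus `per_base`, `weights`, `X`, `feature_names`,
#'   `classes`.
#' @export
stack_shap <- function(object, X, background, bg_size = 50,
                       n_perm = 20, exact = NULL, seed = 1) {
  stopifnot(inherits(object, "hde_stack"))
  Xm <- if (inherits(X, "feature_table")) X$x else as.matrix(X)
  bg <- if (inherits(background, "feature_table")) background$x else
    as.matrix(background)
  if (nrow(bg) > bg_size) {
    set.seed(seed)
    km <- stats::kmeans(bg, centers = bg_size, iter.max = 50,
                        nstart = 1)
    bg <- km$centers
    colnames(bg) <- colnames(Xm)
  }
  pool <- candidate_pool(object$learners)
  classes <- object$classes
  per_base <- vector("list", length(pool))
  names(per_base) <- names(pool)
  for (b in seq_along(pool)) {
    model <- object$base_models[[b]]
    pf <- local({
      spec <- pool[[b]]; m <- model
      function(x) spec$prob(m, x, classes)
    })
    per_base[[b]] <- shap_values(pf, Xm, bg, n_perm = n_perm,
                                 exact = exact, seed = seed + b)
  }
  agg <- aggregate_shap(per_base, unname(object$base_weights))
  structure(list(values = agg$values, base_values = agg$base_values,
                 per_base = per_base, weights = object$base_weights,
                 X = Xm, feature_names = colnames(Xm),
                 classes = classes, method = per_base[[1]]$method),
            class = c("shap_explanation", "shap_values"))
}

#' SHAP summary table
#'
#' Ranks features by mean absolute SHAP value across samples (for each
#' sample, the slice of its predicted class by default) and returns
#' per-point scatter data for a beeswarm-style display.
#'
#' @param e a `shap_explanation` (or `shap_values` with an `X`
#'   element).
#' @param class class label to explain; default: each sample's
#'   predicted class under the weight-mixture surrogate.
#' @return A list with `ranking` (data.frame: `feature`,
#'   `mean_abs_shap`, descending) and `points` (data.frame: `feature`,
#'   `sample`, `shap`, `value`).
#' @export
shap_summary <- function(e, class = NULL) {
  v <- e$values
  n <- dim(v)[1]; p <- dim(v)[2]
  if (is.null(class)) {
    fx <- matrix(e$base_values, n, dim(v)[3], byrow = TRUE) +
      apply(v, c(1, 3), sum)
    ci <- max.col(fx, ties.method = "first")
  } else {
    ci <- rep(match(as.character(class), e$classes), n)
    if (anyNA(ci)) stop("unknown class")
  }
  phi <- t(vapply(seq_len(n), function(i) v[i, , ci[i]], numeric(p)))
  feats <- if (!is.null(e$feature_names)) e$feature_names else
    paste0("f", seq_len(p))
  imp <- colMeans(abs(phi))
  ranking <- data.frame(feature = feats[order(imp, decreasing = TRUE)],
                        mean_abs_shap = sort(imp, decreasing = TRUE),
                        row.names = NULL)
  points <- data.frame(feature = rep(feats, each = n),
                       sample = rep(seq_len(n), p),
                       shap = as.vector(phi),
                       value = if (!is.null(e$X)) as.vector(e$X) else
                         NA_real_)
  list(ranking = ranking, points = points)
}

#' SHAP force data for one sample and class
#'
#' Contributions sorted by absolute value, with the base value and the
#' reconstructed prediction `f(x) = base + sum(phi)` (local accuracy).
#'
#' @param e a `shap_explanation`.
#' @param sample sample index.
#' @param class class label (default: first class).
#' @return List with `contributions` (data.frame `feature`, `phi`,
#'   `value`), `base_value`, `fx`.
#' @export
shap_force <- function(e, sample = 1, class = NULL) {
  v <- e$values
  if (sample < 1 || sample > dim(v)[1]) stop("invalid sample index")
  ci <- if (is.null(class)) 1 else match(as.character(class), e$classes)
  if (is.na(ci)) stop("unknown class")
  phi <- v[sample, , ci]
  feats <- if (!is.null(e$feature_names)) e$feature_names else
    paste0("f", seq_along(phi))
  ord <- order(abs(phi), decreasing = TRUE)
  list(contributions = data.frame(
         feature = feats[ord], phi = phi[ord],
         value = if (!is.null(e$X)) e$X[sample, ord] else NA_real_,
         row.names = NULL),
       base_value = e$base_values[ci],
       fx = e$base_values[ci] + sum(phi))
}

#' @export
print.shap_values <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<shap_values> %d samples x %d features x %d outputs (%s)\n",
              d[1], d[2], d[3], x$method))
  invisible(x)
}

#' @export
plot.shap_explanation <- function(x, top = 15, ...) {
  s <- shap_summary(x)
  r <- utils::head(s$ranking, top)
  graphics::barplot(rev(r$mean_abs_shap), names.arg = rev(r$feature),
                    horiz = TRUE, las = 1, xlab = "mean |SHAP|", ...)
  invisible(s)
}
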