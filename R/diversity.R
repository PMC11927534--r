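#' Pairwise correct/incorrect contingency counts
#'
#' For two classifiers' predictions against the truth (multiclass;
#' "correct" means prediction equals truth): `a` both correct, `b` x
#' correct / y wrong, `c` x wrong / y correct, `d` both wrong.
#'
#' @param pred_x,pred_y predicted labels.
#' @param truth true labels.
#' @return A list with counts `a`, `b`, `c`, `d` and `n`.
#' @export
pair_counts <- function(pred_x, pred_y, truth) {
  if (length(pred_x) != length(truth) || length(pred_y) != length(truth))
    stop("prediction/truth length mismatch")
  cx <- as.character(pred_x) == as.character(truth)
  cy <- as.character(pred_y) == as.character(truth)
  list(a = as.numeric(sum(cx & cy)), b = as.numeric(sum(cx & !cy)),
       c = as.numeric(sum(!cx & cy)), d = as.numeric(sum(!cx & !cy)),
       n = length(truth))
}

#' Pairwise diversity metrics from contingency counts
#'
#' Disagreement `Dis = (b+c)/n`; Q-statistic `Qs = (ad-bc)/(ad+bc)`;
#' correlation `Cor = (ad-bc)/sqrt((a+b)(a+c)(c+d)(b+d))`; kappa
#' `Ks = (p1-p2)/(1-p2)` with `p1 = [(a+b)(a+c)+(c+d)(b+d)]/n^2` and
#' `p2 = (a+d)/n`. A zero denominator yields `NA` (excluded from
#' composite sums).
#'
#' @param pc a [pair_counts()] result.
#' @param which one of `"Dis"`, `"Qs"`, `"Ks"`, `"Cor"`.
#' @return The metric value, or `NA_real_` when undefined.
#' @export
pairwise_metric <- function(pc, which = c("Dis", "Qs", "Ks", "Cor")) {
  which <- match.arg(which)
  a <- pc$a; b <- pc$b; c <- pc$c; d <- pc$d
  n <- a + b + c + d
  switch(which,
    Dis = if (n == 0) NA_real_ else (b + c) / n,
    Qs = {
      den <- a * d + b * c
      if (den == 0) NA_real_ else (a * d - b * c) / den
    },
    Cor = {
      den <- sqrt((a + b) * (a + c) * (c + d) * (b + d))
      if (den == 0) NA_real_ else (a * d - b * c) / den
    },
    Ks = {
      p1 <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
      p2 <- (a + d) / n
      if (1 - p2 == 0) NA_real_ else (p1 - p2) / (1 - p2)
    })
}

#' Macro performance metrics
#'
#' Accuracy plus macro-averaged precision and recall over the classes
#' present in the truth; F1 is the harmonic mean of macro precision
#' and macro recall. Reported in percent.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @return Named numeric vector `accuracy`, `precision`, `recall`,
#'   `f1` (percent).
#' @export
performance_metrics <- function(pred, truth) {
  if (length(pred) == 0) stop("empty predictions")
  pred <- as.character(pred); truth <- as.character(truth)
  classes <- sort(unique(truth))
  prec <- rec <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) NA else tp / (tp + fn)
  }
  P <- mean(prec) * 100
  R <- mean(rec, na.rm = TRUE) * 100
  c(accuracy = mean(pred == truth) * 100,
    precision = P, recall = R,
    f1 = if (P + R == 0) 0 else 2 * P * R / (P + R))
}

# Default metric directions: larger disagreement means more diversity;
# Qs/Ks/Cor measure similarity, so smaller is better.
.metric_directions <- c(Dis = "bigger", Qs = "smaller", Ks = "smaller",
                        Cor = "smaller")

#' Diversity composite index
#'
#' For each metric `t`, per-model difference sums are
#' `d_{x,t} = sum_y d_{xy,t}` (bigger-is-better metrics) or
#' `sum_y (1 - d_{xy,t})` (smaller-is-better), with the diagonal
#' excluded and undefined pairs dropped pairwise. The composite is the
#' per-metric share `d_{x,t} / sum_y d_{y,t}` summed over metrics, so
#' the indices sum to the number of metrics across models
#' (`scale = "unit"` divides by that count instead).
#'
#' @param metrics named list of M x M symmetric metric matrices.
#' @param directions named character vector, `"bigger"` or `"smaller"`
#'   per metric.
#' @param scale `"share"` (default; indices sum to `T`) or `"unit"`
#'   (sum to 1).
#' @return Named numeric vector of composite indices, one per model.
#' @export
diversity_composite <- function(metrics,
                                directions = .metric_directions,
                                scale = c("share", "unit")) {
  scale <- match.arg(scale)
  M <- nrow(metrics[[1]])
  if (M < 2) stop("need at least two models")
  out <- rep(0, M)
  names(out) <- rownames(metrics[[1]])
  used <- 0
  for (t in names(metrics)) {
    mt <- metrics[[t]]
    diag(mt) <- NA
    if (directions[[t]] == "smaller") mt <- 1 - mt
    dxt <- rowSums(mt, na.rm = TRUE)
    tot <- sum(dxt)
    if (abs(tot) < 1e-300) {
      warning("metric ", t, " has zero total; skipped")
      next
    }
    out <- out + dxt / tot
    used <- used + 1
  }
  if (scale == "unit" && used > 0) out <- out / used
  out
}

#' Performance composite index
#'
#' Share-normalized performance sums: for each performance metric `s`,
#' model `x` contributes `a_{x,s} / sum_y a_{y,s}`; the composite is
#' the sum over metrics (so composites sum to `S` across models;
#' `scale = "unit"` divides by `S`).
#'
#' @param perf M x S matrix of performance values (rows = models).
#' @param scale `"share"` or `"unit"`.
#' @return Named numeric vector of composite indices.
#' @export
performance_composite <- function(perf, scale = c("share", "unit")) {
  scale <- match.arg(scale)
  perf <- as.matrix(perf)
  out <- rep(0, nrow(perf))
  names(out) <- rownames(perf)
  used <- 0
  for (s in seq_len(ncol(perf))) {
    tot <- sum(perf[, s])
    if (tot <= 0) {
      warning("performance metric column ", s, " has zero total; skipped")
      next
    }
    out <- out + perf[, s] / tot
    used <- used + 1
  }
  if (scale == "unit" && used > 0) out <- out / used
  out
}

#' Comprehensive evaluation score and ranking
#'
#' `P_x = r * Dci_x + (1 - r) * Pci_x` with `r = 0.5` by default,
#' giving diversity and performance equal weight. Models are ranked in
#' descending score; ties break by higher `Pci`, then model name.
#'
#' @param dci,pci named numeric vectors (same models).
#' @param r diversity weight in `[0, 1]`.
#' @return A data.frame with columns `model`, `dci`, `pci`, `score`,
#'   `rank`, ordered by rank.
#' @export
comprehensive_score <- function(dci, pci, r = 0.5) {
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  stopifnot(identical(names(dci), names(pci)))
  score <- r * dci + (1 - r) * pci
  ord <- order(-score, -pci, names(score))
  data.frame(model = names(score)[ord], dci = dci[ord], pci = pci[ord],
             score = score[ord], rank = seq_along(score),
             row.names = NULL)
}

#' Diversity report for a set of candidate classifiers
#'
#' Builds the four pairwise diversity matrices (Dis, Qs, Ks, Cor), the
#' per-model macro performance metrics, both composite indices and the
#' comprehensive ranking from a set of prediction vectors on common
#' ground truth.
#'
#' @param predictions named list of predicted-label vectors, one per
#'   candidate model.
#' @param truth true labels.
#' @param r diversity weight for the comprehensive score.
#' @param scale normalization for the composite indices (see
#'   [diversity_composite()]).
#' @return An object of class `diversity_report`: list with `metrics`
#'   (four M x M matrices), `perf` (M x 4 matrix, percent), `dci`,
#'   `pci`, `ranking` (the [comprehensive_score()] table) and `r`.
#' @export
diversity_report <- function(predictions, truth, r = 0.5,
                             scale = "share") {
  M <- length(predictions)
  if (M < 2) stop("need at least two candidate models")
  models <- names(predictions)
  if (is.null(models)) stop("predictions must be named")
  metrics <- lapply(c(Dis = "Dis", Qs = "Qs", Ks = "Ks", Cor = "Cor"),
                    function(w) {
    m <- matrix(NA_real_, M, M, dimnames = list(models, models))
    for (i in seq_len(M)) for (j in seq_len(M)) if (i != j)
      m[i, j] <- pairwise_metric(
        pair_counts(predictions[[i]], predictions[[j]], truth), w)
    m
  })
  perf <- t(vapply(predictions, performance_metrics, truth = truth,
                   numeric(4)))
  dci <- diversity_composite(metrics, scale = scale)
  pci <- performance_composite(perf, scale = scale)
  structure(list(metrics = metrics, perf = perf, dci = dci, pci = pci,
                 ranking = comprehensive_score(dci, pci, r), r = r),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report>\n")
  print(cbind(round(x$perf, 2),
              dci = round(x$dci, 4), pci = round(x$pci, 4)))
  cat("\nComprehensive ranking (r =", x$r, "):\n")
  print(x$ranking, digits = 4)
  invisible(x)
}

#' Select the top-K base learners by comprehensive score
#'
#' @param report a [diversity_report()].
#' @param K how many models to keep (1..M).
#' @return Character vector of the top-K model names, best first.
#' @export
select_base_learners <- function(report, K) {
  stopifnot(inherits(report, "diversity_report"))
  M <- nrow(report$ranking)
  if (K < 1 || K > M) stop("K must be in [1, ", M, "]")
  report$ranking$model[seq_len(K)]
}
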