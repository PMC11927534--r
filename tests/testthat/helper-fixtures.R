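# Shared fixtures, all generated in code.

# Spectra-like matrix with collinear smooth nuisance variation and
# class-dependent amplitude at three bump centers: the recovery
# benchmark for the band selectors.
make_band_fixture <- function(seed, n_per = 40, K = 3, p = 120) {
  set.seed(seed)
  wl <- seq(0, 1, length.out = p)
  centers <- c(0.2, 0.5, 0.8)
  width <- 0.03
  bumps <- sapply(centers, function(c0) exp(-(wl - c0)^2 / (2 * width^2)))
  n <- n_per * K
  y <- factor(rep(0:(K - 1), each = n_per))
  co <- matrix(rnorm(n * 4, 0, 0.05), n, 4)
  X <- 0.5 + outer(rep(1, n), 0.2 * sin(2 * pi * wl)) +
    co %*% t(cbind(1, wl, wl^2, wl^3))
  amp <- matrix(rnorm(K * 3, 0, 0.15), K, 3)
  for (k in seq_len(K))
    X[y == levels(y)[k], ] <- X[y == levels(y)[k], ] +
      matrix(bumps %*% amp[k, ], n_per, p, byrow = TRUE)
  X <- X + matrix(rnorm(n * p, 0, 0.01), n, p)
  list(X = X, y = y, inf = round(centers * (p - 1)) + 1,
       halfw = round(0.045 * p))
}

# how many of the informative centers have a selected band nearby
band_hits <- function(selected, inf, halfw) {
  sum(vapply(inf, function(i) any(abs(selected - i) <= halfw),
             logical(1)))
}

# a small, quickly separable fused feature table
make_small_fused <- function(seed = 1, n_classes = 3, n_per = 30,
                             step = 25) {
  cfg <- sim_config(n_classes = n_classes, n_per_class = n_per,
                    wavelength_step = step, seed = seed)
  d <- sim_seed_dataset(cfg)
  suppressMessages(fuse_features(
    minmax_normalize(d$morph),
    minmax_normalize(spectra_to_features(sg_smooth(d$spectra), d$y))))
}

# Independent nested-loop oracle for the diversity/performance
# composites, deliberately naive: per-pair 2x2 counts by explicit
# loops, metric formulas spelled out, composites accumulated term by
# term.
oracle_diversity <- function(predictions, truth, r = 0.5) {
  M <- length(predictions)
  models <- names(predictions)
  n <- length(truth)
  counts <- function(px, py) {
    a <- b <- cc <- d <- 0
    for (i in seq_len(n)) {
      okx <- as.character(px[i]) == as.character(truth[i])
      oky <- as.character(py[i]) == as.character(truth[i])
      if (okx && oky) a <- a + 1
      else if (okx) b <- b + 1
      else if (oky) cc <- cc + 1
      else d <- d + 1
    }
    c(a = a, b = b, c = cc, d = d)
  }
  met <- array(NA_real_, c(M, M, 4),
               dimnames = list(models, models,
                               c("Dis", "Qs", "Ks", "Cor")))
  for (x in seq_len(M)) for (y in seq_len(M)) if (x != y) {
    k <- counts(predictions[[x]], predictions[[y]])
    a <- k["a"]; b <- k["b"]; cc <- k["c"]; d <- k["d"]
    met[x, y, "Dis"] <- (b + cc) / n
    met[x, y, "Qs"] <- (a * d - b * cc) / (a * d + b * cc)
    met[x, y, "Cor"] <- (a * d - b * cc) /
      sqrt((a + b) * (a + cc) * (cc + d) * (b + d))
    p1 <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
    p2 <- (a + d) / n
    met[x, y, "Ks"] <- (p1 - p2) / (1 - p2)
  }
  bigger <- c(Dis = TRUE, Qs = FALSE, Ks = FALSE, Cor = FALSE)
  dxt <- matrix(0, M, 4, dimnames = list(models, dimnames(met)[[3]]))
  for (t in dimnames(met)[[3]]) for (x in seq_len(M)) {
    s <- 0
    for (y in seq_len(M)) if (y != x)
      s <- s + if (bigger[t]) met[x, y, t] else 1 - met[x, y, t]
    dxt[x, t] <- s
  }
  dci <- rep(0, M)
  for (t in dimnames(met)[[3]]) {
    tot <- sum(dxt[, t])
    for (x in seq_len(M)) dci[x] <- dci[x] + dxt[x, t] / tot
  }
  perf <- matrix(0, M, 4, dimnames = list(models, NULL))
  for (x in seq_len(M)) {
    px <- as.character(predictions[[x]])
    tv <- as.character(truth)
    classes <- sort(unique(tv))
    pr <- re <- numeric(length(classes))
    for (ci in seq_along(classes)) {
      k <- classes[ci]
      tp <- sum(px == k & tv == k)
      fp <- sum(px == k & tv != k)
      fn <- sum(px != k & tv == k)
      pr[ci] <- if (tp + fp == 0) 0 else tp / (tp + fp)
      re[ci] <- tp / (tp + fn)
    }
    P <- mean(pr) * 100; R <- mean(re) * 100
    perf[x, ] <- c(mean(px == tv) * 100, P, R, 2 * P * R / (P + R))
  }
  pci <- rep(0, M)
  for (s in 1:4) {
    tot <- sum(perf[, s])
    for (x in seq_len(M)) pci[x] <- pci[x] + perf[x, s] / tot
  }
  list(metrics = met, perf = perf, dci = stats::setNames(dci, models),
       pci = stats::setNames(pci, models),
       score = stats::setNames(r * dci + (1 - r) * pci, models))
}

# random multiclass prediction sets with controlled accuracy spread
random_predictions <- function(seed, M = 4, n = 60, K = 3) {
  set.seed(seed)
  truth <- factor(sample(0:(K - 1), n, replace = TRUE))
  preds <- lapply(seq_len(M), function(m) {
    acc <- 0.3 + 0.15 * m
    ifelse(runif(n) < acc, as.character(truth),
           as.character(sample(0:(K - 1), n, replace = TRUE)))
  })
  names(preds) <- paste0("m", seq_len(M))
  list(predictions = preds, truth = truth)
}
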