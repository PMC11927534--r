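test_that("pair counts match direct enumeration", {
  truth <- rep(1, 10)
  pc <- pair_counts(rep(1, 10), rep(1, 10), truth)
  expect_equal(unlist(pc[c("a", "b", "c", "d")]),
               c(a = 10, b = 0, c = 0, d = 0))
  pc <- pair_counts(rep(1, 10), rep(2, 10), truth)
  expect_equal(pc$b, 10)
  set.seed(1)
  t3 <- sample(0:2, 50, replace = TRUE)
  px <- sample(0:2, 50, replace = TRUE)
  py <- sample(0:2, 50, replace = TRUE)
  pc <- pair_counts(px, py, t3)
  brute <- c(0, 0, 0, 0)
  for (i in 1:50) {
    okx <- px[i] == t3[i]; oky <- py[i] == t3[i]
    j <- if (okx && oky) 1 else if (okx) 2 else if (oky) 3 else 4
    brute[j] <- brute[j] + 1
  }
  expect_equal(unlist(pc[c("a", "b", "c", "d")]),
               c(a = brute[1], b = brute[2], c = brute[3], d = brute[4]))
  expect_equal(pc$a + pc$b + pc$c + pc$d, 50)
  expect_error(pair_counts(1:3, 1:4, 1:4), "mismatch")
})

test_that("pairwise metrics hit their agreement/disagreement anchors", {
  agree <- list(a = 5, b = 0, c = 0, d = 5)
  expect_equal(pairwise_metric(agree, "Dis"), 0)
  expect_equal(pairwise_metric(agree, "Qs"), 1)
  expect_equal(pairwise_metric(agree, "Cor"), 1)
  disagree <- list(a = 0, b = 5, c = 5, d = 0)
  expect_equal(pairwise_metric(disagree, "Dis"), 1)
  expect_equal(pairwise_metric(disagree, "Qs"), -1)
  pc <- list(a = 40, b = 5, c = 10, d = 45)
  n <- 100
  expect_equal(pairwise_metric(pc, "Dis"), 15 / 100, tolerance = 1e-12)
  expect_equal(pairwise_metric(pc, "Qs"),
               (40 * 45 - 5 * 10) / (40 * 45 + 5 * 10),
               tolerance = 1e-12)
  expect_equal(pairwise_metric(pc, "Cor"),
               (40 * 45 - 5 * 10) / sqrt(45 * 50 * 55 * 50),
               tolerance = 1e-12)
  p1 <- (45 * 50 + 55 * 50) / n^2
  p2 <- 85 / 100
  expect_equal(pairwise_metric(pc, "Ks"), (p1 - p2) / (1 - p2),
               tolerance = 1e-12)
  # undefined denominators yield NA
  expect_true(is.na(pairwise_metric(list(a = 5, b = 0, c = 0, d = 0),
                                    "Qs")))
})

test_that("macro metrics satisfy their defining identities", {
  expect_equal(unname(performance_metrics(c(0, 1, 2), c(0, 1, 2))),
               rep(100, 4))
  set.seed(2)
  truth <- sample(0:3, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.6, truth, sample(0:3, 200, TRUE))
  pm <- performance_metrics(pred, truth)
  expect_equal(unname(pm["f1"]),
               2 * pm[["precision"]] * pm[["recall"]] /
                 (pm[["precision"]] + pm[["recall"]]))
  expect_true(all(pm >= 0 & pm <= 100))
})

test_that("diversity composite honours symmetry, dominance and directions", {
  # two models: shares are equal by symmetry
  m2 <- matrix(c(NA, 0.4, 0.4, NA), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  mats <- list(Dis = m2, Qs = m2, Ks = m2, Cor = m2)
  dci <- diversity_composite(mats)
  expect_equal(unname(dci[1]), unname(dci[2]))
  # a model maximally different from all others attains the top index
  mk <- function(v) {
    m <- matrix(v, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    diag(m) <- NA
    m
  }
  dis <- mk(0.2); dis["a", ] <- dis[, "a"] <- 0.9; diag(dis) <- NA
  qs <- mk(0.8); qs["a", ] <- qs[, "a"] <- 0.1; diag(qs) <- NA
  mats3 <- list(Dis = dis, Qs = qs, Ks = qs, Cor = qs)
  dci3 <- diversity_composite(mats3)
  expect_equal(names(which.max(dci3)), "a")
  # an all-equal metric is skipped with a warning
  expect_warning(diversity_composite(list(Dis = mk(0.5) * 0,
                                          Qs = qs, Ks = qs, Cor = qs)),
                 "skipped")
})

test_that("performance composite is share-normalized and monotone", {
  perf <- matrix(70, 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  pci <- performance_composite(perf)
  expect_equal(unname(pci), rep(4 / 3, 3))
  perf2 <- rbind(A = c(90, 90, 90, 90), B = c(60, 60, 60, 60))
  pci2 <- performance_composite(perf2)
  expect_gt(pci2[["A"]], pci2[["B"]])
})

test_that("published candidate table reproduces the performance ordering", {
  perf <- rbind(LR = c(73.33, 73.12, 74.5, 73.81),
                DT = c(61.52, 63.15, 61.9, 61.52),
                MLP = c(82.12, 83.65, 82.43, 83.03),
                KNN = c(70.00, 70.8, 69.75, 70.27),
                GP = c(73.03, 74.56, 72.98, 73.76),
                SVM = c(72.73, 72.45, 73.33, 72.89))
  pci <- performance_composite(perf)
  expect_gt(pci[["MLP"]], pci[["LR"]])
  expect_gt(pci[["LR"]], pci[["SVM"]])
  expect_equal(names(which.min(pci)), "DT")
})

test_that("comprehensive score blends indices and breaks ties deterministically", {
  dci <- c(A = 0.7, B = 0.5)
  pci <- c(A = 0.3, B = 0.5)
  expect_equal(comprehensive_score(dci, pci, r = 1)$score,
               sort(dci, decreasing = TRUE), ignore_attr = TRUE)
  tab <- comprehensive_score(dci, pci, r = 0.5)
  # equal scores: higher pci wins
  expect_equal(tab$model[1], "B")
  expect_error(comprehensive_score(dci, pci, r = 2), "r must")
  # swapping the roles of the two indices leaves r = 0.5 scores intact
  expect_equal(comprehensive_score(pci, dci, r = 0.5)$score,
               tab$score, tolerance = 1e-12)
})

test_that("nested-loop oracle agrees with the vectorized report to 1e-12", {
  rp <- random_predictions(31, M = 4, n = 60, K = 3)
  rep <- diversity_report(rp$predictions, rp$truth)
  ora <- oracle_diversity(rp$predictions, rp$truth)
  for (t in c("Dis", "Qs", "Ks", "Cor"))
    expect_equal(rep$metrics[[t]], ora$metrics[, , t],
                 tolerance = 1e-12)
  expect_equal(unname(rep$perf), unname(ora$perf), tolerance = 1e-12)
  expect_equal(rep$dci, ora$dci, tolerance = 1e-12)
  expect_equal(rep$pci, ora$pci, tolerance = 1e-12)
  expect_equal(stats::setNames(rep$ranking$score, rep$ranking$model),
               ora$score[order(-ora$score)], tolerance = 1e-12)
  # metric matrices are symmetric with excluded diagonals
  for (t in names(rep$metrics)) {
    expect_equal(rep$metrics[[t]], t(rep$metrics[[t]]))
    expect_true(all(is.na(diag(rep$metrics[[t]]))))
  }
})

test_that("top-K selection follows the published ranking example", {
  # the published comprehensive-score column, taken as given
  score <- c(LR = 0.5589, DT = 0.5580, MLP = 0.5241, SVM = 0.5160,
             KNN = 0.4485, GP = 0.4091)
  ranking <- data.frame(model = names(score), score = unname(score),
                        rank = seq_along(score))
  rep <- structure(list(ranking = ranking), class = "diversity_report")
  expect_setequal(select_base_learners(rep, 3), c("LR", "DT", "MLP"))
  expect_equal(select_base_learners(rep, 1), "LR")
  expect_length(select_base_learners(rep, 6), 6)
  expect_error(select_base_learners(rep, 0), "K must")
  # recomputing the blend from the published component indices demotes
  # the one row whose printed score is internally inconsistent: DT's
  # 0.5*(0.7297+0.2864) = 0.508 would rank 4th, not 2nd
  dci <- c(LR = 0.7707, DT = 0.7297, SVM = 0.6889, KNN = 0.5788,
           GP = 0.4819, MLP = 0.6710)
  pci <- c(LR = 0.3472, DT = 0.2864, SVM = 0.3432, KNN = 0.3182,
           GP = 0.3364, MLP = 0.3773)
  tab <- comprehensive_score(dci, pci)
  expect_equal(tab$rank[tab$model == "DT"], 4)
})
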