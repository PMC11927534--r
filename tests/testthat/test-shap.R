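test_that("constant models receive zero attributions", {
  pf <- function(x) matrix(0.3, nrow(x), 2)
  bg <- matrix(rnorm(20 * 3), 20, 3)
  X <- matrix(rnorm(4 * 3), 4, 3)
  for (ex in c(TRUE, FALSE)) {
    sv <- shap_values(pf, X, bg, exact = ex, n_perm = 5)
    expect_equal(max(abs(sv$values)), 0)
    expect_equal(sv$base_values, c(0.3, 0.3))
  }
})

test_that("linear models recover the centered linear contribution", {
  set.seed(1)
  beta <- c(2, -1, 0.5)
  pf <- function(x) cbind(as.matrix(x) %*% beta)
  bg <- matrix(rnorm(30 * 3), 30, 3)
  X <- matrix(rnorm(5 * 3), 5, 3)
  closed <- sweep(X, 2, colMeans(bg)) *
    matrix(beta, 5, 3, byrow = TRUE)
  for (ex in c(TRUE, FALSE)) {
    sv <- shap_values(pf, X, bg, exact = ex, n_perm = 6, seed = 2)
    expect_equal(sv$values[, , 1], closed, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("a depth-1 tree matches exhaustive coalition enumeration", {
  set.seed(2)
  y <- factor(rep(0:1, each = 30))
  xt <- matrix(rnorm(60 * 2), 60, 2)
  xt[, 1] <- xt[, 1] + 2 * as.numeric(y)
  d <- data.frame(xt)
  d$.y <- y
  tr <- rpart::rpart(.y ~ ., d,
                     control = rpart::rpart.control(maxdepth = 1))
  pf <- function(x) {
    dd <- as.data.frame(x)
    names(dd) <- c("X1", "X2")
    predict(tr, dd)[, 2, drop = FALSE]
  }
  sv <- shap_values(pf, xt[1:4, ], xt, exact = TRUE)
  v <- function(S, xi) {
    z <- xt
    if (length(S))
      z[, S] <- matrix(xi[S], nrow(xt), length(S), byrow = TRUE)
    mean(pf(z))
  }
  for (i in 1:4) {
    xi <- xt[i, ]
    phi1 <- 0.5 * (v(1, xi) - v(integer(0), xi)) +
      0.5 * (v(1:2, xi) - v(2, xi))
    phi2 <- 0.5 * (v(2, xi) - v(integer(0), xi)) +
      0.5 * (v(1:2, xi) - v(1, xi))
    expect_equal(unname(sv$values[i, , 1]), c(phi1, phi2),
                 tolerance = 1e-12)
  }
})

test_that("local accuracy is exact for both estimators", {
  set.seed(3)
  pf <- function(x) cbind(sin(x[, 1]) + x[, 2]^2,
                          cos(x[, 1] * x[, 3]))
  bg <- matrix(rnorm(25 * 3), 25, 3)
  X <- matrix(rnorm(6 * 3), 6, 3)
  for (ex in c(TRUE, FALSE)) {
    sv <- shap_values(pf, X, bg, exact = ex, n_perm = 7, seed = 4)
    recon <- sweep(apply(sv$values, c(1, 3), sum), 2, sv$base_values,
                   `+`)
    expect_equal(recon, pf(X), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("aggregation is the exact weighted sum of tensors", {
  set.seed(4)
  mk <- function() {
    structure(list(values = array(rnorm(5 * 3 * 2), c(5, 3, 2)),
                   base_values = rnorm(2), method = "exact"),
              class = "shap_values")
  }
  t1 <- mk(); t2 <- mk()
  a <- aggregate_shap(list(t1, t2), c(0.3, 0.7))
  expect_equal(a$values, 0.3 * t1$values + 0.7 * t2$values,
               tolerance = 1e-15)
  expect_equal(a$base_values, 0.3 * t1$base_values +
                 0.7 * t2$base_values, tolerance = 1e-15)
  # degenerate weights select a single tensor
  a1 <- aggregate_shap(list(t1, t2), c(1, 0))
  expect_equal(a1$values, t1$values)
  # equal tensors are a fixed point for any weights
  aeq <- aggregate_shap(list(t1, t1), c(0.6, 0.4))
  expect_equal(aeq$values, t1$values, tolerance = 1e-15)
  expect_error(aggregate_shap(list(t1, t2), c(0.5, 0.4)), "sum to 1")
  t3 <- mk(); t3$values <- t3$values[, 1:2, ]
  expect_error(aggregate_shap(list(t1, t3), c(0.5, 0.5)), "mismatch")
})

test_that("duplicated identical features share attribution symmetrically", {
  set.seed(5)
  bg <- matrix(rnorm(30), 30, 1)[, c(1, 1)]
  X <- matrix(rnorm(4), 4, 1)[, c(1, 1)]
  pf <- function(x) cbind(x[, 1] + x[, 2])
  sv <- shap_values(pf, X, bg, exact = TRUE)
  expect_equal(sv$values[, 1, 1], sv$values[, 2, 1], tolerance = 1e-10)
})

test_that("stack explanation ranks an injected dominant feature first", {
  set.seed(6)
  y <- factor(rep(0:1, each = 40))
  x <- cbind(sig = as.numeric(y) + rnorm(80, 0, 0.05),
             n1 = rnorm(80), n2 = rnorm(80), n3 = rnorm(80))
  ft <- feature_table(x, y)
  st <- hde_stack(ft, learners = c("LR", "DT"), n_folds = 3, seed = 1)
  ex <- stack_shap(st, x[1:10, ], x, bg_size = 20, exact = TRUE,
                   seed = 1)
  s <- shap_summary(ex)
  expect_equal(as.character(s$ranking$feature[1]), "sig")
  # ranking invariant to sample order
  ex2 <- stack_shap(st, x[10:1, ], x, bg_size = 20, exact = TRUE,
                    seed = 1)
  s2 <- shap_summary(ex2)
  expect_equal(s2$ranking$mean_abs_shap, s$ranking$mean_abs_shap,
               tolerance = 1e-10)
  # zero tensor: all ranks tied at zero importance
  z <- ex
  z$values[] <- 0
  expect_equal(unique(shap_summary(z)$ranking$mean_abs_shap), 0)
})

test_that("force data reconstruct the weight-mixture prediction", {
  set.seed(7)
  y <- factor(rep(0:1, each = 30))
  x <- cbind(a = as.numeric(y) + rnorm(60, 0, 0.1), b = rnorm(60))
  ft <- feature_table(x, y)
  st <- hde_stack(ft, learners = c("LR", "DT"), n_folds = 3, seed = 2)
  ex <- stack_shap(st, x[1:5, ], x, bg_size = 15, exact = TRUE,
                   seed = 1)
  # mixture prediction: weighted base-learner probabilities
  pool <- candidate_pool(st$learners)
  mix <- Reduce(`+`, lapply(seq_along(pool), function(b)
    st$base_weights[b] *
      pool[[b]]$prob(st$base_models[[b]], x[1:5, ], st$classes)))
  for (i in 1:5) for (k in seq_along(st$classes)) {
    fo <- shap_force(ex, sample = i, class = st$classes[k])
    expect_equal(fo$fx, mix[i, k], tolerance = 1e-9)
    expect_equal(fo$base_value + sum(fo$contributions$phi), fo$fx,
                 tolerance = 1e-12)
    # contributions are sorted by magnitude
    expect_true(all(diff(abs(fo$contributions$phi)) <= 1e-12))
  }
  expect_error(shap_force(ex, sample = 99), "invalid")
})
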