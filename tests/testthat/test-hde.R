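test_that("genome decoding maps bounds, log midpoints and categories", {
  sp <- param_space(c = p_num(1e-3, 1e1, "log"),
                    d = p_int(2, 20),
                    k = p_cat(c("a", "b", "c")))
  lo <- decode_genome(sp, c(0, 0, 0))
  hi <- decode_genome(sp, c(1, 1, 1))
  expect_equal(lo$c, 1e-3)
  expect_equal(lo$d, 2L)
  expect_equal(lo$k, "a")
  expect_equal(hi$c, 1e1)
  expect_equal(hi$d, 20L)
  expect_equal(hi$k, "c")
  mid <- decode_genome(sp, c(0.5, 0.5, 0.5))
  expect_equal(mid$c, 1e-1)                # log-space midpoint
  expect_error(decode_genome(sp, c(0.5, 0.5)), "dimension")
  expect_error(p_num(1, 0), "upper")
  expect_error(p_cat(character(0)), "non-empty")
})

test_that("mutation strategies satisfy their defining identities", {
  pop <- matrix(c(0.1, 0.2, 0.4, 0.8), 4, 1)
  fit <- c(1, 2, 3, 4)                      # best is row 4
  # F = 0 identities
  expect_equal(hde_mutate(pop, 1, 4, "best1", F = 0, r_idx = c(2, 3)),
               pop[4, ])
  expect_equal(hde_mutate(pop, 2, 4, "current_to_best1", F = 0,
                          r_idx = c(1, 3)), pop[2, ])
  # hand arithmetic: v = 0.2 + 0.5 * (0.4 - 0.8) = 0.0
  expect_equal(hde_mutate(pop, 1, 4, "rand1", F = 0.5,
                          r_idx = c(2, 3, 4)), 0)
  # best2 (5 rows needed for four distinct donors)
  pop5 <- rbind(pop, 0.6)
  v <- hde_mutate(pop5, 5, 4, "best2", F = 0.5, r_idx = c(1, 2, 3, 4))
  expect_equal(v, 0.8 + 0.5 * (0.1 - 0.2) + 0.5 * (0.4 - 0.8))
  # donors are clipped into the unit interval
  v2 <- hde_mutate(pop, 1, 4, "best1", F = 5, r_idx = c(3, 2))
  expect_true(all(v2 >= 0 & v2 <= 1))
  # index validation
  expect_error(hde_mutate(pop, 1, 4, "best2", r_idx = c(2, 3, 4)),
               "population too small")
  expect_error(hde_mutate(pop, 1, 4, "rand1", r_idx = c(1, 2, 3)),
               "distinct")
})

test_that("mutation strategies are scheduled in thirds with late parity", {
  expect_equal(schedule_strategy(1, 50), "rand1")
  expect_equal(schedule_strategy(16, 50), "rand1")
  expect_equal(schedule_strategy(17, 50), "current_to_best1")
  expect_equal(schedule_strategy(25, 50), "current_to_best1")
  expect_equal(schedule_strategy(49, 50), "best1")
  expect_equal(schedule_strategy(50, 50), "best2")
  expect_error(schedule_strategy(0, 50), "t must")
})

test_that("convergence-adaptive rule matches its branch arithmetic", {
  expect_equal(adapt_convergence(0.03, r = 0.5)$CR, 0.95)
  expect_equal(adapt_convergence(0.03, r = 0)$F, 0.2)
  expect_equal(adapt_convergence(0.07, r = 1)$F, 0.8)
  expect_equal(adapt_convergence(0.07, r = 0.5)$CR, 0.9)
  expect_equal(adapt_convergence(0.2, r = 0)$F, 0.5)
  expect_equal(adapt_convergence(0.2, r = 0.5)$CR, 0.7)
})

test_that("diversity-adaptive rule inflates parameters as diversity drops", {
  expect_equal(adapt_diversity(0.5, 0.9, 0.3, 0.05, 1, 1)$F, 0.5)
  expect_equal(adapt_diversity(0.5, 0.9, 0.3, 0.05, 0, 1)$F, 0.8)
  expect_equal(adapt_diversity(0.5, 0.9, 0.3, 0.05, 0.5, 1)$F, 0.65)
  expect_equal(adapt_diversity(0.5, 0.9, 0.3, 0.05, 0, 1)$CR, 0.95)
  # clamped to the valid CR range
  expect_lte(adapt_diversity(0.5, 0.99, 0.3, 0.3, 0, 1)$CR, 1)
  expect_error(adapt_diversity(0.5, 0.9, 0.3, 0.05, 0.5, 0), "D_max")
})

test_that("binomial crossover honours CR extremes and a scripted trace", {
  parent <- c(0.1, 0.2, 0.3, 0.4)
  donor <- c(0.9, 0.8, 0.7, 0.6)
  expect_equal(hde_crossover(parent, donor, CR = 1), donor)
  tr0 <- hde_crossover(parent, donor, CR = 0, j_rand = 3)
  expect_equal(sum(tr0 != parent), 1)
  expect_equal(tr0[3], donor[3])
  u <- c(0.4, 0.6, 0.2, 0.9)
  tr <- hde_crossover(parent, donor, CR = 0.5, j_rand = 2, u = u)
  expect_equal(tr, c(0.9, 0.8, 0.7, 0.4))   # u<CR at 1,3; forced at 2
  expect_error(hde_crossover(parent, donor[1:2], 0.5), "dimension")
})

test_that("the optimizer is elitist, reproducible and clip-safe", {
  ctrl <- hde_control(NP = 12, G_max = 12, seed = 5)
  res <- hde_optimize(function(g) -sum((g - 0.25)^2), 3, ctrl)
  expect_true(all(diff(res$trace) >= 0))
  expect_true(all(res$population >= 0 & res$population <= 1))
  res2 <- hde_optimize(function(g) -sum((g - 0.25)^2), 3, ctrl)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$best_genome, res2$best_genome)
  # constant objective: valid population, best equals the constant
  resc <- hde_optimize(function(g) 7, 2,
                       hde_control(NP = 6, G_max = 4, seed = 1))
  expect_equal(resc$best_fitness, 7)
  # a failing objective scores -Inf instead of aborting
  resf <- hde_optimize(function(g) if (g[1] > 0.5) stop("boom") else 1,
                       1, hde_control(NP = 6, G_max = 3, seed = 2))
  expect_equal(resf$best_fitness, 1)
})

test_that("the optimizer solves small continuous and discrete problems", {
  ok <- 0
  for (s in 1:5) {
    r <- hde_optimize(function(g) -sum((g - 0.5)^2), 3,
                      hde_control(NP = 20, G_max = 50, seed = s))
    if (-r$best_fitness < 1e-2) ok <- ok + 1
  }
  expect_equal(ok, 5)
  # enumerable discrete space: optimum found by exhaustive comparison
  sp <- param_space(a = p_cat(1:3), b = p_cat(1:4))
  f <- function(p) sin(p$a * 1.3) + cos(p$b * 0.7)
  opt <- max(outer(1:3, 1:4, function(a, b) sin(a * 1.3) + cos(b * 0.7)))
  r <- hde_optimize(f, sp, hde_control(NP = 15, G_max = 20, seed = 3))
  expect_equal(r$best_fitness, opt, tolerance = 1e-12)
})
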