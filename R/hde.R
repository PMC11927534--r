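#' Define a hyperparameter search space
#'
#' A parameter space maps the DE unit hypercube onto mixed
#' hyperparameters: continuous (optionally log-scaled), integer
#' (rounded after mapping) or categorical (index by flooring).
#'
#' @param ... named parameter definitions created by [p_num()],
#'   [p_int()] or [p_cat()].
#' @return An object of class `param_space`.
#' @export
param_space <- function(...) {
  ps <- list(...)
  if (length(ps) == 0 || is.null(names(ps)) || any(names(ps) == ""))
    stop("all parameters must be named")
  structure(ps, class = "param_space")
}

#' @param lower,upper finite bounds.
#' @param scale `"linear"` or `"log"` (log10-uniform over the bounds).
#' @rdname param_space
#' @export
p_num <- function(lower, upper, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!is.finite(lower) || !is.finite(upper) || upper <= lower)
    stop("bounds must be finite with upper > lower")
  if (scale == "log" && lower <= 0) stop("log scale needs lower > 0")
  list(kind = "continuous", lower = lower, upper = upper, scale = scale)
}

#' @rdname param_space
#' @export
p_int <- function(lower, upper) {
  list(kind = "integer", lower = as.integer(lower),
       upper = as.integer(upper), scale = "linear")
}

#' @param choices non-empty vector of categorical levels.
#' @rdname param_space
#' @export
p_cat <- function(choices) {
  if (length(choices) == 0) stop("choices must be non-empty")
  list(kind = "categorical", choices = choices)
}

#' Decode a unit genome into a hyperparameter assignment
#'
#' Continuous parameters map affinely (or log-affinely); integers are
#' rounded after mapping; categorical index is `floor(g * k) + 1`,
#' clamped.
#'
#' @param space a [param_space()].
#' @param genome numeric vector in `[0,1]^length(space)`.
#' @return Named list of decoded values.
#' @export
decode_genome <- function(space, genome) {
  stopifnot(inherits(space, "param_space"))
  if (length(genome) != length(space))
    stop("genome dimension must equal the number of parameters")
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (i in seq_along(space)) {
    p <- space[[i]]
    g <- min(max(genome[i], 0), 1)
    out[[i]] <- switch(p$kind,
      continuous = if (p$scale == "log")
        10^(log10(p$lower) + g * (log10(p$upper) - log10(p$lower)))
      else p$lower + g * (p$upper - p$lower),
      integer = as.integer(round(p$lower + g * (p$upper - p$lower))),
      categorical = p$choices[[min(floor(g * length(p$choices)) + 1,
                                   length(p$choices))]])
  }
  out
}

#' DE mutation strategies
#'
#' Donor vector construction for the four strategies: `rand1`
#' `v = x_r1 + F (x_r2 - x_r3)`; `best1` `v = x_best + F (x_r1 - x_r2)`;
#' `current_to_best1` `v = x_i + F (x_best - x_i) + F (x_r1 - x_r2)`;
#' `best2` `v = x_best + F (x_r1 - x_r2) + F (x_r3 - x_r4)`. The `r`
#' indices are distinct and differ from `i`; components are clipped to
#' `[0, 1]`.
#'
#' @param pop NP x dim population matrix (rows in the unit hypercube).
#' @param i index of the current individual.
#' @param best_idx index of the current best individual.
#' @param strategy mutation strategy name.
#' @param F mutation factor.
#' @param r_idx optional explicit donor indices (testing hook); drawn
#'   from the session RNG when `NULL`.
#' @return Donor vector of length `dim`.
#' @export
hde_mutate <- function(pop, i, best_idx,
                       strategy = c("rand1", "best1",
                                    "current_to_best1", "best2"),
                       F = 0.5, r_idx = NULL) {
  strategy <- match.arg(strategy)
  NP <- nrow(pop)
  need <- switch(strategy, rand1 = 3, best1 = 2,
                 current_to_best1 = 2, best2 = 4)
  if (NP < need + 1)
    stop("population too small for strategy ", strategy)
  if (is.null(r_idx))
    r_idx <- sample(setdiff(seq_len(NP), i), need)
  if (length(r_idx) != need || i %in% r_idx || anyDuplicated(r_idx))
    stop("r_idx must be ", need, " distinct indices != i")
  r <- lapply(r_idx, function(j) pop[j, ])
  v <- switch(strategy,
    rand1 = r[[1]] + F * (r[[2]] - r[[3]]),
    best1 = pop[best_idx, ] + F * (r[[1]] - r[[2]]),
    current_to_best1 = pop[i, ] + F * (pop[best_idx, ] - pop[i, ]) +
      F * (r[[1]] - r[[2]]),
    best2 = pop[best_idx, ] + F * (r[[1]] - r[[2]]) +
      F * (r[[3]] - r[[4]]))
  pmin(pmax(v, 0), 1)
}

#' Stage-scheduled mutation strategy
#'
#' Thirds of the run: exploration (`rand1`) in the first third,
#' balance (`current_to_best1`) in the second, exploitation in the
#' last third alternating `best1` (odd generations) and `best2`
#' (even generations).
#'
#' @param t current generation (1-based).
#' @param G_max total generations.
#' @return Strategy name.
#' @export
schedule_strategy <- function(t, G_max) {
  if (t < 1 || t > G_max) stop("t must be in [1, G_max]")
  if (t <= G_max / 3) "rand1"
  else if (t <= 2 * G_max / 3) "current_to_best1"
  else if (t %% 2 == 1) "best1" else "best2"
}

#' Convergence-adaptive control parameters
#'
#' Piecewise rule on the convergence indicator `c_t` (relative
#' best-fitness improvement): slow convergence keeps exploitation
#' parameters, fast convergence boosts exploration.
#' `F = 0.2 + 0.5 r` for `c_t <= 0.05`, `0.3 + 0.5 r` for
#' `0.05 < c_t <= 0.1`, `0.5 + 0.5 r` otherwise (`r ~ U[0,1]`);
#' `CR = 0.95 / 0.9 / 0.7` over the same branches.
#'
#' @param c_t convergence indicator (>= 0).
#' @param r uniform random draw; taken from the session RNG by default.
#' @return List with `F` and `CR`.
#' @export
adapt_convergence <- function(c_t, r = stats::runif(1)) {
  if (c_t <= 0.05) list(F = 0.2 + 0.5 * r, CR = 0.95)
  else if (c_t <= 0.1) list(F = 0.3 + 0.5 * r, CR = 0.9)
  else list(F = 0.5 + 0.5 * r, CR = 0.7)
}

#' Diversity-adaptive control parameters
#'
#' Linear inflation of `F` and `CR` as population diversity collapses:
#' `F = F_base + dF (1 - D_current / D_max)` and likewise for `CR`,
#' clamped to `(0, 1.2]` and `(0, 1]`.
#'
#' @param F_base,CR_base baseline values.
#' @param dF,dCR adjustment margins.
#' @param D_current current mean pairwise population distance.
#' @param D_max maximum-diversity reference (> 0).
#' @return List with `F` and `CR`.
#' @export
adapt_diversity <- function(F_base, CR_base, dF, dCR, D_current,
                            D_max) {
  if (D_max <= 0) stop("D_max must be > 0")
  shrink <- 1 - D_current / D_max
  list(F = min(max(F_base + dF * shrink, 1e-8), 1.2),
       CR = min(max(CR_base + dCR * shrink, 1e-8), 1))
}

#' Binomial crossover
#'
#' Component `j` comes from the donor when `u_j < CR` or `j = j_rand`
#' (guaranteeing at least one donor component), else from the parent.
#'
#' @param parent,donor equal-length vectors.
#' @param CR crossover rate.
#' @param j_rand forced donor coordinate; drawn uniformly when `NULL`.
#' @param u uniform draws per coordinate; drawn when `NULL`.
#' @return Trial vector.
#' @export
hde_crossover <- function(parent, donor, CR, j_rand = NULL, u = NULL) {
  d <- length(parent)
  if (length(donor) != d) stop("parent/donor dimension mismatch")
  if (is.null(j_rand)) j_rand <- sample.int(d, 1)
  if (is.null(u)) u <- stats::runif(d)
  take <- u < CR
  take[j_rand] <- TRUE
  ifelse(take, donor, parent)
}

#' Control settings for the DE optimizer
#'
#' @param NP population size (>= 5).
#' @param G_max number of generations.
#' @param F_base,CR_base baseline mutation factor and crossover rate.
#' @param dF,dCR diversity adjustment margins.
#' @param adapt_mode `"both"` (convergence rule then diversity shift),
#'   `"convergence"`, `"diversity"`, or `"none"` (plain DE/rand/1/bin
#'   with fixed `F_base`/`CR_base`).
#' @param window generations over which the convergence indicator is
#'   measured.
#' @param seed integer seed; the whole run is reproducible from it.
#' @return A list of class `hde_control`.
#' @export
hde_control <- function(NP = 20, G_max = 50, F_base = 0.5,
                        CR_base = 0.9, dF = 0.3, dCR = 0.05,
                        adapt_mode = c("both", "convergence",
                                       "diversity", "none"),
                        window = 5, seed = 1) {
  if (NP < 5) stop("NP must be >= 5")
  structure(list(NP = as.integer(NP), G_max = as.integer(G_max),
                 F_base = F_base, CR_base = CR_base, dF = dF,
                 dCR = dCR, adapt_mode = match.arg(adapt_mode),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "hde_control")
}

mean_pairwise_dist <- function(pop) {
  if (nrow(pop) < 2) return(0)
  mean(stats::dist(pop))
}

#' Hybrid differential-evolution optimization
#'
#' Maximizes `objective` over the unit hypercube (decoded through
#' `space` when one is given). Each generation measures population
#' diversity (mean pairwise Euclidean distance) and a convergence
#' indicator (window-relative best-fitness improvement), adapts `F`
#' and `CR` accordingly, applies the stage-scheduled mutation strategy,
#' binomial crossover and greedy one-to-one selection.
#'
#' @param objective function of a decoded assignment (or of the raw
#'   genome when `space` is an integer dimension) returning a scalar
#'   fitness to maximize. Failures score `-Inf`.
#' @param space a [param_space()], or an integer giving the genome
#'   dimension for a raw continuous problem.
#' @param control an [hde_control()].
#' @return An object of class `hde_result`: `best_params`,
#'   `best_genome`, `best_fitness`, `trace` (per-generation best,
#'   monotone non-decreasing), `F_trace`, `CR_trace`,
#'   `strategy_trace`, `D_trace`, `population`, `control`.
#' @examples
#' res <- hde_optimize(function(g) -sum((g - 0.3)^2), space = 3,
#'                     control = hde_control(NP = 10, G_max = 10))
#' res$best_fitness
#' @export
hde_optimize <- function(objective, space, control = hde_control()) {
  raw <- !inherits(space, "param_space")
  dim <- if (raw) as.integer(space) else length(space)
  if (dim < 1) stop("empty search space")
  eval_genome <- function(g) {
    val <- tryCatch(
      if (raw) objective(g) else objective(decode_genome(space, g)),
      error = function(e) -Inf)
    if (!is.finite(val) && !identical(val, -Inf)) val <- -Inf
    as.numeric(val)
  }
  set.seed(control$seed)
  NP <- control$NP
  pop <- matrix(stats::runif(NP * dim), NP, dim)
  fit <- apply(pop, 1, eval_genome)
  D_max <- max(mean_pairwise_dist(pop), 1e-12)
  best_hist <- max(fit)
  trace <- F_tr <- CR_tr <- D_tr <- numeric(control$G_max)
  strat_tr <- character(control$G_max)
  w <- control$window
  for (t in seq_len(control$G_max)) {
    D_cur <- mean_pairwise_dist(pop)
    nh <- length(best_hist)
    c_t <- if (nh <= w) 1 else {
      ref <- best_hist[nh - w]
      (best_hist[nh] - ref) / max(abs(ref), 1e-12)
    }
    shrink <- 1 - D_cur / D_max
    FCR <- switch(control$adapt_mode,
      none = list(F = control$F_base, CR = control$CR_base),
      convergence = adapt_convergence(c_t),
      diversity = adapt_diversity(control$F_base, control$CR_base,
                                  control$dF, control$dCR, D_cur,
                                  D_max),
      both = {
        a <- adapt_convergence(c_t)
        list(F = min(max(a$F + control$dF * shrink, 1e-8), 1.2),
             CR = min(max(a$CR + control$dCR * shrink, 1e-8), 1))
      })
    strategy <- if (control$adapt_mode == "none") "rand1"
      else schedule_strategy(t, control$G_max)
    best_idx <- which.max(fit)
    new_pop <- pop; new_fit <- fit
    for (i in seq_len(NP)) {
      donor <- hde_mutate(pop, i, best_idx, strategy, FCR$F)
      trial <- hde_crossover(pop[i, ], donor, FCR$CR)
      trial <- pmin(pmax(trial, 0), 1)
      f_trial <- eval_genome(trial)
      if (f_trial >= fit[i]) {
        new_pop[i, ] <- trial
        new_fit[i] <- f_trial
      }
    }
    pop <- new_pop; fit <- new_fit
    best_hist <- c(best_hist, max(fit))
    trace[t] <- max(fit)
    F_tr[t] <- FCR$F; CR_tr[t] <- FCR$CR; D_tr[t] <- D_cur
    strat_tr[t] <- strategy
  }
  ib <- which.max(fit)
  structure(list(
    best_params = if (raw) pop[ib, ] else decode_genome(space, pop[ib, ]),
    best_genome = pop[ib, ], best_fitness = fit[ib], trace = trace,
    F_trace = F_tr, CR_trace = CR_tr, strategy_trace = strat_tr,
    D_trace = D_tr, population = pop, fitness = fit,
    control = control), class = "hde_result")
}

#' @export
print.hde_result <- function(x, ...) {
  cat(sprintf("<hde_result> best fitness %.6g after %d generations\n",
              x$best_fitness, x$control$G_max))
  invisible(x)
}
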