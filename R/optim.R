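# Population metaheuristics: Harris hawks optimization, differential
# evolution with a fitness-adaptive scaling factor, their nested hybrid
# (the hawks tune the DE controls), grey wolf and grasshopper
# optimizers. All minimize, keep candidates clipped inside the bounds
# after every update, and are bit-reproducible for a fixed seed.

#' Define a box-constrained minimization objective
#'
#' @param fn Fitness function mapping a numeric vector to a finite
#'   scalar (smaller is better).
#' @param dim Problem dimension.
#' @param lower,upper Bounds, scalars or length-`dim` vectors
#'   (`lower < upper` elementwise).
#' @param penalty Optional function adding a non-negative penalty for
#'   constraint violation; infeasible candidates should be made strictly
#'   worse than any feasible one.
#' @return An `objective_spec`.
#' @export
objective_spec <- function(fn, dim, lower, upper, penalty = NULL) {
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower >= upper)) stop("lower must be < upper elementwise")
  structure(list(fn = fn, dim = as.integer(dim), lower = lower,
                 upper = upper, penalty = penalty),
            class = "objective_spec")
}

#' @keywords internal
#' @noRd
obj_eval <- function(objective, x) {
  val <- objective$fn(x)
  if (!is.null(objective$penalty)) val <- val + objective$penalty(x)
  if (!is.finite(val))
    stop(sprintf("fitness returned a non-finite value at candidate (%s)",
                 paste(signif(x, 4), collapse = ", ")))
  val
}

#' @keywords internal
#' @noRd
clip_bounds <- function(x, objective) pmin(pmax(x, objective$lower), objective$upper)

#' @keywords internal
#' @noRd
init_population <- function(objective, pop_size) {
  n <- objective$dim
  t(replicate(pop_size,
              objective$lower + (objective$upper - objective$lower) * stats::runif(n)))
}

#' @keywords internal
#' @noRd
optim_result <- function(best_candidate, best_fitness, trace, iterations_run) {
  structure(list(best_candidate = best_candidate, best_fitness = best_fitness,
                 convergence_trace = trace, iterations_run = iterations_run),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("<optim_result> best fitness %.6g after %d iterations\n",
              x$best_fitness, x$iterations_run))
  invisible(x)
}

#' Escape energy schedule of the Harris hawks optimizer
#'
#' `E = 2 E0 (1 - t / T)`: the prey's escape energy decays linearly with
#' the iteration count; `|E| >= 1` keeps the hawks exploring, `|E| < 1`
#' switches them to the exploitation branches.
#'
#' @param E0 Initial energy in \[-1, 1\].
#' @param t Current iteration (0 <= t <= T).
#' @param T_max Maximum iteration count (> 0).
#' @return The escape energy E.
#' @export
escape_energy <- function(E0, t, T_max) {
  if (T_max == 0) stop("T_max must be positive")
  if (t < 0 || t > T_max) stop("t must lie in [0, T_max]")
  if (abs(E0) > 1) stop("E0 must lie in [-1, 1]")
  2 * E0 * (1 - t / T_max)
}

# Mantegna Levy flight step of given dimension.
#' @keywords internal
#' @noRd
levy_flight <- function(dim, beta = 1.5) {
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  g <- stats::rnorm(dim) * sigma
  h <- stats::rnorm(dim)
  0.01 * g / abs(h)^(1 / beta)
}

#' Harris hawks optimizer configuration
#' @param pop_size Number of hawks (default 50).
#' @param max_iters Iteration cap (default 500).
#' @param levy_beta Levy-flight stability index in \[0.5, 1.5\].
#' @param seed RNG seed.
#' @return An `hho_config` list.
#' @export
hho_config <- function(pop_size = 50L, max_iters = 500L, levy_beta = 1.5, seed = 1L) {
  if (pop_size < 2L) stop("pop_size must be >= 2")
  structure(list(pop_size = as.integer(pop_size), max_iters = as.integer(max_iters),
                 levy_beta = levy_beta, seed = as.integer(seed)),
            class = "hho_config")
}

#' Harris hawks optimization
#'
#' Swarm search alternating exploration (perching at random positions or
#' relative to the flock mean) and four exploitation branches keyed on
#' the prey's escape energy and a random draw: soft besiege, hard
#' besiege, and their rapid-dive variants with Levy flights, the dives
#' accepted greedily. The prey is the best candidate found so far.
#'
#' @param objective An [objective_spec()].
#' @param config An [hho_config()].
#' @return An [optim_result] with a non-increasing best-so-far trace.
#' @export
hho <- function(objective, config = hho_config()) {
  with_seed(config$seed, {
    P <- config$pop_size
    n <- objective$dim
    X <- init_population(objective, P)
    fit <- apply(X, 1, function(x) obj_eval(objective, x))
    ib <- which.min(fit)
    rabbit <- X[ib, ]; rabbit_fit <- fit[ib]
    trace <- numeric(config$max_iters)
    for (t in seq_len(config$max_iters)) {
      xmean <- colMeans(X)
      for (i in seq_len(P)) {
        E <- escape_energy(stats::runif(1, -1, 1), t, config$max_iters)
        Jmp <- 2 * (1 - stats::runif(1))
        if (abs(E) >= 1) {
          if (stats::runif(1) >= 0.5) {
            Xr <- X[sample.int(P, 1), ]
            xi <- Xr - stats::runif(1) * abs(Xr - 2 * stats::runif(1) * X[i, ])
          } else {
            xi <- (rabbit - xmean) -
              stats::runif(1) * (objective$lower +
                                   stats::runif(1) * (objective$upper - objective$lower))
          }
          X[i, ] <- clip_bounds(xi, objective)
          fit[i] <- obj_eval(objective, X[i, ])
        } else {
          r <- stats::runif(1)
          if (r >= 0.5 && abs(E) >= 0.5) {           # soft besiege
            dX <- rabbit - X[i, ]
            X[i, ] <- clip_bounds(dX - E * abs(Jmp * rabbit - X[i, ]), objective)
            fit[i] <- obj_eval(objective, X[i, ])
          } else if (r >= 0.5) {                     # hard besiege
            dX <- rabbit - X[i, ]
            X[i, ] <- clip_bounds(rabbit - E * abs(dX), objective)
            fit[i] <- obj_eval(objective, X[i, ])
          } else {                                   # besiege with rapid dives
            base <- if (abs(E) >= 0.5) X[i, ] else xmean
            A <- clip_bounds(rabbit - E * abs(Jmp * rabbit - base), objective)
            fA <- obj_eval(objective, A)
            if (fA < fit[i]) {
              X[i, ] <- A; fit[i] <- fA
            } else {
              B <- clip_bounds(A + stats::runif(n) * levy_flight(n, config$levy_beta),
                               objective)
              fB <- obj_eval(objective, B)
              if (fB < fit[i]) { X[i, ] <- B; fit[i] <- fB }
            }
          }
        }
        if (fit[i] < rabbit_fit) { rabbit <- X[i, ]; rabbit_fit <- fit[i] }
      }
      trace[t] <- rabbit_fit
    }
    optim_result(rabbit, rabbit_fit, trace, config$max_iters)
  })
}

#' Closeness parameter of an individual
#'
#' Normalized position of a fitness value between the population's worst
#' and best: `CP = (fit_q - fit_worst) / (fit_best - fit_worst)`, 1 at
#' the best, 0 at the worst. When every individual has equal fitness the
#' population has converged and CP is defined as 1 (full exploitation).
#'
#' @param fit_q Fitness of the individual.
#' @param fit_best,fit_worst Best and worst population fitness under the
#'   active orientation.
#' @return CP in \[0, 1\].
#' @export
closeness_parameter <- function(fit_q, fit_best, fit_worst) {
  if (fit_best == fit_worst) return(1)
  (fit_q - fit_worst) / (fit_best - fit_worst)
}

#' Fitness-adaptive scaling factor
#'
#' `S = 1 / (1 + tanh(2 CP))`, strictly decreasing in CP with image
#' (0.5, 1\]: individuals far from the best get a large scale (global
#' exploration), individuals close to it a small one (local
#' exploitation).
#'
#' @param CP Closeness parameter in \[0, 1\].
#' @return Scale S with `0.5 < S <= 1`.
#' @export
adaptive_scale <- function(CP) {
  if (any(CP < 0 | CP > 1)) stop("CP must lie in [0, 1]")
  1 / (1 + tanh(2 * CP))
}

#' Sigmoid binarization of a continuous candidate
#'
#' `bit_i = 1` when `rand_i < 1 / (1 + exp(-x_i))`; at `x_i = 0` the
#' probability is exactly 0.5.
#'
#' @param candidate Numeric vector.
#' @param rand Uniform draws (defaults to fresh `runif`).
#' @return Integer 0/1 vector.
#' @export
binarize <- function(candidate, rand = stats::runif(length(candidate))) {
  as.integer(rand < sigmoid(candidate))
}

#' Adaptive differential evolution configuration
#'
#' @param pop_size Population size NP (>= 4), default 100 (75 when run
#'   inside the nested hybrid).
#' @param max_iters Generation cap, default 1000 (500 in the hybrid).
#' @param cr Binomial crossover probability in (0, 1), default 0.7.
#' @param binary Evaluate candidates through sigmoid binarization
#'   (feature-mask mode).
#' @param scale_mult Multiplier applied to the adaptive scale (tuned by
#'   the nested hybrid), default 1.
#' @param stall_tol,stall_patience Early stop when the best fitness has
#'   improved by less than `stall_tol` over the trailing
#'   `stall_patience` generations (the population best improves in
#'   jumps, so the improvement is measured over a window, not per
#'   generation); `stall_patience = Inf` disables it.
#' @param seed RNG seed.
#' @return An `sfpde_config` list.
#' @export
sfpde_config <- function(pop_size = 100L, max_iters = 1000L, cr = 0.7,
                         binary = FALSE, scale_mult = 1,
                         stall_tol = 1e-8, stall_patience = 50L, seed = 1L) {
  if (pop_size < 4L) stop("pop_size must be >= 4 (three distinct partners needed)")
  if (!(cr > 0 && cr < 1)) stop("cr must lie in (0, 1)")
  structure(list(pop_size = as.integer(pop_size), max_iters = as.integer(max_iters),
                 cr = cr, binary = binary, scale_mult = scale_mult,
                 stall_tol = stall_tol, stall_patience = stall_patience,
                 seed = as.integer(seed)),
            class = "sfpde_config")
}

#' Differential evolution with a fitness-adaptive scaling factor
#'
#' Classic DE/current/1 with binomial crossover, except that each
#' individual's mutation scale is set from its closeness parameter
#' ([adaptive_scale()]): the mutant is
#' `Y_q = X_q + S_q (X_q1 - X_q2)` with distinct random partners.
#' Selection is greedy, so no individual's fitness ever worsens. In
#' binary mode candidates are passed through [binarize()] before
#' evaluation (feature-mask optimization); the reported best candidate
#' is then the bit vector actually evaluated.
#'
#' @param objective An [objective_spec()].
#' @param config An [sfpde_config()].
#' @return An [optim_result]; also carries `scales_ok` (logical: every
#'   adaptive scale observed stayed in (0.5, 1\]) and `fitness_history`
#'   (per-individual fitness per generation) when
#'   `config$track_history` is TRUE.
#' @export
sfpde <- function(objective, config = sfpde_config()) {
  with_seed(config$seed, {
    NP <- config$pop_size
    n <- objective$dim
    X <- init_population(objective, NP)
    eval_cand <- function(x) {
      if (config$binary) {
        bits <- binarize(x)
        list(fit = obj_eval(objective, bits), repr = bits)
      } else list(fit = obj_eval(objective, x), repr = x)
    }
    reprs <- vector("list", NP)
    fit <- numeric(NP)
    for (q in seq_len(NP)) { ev <- eval_cand(X[q, ]); fit[q] <- ev$fit; reprs[[q]] <- ev$repr }
    trace <- numeric(0)
    scales_ok <- TRUE
    history <- if (isTRUE(config$track_history)) list() else NULL
    t_run <- 0L
    for (t in seq_len(config$max_iters)) {
      t_run <- t
      fbest <- min(fit); fworst <- max(fit)
      CP <- vapply(fit, closeness_parameter, numeric(1), fbest, fworst)
      S <- adaptive_scale(CP)
      scales_ok <- scales_ok && all(S > 0.5 & S <= 1)
      S <- S * config$scale_mult
      for (q in seq_len(NP)) {
        partners <- sample(setdiff(seq_len(NP), q), 2L)
        Y <- X[q, ] + S[q] * (X[partners[1], ] - X[partners[2], ])
        i_rand <- sample.int(n, 1)
        mask <- stats::runif(n) <= config$cr
        mask[i_rand] <- TRUE
        Z <- ifelse(mask, Y, X[q, ])
        Z <- clip_bounds(Z, objective)
        ev <- eval_cand(Z)
        if (ev$fit <= fit[q]) {
          X[q, ] <- Z; fit[q] <- ev$fit; reprs[[q]] <- ev$repr
        }
      }
      if (!is.null(history)) history[[t]] <- fit
      trace[t] <- min(fit)
      if (is.finite(config$stall_patience) && t > config$stall_patience &&
          trace[t - config$stall_patience] - trace[t] < config$stall_tol) break
    }
    ib <- which.min(fit)
    out <- optim_result(reprs[[ib]], fit[ib], trace, t_run)
    out$scales_ok <- scales_ok
    out$fitness_history <- history
    out
  })
}

#' Nested hawks-over-DE hyperparameter tuner
#'
#' An outer Harris hawks swarm searches over the DE controls -- the
#' crossover probability `CR` in \[0.1, 0.95\] and a scale-modulation
#' multiplier in \[0.5, 1.5\] applied to the adaptive scale. Each hawk's
#' fitness is the best objective value reached by an inner
#' [sfpde()] run under those controls; the overall best inner solution
#' is returned. The outer loop stops at its iteration cap or when the
#' best fitness improves by less than `outer_tol` between generations.
#'
#' @param objective An [objective_spec()].
#' @param outer An [hho_config()] for the hawks (defaults: 50 hawks,
#'   500 iterations).
#' @param inner An [sfpde_config()] template for the inner runs
#'   (defaults: NP = 75, 500 iterations); its `cr` and `scale_mult` are
#'   overridden by each hawk, and inner seeds are derived
#'   deterministically from the outer seed.
#' @param outer_tol Outer stall tolerance, default 1e-8.
#' @param outer_patience Consecutive stalled outer iterations before
#'   stopping, default 5.
#' @return An [optim_result] for the best inner solution, with
#'   `tuned_controls` (named `cr`, `scale_mult`) and the outer trace.
#' @export
hho_sfpde <- function(objective, outer = hho_config(),
                      inner = sfpde_config(pop_size = 75L, max_iters = 500L),
                      outer_tol = 1e-8, outer_patience = 5L) {
  store <- new.env(parent = emptyenv())
  store$best_fit <- Inf
  store$best_sol <- NULL
  store$best_controls <- NULL
  store$counter <- 0L
  hawk_fitness <- function(theta) {
    store$counter <- store$counter + 1L
    cfg <- inner
    cfg$cr <- min(max(theta[1], 0.1), 0.95)
    cfg$scale_mult <- min(max(theta[2], 0.5), 1.5)
    cfg$seed <- split_seed(outer$seed, store$counter)
    res <- sfpde(objective, cfg)
    if (res$best_fitness < store$best_fit) {
      store$best_fit <- res$best_fitness
      store$best_sol <- res$best_candidate
      store$best_controls <- c(cr = cfg$cr, scale_mult = cfg$scale_mult)
    }
    res$best_fitness
  }
  meta_obj <- objective_spec(hawk_fitness, dim = 2L,
                             lower = c(0.1, 0.5), upper = c(0.95, 1.5))
  # run the hawks generation by generation so the stall rule can apply
  trace <- numeric(0)
  prev <- Inf
  stall <- 0L
  iters <- 0L
  cfg1 <- outer
  for (t in seq_len(outer$max_iters)) {
    cfg1$max_iters <- 1L
    cfg1$seed <- split_seed(outer$seed, 1000000L + t)
    invisible(hho(meta_obj, cfg1))
    iters <- t
    trace[t] <- store$best_fit
    if (prev - store$best_fit < outer_tol) stall <- stall + 1L else stall <- 0L
    prev <- store$best_fit
    if (stall >= outer_patience) break
  }
  out <- optim_result(store$best_sol, store$best_fit, trace, iters)
  out$tuned_controls <- store$best_controls
  out
}

#' Grey wolf optimizer configuration
#' @param pop_size Number of wolves (>= 3), default 50.
#' @param max_iters Iteration cap, default 500.
#' @param seed RNG seed.
#' @return A `gwo_config` list.
#' @export
gwo_config <- function(pop_size = 50L, max_iters = 500L, seed = 1L) {
  if (pop_size < 3L) stop("pop_size must be >= 3 (alpha, beta, gamma leaders)")
  structure(list(pop_size = as.integer(pop_size), max_iters = as.integer(max_iters),
                 seed = as.integer(seed)),
            class = "gwo_config")
}

#' Grey wolf optimization
#'
#' The three best wolves lead; every wolf moves to the mean of three
#' leader-guided steps `W_l - K_l |H_l W_l - W|` with the usual
#' coefficient schedules (`K` drawn from \[-a, a\] with `a` decaying
#' 2 to 0, `H` from \[0, 2\]).
#'
#' @param objective An [objective_spec()].
#' @param config A [gwo_config()].
#' @return An [optim_result].
#' @export
gwo <- function(objective, config = gwo_config()) {
  with_seed(config$seed, {
    P <- config$pop_size
    n <- objective$dim
    X <- init_population(objective, P)
    fit <- apply(X, 1, function(x) obj_eval(objective, x))
    trace <- numeric(config$max_iters)
    for (t in seq_len(config$max_iters)) {
      ord <- order(fit)
      leaders <- X[ord[1:3], , drop = FALSE]
      a <- 2 - 2 * (t - 1) / config$max_iters
      for (i in seq_len(P)) {
        moves <- vapply(1:3, function(l) {
          K <- 2 * a * stats::runif(n) - a
          H <- 2 * stats::runif(n)
          leaders[l, ] - K * abs(H * leaders[l, ] - X[i, ])
        }, numeric(n))
        X[i, ] <- clip_bounds(rowMeans(moves), objective)
        fit[i] <- obj_eval(objective, X[i, ])
      }
      trace[t] <- min(fit)
    }
    trace <- cummin(trace)
    ib <- which.min(fit)
    optim_result(X[ib, ], fit[ib], trace, config$max_iters)
  })
}

#' Grasshopper optimizer configuration
#' @param pop_size Number of agents (>= 2), default 60.
#' @param max_iters Iteration cap, default 400.
#' @param f,l_att Social-force parameters (attraction intensity and
#'   length scale), defaults 0.5 and 1.5.
#' @param c_max,c_min Comfort-zone coefficient range; c decays linearly
#'   from `c_max` to `c_min`.
#' @param seed RNG seed.
#' @return A `goa_config` list.
#' @export
goa_config <- function(pop_size = 60L, max_iters = 400L, f = 0.5, l_att = 1.5,
                       c_max = 1, c_min = 1e-5, seed = 1L) {
  if (pop_size < 2L) stop("pop_size must be >= 2")
  structure(list(pop_size = as.integer(pop_size), max_iters = as.integer(max_iters),
                 f = f, l_att = l_att, c_max = c_max, c_min = c_min,
                 seed = as.integer(seed)),
            class = "goa_config")
}

# social function s(r) = f exp(-r/l) - exp(-r); s(0) defined as 0 so
# coincident agents exert no force on each other
#' @keywords internal
#' @noRd
goa_social <- function(r, f, l_att) ifelse(r == 0, 0, f * exp(-r / l_att) - exp(-r))

#' Grasshopper optimization
#'
#' Each agent moves under the summed pairwise social force of the swarm
#' (per-dimension normalized distances, attraction/repulsion function
#' `s(r) = f e^{-r/l} - e^{-r}`) plus a pull toward the best-so-far
#' target, the whole scaled by a comfort coefficient decaying linearly
#' from `c_max` to `c_min`.
#'
#' @param objective An [objective_spec()].
#' @param config A [goa_config()].
#' @return An [optim_result].
#' @export
goa <- function(objective, config = goa_config()) {
  with_seed(config$seed, {
    P <- config$pop_size
    n <- objective$dim
    X <- init_population(objective, P)
    fit <- apply(X, 1, function(x) obj_eval(objective, x))
    ib <- which.min(fit)
    target <- X[ib, ]; target_fit <- fit[ib]
    trace <- numeric(config$max_iters)
    span <- (objective$upper - objective$lower) / 2
    for (t in seq_len(config$max_iters)) {
      c_t <- config$c_max - t * (config$c_max - config$c_min) / config$max_iters
      X_new <- X
      for (i in seq_len(P)) {
        force <- numeric(n)
        for (j in seq_len(P)) {
          if (j == i) next
          diffv <- X[j, ] - X[i, ]
          dij <- sqrt(sum(diffv^2))
          if (dij == 0) next
          # distances mapped into [1, 4] as is conventional, to keep the
          # social function out of its flat tails
          r <- 2 + (dij %% 2)
          force <- force + c_t * span * goa_social(r, config$f, config$l_att) *
            diffv / dij
        }
        X_new[i, ] <- clip_bounds(c_t * force + target, objective)
      }
      X <- X_new
      fit <- apply(X, 1, function(x) obj_eval(objective, x))
      ib <- which.min(fit)
      if (fit[ib] < target_fit) { target <- X[ib, ]; target_fit <- fit[ib] }
      trace[t] <- target_fit
    }
    optim_result(target, target_fit, trace, config$max_iters)
  })
}
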