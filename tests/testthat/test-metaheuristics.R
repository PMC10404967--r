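# Population metaheuristics: closed-form pieces, invariants, and small
# convergence checks (the full published budgets run in the acceptance
# suite).

sphere_obj <- function(dim = 5, lb = -10, ub = 10)
  objective_spec(function(x) sum(x^2), dim, lb, ub)

test_that("escape energy follows the linear decay schedule", {
  expect_equal(escape_energy(1, 0, 100), 2)
  expect_equal(escape_energy(0.7, 100, 100), 0)
  expect_equal(escape_energy(-0.5, 50, 100), -0.5)
  expect_error(escape_energy(1, 0, 0), "positive")
  expect_error(escape_energy(2, 0, 10), "\\[-1, 1\\]")
})

test_that("closeness parameter and adaptive scale match their formulas", {
  expect_equal(closeness_parameter(5, 8, 2), 0.5)
  expect_equal(closeness_parameter(8, 8, 2), 1)
  expect_equal(closeness_parameter(2, 8, 2), 0)
  expect_equal(closeness_parameter(3, 8, 2), 1 / 6)
  expect_equal(closeness_parameter(4, 4, 4), 1)   # converged population
  expect_equal(adaptive_scale(0), 1)
  expect_equal(adaptive_scale(1), 1 / (1 + tanh(2)))
  grid <- adaptive_scale(seq(0, 1, length.out = 100))
  expect_true(all(diff(grid) < 0))                # strictly decreasing
  expect_true(all(grid > 0.5 & grid <= 1))
  expect_error(adaptive_scale(1.2), "\\[0, 1\\]")
})

test_that("binarization follows the sigmoid rule", {
  expect_equal(binarize(c(1e6, -1e6)), c(1L, 0L))
  expect_equal(respsound:::sigmoid(0), 0.5)
  set.seed(12)
  p <- mean(replicate(200, binarize(rep(2, 500))) == 1)
  expect_lt(abs(p - 1 / (1 + exp(-2))), 0.01)
})

test_that("hawks optimizer: greedy trace, bounds, determinism", {
  obj <- sphere_obj()
  cfg <- hho_config(pop_size = 15, max_iters = 60, seed = 4)
  r1 <- hho(obj, cfg)
  r2 <- hho(obj, cfg)
  expect_identical(r1$convergence_trace, r2$convergence_trace)
  expect_false(is.unsorted(rev(r1$convergence_trace)))
  expect_true(all(r1$best_candidate >= -10 & r1$best_candidate <= 10))
  expect_lt(r1$best_fitness, 1)
  expect_equal(r1$best_fitness, r1$convergence_trace[length(r1$convergence_trace)])
  expect_error(
    hho(objective_spec(function(x) NA_real_, 2, -1, 1),
        hho_config(pop_size = 3, max_iters = 2)),
    "non-finite")
})

test_that("adaptive DE: greedy selection, scale bound, determinism", {
  obj <- sphere_obj()
  cfg <- sfpde_config(pop_size = 12, max_iters = 40, seed = 9,
                      stall_patience = Inf)
  cfg$track_history <- TRUE
  r <- sfpde(obj, cfg)
  expect_true(r$scales_ok)
  hist <- do.call(rbind, r$fitness_history)
  expect_true(all(apply(hist, 2, function(col) all(diff(col) <= 0))))
  expect_false(is.unsorted(rev(r$convergence_trace)))
  r2 <- sfpde(obj, cfg)
  expect_identical(r$convergence_trace, r2$convergence_trace)
  expect_error(sfpde_config(pop_size = 3), ">= 4")
  expect_error(sfpde_config(cr = 1), "\\(0, 1\\)")
})

test_that("binary DE mode returns an evaluated bit vector", {
  # best mask for this objective is exactly bits (1, 0, 1)
  obj <- objective_spec(function(b) sum(abs(b - c(1, 0, 1))), 3, -2, 2)
  r <- sfpde(obj, sfpde_config(pop_size = 8, max_iters = 30, binary = TRUE,
                               seed = 2, stall_patience = Inf))
  expect_true(all(r$best_candidate %in% c(0L, 1L)))
  expect_equal(r$best_fitness, 0)
  expect_equal(r$best_candidate, c(1L, 0L, 1L))
})

test_that("nested tuner stays in control bounds and carries a greedy trace", {
  obj <- sphere_obj(dim = 3)
  r <- hho_sfpde(obj, outer = hho_config(pop_size = 3, max_iters = 3, seed = 1),
                 inner = sfpde_config(pop_size = 6, max_iters = 15,
                                      stall_patience = Inf))
  expect_false(is.unsorted(rev(r$convergence_trace)))
  expect_gte(r$tuned_controls[["cr"]], 0.1)
  expect_lte(r$tuned_controls[["cr"]], 0.95)
  expect_gte(r$tuned_controls[["scale_mult"]], 0.5)
  expect_lte(r$tuned_controls[["scale_mult"]], 1.5)
  expect_lt(r$best_fitness, 1)
})

test_that("grey wolf optimizer converges and respects bounds deterministically", {
  obj <- sphere_obj()
  cfg <- gwo_config(pop_size = 12, max_iters = 60, seed = 3)
  r <- gwo(obj, cfg)
  expect_lt(r$best_fitness, 1e-2)
  expect_true(all(abs(r$best_candidate) <= 10))
  expect_identical(r$convergence_trace, gwo(obj, cfg)$convergence_trace)
  expect_false(is.unsorted(rev(r$convergence_trace)))
  expect_error(gwo_config(pop_size = 2), ">= 3")
})

test_that("grasshopper optimizer converges; coincident agents exert no force", {
  expect_equal(respsound:::goa_social(0, 0.5, 1.5), 0)
  obj <- sphere_obj()
  r <- goa(obj, goa_config(pop_size = 15, max_iters = 80, seed = 6))
  expect_lt(r$best_fitness, 0.5)
  expect_false(is.unsorted(rev(r$convergence_trace)))
})

test_that("penalty handling makes infeasible candidates strictly worse", {
  # feasibility region: x1 >= 0; penalized objective
  obj <- objective_spec(function(x) sum(x^2), 2, -5, 5,
                        penalty = function(x) if (x[1] < 0) 1e6 else 0)
  feas <- respsound:::obj_eval(obj, c(4.9, 4.9))     # worst feasible corner
  infeas <- respsound:::obj_eval(obj, c(-0.01, 0))   # nearly optimal but infeasible
  expect_gt(infeas, feas)
  r <- sfpde(obj, sfpde_config(pop_size = 10, max_iters = 50, seed = 1,
                               stall_patience = Inf))
  expect_gte(r$best_candidate[1], 0)
})
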