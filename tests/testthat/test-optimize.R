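# CMA-ES and the experiment machinery.

test_that("CMA-ES recovers a known 26-D quadratic optimum", {
  xstar <- seq(0.2, 0.8, length.out = 26)
  obj <- function(x) -sum((x - xstar)^2)
  run <- cma_optimize(obj, lower = rep(0, 26), upper = rep(1, 26),
                      popsize = 31, maxiter = 70, seed = 5)
  # value gap below 1e-3 (unit curvature: parameter error below ~0.03)
  expect_lt(-run$best_value, 1e-3)
  expect_lt(max(abs(run$best_par - xstar)), 0.03)
  expect_equal(run$evaluations, 31 * 70)
})

test_that("fixed seeds give bit-identical optimization runs", {
  obj <- function(x) -sum((x - 0.3)^2)
  r1 <- cma_optimize(obj, rep(0, 8), rep(1, 8), popsize = 10, maxiter = 20,
                     seed = 99)
  r2 <- cma_optimize(obj, rep(0, 8), rep(1, 8), popsize = 10, maxiter = 20,
                     seed = 99)
  expect_identical(r1$best_par, r2$best_par)
  expect_identical(r1$history, r2$history)
})

test_that("best-so-far quality is monotone non-decreasing", {
  obj <- function(x) -sum((x - 0.7)^2) + 0.01 * sin(40 * sum(x))
  run <- cma_optimize(obj, rep(0, 6), rep(1, 6), popsize = 8, maxiter = 30,
                      seed = 2)
  expect_true(all(diff(run$history$best_so_far) >= 0))
})

test_that("non-finite samples are treated as worst and counted", {
  obj <- function(x) if (x[1] > 0.9) NaN else -sum(x^2)
  run <- cma_optimize(obj, rep(0, 3), rep(1, 3), x0 = rep(0.85, 3),
                      sigma0 = 0.2, popsize = 8, maxiter = 10, seed = 4)
  expect_gt(run$n_nonfinite, 0)
  expect_true(is.finite(run$best_value))
})

test_that("parallel evaluation reproduces the serial run exactly", {
  pobj <- paddle_objective(fix_preset(), "all")
  b <- plesioswim:::stroke_bounds(fix_preset())
  m0 <- plesioswim:::stroke_initial_mean(fix_preset())
  r1 <- cma_optimize(pobj, b$lower, b$upper, x0 = m0, popsize = 6,
                     maxiter = 4, seed = 21, workers = 1)
  r2 <- cma_optimize(pobj, b$lower, b$upper, x0 = m0, popsize = 6,
                     maxiter = 4, seed = 21, workers = 2)
  expect_equal(r1$best_par, r2$best_par, tolerance = 1e-12)
  expect_equal(r1$history, r2$history, tolerance = 1e-12)
})

test_that("CMA improves the drag-paddle surrogate far beyond the initial mean", {
  preset <- fix_preset()
  pobj <- paddle_objective(preset, "all")
  b <- plesioswim:::stroke_bounds(preset)
  m0 <- plesioswim:::stroke_initial_mean(preset)
  q0 <- pobj(m0)
  run <- cma_optimize(pobj, b$lower, b$upper, x0 = m0, popsize = 16,
                      maxiter = 30, seed = 3)
  expect_gte(run$best_value, 5 * q0)
})

test_that("single-pair experiments search 13 dimensions, all-limb 26", {
  preset <- fix_preset()
  b <- plesioswim:::stroke_bounds(preset)
  expect_length(b$lower, 26)
  expect_length(b$upper, 26)
  expect_equal(plesioswim:::search_dim("fore"), 13L)
  expect_equal(plesioswim:::search_dim("all"), 26L)
  # embedding freezes the inactive pair at a zero-amplitude neutral stroke
  v13 <- plesioswim:::stroke_initial_mean(preset)[1:13]
  full <- plesioswim:::embed_stroke_vector(v13, "fore", preset)
  expect_length(full, 26)
  st <- decode_stroke(full, preset, warn = FALSE)
  expect_equal(st$hind$dv$min, st$hind$dv$max)
  expect_equal(st$hind$dv$min, -30)
  expect_equal(st$hind$ap$min, -27)
  # hind-only embedding freezes the fore pair
  full2 <- plesioswim:::embed_stroke_vector(v13, "hind", preset)
  st2 <- decode_stroke(full2, preset, warn = FALSE)
  expect_equal(st2$fore$dv$min, st2$fore$dv$max)
  expect_equal(st2$fore$dv$min, -15)
})

test_that("run_experiment wires the optimizer to the simulator", {
  cfg <- sim_config("mini", dt = 0.025, n_cycles = 2)
  res <- run_experiment("medium", "fore", config = cfg, popsize = 4,
                        maxiter = 2, seed = 7)
  expect_length(res$run$best_par, 13)
  expect_length(res$stroke_vector, 26)
  expect_s3_class(res$trajectory, "psw_trajectory")
  expect_equal(res$run$evaluations, 8)
  expect_true(is.finite(res$quality$quality))
})
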