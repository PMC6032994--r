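# Optimizer mechanics: chaotic initialization, tumble directions, the
# chemotaxis/swim loop, reproduction, elimination-dispersal, greedy Gaussian
# mutation, and the full nested-loop driver.

sphere <- function(x) rowSums(x^2)

test_that("logistic map iterates the chaotic recurrence", {
  expect_equal(logistic_map(0.3, 1), 0.84)
  expect_equal(logistic_map(0.3, 2)[2], 4 * 0.84 * 0.16)
  traj <- logistic_map(0.137, 5000)
  expect_true(all(traj > 0 & traj < 1))
  expect_error(logistic_map(1.2, 1))
})

test_that("chaotic initialization fills the box", {
  set.seed(5)
  pos <- chaotic_init(40, lower = c(-2, 10), upper = c(3, 20))
  expect_equal(dim(pos), c(40, 2))
  expect_true(all(pos[, 1] > -2 & pos[, 1] < 3))
  expect_true(all(pos[, 2] > 10 & pos[, 2] < 20))
  # affine image of a chaotic (0,1) sequence: strictly interior
  expect_gt(min(pos[, 2]) , 10)
})

test_that("tumble directions are unit vectors with symmetric components", {
  set.seed(9)
  for (d in c(1, 2, 7)) {
    v <- tumble_direction(d)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  }
  expect_true(tumble_direction(1) %in% c(-1, 1))
  draws <- cbfofknn:::tumble_directions(1e5, 3)
  expect_equal(sqrt(rowSums(draws^2)), rep(1, 1e5), tolerance = 1e-12)
  # mean per component ~ 0 within 3 standard errors
  se <- apply(draws, 2, sd) / sqrt(1e5)
  expect_true(all(abs(colMeans(draws)) < 3 * se))
})

test_that("control constructor enforces its invariants", {
  expect_error(cbfo_control(pop = 7), "even")
  expect_error(cbfo_control(ped = 1.5), "ped")
  expect_error(cbfo_control(step = 0), "step")
  expect_error(cbfo_control(chemotaxis = 0), "must be >= 1")
  expect_equal(cbfo_benchmark_control()$pop, 50L)
  expect_equal(cbfo_benchmark_control(pop = 10)$pop, 10L)
})

test_that("a chemotaxis pass swims while improving, up to the swim limit", {
  # step kept tiny so no swim can reach the boundary and stall early
  ctrl <- cbfo_control(pop = 6, swim = 4, step = 1e-6, chaos = FALSE,
                       mutation = FALSE)
  lin <- function(x) rowSums(x)  # improvement persists along a direction
  lower <- rep(-1e6, 2); upper <- rep(1e6, 2)
  set.seed(13)
  state <- cbfofknn:::new_swarm(lin, lower, upper, ctrl)
  before <- state$costs
  e0 <- state$evaluations
  state <- cbfofknn:::chemotaxis_pass(state, lin, lower, upper, ctrl)
  improved <- sum(state$costs < before)
  # every improving bacterium took 1 tumble + exactly 4 swims
  expect_equal(state$evaluations - e0, 6 + 4 * improved)
  expect_gt(improved, 0)
})

test_that("chemotaxis lowers the best cost on the sphere from a fixed seed", {
  ctrl <- cbfo_control(pop = 8, chaos = FALSE, mutation = FALSE)
  lower <- rep(-5, 2); upper <- rep(5, 2)
  set.seed(21)
  state <- cbfofknn:::new_swarm(sphere, lower, upper, ctrl)
  b0 <- state$best_cost
  for (i in 1:5)
    state <- cbfofknn:::chemotaxis_pass(state, sphere, lower, upper, ctrl)
  expect_lt(state$best_cost, b0)
  expect_true(all(state$positions >= -5 & state$positions <= 5))
})

test_that("reproduction duplicates the healthiest half and keeps size", {
  ctrl <- cbfo_control(pop = 8, chaos = FALSE, mutation = FALSE)
  set.seed(2)
  state <- cbfofknn:::new_swarm(sphere, rep(-5, 3), rep(5, 3), ctrl)
  state$health <- c(5, 1, 7, 3, 8, 2, 6, 4)  # bacterium 2 is healthiest
  pos_before <- state$positions
  state <- cbfofknn:::reproduce_swarm(state)
  expect_equal(nrow(state$positions), 8)
  keep <- order(c(5, 1, 7, 3, 8, 2, 6, 4))[1:4]
  expect_equal(state$positions, pos_before[c(keep, keep), ])
  expect_equal(state$health, rep(0, 8))
  # uniform health: stable tie-break keeps the leading half, duplicated
  state2 <- cbfofknn:::new_swarm(sphere, rep(-5, 3), rep(5, 3), ctrl)
  p2 <- state2$positions
  state2$health <- rep(1, 8)
  state2 <- cbfofknn:::reproduce_swarm(state2)
  expect_equal(state2$positions, p2[c(1:4, 1:4), ])
})

test_that("elimination-dispersal degenerates correctly at ped = 0 and 1", {
  set.seed(3)
  lower <- rep(-5, 2); upper <- rep(5, 2)
  ctrl0 <- cbfo_control(pop = 10, ped = 0, chaos = FALSE)
  state <- cbfofknn:::new_swarm(sphere, lower, upper, ctrl0)
  before <- state
  state <- cbfofknn:::eliminate_disperse(state, sphere, lower, upper, ctrl0)
  expect_identical(state, before)

  ctrl1 <- cbfo_control(pop = 10, ped = 1, chaos = FALSE)
  state <- cbfofknn:::eliminate_disperse(before, sphere, lower, upper, ctrl1)
  expect_false(any(state$positions == before$positions))
  expect_true(all(state$positions >= -5 & state$positions <= 5))
  # the best-so-far record never regresses
  expect_lte(state$best_cost, before$best_cost)
})

test_that("Gaussian mutation of the best is greedy and adaptive", {
  lower <- -5; upper <- 5
  ctrl <- cbfo_control(pop = 2, sigma = 0.1, chaos = FALSE)
  state <- list(best_par = 0.1, best_cost = sphere(matrix(0.1)),
                evaluations = 0L, sigma = 0.1, positions = matrix(0.1),
                costs = sphere(matrix(0.1)))
  # a mutant that cannot improve leaves the record untouched
  worse <- function(x) rep(1e9, nrow(x))
  out <- cbfofknn:::mutate_best(state, worse, lower, upper, ctrl)
  expect_equal(out$best_cost, state$best_cost)
  expect_lt(out$sigma, state$sigma)  # failure shrinks the proposal scale

  # sigma = 0 disables mutation entirely
  ctrl0 <- cbfo_control(pop = 2, sigma = 0, chaos = FALSE)
  expect_identical(cbfofknn:::mutate_best(state, sphere, lower, upper, ctrl0),
                   state)

  # repeated greedy mutation polishes a 1-D sphere from 0.1 below 1e-4
  set.seed(17)
  st <- state
  for (i in 1:100)
    st <- cbfofknn:::mutate_best(st, sphere, lower, upper, ctrl)
  expect_lt(st$best_cost, 1e-4)
})

test_that("the driver respects its budget structure and determinism", {
  ctrl <- cbfo_control(pop = 4, chemotaxis = 5, reproduction = 2,
                       elimination = 2, swim = 2)
  fit1 <- cbfo(sphere, rep(-5, 2), rep(5, 2), ctrl, seed = 99,
               vectorized = TRUE)
  fit2 <- cbfo(sphere, rep(-5, 2), rep(5, 2), ctrl, seed = 99,
               vectorized = TRUE)
  expect_identical(fit1[c("par", "value", "curve", "evaluations")],
                   fit2[c("par", "value", "curve", "evaluations")])
  # curve: one entry after init plus one per chemotaxis pass
  expect_length(fit1$curve, 1 + 2 * 2 * 5)
  expect_true(all(diff(fit1$curve) <= 0))
  expect_equal(fit1$value, min(fit1$curve))

  # scalar (non-vectorized) objectives agree with the batch path
  fit3 <- cbfo(function(x) sum(x^2), rep(-5, 2), rep(5, 2), ctrl, seed = 99)
  expect_identical(fit3$value, fit1$value)
})

test_that("plain BFO mode (no chaos, no mutation) still optimizes", {
  ctrl <- cbfo_control(pop = 10, chemotaxis = 20, reproduction = 2,
                       elimination = 2, chaos = FALSE, mutation = FALSE)
  fit <- cbfo(sphere, rep(-5, 2), rep(5, 2), ctrl, seed = 4,
              vectorized = TRUE)
  expect_true(all(diff(fit$curve) <= 0))
  expect_lt(fit$value, fit$curve[1])
  expect_lt(fit$value, 0.5)
})

test_that("chaos and mutation improve the sphere best over plain BFO", {
  ctrl_c <- cbfo_control(pop = 8, chemotaxis = 20, reproduction = 2,
                         elimination = 1)
  ctrl_p <- cbfo_control(pop = 8, chemotaxis = 20, reproduction = 2,
                         elimination = 1, chaos = FALSE, mutation = FALSE)
  f18 <- benchmark_function("F18")
  vals <- sapply(1:10, function(s) c(
    cbfo(f18$fn, f18$lower, f18$upper, ctrl_c, seed = s,
         vectorized = TRUE)$value,
    cbfo(f18$fn, f18$lower, f18$upper, ctrl_p, seed = s,
         vectorized = TRUE)$value))
  expect_lte(mean(vals[1, ]), mean(vals[2, ]))
})

test_that("objectives returning non-finite values raise an error", {
  bad <- function(x) rep(NaN, nrow(x))
  expect_error(cbfo(bad, -1, 1, cbfo_control(pop = 2), seed = 1,
                    vectorized = TRUE), "non-finite")
})

test_that("the swarming term attracts without breaking the best record", {
  ctrl <- cbfo_control(pop = 6, chemotaxis = 10, reproduction = 1,
                       elimination = 1, swarming = TRUE)
  fit <- cbfo(sphere, rep(-5, 2), rep(5, 2), ctrl, seed = 8,
              vectorized = TRUE)
  expect_true(all(diff(fit$curve) <= 0))
  expect_equal(fit$value, min(fit$curve))
})
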