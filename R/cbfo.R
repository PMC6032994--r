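# Bacterial foraging optimization with chaotic logistic-map initialization
# and adaptive Gaussian mutation of the incumbent best. Plain BFO is the
# same engine with chaos/mutation switched off.

#' Control parameters for the bacterial foraging optimizer
#'
#' Defaults follow the hyperparameter-tuning profile (population 8,
#' 25 chemotaxis steps, swim length 4, 3 reproduction steps, 2
#' elimination-dispersal events, dispersal probability 0.25, step size 0.1 of
#' the per-dimension range). Use \code{\link{cbfo_benchmark_control}} for the
#' function-optimization profile.
#'
#' @param pop swarm size S (even: reproduction is binary fission).
#' @param chemotaxis chemotaxis passes Nc per reproduction step.
#' @param swim maximum swim steps Ns along an improving tumble direction.
#' @param reproduction reproduction steps Nre per elimination event.
#' @param elimination elimination-dispersal events Ned.
#' @param ped per-bacterium dispersal probability in [0, 1].
#' @param step chemotaxis step length C(i), as a fraction of each
#'   dimension's search range.
#' @param sigma initial scale of the Gaussian mutation of the incumbent best,
#'   as a fraction of each dimension's range; the scale then self-adapts by
#'   the 1/5-success rule. \code{sigma = 0} disables mutation.
#' @param chaos logical: logistic-map chaotic initialization (otherwise
#'   uniform random initialization).
#' @param mutation logical: Gaussian mutation of the incumbent best once per
#'   chemotaxis pass.
#' @param swarming logical: add the classical cell-to-cell attract/repel
#'   term to the cost guiding chemotaxis moves (off by default; the reported
#'   best always uses the raw objective).
#' @return a list of class \code{"cbfo_control"}.
#' @export
cbfo_control <- function(pop = 8L, chemotaxis = 25L, swim = 4L,
                         reproduction = 3L, elimination = 2L, ped = 0.25,
                         step = 0.1, sigma = 0.1, chaos = TRUE,
                         mutation = TRUE, swarming = FALSE) {
  pop <- as.integer(pop)
  if (pop < 2L || pop %% 2L != 0L) stop("pop must be even and >= 2")
  if (chemotaxis < 1L || reproduction < 1L || elimination < 1L)
    stop("chemotaxis, reproduction and elimination counts must be >= 1")
  if (swim < 0L) stop("swim must be >= 0")
  if (ped < 0 || ped > 1) stop("ped must be in [0, 1]")
  if (step <= 0) stop("step must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(pop = pop, chemotaxis = as.integer(chemotaxis),
                 swim = as.integer(swim),
                 reproduction = as.integer(reproduction),
                 elimination = as.integer(elimination), ped = ped,
                 step = step, sigma = sigma, chaos = isTRUE(chaos),
                 mutation = isTRUE(mutation), swarming = isTRUE(swarming)),
            class = "cbfo_control")
}

#' Benchmark-profile optimizer control
#'
#' Population 50 with Ned x Nre x Nc = 2 x 5 x 50 = 500 chemotaxis passes,
#' the budget used for the function-optimization experiments.
#'
#' @param ... overrides passed on to \code{\link{cbfo_control}}.
#' @export
cbfo_benchmark_control <- function(...) {
  args <- list(pop = 50L, chemotaxis = 50L, swim = 4L, reproduction = 5L,
               elimination = 2L, ped = 0.25, step = 0.1, sigma = 0.1)
  args[names(list(...))] <- list(...)
  do.call(cbfo_control, args)
}

#' Logistic-map iteration
#'
#' Iterates \eqn{x_{t+1} = u x_t (1 - x_t)} with u = 4 (fully chaotic
#' regime) and returns the trajectory after the start value.
#'
#' @param x0 start value in (0, 1), excluding the fixed/periodic points
#'   0.25, 0.5, 0.75.
#' @param n number of iterates to produce.
#' @param u control parameter (default 4).
#' @return numeric vector of \code{n} iterates in (0, 1).
#' @examples
#' logistic_map(0.3, 1)  # 0.84
#' @export
logistic_map <- function(x0, n, u = 4) {
  stopifnot(x0 > 0, x0 < 1, n >= 1)
  out <- numeric(n)
  x <- x0
  for (i in seq_len(n)) {
    x <- u * x * (1 - x)
    out[i] <- x
  }
  out
}

#' Chaotic swarm initialization
#'
#' Draws a logistic-map start value uniformly in (0, 1) (excluding 0.25,
#' 0.5, 0.75, which are fixed or periodic under the map), iterates the map to
#' produce S x d chaotic coordinates in (0, 1), and maps each affinely onto
#' its dimension's bounds. Uses the current RNG stream for the start value
#' only; the rest of the sequence is deterministic given it.
#'
#' @param n swarm size.
#' @param lower,upper per-dimension bounds (equal length = dimension).
#' @return n x d matrix of positions inside the bounds.
#' @export
chaotic_init <- function(n, lower, upper) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)))
  repeat {
    x0 <- stats::runif(1)
    if (x0 > 0 && x0 < 1 && !x0 %in% c(0.25, 0.5, 0.75)) break
  }
  seq_raw <- logistic_map(x0, n * d)
  pos <- matrix(seq_raw, n, d)
  sweep(sweep(pos, 2L, upper - lower, "*"), 2L, lower, "+")
}

#' Random tumble direction
#'
#' Draws a vector with components uniform in [-1, 1] and normalizes it to
#' unit Euclidean length (redrawing the measure-zero all-zero case).
#'
#' @param d dimension.
#' @return unit vector of length \code{d}.
#' @export
tumble_direction <- function(d) {
  repeat {
    delta <- stats::runif(d, -1, 1)
    nrm <- sqrt(sum(delta^2))
    if (nrm > 0) return(delta / nrm)
  }
}

# Matrix of n unit tumble directions (rows).
tumble_directions <- function(n, d) {
  delta <- matrix(stats::runif(n * d, -1, 1), n, d)
  nrm <- sqrt(rowSums(delta^2))
  while (any(nrm == 0)) {
    bad <- which(nrm == 0)
    delta[bad, ] <- stats::runif(length(bad) * d, -1, 1)
    nrm[bad] <- sqrt(rowSums(delta[bad, , drop = FALSE]^2))
  }
  delta / nrm
}

# Classical cell-to-cell attract/repel term, evaluated for each row of `at`
# against the swarm `positions`.
swarm_term <- function(at, positions, d_attract = 0.1, w_attract = 0.2,
                       h_repel = 0.1, w_repel = 10) {
  d2 <- dist2_matrix(at, positions)
  rowSums(-d_attract * exp(-w_attract * d2)) +
    rowSums(h_repel * exp(-w_repel * d2))
}

# ---- swarm state -----------------------------------------------------------

new_swarm <- function(fobj, lower, upper, control) {
  d <- length(lower)
  positions <- if (control$chaos) chaotic_init(control$pop, lower, upper)
  else matrix(stats::runif(control$pop * d, rep(lower, each = control$pop),
                           rep(upper, each = control$pop)),
              control$pop, d)
  costs <- fobj(positions)
  if (any(!is.finite(costs))) stop("objective returned a non-finite value")
  best <- which.min(costs)
  list(positions = positions, costs = costs,
       health = numeric(control$pop),
       best_par = positions[best, ], best_cost = costs[best],
       evaluations = control$pop, curve = costs[best],
       sigma = control$sigma)
}

record_best <- function(state) {
  i <- which.min(state$costs)
  if (state$costs[i] < state$best_cost) {
    state$best_cost <- state$costs[i]
    state$best_par <- state$positions[i, ]
  }
  state
}

# One chemotaxis pass: every bacterium tumbles, takes a step of length
# step * range along its unit direction (clamped to the box), then swims in
# the same direction while the move keeps improving, up to `swim` times.
# Costs of every visited position accumulate into the health record.
chemotaxis_pass <- function(state, fobj, lower, upper, control) {
  s <- control$pop
  d <- length(lower)
  range_ <- upper - lower
  guide <- function(pos, raw) {
    if (control$swarming) raw + swarm_term(pos, state$positions) else raw
  }
  delta <- tumble_directions(s, d) *
    matrix(control$step * range_, s, d, byrow = TRUE)
  old_guide <- guide(state$positions, state$costs)
  pos <- clamp_rows(state$positions + delta, lower, upper)
  raw <- fobj(pos)
  if (any(!is.finite(raw))) stop("objective returned a non-finite value")
  state$evaluations <- state$evaluations + s
  state$health <- state$health + raw
  state$positions <- pos
  state$costs <- raw
  last <- guide(pos, raw)
  improving <- last < old_guide
  swims <- 0L
  while (any(improving) && swims < control$swim) {
    idx <- which(improving)
    pos2 <- clamp_rows(state$positions[idx, , drop = FALSE] +
                         delta[idx, , drop = FALSE], lower, upper)
    raw2 <- fobj(pos2)
    if (any(!is.finite(raw2))) stop("objective returned a non-finite value")
    state$evaluations <- state$evaluations + length(idx)
    state$health[idx] <- state$health[idx] + raw2
    state$positions[idx, ] <- pos2
    state$costs[idx] <- raw2
    g2 <- guide(pos2, raw2)
    improving[idx] <- g2 < last[idx]
    last[idx] <- g2
    swims <- swims + 1L
  }
  record_best(state)
}

# Greedy Gaussian mutation of the incumbent best; the proposal scale
# self-adapts by the 1/5-success rule (grow on success, shrink otherwise).
mutate_best <- function(state, fobj, lower, upper, control) {
  if (!control$mutation || control$sigma <= 0) return(state)
  d <- length(lower)
  range_ <- upper - lower
  prop <- clamp(state$best_par + stats::rnorm(d, 0, state$sigma * range_),
                lower, upper)
  val <- fobj(matrix(prop, nrow = 1L))
  state$evaluations <- state$evaluations + 1L
  if (is.finite(val) && val < state$best_cost) {
    state$best_cost <- val
    state$best_par <- prop
    state$sigma <- min(state$sigma * 1.5, 1)
  } else {
    state$sigma <- max(state$sigma * 1.5^(-0.25), 1e-12)
  }
  state
}

# Binary-fission reproduction: the healthier half (lowest accumulated cost,
# ties broken by index) is copied over the weaker half; health resets.
reproduce_swarm <- function(state) {
  s <- length(state$costs)
  ord <- order(state$health, seq_len(s))
  keep <- ord[seq_len(s %/% 2L)]
  idx <- c(keep, keep)
  state$positions <- state$positions[idx, , drop = FALSE]
  state$costs <- state$costs[idx]
  state$health <- numeric(s)
  state
}

# Elimination-dispersal: each bacterium is independently re-placed uniformly
# in the box with probability ped and re-evaluated. The best-so-far record
# never regresses.
eliminate_disperse <- function(state, fobj, lower, upper, control) {
  s <- length(state$costs)
  hit <- stats::runif(s) < control$ped
  if (!any(hit)) return(state)
  d <- length(lower)
  k <- sum(hit)
  state$positions[hit, ] <- matrix(
    stats::runif(k * d, rep(lower, each = k), rep(upper, each = k)), k, d)
  vals <- fobj(state$positions[hit, , drop = FALSE])
  if (any(!is.finite(vals))) stop("objective returned a non-finite value")
  state$evaluations <- state$evaluations + k
  state$costs[hit] <- vals
  record_best(state)
}

# ---- driver ----------------------------------------------------------------

#' Chaotic bacterial foraging optimization
#'
#' Minimizes an objective over a box by bacterial foraging: nested
#' elimination-dispersal, reproduction and chemotaxis loops (Ned x Nre x Nc
#' passes in total), with logistic-map chaotic initialization and a greedy
#' adaptive Gaussian mutation of the incumbent best once per chemotaxis
#' pass. Switching \code{chaos} and \code{mutation} off in the control
#' recovers plain BFO.
#'
#' @param objective function of a numeric vector returning a scalar cost, or
#'   (with \code{vectorized = TRUE}) of a matrix of row points returning a
#'   vector of costs.
#' @param lower,upper finite per-dimension box bounds.
#' @param control a \code{\link{cbfo_control}} object.
#' @param seed optional integer seed; fixing it makes the whole trajectory
#'   bit-reproducible (a single RNG stream drives initialization, tumbles,
#'   mutation and dispersal).
#' @param vectorized logical: objective accepts a matrix of row points.
#' @return an object of class \code{"cbfo"}: list with \code{par},
#'   \code{value}, \code{curve} (best cost after initialization and after
#'   each chemotaxis pass; non-increasing), \code{evaluations} and
#'   \code{control}.
#' @examples
#' f <- benchmark_function("F16")
#' fit <- cbfo(f$fn, f$lower, f$upper, cbfo_benchmark_control(), seed = 1,
#'             vectorized = TRUE)
#' fit$value  # ~ -1.0316
#' @export
cbfo <- function(objective, lower, upper, control = cbfo_control(),
                 seed = NULL, vectorized = FALSE) {
  stopifnot(inherits(control, "cbfo_control"))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower))
    stop("bounds must be finite with upper > lower")
  fobj <- if (vectorized) function(x) as.numeric(objective(x))
  else function(x) vapply(seq_len(nrow(x)),
                          function(i) as.numeric(objective(x[i, ])), 0)
  with_seed(seed, {
    state <- new_swarm(fobj, lower, upper, control)
    for (l in seq_len(control$elimination)) {
      for (k in seq_len(control$reproduction)) {
        for (j in seq_len(control$chemotaxis)) {
          state <- chemotaxis_pass(state, fobj, lower, upper, control)
          state <- mutate_best(state, fobj, lower, upper, control)
          state$curve <- c(state$curve, state$best_cost)
        }
        state <- reproduce_swarm(state)
      }
      state <- eliminate_disperse(state, fobj, lower, upper, control)
      # dispersal may stumble on an improvement; fold it into the record
      state$curve[length(state$curve)] <- state$best_cost
    }
    structure(list(par = state$best_par, value = state$best_cost,
                   curve = state$curve, evaluations = state$evaluations,
                   control = control, seed = seed),
              class = "cbfo")
  })
}

#' @export
print.cbfo <- function(x, ...) {
  cat(sprintf(
    "CBFO fit: best value %.6g at (%s)\n  %d passes, %d evaluations\n",
    x$value, paste(signif(x$par, 6), collapse = ", "),
    length(x$curve) - 1L, x$evaluations))
  invisible(x)
}

#' Convergence-curve plot for a cbfo fit
#'
#' @param x a \code{"cbfo"} object.
#' @param log plot the cost axis on a log scale after shifting so the
#'   minimum maps above zero (useful for positive-cost benchmarks).
#' @param ... passed to \code{plot}.
#' @export
plot.cbfo <- function(x, log = FALSE, ...) {
  y <- x$curve
  ylog <- ""
  if (log && all(y > 0)) ylog <- "y"
  graphics::plot(seq_along(y) - 1L, y, type = "s", log = ylog,
                 xlab = "chemotaxis pass", ylab = "best cost", ...)
  invisible(x)
}

#' Write a convergence curve as a two-column CSV
#'
#' @param fit a \code{"cbfo"} object.
#' @param path output CSV path (columns \code{pass}, \code{best_cost}).
#' @export
write_convergence_csv <- function(fit, path) {
  stopifnot(inherits(fit, "cbfo"))
  utils::write.csv(data.frame(pass = seq_along(fit$curve) - 1L,
                              best_cost = fit$curve),
                   path, row.names = FALSE)
  invisible(path)
}
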