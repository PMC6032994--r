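# The 23 classical benchmark objectives used to validate the optimizer:
# unimodal (F1-F7, default 30-D), multimodal (F8-F13, default 30-D) and
# fixed-dimension multimodal (F14-F23). Evaluators are vectorised over the
# rows of a point matrix, which is what the optimizer's batch chemotaxis
# steps consume.

row_prod <- function(x) {
  p <- rep(1, nrow(x))
  for (j in seq_len(ncol(x))) p <- p * x[, j]
  p
}

row_max <- function(x) {
  m <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, j])
  m
}

# Boundary penalty u(x; a, k, m) used by the two penalised objectives.
u_penalty <- function(x, a, k, m) {
  out <- matrix(0, nrow(x), ncol(x))
  hi <- x > a
  lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  rowSums(out)
}

# Shekel foxholes 25-column coefficient grid (a_ij), columns over a 5x5 lattice.
foxholes_a <- local({
  v <- c(-32, -16, 0, 16, 32)
  rbind(rep(v, times = 5), rep(v, each = 5))
})

kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.16, 0.0844, 0.0627,
               0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

hart3_alpha <- c(1, 1.2, 3, 3.2)
hart3_A <- matrix(c(3, 10, 30,
                    0.1, 10, 35,
                    3, 10, 30,
                    0.1, 10, 35), 4, 3, byrow = TRUE)
hart3_P <- 1e-4 * matrix(c(3689, 1170, 2673,
                           4699, 4387, 7470,
                           1091, 8732, 5547,
                           381, 5743, 8828), 4, 3, byrow = TRUE)

hart6_alpha <- c(1, 1.2, 3, 3.2)
hart6_A <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                    0.05, 10, 17, 0.1, 8, 14,
                    3, 3.5, 1.7, 10, 17, 8,
                    17, 8, 0.05, 10, 0.1, 14), 4, 6, byrow = TRUE)
hart6_P <- 1e-4 * matrix(c(1312, 1696, 5569, 124, 8283, 5886,
                           2329, 4135, 8307, 3736, 1004, 9991,
                           2348, 1451, 3522, 2883, 3047, 6650,
                           4047, 8828, 8732, 5743, 1091, 381), 4, 6, byrow = TRUE)

shekel_a <- matrix(c(4, 4, 4, 4,
                     1, 1, 1, 1,
                     8, 8, 8, 8,
                     6, 6, 6, 6,
                     3, 7, 3, 7,
                     2, 9, 2, 9,
                     5, 5, 3, 3,
                     8, 1, 8, 1,
                     6, 2, 6, 2,
                     7, 3.6, 7, 3.6), 10, 4, byrow = TRUE)
shekel_c <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)

hartmann <- function(x, alpha, A, P) {
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_along(alpha)) {
    e <- numeric(n)
    for (j in seq_len(ncol(A))) e <- e + A[i, j] * (x[, j] - P[i, j])^2
    out <- out - alpha[i] * exp(-e)
  }
  out
}

shekel <- function(x, mterms) {
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(mterms)) {
    d <- numeric(n)
    for (j in 1:4) d <- d + (x[, j] - shekel_a[i, j])^2
    out <- out - 1 / (d + shekel_c[i])
  }
  out
}

# Registry: name, default dimension (NA = fixed), symmetric bound, known minimum,
# and the row-vectorised evaluator. F7's additive noise is injected separately.
benchmark_registry <- list(
  F1 = list(name = "sphere", dim = 30, fixed = FALSE, lower = -100, upper = 100,
            fmin = 0, fn = function(x, ...) rowSums(x^2)),
  F2 = list(name = "abs-sum-plus-product", dim = 30, fixed = FALSE, lower = -10,
            upper = 10, fmin = 0,
            fn = function(x, ...) rowSums(abs(x)) + row_prod(abs(x))),
  F3 = list(name = "rotated-hyper-ellipsoid", dim = 30, fixed = FALSE,
            lower = -100, upper = 100, fmin = 0,
            fn = function(x, ...) {
              s <- numeric(nrow(x)); acc <- numeric(nrow(x))
              for (j in seq_len(ncol(x))) { s <- s + x[, j]; acc <- acc + s^2 }
              acc
            }),
  F4 = list(name = "max-abs", dim = 30, fixed = FALSE, lower = -100, upper = 100,
            fmin = 0, fn = function(x, ...) row_max(abs(x))),
  F5 = list(name = "rosenbrock", dim = 30, fixed = FALSE, lower = -30, upper = 30,
            fmin = 0,
            fn = function(x, ...) {
              out <- numeric(nrow(x))
              for (j in seq_len(ncol(x) - 1L))
                out <- out + 100 * (x[, j + 1L] - x[, j]^2)^2 + (x[, j] - 1)^2
              out
            }),
  F6 = list(name = "step", dim = 30, fixed = FALSE, lower = -100, upper = 100,
            fmin = 0, fn = function(x, ...) rowSums(floor(x + 0.5)^2)),
  F7 = list(name = "noisy-quartic", dim = 30, fixed = FALSE, lower = -1.28,
            upper = 1.28, fmin = 0, noisy = TRUE,
            fn = function(x, rng = stats::runif)
              drop(x^4 %*% seq_len(ncol(x))) + rng(nrow(x))),
  F8 = list(name = "schwefel", dim = 30, fixed = FALSE, lower = -500, upper = 500,
            fmin = -418.9829 * 30, fmin_per_dim = -418.9829,
            fn = function(x, ...) rowSums(-x * sin(sqrt(abs(x))))),
  F9 = list(name = "rastrigin", dim = 30, fixed = FALSE, lower = -5.12,
            upper = 5.12, fmin = 0,
            fn = function(x, ...) rowSums(x^2 - 10 * cos(2 * pi * x) + 10)),
  F10 = list(name = "ackley", dim = 30, fixed = FALSE, lower = -32, upper = 32,
             fmin = 0,
             fn = function(x, ...)
               -20 * exp(-0.2 * sqrt(rowMeans(x^2))) -
                 exp(rowMeans(cos(2 * pi * x))) + 20 + exp(1)),
  F11 = list(name = "griewank", dim = 30, fixed = FALSE, lower = -600,
             upper = 600, fmin = 0,
             fn = function(x, ...) {
               p <- rep(1, nrow(x))
               for (j in seq_len(ncol(x))) p <- p * cos(x[, j] / sqrt(j))
               rowSums(x^2) / 4000 - p + 1
             }),
  F12 = list(name = "penalized-1", dim = 30, fixed = FALSE, lower = -50,
             upper = 50, fmin = 0,
             fn = function(x, ...) {
               n <- ncol(x)
               y <- 1 + (x + 1) / 4
               core <- 10 * sin(pi * y[, 1L])^2 + (y[, n] - 1)^2
               if (n > 1L)
                 for (j in seq_len(n - 1L))
                   core <- core +
                     (y[, j] - 1)^2 * (1 + 10 * sin(pi * y[, j + 1L])^2)
               pi / n * core + u_penalty(x, 10, 100, 4)
             }),
  F13 = list(name = "penalized-2", dim = 30, fixed = FALSE, lower = -50,
             upper = 50, fmin = 0,
             fn = function(x, ...) {
               n <- ncol(x)
               core <- sin(3 * pi * x[, 1L])^2 +
                 (x[, n] - 1)^2 * (1 + sin(2 * pi * x[, n])^2)
               if (n > 1L)
                 for (j in seq_len(n - 1L))
                   core <- core +
                     (x[, j] - 1)^2 * (1 + sin(3 * pi * x[, j + 1L])^2)
               0.1 * core + u_penalty(x, 5, 100, 4)
             }),
  F14 = list(name = "shekel-foxholes", dim = 2, fixed = TRUE, lower = -65,
             upper = 65, fmin = 1,
             fn = function(x, ...) {
               s <- rep(1 / 500, nrow(x))
               for (j in 1:25)
                 s <- s + 1 / (j + (x[, 1L] - foxholes_a[1L, j])^6 +
                                 (x[, 2L] - foxholes_a[2L, j])^6)
               1 / s
             }),
  F15 = list(name = "kowalik", dim = 4, fixed = TRUE, lower = -5, upper = 5,
             fmin = 0.00030,
             fn = function(x, ...) {
               out <- numeric(nrow(x))
               for (i in seq_along(kowalik_a)) {
                 b <- kowalik_b[i]
                 out <- out + (kowalik_a[i] -
                   x[, 1L] * (b^2 + b * x[, 2L]) /
                     (b^2 + b * x[, 3L] + x[, 4L]))^2
               }
               out
             }),
  F16 = list(name = "six-hump-camel", dim = 2, fixed = TRUE, lower = -5,
             upper = 5, fmin = -1.0316,
             fn = function(x, ...)
               4 * x[, 1L]^2 - 2.1 * x[, 1L]^4 + x[, 1L]^6 / 3 +
                 x[, 1L] * x[, 2L] - 4 * x[, 2L]^2 + 4 * x[, 2L]^4),
  F17 = list(name = "branin", dim = 2, fixed = TRUE, lower = -5, upper = 5,
             fmin = 0.398,
             fn = function(x, ...)
               (x[, 2L] - 5.1 / (4 * pi^2) * x[, 1L]^2 +
                  5 / pi * x[, 1L] - 6)^2 +
                 10 * (1 - 1 / (8 * pi)) * cos(x[, 1L]) + 10),
  F18 = list(name = "goldstein-price", dim = 2, fixed = TRUE, lower = -2,
             upper = 2, fmin = 3,
             fn = function(x, ...) {
               x1 <- x[, 1L]; x2 <- x[, 2L]
               (1 + (x1 + x2 + 1)^2 *
                  (19 - 14 * x1 + 3 * x1^2 - 14 * x2 + 6 * x1 * x2 + 3 * x2^2)) *
                 (30 + (2 * x1 - 3 * x2)^2 *
                    (18 - 32 * x1 + 12 * x1^2 + 48 * x2 - 36 * x1 * x2 +
                       27 * x2^2))
             }),
  F19 = list(name = "hartmann-3", dim = 3, fixed = TRUE, lower = 0, upper = 1,
             fmin = -3.86,
             fn = function(x, ...) hartmann(x, hart3_alpha, hart3_A, hart3_P)),
  F20 = list(name = "hartmann-6", dim = 6, fixed = TRUE, lower = 0, upper = 1,
             fmin = -3.32,
             fn = function(x, ...) hartmann(x, hart6_alpha, hart6_A, hart6_P)),
  F21 = list(name = "shekel-5", dim = 4, fixed = TRUE, lower = 0, upper = 10,
             fmin = -10.1532, fn = function(x, ...) shekel(x, 5L)),
  F22 = list(name = "shekel-7", dim = 4, fixed = TRUE, lower = 0, upper = 10,
             fmin = -10.4028, fn = function(x, ...) shekel(x, 7L)),
  F23 = list(name = "shekel-10", dim = 4, fixed = TRUE, lower = 0, upper = 10,
             fmin = -10.5363, fn = function(x, ...) shekel(x, 10L))
)

#' Benchmark objective registry
#'
#' @return character vector of the available benchmark ids, \code{"F1"} to
#'   \code{"F23"}.
#' @export
benchmark_ids <- function() names(benchmark_registry)

#' Construct a benchmark objective
#'
#' Builds one of the 23 classical optimizer test functions: unimodal
#' (F1--F7), multimodal (F8--F13) -- both 30-dimensional by default with the
#' dimension reducible for cheap testing -- and fixed-dimension multimodal
#' (F14--F23: Shekel's foxholes, Kowalik, six-hump camel-back, Branin,
#' Goldstein--Price, the two Hartmann functions and the three Shekel
#' functions).
#'
#' @param id benchmark id, one of \code{benchmark_ids()}.
#' @param dim dimension override for the scalable functions F1--F13; the
#'   fixed-dimension functions reject overrides.
#' @return an object of class \code{"benchfun"}: a list with \code{id},
#'   \code{name}, \code{dim}, \code{lower}/\code{upper} (per-dimension bound
#'   vectors), \code{fmin} (the tabulated best value) and \code{fn}, an
#'   evaluator vectorised over the rows of a point matrix.
#' @examples
#' f <- benchmark_function("F16")
#' f$fn(rbind(c(0, 0), c(1, 1)))
#' @export
benchmark_function <- function(id, dim = NULL) {
  spec <- benchmark_registry[[match.arg(id, benchmark_ids())]]
  if (is.null(spec)) stop("unknown benchmark id: ", id)
  d <- spec$dim
  if (!is.null(dim)) {
    if (spec$fixed && dim != spec$dim)
      stop(id, " has fixed dimension ", spec$dim)
    d <- as.integer(dim)
    if (d < 1L) stop("dim must be >= 1")
  }
  fmin <- spec$fmin
  if (!is.null(spec$fmin_per_dim)) fmin <- spec$fmin_per_dim * d
  structure(list(
    id = id, name = spec$name, dim = d,
    lower = rep(spec$lower, d), upper = rep(spec$upper, d),
    fmin = fmin, noisy = isTRUE(spec$noisy), fn = spec$fn
  ), class = "benchfun")
}

#' @export
print.benchfun <- function(x, ...) {
  cat(sprintf("Benchmark %s (%s): %d-D, bounds [%g, %g], f_min = %g\n",
              x$id, x$name, x$dim, x$lower[1L], x$upper[1L], x$fmin))
  invisible(x)
}

#' Benchmark metadata table
#'
#' @return data frame with one row per benchmark: id, name, dimension,
#'   per-dimension bounds and tabulated minimum.
#' @export
benchmark_table <- function() {
  rows <- lapply(benchmark_ids(), function(id) {
    f <- benchmark_function(id)
    data.frame(id = id, name = f$name, dim = f$dim, lower = f$lower[1L],
               upper = f$upper[1L], fmin = f$fmin, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a benchmark objective with input-contract checks
#'
#' @param f a \code{"benchfun"} object or a benchmark id.
#' @param x numeric vector (a single point) or matrix of row points.
#' @param rng random source for the additive noise term of F7: a function
#'   \code{n -> n} uniform variates in \code{[0, 1)}. Ignored by the other
#'   functions; stub it (e.g. \code{function(n) numeric(n)}) for determinism.
#' @return numeric vector of objective values, one per row point.
#' @export
bench_evaluate <- function(f, x, rng = stats::runif) {
  if (is.character(f)) f <- benchmark_function(f)
  stopifnot(inherits(f, "benchfun"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != f$dim)
    stop(f$id, " expects dimension ", f$dim, ", got ", ncol(x))
  if (any(!is.finite(x))) stop("non-finite point")
  for (j in seq_len(ncol(x)))
    if (any(x[, j] < f$lower[j] | x[, j] > f$upper[j]))
      stop("point outside bounds in dimension ", j)
  f$fn(x, rng = rng)
}

#' Deterministic reference minimum of a benchmark objective
#'
#' Dense-grid scan over the box followed by Nelder--Mead polish of the best
#' grid cells; bit-reproducible for fixed settings. For dimensions where a
#' grid would exceed the point budget, a fixed multistart pattern (box centre
#' and axis offsets) replaces the scan.
#'
#' @param f a \code{"benchfun"} object or id.
#' @param grid_density grid points per dimension; default picks a density
#'   filling the point budget.
#' @param refine_starts number of best grid points polished by Nelder--Mead.
#' @param budget maximum number of grid evaluations allowed.
#' @return list with \code{par} (argmin found) and \code{value}.
#' @examples
#' reference_minimum("F16")$value  # ~ -1.0316
#' @export
reference_minimum <- function(f, grid_density = NULL, refine_starts = 15L,
                              budget = 2e6) {
  if (is.character(f)) f <- benchmark_function(f)
  stopifnot(inherits(f, "benchfun"))
  d <- f$dim
  no_noise <- function(n) numeric(n)
  if (!is.null(grid_density) && grid_density^d > budget)
    stop("grid of ", grid_density, "^", d, " points exceeds the budget")
  if (is.null(grid_density))
    grid_density <- max(2L, min(400L, floor(budget^(1 / d))))
  if (grid_density^d <= budget && d <= 6L) {
    axes <- lapply(seq_len(d), function(j)
      seq(f$lower[j], f$upper[j], length.out = grid_density))
    grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    dimnames(grid) <- NULL
    vals <- f$fn(grid, rng = no_noise)
    starts <- grid[order(vals)[seq_len(min(refine_starts, nrow(grid)))], ,
                   drop = FALSE]
    best_val <- min(vals)
    best_par <- grid[which.min(vals), ]
  } else {
    centre <- (f$lower + f$upper) / 2
    starts <- rbind(centre,
                    centre + 0.25 * (f$upper - f$lower),
                    centre - 0.25 * (f$upper - f$lower))
    best_val <- Inf
    best_par <- centre
  }
  obj <- function(p) f$fn(matrix(clamp(p, f$lower, f$upper), nrow = 1L),
                          rng = no_noise)
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    # one restart helps Nelder-Mead out of premature collapse
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best_val) {
      best_val <- fit$value
      best_par <- clamp(fit$par, f$lower, f$upper)
    }
  }
  list(par = unname(best_par), value = unname(best_val))
}
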