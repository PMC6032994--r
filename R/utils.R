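# Internal helpers shared across the package.

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Clamp every row of a matrix to per-dimension box bounds.
clamp_rows <- function(x, lower, upper) {
  for (j in seq_len(ncol(x))) x[, j] <- clamp(x[, j], lower[j], upper[j])
  x
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `nfolds` cross-validation folds so that
#' per-class counts differ by at most one across folds. Randomness is drawn
#' from the current RNG stream, so fold construction is reproducible under
#' \code{set.seed()}.
#'
#' @param y class labels (factor or coercible to one).
#' @param nfolds number of folds.
#' @return integer vector of fold ids in \code{1:nfolds}, one per observation.
#' @export
stratified_folds <- function(y, nfolds) {
  y <- as.factor(y)
  if (nfolds < 2) stop("nfolds must be >= 2")
  if (any(table(y) < nfolds))
    stop("stratification infeasible: a class has fewer samples than folds")
  fold <- integer(length(y))
  offset <- sample.int(nfolds, 1L) - 1L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    # rotate the fold cycle per class so small classes don't pile into fold 1
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% nfolds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# Coerce a feature table to a numeric matrix with a helpful error.
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (!is.numeric(x)) stop("features must be numeric")
  storage.mode(x) <- "double"
  x
}
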