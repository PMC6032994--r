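# Synthetic two-class feature tables shaped like per-recording vocal
# measurement datasets: class imbalance, correlated feature blocks (the
# jitter/shimmer families move together) and a controllable class
# separation. Plus readers/writers for the common CSV dialects.

#' Specification of a synthetic two-class dataset
#'
#' Class-conditional Gaussian model: features are grouped into equicorrelated
#' blocks (emulating families of highly correlated perturbation measures);
#' the first \code{n_informative} features are shifted upwards by
#' \code{effect_size} standard deviations in the positive class.
#'
#' @param n_positive,n_negative class sample counts.
#' @param n_features number of features.
#' @param n_informative number of mean-shifted features
#'   (<= \code{n_features}).
#' @param effect_size standardized mean shift per informative feature.
#' @param block_correlation within-block correlation, in [0, 1).
#' @param block_size features per correlated block.
#' @param seed RNG seed used by \code{\link{generate_dataset}}.
#' @return list of class \code{"dataset_spec"}.
#' @export
dataset_spec <- function(n_positive, n_negative, n_features,
                         n_informative = n_features, effect_size = 1,
                         block_correlation = 0.5, block_size = 4L,
                         seed = 1L) {
  if (n_positive < 1L || n_negative < 1L || n_features < 1L)
    stop("counts must be positive")
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features")
  if (block_correlation < 0 || block_correlation >= 1)
    stop("block_correlation must lie in [0, 1)")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 block_correlation = block_correlation,
                 block_size = as.integer(block_size),
                 seed = seed),
            class = "dataset_spec")
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic two-class dataset spec: %d positive / %d negative, ",
    "%d features\n  informative: %d (effect size %.3g), blocks of %d ",
    "(rho = %.2f), seed %s\n"),
    x$n_positive, x$n_negative, x$n_features, x$n_informative,
    x$effect_size, x$block_size, x$block_correlation, format(x$seed)))
  invisible(x)
}

#' Preset emulating the Oxford-style vocal dataset shape
#'
#' 147 positive (patient) and 48 negative (control) recordings with 22
#' features: the per-recording class ratio of the classic sustained-vowel
#' Parkinson's table.
#'
#' @param ... overrides passed to \code{\link{dataset_spec}}.
#' @export
oxford_like <- function(...) {
  args <- list(n_positive = 147L, n_negative = 48L, n_features = 22L,
               effect_size = 1, block_correlation = 0.6, block_size = 4L)
  args[names(list(...))] <- list(...)
  do.call(dataset_spec, args)
}

#' Preset emulating the Istanbul-style vocal dataset shape
#'
#' 192 positive and 96 negative sustained-vowel samples with 26 features.
#'
#' @param ... overrides passed to \code{\link{dataset_spec}}.
#' @export
istanbul_like <- function(...) {
  args <- list(n_positive = 192L, n_negative = 96L, n_features = 26L,
               effect_size = 1, block_correlation = 0.6, block_size = 5L)
  args[names(list(...))] <- list(...)
  do.call(dataset_spec, args)
}

#' Generate a synthetic two-class feature table
#'
#' Deterministic under \code{spec$seed} (the caller's RNG state is
#' preserved). Within each block of \code{block_size} consecutive features
#' the correlation is \code{block_correlation}; across blocks features are
#' independent. Informative features have unit variance and a between-class
#' mean difference of \code{effect_size}.
#'
#' @param spec a \code{\link{dataset_spec}}.
#' @return list with \code{x} (numeric matrix, columns \code{V1..Vd}) and
#'   \code{y} (factor with levels \code{"healthy"}, \code{"pd"};
#'   \code{"pd"} is the positive class).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$n_positive + spec$n_negative
  d <- spec$n_features
  rho <- spec$block_correlation
  with_seed(spec$seed, {
    x <- matrix(0, n, d)
    j <- 1L
    while (j <= d) {
      b <- min(spec$block_size, d - j + 1L)
      # equicorrelated block via a shared factor:
      # x = sqrt(rho) z0 + sqrt(1 - rho) z_i has unit variance, corr rho
      z0 <- stats::rnorm(n)
      z <- matrix(stats::rnorm(n * b), n, b)
      x[, j:(j + b - 1L)] <- sqrt(rho) * z0 + sqrt(1 - rho) * z
      j <- j + b
    }
    y <- factor(rep(c("pd", "healthy"),
                    c(spec$n_positive, spec$n_negative)),
                levels = c("healthy", "pd"))
    if (spec$n_informative > 0L)
      x[y == "pd", seq_len(spec$n_informative)] <-
        x[y == "pd", seq_len(spec$n_informative)] + spec$effect_size
    colnames(x) <- paste0("V", seq_len(d))
    list(x = x, y = y)
  })
}

#' Read a two-class feature CSV
#'
#' Dialects: \code{"oxford"} (a \code{name} identifier column, 22 numeric
#' feature columns, a 0/1 \code{status} label), \code{"istanbul"} (numeric
#' feature columns with the label in the last column) and \code{"generic"}
#' (same as istanbul: last column is the label).
#'
#' @param path CSV file path.
#' @param dialect one of \code{"generic"}, \code{"oxford"},
#'   \code{"istanbul"}.
#' @return list with \code{x} (numeric matrix) and \code{y} (factor with
#'   levels \code{"healthy"}, \code{"pd"}; label 1 maps to \code{"pd"}).
#' @export
read_feature_csv <- function(path,
                             dialect = c("generic", "oxford", "istanbul")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "oxford") {
    if (!"status" %in% names(df)) stop("oxford dialect needs a 'status' column")
    label <- df$status
    drop_cols <- c("name", "status")
    feat <- df[, setdiff(names(df), drop_cols), drop = FALSE]
  } else {
    if (ncol(df) < 2L) stop("need at least one feature column plus a label")
    label <- df[[ncol(df)]]
    feat <- df[, -ncol(df), drop = FALSE]
  }
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v))) {
        row <- which(is.na(num) & !is.na(v))[1L]
        stop(sprintf("non-numeric feature cell at row %d, column '%s': %s",
                     row, names(feat)[j], v[row]))
      }
      feat[[j]] <- num
    }
  }
  lab_num <- suppressWarnings(as.numeric(label))
  if (any(is.na(lab_num)))
    stop("label column must be numeric 0/1")
  y <- factor(ifelse(lab_num > 0, "pd", "healthy"),
              levels = c("healthy", "pd"))
  list(x = as.matrix(feat), y = y)
}

#' Write a two-class feature CSV
#'
#' Inverse of \code{\link{read_feature_csv}}: the round trip is lossless to
#' full double precision.
#'
#' @param x feature matrix.
#' @param y labels (factor; the positive level is written as 1).
#' @param path output path.
#' @param dialect output dialect (see \code{\link{read_feature_csv}}).
#' @param positive level written as 1 (default: last level).
#' @export
write_feature_csv <- function(x, y, path,
                              dialect = c("generic", "oxford", "istanbul"),
                              positive = NULL) {
  dialect <- match.arg(dialect)
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  if (is.null(positive)) positive <- levels(y)[nlevels(y)]
  status <- as.integer(y == positive)
  df <- as.data.frame(x)
  if (is.null(colnames(x))) names(df) <- paste0("V", seq_len(ncol(x)))
  if (dialect == "oxford") {
    df <- cbind(name = sprintf("rec%04d", seq_len(nrow(df))), df,
                status = status)
  } else {
    df$status <- status
  }
  # 17 significant digits round-trip doubles exactly through text
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max scaling fitted on a training table
#'
#' Per-feature affine map sending the training minimum/maximum to 0/1;
#' constant features map to 0. The map is applied unchanged to
#' \code{newdata}, whose values may fall outside [0, 1] and are not clipped
#' (no information from held-out data enters the fit).
#'
#' @param train training feature matrix (the fit data).
#' @param newdata optional matrix to transform with the training map.
#' @return list with \code{train}, \code{newdata} (or NULL), and the fitted
#'   \code{min}/\code{range} vectors.
#' @export
scale_minmax <- function(train, newdata = NULL) {
  train <- as_feature_matrix(train)
  if (nrow(train) == 0L) stop("empty training table")
  mins <- apply(train, 2L, min)
  rng <- apply(train, 2L, max) - mins
  scale_one <- function(tab) {
    tab <- sweep(tab, 2L, mins, "-")
    for (j in seq_len(ncol(tab)))
      tab[, j] <- if (rng[j] > 0) tab[, j] / rng[j] else 0
    tab
  }
  out <- list(train = scale_one(train), newdata = NULL,
              min = mins, range = rng)
  if (!is.null(newdata)) {
    newdata <- as_feature_matrix(newdata)
    if (ncol(newdata) != ncol(train)) stop("feature counts differ")
    out$newdata <- scale_one(newdata)
  }
  out
}
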