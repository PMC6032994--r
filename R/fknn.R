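# Fuzzy k-nearest-neighbour classifier with Keller-style constrained
# training memberships and distance-weighted fuzzy voting.

#' Constrained fuzzy class memberships for training patterns
#'
#' Keller's constrained assignment: each training pattern receives membership
#' 0.51 + 0.49 * n_own/K in its own class and 0.49 * n_j/K in every other
#' class j, where n_j counts the pattern's K nearest training neighbours
#' (Euclidean distance, the pattern itself excluded) that belong to class j.
#' Rows sum to one by construction.
#'
#' @param x numeric feature matrix (rows = training patterns).
#' @param y class labels (factor or coercible).
#' @param k_init neighbourhood size K used for the assignment.
#' @return n x C membership matrix with columns named by class level.
#' @export
fuzzy_memberships <- function(x, y, k_init) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes")
  if (k_init < 1L || k_init > n - 1L)
    stop("k_init must be in [1, n - 1]")
  d2 <- dist2_matrix(x, x)
  u <- matrix(0, n, nlevels(y), dimnames = list(NULL, levels(y)))
  yi <- as.integer(y)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))      # stable: ties by training index
    ord <- ord[ord != i][seq_len(k_init)]  # exclude the pattern itself
    counts <- tabulate(yi[ord], nbins = nlevels(y))
    u[i, ] <- counts / k_init * 0.49
    u[i, yi[i]] <- u[i, yi[i]] + 0.51
  }
  u
}

# Squared Euclidean cross-distance matrix (rows of a vs rows of b).
dist2_matrix <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Fit a fuzzy k-nearest-neighbour classifier
#'
#' Stores the training data together with constrained fuzzy class memberships
#' (see \code{\link{fuzzy_memberships}}). Prediction takes the k nearest
#' training patterns of a query and averages their membership rows with
#' weights \eqn{w_j = \|x - x_j\|^{-2/(m-1)}}; the crisp class is the argmax
#' membership with ties broken towards the lower class index.
#'
#' @param x numeric feature matrix, one row per training pattern.
#' @param y class labels (factor or coercible; at least two classes).
#' @param k prediction neighbourhood size (integer, 1 <= k <= n).
#' @param m fuzzy strength (> 1); small m concentrates the vote on the
#'   nearest neighbour, large m flattens the weights towards an unweighted
#'   mean of the k membership rows.
#' @param k_init neighbourhood size for the training-membership assignment
#'   (at most n - 1: the pattern itself is excluded); defaults to
#'   \code{min(k, n - 1)}.
#' @param memberships optional precomputed n x C membership matrix (rows must
#'   sum to one); overrides \code{k_init}.
#' @return an object of class \code{"fknn"}.
#' @examples
#' fit <- fknn(iris[, 1:4], iris$Species, k = 3, m = 2)
#' predict(fit, iris[1:5, 1:4])
#' @export
fknn <- function(x, y, k = 1L, m = 2, k_init = NULL, memberships = NULL) {
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (m <= 1) stop("fuzzy strength m must be > 1")
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in [1, n]")
  if (is.null(k_init)) k_init <- min(k, n - 1L)
  if (is.null(memberships)) {
    memberships <- fuzzy_memberships(x, y, k_init)
  } else {
    memberships <- as.matrix(memberships)
    if (nrow(memberships) != n || ncol(memberships) != nlevels(y))
      stop("membership matrix has wrong shape")
    if (max(abs(rowSums(memberships) - 1)) > 1e-8)
      stop("membership rows must sum to 1")
  }
  structure(list(x = x, y = y, u = memberships, k = k, m = m,
                 k_init = as.integer(k_init), levels = levels(y)),
            class = "fknn")
}

#' Predict method for fknn models
#'
#' @param object a fitted \code{"fknn"} model.
#' @param newdata feature matrix of query points (or a single vector).
#' @param type \code{"class"} for crisp labels, \code{"membership"} for the
#'   per-class fuzzy membership matrix (rows sum to one).
#' @param ... unused.
#' @return factor of predicted classes, or a membership matrix.
#' @export
predict.fknn <- function(object, newdata,
                         type = c("class", "membership"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata) && !is.data.frame(newdata))
    newdata <- matrix(newdata, nrow = 1L)  # bare vector = one query point
  q <- as_feature_matrix(newdata)
  if (ncol(q) != ncol(object$x))
    stop("newdata has ", ncol(q), " features, model expects ", ncol(object$x))
  u <- fknn_membership_matrix(object$x, object$u, q, object$k, object$m)
  colnames(u) <- object$levels
  if (type == "membership") return(u)
  cls <- max.col(u, ties.method = "first")  # ties -> lowest class index
  factor(object$levels[cls], levels = object$levels)
}

# Core fuzzy vote. Zero-distance rule: if any of the k neighbours lies within
# sqrt(1e-12) of the query, the result is the plain average of the membership
# rows of those coincident neighbours (the continuous limit of the weighted
# vote as a distance tends to zero).
fknn_membership_matrix <- function(xtr, utr, q, k, m) {
  d2 <- dist2_matrix(q, xtr)
  n <- nrow(xtr)
  expo <- 1 / (m - 1)          # weights (1/d)^(2/(m-1)) = (d^2)^(-1/(m-1))
  out <- matrix(0, nrow(q), ncol(utr))
  for (i in seq_len(nrow(q))) {
    ord <- order(d2[i, ], seq_len(n))[seq_len(k)]
    dd <- d2[i, ord]
    zero <- dd < 1e-12
    if (any(zero)) {
      out[i, ] <- colMeans(utr[ord[zero], , drop = FALSE])
    } else {
      w <- dd^(-expo)
      w <- w / sum(w)
      out[i, ] <- drop(w %*% utr[ord, , drop = FALSE])
    }
  }
  out
}

#' @export
print.fknn <- function(x, ...) {
  cat(sprintf("Fuzzy k-NN classifier: n = %d, d = %d, classes = %s\n",
              nrow(x$x), ncol(x$x), paste(x$levels, collapse = "/")))
  cat(sprintf("  k = %d, m = %.4g (membership K = %d)\n", x$k, x$m, x$k_init))
  invisible(x)
}

#' @export
summary.fknn <- function(object, ...) {
  tab <- table(object$y)
  cat("Fuzzy k-NN classifier\n")
  cat(sprintf("  training patterns: %d (%s)\n", nrow(object$x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  features: %d\n", ncol(object$x)))
  cat(sprintf("  k = %d, m = %.4g\n", object$k, object$m))
  cat(sprintf("  mean own-class membership: %.4f\n",
              mean(object$u[cbind(seq_along(object$y),
                                  as.integer(object$y))])))
  invisible(object)
}

#' @export
coef.fknn <- function(object, ...) c(k = object$k, m = object$m)

#' Serialize an fknn model to a plain-text descriptor
#'
#' Writes hyperparameters, class levels, training features, labels and the
#' membership matrix as a readable key-value/TSV file so a fit can be rebuilt
#' without binary artefacts.
#'
#' @param model a fitted \code{"fknn"} model.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fknn <- function(model, path) {
  stopifnot(inherits(model, "fknn"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("k\t%d", model$k),
    sprintf("m\t%.17g", model$m),
    sprintf("k_init\t%d", model$k_init),
    sprintf("levels\t%s", paste(model$levels, collapse = ",")),
    sprintf("n\t%d", nrow(model$x)),
    sprintf("d\t%d", ncol(model$x))
  ), con)
  write_block <- function(tag, mat) {
    writeLines(paste0("[", tag, "]"), con)
    utils::write.table(format(mat, digits = 17, trim = TRUE), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  write_block("features", model$x)
  writeLines("[labels]", con)
  writeLines(as.character(model$y), con)
  write_block("memberships", model$u)
  invisible(path)
}

#' Rebuild an fknn model from a plain-text descriptor
#'
#' @param path file written by \code{\link{write_fknn}}.
#' @return an object of class \code{"fknn"}.
#' @export
read_fknn <- function(path) {
  lines <- readLines(path)
  kv <- function(key) strsplit(grep(paste0("^", key, "\t"), lines,
                                    value = TRUE)[1L], "\t")[[1L]][2L]
  n <- as.integer(kv("n")); d <- as.integer(kv("d"))
  levs <- strsplit(kv("levels"), ",")[[1L]]
  block <- function(tag, nrows, ncols) {
    at <- which(lines == paste0("[", tag, "]"))
    body <- lines[(at + 1L):(at + nrows)]
    matrix(as.numeric(unlist(strsplit(body, "\t"))), nrows, ncols,
           byrow = TRUE)
  }
  x <- block("features", n, d)
  lab_at <- which(lines == "[labels]")
  y <- factor(lines[(lab_at + 1L):(lab_at + n)], levels = levs)
  u <- block("memberships", n, length(levs))
  fknn(x, y, k = as.integer(kv("k")), m = as.numeric(kv("m")),
       k_init = as.integer(kv("k_init")), memberships = u)
}
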