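# Nested stratified cross-validation: the optimizer tunes (k, m) on inner
# stratified folds by classification error; the outer folds report accuracy,
# AUC, sensitivity and specificity with the tuned pair.

#' Decode an optimizer position into (k, m)
#'
#' The optimizer searches a continuous 2-D box; the first coordinate rounds
#' to the integer neighbourhood size k (clamped to [1, k_max]), the second is
#' the fuzzy strength m clamped to [1.01, m_max] (m must exceed 1).
#'
#' @param raw numeric length-2 optimizer position.
#' @param k_max upper bound for k.
#' @param m_max upper bound for m.
#' @return named numeric vector \code{c(k =, m =)}.
#' @export
decode_position <- function(raw, k_max, m_max = 10) {
  stopifnot(length(raw) == 2L)
  c(k = clamp(round(raw[[1L]]), 1, k_max),
    m = clamp(raw[[2L]], 1.01, m_max))
}

#' Inner cross-validated error rate of an FKNN parameter pair
#'
#' Average misclassification rate of \code{fknn(k, m)} over stratified inner
#' folds: the fitness that drives hyperparameter tuning.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param k,m FKNN hyperparameters (k is clamped to the fold training size
#'   minus one when necessary).
#' @param folds number of stratified folds (assignment drawn from the
#'   current RNG stream), or an explicit fold-assignment integer vector.
#' @return mean error rate in [0, 1].
#' @export
inner_fitness <- function(x, y, k, m, folds = 5L) {
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  assign_ <- if (length(folds) == 1L) stratified_folds(y, folds) else folds
  errs <- vapply(sort(unique(assign_)), function(f) {
    tr <- assign_ != f
    if (nlevels(droplevels(y[tr])) < 2L)
      stop("a fold training split lost a class")
    k_eff <- min(k, sum(tr) - 1L)
    fit <- fknn(x[tr, , drop = FALSE], y[tr], k = k_eff, m = m)
    mean(predict(fit, x[!tr, , drop = FALSE]) != y[!tr])
  }, 0)
  mean(errs)
}

# Precomputed per-fold neighbour structures so the tuner can evaluate many
# (k, m) pairs without re-sorting distances. For each fold: the training
# patterns' neighbour order (self excluded) with per-class cumulative
# counts, and the test patterns' sorted squared distances/neighbour order.
build_fitness_cache <- function(x, y, assign_) {
  lapply(sort(unique(assign_)), function(f) {
    tr <- which(assign_ != f)
    te <- which(assign_ == f)
    xtr <- x[tr, , drop = FALSE]
    ytr <- y[tr]
    if (nlevels(droplevels(ytr)) < 2L)
      stop("a fold training split lost a class")
    ntr <- length(tr)
    d2 <- dist2_matrix(xtr, xtr)
    ord <- t(vapply(seq_len(ntr), function(i) {
      o <- order(d2[i, ], seq_len(ntr))
      o[o != i]
    }, integer(ntr - 1L)))
    # cumulative count of class-c patterns among the first K neighbours
    cum <- lapply(seq_len(nlevels(y)), function(c) {
      ind <- matrix(as.integer(ytr)[ord] == c, ntr, ntr - 1L)
      t(apply(ind, 1L, cumsum))
    })
    d2_te <- dist2_matrix(x[te, , drop = FALSE], xtr)
    ord_te <- t(vapply(seq_len(length(te)), function(i)
      order(d2_te[i, ], seq_len(ntr)), integer(ntr)))
    d2_sorted <- t(vapply(seq_len(length(te)), function(i)
      d2_te[i, ord_te[i, ]], numeric(ntr)))
    list(ytr = as.integer(ytr), yte = as.integer(y[te]), ntr = ntr,
         ord = ord, cum = cum, ord_te = ord_te, d2_sorted = d2_sorted,
         nlev = nlevels(y))
  })
}

# Error rate of (k, m) on one cached fold; same arithmetic as predict.fknn.
cached_fold_error <- function(fc, k, m) {
  k <- min(k, fc$ntr - 1L)
  u <- matrix(0, fc$ntr, fc$nlev)
  for (c in seq_len(fc$nlev)) u[, c] <- fc$cum[[c]][, k] / k * 0.49
  u[cbind(seq_len(fc$ntr), fc$ytr)] <-
    u[cbind(seq_len(fc$ntr), fc$ytr)] + 0.51
  nte <- nrow(fc$ord_te)
  neigh <- fc$ord_te[, seq_len(k), drop = FALSE]
  dd <- fc$d2_sorted[, seq_len(k), drop = FALSE]
  w <- dd^(-1 / (m - 1))
  zero_rows <- which(dd[, 1L] < 1e-12)
  w <- w / rowSums(w)
  scores <- matrix(0, nte, fc$nlev)
  for (c in seq_len(fc$nlev)) {
    uc <- matrix(u[neigh, c], nte, k)
    scores[, c] <- rowSums(w * uc)
  }
  for (i in zero_rows) {
    zn <- neigh[i, dd[i, ] < 1e-12]
    scores[i, ] <- colMeans(u[zn, , drop = FALSE])
  }
  pred <- max.col(scores, ties.method = "first")
  mean(pred != fc$yte)
}

cached_fitness <- function(cache, k, m)
  mean(vapply(cache, cached_fold_error, 0, k = k, m = m))

#' Tune (k, m) on a training set by bacterial foraging
#'
#' Runs \code{\link{cbfo}} over the continuous (k, m) box, with the inner
#' stratified cross-validated error rate as fitness (folds fixed once, so
#' the objective is deterministic during the search).
#'
#' @param x training feature matrix (already scaled).
#' @param y training labels.
#' @param control a \code{\link{cbfo_control}}.
#' @param k_max upper bound for k; default \code{min(50, n - 1)}.
#' @param m_max upper bound for the fuzzy strength (default 10).
#' @param inner_folds number of inner stratified folds (default 5).
#' @param seed optional seed making fold assignment and the search
#'   reproducible.
#' @return list with \code{k}, \code{m}, \code{fitness} (inner error rate of
#'   the selected pair), \code{folds} (assignment used) and \code{fit} (the
#'   \code{"cbfo"} object).
#' @export
tune_fold <- function(x, y, control = cbfo_control(), k_max = NULL,
                      m_max = 10, inner_folds = 5L, seed = NULL) {
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (is.null(k_max)) k_max <- min(50L, nrow(x) - 1L)
  with_seed(seed, {
    assign_ <- stratified_folds(y, inner_folds)
    cache <- build_fitness_cache(x, y, assign_)
    objective <- function(v) {
      p <- decode_position(v, k_max, m_max)
      cached_fitness(cache, p[["k"]], p[["m"]])
    }
    fit <- cbfo(objective, lower = c(1, 1.01), upper = c(k_max, m_max),
                control = control)
    p <- decode_position(fit$par, k_max, m_max)
    list(k = as.integer(p[["k"]]), m = p[["m"]], fitness = fit$value,
         folds = assign_, fit = fit)
  })
}

#' Nested stratified cross-validation of the tuned FKNN classifier
#'
#' For each outer stratified fold: min-max scaling is fitted on the outer
#' training split only, (k, m) is tuned by \code{\link{tune_fold}} on that
#' split via inner stratified folds, an FKNN with the selected pair is fitted
#' on the whole split, and accuracy, AUC, sensitivity and specificity are
#' measured on the held-out fold. The held-out data never reaches the tuner.
#'
#' @param x feature matrix.
#' @param y binary class labels; \code{positive} names the "case" level.
#' @param positive the positive-class level (default: last level).
#' @param outer_folds,inner_folds fold counts (default 10 and 5).
#' @param control optimizer control for the tuner.
#' @param k_max,m_max bounds of the (k, m) search box.
#' @param seed optional seed; a fixed seed makes the whole run
#'   bit-reproducible.
#' @return object of class \code{"nested_cv"}: \code{records} (per-fold
#'   data frame with ACC/Sen/Spec in percent, AUC in [0,1], selected k and
#'   m), plus the per-fold train/test index lists and settings.
#' @export
nested_cv <- function(x, y, positive = NULL, outer_folds = 10L,
                      inner_folds = 5L, control = cbfo_control(),
                      k_max = NULL, m_max = 10, seed = NULL) {
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("nested_cv expects a binary outcome")
  if (is.null(positive)) positive <- levels(y)[nlevels(y)]
  if (!positive %in% levels(y)) stop("unknown positive level")
  with_seed(seed, {
    assign_ <- stratified_folds(y, outer_folds)
    splits <- vector("list", outer_folds)
    rows <- vector("list", outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- which(assign_ != f)
      te <- which(assign_ == f)
      if (nlevels(droplevels(y[tr])) < 2L)
        stop("an outer training split lost a class")
      sc <- scale_minmax(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      tuned <- tune_fold(sc$train, y[tr], control = control, k_max = k_max,
                         m_max = m_max, inner_folds = inner_folds)
      fit <- fknn(sc$train, y[tr], k = tuned$k, m = tuned$m)
      memb <- predict(fit, sc$newdata, type = "membership")
      pred <- factor(levels(y)[max.col(memb, ties.method = "first")],
                     levels = levels(y))
      truth <- y[te]
      pos <- truth == positive
      tp <- sum(pred == positive & pos)
      fn <- sum(pred != positive & pos)
      tn <- sum(pred != positive & !pos)
      fp <- sum(pred == positive & !pos)
      met <- confusion_metrics(tp, fn, fp, tn)
      auc <- auc_mw(memb[, positive], truth, positive = positive)
      splits[[f]] <- list(train = tr, test = te)
      rows[[f]] <- data.frame(fold = f, ACC = met[["acc"]], AUC = auc,
                              Sen = met[["sens"]], Spec = met[["spec"]],
                              k = tuned$k, m = tuned$m)
    }
    structure(list(records = do.call(rbind, rows), splits = splits,
                   positive = positive, control = control, seed = seed,
                   outer_folds = outer_folds, inner_folds = inner_folds),
              class = "nested_cv")
  })
}

#' Mean row over the outer folds of a nested CV run
#'
#' @param object a \code{"nested_cv"} object.
#' @param ... unused.
#' @return one-row data frame of arithmetic means (and the records, as the
#'   \code{"records"} attribute of the printed summary).
#' @export
summary.nested_cv <- function(object, ...) {
  r <- object$records
  means <- data.frame(fold = NA, ACC = mean(r$ACC), AUC = mean(r$AUC),
                      Sen = mean(r$Sen), Spec = mean(r$Spec),
                      k = mean(r$k), m = mean(r$m))
  structure(list(records = r, mean = means, positive = object$positive),
            class = "summary.nested_cv")
}

#' @export
print.summary.nested_cv <- function(x, ...) {
  cat("Nested stratified CV (positive class:", x$positive, ")\n")
  tab <- rbind(x$records, x$mean)
  tab$fold <- c(as.character(x$records$fold), "Mean")
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
print.nested_cv <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
as.data.frame.nested_cv <- function(x, ...) x$records

#' Per-fold accuracy plot for a nested CV run
#'
#' @param x a \code{"nested_cv"} object.
#' @param ... passed to \code{barplot}.
#' @export
plot.nested_cv <- function(x, ...) {
  graphics::barplot(x$records$ACC, names.arg = x$records$fold,
                    xlab = "outer fold", ylab = "accuracy (%)",
                    ylim = c(0, 100), ...)
  graphics::abline(h = mean(x$records$ACC), lty = 2)
  invisible(x)
}

#' Write nested CV results as CSV (plus optional JSON summary)
#'
#' CSV columns: fold, ACC, AUC, Sen, Spec, k, m, with a final Mean row.
#'
#' @param object a \code{"nested_cv"} object.
#' @param path output CSV path.
#' @param json_path optional path for a JSON summary (means + settings).
#' @export
write_cv_csv <- function(object, path, json_path = NULL) {
  s <- summary(object)
  tab <- rbind(s$records, s$mean)
  tab$fold <- c(as.character(s$records$fold), "Mean")
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      mean = as.list(s$mean[, c("ACC", "AUC", "Sen", "Spec")]),
      selected_k = object$records$k, selected_m = object$records$m,
      positive = object$positive, seed = object$seed,
      control = unclass(object$control)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Classification metrics from confusion counts
#'
#' @param tp,fn,fp,tn non-negative confusion-matrix counts (positives:
#'   tp + fn > 0; negatives: tn + fp > 0).
#' @return named vector: \code{acc}, \code{sens}, \code{spec}, all in
#'   percent.
#' @examples
#' confusion_metrics(tp = 97, fn = 3, fp = 2, tn = 16)
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (tp + fn == 0 || tn + fp == 0)
    stop("undefined metric: an actual-class margin is empty")
  c(acc = (tp + tn) / sum(counts) * 100,
    sens = tp / (tp + fn) * 100,
    spec = tn / (fp + tn) * 100)
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted half; equals the area under the ROC curve.
#'
#' @param scores numeric scores (higher = more positive); here the
#'   positive-class fuzzy membership.
#' @param labels class labels.
#' @param positive the positive level (default: last level of
#'   \code{factor(labels)}).
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("undefined metric: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Wraps \code{stats::wilcox.test}: exact enumeration when the combined
#' sample size is at most 12 and there are no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param a,b numeric samples (at least 3 observations each).
#' @return two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))  # exact p = 0.1
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 observations per sample")
  exact <- (length(a) + length(b)) <= 12L && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}
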