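# Tuning and evaluation: position decoding, inner fitness, the cached tuner
# objective, nested CV bookkeeping, and the metric arithmetic.

test_that("position decoding rounds k and clamps both parameters", {
  expect_equal(decode_position(c(1.2, 6.5), k_max = 10),
               c(k = 1, m = 6.5))
  expect_equal(decode_position(c(0.4, 0.9), k_max = 10),
               c(k = 1, m = 1.01))
  expect_equal(decode_position(c(99, 42), k_max = 10), c(k = 10, m = 10))
  expect_equal(decode_position(c(3.5, 2), k_max = 10)[["k"]], 4)
})

test_that("confusion metrics reproduce hand-computed percentages", {
  # 97/3/2/16 split: 95.76% accuracy, 97% sensitivity, 88.89% specificity
  m <- confusion_metrics(tp = 97, fn = 3, fp = 2, tn = 16)
  expect_equal(unname(m), c(113 / 118 * 100, 97, 16 / 18 * 100),
               tolerance = 1e-12)
  expect_equal(round(unname(m), 2), c(95.76, 97.00, 88.89))
  # a diagonal matrix scores 100 everywhere
  expect_equal(unname(confusion_metrics(56, 0, 0, 30)), c(100, 100, 100))
  expect_error(confusion_metrics(0, 0, 1, 2), "undefined")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  set.seed(3)
  for (i in 1:10) {
    cnt <- rpois(4, 20) + 1
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    p <- cnt[1] + cnt[2]; n <- cnt[3] + cnt[4]
    expect_equal(m[["acc"]] * (p + n), m[["sens"]] * p + m[["spec"]] * n,
                 tolerance = 1e-9)
  }
})

test_that("rank AUC handles perfect order, ties, and midranks", {
  expect_equal(auc_mw(c(0.1, 0.2, 0.8, 0.9), c("n", "n", "p", "p"),
                      positive = "p"), 1)
  expect_equal(auc_mw(rep(0.5, 6), rep(c("n", "p"), 3), positive = "p"), 0.5)
  # two positive x one negative pairs: one win, one loss
  expect_equal(auc_mw(c(0.9, 0.8, 0.4), c("p", "n", "p"), positive = "p"),
               0.5)
  expect_error(auc_mw(1:3, rep("p", 3), positive = "p"), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:5) {
    scores <- round(runif(40), 2)  # rounding forces ties
    labs <- sample(c("n", "p"), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labs)) < 2) next
    expect_equal(auc_mw(scores, labs, positive = "p"),
                 as.numeric(pROC::auc(pROC::roc(labs, scores, levels =
                   c("n", "p"), direction = "<", quiet = TRUE))))
  }
})

test_that("rank-sum comparison matches the exact permutation oracle", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(oracle_rank_sum_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  set.seed(12)
  for (i in 1:5) {
    a <- round(rnorm(4), 4); b <- round(rnorm(5, 1), 4)
    expect_equal(rank_sum_test(a, b), oracle_rank_sum_p(a, b),
                 tolerance = 1e-12)
    expect_equal(rank_sum_test(a, b), rank_sum_test(b, a))
  }
  # identical samples are never significant
  expect_gte(rank_sum_test(rep(1:3, 4), rep(1:3, 4)), 0.05)
  expect_error(rank_sum_test(1:2, 1:5), "at least 3")
})

test_that("inner fitness is an error rate with the expected extremes", {
  set.seed(20)
  # perfectly separated clusters: zero error
  sep <- generate_dataset(dataset_spec(30, 30, 4, effect_size = 30,
                                       block_correlation = 0, seed = 1))
  expect_equal(inner_fitness(sep$x, sep$y, k = 3, m = 2, folds = 5), 0)

  # uniformly shuffled labels on a balanced problem: error near 0.5
  noise <- generate_dataset(dataset_spec(100, 100, 4, effect_size = 0,
                                         seed = 2))
  err <- inner_fitness(noise$x, noise$y, k = 7, m = 2, folds = 5)
  expect_lt(abs(err - 0.5), 3 * sqrt(0.25 / 200))
  expect_true(err >= 0 && err <= 1)
})

test_that("the cached tuner objective equals the plain inner fitness", {
  set.seed(30)
  p <- generate_dataset(dataset_spec(25, 20, 5, effect_size = 1, seed = 3))
  folds <- stratified_folds(p$y, 5)
  cache <- cbfofknn:::build_fitness_cache(p$x, p$y, folds)
  for (k in c(1, 3, 8)) for (m in c(1.2, 2, 6)) {
    expect_equal(cbfofknn:::cached_fitness(cache, k, m),
                 inner_fitness(p$x, p$y, k, m, folds),
                 label = sprintf("k=%d m=%g", k, m))
  }
})

test_that("stratified folds balance class counts within one", {
  set.seed(40)
  y <- factor(rep(c("a", "b"), c(147, 48)))
  f <- stratified_folds(y, 10)
  expect_equal(sort(unique(f)), 1:10)
  for (cl in levels(y)) {
    counts <- tabulate(f[y == cl], 10)
    expect_lte(diff(range(counts)), 1)
  }
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(30, 3))), 5),
               "infeasible")
})

test_that("tune_fold returns a pair no worse than the (1, 2) default", {
  set.seed(50)
  p <- generate_dataset(dataset_spec(25, 25, 4, effect_size = 1.2, seed = 5))
  ctrl <- cbfo_control(pop = 4, chemotaxis = 5, reproduction = 2,
                       elimination = 1)
  tuned <- tune_fold(p$x, p$y, control = ctrl, seed = 60)
  expect_true(tuned$k >= 1 && tuned$m > 1 && tuned$m <= 10)
  baseline <- inner_fitness(p$x, p$y, 1, 2, folds = tuned$folds)
  expect_lte(tuned$fitness, baseline)
  # identical seed, identical selection
  again <- tune_fold(p$x, p$y, control = ctrl, seed = 60)
  expect_identical(tuned[c("k", "m", "fitness")],
                   again[c("k", "m", "fitness")])
})

test_that("nested CV bookkeeping is sound", {
  set.seed(70)
  p <- generate_dataset(dataset_spec(40, 25, 4, effect_size = 2, seed = 7))
  ctrl <- cbfo_control(pop = 4, chemotaxis = 4, reproduction = 2,
                       elimination = 1)
  res <- nested_cv(p$x, p$y, outer_folds = 5, inner_folds = 3,
                   control = ctrl, seed = 71)
  r <- res$records
  expect_equal(nrow(r), 5)
  expect_true(all(r$ACC >= 0 & r$ACC <= 100))
  expect_true(all(r$AUC >= 0 & r$AUC <= 1))
  expect_true(all(r$k >= 1 & r$m > 1))

  # the mean row is the arithmetic mean of the fold rows
  s <- summary(res)
  expect_equal(s$mean$ACC, mean(r$ACC))
  expect_equal(s$mean$AUC, mean(r$AUC))

  # leakage instrumentation: held-out indices never intersect the
  # training indices of their own fold, and the folds partition the data
  for (f in seq_along(res$splits)) {
    expect_length(intersect(res$splits[[f]]$train, res$splits[[f]]$test), 0)
  }
  expect_equal(sort(unlist(lapply(res$splits, `[[`, "test"))), 1:65)
})

test_that("nested CV rejects degenerate inputs", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(nested_cv(x, rep("a", 10)), "binary")
  p <- generate_dataset(dataset_spec(20, 20, 2, seed = 1))
  expect_error(nested_cv(p$x, p$y, positive = "zz"), "positive")
})

test_that("CV results export as a table with a Mean row plus JSON", {
  set.seed(80)
  p <- generate_dataset(dataset_spec(25, 20, 3, effect_size = 2, seed = 8))
  ctrl <- cbfo_control(pop = 2, chemotaxis = 3, reproduction = 1,
                       elimination = 1)
  res <- nested_cv(p$x, p$y, outer_folds = 3, inner_folds = 3,
                   control = ctrl, seed = 81)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_cv_csv(res, csv, json_path = js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$fold[4], "Mean")
  expect_equal(tab$ACC[4], mean(tab$ACC[1:3]))
  j <- jsonlite::read_json(js)
  expect_equal(j$mean$ACC, mean(res$records$ACC))
  expect_equal(j$control$step, 0.1)
  unlink(c(csv, js))
})
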