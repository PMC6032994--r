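# Independent brute-force oracles. These re-derive the classifier and the
# rank-sum p-value from first principles with literal loops, sharing no code
# with the package internals they check.

# Literal Keller membership assignment: for pattern i, find its K nearest
# training neighbours (Euclidean, self excluded, ties by index) and give
# 0.51 + 0.49 * n_own/K own-class, 0.49 * n_j/K other-class membership.
oracle_memberships <- function(x, y, k_init) {
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  u <- matrix(0, n, nlevels(y))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    ord <- setdiff(order(d, seq_len(n)), i)[seq_len(k_init)]
    for (c in seq_len(nlevels(y))) {
      nj <- sum(as.integer(y[ord]) == c)
      u[i, c] <- nj / k_init * 0.49 + if (c == as.integer(y[i])) 0.51 else 0
    }
  }
  u
}

# Literal fuzzy vote for one query: weights (1/d)^(2/(m-1)) over the k
# nearest training patterns; coincident neighbours (d ~ 0) short-circuit to
# the average of their membership rows.
oracle_predict_membership <- function(x, u, query, k, m) {
  d <- sqrt(colSums((t(x) - query)^2))
  ord <- order(d, seq_len(nrow(x)))[seq_len(k)]
  if (any(d[ord] < 1e-6)) {
    z <- ord[d[ord] < 1e-6]
    return(colSums(u[z, , drop = FALSE]) / length(z))
  }
  w <- (1 / d[ord])^(2 / (m - 1))
  out <- numeric(ncol(u))
  for (c in seq_len(ncol(u)))
    out[c] <- sum(u[ord, c] * w) / sum(w)
  out
}

oracle_classify <- function(x, y, query, k, m, k_init = k) {
  u <- oracle_memberships(x, y, k_init)
  memb <- oracle_predict_membership(as.matrix(x), u, query, k, m)
  levels(as.factor(y))[which.max(memb)]  # which.max: ties -> lowest index
}

# Exact two-sided rank-sum p-value by enumeration of every assignment of the
# pooled observations to the two groups (requires untied pooled values).
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combos <- utils::combn(length(pooled), length(a))
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- length(a) * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Stretched-tetrahedron motifs: same-class edges of length 1, cross-class
# edges 1 + delta. Every pattern's nearest neighbour is its same-class
# partner while the next two are opposite-class at almost the same distance,
# so k = 1 is strictly optimal for every fuzzy strength m.
make_k1_optimal_data <- function(n_motifs = 10, delta = 1e-3) {
  c0 <- sqrt((1 + delta)^2 - 0.5)
  motif <- rbind(c(-0.5, 0, 0), c(0.5, 0, 0), c(0, c0, -0.5), c(0, c0, 0.5))
  x <- do.call(rbind, lapply(seq_len(n_motifs), function(i)
    sweep(motif, 2L, c(100 * i, 0, 0), "+")))
  list(x = x, y = factor(rep(c("a", "a", "b", "b"), n_motifs)))
}

# Small random two-class problem for property tests.
random_problem <- function(n = 10, d = 2, classes = 2) {
  x <- matrix(stats::rnorm(n * d), n, d)
  y <- factor(sample(letters[seq_len(classes)], n, replace = TRUE))
  while (nlevels(droplevels(y)) < 2)
    y <- factor(sample(letters[seq_len(classes)], n, replace = TRUE))
  list(x = x, y = droplevels(y))
}
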