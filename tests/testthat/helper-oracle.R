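# Independent brute-force KNN oracle: full distance computation, explicit
# sort with the (distance, training index) tie policy, explicit vote count
# with the strict-majority reject rule. Kept deliberately naive and separate
# from the package's compiled path.
oracle_knn <- function(train, labels, query, k,
                       classes = sort(unique(labels))) {
  query <- as.matrix(query)
  apply(query, 2L, function(q) {
    d2 <- colSums((train - q)^2)
    ord <- order(d2, seq_along(d2))
    nn <- labels[ord[seq_len(k)]]
    counts <- table(factor(nn, levels = classes))
    top <- which.max(counts)
    if (2 * counts[top] > k) names(counts)[top] else "UNCLASSIFIED"
  })
}

oracle_loo_fitness <- function(train, labels, k,
                               classes = sort(unique(labels))) {
  n <- ncol(train)
  correct <- vapply(seq_len(n), function(i) {
    pred <- oracle_knn(train[, -i, drop = FALSE], labels[-i],
                       train[, i], k, classes)
    pred == labels[i]
  }, logical(1L))
  mean(correct)
}

# Exhaustive enumeration oracle for the hypergeometric upper tail: draw every
# possible top list of size top_n from the universe and count those with at
# least `flagged_in_top` flagged members.
enum_hypergeom <- function(flagged_in_top, top_n, flagged_total, universe) {
  if (top_n == 0L) return(as.numeric(flagged_in_top == 0L))
  subsets <- combn(universe, top_n)
  flagged <- seq_len(flagged_total)  # which labels are flagged is arbitrary
  hits <- colSums(matrix(subsets %in% flagged, nrow = top_n))
  mean(hits >= flagged_in_top)
}

# Independent exact rank-sum oracle: bitmask enumeration of all group
# assignments (different code path from the package's combination walk).
enum_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sums <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) == n1) sums <- c(sums, sum(r[bits == 1L]))
  }
  min(1, 2 * min(mean(sums <= w_obs), mean(sums >= w_obs)))
}

# Random small KNN instance for oracle-equivalence checks.
random_knn_instance <- function(seed) {
  set.seed(seed)
  n <- sample(6:30, 1L)
  p <- sample(1:8, 1L)
  n_classes <- sample(2:5, 1L)
  list(train = matrix(rnorm(p * n), nrow = p),
       labels = sample(LETTERS[seq_len(n_classes)], n, replace = TRUE),
       query = matrix(rnorm(p * 3L), nrow = p))
}
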