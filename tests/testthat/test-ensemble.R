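# Aggregation arithmetic is checked on hand-built prediction matrices via a
# minimal classed stub; end-to-end behaviour on real fits follows below.

test_that("profiles are category counts over runs, pi_cc the true class", {
  preds <- matrix(c("A", "A", "B", "UNCLASSIFIED"), nrow = 4,
                  dimnames = list(NULL, "s1"))
  fit <- fake_fit(preds, test_labels = "A", classes = c("A", "B"))
  prof <- prediction_profiles(fit)
  expect_equal(prof$A, 0.5)
  expect_equal(prof$B, 0.25)
  expect_equal(prof$UNCLASSIFIED, 0.25)
  expect_equal(prof$pi_cc, 0.5)
  expect_equal(prof$A + prof$B + prof$UNCLASSIFIED, 1)

  # unanimity pins pi_cc at 1
  fit2 <- fake_fit(matrix("A", nrow = 6, ncol = 1,
                          dimnames = list(NULL, "s1")),
                   test_labels = "A", classes = c("A", "B"))
  expect_equal(prediction_profiles(fit2)$pi_cc, 1)
})

test_that("profile proportions sum to one for any run count", {
  set.seed(21)
  cats <- c("A", "B", "C", "UNCLASSIFIED")
  for (n_runs in c(1L, 7L, 50L)) {
    preds <- matrix(sample(cats, n_runs * 5, replace = TRUE), nrow = n_runs,
                    dimnames = list(NULL, paste0("s", 1:5)))
    fit <- fake_fit(preds, test_labels = sample(c("A", "B", "C"), 5, TRUE),
                    classes = c("A", "B", "C"),
                    test_ids = paste0("s", 1:5))
    prof <- prediction_profiles(fit)
    sums <- rowSums(prof[, cats])
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(prof$pi_cc >= 0 & prof$pi_cc <= 1))
    # single-run profiles are indicator vectors
    if (n_runs == 1L) {
      expect_true(all(apply(prof[, cats], 1L,
                            function(r) sum(r == 1) == 1 && sum(r) == 1)))
    }
  }
})

test_that("modal accuracy uses the most frequent category with fixed ties", {
  # predicted B 60% / true class A 40% -> modal B -> incorrect
  preds <- matrix(rep(c("B", "B", "B", "A", "A"), 2), nrow = 5,
                  dimnames = list(NULL, c("s1", "s2")))
  fit <- fake_fit(preds, test_labels = c("A", "B"), classes = c("A", "B"),
                  test_ids = c("s1", "s2"))
  ma <- modal_accuracy(fit)
  expect_equal(unname(ma$modal), c("B", "B"))
  expect_equal(unname(ma$per_class), c(0, 1))
  expect_equal(ma$overall, 0.5)

  # exact tie A/B -> lexicographically first class wins
  preds2 <- matrix(c("A", "B", "B", "A"), nrow = 4,
                   dimnames = list(NULL, "s1"))
  fit2 <- fake_fit(preds2, test_labels = "B", classes = c("A", "B"))
  expect_equal(unname(modal_accuracy(fit2)$modal), "A")

  # tie with the reject category -> the class wins, reject sorts last
  preds3 <- matrix(c("UNCLASSIFIED", "B", "B", "UNCLASSIFIED"), nrow = 4,
                   dimnames = list(NULL, "s1"))
  fit3 <- fake_fit(preds3, test_labels = "B", classes = c("A", "B"))
  expect_equal(unname(modal_accuracy(fit3)$modal), "B")
  expect_equal(modal_accuracy(fit3)$overall, 1)

  # an all-reject sample is incorrect
  preds4 <- matrix("UNCLASSIFIED", nrow = 3, ncol = 1,
                   dimnames = list(NULL, "s1"))
  fit4 <- fake_fit(preds4, test_labels = "A", classes = c("A", "B"))
  expect_equal(modal_accuracy(fit4)$overall, 0)
})

test_that("overall modal accuracy equals a brute-force recount", {
  set.seed(31)
  cats <- c("A", "B", "C", "UNCLASSIFIED")
  preds <- matrix(sample(cats, 9 * 40, replace = TRUE), nrow = 9,
                  dimnames = list(NULL, paste0("s", 1:40)))
  truth <- sample(c("A", "B", "C"), 40, replace = TRUE)
  fit <- fake_fit(preds, test_labels = truth, classes = c("A", "B", "C"),
                  test_ids = paste0("s", 1:40))
  ma <- modal_accuracy(fit)
  recount <- vapply(seq_len(40), function(j) {
    counts <- table(factor(preds[, j], levels = cats))
    cats[order(-counts, seq_along(cats))[1L]] == truth[j]
  }, logical(1L))
  expect_equal(ma$overall, mean(recount))
})

test_that("merging profiles averages repeated samples and keeps sums at 1", {
  mk <- function(sample_id, true_class, a, b, uc) {
    df <- data.frame(sample_id = sample_id, true_class = true_class,
                     A = a, B = b, UNCLASSIFIED = uc,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df$pi_cc <- df[[true_class]]
    df
  }
  p1 <- mk("s1", "A", 1, 0, 0)
  p2 <- mk("s1", "A", 0.5, 0.5, 0)
  merged <- merge_profiles(list(p1, p2))
  expect_equal(merged$A, 0.75)
  expect_equal(merged$B, 0.25)
  expect_equal(merged$pi_cc, 0.75)

  # averaging identical profiles is the identity
  expect_equal(merge_profiles(list(p2, p2)), p2)

  # property: random stochastic vectors stay normalized after merging
  set.seed(41)
  for (i in 1:20) {
    rows <- lapply(1:3, function(j) {
      v <- runif(3)
      v <- v / sum(v)
      mk("sX", "B", v[1], v[2], v[3])
    })
    out <- merge_profiles(rows)
    expect_equal(out$A + out$B + out$UNCLASSIFIED, 1)
  }
})

test_that("gene frequencies count runs, conserve totals, rank by count", {
  runs <- list(list(best_subset = c(1L, 2L)), list(best_subset = c(1L, 3L)),
               list(best_subset = c(1L, 2L)))
  fit <- fake_fit(matrix("A", 3, 1, dimnames = list(NULL, "s1")),
                  test_labels = "A", classes = "A",
                  gene_ids = c("g1", "g2", "g3", "g4"), runs = runs,
                  chromosome_length = 2L)
  freq <- gene_frequencies(fit)
  expect_equal(freq$count[match(c("g1", "g2", "g3", "g4"), freq$gene_id)],
               c(3L, 2L, 1L, 0L))
  expect_equal(freq$rank[match(c("g1", "g2", "g3"), freq$gene_id)], 1:3)
  expect_equal(sum(freq$count), 2L * 3L)

  other <- fit
  other$gene_ids <- c("g1", "g2", "g3", "gX")
  expect_error(gene_frequencies(fit, other), "gene universe")
})

test_that("a small ensemble is reproducible run by run", {
  sim <- simulate_expression(synthetic_spec(n_classes = 3,
                                            samples_per_class = 12,
                                            n_genes = 150, seed = 6))
  ds <- log2_transform(sim$dataset)
  cfg <- ga_config(chromosome_length = 5L, population_size = 16L,
                   max_generations = 6L)
  fit1 <- gaknn(ds, n_runs = 6L, config = cfg, seed = 900)
  fit2 <- gaknn(ds, n_runs = 6L, config = cfg, seed = 900)
  expect_identical(fit1$predictions, fit2$predictions)
  expect_identical(lapply(fit1$runs, `[[`, "best_subset"),
                   lapply(fit2$runs, `[[`, "best_subset"))

  # each run is self-contained: re-evolving run r in isolation with its own
  # seed reproduces the stored run (order independence / parallel safety)
  std <- gaknn:::standardize_stats(ds$values, fit1$partition$train)
  train <- gaknn:::apply_standardization(ds$values,
                                         std)[, fit1$partition$train]
  labels <- ds$class_labels[fit1$partition$train]
  for (r in c(2L, 5L)) {
    cfg_r <- cfg
    cfg_r$seed <- 900L + r
    solo <- ga_evolve(train, labels, cfg_r)
    expect_identical(solo$best_subset, fit1$runs[[r]]$best_subset)
    expect_identical(solo$best_fitness, fit1$runs[[r]]$best_fitness)
  }

  # conservation on the real fit
  freq <- gene_frequencies(fit1)
  expect_identical(sum(freq$count), 5L * 6L)
})

test_that("ensembling does not hurt accuracy on separable synthetic data", {
  sim <- simulate_expression(synthetic_spec(n_classes = 3,
                                            samples_per_class = 15,
                                            n_genes = 200,
                                            informative_per_class = 4,
                                            effect_size = 3, seed = 17))
  ds <- log2_transform(sim$dataset)
  fit <- gaknn(ds, n_runs = 10L,
               config = ga_config(chromosome_length = 6L,
                                  population_size = 20L,
                                  max_generations = 15L),
               seed = 17)
  single_run_acc <- vapply(seq_len(fit$n_runs), function(r) {
    mean(fit$predictions[r, ] == fit$test_labels)
  }, numeric(1L))
  expect_gte(modal_accuracy(fit)$overall, mean(single_run_acc))
})

test_that("nothing is learnable from zero-signal data", {
  sim <- simulate_expression(synthetic_spec(n_classes = 5,
                                            samples_per_class = 16,
                                            n_genes = 200, effect_size = 0,
                                            seed = 23))
  ds <- log2_transform(sim$dataset)
  fit <- gaknn(ds, n_runs = 8L,
               config = ga_config(chromosome_length = 5L,
                                  population_size = 16L,
                                  max_generations = 6L),
               seed = 23)
  expect_lt(mean(prediction_profiles(fit)$pi_cc), 0.4)
})

test_that("fit refuses untransformed data and mismatched partitions", {
  sim <- simulate_expression(synthetic_spec(n_classes = 2,
                                            samples_per_class = 6,
                                            n_genes = 30, seed = 2))
  expect_error(gaknn(sim$dataset, n_runs = 1L), "log2")
  ds <- log2_transform(sim$dataset)
  bad <- stratified_split(rep(c("A", "B"), each = 4), 0.75, 1)
  expect_error(gaknn(ds, n_runs = 1L, partition = bad), "partition")
})
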