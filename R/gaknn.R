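#' Fit a GA/KNN ensemble classifier
#'
#' The core estimator of the package. For a fixed stratified train/test
#' partition it repeats the GA/KNN search `n_runs` times: each run evolves a
#' fixed-size gene subset maximizing leave-one-out KNN training accuracy
#' ([ga_evolve()]) and then classifies every test sample with that
#' near-optimal subset ([knn_predict()]), including the reject category.
#' Because every test sample is classified `n_runs` times, the fit supports
#' per-sample prediction profiles (the proportion of runs assigning the
#' sample to each class — the true-class entry is pi_cc), modal prediction
#' accuracies, and frequency-based gene importance ranks.
#'
#' Gene expression is standardized per gene to zero mean and unit variance
#' using training-set statistics only (frozen for test samples), so distances
#' are scale-free. Run `r` is seeded `seed + r`, making the ensemble
#' reproducible and order-independent: running the runs in any order, or one
#' at a time, gives bit-identical results.
#'
#' @param dataset a log2-transformed [expression_dataset()] (see
#'   [log2_transform()]).
#' @param n_runs number of independent GA/KNN runs (the study design uses
#'   1000 per partition; scaled-down designs use fewer).
#' @param config a [ga_config()]; its `seed` field is ignored in favour of
#'   the per-run seeds derived from `seed`.
#' @param partition optional [stratified_split()] result; by default a
#'   75/25 proportional split with seed `seed` is drawn.
#' @param train_fraction training fraction used when `partition` is `NULL`.
#' @param seed integer base seed for the partition and the per-run GA seeds.
#' @return an object of class `"gaknn"`: list with elements `runs` (list of
#'   [ga_evolve()] results), `predictions` (character matrix, runs x test
#'   samples, entries class names or `"UNCLASSIFIED"`), `classes`,
#'   `partition`, `test_ids`, `test_labels`, `gene_ids`, `config`, `n_runs`,
#'   `seed`, plus the frozen standardization and training data needed by
#'   [predict.gaknn()].
#' @seealso [prediction_profiles()], [modal_accuracy()],
#'   [gene_frequencies()], [summary.gaknn()], [predict.gaknn()]
#' @examples
#' \donttest{
#' sim <- simulate_expression(synthetic_spec(n_classes = 3,
#'   samples_per_class = 15, n_genes = 200, seed = 1))
#' ds <- log2_transform(sim$dataset)
#' fit <- gaknn(ds, n_runs = 5,
#'   config = ga_config(chromosome_length = 5, population_size = 20,
#'                      max_generations = 10),
#'   seed = 1)
#' summary(fit)
#' }
#' @export
gaknn <- function(dataset, n_runs = 1000L, config = ga_config(),
                  partition = NULL, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(config, "ga_config"))
  if (!dataset$log2) {
    stop("dataset must be log2-transformed first; see log2_transform()")
  }
  n_runs <- check_count(n_runs, "n_runs")
  seed <- as.integer(seed)
  if (is.null(partition)) {
    partition <- stratified_split(dataset$class_labels, train_fraction, seed)
  }
  validate_partition(partition, ncol(dataset$values))

  classes <- sort(unique(dataset$class_labels))
  std <- standardize_stats(dataset$values, partition$train)
  values_std <- apply_standardization(dataset$values, std)
  train_std <- values_std[, partition$train, drop = FALSE]
  test_std <- values_std[, partition$test, drop = FALSE]
  train_labels <- dataset$class_labels[partition$train]
  test_labels <- dataset$class_labels[partition$test]
  train_codes <- label_codes(train_labels, classes)

  runs <- vector("list", n_runs)
  predictions <- matrix(NA_character_, nrow = n_runs,
                        ncol = length(partition$test),
                        dimnames = list(NULL,
                                        dataset$sample_ids[partition$test]))
  for (r in seq_len(n_runs)) {
    cfg_r <- config
    cfg_r$seed <- seed + r
    run <- ga_evolve(train_std, train_labels, cfg_r)
    codes <- knn_predict_cpp(train_std[run$best_subset, , drop = FALSE],
                             train_codes,
                             test_std[run$best_subset, , drop = FALSE],
                             config$k_neighbors, length(classes))
    predictions[r, ] <- ifelse(codes == 0L, UNCLASSIFIED, classes[pmax(codes, 1L)])
    runs[[r]] <- run
  }

  structure(
    list(runs = runs, predictions = predictions, classes = classes,
         partition = partition,
         test_ids = dataset$sample_ids[partition$test],
         test_labels = test_labels, gene_ids = dataset$gene_ids,
         config = config, n_runs = n_runs, seed = seed,
         standardization = std, train_std = train_std,
         train_labels = train_labels, call = match.call()),
    class = "gaknn"
  )
}

validate_partition <- function(partition, n_samples) {
  stopifnot(inherits(partition, "partition"))
  all_idx <- sort(c(partition$train, partition$test))
  if (length(intersect(partition$train, partition$test)) ||
      !identical(all_idx, seq_len(n_samples))) {
    stop("partition is not a disjoint, exhaustive split of the samples")
  }
  invisible(partition)
}

#' Categories of a fit: classes plus the reject category
#' @param object a `"gaknn"` fit.
#' @return character vector, sorted class names followed by
#'   `"UNCLASSIFIED"`.
#' @export
categories <- function(object) c(object$classes, UNCLASSIFIED)

#' Per-sample prediction profiles
#'
#' For each test sample, the proportion of ensemble runs assigning it to each
#' category (every class plus `UNCLASSIFIED`). The proportions of a sample
#' sum to 1; the entry for the sample's true class is its pi_cc.
#'
#' @param object a [gaknn()] fit.
#' @return data frame with columns `sample_id`, `true_class`, one numeric
#'   column per category, and `pi_cc`.
#' @export
prediction_profiles <- function(object) {
  stopifnot(inherits(object, "gaknn"))
  cats <- categories(object)
  counts <- vapply(cats, function(cat) colSums(object$predictions == cat),
                   numeric(ncol(object$predictions)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, cats))
  props <- counts / object$n_runs
  out <- data.frame(sample_id = object$test_ids,
                    true_class = object$test_labels,
                    props, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pi_cc <- props[cbind(seq_along(object$test_ids),
                           match(object$test_labels, cats))]
  out
}

## Modal category per test sample with the deterministic tie policy:
## higher count first, then class name lexicographically, reject category
## last. `predictions` is the runs x samples character matrix.
modal_categories <- function(predictions, cats) {
  apply(predictions, 2L, function(col) {
    counts <- vapply(cats, function(cat) sum(col == cat), integer(1L))
    cats[order(-counts, seq_along(cats))[1L]]
  })
}

#' Modal prediction accuracy
#'
#' Each test sample's modal category is the one it was assigned most often
#' across runs (ties broken deterministically: higher count, then class name,
#' reject category last). Per-class accuracy is the fraction of that class's
#' test samples whose modal category equals the truth; a sample whose modal
#' category is `UNCLASSIFIED` is incorrect. The overall accuracy is the
#' sample-count-weighted mean, i.e. the fraction of all test samples that are
#' modal-correct.
#'
#' @param object a [gaknn()] fit.
#' @return list with `per_class` (named numeric vector), `overall` (single
#'   proportion) and `modal` (named character vector of modal categories per
#'   test sample).
#' @export
modal_accuracy <- function(object) {
  stopifnot(inherits(object, "gaknn"))
  modal <- modal_categories(object$predictions, categories(object))
  names(modal) <- object$test_ids
  correct <- modal == object$test_labels
  per_class <- vapply(object$classes, function(cl) {
    mean(correct[object$test_labels == cl])
  }, numeric(1L))
  list(per_class = per_class, overall = mean(correct), modal = modal)
}

#' Gene selection frequencies across ensemble runs
#'
#' Counts, for every gene, the number of ensemble runs whose near-optimal
#' subset contained it, pooling all runs of all fits given (e.g. the two or
#' five independent partitions of the study design). Ranks are assigned by
#' descending count with ties broken by gene id, so top-N lists are
#' reproducible.
#'
#' @param ... one or more [gaknn()] fits (or a single list of fits). All fits
#'   must share one gene universe.
#' @return a data frame of class `"gene_frequency"` with columns `gene_id`,
#'   `count`, `rank`, ordered by rank; total runs in attribute `n_runs`,
#'   subset size in attribute `chromosome_length`.
#' @export
gene_frequencies <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "gaknn")) fits <- fits[[1L]]
  stopifnot(length(fits) > 0L, all(vapply(fits, inherits, logical(1L), "gaknn")))
  gene_ids <- fits[[1L]]$gene_ids
  L <- fits[[1L]]$config$chromosome_length
  counts <- integer(length(gene_ids))
  total_runs <- 0L
  for (fit in fits) {
    if (!identical(fit$gene_ids, gene_ids)) {
      stop("fits do not share a common gene universe")
    }
    for (run in fit$runs) {
      counts[run$best_subset] <- counts[run$best_subset] + 1L
    }
    total_runs <- total_runs + fit$n_runs
  }
  ord <- order(-counts, gene_ids)
  out <- data.frame(gene_id = gene_ids[ord], count = counts[ord],
                    rank = seq_along(gene_ids), stringsAsFactors = FALSE)
  attr(out, "n_runs") <- total_runs
  attr(out, "chromosome_length") <- L
  class(out) <- c("gene_frequency", "data.frame")
  out
}

#' Merge prediction profiles across partitions
#'
#' When the ensemble is repeated over several independent train/test
#' partitions, a sample can appear in more than one test set; its proportion
#' vectors are then averaged (arithmetic mean, which preserves the sum-to-1
#' property). Samples appearing once pass through unchanged.
#'
#' @param profile_sets list of profile data frames from
#'   [prediction_profiles()], sharing the same category columns.
#' @return a single profile data frame with one row per distinct sample.
#' @export
merge_profiles <- function(profile_sets) {
  stopifnot(is.list(profile_sets), length(profile_sets) > 0L)
  cols <- names(profile_sets[[1L]])
  for (p in profile_sets) {
    if (!identical(names(p), cols)) {
      stop("profile sets must share identical category columns")
    }
  }
  all_rows <- do.call(rbind, profile_sets)
  prop_cols <- setdiff(cols, c("sample_id", "true_class", "pi_cc"))
  ids <- unique(all_rows$sample_id)
  merged <- lapply(ids, function(id) {
    rows <- all_rows[all_rows$sample_id == id, , drop = FALSE]
    out <- rows[1L, , drop = FALSE]
    out[prop_cols] <- as.list(colMeans(rows[, prop_cols, drop = FALSE]))
    out$pi_cc <- out[[out$true_class[1L]]]
    out
  })
  res <- do.call(rbind, merged)
  row.names(res) <- NULL
  res
}

#' @export
print.gaknn <- function(x, ...) {
  ma <- modal_accuracy(x)
  cat("GA/KNN ensemble fit\n")
  cat(sprintf("  %d runs, chromosome length %d, %d classes\n",
              x$n_runs, x$config$chromosome_length, length(x$classes)))
  cat(sprintf("  %d train / %d test samples\n",
              length(x$partition$train), length(x$partition$test)))
  cat(sprintf("  overall modal prediction accuracy: %.3f\n", ma$overall))
  invisible(x)
}

#' Summarize a GA/KNN ensemble fit
#'
#' Per-class summary of the pi_cc distribution (minimum, quartiles, mean,
#' maximum) together with the modal prediction accuracy, plus the overall
#' sample-weighted modal accuracy — the layout of the study's per-tumor-type
#' summary table.
#'
#' @param object a [gaknn()] fit.
#' @param ... unused.
#' @return an object of class `"summary.gaknn"`: list with `table` (data
#'   frame, one row per class) and `overall_modal_accuracy`.
#' @export
summary.gaknn <- function(object, ...) {
  profiles <- prediction_profiles(object)
  ma <- modal_accuracy(object)
  rows <- lapply(object$classes, function(cl) {
    pi <- profiles$pi_cc[profiles$true_class == cl]
    data.frame(class = cl, n_test = length(pi),
               min = min(pi), q1 = unname(quantile(pi, 0.25)),
               median = unname(quantile(pi, 0.5)), mean = mean(pi),
               q3 = unname(quantile(pi, 0.75)), max = max(pi),
               modal_accuracy = unname(ma$per_class[cl]),
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 overall_modal_accuracy = ma$overall,
                 n_runs = object$n_runs),
            class = "summary.gaknn")
}

#' @export
print.summary.gaknn <- function(x, ...) {
  cat(sprintf("pi_cc summary over %d GA/KNN runs\n", x$n_runs))
  tab <- x$table
  tab[, -(1:2)] <- round(tab[, -(1:2)], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall modal prediction accuracy (sample-weighted): %.3f\n",
              x$overall_modal_accuracy))
  invisible(x)
}

#' Gene importance as model coefficients
#'
#' `coef()` on a GA/KNN fit returns the gene selection-frequency table — the
#' model's importance measure.
#'
#' @param object a [gaknn()] fit.
#' @param ... unused.
#' @return a [gene_frequencies()] table.
#' @export
coef.gaknn <- function(object, ...) gene_frequencies(object)

#' Predict new samples with a fitted ensemble
#'
#' Classifies new samples with every run's near-optimal subset, using the
#' training data and standardization frozen at fit time.
#'
#' @param object a [gaknn()] fit.
#' @param newdata an [expression_dataset()] (log2-transformed) or a numeric
#'   genes x samples matrix with the fit's gene universe.
#' @param type `"modal"` for one category per sample, `"profile"` for the
#'   per-category proportion matrix.
#' @param ... unused.
#' @return character vector of categories, or a samples x categories
#'   proportion matrix.
#' @export
predict.gaknn <- function(object, newdata, type = c("modal", "profile"),
                          ...) {
  type <- match.arg(type)
  if (inherits(newdata, "expression_dataset")) {
    if (!newdata$log2) stop("newdata must be log2-transformed")
    if (!identical(newdata$gene_ids, object$gene_ids)) {
      stop("newdata does not share the fit's gene universe")
    }
    newdata <- newdata$values
  }
  newdata <- as.matrix(newdata)
  if (nrow(newdata) != length(object$gene_ids)) {
    stop("newdata must have one row per gene of the fit")
  }
  q_std <- apply_standardization(newdata, object$standardization)
  classes <- object$classes
  codes <- label_codes(object$train_labels, classes)
  preds <- matrix(NA_character_, nrow = object$n_runs, ncol = ncol(newdata))
  for (r in seq_len(object$n_runs)) {
    sub <- object$runs[[r]]$best_subset
    pc <- knn_predict_cpp(object$train_std[sub, , drop = FALSE], codes,
                          q_std[sub, , drop = FALSE],
                          object$config$k_neighbors, length(classes))
    preds[r, ] <- ifelse(pc == 0L, UNCLASSIFIED, classes[pmax(pc, 1L)])
  }
  cats <- categories(object)
  if (type == "modal") {
    modal <- modal_categories(preds, cats)
    names(modal) <- colnames(newdata)
    modal
  } else {
    props <- sapply(cats, function(cat) colMeans(preds == cat))
    if (is.null(dim(props))) {
      props <- matrix(props, nrow = 1L,
                      dimnames = list(colnames(newdata), cats))
    } else {
      dimnames(props) <- list(colnames(newdata), cats)
    }
    props
  }
}

#' Stem plot of gene selection frequencies
#'
#' Plots the selection count of the top-ranked genes as vertical stems, the
#' classic display of ensemble gene importance.
#'
#' @param x a [gaknn()] fit.
#' @param n_top number of top-ranked genes to show.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the frequency table.
#' @export
plot.gaknn <- function(x, n_top = 50L, ...) {
  freq <- gene_frequencies(x)
  n_top <- min(n_top, nrow(freq))
  top <- freq[seq_len(n_top), ]
  graphics::plot(top$rank, top$count, type = "h", xlab = "gene rank",
                 ylab = "selection count",
                 main = "Gene selection frequency", ...)
  graphics::points(top$rank, top$count, pch = 16, cex = 0.5)
  invisible(freq)
}

#' Write ensemble outputs as TSV
#'
#' Convenience exports of the three standard result tables: per-sample
#' profiles, gene frequency ranks, and the per-class summary.
#'
#' @param object a [gaknn()] fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_gaknn_results <- function(object, dir) {
  stopifnot(inherits(object, "gaknn"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("profiles.tsv", "gene_frequency.tsv",
                            "class_summary.tsv"))
  write.table(prediction_profiles(object), paths[1L], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gene_frequencies(object), paths[2L], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summary(object)$table, paths[3L], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
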