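## Standardize genes to zero mean / unit variance using training-set
## statistics only; zero-variance genes get scale 1 so they contribute
## nothing to training-sample distances. Parameters are frozen per partition
## and reused for test/query samples.
standardize_stats <- function(values, train_idx) {
  tr <- values[, train_idx, drop = FALSE]
  center <- rowMeans(tr)
  scale <- apply(tr, 1L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardization <- function(values, stats) {
  (values - stats$center) / stats$scale
}

label_codes <- function(labels, classes) {
  codes <- match(labels, classes)
  if (anyNA(codes)) stop("label not among known classes: ",
                         labels[which(is.na(codes))[1L]])
  as.integer(codes)
}

#' KNN prediction with a reject option
#'
#' Classifies query samples by Euclidean distance to the training samples,
#' restricted to a gene subset. The predicted class is the one held by a
#' strict majority (more than `k/2`) of the `k` nearest neighbours; when no
#' class reaches a strict majority (e.g. a 2-2-1 vote at `k = 5`) the sample
#' is rejected as `"UNCLASSIFIED"`. Distance ties at the k-th neighbour are
#' broken by training index, so predictions are deterministic and invariant
#' to training-sample permutation.
#'
#' @param train_values numeric matrix, genes x training samples.
#' @param train_labels class name per training sample.
#' @param query numeric vector (one sample) or matrix (genes x queries).
#' @param subset integer vector of gene (row) indices to use; `NULL` uses all
#'   rows.
#' @param k number of neighbours (default 5); must not exceed the number of
#'   training samples.
#' @param classes optional fixed class universe (defaults to the sorted
#'   unique training labels).
#' @return character vector of predicted class names, `"UNCLASSIFIED"` where
#'   no strict majority exists.
#' @examples
#' train <- matrix(c(0, 1, 2, 10, 11), nrow = 1)
#' knn_predict(train, c("A", "A", "A", "B", "B"), 0.5, k = 5) # "A"
#' @export
knn_predict <- function(train_values, train_labels, query, subset = NULL,
                        k = 5L, classes = NULL) {
  train_values <- as.matrix(train_values)
  if (is.null(dim(query))) query <- matrix(query, ncol = 1L)
  k <- check_count(k, "k")
  if (k > ncol(train_values)) {
    stop("k (", k, ") exceeds the number of training samples (",
         ncol(train_values), ")")
  }
  if (nrow(query) != nrow(train_values)) {
    stop("query must have one value per gene")
  }
  if (is.null(classes)) classes <- sort(unique(as.character(train_labels)))
  if (!is.null(subset)) {
    subset <- validate_subset(subset, nrow(train_values))
    train_values <- train_values[subset, , drop = FALSE]
    query <- query[subset, , drop = FALSE]
  }
  codes <- knn_predict_cpp(train_values, label_codes(train_labels, classes),
                           as.matrix(query), k, length(classes))
  ifelse(codes == 0L, UNCLASSIFIED, classes[pmax(codes, 1L)])
}

#' Leave-one-out KNN training fitness
#'
#' The GA's objective: the fraction of training samples whose leave-one-out
#' KNN prediction (the sample excluded from its own neighbour search) equals
#' its true label, using only the genes in `subset`. Rejected
#' (`UNCLASSIFIED`) samples count as incorrect.
#'
#' @inheritParams knn_predict
#' @return a proportion in `[0, 1]`.
#' @export
knn_fitness <- function(train_values, train_labels, subset = NULL, k = 5L) {
  train_values <- as.matrix(train_values)
  k <- check_count(k, "k")
  if (ncol(train_values) < k + 1L) {
    stop("leave-one-out fitness needs at least k + 1 training samples")
  }
  classes <- sort(unique(as.character(train_labels)))
  if (!is.null(subset)) {
    subset <- validate_subset(subset, nrow(train_values))
    train_values <- train_values[subset, , drop = FALSE]
  }
  knn_loo_fitness_cpp(train_values, label_codes(train_labels, classes), k,
                      length(classes))
}

validate_subset <- function(subset, n_genes) {
  subset <- as.integer(subset)
  if (anyNA(subset) || any(subset < 1L) || any(subset > n_genes)) {
    stop("gene subset indices out of range")
  }
  if (anyDuplicated(subset)) stop("gene subset indices must be distinct")
  subset
}
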