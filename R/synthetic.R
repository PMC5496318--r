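#' Specification for a synthetic expression dataset
#'
#' Describes the statistical structure the classifier assumes: many classes
#' with unbalanced sizes, a small set of class-discriminative genes planted
#' among thousands of uninformative ones, per-sample gender labels, and a
#' flagged gene subset standing in for a pseudogene annotation. Expression is
#' modelled in log2 space as
#' `baseline_log_mean + effect_size * informative-in-class + N(0, noise_sd)`
#' and returned on the raw scale as its power of two, so the floor-log2
#' transform recovers the simulated structure exactly.
#'
#' @param n_classes number of classes.
#' @param samples_per_class integer vector of per-class sample counts
#'   (recycled to `n_classes`).
#' @param n_genes total number of genes.
#' @param informative_per_class number of discriminative genes planted per
#'   class; informative sets are disjoint across classes.
#' @param effect_size mean up-shift (log2 units) of an informative gene in
#'   its own class.
#' @param baseline_log_mean baseline log2 expression level.
#' @param noise_sd per-gene Gaussian standard deviation in log2 space.
#' @param flagged_fraction fraction of genes carrying the flag;
#'   `round(flagged_fraction * n_genes)` genes are flagged.
#' @param flagged_informative_bias fraction of each class's informative genes
#'   drawn from the flagged set (rounded per class).
#' @param gender_proportion_per_class probability that a sample is male, per
#'   class (recycled).
#' @param seed integer seed; identical spec + seed gives bit-identical data.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_classes = 5L, samples_per_class = 30L,
                           n_genes = 1000L, informative_per_class = 5L,
                           effect_size = 2, baseline_log_mean = 6,
                           noise_sd = 1, flagged_fraction = 0.1,
                           flagged_informative_bias = 0.5,
                           gender_proportion_per_class = 0.6, seed = 1L) {
  n_classes <- check_count(n_classes, "n_classes")
  n_genes <- check_count(n_genes, "n_genes")
  informative_per_class <- check_count(informative_per_class,
                                       "informative_per_class", min = 0L)
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  if (any(is.na(samples_per_class)) || any(samples_per_class < 1L)) {
    stop("'samples_per_class' must be positive counts")
  }
  if (informative_per_class * n_classes > n_genes) {
    stop("'informative_per_class' x 'n_classes' exceeds 'n_genes'")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size)) {
    stop("'effect_size' must be a single finite number")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("'noise_sd' must be a single non-negative number")
  }
  check_proportion(flagged_fraction, "flagged_fraction")
  check_proportion(flagged_informative_bias, "flagged_informative_bias")
  gender_proportion_per_class <- rep_len(as.numeric(gender_proportion_per_class),
                                         n_classes)
  if (any(is.na(gender_proportion_per_class)) ||
      any(gender_proportion_per_class < 0) ||
      any(gender_proportion_per_class > 1)) {
    stop("'gender_proportion_per_class' entries must be proportions in [0,1]")
  }
  structure(
    list(n_classes = n_classes, samples_per_class = samples_per_class,
         n_genes = n_genes, informative_per_class = informative_per_class,
         effect_size = as.numeric(effect_size),
         baseline_log_mean = as.numeric(baseline_log_mean),
         noise_sd = as.numeric(noise_sd),
         flagged_fraction = as.numeric(flagged_fraction),
         flagged_informative_bias = as.numeric(flagged_informative_bias),
         gender_proportion_per_class = gender_proportion_per_class,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Simulate an expression dataset with planted discriminative genes
#'
#' Draws a raw-scale genes x samples matrix under a [synthetic_spec()] and
#' records the ground truth (which genes were planted where, which genes are
#' flagged) so recovery can be scored exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{dataset}{an [expression_dataset()] on the raw scale
#'       (`log2 = FALSE`); apply [log2_transform()] before analysis.}
#'     \item{truth}{a list with `informative` (named list, class name ->
#'       integer gene indices) and `flagged` (integer gene indices).}
#'   }
#' @examples
#' sim <- simulate_expression(synthetic_spec(n_classes = 2,
#'   samples_per_class = 5, n_genes = 50, seed = 7))
#' dim(sim$dataset)
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_samples <- sum(spec$samples_per_class)
  classes <- sprintf("C%02d", seq_len(spec$n_classes))
  class_labels <- rep(classes, spec$samples_per_class)

  with_seed(spec$seed, {
    n_flagged <- round(spec$flagged_fraction * spec$n_genes)
    flagged <- sort(sample.int(spec$n_genes, n_flagged))

    # informative genes: disjoint across classes, a biased share drawn from
    # the flagged pool so flag enrichment among top-ranked genes is testable
    pool_flagged <- flagged
    pool_plain <- setdiff(seq_len(spec$n_genes), flagged)
    informative <- vector("list", spec$n_classes)
    names(informative) <- classes
    for (ci in seq_len(spec$n_classes)) {
      n_from_flagged <- min(round(spec$flagged_informative_bias *
                                    spec$informative_per_class),
                            length(pool_flagged))
      n_from_plain <- spec$informative_per_class - n_from_flagged
      if (n_from_plain > length(pool_plain)) {
        extra <- n_from_plain - length(pool_plain)
        n_from_plain <- length(pool_plain)
        n_from_flagged <- n_from_flagged + extra
      }
      pick_f <- if (n_from_flagged > 0)
        pool_flagged[sample.int(length(pool_flagged), n_from_flagged)]
      else integer(0)
      pick_p <- if (n_from_plain > 0)
        pool_plain[sample.int(length(pool_plain), n_from_plain)]
      else integer(0)
      informative[[ci]] <- sort(c(pick_f, pick_p))
      pool_flagged <- setdiff(pool_flagged, pick_f)
      pool_plain <- setdiff(pool_plain, pick_p)
    }

    logmat <- matrix(rnorm(spec$n_genes * n_samples, mean = 0,
                           sd = spec$noise_sd),
                     nrow = spec$n_genes) + spec$baseline_log_mean
    for (ci in seq_len(spec$n_classes)) {
      cols <- which(class_labels == classes[ci])
      logmat[informative[[ci]], cols] <-
        logmat[informative[[ci]], cols] + spec$effect_size
    }

    gender <- character(n_samples)
    for (ci in seq_len(spec$n_classes)) {
      cols <- which(class_labels == classes[ci])
      male <- rbinom(length(cols), 1L,
                     spec$gender_proportion_per_class[ci]) == 1L
      gender[cols] <- ifelse(male, "male", "female")
    }
  })

  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
  dataset <- expression_dataset(
    2^logmat,
    gene_ids = gene_ids,
    sample_ids = sprintf("S%04d", seq_len(n_samples)),
    class_labels = class_labels,
    gender = gender,
    gene_flags = gene_ids[flagged],
    log2 = FALSE
  )
  list(dataset = dataset,
       truth = list(informative = informative, flagged = flagged))
}

#' Simulate a single-class dataset with planted sample clusters
#'
#' Fixture generator for silhouette-guided subtype discovery: one nominal
#' class whose samples fall into `n_clusters` Gaussian clusters in log2 gene
#' space. Cluster `j` shifts gene `j` by `separation / sqrt(2)`, so every
#' pair of cluster centroids is Euclidean distance `separation` apart.
#'
#' @param n_clusters number of planted clusters (>= 2).
#' @param samples_per_cluster samples in each cluster.
#' @param n_genes total genes (must be >= `n_clusters`).
#' @param separation Euclidean distance between cluster centroids in log2
#'   space; 0 plants no structure.
#' @param noise_sd per-gene Gaussian sd in log2 space.
#' @param baseline_log_mean baseline log2 expression level.
#' @param seed integer seed.
#' @return list with `dataset` (raw-scale [expression_dataset()], single
#'   class `"tumor"`) and `clusters` (integer vector of planted cluster
#'   labels per sample).
#' @export
simulate_cluster_dataset <- function(n_clusters = 2L, samples_per_cluster = 30L,
                                     n_genes = 50L, separation = 10,
                                     noise_sd = 1, baseline_log_mean = 6,
                                     seed = 1L) {
  n_clusters <- check_count(n_clusters, "n_clusters", min = 2L)
  samples_per_cluster <- check_count(samples_per_cluster, "samples_per_cluster")
  n_genes <- check_count(n_genes, "n_genes", min = n_clusters)
  if (!is.numeric(separation) || separation < 0) {
    stop("'separation' must be non-negative")
  }
  n_samples <- n_clusters * samples_per_cluster
  clusters <- rep(seq_len(n_clusters), each = samples_per_cluster)
  shift <- separation / sqrt(2)
  logmat <- with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), nrow = n_genes) +
      baseline_log_mean
    for (j in seq_len(n_clusters)) {
      m[j, clusters == j] <- m[j, clusters == j] + shift
    }
    m
  })
  dataset <- expression_dataset(
    2^logmat,
    gene_ids = sprintf("G%05d", seq_len(n_genes)),
    sample_ids = sprintf("S%04d", seq_len(n_samples)),
    class_labels = rep("tumor", n_samples),
    log2 = FALSE
  )
  list(dataset = dataset, clusters = clusters)
}
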