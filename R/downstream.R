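#' Silhouette-guided k-means subtype discovery
#'
#' Within one class, clusters the samples on the expression of the top-ranked
#' discriminative genes: takes the `n_top` highest-ranked genes, drops those
#' with zero interquartile range within the class (constant genes carry no
#' subtype signal), runs k-means for each candidate number of clusters
#' (10 random restarts, best within-cluster sum of squares kept), scores each
#' k by the mean silhouette width on Euclidean distance in the filtered gene
#' space, and returns the k with the largest mean silhouette (ties to the
#' smaller k).
#'
#' @param dataset a log2-transformed [expression_dataset()].
#' @param class_name the class whose samples are clustered.
#' @param ranked_genes a [gene_frequencies()] table (or any data frame with
#'   `gene_id` and `rank` columns).
#' @param n_top number of top-ranked genes considered (default 50).
#' @param candidate_k candidate cluster counts (default `c(2, 3)`).
#' @param seed integer seed for the k-means restarts.
#' @return an object of class `"subtype_result"`: list with `class_name`,
#'   `genes_used` (ids surviving the IQR filter), `chosen_k`, `assignments`
#'   (named integer vector of cluster labels) and `silhouette_by_k` (named
#'   numeric vector of mean silhouette widths).
#' @export
subtype_discovery <- function(dataset, class_name, ranked_genes, n_top = 50L,
                              candidate_k = c(2L, 3L), seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!dataset$log2) stop("dataset must be log2-transformed")
  candidate_k <- sort(unique(as.integer(candidate_k)))
  if (any(candidate_k < 2L)) stop("candidate k must be >= 2")
  cols <- which(dataset$class_labels == class_name)
  if (length(cols) == 0L) stop("unknown class: ", class_name)
  if (length(cols) < max(candidate_k) + 1L) {
    stop("class '", class_name, "' has too few samples for k = ",
         max(candidate_k))
  }
  top_ids <- ranked_genes$gene_id[order(ranked_genes$rank)]
  top_ids <- intersect(top_ids, dataset$gene_ids)
  top_ids <- top_ids[seq_len(min(n_top, length(top_ids)))]
  sub <- dataset$values[top_ids, cols, drop = FALSE]
  iqr <- apply(sub, 1L, IQR)
  genes_used <- top_ids[iqr > 0]
  if (length(genes_used) < 2L) {
    stop("fewer than 2 genes with non-zero IQR in class '", class_name, "'")
  }
  x <- t(sub[genes_used, , drop = FALSE])
  d <- stats::dist(x)
  sil <- numeric(length(candidate_k))
  names(sil) <- as.character(candidate_k)
  fits <- vector("list", length(candidate_k))
  with_seed(seed, {
    for (i in seq_along(candidate_k)) {
      km <- kmeans(x, centers = candidate_k[i], nstart = 10L,
                   iter.max = 100L)
      fits[[i]] <- km$cluster
      sw <- cluster::silhouette(km$cluster, d)
      sil[i] <- mean(sw[, "sil_width"])
    }
  })
  best <- which.max(sil)  # ties resolve to the smaller k (first maximum)
  assignments <- fits[[best]]
  names(assignments) <- dataset$sample_ids[cols]
  structure(
    list(class_name = class_name, genes_used = genes_used,
         chosen_k = candidate_k[best], assignments = assignments,
         silhouette_by_k = sil),
    class = "subtype_result"
  )
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("Subtype discovery for class '%s': chosen k = %d\n",
              x$class_name, x$chosen_k))
  cat("Mean silhouette by k: ",
      paste(sprintf("k=%s: %.3f", names(x$silhouette_by_k),
                    x$silhouette_by_k), collapse = ", "), "\n", sep = "")
  cat(sprintf("%d genes used, %d samples\n", length(x$genes_used),
              length(x$assignments)))
  invisible(x)
}

#' Hypergeometric enrichment of a flagged gene class
#'
#' Upper-tail hypergeometric test: the probability of observing at least
#' `flagged_in_top` flagged genes among the `top_n` top-ranked genes when
#' `flagged_total` of the `universe` genes are flagged and the top list were
#' a random draw.
#'
#' @param flagged_in_top flagged genes observed in the top list.
#' @param top_n size of the top list.
#' @param flagged_total flagged genes in the universe.
#' @param universe total number of genes.
#' @return the p-value `P(X >= flagged_in_top)`.
#' @examples
#' hypergeom_enrichment(2, 3, 4, 10) # 1/3
#' @export
hypergeom_enrichment <- function(flagged_in_top, top_n, flagged_total,
                                 universe) {
  flagged_in_top <- check_count(flagged_in_top, "flagged_in_top", 0L)
  top_n <- check_count(top_n, "top_n", 0L)
  flagged_total <- check_count(flagged_total, "flagged_total", 0L)
  universe <- check_count(universe, "universe")
  if (top_n > universe || flagged_total > universe ||
      flagged_in_top > min(top_n, flagged_total)) {
    stop("inconsistent counts for the hypergeometric test")
  }
  phyper(flagged_in_top - 1L, flagged_total, universe - flagged_total, top_n,
         lower.tail = FALSE)
}

#' Compare two gene rankings
#'
#' Union and intersection of the two top-`top_n` lists, with full-table
#' signed rank differences for every gene in the union — so a gene far down
#' one ranking is still comparable — and the set of genes whose absolute rank
#' difference exceeds a threshold.
#'
#' @param table_a,table_b [gene_frequencies()] tables (or data frames with
#'   `gene_id` and `rank`) over the same gene universe.
#' @param top_n list length compared (default 100).
#' @param rank_diff_threshold absolute rank difference beyond which a gene is
#'   flagged as divergent (default 100).
#' @return an object of class `"rank_comparison"`: list with `top_n`,
#'   `union`, `intersection`, `union_size`, `intersection_size`,
#'   `rank_differences` (named vector, `rank_a - rank_b` over the union) and
#'   `divergent` (gene ids with `|difference| > rank_diff_threshold`).
#' @export
compare_rankings <- function(table_a, table_b, top_n = 100L,
                             rank_diff_threshold = 100L) {
  top_n <- check_count(top_n, "top_n")
  if (!setequal(table_a$gene_id, table_b$gene_id)) {
    stop("rankings do not share a common gene universe")
  }
  rank_a <- stats::setNames(table_a$rank, table_a$gene_id)
  rank_b <- stats::setNames(table_b$rank, table_b$gene_id)
  top_a <- table_a$gene_id[table_a$rank <= top_n]
  top_b <- table_b$gene_id[table_b$rank <= top_n]
  u <- sort(union(top_a, top_b))
  i <- sort(intersect(top_a, top_b))
  diffs <- rank_a[u] - rank_b[u]
  structure(
    list(top_n = top_n, union = u, intersection = i,
         union_size = length(u), intersection_size = length(i),
         rank_differences = diffs,
         divergent = names(diffs)[abs(diffs) > rank_diff_threshold]),
    class = "rank_comparison"
  )
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Top-%d comparison: union %d, intersection %d, %d divergent\n",
              x$top_n, x$union_size, x$intersection_size,
              length(x$divergent)))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test between genders
#'
#' Compares one gene's expression between male and female samples of a class.
#' The statistic is the rank sum of the male group. When both groups have at
#' most `exact_limit` samples the null distribution is enumerated exactly
#' over all assignments of the pooled (tied) ranks, and the two-sided p-value
#' is `min(1, 2 * min(P(W <= w), P(W >= w)))`; otherwise a normal
#' approximation with tie and continuity correction is used.
#'
#' @param dataset an [expression_dataset()] with gender labels.
#' @param gene_id the gene tested.
#' @param class_name the class whose samples are compared.
#' @param exact_limit largest group size for the exact branch (default 10).
#' @return list with `statistic` (male rank sum), `p.value`, `method`
#'   (`"exact"` or `"normal"`), and the group sizes.
#' @export
ranksum_by_gender <- function(dataset, gene_id, class_name,
                              exact_limit = 10L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$gender)) stop("dataset has no gender labels")
  cols <- which(dataset$class_labels == class_name)
  if (length(cols) == 0L) stop("unknown class: ", class_name)
  gi <- match(gene_id, dataset$gene_ids)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  g <- dataset$gender[cols]
  x <- dataset$values[gi, cols][g == "male"]
  y <- dataset$values[gi, cols][g == "female"]
  for (gender in c("male", "female")) {
    if (sum(g == gender) == 0L) {
      stop("gender '", gender, "' absent from class '", class_name, "'")
    }
  }
  ranksum_test(x, y, exact_limit = exact_limit)
}

#' @describeIn ranksum_by_gender the underlying two-sample test on plain
#'   numeric vectors (`x` = male-group values).
#' @param x,y numeric value vectors for the two groups.
#' @param method `"auto"` picks the exact branch when both groups are within
#'   `exact_limit`; `"exact"` or `"normal"` force a branch.
#' @export
ranksum_test <- function(x, y, exact_limit = 10L,
                         method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  use_exact <- switch(method,
                      auto = n1 <= exact_limit && n2 <= exact_limit,
                      exact = TRUE, normal = FALSE)
  if (use_exact) {
    sums <- combn_rank_sums(r, n1)
    p <- min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
    list(statistic = w, p.value = p, method = "exact", n_male = n1,
         n_female = n2)
  } else {
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(list(statistic = w, p.value = 1, method = "normal",
                  n_male = n1, n_female = n2))
    }
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    list(statistic = w, p.value = min(1, 2 * pnorm(-abs(z))),
         method = "normal", n_male = n1, n_female = n2)
  }
}

## All possible rank sums of a group of size n1 drawn from the pooled rank
## vector r (ties included), one per combination of positions. The position
## combinations depend only on (n, n1) and are cached across calls.
.combn_cache <- new.env(parent = emptyenv())
combn_rank_sums <- function(r, n1) {
  key <- paste(length(r), n1)
  combs <- .combn_cache[[key]]
  if (is.null(combs)) {
    combs <- combn(length(r), n1)
    .combn_cache[[key]] <- combs
  }
  colSums(matrix(r[combs], nrow = n1))
}

#' Matched cohort subsampling
#'
#' Draws replicate cohorts from one gender that match a target per-class
#' sample count — the device used to test whether cohort differences are
#' artifacts of class-proportion imbalance. Within a replicate each class's
#' samples are drawn uniformly without replacement; replicates are drawn
#' independently of each other.
#'
#' @param dataset an [expression_dataset()] with gender labels.
#' @param source_gender gender drawn from (`"male"` or `"female"`).
#' @param target_counts named integer vector, class name -> number of samples
#'   required.
#' @param n_replicates number of replicate cohorts.
#' @param seed integer seed.
#' @return list of `n_replicates` sorted integer vectors of sample indices.
#' @export
matched_subsample <- function(dataset, source_gender, target_counts,
                              n_replicates = 8L, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$gender)) stop("dataset has no gender labels")
  source_gender <- match.arg(source_gender, c("male", "female"))
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (is.null(names(target_counts)) || any(names(target_counts) == "")) {
    stop("'target_counts' must be named by class")
  }
  pools <- lapply(names(target_counts), function(cl) {
    which(dataset$class_labels == cl & dataset$gender == source_gender)
  })
  names(pools) <- names(target_counts)
  for (cl in names(target_counts)) {
    short <- target_counts[[cl]] - length(pools[[cl]])
    if (short > 0L) {
      stop("class '", cl, "' has ", short, " too few ", source_gender,
           " samples for the requested target")
    }
  }
  with_seed(seed, {
    replicate(n_replicates, {
      sort(unlist(lapply(names(target_counts), function(cl) {
        pool <- pools[[cl]]
        pool[sample.int(length(pool), target_counts[[cl]])]
      }), use.names = FALSE))
    }, simplify = FALSE)
  })
}
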