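#' Genetic-algorithm configuration
#'
#' Defaults follow the study design this package implements: 20-gene
#' chromosomes, a population of 300, at most 300 generations, a stop rule of
#' 90% training accuracy, and KNN with `k = 5`. Variation operators
#' (tournament selection of size 3, uniform union-repair crossover at rate
#' 0.9, per-position replacement mutation at rate 0.05, elitism of 2) are
#' standard choices; every population member is always a distinct-gene subset
#' of fixed size.
#'
#' @param chromosome_length genes per subset.
#' @param population_size chromosomes per generation.
#' @param max_generations generation budget; the initial population counts as
#'   generation 0.
#' @param stop_fitness stop as soon as the best chromosome reaches this
#'   leave-one-out training accuracy.
#' @param k_neighbors KNN `k`.
#' @param mutation_rate per-position replacement probability.
#' @param crossover_rate probability a selected pair is recombined rather
#'   than copied.
#' @param elitism_count top chromosomes copied unchanged each generation.
#' @param tournament_size selection tournament size.
#' @param seed integer seed; identical data + config + seed reproduce the run
#'   exactly.
#' @return an object of class `"ga_config"`.
#' @export
ga_config <- function(chromosome_length = 20L, population_size = 300L,
                      max_generations = 300L, stop_fitness = 0.90,
                      k_neighbors = 5L, mutation_rate = 0.05,
                      crossover_rate = 0.9, elitism_count = 2L,
                      tournament_size = 3L, seed = 1L) {
  cfg <- list(
    chromosome_length = check_count(chromosome_length, "chromosome_length"),
    population_size = check_count(population_size, "population_size", 2L),
    max_generations = check_count(max_generations, "max_generations", 0L),
    stop_fitness = check_proportion(stop_fitness, "stop_fitness"),
    k_neighbors = check_count(k_neighbors, "k_neighbors"),
    mutation_rate = check_proportion(mutation_rate, "mutation_rate"),
    crossover_rate = check_proportion(crossover_rate, "crossover_rate"),
    elitism_count = check_count(elitism_count, "elitism_count", 0L),
    tournament_size = check_count(tournament_size, "tournament_size"),
    seed = as.integer(seed)
  )
  if (cfg$stop_fitness <= 0) stop("'stop_fitness' must be positive")
  if (cfg$elitism_count >= cfg$population_size) {
    stop("'elitism_count' must be smaller than 'population_size'")
  }
  structure(cfg, class = "ga_config")
}

#' Per-position replacement mutation
#'
#' Each position of the subset is, independently with probability `rate`,
#' replaced by a gene drawn uniformly from the genes not currently in the
#' subset, so the result is always a distinct-gene subset of the same size.
#' When no replacement gene exists (subset spans the whole gene pool) the
#' position is left unchanged. Consumes the current R RNG stream.
#'
#' @param subset integer vector of distinct gene indices.
#' @param n_genes size of the gene pool.
#' @param rate per-position mutation probability.
#' @return mutated subset (sorted, distinct, same length).
#' @export
ga_mutate <- function(subset, n_genes, rate) {
  L <- length(subset)
  hit <- runif(L) < rate
  if (any(hit)) {
    for (i in which(hit)) {
      candidates <- setdiff(seq_len(n_genes), subset)
      if (length(candidates) == 0L) break
      subset[i] <- candidates[sample.int(length(candidates), 1L)]
    }
  }
  sort(subset)
}

#' Uniform union-repair crossover
#'
#' Genes shared by both parents are inherited by both children; the genes
#' unique to either parent are partitioned uniformly at random between the
#' two children. Both children are distinct-gene subsets of the parental
#' length drawn entirely from the parents' union. Consumes the current R RNG
#' stream.
#'
#' @param parent_a,parent_b integer vectors of distinct gene indices, same
#'   length.
#' @return list of two child subsets (sorted).
#' @export
ga_crossover <- function(parent_a, parent_b) {
  if (length(parent_a) != length(parent_b)) {
    stop("parents must have the same length")
  }
  shared <- intersect(parent_a, parent_b)
  sym <- setdiff(union(parent_a, parent_b), shared)
  n_pick <- length(parent_a) - length(shared)
  if (n_pick == 0L) {
    child <- sort(parent_a)
    return(list(child, child))
  }
  pick <- sym[sample.int(length(sym), n_pick)]
  list(sort(c(shared, pick)), sort(c(shared, setdiff(sym, pick))))
}

subset_key <- function(subset) paste(subset, collapse = ",")

#' Write / read a GA configuration as a flat key=value file
#'
#' @param config a [ga_config()].
#' @param path file path.
#' @return `write_ga_config()` returns the config invisibly;
#'   `read_ga_config()` returns a validated `"ga_config"`.
#' @export
write_ga_config <- function(config, path) {
  stopifnot(inherits(config, "ga_config"))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, format, character(1L))), path)
  invisible(config)
}

#' @rdname write_ga_config
#' @export
read_ga_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(x[2L]))
  names(vals) <- vapply(kv, `[[`, character(1L), 1L)
  do.call(ga_config, vals)
}

#' Evolve a near-optimal gene subset
#'
#' Runs the genetic algorithm on a (standardized) training matrix: random
#' initial population of distinct-gene subsets, then per generation
#' tournament selection, crossover, mutation, and elitist replacement, each
#' subset scored by [knn_fitness()]. The search halts as soon as the best
#' chromosome of the current generation reaches `stop_fitness` (checked from
#' generation 0, the initial population, onwards) or when `max_generations`
#' is exhausted; the best subset ever seen is returned. Fitness values are
#' cached by gene-set key within the run since subsets recur.
#'
#' @param train_values numeric matrix, genes x training samples (standardize
#'   first for scale-free distances; [gaknn()] does this per partition).
#' @param train_labels class name per training sample.
#' @param config a [ga_config()].
#' @return an object of class `"ga_run"`: list with `best_subset` (sorted
#'   integer vector), `best_fitness`, `generations_used`, `stopped_early`,
#'   `best_by_generation` (best-ever fitness trajectory, generation 0 first)
#'   and `n_evaluations` (distinct subsets scored).
#' @export
ga_evolve <- function(train_values, train_labels, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  train_values <- as.matrix(train_values)
  n_genes <- nrow(train_values)
  L <- config$chromosome_length
  if (n_genes < L) {
    stop("chromosome length (", L, ") exceeds gene count (", n_genes, ")")
  }
  classes <- sort(unique(as.character(train_labels)))
  codes <- label_codes(train_labels, classes)
  k <- config$k_neighbors
  if (ncol(train_values) < k + 1L) {
    stop("training set too small for leave-one-out with k = ", k)
  }

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(subset) {
    key <- subset_key(subset)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- knn_loo_fitness_cpp(train_values[subset, , drop = FALSE], codes, k,
                             length(classes))
    cache[[key]] <- f
    n_eval <<- n_eval + 1L
    f
  }

  with_seed(config$seed, {
    pop <- replicate(config$population_size,
                     sort(sample.int(n_genes, L)), simplify = FALSE)
    fit <- vapply(pop, score, numeric(1L))
    best_idx <- order(-fit)[1L]
    best_subset <- pop[[best_idx]]
    best_fitness <- fit[best_idx]
    best_by_generation <- best_fitness
    generations_used <- 0L
    stopped_early <- FALSE

    gen <- 0L
    while (best_fitness < config$stop_fitness &&
           gen < config$max_generations) {
      gen <- gen + 1L
      elite_order <- order(-fit, seq_along(fit))
      new_pop <- pop[elite_order[seq_len(config$elitism_count)]]
      while (length(new_pop) < config$population_size) {
        pa <- tournament_pick(fit, config$tournament_size)
        pb <- tournament_pick(fit, config$tournament_size)
        if (runif(1L) < config$crossover_rate) {
          children <- ga_crossover(pop[[pa]], pop[[pb]])
        } else {
          children <- list(pop[[pa]], pop[[pb]])
        }
        for (child in children) {
          if (length(new_pop) >= config$population_size) break
          new_pop[[length(new_pop) + 1L]] <-
            ga_mutate(child, n_genes, config$mutation_rate)
        }
      }
      pop <- new_pop
      fit <- vapply(pop, score, numeric(1L))
      gen_best <- order(-fit)[1L]
      if (fit[gen_best] > best_fitness) {
        best_fitness <- fit[gen_best]
        best_subset <- pop[[gen_best]]
      }
      best_by_generation <- c(best_by_generation, best_fitness)
      generations_used <- gen
    }
    stopped_early <- best_fitness >= config$stop_fitness &&
      generations_used < config$max_generations
  })

  structure(
    list(best_subset = best_subset, best_fitness = best_fitness,
         generations_used = generations_used, stopped_early = stopped_early,
         best_by_generation = best_by_generation, n_evaluations = n_eval),
    class = "ga_run"
  )
}

## Tournament selection: sample `size` population indices with replacement,
## return the one with the best fitness (ties to the smaller index).
tournament_pick <- function(fit, size) {
  idx <- sample.int(length(fit), size, replace = TRUE)
  idx[order(-fit[idx], idx)[1L]]
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf(
    "GA run: best fitness %.3f after %d generation(s)%s; subset size %d\n",
    x$best_fitness, x$generations_used,
    if (x$stopped_early) " (stopped early)" else "",
    length(x$best_subset)))
  invisible(x)
}
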