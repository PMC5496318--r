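#' Read an expression dataset from TSV files
#'
#' The expression matrix is tab-separated with gene ids in the first column
#' and sample ids in the header (first header cell ignored). The sample
#' annotation has columns `sample_id`, `class` and optionally `gender`; every
#' matrix sample must appear in it. The optional gene annotation has columns
#' `gene_id` and `flag` (0/1); genes with `flag == 1` become the flagged set.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param sample_annotation_path path to the sample annotation TSV.
#' @param gene_annotation_path optional path to the gene annotation TSV.
#' @param log2 logical; set `TRUE` if the file already holds transformed
#'   values (default `FALSE`: raw scale, transform with [log2_transform()]).
#' @return an [expression_dataset()] with columns ordered as in the matrix
#'   file.
#' @export
read_expression_dataset <- function(matrix_path, sample_annotation_path,
                                    gene_annotation_path = NULL,
                                    log2 = FALSE) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(raw[-1L], is.numeric, logical(1L)))[1L]
    badrow <- which(is.na(suppressWarnings(as.numeric(raw[[bad + 1L]]))))[1L]
    stop(sprintf("non-numeric expression value at row %d, column %d",
                 badrow, bad + 1L))
  }
  sample_ids <- colnames(mat)

  ann <- read.delim(sample_annotation_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(ann))) {
    stop("sample annotation must have columns 'sample_id' and 'class'")
  }
  missing <- setdiff(sample_ids, ann$sample_id)
  if (length(missing)) {
    stop("no annotation for sample: ", paste(missing, collapse = ", "))
  }
  idx <- match(sample_ids, ann$sample_id)
  gender <- if ("gender" %in% names(ann)) as.character(ann$gender[idx]) else NULL

  gene_flags <- NULL
  if (!is.null(gene_annotation_path)) {
    ga <- read.delim(gene_annotation_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("gene_id", "flag") %in% names(ga))) {
      stop("gene annotation must have columns 'gene_id' and 'flag'")
    }
    gene_flags <- intersect(ga$gene_id[ga$flag == 1], gene_ids)
  }

  expression_dataset(mat, gene_ids = gene_ids, sample_ids = sample_ids,
                     class_labels = as.character(ann$class[idx]),
                     gender = gender, gene_flags = gene_flags, log2 = log2)
}

#' Write an expression dataset to TSV files
#'
#' Writes the same three-file layout [read_expression_dataset()] reads, so a
#' write/read round trip reproduces the dataset.
#'
#' @param dataset an [expression_dataset()].
#' @param matrix_path,sample_annotation_path output paths.
#' @param gene_annotation_path optional output path for the gene flags (all
#'   genes written with flag 0/1).
#' @return invisibly, the dataset.
#' @export
write_expression_dataset <- function(dataset, matrix_path,
                                     sample_annotation_path,
                                     gene_annotation_path = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids, dataset$values,
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = dataset$sample_ids,
                    class = dataset$class_labels)
  if (!is.null(dataset$gender)) ann$gender <- dataset$gender
  write.table(ann, sample_annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(gene_annotation_path)) {
    ga <- data.frame(
      gene_id = dataset$gene_ids,
      flag = as.integer(dataset$gene_ids %in% dataset$gene_flags)
    )
    write.table(ga, gene_annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dataset)
}

#' Stratified train/test partition
#'
#' Splits samples into a training and a testing set with samples drawn
#' proportionally from each class without replacement: class `c` with `n_c`
#' samples contributes `round(train_fraction * n_c)` training samples
#' (round half up), clamped to `[1, n_c - 1]` so neither side of the split is
#' ever empty for any class.
#'
#' @param class_labels character vector of class names, one per sample.
#' @param train_fraction proportion of samples assigned to training
#'   (default 0.75).
#' @param seed integer seed; the same seed reproduces the partition exactly.
#' @return an object of class `"partition"`: list with integer vectors
#'   `train` and `test` (disjoint, exhaustive sample indices), `seed` and
#'   `train_fraction`.
#' @examples
#' p <- stratified_split(rep(c("A", "B"), c(100, 60)), 0.75, seed = 1)
#' table(rep(c("A", "B"), c(100, 60))[p$train]) # A 75, B 45
#' @export
stratified_split <- function(class_labels, train_fraction = 0.75, seed = 1L) {
  class_labels <- as.character(class_labels)
  check_proportion(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must be strictly between 0 and 1")
  }
  tab <- table(class_labels)
  if (any(tab < 2L)) {
    stop("class with fewer than 2 samples: ",
         names(tab)[which(tab < 2L)[1L]])
  }
  train <- integer(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(class_labels == cl)
      n_c <- length(idx)
      n_train <- floor(train_fraction * n_c + 0.5)  # round half up
      n_train <- min(max(n_train, 1L), n_c - 1L)
      train <- c(train, idx[sample.int(n_c, n_train)])
    }
  })
  train <- sort(train)
  structure(
    list(train = train,
         test = setdiff(seq_along(class_labels), train),
         seed = as.integer(seed),
         train_fraction = train_fraction),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train), length(x$test), x$train_fraction, x$seed))
  invisible(x)
}

#' Write / read a partition as TSV
#'
#' Serialized as two columns, `sample_id` and `split` (train/test).
#'
#' @param partition a [stratified_split()] result.
#' @param sample_ids sample identifiers in dataset order.
#' @param path output (or input) file path.
#' @return `write_partition()` returns the partition invisibly;
#'   `read_partition()` returns a `"partition"` object (seed and fraction are
#'   not stored in the file and come back as `NA`).
#' @export
write_partition <- function(partition, sample_ids, path) {
  split <- rep("test", length(sample_ids))
  split[partition$train] <- "train"
  write.table(data.frame(sample_id = sample_ids, split = split), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(partition)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, sample_ids) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  idx <- match(sample_ids, df$sample_id)
  if (anyNA(idx)) stop("partition file is missing samples")
  split <- df$split[idx]
  structure(
    list(train = which(split == "train"), test = which(split == "test"),
         seed = NA_integer_, train_fraction = NA_real_),
    class = "partition"
  )
}
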