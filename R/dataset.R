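#' Labeled expression dataset
#'
#' Container for a genes x samples expression matrix together with per-sample
#' class labels, optional gender labels and an optional set of flagged genes
#' (e.g. pseudogenes). Values are stored on the raw normalized scale until
#' [log2_transform()] is applied; the `log2` flag records whether the
#' floor-at-1 log2 transform has been performed, and prevents applying it
#' twice.
#'
#' @param values numeric matrix, genes in rows, samples in columns. All values
#'   must be finite and non-negative.
#' @param gene_ids character vector of unique gene identifiers (row names).
#' @param sample_ids character vector of unique sample identifiers (column
#'   names).
#' @param class_labels character vector, one class name per sample.
#' @param gender optional character vector per sample, values in
#'   `c("male", "female", "unknown")`.
#' @param gene_flags optional character vector of flagged gene ids; every
#'   entry must appear in `gene_ids`.
#' @param log2 logical; `TRUE` if values are already floor-log2 transformed.
#'
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `class_labels`, `gender`,
#'   `gene_flags` and `log2`.
#' @seealso [log2_transform()], [read_expression_dataset()],
#'   [simulate_expression()]
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values), class_labels,
                               gender = NULL, gene_flags = NULL,
                               log2 = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  class_labels <- as.character(class_labels)
  if (nrow(values) != length(gene_ids)) {
    stop("row count does not match number of gene ids")
  }
  if (ncol(values) != length(sample_ids)) {
    stop("column count does not match number of sample ids")
  }
  if (length(class_labels) != length(sample_ids)) {
    stop("'class_labels' must have one entry per sample")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (any(!is.finite(values))) stop("'values' contains non-finite entries")
  if (any(values < 0)) stop("'values' contains negative entries")
  if (any(class_labels == UNCLASSIFIED)) {
    stop("class name '", UNCLASSIFIED, "' is reserved for the reject category")
  }
  if (!is.null(gender)) {
    gender <- as.character(gender)
    if (length(gender) != length(sample_ids)) {
      stop("'gender' must have one entry per sample")
    }
    bad <- setdiff(unique(gender), c("male", "female", "unknown"))
    if (length(bad)) stop("invalid gender value: ", bad[1L])
  }
  if (!is.null(gene_flags)) {
    gene_flags <- as.character(gene_flags)
    missing <- setdiff(gene_flags, gene_ids)
    if (length(missing)) stop("flagged gene not in dataset: ", missing[1L])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         class_labels = class_labels, gender = gender,
         gene_flags = gene_flags, log2 = isTRUE(log2)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "raw"))
  tab <- table(x$class_labels)
  cat(sprintf("Classes (%d): %s\n", length(tab),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (!is.null(x$gender)) {
    gt <- table(x$gender)
    cat("Gender: ", paste(sprintf("%s=%d", names(gt), gt), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$gene_flags)) {
    cat(sprintf("Flagged genes: %d\n", length(x$gene_flags)))
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Floor-at-1 log2 transform
#'
#' Normalized RNA-seq expression values below 1 are mostly noise; every value
#' `v` is replaced by `log2(max(v, 1))`, so the transformed matrix is
#' non-negative and values in `[0, 1]` map to 0.
#'
#' @param raw numeric matrix (or vector) of non-negative finite values.
#' @return matrix (or vector) of the same shape on the log2 scale.
#' @examples
#' floor_log2(c(0.5, 1, 8)) # 0 0 3
#' @export
floor_log2 <- function(raw) {
  if (!is.numeric(raw)) stop("input must be numeric")
  if (any(!is.finite(raw))) stop("input contains non-finite values")
  if (any(raw < 0)) stop("input contains negative values")
  log2(pmax(raw, 1))
}

#' Apply the floor-log2 transform to a dataset
#'
#' @param dataset an [expression_dataset()] on the raw scale.
#' @return the dataset with transformed values and `log2 = TRUE`.
#' @export
log2_transform <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$log2) stop("dataset is already log2-transformed")
  dataset$values <- floor_log2(dataset$values)
  dataset$log2 <- TRUE
  dataset
}
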