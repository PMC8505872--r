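#' Gene-level count matrix with sample metadata
#'
#' The substrate of all differential-expression testing: an integer matrix of
#' read counts (genes x samples), per-gene effective lengths, and a sample
#' metadata table.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param gene_lengths Per-gene effective length in bases (named or in row
#'   order).
#' @param samples Data frame with columns `sample_id`, `species`,
#'   `condition`, `stage`, `replicate` covering every column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_lengths, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop("counts must be non-negative integers")
  }
  if (!is.null(names(gene_lengths))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts) || anyNA(gene_lengths) ||
      any(gene_lengths <= 0)) {
    stop("gene_lengths must be positive and cover every gene")
  }
  samples <- as.data.frame(samples)
  need <- c("sample_id", "species", "condition", "stage", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(colnames(counts) %in% samples$sample_id)) {
    stop("sample metadata does not cover all count columns")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  rownames(samples) <- NULL
  structure(list(counts = counts,
                 gene_lengths = stats::setNames(as.numeric(gene_lengths),
                                                rownames(counts)),
                 samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  tab <- table(x$samples$condition, x$samples$stage)
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param x A `count_matrix`.
#' @param genes,samples Identifiers to keep (`NULL` keeps all).
#' @return A `count_matrix`.
#' @export
subset_count_matrix <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(genes)) genes <- rownames(x$counts)
  if (is.null(samples)) samples <- colnames(x$counts)
  count_matrix(x$counts[genes, samples, drop = FALSE],
               x$gene_lengths[genes],
               x$samples[x$samples$sample_id %in% samples, ])
}
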