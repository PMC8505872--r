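# TSV dialects for every pipeline object. Header rows everywhere, gene ids
# are opaque strings, and parse errors name the offending line (header is
# line 1).

read_tsv_checked <- function(path, required, what = path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("malformed header in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

first_dup_line <- function(x) which(duplicated(x))[1] + 1L

#' Read and write a count matrix
#'
#' The counts file is `gene_id` plus one integer column per sample; sample
#' metadata (`sample_id`, `species`, `condition`, `stage`, `replicate`) and
#' per-gene effective lengths (`gene_id`, `length`) live in companion
#' files.
#'
#' @param counts_path,metadata_path,lengths_path TSV paths. `lengths_path`
#'   may be `NULL` on read, in which case every gene gets `default_length`.
#' @param default_length Effective length used when no lengths file is
#'   given.
#' @return `read_counts` returns a [count_matrix]; `write_counts`
#'   invisibly returns the paths written.
#' @export
read_counts <- function(counts_path, metadata_path, lengths_path = NULL,
                        default_length = 1000) {
  df <- read_tsv_checked(counts_path, "gene_id")
  if (ncol(df) < 2) stop("counts file has no sample columns: ", counts_path)
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene id in ", counts_path, " at line ",
         first_dup_line(df$gene_id))
  }
  num <- df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad) > 0) {
      stop("non-integer count in ", counts_path, ", column '",
           names(num)[j], "', line ", bad[1] + 1L)
    }
    num[[j]] <- as.integer(v)
  }
  counts <- as.matrix(num)
  rownames(counts) <- df$gene_id
  meta <- read_tsv_checked(metadata_path,
                           c("sample_id", "species", "condition", "stage",
                             "replicate"))
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample id in ", metadata_path, " at line ",
         first_dup_line(meta$sample_id))
  }
  meta$replicate <- as.integer(meta$replicate)
  if (is.null(lengths_path)) {
    lengths <- stats::setNames(rep(default_length, nrow(counts)),
                               rownames(counts))
  } else {
    ldf <- read_tsv_checked(lengths_path, c("gene_id", "length"))
    if (anyDuplicated(ldf$gene_id)) {
      stop("duplicate gene id in ", lengths_path, " at line ",
           first_dup_line(ldf$gene_id))
    }
    lengths <- stats::setNames(as.numeric(ldf$length), ldf$gene_id)
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss) > 0) {
      stop("lengths missing for ", length(miss), " genes (first: ",
           miss[1], ")")
    }
  }
  count_matrix(counts, lengths, meta)
}

#' @rdname read_counts
#' @param cm A [count_matrix] to write.
#' @export
write_counts <- function(cm, counts_path, metadata_path,
                         lengths_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(cm$samples, metadata_path)
  if (!is.null(lengths_path)) {
    write_tsv(data.frame(gene_id = names(cm$gene_lengths),
                         length = unname(cm$gene_lengths)), lengths_path)
  }
  invisible(c(counts_path, metadata_path, lengths_path))
}

#' Read and write DEG tables
#'
#' Dialect: `gene_id`, `comparison`, `log2fc`, `pvalue`, `qvalue`, `call`.
#'
#' @param path TSV path.
#' @return `read_deg_table` returns a `deg_table` tibble (or a named list
#'   of them when the file holds several comparisons).
#' @export
read_deg_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "comparison", "log2fc",
                                 "pvalue", "qvalue", "call"))
  for (col in c("log2fc", "pvalue", "qvalue")) df[[col]] <- as.numeric(df[[col]])
  if (!all(df$call %in% c("up", "down", "none"))) {
    stop("invalid call value in ", path, " at line ",
         which(!df$call %in% c("up", "down", "none"))[1] + 1L)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("deg_table", class(out))
  out
}

#' @rdname read_deg_table
#' @param deg A `deg_table` (or several row-bound) to write.
#' @export
write_deg_table <- function(deg, path) {
  write_tsv(as.data.frame(deg)[c("gene_id", "comparison", "log2fc",
                                 "pvalue", "qvalue", "call")], path)
}

#' Read and write an orthology map
#'
#' Dialect: `ct_gene` (diploid), `cp_gene` (tetraploid), `relation`
#' (`one_to_one` / `one_to_multi`); orphan tetraploid genes are rows with
#' an empty `ct_gene` and relation `none`.
#'
#' @param path TSV path.
#' @export
read_orthology <- function(path) {
  df <- read_tsv_checked(path, c("ct_gene", "cp_gene", "relation"))
  orphan <- df$relation == "none" | df$ct_gene == ""
  orthology_map(df[!orphan, ], orphans = df$cp_gene[orphan])
}

#' @rdname read_orthology
#' @param ortho An [orthology_map()] to write.
#' @export
write_orthology <- function(ortho, path) {
  stopifnot(inherits(ortho, "orthology_map"))
  df <- rbind(as.data.frame(ortho$links),
              if (length(ortho$orphans) > 0) {
                data.frame(ct_gene = "", cp_gene = ortho$orphans,
                           relation = "none")
              })
  write_tsv(df, path)
}

#' Read and write cell contours
#'
#' Dialect: `cell_id`, `group`, `vertex_index`, `x`, `y`, vertices in
#' order; the polygon closes implicitly.
#'
#' @param path TSV path.
#' @export
read_contours <- function(path) {
  df <- read_tsv_checked(path, c("cell_id", "group", "vertex_index",
                                 "x", "y"))
  df$vertex_index <- as.integer(df$vertex_index)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  if (anyNA(df$x) || anyNA(df$y)) {
    stop("non-numeric coordinate in ", path, " at line ",
         which(is.na(df$x) | is.na(df$y))[1] + 1L)
  }
  tibble::as_tibble(df)
}

#' @rdname read_contours
#' @param contours Contour tibble to write.
#' @export
write_contours <- function(contours, path) {
  write_tsv(as.data.frame(contours)[c("cell_id", "group", "vertex_index",
                                      "x", "y")], path)
}

#' Read and write annotation tables
#'
#' Dialect: `gene_id`, `has_orf`, `is_tf` (0/1), `go_terms`
#' (semicolon-delimited, possibly empty).
#'
#' @param path TSV path.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "has_orf", "is_tf", "go_terms"))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene id in ", path, " at line ",
         first_dup_line(df$gene_id))
  }
  df$has_orf <- df$has_orf %in% c("1", "TRUE", "true")
  df$is_tf <- df$is_tf %in% c("1", "TRUE", "true")
  tibble::as_tibble(df)
}

#' @rdname read_annotation
#' @param annotation Annotation tibble to write.
#' @export
write_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)[c("gene_id", "has_orf", "is_tf",
                                    "go_terms")]
  df$has_orf <- as.integer(df$has_orf)
  df$is_tf <- as.integer(df$is_tf)
  write_tsv(df, path)
}

#' Read and write candidate reports
#'
#' Per-gene audit trail of the cascade; the summary attribute is
#' reconstructed on read.
#'
#' @param path TSV path.
#' @export
read_candidate_report <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "category", "direction",
                                 "stage_specificity", "exclusion_reason",
                                 "retained", "has_orf", "is_tf",
                                 "tf_candidate"))
  for (col in c("retained", "has_orf", "is_tf", "tf_candidate")) {
    df[[col]] <- df[[col]] %in% c("1", "TRUE", "true")
  }
  tibble::as_tibble(df)
}

#' @rdname read_candidate_report
#' @param report A `candidate_report` to write.
#' @export
write_candidate_report <- function(report, path) {
  df <- as.data.frame(report)[c("gene_id", "category", "direction",
                                "stage_specificity", "exclusion_reason",
                                "retained", "has_orf", "is_tf",
                                "tf_candidate")]
  for (col in c("retained", "has_orf", "is_tf", "tf_candidate")) {
    df[[col]] <- as.integer(df[[col]])
  }
  write_tsv(df, path)
}

#' Write an enrichment result table
#'
#' @param result Tibble from [enrich()].
#' @param path TSV path.
#' @export
write_enrichment <- function(result, path) {
  write_tsv(as.data.frame(result), path)
}
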