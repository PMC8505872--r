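# GO-term over-representation: hypergeometric upper tail, rare-term filter
# applied before testing, BH correction across the tested terms.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric: the probability of observing at least
#' `k` annotated genes in a study set of size `n` drawn from a population of
#' size `N` containing `K` annotated genes.
#'
#' @param k Study hits.
#' @param K Population hits (term size).
#' @param n Study size.
#' @param N Population size.
#' @return Upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(n, K))) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a term map from an annotation table
#'
#' Expands the semicolon-delimited `go_terms` column into (term, gene)
#' pairs.
#'
#' @param annotation Tibble with `gene_id` and `go_terms`.
#' @return Tibble with `term` and `gene_id`.
#' @export
term_map_from_annotation <- function(annotation) {
  stopifnot(all(c("gene_id", "go_terms") %in% names(annotation)))
  terms <- strsplit(annotation$go_terms, ";", fixed = TRUE)
  n <- vapply(terms, length, integer(1))
  out <- tibble::tibble(term = unlist(terms),
                        gene_id = rep(annotation$gene_id, n))
  out[out$term != "", ]
}

#' GO-term over-representation analysis
#'
#' One-sided hypergeometric enrichment of a study set against a population.
#' Terms with fewer than `min_term_size` annotated genes in the population
#' (rare ontologies) are removed *before* testing, so the BH correction runs
#' over the tested terms only; a term is flagged enriched when its q-value
#' is strictly below `fdr_threshold`.
#'
#' @param study_set Character vector of study gene ids (must be a subset of
#'   the population).
#' @param population Character vector of population gene ids (the
#'   transcriptome universe).
#' @param term_map Tibble with `term` and `gene_id` (extra columns such as
#'   `namespace` are carried through per term).
#' @param min_term_size Minimum population count for a term to be tested
#'   (default 5: rare terms `< 5` in the transcriptome are omitted).
#' @param fdr_threshold FDR cutoff for the enriched flag.
#' @param namespace Optional namespace label; when given (and `term_map`
#'   has a `namespace` column) only that namespace is tested, so each
#'   namespace gets its own BH correction.
#' @return Tibble per tested term: `term`, `k`, `n`, `K`, `N`, `pvalue`,
#'   `qvalue`, `enriched`, sorted by p-value.
#' @export
enrich <- function(study_set, population, term_map, min_term_size = 5,
                   fdr_threshold = 0.05, namespace = NULL) {
  if (!is.null(namespace)) {
    if (!"namespace" %in% names(term_map)) {
      stop("term_map has no namespace column")
    }
    term_map <- term_map[term_map$namespace %in% namespace, ]
  }
  study_set <- unique(study_set)
  population <- unique(population)
  bad <- setdiff(study_set, population)
  if (length(bad) > 0) {
    stop("study genes absent from the population: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tm <- term_map[term_map$gene_id %in% population, ]
  tm <- tm[!duplicated(tm[c("term", "gene_id")]), ]
  pop_count <- table(tm$term)
  tested <- names(pop_count)[pop_count >= min_term_size]
  if (length(tested) == 0) {
    return(tibble::tibble(term = character(0), k = integer(0),
                          n = integer(0), K = integer(0), N = integer(0),
                          pvalue = numeric(0), qvalue = numeric(0),
                          enriched = logical(0)))
  }
  n <- length(study_set)
  N <- length(population)
  in_study <- tm$gene_id %in% study_set
  k_count <- table(factor(tm$term[in_study], levels = tested))
  out <- tibble::tibble(
    term = tested,
    k = as.integer(k_count[tested]),
    n = n,
    K = as.integer(pop_count[tested]),
    N = N
  )
  out$pvalue <- hypergeom_upper_tail(out$k, out$K, out$n, out$N)
  out$qvalue <- bh_adjust(out$pvalue)
  out$enriched <- out$qvalue < fdr_threshold
  if ("namespace" %in% names(term_map)) {
    ns <- term_map$namespace[match(out$term, term_map$term)]
    out <- tibble::add_column(out, namespace = ns, .after = "term")
  }
  out[order(out$pvalue), ]
}
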