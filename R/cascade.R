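# The candidate-gene cascade: direction-consistent DEG intersection
# categories, stage-specificity classification, cross-species ortholog
# exclusion, and transcription-factor candidate selection.

check_universe <- function(deg_tables) {
  ids <- lapply(deg_tables, function(d) sort(d$gene_id))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("DEG tables do not share a gene universe")
  }
  invisible(TRUE)
}

#' Assign shared DEG categories across the four treatment comparisons
#'
#' A gene is `SHARED4` when it is a DEG with the same sign in all four
#' treatment-vs-submerged comparisons (aerial, AgNO3, ABA, uniconazole P);
#' `SHARED3_NOT_UNI` when it is a same-sign DEG in aerial, AgNO3 and ABA but
#' not a DEG (either sign) in uniconazole P; otherwise `NONE`. The two
#' colored categories are disjoint by construction.
#'
#' @param deg_tables Named list of four `deg_table`s with elements `aerial`,
#'   `agno3`, `aba`, `uniconazole`, sharing one gene universe.
#' @return Tibble with `gene_id`, `category`, and `direction` (the shared
#'   sign: `"up"`/`"down"` in the treatments relative to the submerged
#'   control; `NA` for `NONE`).
#' @export
assign_shared_categories <- function(deg_tables) {
  need <- c("aerial", "agno3", "aba", "uniconazole")
  if (!all(need %in% names(deg_tables))) {
    stop("deg_tables must be a named list with elements: ",
         paste(need, collapse = ", "))
  }
  deg_tables <- deg_tables[need]
  check_universe(deg_tables)
  g <- sort(deg_tables$aerial$gene_id)
  calls <- vapply(deg_tables, function(d) {
    d$call[match(g, d$gene_id)]
  }, character(length(g)))
  three_same <- calls[, "aerial"] != "none" &
    calls[, "aerial"] == calls[, "agno3"] &
    calls[, "aerial"] == calls[, "aba"]
  shared4 <- three_same & calls[, "uniconazole"] == calls[, "aerial"]
  shared3 <- three_same & calls[, "uniconazole"] == "none"
  category <- ifelse(shared4, "SHARED4",
                     ifelse(shared3, "SHARED3_NOT_UNI", "NONE"))
  tibble::tibble(
    gene_id = g,
    category = category,
    direction = ifelse(category == "NONE", NA_character_, calls[, "aerial"])
  )
}

#' Classify candidates by developmental-stage specificity
#'
#' A candidate is `dev_and_mature` when it is a DEG (either sign) in the
#' mature aerial-vs-submerged comparison, else `dev_specific`; the two
#' labels partition the candidate set.
#'
#' @param candidates Character vector of candidate gene ids, or a tibble
#'   with a `gene_id` column.
#' @param mature_deg_table `deg_table` for the mature-leaf comparison; its
#'   gene universe must cover the candidates.
#' @return Tibble with `gene_id` and `stage_specificity`.
#' @export
classify_stage_specificity <- function(candidates, mature_deg_table) {
  if (is.data.frame(candidates)) candidates <- candidates$gene_id
  miss <- setdiff(candidates, mature_deg_table$gene_id)
  if (length(miss) > 0) {
    stop("candidates absent from the mature comparison's gene universe: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  call <- mature_deg_table$call[match(candidates, mature_deg_table$gene_id)]
  tibble::tibble(
    gene_id = candidates,
    stage_specificity = ifelse(call == "none", "dev_specific",
                               "dev_and_mature")
  )
}

#' Cross-species ortholog exclusion
#'
#' Drops candidates whose behavior in the nonheterophyllous diploid species
#' argues against a role in heterophylly, in the study's order of
#' precedence: (1) `ct_consistent_deg` -- the candidate has a comparable
#' ortholog that is a DEG in the diploid species with the same direction as
#' the candidate; (2) `downreg_ct_unexpressed` -- the candidate is
#' downregulated in submerged primordia (i.e. up in the aerial comparison)
#' and has a comparable ortholog whose TPM is below `tpm_threshold` in every
#' diploid sample. Candidates with no comparable ortholog are always
#' retained. A diploid DEG excludes all of its tetraploid co-orthologs.
#'
#' @param candidates Tibble with `gene_id` and `direction` (`"up"`/`"down"`
#'   in the treatments relative to the submerged control, i.e. the
#'   aerial-vs-submerged sign).
#' @param ortho An [orthology_map()].
#' @param ct_deg_table `deg_table` of the diploid aerial-vs-submerged
#'   comparison (same reference convention). Orthologs absent from it are
#'   treated as non-DEGs (the low-expression filter removes them
#'   legitimately).
#' @param ct_tpm TPM matrix for the diploid species (all genes); every
#'   referenced ortholog must be present.
#' @param tpm_threshold Expression floor defining "not expressed" (default
#'   1, the study's filter value).
#' @return Tibble with `gene_id`, `direction`, `exclusion_reason`
#'   (`none` / `ct_consistent_deg` / `downreg_ct_unexpressed`), `retained`.
#' @export
apply_crossspecies_exclusion <- function(candidates, ortho, ct_deg_table,
                                         ct_tpm, tpm_threshold = 1) {
  stopifnot(inherits(ortho, "orthology_map"),
            all(c("gene_id", "direction") %in% names(candidates)))
  links <- ortho$links[ortho$links$cp_gene %in% candidates$gene_id, ]
  miss <- setdiff(links$ct_gene, rownames(ct_tpm))
  if (length(miss) > 0) {
    stop("orthologs absent from the diploid TPM table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  ct_call <- stats::setNames(ct_deg_table$call, ct_deg_table$gene_id)
  ct_unexpressed <- apply(ct_tpm < tpm_threshold, 1, all)
  reason <- rep("none", nrow(candidates))
  names(reason) <- candidates$gene_id
  for (i in seq_len(nrow(links))) {
    cand <- links$cp_gene[i]
    ct <- links$ct_gene[i]
    dir_cand <- candidates$direction[match(cand, candidates$gene_id)]
    call_ct <- ct_call[ct]
    if (!is.na(call_ct) && call_ct != "none" && call_ct == dir_cand) {
      reason[cand] <- "ct_consistent_deg"
    }
  }
  for (i in seq_len(nrow(links))) {
    cand <- links$cp_gene[i]
    if (reason[cand] != "none") next   # precedence: ct_consistent_deg first
    dir_cand <- candidates$direction[match(cand, candidates$gene_id)]
    if (identical(unname(dir_cand), "up") &&
        ct_unexpressed[links$ct_gene[i]]) {
      reason[cand] <- "downreg_ct_unexpressed"
    }
  }
  tibble::tibble(
    gene_id = candidates$gene_id,
    direction = candidates$direction,
    exclusion_reason = unname(reason[candidates$gene_id]),
    retained = unname(reason[candidates$gene_id]) == "none"
  )
}

#' Select transcription-factor candidates
#'
#' The TF candidate subset is the retained genes that carry a predicted
#' coding region (ORF) and a TF-family flag; the up/down split in submerged
#' leaves is reported alongside (a gene "up in submerged" is down in the
#' aerial-vs-submerged comparison).
#'
#' @param retained Tibble with `gene_id` and `direction` for the retained
#'   candidates (or a character vector of ids, in which case the split is
#'   omitted).
#' @param annotation Tibble with `gene_id`, `has_orf`, `is_tf` covering all
#'   retained genes.
#' @return Tibble of selected TF candidates, with attribute `"summary"`
#'   (`n_tf`, `n_up_submerged`, `n_down_submerged`).
#' @export
select_tf_candidates <- function(retained, annotation) {
  if (!is.data.frame(retained)) {
    retained <- tibble::tibble(gene_id = retained, direction = NA_character_)
  }
  idx <- match(retained$gene_id, annotation$gene_id)
  if (anyNA(idx)) stop("annotation flags missing for some retained genes")
  has_orf <- annotation$has_orf[idx]
  is_tf <- annotation$is_tf[idx] & has_orf   # TF implies ORF
  out <- retained[is_tf, , drop = FALSE]
  out <- tibble::as_tibble(out)
  attr(out, "summary") <- c(
    n_tf = nrow(out),
    n_up_submerged = sum(out$direction == "down", na.rm = TRUE),
    n_down_submerged = sum(out$direction == "up", na.rm = TRUE)
  )
  out
}

# Exclusive UpSet-style intersection counts over named DEG call sets,
# split by shared direction.
upset_counts <- function(deg_tables) {
  check_universe(deg_tables)
  g <- sort(deg_tables[[1]]$gene_id)
  out <- list()
  for (dir in c("up", "down")) {
    member <- vapply(deg_tables, function(d) {
      d$call[match(g, d$gene_id)] == dir
    }, logical(length(g)))
    key <- apply(member, 1, function(m) {
      paste(names(deg_tables)[m], collapse = "&")
    })
    tab <- table(key[key != ""])
    out[[dir]] <- tibble::tibble(direction = dir,
                                 comparisons = names(tab),
                                 n_genes = as.integer(tab))
  }
  do.call(rbind, out)
}

#' Run the full candidate cascade
#'
#' Category assignment, stage classification, cross-species exclusion, and
#' TF selection, composed in the study's order, with a per-gene audit trail
#' and UpSet-style intersection counts.
#'
#' @param deg_tables Named list with the five tetraploid comparisons:
#'   `aerial`, `agno3`, `aba`, `uniconazole` (primordia) and `mature`.
#' @param ortho An [orthology_map()].
#' @param ct_deg_table Diploid aerial-vs-submerged `deg_table`.
#' @param ct_tpm Diploid TPM matrix.
#' @param annotation Tibble with `gene_id`, `has_orf`, `is_tf`.
#' @param tpm_threshold Diploid expression floor for the unexpressed rule.
#' @return A `candidate_report`: per-gene tibble (`gene_id`, `category`,
#'   `direction`, `stage_specificity`, `exclusion_reason`, `retained`,
#'   `has_orf`, `is_tf`, `tf_candidate`) restricted to the candidate set,
#'   with attributes `"summary"` (the cascade's set arithmetic) and
#'   `"upset"` (intersection counts over the five comparisons).
#' @export
run_cascade <- function(deg_tables, ortho, ct_deg_table, ct_tpm, annotation,
                        tpm_threshold = 1) {
  need <- c("aerial", "agno3", "aba", "uniconazole", "mature")
  if (!all(need %in% names(deg_tables))) {
    stop("deg_tables must contain: ", paste(need, collapse = ", "))
  }
  cats <- assign_shared_categories(deg_tables[c("aerial", "agno3", "aba",
                                                "uniconazole")])
  cand <- cats[cats$category != "NONE", ]
  stage <- classify_stage_specificity(cand$gene_id, deg_tables$mature)
  excl <- apply_crossspecies_exclusion(cand, ortho, ct_deg_table, ct_tpm,
                                       tpm_threshold)
  report <- tibble::tibble(
    gene_id = cand$gene_id,
    category = cand$category,
    direction = cand$direction,
    stage_specificity = stage$stage_specificity,
    exclusion_reason = excl$exclusion_reason,
    retained = excl$retained
  )
  idx <- match(report$gene_id, annotation$gene_id)
  if (anyNA(idx)) stop("annotation missing for some candidate genes")
  report$has_orf <- annotation$has_orf[idx]
  report$is_tf <- annotation$is_tf[idx] & report$has_orf
  tf <- select_tf_candidates(report[report$retained,
                                    c("gene_id", "direction")], annotation)
  report$tf_candidate <- report$retained & report$gene_id %in% tf$gene_id
  summary <- c(
    n_shared4 = sum(report$category == "SHARED4"),
    n_shared3_not_uni = sum(report$category == "SHARED3_NOT_UNI"),
    n_candidates = nrow(report),
    n_dev_specific = sum(report$stage_specificity == "dev_specific"),
    n_dev_and_mature = sum(report$stage_specificity == "dev_and_mature"),
    n_excluded_ct_consistent = sum(report$exclusion_reason ==
                                     "ct_consistent_deg"),
    n_excluded_ct_unexpressed = sum(report$exclusion_reason ==
                                      "downreg_ct_unexpressed"),
    n_retained = sum(report$retained),
    n_retained_no_ortholog = sum(report$retained &
                                   !(report$gene_id %in% ortho$links$cp_gene)),
    n_retained_orf = sum(report$retained & report$has_orf),
    n_tf_candidates = sum(report$tf_candidate),
    n_tf_up_submerged = sum(report$tf_candidate & report$direction == "down")
  )
  attr(report, "summary") <- summary
  attr(report, "upset") <- upset_counts(deg_tables)
  class(report) <- c("candidate_report", class(report))
  report
}

#' @export
print.candidate_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("candidate_report:", s["n_candidates"], "candidate genes (",
      s["n_shared4"], "SHARED4 +", s["n_shared3_not_uni"],
      "SHARED3_NOT_UNI )\n")
  cat("  stage:", s["n_dev_specific"], "dev-specific,",
      s["n_dev_and_mature"], "dev-and-mature\n")
  cat("  excluded:", s["n_excluded_ct_consistent"], "ortholog same-direction DEG,",
      s["n_excluded_ct_unexpressed"], "downregulated with unexpressed ortholog\n")
  cat("  retained:", s["n_retained"], "(", s["n_retained_no_ortholog"],
      "without ortholog,", s["n_retained_orf"], "with ORF )\n")
  cat("  TF candidates:", s["n_tf_candidates"], "(",
      s["n_tf_up_submerged"], "up in submerged )\n")
  invisible(x)
}
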