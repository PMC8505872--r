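# Worked-example inputs for the cascade at the DEG-table level: planted
# per-comparison signed calls, an orthology map, diploid DEG/TPM tables and
# annotation flags realizing the reference set arithmetic of the emulated
# study, so the cascade's category totals can be checked exactly.

flat_deg_table <- function(gene_ids, signs, comparison, effect = 2) {
  is_deg <- signs != 0
  out <- tibble::tibble(
    gene_id = gene_ids,
    comparison = comparison,
    log2fc = ifelse(is_deg, signs * effect, 0.05 * sign(signs + 0.5)),
    pvalue = ifelse(is_deg, 1e-6, 0.5),
    qvalue = ifelse(is_deg, 1e-4, 0.6),
    call = ifelse(signs > 0, "up", ifelse(signs < 0, "down", "none"))
  )
  class(out) <- c("deg_table", class(out))
  out
}

#' Worked-example cascade inputs
#'
#' Builds gene-level DEG tables for the four treatment-vs-submerged
#' comparisons plus the mature comparison, an orthology map, diploid
#' DEG/TPM tables, and annotation flags, with planted category sizes
#' defaulting to the emulated study's set arithmetic: 200 genes called with
#' a consistent sign in all four comparisons and 87 in aerial/AgNO3/ABA but
#' not uniconazole (287 candidates); 22 candidates whose comparable
#' orthologs are same-direction diploid DEGs and 15 submerged-downregulated
#' candidates with unexpressed orthologs (so 250 are retained, 145 of them
#' without an ortholog); 134 of the 287 also differential in mature leaves;
#' 208 retained genes with predicted ORFs, 19 of them TFs (5 upregulated in
#' submerged leaves). Background genes carry partial or sign-inconsistent
#' patterns only.
#'
#' @param seed Seed for the background patterns (the planted totals are
#'   exact for every seed).
#' @param n_background Number of background genes.
#' @param sizes Named list overriding individual category sizes (same names
#'   as in [simulate_experiment()]).
#' @return List with `deg_tables` (named list: `aerial`, `agno3`, `aba`,
#'   `uniconazole`, `mature`), `ortho`, `ct_deg_table`, `ct_tpm`,
#'   `annotation`, and `truth`.
#' @export
cascade_example_inputs <- function(seed = 1, n_background = 1000,
                                   sizes = list()) {
  sz <- utils::modifyList(list(
    shared4 = 200, shared3 = 87, ct_consistent = 22, ct_unexpressed = 15,
    no_ortholog = 145, orf_retained = 208, tf = 19, tf_up_submerged = 5,
    mature_shared = 134
  ), sizes)
  n_cand <- sz$shared4 + sz$shared3
  n_retained <- n_cand - sz$ct_consistent - sz$ct_unexpressed
  ids <- sprintf("Cp%05d", seq_len(n_cand + n_background))
  cand <- seq_len(n_cand)
  bg <- n_cand + seq_len(n_background)

  # planted shared categories and directions
  n_up4 <- ceiling(sz$shared4 / 2)
  n_up3 <- ceiling(sz$shared3 / 2)
  direction <- rep(0, length(ids))
  direction[seq_len(sz$shared4)] <- rep(c(1, -1), c(n_up4, sz$shared4 - n_up4))
  direction[sz$shared4 + seq_len(sz$shared3)] <-
    rep(c(1, -1), c(n_up3, sz$shared3 - n_up3))
  category <- rep("BACKGROUND", length(ids))
  category[seq_len(sz$shared4)] <- "SHARED4"
  category[sz$shared4 + seq_len(sz$shared3)] <- "SHARED3_NOT_UNI"

  signs <- matrix(0, length(ids), 4,
                  dimnames = list(ids, c("aerial", "agno3", "aba",
                                         "uniconazole")))
  signs[category == "SHARED4", ] <- direction[category == "SHARED4"]
  signs[category == "SHARED3_NOT_UNI", 1:3] <-
    direction[category == "SHARED3_NOT_UNI"]
  with_seed(seed, {
    for (i in bg) {
      repeat {
        members <- which(stats::runif(4) < 0.4)
        if (length(members) == 0) break   # most background genes are null
        s <- sample(c(-1, 1), length(members), replace = TRUE)
        pat <- numeric(4); pat[members] <- s
        ok4 <- all(pat != 0) && length(unique(pat)) == 1
        ok3 <- all(pat[1:3] != 0) && length(unique(pat[1:3])) == 1 &&
          pat[4] == 0
        if (!ok4 && !ok3) { signs[i, members] <- s; break }
      }
    }
    signs <- signs
  })

  deg_tables <- lapply(stats::setNames(colnames(signs), colnames(signs)),
                       function(cmp) flat_deg_table(ids, signs[, cmp], cmp))

  # mature-leaf status: planted subset of the candidates
  n_mat4 <- min(sz$shared4, ceiling(sz$mature_shared * sz$shared4 / n_cand))
  mature_sign <- rep(0, length(ids))
  mature_sign[seq_len(n_mat4)] <- direction[seq_len(n_mat4)]
  mat3 <- sz$shared4 + seq_len(sz$mature_shared - n_mat4)
  mature_sign[mat3] <- direction[mat3]
  deg_tables$mature <- flat_deg_table(ids, mature_sign, "mature")

  # exclusion layout (from the SHARED4 pool: half the consistent-DEG
  # orthologs up, half down; unexpressed orthologs only for downregulated-
  # in-submerged candidates, i.e. direction +1)
  n_cc_up <- ceiling(sz$ct_consistent / 2)
  cc_idx <- c(seq_len(n_cc_up), n_up4 + seq_len(sz$ct_consistent - n_cc_up))
  cu_idx <- n_cc_up + seq_len(sz$ct_unexpressed)
  exclusion <- rep("none", length(ids))
  exclusion[cc_idx] <- "ct_consistent_deg"
  exclusion[cu_idx] <- "downreg_ct_unexpressed"
  retained_idx <- cand[exclusion[cand] == "none"]
  linked_idx <- c(cc_idx, cu_idx,
                  retained_idx[seq_len(n_retained - sz$no_ortholog)])
  ct_ids <- sprintf("Ct%05d", seq_along(linked_idx))
  links <- tibble::tibble(ct_gene = ct_ids, cp_gene = ids[linked_idx],
                          relation = "one_to_one")
  # every third link becomes one_to_multi via a background co-ortholog
  multi <- seq(1, nrow(links), by = 3)
  extra <- tibble::tibble(ct_gene = ct_ids[multi],
                          cp_gene = ids[bg[seq_along(multi)]],
                          relation = "one_to_multi")
  links$relation[multi] <- "one_to_multi"
  all_links <- rbind(links, extra)
  ortho <- orthology_map(all_links,
                         orphans = setdiff(ids, all_links$cp_gene))

  ct_sign <- rep(0, length(ct_ids))
  ct_sign[seq_along(cc_idx)] <- direction[linked_idx[seq_along(cc_idx)]]
  ct_deg_table <- flat_deg_table(ct_ids, ct_sign, "ct_aerial_vs_submerged")
  ct_tpm <- matrix(50, length(ct_ids), 6,
                   dimnames = list(ct_ids, sprintf("ct_s%d", 1:6)))
  unexpr <- length(cc_idx) + seq_len(sz$ct_unexpressed)
  ct_tpm[unexpr, ] <- 0.01

  has_orf <- rep(FALSE, length(ids))
  has_orf[retained_idx[seq_len(sz$orf_retained)]] <- TRUE
  has_orf[c(cc_idx, cu_idx)] <- TRUE
  has_orf[bg] <- TRUE
  is_tf <- rep(FALSE, length(ids))
  orf_ret <- retained_idx[has_orf[retained_idx]]
  is_tf[orf_ret[direction[orf_ret] == 1][
    seq_len(sz$tf - sz$tf_up_submerged)]] <- TRUE
  is_tf[orf_ret[direction[orf_ret] == -1][
    seq_len(sz$tf_up_submerged)]] <- TRUE
  annotation <- tibble::tibble(gene_id = ids, has_orf = has_orf,
                               is_tf = is_tf, go_terms = "")

  truth <- tibble::tibble(
    gene_id = ids, category = category, direction = direction,
    exclusion = exclusion,
    mature_deg = mature_sign != 0,
    has_ortholog = ids %in% all_links$cp_gene,
    has_orf = has_orf, is_tf = is_tf
  )
  list(deg_tables = deg_tables, ortho = ortho,
       ct_deg_table = ct_deg_table, ct_tpm = ct_tpm,
       annotation = annotation, truth = truth)
}
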