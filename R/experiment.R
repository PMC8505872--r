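# The default simulated experiment: a full two-species bundle (counts,
# orthology, annotation) whose planted structure mirrors the study's set
# arithmetic, so the candidate cascade can be validated end to end against
# known truth.

# Background genes get partial or sign-inconsistent DEG patterns that must
# never satisfy a shared category: not all four same sign, and not
# (aerial/AgNO3/ABA same sign with uniconazole null).
background_patterns <- function(n_bg, n_planted, comparisons, effect_size) {
  lfc <- matrix(0, n_bg, 4, dimnames = list(NULL, comparisons))
  if (n_planted == 0) return(lfc)
  idx <- seq_len(n_planted)
  for (i in idx) {
    repeat {
      members <- which(stats::runif(4) < 0.5)
      if (length(members) == 0) next
      signs <- sample(c(-1, 1), length(members), replace = TRUE)
      pat <- numeric(4)
      pat[members] <- signs
      shared4 <- all(pat != 0) && length(unique(sign(pat))) == 1
      shared3 <- all(pat[1:3] != 0) && length(unique(sign(pat[1:3]))) == 1 &&
        pat[4] == 0
      if (!shared4 && !shared3) break
    }
    lfc[i, members] <- signs * effect_size
  }
  lfc
}

#' Simulate the full comparative two-species experiment
#'
#' Generates every input of the candidate-gene cascade with known truth:
#' a tetraploid (*C. palustris*-like) count matrix over five primordium
#' conditions plus mature aerial/submerged leaves; a diploid
#' (*C. terrestris*-like) count matrix over aerial/submerged primordia; an
#' orthology map; and an annotation table (ORF flag, TF flag, GO terms).
#' Planted category sizes default to the set arithmetic of the study:
#' 200 genes differential with consistent sign in all four
#' treatment-vs-submerged comparisons (SHARED4), 87 consistent in
#' aerial/AgNO3/ABA but null in uniconazole (SHARED3_NOT_UNI); of these 287,
#' 22 carry orthologs that are same-direction diploid DEGs and 15 are
#' submerged-downregulated with unexpressed orthologs (both planted for
#' exclusion); 145 of the 250 genes planted for retention lack an ortholog;
#' 208 carry predicted ORFs of which 19 are TFs (5 upregulated in submerged
#' leaves); 134 of the 287 are also differential in mature leaves.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_genes Tetraploid gene count.
#' @param n_ct_background Diploid background genes beyond the ortholog
#'   partners of planted candidates.
#' @param sizes Named list of planted category sizes (see Details); any
#'   element can be overridden.
#' @param effect_size Planted |log2 fold-change| (relative to the submerged
#'   control).
#' @param baseline Baseline mean count for planted genes.
#' @param dispersion NB dispersion phi.
#' @param depth Expected per-sample total counts.
#' @param replicates Replicates per design cell.
#' @param bg_pattern_frac Fraction of background genes given partial or
#'   sign-inconsistent DEG patterns.
#' @return A list with elements `cp_design`, `cp_profiles`, `cp_counts`,
#'   `ct_design`, `ct_profiles`, `ct_counts`, `orthology`, `annotation`,
#'   and `truth` (per-gene planted category, direction, exclusion fate,
#'   mature status, flags).
#' @export
simulate_experiment <- function(seed = 1, n_genes = 10000,
                                n_ct_background = 2500,
                                sizes = list(), effect_size = 2,
                                baseline = 100, dispersion = 0.05,
                                depth = 5e6, replicates = 3,
                                bg_pattern_frac = 0.05) {
  sz <- utils::modifyList(list(
    shared4 = 200, shared3 = 87, ct_consistent = 22, ct_unexpressed = 15,
    no_ortholog = 145, orf_retained = 208, tf = 19, tf_up_submerged = 5,
    mature_shared = 134, ct_background_deg = 150
  ), sizes)
  n_cand <- sz$shared4 + sz$shared3
  if (sz$ct_consistent + sz$ct_unexpressed > sz$shared4) {
    stop("exclusion categories exceed the SHARED4 pool they are planted in")
  }
  n_retained <- n_cand - sz$ct_consistent - sz$ct_unexpressed
  if (sz$no_ortholog > n_retained || sz$orf_retained > n_retained ||
      sz$tf > sz$orf_retained || sz$mature_shared > n_cand) {
    stop("inconsistent planted category sizes")
  }
  if (n_genes < 2 * n_cand) stop("n_genes too small for the planted layout")

  design <- cp_design(n_genes, replicates, depth, seed = seed)
  ids <- design$gene_ids

  # --- truth layout (deterministic in gene order) -------------------------
  category <- rep("BACKGROUND", n_genes)
  category[seq_len(sz$shared4)] <- "SHARED4"
  category[sz$shared4 + seq_len(sz$shared3)] <- "SHARED3_NOT_UNI"
  n_up4 <- ceiling(sz$shared4 / 2)
  n_up3 <- ceiling(sz$shared3 / 2)
  direction <- rep(NA_real_, n_genes)
  direction[seq_len(sz$shared4)] <- rep(c(1, -1), c(n_up4, sz$shared4 - n_up4))
  direction[sz$shared4 + seq_len(sz$shared3)] <-
    rep(c(1, -1), c(n_up3, sz$shared3 - n_up3))

  exclusion <- rep("none", n_genes)
  # same-direction diploid DEG orthologs: half up, half down, from SHARED4
  n_cc_up <- ceiling(sz$ct_consistent / 2)
  cc_idx <- c(seq_len(n_cc_up),                      # up-direction SHARED4
              n_up4 + seq_len(sz$ct_consistent - n_cc_up))  # down-direction
  exclusion[cc_idx] <- "ct_consistent_deg"
  # downregulated-in-submerged candidates (direction +1) with unexpressed
  # orthologs; planted after the ct-consistent block of the up half
  cu_idx <- n_cc_up + seq_len(sz$ct_unexpressed)
  exclusion[cu_idx] <- "downreg_ct_unexpressed"

  cand_idx <- seq_len(n_cand)
  retained_idx <- cand_idx[exclusion[cand_idx] == "none"]
  has_ortholog <- rep(FALSE, n_genes)
  has_ortholog[exclusion != "none"] <- TRUE
  with_ortho_retained <- retained_idx[seq_len(n_retained - sz$no_ortholog)]
  has_ortholog[with_ortho_retained] <- TRUE

  has_orf <- rep(FALSE, n_genes)
  has_orf[retained_idx[seq_len(sz$orf_retained)]] <- TRUE
  has_orf[exclusion != "none"] <- TRUE
  is_tf <- rep(FALSE, n_genes)
  orf_ret <- retained_idx[has_orf[retained_idx]]
  tf_down <- orf_ret[direction[orf_ret] == -1][seq_len(sz$tf_up_submerged)]
  tf_up <- orf_ret[direction[orf_ret] == 1][seq_len(sz$tf - sz$tf_up_submerged)]
  is_tf[c(tf_up, tf_down)] <- TRUE

  mature_deg <- rep(FALSE, n_genes)
  n_mat4 <- min(sz$shared4, ceiling(sz$mature_shared * sz$shared4 / n_cand))
  mature_deg[seq_len(n_mat4)] <- TRUE
  mature_deg[sz$shared4 + seq_len(sz$mature_shared - n_mat4)] <- TRUE

  # --- planted fold-changes ----------------------------------------------
  comparisons <- c("aerial|primordium", "submerged_AgNO3|primordium",
                   "submerged_ABA|primordium", "submerged_uniconazole|primordium")
  lfc <- matrix(0, n_genes, 5,
                dimnames = list(ids, c(comparisons, "aerial|mature")))
  with_seed(seed + 101L, {
    sel4 <- category == "SHARED4"
    lfc[sel4, comparisons] <- direction[sel4] * effect_size
    sel3 <- category == "SHARED3_NOT_UNI"
    lfc[sel3, comparisons[1:3]] <- direction[sel3] * effect_size
    lfc[mature_deg, "aerial|mature"] <-
      direction[mature_deg] * effect_size
    bg <- which(category == "BACKGROUND")
    n_pat <- round(length(bg) * bg_pattern_frac)
    lfc[bg, comparisons] <- background_patterns(length(bg), n_pat,
                                                comparisons, effect_size)
    # background ORF/TF flags (TF selection must ignore non-candidates)
    has_orf[bg] <- stats::runif(length(bg)) < 0.7
    is_tf[bg] <- has_orf[bg] & stats::runif(length(bg)) < 0.03
  })

  base_vec <- with_seed(seed + 102L, {
    b <- stats::rlnorm(n_genes, log(100), 1.2)
    b <- b * depth / sum(b)
    b[category != "BACKGROUND"] <- baseline
    b
  })
  cp_profiles <- planted_profiles(design, baseline = base_vec,
                                  dispersion = dispersion, lfc = lfc,
                                  category = category)
  cp_counts <- simulate_counts(design, cp_profiles, seed = seed + 1L)

  # --- diploid side: ortholog partners + background -----------------------
  needs_link <- which(has_ortholog)
  n_partner <- length(needs_link)
  ct_n <- n_partner + n_ct_background
  ct_des <- ct_design(ct_n, replicates, depth, seed = seed + 3L)
  ct_ids <- ct_des$gene_ids
  partner_of <- stats::setNames(ct_ids[seq_len(n_partner)], ids[needs_link])

  ct_lfc <- matrix(0, ct_n, 1,
                   dimnames = list(ct_ids, "aerial|primordium"))
  ct_base <- with_seed(seed + 104L, {
    b <- stats::rlnorm(ct_n, log(100), 1.2)
    b * depth / sum(b)
  })
  for (i in seq_along(needs_link)) {
    g <- needs_link[i]
    ct_g <- ct_ids[i]
    if (exclusion[g] == "ct_consistent_deg") {
      ct_lfc[ct_g, 1] <- direction[g] * effect_size
      ct_base[i] <- baseline
    } else if (exclusion[g] == "downreg_ct_unexpressed") {
      ct_base[i] <- 0.02    # unexpressed: TPM far below the floor everywhere
    } else {
      ct_base[i] <- baseline
    }
  }
  ct_category <- rep("BACKGROUND", ct_n)
  ct_category[seq_len(n_partner)] <-
    paste0("PARTNER_", toupper(exclusion[needs_link]))
  with_seed(seed + 105L, {
    bg_ct <- n_partner + seq_len(n_ct_background)
    deg_ct <- sample(bg_ct, sz$ct_background_deg)
    ct_lfc[deg_ct, 1] <- sample(c(-1, 1), sz$ct_background_deg,
                                replace = TRUE) * effect_size
    ct_category[deg_ct] <- "CT_BACKGROUND_DEG"
  })
  ct_profiles <- planted_profiles(ct_des, baseline = ct_base,
                                  dispersion = dispersion, lfc = ct_lfc,
                                  category = ct_category)
  ct_counts <- simulate_counts(ct_des, ct_profiles, seed = seed + 2L)

  # --- orthology map -------------------------------------------------------
  ortho <- with_seed(seed + 106L, {
    links <- tibble::tibble(ct_gene = unname(partner_of),
                            cp_gene = names(partner_of),
                            relation = "one_to_one")
    free_bg <- setdiff(ids[category == "BACKGROUND" & !has_ortholog],
                       character(0))
    free_bg <- sample(free_bg)
    # every third candidate partner becomes one_to_multi via a background
    # co-ortholog (a diploid DEG must then exclude ALL its co-orthologs)
    multi <- seq(1, n_partner, by = 3)
    extra <- tibble::tibble(ct_gene = ct_ids[multi],
                            cp_gene = free_bg[seq_along(multi)],
                            relation = "one_to_multi")
    links$relation[links$ct_gene %in% extra$ct_gene] <- "one_to_multi"
    free_bg <- free_bg[-seq_along(multi)]
    # background diploid genes link 1-2 background tetraploid genes
    bg_ct <- ct_ids[n_partner + seq_len(n_ct_background)]
    k <- 1L + stats::rbinom(n_ct_background, 1, 0.52)
    need <- cumsum(k)
    usable <- which(need <= length(free_bg))
    bg_links <- tibble::tibble(
      ct_gene = rep(bg_ct[usable], k[usable]),
      cp_gene = free_bg[seq_len(need[length(usable)])],
      relation = rep(ifelse(k[usable] == 2, "one_to_multi", "one_to_one"),
                     k[usable])
    )
    all_links <- rbind(links, extra, bg_links)
    orthology_map(all_links,
                  orphans = setdiff(ids, all_links$cp_gene))
  })

  # --- annotation: flags + GO terms ---------------------------------------
  annotation <- with_seed(seed + 107L, {
    vocab <- sprintf("GO:%07d", 2:39)
    terms <- lapply(seq_len(n_genes), function(i) {
      if (!has_orf[i]) return(character(0))
      sample(vocab, sample(1:4, 1))
    })
    # planted enriched term: 15 retained candidates + 15 background genes
    enr <- c(ids[retained_idx[seq_len(15)]],
             sample(ids[category == "BACKGROUND"], 15))
    for (g in enr) terms[[match(g, ids)]] <-
      union(terms[[match(g, ids)]], "GO:0000001")
    # planted rare term (population count 4, removed by the <5 rule)
    for (g in sample(ids, 4)) terms[[match(g, ids)]] <-
      union(terms[[match(g, ids)]], "GO:0000040")
    tibble::tibble(gene_id = ids, has_orf = has_orf, is_tf = is_tf,
                   go_terms = vapply(terms, paste, character(1),
                                     collapse = ";"))
  })

  truth <- tibble::tibble(
    gene_id = ids, category = category, direction = direction,
    exclusion = exclusion, mature_deg = mature_deg,
    has_ortholog = ids %in% ortho$links$cp_gene,
    has_orf = has_orf, is_tf = is_tf
  )
  list(cp_design = design, cp_profiles = cp_profiles, cp_counts = cp_counts,
       ct_design = ct_des, ct_profiles = ct_profiles, ct_counts = ct_counts,
       orthology = ortho, annotation = annotation, truth = truth)
}
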