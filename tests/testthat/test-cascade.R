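# The candidate cascade: shared categories, stage specificity,
# cross-species exclusion, TF selection, and the composed report.

mini_deg <- function(ids, calls, comparison = "c") {
  lfc <- ifelse(calls == "up", 2, ifelse(calls == "down", -2, 0.1))
  q <- ifelse(calls == "none", 0.5, 0.001)
  out <- tibble::tibble(gene_id = ids, comparison = comparison,
                        log2fc = lfc, pvalue = q / 10, qvalue = q,
                        call = calls)
  class(out) <- c("deg_table", class(out))
  out
}

test_that("shared categories require sign consistency across comparisons", {
  ids <- paste0("g", 1:6)
  tabs <- list(
    aerial      = mini_deg(ids, c("up", "up",   "up",   "down", "none", "up")),
    agno3       = mini_deg(ids, c("up", "up",   "up",   "down", "up",   "up")),
    aba         = mini_deg(ids, c("up", "up",   "up",   "down", "up",   "down")),
    uniconazole = mini_deg(ids, c("up", "none", "down", "down", "none", "none"))
  )
  cats <- assign_shared_categories(tabs)
  expect_equal(cats$category[match(ids, cats$gene_id)],
               c("SHARED4",          # up in all four
                 "SHARED3_NOT_UNI",  # up in three, none in uniconazole
                 "NONE",             # sign flip in uniconazole
                 "SHARED4",          # down in all four
                 "NONE",             # partial membership
                 "NONE"))            # sign flip within the three
  expect_equal(cats$direction[match(c("g1", "g4"), cats$gene_id)],
               c("up", "down"))
  # the two colored categories are disjoint by construction
  expect_equal(sum(cats$category == "SHARED4" &
                     cats$category == "SHARED3_NOT_UNI"), 0)
  # mismatched universes are an error
  tabs$aba <- mini_deg(paste0("h", 1:6), rep("none", 6))
  expect_error(assign_shared_categories(tabs), "universe")
})

test_that("stage specificity partitions the candidate set", {
  ids <- paste0("g", 1:5)
  mature <- mini_deg(ids, c("up", "down", "none", "none", "up"))
  lab <- classify_stage_specificity(ids[1:4], mature)
  expect_equal(lab$stage_specificity,
               c("dev_and_mature", "dev_and_mature",
                 "dev_specific", "dev_specific"))
  expect_equal(nrow(lab), 4)
  expect_error(classify_stage_specificity(c("g1", "zz"), mature), "absent")
})

test_that("cross-species exclusion applies the two rules with precedence", {
  cand <- tibble::tibble(gene_id = c("c1", "c2", "c3", "c4", "c5"),
                         direction = c("up", "down", "up", "up", "down"))
  ortho <- orthology_map(tibble::tibble(
    ct_gene = c("t1", "t2", "t3", "t4"),
    cp_gene = c("c1", "c2", "c3", "c4"),
    relation = "one_to_one"))
  ct_deg <- mini_deg(paste0("t", 1:4), c("up", "none", "none", "up"))
  ct_tpm <- matrix(50, 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  ct_tpm["t3", ] <- 0.01   # unexpressed ortholog
  ct_tpm["t4", ] <- 0.01   # unexpressed AND same-direction DEG
  res <- apply_crossspecies_exclusion(cand, ortho, ct_deg, ct_tpm)
  expect_equal(res$exclusion_reason,
               c("ct_consistent_deg",       # same-direction Ct DEG
                 "none",                    # ortholog not a DEG, expressed
                 "downreg_ct_unexpressed",  # down in submerged? no: up
                 "ct_consistent_deg",       # precedence over unexpressed
                 "none"))                   # no ortholog -> retained
  expect_equal(res$retained, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # downregulated-in-submerged rule only fires for direction "up"
  cand2 <- cand
  cand2$direction[3] <- "down"
  res2 <- apply_crossspecies_exclusion(cand2, ortho, ct_deg, ct_tpm)
  expect_equal(res2$exclusion_reason[3], "none")
  # ortholog missing from the TPM table is an error
  expect_error(
    apply_crossspecies_exclusion(cand, ortho, ct_deg, ct_tpm[1:3, ]),
    "absent from the diploid TPM")
})

test_that("a diploid DEG excludes all of its tetraploid co-orthologs", {
  cand <- tibble::tibble(gene_id = c("c1", "c2"), direction = c("up", "up"))
  ortho <- orthology_map(tibble::tibble(
    ct_gene = c("t1", "t1"), cp_gene = c("c1", "c2"),
    relation = "one_to_multi"))
  ct_deg <- mini_deg("t1", "up")
  ct_tpm <- matrix(50, 1, 3, dimnames = list("t1", NULL))
  res <- apply_crossspecies_exclusion(cand, ortho, ct_deg, ct_tpm)
  expect_equal(res$exclusion_reason, rep("ct_consistent_deg", 2))
})

test_that("TF selection requires retention, ORF and TF flags", {
  retained <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                             direction = c("up", "down", "up"))
  ann <- tibble::tibble(gene_id = paste0("g", 1:4),
                        has_orf = c(TRUE, TRUE, FALSE, TRUE),
                        is_tf = c(TRUE, TRUE, TRUE, TRUE))
  tf <- select_tf_candidates(retained, ann)
  expect_equal(tf$gene_id, c("g1", "g2"))   # g3 lacks an ORF
  s <- attr(tf, "summary")
  expect_equal(unname(s["n_tf"]), 2)
  expect_equal(unname(s["n_up_submerged"]), 1)
  expect_equal(nrow(select_tf_candidates(retained[0, ], ann)), 0)
  expect_error(select_tf_candidates(tibble::tibble(gene_id = "zz",
                                                   direction = "up"), ann),
               "missing")
})

test_that("composed cascade recovers planted totals and is order invariant", {
  fx <- cascade_example_inputs(seed = 3)
  rep1 <- run_cascade(fx$deg_tables, fx$ortho, fx$ct_deg_table, fx$ct_tpm,
                      fx$annotation)
  s <- attr(rep1, "summary")
  tr <- fx$truth
  expect_equal(unname(s["n_candidates"]),
               sum(tr$category != "BACKGROUND"))
  expect_equal(unname(s["n_excluded_ct_consistent"]),
               sum(tr$exclusion == "ct_consistent_deg"))
  expect_equal(unname(s["n_excluded_ct_unexpressed"]),
               sum(tr$exclusion == "downreg_ct_unexpressed"))
  expect_equal(unname(s["n_dev_and_mature"]), sum(tr$mature_deg))
  expect_setequal(rep1$gene_id, tr$gene_id[tr$category != "BACKGROUND"])
  # retained/excluded partition the candidates
  expect_equal(sum(rep1$retained) + sum(!rep1$retained), nrow(rep1))

  # permuting gene order leaves the report content identical
  fx2 <- fx
  perm <- sample(nrow(fx2$deg_tables$aerial))
  fx2$deg_tables <- lapply(fx2$deg_tables, function(d) d[perm, ])
  rep2 <- run_cascade(fx2$deg_tables, fx2$ortho, fx2$ct_deg_table,
                      fx2$ct_tpm, fx2$annotation)
  expect_equal(as.data.frame(rep1[order(rep1$gene_id), ]),
               as.data.frame(rep2[order(rep2$gene_id), ]))
})

test_that("all-null data yields zero candidates", {
  ids <- paste0("g", 1:50)
  null_tab <- mini_deg(ids, rep("none", 50))
  tabs <- list(aerial = null_tab, agno3 = null_tab, aba = null_tab,
               uniconazole = null_tab, mature = null_tab)
  ortho <- orthology_map(tibble::tibble(ct_gene = character(0),
                                        cp_gene = character(0),
                                        relation = character(0)),
                         orphans = ids)
  ann <- tibble::tibble(gene_id = ids, has_orf = TRUE, is_tf = FALSE)
  rep0 <- run_cascade(tabs, ortho, null_tab,
                      matrix(1, 50, 2, dimnames = list(ids, NULL)), ann)
  expect_equal(nrow(rep0), 0)
})

test_that("UpSet subset counts sum to each comparison's DEG totals", {
  fx <- cascade_example_inputs(seed = 2, n_background = 500)
  rep1 <- run_cascade(fx$deg_tables, fx$ortho, fx$ct_deg_table, fx$ct_tpm,
                      fx$annotation)
  up <- attr(rep1, "upset")
  for (cmp in c("aerial", "agno3", "aba", "uniconazole", "mature")) {
    d <- fx$deg_tables[[cmp]]
    for (dir in c("up", "down")) {
      in_subsets <- sum(up$n_genes[up$direction == dir &
                                     grepl(paste0("(^|&)", cmp, "(&|$)"),
                                           up$comparisons)])
      expect_equal(in_subsets, sum(d$call == dir))
    }
  }
})
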