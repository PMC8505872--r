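# The synthetic-data generators: orthology, NB counts, cell contours.

test_that("orthology simulation honors degenerate probabilities", {
  o1 <- simulate_orthology(50, duplication_prob = 0, orphan_prob = 0.2,
                           seed = 1)
  expect_true(all(o1$links$relation == "one_to_one"))
  o2 <- simulate_orthology(100, duplication_prob = 1, orphan_prob = 0,
                           seed = 1)
  expect_equal(length(unique(o2$links$ct_gene)), 100)
  expect_equal(nrow(o2$links), 200)
  expect_equal(length(o2$orphans), 0)
  expect_error(simulate_orthology(-5), "non-negative")
  expect_error(simulate_orthology(10, duplication_prob = 1.2), "\\[0, 1\\]")
})

test_that("one-to-many fraction falls in the binomial confidence interval", {
  o <- simulate_orthology(10000, duplication_prob = 0.52, orphan_prob = 0.3,
                          seed = 7)
  per_ct <- table(o$links$ct_gene)
  frac <- mean(per_ct == 2)
  ci <- qnorm(c(0.005, 0.995), 0.52, sqrt(0.52 * 0.48 / 10000))
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("orthology accounting: links plus orphans cover the tetraploid set", {
  o <- simulate_orthology(500, duplication_prob = 0.4, orphan_prob = 0.25,
                          seed = 3)
  per_ct <- table(o$links$ct_gene)
  n_one <- sum(per_ct == 1)
  n_two <- sum(per_ct == 2)
  total_cp <- length(unique(o$links$cp_gene)) + length(o$orphans)
  expect_equal(n_one + 2 * n_two + length(o$orphans), total_cp)
  # relation classes consistent with multiplicity
  rel <- tapply(o$links$relation, o$links$ct_gene, unique)
  expect_true(all((per_ct == 2) == (rel[names(per_ct)] == "one_to_multi")))
})

test_that("count simulation is seed-reproducible and matches its law", {
  des <- experiment_design("x", data.frame(condition = c("a", "b"),
                                           stage = "primordium"),
                           replicates = 3, n_genes = 500, depth = 5e4,
                           gene_prefix = "g", seed = 2)
  prof <- planted_profiles(des, baseline = 100, dispersion = 0.05)
  cm1 <- simulate_counts(des, prof, seed = 11)
  cm2 <- simulate_counts(des, prof, seed = 11)
  expect_identical(cm1$counts, cm2$counts)
  expect_false(identical(cm1$counts,
                         simulate_counts(des, prof, seed = 12)$counts))
  expect_true(all(cm1$counts >= 0))

  # Poisson limit: dispersion 0, equal depths -> variance tracks the mean
  prof0 <- planted_profiles(des, baseline = 100, dispersion = 0)
  cm0 <- simulate_counts(des, prof0, seed = 13, depth_cv = 0)
  vm <- apply(cm0$counts, 1, var) / rowMeans(cm0$counts)
  expect_equal(mean(vm), 1, tolerance = 0.1)

  # null model: no planted fold-change -> group means agree
  grp_a <- cm0$samples$condition == "a"
  ratio <- mean(rowMeans(cm0$counts[, grp_a])) /
    mean(rowMeans(cm0$counts[, !grp_a]))
  expect_equal(ratio, 1, tolerance = 0.02)
  expect_error(planted_profiles(des, baseline = 100, dispersion = -0.1),
               "non-negative")
})

test_that("planted fold-changes are realized at the law-of-large-numbers scale", {
  des <- experiment_design("x", data.frame(condition = c("a", "b"),
                                           stage = "primordium"),
                           replicates = 3, n_genes = 10000, depth = 1e6,
                           gene_prefix = "g", seed = 2)
  lfc <- matrix(2, 10000, 1, dimnames = list(des$gene_ids, "a|primordium"))
  prof <- planted_profiles(des, baseline = 100, dispersion = 0.05,
                           lfc = lfc)
  cm <- simulate_counts(des, prof, seed = 21, depth_cv = 0)
  a <- cm$samples$condition == "a"
  ratio <- mean(cm$counts[, a]) / mean(cm$counts[, !a])
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("depth factors are recovered by median count ratios", {
  des <- experiment_design("x", data.frame(condition = "a",
                                           stage = "primordium"),
                           replicates = 4, n_genes = 10000, depth = 2e6,
                           gene_prefix = "g", seed = 5)
  prof <- planted_profiles(des, dispersion = 0.05)
  cm <- simulate_counts(des, prof, seed = 31, depth_cv = 0.3)
  truth <- attr(cm, "depth_factors")
  ref <- cm$counts[, 1]
  keep <- ref > 5
  est <- apply(cm$counts[keep, ], 2, function(x) {
    median(x / ref[keep])
  })
  expect_equal(unname(est / est[1]), unname(truth / truth[1]),
               tolerance = 0.02)
})

test_that("contour generator attaches exact analytics and respects degeneracies", {
  circ <- generate_cell_population(
    contour_spec("circle", size = 1, n_vertices = 512), 1, jitter = 0,
    seed = 1)
  an <- attr(circ, "analytic")
  expect_equal(an$area, pi)
  expect_equal(area_perimeter(circ)[["area"]], pi, tolerance = 1e-3)

  # lobed with amplitude 0 degenerates to the circle class
  lob0 <- generate_cell_population(
    contour_spec("lobed", size = 1, lobe_amplitude = 0, n_vertices = 64),
    1, jitter = 0, seed = 1)
  circ64 <- generate_cell_population(
    contour_spec("circle", size = 1, n_vertices = 64), 1, jitter = 0,
    seed = 1)
  expect_equal(lob0$x, circ64$x, tolerance = 1e-12)
  expect_equal(lob0$y, circ64$y, tolerance = 1e-12)

  # lobed cells are non-convex: solidity < 1 (hull oracle)
  lob <- generate_cell_population(
    contour_spec("lobed", size = 1, lobe_amplitude = 0.3, lobe_count = 8,
                 n_vertices = 256), 1, jitter = 0, seed = 1)
  expect_lt(solidity(lob), 1)
  expect_true(is_simple_polygon(lob))

  # rectangle vertices include the corners: exact area and perimeter
  rect <- generate_cell_population(
    contour_spec("rectangle", size = 1, aspect = 4, n_vertices = 64), 1,
    jitter = 0, seed = 1)
  expect_equal(area_perimeter(rect)[["area"]], 4, tolerance = 1e-12)
  expect_equal(area_perimeter(rect)[["perimeter"]], 10, tolerance = 1e-12)

  # jittered populations stay simple and reproducible
  pop <- generate_cell_population(
    contour_spec("lobed", size = 20, lobe_amplitude = 0.3, lobe_count = 8),
    5, jitter = 0.03, seed = 9)
  expect_equal(length(unique(pop$cell_id)), 5)
  for (id in unique(pop$cell_id)) {
    expect_true(is_simple_polygon(pop[pop$cell_id == id, ]))
  }
  expect_identical(pop, generate_cell_population(
    contour_spec("lobed", size = 20, lobe_amplitude = 0.3, lobe_count = 8),
    5, jitter = 0.03, seed = 9))
  expect_error(contour_spec("lobed", lobe_amplitude = 0.6), "0, 0.5")
  expect_error(contour_spec("circle", n_vertices = 8), ">= 16")
})

test_that("simulated experiment carries a consistent truth table", {
  sim <- simulate_experiment(seed = 5, n_genes = 2000, n_ct_background = 400,
                             depth = 2e5,
                             sizes = list(shared4 = 40, shared3 = 20,
                                          ct_consistent = 6,
                                          ct_unexpressed = 4,
                                          no_ortholog = 25,
                                          orf_retained = 40, tf = 6,
                                          tf_up_submerged = 2,
                                          mature_shared = 30,
                                          ct_background_deg = 30))
  tr <- sim$truth
  expect_equal(sum(tr$category == "SHARED4"), 40)
  expect_equal(sum(tr$category == "SHARED3_NOT_UNI"), 20)
  expect_equal(sum(tr$exclusion == "ct_consistent_deg"), 6)
  expect_equal(sum(tr$exclusion == "downreg_ct_unexpressed"), 4)
  retained <- tr$category != "BACKGROUND" & tr$exclusion == "none"
  expect_equal(sum(retained & !tr$has_ortholog), 25)
  expect_equal(sum(retained & tr$is_tf), 6)
  # all planted exclusion genes have ortholog links
  expect_true(all(tr$has_ortholog[tr$exclusion != "none"]))
  # counts dimensions match designs
  expect_equal(nrow(sim$cp_counts$counts), 2000)
  expect_equal(ncol(sim$cp_counts$counts), 21)
  expect_equal(ncol(sim$ct_counts$counts), 6)
  # no tetraploid gene in two ortholog links
  expect_equal(anyDuplicated(sim$orthology$links$cp_gene), 0)
})
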