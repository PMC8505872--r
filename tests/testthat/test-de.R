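# The DE stage: TPM, low-expression filter, TMM, dispersion, the
# conditional exact NB test, BH, and the signed DEG decision rule.

test_that("TPM normalization forces column sums of 1e6 and length scaling", {
  # single gene: normalization forces TPM = 1e6
  one <- matrix(5L, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(compute_tpm(one, lengths = 700)[1, ]), c(1e6, 1e6))

  # equal counts, lengths 1000 and 2000 -> TPM ratio 2:1
  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(two, lengths = c(1000, 2000))
  expect_equal(tpm["a", 1] / tpm["b", 1], 2)

  # random matrix: column sums exactly 1e6 (direct summation oracle)
  set.seed(1)
  y <- matrix(rpois(300, 40), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  tpm <- compute_tpm(y, lengths = sample(500:3000, 50))
  expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)

  # all-zero sample is degenerate
  y[, 3] <- 0L
  expect_error(compute_tpm(y, lengths = rep(1000, 50)), "degenerate")
})

test_that("low-expression filter drops genes below the floor in all samples", {
  tpm <- rbind(alllow = rep(0.9, 4),
               onehigh = c(0.9, 0.9, 1.2, 0.9),
               high = rep(5, 4))
  expect_equal(filter_low_expression(tpm, 1), c("onehigh", "high"))
  expect_equal(filter_low_expression(tpm[0, , drop = FALSE], 1), character(0))
  # boundary: exactly at the floor in one sample is retained (TPM >= 1)
  expect_true("g" %in% filter_low_expression(rbind(g = c(0.5, 1.0)), 1))
})

test_that("TMM factors behave under symmetry, depth shifts, and trimming", {
  y <- matrix(rpois(2000, 50), 1000, 2,
              dimnames = list(NULL, c("s1", "s2")))
  y[, 2] <- y[, 1]
  expect_equal(unname(tmm_factors(y)), c(1, 1))

  # pure depth shift: M-values vanish after library-size scaling
  y2 <- cbind(s1 = y[, 1], s2 = 2L * y[, 1])
  expect_equal(unname(tmm_factors(y2)), c(1, 1), tolerance = 1e-12)

  # 5% of genes 8-fold up in B: trimming removes them, so the effective
  # library sizes equalize the unshifted majority; the untrimmed mean-of-M
  # factor keeps a visible composition bias
  set.seed(2)
  y3 <- matrix(rpois(4000, 100), 2000, 2,
               dimnames = list(NULL, c("a", "b")))
  y3[1:100, 2] <- y3[1:100, 2] * 8L
  f <- tmm_factors(y3)
  lib <- colSums(y3)
  eff_ratio <- (lib["b"] * f["b"]) / (lib["a"] * f["a"])
  expect_equal(unname(eff_ratio), 1, tolerance = 0.02)
  m <- log2((y3[, 2] / lib[2]) / (y3[, 1] / lib[1]))
  untrimmed_ratio <- (lib["b"] / lib["a"]) * 2^mean(m[is.finite(m)])
  expect_gt(abs(log2(untrimmed_ratio)), 5 * abs(log2(eff_ratio)))
})

test_that("TMM factors have geometric mean 1 and match the edgeR oracle", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  for (i in 1:3) {
    y <- matrix(rnbinom(3000 * 6, mu = 200, size = 10), 3000, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
    y[seq_len(150 * i), 4:6] <- rnbinom(150 * i * 3, mu = 1000, size = 10)
    f <- tmm_factors(y)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    # boundary ties at the trim quantiles differ slightly between
    # rank-based and quantile-based trimming
    expect_equal(unname(f), unname(edgeR::calcNormFactors(y, method = "TMM")),
                 tolerance = 1e-3)
  }
})

test_that("common dispersion is recovered from simulated data", {
  groups <- rep(c("a", "b"), each = 3)
  set.seed(4)
  pois <- matrix(rpois(2000 * 6, 100), 2000, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
  expect_lte(estimate_common_dispersion(pois, groups), 0.01)

  nb <- matrix(rnbinom(2000 * 6, mu = 100, size = 1 / 0.2), 2000, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  phi <- estimate_common_dispersion(nb, groups)
  expect_gte(phi, 0.1)
  expect_lte(phi, 0.3)

  # identical replicate columns -> zero residuals -> phi = 0
  same <- matrix(rpois(100, 50), 100, 1)[, c(1, 1), drop = FALSE]
  colnames(same) <- c("s1", "s2")
  expect_equal(estimate_common_dispersion(same, c("a", "a"),
                                          factors = c(s1 = 1, s2 = 1)), 0)
  expect_error(estimate_common_dispersion(pois, letters[1:6]),
               "replicates")
})

test_that("exact NB test: symmetry, binomial reduction, zero total", {
  expect_equal(exact_nb_test(c(5, 5, 5), c(5, 5, 5), phi = 0.1), 1)
  # phi = 0, single samples 9 vs 1: the conditional binomial test
  expect_equal(exact_nb_test(9, 1, phi = 0),
               binom.test(9, 10, 0.5)$p.value, tolerance = 1e-12)
  expect_warning(p <- exact_nb_test(c(0, 0), c(0, 0), phi = 0.1),
                 "grand total")
  expect_equal(p, 1)
  expect_error(exact_nb_test(numeric(0), 5), "non-empty")
  expect_error(exact_nb_test(5, 5, phi = -1), "non-negative")
})

test_that("exact NB test equals brute-force conditional enumeration", {
  set.seed(5)
  for (i in 1:25) {
    n_a <- sample(1:4, 1)
    n_b <- sample(1:4, 1)
    phi <- sample(c(0, 0.05, 0.5), 1)
    repeat {
      ca <- rpois(n_a, 20)
      cb <- rpois(n_b, 20)
      if (sum(ca, cb) > 0 && sum(ca, cb) <= 200) break
    }
    expect_equal(exact_nb_test(ca, cb, phi = phi),
                 brute_force_exact_p(ca, cb, phi), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the textbook step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(6)
  p <- runif(100)
  expect_equal(bh_adjust(p), textbook_bh(p), tolerance = 1e-12)
  # order preserving: q is monotone in p
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calls apply strict thresholds on both criteria", {
  d <- tibble::tibble(gene_id = paste0("g", 1:4),
                      log2fc = c(1.5, 0.5, 2, -1.5),
                      qvalue = c(0.04, 0.04, 0.05, 0.01))
  out <- call_degs(d, 0.05, 1)
  expect_equal(out$call, c("up", "none", "none", "down"))
  # monotone: lowering either threshold never removes a call
  loose <- call_degs(d, 0.10, 0.5)
  expect_true(all(out$call == "none" | out$call == loose$call))
})

test_that("full DE stage controls type-I error and recovers planted effects", {
  null_cm <- two_group_cm(rep(100, 2000), rep(100, 2000), phi = 0.05)
  d0 <- test_differential_expression(null_cm, "a", "b", phi = 0.05)
  rate <- mean(d0$pvalue < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)

  mu_b <- rep(100, 2000)
  mu_a <- mu_b
  mu_a[1:100] <- 400      # planted log2FC = +2
  mu_a[101:200] <- 25     # planted log2FC = -2
  cm <- two_group_cm(mu_a, mu_b, phi = 0.05, seed = 42)
  d <- test_differential_expression(cm, "a", "b")
  calls <- d$gene_id[d$call != "none"]
  planted <- rownames(cm$counts)[1:200]
  expect_gte(mean(planted %in% calls), 0.90)
  expect_lte(mean(!calls %in% planted), 0.10)
  # signs recovered
  expect_true(all(d$call[match(rownames(cm$counts)[1:100], d$gene_id)]
                  %in% c("up", "none")))
})
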