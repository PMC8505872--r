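#' Transcripts per million
#'
#' Length-normalizes a count matrix within each sample: counts are divided by
#' effective gene length (rate of read starts per base), then rescaled so each
#' sample column sums to one million.
#'
#' @param counts A [count_matrix] object, or an integer matrix of counts
#'   (genes x samples) together with `lengths`.
#' @param lengths Per-gene effective lengths in bases; ignored when `counts`
#'   is a `count_matrix` (which carries its own lengths).
#' @return A numeric matrix of TPM values with the dimensions and dimnames of
#'   the count matrix. Every column sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$gene_lengths
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lengths)) stop("per-gene effective lengths are required")
  if (length(lengths) != nrow(counts)) {
    stop("length vector does not match the number of genes")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop("degenerate sample with all-zero counts: ",
         paste(colnames(counts)[denom == 0], collapse = ", "))
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Filter genes expressed at low levels
#'
#' A gene is dropped only when its TPM is below `threshold` in *every*
#' sample; reaching the floor in a single sample is enough to retain it.
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param threshold TPM floor (default 1).
#' @return Character vector of retained gene identifiers.
#' @export
filter_low_expression <- function(tpm, threshold = 1) {
  stopifnot(threshold > 0)
  tpm <- as.matrix(tpm)
  if (nrow(tpm) == 0) return(character(0))
  keep <- apply(tpm, 1, function(x) any(x >= threshold))
  rn <- rownames(tpm)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(tpm)))
  rn[keep]
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM recipe: per gene, the
#' log2 expression ratio (M) of a sample against a reference sample and the
#' average log2 abundance (A) are formed from library-size-scaled counts;
#' genes in the tails of either distribution are trimmed; the factor is the
#' precision-weighted mean of the surviving M values. Factors are rescaled so
#' their geometric mean is exactly 1.
#'
#' @param counts Count matrix (genes x samples) or a [count_matrix].
#' @param reference Column name or index of the reference sample, or `NULL`
#'   to pick the sample whose upper-quartile expression is closest to the
#'   mean upper quartile.
#' @param logratio_trim Two-sided trim fraction on M (default 0.30).
#' @param sum_trim Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts, reference = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM requires at least two samples")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  if (is.null(reference)) {
    f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    reference <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(counts))
    if (is.na(reference)) stop("reference sample not found")
  }
  yr <- counts[, reference]
  nr <- lib[reference]
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == reference) return(1)
    y <- counts[, j]
    keep <- y > 0 & yr > 0
    if (!any(keep)) {
      stop("sample ", colnames(counts)[j],
           " shares no expressed genes with the reference")
    }
    n <- lib[j]
    m <- log2((y[keep] / n) / (yr[keep] / nr))
    a <- 0.5 * log2((y[keep] / n) * (yr[keep] / nr))
    # asymptotic delta-method weights (inverse approximate variance of M)
    w <- (n - y[keep]) / (n * y[keep]) + (nr - yr[keep]) / (nr * yr[keep])
    lo_m <- stats::quantile(m, logratio_trim)
    hi_m <- stats::quantile(m, 1 - logratio_trim)
    lo_a <- stats::quantile(a, sum_trim)
    hi_a <- stats::quantile(a, 1 - sum_trim)
    use <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
    if (!any(use) || all(w[use] == 0)) return(1)
    2^(sum(m[use] / w[use]) / sum(1 / w[use]))
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(counts)
  fac
}

# Counts rescaled to a common (geometric-mean) effective library size and
# rounded: the integer substrate the conditional exact test expects.
pseudo_counts <- function(counts, eff_lib) {
  common <- exp(mean(log(eff_lib)))
  pmax(round(sweep(as.matrix(counts), 2, common / eff_lib, "*")), 0)
}

#' Common negative-binomial dispersion by method of moments
#'
#' For every gene with replicated groups, a per-gene dispersion is computed
#' from within-group residuals of normalized counts via the moment relation
#' `var = mu + phi * mu^2`, pooled across groups by degrees of freedom; the
#' common dispersion is the median over informative genes, floored at zero.
#'
#' @param counts Count matrix (genes x samples) or [count_matrix].
#' @param groups Factor or vector of group labels, one per sample.
#' @param factors Optional TMM factors; computed with [tmm_factors()] when
#'   `NULL`.
#' @param min_mean Genes whose normalized grand mean falls below this value
#'   are ignored (too noisy to inform the moment estimate).
#' @return A single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL,
                                       min_mean = 1) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("groups must have one label per sample")
  }
  if (!any(table(groups) >= 2)) {
    stop("at least one group must contain replicates")
  }
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors
  z <- sweep(counts, 2, exp(mean(log(eff))) / eff, "*")
  phi_g <- apply(z, 1, function(x) {
    num <- 0
    den <- 0
    mu_all <- mean(x)
    if (mu_all < min_mean) return(NA_real_)
    for (g in levels(groups)) {
      xg <- x[groups == g]
      if (length(xg) < 2) next
      m <- mean(xg)
      if (m <= 0) next
      v <- stats::var(xg)
      num <- num + (length(xg) - 1) * (v - m) / m^2
      den <- den + (length(xg) - 1)
    }
    if (den == 0) return(NA_real_)
    num / den
  })
  phi_g <- phi_g[is.finite(phi_g)]
  if (length(phi_g) == 0) stop("no informative genes for dispersion estimation")
  max(0, stats::median(phi_g))
}

# Conditional pmf of the group-A total given the grand total, for nA and nB
# negative-binomial samples of common mean and dispersion phi. Returns the
# normalized probability vector over s = 0..t.
cond_nb_pmf <- function(t, n_a, n_b, phi) {
  s <- 0:t
  mu <- t / (n_a + n_b)
  if (phi <= 0) {
    lp <- stats::dpois(s, n_a * mu, log = TRUE) +
      stats::dpois(t - s, n_b * mu, log = TRUE)
  } else {
    # sum of n iid NB(mu, phi) is NB(n*mu, phi/n), i.e. size n/phi
    lp <- stats::dnbinom(s, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(t - s, size = n_b / phi, mu = n_b * mu, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Conditional exact negative-binomial two-group test
#'
#' Tests equality of means between two groups of negative-binomial counts by
#' conditioning on the grand total: under the null the group-A total given
#' the total follows the ratio law of two NB sums, enumerated exactly. The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one. At `phi = 0` this reduces to the conditional
#' binomial (exact Poisson two-sample) test. Counts are first rescaled to a
#' common effective library size and rounded.
#'
#' @param counts_a,counts_b Integer count vectors for the two groups (one
#'   gene).
#' @param eff_lib_a,eff_lib_b Effective library sizes (library size times
#'   normalization factor) for each sample; defaults assume equal sizes.
#' @param phi Negative-binomial dispersion (>= 0).
#' @param enum_cap Grand totals above this switch to a normal approximation
#'   of the conditional law (with continuity correction).
#' @return Two-sided p-value. A grand total of zero returns p = 1 with a
#'   warning (no information).
#' @export
exact_nb_test <- function(counts_a, counts_b,
                          eff_lib_a = rep(1, length(counts_a)),
                          eff_lib_b = rep(1, length(counts_b)),
                          phi = 0, enum_cap = 5000) {
  if (length(counts_a) == 0 || length(counts_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (phi < 0) stop("dispersion must be non-negative")
  if (any(c(counts_a, counts_b) < 0)) stop("counts must be non-negative")
  eff <- c(eff_lib_a, eff_lib_b)
  y <- pseudo_counts(matrix(c(counts_a, counts_b), nrow = 1), eff)
  n_a <- length(counts_a)
  s_a <- sum(y[seq_len(n_a)])
  t <- sum(y)
  if (t == 0) {
    warning("grand total is zero; p = 1 by convention")
    return(1)
  }
  n_b <- length(counts_b)
  if (t <= enum_cap) {
    p <- cond_nb_pmf(t, n_a, n_b, phi)
    p_obs <- p[s_a + 1]
    min(1, sum(p[p <= p_obs * (1 + 1e-8)]))
  } else {
    mu <- t / (n_a + n_b)
    v_a <- n_a * (mu + phi * mu^2)
    v_b <- n_b * (mu + phi * mu^2)
    v <- v_a * v_b / (v_a + v_b)
    m <- t * n_a / (n_a + n_b)
    z <- (abs(s_a - m) - 0.5) / sqrt(v)
    min(1, 2 * stats::pnorm(-max(z, 0)))
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a validated wrapper around
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the study's decision rule: a gene is a DEG when its adjusted
#' q-value is strictly below `fdr_threshold` *and* its absolute log2
#' fold-change is strictly above `lfc_threshold`; the call is signed by the
#' fold-change direction.
#'
#' @param de_results Data frame with columns `log2fc` and `qvalue` (and
#'   typically `gene_id`, `pvalue`).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param lfc_threshold log2 fold-change cutoff (default 1).
#' @return The input with a `call` column in `c("up", "down", "none")`.
#' @export
call_degs <- function(de_results, fdr_threshold = 0.05, lfc_threshold = 1) {
  stopifnot(fdr_threshold > 0, lfc_threshold > 0)
  sig <- de_results$qvalue < fdr_threshold &
    abs(de_results$log2fc) > lfc_threshold
  de_results$call <- ifelse(sig & de_results$log2fc > 0, "up",
                            ifelse(sig, "down", "none"))
  de_results
}

#' Differential expression between two conditions
#'
#' Runs the full DE stage for one comparison: subsets the samples, filters
#' low-expression genes (TPM floor over *all* samples of the species),
#' computes TMM factors on the comparison samples, estimates a common
#' dispersion unless one is supplied, applies the conditional exact NB test
#' per gene, adjusts p-values by BH, and calls signed DEGs. Fold-changes are
#' log2 ratios of normalized group means (treatment over reference) with a
#' 0.5 pseudo-count added to each group mean.
#'
#' @param cm A [count_matrix].
#' @param treatment,reference Condition labels; `reference` is the
#'   denominator of the fold-change (the submerged control in the study
#'   design).
#' @param stage Stage label to subset on (`NULL` keeps all stages).
#' @param comparison Label stored in the output (default
#'   `"<treatment>_vs_<reference>"`).
#' @param fdr_threshold,lfc_threshold DEG decision thresholds.
#' @param tpm_floor Low-expression TPM floor (applied across all samples in
#'   `cm`, so every comparison of a species shares one gene universe).
#' @param phi Common dispersion; estimated from the comparison samples when
#'   `NULL`.
#' @param enum_cap Passed to [exact_nb_test()].
#' @return A `deg_table` tibble: `gene_id`, `comparison`, `log2fc`,
#'   `pvalue`, `qvalue`, `call`, with the dispersion used as attribute
#'   `"phi"`.
#' @export
test_differential_expression <- function(cm, treatment, reference,
                                         stage = NULL, comparison = NULL,
                                         fdr_threshold = 0.05,
                                         lfc_threshold = 1, tpm_floor = 1,
                                         phi = NULL, enum_cap = 5000) {
  stopifnot(inherits(cm, "count_matrix"))
  meta <- cm$samples
  pick <- meta$condition %in% c(treatment, reference)
  if (!is.null(stage)) pick <- pick & meta$stage == stage
  meta <- meta[pick, , drop = FALSE]
  if (!any(meta$condition == treatment) || !any(meta$condition == reference)) {
    stop("treatment or reference condition has no samples",
         if (!is.null(stage)) paste0(" at stage '", stage, "'"))
  }
  keep_genes <- filter_low_expression(compute_tpm(cm), tpm_floor)
  y <- cm$counts[keep_genes, meta$sample_id, drop = FALSE]
  grp <- factor(ifelse(meta$condition == treatment, "A", "B"),
                levels = c("A", "B"))
  fac <- tmm_factors(y)
  eff <- colSums(y) * fac
  if (is.null(phi)) phi <- estimate_common_dispersion(y, grp, factors = fac)
  z <- pseudo_counts(y, eff)
  ia <- which(grp == "A")
  ib <- which(grp == "B")
  n_a <- length(ia)
  n_b <- length(ib)
  pvals <- vapply(seq_len(nrow(z)), function(i) {
    s_a <- sum(z[i, ia])
    t <- s_a + sum(z[i, ib])
    if (t == 0) return(1)
    if (t <= enum_cap) {
      p <- cond_nb_pmf(t, n_a, n_b, phi)
      min(1, sum(p[p <= p[s_a + 1] * (1 + 1e-8)]))
    } else {
      mu <- t / (n_a + n_b)
      v_a <- n_a * (mu + phi * mu^2)
      v_b <- n_b * (mu + phi * mu^2)
      v <- v_a * v_b / (v_a + v_b)
      m <- t * n_a / (n_a + n_b)
      zz <- (abs(s_a - m) - 0.5) / sqrt(v)
      min(1, 2 * stats::pnorm(-max(zz, 0)))
    }
  }, numeric(1))
  mean_a <- rowMeans(z[, ia, drop = FALSE])
  mean_b <- rowMeans(z[, ib, drop = FALSE])
  log2fc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  if (is.null(comparison)) comparison <- paste0(treatment, "_vs_", reference)
  out <- tibble::tibble(
    gene_id = keep_genes,
    comparison = comparison,
    log2fc = log2fc,
    pvalue = pvals,
    qvalue = bh_adjust(pvals)
  )
  out <- call_degs(out, fdr_threshold, lfc_threshold)
  out <- tibble::as_tibble(out)
  attr(out, "phi") <- phi
  class(out) <- c("deg_table", class(out))
  out
}
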