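# Statistical layer over the morphometric indices: Welch's t, Hedges' g
# effect size, Tukey-Kramer multiple comparisons, and standardized PCA.

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance and equal
#' means the test is uninformative and p = 1 by convention.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @return Named list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least two values")
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  na <- length(group_a); nb <- length(group_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = na + nb - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means")
  }
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Hedges' g effect size
#'
#' Pooled-SD standardized mean difference with the small-sample bias
#' correction `J = 1 - 3 / (4 (n_a + n_b - 2) - 1)`.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @return The corrected effect size g (sign: a minus b).
#' @export
hedges_g <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least two values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  j <- 1 - 3 / (4 * (na + nb - 2) - 1)
  (mean(group_a) - mean(group_b)) / sqrt(sp2) * j
}

#' Tukey-Kramer honestly significant differences
#'
#' Pairwise comparisons of group means against the studentized range
#' distribution with pooled within-group variance (wraps a one-way
#' `stats::aov` fit and `stats::TukeyHSD`); optionally derives a compact
#' letter display (groups sharing a letter are not significantly different).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each >= 2 values).
#' @param alpha Significance level for the letter display.
#' @param letters Also compute the letter grouping.
#' @return Tibble of pairwise comparisons (`group_1`, `group_2`, `diff`,
#'   `lwr`, `upr`, `p_adj`); letter display as attribute `"letters"` when
#'   requested.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05, letters = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs at least two values")
  if (all(stats::ave(values, groups, FUN = stats::var) == 0)) {
    stop("zero pooled within-group variance")
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- tibble::tibble(
    group_1 = vapply(pair, `[`, character(1), 1),
    group_2 = vapply(pair, `[`, character(1), 2),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"])
  )
  if (letters) {
    attr(out, "letters") <- letter_display(out, levels(groups), alpha)
  }
  out
}

# Insert-and-absorb compact letter display from pairwise adjusted p-values.
letter_display <- function(pairs, level_names, alpha = 0.05) {
  k <- length(level_names)
  sig <- matrix(FALSE, k, k, dimnames = list(level_names, level_names))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$p_adj[i] < alpha) {
      sig[pairs$group_1[i], pairs$group_2[i]] <- TRUE
      sig[pairs$group_2[i], pairs$group_1[i]] <- TRUE
    }
  }
  # insert-and-absorb: split every letter containing a significant pair,
  # then drop letters whose member set is contained in another letter's
  cols <- list(rep(TRUE, k))   # start: one letter containing every group
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[j] <- FALSE
          b <- col; b[i] <- FALSE
          new_cols <- c(new_cols, list(a, b))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      keep <- rep(TRUE, length(new_cols))
      for (ci in seq_along(new_cols)) {
        for (cj in seq_along(new_cols)) {
          if (ci == cj || !keep[ci] || !keep[cj]) next
          ci_in_cj <- all(!new_cols[[ci]] | new_cols[[cj]])
          if (ci_in_cj && !identical(new_cols[[ci]], new_cols[[cj]])) {
            keep[ci] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  labs <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(labs, level_names)
}

#' Principal component analysis of a descriptor table
#'
#' Descriptors are centered and scaled to unit variance (their units differ),
#' zero-variance descriptors are dropped with a warning, and the rotation is
#' computed by singular value decomposition (`stats::prcomp`).
#'
#' @param index_table Data frame of numeric shape descriptors, one row per
#'   cell (non-numeric columns such as `cell_id`/`group` are carried through
#'   to the scores).
#' @return List with `scores` (tibble), `loadings` (matrix, descriptors x
#'   components), `explained_variance` (eigenvalues; sums to the number of
#'   descriptors) and `prop_variance`.
#' @export
pca_scores <- function(index_table) {
  num <- vapply(index_table, is.numeric, logical(1))
  x <- as.matrix(index_table[, num, drop = FALSE])
  if (ncol(x) < 2) stop("need at least two numeric descriptors")
  if (nrow(x) < 3) stop("need at least three cells")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance descriptors: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- tibble::as_tibble(as.data.frame(p$x))
  meta <- index_table[, !num, drop = FALSE]
  if (ncol(meta) > 0) scores <- tibble::as_tibble(cbind(meta, scores))
  list(scores = scores, loadings = p$rotation,
       explained_variance = p$sdev^2,
       prop_variance = p$sdev^2 / sum(p$sdev^2))
}
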