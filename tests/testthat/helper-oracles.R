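# Independent oracles used across the suite. These re-derive expected
# values by brute force or textbook formulas and never share code with the
# implementation paths they check.

# Conditional exact NB p-value by explicit convolution of per-sample pmfs
# (the implementation uses the closed-form NB-sum law instead).
brute_force_exact_p <- function(counts_a, counts_b, phi) {
  t <- sum(counts_a, counts_b)
  n_a <- length(counts_a)
  n_b <- length(counts_b)
  mu <- t / (n_a + n_b)
  pmf1 <- if (phi == 0) {
    stats::dpois(0:t, mu)
  } else {
    stats::dnbinom(0:t, size = 1 / phi, mu = mu)
  }
  conv_n <- function(p, n) {
    r <- p
    if (n > 1) {
      for (i in 2:n) {
        r2 <- numeric(t + 1)
        for (s in 0:t) r2[s + 1] <- sum(r[1:(s + 1)] * p[(s + 1):1])
        r <- r2
      }
    }
    r
  }
  joint <- conv_n(pmf1, n_a) * rev(conv_n(pmf1, n_b))
  joint <- joint / sum(joint)
  obs <- joint[sum(counts_a) + 1]
  sum(joint[joint <= obs * (1 + 1e-8)])
}

# Textbook BH step-up, written independently of stats::p.adjust.
textbook_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by exhaustive summation of the pmf.
enumerate_hypergeom <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# Minimum bounding rectangle by brute-force angle sweep: 3600 uniform
# angles plus the hull edge directions (axis-aligned box at each angle).
sweep_mbr <- function(xy) {
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  n <- nrow(hull)
  edges <- hull[c(2:n, 1), ] - hull
  ea <- atan2(edges[, 2], edges[, 1])
  angles <- c(seq(0, pi / 2, length.out = 3600),
              ea %% (pi / 2), (-ea) %% (pi / 2))
  best <- Inf
  dims <- c(NA, NA)
  for (th in angles) {
    r <- hull %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    dx <- diff(range(r[, 1]))
    dy <- diff(range(r[, 2]))
    if (dx * dy < best) {
      best <- dx * dy
      dims <- sort(c(dx, dy), decreasing = TRUE)
    }
  }
  c(length = dims[1], width = dims[2])
}

# Regular n-gon inscribed in a circle, optionally rotated/translated.
ngon <- function(n, r = 1, rot = 0, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + rot
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Small count_matrix for two groups of three with given per-group means.
two_group_cm <- function(mu_a, mu_b, phi = 0.05, n_genes = length(mu_a),
                         depth_seed = 1, seed = 99) {
  des <- experiment_design(
    "sim", data.frame(condition = c("a", "b"), stage = "primordium"),
    replicates = 3, n_genes = n_genes, depth = sum(mu_a), gene_prefix = "g",
    seed = depth_seed)
  lfc <- matrix(log2(mu_a / mu_b), n_genes, 1,
                dimnames = list(des$gene_ids, "a|primordium"))
  prof <- planted_profiles(des, baseline = mu_b, dispersion = phi, lfc = lfc)
  simulate_counts(des, prof, seed = seed)
}
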