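# Synthetic-data generators: the statistical structure the analysis assumes
# (NB counts with planted fold-changes, a ploidy-aware orthology map,
# annotation flags), so the whole cascade is testable without sequencing data.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

cell_key <- function(condition, stage) paste(condition, stage, sep = "|")

#' Define a simulated RNA-seq experiment
#'
#' @param species Species label (e.g. `"C_palustris"`).
#' @param cells Data frame with columns `condition` and `stage`: one row per
#'   design cell. The study design is not factorial (leaf primordia are
#'   sampled under five conditions, mature leaves under two), so cells are
#'   listed explicitly.
#' @param replicates Biological replicates per design cell (>= 2; the study
#'   used three sibling plants).
#' @param n_genes Number of genes to simulate.
#' @param gene_lengths Per-gene effective lengths in bases; when `NULL`,
#'   sampled once log-normally (median 1500 b, sdlog 0.35) under `seed`.
#' @param depth Expected total counts per sample at depth factor 1.
#' @param gene_prefix Prefix for generated gene identifiers.
#' @param seed Seed used only for the length sampling.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(species, cells, replicates = 3,
                              n_genes = 10000, gene_lengths = NULL,
                              depth = 5e6, gene_prefix = "g", seed = 1) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("condition", "stage") %in% names(cells)),
            nrow(cells) >= 1)
  if (replicates < 2) stop("replicates must be >= 2 per design cell")
  if (n_genes < 1) stop("n_genes must be >= 1")
  gene_ids <- sprintf("%s%05d", gene_prefix, seq_len(n_genes))
  if (is.null(gene_lengths)) {
    gene_lengths <- with_seed(seed,
      round(stats::rlnorm(n_genes, log(1500), 0.35)))
  }
  if (length(gene_lengths) != n_genes || any(gene_lengths <= 0)) {
    stop("gene lengths must be positive, one per gene")
  }
  samples <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%s_%s_r%d", species, cells$condition[i],
                          cells$stage[i], seq_len(replicates)),
      species = species,
      condition = cells$condition[i],
      stage = cells$stage[i],
      replicate = seq_len(replicates)
    )
  }))
  structure(list(species = species, cells = cells, replicates = replicates,
                 n_genes = n_genes, gene_ids = gene_ids,
                 gene_lengths = stats::setNames(gene_lengths, gene_ids),
                 depth = depth, samples = samples),
            class = "experiment_design")
}

#' Default C. palustris design
#'
#' Leaf primordia under five conditions (aerial; submerged control;
#' submerged + AgNO3; submerged + uniconazole P; submerged + ABA) plus
#' mature aerial and submerged leaves, three replicates each.
#'
#' @inheritParams experiment_design
#' @export
cp_design <- function(n_genes = 10000, replicates = 3, depth = 5e6,
                      seed = 1) {
  cells <- data.frame(
    condition = c("aerial", "submerged", "submerged_AgNO3",
                  "submerged_uniconazole", "submerged_ABA",
                  "aerial", "submerged"),
    stage = c(rep("primordium", 5), rep("mature", 2))
  )
  experiment_design("C_palustris", cells, replicates, n_genes,
                    depth = depth, gene_prefix = "Cp", seed = seed)
}

#' Default C. terrestris design
#'
#' Leaf primordia under aerial and submerged conditions, three replicates
#' each (the terrestrial outgroup species is diploid and nonheterophyllous).
#'
#' @inheritParams experiment_design
#' @export
ct_design <- function(n_genes = 4000, replicates = 3, depth = 5e6,
                      seed = 2) {
  cells <- data.frame(condition = c("aerial", "submerged"),
                      stage = "primordium")
  experiment_design("C_terrestris", cells, replicates, n_genes,
                    depth = depth, gene_prefix = "Ct", seed = seed)
}

#' Planted expression profiles
#'
#' Builds the per-gene truth table the simulator draws counts from: a
#' baseline mean, a dispersion, and a log2 fold-change relative to the
#' submerged control for every design cell. Most genes are background
#' (null); `lfc` plants effects.
#'
#' @param design An [experiment_design()].
#' @param baseline Baseline mean counts (at depth factor 1). Either a single
#'   value or one per gene; when `NULL`, sampled log-normally and rescaled so
#'   the expected sample total equals `design$depth`.
#' @param dispersion NB dispersion phi (variance `mu + phi mu^2`), single
#'   value or per gene.
#' @param lfc Matrix of planted log2 fold-changes (genes x design cells,
#'   columns named `"<condition>|<stage>"`); zero where absent.
#' @param category Per-gene intended cascade category label (default
#'   `"BACKGROUND"`).
#' @param seed Seed for the baseline sampling.
#' @return A `planted_profiles` object: `$genes` (tibble with `gene_id`,
#'   `baseline`, `dispersion`, `category`) and `$lfc` (dense matrix).
#' @export
planted_profiles <- function(design, baseline = NULL, dispersion = 0.05,
                             lfc = NULL, category = NULL, seed = 1) {
  n <- design$n_genes
  keys <- cell_key(design$cells$condition, design$cells$stage)
  if (is.null(baseline)) {
    baseline <- with_seed(seed, stats::rlnorm(n, log(100), 1.2))
    baseline <- baseline * design$depth / sum(baseline)
  }
  baseline <- rep_len(baseline, n)
  dispersion <- rep_len(dispersion, n)
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  if (any(baseline <= 0)) stop("baseline means must be positive")
  full <- matrix(0, n, length(keys), dimnames = list(design$gene_ids, keys))
  if (!is.null(lfc)) {
    lfc <- as.matrix(lfc)
    miss <- setdiff(colnames(lfc), keys)
    if (length(miss)) stop("unknown design cells: ", paste(miss, collapse = ", "))
    full[rownames(lfc), colnames(lfc)] <- lfc
  }
  if (is.null(category)) category <- rep("BACKGROUND", n)
  genes <- tibble::tibble(gene_id = design$gene_ids,
                          baseline = baseline,
                          dispersion = dispersion,
                          category = rep_len(category, n))
  structure(list(genes = genes, lfc = full), class = "planted_profiles")
}

#' Simulate a negative-binomial count matrix
#'
#' Counts for gene g in sample j are drawn from NB with mean
#' `baseline_g * 2^lfc(g, cell(j)) * depth_factor_j` and variance
#' `mu + phi mu^2`; `phi = 0` is the Poisson limit. Per-sample depth factors
#' are log-normal with coefficient of variation `depth_cv`.
#'
#' @param design An [experiment_design()].
#' @param profiles A [planted_profiles()] covering every gene of the design.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param depth_cv Spread of per-sample depth factors (0 for equal depths).
#' @return A [count_matrix] with attribute `"depth_factors"`.
#' @export
simulate_counts <- function(design, profiles, seed, depth_cv = 0.1) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(profiles, "planted_profiles"))
  if (!identical(profiles$genes$gene_id, design$gene_ids)) {
    stop("every gene in the design needs a profile")
  }
  if (any(profiles$genes$dispersion < 0)) {
    stop("dispersion must be non-negative")
  }
  samples <- design$samples
  n <- design$n_genes
  m <- nrow(samples)
  with_seed(seed, {
    depth_factors <- if (depth_cv > 0) {
      exp(stats::rnorm(m, 0, depth_cv) - depth_cv^2 / 2)
    } else rep(1, m)
    names(depth_factors) <- samples$sample_id
    keys <- cell_key(samples$condition, samples$stage)
    mu <- profiles$genes$baseline * 2^profiles$lfc[, keys, drop = FALSE]
    mu <- sweep(mu, 2, depth_factors, "*")
    phi <- profiles$genes$dispersion
    counts <- matrix(0L, n, m)
    pois <- phi == 0
    if (any(pois)) {
      counts[pois, ] <- stats::rpois(sum(pois) * m, mu[pois, ])
    }
    if (any(!pois)) {
      counts[!pois, ] <- stats::rnbinom(sum(!pois) * m,
                                        size = 1 / phi[!pois],
                                        mu = mu[!pois, ])
    }
    dimnames(counts) <- list(design$gene_ids, samples$sample_id)
    cm <- count_matrix(counts, design$gene_lengths, samples)
    attr(cm, "depth_factors") <- depth_factors
    cm
  })
}

#' Orthology map between a diploid and a tetraploid species
#'
#' @param links Data frame with columns `ct_gene` (diploid), `cp_gene`
#'   (tetraploid), `relation` (`"one_to_one"` or `"one_to_multi"`).
#' @param orphans Tetraploid genes with no ortholog link.
#' @return An `orthology_map` object.
#' @export
orthology_map <- function(links, orphans = character(0)) {
  links <- tibble::as_tibble(links)
  stopifnot(all(c("ct_gene", "cp_gene", "relation") %in% names(links)))
  if (!all(links$relation %in% c("one_to_one", "one_to_multi"))) {
    stop("relation must be one_to_one or one_to_multi")
  }
  if (anyDuplicated(links$cp_gene)) {
    stop("a tetraploid gene appears in more than one link")
  }
  by_ct <- split(links$relation, links$ct_gene)
  if (any(vapply(by_ct, function(r) length(unique(r)) > 1, logical(1)))) {
    stop("a diploid gene's links must all share its relation class")
  }
  structure(list(links = links, orphans = unique(orphans)),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  tab <- table(x$links$relation[!duplicated(x$links$ct_gene)])
  cat("orthology_map:", nrow(x$links), "links,",
      length(unique(x$links$ct_gene)), "diploid genes (",
      paste(names(tab), tab, collapse = ", "), "),",
      length(x$orphans), "orphan tetraploid genes\n")
  invisible(x)
}

#' Simulate a diploid-tetraploid orthology map
#'
#' Each diploid gene links to one tetraploid co-ortholog with probability
#' `1 - duplication_prob` or to two with probability `duplication_prob`
#' (retained duplicates from genome duplication; multiplicity is capped at
#' two, tetraploid vs diploid). An `orphan_prob` fraction of tetraploid
#' genes carries no link.
#'
#' @param n_diploid_genes Number of diploid genes.
#' @param duplication_prob Probability a diploid gene has two co-orthologs.
#' @param orphan_prob Fraction of tetraploid genes with no ortholog.
#' @param seed Integer seed.
#' @param ct_prefix,cp_prefix Identifier prefixes.
#' @return An [orthology_map()].
#' @export
simulate_orthology <- function(n_diploid_genes, duplication_prob = 0.52,
                               orphan_prob = 0.55, seed = 1,
                               ct_prefix = "Ct", cp_prefix = "Cp") {
  if (n_diploid_genes < 0) stop("n_diploid_genes must be non-negative")
  if (duplication_prob < 0 || duplication_prob > 1 ||
      orphan_prob < 0 || orphan_prob > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  with_seed(seed, {
    ct <- sprintf("%s%05d", ct_prefix, seq_len(n_diploid_genes))
    k <- 1L + stats::rbinom(n_diploid_genes, 1, duplication_prob)
    n_linked <- sum(k)
    n_orphan <- if (orphan_prob >= 1) {
      stop("orphan_prob = 1 leaves no linked tetraploid genes")
    } else round(n_linked * orphan_prob / (1 - orphan_prob))
    cp <- sprintf("%s%05d", cp_prefix, seq_len(n_linked + n_orphan))
    cp_linked <- sample(cp, n_linked)
    links <- tibble::tibble(
      ct_gene = rep(ct, k),
      cp_gene = cp_linked,
      relation = rep(ifelse(k == 2, "one_to_multi", "one_to_one"), k)
    )
    orthology_map(links, orphans = setdiff(cp, cp_linked))
  })
}
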