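# File-based pipeline: simulate -> de -> cascade -> enrich -> morph ->
# report. Every stage reads its predecessors' TSV outputs from one working
# directory and logs row counts, so the cascade's set arithmetic can be
# audited from logs alone.

#' Default pipeline configuration
#'
#' The study's analysis constants (FDR < 0.05, |log2 fold-change| > 1,
#' TPM floor 1, GO terms with fewer than 5 population genes omitted) plus
#' the simulator's defaults.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_genes = 10000L,
    replicates = 3L,
    depth = 5e6,
    dispersion = 0.05,
    effect_size = 2,
    fdr = 0.05,
    lfc = 1,
    tpm_floor = 1,
    min_term_size = 5,
    enum_cap = 5000,
    n_cells = 30L,
    jitter = 0.03
  )
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys override [default_config()]; unknown keys are an
#' error.
#'
#' @param path YAML path (`NULL` for pure defaults).
#' @param overrides Named list applied last (e.g. command-line flags).
#' @return Configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad) > 0) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    }
    cfg <- utils::modifyList(cfg, user)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  utils::modifyList(cfg, overrides)
}

# The study's comparisons; the submerged control is the fold-change
# denominator everywhere.
cp_comparisons <- function() {
  list(
    aerial = list(treatment = "aerial", stage = "primordium",
                  label = "aerial_vs_submerged"),
    agno3 = list(treatment = "submerged_AgNO3", stage = "primordium",
                 label = "AgNO3_vs_submerged"),
    aba = list(treatment = "submerged_ABA", stage = "primordium",
               label = "ABA_vs_submerged"),
    uniconazole = list(treatment = "submerged_uniconazole",
                       stage = "primordium",
                       label = "uniconazole_vs_submerged"),
    mature = list(treatment = "aerial", stage = "mature",
                  label = "mature_aerial_vs_submerged")
  )
}

#' Differential expression over all study comparisons
#'
#' Runs [test_differential_expression()] for the four treatment-vs-submerged
#' primordium comparisons, the mature-leaf comparison, and the diploid
#' species' aerial-vs-submerged comparison.
#'
#' @param cp_counts,ct_counts [count_matrix] objects for the two species.
#' @param config Configuration list (see [default_config()]).
#' @return Named list of `deg_table`s (`aerial`, `agno3`, `aba`,
#'   `uniconazole`, `mature`, `ct`).
#' @export
run_de <- function(cp_counts, ct_counts, config = default_config()) {
  out <- lapply(cp_comparisons(), function(cmp) {
    test_differential_expression(
      cp_counts, treatment = cmp$treatment, reference = "submerged",
      stage = cmp$stage, comparison = cmp$label,
      fdr_threshold = config$fdr, lfc_threshold = config$lfc,
      tpm_floor = config$tpm_floor, enum_cap = config$enum_cap)
  })
  out$ct <- test_differential_expression(
    ct_counts, treatment = "aerial", reference = "submerged",
    stage = "primordium", fdr_threshold = config$fdr,
    lfc_threshold = config$lfc, tpm_floor = config$tpm_floor,
    enum_cap = config$enum_cap)
  out
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

need_file <- function(dir, name, producer) {
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("missing ", name, ": run the '", producer, "' stage first")
  }
  path
}

#' Pipeline stages
#'
#' Each stage reads its inputs from `dir`, writes its TSV outputs there,
#' and logs per-stage row counts. `stage_simulate` writes the synthetic
#' two-species experiment and cell contours; `stage_de` the DEG tables and
#' the diploid TPM table; `stage_cascade` the candidate report and UpSet
#' counts; `stage_enrich` the GO enrichment of the retained candidates;
#' `stage_morph` the per-cell shape descriptors; `stage_report` the run
#' manifest (thresholds, seed, output checksums, summary counts).
#'
#' @param config Configuration list.
#' @param dir Working directory for pipeline files.
#' @return Invisibly, the main object produced by the stage.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(
    seed = config$seed, n_genes = config$n_genes,
    effect_size = config$effect_size, dispersion = config$dispersion,
    depth = config$depth, replicates = config$replicates)
  write_counts(sim$cp_counts, file.path(dir, "cp_counts.tsv"),
               file.path(dir, "cp_metadata.tsv"),
               file.path(dir, "cp_lengths.tsv"))
  write_counts(sim$ct_counts, file.path(dir, "ct_counts.tsv"),
               file.path(dir, "ct_metadata.tsv"),
               file.path(dir, "ct_lengths.tsv"))
  write_orthology(sim$orthology, file.path(dir, "orthology.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(as.data.frame(sim$truth), file.path(dir, "truth.tsv"))
  cells <- default_cell_populations(n = config$n_cells, seed = config$seed)
  write_contours(cells, file.path(dir, "contours.tsv"))
  stage_log("simulate", nrow(sim$cp_counts$counts), " tetraploid genes, ",
            nrow(sim$ct_counts$counts), " diploid genes, ",
            nrow(sim$orthology$links), " ortholog links, ",
            length(unique(cells$cell_id)), " cells")
  invisible(sim)
}

#' @rdname stage_simulate
#' @export
stage_de <- function(config, dir) {
  cp <- read_counts(need_file(dir, "cp_counts.tsv", "simulate"),
                    need_file(dir, "cp_metadata.tsv", "simulate"),
                    need_file(dir, "cp_lengths.tsv", "simulate"))
  ct <- read_counts(need_file(dir, "ct_counts.tsv", "simulate"),
                    need_file(dir, "ct_metadata.tsv", "simulate"),
                    need_file(dir, "ct_lengths.tsv", "simulate"))
  degs <- run_de(cp, ct, config)
  cp_tab <- do.call(rbind, lapply(degs[names(cp_comparisons())],
                                  as.data.frame))
  write_tsv(cp_tab[c("gene_id", "comparison", "log2fc", "pvalue", "qvalue",
                     "call")], file.path(dir, "deg_cp.tsv"))
  write_deg_table(degs$ct, file.path(dir, "deg_ct.tsv"))
  ct_tpm <- compute_tpm(ct)
  write_tsv(data.frame(gene_id = rownames(ct_tpm), ct_tpm,
                       check.names = FALSE), file.path(dir, "ct_tpm.tsv"))
  for (nm in names(degs)) {
    stage_log("de", nm, ": ", sum(degs[[nm]]$call != "none"), " DEGs of ",
              nrow(degs[[nm]]), " genes (phi = ",
              signif(attr(degs[[nm]], "phi"), 3), ")")
  }
  invisible(degs)
}

#' @rdname stage_simulate
#' @export
stage_cascade <- function(config, dir) {
  tab <- read_deg_table(need_file(dir, "deg_cp.tsv", "de"))
  labels <- vapply(cp_comparisons(), `[[`, character(1), "label")
  degs <- lapply(labels, function(lbl) {
    d <- tab[tab$comparison == lbl, ]
    if (nrow(d) == 0) stop("comparison '", lbl, "' missing from deg_cp.tsv")
    d
  })
  ortho <- read_orthology(need_file(dir, "orthology.tsv", "simulate"))
  ct_deg <- read_deg_table(need_file(dir, "deg_ct.tsv", "de"))
  tpm_df <- read_tsv_checked(need_file(dir, "ct_tpm.tsv", "de"), "gene_id")
  ct_tpm <- as.matrix(vapply(tpm_df[-1], as.numeric,
                             numeric(nrow(tpm_df))))
  rownames(ct_tpm) <- tpm_df$gene_id
  annotation <- read_annotation(need_file(dir, "annotation.tsv", "simulate"))
  report <- run_cascade(degs, ortho, ct_deg, ct_tpm, annotation,
                        tpm_threshold = config$tpm_floor)
  write_candidate_report(report, file.path(dir, "candidate_report.tsv"))
  write_tsv(as.data.frame(attr(report, "upset")),
            file.path(dir, "upset_counts.tsv"))
  s <- attr(report, "summary")
  stage_log("cascade", s[["n_candidates"]], " candidates -> ",
            s[["n_retained"]], " retained -> ", s[["n_tf_candidates"]],
            " TF candidates")
  invisible(report)
}

#' @rdname stage_simulate
#' @export
stage_enrich <- function(config, dir) {
  report <- read_candidate_report(need_file(dir, "candidate_report.tsv",
                                            "cascade"))
  annotation <- read_annotation(need_file(dir, "annotation.tsv", "simulate"))
  deg_cp <- read_deg_table(need_file(dir, "deg_cp.tsv", "de"))
  population <- unique(deg_cp$gene_id)
  study <- intersect(report$gene_id[report$retained], population)
  tm <- term_map_from_annotation(annotation)
  res <- enrich(study, population, tm,
                min_term_size = config$min_term_size,
                fdr_threshold = config$fdr)
  write_enrichment(res, file.path(dir, "enrichment.tsv"))
  stage_log("enrich", nrow(res), " terms tested, ", sum(res$enriched),
            " enriched (study n = ", length(study), ")")
  invisible(res)
}

#' @rdname stage_simulate
#' @export
stage_morph <- function(config, dir) {
  cells <- read_contours(need_file(dir, "contours.tsv", "simulate"))
  desc <- shape_descriptors(cells)
  write_tsv(as.data.frame(desc), file.path(dir, "shape_descriptors.tsv"))
  stage_log("morph", nrow(desc), " cells in ",
            length(unique(desc$group)), " groups")
  invisible(desc)
}

#' @rdname stage_simulate
#' @export
stage_report <- function(config, dir) {
  report_path <- need_file(dir, "candidate_report.tsv", "cascade")
  outputs <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  cfg_path <- file.path(dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "heterophylly",
    package_version = as.character(utils::packageVersion("heterophylly")),
    r_version = R.version.string,
    seed = config$seed,
    thresholds = config[c("fdr", "lfc", "tpm_floor", "min_term_size")],
    config = config,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(md5 = unname(tools::md5sum(p)),
                                      rows = length(readLines(p)) - 1L))
  )
  report <- read_candidate_report(report_path)
  manifest$summary <- list(
    n_candidates = nrow(report),
    n_retained = sum(report$retained),
    n_tf_candidates = sum(report$tf_candidate)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("report", "manifest written for ", length(outputs), " outputs")
  invisible(manifest)
}

#' Run the full pipeline
#'
#' Executes simulate, de, cascade, enrich, morph and report in order.
#'
#' @param config Configuration list from [read_config()].
#' @param dir Working directory for all pipeline files.
#' @return Invisibly, the run manifest.
#' @export
run_pipeline <- function(config = default_config(), dir) {
  stage_simulate(config, dir)
  stage_de(config, dir)
  stage_cascade(config, dir)
  stage_enrich(config, dir)
  stage_morph(config, dir)
  invisible(stage_report(config, dir))
}
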