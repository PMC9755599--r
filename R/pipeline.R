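#' Pipeline configuration and presets
#'
#' Bundles a simulation config with every stage parameter. Three presets
#' describe canonical study conditions: `"null"` (no planted effects
#' anywhere), `"differential"` (10 MGS and 10 metabolites per layer shifted
#' 2-fold in the diabetic groups), and `"load-shift"` (no per-taxon effects
#' but a 2-fold difference in total microbial load — the condition under
#' which relative and quantitative profiles disagree).
#'
#' @param preset One of `"differential"`, `"null"`, `"load-shift"`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides passed to [sim_config()].
#' @param target_depth Rarefaction depth for MGS counts (`NULL` = minimum
#'   per-sample total).
#' @param zero_below Post-rarefaction zeroing threshold (default 3).
#' @param min_breadth,min_prevalence Phage filter parameters.
#' @param coverage_threshold GMM step-coverage cutoff (default 2/3).
#' @param fdr FDR threshold for the differential layer (default 0.10).
#' @param covariates Metadata columns adjusted for in differential tests.
#' @return A list of class `qmp_run_config`.
#' @export
pipeline_config <- function(preset = c("differential", "null", "load-shift"),
                            seed = 1L, ...,
                            target_depth = NULL, zero_below = 3,
                            min_breadth = 0.75, min_prevalence = 0.10,
                            coverage_threshold = 2 / 3, fdr = 0.10,
                            covariates = c("age", "sex", "bmi", "diet_fiber")) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "differential" = list(n_differential_mgs = 10L, effect_size = 2,
                          total_load_fold = 1,
                          n_differential_metabolites = 10L),
    "null" = list(n_differential_mgs = 0L, effect_size = 1,
                  total_load_fold = 1, n_differential_metabolites = 0L),
    "load-shift" = list(n_differential_mgs = 0L, effect_size = 1,
                        total_load_fold = 2, n_differential_metabolites = 0L)
  )
  sim <- do.call(sim_config, modifyList(c(list(seed = as.integer(seed)), base),
                                        list(...)))
  structure(list(preset = preset, seed = as.integer(seed), sim = sim,
                 target_depth = target_depth, zero_below = zero_below,
                 min_breadth = min_breadth, min_prevalence = min_prevalence,
                 coverage_threshold = coverage_threshold, fdr = fdr,
                 covariates = covariates),
            class = "qmp_run_config")
}

#' Validate a pipeline configuration
#'
#' Report-only check: lists out-of-range parameters and missing pieces
#' without stopping.
#'
#' @param config A [pipeline_config()] (or plain list shaped like one).
#' @return Tibble (`field`, `problem`); zero rows when the config is clean.
#' @export
validate_config <- function(config) {
  probs <- list()
  note <- function(field, problem) {
    probs[[length(probs) + 1]] <<- tibble(field = field, problem = problem)
  }
  if (is.null(config$seed) || is.na(config$seed)) {
    note("seed", "missing master seed")
  }
  if (!is.null(config$fdr) && (config$fdr <= 0 || config$fdr >= 1)) {
    note("fdr", "FDR level must be in (0, 1)")
  }
  if (!is.null(config$min_breadth) &&
      (config$min_breadth < 0 || config$min_breadth > 1)) {
    note("min_breadth", "breadth fraction must be in [0, 1]")
  }
  if (!is.null(config$min_prevalence) &&
      (config$min_prevalence < 0 || config$min_prevalence > 1)) {
    note("min_prevalence", "prevalence fraction must be in [0, 1]")
  }
  if (!is.null(config$target_depth) && config$target_depth <= 0) {
    note("target_depth", "rarefaction depth must be >= 1")
  }
  if (is.null(config$sim)) {
    note("sim", "missing simulation config")
  } else {
    ok <- tryCatch({ validate_sim_config(config$sim); TRUE },
                   error = function(e) { note("sim", conditionMessage(e)); FALSE })
    invisible(ok)
  }
  for (p in config$paths %||% list()) {
    if (!file.exists(p)) note("paths", sprintf("missing input file: %s", p))
  }
  if (length(probs) == 0) {
    tibble(field = character(), problem = character())
  } else {
    bind_rows(probs)
  }
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate, classify, quantify (MGS counts, rarefaction,
#' effective-length normalisation, relative abundance, QMP), phage
#' filtering, GMM profiling and the differential-statistics layer in order,
#' against a freshly simulated cohort. Deterministic given the config; a
#' machine-readable manifest records parameters, seeds and content hashes
#' of every output table.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV together with `manifest.json`-style metadata.
#' @param layers Which downstream layers to run
#'   (subset of `c("phage", "gmm", "metabolome")`).
#' @param community Compute the community-level statistics (diversity,
#'   ordination, PERMANOVA, Procrustes)? Default `TRUE`; replicate studies
#'   that only need the differential layer can switch it off.
#' @return A list of class `qmp_run` with elements `tables` (all abundance
#'   tables), `diff` (per-layer differential results), `community`
#'   (diversity/ordination/PERMANOVA/Procrustes), `truth`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         layers = c("phage", "gmm", "metabolome"),
                         community = TRUE) {
  stopifnot(inherits(config, "qmp_run_config"))
  rep <- validate_config(config)
  if (nrow(rep) > 0) {
    abort(paste0("invalid config:\n",
                 paste(" -", rep$field, ":", rep$problem, collapse = "\n")))
  }
  sim <- config$sim
  catalogue <- generate_catalogue(sim)
  cohort <- generate_cohort(sim, catalogue)
  md <- cohort$metadata
  md$t1d_group <- ifelse(md$group == "HC", "HC", "T1D")

  # classify every sample's simulated alignments into gene counts
  per_sample <- purrr::map(md$sample_id, function(sid) {
    aln <- generate_alignments(sim, catalogue, cohort, sid)
    gc <- build_gene_counts(aln$records, catalogue)
    list(gc = gc, truth = aln$pair_truth)
  })
  names(per_sample) <- md$sample_id
  gene_counts <- purrr::imap_dfr(per_sample, function(x, sid) {
    mutate(x$gc$counts, sample_id = sid, .before = 1)
  })
  tallies <- purrr::imap_dfr(per_sample, function(x, sid) {
    tibble(sample_id = sid, !!!as.list(x$gc$tallies),
           n_duplicates = x$gc$n_duplicates)
  })

  # quantify: core genes from the cohort's own length-normalised gene profiles
  gene_wide <- gene_counts |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "n",
                       values_fill = 0L)
  gene_lengths <- setNames(catalogue$genes$length, catalogue$genes$gene_id)
  gene_norm <- effective_length_normalize(gene_wide, gene_lengths,
                                          read_length = sim$read_length)
  core <- core_gene_sets(catalogue, gene_norm, k = sim$core_genes_per_mgs)
  mgs_raw <- mgs_counts(gene_counts, core)
  depth <- config$target_depth %||% min(rowSums(abundance_matrix(mgs_raw)))
  mgs_rare <- rarefy_counts(mgs_raw, target_depth = depth,
                            seed = derive_seed(config$seed, "rarefy"),
                            zero_below = config$zero_below)
  core_len <- mgs_core_lengths(catalogue, core)
  mgs_norm <- effective_length_normalize(mgs_rare, core_len,
                                         read_length = sim$read_length)
  mgs_rel <- relative_abundance(mgs_norm)
  qmp <- quantitative_profile(mgs_rel, md)
  qmp_clr <- clr_transform(qmp, pseudocount = min_positive_half(qmp))

  tables <- list(gene_counts = gene_counts, tallies = tallies,
                 mgs_counts = mgs_raw, mgs_rarefied = mgs_rare,
                 mgs_relative = mgs_rel, qmp = qmp, qmp_clr = qmp_clr,
                 metadata = md)
  diff <- list()
  truth <- list(differential_mgs = cohort$truth$differential_mgs,
                bloom_mgs = cohort$truth$bloom_mgs,
                abundance = cohort$truth$abundance,
                cell_count_true = cohort$truth$cell_count_true,
                pair_classes = purrr::imap_dfr(per_sample, function(x, sid) {
                  mutate(x$truth, sample_id = sid, .before = 1)
                }))

  diff$mgs <- differential_abundance(qmp_clr, md, c("T1D", "HC"),
                                     group_col = "t1d_group",
                                     covariates = config$covariates,
                                     fdr = config$fdr)

  phage_clr <- NULL
  if ("phage" %in% layers) {
    ph <- generate_phage_truth(sim, md$sample_id)
    pr <- phage_pipeline(ph$summaries, min_breadth = config$min_breadth,
                         min_prevalence = config$min_prevalence,
                         seed = derive_seed(config$seed, "phage_rarefy"))
    tables$phage_counts <- pr$counts
    tables$phage_clr <- phage_clr <- pr$clr
    truth$phage <- ph$truth
    if (nrow(pr$clr) > 0 && ncol(pr$clr) > 1) {
      diff$phage <- differential_abundance(
        pr$clr, md, c("T1D", "HC"), group_col = "t1d_group",
        covariates = config$covariates, fdr = config$fdr)
    }
  }
  if ("gmm" %in% layers) {
    defs <- generate_gmm_definitions(sim)
    gene_rel <- relative_abundance(gene_norm, percent = FALSE)
    gene_qmp <- quantitative_profile(gene_rel, md)
    ko <- ko_abundance(gene_qmp,
                       select(catalogue$genes, "gene_id", "ko"))
    gmm <- gmm_abundance(ko, defs,
                         coverage_threshold = config$coverage_threshold)
    tables$gmm <- gmm
    tables$gmm_clr <- clr_modules(gmm)
    diff$gmm <- differential_abundance(
      tables$gmm_clr, md, c("T1D", "HC"), group_col = "t1d_group",
      covariates = config$covariates, fdr = config$fdr)
  }
  if ("metabolome" %in% layers) {
    met <- generate_metabolome(sim, md)
    tables$polar <- met$polar
    tables$lipids <- met$lipids
    truth$differential_polar <- met$truth$differential_polar
    truth$differential_lipids <- met$truth$differential_lipids
    for (layer in c("polar", "lipids")) {
      adj <- covariate_adjust(tables[[layer]], md$egfr)
      diff[[layer]] <- differential_abundance(
        adj, md, c("T1D", "HC"), group_col = "t1d_group",
        covariates = config$covariates, fdr = config$fdr)
    }
  }

  # community-level statistics on the bacteriome
  comm <- NULL
  if (community) {
  rel_frac <- relative_abundance(mgs_rel, percent = FALSE)
  jsd <- jsd_distance(rel_frac)
  comm <- list(
    shannon = alpha_diversity_table(rel_frac, "shannon"),
    pcoa = pcoa_ordination(jsd),
    permanova = permanova(jsd, md$t1d_group[match(labels(jsd), md$sample_id)],
                          n_perm = 999,
                          seed = derive_seed(config$seed, "permanova"))
  )
  if (!is.null(phage_clr) && nrow(phage_clr) > 1 && ncol(phage_clr) > 2) {
    shared <- intersect(md$sample_id, phage_clr$sample_id)
    bx <- pcoa_ordination(jsd_distance(
      rel_frac[match(shared, rel_frac$sample_id), , drop = FALSE]))
    py <- pcoa_ordination(stats::dist(
      abundance_matrix(phage_clr)[shared, , drop = FALSE]))
    kdim <- min(ncol(bx$coordinates), ncol(py$coordinates)) - 1
    comm$procrustes <- procrustes_correlation(
      bx$coordinates[, 1:(1 + kdim)], py$coordinates[, 1:(1 + kdim)],
      n_perm = 199, seed = derive_seed(config$seed, "procrustes"))
  }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("qmpflow")),
    preset = config$preset, seed = config$seed,
    parameters = config[c("target_depth", "zero_below", "min_breadth",
                          "min_prevalence", "coverage_threshold", "fdr")],
    sim = unclass(sim),
    table_hashes = purrr::map_chr(tables, rlang::hash),
    rarefaction_depth = depth
  )
  res <- structure(list(tables = tables, diff = diff, community = comm,
                        truth = truth, manifest = manifest),
                   class = "qmp_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

min_positive_half <- function(x) {
  m <- abundance_matrix(x)
  pos <- m[m > 0]
  if (length(pos) == 0) 1 else min(pos) / 2
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$tables)) {
    readr::write_tsv(run$tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  for (nm in names(run$diff)) {
    readr::write_tsv(run$diff[[nm]],
                     file.path(out_dir, paste0("diff_", nm, ".tsv")))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.qmp_run <- function(x, ...) {
  cat("<qmp_run> preset '", x$manifest$preset, "', seed ", x$manifest$seed,
      "\n", sep = "")
  cat("  samples:", nrow(x$tables$metadata),
      " | MGS:", ncol(x$tables$qmp) - 1, "\n")
  for (nm in names(x$diff)) {
    cat(sprintf("  %-8s %d/%d significant at %d%% FDR\n", nm,
                sum(x$diff[[nm]]$significant),
                sum(!x$diff[[nm]]$untestable),
                round(100 * attr(x$diff[[nm]], "fdr"))))
  }
  invisible(x)
}
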