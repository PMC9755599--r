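#' Simulation configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module into one validated object.
#' The defaults describe the cohort structure the generators emulate: four
#' study groups (healthy controls and three albuminuria strata of long-standing
#' type 1 diabetes), a gene catalogue organised into metagenomic species (MGS)
#' with 100 designated core genes each, paired-end alignment summaries with
#' planted defective records, a phage layer with breadths straddling the 75%
#' genome-coverage rule, and log-normal polar-metabolite / lipid matrices with
#' planted group shifts and an optional eGFR confounder.
#'
#' @param seed Integer master seed; every generator derives its own sub-seed
#'   from it, so an identical config yields byte-identical output.
#' @param n_mgs Number of metagenomic species in the catalogue.
#' @param genes_per_mgs Length-2 integer range of member genes per MGS; the
#'   lower bound must be at least 3 or the core-gene detection rule becomes
#'   untestable.
#' @param gene_length Length-2 range of gene lengths in bp.
#' @param n_unbinned_genes Catalogue genes with no MGS membership.
#' @param core_genes_per_mgs Number of designated true core genes per MGS
#'   (capped at the MGS size).
#' @param ko_pool Size of the KEGG-orthology identifier pool.
#' @param frac_annotated Fraction of catalogue genes carrying a KO annotation.
#' @param group_sizes Named integer vector of samples per group.
#' @param n_differential_mgs Number of MGS with a planted abundance shift in
#'   the diabetic groups.
#' @param effect_size Multiplicative fold-change applied to planted MGS
#'   (half up, half down); must be > 0.
#' @param total_load_fold Ratio of total microbial load between the diabetic
#'   groups and healthy controls (1 = equal loads).
#' @param load_bloom How the load difference arises. `FALSE` (default):
#'   every taxon is scaled by `total_load_fold` in the diabetic groups.
#'   `TRUE`: a single designated "bloomer" MGS (the first) expands until the
#'   group total reaches `total_load_fold` times its original value while
#'   every other taxon keeps its absolute abundance — the construction under
#'   which relative profiles are diluted but quantitative profiles are not.
#' @param sigma_log Between-subject standard deviation of log absolute MGS
#'   abundance (natural-log scale).
#' @param mean_cells_per_gram Cohort-average total microbial load (cells/g).
#' @param cellcount_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise on flow-cytometry cell counts.
#' @param read_length Read length in bp used for effective-length
#'   normalisation and alignment simulation.
#' @param pairs_per_sample Read pairs simulated per sample.
#' @param frac_multimap,frac_lowident,frac_short,frac_overhang,frac_duplicate
#'   Probabilities of planting, per pair, the corresponding defective record
#'   class (MAPQ < 20; identity < 95%; alignment < 100 bp; > 10 bp end
#'   overhang away from a gene terminus; PCR/optical duplicate).
#' @param n_phages Number of phages in the synthetic phage database.
#' @param phage_prevalence Length-2 range of per-phage presence probability.
#' @param breadth_spectrum Breadth-of-coverage fractions planted for present
#'   phages; should straddle the 0.75 filter boundary.
#' @param n_polar,n_lipids Number of polar-metabolite / lipid features.
#' @param n_differential_metabolites Features per metabolome layer with a
#'   planted group shift.
#' @param metabolite_effect Planted shift in natural-log units.
#' @param metabolite_sigma Between-subject sd of log intensities.
#' @param egfr_slope Log-intensity change per unit eGFR for the confounded
#'   feature subset (0 disables the confounder).
#' @param frac_egfr_confounded Fraction of metabolome features linearly tied
#'   to eGFR.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_mgs = 10, genes_per_mgs = c(20, 30))
#' cfg$n_mgs
sim_config <- function(seed = 1L,
                       n_mgs = 100L,
                       genes_per_mgs = c(100L, 150L),
                       gene_length = c(500L, 3000L),
                       n_unbinned_genes = 200L,
                       core_genes_per_mgs = 100L,
                       ko_pool = 400L,
                       frac_annotated = 0.65,
                       group_sizes = c(HC = 20L, normo = 20L,
                                       moderate = 20L, severe = 20L),
                       n_differential_mgs = 10L,
                       effect_size = 2,
                       total_load_fold = 1,
                       load_bloom = FALSE,
                       sigma_log = 0.5,
                       mean_cells_per_gram = 1e11,
                       cellcount_cv = 0.10,
                       read_length = 150L,
                       pairs_per_sample = 20000L,
                       frac_multimap = 0.05,
                       frac_lowident = 0.04,
                       frac_short = 0.03,
                       frac_overhang = 0.03,
                       frac_duplicate = 0.05,
                       n_phages = 300L,
                       phage_prevalence = c(0.05, 0.9),
                       breadth_spectrum = c(0.50, 0.74, 0.75, 0.90),
                       n_polar = 200L,
                       n_lipids = 100L,
                       n_differential_metabolites = 10L,
                       metabolite_effect = 1.0,
                       metabolite_sigma = 0.75,
                       egfr_slope = 0,
                       frac_egfr_confounded = 0.10) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_count(cfg$seed, "seed", min = 0)
  assert_count(cfg$n_mgs, "n_mgs")
  assert_count(cfg$genes_per_mgs, "genes_per_mgs")
  if (length(cfg$genes_per_mgs) != 2 || cfg$genes_per_mgs[1] > cfg$genes_per_mgs[2]) {
    abort("`genes_per_mgs` must be an increasing length-2 range")
  }
  if (cfg$genes_per_mgs[1] < 3) {
    abort("`genes_per_mgs` lower bound must be >= 3 (MGS detection needs 3 core genes)")
  }
  assert_count(cfg$n_unbinned_genes, "n_unbinned_genes", min = 0)
  assert_count(cfg$core_genes_per_mgs, "core_genes_per_mgs", min = 3)
  if (length(cfg$group_sizes) < 1 || is.null(names(cfg$group_sizes))) {
    abort("`group_sizes` must be a nonempty named vector")
  }
  assert_count(cfg$group_sizes, "group_sizes")
  if (cfg$effect_size <= 0) abort("`effect_size` must be > 0")
  if (cfg$total_load_fold <= 0) abort("`total_load_fold` must be > 0")
  for (f in c("frac_annotated", "frac_multimap", "frac_lowident", "frac_short",
              "frac_overhang", "frac_duplicate", "frac_egfr_confounded")) {
    assert_prob(cfg[[f]], f)
  }
  tot <- cfg$frac_multimap + cfg$frac_lowident + cfg$frac_short +
    cfg$frac_overhang + cfg$frac_duplicate
  if (tot > 1) abort("planted defect fractions must sum to <= 1")
  assert_count(cfg$pairs_per_sample, "pairs_per_sample", min = 0)
  if (any(cfg$breadth_spectrum < 0 | cfg$breadth_spectrum > 1)) {
    abort("`breadth_spectrum` entries must be in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  catalogue:", x$n_mgs, "MGS x", paste(x$genes_per_mgs, collapse = "-"),
      "genes,", x$n_unbinned_genes, "unbinned\n")
  cat("  cohort:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                         collapse = ", "), "\n")
  cat("  planted: ", x$n_differential_mgs, " MGS x", x$effect_size,
      " fold; load fold ", x$total_load_fold, "\n", sep = "")
  invisible(x)
}
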