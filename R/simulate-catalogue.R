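#' Generate a synthetic gene catalogue with MGS definitions
#'
#' Builds a mock gene catalogue organised into metagenomic species (MGS):
#' each MGS gets a random number of member genes within the configured range,
#' of which the first `core_genes_per_mgs` are designated true core genes
#' (ground truth for core-gene selection). A configurable number of unbinned
#' genes carry no MGS membership, and a fraction of all genes receive a KO
#' annotation drawn from the configured pool.
#'
#' @param config A [sim_config()].
#' @return A list of class `qmp_catalogue` with elements
#'   * `genes`: tibble (`gene_id`, `length`, `mgs_id` (`NA` = unbinned), `ko`),
#'   * `core_genes`: tibble (`mgs_id`, `gene_id`) of true core genes.
#' @export
#' @examples
#' cat10 <- generate_catalogue(sim_config(seed = 7, n_mgs = 5,
#'                                        genes_per_mgs = c(10, 15)))
#' dplyr::count(cat10$genes, is.na(mgs_id))
generate_catalogue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "catalogue"), {
    n_genes_mgs <- sample(config$genes_per_mgs[1]:config$genes_per_mgs[2],
                          config$n_mgs, replace = TRUE)
    mgs_ids <- sprintf("MGS%04d", seq_len(config$n_mgs))
    genes <- purrr::map2_dfr(mgs_ids, n_genes_mgs, function(mid, ng) {
      tibble(
        gene_id = sprintf("%s_g%04d", mid, seq_len(ng)),
        length = sample(config$gene_length[1]:config$gene_length[2], ng,
                        replace = TRUE),
        mgs_id = mid
      )
    })
    if (config$n_unbinned_genes > 0) {
      genes <- bind_rows(genes, tibble(
        gene_id = sprintf("UNBIN_g%04d", seq_len(config$n_unbinned_genes)),
        length = sample(config$gene_length[1]:config$gene_length[2],
                        config$n_unbinned_genes, replace = TRUE),
        mgs_id = NA_character_
      ))
    }
    ko_ids <- sprintf("K%05d", seq_len(config$ko_pool))
    annotated <- runif(nrow(genes)) < config$frac_annotated
    genes$ko <- ifelse(annotated, sample(ko_ids, nrow(genes), replace = TRUE),
                       NA_character_)
    core_genes <- genes |>
      filter(!is.na(.data$mgs_id)) |>
      group_by(.data$mgs_id) |>
      dplyr::slice_head(n = config$core_genes_per_mgs) |>
      ungroup() |>
      select("mgs_id", "gene_id")
  })
  structure(list(genes = genes, core_genes = core_genes),
            class = "qmp_catalogue")
}

#' @export
print.qmp_catalogue <- function(x, ...) {
  cat("<qmp_catalogue> ", nrow(x$genes), " genes, ",
      dplyr::n_distinct(x$core_genes$mgs_id), " MGS, ",
      sum(is.na(x$genes$mgs_id)), " unbinned\n", sep = "")
  invisible(x)
}

# unit used by pair classification: MGS id, or a singleton unit per unbinned gene
gene_units <- function(catalogue) {
  genes <- catalogue$genes
  setNames(
    ifelse(is.na(genes$mgs_id), paste0("singleton:", genes$gene_id),
           genes$mgs_id),
    genes$gene_id
  )
}

#' Generate a synthetic cohort with ground-truth absolute abundances
#'
#' Draws per-sample absolute MGS abundances (cells/g) from a log-normal law,
#' plants multiplicative fold-changes on `n_differential_mgs` randomly chosen
#' MGS in the diabetic groups (half up-, half down-regulated), optionally
#' scales the total microbial load of the diabetic groups by
#' `total_load_fold`, and derives a flow-cytometry cell count per sample as
#' the true total abundance times multiplicative log-normal measurement noise.
#' Clinical covariates (age, sex, BMI, eGFR, diabetes duration, dietary fibre)
#' are drawn from documented distributions and the urinary albumin/creatinine
#' ratio (UACR) is drawn inside each group's defining interval.
#'
#' @param config A [sim_config()].
#' @param catalogue A [generate_catalogue()] result.
#' @return A list of class `qmp_cohort` with
#'   * `metadata`: tibble of per-sample clinical variables incl. measured
#'     `cell_count` (cells/g),
#'   * `truth`: list with `abundance` (wide tibble, true cells/g per MGS),
#'     `unbinned` (wide tibble of unbinned-gene abundance used by the
#'     alignment simulator), `differential_mgs` (tibble `mgs_id`, `direction`,
#'     `fold`), `cell_count_true`.
#' @export
generate_cohort <- function(config, catalogue) {
  stopifnot(inherits(config, "sim_config"), inherits(catalogue, "qmp_catalogue"))
  if (config$effect_size <= 0) abort("`effect_size` must be > 0")
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  mgs_ids <- unique(catalogue$core_genes$mgs_id)
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    sample_ids <- sprintf("S%03d", seq_len(n))
    # per-MGS baseline mean (log scale) gives a heavy-tailed rank-abundance curve
    mu <- rnorm(length(mgs_ids), mean = 0, sd = 1.0)
    logab <- matrix(rnorm(n * length(mgs_ids), mean = rep(mu, each = n),
                          sd = config$sigma_log),
                    nrow = n, dimnames = list(sample_ids, mgs_ids))
    ab <- exp(logab)
    # planted differential MGS: multiplied in all diabetic (non-HC) groups
    n_diff <- min(config$n_differential_mgs, length(mgs_ids))
    diff_idx <- if (n_diff > 0) sample(seq_along(mgs_ids), n_diff) else integer()
    direction <- rep(c("up", "down"), length.out = n_diff)
    t1d <- groups != "HC"
    if (n_diff > 0) {
      fold <- ifelse(direction == "up", config$effect_size, 1 / config$effect_size)
      ab[t1d, diff_idx] <- sweep(ab[t1d, diff_idx, drop = FALSE], 2, fold, `*`)
    }
    bloom_mgs <- NULL
    if (config$total_load_fold != 1) {
      if (isTRUE(config$load_bloom)) {
        # one designated MGS absorbs the whole load difference
        bloom_mgs <- mgs_ids[1]
        extra <- (config$total_load_fold - 1) * rowSums(ab[t1d, , drop = FALSE])
        ab[t1d, 1] <- ab[t1d, 1] + extra
      } else {
        ab[t1d, ] <- ab[t1d, ] * config$total_load_fold
      }
    }
    # rescale so the cohort-average load matches the configured cells/g
    ab <- ab * (config$mean_cells_per_gram / mean(rowSums(ab)))
    cell_true <- rowSums(ab)
    sdlog_cc <- sqrt(log(1 + config$cellcount_cv^2))
    cell_meas <- cell_true * exp(rnorm(n, -sdlog_cc^2 / 2, sdlog_cc))
    # unbinned genes get a small shared abundance pool (~5% of total mass)
    unb_genes <- catalogue$genes$gene_id[is.na(catalogue$genes$mgs_id)]
    unb <- NULL
    if (length(unb_genes) > 0) {
      unb_mu <- rnorm(length(unb_genes), 0, 1)
      unb <- exp(matrix(rnorm(n * length(unb_genes),
                              mean = rep(unb_mu, each = n), sd = config$sigma_log),
                        nrow = n, dimnames = list(sample_ids, unb_genes)))
      unb <- unb * (0.05 * mean(cell_true) / mean(rowSums(unb)))
    }
    uacr <- unname(vapply(groups, draw_uacr, numeric(1)))
    metadata <- tibble(
      sample_id = sample_ids,
      group = factor(groups, levels = names(config$group_sizes)),
      uacr = uacr,
      age = rnorm(n, 60, 11),
      sex = ifelse(runif(n) < 0.42, "female", "male"),
      bmi = rnorm(n, 25, 3.5),
      egfr = ifelse(t1d, pmax(rnorm(n, 75, 25), 16), rnorm(n, 90, 12)),
      diabetes_duration = ifelse(t1d, pmax(rnorm(n, 42, 15), 1), 0),
      diet_fiber = pmax(rnorm(n, 22, 7), 2),
      cell_count = unname(cell_meas)
    )
  })
  truth <- list(
    abundance = abundance_tibble(ab, kind = "true_cells_per_gram"),
    unbinned = if (!is.null(unb)) abundance_tibble(unb) else NULL,
    differential_mgs = tibble(mgs_id = mgs_ids[diff_idx], direction = direction,
                              fold = if (n_diff > 0)
                                ifelse(direction == "up", config$effect_size,
                                       1 / config$effect_size) else numeric()),
    bloom_mgs = bloom_mgs,
    cell_count_true = setNames(cell_true, sample_ids)
  )
  structure(list(metadata = metadata, truth = truth), class = "qmp_cohort")
}

# group-conditional UACR draw (mg/mmol), log-uniform inside each stratum
draw_uacr <- function(group) {
  cut <- albuminuria_cutoffs()
  r <- switch(group,
    severe = c(cut[["severe"]], 400),
    moderate = c(cut[["moderate_lower"]], cut[["severe"]]),
    c(0.3, cut[["moderate_lower"]])
  )
  exp(runif(1, log(r[1]), log(r[2]) - 1e-9))
}

#' @export
print.qmp_cohort <- function(x, ...) {
  cat("<qmp_cohort> ", nrow(x$metadata), " samples (",
      paste(levels(x$metadata$group), table(x$metadata$group), sep = "=",
            collapse = ", "), "), ",
      nrow(x$truth$differential_mgs), " planted differential MGS\n", sep = "")
  invisible(x)
}
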