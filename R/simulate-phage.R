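#' Simulate phage alignment summaries with planted breadths
#'
#' Emulates per-(phage, sample) alignment summaries against a phage genome
#' database: each phage gets a genome length (a multiple of 100 bp) and a
#' per-phage prevalence; for present cells a breadth of genome coverage is
#' planted by drawing exactly from `config$breadth_spectrum` (so covered-base
#' fractions are exact) and a read count is drawn log-normal.
#'
#' @param config A [sim_config()].
#' @param sample_ids Character vector of samples to simulate.
#' @return List of class `qmp_phage_sim`:
#'   * `summaries`: tibble (`phage_id`, `genome_length`, `sample_id`,
#'     `covered_bases`, `read_count`);
#'   * `truth`: tibble (`phage_id`, `sample_id`, `breadth`) of planted
#'     breadths for present cells.
#' @export
generate_phage_truth <- function(config, sample_ids) {
  stopifnot(inherits(config, "sim_config"), length(sample_ids) >= 1)
  withr::with_seed(derive_seed(config$seed, "phage"), {
    phage_ids <- sprintf("uvig_%05d", seq_len(config$n_phages))
    glen <- sample(seq(10000L, 100000L, by = 100L), config$n_phages,
                   replace = TRUE)
    prev <- runif(config$n_phages, config$phage_prevalence[1],
                  config$phage_prevalence[2])
    grid <- tidyr::expand_grid(phage_id = phage_ids, sample_id = sample_ids) |>
      left_join(tibble(phage_id = phage_ids, genome_length = glen,
                       prevalence = prev), by = "phage_id")
    present <- runif(nrow(grid)) < grid$prevalence
    breadth <- ifelse(present,
                      sample(config$breadth_spectrum, nrow(grid), replace = TRUE),
                      0)
    counts <- ifelse(present, pmax(round(rlnorm(nrow(grid), 4, 1)), 1L), 0L)
    summaries <- grid |>
      mutate(covered_bases = as.integer(round(breadth * .data$genome_length)),
             read_count = as.integer(counts)) |>
      select("phage_id", "genome_length", "sample_id", "covered_bases",
             "read_count")
    truth <- grid |>
      mutate(breadth = breadth) |>
      filter(present) |>
      select("phage_id", "sample_id", "breadth")
  })
  structure(list(summaries = summaries, truth = truth),
            class = "qmp_phage_sim")
}

#' Simulate polar-metabolite and lipid intensity matrices
#'
#' Draws log-normal feature intensities, plants additive log-scale group
#' shifts of `metabolite_effect` on `n_differential_metabolites` features per
#' layer in the diabetic groups (half up, half down), and, when
#' `egfr_slope != 0`, ties a random `frac_egfr_confounded` subset of features
#' linearly to each sample's eGFR.
#'
#' @param config A [sim_config()].
#' @param metadata Cohort metadata tibble (needs `sample_id`, `group`, `egfr`).
#' @return List of class `qmp_metabolome_sim`:
#'   * `polar`, `lipids`: wide tibbles of log-intensities (natural log);
#'   * `truth`: list with `differential_polar`, `differential_lipids`
#'     (tibbles `feature`, `direction`) and `egfr_confounded` feature ids.
#' @export
generate_metabolome <- function(config, metadata) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(metadata))
  t1d <- metadata$group != "HC"
  n <- nrow(metadata)
  withr::with_seed(derive_seed(config$seed, "metabolome"), {
    layer <- function(prefix, n_feat) {
      feats <- sprintf("%s_%04d", prefix, seq_len(n_feat))
      mu <- rnorm(n_feat, 10, 2)
      m <- matrix(rnorm(n * n_feat, mean = rep(mu, each = n),
                        sd = config$metabolite_sigma),
                  nrow = n, dimnames = list(metadata$sample_id, feats))
      nd <- min(config$n_differential_metabolites, n_feat)
      idx <- if (nd > 0) sample(n_feat, nd) else integer()
      dirn <- rep(c("up", "down"), length.out = nd)
      shift <- ifelse(dirn == "up", config$metabolite_effect,
                      -config$metabolite_effect)
      if (nd > 0) {
        m[t1d, idx] <- sweep(m[t1d, idx, drop = FALSE], 2, shift, `+`)
      }
      conf <- integer()
      if (config$egfr_slope != 0 && config$frac_egfr_confounded > 0) {
        conf <- sample(setdiff(seq_len(n_feat), idx),
                       round(config$frac_egfr_confounded * n_feat))
        egfr_c <- metadata$egfr - mean(metadata$egfr)
        m[, conf] <- m[, conf, drop = FALSE] +
          outer(egfr_c, rep(config$egfr_slope, length(conf)))
      }
      list(mat = abundance_tibble(m, kind = "log_intensity"),
           differential = tibble(feature = feats[idx], direction = dirn),
           confounded = feats[conf])
    }
    pol <- layer("polar", config$n_polar)
    lip <- layer("lipid", config$n_lipids)
  })
  structure(list(
    polar = pol$mat, lipids = lip$mat,
    truth = list(differential_polar = pol$differential,
                 differential_lipids = lip$differential,
                 egfr_confounded = c(pol$confounded, lip$confounded))
  ), class = "qmp_metabolome_sim")
}

#' Simulate gut-metabolic-module definitions over the KO pool
#'
#' Builds random module definitions in the same shape as curated GMM
#' databases: each module has 1-6 ordered steps, each step 1-3 alternative
#' KOs drawn from the catalogue's KO pool.
#'
#' @param config A [sim_config()].
#' @param n_modules Number of modules to generate.
#' @return A tibble (`module_id`, `name`, `step`, `ko`) — one row per
#'   (step, alternative KO).
#' @export
generate_gmm_definitions <- function(config, n_modules = 30L) {
  stopifnot(inherits(config, "sim_config"))
  ko_ids <- sprintf("K%05d", seq_len(config$ko_pool))
  withr::with_seed(derive_seed(config$seed, "gmm"), {
    purrr::map_dfr(seq_len(n_modules), function(i) {
      n_steps <- sample(1:6, 1)
      purrr::map_dfr(seq_len(n_steps), function(s) {
        tibble(module_id = sprintf("MF%04d", i),
               name = sprintf("synthetic module %d", i),
               step = s,
               ko = sample(ko_ids, sample(1:3, 1)))
      })
    })
  })
}
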