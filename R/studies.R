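#' Replicated end-to-end recovery study on the differential preset
#'
#' Runs the full simulate-classify-quantify-test pipeline `n_reps` times
#' under the `"differential"` preset (each replicate with its own seed
#' derived from `seed`) and records, per replicate, the sensitivity
#' (fraction of planted differential MGS called at the FDR threshold) and
#' the empirical false-discovery proportion among the calls (0 when nothing
#' is called).
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return Tibble (`replicate`, `sensitivity`, `fdp`, `n_calls`).
#' @export
recovery_study <- function(n_reps = 50, seed = 1L, ...) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    cfg <- pipeline_config("differential",
                           seed = derive_seed(seed, paste0("rep", i)), ...)
    run <- run_pipeline(cfg, layers = character(), community = FALSE)
    truth <- run$truth$differential_mgs$mgs_id
    calls <- run$diff$mgs$feature[run$diff$mgs$significant]
    tibble(replicate = i,
           sensitivity = mean(truth %in% calls),
           fdp = if (length(calls) == 0) 0 else mean(!calls %in% truth),
           n_calls = length(calls))
  })
}

#' Type-I error of the PERMANOVA under a global null
#'
#' Repeatedly draws unstructured multivariate-normal data, assigns
#' meaningless two-group labels, and records the rejection rate of
#' [permanova()] at level `alpha`. Under exchangeability the add-one
#' permutation p-value is (discretely) uniform, so the rejection rate
#' should match `alpha`.
#'
#' @param n_reps Null replicates (default 500).
#' @param n_per_group Samples per group (default 10).
#' @param n_dim Dimensions of the null data (default 5).
#' @param n_perm Permutations per test (default 199).
#' @param alpha Nominal level (default 0.05).
#' @param seed Master seed.
#' @return List with `rejection_rate` and the vector of `p_values`.
#' @export
permanova_null_study <- function(n_reps = 500, n_per_group = 10, n_dim = 5,
                                 n_perm = 199, alpha = 0.05, seed = 1L) {
  n <- 2 * n_per_group
  g <- rep(c("a", "b"), each = n_per_group)
  p <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_reps), function(i) {
      x <- matrix(rnorm(n * n_dim), nrow = n)
      permanova(stats::dist(x), g, n_perm = n_perm,
                seed = sample.int(2^30, 1))$p_value
    }, numeric(1))
  })
  list(rejection_rate = mean(p <= alpha), p_values = p)
}
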