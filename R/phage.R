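#' Filter phage counts by breadth of genome coverage
#'
#' A phage's reads in a sample are kept only if they cover at least
#' `min_breadth` of the phage genome length (breadth of coverage, boundary
#' inclusive); cells below the breadth threshold are set to zero. The filter
#' is idempotent.
#'
#' @param summaries Tibble (`phage_id`, `genome_length`, `sample_id`,
#'   `covered_bases`, `read_count`).
#' @param min_breadth Minimum breadth fraction (default 0.75).
#' @return Wide tibble (samples x phages) of read counts, kind
#'   `"raw_counts"`.
#' @export
#' @examples
#' s <- tibble::tibble(phage_id = "ph1", genome_length = 100L,
#'                     sample_id = c("a", "b"), covered_bases = c(75L, 74L),
#'                     read_count = c(10L, 10L))
#' breadth_filter(s)
breadth_filter <- function(summaries, min_breadth = 0.75) {
  need <- c("phage_id", "genome_length", "sample_id", "covered_bases",
            "read_count")
  stopifnot(all(need %in% names(summaries)))
  if (any(summaries$genome_length <= 0)) abort("genome_length must be > 0")
  if (any(summaries$covered_bases > summaries$genome_length)) {
    abort("covered_bases exceeds genome_length")
  }
  if (any(summaries$covered_bases < 0) || any(summaries$read_count < 0)) {
    abort("covered_bases and read_count must be non-negative")
  }
  filtered <- summaries |>
    mutate(breadth = .data$covered_bases / .data$genome_length,
           kept = ifelse(.data$breadth >= min_breadth, .data$read_count, 0L))
  wide <- filtered |>
    select("sample_id", "phage_id", "kept") |>
    tidyr::pivot_wider(names_from = "phage_id", values_from = "kept",
                       values_fill = 0L)
  attr(wide, "kind") <- "raw_counts"
  wide
}

#' Rarefy phage counts to the minimum per-sample total
#'
#' Down-samples every retained sample, without replacement, to the smallest
#' positive per-sample read total, so rarefied totals are exactly equal
#' across samples. Samples with zero total are excluded and reported.
#'
#' @param counts Wide tibble of phage read counts.
#' @param seed Integer seed.
#' @return Wide tibble of rarefied counts, kind `"rarefied_counts"`, with
#'   `"excluded_samples"` and `"target_depth"` attributes.
#' @export
rarefy_phages <- function(counts, seed = 1L) {
  m <- abundance_matrix(counts)
  tot <- rowSums(m)
  if (all(tot == 0)) abort("no sample with positive phage read total")
  min_depth <- min(tot[tot > 0])
  rarefy_counts(counts, target_depth = min_depth, seed = seed, zero_below = 0)
}

#' Filter phage features by prevalence
#'
#' Retains a phage only if it is nonzero in at least
#' `floor(min_fraction * n_samples)` samples (so 10% of 211 samples gives a
#' threshold of 21).
#'
#' @param counts Wide tibble (samples x phages).
#' @param min_fraction Minimum prevalence fraction (default 0.10).
#' @return Wide tibble restricted to retained phages; the integer threshold
#'   used is stored in the `"prevalence_threshold"` attribute.
#' @export
prevalence_filter <- function(counts, min_fraction = 0.10) {
  m <- abundance_matrix(counts)
  thr <- floor(min_fraction * nrow(m))
  present <- colSums(m > 0)
  keep <- present >= thr
  out <- abundance_tibble(m[, keep, drop = FALSE], kind = abund_kind(counts))
  attr(out, "prevalence_threshold") <- thr
  out
}

#' Full phage quantification: breadth filter, rarefy, prevalence filter, CLR
#'
#' @param summaries Phage alignment summaries (see [breadth_filter()]).
#' @param min_breadth,min_prevalence Filter parameters.
#' @param seed Rarefaction seed.
#' @return List with `counts` (filtered rarefied wide tibble) and `clr`
#'   (CLR-transformed with +1 pseudocount).
#' @export
phage_pipeline <- function(summaries, min_breadth = 0.75,
                           min_prevalence = 0.10, seed = 1L) {
  filtered <- breadth_filter(summaries, min_breadth = min_breadth)
  rare <- rarefy_phages(filtered, seed = seed)
  kept <- prevalence_filter(rare, min_fraction = min_prevalence)
  list(counts = kept, clr = clr_transform(kept, pseudocount = 1))
}
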