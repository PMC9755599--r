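#' Select core genes for an MGS from reference gene profiles
#'
#' An MGS is quantified through its "core" genes: the `k` member genes whose
#' across-sample abundance profiles best track the MGS signal. Each gene is
#' scored by (i) Pearson correlation with the across-gene mean profile
#' (higher is better) and (ii) mean absolute deviation from that profile
#' after rescaling the gene to the profile's mean (lower is better); the two
#' ranks are summed and the `k` best-ranked genes selected, with ties broken
#' lexicographically by gene id so the set is stable across runs.
#'
#' @param gene_profiles Reference samples-by-member-genes matrix of
#'   length-normalised abundances (matrix or wide tibble with `sample_id`).
#' @param k Number of core genes (default 100); if the MGS has fewer member
#'   genes, all are taken.
#' @return Character vector of selected gene ids (in catalogue order of
#'   selection quality).
#' @export
#' @examples
#' m <- matrix(rep(c(1, 2, 4), 3), ncol = 3,
#'             dimnames = list(NULL, c("gA", "gB", "gC")))
#' select_core_genes(m, k = 2)
select_core_genes <- function(gene_profiles, k = 100) {
  m <- abundance_matrix(gene_profiles)
  if (nrow(m) < 2) abort("core-gene selection needs >= 2 reference samples")
  if (all(m == 0)) abort("all-zero gene profiles: cannot select core genes")
  if (ncol(m) <= k) return(sort(colnames(m)))
  mean_profile <- rowMeans(m)
  cors <- suppressWarnings(as.numeric(cor(m, mean_profile)))
  cors[is.na(cors)] <- -Inf                      # constant/zero genes last
  gm <- colMeans(m)
  scale_to <- mean(mean_profile)
  mad_dev <- vapply(seq_len(ncol(m)), function(j) {
    if (gm[j] <= 0) return(Inf)
    mean(abs(m[, j] * scale_to / gm[j] - mean_profile))
  }, numeric(1))
  ord_ids <- colnames(m)
  r_cor <- rank(-cors, ties.method = "min")
  r_dev <- rank(mad_dev, ties.method = "min")
  combined <- r_cor + r_dev
  sel <- order(combined, ord_ids)[seq_len(k)]
  sort(ord_ids[sel])
}

#' Core-gene sets for every MGS in a catalogue
#'
#' Applies [select_core_genes()] per MGS to a reference gene-abundance table,
#' or falls back to the catalogue's designated core genes when no reference
#' profiles are given (the usual situation when a pre-built MGS set is used).
#'
#' @param catalogue A `qmp_catalogue`.
#' @param gene_abundance Optional wide tibble/matrix of length-normalised
#'   reference gene abundances (samples x genes).
#' @param k Core genes per MGS.
#' @return Tibble (`mgs_id`, `gene_id`).
#' @export
core_gene_sets <- function(catalogue, gene_abundance = NULL, k = 100) {
  if (is.null(gene_abundance)) {
    return(catalogue$core_genes)
  }
  m <- abundance_matrix(gene_abundance)
  genes <- catalogue$genes |> filter(!is.na(.data$mgs_id))
  split(genes$gene_id, genes$mgs_id) |>
    purrr::imap_dfr(function(gids, mid) {
      gids <- intersect(gids, colnames(m))
      sub <- m[, gids, drop = FALSE]
      sel <- if (length(gids) <= k || all(sub == 0)) sort(gids)
             else select_core_genes(sub, k = k)
      tibble(mgs_id = mid, gene_id = sel)
    })
}

#' MGS counts from a gene counts table, with the core-gene detection rule
#'
#' The count of an MGS in a sample is the total mapped-pair count over its
#' core genes — but the MGS is considered *detected* only if pairs mapped to
#' at least `min_core_genes` distinct core genes; otherwise its count is set
#' to zero.
#'
#' @param gene_counts Long tibble (`sample_id`, `gene_id`, `n`) of mapped
#'   pair counts per gene.
#' @param core_sets Tibble (`mgs_id`, `gene_id`) of core genes per MGS.
#' @param min_core_genes Distinct core genes required for detection
#'   (default 3).
#' @return Wide tibble (samples x MGS) of integer counts, kind
#'   `"raw_counts"`.
#' @export
mgs_counts <- function(gene_counts, core_sets, min_core_genes = 3) {
  stopifnot(all(c("sample_id", "gene_id", "n") %in% names(gene_counts)))
  sizes <- count(core_sets, .data$mgs_id)
  if (any(sizes$n < min_core_genes)) {
    abort(sprintf("MGS with fewer than %d core genes defined: %s",
                  min_core_genes,
                  paste(sizes$mgs_id[sizes$n < min_core_genes], collapse = ", ")))
  }
  samples <- unique(gene_counts$sample_id)
  per <- gene_counts |>
    inner_join(core_sets, by = "gene_id") |>
    filter(.data$n > 0) |>
    group_by(.data$sample_id, .data$mgs_id) |>
    summarise(total = sum(.data$n), hit_genes = dplyr::n_distinct(.data$gene_id),
              .groups = "drop") |>
    mutate(total = ifelse(.data$hit_genes >= min_core_genes, .data$total, 0L))
  wide <- tidyr::expand_grid(sample_id = samples,
                             mgs_id = unique(core_sets$mgs_id)) |>
    left_join(select(per, "sample_id", "mgs_id", "total"),
              by = c("sample_id", "mgs_id")) |>
    mutate(total = as.integer(tidyr::replace_na(.data$total, 0L))) |>
    tidyr::pivot_wider(names_from = "mgs_id", values_from = "total")
  attr(wide, "kind") <- "raw_counts"
  wide
}

#' Normalise counts by effective feature length
#'
#' Divides each feature's count by its effective length
#' `max(L - read_length + 1, 1)` — the number of positions a read start can
#' occupy on the feature. For MGS-level tables `L` is the summed length of
#' the MGS's core genes.
#'
#' @param counts Wide counts tibble (samples x features).
#' @param lengths Named numeric vector of feature lengths (bp), covering
#'   every feature column.
#' @param read_length Mean read length in bp (default 150); `read_length = 1`
#'   reduces to plain length normalisation.
#' @return Wide tibble of length-normalised abundances, kind
#'   `"length_normalized"`.
#' @export
effective_length_normalize <- function(counts, lengths, read_length = 150) {
  m <- abundance_matrix(counts)
  if (!all(colnames(m) %in% names(lengths))) {
    abort("`lengths` must cover every feature column")
  }
  L <- lengths[colnames(m)]
  if (any(!is.finite(L)) || any(L <= 0)) abort("feature lengths must be > 0")
  eff <- pmax(L - read_length + 1, 1)
  out <- abundance_tibble(sweep(m, 2, eff, `/`), kind = "length_normalized")
  out
}

#' Core-gene length per MGS
#'
#' @param catalogue A `qmp_catalogue`.
#' @param core_sets Tibble (`mgs_id`, `gene_id`); defaults to the catalogue's
#'   designated core genes.
#' @return Named numeric vector of summed core-gene lengths per MGS.
#' @export
mgs_core_lengths <- function(catalogue, core_sets = NULL) {
  core_sets <- core_sets %||% catalogue$core_genes
  tab <- core_sets |>
    inner_join(select(catalogue$genes, "gene_id", "length"), by = "gene_id") |>
    group_by(.data$mgs_id) |>
    summarise(L = sum(.data$length), .groups = "drop")
  setNames(tab$L, tab$mgs_id)
}

#' Relative abundance (rows summing to 100%)
#'
#' @param x Wide abundance tibble (samples x features), non-negative.
#' @param percent Scale rows to 100 (default) or to 1.
#' @return Wide tibble, kind `"relative_percent"` (or `"relative_fraction"`);
#'   all-zero samples stay all-zero and are listed in the
#'   `"empty_samples"` attribute.
#' @export
relative_abundance <- function(x, percent = TRUE) {
  m <- abundance_matrix(x)
  if (any(m < 0)) abort("abundances must be non-negative")
  tot <- rowSums(m)
  empty <- rownames(m)[tot == 0]
  scale <- ifelse(tot > 0, (if (percent) 100 else 1) / tot, 0)
  out <- abundance_tibble(m * scale,
                          kind = if (percent) "relative_percent"
                                 else "relative_fraction")
  attr(out, "empty_samples") <- empty
  out
}

#' Rarefy a counts table by sampling without replacement
#'
#' Down-samples every sample to `target_depth` reads without replacement
#' (multivariate hypergeometric, via [vegan::rrarefy()]), then zeroes
#' entries that end up below `zero_below` counts — low-count observations
#' after down-sampling are treated as non-detections. Samples shallower than
#' the target are excluded and reported in the `"excluded_samples"`
#' attribute.
#'
#' @param counts Wide tibble of non-negative integer counts.
#' @param target_depth Reads to keep per sample (>= 1).
#' @param seed Integer seed; the same seed yields an identical table.
#' @param zero_below Entries below this count are set to 0 (default 3).
#' @return Wide tibble of rarefied integer counts, kind `"rarefied_counts"`.
#' @export
rarefy_counts <- function(counts, target_depth, seed = 1L, zero_below = 3) {
  if (target_depth <= 0) abort("`target_depth` must be >= 1")
  m <- abundance_matrix(counts)
  if (any(m < 0) || any(m != floor(m))) {
    abort("rarefaction needs non-negative integer counts")
  }
  depth <- rowSums(m)
  keep <- depth >= target_depth
  excluded <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  if (nrow(m) > 0) {
    r <- withr::with_seed(as.integer(seed),
                          suppressWarnings(vegan::rrarefy(m, target_depth)))
    r[r < zero_below] <- 0
  } else {
    r <- m
  }
  out <- abundance_tibble(r, kind = "rarefied_counts")
  attr(out, "excluded_samples") <- excluded
  attr(out, "target_depth") <- target_depth
  out
}

#' Quantitative microbial profile: scale composition by total cell counts
#'
#' Converts a relative microbial composition into absolute abundances
#' (cells per gram of faeces) by multiplying each sample's relative
#' fractions with its flow-cytometry total cell count, so per-sample QMP
#' totals equal the cell counts exactly. Samples without a (positive) cell
#' count are excluded and reported.
#'
#' @param relative Wide tibble of relative abundances — kind
#'   `"relative_percent"` (rows sum to 100) or `"relative_fraction"`
#'   (rows sum to 1); percent tables are detected via their kind attribute
#'   or row sums.
#' @param cell_counts Named numeric vector (cells/g) or metadata tibble with
#'   `sample_id` and `cell_count` columns.
#' @return Wide tibble, kind `"qmp_cells_per_gram"`, with excluded samples
#'   in the `"excluded_samples"` attribute.
#' @export
quantitative_profile <- function(relative, cell_counts) {
  m <- abundance_matrix(relative)
  if (is.data.frame(cell_counts)) {
    cell_counts <- setNames(cell_counts$cell_count, cell_counts$sample_id)
  }
  kind <- abund_kind(relative)
  frac <- if (identical(kind, "relative_fraction")) m else {
    rs <- rowSums(m)
    if (any(rs > 1.5)) m / 100 else m            # percent table
  }
  cc <- cell_counts[rownames(frac)]
  ok <- !is.na(cc) & cc > 0
  excluded <- rownames(frac)[!ok]
  qmp <- frac[ok, , drop = FALSE] * cc[ok]
  out <- abundance_tibble(qmp, kind = "qmp_cells_per_gram")
  attr(out, "excluded_samples") <- excluded
  out
}
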