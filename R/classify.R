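#' Read-classification thresholds
#'
#' The per-read mapping criteria applied to catalogue alignments: an aligned
#' block of at least `min_alignment` bases at `min_identity` percent identity
#' with mapping quality at least `min_mapq`; a read whose unaligned tail
#' exceeds `max_end_overhang` bases at either end is unmapped, unless
#' (`terminus_exempt`) the overhang extends past the gene's boundary —
#' catalogue genes are fragments, so a read running off a gene terminus is
#' not evidence of a bad alignment.
#'
#' @param min_alignment Minimum aligned bases (default 100).
#' @param min_identity Minimum percent identity (default 95).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param max_end_overhang Maximum unaligned bases tolerated at an end
#'   (default 10).
#' @param terminus_exempt Exempt overhangs at gene termini (default `TRUE`).
#' @return A `class_thresholds` list.
#' @export
classification_thresholds <- function(min_alignment = 100,
                                      min_identity = 95,
                                      min_mapq = 20,
                                      max_end_overhang = 10,
                                      terminus_exempt = TRUE) {
  vals <- c(min_alignment, min_identity, min_mapq, max_end_overhang)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all thresholds must be finite and >= 0")
  }
  structure(list(min_alignment = min_alignment, min_identity = min_identity,
                 min_mapq = min_mapq, max_end_overhang = max_end_overhang,
                 terminus_exempt = isTRUE(terminus_exempt)),
            class = "class_thresholds")
}

#' Construct alignment records
#'
#' Convenience row constructor for the alignment-record table consumed by
#' [classify_read()] and [build_gene_counts()].
#'
#' @param pair_id,mate Pair identifier and mate number (1 or 2).
#' @param gene_id Target catalogue gene, or `NA` for no alignment.
#' @param alignment_length Aligned bases.
#' @param identity Percent identity of the aligned block.
#' @param mapq Mapping quality.
#' @param left_overhang,right_overhang Unaligned bases beyond the aligned
#'   block at each read end.
#' @param at_terminus_left,at_terminus_right Does the overhang extend past
#'   the gene boundary at that end?
#' @param duplicate PCR/optical duplicate flag.
#' @param pos 1-based alignment start on the gene (used when writing SAM).
#' @return One-row tibble.
#' @export
alignment_record <- function(pair_id = "p1", mate = 1L, gene_id = NA_character_,
                             alignment_length = 0L, identity = 0, mapq = 0L,
                             left_overhang = 0L, right_overhang = 0L,
                             at_terminus_left = FALSE, at_terminus_right = FALSE,
                             duplicate = FALSE, pos = 1L) {
  tibble(pair_id = pair_id, mate = as.integer(mate), gene_id = gene_id,
         pos = as.integer(pos),
         alignment_length = as.integer(alignment_length),
         identity = as.numeric(identity), mapq = as.integer(mapq),
         left_overhang = as.integer(left_overhang),
         right_overhang = as.integer(right_overhang),
         at_terminus_left = at_terminus_left,
         at_terminus_right = at_terminus_right,
         duplicate = duplicate)
}

#' Classify individual reads against the gene catalogue
#'
#' Applies the per-read criteria: *mapped* iff the alignment is at least
#' `min_alignment` bases long, at `min_identity` percent identity, with
#' MAPQ at least `min_mapq`, and neither end's unaligned overhang exceeds
#' `max_end_overhang` bases (ends at a gene terminus are exempt by default);
#' *multimapped* iff length, identity and the overhang rule pass but MAPQ is
#' below the threshold; *unmapped* otherwise (including records with no
#' alignment at all).
#'
#' @param records Alignment-record tibble (see [alignment_record()]).
#' @param thresholds A [classification_thresholds()].
#' @return The input with an appended `read_status` column
#'   (`mapped`/`multimapped`/`unmapped`).
#' @export
#' @examples
#' classify_read(alignment_record(gene_id = "g1", alignment_length = 100,
#'                                identity = 95, mapq = 20))$read_status
classify_read <- function(records, thresholds = classification_thresholds()) {
  stopifnot(is.data.frame(records))
  num <- records[c("alignment_length", "identity", "mapq",
                   "left_overhang", "right_overhang")]
  aligned <- !is.na(records$gene_id)
  if (any(aligned & (num$alignment_length < 0 | num$identity < 0 |
                     num$mapq < 0 | num$left_overhang < 0 |
                     num$right_overhang < 0), na.rm = TRUE)) {
    abort("alignment record fields must be non-negative")
  }
  thr <- thresholds
  left_ok <- records$left_overhang <= thr$max_end_overhang |
    (thr$terminus_exempt & records$at_terminus_left)
  right_ok <- records$right_overhang <= thr$max_end_overhang |
    (thr$terminus_exempt & records$at_terminus_right)
  len_id_ok <- records$alignment_length >= thr$min_alignment &
    records$identity >= thr$min_identity
  passes <- aligned & len_id_ok & left_ok & right_ok
  status <- dplyr::case_when(
    passes & records$mapq >= thr$min_mapq ~ "mapped",
    passes ~ "multimapped",
    .default = "unmapped"
  )
  dplyr::mutate(records, read_status = status)
}

#' Classify read pairs from their mates' read statuses
#'
#' Pair rules: both mates unmapped gives an *unmapped* pair; both
#' multimapped, mapped to genes in different MGS units, or one multimapped
#' plus one unmapped gives a *multimapped* pair; every other combination is
#' *mapped* — credited to the mapped gene, or, when both mates map to
#' distinct genes of the same MGS, to mate 1's gene (a deterministic choice
#' that cannot affect MGS-level counts). Genes without MGS membership act as
#' singleton units: two different unbinned genes count as different units.
#'
#' @param pairs Tibble with one row per pair: `pair_id`, `status_1`,
#'   `gene_1`, `status_2`, `gene_2` (statuses from [classify_read()]).
#' @param catalogue A `qmp_catalogue` (for gene-to-MGS resolution).
#' @return Tibble `pair_id`, `pair_class`, `credited_gene`, `credited_mgs`.
#' @export
classify_pair <- function(pairs, catalogue) {
  stopifnot(is.data.frame(pairs))
  units <- gene_units(catalogue)
  mgs_of <- setNames(catalogue$genes$mgs_id, catalogue$genes$gene_id)
  s1 <- pairs$status_1; s2 <- pairs$status_2
  g1 <- as.character(pairs$gene_1); g2 <- as.character(pairs$gene_2)
  u1 <- unname(units[g1]); u2 <- unname(units[g2])
  both_mapped <- s1 == "mapped" & s2 == "mapped"
  cls <- dplyr::case_when(
    s1 == "unmapped" & s2 == "unmapped" ~ "unmapped",
    s1 == "multimapped" & s2 == "multimapped" ~ "multimapped",
    (s1 == "multimapped" & s2 == "unmapped") |
      (s1 == "unmapped" & s2 == "multimapped") ~ "multimapped",
    both_mapped & u1 != u2 ~ "multimapped",
    .default = "mapped"
  )
  credited <- dplyr::case_when(
    cls != "mapped" ~ NA_character_,
    s1 == "mapped" ~ g1,
    .default = g2
  )
  tibble(pair_id = pairs$pair_id, pair_class = cls,
         credited_gene = credited,
         credited_mgs = unname(mgs_of[credited]))
}

#' Build a per-sample gene counts table from alignment records
#'
#' Drops duplicate-flagged pairs, classifies the remaining reads and pairs,
#' and tallies mapped pairs per credited gene plus the multimapped and
#' unmapped pair totals. The three tallies always sum to the number of
#' retained (non-duplicate) pairs.
#'
#' @param records Alignment-record tibble (at most one record per mate; a
#'   pair may have a single record, its missing mate counts as unmapped).
#' @param catalogue A `qmp_catalogue`.
#' @param thresholds A [classification_thresholds()].
#' @return List of class `gene_counts`: `counts` (tibble `gene_id`, `n`),
#'   `tallies` (named vector mapped/multimapped/unmapped), `n_pairs`
#'   (retained pairs), `n_duplicates`, `pair_classes` (per-pair tibble).
#' @export
build_gene_counts <- function(records, catalogue,
                              thresholds = classification_thresholds()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0 &&
      (anyDuplicated(records$pair_id[records$mate == 1L]) > 0 ||
       anyDuplicated(records$pair_id[records$mate == 2L]) > 0)) {
    abort("more than one record per mate: stream must be primary alignments only")
  }
  dup_pairs <- unique(records$pair_id[records$duplicate])
  retained <- records[!records$pair_id %in% dup_pairs, , drop = FALSE]
  if (nrow(retained) == 0) {
    return(structure(list(
      counts = tibble(gene_id = character(), n = integer()),
      tallies = c(mapped = 0L, multimapped = 0L, unmapped = 0L),
      n_pairs = 0L, n_duplicates = length(dup_pairs),
      pair_classes = tibble(pair_id = character(), pair_class = character(),
                            credited_gene = character(),
                            credited_mgs = character())
    ), class = "gene_counts"))
  }
  classified <- classify_read(retained, thresholds)
  pid <- classified$pair_id
  upid <- unique(pid)
  slot <- match(pid, upid)
  np <- length(upid)
  # scatter each mate's record into its pair slot; a missing mate is unmapped
  g1 <- rep(NA_character_, np); g2 <- g1
  s1 <- rep("unmapped", np); s2 <- s1
  m1 <- classified$mate == 1L
  g1[slot[m1]] <- classified$gene_id[m1]
  s1[slot[m1]] <- classified$read_status[m1]
  g2[slot[!m1]] <- classified$gene_id[!m1]
  s2[slot[!m1]] <- classified$read_status[!m1]
  pairs <- tibble(pair_id = upid, status_1 = s1, gene_1 = g1,
                  status_2 = s2, gene_2 = g2)
  pc <- classify_pair(pairs, catalogue)
  tb <- table(pc$credited_gene[pc$pair_class == "mapped"])
  counts <- tibble(gene_id = names(tb), n = as.integer(tb))
  tallies <- c(
    mapped = sum(pc$pair_class == "mapped"),
    multimapped = sum(pc$pair_class == "multimapped"),
    unmapped = sum(pc$pair_class == "unmapped")
  )
  structure(list(counts = counts, tallies = tallies,
                 n_pairs = nrow(pc), n_duplicates = length(dup_pairs),
                 pair_classes = pc),
            class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("<gene_counts> ", x$n_pairs, " pairs: ",
      paste(names(x$tallies), x$tallies, sep = "=", collapse = ", "),
      " (+", x$n_duplicates, " duplicate)\n", sep = "")
  invisible(x)
}

#' @rdname tidy_qmpflow
#' @export
tidy.gene_counts <- function(x, ...) x$counts
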