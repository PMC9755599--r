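# Independent brute-force oracles, written as direct transcriptions of the
# classification and statistics rules; deliberately slow and naive so they
# share no code path with the implementation.

# -- per-read rule, one record at a time -------------------------------------
oracle_read_status <- function(rec, min_len = 100, min_id = 95, min_mapq = 20,
                               max_over = 10, terminus_exempt = TRUE) {
  if (is.na(rec$gene_id)) return("unmapped")
  left_bad <- rec$left_overhang > max_over &&
    !(terminus_exempt && rec$at_terminus_left)
  right_bad <- rec$right_overhang > max_over &&
    !(terminus_exempt && rec$at_terminus_right)
  if (left_bad || right_bad) return("unmapped")
  if (rec$alignment_length >= min_len && rec$identity >= min_id) {
    if (rec$mapq >= min_mapq) "mapped" else "multimapped"
  } else {
    "unmapped"
  }
}

# -- pair rule; units: MGS id or the gene itself when unbinned ---------------
oracle_pair_class <- function(s1, g1, s2, g2, gene2mgs) {
  unit <- function(g) {
    if (is.na(g)) return(NA_character_)
    m <- gene2mgs[[g]]
    if (is.null(m) || is.na(m)) paste0("un:", g) else m
  }
  if (s1 == "unmapped" && s2 == "unmapped") return("unmapped")
  if (s1 == "multimapped" && s2 == "multimapped") return("multimapped")
  if ((s1 == "multimapped" && s2 == "unmapped") ||
      (s1 == "unmapped" && s2 == "multimapped")) return("multimapped")
  if (s1 == "mapped" && s2 == "mapped" && unit(g1) != unit(g2)) {
    return("multimapped")
  }
  "mapped"
}

# -- textbook Benjamini-Hochberg step-up -------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# -- pairwise-count Cliff's delta --------------------------------------------
oracle_cliffs <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# -- tiny catalogue fixture ---------------------------------------------------
# two MGS (A: a1..a4, B: b1..b3) plus two unbinned genes
toy_catalogue <- function() {
  genes <- tibble::tibble(
    gene_id = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "u1", "u2"),
    length = c(1000L, 1200L, 800L, 1500L, 900L, 1100L, 1000L, 700L, 600L),
    mgs_id = c(rep("A", 4), rep("B", 3), NA, NA),
    ko = c("K00001", "K00001", "K00002", NA, "K00003", NA, "K00002",
           "K00004", NA)
  )
  structure(list(
    genes = genes,
    core_genes = dplyr::filter(genes, !is.na(mgs_id)) |>
      dplyr::select(mgs_id, gene_id)
  ), class = "qmp_catalogue")
}

# a clean mapped record with overridable fields
rec <- function(...) {
  do.call(alignment_record,
          utils::modifyList(list(gene_id = "a1", alignment_length = 150L,
                                 identity = 99, mapq = 60), list(...)))
}

small_sim_config <- function(seed = 42, ...) {
  do.call(sim_config, utils::modifyList(list(
    seed = seed, n_mgs = 8, genes_per_mgs = c(8L, 12L),
    core_genes_per_mgs = 6L, n_unbinned_genes = 10L,
    pairs_per_sample = 2000L, n_phages = 40L, n_polar = 30L, n_lipids = 15L,
    group_sizes = c(HC = 8L, severe = 8L), n_differential_mgs = 3L
  ), list(...)))
}
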