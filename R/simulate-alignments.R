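#' Simulate per-sample alignment records with planted classification truth
#'
#' Emulates the per-read output of aligning one sample's read pairs against
#' the gene catalogue. Pairs are assigned to genes with probability
#' proportional to true abundance times effective gene length; each pair is
#' then planted into one of the classification classes of the read-pair
#' rules (clean mapped, both-multimapped, cross-MGS, mate-unmapped variants,
#' duplicate, ...), with record fields (alignment length, identity, MAPQ,
#' end overhangs, duplicate flag) constructed so the classifier must recover
#' the planted class exactly.
#'
#' @param config A [sim_config()].
#' @param catalogue A [generate_catalogue()] result.
#' @param cohort A [generate_cohort()] result.
#' @param sample_id Sample to simulate (must exist in the cohort).
#' @return A list of class `qmp_alignments`:
#'   * `records`: tibble with one row per read (two per pair): `pair_id`,
#'     `mate`, `gene_id` (`NA` = no alignment), `pos`, `alignment_length`,
#'     `identity`, `mapq`, `left_overhang`, `right_overhang`,
#'     `at_terminus_left`, `at_terminus_right`, `duplicate`, and the
#'     generator's own annotation `planted_read_status`;
#'   * `pair_truth`: tibble (`pair_id`, `planted_class`) with the intended
#'     pair-level category (`mapped`/`multimapped`/`unmapped`/`duplicate`).
#' @export
generate_alignments <- function(config, catalogue, cohort, sample_id) {
  stopifnot(inherits(config, "sim_config"), inherits(catalogue, "qmp_catalogue"))
  md <- cohort$metadata
  if (!sample_id %in% md$sample_id) {
    abort(sprintf("sample `%s` not found in cohort", sample_id))
  }
  n_pairs <- config$pairs_per_sample
  genes <- catalogue$genes
  units <- gene_units(catalogue)
  if (n_pairs == 0) {
    return(structure(list(records = empty_alignment_records(),
                          pair_truth = tibble(pair_id = character(),
                                              planted_class = character())),
                     class = "qmp_alignments"))
  }
  ab_m <- abundance_matrix(cohort$truth$abundance)[sample_id, ]
  gene_ab <- numeric(nrow(genes))
  binned <- !is.na(genes$mgs_id)
  gene_ab[binned] <- ab_m[genes$mgs_id[binned]]
  if (!is.null(cohort$truth$unbinned)) {
    unb <- abundance_matrix(cohort$truth$unbinned)[sample_id, ]
    gene_ab[!binned] <- unb[genes$gene_id[!binned]]
  }
  eff_len <- pmax(genes$length - config$read_length + 1, 1)
  prob <- gene_ab * eff_len
  rl <- config$read_length

  withr::with_seed(derive_seed(config$seed, paste0("aln:", sample_id)), {
    gidx <- sample.int(nrow(genes), n_pairs, replace = TRUE, prob = prob)
    cls <- sample(
      c("duplicate", "multimap_pair", "cross_mgs", "mm_unmapped",
        "unmapped_pair", "overhang_read", "mapped_mixed", "mapped_same_mgs",
        "mapped_clean"),
      n_pairs, replace = TRUE,
      prob = c(config$frac_duplicate,
               config$frac_multimap * 0.6,
               config$frac_multimap * 0.25,
               config$frac_multimap * 0.15,
               config$frac_lowident + config$frac_short,
               config$frac_overhang,
               0.10, 0.05,
               max(1 - config$frac_duplicate - config$frac_multimap -
                     config$frac_lowident - config$frac_short -
                     config$frac_overhang - 0.15, 0)))
    # cross-MGS and same-MGS patterns need a binned gene with >1 member
    need_binned <- cls %in% c("cross_mgs", "mapped_same_mgs")
    gidx[need_binned & !binned[gidx]] <-
      sample(which(binned), sum(need_binned & !binned[gidx]), replace = TRUE)

    pair_ids <- sprintf("%s_p%06d", sample_id, seq_len(n_pairs))
    mk <- function(status, gene_idx) make_mate_records(status, gene_idx, genes,
                                                       rl, catalogue)
    # mate-level planted statuses per pattern
    st1 <- character(n_pairs); st2 <- character(n_pairs)
    g1 <- gidx; g2 <- gidx
    st1[cls %in% c("mapped_clean", "mapped_mixed", "mapped_same_mgs",
                   "overhang_read", "duplicate")] <- "mapped"
    st2[cls %in% c("mapped_clean", "duplicate")] <- "mapped"
    st1[cls == "multimap_pair"] <- "multimapped"
    st2[cls == "multimap_pair"] <- "multimapped"
    st1[cls == "cross_mgs"] <- "mapped"; st2[cls == "cross_mgs"] <- "mapped"
    st1[cls == "mm_unmapped"] <- "multimapped"
    st2[cls == "mm_unmapped"] <- "unmapped"
    st1[cls == "unmapped_pair"] <- "unmapped"
    st2[cls == "unmapped_pair"] <- "unmapped"
    mixed_other <- sample(c("unmapped", "multimapped"),
                          sum(cls == "mapped_mixed"), replace = TRUE)
    st2[cls == "mapped_mixed"] <- mixed_other
    st2[cls == "overhang_read"] <- "unmapped_overhang"
    members <- split(which(binned), genes$mgs_id[binned])
    # second mate of a cross-MGS pair maps to a gene in a different MGS
    ci <- which(cls == "cross_mgs")
    if (length(ci) > 0) {
      binned_idx <- which(binned)
      g2[ci] <- binned_idx[sample.int(length(binned_idx), length(ci),
                                      replace = TRUE)]
      clash <- ci[genes$mgs_id[g2[ci]] == genes$mgs_id[g1[ci]]]
      for (i in clash) {                      # rare; resolve individually
        pool <- binned_idx[genes$mgs_id[binned_idx] != genes$mgs_id[g1[i]]]
        if (length(pool) > 0) {
          g2[i] <- pool[sample.int(length(pool), 1)]
        } else {                              # degenerate single-MGS catalogue
          g2[i] <- g1[i]; st2[i] <- "unmapped"; cls[i] <- "mapped_mixed"
        }
      }
    }
    # second mate of a same-MGS pair hits a different gene of the same MGS
    si <- which(cls == "mapped_same_mgs")
    for (i in si) {
      sib <- setdiff(members[[genes$mgs_id[gidx[i]]]], gidx[i])
      if (length(sib) > 0) {
        g2[i] <- if (length(sib) == 1) sib else sib[sample.int(length(sib), 1)]
        st2[i] <- "mapped"
      } else {                                 # singleton MGS: degrade
        st2[i] <- "unmapped"; cls[i] <- "mapped_mixed"
      }
    }
    rec1 <- mk(st1, g1); rec2 <- mk(st2, g2)
    rec1$pair_id <- pair_ids; rec2$pair_id <- pair_ids
    rec1$mate <- 1L; rec2$mate <- 2L
    dup <- cls == "duplicate"
    rec1$duplicate <- dup; rec2$duplicate <- dup
    records <- bind_rows(rec1, rec2)

    planted <- unname(dplyr::case_when(
      cls == "duplicate" ~ "duplicate",
      cls %in% c("mapped_clean", "mapped_mixed", "mapped_same_mgs",
                 "overhang_read") ~ "mapped",
      cls %in% c("multimap_pair", "mm_unmapped") ~ "multimapped",
      cls == "unmapped_pair" ~ "unmapped",
      cls == "cross_mgs" ~ ifelse(units[genes$gene_id[g1]] ==
                                    units[genes$gene_id[g2]],
                                  "mapped", "multimapped")
    ))
    pair_truth <- tibble(pair_id = pair_ids, planted_class = planted,
                         pattern = cls)
  })
  structure(list(records = records, pair_truth = pair_truth),
            class = "qmp_alignments")
}

# build one tibble of mate records for a vector of planted statuses
make_mate_records <- function(status, gene_idx, genes, rl, catalogue) {
  n <- length(status)
  out <- tibble(
    pair_id = NA_character_, mate = NA_integer_,
    gene_id = genes$gene_id[gene_idx],
    pos = 1L, alignment_length = rl, identity = 0, mapq = 0L,
    left_overhang = 0L, right_overhang = 0L,
    at_terminus_left = FALSE, at_terminus_right = FALSE,
    duplicate = FALSE, planted_read_status = status
  )
  glen <- genes$length[gene_idx]
  u <- function(a, b) a + floor(runif(n) * (b - a + 1))
  mapped_like <- status %in% c("mapped", "multimapped")
  out$alignment_length <- ifelse(mapped_like, pmin(u(100, rl), glen), rl)
  out$identity[mapped_like] <- 95 + runif(sum(mapped_like)) * 5
  out$mapq <- ifelse(status == "mapped", u(20, 60), u(0, 19))
  # position placed fully inside the gene
  out$pos <- pmax(1L, as.integer(floor(runif(n) *
                    pmax(glen - out$alignment_length, 0))) + 1L)
  # a slice of clean mapped reads overhang a gene terminus (> 10 bp), which the
  # terminus exemption keeps mapped
  term <- status == "mapped" & runif(n) < 0.05
  out$left_overhang[term] <- 11L + u(0, 20)[term]
  out$at_terminus_left[term] <- TRUE
  out$pos[term] <- 1L
  # small in-gene overhangs (<= 10 bp) on some mapped reads: still mapped
  small <- status == "mapped" & !term & runif(n) < 0.10
  out$right_overhang[small] <- u(1, 10)[small]
  # unmapped variants
  unm <- which(status == "unmapped")
  if (length(unm) > 0) {
    kind <- sample(c("lowident", "short", "nohit"), length(unm), replace = TRUE)
    li <- unm[kind == "lowident"]
    out$identity[li] <- 70 + runif(length(li)) * 24.5   # < 95
    out$mapq[li] <- u(20, 60)[li]
    sh <- unm[kind == "short"]
    out$alignment_length[sh] <- u(30, 99)[sh]
    out$identity[sh] <- 95 + runif(length(sh)) * 5
    out$mapq[sh] <- u(20, 60)[sh]
    nh <- unm[kind == "nohit"]
    out$gene_id[nh] <- NA_character_
  }
  ov <- which(status == "unmapped_overhang")
  if (length(ov) > 0) {
    out$identity[ov] <- 95 + runif(length(ov)) * 5
    out$mapq[ov] <- u(20, 60)[ov]
    out$left_overhang[ov] <- 11L + u(0, 20)[ov]
    # away from the terminus: alignment start leaves room for the overhang
    out$pos[ov] <- pmax(out$left_overhang[ov] + 1L,
                        pmin(out$pos[ov], glen[ov] - out$alignment_length[ov] + 1L))
    out$at_terminus_left[ov] <- FALSE
    out$planted_read_status[ov] <- "unmapped"
  }
  out$identity[!mapped_like & is.na(out$gene_id)] <- 0
  out
}

empty_alignment_records <- function() {
  tibble(
    pair_id = character(), mate = integer(), gene_id = character(),
    pos = integer(), alignment_length = integer(), identity = double(),
    mapq = integer(), left_overhang = integer(), right_overhang = integer(),
    at_terminus_left = logical(), at_terminus_right = logical(),
    duplicate = logical(), planted_read_status = character()
  )
}

#' @export
print.qmp_alignments <- function(x, ...) {
  cat("<qmp_alignments> ", nrow(x$pair_truth), " pairs (",
      nrow(x$records), " records)\n", sep = "")
  invisible(x)
}
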