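test_that("core-gene selection keeps profile-tracking genes and drops outliers", {
  # an MGS with exactly k genes keeps them all
  m <- matrix(runif(20), nrow = 5, dimnames = list(NULL, paste0("g", 1:4)))
  expect_setequal(select_core_genes(m, k = 4), paste0("g", 1:4))
  expect_setequal(select_core_genes(m, k = 10), paste0("g", 1:4))

  # planted outlier: 149 genes proportional to a common profile + 1 inverted
  set.seed(10)
  profile <- exp(rnorm(12))
  good <- sapply(1:149, function(i) profile * runif(1, 0.5, 2) *
                   exp(rnorm(12, 0, 0.05)))
  bad <- rev(profile) * 1.5
  mm <- cbind(good, bad)
  colnames(mm) <- c(sprintf("g%03d", 1:149), "outlier")
  sel <- select_core_genes(mm, k = 100)
  expect_length(sel, 100)
  expect_false("outlier" %in% sel)

  # identical profiles: lexicographic tie-break, stable across calls
  ties <- matrix(rep(profile, 10), ncol = 10,
                 dimnames = list(NULL, sprintf("t%02d", 10:1)))
  s1 <- select_core_genes(ties, k = 4)
  expect_equal(s1, sort(sprintf("t%02d", 1:4)))
  expect_identical(s1, select_core_genes(ties, k = 4))

  expect_error(select_core_genes(matrix(0, 4, 6), k = 2), "all-zero")
  expect_error(select_core_genes(mm[1, , drop = FALSE], k = 2), "samples")
})

test_that("MGS counting enforces the three-core-gene detection rule", {
  core <- tibble::tibble(mgs_id = "A", gene_id = c("g1", "g2", "g3", "g4"))
  cnt <- function(...) {
    gc <- tibble::tibble(sample_id = "s1", !!!list(...)) |>
      tidyr::pivot_longer(-sample_id, names_to = "gene_id", values_to = "n")
    abundance_matrix(mgs_counts(gc, core))["s1", "A"]
  }
  # hits on only two core genes are zeroed however large
  expect_equal(cnt(g1 = 5L, g2 = 7L), 0)
  # three singleton hits are detected
  expect_equal(cnt(g1 = 1L, g2 = 1L, g3 = 1L), 3)
  # no reads at all
  expect_equal(cnt(g1 = 0L, g2 = 0L), 0)
  # counts sum over all core genes once detected
  expect_equal(cnt(g1 = 2L, g2 = 3L, g3 = 4L, g4 = 10L), 19)
  # a definition with fewer than three core genes is rejected up front
  expect_error(
    mgs_counts(tibble::tibble(sample_id = "s1", gene_id = "x", n = 1L),
               tibble::tibble(mgs_id = "B", gene_id = c("x", "y"))),
    "fewer than 3")
})

test_that("detection rule holds across random tables", {
  set.seed(4)
  core <- tibble::tibble(mgs_id = rep(c("A", "B", "C"), each = 5),
                         gene_id = sprintf("g%02d", 1:15))
  for (i in 1:30) {
    hit <- sample(15, sample(0:6, 1))
    if (length(hit) == 0) next
    gc <- tibble::tibble(sample_id = "s", gene_id = sprintf("g%02d", hit),
                         n = sample(1:20, length(hit), replace = TRUE))
    m <- abundance_matrix(mgs_counts(gc, core))
    for (mg in c("A", "B", "C")) {
      hits_in <- sum(core$gene_id[core$mgs_id == mg] %in% gc$gene_id)
      if (hits_in <= 2) expect_equal(unname(m["s", mg]), 0)
    }
  }
})

test_that("effective-length normalisation uses L - r + 1 with clamping", {
  counts <- tibble::tibble(sample_id = "s1", A = 10, B = 10)
  out <- effective_length_normalize(counts, c(A = 1000, B = 2000),
                                    read_length = 150)
  expect_equal(out$A, 10 / 851)
  expect_equal(out$B, 10 / 1851)
  # read length 1 reduces to plain length normalisation
  out1 <- effective_length_normalize(counts, c(A = 1000, B = 2000),
                                     read_length = 1)
  expect_equal(out1$A, 10 / 1000)
  # equal counts on L vs 2L favour the shorter ~2:1
  expect_gt(out1$A / out1$B, 1.99)
  # clamped at 1 when reads are longer than the feature
  outc <- effective_length_normalize(counts, c(A = 100, B = 2000),
                                     read_length = 150)
  expect_equal(outc$A, 10)
  expect_error(effective_length_normalize(counts, c(A = 0, B = 10), 50),
               "> 0")
  expect_error(effective_length_normalize(counts, c(A = 10), 50), "cover")
})

test_that("relative abundance rows sum to 100 and zero rows are flagged", {
  x <- tibble::tibble(sample_id = c("a", "b"), f1 = c(1, 0), f2 = c(3, 0))
  rel <- relative_abundance(x)
  expect_equal(unlist(rel[1, c("f1", "f2")], use.names = FALSE), c(25, 75))
  expect_equal(unlist(rel[2, c("f1", "f2")], use.names = FALSE), c(0, 0))
  expect_equal(attr(rel, "empty_samples"), "b")
  # property: 200 random rows all sum to 100
  set.seed(5)
  m <- matrix(rexp(200 * 10), nrow = 200,
              dimnames = list(sprintf("r%03d", 1:200), letters[1:10]))
  rs <- rowSums(abundance_matrix(relative_abundance(abundance_tibble(m))))
  expect_true(all(abs(rs - 100) < 1e-9))
  expect_error(relative_abundance(abundance_tibble(-m)), "non-negative")
})

test_that("rarefaction preserves depth, zeroes low counts, and is reproducible", {
  x <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                      a = c(50L, 98L, 10L), b = c(0L, 2L, 5L))
  r <- rarefy_counts(x, target_depth = 25, seed = 9, zero_below = 3)
  m <- abundance_matrix(r)
  # single-taxon sample: all 25 draws hit the only taxon
  expect_equal(unname(m["s1", ]), c(25, 0))
  # only 2 copies of b exist: it can never reach 3 and is always zeroed
  expect_equal(unname(m["s2", "b"]), 0)
  # without zeroing, every retained sample totals exactly the target depth
  expect_equal(unname(rowSums(abundance_matrix(
    rarefy_counts(x, 25, seed = 9, zero_below = 0)))), c(25, 25))
  # same seed, same table; different seed may differ
  expect_identical(rarefy_counts(x, 10, seed = 3),
                   rarefy_counts(x, 10, seed = 3))
  # shallow samples are excluded and reported
  r2 <- rarefy_counts(x, target_depth = 40, seed = 1)
  expect_equal(attr(r2, "excluded_samples"), "s3")
  expect_false("s3" %in% r2$sample_id)
  # rarefied count never exceeds the original
  orig <- abundance_matrix(x)[r2$sample_id, ]
  expect_true(all(abundance_matrix(r2) <= orig))
  # depth equal to the sample total leaves counts (minus zeroing) unchanged
  r3 <- rarefy_counts(x[3, ], target_depth = 15, seed = 2, zero_below = 3)
  expect_equal(unname(abundance_matrix(r3)["s3", ]), c(10, 5))
  expect_error(rarefy_counts(x, 0), ">= 1")
})

test_that("QMP scales composition to cell counts and conserves totals", {
  rel <- tibble::tibble(sample_id = "s1", A = 60, B = 40)
  attr(rel, "kind") <- "relative_percent"
  cc <- c(s1 = 1e11)
  q <- quantitative_profile(rel, cc)
  expect_equal(unname(unlist(q[1, c("A", "B")])), c(6e10, 4e10))
  expect_equal(sum(abundance_matrix(q)), 1e11)
  # missing or zero cell counts exclude the sample, reported
  rel2 <- tibble::tibble(sample_id = c("s1", "s2"), A = c(60, 10),
                         B = c(40, 90))
  q2 <- quantitative_profile(rel2, c(s1 = 1e11, s2 = 0))
  expect_equal(attr(q2, "excluded_samples"), "s2")
  expect_equal(nrow(q2), 1L)
  # metadata-tibble interface
  md <- tibble::tibble(sample_id = "s1", cell_count = 2e10)
  expect_equal(sum(abundance_matrix(quantitative_profile(rel, md))), 2e10)
})

test_that("doubling total load doubles QMP but leaves relative profiles unchanged", {
  cfg1 <- small_sim_config(seed = 61, n_mgs = 12, total_load_fold = 1,
                           n_differential_mgs = 0L, cellcount_cv = 0)
  cfg2 <- small_sim_config(seed = 61, n_mgs = 12, total_load_fold = 2,
                           n_differential_mgs = 0L, cellcount_cv = 0)
  catg <- generate_catalogue(cfg1)
  coh1 <- generate_cohort(cfg1, catg)
  coh2 <- generate_cohort(cfg2, catg)
  # same relative composition, different absolute scale in the T1D group
  rel1 <- relative_abundance(coh1$truth$abundance)
  rel2 <- relative_abundance(coh2$truth$abundance)
  sev <- coh1$metadata$group == "severe"
  q1 <- quantitative_profile(rel1, coh1$metadata)
  q2 <- quantitative_profile(rel2, coh2$metadata)
  m1 <- abundance_matrix(q1); m2 <- abundance_matrix(q2)
  # cohort-level mean rescaling makes the ratio fold/(mean fold) per group:
  # the severe:HC contrast must differ 2x between the two cohorts
  contrast <- function(m, sev) mean(rowSums(m[sev, ])) / mean(rowSums(m[!sev, ]))
  expect_equal(contrast(m2, sev) / contrast(m1, sev), 2, tolerance = 1e-6)
  expect_equal(abundance_matrix(rel1), abundance_matrix(rel2),
               tolerance = 1e-9)
})
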