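test_that("CLR rows sum to zero and the transform is scale-invariant", {
  x <- matrix(c(1, 1, 1, 1), nrow = 1, dimnames = list("s", letters[1:4]))
  expect_equal(unname(abundance_matrix(clr_transform(x))[1, ]), rep(0, 4))
  y <- matrix(c(1, 4), nrow = 1, dimnames = list("s", c("a", "b")))
  expect_equal(unname(abundance_matrix(clr_transform(y))[1, ]),
               c(log(1 / 2), log(4 / 2)), tolerance = 1e-6)
  set.seed(1)
  m <- matrix(rexp(60) + 0.1, nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  cm <- abundance_matrix(clr_transform(m))
  expect_true(all(abs(rowSums(cm)) < 1e-9))
  expect_equal(abundance_matrix(clr_transform(m * 17)), cm, tolerance = 1e-9)
  # zeros demand a positive pseudocount; integer tables default to +1
  mi <- matrix(c(0L, 3L, 2L, 5L), nrow = 1,
               dimnames = list("s", letters[1:4]))
  expect_equal(abundance_matrix(clr_transform(mi)),
               abundance_matrix(clr_transform(mi + 1L, pseudocount = 0)))
  expect_error(clr_transform(mi, pseudocount = 0), "pseudocount")
  expect_error(clr_transform(-y), "non-negative")
})

test_that("alpha diversity matches closed forms and vegan agrees", {
  expect_equal(alpha_diversity(rep(0.25, 4)), log(4))
  expect_equal(alpha_diversity(rep(0.25, 4), "simpson"), 0.75)
  expect_equal(alpha_diversity(c(1, 0, 0)), 0)
  expect_equal(alpha_diversity(c(1, 0, 0), "simpson"), 0)
  expect_equal(alpha_diversity(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_equal(alpha_diversity(c(0.2, 0.8, 0), "richness"), 2)
  # bounds: uniform maximises Shannon; Simpson stays within [0, 1 - 1/K]
  set.seed(3)
  for (i in 1:25) {
    p <- rexp(8); p <- p / sum(p)
    expect_lte(alpha_diversity(p), log(8) + 1e-12)
    expect_lte(alpha_diversity(p, "simpson"), 1 - 1 / 8 + 1e-12)
    expect_gte(alpha_diversity(p, "simpson"), 0)
    # independent implementation in vegan
    expect_equal(alpha_diversity(p), unname(vegan::diversity(p)),
                 tolerance = 1e-12)
    expect_equal(alpha_diversity(p, "simpson"),
                 unname(vegan::diversity(p, "simpson")), tolerance = 1e-12)
  }
  expect_error(alpha_diversity(c(-0.5, 1.5)), "non-negative")
  expect_error(alpha_diversity(c(0.2, 0.2)), "sum to 1")
})

test_that("Jensen-Shannon distance has its closed-form landmarks", {
  m <- rbind(p = c(1, 0), q = c(0.5, 0.5), r = c(0, 1), p2 = c(1, 0))
  colnames(m) <- c("a", "b")
  d <- as.matrix(jsd_distance(m))
  expect_equal(d["p", "p2"], 0)
  expect_equal(d["p", "r"], sqrt(log(2)), tolerance = 1e-12)  # disjoint support
  # p vs uniform: JSD = ln 2 - 0.75 ln 3 + 0.5 ln 4 ... evaluate directly
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  mid <- c(0.75, 0.25)
  jsd_exp <- 0.5 * kl(c(1, 0), mid) + 0.5 * kl(c(0.5, 0.5), mid)
  expect_equal(d["p", "q"], sqrt(jsd_exp), tolerance = 1e-12)
  expect_equal(round(d["p", "q"], 4), 0.4645)
  # symmetry and zero diagonal on random compositions
  set.seed(6)
  mm <- matrix(rexp(40), nrow = 5); mm <- mm / rowSums(mm)
  dd <- as.matrix(jsd_distance(mm))
  expect_equal(dd, t(dd))
  expect_true(all(diag(dd) == 0))
  expect_true(all(dd <= sqrt(log(2)) + 1e-12))
})

test_that("PCoA recovers planted configurations up to rotation", {
  set.seed(9)
  pts <- cbind(rnorm(12), rnorm(12))
  rownames(pts) <- paste0("s", 1:12)
  ord <- pcoa_ordination(stats::dist(pts))
  expect_s3_class(ord, "qmp_pcoa")
  # eigenvalues non-increasing, variance shares sum to 1
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_equal(sum(ord$variance_explained), 1)
  # round trip: recovered coordinates match the originals after Procrustes
  pro <- procrustes_correlation(pts,
                                abundance_matrix(ord$coordinates)[, 1:2],
                                n_perm = 0)
  expect_equal(pro$correlation, 1, tolerance = 1e-9)
  # duplicated samples land on identical coordinates
  pts2 <- rbind(pts, s13 = pts[1, ])
  ord2 <- pcoa_ordination(stats::dist(pts2))
  cm <- abundance_matrix(ord2$coordinates)
  expect_equal(unname(cm["s13", 1:2]), unname(cm["s1", 1:2]),
               tolerance = 1e-9)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA separates planted clusters and matches vegan's F", {
  set.seed(12)
  x <- rbind(matrix(rnorm(20, 0), ncol = 2), matrix(rnorm(20, 6), ncol = 2))
  rownames(x) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  d <- stats::dist(x)
  res <- permanova(d, g, n_perm = 999, seed = 4)
  # minimal attainable p with 999 permutations and maximal F
  expect_equal(res$p_value, 0.001)
  # F agrees with the independent vegan implementation
  va <- vegan::adonis2(d ~ g, permutations = 5)
  expect_equal(res$f_statistic, va$F[1], tolerance = 1e-9)
  # permuting the sample order together with labels leaves F unchanged
  perm <- sample(20)
  res2 <- permanova(as.matrix(d)[perm, perm], g[perm], n_perm = 9, seed = 1)
  expect_equal(res2$f_statistic, res$f_statistic, tolerance = 1e-12)
  expect_error(permanova(d, rep("a", 20), n_perm = 9), "2 groups")
  expect_error(permanova(d, c("b", rep("a", 19)), n_perm = 9), "2 samples")
  out <- tidy(res)
  expect_equal(out$p_value, 0.001)
})

test_that("Cliff's delta equals brute force and is antisymmetric", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffs_delta(c(1, 2), c(1, 2)), 0)
  expect_equal(cliffs_delta(c(1, 3), c(2, 4)), -0.5)
  set.seed(14)
  for (i in 1:200) {
    x <- sample(0:8, sample(2:10, 1), replace = TRUE)
    y <- sample(0:8, sample(2:10, 1), replace = TRUE)
    d <- cliffs_delta(x, y)
    expect_equal(d, oracle_cliffs(x, y), tolerance = 1e-12)
    expect_equal(cliffs_delta(y, x), -d, tolerance = 1e-12)
    expect_lte(abs(d), 1)
  }
  expect_error(cliffs_delta(numeric(), 1), "nonempty")
})

test_that("BH q-values equal an independent step-up transcription", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(15)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("covariate adjustment leaves zero residual correlation and is idempotent", {
  set.seed(16)
  egfr <- rnorm(30, 75, 20)
  f_conf <- 2 * egfr + rnorm(30)
  f_free <- rnorm(30)
  x <- abundance_tibble(cbind(conf = f_conf, free = f_free) |>
                          `rownames<-`(paste0("s", 1:30)))
  adj <- covariate_adjust(x, egfr)
  m <- abundance_matrix(adj)
  expect_lt(abs(cor(m[, "conf"], egfr)), 1e-9)
  # uncorrelated features barely move; grand means preserved
  expect_equal(mean(m[, "free"]), mean(f_free))
  expect_gt(cor(m[, "free"], f_free), 0.95)
  expect_equal(abundance_matrix(covariate_adjust(adj, egfr)), m,
               tolerance = 1e-9)
  expect_error(covariate_adjust(x, rep(1, 30)), "constant")
})

test_that("Kruskal-Wallis wrapper reduces to Wilcoxon at two groups and finds big shifts", {
  set.seed(17)
  v <- c(rnorm(20), rnorm(20, 5))
  g <- rep(c("a", "b"), each = 20)
  res <- kw_pairwise(v, g)
  expect_lt(res$omnibus_p, 1e-3)
  expect_equal(nrow(res$pairwise), 1)
  # k = 2: omnibus and the single pairwise test broadly agree
  expect_equal(log10(res$omnibus_p), log10(res$pairwise$p_value),
               tolerance = 0.35)
  # three groups give three pairwise comparisons
  v3 <- c(v, rnorm(10)); g3 <- c(g, rep("c", 10))
  res3 <- kw_pairwise(v3, g3)
  expect_equal(nrow(res3$pairwise), 3)
  expect_equal(nrow(tidy(res3)), 4)
  # null: p roughly uniform (coarse check on the median over replicates)
  ps <- replicate(60, kw_pairwise(rnorm(24), rep(c("a", "b", "c"), 8))$omnibus_p)
  expect_gt(median(ps), 0.2); expect_lt(median(ps), 0.8)
  expect_error(kw_pairwise(v, rep("a", 40)), "2 nonempty")
})

test_that("Procrustes correlation is similarity-invariant, symmetric, and matches vegan", {
  set.seed(18)
  x <- matrix(rnorm(40), ncol = 2)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  y <- 2 * x %*% rot + 5
  res <- procrustes_correlation(x, y, n_perm = 99, seed = 2)
  expect_equal(res$correlation, 1, tolerance = 1e-9)
  expect_equal(res$p_value, 0.01)
  # symmetric in its arguments
  z <- matrix(rnorm(40), ncol = 2)
  expect_equal(procrustes_correlation(x, z, n_perm = 0)$correlation,
               procrustes_correlation(z, x, n_perm = 0)$correlation,
               tolerance = 1e-9)
  # agrees with vegan's symmetric protest statistic
  vp <- vegan::protest(x, z, permutations = 19)
  expect_equal(procrustes_correlation(x, z, n_perm = 0)$correlation,
               vp$t0, tolerance = 1e-9)
  # independent configurations: typically non-significant
  expect_gt(procrustes_correlation(x, z, n_perm = 199, seed = 3)$p_value,
            0.05)
  expect_error(procrustes_correlation(x, matrix(1, 20, 2), n_perm = 0),
               "degenerate")
})

test_that("albuminuria grading reproduces the printed cutoffs and closes the gap", {
  cuts <- albuminuria_cutoffs()
  expect_equal(unname(cuts), c(3.39, 33.79, 33.90))
  expect_equal(classify_albuminuria(2.0), "normo")
  expect_equal(classify_albuminuria(3.39), "moderate")
  expect_equal(classify_albuminuria(33.90), "severe")
  expect_equal(classify_albuminuria(33.85), "moderate")   # printed gap
  expect_equal(classify_albuminuria(0), "normo")
  expect_error(classify_albuminuria(-1), ">= 0")
})

test_that("differential abundance recovers planted shifts and respects confounding", {
  set.seed(20)
  n <- 40
  md <- tibble::tibble(sample_id = paste0("s", 1:n),
                       group = rep(c("T1D", "HC"), each = n / 2),
                       egfr = rnorm(n, 75, 20),
                       age = rnorm(n, 60, 10))
  m <- matrix(rnorm(n * 50), nrow = n,
              dimnames = list(md$sample_id, paste0("f", 1:50)))
  m[md$group == "T1D", 1:5] <- m[md$group == "T1D", 1:5] + 2
  m[, 50] <- 3                                            # constant feature
  res <- differential_abundance(abundance_tibble(m), md, c("T1D", "HC"))
  expect_true(all(res$significant[1:5]))
  expect_true(all(res$cliffs_delta[1:5] > 0.5))
  expect_true(res$untestable[res$feature == "f50"])
  expect_true(is.na(res$q_value[res$feature == "f50"]))
  expect_lt(sum(res$significant[6:49]), 4)
  # a feature whose whole effect rides on a covariate is killed by adjustment
  md$age2 <- md$age + ifelse(md$group == "T1D", 8, 0)
  m2 <- m
  m2[, 10] <- 0.5 * md$age2 + rnorm(n, 0, 0.5)
  raw <- differential_abundance(abundance_tibble(m2), md, c("T1D", "HC"))
  adj <- differential_abundance(abundance_tibble(m2), md, c("T1D", "HC"),
                                covariates = "age2")
  expect_lt(raw$p_value[raw$feature == "f10"], 0.05)
  expect_gt(adj$p_value[adj$feature == "f10"], 0.05)
  expect_error(differential_abundance(abundance_tibble(m), md[1:2, ],
                                      c("T1D", "HC")), ">= 2 samples")
})

test_that("metabolite differential testing attains planted power and controls FDR", {
  # power: planted 1.0 log-unit shifts on 10 of 200 features, n = 20/group,
  # tested with the group-independent model covariates (eGFR pre-adjustment
  # is exercised by its own tests: in this cohort eGFR differs between
  # groups, so regressing it out deliberately attenuates group effects)
  cfg <- sim_config(seed = 71, n_mgs = 5, genes_per_mgs = c(5L, 8L),
                    core_genes_per_mgs = 3L, n_polar = 200L,
                    n_differential_metabolites = 10L, metabolite_effect = 1.0)
  coh <- generate_cohort(cfg, generate_catalogue(cfg))
  met <- generate_metabolome(cfg, coh$metadata)
  md <- dplyr::mutate(coh$metadata,
                      t1d_group = ifelse(group == "HC", "HC", "T1D"))
  res <- differential_abundance(met$polar, md, c("T1D", "HC"),
                                group_col = "t1d_group",
                                covariates = c("age", "sex", "bmi"))
  truth <- met$truth$differential_polar$feature
  expect_gte(mean(truth %in% res$feature[res$significant]), 0.8)
  # with no planted eGFR slope, adjustment leaves unconfounded features
  # unchanged up to the noise of estimating a near-zero coefficient
  # (planted features do correlate with eGFR through the group contrast)
  adj <- covariate_adjust(met$polar, coh$metadata$egfr)
  # chance sample correlations with eGFR reach ~0.33 over 190 features at
  # n = 80, so the adjusted feature retains cor >= sqrt(1 - 0.33^2) ~ 0.94
  plain <- setdiff(res$feature, truth)
  expect_gt(min(diag(cor(abundance_matrix(adj)[, plain],
                         abundance_matrix(met$polar)[, plain]))), 0.9)
  # null calibration: 200 replicates with no planted effect
  set.seed(72)
  fdps <- replicate(200, {
    m <- matrix(rnorm(nrow(md) * 100), nrow = nrow(md),
                dimnames = list(md$sample_id, sprintf("f%03d", 1:100)))
    r <- differential_abundance(abundance_tibble(m), md, c("T1D", "HC"),
                                group_col = "t1d_group")
    n_called <- sum(r$significant)
    if (n_called == 0) 0 else 1            # any call on a global null is false
  })
  expect_lte(mean(fdps), 0.15)             # BH family-wise false-call rate ~ 0.1
})
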