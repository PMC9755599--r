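#' Centred log-ratio transform
#'
#' Per sample (row): `ln((x + eps) / g(x + eps))` with `g` the geometric
#' mean, so every row sums to zero. CLR is scale-invariant — multiplying a
#' row by a positive constant leaves it unchanged — which removes the unit
#' sum constraint of compositional data before ordinary statistics are
#' applied.
#'
#' @param x Wide abundance tibble or matrix, non-negative.
#' @param pseudocount Added before the log. Default: 0 when the table has no
#'   zeros; 1 for integer count tables with zeros; half the minimum positive
#'   value for continuous tables with zeros.
#' @return Wide tibble, kind `"clr"`; rows sum to 0 (within 1e-9).
#' @export
#' @examples
#' clr_transform(matrix(c(1, 4), nrow = 1, dimnames = list("s1", c("a", "b"))))
clr_transform <- function(x, pseudocount = NULL) {
  m <- abundance_matrix(x)
  if (any(m < 0)) abort("CLR requires non-negative entries")
  if (is.null(pseudocount)) {
    pseudocount <- if (!any(m == 0)) 0
      else if (all(m == floor(m))) 1
      else min(m[m > 0]) / 2
  }
  if (any(m == 0) && pseudocount <= 0) {
    abort("a positive pseudocount is required when the table has zeros")
  }
  lm_ <- log(m + pseudocount)
  out <- abundance_tibble(lm_ - rowMeans(lm_), kind = "clr")
  out
}

#' Alpha diversity of a relative-abundance vector
#'
#' Shannon `H = -sum p ln p` (with `0 ln 0 = 0`), Simpson `1 - sum p^2`, or
#' richness `#\{p > 0\}`.
#'
#' @param p Non-negative numeric vector; must sum to 1 (within 1e-9) for
#'   Shannon/Simpson.
#' @param index One of `"shannon"`, `"simpson"`, `"richness"`.
#' @return A single number.
#' @export
#' @examples
#' alpha_diversity(rep(0.25, 4))               # ln 4
#' alpha_diversity(rep(0.25, 4), "simpson")    # 0.75
alpha_diversity <- function(p, index = c("shannon", "simpson", "richness")) {
  index <- match.arg(index)
  if (any(p < 0)) abort("abundances must be non-negative")
  if (index == "richness") return(sum(p > 0))
  if (abs(sum(p) - 1) > 1e-9) abort("`p` must sum to 1 for shannon/simpson")
  switch(index,
    shannon = { q <- p[p > 0]; -sum(q * log(q)) },
    simpson = 1 - sum(p^2)
  )
}

#' Alpha diversity for every sample of a table
#'
#' @param x Wide abundance tibble (any non-negative scale; rows are
#'   renormalised to fractions).
#' @param index Diversity index, see [alpha_diversity()].
#' @return Tibble (`sample_id`, `diversity`).
#' @export
alpha_diversity_table <- function(x, index = "shannon") {
  m <- abundance_matrix(x)
  frac <- m / pmax(rowSums(m), .Machine$double.xmin)
  tibble(sample_id = rownames(m),
         diversity = apply(frac, 1, alpha_diversity, index = index))
}

shannon_entropy <- function(p) { q <- p[p > 0]; -sum(q * log(q)) }

#' Jensen-Shannon distance matrix
#'
#' `d(i, j) = sqrt(JSD(p_i, p_j))` with the Jensen-Shannon divergence in
#' natural log (nats); the square root makes it a metric. The maximal value,
#' for distributions with disjoint support, is `sqrt(ln 2)`.
#'
#' @param x Wide tibble/matrix of relative abundances; rows are renormalised
#'   to sum to 1.
#' @return A [stats::dist] object.
#' @export
jsd_distance <- function(x) {
  m <- abundance_matrix(x)
  if (any(m < 0)) abort("abundances must be non-negative")
  m <- m / rowSums(m)
  n <- nrow(m)
  h <- apply(m, 1, shannon_entropy)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jsd <- shannon_entropy((m[i, ] + m[j, ]) / 2) - (h[i] + h[j]) / 2
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centres the squared distance matrix and eigendecomposes it
#' (via [stats::cmdscale]); axes with non-positive eigenvalues are dropped.
#'
#' @param d A [stats::dist] or symmetric zero-diagonal matrix.
#' @return List of class `qmp_pcoa`: `coordinates` (tibble `sample_id`,
#'   `PC1`, ...), `eigenvalues`, `variance_explained`.
#' @export
pcoa_ordination <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      abort("distance matrix must be symmetric with zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  pts <- fit$points   # cmdscale keeps only axes with positive eigenvalues
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  eig <- fit$eig[seq_len(ncol(pts))]
  structure(list(
    coordinates = bind_cols(tibble(sample_id = attr(d, "Labels") %||%
                                     as.character(seq_len(n))),
                            as_tibble(pts)),
    eigenvalues = eig,
    variance_explained = eig / sum(eig)
  ), class = "qmp_pcoa")
}

#' @export
print.qmp_pcoa <- function(x, ...) {
  cat("<qmp_pcoa> ", nrow(x$coordinates), " samples, ",
      length(x$eigenvalues), " positive axes; PC1 ",
      sprintf("%.1f%%", 100 * x$variance_explained[1]), "\n", sep = "")
  invisible(x)
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lv <- unique(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lv) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(lv)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Tests whether group centroids differ in a distance matrix via the
#' pseudo-F ratio of among- to within-group sums of squared distances;
#' significance by seeded random permutation of the group labels with the
#' add-one estimator `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param d Distance matrix ([stats::dist] or symmetric matrix).
#' @param groups Group labels, one per sample; at least 2 groups with >= 2
#'   samples each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List of class `qmp_permanova`: `f_statistic`, `p_value`,
#'   `n_perm`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm)) abort("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) abort("PERMANOVA needs >= 2 groups")
  if (any(tab < 2)) abort("every group needs >= 2 samples")
  d2 <- dm^2
  f_obs <- permanova_f(d2, groups)
  f_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm),
           function(i) permanova_f(d2, sample(groups)), numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(list(f_statistic = f_obs, p_value = p, n_perm = n_perm,
                 df = c(between = length(tab) - 1,
                        within = nrow(dm) - length(tab))),
            class = "qmp_permanova")
}

#' @export
print.qmp_permanova <- function(x, ...) {
  cat(sprintf("<qmp_permanova> pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$f_statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)`; ties contribute
#' zero. Ranges over \[-1, 1\]; positive values mean `x` tends to exceed `y`.
#'
#' @param x,y Nonempty numeric vectors.
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' cliffs_delta(c(1, 2, 3), c(4, 5, 6))   # -1: complete separation
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  # rank-based O((m+n) log(m+n)) formulation of the pairwise count
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  # sum of "x > y" minus "x < y" pairs via rank sums, ties cancelling
  rx <- sum(r[seq_len(nx)])
  gt_minus_lt <- 2 * rx - nx * (nx + ny + 1)
  gt_minus_lt / (nx * ny)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`); `NA` p-values get `NA` q-values and do
#' not enter the denominator.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Remove a covariate's linear effect from every feature
#'
#' Per feature column: residuals of the least-squares fit on the covariate,
#' with the feature's grand mean re-added, so the adjusted feature has zero
#' sample correlation with the covariate. Adjusting twice equals adjusting
#' once.
#'
#' @param features Wide tibble (samples x features).
#' @param covariate Numeric vector, one value per sample, non-constant.
#' @return Wide tibble of adjusted features.
#' @export
covariate_adjust <- function(features, covariate) {
  m <- abundance_matrix(features)
  if (length(covariate) != nrow(m)) abort("one covariate value per sample")
  if (var(covariate) == 0) abort("covariate is constant; nothing to adjust")
  x <- cbind(1, covariate)
  beta <- solve(crossprod(x), crossprod(x, m))
  resid <- m - x %*% beta
  adj <- sweep(resid, 2, colMeans(m), `+`)
  abundance_tibble(adj, kind = abund_kind(features))
}

#' Covariate-adjusted differential abundance with Cliff's delta and BH-FDR
#'
#' For every feature, fits a fixed-effects linear model of the (already
#' transformed: CLR for compositions, log for intensities) feature on the
#' two-group contrast plus covariates and tests the group term by a partial
#' F-test; computes Cliff's delta between the two groups on the transformed
#' values; and controls the FDR across the feature set by Benjamini-Hochberg,
#' calling features significant at `q < fdr`. Constant features are flagged
#' untestable (`NA` p) and excluded from the FDR denominator.
#'
#' @param features Wide tibble (samples x features), transformed scale.
#' @param metadata Tibble with `sample_id`, the grouping column and any
#'   covariate columns.
#' @param comparison Length-2 character: the two levels to compare, delta
#'   computed as first-level values vs second-level values.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param covariates Character vector of metadata columns to adjust for
#'   (default none).
#' @param fdr FDR threshold (default 0.10).
#' @return A tibble of class `qmp_diff`: `feature`, `p_value`, `q_value`,
#'   `cliffs_delta`, `mean_1`, `mean_2`, `significant`, `untestable`.
#' @export
differential_abundance <- function(features, metadata, comparison,
                                   group_col = "group", covariates = character(),
                                   fdr = 0.10) {
  stopifnot(length(comparison) == 2)
  m <- abundance_matrix(features)
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  g <- as.character(md[[group_col]])
  sel <- g %in% comparison
  if (min(table(g[sel])) < 2 || length(unique(g[sel])) < 2) {
    abort("each compared group needs >= 2 samples")
  }
  m <- m[sel, , drop = FALSE]
  md <- md[sel, , drop = FALSE]
  grp <- factor(as.character(md[[group_col]]), levels = comparison)
  x_red <- if (length(covariates) == 0) {
    matrix(1, nrow(m), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(md[, covariates,
                                                     drop = FALSE]))
  }
  x_full <- cbind(x_red, group = as.numeric(grp == comparison[1]))
  rss <- function(x) {
    q <- qr(x)
    resid <- qr.resid(q, m)
    list(rss = colSums(resid^2), df = nrow(m) - q$rank)
  }
  full <- rss(x_full); red <- rss(x_red)
  fstat <- (red$rss - full$rss) / ((red$df - full$df) *
                                     full$rss / full$df)
  p <- stats::pf(fstat, red$df - full$df, full$df, lower.tail = FALSE)
  untestable <- apply(m, 2, var) <= 0
  p[untestable] <- NA_real_
  q <- bh_fdr(p)
  in1 <- grp == comparison[1]
  delta <- vapply(seq_len(ncol(m)),
                  function(j) cliffs_delta(m[in1, j], m[!in1, j]), numeric(1))
  out <- tibble(
    feature = colnames(m),
    p_value = unname(p),
    q_value = unname(q),
    cliffs_delta = delta,
    mean_1 = colMeans(m[in1, , drop = FALSE]),
    mean_2 = colMeans(m[!in1, , drop = FALSE]),
    significant = !is.na(q) & q < fdr,
    untestable = unname(untestable)
  )
  names(out)[names(out) == "mean_1"] <- paste0("mean_", comparison[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", comparison[2])
  attr(out, "comparison") <- comparison
  attr(out, "fdr") <- fdr
  class(out) <- c("qmp_diff", class(out))
  out
}

#' Kruskal-Wallis omnibus test with pairwise Wilcoxon comparisons
#'
#' @param values Numeric vector of one feature's values.
#' @param groups Group labels (>= 2 nonempty groups).
#' @param p_adjust Adjustment for the pairwise p-values (default `"none"`,
#'   i.e. raw rank-sum p-values).
#' @return List of class `qmp_kw`: `omnibus_p`, `pairwise` (tibble
#'   `group_1`, `group_2`, `p_value`).
#' @export
kw_pairwise <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) == 0)) {
    abort("need >= 2 nonempty groups")
  }
  groups <- droplevels(groups)
  kw <- kruskal.test(values, groups)
  combos <- utils::combn(levels(groups), 2)
  pw <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    p <- suppressWarnings(
      wilcox.test(values[groups == a], values[groups == b], exact = FALSE)
    )$p.value
    tibble(group_1 = a, group_2 = b, p_value = p)
  })
  if (p_adjust != "none") pw$p_value <- p.adjust(pw$p_value, method = p_adjust)
  structure(list(omnibus_p = kw$p.value, pairwise = pw), class = "qmp_kw")
}

#' Procrustes concordance between two ordinations
#'
#' Centres both configurations, scales each to unit Frobenius norm, finds
#' the optimal rotation from the SVD of the cross-covariance, and reports
#' the symmetric Procrustes correlation `sqrt(1 - m2)` (the sum of singular
#' values under unit scaling). Significance by seeded permutation of the
#' sample order of `Y` with the add-one estimator.
#'
#' @param x,y Coordinate matrices or tibbles with `sample_id` (same samples,
#'   at least 2 columns each; the narrower one is zero-padded).
#' @param n_perm Permutations (default 999); 0 skips the test.
#' @param seed Integer seed.
#' @return List of class `qmp_procrustes`: `correlation`, `m2`, `p_value`,
#'   `n_perm`.
#' @export
procrustes_correlation <- function(x, y, n_perm = 999, seed = 1L) {
  as_coord <- function(z) {
    if (is.data.frame(z)) z <- abundance_matrix(z)
    z
  }
  xm <- as_coord(x); ym <- as_coord(y)
  if (nrow(xm) != nrow(ym)) abort("x and y must contain the same samples")
  k <- max(ncol(xm), ncol(ym))
  pad <- function(z) cbind(z, matrix(0, nrow(z), k - ncol(z)))
  xm <- pad(xm); ym <- pad(ym)
  norm_c <- function(z) {
    z <- sweep(z, 2, colMeans(z))
    nz <- sqrt(sum(z^2))
    if (nz < .Machine$double.eps) abort("degenerate (constant) configuration")
    z / nz
  }
  xs <- norm_c(xm)
  corr_of <- function(yz) sum(svd(crossprod(xs, norm_c(yz)))$d)
  r_obs <- corr_of(ym)
  p <- NA_real_
  if (n_perm > 0) {
    r_perm <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm),
             function(i) corr_of(ym[sample(nrow(ym)), , drop = FALSE]),
             numeric(1))
    })
    p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  }
  structure(list(correlation = r_obs, m2 = 1 - r_obs^2, p_value = p,
                 n_perm = n_perm),
            class = "qmp_procrustes")
}

#' @export
print.qmp_procrustes <- function(x, ...) {
  cat(sprintf("<qmp_procrustes> correlation = %.3f (m2 = %.3f), p = %.4g\n",
              x$correlation, x$m2, x$p_value))
  invisible(x)
}

#' Albuminuria cutoffs in mg/mmol
#'
#' The clinical strata are defined in mg albumin per g creatinine (normo
#' < 30, moderate 30-299, severe >= 300); dividing by creatinine's molar
#' mass (113 g/mol) converts to mg/mmol: 3.39, 33.79 and 33.90.
#'
#' @param creatinine_molar_mass Creatinine molar mass in g/mol (default 113).
#' @return Named vector `moderate_lower`, `moderate_upper`, `severe`
#'   (mg/mmol, rounded to 2 decimals).
#' @export
albuminuria_cutoffs <- function(creatinine_molar_mass = 113) {
  round(c(moderate_lower = 30, moderate_upper = 299, severe = 300) *
          creatinine_molar_mass / 1000, 2)
}

#' Classify albuminuria grade from UACR
#'
#' Normoalbuminuria below 3.39 mg/mmol, severely increased albuminuria at or
#' above 33.90 mg/mmol, moderately increased in between (the printed
#' moderate band ends at 33.79 while severe starts at 33.90; values in the
#' gap are graded moderate, matching the < 300 mg/g definition).
#'
#' @param uacr Urinary albumin/creatinine ratio(s) in mg/mmol, >= 0.
#' @return Character vector in `{"normo", "moderate", "severe"}`.
#' @export
#' @examples
#' classify_albuminuria(c(2, 3.39, 33.85, 33.90))
classify_albuminuria <- function(uacr) {
  if (any(is.na(uacr)) || any(uacr < 0)) abort("UACR must be >= 0")
  cut <- albuminuria_cutoffs()
  dplyr::case_when(
    uacr < cut[["moderate_lower"]] ~ "normo",
    uacr >= cut[["severe"]] ~ "severe",
    .default = "moderate"
  )
}
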