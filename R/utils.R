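#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols across all_of n distinct pull
#'   rename count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median rnorm runif rbinom setNames lm p.adjust var cor sd
#'   cmdscale kruskal.test wilcox.test pairwise.wilcox.test quantile rlnorm
#'   complete.cases
#' @importFrom utils head modifyList
NULL

# samples-by-features tables travel as wide tibbles whose first column is
# `sample_id`; these two helpers convert to/from a plain numeric matrix.

#' Convert a wide abundance tibble to a numeric matrix
#'
#' @param x A data frame whose first column is `sample_id` and whose remaining
#'   columns are numeric features, or an already-numeric matrix.
#' @return A numeric matrix with sample ids as row names.
#' @export
abundance_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!"sample_id" %in% names(x)) {
    abort("expected a `sample_id` column in a wide abundance table")
  }
  ids <- as.character(x$sample_id)
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a numeric matrix back to a wide abundance tibble
#'
#' @param m A numeric matrix with sample ids as row names.
#' @param kind Optional label describing the scale of the values (stored as an
#'   attribute, e.g. `"raw_counts"`, `"relative_percent"`, `"qmp_cells_per_gram"`,
#'   `"clr"`).
#' @return A tibble with a `sample_id` column followed by one column per feature.
#' @export
abundance_tibble <- function(m, kind = NULL) {
  out <- dplyr::bind_cols(
    tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m)))),
    as_tibble(m, .name_repair = "minimal")
  )
  if (!is.null(kind)) attr(out, "kind") <- kind
  out
}

abund_kind <- function(x) attr(x, "kind") %||% NA_character_

# deterministic sub-seed per stage so stages can be re-run in isolation;
# stays below 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483399 + 1)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x))) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(x)
}
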