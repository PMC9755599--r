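#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for qmpflow result objects
#'
#' `tidy()` returns one row per term/feature; `glance()` a one-row model
#' summary.
#'
#' @param x A qmpflow result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_qmpflow
NULL

#' @rdname tidy_qmpflow
#' @export
tidy.qmp_permanova <- function(x, ...) {
  tibble(term = "group", statistic = x$f_statistic, p_value = x$p_value,
         df = x$df[["between"]], df_residual = x$df[["within"]])
}

#' @rdname tidy_qmpflow
#' @export
glance.qmp_permanova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value, n_perm = x$n_perm)
}

#' @rdname tidy_qmpflow
#' @export
tidy.qmp_procrustes <- function(x, ...) {
  tibble(correlation = x$correlation, m2 = x$m2, p_value = x$p_value,
         n_perm = x$n_perm)
}

#' @rdname tidy_qmpflow
#' @export
glance.qmp_procrustes <- function(x, ...) tidy.qmp_procrustes(x, ...)

#' @rdname tidy_qmpflow
#' @export
tidy.qmp_kw <- function(x, ...) {
  bind_rows(tibble(group_1 = "omnibus", group_2 = NA_character_,
                   p_value = x$omnibus_p),
            x$pairwise)
}

#' @rdname tidy_qmpflow
#' @export
tidy.qmp_pcoa <- function(x, ...) {
  tibble(axis = paste0("PC", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         variance_explained = x$variance_explained)
}

#' @rdname tidy_qmpflow
#' @export
glance.qmp_run <- function(x, ...) {
  tibble(preset = x$manifest$preset, seed = x$manifest$seed,
         n_samples = nrow(x$tables$metadata),
         n_mgs = ncol(x$tables$qmp) - 1,
         rarefaction_depth = x$manifest$rarefaction_depth,
         !!!setNames(purrr::map_int(x$diff, ~ sum(.x$significant)),
                     paste0("significant_", names(x$diff))))
}
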