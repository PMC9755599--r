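#' Read gut-metabolic-module definitions from a flat file
#'
#' Parses the flat-file dialect used by curated GMM databases: a module
#' starts with a header line (`module_id<TAB>name`), followed by one line
#' per reaction step listing tab-separated alternative KOs; a comma inside
#' an alternative denotes an enzyme complex (its KOs are summed). Lines of
#' `///` (and blank lines) separate modules.
#'
#' @param path Path to the definition file, or a character vector of lines
#'   via `text`.
#' @param text Optional character scalar/vector of raw lines (instead of
#'   `path`).
#' @return A tibble (`module_id`, `name`, `step`, `ko`), one row per
#'   (step, KO); complex members share the step.
#' @export
read_gmm_definitions <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n", fixed = TRUE))
           else readr::read_lines(path)
  lines <- trimws(lines, which = "right")
  out <- list()
  module_id <- NULL; mod_name <- NA_character_; step <- 0L
  for (ln in lines) {
    if (ln == "" || startsWith(ln, "///") || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (!grepl("^K\\d{5}", fields[1])) {        # header line
      module_id <- fields[1]
      mod_name <- if (length(fields) > 1) fields[2] else NA_character_
      step <- 0L
      next
    }
    if (is.null(module_id)) abort("step line before any module header")
    step <- step + 1L
    kos <- unlist(strsplit(fields, ",", fixed = TRUE))
    out[[length(out) + 1]] <- tibble(module_id = module_id, name = mod_name,
                                     step = step, ko = trimws(kos))
  }
  defs <- bind_rows(out)
  if (nrow(defs) == 0) abort("no module definitions found")
  defs
}

#' Aggregate gene abundances to KO abundances
#'
#' KO abundance is the sum of the abundances of all genes annotated to that
#' KO; unannotated genes contribute nothing, so total annotated mass is
#' conserved.
#'
#' @param gene_abundance Wide tibble (samples x genes) of non-negative
#'   abundances (any scale; typically QMP-scaled).
#' @param annotations Tibble (`gene_id`, `ko`) mapping genes to KOs (possibly
#'   partial; `NA` KOs are dropped).
#' @return Wide tibble (samples x KOs).
#' @export
ko_abundance <- function(gene_abundance, annotations) {
  stopifnot(all(c("gene_id", "ko") %in% names(annotations)))
  m <- abundance_matrix(gene_abundance)
  ann <- annotations |> filter(!is.na(.data$ko),
                               .data$gene_id %in% colnames(m))
  if (nrow(ann) == 0) {
    return(abundance_tibble(matrix(numeric(0), nrow = nrow(m),
                                   dimnames = list(rownames(m), NULL))))
  }
  # genes x KOs indicator, then one matrix product
  kos <- sort(unique(ann$ko))
  ind <- matrix(0, nrow = ncol(m), ncol = length(kos),
                dimnames = list(colnames(m), kos))
  ind[cbind(match(ann$gene_id, colnames(m)), match(ann$ko, kos))] <- 1
  abundance_tibble(m %*% ind, kind = abund_kind(gene_abundance))
}

#' Gut-metabolic-module abundance from KO abundances
#'
#' For each module and sample: every reaction step's abundance is the sum
#' over its alternative KOs; module *coverage* is the fraction of steps with
#' positive abundance; the module abundance is the median of the step
#' abundances when coverage reaches `coverage_threshold` (inclusive), else 0.
#'
#' @param ko_table Wide tibble (samples x KOs).
#' @param definitions GMM definition tibble
#'   (see [read_gmm_definitions()] / [generate_gmm_definitions()]).
#' @param coverage_threshold Minimum step-coverage fraction (default 2/3).
#' @return Wide tibble (samples x modules) with a long
#'   `"coverage"` attribute tibble (`module_id`, `sample_id`, `coverage`).
#' @export
gmm_abundance <- function(ko_table, definitions, coverage_threshold = 2 / 3) {
  stopifnot(all(c("module_id", "step", "ko") %in% names(definitions)))
  if (nrow(definitions) == 0) abort("module set with zero steps")
  sizes <- definitions |> distinct(.data$module_id, .data$step) |>
    count(.data$module_id)
  if (any(sizes$n < 1)) abort("module with zero steps")
  m <- abundance_matrix(ko_table)
  mods <- sort(unique(definitions$module_id))
  res <- matrix(0, nrow = nrow(m), ncol = length(mods),
                dimnames = list(rownames(m), mods))
  cov_rows <- list()
  for (mod in mods) {
    d <- definitions[definitions$module_id == mod, ]
    steps <- split(d$ko, d$step)
    step_ab <- vapply(steps, function(kos) {
      kos <- intersect(kos, colnames(m))
      if (length(kos) == 0) rep(0, nrow(m))
      else rowSums(m[, kos, drop = FALSE])
    }, numeric(nrow(m)))
    if (is.null(dim(step_ab))) step_ab <- matrix(step_ab, nrow = nrow(m))
    coverage <- rowMeans(step_ab > 0)
    med <- apply(step_ab, 1, median)
    res[, mod] <- ifelse(coverage >= coverage_threshold, med, 0)
    cov_rows[[mod]] <- tibble(module_id = mod, sample_id = rownames(m),
                              coverage = coverage)
  }
  out <- abundance_tibble(res, kind = "gmm_abundance")
  attr(out, "coverage") <- bind_rows(cov_rows)
  out
}

#' CLR-transform a module abundance table
#'
#' Delegates to [clr_transform()] with a pseudocount of half the minimum
#' positive value (module abundances are continuous).
#'
#' @param module_table Wide tibble of module abundances.
#' @return CLR wide tibble (rows sum to 0).
#' @export
clr_modules <- function(module_table) {
  clr_transform(module_table)
}
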