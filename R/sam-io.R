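#' Write alignment records as a minimal SAM file
#'
#' Emits one `@SQ` header per catalogue gene and one alignment line per
#' record: end overhangs become soft clips in the CIGAR, percent identity is
#' encoded in the `NM` tag (`identity = 1 - NM / alignment_length`, rounded
#' to the nearest integer edit distance), and the duplicate flag maps to SAM
#' FLAG bit 0x400. Records without an alignment are written as unmapped.
#'
#' @param records Alignment-record tibble (with a `pos` column; defaults
#'   to 1).
#' @param catalogue A `qmp_catalogue`.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(records, catalogue, path) {
  genes <- catalogue$genes
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", genes$gene_id, genes$length))
  pos <- records$pos %||% rep(1L, nrow(records))
  aligned <- !is.na(records$gene_id)
  flag <- 1L +                                         # paired
    ifelse(records$mate == 1L, 64L, 128L) +
    ifelse(aligned, 0L, 4L) +
    ifelse(records$duplicate, 1024L, 0L)
  nm <- ifelse(aligned,
               round((1 - records$identity / 100) * records$alignment_length),
               0)
  cigar <- ifelse(aligned,
                  paste0(ifelse(records$left_overhang > 0,
                                paste0(records$left_overhang, "S"), ""),
                         records$alignment_length, "M",
                         ifelse(records$right_overhang > 0,
                                paste0(records$right_overhang, "S"), "")),
                  "*")
  read_len <- ifelse(aligned,
                     records$alignment_length + records$left_overhang +
                       records$right_overhang, 100L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  records$pair_id, flag,
                  ifelse(aligned, records$gene_id, "*"),
                  ifelse(aligned, pos, 0L),
                  ifelse(aligned, records$mapq, 0L),
                  cigar,
                  strrep("N", read_len),
                  as.integer(nm))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read alignment records from a SAM/BAM file
#'
#' Inverse of [write_alignments_sam()]: identity is recovered from the `NM`
#' tag, end overhangs from soft/hard clips in the CIGAR, the duplicate flag
#' from FLAG bit 0x400, and the terminus flags from the alignment position
#' against the gene length (an overhang is "at a terminus" when the clipped
#' read extends past the gene boundary). Only primary alignments are kept.
#' Requires the `Rsamtools` package.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param catalogue A `qmp_catalogue` (for gene lengths).
#' @return Alignment-record tibble as consumed by [build_gene_counts()].
#' @export
read_alignments_sam <- function(path, catalogue) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading SAM/BAM requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = prm)[[1]]
  n <- length(b$qname)
  clip <- function(cigar, side) {
    re <- if (side == "left") "^(\\d+)[SH]" else "(\\d+)[SH]$"
    out <- rep(0L, length(cigar))
    hit <- !is.na(cigar) & grepl(re, cigar)
    out[hit] <- as.integer(stringr::str_match(cigar[hit], re)[, 2])
    out
  }
  mlen <- function(cigar) {
    out <- rep(0L, length(cigar))
    ok <- !is.na(cigar)
    out[ok] <- vapply(stringr::str_match_all(cigar[ok], "(\\d+)([MIDN=X])"),
                      function(m) {
                        consumes <- m[, 3] %in% c("M", "D", "N", "=", "X")
                        sum(as.integer(m[consumes, 2]))
                      }, integer(1))
    out
  }
  unmapped <- bitwAnd(b$flag, 4L) > 0
  gene <- as.character(b$rname)
  gene[unmapped] <- NA_character_
  glen <- setNames(catalogue$genes$length, catalogue$genes$gene_id)
  ref_span <- mlen(b$cigar)
  lo <- clip(b$cigar, "left")
  ro <- clip(b$cigar, "right")
  nm <- b$tag$NM %||% rep(0L, n)
  nm[is.na(nm)] <- 0L
  alen <- ref_span          # matches the writer: M length = alignment length
  tibble(
    pair_id = b$qname,
    mate = ifelse(bitwAnd(b$flag, 64L) > 0, 1L, 2L),
    gene_id = gene,
    pos = ifelse(unmapped, 1L, b$pos),
    alignment_length = ifelse(unmapped, 0L, alen),
    identity = ifelse(unmapped | alen == 0, 0, (1 - nm / alen) * 100),
    mapq = ifelse(unmapped, 0L, b$mapq),
    left_overhang = lo,
    right_overhang = ro,
    at_terminus_left = !unmapped & (b$pos - lo) < 1,
    at_terminus_right = !unmapped &
      (b$pos + alen - 1 + ro) > unname(glen[gene]),
    duplicate = bitwAnd(b$flag, 1024L) > 0
  )
}

#' Write/read the 13-column TSV alignment dialect
#'
#' A plain-text equivalent of the SAM representation with one column per
#' alignment-record field, for workflows without SAM tooling.
#'
#' @param records Alignment-record tibble.
#' @param path File path.
#' @return `path` (write) or the records tibble (read).
#' @export
write_alignments_tsv <- function(records, path) {
  cols <- c("pair_id", "mate", "gene_id", "pos", "alignment_length",
            "identity", "mapq", "left_overhang", "right_overhang",
            "at_terminus_left", "at_terminus_right", "duplicate")
  pos <- records$pos %||% rep(1L, nrow(records))
  records$pos <- pos
  readr::write_tsv(records[intersect(cols, names(records))], path)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pair_id = "c", mate = "i", gene_id = "c", pos = "i",
                    alignment_length = "i", identity = "d", mapq = "i",
                    left_overhang = "i", right_overhang = "i",
                    at_terminus_left = "l", at_terminus_right = "l",
                    duplicate = "l"))
}
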