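# SAM -> BED decompilation: CIGAR reference-span arithmetic, flag-driven
# strand assignment, and deterministic coordinate sorting.

CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")
CIGAR_ALL_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar))
    stop("empty CIGAR string", call. = FALSE)
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))[[1]]
  if (paste(toks, collapse = "") != cigar)
    stop("malformed CIGAR string: '", cigar, "'", call. = FALSE)
  op <- substring(toks, nchar(toks))
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  bad <- which(!op %in% CIGAR_ALL_OPS)
  if (length(bad))
    stop("unknown CIGAR opcode '", op[bad[1]], "' in '", cigar, "'",
         call. = FALSE)
  if (any(len <= 0L))
    stop("non-positive CIGAR length in '", cigar, "'", call. = FALSE)
  list(op = op, len = len)
}

#' Reference span of a CIGAR string
#'
#' Sums the lengths of reference-consuming operations (`M`, `D`, `N`, `=`,
#' `X`); `I`, `S`, `H` and `P` contribute nothing.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference spans in bases.
#' @export
cigar_reference_span <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% CIGAR_REF_OPS])
  }, integer(1), USE.NAMES = FALSE)
}

#' Decompile mapped SAM records into BED6 intervals
#'
#' Each record becomes a 0-based half-open interval: `start = pos - 1`,
#' `end = start + cigar_reference_span(cigar)`; strand is `-` when flag bit
#' 0x10 is set; name is the read id and score the mapping quality.
#' Secondary (0x100) and supplementary (0x800) alignments are excluded
#' unless `keep_secondary = TRUE`.  Records with zero reference span
#' (fully clipped) are skipped with a warning; the number skipped is
#' attached as attribute `"skipped"`.
#'
#' @param sam A data.frame of mapped SAM records as returned by [read_sam].
#' @param keep_secondary Keep secondary/supplementary alignments?
#' @return A data.frame of mapped-read intervals (BED6 semantics).
#' @export
sam_to_bed <- function(sam, keep_secondary = FALSE) {
  if (!keep_secondary)
    sam <- sam[bitwAnd(sam$flag, 0x100L) == 0L &
                 bitwAnd(sam$flag, 0x800L) == 0L, , drop = FALSE]
  span <- cigar_reference_span(sam$cigar)
  zero <- span == 0L
  if (any(zero))
    warning(sum(zero), " alignment(s) with zero reference span skipped",
            call. = FALSE)
  sam <- sam[!zero, , drop = FALSE]
  span <- span[!zero]
  out <- new_intervals(chrom = sam$chrom,
                       start = sam$pos - 1L,
                       end = sam$pos - 1L + span,
                       name = sam$read_id,
                       score = sam$mapq,
                       strand = ifelse(bitwAnd(sam$flag, 0x10L) != 0L,
                                       "-", "+"))
  attr(out, "skipped") <- sum(zero)
  out
}

#' Sort intervals by genomic coordinate
#'
#' Stable sort by (chrom, start, end, name) in the C locale, so repeated
#' runs and permuted inputs give identical output files.
#'
#' @param intervals A data.frame of intervals.
#' @return The same records in sorted order.
#' @export
sort_intervals <- function(intervals) {
  o <- order(intervals$chrom, intervals$start, intervals$end,
             intervals$name, method = "radix")
  out <- intervals[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
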