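# Flush an information-rich NCBI GFF3 down to a minimal CDS-only
# annotation keyed by locus_tag.

#' Extract CDS features from a GFF3 annotation
#'
#' Keeps only lines whose feature type (column 3) is `CDS` and retrieves
#' the `locus_tag` attribute as the feature identifier.  GFF's 1-based
#' closed coordinates are converted to the internal 0-based half-open
#' convention.  CDS lines without a `locus_tag` are skipped with a warning;
#' duplicated locus_tags (e.g. joined CDS segments) keep their first
#' occurrence.  The counts of both are attached as attributes
#' `"skipped_no_locus_tag"` and `"skipped_duplicate"`.
#'
#' @param path Path to a GFF3/GFF file.
#' @return A data.frame of CDS features with columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `locus_tag`, in input order.
#' @export
extract_cds <- function(path) {
  gff <- read_gff(path)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  n_cds_lines <- nrow(cds)
  tags <- vapply(cds$attributes, function(a) {
    at <- parse_gff_attributes(a)
    if ("locus_tag" %in% names(at) && nzchar(at[["locus_tag"]]))
      at[["locus_tag"]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  missing <- is.na(tags)
  if (any(missing))
    warning(sum(missing), " CDS line(s) without a locus_tag attribute ",
            "skipped", call. = FALSE)
  cds <- cds[!missing, , drop = FALSE]
  tags <- tags[!missing]
  dup <- duplicated(tags)
  if (any(dup))
    warning(sum(dup), " CDS line(s) with a duplicated locus_tag skipped ",
            "(first occurrence kept): ",
            paste(unique(tags[dup]), collapse = ", "), call. = FALSE)
  cds <- cds[!dup, , drop = FALSE]
  tags <- tags[!dup]
  out <- new_cds(chrom = cds$chrom, start = cds$start - 1L, end = cds$end,
                 strand = cds$strand, locus_tag = tags)
  if (any(out$start >= out$end))
    stop("GFF '", path, "': CDS with end <= start", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_no_locus_tag") <- sum(missing)
  attr(out, "skipped_duplicate") <- sum(dup)
  attr(out, "n_cds_lines") <- n_cds_lines
  out
}
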