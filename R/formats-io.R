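# Readers/writers for FASTQ(.gz), text SAM, BED6 and GFF.  Internal
# coordinates are uniformly 0-based half-open; the GFF reader/writer is the
# only place the 1-based closed convention appears.

#' Detect gzip compression by magic bytes
#'
#' File extensions lie; the two-byte gzip signature (0x1f 0x8b) does not.
#' @param path Path to a file.
#' @return `TRUE` if the file starts with the gzip magic bytes.
#' @keywords internal
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

open_text_input <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
}

#' Construct a set of sequenced reads
#'
#' A `fastq_reads` object holds parallel vectors: read identifiers, base
#' strings over `{A,C,G,T,N}`, and a list of integer Phred quality vectors,
#' one value per base.
#'
#' @param read_id Character vector of read identifiers.
#' @param bases Character vector of base strings.
#' @param quals List of integer vectors of Phred scores (one per base, each
#'   in `[0, 93]`).
#' @return An object of class `fastq_reads`.
#' @export
fastq_reads <- function(read_id, bases, quals) {
  read_id <- as.character(read_id)
  bases <- as.character(bases)
  if (length(read_id) != length(bases) || length(bases) != length(quals))
    stop("read_id, bases and quals must have equal length", call. = FALSE)
  nb <- nchar(bases)
  nq <- lengths(quals)
  bad <- which(nb != nq)
  if (length(bad))
    stop("record ", bad[1], ": ", nb[bad[1]], " bases but ", nq[bad[1]],
         " quality values", call. = FALSE)
  rng <- range(c(0L, unlist(quals, use.names = FALSE)))
  if (rng[1] < 0L || rng[2] > 93L)
    stop("Phred scores must lie in [0, 93]", call. = FALSE)
  structure(list(read_id = read_id, bases = bases,
                 quals = lapply(quals, as.integer)),
            class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$read_id)

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads:", length(x), "read(s)\n")
  if (length(x))
    cat("  first:", x$read_id[1], substr(x$bases[1], 1, 40), "\n")
  invisible(x)
}

#' Subset reads
#' @param x A `fastq_reads` object.
#' @param i Index vector.
#' @param ... Unused.
#' @return A `fastq_reads` object.
#' @export
`[.fastq_reads` <- function(x, i, ...) {
  fastq_reads(x$read_id[i], x$bases[i], x$quals[i])
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records, optionally gzip-compressed (detected by
#' magic bytes, not extension).  Quality characters are decoded as
#' `ASCII - encoding_offset` (Phred+33 or Phred+64).
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param encoding_offset Phred encoding offset, 33 (default) or 64.
#' @return A [fastq_reads] object, record order preserved.
#' @export
read_fastq <- function(path, encoding_offset = 33L) {
  encoding_offset <- match.arg(as.character(encoding_offset), c("33", "64"))
  encoding_offset <- as.integer(encoding_offset)
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(fastq_reads(character(), character(), list()))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  bases <- lines[seq(2L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr))
    stop("malformed FASTQ '", path, "': record ", bad_hdr[1],
         " does not start with '@'", call. = FALSE)
  bad_len <- which(nchar(bases) != nchar(qstr))
  if (length(bad_len))
    stop("malformed FASTQ '", path, "': record ", bad_len[1],
         " has ", nchar(bases)[bad_len[1]], " bases but ",
         nchar(qstr)[bad_len[1]], " quality characters", call. = FALSE)
  ids <- sub("^@", "", sub("[ \t].*$", "", hdr))
  quals <- lapply(seq_len(n), function(i) {
    q <- utf8ToInt(qstr[i]) - encoding_offset
    if (length(q) && min(q) < 0L)
      stop("encoding error in '", path, "': record ", i,
           " has a quality character below the Phred+", encoding_offset,
           " offset", call. = FALSE)
    as.integer(q)
  })
  fastq_reads(ids, bases, quals)
}

#' Write a FASTQ file
#'
#' @param reads A [fastq_reads] object.
#' @param path Output path; written gzip-compressed if it ends in `.gz`.
#' @param encoding_offset Phred encoding offset, 33 (default) or 64.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, encoding_offset = 33L) {
  stopifnot(inherits(reads, "fastq_reads"))
  encoding_offset <- as.integer(encoding_offset)
  n <- length(reads)
  qstr <- vapply(reads$quals, function(q) {
    if (length(q) == 0L) "" else intToUtf8(q + encoding_offset)
  }, character(1))
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
    lines[seq(2L, by = 4L, length.out = n)] <- reads$bases
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- qstr
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read mapped records from a text SAM file
#'
#' Header lines (starting with `@`) are skipped; mandatory fields 1-6
#' (QNAME, FLAG, RNAME, POS, MAPQ, CIGAR) are extracted; records with the
#' unmapped flag bit (0x4) are excluded.
#'
#' @param path Path to a SAM text file (optionally gzip-compressed).
#' @return A data.frame with columns `read_id`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `mapq`, `cigar` — mapped records only, in file
#'   order.
#' @export
read_sam <- function(path) {
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad))
    stop("malformed SAM '", path, "': line ", body[bad[1]], " has ",
         nf[bad[1]], " fields (11 required)", call. = FALSE)
  get <- function(k) vapply(fields, `[[`, character(1), k)
  out <- data.frame(read_id = get(1L),
                    flag = as.integer(get(2L)),
                    chrom = get(3L),
                    pos = as.integer(get(4L)),
                    mapq = as.integer(get(5L)),
                    cigar = get(6L),
                    stringsAsFactors = FALSE)
  out[bitwAnd(out$flag, 4L) == 0L, , drop = FALSE]
}

new_intervals <- function(chrom, start, end, name, score, strand) {
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), name = as.character(name),
             score = as.numeric(score), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

validate_intervals <- function(x, where = "intervals") {
  bad <- which(!(x$start >= 0L & x$end > x$start))
  if (length(bad))
    stop(where, ": record ", bad[1], " violates 0 <= start < end", call. = FALSE)
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad))
    stop(where, ": record ", bad[1], " has strand '", x$strand[bad[1]],
         "' (must be + or -)", call. = FALSE)
  x
}

#' Read a BED6 file of mapped-read intervals
#'
#' BED coordinates are 0-based half-open, which is also the internal
#' convention, so no conversion is performed.
#'
#' @param path Path to a 6-column tab-separated BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(new_intervals(character(), integer(), integer(), character(),
                         numeric(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad))
    stop("malformed BED '", path, "': line ", bad[1], " has ", nf[bad[1]],
         " columns (6 required)", call. = FALSE)
  get <- function(k) vapply(fields, `[[`, character(1), k)
  out <- new_intervals(get(1L), as.integer(get(2L)), as.integer(get(3L)),
                       get(4L), as.numeric(get(5L)), get(6L))
  validate_intervals(out, where = paste0("BED '", path, "'"))
}

#' Write mapped-read intervals as BED6
#'
#' @param intervals A data.frame as returned by [read_bed] or [sam_to_bed].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   intervals$chrom, intervals$start, intervals$end,
                   intervals$name,
                   format(intervals$score, trim = TRUE, scientific = FALSE),
                   intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a 9-column GFF/GFF3 file
#'
#' Returns raw columns with GFF's native 1-based closed coordinates;
#' use [extract_cds] to obtain internally-convened CDS features.
#'
#' @param path Path to a GFF/GFF3 file (optionally gzip-compressed).
#' @return A data.frame with columns `chrom`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase`, `attributes` (coordinates 1-based
#'   closed, exactly as in the file).
#' @export
read_gff <- function(path) {
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  empty <- data.frame(chrom = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(), attributes = character(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 9L)
  if (length(bad))
    stop("malformed GFF '", path, "': line ", keep[bad[1]], " has ",
         nf[bad[1]], " columns (9 required)", call. = FALSE)
  get <- function(k) vapply(fields, `[[`, character(1), k)
  data.frame(chrom = get(1L), source = get(2L), type = get(3L),
             start = as.integer(get(4L)), end = as.integer(get(5L)),
             score = get(6L), strand = get(7L), phase = get(8L),
             attributes = get(9L), stringsAsFactors = FALSE)
}

#' Parse a GFF3 attribute column
#'
#' Splits on `;`, then on the first `=`; percent-escapes are decoded.
#'
#' @param attr A single attribute string, e.g. `"ID=cds0;locus_tag=b0001"`.
#' @return A named character vector of attribute values.
#' @export
parse_gff_attributes <- function(attr) {
  parts <- strsplit(attr, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  has_eq <- grepl("=", parts, fixed = TRUE)
  parts <- parts[has_eq]
  if (!length(parts)) return(stats::setNames(character(), character()))
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  vals <- vapply(vals, utils::URLdecode, character(1), USE.NAMES = FALSE)
  stats::setNames(vals, trimws(keys))
}

new_cds <- function(chrom, start, end, strand, locus_tag) {
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             locus_tag = as.character(locus_tag), stringsAsFactors = FALSE)
}

#' Write CDS features as a minimal GFF file
#'
#' Internal 0-based half-open `[start, end)` coordinates are converted to
#' GFF's 1-based closed convention (`start + 1`, `end`); the attribute
#' column carries `locus_tag=<id>`.
#'
#' @param cds A data.frame of CDS features with columns `chrom`, `start`,
#'   `end`, `strand`, `locus_tag` (internal coordinates).
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_cds_gff <- function(cds, path, source = "ribostat") {
  stopifnot(all(c("chrom", "start", "end", "strand", "locus_tag") %in%
                  names(cds)))
  if (any(cds$start >= cds$end))
    stop("CDS features must satisfy start < end", call. = FALSE)
  lines <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tlocus_tag=%s",
                   cds$chrom, source, cds$start + 1L, cds$end,
                   cds$strand, cds$locus_tag)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
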