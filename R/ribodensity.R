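# Metagene ribosome density around start codons, three-nucleotide
# periodicity scoring, A-site mapping, and normalized genome-wide
# footprint profiles.
#
# Coordinate conventions: all positions are 0-based; the adenine of the
# start codon sits at relative position 0 of its CDS (not +1).

#' Genomic position of a read end
#'
#' Returns the biological 5' or 3' end of each mapped-read interval.
#' On the plus strand the 5' end is `start` and the 3' end is `end - 1`;
#' on the minus strand the roles are mirrored.
#'
#' @param intervals A data.frame of mapped-read intervals.
#' @param end Which end represents the ribosome position: 5 or 3.
#' @return Integer vector of 0-based genomic positions.
#' @export
assigned_end <- function(intervals, end = 5) {
  end <- match.arg(as.character(end), c("5", "3"))
  plus <- intervals$strand == "+"
  if (end == "5")
    ifelse(plus, intervals$start, intervals$end - 1L)
  else
    ifelse(plus, intervals$end - 1L, intervals$start)
}

#' Metagene ribosome density around start codons
#'
#' For every CDS and both read-end assignments, read ends on the CDS
#' strand falling inside a window of relative positions around the start
#' codon are accumulated; relative position 0 is the adenine of the start
#' codon (for a minus-strand CDS, genomic position `end - 1`).  Per-position
#' sums are divided by the number of CDSs, giving the average end count per
#' CDS.  A CDS shorter than the downstream window bound contributes only up
#' to its own 3' end; reads may contribute to several overlapping CDS
#' windows.
#'
#' @param intervals A data.frame of mapped-read intervals.
#' @param cds A data.frame of CDS features (see [extract_cds]).
#' @param window Integer pair `c(r_min, r_max)` of relative positions.
#' @param read_len_range Optional integer pair; if given, only reads whose
#'   length falls in this closed range are aggregated.
#' @return A data.frame of class `meta_density` with columns
#'   `rel_pos`, `density5`, `density3`; the number of CDSs aggregated is
#'   attached as attribute `"n_cds"`.
#' @export
metagene_density <- function(intervals, cds, window = c(-50L, 100L),
                             read_len_range = NULL) {
  if (nrow(cds) < 1L) stop("at least one CDS is required", call. = FALSE)
  r_min <- as.integer(window[1])
  r_max <- as.integer(window[2])
  if (r_min > r_max) stop("window must satisfy r_min <= r_max", call. = FALSE)
  if (!is.null(read_len_range)) {
    len <- intervals$end - intervals$start
    intervals <- intervals[len >= read_len_range[1] &
                             len <= read_len_range[2], , drop = FALSE]
  }
  W <- r_max - r_min + 1L
  counts5 <- numeric(W)
  counts3 <- numeric(W)
  pos5 <- assigned_end(intervals, 5)
  pos3 <- assigned_end(intervals, 3)
  for (i in seq_len(nrow(cds))) {
    sel <- intervals$chrom == cds$chrom[i] &
      intervals$strand == cds$strand[i]
    if (!any(sel)) next
    L <- cds$end[i] - cds$start[i]
    hi <- min(r_max, L - 1L)
    for (e in c("5", "3")) {
      p <- if (e == "5") pos5[sel] else pos3[sel]
      rel <- if (cds$strand[i] == "+") p - cds$start[i]
             else (cds$end[i] - 1L) - p
      rel <- rel[rel >= r_min & rel <= hi]
      if (!length(rel)) next
      add <- tabulate(rel - r_min + 1L, nbins = W)
      if (e == "5") counts5 <- counts5 + add else counts3 <- counts3 + add
    }
  }
  if (sum(counts5) + sum(counts3) == 0)
    warning("no read end falls inside any CDS window; densities are all ",
            "zero", call. = FALSE)
  out <- data.frame(rel_pos = r_min:r_max,
                    density5 = counts5 / nrow(cds),
                    density3 = counts3 / nrow(cds))
  class(out) <- c("meta_density", "data.frame")
  attr(out, "n_cds") <- nrow(cds)
  out
}

#' Periodicity statistics of a positional density vector
#'
#' `frame_fractions[k]` is the fraction of total density at positions
#' congruent to `k` modulo the period (position 0 of the vector is frame
#' 0); `lag_autocorr` is the Pearson correlation of the density with
#' itself shifted by one period.  Elongating ribosomes step one codon at a
#' time, so a valid Ribo-Seq library shows a dominant frame and a positive
#' lag-3 autocorrelation.
#'
#' @param d Numeric density vector over positions `0 .. W-1`.
#' @param period Periodicity lag in nt (3 for codons).
#' @return A list with `frame_fractions` (length `period`) and
#'   `lag_autocorr`.  Zero-variance shifts yield `lag_autocorr = 0`.
#' @export
periodicity_score <- function(d, period = 3L) {
  period <- as.integer(period)
  W <- length(d)
  if (W < 2L * period)
    stop("density vector must span at least two periods", call. = FALSE)
  if (any(d < 0)) stop("densities must be nonnegative", call. = FALSE)
  tot <- sum(d)
  if (tot == 0)
    stop("all-zero density: periodicity is undefined", call. = FALSE)
  frame <- (seq_len(W) - 1L) %% period
  fracs <- vapply(0:(period - 1L), function(k) sum(d[frame == k]) / tot,
                  numeric(1))
  x <- d[seq_len(W - period)]
  y <- d[(period + 1L):W]
  ac <- if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)
  list(frame_fractions = fracs, lag_autocorr = ac)
}

#' Map a footprint to its ribosomal A-site
#'
#' The A-site of a bacterial ribosome lies a fixed distance (default 14 nt)
#' upstream of the 3' end of the protected fragment, measured along the
#' read's own 5'->3' axis.
#'
#' @param intervals A data.frame of mapped-read intervals.
#' @param offset Distance in nt from the 3' end toward the 5' end.
#' @return Integer vector of 0-based genomic A-site positions.
#' @export
a_site_map <- function(intervals, offset = 14L) {
  offset <- as.integer(offset)
  len <- intervals$end - intervals$start
  bad <- which(len <= offset)
  if (length(bad))
    stop("read ", intervals$name[bad[1]], " has length ", len[bad[1]],
         " <= offset ", offset, ": A-site position undefined",
         call. = FALSE)
  ifelse(intervals$strand == "+",
         intervals$end - 1L - offset,
         intervals$start + offset)
}

#' Genome-wide footprint profile
#'
#' Counts assigned read ends at every (chromosome, strand, position).  If a
#' numeric `norm_factor` is given, counts are rescaled so the grand total
#' over all positions and strands equals it — the per-position count
#' expected if `norm_factor` reads had been mapped in total (TPM-like).
#' `norm_factor = "raw"` leaves integer counts.
#'
#' @param intervals A data.frame of mapped-read intervals (at least one).
#' @param end Which read end carries the signal: 5 or 3.
#' @param norm_factor Positive number, or `"raw"` for unnormalized counts.
#' @return A data.frame of class `genome_profile` with columns `chrom`,
#'   `pos` (0-based), `strand`, `value`, sorted by (chrom, pos, strand);
#'   attributes `"norm_factor"` and `"n_reads"`.
#' @export
genome_profile <- function(intervals, end = 5, norm_factor = "raw") {
  if (nrow(intervals) < 1L)
    stop("at least one mapped interval is required", call. = FALSE)
  if (!identical(norm_factor, "raw")) {
    if (!is.numeric(norm_factor) || length(norm_factor) != 1L ||
        norm_factor <= 0)
      stop("norm_factor must be a positive number or \"raw\"",
           call. = FALSE)
  }
  pos <- assigned_end(intervals, end)
  df <- data.frame(chrom = intervals$chrom, pos = pos,
                   strand = intervals$strand, value = 1,
                   stringsAsFactors = FALSE)
  agg <- aggregate(value ~ chrom + pos + strand, data = df, FUN = sum)
  if (!identical(norm_factor, "raw"))
    agg$value <- agg$value * norm_factor / nrow(intervals)
  agg <- agg[order(agg$chrom, agg$pos, agg$strand, method = "radix"), ,
             drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("genome_profile", "data.frame")
  attr(agg, "norm_factor") <- norm_factor
  attr(agg, "n_reads") <- nrow(intervals)
  agg
}

#' Write a genome profile as GFF point features
#'
#' One line per nonzero position: type `ribosome_footprint`, `start = end =
#' position + 1` (GFF 1-based), score = signal with six decimal places,
#' strand column set.  The file can be loaded in genome browsers that
#' accept GFF signal tracks.
#'
#' @param profile A [genome_profile].
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_profile_gff <- function(profile, path, source = "ribostat") {
  p <- profile[profile$value != 0, , drop = FALSE]
  p <- p[order(p$chrom, p$pos, p$strand, method = "radix"), , drop = FALSE]
  lines <- sprintf("%s\t%s\tribosome_footprint\t%d\t%d\t%.6f\t%s\t.\t.",
                   p$chrom, source, p$pos + 1L, p$pos + 1L, p$value,
                   p$strand)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a genome profile written by [write_profile_gff]
#'
#' @param path Path to a profile GFF file.
#' @return A data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `value`.
#' @export
read_profile_gff <- function(path) {
  gff <- read_gff(path)
  data.frame(chrom = gff$chrom, pos = gff$start - 1L, strand = gff$strand,
             value = as.numeric(gff$score), stringsAsFactors = FALSE)
}
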