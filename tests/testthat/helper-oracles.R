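# Shared fixtures and independent oracles, all built in code.

# Random BED6-style intervals.
random_intervals <- function(n, chroms = c("chrA", "chrB"),
                             max_pos = 5000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample(1:60, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             name = sprintf("r%05d", seq_len(n)),
             score = as.numeric(sample(0:60, n, replace = TRUE)),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Random valid CIGAR strings.
random_cigar <- function() {
  ops <- sample(c("M", "I", "D", "N", "S", "H", "P", "=", "X"),
                sample(1:6, 1), replace = TRUE)
  lens <- sample(1:30, length(ops), replace = TRUE)
  paste0(lens, ops, collapse = "")
}

# Independent CIGAR span oracle: expand every operation to one character
# per base and count the reference-consuming ones.
cigar_span_oracle <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+.", cigar))[[1]]
  walk <- unlist(lapply(toks, function(t) {
    rep(substring(t, nchar(t)), as.integer(substr(t, 1, nchar(t) - 1)))
  }))
  sum(walk %in% c("M", "D", "N", "=", "X"))
}

# All-pairs brute-force counting oracle.
count_oracle <- function(intervals, cds, same_strand = TRUE) {
  vapply(seq_len(nrow(cds)), function(i) {
    hits <- 0L
    for (j in seq_len(nrow(intervals))) {
      if (intervals$chrom[j] != cds$chrom[i]) next
      same <- intervals$strand[j] == cds$strand[i]
      if (same_strand != same) next
      if (intervals$start[j] < cds$end[i] &&
          intervals$end[j] > cds$start[i]) hits <- hits + 1L
    }
    hits
  }, integer(1))
}

# Random CDS features that do not need to be biologically coherent.
random_cds <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample(90:600, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             locus_tag = sprintf("b%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

random_reads <- function(n, len_range = c(10L, 40L)) {
  bases <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"),
                 sample(seq(len_range[1], len_range[2]), 1),
                 replace = TRUE), collapse = "")
  }, character(1))
  quals <- lapply(nchar(bases), function(k) sample(2:40, k, replace = TRUE))
  fastq_reads(sprintf("q%04d", seq_len(n)), bases, quals)
}
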