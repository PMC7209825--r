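# Seeded generators for every input the pipeline consumes — genome +
# CDS annotation, ribosome-protected-fragment reads (FASTQ with adapter
# read-through and decaying qualities, ideal-aligner SAM, truth BED), and
# negative-binomial count matrices — together with the ground truth needed
# to test every downstream stage.

revcomp <- function(s) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Simulate a bacterial genome with non-overlapping CDS annotation
#'
#' Generates a uniform-random genome and packs `n_genes` non-overlapping
#' CDSs on alternating strands, each 150-600 nt (a multiple of 3) and
#' beginning with ATG on its own strand; locus_tags are `g0001`, `g0002`,
#' ...  A 50 nt margin at both genome ends and 20-100 nt intergenic gaps
#' leave room for footprints that overhang gene boundaries.  Output is
#' byte-deterministic under the seed.
#'
#' @param n_genes Number of CDSs.
#' @param genome_length Genome length in bases; default `600 * n_genes +
#'   200`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `chrom` (sequence name), `genome` (one DNA string)
#'   and `cds` (data.frame of CDS features, internal coordinates).
#' @export
simulate_genome_annotation <- function(n_genes = 20L,
                                       genome_length = 600L * n_genes + 200L,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_genes <- as.integer(n_genes)
  genome_length <- as.integer(genome_length)
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (n_genes * 300L > genome_length)
    stop("infeasible packing: need at least 300 bases per gene",
         call. = FALSE)
  margin <- 50L
  lens <- 3L * sample(50:200, n_genes, replace = TRUE)
  gaps <- sample(20:100, n_genes, replace = TRUE)
  if (2L * margin + sum(lens) + sum(gaps) > genome_length)
    stop("infeasible packing: genome_length too small for the drawn gene ",
         "lengths; increase genome_length", call. = FALSE)
  starts <- margin + cumsum(c(0L, (lens + gaps)[-n_genes]))
  ends <- starts + lens
  strand <- rep(c("+", "-"), length.out = n_genes)
  chars <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  for (i in seq_len(n_genes)) {
    if (strand[i] == "+")
      chars[(starts[i] + 1L):(starts[i] + 3L)] <- c("A", "T", "G")
    else
      chars[(ends[i] - 2L):ends[i]] <- c("C", "A", "T")
  }
  list(chrom = "synth_chr",
       genome = paste(chars, collapse = ""),
       cds = new_cds(chrom = "synth_chr", start = starts, end = ends,
                     strand = strand,
                     locus_tag = sprintf("g%04d", seq_len(n_genes))))
}

#' Write a single-sequence FASTA file
#'
#' @param name Sequence name.
#' @param seq DNA string.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(name, seq, path, width = 70L) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = width)
  writeLines(c(paste0(">", name),
               substring(seq, starts, pmin(starts + width - 1L, n))), path)
  invisible(path)
}

#' Simulate ribosome-protected-fragment reads with ground truth
#'
#' Footprint 5' ends are placed inside CDSs with probability mass
#' `frame0_bias : 1 : 1` across the three reading frames (relative to each
#' gene's own frame); fragment lengths are uniform in
#' `fragment_len_range`.  Since every insert is shorter than the
#' sequencing read length, reads run through into the 3' adapter, which is
#' appended and the read truncated at `read_len` — exercising the adapter
#' clip by construction.  Base qualities decay linearly toward the 3' end
#' (mean `qual_start - qual_decay * position`, Gaussian jitter, floored at
#' 2).  Alongside the FASTQ, the ideal-aligner SAM (perfect local
#' alignments, correct FLAG and CIGAR) and the ground-truth BED are
#' returned so downstream stages can be tested with or without the
#' trimming front end.
#'
#' @param sim A genome/annotation list from [simulate_genome_annotation].
#' @param n_reads Number of reads.
#' @param expression Per-gene sampling weights; default uniform.
#' @param frame0_bias Ratio of frame-0 to each off-frame placement.
#' @param fragment_len_range Closed range of insert lengths in nt.
#' @param read_len Sequencing read length (cycles).
#' @param adapter 3' adapter sequence appended on read-through.
#' @param qual_start Mean Phred quality of the first cycle.
#' @param qual_decay Mean quality lost per cycle.
#' @param qual_jitter_sd Gaussian jitter of per-base quality (0 for a
#'   deterministic profile).
#' @param stall Optional list of per-gene stalls: each element
#'   `list(locus_tag =, rel_pos =, multiplier =)` multiplies the occupancy
#'   of footprints whose 5' end sits at that relative position.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `reads` ([fastq_reads]), `sam` (data.frame of
#'   alignment records incl. `seq`), `bed` (truth intervals) and `truth`
#'   (per-read table and per-gene counts).
#' @export
simulate_footprint_reads <- function(sim, n_reads = 10000L,
                                     expression = NULL,
                                     frame0_bias = 4,
                                     fragment_len_range = c(26L, 34L),
                                     read_len = 50L,
                                     adapter = "AGATCGGAAGAGCACACGTCT",
                                     qual_start = 38,
                                     qual_decay = 0.6,
                                     qual_jitter_sd = 3,
                                     stall = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- sim$cds
  n_g <- nrow(cds)
  if (frame0_bias < 1) stop("frame0_bias must be >= 1", call. = FALSE)
  if (fragment_len_range[1] < 15L || fragment_len_range[2] > 50L)
    stop("fragment_len_range must lie within [15, 50]", call. = FALSE)
  w <- if (is.null(expression)) rep(1, n_g) else as.numeric(expression)
  if (length(w) != n_g || sum(w) <= 0)
    stop("expression must be positive weights, one per gene", call. = FALSE)
  gidx <- sample.int(n_g, n_reads, replace = TRUE, prob = w)
  flen <- sample(seq(fragment_len_range[1], fragment_len_range[2]),
                 n_reads, replace = TRUE)
  frame <- sample(0:2, n_reads, replace = TRUE,
                  prob = c(frame0_bias, 1, 1))
  stall_by_gene <- list()
  for (st in stall)
    stall_by_gene[[st$locus_tag]] <-
      rbind(stall_by_gene[[st$locus_tag]],
            c(st$rel_pos, st$multiplier))
  rel5 <- integer(n_reads)
  gene_len <- cds$end - cds$start
  for (g in unique(gidx)) {
    L <- gene_len[g]
    st <- stall_by_gene[[cds$locus_tag[g]]]
    for (f in 0:2) {
      sel <- which(gidx == g & frame == f)
      if (!length(sel)) next
      cand <- seq.int(f, L - 1L, by = 3L)
      pw <- rep(1, length(cand))
      if (!is.null(st))
        for (r in seq_len(nrow(st)))
          pw[cand == st[r, 1]] <- pw[cand == st[r, 1]] * st[r, 2]
      rel5[sel] <- if (length(cand) == 1L) cand
                   else sample(cand, length(sel), replace = TRUE, prob = pw)
    }
  }
  plus <- cds$strand[gidx] == "+"
  p5 <- ifelse(plus, cds$start[gidx] + rel5, cds$end[gidx] - 1L - rel5)
  start <- ifelse(plus, p5, p5 - flen + 1L)
  end <- start + flen
  glen <- nchar(sim$genome)
  start <- pmax(start, 0L)
  end <- pmin(end, glen)

  fwd_seq <- substring(sim$genome, start + 1L, end)
  insert <- ifelse(plus, fwd_seq, revcomp(fwd_seq))
  raw <- substr(paste0(insert, adapter, strrep("A", read_len)),
                1L, read_len)
  mu <- qual_start - qual_decay * (seq_len(read_len) - 1L)
  qmat <- matrix(rep(mu, each = n_reads), nrow = n_reads)
  if (qual_jitter_sd > 0)
    qmat <- qmat + matrix(rnorm(n_reads * read_len, 0, qual_jitter_sd),
                          nrow = n_reads)
  qmat <- matrix(as.integer(round(pmin(40, pmax(2, qmat)))),
                 nrow = n_reads)
  ids <- sprintf("read%06d", seq_len(n_reads))
  reads <- fastq_reads(ids, raw,
                       lapply(seq_len(n_reads), function(i) qmat[i, ]))
  sam <- data.frame(read_id = ids,
                    flag = ifelse(plus, 0L, 16L),
                    chrom = sim$chrom,
                    pos = start + 1L,
                    mapq = 42L,
                    cigar = paste0(flen, "M"),
                    seq = fwd_seq,
                    stringsAsFactors = FALSE)
  bed <- new_intervals(chrom = sim$chrom, start = start, end = end,
                       name = ids, score = 42,
                       strand = cds$strand[gidx])
  gene_counts <- tabulate(gidx, nbins = n_g)
  names(gene_counts) <- cds$locus_tag
  truth <- list(reads = data.frame(read_id = ids,
                                   locus_tag = cds$locus_tag[gidx],
                                   start = start, end = end,
                                   strand = cds$strand[gidx],
                                   frame = frame, insert_len = flen,
                                   stringsAsFactors = FALSE),
                gene_counts = gene_counts)
  list(reads = reads, sam = sam, bed = bed, truth = truth)
}

#' Write alignment records as a text SAM file
#'
#' @param sam A data.frame of alignment records (as in the `sam` element of
#'   [simulate_footprint_reads]); a `seq` column is used when present.
#' @param path Output path.
#' @param chrom_lengths Named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path, chrom_lengths) {
  seqs <- if ("seq" %in% names(sam)) sam$seq else "*"
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  sam$read_id, sam$flag, sam$chrom, sam$pos, sam$mapq,
                  sam$cigar, seqs)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a negative-binomial count matrix with known truth
#'
#' Gene base means are log-normal; counts are negative binomial with
#' `size = 1 / dispersion`, scaled per sample by `depth_factors` and, for
#' the differentially translated fraction, by `fold_change` (half up, half
#' down) in every non-reference condition.
#'
#' @param n_genes Number of genes.
#' @param conditions Character vector of condition labels (first =
#'   reference).
#' @param reps Replicates per condition.
#' @param depth_factors Per-sample sequencing-depth multipliers (length
#'   `length(conditions) * reps`); default all 1.
#' @param de_fraction Fraction of genes that are truly differential.
#' @param fold_change True fold change of differential genes (> 1).
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param mean_log,sd_log Log-normal parameters of gene base means.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `counts` (integer matrix genes x samples), `design`
#'   (data.frame sample/condition) and `truth` (`de_genes`, per-gene
#'   `fold_change` by condition).
#' @export
simulate_count_matrix <- function(n_genes = 2000L,
                                  conditions = c("Control", "Treated"),
                                  reps = 2L,
                                  depth_factors = NULL,
                                  de_fraction = 0.1,
                                  fold_change = 4,
                                  dispersion = 0.1,
                                  mean_log = log(100),
                                  sd_log = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  n_cond <- length(conditions)
  n_s <- n_cond * reps
  if (is.null(depth_factors)) depth_factors <- rep(1, n_s)
  if (length(depth_factors) != n_s)
    stop("depth_factors must have one entry per sample", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- paste0(rep(gsub(" ", "_", conditions), each = reps), "_",
                    rep(seq_len(reps), times = n_cond))
  cond_of <- rep(conditions, each = reps)
  mu0 <- rlnorm(n_genes, meanlog = mean_log, sdlog = sd_log)
  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer()
  direction <- rep(1, n_genes)
  if (n_de > 0)
    direction[de_idx] <- sample(c(1, -1), n_de, replace = TRUE)
  fc <- matrix(1, nrow = n_genes, ncol = n_cond,
               dimnames = list(genes, conditions))
  if (n_cond > 1 && n_de > 0)
    for (k in 2:n_cond)
      fc[de_idx, k] <- fold_change^direction[de_idx]
  counts <- matrix(0L, nrow = n_genes, ncol = n_s,
                   dimnames = list(genes, samples))
  for (s in seq_len(n_s)) {
    mu <- mu0 * fc[, cond_of[s]] * depth_factors[s]
    counts[, s] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  list(counts = counts,
       design = data.frame(sample = samples, condition = cond_of,
                           stringsAsFactors = FALSE),
       truth = list(de_genes = genes[de_idx], fold_change = fc,
                    depth_factors = stats::setNames(depth_factors, samples)))
}
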