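# Quality and adapter trimming of single-end reads: simple adapter clipping
# (seeded alignment scan, log10(4) per match, -Q/10 per mismatch), 5'->3'
# sliding-window quality truncation, and a minimum-length filter.

#' Trimming configuration
#'
#' Parameters of the single-end trimming stage.  The adapter clip uses a
#' seed-and-extend scan: a candidate alignment offset is seeded when the
#' first `min(seed_len, overlap)` bases show at most `seed_mismatches`
#' mismatches, then scored over the full overlap with `+match_increment`
#' per match and `-Q/10` per mismatch (`Q` = read base quality).  With the
#' default increment `log10(4)` (~0.602), ten perfect matches are the
#' smallest number reaching the default clip threshold of 6.
#'
#' @param adapter Adapter sequence (DNA string), 3' read-through adapter.
#' @param seed_len Seed length in nt for the mismatch-limited seeding step.
#' @param seed_mismatches Maximum mismatches allowed in the seed.
#' @param clip_score_threshold Minimum alignment score required to clip.
#' @param match_increment Score added per matching base.
#' @param window_len Sliding-window width in nt.
#' @param window_min_mean_q Reads are truncated at the first window whose
#'   mean quality drops below this value (strict `<`).
#' @param min_len Reads shorter than this after trimming are dropped.
#' @param encoding_offset Phred encoding offset of the FASTQ input, 33 or 64.
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(adapter = "AGATCGGAAGAGCACACGTCT",
                        seed_len = 16L,
                        seed_mismatches = 2L,
                        clip_score_threshold = 6,
                        match_increment = log10(4),
                        window_len = 4L,
                        window_min_mean_q = 15,
                        min_len = 12L,
                        encoding_offset = 33L) {
  adapter <- toupper(as.character(adapter))
  if (!nzchar(adapter)) stop("adapter must be nonempty", call. = FALSE)
  if (seed_mismatches < 0L) stop("seed_mismatches must be >= 0", call. = FALSE)
  if (clip_score_threshold <= 0) stop("clip_score_threshold must be > 0",
                                      call. = FALSE)
  if (window_len < 1L) stop("window_len must be >= 1", call. = FALSE)
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  if (!encoding_offset %in% c(33L, 64L))
    stop("encoding_offset must be 33 or 64", call. = FALSE)
  structure(list(adapter = adapter,
                 adapter_chars = strsplit(adapter, "", fixed = TRUE)[[1]],
                 seed_len = as.integer(seed_len),
                 seed_mismatches = as.integer(seed_mismatches),
                 clip_score_threshold = clip_score_threshold,
                 match_increment = match_increment,
                 window_len = as.integer(window_len),
                 window_min_mean_q = window_min_mean_q,
                 min_len = as.integer(min_len),
                 encoding_offset = as.integer(encoding_offset)),
            class = "trim_config")
}

# Number of 5' bases kept after adapter clipping (read length if no clip).
# Scans every offset left to right; the leftmost seeded candidate whose
# extension score reaches the threshold wins, so the adapter and all bases
# 3' of it are removed.
clip_point <- function(base_chars, quals, cfg) {
  rlen <- length(base_chars)
  alen <- length(cfg$adapter_chars)
  if (rlen == 0L) return(0L)
  for (o in 0:(rlen - 1L)) {
    L <- min(alen, rlen - o)
    idx <- (o + 1L):(o + L)
    m <- base_chars[idx] == cfg$adapter_chars[seq_len(L)]
    sl <- min(cfg$seed_len, L)
    if (sum(!m[seq_len(sl)]) > cfg$seed_mismatches) next
    score <- cfg$match_increment * sum(m) - sum(quals[idx][!m]) / 10
    if (score >= cfg$clip_score_threshold) return(o)
  }
  rlen
}

# Number of 5' bases kept after sliding-window quality truncation.  Only
# full-length windows are evaluated (a window mean of exactly the threshold
# passes: the test is a strict '<'); a read shorter than the window is
# judged by the mean of all its bases.
window_point <- function(quals, cfg) {
  n <- length(quals)
  if (n == 0L) return(0L)
  if (n < cfg$window_len)
    return(if (mean(quals) < cfg$window_min_mean_q) 0L else n)
  cs <- cumsum(as.numeric(quals))
  starts <- seq_len(n - cfg$window_len + 1L)
  ends <- starts + cfg$window_len - 1L
  means <- (cs[ends] - c(0, cs)[starts]) / cfg$window_len
  fail <- which(means < cfg$window_min_mean_q)
  if (length(fail)) fail[1] - 1L else n
}

#' Clip a 3' read-through adapter from one read
#'
#' @param bases Base string of one read.
#' @param quals Integer Phred scores, one per base.
#' @param cfg A [trim_config].
#' @return A list with elements `bases`, `quals` (the retained 5' prefix)
#'   and `clipped` (logical).
#' @export
clip_adapter <- function(bases, quals, cfg = trim_config()) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  k <- clip_point(chars, quals, cfg)
  list(bases = substr(bases, 1L, k), quals = quals[seq_len(k)],
       clipped = k < length(chars))
}

#' Sliding-window quality trimming of one read
#'
#' @inheritParams clip_adapter
#' @return A list with elements `bases` and `quals` (the retained 5'
#'   prefix).
#' @export
window_trim <- function(bases, quals, cfg = trim_config()) {
  k <- window_point(quals, cfg)
  list(bases = substr(bases, 1L, k), quals = quals[seq_len(k)])
}

#' Trim a FASTQ dataset
#'
#' Each read is adapter-clipped, then window-trimmed; reads whose final
#' length is below `cfg$min_len` are dropped.  Surviving reads are written
#' in input order.
#'
#' @param input Input FASTQ(.gz) path.
#' @param output Output FASTQ path (gzip-compressed if ending in `.gz`).
#' @param cfg A [trim_config].
#' @return Trimming statistics: a list with `reads_in`, `reads_kept`,
#'   `reads_dropped`, `adapters_clipped`, `bases_quality_trimmed`.
#' @export
trim_dataset <- function(input, output, cfg = trim_config()) {
  rd <- tryCatch(read_fastq(input, encoding_offset = cfg$encoding_offset),
                 error = function(e)
                   stop("trim_dataset: reading '", input, "': ",
                        conditionMessage(e), call. = FALSE))
  n <- length(rd)
  keep_len <- integer(n)
  clipped <- logical(n)
  qtrimmed <- integer(n)
  base_chars <- strsplit(rd$bases, "", fixed = TRUE)
  for (i in seq_len(n)) {
    q <- rd$quals[[i]]
    cl <- clip_point(base_chars[[i]], q, cfg)
    clipped[i] <- cl < length(q)
    wl <- window_point(q[seq_len(cl)], cfg)
    qtrimmed[i] <- cl - wl
    keep_len[i] <- wl
  }
  keep <- keep_len >= cfg$min_len
  out <- fastq_reads(rd$read_id[keep],
                     substr(rd$bases[keep], 1L, keep_len[keep]),
                     mapply(function(q, k) q[seq_len(k)],
                            rd$quals[keep], keep_len[keep],
                            SIMPLIFY = FALSE))
  tryCatch(write_fastq(out, output, encoding_offset = cfg$encoding_offset),
           error = function(e)
             stop("trim_dataset: writing '", output, "': ",
                  conditionMessage(e), call. = FALSE))
  list(reads_in = n,
       reads_kept = sum(keep),
       reads_dropped = n - sum(keep),
       adapters_clipped = sum(clipped),
       bases_quality_trimmed = sum(qtrimmed))
}
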