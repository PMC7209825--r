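# End-to-end pipeline runner: trim -> decompile -> annotate -> metagene ->
# profile -> count -> merge -> diffexpr, driven by a flat key=value config.
# Every stage is a thin call into one library function; reruns on identical
# inputs produce byte-identical text outputs.

#' Read a flat key=value pipeline configuration
#'
#' Lines of the form `key=value`; blank lines and `#` comments ignored.
#'
#' @param path Path to the config file.
#' @return A named list of character values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- which(!grepl("=", lines, fixed = TRUE))
  if (length(bad))
    stop("config '", path, "': line '", lines[bad[1]],
         "' is not key=value", call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Run the full Ribo-Seq processing pipeline
#'
#' Executes, for every sample: FASTQ trimming, SAM-to-BED decompilation
#' (sorted), metagene density, genome profile and per-CDS counting; then
#' merges counts across samples and, when at least two conditions are
#' present, writes the differential-translation summary.  Stage logs with
#' record counts go to the message stream; a missing upstream input raises
#' an error naming the stage to run first.
#'
#' Required config keys: `out_dir`, `annotation` (GFF3 path), `samples`
#' (comma-separated names), and per sample `fastq.<name>`, `sam.<name>`,
#' `condition.<name>`.  Optional: `adapter`, `min_len`, `end` (5/3,
#' default 5), `norm_factor` (default 1000000; `raw` disables), `window`
#' (`min:max`, default `-50:100`).
#'
#' @param config A named list or the path to a key=value config file.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  for (key in c("out_dir", "annotation", "samples"))
    if (is.null(config[[key]]))
      stop("config key '", key, "' is required", call. = FALSE)
  out_dir <- config$out_dir
  samples <- trimws(strsplit(config$samples, ",", fixed = TRUE)[[1]])
  if (!file.exists(config$annotation))
    stop("annotation '", config$annotation, "' not found; provide the ",
         "genome GFF3 before running the pipeline", call. = FALSE)
  window <- as.integer(strsplit(cfg_get(config, "window", "-50:100"),
                                ":", fixed = TRUE)[[1]])
  end_choice <- cfg_get(config, "end", "5")
  nf_raw <- cfg_get(config, "norm_factor", "1000000")
  norm_factor <- if (identical(nf_raw, "raw")) "raw" else as.numeric(nf_raw)
  tcfg <- trim_config(
    adapter = cfg_get(config, "adapter", trim_config()$adapter),
    min_len = as.integer(cfg_get(config, "min_len", 12L)))

  sub <- function(d) {
    p <- file.path(out_dir, d)
    dir.create(p, showWarnings = FALSE, recursive = TRUE)
    p
  }
  paths <- list()

  message("[annotate] extracting CDS features from ", config$annotation)
  cds <- extract_cds(config$annotation)
  message("[annotate] ", nrow(cds), " CDS feature(s)")
  paths$annotation <- file.path(sub("annotation"), "genome_CDS.gff")
  write_cds_gff(cds, paths$annotation)

  cov_paths <- character()
  for (s in samples) {
    fq <- config[[paste0("fastq.", s)]]
    sam_path <- config[[paste0("sam.", s)]]
    if (is.null(fq) || !file.exists(fq))
      stop("sample '", s, "': FASTQ input missing; provide fastq.", s,
           " before the trim stage", call. = FALSE)
    if (is.null(sam_path) || !file.exists(sam_path))
      stop("sample '", s, "': SAM alignment missing; run the aligner and ",
           "provide sam.", s, " before the decompile stage", call. = FALSE)

    trimmed <- file.path(sub("trimmed"), paste0(s, "_trimmed.fastq"))
    st <- trim_dataset(fq, trimmed, tcfg)
    message("[trim] ", s, ": in=", st$reads_in, " kept=", st$reads_kept,
            " dropped=", st$reads_dropped, " clipped=",
            st$adapters_clipped)

    sam <- read_sam(sam_path)
    bed <- sort_intervals(sam_to_bed(sam))
    bed_path <- file.path(sub("decompiled"), paste0(s, ".bed"))
    write_bed(bed, bed_path)
    message("[decompile] ", s, ": ", nrow(bed), " mapped interval(s)")
    if (nrow(bed) == 0L)
      stop("sample '", s, "': no mapped reads after decompilation; ",
           "check the alignment stage", call. = FALSE)

    meta <- metagene_density(bed, cds, window = window)
    meta_path <- file.path(sub("meta"), paste0(s, "_meta.tsv"))
    write.table(data.frame(relative_position = meta$rel_pos,
                           density_5prime = meta$density5,
                           density_3prime = meta$density3),
                meta_path, sep = "\t", quote = FALSE, row.names = FALSE)

    prof <- genome_profile(bed, end = end_choice,
                           norm_factor = norm_factor)
    prof_path <- file.path(sub("profile"), paste0(s, "_Profile.gff"))
    write_profile_gff(prof, prof_path)
    message("[profile] ", s, ": ", nrow(prof), " nonzero position(s)")

    cov <- count_reads_per_cds(bed, cds)
    cov_path <- file.path(sub("coverage"), paste0(s, ".cov"))
    write_coverage(cov, cov_path)
    message("[count] ", s, ": ", sum(cov$read_count),
            " read-CDS assignment(s)")
    cov_paths <- c(cov_paths, cov_path)
  }

  counts <- merge_counts(cov_paths, samples)
  paths$counts <- file.path(out_dir, "counts.txt")
  write.table(data.frame(locus_tag = rownames(counts), counts,
                         check.names = FALSE),
              paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  message("[merge] ", nrow(counts), " gene(s) x ", ncol(counts),
          " sample(s)")

  conds <- vapply(samples, function(s)
    cfg_get(config, paste0("condition.", s), NA_character_), character(1))
  if (anyNA(conds))
    stop("condition.<sample> missing for: ",
         paste(samples[is.na(conds)], collapse = ", "), call. = FALSE)
  design <- data.frame(sample = samples, condition = conds,
                       stringsAsFactors = FALSE)
  paths$design <- file.path(out_dir, "design.txt")
  write.table(data.frame(Sample = design$sample,
                         Condition = design$condition),
              paths$design, sep = "\t", quote = FALSE, row.names = FALSE)

  if (length(unique(conds)) >= 2L) {
    de <- run_diffexpr(counts, design, file.path(out_dir, "diffexpr"))
    paths$diffexpr <- de$paths
    message("[diffexpr] ", length(de$paths), " file(s) written")
  } else {
    message("[diffexpr] skipped: a single condition has no contrasts")
  }
  invisible(paths)
}
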