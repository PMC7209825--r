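# Strand-specific per-CDS counting, count-matrix assembly, median-of-ratios
# normalization, reproducibility diagnostics, and pairwise contrast tables.

interval_union_length <- function(s, e) {
  if (!length(s)) return(0L)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0L
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else if (e[i] > cur_e) cur_e <- e[i]
  }
  tot + (cur_e - cur_s)
}

#' Strand-specific read counting per CDS
#'
#' A read counts toward a CDS iff their intervals overlap by at least one
#' base on the same chromosome and — Ribo-Seq being strand-specific — on
#' the same strand (default).  A read overlapping several CDSs increments
#' each of them.  `covered_bases` is the length of the union of read
#' overlaps with the feature.
#'
#' @param intervals A data.frame of mapped-read intervals.
#' @param cds A data.frame of CDS features.
#' @param same_strand Count only reads on the CDS strand (default `TRUE`;
#'   `FALSE` counts reads on the opposite strand instead).
#' @return A data.frame with columns `locus_tag`, `read_count`,
#'   `covered_bases`, `feature_length`, `covered_fraction`, one row per
#'   CDS in input order.
#' @export
count_reads_per_cds <- function(intervals, cds, same_strand = TRUE) {
  n <- nrow(cds)
  cnt <- integer(n)
  cov <- integer(n)
  for (i in seq_len(n)) {
    want_strand <- if (same_strand) cds$strand[i]
                   else setdiff(c("+", "-"), cds$strand[i])
    sel <- intervals$chrom == cds$chrom[i] &
      intervals$strand == want_strand &
      intervals$start < cds$end[i] &
      intervals$end > cds$start[i]
    cnt[i] <- sum(sel)
    cov[i] <- interval_union_length(pmax(intervals$start[sel], cds$start[i]),
                                    pmin(intervals$end[sel], cds$end[i]))
  }
  len <- cds$end - cds$start
  data.frame(locus_tag = cds$locus_tag,
             read_count = cnt,
             covered_bases = cov,
             feature_length = len,
             covered_fraction = cov / len,
             stringsAsFactors = FALSE)
}

#' Write a per-CDS coverage table
#'
#' Five tab-separated columns without header: locus_tag, read count,
#' covered bases, feature length, covered fraction.
#'
#' @param cov A data.frame as returned by [count_reads_per_cds].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%.7f", cov$locus_tag, cov$read_count,
                   cov$covered_bases, cov$feature_length,
                   cov$covered_fraction)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-CDS coverage table
#'
#' @param path Path to a file written by [write_coverage].
#' @return A data.frame with the five coverage columns.
#' @export
read_coverage <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  stringsAsFactors = FALSE,
                  col.names = c("locus_tag", "read_count", "covered_bases",
                                "feature_length", "covered_fraction"),
                  colClasses = c("character", "integer", "integer",
                                 "integer", "numeric"))
  x
}

#' Merge per-sample coverage files into a count matrix
#'
#' All files must carry the same locus_tag set; rows are aligned by
#' locus_tag (not row index) to the gene order of the first file.
#'
#' @param paths Character vector of coverage-file paths, in sample order.
#' @param sample_names Sample names for the columns; defaults to file base
#'   names without extension.
#' @return An integer matrix, genes x samples, with locus_tags as row
#'   names and sample names as column names.
#' @export
merge_counts <- function(paths,
                         sample_names = sub("\\.[^.]*$", "",
                                            basename(paths))) {
  if (length(paths) != length(sample_names))
    stop("one sample name per file is required", call. = FALSE)
  if (anyDuplicated(sample_names))
    stop("duplicate sample names", call. = FALSE)
  covs <- lapply(paths, read_coverage)
  genes <- covs[[1]]$locus_tag
  if (anyDuplicated(genes))
    stop("duplicate locus_tag in '", paths[1], "'", call. = FALSE)
  m <- matrix(0L, nrow = length(genes), ncol = length(paths),
              dimnames = list(genes, sample_names))
  for (j in seq_along(covs)) {
    idx <- match(genes, covs[[j]]$locus_tag)
    if (anyNA(idx) || nrow(covs[[j]]) != length(genes)) {
      diff <- if (anyNA(idx)) genes[which(is.na(idx))[1]]
              else setdiff(covs[[j]]$locus_tag, genes)[1]
      stop("gene set of '", paths[j], "' does not match '", paths[1],
           "': first differing gene '", diff, "'", call. = FALSE)
    }
    m[, j] <- as.integer(covs[[j]]$read_count[idx])
  }
  m
}

#' Read a design sheet
#'
#' A tab-separated text file with header `Sample<TAB>Condition` coupling
#' each sample with its experimental condition.
#'
#' @param path Path to the design sheet.
#' @return A data.frame with columns `sample` and `condition`.
#' @export
read_design <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(d) < 2L)
    stop("design sheet '", path, "' needs columns Sample and Condition",
         call. = FALSE)
  data.frame(sample = as.character(d[[1]]), condition = as.character(d[[2]]),
             stringsAsFactors = FALSE)
}

#' Median-of-ratios size factors
#'
#' The reference for each gene is its geometric mean across samples,
#' computed over genes with no zero count; each sample's factor is the
#' median over those genes of the ratio of the sample's count to the
#' reference.  Dividing counts by the factors removes sequencing-depth
#' differences while being robust to a minority of differentially
#' translated genes.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- log(counts)
  loggeo <- rowMeans(lg)
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has a positive count in every sample; add a pseudocount ",
         "or filter the matrix", call. = FALSE)
  ref <- exp(loggeo[use])
  apply(counts[use, , drop = FALSE], 2, function(col) median(col / ref))
}

#' Sample-level reproducibility diagnostics
#'
#' Counts are normalized by the size factors and transformed as
#' `log2(count / factor + 1)`; samples are compared by Euclidean distance
#' over genes, clustered by complete linkage, and projected onto the top
#' two principal components of the gene-centered transformed data.
#'
#' @param counts Integer matrix, genes x samples (at least two samples).
#' @param factors Per-sample size factors; default [size_factors].
#' @return A list with `distances` (sample x sample matrix), `pca`
#'   (data.frame: sample, PC1, PC2), `var_explained` (fractions for the
#'   reported components), and `hclust_order` (sample names in dendrogram
#'   order, complete linkage).
#' @export
sample_structure <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("at least two samples are required", call. = FALSE)
  x <- log2(sweep(counts, 2, factors, "/") + 1)
  d <- dist(t(x))
  hc <- hclust(d, method = "complete")
  xc <- x - rowMeans(x)
  pc <- prcomp(t(xc), center = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) scores <- cbind(scores, PC2 = 0)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(distances = as.matrix(d),
       pca = data.frame(sample = colnames(counts),
                        PC1 = scores[, 1], PC2 = scores[, 2],
                        stringsAsFactors = FALSE),
       var_explained = varfrac[seq_len(min(2L, length(varfrac)))],
       hclust_order = colnames(counts)[hc$order])
}

#' Pairwise differential-translation contrast table
#'
#' On size-factor-normalized counts, reports per gene the mean normalized
#' count across the two conditions' samples (`baseMean`), the fold change
#' `log2((meanB + 0.5) / (meanA + 0.5))`, a Welch two-sample t-test on
#' `log2(normalized + 1)` values, and Benjamini-Hochberg adjusted
#' p-values.  With a single sample in a condition the fold change is still
#' reported but p-values are `NA` (with a warning).
#'
#' @param counts Integer matrix, genes x samples.
#' @param design A design data.frame (see [read_design]).
#' @param cond_a,cond_b Condition labels to contrast (B relative to A).
#' @param factors Per-sample size factors; default [size_factors] of the
#'   full matrix.
#' @return A data.frame with columns `locus_tag`, `baseMean`,
#'   `log2FoldChange`, `p_value`, `adjusted_p`.
#' @export
contrast_table <- function(counts, design, cond_a, cond_b,
                           factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  sa <- intersect(design$sample[design$condition == cond_a],
                  colnames(counts))
  sb <- intersect(design$sample[design$condition == cond_b],
                  colnames(counts))
  if (!length(sa) || !length(sb))
    stop("conditions '", cond_a, "' and '", cond_b,
         "' must both have at least one sample in the matrix",
         call. = FALSE)
  norm <- sweep(counts, 2, factors, "/")
  mean_a <- rowMeans(norm[, sa, drop = FALSE])
  mean_b <- rowMeans(norm[, sb, drop = FALSE])
  base_mean <- rowMeans(norm[, c(sa, sb), drop = FALSE])
  l2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  if (length(sa) < 2L || length(sb) < 2L) {
    warning("a condition has a single sample: p-values are undefined",
            call. = FALSE)
    p <- rep(NA_real_, nrow(counts))
  } else {
    lt <- log2(norm + 1)
    p <- vapply(seq_len(nrow(counts)), function(g) {
      tryCatch(t.test(lt[g, sb], lt[g, sa])$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  data.frame(locus_tag = rownames(counts),
             baseMean = base_mean,
             log2FoldChange = l2fc,
             p_value = p,
             adjusted_p = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Differential-translation summary over all condition pairs
#'
#' Writes, into `out_dir`: `Normalized_expression.txt` (genes x samples,
#' 4 decimal places), `Distances.txt` (pairwise sample Euclidean
#' distances), `PCA.txt` (sample scores on the top two components), and one
#' `Contrast_<A>_vs_<B>.txt` per unordered condition pair (choose(N, 2)
#' files), conditions ordered by first appearance in the design sheet and
#' spaces in labels mapped to `_` in file names.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design A design data.frame (see [read_design]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the size factors and the paths written.
#' @export
run_diffexpr <- function(counts, design, out_dir) {
  counts <- as.matrix(counts)
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing))
    stop("sample(s) absent from the design sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  design <- design[design$sample %in% colnames(counts), , drop = FALSE]
  conds <- unique(design$condition)
  if (length(conds) < 2L)
    stop("at least two conditions are required for contrasts",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  paths <- character()
  norm_path <- file.path(out_dir, "Normalized_expression.txt")
  norm_out <- data.frame(locus_tag = rownames(counts),
                         round(norm, 4), check.names = FALSE)
  write.table(norm_out, norm_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, norm_path)

  st <- sample_structure(counts, sf)
  dist_path <- file.path(out_dir, "Distances.txt")
  write.table(data.frame(sample = rownames(st$distances),
                         round(st$distances, 4), check.names = FALSE),
              dist_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pca_path <- file.path(out_dir, "PCA.txt")
  pca_out <- st$pca
  pca_out$PC1 <- round(pca_out$PC1, 4)
  pca_out$PC2 <- round(pca_out$PC2, 4)
  write.table(pca_out, pca_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, dist_path, pca_path)

  pairs <- utils::combn(conds, 2L)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ct <- contrast_table(counts, design, a, b, factors = sf)
    fn <- sprintf("Contrast_%s_vs_%s.txt", gsub(" ", "_", a),
                  gsub(" ", "_", b))
    cp <- file.path(out_dir, fn)
    write.table(ct, cp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, cp)
  }
  invisible(list(size_factors = sf, paths = paths))
}
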