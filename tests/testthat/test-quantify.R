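# Strand-specific counting, count-matrix assembly, normalization,
# reproducibility diagnostics and contrast tables.

test_that("a read counts toward a same-strand overlapping CDS only", {
  cds <- data.frame(chrom = "c", start = 0L, end = 90L, strand = "+",
                    locus_tag = "gA", stringsAsFactors = FALSE)
  iv <- data.frame(chrom = "c", start = 10L, end = 40L, name = "r",
                   score = 0, strand = "+", stringsAsFactors = FALSE)
  cov <- count_reads_per_cds(iv, cds)
  expect_equal(cov$read_count, 1L)
  expect_equal(cov$covered_bases, 30L)
  expect_equal(cov$covered_fraction, 30 / 90)

  cds_minus <- transform(cds, strand = "-")
  expect_equal(count_reads_per_cds(iv, cds_minus)$read_count, 0L)
  # the antisense option counts exactly the reads the default rejects
  expect_equal(count_reads_per_cds(iv, cds_minus,
                                   same_strand = FALSE)$read_count, 1L)
})

test_that("covered_bases is the union of overlaps, capped at the feature", {
  cds <- data.frame(chrom = "c", start = 100L, end = 200L, strand = "+",
                    locus_tag = "gA", stringsAsFactors = FALSE)
  iv <- data.frame(chrom = "c",
                   start = c(90L, 120L, 130L, 190L),
                   end = c(125L, 140L, 135L, 230L),
                   name = paste0("r", 1:4), score = 0, strand = "+",
                   stringsAsFactors = FALSE)
  cov <- count_reads_per_cds(iv, cds)
  # union over the feature: [100,140) + [190,200) = 40 + 10
  expect_equal(cov$covered_bases, 50L)
  expect_equal(cov$read_count, 4L)
})

test_that("counts equal an all-pairs brute-force oracle", {
  set.seed(601)
  iv <- random_intervals(500)
  cds <- random_cds(20)
  for (ss in c(TRUE, FALSE)) {
    got <- count_reads_per_cds(iv, cds, same_strand = ss)$read_count
    expect_equal(got, count_oracle(iv, cds, same_strand = ss))
  }
})

test_that("coverage files merge into a matrix aligned by locus_tag", {
  cds <- random_cds(6, chroms = "c")
  set.seed(602)
  iv <- random_intervals(200, chroms = "c", max_pos = 4000L)
  cov <- count_reads_per_cds(iv, cds)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "Ctrl1.cov"); write_coverage(cov, p1)
  # same counts, shuffled gene order: must align by id, not by row
  p2 <- file.path(d, "Ctrl2.cov")
  write_coverage(cov[sample(nrow(cov)), ], p2)
  m <- merge_counts(c(p1, p2))
  expect_equal(colnames(m), c("Ctrl1", "Ctrl2"))
  expect_equal(rownames(m), cov$locus_tag)
  expect_equal(m[, 1], m[, 2])

  # single-gene worked example
  one <- data.frame(locus_tag = "gX", read_count = 7L, covered_bases = 10L,
                    feature_length = 90L, covered_fraction = 10 / 90)
  pa <- file.path(d, "a.cov"); pb <- file.path(d, "b.cov")
  write_coverage(one, pa); write_coverage(one, pb)
  expect_equal(unname(merge_counts(c(pa, pb))), matrix(7L, 1, 2))

  # four samples keep the given column order
  ps <- file.path(d, paste0(c("Ctrl1", "Ctrl2", "Exp1", "Exp2"), ".cov"))
  for (p in ps) write_coverage(cov, p)
  expect_equal(colnames(merge_counts(ps)),
               c("Ctrl1", "Ctrl2", "Exp1", "Exp2"))

  # mismatched gene sets are an error naming the file and gene
  bad <- cov; bad$locus_tag[1] <- "zzzz"
  pbad <- file.path(d, "bad.cov"); write_coverage(bad, pbad)
  expect_error(merge_counts(c(p1, pbad)), "bad.cov.*differing gene",
               ignore.case = TRUE)
})

test_that("median-of-ratios factors: identity, scaling, and recovery", {
  set.seed(603)
  a <- matrix(rpois(200, 50), ncol = 2,
              dimnames = list(sprintf("g%03d", 1:100), c("s1", "s2")))
  a[, 2] <- a[, 1]
  expect_equal(unname(size_factors(a)), c(1, 1))

  b <- cbind(s1 = a[, 1] + 1L, s2 = 2L * (a[, 1] + 1L))
  expect_equal(unname(size_factors(b)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # depth recovery on simulated libraries
  cm <- simulate_count_matrix(n_genes = 2000, conditions = c("A", "B", "C"),
                              reps = 1, depth_factors = c(0.5, 1, 2),
                              de_fraction = 0, seed = 11)
  sf <- size_factors(cm$counts)
  sf <- sf / exp(mean(log(sf)))
  target <- c(0.5, 1, 2) / exp(mean(log(c(0.5, 1, 2))))
  expect_equal(unname(sf), target, tolerance = 0.05)

  # scale equivariance: scaling one sample scales its factor relative to
  # the others by the same constant
  sf0 <- size_factors(b)
  b2 <- b; b2[, 2] <- b2[, 2] * 3L
  sf2 <- size_factors(b2)
  expect_equal(sf2[2] / sf2[1], 3 * sf0[2] / sf0[1], tolerance = 1e-12)

  z <- matrix(c(0L, 5L, 7L, 0L), 2, 2)
  expect_error(size_factors(z), "pseudocount|filter")
})

test_that("median-of-ratios agrees with an independent implementation", {
  cm <- simulate_count_matrix(n_genes = 500, reps = 3, seed = 604)
  # DESeq2 takes the median in log space, this implementation in ratio
  # space; with an even number of usable genes the interpolated medians
  # differ in the far decimals only
  expect_equal(unname(size_factors(cm$counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cm$counts)),
               tolerance = 1e-4)
})

test_that("sample structure: metric distances, duplicates, separation", {
  cm <- simulate_count_matrix(n_genes = 400, reps = 2, seed = 605)
  counts <- cbind(cm$counts, dup = cm$counts[, 1])
  st <- sample_structure(counts)
  D <- st$distances
  expect_equal(D[1, "dup"], 0)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))

  # triangle inequality over random matrices
  set.seed(606)
  for (r in 1:50) {
    m <- matrix(rpois(200, 30), ncol = 4)
    rownames(m) <- sprintf("g%02d", 1:50)
    colnames(m) <- paste0("s", 1:4)
    D <- sample_structure(m)$distances
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }

  # strong differential translation separates the conditions
  cm <- simulate_count_matrix(n_genes = 500, reps = 3, de_fraction = 0.3,
                              fold_change = 6, dispersion = 0.02, seed = 3)
  st <- sample_structure(cm$counts)
  cond <- cm$design$condition[match(colnames(cm$counts), cm$design$sample)]
  D <- st$distances
  same <- D[outer(cond, cond, "==") & upper.tri(D)]
  diff <- D[outer(cond, cond, "!=") & upper.tri(D)]
  expect_lt(max(same), min(diff))

  expect_error(sample_structure(cm$counts[, 1, drop = FALSE]),
               "two samples")
})

test_that("contrast tables: identity, antisymmetry, BH monotonicity,
           pair count", {
  cm <- simulate_count_matrix(n_genes = 300, reps = 3, de_fraction = 0.2,
                              seed = 607)
  # identical groups: fold change exactly zero
  dup <- cbind(cm$counts[, 1:3], cm$counts[, 1:3])
  colnames(dup) <- paste0("s", 1:6)
  des <- data.frame(sample = colnames(dup),
                    condition = rep(c("A", "B"), each = 3))
  ct0 <- contrast_table(dup, des, "A", "B")
  expect_true(all(ct0$log2FoldChange == 0))

  ct_ab <- contrast_table(cm$counts, cm$design, "Control", "Treated")
  ct_ba <- contrast_table(cm$counts, cm$design, "Treated", "Control")
  expect_equal(ct_ba$log2FoldChange, -ct_ab$log2FoldChange)
  expect_equal(ct_ba$p_value, ct_ab$p_value)
  expect_equal(ct_ba$baseMean, ct_ab$baseMean)

  # BH adjusted p is nondecreasing in the rank of p
  ord <- order(ct_ab$p_value)
  expect_true(!is.unsorted(ct_ab$adjusted_p[ord], na.rm = TRUE))
  expect_true(all(ct_ab$adjusted_p >= ct_ab$p_value, na.rm = TRUE))

  # one contrast file per unordered condition pair: choose(N, 2)
  d <- withr::local_tempdir()
  for (k in 2:4) {
    cmk <- simulate_count_matrix(n_genes = 60, reps = 2,
                                 conditions = paste0("C", 1:k),
                                 seed = 608 + k)
    out <- file.path(d, paste0("de", k))
    run_diffexpr(cmk$counts, cmk$design, out)
    expect_length(list.files(out, pattern = "^Contrast_"), choose(k, 2))
  }

  # single-sample condition: fold change reported, p undefined
  des1 <- data.frame(sample = colnames(cm$counts)[1:3],
                     condition = c("A", "A", "B"))
  expect_warning(
    ct1 <- contrast_table(cm$counts[, 1:3], des1, "A", "B"),
    "single sample")
  expect_true(all(is.na(ct1$p_value)))
  expect_true(all(is.finite(ct1$log2FoldChange)))
})

test_that("true differential translation is recovered with controlled
           false discoveries", {
  # tight biological replicates (dispersion 0.02), 10% of genes at 4-fold,
  # three replicates per condition
  set.seed(5)
  rec <- fdp <- numeric(20)
  for (r in 1:20) {
    cm <- simulate_count_matrix(n_genes = 500, reps = 3, de_fraction = 0.1,
                                fold_change = 4, dispersion = 0.02)
    ct <- contrast_table(cm$counts, cm$design, "Control", "Treated")
    sig <- ct$locus_tag[!is.na(ct$adjusted_p) & ct$adjusted_p < 0.05]
    rec[r] <- mean(cm$truth$de_genes %in% sig)
    fdp[r] <- if (length(sig)) mean(!sig %in% cm$truth$de_genes) else 0
  }
  expect_gte(mean(rec), 0.5)
  expect_lte(mean(fdp), 0.15)
})
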