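# Metagene density, periodicity scoring, A-site mapping and genome-wide
# profiles.

test_that("assigned ends follow the biological 5'/3' of each strand", {
  iv <- data.frame(chrom = "c", start = 99L, end = 129L, name = "r",
                   score = 0, strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  expect_equal(assigned_end(iv, 5), c(99L, 128L))
  expect_equal(assigned_end(iv, 3), c(128L, 99L))

  set.seed(501)
  rnd <- random_intervals(300)
  e5 <- assigned_end(rnd, 5)
  e3 <- assigned_end(rnd, 3)
  # the two ends always partition {start, end-1}
  expect_true(all(pmin(e5, e3) == rnd$start & pmax(e5, e3) == rnd$end - 1L))
})

test_that("a read end on the start-codon adenine maps to relative
           position 0", {
  cds <- data.frame(chrom = "c", start = c(500L, 2000L),
                    end = c(800L, 2300L), strand = c("+", "-"),
                    locus_tag = c("gA", "gB"), stringsAsFactors = FALSE)
  # 5' ends exactly on both start codons (genomic 500 for +, 2299 for -)
  iv <- data.frame(chrom = "c", start = c(500L, 2270L),
                   end = c(530L, 2300L), name = c("r1", "r2"), score = 0,
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  md <- metagene_density(iv, cds)
  expect_equal(md$rel_pos[md$density5 > 0], 0L)
  expect_equal(md$density5[md$rel_pos == 0], 2 / 2)
})

test_that("metagene is strand-mirror symmetric and strand-specific", {
  cds <- data.frame(chrom = "c", start = c(100L, 1000L),
                    end = c(400L, 1300L), strand = c("+", "-"),
                    locus_tag = c("gP", "gM"), stringsAsFactors = FALSE)
  # one read per CDS with its 5' end at relative +3 on each strand
  iv <- data.frame(chrom = "c", start = c(103L, 1267L),
                   end = c(133L, 1297L), name = c("r1", "r2"), score = 0,
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  md <- metagene_density(iv, cds)
  expect_equal(md$rel_pos[md$density5 > 0], 3L)
  expect_equal(md$density5[md$rel_pos == 3], 1)

  # reads on the opposite strand of every CDS contribute nothing
  flipped <- iv
  flipped$strand <- c("-", "+")
  expect_warning(md0 <- metagene_density(flipped, cds), "all.*zero|zero")
  expect_true(all(md0$density5 == 0) && all(md0$density3 == 0))

  # flipping the whole experiment leaves the densities unchanged
  glen <- 2000L
  mirror <- function(df) {
    out <- df
    out$start <- glen - df$end
    out$end <- glen - df$start
    out$strand <- ifelse(df$strand == "+", "-", "+")
    out
  }
  set.seed(502)
  sim <- simulate_genome_annotation(n_genes = 6, seed = 502)
  fr <- simulate_footprint_reads(sim, n_reads = 1500, seed = 502)
  glen <- nchar(sim$genome)
  m1 <- metagene_density(fr$bed, sim$cds)
  m2 <- metagene_density(mirror(fr$bed), mirror(sim$cds))
  expect_equal(m2$density5, m1$density5)
  expect_equal(m2$density3, m1$density3)
})

test_that("short CDSs only contribute up to their own 3' end", {
  cds <- data.frame(chrom = "c", start = 100L, end = 160L, strand = "+",
                    locus_tag = "tiny", stringsAsFactors = FALSE)
  # one end inside the gene, one beyond its 3' end but inside the window
  iv <- data.frame(chrom = "c", start = c(130L, 180L),
                   end = c(160L, 210L), name = c("in", "out"), score = 0,
                   strand = "+", stringsAsFactors = FALSE)
  md <- metagene_density(iv, cds, window = c(-50L, 100L))
  expect_equal(md$rel_pos[md$density5 > 0], 30L)
})

test_that("periodicity statistics recover frame structure", {
  d <- rep(c(9, 1, 1), 20)
  ps <- periodicity_score(d)
  expect_equal(ps$frame_fractions, c(9, 1, 1) / 11, tolerance = 1e-12)
  expect_equal(which.max(ps$frame_fractions), 1L)

  u <- rep(2, 30)
  psu <- periodicity_score(u)
  expect_equal(psu$frame_fractions, rep(1 / 3, 3))
  expect_equal(psu$lag_autocorr, 0)   # zero variance handled as 0

  expect_error(periodicity_score(rep(0, 30)), "all-zero")
  expect_error(periodicity_score(c(1, 2, 3)), "two periods")

  # periodic signal with noise: lag-3 autocorrelation beats lags 2 and 4
  set.seed(7)
  d3 <- rep(c(8, 1, 1), 40) + runif(120, 0, 0.5)
  ac <- vapply(2:4, function(p) periodicity_score(d3, p)$lag_autocorr,
               numeric(1))
  expect_gt(ac[2], ac[1])
  expect_gt(ac[2], ac[3])
})

test_that("A-site mapping sits offset nt upstream of the 3' end", {
  iv <- data.frame(chrom = "c", start = 100L, end = 130L, name = "r",
                   score = 0, strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  expect_equal(a_site_map(iv, 14), c(115L, 114L))
  expect_equal(a_site_map(iv, 0), assigned_end(iv, 3))
  expect_error(a_site_map(iv, 30), "undefined")

  # A-site and 3' end differ by the offset along the read's own axis
  set.seed(503)
  rnd <- random_intervals(200)
  rnd <- rnd[rnd$end - rnd$start > 14L, ]
  a <- a_site_map(rnd, 14)
  e3 <- assigned_end(rnd, 3)
  expect_true(all(abs(a - e3) == 14L))
  # and the A-site lies between the read ends
  expect_true(all(a >= rnd$start & a < rnd$end))
})

test_that("genome profile conserves totals raw and normalized", {
  set.seed(504)
  sim <- simulate_genome_annotation(n_genes = 5, seed = 504)
  fr <- simulate_footprint_reads(sim, n_reads = 10, seed = 504)
  raw <- genome_profile(fr$bed, 5, "raw")
  expect_equal(sum(raw$value), 10)
  expect_true(all(raw$value == as.integer(raw$value)))

  norm <- genome_profile(fr$bed, 5, 1e6)
  expect_true(all(norm$value %% 1e5 == 0))   # 10 reads -> multiples of 1e5
  expect_equal(sum(norm$value), 1e6, tolerance = 1e-6)

  # duplicating every read leaves the normalized profile unchanged
  doubled <- rbind(fr$bed, fr$bed)
  norm2 <- genome_profile(doubled, 5, 1e6)
  expect_equal(norm2$value, norm$value)

  expect_error(genome_profile(fr$bed, 5, -1), "norm_factor")
  expect_error(genome_profile(fr$bed[0, ], 5), "at least one")
})

test_that("profile GFF uses 1-based point features and round-trips", {
  iv <- data.frame(chrom = "c", start = 99L, end = 129L, name = "r",
                   score = 0, strand = "+", stringsAsFactors = FALSE)
  p <- genome_profile(iv, 5, "raw")
  f <- withr::local_tempfile(fileext = ".gff")
  write_profile_gff(p, f)
  line <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_equal(as.integer(line[4:5]), c(100L, 100L))
  expect_equal(line[3], "ribosome_footprint")

  set.seed(505)
  sim <- simulate_genome_annotation(n_genes = 6, seed = 505)
  fr <- simulate_footprint_reads(sim, n_reads = 500, seed = 505)
  prof <- genome_profile(fr$bed, 3, 1e6)
  write_profile_gff(prof, f)
  back <- read_profile_gff(f)
  expect_equal(sum(back$value), sum(prof$value), tolerance = 1e-3)
  expect_equal(nrow(back), nrow(prof))

  write_profile_gff(prof[0, ], f)
  expect_equal(readLines(f), "##gff-version 3")
})
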