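test_that("coverage dialects are parsed with correct coordinate conventions", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t101\t101\t80.0\t4\t1",
               "chr2\t51\t51\t50.0\t3\t3"), f)
  calls <- read_methylation_calls(f, dialect = "bismark_cov")
  expect_equal(calls$pos, c(100L, 50L))
  expect_equal(calls$meth, c(4L, 3L))
  expect_equal(calls$unmeth, c(1L, 3L))

  g <- withr::local_tempfile(fileext = ".bg")
  writeLines("chr1\t100\t101\t80.0\t4\t1", g)
  calls_bg <- read_methylation_calls(g, dialect = "bedgraph_counts")
  expect_equal(calls_bg$pos, 100L)

  # space-separated input is accepted too
  h <- withr::local_tempfile()
  writeLines("chr1 101 101 80.0 4 1", h)
  expect_equal(read_methylation_calls(h, "bismark_cov")$pos, 100L)
})

test_that("malformed call files error with a line number", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t101\t101\t80.0\t4\t1",
               "chr1\t102\t102\t50.0\t4.5\t1"), f)
  expect_error(read_methylation_calls(f), "line 2")
  writeLines("chr1\t101\t101", f)
  expect_error(read_methylation_calls(f), "line 1")
  writeLines("chr1\t101\t101\t80.0\t-4\t1", f)
  expect_error(read_methylation_calls(f), "negative")
})

test_that("an empty file yields an empty call table", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_equal(nrow(read_methylation_calls(f)), 0)
})

test_that("read -> write -> read round trip is count-exact for both dialects", {
  calls <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), pos = c(10L, 25L, 7L),
    strand = "+", context = "CpG",
    meth = c(3L, 0L, 12L), unmeth = c(7L, 9L, 0L)
  )
  for (d in c("bismark_cov", "bedgraph_counts")) {
    f <- withr::local_tempfile()
    write_methylation_calls(calls, f, dialect = d)
    back <- read_methylation_calls(f, dialect = d)
    expect_equal(back[c("chrom", "pos", "meth", "unmeth")],
                 calls[c("chrom", "pos", "meth", "unmeth")])
  }
})

test_that("strand pooling sums mates, keeps singletons, conserves counts", {
  calls <- tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 101L, 200L, 300L, 301L),
    strand = c("+", "-", "+", "+", "-"),
    context = "CpG",
    meth = c(3L, 1L, 5L, 2L, 4L),
    unmeth = c(2L, 4L, 5L, 1L, 0L)
  )
  pooled <- pool_strands(calls)
  expect_equal(nrow(pooled), 3)
  # dinucleotide at 100: (+ at 100) + (- at 101)
  expect_equal(pooled$meth[pooled$pos == 100], 4L)
  expect_equal(pooled$unmeth[pooled$pos == 100], 6L)
  expect_equal(pooled$level[pooled$pos == 100], 0.4)
  # singleton + strand passes through
  expect_equal(pooled$meth[pooled$pos == 200], 5L)
  # conservation
  expect_equal(sum(pooled$meth) + sum(pooled$unmeth),
               sum(calls$meth) + sum(calls$unmeth))
})

test_that("explicit cpg_pairs mapping is honoured and unmapped calls error", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 105L), strand = c("+", "-"),
    context = "CpG", meth = c(1L, 2L), unmeth = c(3L, 4L)
  )
  pairs <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 105L), strand = c("+", "-"),
    cpg_pos = c(100L, 100L)
  )
  pooled <- pool_strands(calls, cpg_pairs = pairs)
  expect_equal(pooled$meth, 3L)
  expect_error(pool_strands(calls, cpg_pairs = pairs[1, ]), "no CpG key")
  expect_error(
    pool_strands(dplyr::mutate(calls, context = "nonCpG")),
    "CpG-context"
  )
})

test_that("SNP masking removes exactly the overlapping sites", {
  m <- toy_methylome()
  mask <- tibble::tibble(chrom = c("chr1", "chr1", "chr9"),
                         pos = c(200L, 1100L, 5L))
  masked <- mask_snp_sites(m, mask)
  expect_equal(nrow(masked$meth), 4)
  expect_false(any(masked$sites$pos %in% c(200L, 1100L)))
  # empty mask is the identity; position between CpGs removes nothing
  expect_equal(mask_snp_sites(m, mask[0, ])$sites, m$sites)
  between <- tibble::tibble(chrom = "chr1", pos = 150L)
  expect_equal(nrow(mask_snp_sites(m, between)$meth), 6)
})

test_that("conversion efficiency is one minus the false-positive rate", {
  calls <- tibble::tibble(meth = c(2L, 3L), unmeth = c(500L, 495L))
  expect_equal(estimate_conversion_efficiency(calls), 0.995)
  expect_equal(estimate_conversion_efficiency(
    tibble::tibble(meth = 0L, unmeth = 100L)), 1.0)
  expect_equal(estimate_conversion_efficiency(
    tibble::tibble(meth = 50L, unmeth = 50L)), 0.5)
  expect_error(estimate_conversion_efficiency(
    tibble::tibble(meth = 0L, unmeth = 0L)), "zero total depth")
  # equals a brute-force weighted mean over calls
  set.seed(7)
  rc <- tibble::tibble(meth = rpois(50, 2), unmeth = rpois(50, 300))
  fp <- with(rc, sum(meth) / sum(meth + unmeth))
  expect_equal(estimate_conversion_efficiency(rc), 1 - fp)
})

test_that("genome-wide mean skips missing sites and errors when all missing", {
  expect_equal(genome_wide_mean(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(genome_wide_mean(0.7), 0.7)
  expect_equal(genome_wide_mean(c(0.2, NA, 0.6)), 0.4)
  expect_error(genome_wide_mean(c(NA_real_, NA_real_)), "missing")
  gw <- genome_wide_mean(toy_methylome())
  expect_equal(nrow(gw), 3)
  expect_true(all(gw$genome_wide_mean >= 0 & gw$genome_wide_mean <= 1))
})

test_that("filter_sites applies depth, missingness and sd rules and is idempotent", {
  sim <- small_cohort()
  crit <- filter_criteria(mean_depth_range = c(10, 25),
                          sample_depth_range = c(5, 50),
                          max_missing_fraction = 0.2, min_sd = 0.1)
  f1 <- filter_sites(sim$methylome, crit)
  expect_true(nrow(f1$meth) > 0)
  expect_true(nrow(f1$meth) < nrow(sim$methylome$meth))
  # per-cell depth bounds produced missing cells, never out-of-range depths
  d <- meth_depth(f1)
  expect_true(all(is.na(d) | (d >= 5 & d <= 50)))
  # mean depth band on the single-stranded scale
  md <- rowMeans(d, na.rm = TRUE) / 2
  expect_true(all(md >= 10 & md <= 25))
  # sd rule
  sds <- apply(meth_level(f1), 1, sd, na.rm = TRUE)
  expect_true(all(sds >= 0.1))
  # idempotence
  f2 <- filter_sites(f1, crit)
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$meth, f2$meth)
})

test_that("a low-variability site is dropped by the sd threshold", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(0L, 10L))
  n <- 20
  # site 1: sd ~ 0.02; site 2: alternating high/low
  meth <- rbind(as.integer(round(30 * c(rep(0.5, n)) + rep(c(0, 1), n / 2))),
                as.integer(30 * rep(c(0.2, 0.8), n / 2)))
  unmeth <- matrix(30L, 2, n) - meth
  m <- methylome(sites, meth, unmeth, samples = paste0("S", 1:n))
  crit <- filter_criteria(mean_depth_range = c(10, 25),
                          sample_depth_range = c(5, 50),
                          max_missing_fraction = 0, min_sd = 0.1)
  f <- filter_sites(m, crit)
  expect_equal(f$sites$pos, 10L)
})

test_that("methylome TSV round trip is exact and provenance is written", {
  sim <- small_cohort()
  f <- filter_sites(sim$methylome, filter_criteria(max_missing_fraction = 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_methylome(f, path)
  expect_true(file.exists(paste0(path, ".provenance.json")))
  back <- read_methylome(path)
  expect_identical(back$meth, f$meth)
  expect_identical(back$unmeth, f$unmeth)
  expect_equal(back$sites, f$sites)
})
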