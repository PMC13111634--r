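make_md <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    individual_id = sprintf("I%02d", seq_len(n)),
    group = rep(c("wild", "zoo"), length.out = n),
    age = runif(n, 2, 25),
    eaa = rnorm(n, 0, 1.5),
    conversion_efficiency = runif(n, 0.97, 0.999),
    genome_wide_mean = runif(n, 0.55, 0.65)
  ))
}

test_that("site binomial model recovers a constructed odds ratio", {
  md <- make_md(40)
  md$age <- 10; md$eaa <- 0  # constant covariates get dropped
  # wild pi = 1/3, zoo pi = 1/2  ->  OR = 2, log2 OR = 1
  depth <- 10000L
  pi <- ifelse(md$group == "zoo", 0.5, 1 / 3)
  counts <- tibble::tibble(
    sample_id = md$sample_id,
    meth = as.integer(round(depth * pi)), unmeth = depth - as.integer(round(depth * pi))
  )
  res <- fit_site_binomial_model(counts, md)
  expect_false(res$separation)
  expect_equal(res$log2_or, 1, tolerance = 0.02)
})

test_that("site binomial model is null under identical distributions", {
  md <- make_md(40)
  withr::with_seed(2, {
    counts <- tibble::tibble(
      sample_id = md$sample_id,
      meth = rbinom(40, 1000, 0.4),
      unmeth = 1000L - rbinom(40, 1000, 0.4)
    )
  })
  counts$unmeth <- 1000L - counts$meth
  res <- fit_site_binomial_model(counts, md)
  expect_lt(abs(res$log2_or), 0.1)
})

test_that("complete separation is flagged with no estimate", {
  md <- make_md(20)
  counts <- tibble::tibble(
    sample_id = md$sample_id,
    meth = ifelse(md$group == "zoo", 30L, 0L),
    unmeth = ifelse(md$group == "zoo", 0L, 30L)
  )
  res <- fit_site_binomial_model(counts, md)
  expect_true(res$separation)
  expect_true(is.na(res$log2_or))
})

test_that("site model agrees with a direct glm fit", {
  md <- make_md(30, seed = 5)
  withr::with_seed(6, {
    pi <- plogis(qlogis(0.4) + 0.5 * (md$group == "zoo") + 0.02 * md$age)
    meth <- rbinom(30, 40, pi)
  })
  counts <- tibble::tibble(sample_id = md$sample_id, meth = meth,
                           unmeth = 40L - meth)
  res <- fit_site_binomial_model(counts, md)
  ref <- glm(cbind(meth, 40 - meth) ~ factor(group, c("wild", "zoo")) + age +
               eaa + conversion_efficiency + genome_wide_mean,
             data = cbind(md, meth = meth), family = binomial())
  expect_equal(res$log2_or, coef(ref)[[2]] / log(2), tolerance = 1e-6)
})

test_that("beta regression ML fit matches glmmTMB on fixed effects", {
  skip_if_not_installed("glmmTMB")
  withr::with_seed(11, {
    n <- 80
    x <- runif(n, -1, 1)
    mu <- plogis(0.3 + 0.8 * x)
    phi <- 25
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
  })
  ours <- epiaccel:::.cpp_betareg_fit(y, cbind(1, x))
  ref <- glmmTMB::glmmTMB(y ~ x, family = glmmTMB::beta_family())
  expect_true(ours$converged)
  expect_equal(as.vector(ours$coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(ours$phi, exp(glmmTMB::fixef(ref)$disp[[1]]),
               tolerance = 1e-2)
})

test_that("beta correction is near-identity when levels ignore covariates", {
  md <- make_md(64, seed = 3)
  withr::with_seed(4, {
    y <- rbeta(64, 20, 20)  # centred at 0.5, independent of covariates
  })
  corr <- beta_correct(y, md)
  expect_equal(attr(corr, "method"), "beta")
  expect_lt(max(abs(corr - y)), 0.02)
})

test_that("beta correction removes a planted age signal", {
  md <- make_md(64, seed = 7)
  withr::with_seed(8, {
    mu <- plogis(-0.5 + 0.06 * md$age)
    y <- rbeta(64, mu * 60, (1 - mu) * 60)
  })
  corr <- beta_correct(y, md)
  expect_gt(abs(cor(y, md$age)), 0.5)      # signal present before
  expect_lt(abs(cor(corr, md$age)), 0.05)  # gone after
})

test_that("beta correction keeps constants, propagates NA, enforces bounds", {
  md <- make_md(20)
  corr <- beta_correct(rep(0.5, 20), md)
  expect_equal(as.vector(corr), rep(0.5, 20))
  y <- runif(20, 0.2, 0.8); y[c(3, 9)] <- NA
  corr2 <- beta_correct(y, md)
  expect_true(all(is.na(corr2[c(3, 9)])))
  expect_true(all(corr2 > 0 & corr2 < 1, na.rm = TRUE))
  expect_error(beta_correct(c(0.5, 0.5, NA), md[1:3, ]), "at least 10")
})

test_that("windows respect gaps, chromosome breaks, sd filter and size", {
  pos <- as.integer(seq(0, by = 100, length.out = 12))
  sds <- rep(0.2, 12)
  w <- build_windows(pos, sds)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start_idx, w$end_idx), c(1L, 12L))
  # a 600 bp gap splits 20 CpGs into two windows of 10
  pos2 <- as.integer(c(seq(0, by = 100, length.out = 10),
                       seq(1500, by = 100, length.out = 10)))
  w2 <- build_windows(pos2, rep(0.2, 20))
  expect_equal(nrow(w2), 2)
  expect_equal(w2$n_cpgs, c(10L, 10L))
  # 9 CpGs never form a window
  expect_equal(nrow(build_windows(pos[1:9], sds[1:9])), 0)
  # low-sd member breaks the run
  sds3 <- rep(0.2, 12); sds3[6] <- 0.05
  expect_equal(nrow(build_windows(pos, sds3)), 0)
  # chromosome change breaks the run even with close positions
  w4 <- build_windows(rep(pos2[1:10], 2)[1:20], rep(0.2, 20),
                      chrom = rep(c("a", "b"), each = 10))
  expect_equal(nrow(w4), 2)
})

# brute-force oracle: best sub-segment by exhaustive scan
oracle_best_segment <- function(d, min_cpgs, tol = 1e-9) {
  best <- c(NA, NA, 0)
  n <- length(d)
  for (i in seq_len(n - min_cpgs + 1)) {
    for (j in (i + min_cpgs - 1):n) {
      m <- mean(d[i:j])
      longer <- !is.na(best[1]) && (j - i) > (best[2] - best[1])
      if (abs(m) > abs(best[3]) + tol ||
          (abs(m) > abs(best[3]) - tol && (is.na(best[1]) || longer))) {
        best <- c(i, j, m)
      }
    }
  }
  best
}

test_that("segmentation equals the exhaustive oracle on planted signals", {
  # a 15-CpG stretch of d = 0.3 inside a 40-CpG window of zeros
  d <- rep(0, 40); d[13:27] <- 0.3
  seg <- segment_window(d)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start_idx, seg$end_idx), c(13L, 27L))
  orc <- oracle_best_segment(d, 10)
  expect_equal(c(seg$start_idx, seg$end_idx), as.integer(orc[1:2]))
  # constant shift: the whole window is one segment
  seg2 <- segment_window(rep(0.2, 25))
  expect_equal(nrow(seg2), 1)
  expect_equal(c(seg2$start_idx, seg2$end_idx), c(1L, 25L))
  # null signal: nothing
  expect_equal(nrow(segment_window(rep(0, 30))), 0)
})

test_that("segmentation top segment matches the oracle on random windows", {
  withr::with_seed(21, {
    for (rep in 1:15) {
      L <- sample(10:40, 1)
      d <- rnorm(L, 0, 0.08)
      if (runif(1) < 0.7) {
        a <- sample(seq_len(max(L - 10, 1)), 1)
        b <- min(L, a + sample(10:20, 1))
        d[a:b] <- d[a:b] + sample(c(-0.25, 0.25), 1)
      }
      seg <- segment_window(d)
      orc <- oracle_best_segment(d, 10)
      if (abs(orc[3]) <= 0.1) {
        expect_equal(nrow(seg), 0)
      } else {
        top <- seg[which.max(abs(seg$mean_diff)), ]
        expect_equal(c(top$start_idx, top$end_idx), as.integer(orc[1:2]))
        expect_equal(top$mean_diff, orc[3], tolerance = 1e-12)
      }
      # emitted segments are disjoint and all above threshold
      if (nrow(seg) > 1) {
        seg <- seg[order(seg$start_idx), ]
        expect_true(all(seg$start_idx[-1] > seg$end_idx[-nrow(seg)]))
      }
      expect_true(all(abs(seg$mean_diff) > 0.1))
    }
  })
})

test_that("Mann-Whitney exact p matches enumeration and wilcox.test", {
  r <- mwu_test(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
  expect_equal(r$U, 9)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  # identical groups are degenerate
  expect_equal(mwu_test(rep(1, 4), rep(1, 5))$p, 1)
  # random small samples: agree with wilcox.test exact (no ties)
  withr::with_seed(31, {
    for (i in 1:20) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      x <- rnorm(n1); y <- rnorm(n2)
      ours <- mwu_test(x, y)
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$U, unname(ref$statistic))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      # U agrees with brute-force pair counting
      u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
      expect_equal(ours$U, u_brute)
    }
  })
})

test_that("Mann-Whitney normal approximation matches wilcox.test with ties", {
  withr::with_seed(32, {
    for (i in 1:10) {
      x <- sample(seq(0, 1, 0.1), 15, replace = TRUE)
      y <- sample(seq(0, 1, 0.1), 12, replace = TRUE) + 0.05
      ours <- mwu_test(x, y)
      expect_equal(ours$method, "normal")
      ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                          correct = TRUE))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("BH correction equals a brute-force step-up on random inputs", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      js <- which(p[o] >= p[o][i])
      q[o[i]] <- min(m * p[o][js] / js)
    }
    pmin(q, 1)
  }
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04, 0.05))$q, rep(0.05, 5))
  expect_equal(bh_correct(0.2)$q, 0.2)
  expect_equal(bh_correct(rep(1, 4))$reject, rep(FALSE, 4))
  withr::with_seed(41, {
    for (i in 1:5) {
      p <- runif(sample(c(10, 100, 1000), 1))^2
      res <- bh_correct(p)
      expect_equal(res$q, brute_bh(p), tolerance = 1e-12)
      expect_equal(res$q, p.adjust(p, "BH"))
    }
  })
})

test_that("call_dmrs recovers planted regions and rejects nothing under the null", {
  sim <- small_dmr_cohort()
  md <- with_eaa(sim)
  dmrs <- call_dmrs(sim$methylome, md)
  sig <- dmrs[dmrs$significant, ]
  truth <- sim$truth$dmrs
  # every planted region is hit by a significant call
  hit <- vapply(seq_len(nrow(truth)), function(k) {
    any(sig$chrom == truth$chrom[k] & sig$start < truth$end[k] &
          sig$end > truth$start[k])
  }, logical(1))
  expect_equal(sum(hit), nrow(truth))
  # and every significant call overlaps a planted region (no false positives)
  fp <- vapply(seq_len(nrow(sig)), function(k) {
    !any(truth$chrom == sig$chrom[k] & truth$start < sig$end[k] &
           truth$end > sig$start[k])
  }, logical(1))
  expect_equal(sum(fp), 0)
  # directionality matches the planted sign
  for (k in seq_len(nrow(truth))) {
    ov <- sig[sig$chrom == truth$chrom[k] & sig$start < truth$end[k] &
                sig$end > truth$start[k], ]
    expect_true(all(ov$direction == truth$direction[k]))
  }

  null_dmrs <- call_dmrs(small_null_cohort()$methylome,
                         with_eaa(small_null_cohort()))
  expect_lte(sum(null_dmrs$significant), 1)
})

test_that("DMR BED export has the documented coordinate convention", {
  sim <- small_dmr_cohort()
  dmrs <- call_dmrs(sim$methylome, with_eaa(sim))
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, f)
  bed <- utils::read.table(f, sep = "\t")
  expect_equal(nrow(bed), sum(dmrs$significant))
  expect_true(all(bed$V3 > bed$V2))
  expect_true(all(bed$V7 >= 10))  # n_cpgs column
})

test_that("DMR annotation respects distance, promoter window and priority", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    start = c(10000L, 10000L, 40000L, 60000L),
    end = c(20000L, 12000L, 45000L, 61000L),
    strand = c("+", "+", "-", "+"),
    type = c("gene", "exon", "gene", "gene")
  )
  dmrs <- tibble::tibble(
    chrom = "chr1",
    start = c(3600L, 3400L, 9000L, 11500L, 15000L, 46600L),
    end   = c(3700L, 3500L, 9100L, 11600L, 15100L, 46700L)
  )
  ann <- annotate_dmrs(dmrs, genes, max_dist = 5000)
  # gene span of g1 includes promoter from 8500; DMR1 ends 3700: gap 4800 -> in
  expect_true(any(ann$dmr == 1 & ann$gene_id == "g1"))
  # DMR2 ends 3500: gap 5000 -> still in (<=); shift by 200 more would drop
  expect_true(any(ann$dmr == 2 & ann$gene_id == "g1"))
  # DMR at 9000 lies inside the promoter window (8500..10500)
  expect_equal(ann$feature[ann$dmr == 3 & ann$gene_id == "g1"], "promoter")
  # DMR at 11500 overlaps an exon
  expect_equal(ann$feature[ann$dmr == 4 & ann$gene_id == "g1"], "exon")
  # DMR at 15000 is intronic (inside gene body, no exon)
  expect_equal(ann$feature[ann$dmr == 5 & ann$gene_id == "g1"], "intron")
  # DMR 6 sits 100 bp beyond the promoter span of minus-strand g2: a flank
  # on the 5-prime (upstream) side, so the signed distance is negative
  g2 <- ann[ann$dmr == 6 & ann$gene_id == "g2", ]
  expect_equal(nrow(g2), 1)
  expect_equal(g2$feature, "flank")
  expect_equal(g2$distance, -100L)
  # no gene within 5 kb -> empty
  far <- annotate_dmrs(tibble::tibble(chrom = "chr1", start = 30000L,
                                      end = 30100L),
                       genes[genes$type == "gene" & genes$gene_id == "g3", ],
                       max_dist = 5000)
  expect_equal(nrow(far), 0)
})

test_that("unknown strand is treated as plus with a warning", {
  genes <- tibble::tibble(gene_id = "g", chrom = "c", start = 1000L,
                          end = 2000L, strand = "*", type = "gene")
  dmr <- tibble::tibble(chrom = "c", start = 100L, end = 200L)
  expect_warning(ann <- annotate_dmrs(dmr, genes), "strand")
  expect_equal(nrow(ann), 1)
})

test_that("annotation distances agree with a GenomicRanges computation", {
  skip_if_not_installed("GenomicRanges")
  withr::with_seed(61, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:15),
      chrom = sample(c("c1", "c2"), 15, replace = TRUE),
      start = as.integer(sort(sample(seq(1000, 2e5, by = 100), 15))),
      strand = sample(c("+", "-"), 15, replace = TRUE),
      type = "gene"
    )
    genes$end <- genes$start + sample(2000:8000, 15)
    dmrs <- tibble::tibble(
      chrom = sample(c("c1", "c2"), 25, replace = TRUE),
      start = as.integer(sample(seq(1, 2.2e5), 25))
    )
    dmrs$end <- dmrs$start + 300L
  })
  ann <- annotate_dmrs(dmrs, genes, max_dist = 5000)
  # reference: extended spans (gene body + strand-aware promoter) in GRanges
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  span_start <- pmin(genes$start,
                     ifelse(genes$strand == "+", tss - 1500L, tss - 499L))
  span_end <- pmax(genes$end,
                   ifelse(genes$strand == "+", tss + 500L, tss + 1501L))
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(span_start + 1L, span_end))
  d_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  dist <- GenomicRanges::distance(rep(d_gr, each = length(g_gr)),
                                  rep(g_gr, length(d_gr)))
  ref <- tibble::tibble(
    dmr = rep(seq_along(d_gr), each = length(g_gr)),
    gene_id = rep(genes$gene_id, length(d_gr)),
    ref_dist = dist
  )
  ref <- ref[!is.na(ref$ref_dist) & ref$ref_dist <= 5000, ]
  got <- dplyr::arrange(ann[c("dmr", "gene_id", "distance")],
                        .data$dmr, .data$gene_id)
  ref <- dplyr::arrange(ref, .data$dmr, .data$gene_id)
  expect_equal(got[c("dmr", "gene_id")], ref[c("dmr", "gene_id")])
  expect_equal(abs(got$distance), ref$ref_dist)
})
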