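test_that("mean shift pulls nearby midpoints into one region", {
  # midpoints 100, 110, 120 with bandwidth 50: every point sees all three,
  # so each converges to their joint mean 110 -> one region spanning all
  s <- interval_set(rep("chr1", 3), c(95, 105, 115), c(105, 115, 125))
  ss <- consolidate_meanshift(list(peaks = s), bandwidth = 50)
  expect_equal(nrow(ss$regions), 1)
  expect_equal(c(ss$regions$start, ss$regions$end), c(95, 125))

  far <- interval_set(rep("chr1", 2), c(95, 9995), c(105, 10005))
  expect_equal(nrow(consolidate_meanshift(list(far), 50)$regions), 2)

  single <- interval_set("chr1", 40, 60)
  one <- consolidate_meanshift(list(single), 50)
  expect_equal(as.data.frame(one$regions)[c("start", "end")],
               data.frame(start = 40, end = 60))
})

test_that("consolidation is invariant to input order and audits containment", {
  withr::with_seed(7, {
    mk <- function(n) {
      start <- sample.int(50000, n)
      interval_set(rep("chr1", n), start, start + sample.int(400, n, TRUE))
    }
    a <- mk(30); b <- mk(20); c3 <- mk(10)
    r1 <- consolidate_meanshift(list(a = a, b = b, c = c3), 500)
    r2 <- consolidate_meanshift(list(c = c3, a = a, b = b), 500)
    expect_equal(as.data.frame(r1$regions)[c("chrom", "start", "end")],
                 as.data.frame(r2$regions)[c("chrom", "start", "end")])

    # shuffling rows within a set changes nothing (sets are sorted anyway)
    a_shuf <- a[sample.int(nrow(a)), ]
    r3 <- consolidate_meanshift(list(a = as_interval_set(a_shuf), b = b, c = c3), 500)
    expect_equal(as.data.frame(r1$regions), as.data.frame(r3$regions))

    # every input peak contained in exactly one region
    all_peaks <- rbind(as.data.frame(a), as.data.frame(b), as.data.frame(c3))
    reg <- r1$regions
    for (i in seq_len(nrow(all_peaks))) {
      inside <- sum(reg$chrom == all_peaks$chrom[i] &
                      reg$start <= all_peaks$start[i] &
                      reg$end >= all_peaks$end[i])
      expect_gte(inside, 1)
    }
    expect_equal(length(r1$peak_region), nrow(all_peaks))
    # superset regions are non-overlapping
    expect_false(hushmap:::has_self_overlap(reg))
  })
})

test_that("size factors follow the median-of-ratios closed forms", {
  counts <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(compute_size_factors(counts)), c(1, 1))

  counts2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(unname(compute_size_factors(counts2)),
               c(1 / sqrt(2), sqrt(2)))

  # all-zero rows are excluded and do not change the factors
  counts3 <- rbind(counts2, c(0, 0))
  expect_equal(compute_size_factors(counts3), compute_size_factors(counts2))

  expect_error(compute_size_factors(cbind(c(0, 1), c(1, 0))),
               "pseudocount")
  expect_error(compute_size_factors(matrix(1, 3, 1)), ">= 2 samples")
})

test_that("nb_enrichment_test computes fold changes and calls as documented", {
  # identical IP and control: log2FC 0, no call
  counts <- cbind(ip1 = c(50, 100), ip2 = c(50, 100),
                  c1 = c(50, 100), c2 = c(50, 100))
  r <- nb_enrichment_test(counts, 1:2, 3:4, size_factors = rep(1, 4))
  expect_equal(r$log2fc, c(0, 0))
  expect_false(any(r$call))
  expect_true(all(r$q >= r$p))

  # IP mean 64 vs control mean 4 with unit factors: log2FC exactly 4
  withr::with_seed(2, {
    null_block <- matrix(rnbinom(400 * 4, mu = 60, size = 10), ncol = 4)
    counts2 <- rbind(c(64, 64, 4, 4), null_block)
    r2 <- nb_enrichment_test(counts2, 1:2, 3:4, size_factors = rep(1, 4))
    expect_equal(r2$log2fc[1], 4)
    expect_true(r2$call[1])
  })

  expect_error(nb_enrichment_test(counts, integer(0), 3:4), "at least one")
  expect_error(nb_enrichment_test(counts, 1:2, 3:4, alpha = 1.2), "alpha")
})

test_that("nb test p-values are calibrated under its own null", {
  # under the null the raw p-values should be close to uniform for the BH
  # step to control FDR; check the lower tail at two dispersions (the full
  # FDR simulation runs in the acceptance suite)
  withr::with_seed(33, {
    for (disp in c(0.05, 0.5)) {
      counts <- matrix(rnbinom(4000 * 4, mu = 80, size = 1 / disp), ncol = 4)
      r <- nb_enrichment_test(counts, 1:2, 3:4, alpha = 0.05,
                              size_factors = rep(1, 4))
      frac10 <- mean(r$p <= 0.10)
      # binomial sd at n = 4000 is ~0.005; allow approximation error too
      expect_gt(frac10, 0.05)
      expect_lt(frac10, 0.16)
    }
  })
})

test_that("classification labels follow the definition table", {
  g <- toy_genome()
  regions <- interval_set(rep("chr1", 4), c(0, 1000, 2000, 3000),
                          c(100, 1100, 2100, 3100),
                          name = sprintf("R%04d", 1:4))
  mpp8 <- interval_set(rep("chr1", 3), c(0, 1000, 2000), c(100, 1100, 2100))
  tasor <- interval_set(rep("chr1", 3), c(0, 1000, 3000), c(100, 1100, 3100))
  k9 <- data.frame(region = sprintf("R%04d", 1:4),
                   log2fc = c(3, 0, 3, 3), q = c(0.001, 0.9, 0.001, 0.001),
                   call = c(TRUE, FALSE, TRUE, TRUE))
  cls <- classify_regions(regions, mpp8, tasor, k9)
  expect_equal(as.character(cls$label),
               c("HUSH_K9POS", "HUSH_K9NEG", "MPP8_ONLY", "UNCLASSIFIED"))
  # partition: labels are exclusive and exhaustive
  expect_false(any(is.na(cls$label)))
  expect_equal(nrow(cls), 4)

  expect_error(classify_regions(regions, mpp8, tasor, k9[-2, ]),
               "without an H3K9me3 call")
})

test_that("PRO-seq orientation uses the plus >= minus tie rule", {
  g <- toy_genome()
  regions <- interval_set(rep("chr1", 3), c(1000, 3000, 5000),
                          c(1200, 3200, 5200))
  plus <- toy_track(c(rep(1100, 10), rep(5100, 5)))
  minus <- toy_track(c(rep(1100, 2), rep(3100, 7), rep(5100, 5)))
  out <- orient_by_proseq(regions, plus, minus, window = 1000)
  expect_equal(out$strand, c("+", "-", "+")) # last is the 5 vs 5 tie
  expect_equal(out$proseq_plus_tags, c(10, 0, 5))
  expect_equal(out$proseq_minus_tags, c(2, 7, 5))
})
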