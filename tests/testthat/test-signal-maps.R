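oriented <- function(chrom, start, end, strand, name = NULL) {
  if (is.null(name)) name <- sprintf("R%04d", seq_along(start))
  interval_set(chrom, start, end, name = name, strand = strand)
}

test_that("heatmap bins tags by oriented distance and scales per million", {
  # '+' region centered at 1000, tag at 1010 -> bin covering +10
  reg <- oriented("chr1", 900, 1100, "+")
  tr <- toy_track(1010, total_aligned = 1e6)
  h <- build_heatmap(tr, reg, half_width = 100, bin_size = 20)
  expect_equal(ncol(h$values), 10)
  expect_equal(sum(h$values), 1)
  expect_equal(unname(h$values[1, h$bin_centers == 10]), 1)

  # same tag, '-' region: lands in the bin covering -10
  regm <- oriented("chr1", 900, 1100, "-")
  hm <- build_heatmap(tr, regm, half_width = 100, bin_size = 20)
  expect_equal(unname(hm$values[1, hm$bin_centers == -10]), 1)

  # scaling: total 2e6 and 4 tags in one bin -> 2.0
  tr4 <- toy_track(rep(1010, 4), total_aligned = 2e6)
  h4 <- build_heatmap(tr4, reg, half_width = 100, bin_size = 20)
  expect_equal(max(h4$values), 2)

  expect_error(build_heatmap(tr, reg, half_width = 100, bin_size = 30),
               "divide")
})

test_that("heatmap mass conservation and scaling linearity hold exactly", {
  withr::with_seed(14, {
    reg <- oriented(rep("chr1", 3), c(2000, 30000, 60000),
                    c(2600, 30600, 60600), c("+", "-", "+"))
    pos <- sample.int(9e4, 3000) - 1
    tr <- toy_track(pos, total_aligned = 5e6)
    h <- build_heatmap(tr, reg, half_width = 1000, bin_size = 50,
                       genome = toy_genome())
    # raw counts sum to the tags falling inside the (disjoint) windows
    centers <- floor((reg$start + reg$end) / 2)
    inside <- sum(vapply(seq_len(3), function(i) {
      if (reg$strand[i] == "+")
        sum(pos >= centers[i] - 1000 & pos < centers[i] + 1000)
      else sum(pos > centers[i] - 1000 & pos <= centers[i] + 1000)
    }, 0))
    expect_equal(sum(raw_counts(h)), inside)

    # doubling total_aligned halves every value
    tr2 <- toy_track(pos, total_aligned = 1e7)
    h2 <- build_heatmap(tr2, reg, half_width = 1000, bin_size = 50,
                        genome = toy_genome())
    expect_equal(h2$values, h$values / 2)

    # flipping all strands twice reproduces the matrix
    flip <- function(r) { r$strand <- ifelse(r$strand == "+", "-", "+"); r }
    h3 <- build_heatmap(tr, flip(flip(reg)), half_width = 1000, bin_size = 50,
                        genome = toy_genome())
    expect_equal(h3$values, h$values)
  })
})

test_that("windows beyond chromosome bounds yield NA bins, not zeros", {
  g <- toy_genome()
  reg <- oriented("chr2", 100, 300, "+") # center 200, window +/-1000
  tr <- tag_track("chr2", 150, genome = g)
  h <- build_heatmap(tr, reg, half_width = 1000, bin_size = 100, genome = g)
  expect_true(any(is.na(h$values)))
  expect_true(all(is.na(h$values[1, h$bin_centers < -200 + 50])))
  expect_false(anyNA(h$values[1, h$bin_centers > 0]))
})

test_that("rows sort into class blocks by central signal with id ties", {
  reg <- oriented(rep("chr1", 4), c(1000, 3000, 5000, 7000),
                  c(1400, 3400, 5400, 7400), "+",
                  name = c("R0001", "R0002", "R0003", "R0004"))
  mk <- function(vals) {
    tr <- tag_track(rep("chr1", 0), numeric(0), total_aligned = 1e6)
    h <- build_heatmap(tr, reg, half_width = 2000, bin_size = 100)
    h$values[] <- 0
    central <- abs(h$bin_centers) <= 1000
    for (i in seq_len(4)) h$values[i, central] <- vals[i]
    h
  }
  classes <- data.frame(
    chrom = reg$chrom, start = reg$start, end = reg$end,
    region_id = reg$name,
    label = factor(c("HUSH_K9NEG", "HUSH_K9POS", "HUSH_K9POS", "MPP8_ONLY"),
                   levels = hushmap:::HUSH_CLASSES),
    stringsAsFactors = FALSE)
  class(classes) <- c("region_classification", "data.frame")
  k9 <- mk(c(1, 3, 5, 1)); mpp8 <- mk(c(1, 1, 1, 1)); tasor <- mk(c(0, 0, 0, 0))
  ord <- sort_by_class(classes, k9, mpp8, tasor)
  # blocks: K9POS rows (descending central K9: R0003 then R0002),
  # then K9NEG (R0001), then MPP8_ONLY (R0004)
  expect_equal(classes$region_id[ord], c("R0003", "R0002", "R0001", "R0004"))

  # identical signals: region-id order within the block
  k9t <- mk(c(1, 2, 2, 1))
  ordt <- sort_by_class(classes, k9t, mpp8, tasor)
  expect_equal(classes$region_id[ordt][1:2], c("R0002", "R0003"))
})

test_that("aggregate profiles reproduce rows and the per-billion unit", {
  reg <- oriented(rep("chr1", 2), c(1000, 5000), c(1400, 5400), "+")
  tr <- tag_track(rep("chr1", 4), c(rep(1200, 2), rep(5200, 2)),
                  total_aligned = 1e9)
  h <- build_heatmap(tr, reg, half_width = 100, bin_size = 10)
  # identical rows: mean and median profiles equal any row
  p <- aggregate_profile(h, "mean")
  expect_equal(p$value, unname(h$values[1, ]))
  pm <- aggregate_profile(h, "median")
  expect_equal(pm$value, unname(h$values[1, ]))

  # 2 regions, bin 10, 4 raw tags per bin at center, total 1e9 -> 0.2
  pb <- aggregate_profile(h, "mean", "per_billion_per_base_per_region")
  expect_equal(max(pb$value), 4 / (2 * 10))
})

test_that("bootstrap bands are deterministic, tight on constants, calibrated", {
  M <- matrix(3, nrow = 20, ncol = 6)
  b <- bootstrap_band(M, n_boot = 50, seed = 4)
  expect_equal(b$lower, rep(3, 6))
  expect_equal(b$upper, rep(3, 6))

  withr::with_seed(8, M2 <- matrix(rnorm(40 * 8, 2), 40, 8))
  b1 <- bootstrap_band(M2, n_boot = 100, seed = 9)
  b2 <- bootstrap_band(M2, n_boot = 100, seed = 9)
  expect_equal(b1, b2)
  expect_true(all(b1$lower <= b1$value & b1$value <= b1$upper))

  # n_boot = 1: both band edges equal the single resample's profile
  b3 <- bootstrap_band(M2, n_boot = 1, seed = 10)
  expect_equal(b3$lower, b3$upper)

  # median statistic path agrees with a direct resample computation
  idx <- withr::with_seed(11, matrix(sample.int(40, 40, TRUE), nrow = 1))
  b4 <- bootstrap_band(M2, n_boot = 1, stat = "median", seed = 11)
  expect_equal(b4$lower, unname(apply(M2[idx[1, ], ], 2, median)))
})

test_that("unit_scale is an idempotent, scale-invariant affine map", {
  p <- hushmap:::new_profile(c(-1, 0, 1), c(2, 4, 6))
  u <- unit_scale(p)
  expect_equal(u$value, c(0, 0.5, 1))
  expect_equal(unit_scale(u)$value, u$value)
  p10 <- p; p10$value <- p$value * 10
  expect_equal(unit_scale(p10)$value, u$value)
  pc <- hushmap:::new_profile(1:3, rep(5, 3))
  expect_error(unit_scale(pc), "constant")
})

test_that("differential matrices subtract elementwise and commute with aggregation", {
  withr::with_seed(21, {
    reg <- oriented(rep("chr1", 5), seq(5000, 45000, 10000),
                    seq(5400, 45400, 10000), sample(c("+", "-"), 5, TRUE))
    tr_a <- toy_track(sample.int(9e4, 4000) - 1, total_aligned = 1e6)
    tr_b <- toy_track(sample.int(9e4, 2500) - 1, total_aligned = 2e6)
    a <- build_heatmap(tr_a, reg, 1000, 50)
    b <- build_heatmap(tr_b, reg, 1000, 50)
    d <- differential_matrix(a, b)
    expect_equal(d$values, a$values - b$values)
    expect_equal(differential_matrix(a, a)$values, a$values * 0)
    # aggregate(mean) commutes with subtraction
    expect_equal(aggregate_profile(d, "mean")$value,
                 aggregate_profile(a, "mean")$value -
                   aggregate_profile(b, "mean")$value)
    bad <- build_heatmap(tr_b, reg, 1000, 100)
    expect_error(differential_matrix(a, bad), "geometr")
  })
})

test_that("centroid_shift recovers translations and degenerates safely", {
  x <- seq(-975, 975, by = 50)
  peak <- function(mu) exp(-(x - mu)^2 / (2 * 150^2))
  wt <- hushmap:::new_profile(x, peak(0))
  ko <- hushmap:::new_profile(x, peak(200))
  expect_lt(abs(centroid_shift(wt, ko) - 200), 25)
  expect_equal(centroid_shift(wt, wt), 0)
  flat <- hushmap:::new_profile(x, rep(1, length(x)))
  expect_error(centroid_shift(flat, flat), "mass")
  wt2 <- hushmap:::new_profile(seq(-495, 495, 10), peak(0)[1:100])
  expect_error(centroid_shift(wt, wt2), "share bins")
})

test_that("readthrough index follows the pseudocount arithmetic", {
  g <- toy_genome()
  tts <- interval_set("chr1", 10000, 10001, strand = "+")
  # 100 sense tags in the body window (8001..10000), none downstream -> 1/101
  up <- tag_track(rep("chr1", 100),
                  withr::with_seed(3, sample(8001:10000, 100, TRUE)), "+",
                  genome = g)
  expect_equal(readthrough_index(up, tts), 1 / 101)
  # symmetric signal k/k -> 1
  both <- tag_track(rep("chr1", 40), c(rep(9500, 20), rep(10500, 20)), "+",
                    genome = g)
  expect_equal(readthrough_index(both, tts), 1)
  # '-' terminator: downstream means decreasing coordinates
  ttsm <- interval_set("chr1", 10000, 10001, strand = "-")
  dn <- tag_track(rep("chr1", 10), rep(9000, 10), "-", genome = g)
  expect_equal(readthrough_index(dn, ttsm), 11 / 1)
  expect_error(readthrough_index(up, interval_set("chr1", 1, 2)), "stranded")
})

test_that("heatmap and profile TSV exports carry the header block", {
  reg <- oriented("chr1", 900, 1100, "+")
  tr <- toy_track(1010, total_aligned = 1e6)
  h <- build_heatmap(tr, reg, half_width = 100, bin_size = 20)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_heatmap_tsv(h, p1)
  tab <- read.delim(p1, check.names = FALSE)
  expect_equal(names(tab)[1:5], c("region_id", "chrom", "start", "end", "strand"))
  expect_equal(ncol(tab), 5 + 10)
  write_profile_tsv(bootstrap_band(h, 10, seed = 1), p2)
  expect_equal(names(read.delim(p2)),
               c("bin_center", "value", "lower", "upper"))
})
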