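mk_annot <- function(chrom, start, end, category, strand = "*") {
  annotation_track(interval_set(chrom, start, end, strand = strand),
                   category = category)
}

test_that("presence matrix marks exactly the overlapped bins", {
  reg <- interval_set("chr1", 9000, 11000, name = "R0001", strand = "+")
  ctr <- 10000
  ann <- mk_annot("chr1", ctr + 100, ctr + 300, "L1like")
  h <- presence_matrix(ann, reg, half_width = 500, bin_size = 50,
                       category = "L1like")
  on_bins <- h$bin_centers[h$values[1, ] == 1]
  expect_equal(range(on_bins), c(125, 275)) # bins covering [+100, +300)
  expect_true(all(h$values %in% c(0, 1)))

  # repeat spanning the center lights the central bins; none -> all zero
  ann2 <- mk_annot("chr1", ctr - 60, ctr + 60, "L1like")
  h2 <- presence_matrix(ann2, reg, 500, 50, "L1like")
  expect_equal(unname(h2$values[1, h2$bin_centers == 25]), 1)
  h3 <- presence_matrix(mk_annot("chr1", 50000, 50100, "L1like"),
                        reg, 500, 50, "L1like")
  expect_equal(sum(h3$values), 0)

  expect_error(presence_matrix(ann, reg, 500, 50, "Alu"), "vocabulary")
})

test_that("presence matrix orientation mirrors the signal heatmaps", {
  regm <- interval_set("chr1", 9000, 11000, name = "R0001", strand = "-")
  ann <- mk_annot("chr1", 10100, 10300, "L1like")
  h <- presence_matrix(ann, regm, 500, 50, "L1like")
  on_bins <- h$bin_centers[h$values[1, ] == 1]
  expect_true(all(on_bins < 0)) # downstream in genome = upstream in sense
})

test_that("presence of a union equals elementwise OR of the parts", {
  withr::with_seed(19, {
    reg <- interval_set(rep("chr1", 3), c(10000, 40000, 70000),
                        c(11000, 41000, 71000),
                        name = sprintf("R%04d", 1:3), strand = "+")
    s1 <- sort(sample.int(9e4, 6))
    s2 <- sort(sample.int(9e4, 6))
    a <- mk_annot(rep("chr1", 6), s1, s1 + 200, "fam1")
    b <- mk_annot(rep("chr1", 6), s2, s2 + 200, "fam2")
    both <- annotation_track(
      interval_set(rep("chr1", 12), c(s1, s2), c(s1, s2) + 200),
      category = "union")
    ha <- presence_matrix(a, reg, 2000, 100, "fam1")
    hb <- presence_matrix(b, reg, 2000, 100, "fam2")
    hu <- presence_matrix(both, reg, 2000, 100, "union")
    expect_equal(hu$values, pmax(ha$values, hb$values))
  })
})

mk_classes <- function(labels, start) {
  df <- data.frame(chrom = "chr1", start = start, end = start + 200,
                   region_id = sprintf("R%04d", seq_along(start)),
                   label = factor(labels, levels = hushmap:::HUSH_CLASSES),
                   strand = "+", stringsAsFactors = FALSE)
  class(df) <- c("region_classification", "data.frame")
  df
}

test_that("class/category enrichment reproduces hand-built 2x2 tables", {
  start <- seq(1000, 20000, by = 1000)[1:20]
  cls <- mk_classes(rep(c("HUSH_K9POS", "HUSH_K9NEG"), each = 10), start)
  # category hits 8/10 of class A but 1/10 of class B -> OR = (8*9)/(2*1)
  hit_idx <- c(1:8, 11)
  ann <- mk_annot(rep("chr1", 9), start[hit_idx] + 50, start[hit_idx] + 100,
                  rep("fam", 9))
  r <- class_category_enrichment(cls, ann, "HUSH_K9POS", "HUSH_K9NEG")
  expect_equal(r$odds_ratio, (8 * 9) / (2 * 1))
  expect_equal(c(r$a_overlap, r$b_overlap), c(8, 1))

  # swapped classes invert the odds ratio
  r2 <- class_category_enrichment(cls, ann, "HUSH_K9NEG", "HUSH_K9POS")
  expect_equal(r2$odds_ratio, 1 / r$odds_ratio)
  expect_equal(r2$p, r$p)

  expect_error(class_category_enrichment(cls, ann, "HUSH_K9POS", "MPP8_ONLY"),
               "non-empty")
})

test_that("degenerate and symmetric enrichment tables use the conventions", {
  start <- seq(1000, 20000, by = 1000)[1:20]
  cls <- mk_classes(rep(c("HUSH_K9POS", "HUSH_K9NEG"), each = 10), start)
  far <- mk_annot("chr1", 90000, 90100, "absent")
  r <- class_category_enrichment(cls, far, "HUSH_K9POS", "HUSH_K9NEG")
  expect_equal(c(r$odds_ratio, r$p, r$q), c(1, 1, 1))

  # same regions on both sides: OR 1, p 1 for every category
  cls_same <- mk_classes(rep(c("HUSH_K9POS", "HUSH_K9NEG"), 10), start)
  both <- mk_annot(rep("chr1", 4), start[c(1, 2, 5, 6)] + 10,
                   start[c(1, 2, 5, 6)] + 60, rep("fam", 4))
  # construct identical membership by mirroring labels pairwise
  rs <- class_category_enrichment(cls_same, both, "HUSH_K9POS", "HUSH_K9NEG")
  expect_equal(rs$odds_ratio, 1)
  expect_equal(rs$p, 1)
})

test_that("trinucleotide densities count overlapping windows strand-awarely", {
  seqs <- Biostrings::DNAStringSet(c(chrA = "AAAAAACGTGCATGCA"))
  reg <- interval_set("chrA", 0, 6, strand = "+")   # "AAAAAA"
  d <- hushmap:::pooled_trinuc_density(seqs, reg)
  expect_equal(unname(d["AAA"] * (6 - 2)), 4) # 4 overlapping windows

  # reverse complement symmetry: density on '-' equals revcomp density
  regm <- interval_set("chrA", 6, 16, strand = "-")
  regp <- interval_set("chrA", 6, 16, strand = "+")
  dm <- hushmap:::pooled_trinuc_density(seqs, regm)
  dp <- hushmap:::pooled_trinuc_density(seqs, regp)
  revcomp_name <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  for (tri in c("ACG", "TGC", "AAA", "CAT"))
    expect_equal(unname(dm[tri]), unname(dp[revcomp_name(tri)]))

  # class identical to background -> ratio 1 everywhere observed
  r <- trinucleotide_enrichment(seqs, list(k9pos = regp), regp)
  obs <- r$ratio[!is.na(r$ratio[, 1]), 1]
  expect_true(all(obs == 1))

  expect_error(trinucleotide_enrichment(seqs, list(a = reg),
                                        interval_set("chrB", 0, 5)),
               "no sequence")
})

test_that("N bases void their trinucleotide windows", {
  seqs <- Biostrings::DNAStringSet(c(chrA = "AANAAA"))
  d <- hushmap:::pooled_trinuc_density(seqs, interval_set("chrA", 0, 6))
  expect_equal(unname(d["AAA"] * 4), 1) # only the final window counts
})

test_that("feature overlap fraction applies slop monotonically", {
  reg <- interval_set(rep("chr1", 4), c(1000, 2000, 3000, 4000),
                      c(1100, 2100, 3100, 4100))
  feats <- mk_annot(rep("chr1", 3), c(1010, 2150, 3500), c(1020, 2160, 3510),
                    rep("TTS", 3))
  expect_equal(as.numeric(feature_overlap_fraction(reg, feats, "TTS")), 1 / 4)
  f100 <- feature_overlap_fraction(reg, feats, "TTS", slop = 100)
  expect_equal(as.numeric(f100), 2 / 4)
  # monotone in slop
  fr <- vapply(c(0, 50, 100, 400, 1000), function(s)
    as.numeric(feature_overlap_fraction(reg, feats, "TTS", slop = s)), 0)
  expect_true(all(diff(fr) >= 0))
  empty <- annotation_track(interval_set("chr1", 1, 2), category = "x")
  expect_equal(as.numeric(feature_overlap_fraction(reg, empty, "TTS")), 0)
})

test_that("gene anchors deduplicate and meta profiles orient by strand", {
  g <- toy_genome()
  genes <- interval_set(rep("chr1", 3), c(10000, 10000, 30000),
                        c(20000, 20000, 40000),
                        name = c("g1", "g2", "g3"), strand = c("+", "+", "-"))
  tss <- gene_anchors(genes, "TSS")
  expect_equal(nrow(tss), 2) # shared TSS collapses
  expect_equal(tss$start, c(10000, 39999))

  tts <- gene_anchors(genes, "TTS")
  expect_equal(tts$start, c(19999, 30000))

  # '+' gene, tag at TSS+100 -> +100 in the TSS profile; '-' gene mirror
  tr <- tag_track(c("chr1", "chr1"), c(10100, 39899), genome = g)
  p <- meta_feature_profiles(tr, genes, "TSS", half_width = 500,
                             bin_size = 50, n_boot = 10, seed = 1, genome = g)
  expect_equal(sum(p$value > 0), 1)
  expect_equal(p$bin_center[p$value > 0], 125)

  expect_error(gene_anchors(interval_set("chr1", 1, 10)), "stranded")
})
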