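# shared in-code fixtures

toy_genome <- function() hush_genome(c(chr1 = 1e5, chr2 = 5e4))

# a small track from explicit positions
toy_track <- function(pos, strand = "+", chrom = "chr1", total_aligned = NULL,
                      genome = toy_genome()) {
  tag_track(rep_len(chrom, length(pos)), pos, strand,
            total_aligned = total_aligned, genome = genome)
}

# random merged interval set for property tests
random_merged_set <- function(n, genome_len = 10000, max_w = 400) {
  start <- sort(sample.int(genome_len - max_w, n))
  end <- pmin(start + sample.int(max_w, n, replace = TRUE), genome_len)
  merge_intervals(interval_set(rep("chr1", n), start, end))
}

# brute-force construction of the overlap fisher table: direct pairwise
# sweeps, independent of the package's findOverlaps-based path
brute_fisher_table <- function(a, b, genome) {
  pairs <- 0L
  a_hit <- logical(nrow(a)); b_hit <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        pairs <- pairs + 1L
        a_hit[i] <- TRUE; b_hit[j] <- TRUE
      }
    }
  }
  n11 <- pairs
  n12 <- sum(!a_hit)
  n21 <- sum(!b_hit)
  slots <- floor(genome_size(genome) /
                   (mean(a$end - a$start) + mean(b$end - b$start)))
  n22 <- max(0, slots - n11 - n12 - n21)
  c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
}

# tiny synthetic configuration for fast end-to-end tests
tiny_config <- function(seed = 1, ...) {
  synthetic_config(
    seed = seed,
    chrom_lengths = c(chrS1 = 4e5, chrS2 = 3e5),
    n_regions = c(HUSH_K9POS = 8, HUSH_K9NEG = 12, MPP8_ONLY = 8),
    min_gap = 11000,
    n_background_genes = 5,
    ...)
}
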