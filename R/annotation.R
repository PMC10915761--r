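#' Construct an annotation track
#'
#' An interval set in which every interval carries exactly one category
#' label (repeat family, exon, TSS, TTS, ...), stored in the `category`
#' column. The category vocabulary is the set of observed labels.
#'
#' @param intervals An [interval_set()] (its `name` column is used as the
#'   category when `category` is missing).
#' @param category Optional character vector of per-interval categories.
#' @return An `annotation_track` (an `interval_set` with a `category`
#'   column).
#' @export
annotation_track <- function(intervals, category = NULL) {
  stopifnot(inherits(intervals, "interval_set"))
  if (is.null(category)) category <- intervals$name
  category <- rep_len(as.character(category), nrow(intervals))
  if (nrow(intervals) > 0 && any(is.na(category) | !nzchar(category)))
    stop("every annotation interval must carry a category")
  intervals$category <- category
  class(intervals) <- c("annotation_track", class(intervals))
  intervals
}

#' Categories present in an annotation track
#' @param annot An [annotation_track()].
#' @export
annotation_categories <- function(annot) sort(unique(annot$category))

check_category <- function(annot, category) {
  vocab <- annotation_categories(annot)
  bad <- setdiff(category, vocab)
  if (length(bad))
    stop("unknown category '", bad[1], "'; vocabulary: ",
         paste(vocab, collapse = ", "))
  invisible(category)
}

#' Binary presence matrix of an annotation category around regions
#'
#' Same geometry and orientation rules as [build_heatmap()], but each bin is
#' 1 if at least one annotated bp of the category overlaps the bin's genomic
#' footprint and 0 otherwise.
#'
#' @param annot An [annotation_track()].
#' @param regions Oriented [interval_set()].
#' @param half_width,bin_size As in [build_heatmap()].
#' @param category Category to test (must be in the vocabulary).
#' @param genome Optional [hush_genome()] for boundary clipping.
#' @return A binary `hush_heatmap` (with `total_aligned = NA`).
#' @export
presence_matrix <- function(annot, regions, half_width = 5000, bin_size = 50,
                            category, genome = NULL) {
  stopifnot(inherits(annot, "annotation_track"))
  check_category(annot, category)
  if ((2 * half_width) %% bin_size != 0)
    stop("bin_size must divide 2 * half_width exactly")
  sub <- annot[annot$category == category, , drop = FALSE]
  n_bins <- as.integer(2 * half_width / bin_size)
  edges <- seq(-half_width, half_width, by = bin_size)
  centers <- interval_centers(regions)
  strand <- regions$strand
  strand[strand == "*"] <- "+"
  n <- nrow(regions)
  vals <- matrix(0, n, n_bins, dimnames = list(region_ids(regions), NULL))
  win <- data.frame(chrom = regions$chrom,
                    start = pmax(0, centers - half_width),
                    end = centers + half_width)
  hits <- overlap_hits(win, sub)
  for (k in seq_len(nrow(hits))) {
    i <- hits$a[k]; j <- hits$b[k]
    if (strand[i] == "+") {
      lo <- sub$start[j] - centers[i]
      hi <- sub$end[j] - centers[i]
    } else {
      lo <- centers[i] - sub$end[j] + 1
      hi <- centers[i] - sub$start[j] + 1
    }
    b1 <- max(1L, as.integer(floor((lo + half_width) / bin_size)) + 1L)
    b2 <- min(n_bins, as.integer(ceiling((hi + half_width) / bin_size)))
    if (b2 >= b1) vals[i, b1:b2] <- 1
  }
  if (!is.null(genome)) {
    for (i in seq_len(n)) {
      len <- unclass(genome)[[regions$chrom[i]]]
      if (strand[i] == "+") {
        glo <- centers[i] + edges[-length(edges)]
        ghi <- centers[i] + edges[-1]
      } else {
        glo <- centers[i] - edges[-1] + 1
        ghi <- centers[i] - edges[-length(edges)] + 1
      }
      vals[i, glo < 0 | ghi > len] <- NA
    }
  }
  structure(list(values = vals, regions = regions, bin_edges = edges,
                 bin_centers = edges[-length(edges)] + bin_size / 2,
                 half_width = half_width, bin_size = bin_size,
                 total_aligned = NA_real_, track_id = paste0("presence:", category)),
            class = "hush_heatmap")
}

#' Category enrichment between two region classes
#'
#' For every annotation category, a 2x2 Fisher exact test on the per-region
#' overlap indicator between two classes. The odds ratio is the sample odds
#' ratio of the 2x2 table; degenerate tables (the category overlaps no
#' region, or every region, in both classes) are reported as odds ratio 1
#' with p = 1. P-values are BH-adjusted across categories.
#'
#' @param classes A `region_classification`.
#' @param annot An [annotation_track()].
#' @param class_a,class_b Class labels to compare (non-empty in `classes`).
#' @return data.frame with one row per category: counts, `odds_ratio`, `p`,
#'   `q`.
#' @export
class_category_enrichment <- function(classes, annot, class_a, class_b) {
  ra <- classes[classes$label == class_a, , drop = FALSE]
  rb <- classes[classes$label == class_b, , drop = FALSE]
  if (nrow(ra) == 0 || nrow(rb) == 0)
    stop("both classes must be non-empty (", class_a, ": ", nrow(ra),
         ", ", class_b, ": ", nrow(rb), ")")
  cats <- annotation_categories(annot)
  res <- lapply(cats, function(cc) {
    sub <- annot[annot$category == cc, , drop = FALSE]
    a_ov <- sum(overlaps_any(ra, sub))
    b_ov <- sum(overlaps_any(rb, sub))
    n11 <- a_ov; n12 <- nrow(ra) - a_ov
    n21 <- b_ov; n22 <- nrow(rb) - b_ov
    degenerate <- (n11 == 0 && n21 == 0) || (n12 == 0 && n22 == 0)
    if (degenerate) {
      or <- 1; p <- 1
    } else {
      or <- odds_ratio_2x2(n11, n12, n21, n22)
      p <- stats::fisher.test(matrix(c(n11, n12, n21, n22), 2, byrow = TRUE))$p.value
    }
    data.frame(category = cc, a_overlap = n11, a_total = nrow(ra),
               b_overlap = n21, b_total = nrow(rb),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Trinucleotide density ratios between region classes and background
#'
#' Counts overlapping trinucleotide windows in the sequence of each region
#' (reverse-complemented for `-` regions), pools counts per class, and
#' reports the pooled density (count per available window,
#' `region length - 2`) relative to the same density over a background
#' region set. Windows containing ambiguous bases are not counted.
#'
#' @param seqs A [Biostrings::DNAStringSet] named by chromosome.
#' @param regions_by_class Named list of [interval_set()]s (one per class).
#' @param background An [interval_set()] of background regions.
#' @param trinucleotides Optional subset of the 64 trinucleotides.
#' @return A list with `density` (trinucleotide x class matrix, background
#'   in the last column) and `ratio` (class densities / background density).
#' @export
trinucleotide_enrichment <- function(seqs, regions_by_class, background,
                                     trinucleotides = NULL) {
  stopifnot(methods::is(seqs, "DNAStringSet"), is.list(regions_by_class))
  groups <- c(regions_by_class, list(.background = background))
  dens <- vapply(groups, function(rg) pooled_trinuc_density(seqs, rg),
                 numeric(64))
  if (!is.null(trinucleotides)) {
    miss <- setdiff(trinucleotides, rownames(dens))
    if (length(miss)) stop("not trinucleotides: ", paste(miss, collapse = ", "))
    dens <- dens[trinucleotides, , drop = FALSE]
  }
  bg <- dens[, ".background"]
  ratio <- sweep(dens[, setdiff(colnames(dens), ".background"), drop = FALSE],
                 1, ifelse(bg > 0, bg, NA_real_), "/")
  list(density = dens, ratio = ratio)
}

pooled_trinuc_density <- function(seqs, regions) {
  stopifnot(inherits(regions, "interval_set"), nrow(regions) > 0)
  bad <- !regions$chrom %in% names(seqs)
  if (any(bad))
    stop("no sequence for chromosome(s): ",
         paste(unique(regions$chrom[bad]), collapse = ", "))
  if (any(regions$end > Biostrings::width(seqs)[match(regions$chrom, names(seqs))]))
    stop("region extends beyond the available sequence")
  ss <- Biostrings::DNAStringSet(lapply(seq_len(nrow(regions)), function(i)
    Biostrings::subseq(seqs[[regions$chrom[i]]],
                       start = regions$start[i] + 1, end = regions$end[i])))
  minus <- regions$strand == "-"
  if (any(minus)) ss[minus] <- Biostrings::reverseComplement(ss[minus])
  counts <- colSums(Biostrings::oligonucleotideFrequency(ss, width = 3, step = 1))
  windows <- sum(pmax(regions$end - regions$start - 2, 0))
  if (windows == 0) stop("all regions shorter than 3 bp")
  counts / windows
}

#' Fraction of regions overlapping a feature category
#'
#' Fraction of regions with >= 1 bp overlap to any interval of the given
#' category after extending the features by `slop` bp on each side
#' (monotone non-decreasing in `slop`).
#'
#' @param regions An [interval_set()].
#' @param features An [annotation_track()].
#' @param category Category to test.
#' @param slop Symmetric feature extension in bp (default 0).
#' @return Fraction in [0, 1]; attribute `n_overlap` carries the count.
#' @export
feature_overlap_fraction <- function(regions, features, category, slop = 0) {
  stopifnot(slop >= 0, nrow(regions) > 0)
  sub <- features[features$category == category, , drop = FALSE]
  if (nrow(sub) == 0) return(structure(0, n_overlap = 0L))
  class(sub) <- c("interval_set", "data.frame")
  if (slop > 0) sub <- slop_intervals(sub, slop)
  hit <- overlaps_any(regions, sub)
  structure(sum(hit) / nrow(regions), n_overlap = sum(hit))
}

#' Anchor coordinates of gene models
#'
#' TSS, midpoint and TTS anchors of stranded gene intervals, as 1-bp
#' oriented intervals. For a `+` gene the TSS is the first base and the TTS
#' the last base; reversed for `-` genes.
#'
#' @param genes Stranded [interval_set()] of gene bodies.
#' @param anchor One of `"TSS"`, `"midpoint"`, `"TTS"`.
#' @param unique_anchors Collapse genes sharing identical anchor
#'   coordinates (and strand) to one anchor (default TRUE).
#' @return An [interval_set()] of 1-bp anchors carrying the gene strand.
#' @export
gene_anchors <- function(genes, anchor = c("TSS", "midpoint", "TTS"),
                         unique_anchors = TRUE) {
  anchor <- match.arg(anchor)
  if (any(genes$strand == "*")) stop("gene models must be stranded")
  plus <- genes$strand == "+"
  pos <- switch(anchor,
    TSS = ifelse(plus, genes$start, genes$end - 1),
    midpoint = interval_centers(genes),
    TTS = ifelse(plus, genes$end - 1, genes$start))
  df <- data.frame(chrom = genes$chrom, pos = pos, strand = genes$strand,
                   name = genes$name, stringsAsFactors = FALSE)
  if (unique_anchors)
    df <- df[!duplicated(df[c("chrom", "pos", "strand")]), , drop = FALSE]
  interval_set(df$chrom, df$pos, df$pos + 1, name = df$name, strand = df$strand)
}

#' Meta-profiles of coverage around gene feature anchors
#'
#' Windows are centered on the deduplicated TSS, midpoint or TTS anchors of
#' the gene models, oriented by gene strand, and summarized with
#' [build_heatmap()] + [bootstrap_band()] under the
#' `per_billion_per_base_per_region` normalization.
#'
#' @param track A [tag_track()].
#' @param genes Stranded [interval_set()] of gene bodies.
#' @param anchor `"TSS"`, `"midpoint"` or `"TTS"`.
#' @param half_width,bin_size Window geometry (defaults 5000 / 50).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param stat Center statistic (default `"median"`).
#' @param seed Bootstrap seed.
#' @param strand_mode Tag filter (default `"both"`).
#' @param genome Optional [hush_genome()] for clipping.
#' @return A `hush_profile` with bootstrap band.
#' @export
meta_feature_profiles <- function(track, genes, anchor = c("TSS", "midpoint", "TTS"),
                                  half_width = 5000, bin_size = 50,
                                  n_boot = 1000, stat = "median", seed = 1,
                                  strand_mode = "both", genome = NULL) {
  anchor <- match.arg(anchor)
  anchors <- gene_anchors(genes, anchor)
  h <- build_heatmap(track, anchors, half_width = half_width,
                     bin_size = bin_size, strand_mode = strand_mode,
                     genome = genome, track_id = paste0("meta:", anchor))
  bootstrap_band(h, n_boot = n_boot, stat = stat, seed = seed,
                 normalization = "per_billion_per_base_per_region")
}
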