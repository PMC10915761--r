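#' Class vocabulary for consolidated regions
#' @keywords internal
HUSH_CLASSES <- c("HUSH_K9POS", "HUSH_K9NEG", "MPP8_ONLY", "UNCLASSIFIED")

#' Classify consolidated regions into HUSH target classes
#'
#' Regions overlapping (>= 1 bp) an MPP8 peak are classified; among those,
#' TASOR overlap distinguishes bona fide HUSH targets, split by the
#' H3K9me3 enrichment call into `HUSH_K9POS` and `HUSH_K9NEG`, while MPP8
#' overlap without TASOR yields `MPP8_ONLY`. Regions overlapping neither
#' are `UNCLASSIFIED`. The four labels are mutually exclusive and
#' exhaustive.
#'
#' @param superset A [consolidate_meanshift()] result (or an
#'   [interval_set()] of regions).
#' @param mpp8,tasor [interval_set()]s of called MPP8 and TASOR peaks.
#' @param k9_calls An [nb_enrichment_test()] result indexed by the superset
#'   regions (matched by region id; every region must have a call).
#' @return data.frame of class `region_classification`: region coordinates
#'   plus `region_id`, `label`, `mpp8_overlap`, `tasor_overlap`, `k9_call`,
#'   `log2fc`, `q`, and `strand` (filled by [orient_by_proseq()], `"*"`
#'   until then).
#' @export
classify_regions <- function(superset, mpp8, tasor, k9_calls) {
  regions <- if (inherits(superset, "region_superset")) superset$regions else superset
  stopifnot(inherits(regions, "interval_set"))
  ids <- region_ids(regions)
  m <- match(ids, k9_calls$region)
  if (any(is.na(m)))
    stop("region(s) without an H3K9me3 call: ",
         paste(utils::head(ids[is.na(m)], 3), collapse = ", "))
  mpp8_ov <- overlaps_any(regions, mpp8)
  tasor_ov <- overlaps_any(regions, tasor)
  k9 <- k9_calls$call[m]
  label <- ifelse(mpp8_ov & tasor_ov & k9, "HUSH_K9POS",
           ifelse(mpp8_ov & tasor_ov, "HUSH_K9NEG",
           ifelse(mpp8_ov, "MPP8_ONLY", "UNCLASSIFIED")))
  res <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, region_id = ids,
                    label = factor(label, levels = HUSH_CLASSES),
                    mpp8_overlap = mpp8_ov, tasor_overlap = tasor_ov,
                    k9_call = k9, log2fc = k9_calls$log2fc[m],
                    q = k9_calls$q[m], strand = "*",
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("region_classification", "data.frame")
  res
}

#' Orient regions by nascent-transcription strand ratio
#'
#' Counts plus- and minus-strand PRO-seq tags in a window of `+/- window` bp
#' around each region center and sets the region strand to `"+"` when the
#' plus-strand count is greater than or equal to the minus-strand count
#' (deterministic tie-break), `"-"` otherwise. The counts are recorded as
#' evidence columns.
#'
#' @param regions An [interval_set()] or `region_classification`.
#' @param proseq_plus,proseq_minus [tag_track()]s of plus- and minus-strand
#'   PRO-seq tags (each track's tags may carry either strand label; all its
#'   tags are counted).
#' @param window Half-width of the counting window in bp (default 1000).
#' @return The input with `strand` set and columns `proseq_plus_tags`,
#'   `proseq_minus_tags` appended.
#' @export
orient_by_proseq <- function(regions, proseq_plus, proseq_minus, window = 1000) {
  stopifnot(window > 0)
  centers <- interval_centers(regions)
  win <- data.frame(chrom = regions$chrom, start = pmax(0, centers - window),
                    end = centers + window, strand = "*")
  p <- count_tags(proseq_plus, win, "both")
  m <- count_tags(proseq_minus, win, "both")
  regions$strand <- ifelse(p >= m, "+", "-")
  regions$proseq_plus_tags <- p
  regions$proseq_minus_tags <- m
  regions
}

#' Write a region classification as extended BED
#'
#' BED6 (name = region id, score = log2FC, strand = orientation) plus
#' columns label, q, and the evidence flags.
#'
#' @param x A `region_classification`.
#' @param path Output path.
#' @export
write_classification <- function(x, path) {
  stopifnot(inherits(x, "region_classification"))
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  df <- data.frame(x$chrom, fmt(x$start), fmt(x$end), x$region_id,
                   signif(x$log2fc, 4), ifelse(x$strand == "*", ".", x$strand),
                   as.character(x$label), signif(x$q, 4),
                   as.integer(x$mpp8_overlap), as.integer(x$tasor_overlap),
                   as.integer(x$k9_call))
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
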