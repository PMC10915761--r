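#' Assign CLIP RT stops to annotation categories by priority
#'
#' Each RT stop is assigned to the single highest-priority category whose
#' interval contains it on the same strand (or on either strand when
#' `stranded = FALSE`); stops contained in no category are counted as
#' `"unassigned"`. The returned counts always partition the total stop
#' count.
#'
#' @param stops A [tag_track()] of RT-stop positions (stranded).
#' @param annot An [annotation_track()] (stranded intervals for stranded
#'   assignment).
#' @param priority Character vector ordering all categories of `annot`
#'   (highest first); defaults to the vocabulary order.
#' @param stranded Require the stop strand to match the feature strand
#'   (default TRUE).
#' @return Named integer vector of per-category counts plus `"unassigned"`,
#'   summing to the number of stored stops.
#' @export
assign_stops <- function(stops, annot, priority = NULL, stranded = TRUE) {
  stopifnot(inherits(stops, "tag_track"), inherits(annot, "annotation_track"))
  vocab <- annotation_categories(annot)
  if (is.null(priority)) priority <- vocab
  if (!setequal(priority, vocab))
    stop("priority must cover exactly the annotation categories: ",
         paste(vocab, collapse = ", "))
  # flatten stops to a data.frame once
  sdf <- stops_as_df(stops)
  assigned <- rep(NA_character_, nrow(sdf))
  if (nrow(sdf) > 0) {
    stop_iv <- data.frame(chrom = sdf$chrom, start = sdf$pos,
                          end = sdf$pos + 1, strand = sdf$strand)
    class(stop_iv) <- c("interval_set", "data.frame")
    for (cc in priority) {
      open <- is.na(assigned)
      if (!any(open)) break
      sub <- annot[annot$category == cc, , drop = FALSE]
      if (nrow(sub) == 0) next
      hits <- overlap_hits(stop_iv[open, , drop = FALSE], sub)
      if (stranded && nrow(hits) > 0) {
        ok <- sub$strand[hits$b] == "*" |
          sub$strand[hits$b] == stop_iv$strand[which(open)[hits$a]]
        hits <- hits[ok, , drop = FALSE]
      }
      assigned[which(open)[unique(hits$a)]] <- cc
    }
  }
  assigned[is.na(assigned)] <- "unassigned"
  counts <- table(factor(assigned, levels = c(priority, "unassigned")))
  stats::setNames(as.integer(counts), names(counts))
}

stops_as_df <- function(track) {
  out <- list()
  for (cc in names(track$tags)) {
    t <- track$tags[[cc]]
    out[[cc]] <- data.frame(
      chrom = cc, pos = c(t$plus, t$minus),
      strand = rep(c("+", "-"), c(length(t$plus), length(t$minus))),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), pos = numeric(), strand = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CLIP RT-stop enrichment normalized for feature length and transcription
#'
#' For each category f the enrichment is
#' \deqn{E_f = \frac{S_f / S_{tot}}{(L_f / L_{tot}) \cdot (T_f / \bar T)}}
#' where `S_f` is the stop count assigned to f, `L_f` the union length of
#' the category's intervals, `T_f` the sense PRO-seq tag density in f
#' (tags per bp), and `\bar T` the length-weighted mean of the `T_f`. Under
#' null stop placement proportional to `L_f * T_f` every `E_f` equals 1.
#' A pseudocount of 1 tag is applied to each category's stop count and
#' PRO-seq count.
#'
#' @param stops A [tag_track()] of RT stops.
#' @param annot An [annotation_track()] with positive-length categories.
#' @param proseq A stranded [tag_track()] of PRO-seq tags.
#' @param priority Optional stop-assignment priority (see [assign_stops()]).
#' @param stranded Strand-matched assignment and sense PRO-seq counting
#'   (default TRUE).
#' @param raw Report the simpler unnormalized form
#'   `S_f / (L_f * T_f)` instead of the doubly-normalized ratio.
#' @return data.frame with one row per category: `S` (stops), `L` (bp),
#'   `T` (PRO tags/bp), `enrichment`.
#' @export
clip_enrichment <- function(stops, annot, proseq, priority = NULL,
                            stranded = TRUE, raw = FALSE) {
  vocab <- if (is.null(priority)) annotation_categories(annot) else priority
  counts <- assign_stops(stops, annot, priority = vocab, stranded = stranded)
  s_tot <- sum(counts)
  res <- lapply(vocab, function(cc) {
    sub <- annot[annot$category == cc, , drop = FALSE]
    class(sub) <- c("interval_set", "data.frame")
    merged <- merge_intervals(sub)
    L <- sum(merged$end - merged$start)
    if (L <= 0) stop("category '", cc, "' has zero length")
    pro_iv <- sub
    pro <- sum(count_tags(proseq, pro_iv, if (stranded) "sense" else "both")) + 1
    data.frame(category = cc, S = counts[[cc]], L = L, T = pro / L,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  L_tot <- sum(df$L)
  T_bar <- sum(df$L * df$T) / L_tot
  s_frac <- (df$S + 1) / (s_tot + nrow(df))
  df$enrichment <- if (raw) df$S / (df$L * df$T)
                   else s_frac / ((df$L / L_tot) * (df$T / T_bar))
  rownames(df) <- NULL
  df
}

#' CLIP RT-stop aggregate profiles per region class
#'
#' Builds an RT-stop heatmap for each class's regions (per-million scaling,
#' both strands) and returns its mean aggregate profile. Empty classes
#' yield a `NULL` entry flagged in the names.
#'
#' @param stops A [tag_track()] of RT stops.
#' @param classes A `region_classification` with orientation applied.
#' @param half_width,bin_size Window geometry (defaults 5000 / 50).
#' @param genome Optional [hush_genome()] for clipping.
#' @return Named list of `hush_profile`s (one per class label; `NULL` for
#'   empty classes).
#' @export
clip_aggregate <- function(stops, classes, half_width = 5000, bin_size = 50,
                           genome = NULL) {
  stopifnot(inherits(classes, "region_classification"))
  out <- stats::setNames(vector("list", length(HUSH_CLASSES)), HUSH_CLASSES)
  for (lab in HUSH_CLASSES) {
    sub <- classes[classes$label == lab, , drop = FALSE]
    if (nrow(sub) == 0) next
    h <- build_heatmap(stops, sub, half_width = half_width,
                       bin_size = bin_size, strand_mode = "both",
                       genome = genome, track_id = paste0("clip:", lab))
    out[[lab]] <- aggregate_profile(h, stat = "mean")
  }
  out
}
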