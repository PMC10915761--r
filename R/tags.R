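#' Construct a single-base tag track
#'
#' A tag track stores one genomic position per sequenced tag (the 5' end of
#' the read on its own strand; for CLIP data, the RT-stop base), together
#' with the tag's strand and the library's total aligned-tag count used for
#' depth scaling.
#'
#' @param chrom Character vector of chromosome names, one per tag.
#' @param pos Numeric vector of 0-based tag positions.
#' @param strand Strand per tag (`"+"` or `"-"`); unstranded libraries may
#'   pass all `"+"`.
#' @param total_aligned Total aligned tags in the library; defaults to the
#'   number of tags supplied. Must be `>=` the number of stored tags.
#' @param genome Optional [hush_genome()] for bounds validation.
#' @return An object of class `tag_track`.
#' @export
tag_track <- function(chrom, pos, strand = "+", total_aligned = NULL,
                      genome = NULL) {
  n <- length(pos)
  chrom <- as.character(chrom)
  pos <- as.double(pos)
  strand <- rep_len(as.character(strand), n)
  if (n > 0 && any(!strand %in% c("+", "-")))
    stop("tag strand must be '+' or '-'")
  if (!is.null(genome) && n > 0) {
    bad <- !chrom %in% names(genome)
    if (any(bad)) stop("tags on unknown chromosome(s): ",
                       paste(unique(chrom[bad]), collapse = ", "))
    if (any(pos < 0) || any(pos >= unclass(genome)[chrom]))
      stop("tag position outside chromosome bounds")
  }
  if (is.null(total_aligned)) total_aligned <- n
  if (total_aligned < n) stop("total_aligned must be >= number of stored tags")
  tags <- list()
  if (n > 0) {
    for (cc in unique(chrom)) {
      sel <- chrom == cc
      p <- pos[sel]; s <- strand[sel]
      tags[[cc]] <- list(plus = sort(p[s == "+"]), minus = sort(p[s == "-"]))
    }
  }
  structure(list(tags = tags, total_aligned = as.double(total_aligned)),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat("<tag_track> ", n_tags(x), " tags on ", length(x$tags),
      " chromosome(s); total_aligned = ",
      format(x$total_aligned, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Number of tags stored in a track
#' @param track A [tag_track()].
#' @export
n_tags <- function(track) {
  sum(vapply(track$tags, function(t) length(t$plus) + length(t$minus), 0))
}

#' Read single-base tags from a BED file
#'
#' Each BED row contributes one tag (or `score` tags when
#' `multiplicity = TRUE`, as for collapsed CLIP RT-stop files). The tag
#' position is the 5' end of the row on its own strand: `start` for `+` or
#' unstranded rows, `end - 1` for `-` rows.
#'
#' @param path BED file of tags.
#' @param genome A [hush_genome()].
#' @param multiplicity Honor the BED score column as a per-row tag count.
#' @param total_aligned Optional override for the library total.
#' @return A [tag_track()].
#' @export
read_tags <- function(path, genome, multiplicity = FALSE, total_aligned = NULL) {
  bed <- read_bed(path, genome)
  pos <- ifelse(bed$strand == "-", bed$end - 1, bed$start)
  strand <- ifelse(bed$strand == "-", "-", "+")
  chrom <- bed$chrom
  if (multiplicity) {
    k <- bed$score
    k[is.na(k) | k < 1] <- 1
    k <- as.integer(round(k))
    chrom <- rep(chrom, k); pos <- rep(pos, k); strand <- rep(strand, k)
  }
  tag_track(chrom, pos, strand, total_aligned = total_aligned, genome = genome)
}

# count of sorted positions v in [lo, hi)  (integer positions assumed)
.count_sorted <- function(v, lo, hi) {
  if (length(v) == 0) return(0L)
  findInterval(hi - 0.5, v) - findInterval(lo - 0.5, v)
}

# positions of sorted v lying in [lo, hi)
.slice_sorted <- function(v, lo, hi) {
  if (length(v) == 0) return(numeric())
  i1 <- findInterval(lo - 0.5, v) + 1L
  i2 <- findInterval(hi - 0.5, v)
  if (i2 < i1) numeric() else v[i1:i2]
}

#' Merge two tag tracks into one
#'
#' Tags of both tracks are pooled (keeping their strands); the totals add.
#' Useful for combining strand-split files of one library.
#'
#' @param a,b [tag_track()]s.
#' @return A [tag_track()].
#' @export
merge_tag_tracks <- function(a, b) {
  stopifnot(inherits(a, "tag_track"), inherits(b, "tag_track"))
  da <- stops_as_df(a)
  db <- stops_as_df(b)
  d <- rbind(da, db)
  tag_track(d$chrom, d$pos, d$strand,
            total_aligned = a$total_aligned + b$total_aligned)
}

#' Count tags overlapping intervals
#'
#' Counts tags with position in `[start, end)` of each interval, filtered by
#' strand. Modes `"sense"`/`"antisense"` compare tag strand with the
#' interval's own strand and require stranded intervals.
#'
#' @param track A [tag_track()].
#' @param intervals An [interval_set()] (or single-row data.frame).
#' @param strand_mode One of `"both"`, `"+"`, `"-"`, `"sense"`, `"antisense"`.
#' @return Integer vector of counts, one per interval.
#' @export
count_tags <- function(track, intervals,
                       strand_mode = c("both", "+", "-", "sense", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(track, "tag_track"))
  n <- nrow(intervals)
  if (strand_mode %in% c("sense", "antisense") && any(intervals$strand == "*"))
    stop("strand_mode '", strand_mode, "' requires stranded intervals")
  out <- integer(n)
  for (i in seq_len(n)) {
    t <- track$tags[[intervals$chrom[i]]]
    if (is.null(t)) next
    want <- switch(strand_mode,
      both = c("plus", "minus"),
      "+" = "plus", "-" = "minus",
      sense = if (intervals$strand[i] == "+") "plus" else "minus",
      antisense = if (intervals$strand[i] == "+") "minus" else "plus")
    out[i] <- sum(vapply(want, function(w)
      .count_sorted(t[[w]], intervals$start[i], intervals$end[i]), 0L))
  }
  out
}

#' Per-base coverage of a tag track as run-length spans
#'
#' Tabulates both-strand tag counts per base and collapses equal-value runs,
#' the form emitted by `write_bedgraph()`. Zero-coverage spans are omitted.
#'
#' @param track A [tag_track()].
#' @param genome A [hush_genome()].
#' @param per_million Scale values by `1e6 / total_aligned`.
#' @return data.frame with columns chrom, start, end, value.
#' @export
track_coverage <- function(track, genome, per_million = TRUE) {
  stopifnot(inherits(track, "tag_track"), inherits(genome, "hush_genome"))
  scale <- if (per_million) 1e6 / track$total_aligned else 1
  out <- list()
  for (cc in names(track$tags)) {
    t <- track$tags[[cc]]
    pos <- sort(c(t$plus, t$minus))
    if (length(pos) == 0) next
    cnt <- tabulate(as.integer(pos) + 1L, nbins = as.integer(unclass(genome)[cc]))
    r <- rle(cnt)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    out[[cc]] <- data.frame(chrom = cc, start = starts[keep], end = ends[keep],
                            value = r$values[keep] * scale)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Write coverage spans as bedGraph
#'
#' Adjacent spans with equal values are collapsed before writing, so the
#' output is the minimal run-length representation of the coverage.
#'
#' @param cov data.frame with columns chrom, start, end, value (finite).
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(cov)))
  if (any(!is.finite(cov$value))) stop("non-finite coverage values")
  cov <- cov[order(cov$chrom, cov$start), , drop = FALSE]
  if (nrow(cov) > 1) {
    # collapse runs of adjacent equal-value spans
    joinable <- cov$chrom[-1] == cov$chrom[-nrow(cov)] &
      cov$start[-1] == cov$end[-nrow(cov)] &
      cov$value[-1] == cov$value[-nrow(cov)]
    grp <- cumsum(c(TRUE, !joinable))
    cov <- data.frame(chrom = tapply(cov$chrom, grp, `[`, 1),
                      start = as.double(tapply(cov$start, grp, `[`, 1)),
                      end = as.double(tapply(cov$end, grp, function(v) v[length(v)])),
                      value = as.double(tapply(cov$value, grp, `[`, 1)))
    cov <- cov[order(cov$chrom, cov$start), , drop = FALSE]
  }
  lines <- sprintf("%s\t%s\t%s\t%s", cov$chrom,
                   format(cov$start, scientific = FALSE, trim = TRUE),
                   format(cov$end, scientific = FALSE, trim = TRUE),
                   format(cov$value, scientific = FALSE, trim = TRUE, digits = 10))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path.
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric", "numeric"))
  tab[order(tab$chrom, tab$start), , drop = FALSE]
}

# value of run-length coverage at given single positions (0 where absent)
coverage_at <- function(cov, chrom, pos) {
  out <- numeric(length(pos))
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    sub <- cov[cov$chrom == cc, , drop = FALSE]
    if (nrow(sub) == 0) next
    idx <- findInterval(pos[sel], sub$start)
    ok <- idx >= 1 & pos[sel] < sub$end[pmax(idx, 1)]
    out[sel[ok]] <- sub$value[idx[ok]]
  }
  out
}
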