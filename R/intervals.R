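#' Construct a set of genomic intervals
#'
#' Intervals are kept in BED convention throughout: 0-based starts, half-open
#' ends (`start <= pos < end`). The set is a plain `data.frame` sorted by
#' (chrom, start, end) with columns `chrom`, `start`, `end`, `name`, `score`,
#' `strand`. Strand is one of `"+"`, `"-"`, `"*"` (unstranded).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors of 0-based half-open coordinates.
#' @param name Optional interval names.
#' @param score Optional numeric scores.
#' @param strand Strand per interval; defaults to unstranded (`"*"`).
#' @param genome Optional [hush_genome()]; when supplied, coordinates are
#'   validated against chromosome bounds.
#' @return A `data.frame` of class `interval_set`, sorted by (chrom, start).
#' @export
interval_set <- function(chrom, start, end, name = NA_character_,
                         score = NA_real_, strand = "*", genome = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.double(start),
                   end = as.double(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.double(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_interval_set(df, genome)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

validate_interval_set <- function(df, genome = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("non-finite interval coordinates")
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$end <= df$start)) stop("interval end must exceed start (half-open convention)")
  if (any(!df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (!is.null(genome)) {
    bad <- !df$chrom %in% names(genome)
    if (any(bad)) stop("unknown chromosome(s): ", paste(unique(df$chrom[bad]), collapse = ", "))
    if (any(df$end > unclass(genome)[df$chrom]))
      stop("interval extends beyond chromosome end")
  }
  invisible(df)
}

as_interval_set <- function(df, genome = NULL) {
  interval_set(df$chrom, df$start, df$end,
               name = if ("name" %in% names(df)) df$name else NA_character_,
               score = if ("score" %in% names(df)) df$score else NA_real_,
               strand = if ("strand" %in% names(df)) df$strand else "*",
               genome = genome)
}

#' @export
print.interval_set <- function(x, ...) {
  cat("<interval_set> ", nrow(x), " intervals",
      if (nrow(x)) paste0(", mean width ", round(mean(x$end - x$start), 1), " bp"),
      "\n", sep = "")
  NextMethod()
}

n_intervals <- function(x) nrow(x)

mean_width <- function(x) {
  if (nrow(x) == 0) stop("mean width undefined for an empty interval set")
  mean(x$end - x$start)
}

# GRanges view used internally for overlap queries (1-based closed coords).
# Strand is deliberately not propagated: strandedness is handled explicitly
# by the callers that need it.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(start = x$start + 1, end = x$end))
}

# Hits between two interval sets (>= 1 bp overlap), as a two-column
# data.frame of row indices.
overlap_hits <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b))
  data.frame(a = S4Vectors::queryHits(hits), b = S4Vectors::subjectHits(hits))
}

overlaps_any <- function(a, b) {
  GenomicRanges::countOverlaps(as_granges0(a), as_granges0(b)) > 0
}

#' Read a BED file
#'
#' Accepts 3-6+ column BED. Lines starting with `track`, `browser` or `#`
#' are skipped. Rows on chromosomes absent from `genome` are rejected and
#' their count reported via a message and the `n_rejected` attribute.
#' Malformed rows (non-integer coordinates, `start >= end`) raise an error
#' naming the offending line.
#'
#' @param path Path to a BED file.
#' @param genome A [hush_genome()] used to validate chromosomes.
#' @return An [interval_set()] with attribute `n_rejected`.
#' @export
read_bed <- function(path, genome) {
  stopifnot(inherits(genome, "hush_genome"))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(structure(interval_set(character(), numeric(), numeric()), n_rejected = 0L))
  fields <- strsplit(lines, "[ \t]+")
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop(sprintf("line %d: fewer than 3 BED columns", lineno[which(ncol < 3)[1]]))
  chrom <- vapply(fields, `[[`, "", 1)
  s_chr <- vapply(fields, `[[`, "", 2)
  e_chr <- vapply(fields, `[[`, "", 3)
  start <- suppressWarnings(as.numeric(s_chr))
  end <- suppressWarnings(as.numeric(e_chr))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop(sprintf("line %d: non-integer BED coordinates ('%s', '%s')",
                 lineno[which(bad)[1]], s_chr[which(bad)[1]], e_chr[which(bad)[1]]))
  bad <- start >= end | start < 0
  if (any(bad))
    stop(sprintf("line %d: invalid interval [%s, %s) (need 0 <= start < end)",
                 lineno[which(bad)[1]], s_chr[which(bad)[1]], e_chr[which(bad)[1]]))
  name <- ifelse(ncol >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA_character_)
  name[ncol < 4] <- NA_character_
  score <- rep(NA_real_, length(fields))
  has5 <- ncol >= 5
  score[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[[`, "", 5)))
  strand <- rep("*", length(fields))
  has6 <- ncol >= 6
  s6 <- vapply(fields[has6], `[[`, "", 6)
  s6[!s6 %in% c("+", "-")] <- "*"
  strand[has6] <- s6
  known <- chrom %in% names(genome)
  n_rejected <- sum(!known)
  if (n_rejected > 0)
    message(n_rejected, " record(s) on chromosomes absent from the genome were rejected")
  out <- interval_set(chrom[known], start[known], end[known],
                      name = name[known], score = score[known],
                      strand = strand[known], genome = genome)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write an interval set as BED
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @param columns Number of BED columns to emit (3 or 6).
#' @export
write_bed <- function(x, path, columns = 6) {
  stopifnot(inherits(x, "interval_set"), columns %in% c(3, 6))
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  df <- data.frame(x$chrom, fmt(x$start), fmt(x$end))
  if (columns == 6) {
    df$name <- ifelse(is.na(x$name), ".", x$name)
    df$score <- ifelse(is.na(x$score), "0", fmt(x$score))
    df$strand <- ifelse(x$strand == "*", ".", x$strand)
  }
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping or nearby intervals
#'
#' Intervals on the same chromosome that overlap or lie within `max_gap` bp
#' of each other are unioned. Strand, name and score are dropped.
#'
#' @param x An [interval_set()].
#' @param max_gap Maximum gap (bp, `>= 0`) across which to union.
#' @return An [interval_set()] of disjoint intervals.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  stopifnot(inherits(x, "interval_set"), max_gap >= 0)
  if (nrow(x) == 0) return(x)
  # x is sorted by (chrom, start); single sweep
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$start[-1] > cummax_by_chrom(x) + max_gap)
  grp <- cumsum(new_run)
  interval_set(chrom = tapply(x$chrom, grp, `[`, 1),
               start = as.double(tapply(x$start, grp, min)),
               end = as.double(tapply(x$end, grp, max)))
}

# running maximum of `end` within each chromosome, lagged for the sweep
cummax_by_chrom <- function(x) {
  ave(x$end, x$chrom, FUN = cummax)[-nrow(x)]
}

# TRUE if the set contains self-overlapping intervals on any chromosome
has_self_overlap <- function(x) {
  if (nrow(x) < 2) return(FALSE)
  same <- x$chrom[-1] == x$chrom[-nrow(x)]
  any(same & x$start[-1] < ave(x$end, x$chrom, FUN = cummax)[-nrow(x)])
}

#' Extend intervals symmetrically
#'
#' @param x An [interval_set()].
#' @param slop Extension in bp on each side (clipped at 0 and, when a genome
#'   is given, at the chromosome end).
#' @param genome Optional [hush_genome()] for right-clipping.
#' @export
slop_intervals <- function(x, slop, genome = NULL) {
  stopifnot(inherits(x, "interval_set"), slop >= 0)
  if (nrow(x) == 0) return(x)
  start <- pmax(0, x$start - slop)
  end <- x$end + slop
  if (!is.null(genome)) end <- pmin(end, unclass(genome)[x$chrom])
  interval_set(x$chrom, start, end, name = x$name, score = x$score,
               strand = x$strand, genome = genome)
}

# center base of each interval (0-based)
interval_centers <- function(x) floor((x$start + x$end) / 2)
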