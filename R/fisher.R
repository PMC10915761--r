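#' Interval-overlap Fisher statistic
#'
#' Association between two merged interval sets against a genome-size null,
#' in the spirit of the classic "available genomic slots" construction. The
#' 2x2 table is
#' \describe{
#'   \item{n11}{number of (A, B) interval pairs with >= 1 bp overlap}
#'   \item{n12}{A intervals with no overlap in B}
#'   \item{n21}{B intervals with no overlap in A}
#'   \item{n22}{`max(0, floor(G / (Lbar_A + Lbar_B)) - n11 - n12 - n21)`,
#'     the remaining empty genomic slots, where `G` is the genome size and
#'     `Lbar` the mean interval length of each set}
#' }
#' The odds ratio is the sample odds ratio `n11 * n22 / (n12 * n21)`,
#' reported as `Inf` when `n12 * n21 == 0` with `n11 * n22 > 0`, and `0`
#' when `n11 * n22 == 0`. The p-value is the two-sided Fisher exact test on
#' the table.
#'
#' @param a,b Merged (self-overlap-free), non-empty [interval_set()]s.
#' @param genome A [hush_genome()].
#' @param haldane Apply a Haldane 0.5 continuity correction to all cells for
#'   the odds ratio (the table and p-value are unchanged). Off by default.
#' @return A list of class `overlap_fisher` with elements `n11`, `n12`,
#'   `n21`, `n22`, `odds_ratio`, `p_two_sided`.
#' @export
fisher_overlap <- function(a, b, genome, haldane = FALSE) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"),
            inherits(genome, "hush_genome"))
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("fisher_overlap requires non-empty interval sets")
  if (has_self_overlap(a) || has_self_overlap(b))
    stop("fisher_overlap requires merged inputs (see merge_intervals)")
  hits <- overlap_hits(a, b)
  n11 <- nrow(hits)
  n12 <- nrow(a) - length(unique(hits$a))
  n21 <- nrow(b) - length(unique(hits$b))
  slots <- floor(genome_size(genome) / (mean_width(a) + mean_width(b)))
  n22 <- max(0, slots - n11 - n12 - n21)
  or <- odds_ratio_2x2(n11, n12, n21, n22, haldane = haldane)
  p <- stats::fisher.test(matrix(c(n11, n12, n21, n22), nrow = 2, byrow = TRUE))$p.value
  structure(list(n11 = n11, n12 = n12, n21 = n21, n22 = n22,
                 odds_ratio = or, p_two_sided = p),
            class = "overlap_fisher")
}

# sample odds ratio with the zero-cell conventions used throughout
odds_ratio_2x2 <- function(n11, n12, n21, n22, haldane = FALSE) {
  if (haldane) {
    n11 <- n11 + 0.5; n12 <- n12 + 0.5; n21 <- n21 + 0.5; n22 <- n22 + 0.5
  }
  num <- n11 * n22
  den <- n12 * n21
  if (num == 0) return(0)
  if (den == 0) return(Inf)
  num / den
}

#' @export
print.overlap_fisher <- function(x, ...) {
  cat("<overlap_fisher> table [", x$n11, x$n12, "/", x$n21, x$n22,
      "] OR =", signif(x$odds_ratio, 4), ", p =", signif(x$p_two_sided, 3), "\n")
  invisible(x)
}
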