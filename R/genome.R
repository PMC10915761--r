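#' Genome description
#'
#' A genome is a named vector of chromosome lengths. It anchors coordinate
#' validation for all interval and tag containers and supplies the total
#' genome length used by the interval-overlap null model.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp; all
#'   lengths must be positive and names unique.
#' @return An object of class `hush_genome`: named numeric vector of
#'   chromosome lengths with attribute `size` (total length).
#' @export
#' @examples
#' g <- hush_genome(c(chr1 = 1e6, chr2 = 5e5))
#' genome_size(g)
hush_genome <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names")
  lengths <- stats::setNames(as.double(lengths), names(lengths))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive and finite")
  structure(lengths, class = "hush_genome")
}

#' @rdname hush_genome
#' @param genome A `hush_genome`.
#' @export
genome_size <- function(genome) {
  stopifnot(inherits(genome, "hush_genome"))
  sum(unclass(genome))
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a whitespace-separated file with columns
#'   chromosome name and length (UCSC `chrom.sizes` layout).
#' @return A [hush_genome()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  hush_genome(stats::setNames(tab$length, tab$chrom))
}

#' Write a chromosome-sizes file
#'
#' @param genome A [hush_genome()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "hush_genome"))
  utils::write.table(
    data.frame(chrom = names(genome), length = format(unclass(genome), scientific = FALSE, trim = TRUE)),
    path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.hush_genome <- function(x, ...) {
  cat("<hush_genome> ", length(x), " chromosomes, ",
      format(sum(unclass(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}
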