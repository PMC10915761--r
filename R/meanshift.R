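#' Consolidate peak sets into a region superset by 1-D mean shift
#'
#' Peaks from several factors/marks are reduced to their midpoints and
#' clustered per chromosome with a one-dimensional mean-shift procedure
#' using a flat (boxcar) kernel of half-width `bandwidth`: each midpoint is
#' iteratively moved to the mean of all midpoints within `bandwidth` of its
#' current position until the step falls below `tol`. Midpoints that
#' converge to the same mode form one region whose extent is the span of its
#' member peaks; overlapping spans are merged. Every input peak maps to
#' exactly one region.
#'
#' @param peak_sets A (optionally named) list of [interval_set()]s.
#' @param bandwidth Kernel half-width in bp (default 500).
#' @param tol Convergence tolerance in bp (default 1e-3).
#' @param max_iter Maximum mean-shift iterations (default 200).
#' @param mode_tol Converged modes closer than this are treated as one mode
#'   (default 0.5 bp).
#' @return A list of class `region_superset` with elements
#'   \describe{
#'     \item{regions}{[interval_set()] of consolidated regions, named
#'       `R0001`, `R0002`, ... in (chrom, start) order}
#'     \item{provenance}{logical matrix regions x input sets}
#'     \item{peak_region}{integer vector mapping each input peak (in
#'       concatenation order) to its region index}
#'     \item{bandwidth}{the bandwidth used}
#'   }
#' @export
consolidate_meanshift <- function(peak_sets, bandwidth = 500, tol = 1e-3,
                                  max_iter = 200, mode_tol = 0.5) {
  stopifnot(is.list(peak_sets), bandwidth > 0)
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets))))
    names(peak_sets) <- paste0("set", seq_along(peak_sets))
  n_per <- vapply(peak_sets, nrow, 0L)
  if (sum(n_per) == 0) stop("no peaks supplied")
  peaks <- do.call(rbind, lapply(seq_along(peak_sets), function(i) {
    p <- peak_sets[[i]]
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               set = names(peak_sets)[i], stringsAsFactors = FALSE)
  }))
  peaks$mid <- (peaks$start + peaks$end) / 2
  peaks$idx <- seq_len(nrow(peaks))

  cluster <- integer(nrow(peaks))
  n_clust <- 0L
  for (cc in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == cc)
    modes <- meanshift_1d(peaks$mid[sel], bandwidth, tol, max_iter)
    # group modes: sort, split where gap > mode_tol
    o <- order(modes)
    gap <- c(FALSE, diff(modes[o]) > mode_tol)
    grp <- integer(length(modes))
    grp[o] <- cumsum(c(TRUE, diff(modes[o]) > mode_tol))
    cluster[sel] <- grp + n_clust
    n_clust <- n_clust + max(grp)
  }

  # extents per cluster; merge clusters whose spans overlap
  ext_start <- tapply(peaks$start, cluster, min)
  ext_end <- tapply(peaks$end, cluster, max)
  ext_chrom <- tapply(peaks$chrom, cluster, `[`, 1)
  cl_ids <- as.integer(names(ext_start))
  ext <- data.frame(chrom = as.character(ext_chrom),
                    start = as.double(ext_start), end = as.double(ext_end),
                    cl = cl_ids, stringsAsFactors = FALSE)
  ext <- ext[order(ext$chrom, ext$start, ext$end), , drop = FALSE]
  new_run <- c(TRUE, ext$chrom[-1] != ext$chrom[-nrow(ext)] |
                 ext$start[-1] >= ave(ext$end, ext$chrom, FUN = cummax)[-nrow(ext)])
  region_of_cluster <- integer(max(cl_ids))
  region_of_cluster[ext$cl] <- cumsum(new_run)
  region_id <- region_of_cluster[cluster]

  r_start <- as.double(tapply(peaks$start, region_id, min))
  r_end <- as.double(tapply(peaks$end, region_id, max))
  r_chrom <- as.character(tapply(peaks$chrom, region_id, `[`, 1))
  ord_ids <- as.integer(names(tapply(peaks$start, region_id, min)))
  # build in (chrom, start) order with stable region names
  o <- order(r_chrom, r_start, r_end)
  n_reg <- length(o)
  names_sorted <- sprintf("R%04d", seq_len(n_reg))
  rank_of <- integer(n_reg)
  rank_of[ord_ids[o]] <- seq_len(n_reg)
  regions <- interval_set(r_chrom[o], r_start[o], r_end[o], name = names_sorted)
  peak_region <- rank_of[region_id]

  prov <- matrix(FALSE, n_reg, length(peak_sets),
                 dimnames = list(names_sorted, names(peak_sets)))
  for (i in seq_len(nrow(peaks)))
    prov[peak_region[i], peaks$set[i]] <- TRUE

  structure(list(regions = regions, provenance = prov,
                 peak_region = peak_region, bandwidth = bandwidth),
            class = "region_superset")
}

# converged mode position for each point (flat kernel over the data points)
meanshift_1d <- function(m, bandwidth, tol = 1e-3, max_iter = 200) {
  ms <- sort(m)
  cs <- cumsum(ms)
  x <- m
  active <- rep(TRUE, length(x))
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    xa <- x[active]
    hi <- findInterval(xa + bandwidth + 1e-9, ms)
    lo <- findInterval(xa - bandwidth - 1e-9, ms) + 1L
    tot <- cs[hi] - c(0, cs)[lo]
    cnt <- hi - lo + 1L
    xn <- tot / cnt
    moved <- abs(xn - xa) > tol
    x[active] <- xn
    active[active] <- moved
  }
  x
}

#' @export
print.region_superset <- function(x, ...) {
  cat("<region_superset> ", nrow(x$regions), " regions from ",
      ncol(x$provenance), " peak set(s), bandwidth ", x$bandwidth, " bp\n",
      sep = "")
  invisible(x)
}
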