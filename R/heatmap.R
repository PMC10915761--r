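#' Build a regions x position-bins coverage heatmap
#'
#' For each region, tags are tabulated by signed distance from the region
#' center (the sign is flipped for `-` regions, so the positive axis always
#' points in the region's sense direction) into bins of `bin_size` bp
#' spanning `[-half_width, half_width)`, and scaled by
#' `1e6 / total_aligned` ("per million"). Bins whose genomic footprint
#' falls partly outside the chromosome are recorded as `NA` and excluded
#' from downstream aggregates.
#'
#' @param track A [tag_track()].
#' @param regions An oriented [interval_set()] or `region_classification`
#'   (strand `"*"` is treated as `"+"`).
#' @param half_width Window half-width in bp (default 5000).
#' @param bin_size Bin width in bp; must divide `2 * half_width` (default 50).
#' @param strand_mode Tag filter as in [count_tags()] (default `"both"`).
#' @param genome Optional [hush_genome()]; required for boundary clipping.
#' @param track_id Label stored in the result.
#' @return A list of class `hush_heatmap` with `values` (scaled matrix,
#'   rows named by region id), `regions`, `bin_edges` (relative bp,
#'   length bins + 1), `bin_centers`, `half_width`, `bin_size`,
#'   `total_aligned`, `track_id`.
#' @export
build_heatmap <- function(track, regions, half_width = 5000, bin_size = 50,
                          strand_mode = "both", genome = NULL, track_id = NULL) {
  stopifnot(inherits(track, "tag_track"), half_width > 0, bin_size > 0)
  if ((2 * half_width) %% bin_size != 0)
    stop("bin_size must divide 2 * half_width exactly")
  n_bins <- as.integer(2 * half_width / bin_size)
  edges <- seq(-half_width, half_width, by = bin_size)
  centers <- interval_centers(regions)
  strand <- regions$strand
  strand[strand == "*"] <- "+"
  n <- nrow(regions)
  vals <- matrix(0, n, n_bins, dimnames = list(region_ids(regions), NULL))
  for (i in seq_len(n)) {
    t <- track$tags[[regions$chrom[i]]]
    ctr <- centers[i]
    if (!is.null(t)) {
      want <- switch(strand_mode,
        both = c("plus", "minus"), "+" = "plus", "-" = "minus",
        sense = if (strand[i] == "+") "plus" else "minus",
        antisense = if (strand[i] == "+") "minus" else "plus",
        stop("unknown strand_mode"))
      for (w in want) {
        v <- t[[w]]
        if (strand[i] == "+") {
          p <- .slice_sorted(v, ctr - half_width, ctr + half_width)
          rel <- p - ctr
        } else {
          # fetch (ctr - hw, ctr + hw] so the reflected distance stays in
          # [-hw, hw)
          p <- .slice_sorted(v, ctr - half_width + 1, ctr + half_width + 1)
          rel <- ctr - p
        }
        if (length(p)) {
          b <- floor((rel + half_width) / bin_size) + 1L
          vals[i, ] <- vals[i, ] + tabulate(b, nbins = n_bins)
        }
      }
    }
    if (!is.null(genome)) {
      len <- unclass(genome)[[regions$chrom[i]]]
      # genomic footprint of each bin
      if (strand[i] == "+") {
        glo <- ctr + edges[-length(edges)]
        ghi <- ctr + edges[-1]
      } else {
        glo <- ctr - edges[-1] + 1
        ghi <- ctr - edges[-length(edges)] + 1
      }
      vals[i, glo < 0 | ghi > len] <- NA
    }
  }
  structure(list(values = vals * (1e6 / track$total_aligned),
                 regions = regions, bin_edges = edges,
                 bin_centers = edges[-length(edges)] + bin_size / 2,
                 half_width = half_width, bin_size = bin_size,
                 total_aligned = track$total_aligned,
                 track_id = track_id),
            class = "hush_heatmap")
}

#' @export
print.hush_heatmap <- function(x, ...) {
  cat("<hush_heatmap> ", nrow(x$values), " regions x ", ncol(x$values),
      " bins (half_width ", x$half_width, ", bin ", x$bin_size, ")",
      if (!is.null(x$track_id)) paste0(" [", x$track_id, "]"), "\n", sep = "")
  invisible(x)
}

#' Raw (unscaled) tag counts of a heatmap
#' @param h A `hush_heatmap`.
#' @export
raw_counts <- function(h) {
  stopifnot(inherits(h, "hush_heatmap"))
  h$values * h$total_aligned / 1e6
}

#' Class-block row order for heatmap display
#'
#' Rows are arranged in class blocks (`HUSH_K9POS`, `HUSH_K9NEG`,
#' `MPP8_ONLY`, then `UNCLASSIFIED`); within each block rows are sorted
#' descending by mean central H3K9me3 signal (central `+/- central_width`
#' bp), then descending by mean central MPP8 + TASOR signal, with ties
#' broken by region id.
#'
#' @param classes A `region_classification` whose rows match the heatmap
#'   region order.
#' @param k9,mpp8,tasor `hush_heatmap`s sharing the region order.
#' @param central_width Half-width of the central window used for sorting
#'   (default 1000 bp).
#' @return Integer vector: row indices in display order.
#' @export
sort_by_class <- function(classes, k9, mpp8, tasor, central_width = 1000) {
  for (h in list(k9, mpp8, tasor)) {
    if (!identical(rownames(h$values), classes$region_id))
      stop("heatmap region order does not match the classification")
  }
  central <- abs(k9$bin_centers) <= central_width
  cmean <- function(h) rowMeans(h$values[, central, drop = FALSE], na.rm = TRUE)
  k9_sig <- cmean(k9)
  mt_sig <- cmean(mpp8) + cmean(tasor)
  block <- as.integer(factor(classes$label, levels = HUSH_CLASSES))
  order(block, -k9_sig, -mt_sig, classes$region_id)
}

#' Aggregate a heatmap into a per-bin profile
#'
#' @param h A `hush_heatmap`.
#' @param stat Row statistic per bin: `"mean"` or `"median"` (computed
#'   across regions, `NA` bins excluded).
#' @param normalization One of
#'   \describe{
#'     \item{`per_million`}{tags per bin scaled by `1e6 / total_aligned`
#'       (the heatmap's stored values)}
#'     \item{`per_billion_per_base_per_region`}{raw tag counts divided by
#'       `bin_size` (per base), statistic across regions, times
#'       `1e9 / total_aligned`}
#'     \item{`unit_scaled`}{the `per_million` profile affinely mapped to
#'       span [0, 1]}
#'   }
#' @return data.frame of class `hush_profile` with columns `bin_center`,
#'   `value`; attributes `stat`, `normalization`, `n_regions`, `bin_size`.
#' @export
aggregate_profile <- function(h, stat = c("mean", "median"),
                              normalization = c("per_million",
                                                "per_billion_per_base_per_region",
                                                "unit_scaled")) {
  stopifnot(inherits(h, "hush_heatmap"), nrow(h$values) >= 1)
  stat <- match.arg(stat)
  normalization <- match.arg(normalization)
  M <- profile_matrix(h, normalization)
  v <- col_stat(M, stat)
  p <- new_profile(h$bin_centers, v, stat = stat, normalization = normalization,
                   n_regions = nrow(M), bin_size = h$bin_size)
  if (normalization == "unit_scaled") p <- unit_scale(p)
  p
}

profile_matrix <- function(h, normalization) {
  switch(normalization,
    per_million = h$values,
    per_billion_per_base_per_region = h$values * (1000 / h$bin_size),
    unit_scaled = h$values)
}

col_stat <- function(M, stat) {
  if (stat == "mean") colMeans(M, na.rm = TRUE)
  else apply(M, 2, stats::median, na.rm = TRUE)
}

new_profile <- function(bin_center, value, lower = NULL, upper = NULL, ...) {
  p <- data.frame(bin_center = bin_center, value = value)
  if (!is.null(lower)) { p$lower <- lower; p$upper <- upper }
  class(p) <- c("hush_profile", "data.frame")
  extra <- list(...)
  for (nm in names(extra)) attr(p, nm) <- extra[[nm]]
  p
}

#' Bootstrap confidence band for an aggregate profile
#'
#' Rows of the heatmap matrix are resampled with replacement (`n_boot`
#' resamples of the full row count), the per-bin statistic is computed for
#' each resample, and the band is the (0.025, 0.975) quantile across
#' resamples per bin. The center line is the statistic on the original
#' rows. Deterministic given `seed`.
#'
#' @param h A `hush_heatmap` or a plain numeric matrix (rows = units).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param stat `"mean"` or `"median"`.
#' @param seed Integer seed controlling the resampling.
#' @param normalization As in [aggregate_profile()] (matrices are used
#'   as-is).
#' @param quantiles Band quantiles (default `c(0.025, 0.975)`).
#' @return A `hush_profile` with columns `bin_center`, `value`, `lower`,
#'   `upper`.
#' @export
bootstrap_band <- function(h, n_boot = 1000, stat = c("mean", "median"),
                           seed = 1, normalization = "per_million",
                           quantiles = c(0.025, 0.975)) {
  stat <- match.arg(stat)
  stopifnot(n_boot >= 1)
  if (inherits(h, "hush_heatmap")) {
    M <- profile_matrix(h, normalization)
    centers <- h$bin_centers
    bin_size <- h$bin_size
  } else {
    M <- as.matrix(h)
    centers <- seq_len(ncol(M))
    bin_size <- NA_real_
  }
  n <- nrow(M)
  stopifnot(n >= 1)
  idx <- withr::with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot))
  if (stat == "mean") {
    # resample means via a weight matrix; NA cells handled by count matrix
    M0 <- M; M0[is.na(M0)] <- 0
    obs <- !is.na(M)
    W <- matrix(0, n_boot, n)
    for (b in seq_len(n_boot)) W[b, ] <- tabulate(idx[b, ], nbins = n)
    boots <- (W %*% M0) / (W %*% obs)
  } else {
    boots <- t(vapply(seq_len(n_boot), function(b)
      apply(M[idx[b, ], , drop = FALSE], 2, stats::median, na.rm = TRUE),
      numeric(ncol(M))))
  }
  band <- apply(boots, 2, stats::quantile, probs = quantiles, na.rm = TRUE,
                names = FALSE)
  new_profile(centers, col_stat(M, stat), lower = band[1, ], upper = band[2, ],
              stat = stat, normalization = normalization, n_regions = n,
              bin_size = bin_size, n_boot = n_boot, seed = seed)
}

#' Unit-scale a profile to span [0, 1]
#'
#' Affine map sending the profile minimum to 0 and maximum to 1; the band,
#' when present, is transformed with the same map. Constant profiles have
#' no shape and raise an error.
#'
#' @param p A `hush_profile`.
#' @export
unit_scale <- function(p) {
  stopifnot(inherits(p, "hush_profile"))
  rng <- range(p$value, na.rm = TRUE)
  if (diff(rng) == 0) stop("cannot unit-scale a constant profile")
  f <- function(v) (v - rng[1]) / diff(rng)
  p$value <- f(p$value)
  if (!is.null(p$lower)) { p$lower <- f(p$lower); p$upper <- f(p$upper) }
  attr(p, "normalization") <- "unit_scaled"
  p
}

#' Elementwise difference of two heatmaps
#'
#' Signed differential map `a - b` on scaled values; both heatmaps must
#' share region order, window and bin geometry (e.g. depleted minus
#' control RNA-seq coverage, or KO minus WT PRO-seq coverage).
#'
#' @param a,b `hush_heatmap`s with identical geometry.
#' @return A `hush_heatmap` with the signed difference in `values`.
#' @export
differential_matrix <- function(a, b) {
  stopifnot(inherits(a, "hush_heatmap"), inherits(b, "hush_heatmap"))
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(rownames(a$values), rownames(b$values)) ||
      a$half_width != b$half_width || a$bin_size != b$bin_size)
    stop("heatmap geometries do not match")
  out <- a
  out$values <- a$values - b$values
  out$total_aligned <- NA_real_
  out$track_id <- paste0(a$track_id %||% "a", " - ", b$track_id %||% "b")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signed centroid shift between two profiles
#'
#' Difference of signal-weighted mean positions (`ko - wt`) in bp; positive
#' values indicate a downstream shift in the sense orientation. Each
#' profile's baseline is first estimated from its flank bins (the outermost
#' `flank_frac` of bins on each side) and subtracted, so a flat background
#' does not dilute the centroid; the weighted mean is then taken over bins
#' within `+/- signal_window` of the center (all bins when `NULL`).
#'
#' @param wt,ko `hush_profile`s on identical bins.
#' @param signal_window Half-width (bp) of the centroid window, or `NULL`.
#' @param baseline `"flank"` (default) or `"none"`.
#' @param flank_frac Fraction of bins on each side used as flank.
#' @return Signed shift in bp.
#' @export
centroid_shift <- function(wt, ko, signal_window = NULL,
                           baseline = c("flank", "none"), flank_frac = 0.25) {
  baseline <- match.arg(baseline)
  if (!isTRUE(all.equal(wt$bin_center, ko$bin_center)))
    stop("profiles must share bins")
  profile_centroid(ko, signal_window, baseline, flank_frac) -
    profile_centroid(wt, signal_window, baseline, flank_frac)
}

profile_centroid <- function(p, signal_window, baseline, flank_frac) {
  x <- p$bin_center
  v <- p$value
  b0 <- 0
  if (baseline == "flank") {
    nf <- max(1L, floor(flank_frac * length(x)))
    flank <- c(seq_len(nf), length(x) - seq_len(nf) + 1L)
    b0 <- mean(v[flank], na.rm = TRUE)
  }
  w <- v - b0
  keep <- if (is.null(signal_window)) rep(TRUE, length(x)) else abs(x) <= signal_window
  keep <- keep & !is.na(w)
  mass <- sum(w[keep])
  if (!is.finite(mass) || mass <= 0)
    stop("profile has no positive signal mass; centroid undefined")
  sum(w[keep] * x[keep]) / mass
}

#' Per-region transcriptional readthrough index
#'
#' For each oriented terminator interval the index is
#' `(sense tags downstream of the TTS + eps) / (sense tags in the upstream
#' body window + eps)` with `eps = 1`; the TTS is the interval's 3' end
#' base. Larger values indicate more readthrough past the terminator.
#'
#' @param proseq A stranded [tag_track()] (e.g. combined PRO-seq; tags
#'   carry their strand).
#' @param tts Oriented [interval_set()] of terminator intervals (strand
#'   `+` or `-`).
#' @param body_window Upstream window length in bp (default 2000).
#' @param down_window Downstream window length in bp (default 2000).
#' @param eps Pseudocount (default 1).
#' @return Numeric vector of readthrough indices, one per interval.
#' @export
readthrough_index <- function(proseq, tts, body_window = 2000,
                              down_window = 2000, eps = 1) {
  stopifnot(body_window > 0, down_window > 0)
  if (any(tts$strand == "*")) stop("terminator intervals must be stranded")
  plus <- tts$strand == "+"
  a <- ifelse(plus, tts$end - 1, tts$start) # 3' end base (0-based)
  body <- data.frame(chrom = tts$chrom,
                     start = ifelse(plus, pmax(0, a - body_window + 1), a),
                     end = ifelse(plus, a + 1, a + body_window),
                     strand = tts$strand)
  down <- data.frame(chrom = tts$chrom,
                     start = ifelse(plus, a + 1, pmax(0, a - down_window)),
                     end = ifelse(plus, a + 1 + down_window, a),
                     strand = tts$strand)
  nb <- count_tags(proseq, body, "sense")
  nd <- count_tags(proseq, down, "sense")
  (nd + eps) / (nb + eps)
}

#' Persist a heatmap as TSV
#'
#' Header block columns (region id, chrom, start, end, strand) followed by
#' one column per bin (named by bin center).
#'
#' @param h A `hush_heatmap`.
#' @param path Output path.
#' @export
write_heatmap_tsv <- function(h, path) {
  stopifnot(inherits(h, "hush_heatmap"))
  df <- data.frame(region_id = rownames(h$values), chrom = h$regions$chrom,
                   start = h$regions$start, end = h$regions$end,
                   strand = h$regions$strand, h$values, check.names = FALSE)
  colnames(df)[-(1:5)] <- h$bin_centers
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Persist a profile as TSV (bin_center, value, lower, upper)
#' @param p A `hush_profile`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(p, path) {
  utils::write.table(as.data.frame(p), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
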