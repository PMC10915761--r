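#' Build a regions x samples tag-count table
#'
#' @param regions An [interval_set()] (e.g. superset regions).
#' @param tracks Named list of [tag_track()]s, one per sample.
#' @param strand_mode Passed to [count_tags()] (default `"both"`).
#' @return A list of class `count_table` with `counts` (integer matrix,
#'   regions x samples), `total_aligned` (per-sample), and `regions`.
#' @export
count_table <- function(regions, tracks, strand_mode = "both") {
  stopifnot(inherits(regions, "interval_set"), is.list(tracks), length(tracks) >= 1)
  if (is.null(names(tracks))) names(tracks) <- paste0("sample", seq_along(tracks))
  counts <- vapply(tracks, function(tr) count_tags(tr, regions, strand_mode),
                   integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(region_ids(regions), names(tracks)))
  structure(list(counts = counts,
                 total_aligned = vapply(tracks, function(t) t$total_aligned, 0),
                 regions = regions),
            class = "count_table")
}

region_ids <- function(regions) {
  ids <- regions$name
  if (any(is.na(ids)) || anyDuplicated(ids))
    ids <- sprintf("R%04d", seq_len(nrow(regions)))
  ids
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across regions of
#' the ratio of each sample's count to the row geometric mean, using only
#' regions with all-positive counts; factors are then rescaled to geometric
#' mean 1.
#'
#' @param x A [count_table()] or a counts matrix (regions x samples).
#' @return Numeric vector of positive factors, one per sample, with
#'   geometric mean 1.
#' @export
compute_size_factors <- function(x) {
  counts <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (ncol(counts) < 2) stop("size factors require >= 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no region with all-positive counts; consider adding pseudocounts")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- exp(apply(lc - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial enrichment test (IP vs. control)
#'
#' Per-region Wald test on the log2 fold change of size-factor-normalized
#' counts between an IP group and a control group, under a negative-binomial
#' model. Dispersions are estimated by method of moments and pooled across
#' regions within count-abundance bins (mean of per-region estimates per
#' bin, which keeps the moment estimator unbiased after pooling). The log2 fold change is `log2(mu_ip / mu_ctrl)`; when either group
#' mean is zero, 0.5 is added to both. The Wald variance of the log mean for
#' a group with `n` samples and normalized mean `mu` is
#' `(1/n) * (1/max(mu, 0.5) + alpha_disp)`. P-values are BH-adjusted across
#' all regions jointly; a region is called enriched when `q <= alpha` and
#' `log2FC >= lfc_min`.
#'
#' @param x A [count_table()] or counts matrix.
#' @param ip_samples,control_samples Column names or indices of the two
#'   groups (each non-empty).
#' @param alpha Nominal FDR level in (0, 1) (default 0.05).
#' @param lfc_min Minimum log2 fold change for a call (default 1).
#' @param size_factors Optional precomputed factors; computed from all
#'   samples otherwise.
#' @param n_bins Number of abundance bins for dispersion pooling.
#' @return data.frame of class `nb_test` with columns `region`, `base_mean`,
#'   `log2fc`, `se`, `p`, `q`, `call`, `dispersion`.
#' @export
nb_enrichment_test <- function(x, ip_samples, control_samples, alpha = 0.05,
                               lfc_min = 1, size_factors = NULL, n_bins = 20) {
  counts <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("R%04d", seq_len(nrow(counts)))
  ip <- resolve_cols(counts, ip_samples)
  ctrl <- resolve_cols(counts, control_samples)
  if (length(ip) == 0 || length(ctrl) == 0)
    stop("both the IP and control group must contain at least one sample")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  norm <- sweep(counts, 2, size_factors, "/")

  mu_ip <- rowMeans(norm[, ip, drop = FALSE])
  mu_ctrl <- rowMeans(norm[, ctrl, drop = FALSE])
  base_mean <- rowMeans(norm)

  disp <- pooled_dispersion(norm, ip, ctrl, base_mean, n_bins)

  zero <- mu_ip == 0 | mu_ctrl == 0
  num <- ifelse(zero, mu_ip + 0.5, mu_ip)
  den <- ifelse(zero, mu_ctrl + 0.5, mu_ctrl)
  log2fc <- log2(num / den)
  v_ip <- (1 / length(ip)) * (1 / pmax(mu_ip, 0.5) + disp)
  v_ctrl <- (1 / length(ctrl)) * (1 / pmax(mu_ctrl, 0.5) + disp)
  se <- sqrt(v_ip + v_ctrl) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[base_mean == 0] <- 1
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(region = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, se = se, p = p, q = q,
                    call = q <= alpha & log2fc >= lfc_min,
                    dispersion = disp, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("nb_test", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "lfc_min") <- lfc_min
  res
}

resolve_cols <- function(counts, cols) {
  if (is.character(cols)) match(cols, colnames(counts)) else as.integer(cols)
}

# method-of-moments dispersion pooled within abundance bins
pooled_dispersion <- function(norm, ip, ctrl, base_mean, n_bins) {
  n_ip <- length(ip); n_ctrl <- length(ctrl)
  df_within <- (n_ip - 1) + (n_ctrl - 1)
  if (df_within >= 1) {
    ss_ip <- if (n_ip > 1) apply(norm[, ip, drop = FALSE], 1, stats::var) * (n_ip - 1) else 0
    ss_ctrl <- if (n_ctrl > 1) apply(norm[, ctrl, drop = FALSE], 1, stats::var) * (n_ctrl - 1) else 0
    s2 <- (ss_ip + ss_ctrl) / df_within
  } else {
    # no replicates: fall back to cross-group variance (conservative)
    s2 <- apply(norm, 1, stats::var)
  }
  ahat <- ifelse(base_mean > 0, (s2 - base_mean) / base_mean^2, NA_real_)
  ahat <- pmax(ahat, 0)
  # quantile bins on base mean, at least ~100 regions per bin so bin means
  # are stable (per-region moment estimates are very noisy at small n)
  n_ok <- sum(base_mean > 0)
  k <- max(1L, min(n_bins, floor(n_ok / 100)))
  br <- unique(stats::quantile(base_mean[base_mean > 0], probs = seq(0, 1, length.out = k + 1)))
  if (length(br) < 2) br <- range(base_mean[base_mean > 0]) + c(-1, 1)
  bin <- cut(base_mean, breaks = br, include.lowest = TRUE)
  # bin means keep the method-of-moments estimator unbiased after pooling;
  # flooring each bin at the global mean stops downward bin noise (and the
  # selection of apparently clean bins) from inflating the Wald far tail,
  # and a 2-SE margin propagates the dispersion-estimation uncertainty that
  # the plug-in Wald variance would otherwise ignore
  disp_bin <- tapply(ahat, bin, mean, na.rm = TRUE)
  disp_se <- tapply(ahat, bin, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  global <- mean(ahat, na.rm = TRUE)
  if (!is.finite(global)) global <- 0
  global_se <- stats::sd(ahat, na.rm = TRUE) / sqrt(max(1, sum(!is.na(ahat))))
  if (!is.finite(global_se)) global_se <- 0
  margin <- 2 * as.double(disp_se[as.character(bin)])
  margin[is.na(margin)] <- 2 * global_se
  disp <- pmax(as.double(disp_bin[as.character(bin)]), global) + margin
  disp[is.na(disp)] <- global + 2 * global_se
  pmax(disp, 1e-8)
}
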