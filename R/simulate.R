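#' Configuration for the synthetic multi-assay dataset
#'
#' Defines the planted study conditions: three region classes with distinct
#' ChIP/RNA/PRO/CLIP signal structure on a small two-chromosome genome,
#' terminator-associated H3K9me3-negative HUSH regions, and two perturbation
#' conditions (WDR82 knockout with HUSH signal loss, a downstream peak
#' shift at terminator-proximal HUSH regions and transcriptional
#' readthrough; MPP8 depletion with de-repression of H3K9me3-positive
#' targets and reduced expression of H3K9me3-negative targets).
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param chrom_lengths Named chromosome lengths (default two 5 Mb
#'   chromosomes).
#' @param n_regions Planted regions per class.
#' @param width_meanlog,width_sdlog Log-normal region width parameters
#'   (median 1 kb by default).
#' @param width_range Hard clamp on region widths in bp.
#' @param min_gap Minimum gap between planted regions in bp (default 11 kb,
#'   keeping default +/-5 kb heatmap windows disjoint).
#' @param background_rate Background tag rate per bp per library.
#' @param dispersion Negative-binomial dispersion of per-bp tag counts.
#' @param folds Named list of per-assay, per-class enrichment folds over
#'   background.
#' @param tts_fraction Fraction of HUSH_K9NEG regions planted at gene
#'   terminators (default 0.75).
#' @param gene_length Length of planted genes in bp.
#' @param n_background_genes Genes placed away from planted regions.
#' @param pro_gene_fold Sense-strand PRO-seq fold over background in gene
#'   bodies.
#' @param k9_replicates Replicates simulated for the H3K9me3 IP and input.
#' @param wdr82_ko List: `hush_fold_mult` (HUSH ChIP signal retained in the
#'   KO), `shift_bp` (downstream shift of the KO signal at the shifted
#'   subset, which is the terminator-proximal HUSH_K9NEG regions),
#'   `readthrough_fold` (PRO-seq fold past affected terminators),
#'   `readthrough_window` (bp).
#' @param mpp8_depletion List: multipliers on RNA rates at HUSH_K9POS and
#'   HUSH_K9NEG regions.
#' @param a_rich_prob Probability of `A` at HUSH_K9POS bases in the
#'   synthetic sequence (background bases are uniform).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    chrom_lengths = c(chrS1 = 5e6, chrS2 = 5e6),
    n_regions = c(HUSH_K9POS = 100, HUSH_K9NEG = 200, MPP8_ONLY = 100),
    width_meanlog = log(1000), width_sdlog = 0.3,
    width_range = c(300, 2000),
    min_gap = 11000,
    background_rate = 0.01,
    dispersion = 0.2,
    folds = list(
      mpp8    = c(HUSH_K9POS = 8, HUSH_K9NEG = 8, MPP8_ONLY = 8),
      tasor   = c(HUSH_K9POS = 8, HUSH_K9NEG = 8, MPP8_ONLY = 1),
      h3k9me3 = c(HUSH_K9POS = 10, HUSH_K9NEG = 1, MPP8_ONLY = 10),
      input   = c(HUSH_K9POS = 1, HUSH_K9NEG = 1, MPP8_ONLY = 1),
      rna     = c(HUSH_K9POS = 2, HUSH_K9NEG = 10, MPP8_ONLY = 1),
      pro     = c(HUSH_K9POS = 5, HUSH_K9NEG = 10, MPP8_ONLY = 5),
      clip    = c(HUSH_K9POS = 10, HUSH_K9NEG = 10, MPP8_ONLY = 1)),
    tts_fraction = 0.75,
    gene_length = 5000,
    n_background_genes = 50,
    pro_gene_fold = 10,
    k9_replicates = 2,
    wdr82_ko = list(hush_fold_mult = 0.2, shift_bp = 500,
                    readthrough_fold = 5, readthrough_window = 2000),
    mpp8_depletion = list(rna_k9pos_mult = 4, rna_k9neg_mult = 0.5),
    a_rich_prob = 0.5) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg$folds) > 0), cfg$tts_fraction >= 0,
            cfg$tts_fraction <= 1, all(cfg$n_regions >= 1),
            cfg$background_rate > 0, cfg$dispersion >= 0,
            cfg$k9_replicates >= 1, cfg$k9_replicates <= 4)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate the synthetic genome, annotations and ground truth
#'
#' Places non-overlapping regions of the three classes (log-normal widths,
#' minimum gap enforced), co-locates the configured fraction of
#' `HUSH_K9NEG` regions with gene terminators (gene TTS at the region
#' center, gene strand = region orientation), plants `L1like` repeats at
#' `HUSH_K9POS` regions and `LTRlike` repeats at `MPP8_ONLY` regions plus
#' scattered background repeats, and adds background genes away from all
#' planted regions. Deterministic given the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_annotations`: `genome`, `truth`
#'   (data.frame with one row per planted region: `region_id`, coordinates,
#'   `width`, `class`, `strand`, `at_terminator`, `shifted`), `regions`,
#'   `genes`, `repeats` (an [annotation_track()]) and `peaks` (named list
#'   of per-factor peak interval sets).
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    genome <- hush_genome(cfg$chrom_lengths)
    n_tot <- sum(cfg$n_regions)
    widths <- round(stats::rlnorm(n_tot, cfg$width_meanlog, cfg$width_sdlog))
    widths <- pmin(pmax(widths, cfg$width_range[1]), cfg$width_range[2])

    # allocate regions to chromosomes proportionally to length
    lens <- unclass(genome)
    n_chr <- pmax(1L, round(n_tot * lens / sum(lens)))
    while (sum(n_chr) > n_tot) n_chr[which.max(n_chr)] <- n_chr[which.max(n_chr)] - 1L
    while (sum(n_chr) < n_tot) n_chr[which.min(n_chr)] <- n_chr[which.min(n_chr)] + 1L

    chrom <- character(0); start <- numeric(0)
    w_idx <- 0L
    for (ci in seq_along(lens)) {
      k <- n_chr[ci]
      w <- widths[w_idx + seq_len(k)]
      w_idx <- w_idx + k
      need <- sum(w) + (k + 1) * cfg$min_gap
      if (need > lens[ci])
        stop("genome too small to place ", k, " regions on ", names(lens)[ci],
             " without overlap; need ", need, " bp")
      slack <- lens[ci] - need
      u <- stats::runif(k + 1)
      extra <- floor(slack * u / sum(u))
      gaps <- cfg$min_gap + extra
      s <- cumsum(gaps[seq_len(k)] + c(0, w[-k]))
      chrom <- c(chrom, rep(names(lens)[ci], k))
      start <- c(start, s)
    }
    label <- sample(rep(names(cfg$n_regions), cfg$n_regions))
    strand <- sample(c("+", "-"), n_tot, replace = TRUE)

    truth <- data.frame(region_id = sprintf("T%04d", seq_len(n_tot)),
                        chrom = chrom, start = start, end = start + widths,
                        width = widths, class = label, strand = strand,
                        at_terminator = FALSE, shifted = FALSE,
                        stringsAsFactors = FALSE)
    k9neg <- which(truth$class == "HUSH_K9NEG")
    n_term <- floor(cfg$tts_fraction * length(k9neg))
    at_term <- sample(k9neg, n_term)
    truth$at_terminator[at_term] <- TRUE
    # the WDR82-KO shifted subset: terminator-proximal HUSH_K9NEG regions
    truth$shifted[at_term] <- TRUE

    regions <- interval_set(truth$chrom, truth$start, truth$end,
                            name = truth$region_id, strand = truth$strand,
                            genome = genome)

    # terminator genes: TTS at the region center, strand = orientation
    centers <- floor((truth$start + truth$end) / 2)
    tg <- truth[truth$at_terminator, , drop = FALSE]
    tg_centers <- centers[truth$at_terminator]
    g_start <- ifelse(tg$strand == "+", tg_centers - cfg$gene_length + 1,
                      tg_centers)
    g_end <- g_start + cfg$gene_length
    g_start <- pmax(0, g_start)
    genes <- data.frame(chrom = tg$chrom, start = g_start, end = g_end,
                        strand = tg$strand,
                        name = paste0("gene_", tg$region_id),
                        stringsAsFactors = FALSE)

    # background genes in gaps, kept clear of every planted region
    bg_genes <- place_in_gaps(truth, lens, n = cfg$n_background_genes,
                              width = cfg$gene_length, margin = 2000)
    if (nrow(bg_genes) > 0) {
      bg_genes$strand <- sample(c("+", "-"), nrow(bg_genes), replace = TRUE)
      bg_genes$name <- paste0("bggene_", seq_len(nrow(bg_genes)))
      genes <- rbind(genes, bg_genes[names(genes)])
    }
    genes <- interval_set(genes$chrom, genes$start, genes$end,
                          name = genes$name, strand = genes$strand,
                          genome = genome)

    # repeats: class-specific families inside regions + scattered background
    rep_list <- list()
    for (cls in c("HUSH_K9POS", "MPP8_ONLY")) {
      fam <- if (cls == "HUSH_K9POS") "L1like" else "LTRlike"
      sub <- truth[truth$class == cls, , drop = FALSE]
      ctr <- floor((sub$start + sub$end) / 2)
      hw <- pmin(300, floor(sub$width / 2) - 10)
      rep_list[[fam]] <- data.frame(chrom = sub$chrom, start = ctr - hw,
                                    end = ctr + hw, category = fam,
                                    stringsAsFactors = FALSE)
    }
    bg_rep <- place_in_gaps(truth, lens, n = 100, width = 300, margin = 2000)
    if (nrow(bg_rep) > 0)
      bg_rep$category <- sample(c("L1like", "LTRlike"), nrow(bg_rep),
                                replace = TRUE)
    rep_df <- rbind(do.call(rbind, rep_list),
                    if (nrow(bg_rep) > 0) bg_rep[c("chrom", "start", "end", "category")])
    repeats <- annotation_track(
      interval_set(rep_df$chrom, rep_df$start, rep_df$end,
                   name = rep_df$category, genome = genome))

    # per-factor peak calls are emitted from truth (peak calling is out of
    # scope): every region is an MPP8 peak, HUSH regions are TASOR peaks,
    # H3K9me3 peaks sit where the mark is planted
    peak_of <- function(keep) interval_set(truth$chrom[keep], truth$start[keep],
                                           truth$end[keep],
                                           name = truth$region_id[keep])
    peaks <- list(
      mpp8 = peak_of(rep(TRUE, n_tot)),
      tasor = peak_of(truth$class %in% c("HUSH_K9POS", "HUSH_K9NEG")),
      h3k9me3 = peak_of(truth$class %in% c("HUSH_K9POS", "MPP8_ONLY")))

    structure(list(genome = genome, truth = truth, regions = regions,
                   genes = genes, repeats = repeats, peaks = peaks,
                   config = cfg),
              class = "synthetic_annotations")
  })
}

# place n non-overlapping intervals of the given width inside gaps between
# planted regions, at least `margin` bp away from any region
place_in_gaps <- function(truth, lens, n, width, margin) {
  out <- list()
  for (cc in names(lens)) {
    sub <- truth[truth$chrom == cc, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gap_lo <- c(0, sub$end + margin)
    gap_hi <- c(sub$start - margin, lens[[cc]])
    ok <- gap_hi - gap_lo >= width
    out[[cc]] <- data.frame(chrom = cc, lo = gap_lo[ok],
                            hi = gap_hi[ok] - width)
  }
  gaps <- do.call(rbind, out)
  if (nrow(gaps) == 0 || n == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  pick <- gaps[sample.int(nrow(gaps), min(n, nrow(gaps))), , drop = FALSE]
  start <- floor(stats::runif(nrow(pick), pick$lo, pick$hi))
  data.frame(chrom = pick$chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

#' Simulate tag tracks for the synthetic dataset
#'
#' Per-bp tag counts are drawn from a negative binomial with mean
#' `background_rate x fold(region, assay, condition)` and the configured
#' dispersion (Poisson in the `dispersion = 0` limit). PRO-seq and CLIP
#' strands follow the planted region orientation; gene bodies carry
#' sense-strand PRO-seq signal. KO conditions apply the configured effects:
#' the WDR82-KO TASOR signal is attenuated and, at the shifted subset,
#' displaced downstream; WDR82-KO PRO-seq gains readthrough past affected
#' terminators; MPP8 depletion rescales RNA rates per class.
#'
#' @param cfg A [synthetic_config()].
#' @param ann A [simulate_annotations()] result built from `cfg`.
#' @param assays Subset of
#'   `c("mpp8","tasor","h3k9me3","input","rna","pro","clip")` to simulate.
#' @param conditions Subset of `c("wt","wdr82_ko","mpp8_depletion")`.
#' @return Named list of [tag_track()]s. WT tracks: `mpp8`, `tasor`,
#'   `k9_ip_1..k`, `input_1..k`, `rna`, `pro_plus`, `pro_minus`, `clip`.
#'   Condition tracks: `tasor_wdr82ko`, `pro_plus_wdr82ko`,
#'   `pro_minus_wdr82ko`, `rna_mpp8dep`.
#' @export
simulate_tracks <- function(cfg, ann,
                            assays = c("mpp8", "tasor", "h3k9me3", "input",
                                       "rna", "pro", "clip"),
                            conditions = c("wt", "wdr82_ko", "mpp8_depletion")) {
  stopifnot(inherits(ann, "synthetic_annotations"))
  truth <- ann$truth
  lens <- unclass(ann$genome)
  bg <- cfg$background_rate
  tracks <- list()

  # one stable sub-seed per track name, so a track is byte-identical
  # whether simulated alone or as part of the full set
  seed_of <- c(mpp8 = 11L, tasor = 12L, k9_ip_1 = 13L, k9_ip_2 = 14L,
               k9_ip_3 = 15L, k9_ip_4 = 16L, input_1 = 21L, input_2 = 22L,
               input_3 = 23L, input_4 = 24L, rna = 31L, pro_plus = 41L,
               pro_minus = 42L, clip_plus = 51L, clip_minus = 52L,
               tasor_wdr82ko = 61L, pro_plus_wdr82ko = 62L,
               pro_minus_wdr82ko = 63L, rna_mpp8dep = 71L)
  track_seed <- function(nm) (cfg$seed * 1009L + seed_of[[nm]]) %% .Machine$integer.max

  base_rates <- function() lapply(lens, function(L) rep(bg, L))
  add_regions <- function(rates, sub, add) {
    for (i in seq_len(nrow(sub))) {
      cc <- sub$chrom[i]
      idx <- (sub$start[i] + 1):sub$end[i]
      rates[[cc]][idx] <- rates[[cc]][idx] + add[i]
    }
    rates
  }
  draw <- function(rates, nm, strand = NULL) {
    sample_track_nb(rates, cfg$dispersion, track_seed(nm), strand = strand)
  }

  chip_rates <- function(fold_by_class) {
    add <- bg * (fold_by_class[truth$class] - 1)
    add_regions(base_rates(), truth, pmax(add, -bg + 1e-9))
  }

  if ("wt" %in% conditions) {
    if ("mpp8" %in% assays) tracks$mpp8 <- draw(chip_rates(cfg$folds$mpp8), "mpp8")
    if ("tasor" %in% assays) tracks$tasor <- draw(chip_rates(cfg$folds$tasor), "tasor")
    if ("h3k9me3" %in% assays) {
      for (r in seq_len(cfg$k9_replicates)) {
        nm <- paste0("k9_ip_", r)
        tracks[[nm]] <- draw(chip_rates(cfg$folds$h3k9me3), nm)
      }
      for (r in seq_len(cfg$k9_replicates)) {
        nm <- paste0("input_", r)
        tracks[[nm]] <- draw(chip_rates(cfg$folds$input), nm)
      }
    }
    if ("rna" %in% assays) tracks$rna <- draw(chip_rates(cfg$folds$rna), "rna")
    if ("pro" %in% assays) {
      pr <- pro_rates(cfg, ann, readthrough = FALSE)
      tracks$pro_plus <- draw(pr$plus, "pro_plus", strand = "+")
      tracks$pro_minus <- draw(pr$minus, "pro_minus", strand = "-")
    }
    if ("clip" %in% assays) {
      cl <- stranded_region_rates(cfg, ann, cfg$folds$clip)
      plus <- draw(cl$plus, "clip_plus", strand = "+")
      minus <- draw(cl$minus, "clip_minus", strand = "-")
      tracks$clip <- combine_tracks(plus, minus)
    }
  }
  if ("wdr82_ko" %in% conditions) {
    if ("tasor" %in% assays) {
      ko <- cfg$wdr82_ko
      hush <- truth[truth$class %in% c("HUSH_K9POS", "HUSH_K9NEG"), , drop = FALSE]
      add <- bg * (cfg$folds$tasor[hush$class] - 1) * ko$hush_fold_mult
      shift <- ifelse(hush$shifted,
                      ifelse(hush$strand == "+", ko$shift_bp, -ko$shift_bp), 0)
      shifted <- hush
      shifted$start <- pmax(0, hush$start + shift)
      shifted$end <- pmin(lens[hush$chrom], hush$end + shift)
      tracks$tasor_wdr82ko <- draw(add_regions(base_rates(), shifted, add),
                                   "tasor_wdr82ko")
    }
    if ("pro" %in% assays) {
      pr <- pro_rates(cfg, ann, readthrough = TRUE)
      tracks$pro_plus_wdr82ko <- draw(pr$plus, "pro_plus_wdr82ko", strand = "+")
      tracks$pro_minus_wdr82ko <- draw(pr$minus, "pro_minus_wdr82ko", strand = "-")
    }
  }
  if ("mpp8_depletion" %in% conditions && "rna" %in% assays) {
    dep <- cfg$mpp8_depletion
    f <- cfg$folds$rna
    f["HUSH_K9POS"] <- f["HUSH_K9POS"] * dep$rna_k9pos_mult
    f["HUSH_K9NEG"] <- f["HUSH_K9NEG"] * dep$rna_k9neg_mult
    tracks$rna_mpp8dep <- draw(chip_rates(f), "rna_mpp8dep")
  }
  tracks
}

# sense-strand rates at regions split onto genomic strands by orientation
stranded_region_rates <- function(cfg, ann, fold_by_class) {
  truth <- ann$truth
  lens <- unclass(ann$genome)
  bg <- cfg$background_rate
  plus <- lapply(lens, function(L) rep(bg / 2, L))
  minus <- lapply(lens, function(L) rep(bg / 2, L))
  for (i in seq_len(nrow(truth))) {
    add <- bg * (fold_by_class[[truth$class[i]]] - 1)
    if (add == 0) next
    cc <- truth$chrom[i]
    idx <- (truth$start[i] + 1):truth$end[i]
    if (truth$strand[i] == "+") plus[[cc]][idx] <- plus[[cc]][idx] + add
    else minus[[cc]][idx] <- minus[[cc]][idx] + add
  }
  list(plus = plus, minus = minus)
}

# PRO-seq rates: stranded region signal plus sense-strand gene-body signal;
# optional readthrough past terminators of shifted regions (WDR82 KO).
# At terminator-proximal regions the region signal models RNAPII
# accumulating up to the TTS (the region center), so it is planted on the
# upstream side only; elsewhere it spans the whole region.
pro_rates <- function(cfg, ann, readthrough = FALSE) {
  truth <- ann$truth
  lens <- unclass(ann$genome)
  bg <- cfg$background_rate
  trunc <- truth
  ctr_all <- floor((truth$start + truth$end) / 2)
  at <- truth$at_terminator
  trunc$end[at & truth$strand == "+"] <- ctr_all[at & truth$strand == "+"] + 1
  trunc$start[at & truth$strand == "-"] <- ctr_all[at & truth$strand == "-"]
  rr <- stranded_region_rates(cfg, structure(list(truth = trunc,
                                                  genome = ann$genome),
                                             class = "synthetic_annotations"),
                              cfg$folds$pro)
  genes <- ann$genes
  add_span <- function(rr, cc, lo, hi, strand, add) {
    lo <- max(0, lo); hi <- min(lens[[cc]], hi)
    if (hi <= lo) return(rr)
    idx <- (lo + 1):hi
    side <- if (strand == "+") "plus" else "minus"
    rr[[side]][[cc]][idx] <- rr[[side]][[cc]][idx] + add
    rr
  }
  g_add <- bg * (cfg$pro_gene_fold - 1)
  for (i in seq_len(nrow(genes)))
    rr <- add_span(rr, genes$chrom[i], genes$start[i], genes$end[i],
                   genes$strand[i], g_add)
  if (readthrough) {
    ko <- cfg$wdr82_ko
    shifted <- truth[truth$shifted, , drop = FALSE]
    ctr <- floor((shifted$start + shifted$end) / 2) # = the planted TTS
    rt_add <- (bg / 2) * (ko$readthrough_fold - 1)
    for (i in seq_len(nrow(shifted))) {
      if (shifted$strand[i] == "+")
        rr <- add_span(rr, shifted$chrom[i], ctr[i] + 1,
                       ctr[i] + 1 + ko$readthrough_window, "+", rt_add)
      else
        rr <- add_span(rr, shifted$chrom[i], ctr[i] - ko$readthrough_window,
                       ctr[i], "-", rt_add)
    }
  }
  rr
}

# draw a tag track from per-bp NB rates (Poisson when dispersion == 0)
sample_track_nb <- function(rates, dispersion, seed, strand = NULL) {
  withr::with_seed(seed, {
    chrom <- character(0); pos <- numeric(0); str <- character(0)
    for (cc in names(rates)) {
      mu <- rates[[cc]]
      cnt <- if (dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else stats::rpois(length(mu), mu)
      nz <- which(cnt > 0L)
      if (length(nz) == 0) next
      p <- rep.int(nz - 1L, cnt[nz])
      chrom <- c(chrom, rep(cc, length(p)))
      pos <- c(pos, p)
      str <- c(str, if (is.null(strand))
        sample(c("+", "-"), length(p), replace = TRUE)
        else rep(strand, length(p)))
    }
    tag_track(chrom, pos, str)
  })
}

combine_tracks <- function(a, b) merge_tag_tracks(a, b)

#' Simulate the full synthetic dataset
#'
#' Convenience wrapper running [simulate_annotations()] and
#' [simulate_tracks()].
#'
#' @param cfg A [synthetic_config()] (default configuration when missing).
#' @param assays,conditions Passed to [simulate_tracks()].
#' @return List of class `synthetic_dataset` with `config`, `annotations`,
#'   `truth`, `tracks`, `peaks`.
#' @export
simulate_hush <- function(cfg = synthetic_config(),
                          assays = c("mpp8", "tasor", "h3k9me3", "input",
                                     "rna", "pro", "clip"),
                          conditions = c("wt", "wdr82_ko", "mpp8_depletion")) {
  ann <- simulate_annotations(cfg)
  tracks <- simulate_tracks(cfg, ann, assays = assays, conditions = conditions)
  structure(list(config = cfg, annotations = ann, truth = ann$truth,
                 tracks = tracks, peaks = ann$peaks),
            class = "synthetic_dataset")
}

#' Simulate the synthetic genome sequence
#'
#' Random sequence with uniform base composition except at `HUSH_K9POS`
#' regions, where `A` is drawn with probability `a_rich_prob` (the three
#' other bases share the remainder equally).
#'
#' @param cfg A [synthetic_config()].
#' @param ann A [simulate_annotations()] result.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_sequences <- function(cfg, ann) {
  stopifnot(inherits(ann, "synthetic_annotations"))
  lens <- unclass(ann$genome)
  truth <- ann$truth
  withr::with_seed(cfg$seed + 7L, {
    seqs <- lapply(names(lens), function(cc) {
      s <- sample(c("A", "C", "G", "T"), lens[[cc]], replace = TRUE)
      sub <- truth[truth$chrom == cc & truth$class == "HUSH_K9POS", , drop = FALSE]
      p <- cfg$a_rich_prob
      for (i in seq_len(nrow(sub))) {
        idx <- (sub$start[i] + 1):sub$end[i]
        s[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE,
                         prob = c(p, rep((1 - p) / 3, 3)))
      }
      paste0(s, collapse = "")
    })
    stats::setNames(Biostrings::DNAStringSet(unlist(seqs)), names(lens))
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits chrom.sizes, per-factor peak BEDs, region/truth tables, gene and
#' repeat BEDs, and one tag BED per track (one row per tag).
#'
#' @param sim A [simulate_hush()] result.
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim$annotations
  write_chrom_sizes(ann$genome, file.path(dir, "chrom.sizes"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  write_bed(ann$regions, file.path(dir, "regions.bed"))
  write_bed(ann$genes, file.path(dir, "genes.bed"))
  write_bed(ann$repeats, file.path(dir, "repeats.bed"))
  for (nm in names(sim$peaks))
    write_bed(sim$peaks[[nm]], file.path(dir, paste0("peaks_", nm, ".bed")))
  for (nm in names(sim$tracks)) {
    d <- stops_as_df(sim$tracks[[nm]])
    utils::write.table(
      data.frame(d$chrom, format(d$pos, scientific = FALSE, trim = TRUE),
                 format(d$pos + 1, scientific = FALSE, trim = TRUE),
                 ".", 1, d$strand),
      file.path(dir, paste0("tags_", nm, ".bed")), quote = FALSE,
      sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Run the classification pipeline on simulated (or real) inputs
#'
#' Consolidates the peak sets with mean shift, counts H3K9me3 IP/input tags
#' over the superset regions, runs the NB enrichment test, classifies the
#' regions, and orients them by PRO-seq strand ratio when PRO tracks are
#' given.
#'
#' @param peaks Named list with elements `mpp8`, `tasor` and optionally
#'   more peak sets; all seed the superset.
#' @param k9_ip,k9_input Lists of [tag_track()]s (replicates).
#' @param pro_plus,pro_minus Optional [tag_track()]s for orientation.
#' @param bandwidth Mean-shift bandwidth (default 500 bp).
#' @param alpha,lfc_min H3K9me3 call thresholds (defaults 0.05 / 1).
#' @param window Orientation window half-width (default 1000 bp).
#' @return A `region_classification`; the superset and NB test are attached
#'   as attributes `superset` and `nb_test`.
#' @export
classify_pipeline <- function(peaks, k9_ip, k9_input, pro_plus = NULL,
                              pro_minus = NULL, bandwidth = 500,
                              alpha = 0.05, lfc_min = 1, window = 1000) {
  stopifnot(all(c("mpp8", "tasor") %in% names(peaks)))
  superset <- consolidate_meanshift(peaks, bandwidth = bandwidth)
  tracks <- c(stats::setNames(k9_ip, paste0("ip_", seq_along(k9_ip))),
              stats::setNames(k9_input, paste0("input_", seq_along(k9_input))))
  ct <- count_table(superset$regions, tracks)
  # depth-based size factors: consolidated regions are mostly enriched in
  # the IP, which violates the median-of-ratios assumption that most
  # features are unchanged, so normalize by total aligned tags instead
  sf <- ct$total_aligned / exp(mean(log(ct$total_aligned)))
  nb <- nb_enrichment_test(ct, ip_samples = seq_along(k9_ip),
                           control_samples = length(k9_ip) + seq_along(k9_input),
                           alpha = alpha, lfc_min = lfc_min,
                           size_factors = sf)
  cls <- classify_regions(superset, peaks$mpp8, peaks$tasor, nb)
  if (!is.null(pro_plus) && !is.null(pro_minus))
    cls <- orient_by_proseq(cls, pro_plus, pro_minus, window = window)
  attr(cls, "superset") <- superset
  attr(cls, "nb_test") <- nb
  cls
}

#' Fraction of planted regions recovering their true class
#'
#' Each planted truth region is matched to the classified superset region
#' with the largest overlap; the recovery is the fraction of truth regions
#' whose matched label equals the planted class (unmatched regions count
#' as errors).
#'
#' @param classification A `region_classification`.
#' @param truth The simulator truth table.
#' @return Fraction in [0, 1]; attribute `table` holds the planted-vs-called
#'   label table.
#' @export
class_recovery <- function(classification, truth) {
  tr <- interval_set(truth$chrom, truth$start, truth$end, name = truth$region_id)
  hits <- overlap_hits(tr, classification)
  called <- rep(NA_character_, nrow(truth))
  if (nrow(hits) > 0) {
    ov <- pmin(classification$end[hits$b], tr$end[hits$a]) -
      pmax(classification$start[hits$b], tr$start[hits$a])
    hits <- hits[order(hits$a, -ov), , drop = FALSE]
    best <- hits[!duplicated(hits$a), , drop = FALSE]
    called[best$a] <- as.character(classification$label[best$b])
  }
  ok <- !is.na(called) & called == truth$class[match(tr$name, truth$region_id)]
  structure(mean(ok),
            table = table(planted = truth$class[match(tr$name, truth$region_id)],
                          called = ifelse(is.na(called), "none", called)))
}
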