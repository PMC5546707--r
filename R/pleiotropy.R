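#' Tile the genome into analysis windows
#'
#' Partitions each retained chromosome into consecutive windows of
#' `window_bp` (default 1 Mb) anchored at position 1; the last partial window
#' is kept. Sex chromosomes are dropped, as are windows containing no SNP
#' from the supplied summary statistics.
#'
#' @param layout A [genome_layout()].
#' @param stats One [sumstats()] table, or a list of them; a window is
#'   retained if any supplied study has a SNP in it.
#' @param window_bp Window length in bp.
#' @param drop_sex Drop chromosomes named chrX/chrY/X/Y.
#' @return An object of class `window_grid` with `windows` (`GRanges`) and
#'   `window_bp`.
#' @export
window_grid <- function(layout, stats, window_bp = 1e6, drop_sex = TRUE) {
  if (inherits(stats, "sumstats")) stats <- list(stats)
  chroms <- layout$names
  if (drop_sex) chroms <- setdiff(chroms, c("chrX", "chrY", "X", "Y"))
  grl <- lapply(chroms, function(chr) {
    len <- layout$lengths[match(chr, layout$names)]
    starts <- seq(1, len, by = window_bp)
    GenomicRanges::GRanges(chr,
      IRanges::IRanges(start = starts, end = pmin(starts + window_bp - 1, len)),
      seqinfo = as_seqinfo(layout))
  })
  win <- do.call(c, grl)
  pos <- do.call(rbind, lapply(stats, function(s) s[c("chr", "bp")]))
  snp_gr <- positions_to_granges(pos, layout)
  if (!length(snp_gr)) stop("no SNPs supplied to anchor the window grid")
  win <- win[IRanges::overlapsAny(win, snp_gr)]
  if (!length(win)) stop("no window contains a SNP")
  structure(list(windows = win, window_bp = window_bp, layout = layout),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %s bp\n", length(x$windows),
              format(x$window_bp, big.mark = ",")))
  invisible(x)
}

# per-SNP window index (NA when outside every retained window)
snp_window_index <- function(stats, grid) {
  gr <- positions_to_granges(stats[c("chr", "bp")], grid$layout)
  hits <- GenomicRanges::findOverlaps(gr, grid$windows, select = "first")
  as.integer(hits)
}

#' Label windows by annotation-localized association
#'
#' A window is labeled 1 for a study when (1) it contains at least one SNP
#' with p below `p_cut` and (2) at least one of those sub-threshold SNPs
#' lies inside the annotation track; otherwise 0. With an all-ones
#' annotation, condition 2 is vacuous and the label reduces to condition 1.
#'
#' @param stats A [sumstats()] table.
#' @param annot_track A [binary_track()] marking the functional genome.
#' @param grid A [window_grid()] built on the same layout.
#' @param p_cut Association p-value threshold (default 1e-3).
#' @return An object of class `window_labels`: `labels` (0/1 per window),
#'   `k` (number labeled 1), `n` (windows), `study`.
#' @export
label_windows <- function(stats, annot_track, grid, p_cut = 1e-3) {
  if (!nrow(stats)) stop("summary statistics contain no SNPs")
  widx <- snp_window_index(stats, grid)
  sig <- stats$p < p_cut
  in_track <- scores_at(annot_track,
                        data.frame(chr = stats$chr, bp = stats$bp)) > 0
  lab <- rep(0L, length(grid$windows))
  hit <- !is.na(widx) & sig & in_track
  lab[unique(widx[hit])] <- 1L
  structure(list(labels = lab, k = sum(lab), n = length(lab),
                 study = attr(stats, "study"), p_cut = p_cut),
            class = "window_labels")
}

#' Hypergeometric test of joint window labeling
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' number of windows labeled 1 for both studies, with the retained windows as
#' the population, study-A labels as successes and study-B labels as draws.
#' Symmetric in A and B.
#'
#' @param labels_a,labels_b [label_windows()] results on the same grid.
#' @return List with `p_value`, `overlap`, `k_a`, `k_b`, `n`.
#' @export
hypergeom_overlap <- function(labels_a, labels_b) {
  if (labels_a$n != labels_b$n)
    stop("label vectors come from different grids")
  ov <- sum(labels_a$labels == 1 & labels_b$labels == 1)
  p <- stats::phyper(ov - 1, labels_a$k, labels_a$n - labels_a$k,
                     labels_b$k, lower.tail = FALSE)
  list(p_value = p, overlap = ov, k_a = labels_a$k, k_b = labels_b$k,
       n = labels_a$n)
}

#' Permutation test for shared annotation-localized association
#'
#' The observed statistic is the number of windows labeled 1 for both
#' studies. Each permutation shuffles the per-SNP annotation-membership
#' indicator uniformly across SNPs — preserving the total annotated
#' proportion and per-window SNP counts — relabels windows for both studies
#' (condition 1 is unchanged; condition 2 is recomputed), and records the
#' joint count. The p-value uses the add-one estimator
#' (1 + #\{null >= observed\}) / (n_perm + 1), which cannot be zero. Because
#' association signals are never permuted, confounding shared between the
#' two studies (e.g. overlapping control samples) inflates both the observed
#' and the null counts alike.
#'
#' @param stats_a,stats_b [sumstats()] tables for the two traits.
#' @param annot_track A [binary_track()] of the functional genome.
#' @param grid A [window_grid()].
#' @param p_cut Association p-value threshold.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @return An object of class `pleiotropy_test`: `p_value`, `observed`,
#'   `null` (permutation counts), `hypergeom` (companion exact test),
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(stats_a, stats_b, annot_track, grid,
                             p_cut = 1e-3, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1)
  # unique SNP positions across both studies carry one membership indicator
  key_a <- paste(stats_a$chr, stats_a$bp)
  key_b <- paste(stats_b$chr, stats_b$bp)
  keys <- unique(c(key_a, key_b))
  pos <- do.call(rbind, strsplit(keys, " "))
  posdf <- data.frame(chr = pos[, 1], bp = as.numeric(pos[, 2]))
  member <- scores_at(annot_track, posdf) > 0

  widx_a <- snp_window_index(stats_a, grid)
  widx_b <- snp_window_index(stats_b, grid)
  sig_a <- stats_a$p < p_cut
  sig_b <- stats_b$p < p_cut
  ia <- match(key_a, keys)
  ib <- match(key_b, keys)
  nw <- length(grid$windows)

  joint_count <- function(memb) {
    la <- rep(FALSE, nw); lb <- rep(FALSE, nw)
    ha <- !is.na(widx_a) & sig_a & memb[ia]
    hb <- !is.na(widx_b) & sig_b & memb[ib]
    la[widx_a[ha]] <- TRUE
    lb[widx_b[hb]] <- TRUE
    sum(la & lb)
  }
  obs <- joint_count(member)
  set.seed(seed)
  nulls <- vapply(seq_len(n_perm), function(i)
    joint_count(sample(member)), integer(1))
  p <- (1 + sum(nulls >= obs)) / (n_perm + 1)

  la <- label_windows(stats_a, annot_track, grid, p_cut)
  lb <- label_windows(stats_b, annot_track, grid, p_cut)
  structure(list(p_value = p, observed = obs, null = nulls,
                 hypergeom = hypergeom_overlap(la, lb),
                 labels_a = la, labels_b = lb,
                 n_perm = n_perm, seed = seed),
            class = "pleiotropy_test")
}

#' @export
print.pleiotropy_test <- function(x, ...) {
  cat(sprintf("Window pleiotropy test: %d joint window(s) of %d retained\n",
              x$observed, x$hypergeom$n))
  cat(sprintf("  permutation p = %.4g (%d permutations, seed %d)\n",
              x$p_value, x$n_perm, x$seed))
  cat(sprintf("  hypergeometric p = %.4g (k_A = %d, k_B = %d)\n",
              x$hypergeom$p_value, x$hypergeom$k_a, x$hypergeom$k_b))
  invisible(x)
}

#' Report candidate pleiotropic loci
#'
#' For every window labeled 1 in both studies: the minimum p-value and its
#' peak SNP per study, and the count of annotated sub-threshold SNPs; sorted
#' by the smaller of the two peak p-values.
#'
#' @param labels_a,labels_b [label_windows()] results on `grid`.
#' @param stats_a,stats_b The matching [sumstats()] tables.
#' @param grid The [window_grid()].
#' @param annot_track Optional [binary_track()]; when given, per-window
#'   counts of annotated sub-threshold SNPs are reported.
#' @return Data frame with one row per joint window (possibly empty, with a
#'   warning).
#' @export
candidate_loci <- function(labels_a, labels_b, stats_a, stats_b, grid,
                           annot_track = NULL) {
  joint <- which(labels_a$labels == 1 & labels_b$labels == 1)
  if (!length(joint)) {
    warning("no window is labeled for both studies")
    return(data.frame())
  }
  widx_a <- snp_window_index(stats_a, grid)
  widx_b <- snp_window_index(stats_b, grid)
  win <- grid$windows[joint]
  rows <- lapply(seq_along(joint), function(i) {
    w <- joint[i]
    sa <- stats_a[!is.na(widx_a) & widx_a == w, ]
    sb <- stats_b[!is.na(widx_b) & widx_b == w, ]
    pa <- which.min(sa$p); pb <- which.min(sb$p)
    row <- data.frame(
      chr = as.character(GenomicRanges::seqnames(win))[i],
      start = GenomicRanges::start(win)[i],
      end = GenomicRanges::end(win)[i],
      min_p_a = sa$p[pa], peak_snp_a = sa$snp[pa], peak_bp_a = sa$bp[pa],
      min_p_b = sb$p[pb], peak_snp_b = sb$snp[pb], peak_bp_b = sb$bp[pb])
    if (!is.null(annot_track)) {
      ina <- scores_at(annot_track, data.frame(chr = sa$chr, bp = sa$bp)) > 0
      inb <- scores_at(annot_track, data.frame(chr = sb$chr, bp = sb$bp)) > 0
      row$n_annot_a <- sum(sa$p < labels_a$p_cut & ina)
      row$n_annot_b <- sum(sb$p < labels_b$p_cut & inb)
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(pmin(out$min_p_a, out$min_p_b)), ]
}
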