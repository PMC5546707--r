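#' Per-nucleotide binary annotation track
#'
#' A `binary_track` records, for every base of a genome, the presence (1) or
#' absence (0) of an annotation, stored as sorted disjoint one-intervals.
#' Adjacent or overlapping intervals are merged at construction.
#'
#' @param intervals One-intervals, as `GRanges` or BED-style data frame
#'   (0-based half-open).
#' @param layout A [genome_layout()].
#' @param resolution Declared resolution in bp (1 for per-base chromatin
#'   tracks, 25 for binned RNA-seq).
#' @return An object of class `binary_track`.
#' @export
binary_track <- function(intervals, layout, resolution = 1L) {
  gr <- GenomicRanges::reduce(as_intervals(intervals, layout))
  structure(list(layout = layout, intervals = gr,
                 resolution = as.integer(resolution)),
            class = "binary_track")
}

#' Per-nucleotide score track
#'
#' A `score_track` carries a value in \[0, 1\] for every base; bases not
#' covered by any run have implicit score 0. Used for posterior functionality
#' scores and smoothed tracks.
#'
#' @param runs Scored intervals: `GRanges` with a numeric `score` column, or a
#'   BED-style data frame with a `score` column.
#' @param layout A [genome_layout()].
#' @param resolution Declared resolution in bp.
#' @return An object of class `score_track`.
#' @export
score_track <- function(runs, layout, resolution = 1L) {
  gr <- as_intervals(runs, layout)
  if (!"score" %in% names(S4Vectors::mcols(gr)))
    stop("score_track runs need a `score` column")
  sc <- S4Vectors::mcols(gr)$score
  if (any(sc < 0 | sc > 1)) stop("scores must lie in [0, 1]")
  o <- order(as.integer(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr <- gr[o]
  if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)) > 0)
    stop("score runs must be disjoint")
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  structure(list(layout = layout, runs = gr,
                 resolution = as.integer(resolution)),
            class = "score_track")
}

#' @export
print.binary_track <- function(x, ...) {
  cat(sprintf("<binary_track> %d interval(s), %s bp covered (%.2f%% of genome), resolution %d bp\n",
              length(x$intervals), format(covered_bp(x), big.mark = ","),
              100 * coverage_fraction(x), x$resolution))
  invisible(x)
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %d run(s), genome-wide mean score %.4f, resolution %d bp\n",
              length(x$runs), track_mean(x), x$resolution))
  invisible(x)
}

is_binary_track <- function(x) inherits(x, "binary_track")
is_score_track <- function(x) inherits(x, "score_track")

#' Covered base pairs of a binary track
#' @param track A `binary_track`.
#' @return Number of bases set to 1.
#' @export
covered_bp <- function(track) {
  stopifnot(is_binary_track(track))
  sum(as.numeric(GenomicRanges::width(track$intervals)))
}

#' Fraction of the genome covered by a binary track
#' @param track A `binary_track`.
#' @export
coverage_fraction <- function(track) {
  covered_bp(track) / sum(track$layout$lengths)
}

# Full-length per-chromosome Rle of track values (0/1 for binary, numeric
# with implicit-0 gaps for score tracks).
track_rle <- function(track) {
  si <- as_seqinfo(track$layout)
  if (is_binary_track(track)) {
    GenomicRanges::coverage(track$intervals, width = GenomeInfoDb::seqlengths(si))
  } else {
    GenomicRanges::coverage(track$runs, width = GenomeInfoDb::seqlengths(si),
                            weight = "score")
  }
}

# Rebuild a track from a per-chromosome RleList.
rle_to_score_track <- function(rl, layout, resolution = 1L) {
  grl <- lapply(layout$names, function(chr) {
    r <- rl[[chr]]
    keep <- S4Vectors::runValue(r) != 0
    ir <- IRanges::ranges(r)[keep]
    if (!length(ir)) return(GenomicRanges::GRanges(seqinfo = as_seqinfo(layout)))
    gr <- GenomicRanges::GRanges(chr, ir, seqinfo = as_seqinfo(layout))
    S4Vectors::mcols(gr)$score <- S4Vectors::runValue(r)[keep]
    gr
  })
  score_track(do.call(c, grl), layout, resolution = resolution)
}

rle_to_binary_track <- function(rl, layout, resolution = 1L) {
  grl <- lapply(layout$names, function(chr) {
    r <- rl[[chr]]
    keep <- S4Vectors::runValue(r) != 0
    GenomicRanges::GRanges(chr, IRanges::ranges(r)[keep],
                           seqinfo = as_seqinfo(layout))
  })
  binary_track(do.call(c, grl), layout, resolution = resolution)
}

#' Binarize peak calls by enrichment p-value
#'
#' Keeps peaks whose signal-enrichment p-value falls below `p_threshold`
#' (default 0.01, the conventional Poisson p-value cutoff for strong ChIP-seq
#' signal) and merges the survivors into disjoint one-intervals.
#'
#' @param peaks Peak intervals with a `pvalue` column (linear scale), as
#'   `GRanges` or BED-style data frame.
#' @param layout A [genome_layout()].
#' @param p_threshold Strict upper bound on the peak p-value; in (0, 1).
#' @return A [binary_track()].
#' @export
binarize_peaks <- function(peaks, layout, p_threshold = 0.01) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  gr <- as_intervals(peaks, layout)
  pv <- S4Vectors::mcols(gr)$pvalue
  if (is.null(pv)) stop("peaks need a `pvalue` column")
  binary_track(gr[pv < p_threshold], layout, resolution = 1L)
}

#' Binarize CpG-island methylation
#'
#' An island is encoded as present (unmethylated) when its fractionated
#' methylation is strictly below `cutoff` (default 0.5).
#'
#' @param cpg_islands Island intervals (`GRanges` or BED-style data frame).
#' @param fraction Per-island methylated fraction in \[0, 1\]; may also be
#'   supplied as a `fraction` column on `cpg_islands`.
#' @param layout A [genome_layout()].
#' @param cutoff Strict upper bound on the methylated fraction.
#' @return A [binary_track()].
#' @export
binarize_methylation <- function(cpg_islands, layout, fraction = NULL,
                                 cutoff = 0.5) {
  gr <- as_intervals(cpg_islands, layout)
  if (is.null(fraction)) fraction <- S4Vectors::mcols(gr)$fraction
  if (is.null(fraction) || length(fraction) != length(gr))
    stop("need one methylation fraction per island")
  if (any(fraction < 0 | fraction > 1))
    stop("methylation fractions must lie in [0, 1]")
  binary_track(gr[fraction < cutoff], layout, resolution = 1L)
}

#' Binarize binned RNA-seq signal
#'
#' Bins with rpkm at or above the cutoff (default 0.5) become one-intervals;
#' the track resolution is the bin width (default 25 bp). Bins must sit on the
#' bin-width grid.
#'
#' @param bins Bin intervals (`GRanges` or BED-style data frame) with an
#'   `rpkm` column (or supplied via `rpkm`).
#' @param layout A [genome_layout()].
#' @param rpkm Optional per-bin rpkm values.
#' @param rpkm_cutoff Inclusive lower bound for an expressed bin.
#' @param bin_bp Bin width in bp.
#' @return A [binary_track()] with `resolution = bin_bp`.
#' @export
binarize_rnaseq <- function(bins, layout, rpkm = NULL, rpkm_cutoff = 0.5,
                            bin_bp = 25L) {
  gr <- as_intervals(bins, layout)
  if (is.null(rpkm)) rpkm <- S4Vectors::mcols(gr)$rpkm
  if (is.null(rpkm) || length(rpkm) != length(gr))
    stop("need one rpkm value per bin")
  start0 <- GenomicRanges::start(gr) - 1L
  if (any(start0 %% bin_bp != 0) || any(GenomicRanges::width(gr) != bin_bp))
    stop("bins must be aligned to the ", bin_bp, "-bp grid")
  binary_track(gr[rpkm >= rpkm_cutoff], layout, resolution = as.integer(bin_bp))
}

#' Dichotomize a score track
#'
#' Bases with score at or above `cutoff` become one-intervals. The tie rule
#' (score equal to the cutoff counts as functional) is fixed package-wide.
#'
#' @param track A [score_track()].
#' @param cutoff Dichotomization cutoff in (0, 1); default 0.5.
#' @return A [binary_track()].
#' @export
dichotomize <- function(track, cutoff = 0.5) {
  stopifnot(is_score_track(track), cutoff > 0, cutoff < 1)
  gr <- track$runs[S4Vectors::mcols(track$runs)$score >= cutoff]
  binary_track(gr, track$layout, resolution = track$resolution)
}

#' Smooth a score track over fixed windows
#'
#' Tiles each chromosome into non-overlapping windows of `window_bp` and
#' assigns every base the mean score of its window. The last window of a
#' chromosome may be shorter; its mean is taken over its actual length, so the
#' genome-wide mean score is preserved exactly.
#'
#' @param track A [score_track()].
#' @param window_bp Window length in bp (default 10 kb); must be a positive
#'   multiple of the track resolution.
#' @return A smoothed [score_track()].
#' @export
smooth_windows <- function(track, window_bp = 10000L) {
  stopifnot(is_score_track(track))
  if (window_bp <= 0) stop("window_bp must be positive")
  if (window_bp %% track$resolution != 0)
    stop("window_bp must be a multiple of the track resolution")
  rl <- track_rle(track)
  layout <- track$layout
  grl <- lapply(layout$names, function(chr) {
    len <- layout$lengths[match(chr, layout$names)]
    starts <- seq(1, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1, len)
    v <- IRanges::Views(rl[[chr]], start = starts, end = ends)
    m <- IRanges::viewMeans(v)
    keep <- m != 0
    gr <- GenomicRanges::GRanges(chr,
      IRanges::IRanges(start = starts[keep], end = ends[keep]),
      seqinfo = as_seqinfo(layout))
    S4Vectors::mcols(gr)$score <- unname(m[keep])
    gr
  })
  score_track(do.call(c, grl), layout, resolution = track$resolution)
}

#' Combine annotation tracks
#'
#' `mode = "union"` takes the bitwise OR of binary tracks (the convention for
#' pooling biologically related cell types into one cluster annotation);
#' `mode = "mean"` averages scores per base (the convention for multiple
#' donors of the same tissue, applied before any dichotomization).
#'
#' @param tracks A list of tracks sharing one layout; all binary for
#'   `"union"`, binary or score for `"mean"` (binary counts as 0/1).
#' @param mode `"union"` or `"mean"`.
#' @return A [binary_track()] for `"union"`, a [score_track()] for `"mean"`.
#' @export
combine_tracks <- function(tracks, mode = c("union", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(tracks) >= 1)
  layout <- tracks[[1]]$layout
  same <- vapply(tracks, function(t)
    identical(t$layout$names, layout$names) &&
      identical(t$layout$lengths, layout$lengths), logical(1))
  if (!all(same)) stop("all tracks must share one genome layout")
  res <- max(vapply(tracks, function(t) t$resolution, integer(1)))
  if (mode == "union") {
    if (!all(vapply(tracks, is_binary_track, logical(1))))
      stop("union requires binary tracks")
    grs <- lapply(tracks, function(t) t$intervals)
    binary_track(do.call(c, lapply(grs, GenomicRanges::granges)), layout,
                 resolution = res)
  } else {
    rls <- lapply(tracks, track_rle)
    total <- Reduce(`+`, rls)
    rle_to_score_track(total / length(tracks), layout, resolution = res)
  }
}

#' Functional proportion of an element set
#'
#' The fraction of element bases that are functional: covered bases for a
#' binary track, bases with score at or above `cutoff` for a score track.
#' Elements are merged before counting, so overlapping transcripts are not
#' double-counted.
#'
#' @param track A [binary_track()] or [score_track()].
#' @param elements Element intervals (`GRanges` or BED-style data frame);
#'   must be non-empty.
#' @param cutoff Score cutoff, ignored for binary tracks.
#' @return A fraction in \[0, 1\].
#' @export
functional_proportion <- function(track, elements, cutoff = 0.5) {
  gr <- GenomicRanges::reduce(as_intervals(elements, track$layout))
  if (!length(gr)) stop("element set is empty")
  total <- sum(as.numeric(GenomicRanges::width(gr)))
  if (is_binary_track(track)) {
    hit <- GenomicRanges::intersect(gr, track$intervals)
    return(sum(as.numeric(GenomicRanges::width(hit))) / total)
  }
  mask <- dichotomize(track, cutoff = cutoff)
  hit <- GenomicRanges::intersect(gr, mask$intervals)
  sum(as.numeric(GenomicRanges::width(hit))) / total
}

#' Extend elements by flanking sequence
#'
#' Each interval \[s, e) becomes \[s - flank, e + flank), clipped to the
#' chromosome bounds, with overlaps merged.
#'
#' @param elements Intervals (`GRanges` or BED-style data frame).
#' @param layout A [genome_layout()].
#' @param flank_bp Flank length in bp (>= 0); default 200.
#' @return A merged `GRanges`.
#' @export
flank_regions <- function(elements, layout, flank_bp = 200L) {
  stopifnot(flank_bp >= 0)
  gr <- as_intervals(elements, layout)
  lens <- layout$lengths[as.character(GenomicRanges::seqnames(gr))]
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(start = pmax(GenomicRanges::start(gr) - flank_bp, 1),
                     end = pmin(GenomicRanges::end(gr) + flank_bp, lens)),
    seqinfo = as_seqinfo(layout))
  GenomicRanges::reduce(gr)
}

#' Count tracks functional in each region
#'
#' For each region, the number of tracks with at least one functional base
#' overlapping it, plus a histogram of those counts — the summary used to ask
#' how much of the genome is functional in many tissues at once.
#'
#' @param tracks List of [binary_track()]s.
#' @param regions Region intervals (`GRanges` or BED-style data frame).
#' @return A list with `counts` (integer per region) and `histogram`
#'   (named table over 0..n_tracks).
#' @export
count_functional_tracks <- function(tracks, regions) {
  stopifnot(length(tracks) >= 1)
  gr <- as_intervals(regions, tracks[[1]]$layout)
  hits <- vapply(tracks, function(t)
    IRanges::overlapsAny(gr, t$intervals), logical(length(gr)))
  counts <- as.integer(if (length(gr) == 1) sum(hits) else rowSums(hits))
  hist <- table(factor(counts, levels = 0:length(tracks)))
  list(counts = counts, histogram = hist)
}

#' Dichotomize a score track at a reference quantile
#'
#' The cutoff is the `quantile` order statistic (nearest-rank, no
#' interpolation) of the track's scores at a set of reference positions —
#' typically common variants — and bases scoring at or above it become
#' functional. This puts annotation scores with different scales on a common
#' footing before enrichment comparisons.
#'
#' @param track A [score_track()].
#' @param reference_positions Reference positions (`GRanges`, or data frame
#'   with `chr` and `bp` columns, 1-based positions).
#' @param quantile Quantile level in (0, 1); default 0.90 (top 10% of
#'   reference scores become functional).
#' @return A [binary_track()]; the cutoff used is attached as attribute
#'   `"cutoff"`.
#' @export
quantile_binarize <- function(track, reference_positions, quantile = 0.90) {
  stopifnot(is_score_track(track), quantile > 0, quantile < 1)
  pos <- positions_to_granges(reference_positions, track$layout)
  if (!length(pos)) stop("reference positions must be non-empty")
  sc <- scores_at(track, pos)
  if (length(unique(sc)) == 1L)
    warning("all reference scores identical; quantile cutoff is degenerate")
  xs <- sort(sc)
  cutoff <- xs[ceiling(quantile * length(xs))]
  gr <- track$runs[S4Vectors::mcols(track$runs)$score >= cutoff]
  out <- binary_track(gr, track$layout, resolution = track$resolution)
  attr(out, "cutoff") <- cutoff
  out
}

# 1-based point positions -> width-1 GRanges
positions_to_granges <- function(x, layout) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chr", "bp") %in% names(x)))
    GenomicRanges::GRanges(x$chr, IRanges::IRanges(x$bp, x$bp),
                           seqinfo = as_seqinfo(layout))
  } else {
    as_intervals(x, layout)
  }
}

#' Track value at point positions
#'
#' @param track A [binary_track()] or [score_track()].
#' @param positions Positions (`GRanges` or data frame with `chr`, `bp`).
#' @return Numeric vector of per-position values (0/1 for binary tracks).
#' @export
scores_at <- function(track, positions) {
  pos <- positions_to_granges(positions, track$layout)
  if (is_binary_track(track))
    return(as.numeric(IRanges::overlapsAny(pos, track$intervals)))
  hits <- GenomicRanges::findOverlaps(pos, track$runs)
  out <- numeric(length(pos))
  out[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(track$runs)$score[S4Vectors::subjectHits(hits)]
  out
}

#' Genome-wide mean value of a track
#' @param track A [binary_track()] or [score_track()].
#' @export
track_mean <- function(track) {
  if (is_binary_track(track)) return(coverage_fraction(track))
  sc <- S4Vectors::mcols(track$runs)$score
  w <- as.numeric(GenomicRanges::width(track$runs))
  sum(sc * w) / sum(track$layout$lengths)
}
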