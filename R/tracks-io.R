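#' Read a narrowPeak file
#'
#' ENCODE narrowPeak: BED6 plus signalValue, pValue (-log10), qValue (-log10)
#' and peak offset. The -log10 p-value column is converted back to the linear
#' scale and exposed as the `pvalue` metadata column expected by
#' [binarize_peaks()].
#'
#' @param path Path to a narrowPeak file.
#' @param layout A [genome_layout()].
#' @return A `GRanges` with `pvalue` (linear) and `signalValue` columns.
#' @export
read_narrowpeak <- function(path, layout) {
  gr <- rtracklayer::import(path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  gr <- as_intervals(gr, layout)
  S4Vectors::mcols(gr)$pvalue <- 10^(-S4Vectors::mcols(gr)$pValue)
  gr
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED file (3+ columns). A numeric 5th (score) column,
#'   when present, is exposed as `value` — the convention used here for
#'   CpG-island methylation fractions.
#' @param layout A [genome_layout()].
#' @return A `GRanges`.
#' @export
read_bed <- function(path, layout) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- as_intervals(gr, layout)
  mc <- S4Vectors::mcols(gr)
  if ("score" %in% names(mc)) S4Vectors::mcols(gr)$value <- mc$score
  gr
}

#' Read a bedGraph file
#'
#' @param path Path to a bedGraph file; the fourth column becomes `score`.
#' @param layout A [genome_layout()].
#' @return A `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path, layout) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  as_intervals(gr, layout)
}

#' Write a track to a text file
#'
#' Binary tracks are written as 3-column BED (their one-intervals); score
#' tracks as bedGraph runs. Both use the standard 0-based half-open text
#' convention.
#'
#' @param track A [binary_track()] or [score_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  if (is_binary_track(track)) {
    rtracklayer::export(track$intervals, path, format = "BED")
  } else {
    rtracklayer::export(track$runs, path, format = "bedGraph")
  }
  invisible(path)
}

#' Read a score track from bedGraph
#'
#' @inheritParams read_bedgraph
#' @param resolution Declared resolution in bp.
#' @return A [score_track()].
#' @export
read_score_track <- function(path, layout, resolution = 1L) {
  score_track(read_bedgraph(path, layout), layout, resolution = resolution)
}

#' Read a binary track from BED
#'
#' @inheritParams read_bed
#' @param resolution Declared resolution in bp.
#' @return A [binary_track()].
#' @export
read_binary_track <- function(path, layout, resolution = 1L) {
  binary_track(read_bed(path, layout), layout, resolution = resolution)
}
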