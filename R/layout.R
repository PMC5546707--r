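#' Define a genome layout
#'
#' A genome layout fixes the chromosome names, their lengths in base pairs and
#' an assembly tag. Every interval-valued object in the package is validated
#' against a layout, so out-of-bounds coordinates are caught at construction
#' time rather than deep inside an analysis.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp; names are
#'   the chromosome names, in the order they should be iterated.
#' @param assembly Character tag for the assembly (e.g. `"hg19"`); purely
#'   descriptive.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths, assembly = "custom") {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("`lengths` must be named with unique chromosome names")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  structure(
    list(names = names(lengths),
         lengths = stats::setNames(as.numeric(lengths), names(lengths)),
         assembly = assembly),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %s: %d chromosome(s), %s bp total\n",
              x$assembly, length(x$names),
              format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Read a chromosome-sizes file
#'
#' Two-column whitespace-delimited text (`chrom<TAB>length`), the format used
#' by the UCSC `fetchChromSizes` output.
#'
#' @param path Path to the file.
#' @param assembly Assembly tag to record.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, assembly = "custom") {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(stats::setNames(df$length, df$chrom), assembly = assembly)
}

as_seqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = layout$names,
                        seqlengths = layout$lengths,
                        genome = layout$assembly)
}

#' Coerce intervals to GRanges validated against a layout
#'
#' Accepts a `GRanges` or a data frame with columns `chr`, `start`, `end` in
#' the BED convention (0-based half-open). Strand is dropped; all tracks are
#' strandless.
#'
#' @param x Intervals as `GRanges` or BED-style data frame.
#' @param layout A [genome_layout()].
#' @return A strandless `GRanges` with seqinfo from the layout.
#' @export
as_intervals <- function(x, layout) {
  if (is.data.frame(x)) {
    need <- c("chr", "start", "end")
    if (!all(need %in% names(x)))
      stop("data-frame intervals need columns chr, start, end (0-based half-open)")
    bad <- !as.character(x$chr) %in% layout$names
    if (any(bad))
      stop("intervals on chromosomes absent from the layout: ",
           paste(unique(as.character(x$chr)[bad]), collapse = ", "))
    if (any(x$start < 0) || any(x$end > layout$lengths[as.character(x$chr)]))
      stop("interval beyond chromosome bounds for layout '",
           layout$assembly, "'")
    gr <- GenomicRanges::GRanges(
      seqnames = factor(x$chr, levels = layout$names),
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      seqinfo = as_seqinfo(layout)
    )
    extra <- setdiff(names(x), need)
    if (length(extra))
      S4Vectors::mcols(gr)[extra] <- x[extra]
  } else if (methods::is(x, "GRanges")) {
    gr <- GenomicRanges::granges(x, use.mcols = TRUE)
    GenomicRanges::strand(gr) <- "*"
    bad <- !as.character(GenomicRanges::seqnames(gr)) %in% layout$names
    if (any(bad))
      stop("intervals on chromosomes absent from the layout: ",
           paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
                 collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- layout$names
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(layout)
  } else {
    stop("cannot interpret intervals of class ", class(x)[1])
  }
  lens <- layout$lengths[as.character(GenomicRanges::seqnames(gr))]
  if (any(GenomicRanges::start(gr) < 1) || any(GenomicRanges::end(gr) > lens))
    stop("interval beyond chromosome bounds for layout '", layout$assembly, "'")
  gr
}
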