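#' Construct a GWAS summary-statistics table
#'
#' Validates and normalizes per-SNP association records. Either `z` or `p`
#' may be supplied; the missing one is derived under the two-sided normal
#' convention (`p = 2 * pnorm(-|z|)`; a z derived from p alone is given a
#' positive sign unless a `sign` column is present). When both are supplied
#' their consistency is checked.
#'
#' @param df Data frame with columns `snp`, `chr`, `bp`, and `z` and/or `p`,
#'   plus optional `n` (per-SNP sample size) and `sign`.
#' @param study Study label.
#' @param n Constant sample size used when `df` lacks an `n` column.
#' @return A data frame of class `sumstats` with columns
#'   `snp, chr, bp, z, p, n` and attribute `"study"`.
#' @export
sumstats <- function(df, study = "study", n = NULL) {
  need <- c("snp", "chr", "bp")
  if (!all(need %in% names(df)))
    stop("sumstats need columns snp, chr, bp")
  if (anyDuplicated(df$snp)) stop("SNP ids must be unique")
  if (is.null(df$z) && is.null(df$p)) stop("need a z or p column")
  if (is.null(df$z)) {
    if (any(df$p <= 0 | df$p > 1)) stop("p-values must lie in (0, 1]")
    sgn <- if (!is.null(df$sign)) sign(df$sign) else 1
    df$z <- sgn * stats::qnorm(df$p / 2, lower.tail = FALSE)
  }
  if (is.null(df$p)) {
    df$p <- 2 * stats::pnorm(-abs(df$z))
  } else {
    if (any(df$p <= 0 | df$p > 1)) stop("p-values must lie in (0, 1]")
    pz <- 2 * stats::pnorm(-abs(df$z))
    if (any(abs(pz - df$p) > 1e-4 & abs(log(pmax(pz, 1e-300)) -
                                          log(pmax(df$p, 1e-300))) > 0.01))
      stop("z and p columns are mutually inconsistent (two-sided convention)")
  }
  if (is.null(df$n)) {
    if (is.null(n)) stop("supply per-SNP `n` column or constant `n`")
    df$n <- n
  }
  out <- df[c("snp", "chr", "bp", "z", "p", "n")]
  out <- out[order(match(out$chr, unique(out$chr)), out$bp), ]
  rownames(out) <- NULL
  attr(out, "study") <- study
  class(out) <- c("sumstats", "data.frame")
  out
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> study '%s': %d SNPs on %d chromosome(s); min p = %.3g\n",
              attr(x, "study"), nrow(x), length(unique(x$chr)), min(x$p)))
  invisible(x)
}

#' Read summary statistics from a delimited file
#'
#' Whitespace- or tab-delimited with a header; columns are matched
#' case-insensitively against \{SNP, CHR, BP, Z, P, N\} (aliases: POS for BP,
#' PVAL/P_VALUE for P).
#'
#' @param path Input path.
#' @param study Study label; defaults to the file name.
#' @param n Constant sample size fallback.
#' @return A [sumstats()] table.
#' @export
read_sumstats <- function(path, study = basename(path), n = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- toupper(names(df))
  nm[nm %in% c("POS", "POSITION")] <- "BP"
  nm[nm %in% c("PVAL", "P_VALUE", "P-VALUE")] <- "P"
  nm[nm %in% c("MARKERNAME", "RSID")] <- "SNP"
  names(df) <- nm
  keep <- intersect(c("SNP", "CHR", "BP", "Z", "P", "N", "SIGN"), nm)
  df <- df[keep]
  names(df) <- tolower(names(df))
  sumstats(df, study = study, n = n)
}

#' Write summary statistics
#'
#' Tab-delimited with upper-case header (SNP, CHR, BP, Z, P, N), the dialect
#' consumed by LD-score tooling.
#'
#' @param stats A [sumstats()] table.
#' @param path Output path.
#' @export
write_sumstats <- function(stats, path) {
  out <- stats
  names(out) <- toupper(names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Named genomic exclusion masks
#'
#' `genomic_mask()` builds a mask from intervals; `mhc_mask()` and
#' `apoe_mask()` return the two standard hg19 exclusions: the extended MHC
#' (chr6:28,477,797-33,448,354), removed from heritability analyses for its
#' atypical LD, and the APOE region (chr19:45,147,340-45,594,595), removed
#' before SNP reprioritization of late-onset Alzheimer's GWAS because its
#' outsized effect would dominate the p-value mixture.
#'
#' @param intervals `GRanges` or data frame with `chr`, `start`, `end`
#'   (1-based inclusive here, matching how such regions are quoted) and
#'   optionally `name`.
#' @return A data frame of class `genomic_mask` with columns
#'   `chr, start, end, name` (1-based inclusive).
#' @export
genomic_mask <- function(intervals) {
  if (methods::is(intervals, "GRanges")) {
    intervals <- data.frame(
      chr = as.character(GenomicRanges::seqnames(intervals)),
      start = GenomicRanges::start(intervals),
      end = GenomicRanges::end(intervals),
      name = if (!is.null(S4Vectors::mcols(intervals)$name))
        S4Vectors::mcols(intervals)$name else NA_character_)
  }
  stopifnot(all(c("chr", "start", "end") %in% names(intervals)))
  if (is.null(intervals$name))
    intervals$name <- rep(NA_character_, nrow(intervals))
  if (any(intervals$end < intervals$start)) stop("invalid mask intervals")
  out <- intervals[c("chr", "start", "end", "name")]
  class(out) <- c("genomic_mask", "data.frame")
  out
}

#' @rdname genomic_mask
#' @export
mhc_mask <- function() {
  genomic_mask(data.frame(chr = "chr6", start = 28477797, end = 33448354,
                          name = "MHC"))
}

#' @rdname genomic_mask
#' @export
apoe_mask <- function() {
  genomic_mask(data.frame(chr = "chr19", start = 45147340, end = 45594595,
                          name = "APOE"))
}

#' Remove SNPs falling inside masked regions
#'
#' @param stats A [sumstats()] table.
#' @param mask A [genomic_mask()]; an empty mask is the identity.
#' @return The filtered `sumstats`; errors if no SNP survives.
#' @export
exclude_regions <- function(stats, mask) {
  if (nrow(mask) == 0) return(stats)
  inside <- rep(FALSE, nrow(stats))
  for (k in seq_len(nrow(mask))) {
    inside <- inside | (stats$chr == mask$chr[k] &
                          stats$bp >= mask$start[k] &
                          stats$bp <= mask$end[k])
  }
  message("excluded ", sum(inside), " SNP(s) in masked region(s)")
  if (all(inside)) stop("mask removed every SNP")
  out <- stats[!inside, ]
  rownames(out) <- NULL
  attr(out, "study") <- attr(stats, "study")
  class(out) <- class(stats)
  out
}

#' Infer a stage-II z-score from stage-I and combined meta-analysis
#'
#' Under the sample-size-weighted meta-analysis model, the combined z-score
#' is z12 = (z1 * sqrt(n1) + z2 * sqrt(n2)) / sqrt(n1 + n2); inverting for
#' the stage-II component gives
#' z2 = z12 * sqrt(n1 + n2) / sqrt(n2) - z1 * sqrt(n1) / sqrt(n2).
#' This recovers replication-cohort z-scores when only the discovery and
#' combined statistics are published.
#'
#' @param z1 Stage-I z-score(s).
#' @param z12 Combined-stage z-score(s).
#' @param n1,n2 Stage sample sizes (> 0).
#' @return Stage-II z-score(s).
#' @seealso [meta_z()], its exact inverse.
#' @export
infer_stage2_z <- function(z1, z12, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("sample sizes must be positive")
  z12 * sqrt(n1 + n2) / sqrt(n2) - z1 * sqrt(n1) / sqrt(n2)
}

#' Sample-size-weighted meta-analysis z-score
#'
#' @param z1,z2 Per-stage z-scores.
#' @param n1,n2 Per-stage sample sizes (> 0).
#' @return Combined z-score (z1 * sqrt(n1) + z2 * sqrt(n2)) / sqrt(n1 + n2).
#' @export
meta_z <- function(z1, z2, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("sample sizes must be positive")
  (z1 * sqrt(n1) + z2 * sqrt(n2)) / sqrt(n1 + n2)
}
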