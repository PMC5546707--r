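#' Tissue specificity index
#'
#' For element j over N tissues, TSI_j = sum_i (1 - x_ji) / (N - 1), where
#' x_ji is the expression of tissue i divided by the element's maximum
#' expression across tissues. TSI is 1 when an element is expressed in exactly
#' one tissue and 0 when expression is uniform; it is invariant to rescaling a
#' row by a positive constant.
#'
#' @param expr Numeric elements x tissues matrix (or data frame) of
#'   non-negative expression intensities, with at least two tissue columns.
#' @return Numeric vector of per-element TSI values in \[0, 1\].
#' @export
compute_tsi <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least two tissues")
  if (any(expr < 0)) stop("expression intensities must be non-negative")
  mx <- apply(expr, 1, max)
  if (any(mx == 0)) {
    bad <- which(mx == 0)[1]
    nm <- if (!is.null(rownames(expr))) rownames(expr)[bad] else bad
    stop("element '", nm, "' has all-zero expression; TSI undefined")
  }
  rowSums(1 - expr / mx) / (ncol(expr) - 1)
}

#' Select tissue-specific elements
#'
#' Retains elements with TSI strictly greater than `tsi_threshold` (default
#' 0.75) and labels each with its maximally expressed tissue. Ties at the
#' maximum resolve deterministically to the lowest-index tissue, with a
#' message.
#'
#' @param expr Elements x tissues expression matrix with tissue column names.
#' @param tsi_threshold Strict lower bound on TSI.
#' @return Data frame with columns `element`, `tsi`, `tissue`.
#' @export
select_specific <- function(expr, tsi_threshold = 0.75) {
  expr <- as.matrix(expr)
  tsi <- compute_tsi(expr)
  keep <- which(tsi > tsi_threshold)
  sub <- expr[keep, , drop = FALSE]
  idx <- apply(sub, 1, which.max)
  nties <- sum(apply(sub, 1, function(r) sum(r == max(r)) > 1))
  if (nties > 0)
    message(nties, " element(s) had tied maximal expression; ",
            "lowest-index tissue kept")
  tiss <- if (!is.null(colnames(expr))) colnames(expr)[idx] else idx
  data.frame(
    element = if (!is.null(rownames(expr))) rownames(expr)[keep] else keep,
    tsi = unname(tsi[keep]),
    tissue = tiss,
    row.names = NULL)
}

#' Functional proportions of element sets across annotation tracks
#'
#' For each named element set (rows) and each annotation track (columns), the
#' per-nucleotide functional proportion of the set — the core validation that
#' elements specific to a tissue should score highest in the matching tissue
#' track. Values are exactly [functional_proportion()] outputs.
#'
#' @param element_sets Named list of element interval sets (`GRanges` or
#'   BED-style data frames), one per tissue/element class; all non-empty.
#' @param tracks Named list of [score_track()]s or [binary_track()]s.
#' @param cutoff Score cutoff passed to [functional_proportion()].
#' @return A matrix (element sets x tracks) with attribute `"best_track"`:
#'   the column name maximizing each row.
#' @export
validate_elements <- function(element_sets, tracks, cutoff = 0.5) {
  stopifnot(length(element_sets) >= 1, length(tracks) >= 1)
  m <- vapply(tracks, function(tr)
    vapply(element_sets, function(el)
      functional_proportion(tr, el, cutoff = cutoff), numeric(1)),
    numeric(length(element_sets)))
  m <- matrix(m, nrow = length(element_sets),
              dimnames = list(names(element_sets), names(tracks)))
  attr(m, "best_track") <- colnames(m)[apply(m, 1, which.max)]
  m
}

#' Functional profile of conserved sites with flanks
#'
#' Extends a set of conserved noncoding sites by `flank_bp` on each side,
#' merges them, and reports each track's functional proportion over the
#' extended set — the comparison used to ask which cell type an enhancer
#' region is active in.
#'
#' @param cns_sites Site intervals (`GRanges` or BED-style data frame).
#' @param tracks Named list of tracks.
#' @param flank_bp Flank length in bp; 0 reproduces [validate_elements()] on
#'   the raw sites.
#' @param cutoff Score cutoff.
#' @return Named numeric vector, one functional proportion per track.
#' @export
cns_flank_profile <- function(cns_sites, tracks, flank_bp = 200L,
                              cutoff = 0.5) {
  stopifnot(length(tracks) >= 1)
  layout <- tracks[[1]]$layout
  reg <- flank_regions(cns_sites, layout, flank_bp = flank_bp)
  vapply(tracks, function(tr)
    functional_proportion(tr, reg, cutoff = cutoff), numeric(1))
}

#' Read an expression matrix with element coordinates
#'
#' Tab-delimited elements x tissues matrix (first column element id, header
#' row of tissue names) plus a sidecar BED file giving each element's genomic
#' interval (name column matching the element ids).
#'
#' @param path Path to the expression table.
#' @param bed_path Optional path to the coordinate BED.
#' @param layout Required with `bed_path`.
#' @return A list with `expr` (matrix) and `coords` (`GRanges` or `NULL`).
#' @export
read_expression_matrix <- function(path, bed_path = NULL, layout = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  expr <- as.matrix(df)
  coords <- NULL
  if (!is.null(bed_path)) {
    stopifnot(!is.null(layout))
    coords <- read_bed(bed_path, layout)
    nm <- S4Vectors::mcols(coords)$name
    if (!is.null(nm)) coords <- coords[match(rownames(expr), nm)]
  }
  list(expr = expr, coords = coords)
}
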