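#' Canonical annotation order
#'
#' The ten binary annotations integrated by the functional mixture model, in
#' their fixed order: seven histone ChIP-seq marks, DNase I hypersensitivity,
#' unmethylated CpG islands and expressed RNA-seq bins.
#'
#' @return Character vector of length 10.
#' @export
annotation_names <- function() {
  c("H3K4me1", "H3K4me3", "H3K36me3", "H3K27me3", "H3K9me3",
    "H3K27ac", "H3K9ac", "DNase", "CpG_unmeth", "RNA")
}

# Marks expected to predict functionality positively; used to resolve the
# label switching inherent to a two-class mixture.
.activating_marks <- c("H3K4me3", "H3K9ac", "DNase")

.eps <- 1e-6

#' Build training regions around index SNPs
#'
#' Each SNP position is expanded into a centered interval of `flank_total_bp`
#' (default 1 kb, i.e. \[bp - 500, bp + 500)); overlapping intervals are
#' merged. Duplicated SNP positions are dropped with a message. The merged
#' regions sample functional and background sequence for model training.
#'
#' @param snp_positions Data frame with `chr` and `bp` (1-based) columns, or a
#'   `GRanges` of width-1 positions.
#' @param layout A [genome_layout()].
#' @param flank_total_bp Total interval length per SNP.
#' @return A list of class `training_regions` with `regions` (`GRanges`),
#'   `total_bp` and `n_snps`.
#' @export
build_training_regions <- function(snp_positions, layout,
                                   flank_total_bp = 1000L) {
  pos <- positions_to_granges(snp_positions, layout)
  n0 <- length(pos)
  pos <- unique(pos)
  if (length(pos) < n0)
    message("dropped ", n0 - length(pos), " duplicated SNP position(s)")
  half <- flank_total_bp %/% 2L
  # centered [bp - half, bp + half) in 0-based terms
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(pos),
    IRanges::IRanges(start = GenomicRanges::start(pos) - half + 1L,
                     width = flank_total_bp),
    seqinfo = as_seqinfo(layout))
  gr <- GenomicRanges::reduce(GenomicRanges::trim(gr))
  structure(list(regions = gr,
                 total_bp = sum(as.numeric(GenomicRanges::width(gr))),
                 n_snps = length(pos)),
            class = "training_regions")
}

#' @export
print.training_regions <- function(x, ...) {
  cat(sprintf("<training_regions> %d SNP(s) -> %d merged interval(s), %s bp\n",
              x$n_snps, length(x$regions), format(x$total_bp, big.mark = ",")))
  invisible(x)
}

#' Tabulate annotation patterns over regions
#'
#' Collapses a set of binary tracks into the distinct 10-bit (or K-bit)
#' annotation patterns observed over `regions` (default: the whole genome),
#' with per-pattern base-pair counts. Aggregating identical patterns leaves
#' the mixture likelihood unchanged while making EM cost independent of
#' genome size.
#'
#' @param tracks Named list of [binary_track()]s sharing one layout, in model
#'   annotation order.
#' @param regions Optional `GRanges` restricting the tabulation.
#' @return A list with `patterns` (n x K 0/1 matrix) and `counts` (bp per
#'   pattern).
#' @export
annotation_patterns <- function(tracks, regions = NULL) {
  stopifnot(length(tracks) >= 1)
  layout <- tracks[[1]]$layout
  K <- length(tracks)
  rls <- lapply(tracks, track_rle)
  pid <- Reduce(`+`, lapply(seq_len(K), function(i) rls[[i]] * 2^(i - 1)))
  acc <- new.env()
  add <- function(r) {
    tb <- tapply(S4Vectors::runLength(r), S4Vectors::runValue(r), sum)
    for (id in names(tb)) {
      prev <- acc[[id]]
      acc[[id]] <- if (is.null(prev)) tb[[id]] else prev + tb[[id]]
    }
  }
  for (chr in layout$names) {
    r <- pid[[chr]]
    if (is.null(regions)) add(r)
    else {
      ir <- IRanges::ranges(regions[GenomicRanges::seqnames(regions) == chr])
      if (length(ir)) add(r[ir])
    }
  }
  ids <- as.numeric(ls(acc))
  counts <- vapply(as.character(ids), function(k) as.numeric(acc[[k]]),
                   numeric(1))
  pat <- vapply(seq_len(K), function(i) (ids %/% 2^(i - 1)) %% 2,
                numeric(length(ids)))
  pat <- matrix(pat, ncol = K,
                dimnames = list(NULL, names(tracks)))
  list(patterns = pat, counts = unname(counts))
}

#' Fit the two-class Bernoulli mixture of annotations
#'
#' The generative model: each position carries a latent functionality
#' indicator Z ~ Bernoulli(pi); given Z = c, the K binary annotations are
#' independent Bernoulli(p_ic). The per-position posterior P(Z = 1 | A) is the
#' tissue-specific functionality score. Parameters (pi and the K x 2 matrix
#' p_ic, 2K + 1 in total) are estimated by expectation-maximization on the
#' observed annotation patterns; the log-likelihood is non-decreasing at every
#' iteration and iteration stops when its relative change falls below `tol`.
#'
#' Two-class mixtures are identified only up to label switching; after
#' convergence classes are relabeled so that the summed log odds ratios of the
#' canonical activating marks (H3K4me3, H3K9ac, DNase I — or, when annotation
#' names are non-standard, all annotations) are positive, making class 1 the
#' functional class.
#'
#' @param x Either an n x K 0/1 matrix of annotation observations, a list as
#'   returned by [annotation_patterns()], or a named list of
#'   [binary_track()]s (tabulated over `regions`).
#' @param counts Optional per-row weights for a matrix `x` (bp counts).
#' @param regions Optional `GRanges` of training regions when `x` is a track
#'   list.
#' @param init Optional list with starting `pi` and `p` (K x 2); otherwise
#'   initialized from empirical annotation frequencies with seeded jitter.
#' @param seed RNG seed for the initialization jitter; recorded in the fit.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations; non-convergence warns, never errors.
#' @return An object of class `func_mixture` with components `pi`, `p`
#'   (K x 2 matrix, columns `nonfunctional`/`functional`), `loglik` (trace),
#'   `converged`, `n_obs`, `annotations`, `seed`.
#' @seealso [posterior_score()], [score_genome()], [annotation_odds_ratio()]
#' @export
fit_functional_mixture <- function(x, counts = NULL, regions = NULL,
                                   init = NULL, seed = 1L, tol = 1e-6,
                                   max_iter = 1000L) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    if (!is.null(x$patterns)) {
      counts <- x$counts; x <- x$patterns
    } else {
      ap <- annotation_patterns(x, regions = regions)
      counts <- ap$counts; x <- ap$patterns
    }
  }
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("annotation matrix must be binary")
  if (is.null(counts)) counts <- rep(1, nrow(x))
  stopifnot(length(counts) == nrow(x), all(counts > 0))
  K <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("A", seq_len(K))
  # aggregate duplicate patterns
  key <- apply(x, 1, paste, collapse = "")
  if (anyDuplicated(key)) {
    agg <- rowsum(counts, key)          # sums weights by sorted unique pattern
    x <- x[match(rownames(agg), key), , drop = FALSE]
    counts <- as.numeric(agg)
  }
  if (nrow(x) < 2)
    stop("degenerate data: need at least two distinct annotation patterns")

  freq <- colSums(x * counts) / sum(counts)
  if (is.null(init)) {
    set.seed(seed)
    pos <- rowSums(x) > 0
    f1 <- if (any(pos)) colSums(x[pos, , drop = FALSE] * counts[pos]) /
      sum(counts[pos]) else freq
    p1 <- pmin(pmax(f1, 0.05), 0.95) * stats::runif(K, 0.9, 1.1)
    p0 <- pmin(pmax(freq * 0.5, 0.01), 0.5) * stats::runif(K, 0.9, 1.1)
    pi_c <- 0.5
    p <- cbind(nonfunctional = pmin(pmax(p0, .eps), 1 - .eps),
               functional = pmin(pmax(p1, .eps), 1 - .eps))
  } else {
    pi_c <- init$pi
    p <- init$p
    colnames(p) <- c("nonfunctional", "functional")
  }

  loglik <- numeric(0)
  clamped <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- log(pi_c) + x %*% log(p[, 2]) + (1 - x) %*% log(1 - p[, 2])
    l0 <- log(1 - pi_c) + x %*% log(p[, 1]) + (1 - x) %*% log(1 - p[, 1])
    m <- pmax(l1, l0)
    ll <- sum(counts * (m + log(exp(l1 - m) + exp(l0 - m))))
    loglik <- c(loglik, ll)
    gam <- as.vector(1 / (1 + exp(l0 - l1)))
    w1 <- counts * gam
    w0 <- counts * (1 - gam)
    pi_c <- sum(w1) / sum(counts)
    p_new <- cbind(colSums(x * w0) / sum(w0), colSums(x * w1) / sum(w1))
    if (any(p_new < .eps | p_new > 1 - .eps) ||
        pi_c < .eps || pi_c > 1 - .eps) clamped <- TRUE
    p <- pmin(pmax(p_new, .eps), 1 - .eps)
    colnames(p) <- c("nonfunctional", "functional")
    pi_c <- min(max(pi_c, .eps), 1 - .eps)
    if (it > 1 &&
        abs(loglik[it] - loglik[it - 1]) < tol * abs(loglik[it - 1])) break
  }
  converged <- it < max_iter ||
    (it == max_iter && length(loglik) > 1 &&
       abs(loglik[it] - loglik[it - 1]) < tol * abs(loglik[it - 1]))
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  if (clamped)
    warning("some Bernoulli probabilities hit {0,1} and were clamped to [",
            .eps, ", ", 1 - .eps, "]")

  rownames(p) <- colnames(x)
  marks <- intersect(.activating_marks, colnames(x))
  if (!length(marks)) marks <- colnames(x)
  lor <- log(p[marks, 2] / (1 - p[marks, 2])) -
    log(p[marks, 1] / (1 - p[marks, 1]))
  if (sum(lor) < 0) {       # swap labels so class 1 is the functional class
    pi_c <- 1 - pi_c
    p <- p[, 2:1]
    colnames(p) <- c("nonfunctional", "functional")
  }

  structure(list(pi = pi_c, p = p, loglik = loglik, n_iter = it,
                 converged = converged, n_obs = sum(counts),
                 annotations = colnames(x), seed = seed,
                 call = match.call()),
            class = "func_mixture")
}

#' @export
print.func_mixture <- function(x, ...) {
  cat("Two-class Bernoulli mixture of", length(x$annotations), "annotations\n")
  cat(sprintf("  pi (prior functional fraction): %.4f\n", x$pi))
  cat(sprintf("  %d free parameters; logLik %.2f after %d EM iteration(s)%s\n",
              n_parameters(x), x$loglik[length(x$loglik)], x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.func_mixture <- function(object, ...) {
  tab <- data.frame(
    annotation = object$annotations,
    p_functional = object$p[, "functional"],
    p_nonfunctional = object$p[, "nonfunctional"],
    odds_ratio = annotation_odds_ratio(object),
    row.names = NULL)
  out <- list(pi = object$pi, table = tab,
              loglik = object$loglik[length(object$loglik)],
              n_parameters = n_parameters(object))
  class(out) <- "summary.func_mixture"
  out
}

#' @export
print.summary.func_mixture <- function(x, ...) {
  cat(sprintf("pi = %.4f; %d parameters; logLik = %.2f\n",
              x$pi, x$n_parameters, x$loglik))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.func_mixture <- function(object, ...) {
  c(pi = object$pi,
    stats::setNames(object$p[, "nonfunctional"],
                    paste0("p0.", object$annotations)),
    stats::setNames(object$p[, "functional"],
                    paste0("p1.", object$annotations)))
}

#' @export
logLik.func_mixture <- function(object, ...) {
  structure(object$loglik[length(object$loglik)],
            df = n_parameters(object), nobs = object$n_obs, class = "logLik")
}

#' Number of free parameters of a fitted mixture
#' @param object A `func_mixture`.
#' @return Integer: 2K + 1 for K annotations (21 for the canonical ten).
#' @export
n_parameters <- function(object) {
  length(coef(object))
}

#' Posterior functionality score for annotation patterns
#'
#' Bayes posterior P(Z = 1 | A) under a fitted (or hand-specified) mixture:
#' pi * prod f_i(A_i | 1) / (pi * prod f_i(A_i | 1) + (1 - pi) *
#' prod f_i(A_i | 0)). This per-nucleotide posterior is the tissue-specific
#' functionality score.
#'
#' @param object A `func_mixture`, or a list with elements `pi` and `p`
#'   (K x 2 matrix, columns nonfunctional/functional).
#' @param a A 0/1 vector of length K, or an n x K matrix of patterns.
#' @return Posterior probabilities in (0, 1), one per pattern.
#' @export
posterior_score <- function(object, a) {
  p <- object$p
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  stopifnot(ncol(a) == nrow(p), all(a %in% c(0, 1)))
  l1 <- log(object$pi) + a %*% log(p[, 2]) + (1 - a) %*% log(1 - p[, 2])
  l0 <- log(1 - object$pi) + a %*% log(p[, 1]) + (1 - a) %*% log(1 - p[, 1])
  as.vector(1 / (1 + exp(l0 - l1)))
}

#' @export
predict.func_mixture <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) && !is.matrix(newdata))
    return(score_genome(object, newdata))
  posterior_score(object, as.matrix(newdata))
}

#' Simulate annotation patterns from a fitted mixture
#'
#' Draws latent functionality indicators Bernoulli(pi) and annotation vectors
#' Bernoulli(p_ic) given each indicator; the latent truth is attached as
#' attribute `"z"`.
#'
#' @param object A `func_mixture`.
#' @param nsim Number of positions to draw.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return An `nsim` x K 0/1 matrix with attribute `"z"`.
#' @export
simulate.func_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(object$p)
  z <- stats::rbinom(nsim, 1, object$pi)
  pr <- object$p[, z + 1]            # K x nsim
  a <- matrix(stats::rbinom(nsim * K, 1, as.vector(pr)), nrow = K)
  out <- t(a)
  colnames(out) <- object$annotations
  attr(out, "z") <- z
  out
}

#' Score a genome from binary annotation tracks
#'
#' Applies [posterior_score()] base-by-base across the genome. Because the
#' posterior depends only on the local annotation pattern, the result is
#' piecewise constant and is computed once per distinct pattern.
#'
#' @param object A `func_mixture`.
#' @param tracks Named list of [binary_track()]s in the fit's annotation
#'   order (names are checked when present).
#' @return A [score_track()] of per-base posterior scores.
#' @export
score_genome <- function(object, tracks) {
  K <- nrow(object$p)
  if (length(tracks) != K)
    stop("expected ", K, " tracks, got ", length(tracks))
  if (!is.null(names(tracks)) &&
      !identical(names(tracks), object$annotations))
    tracks <- tracks[object$annotations]
  layout <- tracks[[1]]$layout
  rls <- lapply(tracks, track_rle)
  pid <- Reduce(`+`, lapply(seq_len(K), function(i) rls[[i]] * 2^(i - 1)))
  score_of <- function(ids) {
    pat <- vapply(seq_len(K), function(i) (ids %/% 2^(i - 1)) %% 2,
                  numeric(length(ids)))
    posterior_score(object, matrix(pat, ncol = K))
  }
  out <- methods::as(lapply(layout$names, function(chr) {
    r <- pid[[chr]]
    S4Vectors::Rle(score_of(S4Vectors::runValue(r)), S4Vectors::runLength(r))
  }), "RleList")
  names(out) <- layout$names
  rle_to_score_track(out, layout,
                     resolution = min(vapply(tracks, function(t) t$resolution,
                                             integer(1))))
}

#' Annotation odds ratio of predicting functionality
#'
#' For annotation i, the odds of observing the mark in functional versus
#' non-functional sequence: \[p_i1 / (1 - p_i1)\] / \[p_i0 / (1 - p_i0)\].
#' Values above 1 mark positive predictors of functionality; repressive marks
#' can fall below 1.
#'
#' @param object A `func_mixture`.
#' @param i Optional annotation index or name; default all.
#' @return Named numeric vector of odds ratios.
#' @export
annotation_odds_ratio <- function(object, i = NULL) {
  p <- object$p
  or <- (p[, "functional"] / (1 - p[, "functional"])) /
    (p[, "nonfunctional"] / (1 - p[, "nonfunctional"]))
  names(or) <- object$annotations
  if (!is.null(i)) or[i] else or
}
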