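#' Partition SNPs by annotation score
#'
#' Splits SNPs into high and low groups at a score threshold (default 0.1)
#' for both the tissue-specific and the general functionality score. The
#' high-group fractions estimate P(Z_T = 1) and P(Z = 1); the low groups
#' supply null p-value distributions.
#'
#' @param stats A [sumstats()] table.
#' @param tissue_scores,general_scores Per-SNP scores aligned with `stats`.
#' @param threshold Score threshold; a SNP is "high" when score >= threshold.
#' @return List with `high_tissue`, `low_tissue`, `high_general`,
#'   `low_general` (logical vectors), `p_zt1`, `p_z1`.
#' @export
partition_snps <- function(stats, tissue_scores, general_scores,
                           threshold = 0.1) {
  stopifnot(length(tissue_scores) == nrow(stats),
            length(general_scores) == nrow(stats))
  ht <- tissue_scores >= threshold
  hg <- general_scores >= threshold
  if (!any(ht) || all(ht))
    stop("tissue-score partition left a group empty; adjust the threshold")
  if (!any(hg) || all(hg))
    stop("general-score partition left a group empty; adjust the threshold")
  list(high_tissue = ht, low_tissue = !ht,
       high_general = hg, low_general = !hg,
       p_zt1 = mean(ht), p_z1 = mean(hg))
}

#' Histogram estimate of a null p-value density
#'
#' Equal-width histogram density on (0, 1\]. Zero-count bins are floored at a
#' small epsilon and the density renormalized, so posterior denominators stay
#' strictly positive. With fewer than 10 observations per bin the binning is
#' coarsened, with a warning.
#'
#' @param pvals P-values in (0, 1\].
#' @param n_bins Number of bins (default 500).
#' @param eps Floor for empty bins.
#' @return An object of class `pval_density` with `breaks`, `density`
#'   (integrates to 1) and `n_bins`.
#' @export
estimate_null_density <- function(pvals, n_bins = 500L, eps = 1e-8) {
  if (!length(pvals)) stop("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (length(pvals) < 10 * n_bins) {
    n_bins <- max(10L, length(pvals) %/% 10L)
    warning("few observations; coarsened histogram to ", n_bins, " bins")
  }
  cnt <- tabulate(pmin(ceiling(pvals * n_bins), n_bins), nbins = n_bins)
  dens <- pmax(cnt / length(pvals) * n_bins, eps)
  dens <- dens / (sum(dens) / n_bins)      # renormalize to integrate to 1
  structure(list(breaks = seq(0, 1, length.out = n_bins + 1),
                 density = dens, n_bins = n_bins),
            class = "pval_density")
}

#' Evaluate a binned p-value density
#'
#' @param d A `pval_density`.
#' @param p P-values in (0, 1\].
#' @return Density values.
#' @export
density_at <- function(d, p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  d$density[pmin(ceiling(p * d$n_bins), d$n_bins)]
}

#' Fit the signal/null p-value mixture by EM
#'
#' Among SNPs in tissue-functional regions, p-values follow
#' w * Beta(alpha, 1) + (1 - w) * f0(p), where the Beta(alpha, 1) density
#' alpha * p^(alpha - 1) with 0 < alpha < 1 models phenotype-relevant SNPs
#' (mass near zero) and f0 is the histogram null. The M-step is closed form:
#' alpha = -sum(w_j) / sum(w_j * log p_j), projected into
#' \[1e-4, 1 - 1e-4\]; the likelihood is monotone non-decreasing.
#'
#' When the data carry no signal the mixture is barely identified: as alpha
#' approaches 1 the Beta component becomes uniform and the likelihood is
#' nearly flat in w, so EM can stall at an arbitrary weight while improving
#' on the no-signal model by only a noise-level margin. A model-selection
#' guard handles this: if the fitted mixture beats the w = 0 model by less
#' than `lrt_min` log-likelihood units (default 2, the AIC cost of the two
#' extra parameters), the no-signal fit w = 0 is reported.
#'
#' @param pvals P-values from the high-tissue-score subgroup, in (0, 1\].
#' @param null_density A `pval_density` for f0.
#' @param tol Relative log-likelihood tolerance.
#' @param max_iter Iteration cap.
#' @param init Starting `c(w, alpha)`.
#' @param lrt_min Minimum log-likelihood improvement over w = 0 for a
#'   non-null fit to be retained.
#' @return An object of class `signal_mixture` with `w`
#'   (P(Z_D = 1 | Z_T = 1)), `alpha`, `loglik` trace, `converged`,
#'   `no_signal`.
#' @export
fit_signal_mixture <- function(pvals, null_density, tol = 1e-6,
                               max_iter = 1000L, init = c(w = 0.5, alpha = 0.5),
                               lrt_min = 2) {
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (all(pvals == 1)) stop("degenerate input: all p-values equal 1")
  lp <- log(pvals)
  f0 <- density_at(null_density, pvals)
  w <- init[["w"]]; alpha <- init[["alpha"]]
  loglik <- numeric(0)
  boundary <- FALSE
  for (it in seq_len(max_iter)) {
    f1 <- alpha * pvals^(alpha - 1)
    mix <- w * f1 + (1 - w) * f0
    loglik <- c(loglik, sum(log(mix)))
    r <- w * f1 / mix
    w <- mean(r)
    alpha_new <- -sum(r) / sum(r * lp)
    if (!is.finite(alpha_new)) alpha_new <- 1 - 1e-4
    if (alpha_new <= 1e-4 || alpha_new >= 1 - 1e-4) boundary <- TRUE
    alpha <- min(max(alpha_new, 1e-4), 1 - 1e-4)
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) <
          tol * (abs(loglik[it - 1]) + 1e-12)) break
  }
  if (boundary)
    warning("alpha was projected back into (0, 1) during EM")
  no_signal <- loglik[length(loglik)] - sum(log(f0)) < lrt_min
  if (no_signal) w <- 0
  structure(list(w = w, alpha = alpha, loglik = loglik, n_iter = it,
                 converged = it < max_iter, no_signal = no_signal),
            class = "signal_mixture")
}

#' @export
print.signal_mixture <- function(x, ...) {
  cat(sprintf("Signal/null p-value mixture: w = %.4f, alpha = %.4f (%d EM iterations)\n",
              x$w, x$alpha, x$n_iter))
  invisible(x)
}

#' Assemble reprioritization components
#'
#' @param p_zt1 P(Z_T = 1), tissue-functional prior.
#' @param p_z1 P(Z = 1), general-functional prior.
#' @param f_zt0 `pval_density` of p given Z_T = 0 (low tissue score).
#' @param f_z0 `pval_density` of p given Z = 0 (low general score).
#' @param w Mixture weight P(Z_D = 1 | Z_T = 1).
#' @param alpha Beta shape in (0, 1).
#' @return A list of class `genowap_components`.
#' @export
genowap_components <- function(p_zt1, p_z1, f_zt0, f_z0, w, alpha) {
  stopifnot(p_zt1 >= 0, p_zt1 <= 1, w >= 0, w <= 1,
            alpha > 0, alpha < 1,
            inherits(f_zt0, "pval_density"), inherits(f_z0, "pval_density"))
  structure(list(p_zt1 = p_zt1, p_z1 = p_z1, f_zt0 = f_zt0, f_z0 = f_z0,
                 w = w, alpha = alpha),
            class = "genowap_components")
}

#' Posterior probability that a SNP is tissue-functional and trait-relevant
#'
#' Three disjoint cases: (1) tissue-functional and phenotype-relevant, with
#' p ~ Beta(alpha, 1); (2) tissue-functional but phenotype-irrelevant, whose
#' p-values follow the general null f(p | Z = 0); (3) not tissue-functional,
#' following f(p | Z_T = 0). The posterior is
#' f(p | case 1) P(case 1) / sum_k f(p | case k) P(case k), with
#' P(case 1) = w P(Z_T = 1), P(case 2) = (1 - w) P(Z_T = 1),
#' P(case 3) = 1 - P(Z_T = 1).
#'
#' @param p P-values in (0, 1\].
#' @param comp A [genowap_components()].
#' @return Posterior probabilities in \[0, 1\].
#' @export
genowap_posterior <- function(p, comp) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  f1 <- comp$alpha * p^(comp$alpha - 1)
  f2 <- density_at(comp$f_z0, p)
  f3 <- density_at(comp$f_zt0, p)
  pr1 <- comp$w * comp$p_zt1
  pr2 <- (1 - comp$w) * comp$p_zt1
  pr3 <- 1 - comp$p_zt1
  num <- f1 * pr1
  num / (num + f2 * pr2 + f3 * pr3)
}

#' Reprioritize GWAS SNPs with tissue and general functionality scores
#'
#' End-to-end pipeline: score each SNP with the tissue-specific track and a
#' general functionality track (by convention the 10-kb smoothed general
#' score; both conventions are point lookups at the SNP base and are
#' configurable by passing per-SNP scores directly), partition at the score
#' threshold, estimate the two null histograms from the low-score groups,
#' fit the signal mixture on the high-tissue group, and compute every SNP's
#' posterior. An optional mask (e.g. the APOE region for late-onset
#' Alzheimer's) is excluded before estimation.
#'
#' @param stats A [sumstats()] table.
#' @param tissue_track,general_track [score_track()]s, or per-SNP numeric
#'   score vectors aligned with `stats`.
#' @param threshold Score partition threshold (default 0.1).
#' @param n_bins Histogram bins for the null densities.
#' @param mask Optional [genomic_mask()] applied first.
#' @return An object of class `genowap_fit` with `records` (data frame:
#'   `snp, chr, bp, p, tissue_score, general_score, posterior`),
#'   `components`, `mixture`.
#' @export
genowap <- function(stats, tissue_track, general_track, threshold = 0.1,
                    n_bins = 500L, mask = NULL) {
  if (!is.null(mask)) {
    kept <- exclude_regions(stats, mask)
    keep <- stats$snp %in% kept$snp
    if (is.numeric(tissue_track)) tissue_track <- tissue_track[keep]
    if (is.numeric(general_track)) general_track <- general_track[keep]
    stats <- kept
  }
  pos <- data.frame(chr = stats$chr, bp = stats$bp)
  ts <- if (is.numeric(tissue_track)) tissue_track
        else scores_at(tissue_track, pos)
  gs <- if (is.numeric(general_track)) general_track
        else scores_at(general_track, pos)
  part <- partition_snps(stats, ts, gs, threshold = threshold)
  f_zt0 <- estimate_null_density(stats$p[part$low_tissue], n_bins = n_bins)
  f_z0 <- estimate_null_density(stats$p[part$low_general], n_bins = n_bins)
  mix <- fit_signal_mixture(stats$p[part$high_tissue], f_z0)
  comp <- genowap_components(part$p_zt1, part$p_z1, f_zt0, f_z0,
                             mix$w, mix$alpha)
  rec <- data.frame(snp = stats$snp, chr = stats$chr, bp = stats$bp,
                    p = stats$p, tissue_score = ts, general_score = gs,
                    posterior = genowap_posterior(stats$p, comp))
  structure(list(records = rec, components = comp, mixture = mix,
                 threshold = threshold),
            class = "genowap_fit")
}

#' @export
print.genowap_fit <- function(x, ...) {
  cat(sprintf("SNP reprioritization: %d SNPs; P(Z_T=1) = %.3f, w = %.3f, alpha = %.3f\n",
              nrow(x$records), x$components$p_zt1, x$components$w,
              x$components$alpha))
  cat(sprintf("  %d SNP(s) with posterior >= 0.95\n",
              sum(x$records$posterior >= 0.95)))
  invisible(x)
}

#' Cluster high-posterior SNPs into loci
#'
#' SNPs with posterior at or above `posterior_cutoff` (default 0.95) are
#' clustered: successive qualifying SNPs on one chromosome closer than
#' `locus_merge_bp` join one locus; the SNP with the highest posterior (ties:
#' smallest p) represents it.
#'
#' @param records The `records` data frame of a [genowap()] fit (or the fit).
#' @param posterior_cutoff Posterior threshold.
#' @param locus_merge_bp Merge radius in bp.
#' @return Data frame with one row per locus: `chr, start, end, n_snps,
#'   top_snp, top_bp, top_posterior, top_p`; empty when nothing qualifies.
#' @export
rank_loci <- function(records, posterior_cutoff = 0.95,
                      locus_merge_bp = 1e6) {
  if (inherits(records, "genowap_fit")) records <- records$records
  q <- records[records$posterior >= posterior_cutoff, ]
  if (!nrow(q)) return(data.frame())
  q <- q[order(match(q$chr, unique(q$chr)), q$bp), ]
  new_locus <- c(TRUE, q$chr[-1] != q$chr[-nrow(q)] |
                   diff(q$bp) > locus_merge_bp)
  locus <- cumsum(new_locus)
  rows <- lapply(split(q, locus), function(s) {
    top <- order(-s$posterior, s$p)[1]
    data.frame(chr = s$chr[1], start = min(s$bp), end = max(s$bp),
               n_snps = nrow(s), top_snp = s$snp[top], top_bp = s$bp[top],
               top_posterior = s$posterior[top], top_p = s$p[top])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$top_posterior, out$top_p), ]
}
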