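write_truth_json <- function(truth, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".truth.json"))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate binary annotation tracks with planted mixture truth
#'
#' Emulates the generative model behind the functional mixture: the genome is
#' tiled into segments of `segment_bp`; each segment draws a latent
#' functionality indicator Z ~ Bernoulli(pi) and each annotation is then
#' Bernoulli(p_i1) or Bernoulli(p_i0) given Z. The defaults plant a sparse
#' functional genome (pi = 0.1) with strongly informative marks (p_i1 = 0.8
#' vs p_i0 = 0.05) over a 1-Mb toy chromosome — enough positions that
#' empirical frequencies sit within binomial noise of the planted values.
#'
#' @param seed RNG seed; identical seeds give identical outputs.
#' @param genome_bp Genome length (single chromosome `chr1`).
#' @param segment_bp Segment length; each segment is one independent draw.
#' @param pi Planted prior functional probability.
#' @param p_functional,p_nonfunctional Planted per-annotation Bernoulli
#'   probabilities given Z = 1 / Z = 0 (length 1 or K).
#' @param annotations Annotation names (default the canonical ten).
#' @param out_dir Optional directory: tracks are written as BED plus a
#'   `tracks.truth.json` sidecar with the planted parameters.
#' @return List with `tracks` (named [binary_track()]s), `truth_track`
#'   (latent Z as a [binary_track()]), `layout`, and `truth` (planted
#'   parameters, seed, realized functional fraction).
#' @export
gen_annotation_tracks <- function(seed = 1L, genome_bp = 1e6,
                                  segment_bp = 10L, pi = 0.1,
                                  p_functional = 0.8,
                                  p_nonfunctional = 0.05,
                                  annotations = annotation_names(),
                                  out_dir = NULL) {
  K <- length(annotations)
  p1 <- rep_len(p_functional, K)
  p0 <- rep_len(p_nonfunctional, K)
  n_seg <- as.integer(ceiling(genome_bp / segment_bp))
  layout <- genome_layout(c(chr1 = n_seg * as.numeric(segment_bp)),
                          assembly = "synthetic")
  set.seed(seed)
  z <- stats::rbinom(n_seg, 1, pi)
  seg_track <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values == 1
    gr <- if (any(keep)) GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = (starts[keep] - 1) * segment_bp + 1,
                       end = ends[keep] * segment_bp),
      seqinfo = as_seqinfo(layout))
    else GenomicRanges::GRanges(seqinfo = as_seqinfo(layout))
    binary_track(gr, layout, resolution = 1L)
  }
  tracks <- lapply(seq_len(K), function(i)
    seg_track(stats::rbinom(n_seg, 1, ifelse(z == 1, p1[i], p0[i]))))
  names(tracks) <- annotations
  truth <- list(seed = seed, pi = pi, p_functional = p1,
                p_nonfunctional = p0, segment_bp = segment_bp,
                genome_bp = genome_bp, annotations = annotations,
                functional_fraction = mean(z))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tracks))
      write_track(tracks[[nm]], file.path(out_dir, paste0(nm, ".bed")))
    write_truth_json(truth, out_dir, "tracks")
  }
  list(tracks = tracks, truth_track = seg_track(z), layout = layout,
       truth = truth)
}

#' Simulate a genotype panel and a pair of GWAS with planted architecture
#'
#' Genotypes come from a first-order haplotype-copying model: allele
#' frequencies are uniform per SNP and each haplotype copies its previous
#' allele with probability sqrt(`adjacent_r2`), giving adjacent-SNP r^2 near
#' the target (0.5 by default) and geometric LD decay — a deliberately simple
#' stand-in for human LD. Genetic positions are linear at 1 cM/Mb.
#'
#' A "functional" category of contiguous SNP blocks covers `coverage` of
#' SNPs; per-SNP standardized effect variances inside/outside the category
#' are set so the category's heritability share is `fold` times its coverage,
#' with total heritability `h2`. Marginal z-scores are drawn as
#' z = sqrt(N) R beta + e with e ~ N(0, R) (R the panel LD), independently
#' per trait, so the LD-score regression expectation
#' E\[chi2\] = 1 + N sum_c tau_c l(j,c) holds by construction. Optionally,
#' `shared_windows` windows receive one common causal SNP inside the
#' category whose effect (z-scale `shared_z`) is added to both traits,
#' planting pleiotropic windows.
#'
#' @param seed RNG seed.
#' @param n_ind Panel individuals.
#' @param n_chrom,snps_per_chrom,spacing_bp Marker layout (defaults: 20
#'   chromosomes x 1,000 SNPs at 1-kb spacing = 20,000 SNPs).
#' @param adjacent_r2 Target adjacent-SNP r^2.
#' @param h2 Total (standardized-scale) heritability per trait; 0 gives a
#'   pure null with mean chi-square 1.
#' @param coverage Fraction of SNPs in the functional category.
#' @param fold Planted heritability enrichment of the category (1 = none).
#' @param N GWAS sample size (scalar, both traits).
#' @param shared_windows Number of pleiotropic windows to plant.
#' @param window_bp Window size used for planting.
#' @param shared_z z-scale effect of each shared causal SNP.
#' @param scatter_annot Scatter category membership i.i.d. across SNPs
#'   instead of contiguous blocks. Scattered membership is exchangeable with
#'   the SNP-level annotation shuffle of the pleiotropy permutation test, so
#'   it is the right null fixture for calibration checks; blocks emulate the
#'   clumped geometry of real functional annotations.
#' @param ld `"copying"` (default) or `"independent"` (no LD; faster, for
#'   window-test fixtures).
#' @param panel_from Optional result of a previous `gen_gwas_pair()` call:
#'   its panel, marker layout and category are reused and only the effect
#'   sizes and z-scores are redrawn — the cheap way to replicate traits on a
#'   fixed reference panel.
#' @param out_dir Optional output directory (sumstats, annot and a
#'   `gwas.truth.json` sidecar).
#' @return List with `panel` ([genotype_panel()]), `stats_a`, `stats_b`
#'   ([sumstats()]), `annot` ([annot_matrix()]: base + functional),
#'   `functional_track` ([binary_track()]), `layout`, `truth`.
#' @export
gen_gwas_pair <- function(seed = 1L, n_ind = 500L, n_chrom = 20L,
                          snps_per_chrom = 1000L, spacing_bp = 1000L,
                          adjacent_r2 = 0.5, h2 = 0.5, coverage = 0.10,
                          fold = 5, N = 50000L, shared_windows = 0L,
                          window_bp = 1e6, shared_z = 6,
                          ld = c("copying", "independent"),
                          scatter_annot = FALSE,
                          panel_from = NULL, out_dir = NULL) {
  ld <- match.arg(ld)
  set.seed(seed)
  if (!is.null(panel_from)) {
    panel <- panel_from$panel; map <- panel_from$map
    layout <- panel_from$layout; annot <- panel_from$annot
    ftrack <- panel_from$functional_track
    member <- unclass(annot)[, "functional"] == 1
    n_ind <- panel$n_ind
    n_chrom <- length(unique(map$chr))
    m_chr <- nrow(map) %/% n_chrom
    M <- nrow(map)
    ld <- panel_from$truth$ld
    geno <- panel$geno
  } else {
  m_chr <- snps_per_chrom
  M <- n_chrom * m_chr
  chroms <- paste0("chr", seq_len(n_chrom))
  chr_len <- m_chr * spacing_bp
  layout <- genome_layout(stats::setNames(rep(chr_len, n_chrom), chroms),
                          assembly = "synthetic")
  map <- data.frame(
    chr = rep(chroms, each = m_chr),
    snp = paste0("rs", seq_len(M)),
    cM = rep((seq_len(m_chr) - 0.5) * spacing_bp, n_chrom) / 1e6,
    bp = rep(as.integer((seq_len(m_chr) - 0.5) * spacing_bp), n_chrom))

  rho <- sqrt(adjacent_r2)
  nh <- 2L * n_ind
  sim_chrom <- function() {
    f <- stats::runif(m_chr, 0.05, 0.95)
    h <- matrix(0L, nh, m_chr)
    h[, 1] <- stats::rbinom(nh, 1, f[1])
    if (ld == "copying") {
      for (j in 2:m_chr) {
        fresh <- stats::rbinom(nh, 1, f[j])
        copy <- stats::rbinom(nh, 1, rho)
        h[, j] <- ifelse(copy == 1, h[, j - 1], fresh)
      }
    } else {
      for (j in 2:m_chr) h[, j] <- stats::rbinom(nh, 1, f[j])
    }
    g <- h[seq_len(n_ind), ] + h[n_ind + seq_len(n_ind), ]
    mono <- which(apply(g, 2, function(x) length(unique(x)) == 1))
    for (j in mono) {   # flip one allele to keep the panel polymorphic
      i <- sample(n_ind, 1)
      g[i, j] <- if (g[i, j] == 0) 1L else g[i, j] - 1L
    }
    g
  }
  geno <- do.call(cbind, lapply(seq_len(n_chrom), function(ch) sim_chrom()))
  panel <- genotype_panel(geno, map)

  member <- logical(M)
  if (scatter_annot) {
    member[sample(M, round(coverage * M))] <- TRUE
  } else {
    # contiguous functional blocks covering `coverage` of each chromosome
    block_snps <- max(10L, as.integer(coverage * m_chr / 5))
    n_block <- max(1L, round(coverage * m_chr / block_snps))
    for (ch in seq_len(n_chrom)) {
      off <- (ch - 1L) * m_chr
      starts <- sort(sample(seq_len(m_chr - block_snps), n_block))
      for (s in starts) member[off + s:(s + block_snps - 1L)] <- TRUE
    }
  }
  annot <- annot_matrix(cbind(base = rep(1, M), functional = as.numeric(member)),
                        snp = map$snp)
  ftrack <- binary_track(GenomicRanges::reduce(positions_to_granges(
    data.frame(chr = map$chr[member], bp = map$bp[member]), layout)
    + (spacing_bp %/% 2 - 1L)), layout)
  }

  cov_real <- mean(member)
  if (fold * cov_real >= 1 && fold != 1)
    stop("fold * coverage must be < 1")
  if (h2 > 0) {
    r <- if (fold == 1) 1 else fold * (1 - cov_real) / (1 - fold * cov_real)
    v_out <- h2 / (M * (1 - cov_real + cov_real * r))
    v_in <- r * v_out
  } else v_out <- v_in <- 0
  v <- ifelse(member, v_in, v_out)

  # plant shared causal SNPs in distinct windows, inside the category
  shared <- integer(0)
  if (shared_windows > 0) {
    wid <- paste(map$chr, (map$bp - 1) %/% window_bp)
    cand <- which(member)
    pick <- cand[!duplicated(wid[cand])]
    if (length(pick) < shared_windows)
      stop("not enough annotated windows to plant ", shared_windows)
    shared <- sort(sample(pick, shared_windows))
  }

  sim_trait <- function() {
    beta <- stats::rnorm(M, 0, sqrt(v))
    beta[shared] <- beta[shared] + shared_z / sqrt(N)
    z <- numeric(M)
    for (ch in seq_len(n_chrom)) {
      idx <- (ch - 1L) * m_chr + seq_len(m_chr)
      if (ld == "copying") {
        Xs <- scale(geno[, idx, drop = FALSE])
        u <- Xs %*% beta[idx]
        rb <- crossprod(Xs, u) / (n_ind - 1)
        e <- crossprod(Xs, stats::rnorm(n_ind)) / sqrt(n_ind - 1)
        z[idx] <- sqrt(N) * rb + e
      } else {
        z[idx] <- sqrt(N) * beta[idx] + stats::rnorm(m_chr)
      }
    }
    z
  }
  za <- sim_trait()
  zb <- sim_trait()
  mk <- function(z, label) sumstats(
    data.frame(snp = map$snp, chr = map$chr, bp = map$bp, z = z),
    study = label, n = N)
  stats_a <- mk(za, "trait_A")
  stats_b <- mk(zb, "trait_B")

  truth <- list(seed = seed, n_ind = n_ind, M = M, N = N, h2 = h2,
                coverage = cov_real, fold = fold,
                tau = c(base = v_out, functional = v_in - v_out),
                shared_snps = map$snp[shared],
                shared_windows = shared_windows, window_bp = window_bp,
                ld = ld)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sumstats(stats_a, file.path(out_dir, "trait_A.sumstats"))
    write_sumstats(stats_b, file.path(out_dir, "trait_B.sumstats"))
    write_annot(annot, map, file.path(out_dir, "categories.annot"))
    write_truth_json(truth, out_dir, "gwas")
  }
  list(panel = panel, stats_a = stats_a, stats_b = stats_b, annot = annot,
       functional_track = ftrack, layout = layout, map = map, truth = truth)
}

#' Simulate an expression matrix with planted tissue specificity
#'
#' A fraction of elements is strictly one-hot (expressed in a single tissue,
#' TSI exactly 1, tissues assigned cyclically); the remainder is near-uniform
#' noise (TSI well below 0.5). Elements get genomic coordinates on a toy
#' chromosome, and per-tissue binary tracks are planted so that each
#' tissue's track covers `covered_frac` of the bases of its own specific
#' elements but only a `background_frac` sprinkle of other elements —
#' mirroring what a matched functional annotation should recover.
#'
#' @param seed RNG seed.
#' @param n_elements,n_tissues Matrix dimensions.
#' @param specific_frac Fraction of one-hot elements (0 gives pure noise).
#' @param element_bp Element width.
#' @param covered_frac,background_frac Planted coverage of matched vs
#'   unmatched elements.
#' @param out_dir Optional output directory (expression table, BED,
#'   `expression.truth.json`).
#' @return List with `expr` (matrix), `coords` (`GRanges` named by element),
#'   `tracks` (per-tissue [binary_track()]s), `layout`, `truth`.
#' @export
gen_expression <- function(seed = 1L, n_elements = 200L, n_tissues = 10L,
                           specific_frac = 0.3, element_bp = 500L,
                           covered_frac = 0.8, background_frac = 0.1,
                           out_dir = NULL) {
  set.seed(seed)
  tissues <- paste0("tissue", seq_len(n_tissues))
  elements <- sprintf("el%03d", seq_len(n_elements))
  n_spec <- round(specific_frac * n_elements)
  spec_tissue <- rep(NA_integer_, n_elements)
  if (n_spec > 0)
    spec_tissue[seq_len(n_spec)] <- rep_len(seq_len(n_tissues), n_spec)
  expr <- matrix(stats::runif(n_elements * n_tissues, 1, 2) *
                   stats::runif(n_elements * n_tissues, 0.8, 1.2),
                 n_elements, n_tissues, dimnames = list(elements, tissues))
  for (j in which(!is.na(spec_tissue))) {
    expr[j, ] <- 0
    expr[j, spec_tissue[j]] <- stats::runif(1, 5, 10)
  }
  gap <- 4L * element_bp
  starts <- (seq_len(n_elements) - 1L) * gap + 1L
  layout <- genome_layout(c(chr1 = n_elements * gap), assembly = "synthetic")
  coords <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = starts, width = element_bp),
    seqinfo = as_seqinfo(layout))
  S4Vectors::mcols(coords)$name <- elements

  tracks <- lapply(seq_len(n_tissues), function(t) {
    own <- which(!is.na(spec_tissue) & spec_tissue == t)
    other <- setdiff(seq_len(n_elements), own)
    bg <- other[stats::runif(length(other)) < background_frac]
    pieces <- list()
    if (length(own))
      pieces <- c(pieces, GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = starts[own],
                         width = as.integer(covered_frac * element_bp)),
        seqinfo = as_seqinfo(layout)))
    if (length(bg))
      pieces <- c(pieces, GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = starts[bg], width = element_bp),
        seqinfo = as_seqinfo(layout)))
    iv <- if (length(pieces)) do.call(c, pieces)
          else GenomicRanges::GRanges(seqinfo = as_seqinfo(layout))
    binary_track(iv, layout)
  })
  names(tracks) <- tissues

  truth <- list(seed = seed, n_elements = n_elements, n_tissues = n_tissues,
                specific_frac = specific_frac,
                specific_tissue = ifelse(is.na(spec_tissue), NA,
                                         tissues[spec_tissue]),
                covered_frac = covered_frac,
                background_frac = background_frac)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(element = elements, expr, check.names = FALSE),
      file.path(out_dir, "expression.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rtracklayer::export(coords, file.path(out_dir, "elements.bed"),
                        format = "BED")
    write_truth_json(truth, out_dir, "expression")
  }
  list(expr = expr, coords = coords, tracks = tracks, layout = layout,
       truth = truth)
}
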