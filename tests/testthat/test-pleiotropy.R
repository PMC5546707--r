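# desk-scale pleiotropy fixture: 20 chromosomes x 5 Mb, SNPs every 5 kb,
# 100 one-Mb windows of 200 SNPs each
pleio_gen <- function(seed, shared = 0, h2 = 0.2) {
  gen_gwas_pair(seed = seed, n_chrom = 20, snps_per_chrom = 1000,
                spacing_bp = 5000, ld = "independent", h2 = h2,
                fold = 1, N = 20000, shared_windows = shared,
                window_bp = 1e6, shared_z = 7)
}

test_that("window labels match hand enumeration on a toy fixture", {
  lay <- genome_layout(c(chr1 = 6e6))
  # 6 windows; SNPs: (window, p, in-track)
  snp <- data.frame(
    snp = paste0("s", 1:8), chr = "chr1",
    bp = c(5e5, 6e5, 1.5e6, 2.5e6, 3.5e6, 4.2e6, 4.6e6, 5.5e6),
    p = c(5e-4, 0.2, 5e-4, 0.5, 1e-5, 5e-4, 2e-4, 0.9))
  s <- sumstats(snp, n = 1000)
  track <- binary_track(data.frame(chr = "chr1",
                                   start = c(4e5, 4.5e6),
                                   end = c(7e5, 4.7e6)), lay)
  grid <- window_grid(lay, s, window_bp = 1e6)
  expect_equal(length(grid$windows), 6L)
  lab <- label_windows(s, track, grid)
  # w1: s1 sig+in -> 1; w2: s3 sig, outside -> 0; w3: s4 not sig -> 0
  # w4: s5 sig, outside -> 0; w5: s6 sig outside, s7 sig inside -> 1; w6: 0
  expect_equal(lab$labels, c(1L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(lab$k, 2L)

  # an all-ones annotation reduces condition 2 to condition 1
  all1 <- binary_track(data.frame(chr = "chr1", start = 0, end = 6e6), lay)
  lab1 <- label_windows(s, all1, grid)
  expect_equal(lab1$labels, c(1L, 1L, 0L, 1L, 1L, 0L))  # condition 1 alone
})

test_that("hypergeometric overlap equals exact tail enumeration and is symmetric", {
  la <- structure(list(labels = c(rep(1L, 4), rep(0L, 6)), k = 4L, n = 10L),
                  class = "window_labels")
  lb <- structure(list(labels = c(rep(1L, 4), 1L, rep(0L, 5)), k = 5L, n = 10L),
                  class = "window_labels")
  h <- hypergeom_overlap(la, lb)
  expect_equal(h$overlap, 4L)
  expect_equal(h$p_value, 6 / 252, tolerance = 1e-12)  # C(4,4)C(6,1)/C(10,5)
  expect_equal(hypergeom_overlap(lb, la)$p_value, h$p_value)

  lz <- structure(list(labels = c(rep(0L, 4), 1L, rep(1L, 5)), k = 6L, n = 10L),
                  class = "window_labels")
  l0 <- structure(list(labels = rep(c(1L, 0L), 5), k = 5L, n = 10L),
                  class = "window_labels")
  # overlap 0 -> upper tail at >= 0 is 1... overlap here is computed from labels
  la0 <- structure(list(labels = c(rep(1L, 3), rep(0L, 7)), k = 3L, n = 10L),
                   class = "window_labels")
  lb0 <- structure(list(labels = c(rep(0L, 3), rep(1L, 3), rep(0L, 4)),
                        k = 3L, n = 10L), class = "window_labels")
  expect_equal(hypergeom_overlap(la0, lb0)$overlap, 0L)
  expect_gt(hypergeom_overlap(la0, lb0)$p_value, 0.7)

  expect_error(hypergeom_overlap(la, structure(list(labels = 1L, k = 1L,
                                                    n = 5L),
                                               class = "window_labels")),
               "grids")
})

test_that("permutation p respects the add-one lower bound and detects planted sharing", {
  g <- pleio_gen(seed = 201, shared = 8)
  grid <- window_grid(g$layout, list(g$stats_a, g$stats_b))
  pt <- permutation_test(g$stats_a, g$stats_b, g$functional_track, grid,
                         n_perm = 199, seed = 1)
  expect_gte(pt$p_value, 1 / 200)
  expect_lt(pt$p_value, 0.05)
  expect_gte(pt$observed, 6)       # most planted windows labeled for both
})

test_that("planted-fixture conclusion is stable at 1 Mb and 500 kb windows", {
  g <- pleio_gen(seed = 202, shared = 8)
  for (wbp in c(1e6, 5e5)) {
    grid <- window_grid(g$layout, list(g$stats_a, g$stats_b), window_bp = wbp)
    pt <- permutation_test(g$stats_a, g$stats_b, g$functional_track, grid,
                           n_perm = 199, seed = 2)
    expect_lt(pt$p_value, 0.05)
  }
})

test_that("null permutation p and hypergeometric p agree in order of magnitude", {
  g <- pleio_gen(seed = 203, shared = 0)
  grid <- window_grid(g$layout, list(g$stats_a, g$stats_b))
  pt <- permutation_test(g$stats_a, g$stats_b, g$functional_track, grid,
                         n_perm = 199, seed = 3)
  expect_gt(pt$p_value, 0.01)
  expect_gt(pt$hypergeom$p_value, 0.001)
})

test_that("candidate loci report peak SNPs per joint window", {
  lay <- genome_layout(c(chr1 = 3e6))
  mk <- function(p, label) sumstats(
    data.frame(snp = paste0(label, seq_along(p)), chr = "chr1",
               bp = seq_along(p) * 2e5, p = p), study = label, n = 1000)
  # 15 SNPs -> windows of 5 SNPs each
  pa <- rep(0.5, 15); pa[c(2, 7)] <- c(1e-5, 2e-4)
  pb <- rep(0.5, 15); pb[c(3, 8)] <- c(5e-4, 1e-6)
  sa <- mk(pa, "A"); sb <- mk(pb, "B")
  track <- binary_track(data.frame(chr = "chr1", start = 0, end = 3e6), lay)
  grid <- window_grid(lay, list(sa, sb))
  la <- label_windows(sa, track, grid)
  lb <- label_windows(sb, track, grid)
  loci <- candidate_loci(la, lb, sa, sb, grid, annot_track = track)
  expect_equal(nrow(loci), 2L)
  # sorted by the smaller of the two peak p-values: window 2 (1e-6) first
  expect_equal(loci$peak_snp_a, c("A7", "A2"))
  expect_equal(loci$peak_snp_b, c("B8", "B3"))
  expect_equal(loci$n_annot_a, c(1L, 1L))

  la0 <- label_windows(sa, binary_track(data.frame(chr = "chr1",
    start = 2.9e6, end = 3e6), lay), grid)
  expect_warning(out <- candidate_loci(la0, lb, sa, sb, grid), "no window")
  expect_equal(nrow(out), 0L)
})
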