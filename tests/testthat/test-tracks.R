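test_that("peak binarization filters by p-value and merges overlaps", {
  lay <- toy_layout()
  tr <- binarize_peaks(data.frame(chr = "chr1", start = 100, end = 200,
                                  pvalue = 0.001), lay)
  expect_equal(covered_bp(tr), 100)

  empty <- binarize_peaks(data.frame(chr = character(), start = numeric(),
                                     end = numeric(), pvalue = numeric()), lay)
  expect_equal(covered_bp(empty), 0)
  expect_equal(coverage_fraction(empty), 0)

  # overlapping passing peaks merge; failing peak dropped
  tr <- binarize_peaks(data.frame(chr = "chr1",
                                  start = c(100, 150, 400),
                                  end = c(200, 300, 450),
                                  pvalue = c(0.001, 0.005, 0.05)), lay)
  expect_equal(covered_bp(tr), 200)
  expect_equal(length(tr$intervals), 1L)

  expect_error(binarize_peaks(data.frame(chr = "chr1", start = 100,
                                         end = 20000, pvalue = 1e-5), lay),
               "bounds")
})

test_that("methylation binarization keeps islands strictly below the cutoff", {
  lay <- toy_layout()
  isl <- data.frame(chr = "chr1", start = c(0, 1000, 2000),
                    end = c(100, 1100, 2100))
  tr <- binarize_methylation(isl, lay, fraction = c(0.1, 0.5, 0.9))
  expect_equal(covered_bp(tr), 100)  # 0.5 excluded: strictly less than
  tr04 <- binarize_methylation(isl[1, ], lay, fraction = 0.4)
  expect_equal(covered_bp(tr04), 100)
  expect_error(binarize_methylation(isl[1, ], lay, fraction = 1.2), "\\[0, 1\\]")
})

test_that("RNA-seq binarization thresholds 25-bp bins on the grid", {
  lay <- toy_layout()
  bins <- data.frame(chr = "chr1", start = c(0, 25, 50), end = c(25, 50, 75))
  tr <- binarize_rnaseq(bins, lay, rpkm = c(0.0, 0.5, 1.2))
  expect_equal(covered_bp(tr), 50)    # >= cutoff: 0.5 and 1.2 pass
  expect_equal(tr$resolution, 25L)

  tr0 <- binarize_rnaseq(bins, lay, rpkm = c(0.1, 0.2, 0.3))
  expect_equal(covered_bp(tr0), 0)

  set.seed(42)
  n <- 100
  vals <- round(stats::runif(n, 0, 1), 3)
  big <- data.frame(chr = "chr1", start = (0:(n - 1)) * 25, end = (1:n) * 25)
  trn <- binarize_rnaseq(big, lay, rpkm = vals)
  expect_equal(covered_bp(trn), 25 * sum(vals >= 0.5))

  off <- data.frame(chr = "chr1", start = 10, end = 35)
  expect_error(binarize_rnaseq(off, lay, rpkm = 1), "grid")
})

test_that("dichotomization sends ties to the functional class", {
  expect_equal(covered_bp(dichotomize(const_track(0.7))), 10000)
  expect_equal(covered_bp(dichotomize(const_track(0.5))), 10000)
  tr <- st(c(0, 25, 50, 75), c(25, 50, 75, 100), c(0.2, 0.6, 0.4, 0.9))
  expect_equal(covered_bp(dichotomize(tr)), 50)
})

test_that("binarizations are idempotent", {
  lay <- toy_layout()
  tr <- binarize_peaks(data.frame(chr = "chr1", start = c(10, 500),
                                  end = c(200, 900),
                                  pvalue = c(1e-4, 1e-3)), lay)
  # re-binarizing a binary track's own intervals changes nothing
  again <- binary_track(tr$intervals, lay)
  expect_identical(as.data.frame(again$intervals), as.data.frame(tr$intervals))
  d <- dichotomize(st(c(0, 100), c(100, 300), c(0.8, 0.3)))
  d2 <- binary_track(d$intervals, toy_layout())
  expect_identical(as.data.frame(d2$intervals), as.data.frame(d$intervals))
})

test_that("window smoothing averages windows and conserves the mean", {
  expect_equal(track_mean(smooth_windows(const_track(0.37), 1000)), 0.37)

  lay <- toy_layout(len = 10000)
  half <- st(0, 5000, 1.0, layout = lay)
  sm <- smooth_windows(half, 10000)
  expect_equal(S4Vectors::mcols(sm$runs)$score, 0.5)

  # three windows with known values
  tr <- st(c(0, 1000, 2500), c(500, 2000, 3000), c(1, 0.4, 0.8), layout = lay)
  sm <- smooth_windows(tr, 1000)
  # window means: (1*500)/1000, (0.4*1000)/1000, (0.8*500)/1000
  expect_equal(scores_at(sm, data.frame(chr = "chr1", bp = c(1, 1001, 2001))),
               c(0.5, 0.4, 0.4))
  expect_equal(track_mean(sm), track_mean(tr))
  expect_error(smooth_windows(tr, -5), "positive")
})

test_that("smoothing conserves the mean with a partial last window", {
  lay <- toy_layout(len = 10500)   # last window is 500 bp
  set.seed(7)
  n <- 21
  tr <- st((0:(n - 1)) * 500, (1:n) * 500, stats::runif(n), layout = lay)
  sm <- smooth_windows(tr, 1000)
  expect_equal(track_mean(sm), track_mean(tr), tolerance = 1e-12)
})

test_that("track combination: union is OR, mean averages per base", {
  lay <- toy_layout()
  u <- combine_tracks(list(bt(0, 100, lay), bt(50, 150, lay)), "union")
  expect_equal(covered_bp(u), 150)
  expect_equal(GenomicRanges::start(u$intervals), 1)
  expect_equal(GenomicRanges::end(u$intervals), 150)

  m <- combine_tracks(list(const_track(0.2), const_track(0.8)), "mean")
  expect_equal(unique(S4Vectors::mcols(m$runs)$score), 0.5)

  tr3 <- list(bt(0, 100, lay), bt(80, 200, lay), bt(500, 600, lay))
  expect_equal(covered_bp(combine_tracks(tr3, "union")), 300)

  expect_error(combine_tracks(list(bt(0, 10), bt(0, 10, toy_layout(5000))),
                              "union"), "layout")
  expect_error(combine_tracks(list(const_track(0.5)), "union"), "binary")
})

test_that("combination bounds: union covers at least each input; mean stays in [0,1]", {
  set.seed(11)
  lay <- toy_layout()
  for (rep in 1:5) {
    tracks <- lapply(1:3, function(i) {
      s <- sort(sample(0:9000, 4))
      bt(s, s + sample(50:400, 4, replace = TRUE), lay)
    })
    u <- combine_tracks(tracks, "union")
    expect_gte(covered_bp(u), max(vapply(tracks, covered_bp, numeric(1))))
    m <- combine_tracks(tracks, "mean")
    sc <- S4Vectors::mcols(m$runs)$score
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("functional proportion counts qualifying element bases", {
  lay <- toy_layout()
  el <- data.frame(chr = "chr1", start = 100, end = 300)
  expect_equal(functional_proportion(const_track(1), el), 1.0)
  expect_equal(functional_proportion(const_track(1e-9), el), 0.0)

  tr <- st(c(100, 200), c(160, 400), c(0.9, 0.2), layout = lay)
  expect_equal(functional_proportion(tr, el), 60 / 200)

  expect_error(functional_proportion(const_track(1),
                                     data.frame(chr = character(),
                                                start = numeric(),
                                                end = numeric())), "empty")
})

test_that("functional proportion of a union dominates each input", {
  set.seed(13)
  lay <- toy_layout()
  el <- data.frame(chr = "chr1", start = c(0, 4000), end = c(2000, 6000))
  for (rep in 1:5) {
    s1 <- sort(sample(0:9000, 3)); s2 <- sort(sample(0:9000, 3))
    a <- bt(s1, s1 + 300, lay); b <- bt(s2, s2 + 300, lay)
    u <- combine_tracks(list(a, b), "union")
    expect_gte(functional_proportion(u, el) + 1e-12,
               max(functional_proportion(a, el), functional_proportion(b, el)))
  }
})

test_that("flanking extends, clips and merges", {
  lay <- toy_layout()
  fl <- flank_regions(data.frame(chr = "chr1", start = 1000, end = 1100), lay)
  expect_equal(GenomicRanges::start(fl), 801)
  expect_equal(GenomicRanges::end(fl), 1300)

  edge <- flank_regions(data.frame(chr = "chr1", start = 50, end = 100), lay)
  expect_equal(GenomicRanges::start(edge), 1)  # clipped at chromosome start

  two <- flank_regions(data.frame(chr = "chr1", start = c(1000, 1400),
                                  end = c(1100, 1500)), lay)
  expect_equal(length(two), 1L)   # 300 bp apart, 200-bp flanks meet
})

test_that("per-region functional track counts match enumeration", {
  lay <- toy_layout()
  regions <- data.frame(chr = "chr1", start = c(0, 1000, 2000),
                        end = c(500, 1500, 2500))
  zeros <- lapply(1:5, function(i) bt(numeric(0), numeric(0), lay))
  expect_equal(count_functional_tracks(zeros, regions)$counts, c(0L, 0L, 0L))
  ones <- lapply(1:3, function(i) bt(0, 10000, lay))
  expect_equal(count_functional_tracks(ones, regions)$counts, c(3L, 3L, 3L))

  tracks <- list(bt(0, 100, lay),          # region 1 only
                 bt(c(0, 1100), c(50, 1200), lay),  # regions 1, 2
                 bt(2400, 2600, lay),      # region 3
                 bt(600, 900, lay))        # none
  res <- count_functional_tracks(tracks, regions)
  expect_equal(res$counts, c(2L, 1L, 1L))
  expect_equal(as.vector(res$histogram), c(0L, 2L, 1L, 0L, 0L))
})

test_that("quantile binarization uses the nearest-rank reference cutoff", {
  lay <- toy_layout(len = 101000)
  n <- 100
  tr <- st((0:(n - 1)) * 1000, (1:n) * 1000, (1:n) / 100, layout = lay)
  refs <- data.frame(chr = "chr1", bp = (0:(n - 1)) * 1000 + 500)
  qb <- quantile_binarize(tr, refs, quantile = 0.90)
  expect_equal(attr(qb, "cutoff"), 0.90)
  # bases at score >= 0.90: runs 90..100
  expect_equal(covered_bp(qb), 11 * 1000)

  expect_warning(quantile_binarize(const_track(0.4),
                                   data.frame(chr = "chr1", bp = c(10, 20))),
                 "identical")
})

test_that("quantile binarization annotates about the top decile of references", {
  set.seed(99)
  n <- 10000
  lay <- toy_layout(len = n * 10)
  sc <- stats::runif(n)
  tr <- st((0:(n - 1)) * 10, (1:n) * 10, sc, layout = lay)
  refs <- data.frame(chr = "chr1", bp = (0:(n - 1)) * 10 + 5)
  qb <- quantile_binarize(tr, refs, quantile = 0.90)
  frac <- mean(scores_at(qb, refs))
  expect_lt(abs(frac - 0.10), 0.02)
})
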