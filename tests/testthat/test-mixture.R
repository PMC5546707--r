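test_that("training regions are centered, merged 1-kb intervals", {
  lay <- toy_layout(len = 1e6)
  tr <- build_training_regions(data.frame(chr = "chr1", bp = 10000), lay)
  expect_equal(tr$total_bp, 1000)
  expect_equal(GenomicRanges::start(tr$regions), 9501)
  expect_equal(GenomicRanges::end(tr$regions), 10500)

  near <- build_training_regions(data.frame(chr = "chr1",
                                            bp = c(10000, 10400)), lay)
  expect_equal(near$total_bp, 1400)
  expect_equal(length(near$regions), 1L)

  far <- build_training_regions(data.frame(chr = "chr1",
                                           bp = c(10000, 20000)), lay)
  expect_equal(far$total_bp, 2000)

  expect_message(build_training_regions(
    data.frame(chr = "chr1", bp = c(5000, 5000)), lay), "duplicated")
})

test_that("posterior matches an independent brute-force Bayes oracle on all patterns", {
  set.seed(5)
  K <- 10
  p <- cbind(stats::runif(K, 0.02, 0.4), stats::runif(K, 0.4, 0.95))
  params <- list(pi = 0.13, p = p)
  pats <- all_patterns(K)
  got <- posterior_score(params, pats)
  want <- apply(pats, 1, function(a) oracle_posterior(0.13, p, a))
  expect_lt(max(abs(got - want)), 1e-12)
  expect_true(all(got > 0 & got < 1))
})

test_that("posterior reduces to the prior and to direct Bayes arithmetic", {
  K <- 10
  flat <- list(pi = 0.3, p = cbind(rep(0.5, K), rep(0.5, K)))
  pats <- all_patterns(K)[c(1, 17, 1024), ]
  expect_equal(posterior_score(flat, pats), rep(0.3, 3))

  p <- cbind(c(0.1, rep(0.5, K - 1)), c(0.9, rep(0.5, K - 1)))
  one <- list(pi = 0.5, p = p)
  a <- c(1, rep(0, K - 1))
  expect_equal(posterior_score(one, a), 0.45 / (0.45 + 0.05))
})

test_that("EM recovers planted parameters and keeps the likelihood monotone", {
  g <- gen_annotation_tracks(seed = 11, genome_bp = 1e6, segment_bp = 10)
  fit <- fit_functional_mixture(g$tracks, seed = 11)
  expect_true(all(diff(fit$loglik) >= -1e-7 * abs(fit$loglik[-1])))
  expect_lt(abs(fit$pi - g$truth$pi), 0.01)
  expect_lt(max(abs(fit$p[, "functional"] - g$truth$p_functional)), 0.02)
  expect_lt(max(abs(fit$p[, "nonfunctional"] - g$truth$p_nonfunctional)), 0.02)
  expect_equal(n_parameters(fit), 21L)
  expect_length(coef(fit), 21L)
})

test_that("non-informative annotations give odds ratios near 1", {
  set.seed(21)
  K <- 10
  params <- list(pi = 0.5, p = cbind(rep(0.3, K), rep(0.3, K)))
  x <- matrix(stats::rbinom(20000 * K, 1, 0.3), ncol = K)
  colnames(x) <- annotation_names()
  fit <- fit_functional_mixture(x, seed = 2)
  expect_true(all(abs(log(annotation_odds_ratio(fit))) < 0.6))
})

test_that("odds ratios follow their closed form and swap to reciprocals", {
  obj <- list(pi = 0.2,
              p = matrix(c(0.2, 0.8), 1, 2,
                         dimnames = list(NULL, c("nonfunctional", "functional"))),
              annotations = "A1")
  expect_equal(unname(annotation_odds_ratio(obj, 1)), 16.0)
  swapped <- obj
  swapped$p <- swapped$p[, 2:1, drop = FALSE]
  colnames(swapped$p) <- c("nonfunctional", "functional")
  expect_equal(unname(annotation_odds_ratio(swapped, 1)), 1 / 16.0)

  same <- list(pi = 0.2,
               p = matrix(c(0.4, 0.4), 1, 2,
                          dimnames = list(NULL, c("nonfunctional", "functional"))),
               annotations = "A1")
  expect_equal(unname(annotation_odds_ratio(same, 1)), 1.0)
})

test_that("class labels are anchored to the activating marks", {
  g <- gen_annotation_tracks(seed = 31, genome_bp = 3e5, segment_bp = 10)
  for (s in c(1, 2)) {
    fit <- fit_functional_mixture(g$tracks, seed = s)
    or <- annotation_odds_ratio(fit)
    expect_true(all(or[c("H3K4me3", "H3K9ac", "DNase")] >= 1))
  }
})

test_that("genome scoring equals the per-base posterior", {
  g <- gen_annotation_tracks(seed = 41, genome_bp = 5e4, segment_bp = 25)
  fit <- fit_functional_mixture(g$tracks, seed = 1)
  sc <- score_genome(fit, g$tracks)
  pos <- data.frame(chr = "chr1", bp = sort(sample(1:5e4, 200)))
  pat <- vapply(g$tracks, function(t) scores_at(t, pos), numeric(200))
  expect_equal(scores_at(sc, pos), posterior_score(fit, pat), tolerance = 1e-12)

  zero <- lapply(g$tracks, function(t)
    binary_track(data.frame(chr = character(), start = numeric(),
                            end = numeric()), g$layout))
  names(zero) <- names(g$tracks)
  sz <- score_genome(fit, zero)
  expect_equal(length(sz$runs), 1L)    # constant posterior of the zero pattern
  expect_equal(unique(S4Vectors::mcols(sz$runs)$score),
               posterior_score(fit, rep(0, 10)))
})

test_that("degenerate inputs are rejected", {
  x <- matrix(1, 50, 10)
  expect_error(fit_functional_mixture(x), "degenerate")
  expect_error(score_genome(list(pi = 0.5, p = matrix(0.5, 10, 2)),
                            list()), "tracks")
})

test_that("simulate() reproduces planted frequencies and is seeded", {
  obj <- structure(list(pi = 0.25,
                        p = matrix(c(rep(0.05, 10), rep(0.9, 10)), 10, 2,
                                   dimnames = list(NULL,
                                     c("nonfunctional", "functional"))),
                        annotations = annotation_names()),
                   class = "func_mixture")
  a1 <- simulate(obj, 5000, seed = 3)
  a2 <- simulate(obj, 5000, seed = 3)
  expect_identical(a1, a2)
  z <- attr(a1, "z")
  expect_lt(abs(mean(z) - 0.25), 0.03)
  expect_lt(abs(mean(a1[z == 1, 1]) - 0.9), 0.03)
})
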