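test_that("score partition estimates the tissue-functional prior", {
  s <- toy_sumstats(stats::runif(10))
  ts <- c(rep(0.9, 5), rep(0.01, 5))
  gs <- c(rep(0.8, 4), rep(0.02, 6))
  part <- partition_snps(s, ts, gs)
  expect_equal(part$p_zt1, 0.5)
  expect_equal(part$p_z1, 0.4)
  expect_equal(sum(part$high_tissue), 5)

  expect_error(partition_snps(s, rep(0, 10), gs), "threshold")
  expect_error(partition_snps(s, ts, rep(0.9, 10)), "threshold")
})

test_that("null density is flat for uniform p-values and always integrates to 1", {
  set.seed(41)
  d <- estimate_null_density(stats::runif(1e5), n_bins = 500)
  expect_lt(max(abs(d$density - 1)), 0.35)          # per-bin binomial noise
  expect_equal(sum(d$density) / d$n_bins, 1, tolerance = 1e-12)
  # flat within 0.1 at coarser bins where each bin holds ~2000 draws
  d50 <- estimate_null_density(stats::runif(1e5), n_bins = 50)
  expect_lt(max(abs(d50$density - 1)), 0.1)

  spike <- estimate_null_density(rep(0.25, 5000), n_bins = 500)
  expect_equal(sum(spike$density) / spike$n_bins, 1, tolerance = 1e-12)
  expect_gt(max(spike$density), 100)

  expect_warning(estimate_null_density(stats::runif(100), n_bins = 500),
                 "coarsened")
  expect_error(estimate_null_density(numeric(0)), "no p-values")
  expect_error(estimate_null_density(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("signal-mixture EM: weight vanishes under the null, alpha is recovered", {
  set.seed(43)
  # the true null here is exactly uniform; a single-bin histogram encodes it,
  # keeping the test about the EM rather than about histogram noise
  d <- estimate_null_density(stats::runif(5e4), n_bins = 1)
  u <- stats::runif(5e4)
  m0 <- fit_signal_mixture(u, d)
  expect_lt(m0$w, 0.05)
  expect_true(all(diff(m0$loglik) >= -1e-6 * abs(m0$loglik[-1])))

  pb <- stats::rbeta(5e4, 0.3, 1)
  m1 <- fit_signal_mixture(pb, d)
  expect_lt(abs(m1$alpha - 0.3), 0.03)
  expect_gt(m1$w, 0.9)

  expect_error(fit_signal_mixture(rep(1, 10), d), "degenerate")
})

test_that("planted 30% Beta(0.5,1) mixture weight is recovered", {
  d <- estimate_null_density(stats::runif(5e4), n_bins = 1)
  ws <- vapply(1:10, function(s) {
    set.seed(s)
    p <- c(stats::rbeta(6000, 0.5, 1), stats::runif(14000))
    fit_signal_mixture(p, d)$w
  }, numeric(1))
  expect_lt(abs(mean(ws) - 0.3), 0.05)
})

test_that("posterior equals hand evaluation and behaves in its limits", {
  flat <- estimate_null_density(stats::runif(2e4), n_bins = 1)
  comp <- genowap_components(p_zt1 = 0.3, p_z1 = 0.4, f_zt0 = flat,
                             f_z0 = flat, w = 0.4, alpha = 0.5)
  # hand arithmetic: f1 = 0.5 * 0.01^-0.5 = 5; priors 0.12 / 0.18 / 0.7
  expect_equal(genowap_posterior(0.01, comp), 0.6 / 1.48, tolerance = 1e-6)
  # likelihoods cancel when all densities are equal: posterior = P(case 1)
  p_at_f1_1 <- (1 / comp$alpha)^(1 / (comp$alpha - 1)) # where alpha*p^(a-1)=1
  expect_equal(genowap_posterior(p_at_f1_1, comp), 0.4 * 0.3, tolerance = 1e-6)
  # p -> 0 with alpha < 1 and bounded nulls: posterior -> 1
  expect_gt(genowap_posterior(1e-12, comp), 0.999)
  # monotone non-increasing in p for uniform nulls
  ps <- sort(stats::runif(100, 1e-6, 1))
  post <- genowap_posterior(ps, comp)
  expect_true(all(diff(post) <= 1e-12))
  expect_error(genowap_posterior(0, comp), "\\(0, 1\\]")
})

test_that("locus ranking clusters qualifying SNPs by proximity", {
  rec <- data.frame(
    snp = paste0("s", 1:6), chr = c(rep("chr1", 4), "chr2", "chr2"),
    bp = c(1e6, 1.01e6, 5e6, 5.2e6, 2e6, 8e6),
    p = c(1e-8, 1e-6, 1e-7, 0.5, 1e-9, 1e-5),
    posterior = c(0.99, 0.97, 0.96, 0.1, 0.999, 0.98))
  loci <- rank_loci(rec, posterior_cutoff = 0.95, locus_merge_bp = 1e6)
  expect_equal(nrow(loci), 4L)
  expect_equal(loci$top_snp[1], "s5")   # highest posterior first
  l1 <- loci[loci$chr == "chr1" & loci$start == 1e6, ]
  expect_equal(l1$n_snps, 2L)           # s1, s2 merge (10 kb apart)
  expect_equal(nrow(rank_loci(rec, posterior_cutoff = 0.999999)), 0L)
})

test_that("end-to-end reprioritization favors tissue-functional signal SNPs", {
  set.seed(53)
  n <- 20000
  tissue <- stats::rbinom(n, 1, 0.3)
  general <- pmax(tissue, stats::rbinom(n, 1, 0.2))
  causal <- tissue == 1 & stats::runif(n) < 0.15
  p <- ifelse(causal, stats::rbeta(n, 0.2, 1), stats::runif(n))
  s <- sumstats(data.frame(snp = paste0("s", 1:n), chr = "chr1",
                           bp = seq_len(n) * 100, p = pmax(p, 1e-300)),
                n = 5e4)
  fitw <- genowap(s, tissue_track = as.numeric(tissue),
                  general_track = as.numeric(general))
  rec <- fitw$records
  expect_equal(fitw$components$p_zt1, mean(tissue))
  # among equally significant SNPs, tissue-functional ones rank higher
  sig <- rec$p < 0.01
  expect_gt(mean(rec$posterior[sig & tissue == 1]),
            mean(rec$posterior[sig & tissue == 0]))
  expect_true(all(rec$posterior >= 0 & rec$posterior <= 1))
})

test_that("the APOE mask is honored before fitting", {
  set.seed(59)
  n <- 6000
  bp <- seq(45e6, 46.2e6, length.out = n)
  s <- sumstats(data.frame(snp = paste0("s", 1:n), chr = "chr19",
                           bp = round(bp), p = stats::runif(n)), n = 1e4)
  ts <- stats::runif(n); gs <- stats::runif(n)
  suppressWarnings(suppressMessages(
    fitw <- genowap(s, ts[1:n], gs[1:n], mask = apoe_mask())))
  expect_false(any(fitw$records$bp >= 45147340 & fitw$records$bp <= 45594595))
})
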