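# The simulator's contract tests run at reduced scale (hundreds of
# diploids, hundreds of sites); the full preset worlds are exercised by
# test-acceptance.R.

test_that("no mutational input means no segregating sites", {
  spec <- genome_spec(c(chr1 = 1e5), 200, mu = 0)
  demo <- demography_params(50, 10, 50, 5, 20)
  sim <- simulate_dedomestication(spec, demo, list(), 10, 10, seed = 1)
  expect_equal(n_sites(sim$genotypes), 0L)
})

test_that("seeded runs are bit-reproducible and validated", {
  spec <- genome_spec(c(chr1 = 2e5), 300, mu = 1e-4)
  demo <- demography_params(60, 10, 60, 5, 30, m = 0.01)
  a <- simulate_dedomestication(spec, demo, list(), 10, 10, seed = 99)
  b <- simulate_dedomestication(spec, demo, list(), 10, 10, seed = 99)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_dedomestication(spec, demo, list(), 10, 10, seed = 100)
  expect_false(identical(a$genotypes$geno, c2$genotypes$geno))
  expect_error(simulate_dedomestication(spec, demo, list(), 100, 10),
               class = "fs_param_error")   # sample > population
  expect_error(demography_params(50, 1, 50, 5, 5), class = "fs_param_error")
  expect_error(demography_params(50, 10, 50, 5, 5, m = 0.6),
               class = "fs_param_error")
  expect_error(selection_locus("chr1", 10, "balancing", 0.1),
               class = "fs_param_error")
})

test_that("neutral equilibrium diversity matches E[pi] = 4 N mu", {
  # N = 500, mu so that theta = 4 N mu = 0.004/site, 200 replicate loci
  N <- 500; theta <- 0.004; mu <- theta / (4 * N)
  spec <- genome_spec(c(chr1 = 2e5), 200, mu = mu)
  demo <- demography_params(N, N, N, 0, 0)
  sim <- simulate_dedomestication(spec, demo, list(), 40, 40, seed = 20,
                                  burn_in = 8L * N)
  # per-site pi over ALL 200 target loci (not only output segregating ones)
  sc <- site_counts(sim$genotypes)
  pis <- site_pi(sc$n_alt, sc$n_called)
  mean_pi <- sum(pis) / 200
  se <- sd(c(pis, rep(0, 200 - length(pis)))) / sqrt(200)
  expect_lt(abs(mean_pi - theta), 3 * se + 1e-12)
})

test_that("a bottleneck lowers weedy diversity relative to cultivated", {
  spec <- genome_spec(c(chr1 = 2e5), 400, mu = 2e-5)
  bn <- demography_params(100, 8, 100, 20, 40)
  ctrl <- demography_params(100, 100, 100, 20, 40)
  lower <- logical(20)
  for (r in 1:20) {
    sim <- simulate_dedomestication(spec, bn, list(), 20, 20,
                                    seed = 500 + r, burn_in = 800L)
    w <- pm_samples(sim$pop_map, role = "weedy")
    cu <- pm_samples(sim$pop_map, role = "cultivated")
    scw <- site_counts(sim$genotypes, w)
    scc <- site_counts(sim$genotypes, cu)
    lower[r] <- sum(site_pi(scw$n_alt, scw$n_called)) <
      sum(site_pi(scc$n_alt, scc$n_called))
  }
  expect_gte(mean(lower), 0.95)
  # control with the same seed protocol shows no such systematic loss
  sim0 <- simulate_dedomestication(spec, ctrl, list(), 20, 20, seed = 501,
                                   burn_in = 800L)
  expect_gt(n_sites(sim0$genotypes), 0)
})

test_that("neutral alleles fix with probability ~ their frequency", {
  # internal engine property, vectorized over 600 replicate sites
  set.seed(77)
  N <- 30; p0 <- 0.3; reps <- 600
  g <- feralscan:::wf_resample(rep(p0, reps), N)
  for (gen in 1:600) {
    p <- feralscan:::wf_gamete_freq(g, N, mu = 0)
    g <- feralscan:::wf_resample(p, N)
  }
  x <- g$n1 + 2 * g$n2
  resolved <- x == 0L | x == 2L * N
  expect_gte(mean(resolved), 0.99)   # essentially all resolved by now
  fixed <- mean(x[resolved] == 2L * N)
  expect_lt(abs(fixed - p0), 3 * sqrt(p0 * (1 - p0) / sum(resolved)))
})

test_that("overdominance holds weedy frequencies near 0.5", {
  # 150 replicate overdominant loci, s = 0.1, N_w = 500, T = 200
  pos <- seq(1000L, by = 1000L, length.out = 150)
  loci <- lapply(pos, function(p)
    selection_locus("chr1", p, "overdominant", s = 0.1, init_freq = 0.5))
  spec <- genome_spec(c(chr1 = 2e5), 10, mu = 1e-5)
  demo <- demography_params(500, 500, 500, 0, 200)
  sim <- simulate_dedomestication(spec, demo, loci, 100, 10, seed = 4,
                                  burn_in = 100L)
  w <- pm_samples(sim$pop_map, role = "weedy")
  tr <- sim$truth
  keep <- match(paste("chr1", pos), paste(tr$chrom, tr$pos))
  freq <- (tr$weedy_pop_alt / (2 * 500))[keep]
  freq <- freq[!is.na(freq)]
  expect_gte(length(freq), 140)   # overdominant loci rarely lost
  expect_gte(mean(freq >= 0.25 & freq <= 0.75), 0.8)
})

test_that("truth tables round-trip exactly and record selection", {
  spec <- genome_spec(c(chr1 = 1e5), 100, mu = 5e-5)
  demo <- demography_params(50, 10, 50, 5, 20)
  loci <- list(selection_locus("chr1", 5000L, "directional", 0.2,
                               init_freq = 0.3))
  sim <- simulate_dedomestication(spec, demo, loci, 10, 10, seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, p)
  expect_identical(read_truth(p), sim$truth)
  expect_equal(sum(sim$truth$regime == "directional"), 1L)
  expect_equal(sim$truth$s[sim$truth$regime == "directional"], 0.2)
  # empty truth -> header-only file
  write_truth(sim$truth[0, ], p)
  expect_equal(length(readLines(p)), 1L)
  expect_equal(nrow(read_truth(p)), 0L)
})

test_that("allele counts stay within [0, 2N] and rescaling conserves theta", {
  spec <- genome_spec(c(chr1 = 1e5), 200, mu = 1e-4)
  demo <- demography_params(80, 10, 80, 10, 30)
  sim <- simulate_dedomestication(spec, demo, list(), 20, 20, seed = 8)
  expect_true(all(sim$truth$weedy_pop_alt >= 0 &
                    sim$truth$weedy_pop_alt <= 2 * 80))
  expect_true(all(sim$truth$cult_pop_alt >= 0 &
                    sim$truth$cult_pop_alt <= 2 * 80))
  rs <- rescale_demography(demo, spec, lambda = 2)
  expect_equal(rs$demo$N_a * rs$spec$mu, demo$N_a * spec$mu, tolerance = 0.02)
  expect_equal(rs$demo$T_r / rs$demo$N_a, demo$T_r / demo$N_a,
               tolerance = 0.05)
})
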