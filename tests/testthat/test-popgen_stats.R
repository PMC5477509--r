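test_that("site_pi matches pairwise enumeration and handles edge cases", {
  # j = 2 of n = 4: brute force over the 6 haplotype pairs gives 4/6
  expect_equal(site_pi(2, 4), oracle_site_pi(c(1L, 1L)))
  expect_equal(site_pi(2, 4), 2 / 3, tolerance = 1e-12)
  expect_equal(site_pi(0, 8), 0)
  expect_equal(site_pi(8, 8), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_equal(site_pi(1, 1), 0)  # < 2 called alleles contributes 0
  expect_equal(site_pi(2, 4) / 1e5, 6.6667e-6, tolerance = 1e-4)
  # vectorized path equals enumeration on random configurations
  set.seed(4)
  for (rep in 1:25) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 12, replace = TRUE), nrow = 2)
    G <- tiny_gm(g)
    sc <- site_counts(G)
    expect_equal(site_pi(sc$n_alt, sc$n_called),
                 apply(g, 1, oracle_site_pi), tolerance = 1e-12)
  }
})

test_that("tajimas_d reproduces the independently evaluated constants", {
  # n = 4, single singleton, pi_sum = 0.5: a1 = 11/6, e1 ~ 0.005511
  k <- tajima_constants(4)
  expect_equal(k$a1, 11 / 6, tolerance = 1e-12)
  expect_equal(k$e1, 6 / 1089, tolerance = 1e-12)  # c1/a1 = (1/99)/(11/6)
  expect_equal(tajimas_d(1, 0.5, 4), oracle_tajd(1, 0.5, 4), tolerance = 1e-12)
  expect_equal(tajimas_d(1, 0.5, 4), -0.6123724, tolerance = 1e-6)
  expect_true(is.na(tajimas_d(0, 0, 10)))
  expect_error(tajimas_d(3, 1, 3), class = "fs_param_error")
  # folding symmetry: swapping ref/alt labels at every site leaves D unchanged
  G <- random_gm(11, n_sites = 40, n_samples = 8, chrom_len = 2e5, miss = 0)
  Gsw <- genotype_matrix(2L - G$geno, G$chrom, G$pos, G$alt, G$ref,
                         G$sample_ids)
  win <- make_windows(c(chr1 = 2e5))
  expect_equal(window_tajimas_d(G, NULL, win)$D,
               window_tajimas_d(Gsw, NULL, win)$D)
})

test_that("window_pi divides summed site pi by the full window span", {
  g <- matrix(c(1L, 1L, 0L, 0L), nrow = 1)   # j = 2 of n = 8? no: 2 het of 4
  G <- tiny_gm(g, pos = 55000L)
  win <- make_windows(c(chr1 = 150000L))
  wp <- window_pi(G, NULL, win)
  # single SNP with j=2, n=8 -> site pi = 2*2*6/(8*7); window span 100 kb
  expect_equal(wp$pi[wp$start == 0],
               (2 * 2 * 6 / (8 * 7)) / 100000, tolerance = 1e-12)
  # the sliding windows at 0..50000 all contain the SNP; others are empty
  containing <- wp$start <= 55000 & wp$end > 55000
  expect_true(all(wp$n_snps[containing] == 1))
  expect_true(all(wp$pi[!containing] == 0))
  expect_true(all(wp$n_snps[!containing] == 0))
})

test_that("Weir-Cockerham FST behaves at the anchor cases", {
  # fixed difference, equal sizes, no missing data -> 1
  g <- matrix(c(rep(0L, 5), rep(2L, 5)), nrow = 1)
  G <- tiny_gm(g, pos = 10L)
  win <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(wc_fst_window(G, 1:5, 6:10, win)$fst, 1)
  # frozen single-site value (a = 0.0708333, b = 0.0041667, c = 0.175 by
  # hand), cross-checked against the general-r per-allele transcription
  comp <- wc_fst_components(10, 0.5, 0.5, 10, 0.1, 0.2)
  orc <- oracle_wc_summary(c(10, 10), c(0.5, 0.1), c(0.5, 0.2))
  expect_equal(comp$a / (comp$a + comp$b + comp$c),
               unname(orc["a"] / sum(orc)), tolerance = 1e-12)
  expect_equal(comp$a, 0.0708333, tolerance = 1e-6)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 0.2833333,
               tolerance = 1e-6)
  # identical sample sets -> ~0 over many neutral sites (the estimator has
  # a small O(1/n) negative bias, hence a decent sample size here)
  G2 <- random_gm(21, n_sites = 150, n_samples = 20, miss = 0)
  win2 <- data.frame(chrom = "chr1", start = 0L, end = 1000000L)
  f <- wc_fst_window(G2, 1:20, 1:20, win2)$fst
  expect_lt(abs(f), 0.05)
  # window with no usable sites -> NA
  G3 <- tiny_gm(matrix(c(1L, NA, 0L, 0L), nrow = 1))
  expect_true(is.na(wc_fst_window(G3, 1:2, 3:4,
                                  data.frame(chrom = "chr1", start = 0L,
                                             end = 10L))$fst))
})

test_that("observed_het is n_het over called samples", {
  expect_equal(observed_het(5, 20), 0.5)
  expect_equal(observed_het(0, 12), 0)
  expect_equal(observed_het(6, 12), 1)
  expect_true(is.na(observed_het(0, 0)))
})

test_that("windowed statistics equal brute-force recomputation (oracle)", {
  G <- random_gm(99, n_sites = 1000, n_samples = 12, chrom_len = 5e5,
                 miss = 0.12)
  win <- make_windows(c(chr1 = 5e5))
  pop1 <- 1:6; pop2 <- 7:12
  orc <- oracle_window_stats(G, pop1, win, pop2 = pop2)
  expect_equal(window_pi(G, pop1, win)$pi, orc$pi, tolerance = 1e-9)
  expect_equal(window_het(G, pop1, win)$ho, orc$ho, tolerance = 1e-9)
  expect_equal(window_tajimas_d(G, pop1, win)$D, orc$D, tolerance = 1e-9)
  expect_equal(wc_fst_window(G, pop1, pop2, win)$fst, orc$fst,
               tolerance = 1e-9)
})
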