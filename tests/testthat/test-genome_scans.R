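test_that("make_windows follows the 100 kb / 10 kb sliding grid rules", {
  w <- make_windows(c(chr1 = 250000L))
  expect_equal(nrow(w), 25L)
  expect_equal(unlist(w[25, c("start", "end")], use.names = FALSE),
               c(240000L, 250000L))
  # chromosome shorter than the window size: truncation
  w2 <- make_windows(c(chr1 = 50000L))
  expect_equal(w2$start, seq(0L, 40000L, by = 10000L))
  expect_true(all(w2$end == 50000L))
  expect_equal(nrow(make_windows(c(chr1 = 0L))), 0L)
  expect_error(make_windows(c(chr1 = 1e5), size = 5000, step = 10000),
               class = "fs_param_error")
})

test_that("zscore normalizes genome-wide and flags degeneracy", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(c(2, 2, 2)), class = "fs_degenerate_error")
  set.seed(3)
  v <- c(rnorm(50), NA, NA)
  z <- zscore(v)
  expect_true(all(is.na(z[51:52])))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-9)
})

make_fst_windows <- function(fst, chrom = "chr1", step = 10000L,
                             size = 100000L) {
  n <- length(fst)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * step,
             end = (seq_len(n) - 1L) * step + size,
             n_snps = 10L, fst = fst, stringsAsFactors = FALSE)
}

test_that("divergent_regions selects and merges qualifying windows", {
  # 3 consecutive passing windows on the 10-kb grid merge into 120 kb
  fst <- c(rep(0.1, 40), rep(0.9, 3), rep(0.1, 40))
  fw <- make_fst_windows(fst)
  reg <- divergent_regions(fw)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$length_bp, 120000L)
  expect_equal(reg$n_windows, sum(fw$start < reg$end & fw$end > reg$start))
  # no window passes -> empty
  expect_equal(nrow(divergent_regions(make_fst_windows(rnorm(60, 0.1, 0.01)),
                                      z_threshold = 10)), 0L)
  # passing windows on different chromosomes stay distinct regions
  fw2 <- rbind(make_fst_windows(c(rep(0.1, 30), 0.9)),
               make_fst_windows(c(0.9, rep(0.1, 30)), chrom = "chr2"))
  reg2 <- divergent_regions(fw2)
  expect_equal(nrow(reg2), 2L)
  expect_equal(sort(unique(reg2$chrom)), c("chr1", "chr2"))
  # outputs sorted and non-overlapping
  expect_true(all(diff(reg2$start[reg2$chrom == reg2$chrom[1]]) > 0) ||
                nrow(reg2) < 2)
})

test_that("map_genes respects half-open overlap and de-duplicates", {
  reg <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                    end = c(2000L, 6000L))
  ann <- annotation_set(
    chrom = rep("chr1", 4),
    start = c(2000L, 1500L, 900L, 5500L),
    end = c(2100L, 5500L, 1100L, 5800L),
    name = c("abutting", "spanning", "left", "te_gene"),
    is_te = c(FALSE, FALSE, FALSE, TRUE))
  m <- map_genes(reg, ann)
  expect_false("abutting" %in% unlist(m$genes))    # end == start: no overlap
  expect_equal(sum(attr(m, "gene_union") == "spanning"), 1L)  # counted once
  expect_true("te_gene" %in% attr(m, "gene_union"))
  m2 <- map_genes(reg, ann, non_te_only = TRUE)
  expect_false("te_gene" %in% attr(m2, "gene_union"))
})

test_that("overlap_rate and shared_genes do count arithmetic", {
  genes <- annotation_set("chr1", seq(0, 7000, by = 1000),
                          seq(500, 7500, by = 1000),
                          name = paste0("g", 1:8))
  doms <- annotation_set("chr1", c(0, 1000), c(400, 1200),
                         name = c("d1", "d2"))
  expect_equal(overlap_rate(genes, doms), 25)      # 2 of 8
  expect_equal(overlap_rate(genes, genes), 100)
  expect_equal(overlap_rate(genes[0, ], doms), NA_real_)
  expect_equal(overlap_rate(genes, doms[0, ]), 0)

  sets <- list(c("a", "b"), c("a", "c"), c("a", "b"), c("d"))
  expect_equal(shared_genes(sets, 3), "a")
  expect_equal(shared_genes(list(c("x"), c("y"), c("z")), 3), character(0))
  expect_error(shared_genes(list(c("a")), 3), class = "fs_param_error")
})

make_d_windows <- function(D, chrom = "chr1") {
  n <- length(D)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 10000L,
             end = (seq_len(n) - 1L) * 10000L + 100000L,
             n_snps = 10L, D = D, stringsAsFactors = FALSE)
}

test_that("balancing_regions applies the four-step rule", {
  # weedy: a 61-window run of D = 3 (spans 0.7 Mb on the 10-kb grid) in a
  # noisy background, so the top-5% order-statistic threshold separates
  # the run from the background; cultivated flat at -1
  set.seed(5)
  base <- rnorm(2000, -0.5, 0.1)
  base[1000:1060] <- 3
  dw <- make_d_windows(base)
  dc <- make_d_windows(rep(-1, 2000))
  reg <- balancing_regions(dw, dc)
  expect_equal(nrow(reg), 1L)
  expect_gt(reg$length_bp, 500000L)
  expect_equal(reg$cult_mean_stat, -1)
  # one hot cultivated window inside the span kills the region
  dc2 <- dc; dc2$D[1030] <- 2.5
  expect_equal(nrow(balancing_regions(dw, dc2)), 0L)
  # mean cultivated D > 1 also kills it
  dc3 <- dc; dc3$D[dw$start < 1070 * 10000 & dw$end > 1000 * 10000] <- 1.6
  expect_equal(nrow(balancing_regions(dw, dc3)), 0L)
  # a too-short run (<= 0.5 Mb region) is dropped: 30 windows span 390 kb
  # (leaving head-room for chance background qualifiers abutting the run)
  base4 <- base; base4[1000:1060] <- -0.5; base4[1000:1029] <- 3
  expect_equal(nrow(balancing_regions(make_d_windows(base4), dc)), 0L)
  # all weedy D below threshold -> empty (constant D has a defined
  # quantile, every window qualifies, but cultivated filter then applies)
  expect_equal(nrow(balancing_regions(make_d_windows(rep(-2, 2000)),
                                      make_d_windows(rep(3, 2000)))), 0L)
  # grid mismatch is an input error
  expect_error(balancing_regions(dw[-1, ], dc), class = "fs_input_error")
  # fst_z reporting covers all windows overlapping the region span
  z <- rep(0, 2000); z[985:1075] <- 5
  regz <- balancing_regions(dw, dc, fst_z = z)
  expect_gt(regz$pct_zfst_ge3, 80)
})

test_that("per_gene_tajimas_d agrees with tajimas_d on a gene's SNPs", {
  G <- random_gm(31, n_sites = 200, n_samples = 10, chrom_len = 2e5, miss = 0)
  ann <- annotation_set("chr1", c(0L, 150000L, 190000L),
                        c(50000L, 160000L, 190500L),
                        name = c("geneA", "geneB", "empty_gene"))
  tab <- per_gene_tajimas_d(G, NULL, ann)
  idx <- G$pos >= 0 & G$pos < 50000
  sc <- site_counts(gm_subset(G, sites = idx))
  S <- sum(sc$n_alt > 0 & sc$n_alt < sc$n_called)
  D_direct <- tajimas_d(S, sum(site_pi(sc$n_alt, sc$n_called)), 20)
  expect_equal(tab$D[tab$name == "geneA"], D_direct, tolerance = 1e-12)
  if (tab$n_snps[3] == 0) expect_true(is.na(tab$D[3]))
  # counting genes above a D threshold is plain arithmetic on the table
  expect_equal(sum(tab$D > 2, na.rm = TRUE),
               length(which(tab$D > 2)))
})
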