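# Independent brute-force oracles.  These deliberately avoid the package's
# computational paths: per-site pi is enumerated over haplotype pairs,
# Tajima's D constants are evaluated from a second transcription, and the
# Weir-Cockerham components are computed with the general-r, per-allele
# formulation (both alleles summed) rather than the two-population
# single-allele shortcut used in R/popgen.R.

# pi at one site by enumerating all C(n,2) allele pairs
oracle_site_pi <- function(geno) {
  g <- geno[!is.na(geno)]
  alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
  n <- length(alleles)
  if (n < 2) return(0)
  diff <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

# Tajima 1989 constants + D, second transcription
oracle_tajd <- function(S, pi_sum, n) {
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_sum - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Weir & Cockerham (1984) a, b, c at one site, general-r per-allele form
# geno_pops: list of genotype vectors (0/1/2/NA), one per population
oracle_wc_site <- function(geno_pops) {
  r <- length(geno_pops)
  n_i <- vapply(geno_pops, function(g) sum(!is.na(g)), numeric(1))
  if (any(n_i < 2)) return(c(a = NA, b = NA, c = NA))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  out <- c(a = 0, b = 0, c = 0)
  for (allele in c(0, 1)) {   # both alleles; components sum over alleles
    p_i <- vapply(geno_pops, function(g) {
      g <- g[!is.na(g)]
      if (allele == 1) sum(g) / (2 * length(g))
      else sum(2 - g) / (2 * length(g))
    }, numeric(1))
    h_i <- vapply(geno_pops, function(g) mean(g[!is.na(g)] == 1), numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    out <- out + c(a = a, b = b, c = cc)
  }
  out
}

# same general-r per-allele transcription, from (n, p, h) summaries
# (some textbook configurations, e.g. p = 0.5 with 5 of 10 heterozygous,
# are not realizable as integer genotypes)
oracle_wc_summary <- function(n_i, p_list, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  out <- c(a = 0, b = 0, c = 0)
  for (allele in 1:2) {
    p_i <- if (allele == 1) p_list else 1 - p_list
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    out <- out + c(a = a, b = b, c = hbar / 2)
  }
  out
}

# brute-force windowed recomputation of pi, D, H_O and W&C FST
oracle_window_stats <- function(G, samples, windows, pop2 = NULL,
                                min_snps = 3L) {
  idx <- feralscan:::resolve_samples(G, samples)
  idx2 <- if (!is.null(pop2)) feralscan:::resolve_samples(G, pop2)
  out <- windows
  out$pi <- out$D <- out$ho <- out$fst <- NA_real_
  for (k in seq_len(nrow(windows))) {
    in_win <- which(G$chrom == windows$chrom[k] &
                      G$pos >= windows$start[k] & G$pos < windows$end[k])
    pis <- numeric(0); ns <- integer(0); hos <- numeric(0)
    S <- 0
    asum <- bsum <- 0
    for (i in in_win) {
      g <- G$geno[i, idx]
      called <- sum(!is.na(g))
      pis <- c(pis, oracle_site_pi(g))
      ns <- c(ns, 2L * called)
      if (called >= 1) {
        hos <- c(hos, mean(g[!is.na(g)] == 1))
        alt <- sum(g, na.rm = TRUE)
        if (alt > 0 && alt < 2 * called) S <- S + 1
      }
      if (!is.null(pop2)) {
        comp <- oracle_wc_site(list(G$geno[i, idx], G$geno[i, idx2]))
        tot <- sum(comp)
        if (!any(is.na(comp)) && tot != 0) {
          asum <- asum + comp["a"]; bsum <- bsum + tot
        }
      }
    }
    out$pi[k] <- sum(pis) / (windows$end[k] - windows$start[k])
    out$ho[k] <- if (length(hos)) mean(hos) else NA_real_
    out$D[k] <- if (length(in_win) >= min_snps && S > 0 &&
                    round(median(ns)) >= 4)
      oracle_tajd(S, sum(pis), round(median(ns))) else NA_real_
    if (!is.null(pop2)) out$fst[k] <- if (bsum != 0) asum / bsum else NA_real_
  }
  out
}

# random genotype matrix on one chromosome
random_gm <- function(seed, n_sites = 100, n_samples = 10, chrom_len = 1e6,
                      miss = 0.1) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n_sites)) - 1L
  p <- runif(n_sites, 0.05, 0.95)
  geno <- vapply(seq_len(n_samples), function(j) rbinom(n_sites, 2, p),
                 integer(n_sites))
  geno[runif(length(geno)) < miss] <- NA_integer_
  genotype_matrix(geno, rep("chr1", n_sites), pos,
                  rep("A", n_sites), rep("G", n_sites),
                  sprintf("s%02d", seq_len(n_samples)))
}

# tiny hand-built genotype matrix from a sites x samples integer matrix
tiny_gm <- function(m, pos = NULL, chrom = "chr1") {
  m <- as.matrix(m)
  if (is.null(pos)) pos <- seq_len(nrow(m)) * 100L
  genotype_matrix(m, rep(chrom, nrow(m)), pos, rep("A", nrow(m)),
                  rep("C", nrow(m)), sprintf("s%d", seq_len(ncol(m))))
}
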