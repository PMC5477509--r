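## Per-site and sliding-window population statistics: nucleotide
## diversity, Tajima's D, Weir & Cockerham (1984) FST, observed
## heterozygosity.  Window statistics are assembled from per-site values
## via a shared window->site mapping (windows overlap, so one site feeds
## several windows).

#' Sliding windows over chromosomes
#'
#' Per chromosome, emits windows `[k*step, k*step + size)` for
#' `k = 0, 1, ...` while `k*step` is inside the chromosome; the final
#' windows are truncated at the chromosome end.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param size Window size in bp (default 100 kb).
#' @param step Window step in bp (default 10 kb).
#' @return data.frame with columns chrom, start, end (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, size = 100000L, step = 10000L) {
  size <- as.integer(size); step <- as.integer(step)
  if (step <= 0 || size < step)
    fs_param_error("need size >= step > 0")
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    if (L <= 0) return(NULL)
    k <- 0:((L - 1L) %/% step)
    data.frame(chrom = ch, start = k * step,
               end = pmin(k * step + size, L), stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Map sites onto (possibly overlapping) windows of a regular grid.
## Returns a list(win = window index, site = site index) of membership
## pairs.  Assumes `windows` came from make_windows on the same grid;
## falls back to interval overlap via IRanges otherwise.
window_site_map <- function(windows, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start = pos + 1L, width = 1L))
  s <- as_granges0(windows)
  hits <- GenomicRanges::findOverlaps(q, s)
  list(win = S4Vectors::subjectHits(hits), site = S4Vectors::queryHits(hits))
}

## Sum per-site values over windows. values: matrix sites x k (or vector).
## Returns list(n_snps, sums = matrix n_windows x k).
window_accumulate <- function(windows, chrom, pos, values) {
  values <- as.matrix(values)
  mp <- window_site_map(windows, chrom, pos)
  nw <- nrow(windows)
  n_snps <- tabulate(mp$win, nbins = nw)
  sums <- matrix(0, nrow = nw, ncol = ncol(values),
                 dimnames = list(NULL, colnames(values)))
  if (length(mp$win)) {
    agg <- rowsum(values[mp$site, , drop = FALSE], group = mp$win)
    sums[as.integer(rownames(agg)), ] <- agg
  }
  list(n_snps = n_snps, sums = sums)
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2 j (n - j) / (n (n - 1))` with `j`
#' alternative alleles among `n` called alleles.  Sites with fewer than two
#' called alleles contribute 0.
#'
#' @param n_alt Alternative allele count(s).
#' @param n_called Called allele count(s) (2 x called samples).
#' @return Numeric vector of per-site pi.
#' @export
site_pi <- function(n_alt, n_called) {
  ok <- n_called >= 2L
  if (any(!ok)) fs_log("site_pi: %d site(s) with < 2 called alleles skipped",
                       sum(!ok), level = "DEBUG")
  out <- numeric(length(n_alt))
  j <- n_alt[ok]; n <- n_called[ok]
  out[ok] <- 2 * j * (n - j) / (n * (n - 1))
  out
}

#' Windowed nucleotide diversity
#'
#' Per window, the sum of per-site pi over contained SNPs divided by the
#' full window span in bp (invariant bases included in the denominator,
#' matching the windowed estimator of the standard VCF toolkits).
#'
#' @param G A [genotype_matrix()].
#' @param samples Sample ids or index.
#' @param windows Window table from [make_windows()].
#' @return data.frame: chrom, start, end, n_snps, pi.
#' @export
window_pi <- function(G, samples, windows) {
  sc <- site_counts(G, samples)
  acc <- window_accumulate(windows, G$chrom, G$pos,
                           site_pi(sc$n_alt, sc$n_called))
  data.frame(windows, n_snps = acc$n_snps,
             pi = acc$sums[, 1] / (windows$end - windows$start),
             stringsAsFactors = FALSE)
}

#' Tajima's (1989) normalization constants
#'
#' @param n Allele-sample size (number of sequences), `n >= 2`.
#' @return List with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) fs_param_error("tajima_constants needs n >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D from summary quantities
#'
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the constants of
#' [tajima_constants()] at allele-sample size `n`.
#'
#' @param S Number of segregating sites.
#' @param pi_sum Sum of per-site pi over the same sites.
#' @param n Allele-sample size (`n >= 4`).
#' @return Tajima's D, or `NA` when `S == 0` (undefined).
#' @export
tajimas_d <- function(S, pi_sum, n) {
  if (n < 4) fs_param_error("tajimas_d needs n >= 4")
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Windowed Tajima's D
#'
#' Per window: `S` = segregating sites, `pi_sum` = summed per-site pi, and
#' `n` = the median per-site called-allele number over the window's sites
#' (missing data makes `n` vary by site; a single-n approximation is used).
#' Windows with fewer than `min_snps` SNPs, `S = 0`, or `n < 4` get `NA`
#' and are excluded from downstream quantile steps.
#'
#' @inheritParams window_pi
#' @param min_snps Minimum SNPs for a defined window value (default 3).
#' @return data.frame: chrom, start, end, n_snps, D.
#' @export
window_tajimas_d <- function(G, samples, windows, min_snps = 3L) {
  sc <- site_counts(G, samples)
  seg <- as.numeric(sc$n_alt > 0L & sc$n_alt < sc$n_called & sc$n_called >= 2L)
  vals <- cbind(S = seg, pi = site_pi(sc$n_alt, sc$n_called), n = sc$n_called,
                nsite = 1)
  acc <- window_accumulate(windows, G$chrom, G$pos, vals)
  ## median n per window needs the full membership map, redo cheaply
  mp <- window_site_map(windows, G$chrom, G$pos)
  med_n <- rep(NA_real_, nrow(windows))
  if (length(mp$win)) {
    med <- tapply(sc$n_called[mp$site], mp$win, median)
    med_n[as.integer(names(med))] <- as.numeric(med)
  }
  S <- acc$sums[, "S"]; pi_sum <- acc$sums[, "pi"]
  D <- rep(NA_real_, nrow(windows))
  ok <- which(acc$n_snps >= min_snps & S > 0 & !is.na(med_n) & med_n >= 4)
  for (i in ok) D[i] <- tajimas_d(S[i], pi_sum[i], round(med_n[i]))
  data.frame(windows, n_snps = acc$n_snps, D = D, stringsAsFactors = FALSE)
}

#' Per-site Weir & Cockerham (1984) variance components
#'
#' Two-population components a (among populations), b (among individuals
#' within populations) and c (within individuals), from per-population
#' sample sizes (diploid individuals), alternative allele frequencies and
#' heterozygote proportions.  Sites where either population has fewer than
#' 2 called individuals are unusable (`NA` components).
#'
#' @param n1,n2 Called diploid individuals per population (vectors).
#' @param p1,p2 Alternative allele frequencies per population.
#' @param h1,h2 Heterozygote proportions per population.
#' @return data.frame with columns a, b, c.
#' @export
wc_fst_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  usable <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Windowed Weir & Cockerham FST
#'
#' Per-site variance components are summed over each window and the window
#' estimate is `sum(a) / sum(a + b + c)` (the weighted/"ratio of averages"
#' estimator used by the standard windowed FST tools).  Monomorphic sites
#' (`a + b + c = 0`) and sites with under 2 called individuals in either
#' population are skipped; negative estimates are retained, not clamped.
#' Windows with no usable site get `NA`.
#'
#' @param G A [genotype_matrix()].
#' @param pop1_samples,pop2_samples Sample ids or indices of the two
#'   populations.
#' @param windows Window table from [make_windows()].
#' @return data.frame: chrom, start, end, n_snps, fst.
#' @export
wc_fst_window <- function(G, pop1_samples, pop2_samples, windows) {
  c1 <- site_counts(G, pop1_samples); c2 <- site_counts(G, pop2_samples)
  n1 <- c1$n_called / 2; n2 <- c2$n_called / 2
  comp <- wc_fst_components(
    n1, c1$n_alt / pmax(c1$n_called, 1), c1$n_het / pmax(n1, 1),
    n2, c2$n_alt / pmax(c2$n_called, 1), c2$n_het / pmax(n2, 1))
  tot <- comp$a + comp$b + comp$c
  use <- !is.na(tot) & tot != 0
  vals <- cbind(a = ifelse(use, comp$a, 0), abc = ifelse(use, tot, 0),
                used = as.numeric(use))
  acc <- window_accumulate(windows, G$chrom, G$pos, vals)
  fst <- ifelse(acc$sums[, "used"] > 0,
                acc$sums[, "a"] / acc$sums[, "abc"], NA_real_)
  data.frame(windows, n_snps = acc$n_snps, fst = fst, stringsAsFactors = FALSE)
}

#' Per-site observed heterozygosity
#'
#' `H_O = n_het / (n_called / 2)`, the fraction of called samples that are
#' heterozygous at a SNP.
#'
#' @param n_het Heterozygous sample count(s).
#' @param n_called Called allele count(s).
#' @return Numeric vector; `NA` where no samples are called.
#' @export
observed_het <- function(n_het, n_called) {
  ifelse(n_called >= 2, n_het / (n_called / 2), NA_real_)
}

#' Windowed mean observed heterozygosity
#'
#' Mean per-SNP `H_O` over the SNPs in each window (not per-bp).
#'
#' @inheritParams window_pi
#' @return data.frame: chrom, start, end, n_snps, ho.
#' @export
window_het <- function(G, samples, windows) {
  sc <- site_counts(G, samples)
  ho <- observed_het(sc$n_het, sc$n_called)
  ok <- !is.na(ho)
  acc <- window_accumulate(windows, G$chrom, G$pos,
                           cbind(ho = ifelse(ok, ho, 0), k = as.numeric(ok)))
  data.frame(windows, n_snps = acc$n_snps,
             ho = ifelse(acc$sums[, "k"] > 0,
                         acc$sums[, "ho"] / acc$sums[, "k"], NA_real_),
             stringsAsFactors = FALSE)
}
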