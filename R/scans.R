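## Region calling on windowed statistics: Z(FST) divergent regions with
## gene mapping/overlap rates, and the balancing-selection region
## detector (top-quantile Tajima's D runs in the weedy population,
## filtered on the cultivated population's D over the same span).

#' Z-transform a vector of window statistics
#'
#' `(v - mean) / sd` over the non-missing entries (sample sd, n-1
#' denominator); missing entries stay missing.  Computed genome-wide (all
#' chromosomes jointly).
#'
#' @param values Numeric vector (may contain `NA`).
#' @return Z-scores, same length and missingness as input.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) fs_param_error("zscore needs >= 2 non-missing values")
  s <- sd(values[ok])
  if (s == 0) fs_degenerate_error("zscore: zero variance")
  out <- rep(NA_real_, length(values))
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

## Merge qualifying windows (logical `pass`) into maximal regions.
## Overlapping or abutting windows merge; per-region summaries are taken
## over `stat` of ALL windows overlapping the merged span (not only the
## qualifying ones), which is how region-average statistics are reported.
merge_windows <- function(windows, pass, stat) {
  pass <- which(pass)
  if (!length(pass))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      length_bp = integer(), n_windows = integer(),
                      mean_stat = numeric(), max_stat = numeric(),
                      stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(as_granges0(windows[pass, , drop = FALSE]))
  reg <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
  reg <- reg[order(match(reg$chrom, unique(windows$chrom)), reg$start), ,
             drop = FALSE]
  rownames(reg) <- NULL
  hits <- GenomicRanges::findOverlaps(as_granges0(reg), as_granges0(windows))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  reg$length_bp <- reg$end - reg$start
  reg$n_windows <- as.integer(tabulate(qh, nbins = nrow(reg)))
  reg$mean_stat <- vapply(seq_len(nrow(reg)), function(i)
    mean(stat[sh[qh == i]], na.rm = TRUE), numeric(1))
  reg$max_stat <- vapply(seq_len(nrow(reg)), function(i) {
    v <- stat[sh[qh == i]]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  reg
}

#' Call divergent regions from windowed FST
#'
#' Z-transforms the windowed FST genome-wide, selects windows with
#' `Z >= z_threshold`, and merges overlapping/abutting qualifying windows
#' into maximal regions.
#'
#' @param fst_windows data.frame from [wc_fst_window()] (columns chrom,
#'   start, end, n_snps, fst; a precomputed `z` column is used if present).
#' @param z_threshold Z(FST) cutoff (default 3.0).
#' @return data.frame of regions: chrom, start, end, length_bp, n_windows,
#'   mean_stat, max_stat (stat = Z(FST) of overlapping windows), sorted and
#'   non-overlapping.
#' @export
divergent_regions <- function(fst_windows, z_threshold = 3.0) {
  z <- fst_windows$z %||% zscore(fst_windows$fst)
  merge_windows(fst_windows, !is.na(z) & z >= z_threshold, z)
}

#' Map genes onto called regions
#'
#' A gene is assigned to a region iff they overlap by at least 1 bp
#' (half-open coordinates: an abutting gene is not assigned).
#'
#' @param regions Region data.frame (from [divergent_regions()] or
#'   [balancing_regions()]).
#' @param annotation An [annotation_set()] of genes.
#' @param non_te_only Drop TE-flagged genes first (default FALSE).
#' @return `regions` with a `genes` list-column; the de-duplicated union
#'   over the scan is in `attr(, "gene_union")`.
#' @export
map_genes <- function(regions, annotation, non_te_only = FALSE) {
  if (non_te_only) annotation <- annotation[!annotation$is_te, , drop = FALSE]
  genes <- rep(list(character(0)), nrow(regions))
  if (nrow(regions) > 0 && nrow(annotation) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(regions),
                                        as_granges0(annotation))
    sp <- split(annotation$name[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
    genes <- lapply(sp, unique)
  }
  regions$genes <- unname(genes)
  attr(regions, "gene_union") <- unique(unlist(genes, use.names = FALSE))
  regions
}

#' Percent of genes overlapping a reference region set
#'
#' Fraction (as percent) of genes in `geneset_a` that overlap, by at least
#' 1 bp, any interval of `regions_b` (e.g. de-domestication candidate genes
#' vs published domestication regions).
#'
#' @param geneset_a An [annotation_set()] of genes.
#' @param regions_b An [annotation_set()] of reference intervals.
#' @return Percent in `[0, 100]`, or `NA` for an empty gene set.
#' @export
overlap_rate <- function(geneset_a, regions_b) {
  if (nrow(geneset_a) == 0) return(NA_real_)
  if (nrow(regions_b) == 0) return(0)
  hits <- GenomicRanges::findOverlaps(as_granges0(geneset_a),
                                      as_granges0(regions_b))
  100 * length(unique(S4Vectors::queryHits(hits))) / nrow(geneset_a)
}

#' Genes shared across scans
#'
#' @param gene_sets List of character vectors (one per weedy group).
#' @param min_groups Minimum number of sets a gene must appear in.
#' @return Character vector of shared genes.
#' @export
shared_genes <- function(gene_sets, min_groups = 3L) {
  if (length(gene_sets) < min_groups)
    fs_param_error("need at least min_groups gene sets")
  tab <- table(unlist(lapply(gene_sets, unique), use.names = FALSE))
  sort(names(tab)[tab >= min_groups])
}

#' Detect regions under balancing selection
#'
#' Implements the four-step rule: (1) the Tajima's D threshold is the
#' empirical top-`top_quantile` order statistic (type-1 quantile, no
#' interpolation) of the non-missing weedy window D values; (2) windows at
#' or above the threshold are merged into maximal runs as in
#' [divergent_regions()]; (3) regions with `length_bp <= min_len` are
#' dropped (strictly greater than 0.5 Mb survives); (4) a region is removed
#' if over the same span the cultivated windows have mean `D > cult_mean_max`
#' or any single window `D > cult_window_max`.
#'
#' @param d_windows_weedy,d_windows_cult Window tables from
#'   [window_tajimas_d()] on identical grids.
#' @param top_quantile Weedy-D quantile defining "high" (default 0.95).
#' @param min_len Minimum region length in bp, strict (default 500000).
#' @param cult_mean_max Max allowed mean cultivated D over the span.
#' @param cult_window_max Max allowed single cultivated window D.
#' @param fst_z Optional vector of Z(FST) per window on the same grid; when
#'   supplied, the fraction of each region's windows with `Z >= 3` is
#'   reported (`pct_zfst_ge3`).
#' @return Region data.frame with weedy mean/max D (`mean_stat`,
#'   `max_stat`), `cult_mean_stat`, and `pct_zfst_ge3`.
#' @export
balancing_regions <- function(d_windows_weedy, d_windows_cult,
                              top_quantile = 0.95, min_len = 500000L,
                              cult_mean_max = 1.0, cult_window_max = 2.0,
                              fst_z = NULL) {
  w <- d_windows_weedy; cu <- d_windows_cult
  if (nrow(w) != nrow(cu) || !all(w$chrom == cu$chrom) ||
      !all(w$start == cu$start) || !all(w$end == cu$end))
    fs_input_error("weedy and cultivated window grids differ")
  dw <- w$D
  if (all(is.na(dw))) {
    reg <- merge_windows(w, rep(FALSE, nrow(w)), dw)
    reg$cult_mean_stat <- numeric(0); reg$pct_zfst_ge3 <- numeric(0)
    return(reg)
  }
  thr <- quantile(dw[!is.na(dw)], probs = top_quantile, type = 1, names = FALSE)
  reg <- merge_windows(w, !is.na(dw) & dw >= thr, dw)
  attr(reg, "d_threshold") <- thr
  reg <- reg[reg$length_bp > min_len, , drop = FALSE]
  rownames(reg) <- NULL
  if (nrow(reg) == 0) {
    reg$cult_mean_stat <- numeric(0); reg$pct_zfst_ge3 <- numeric(0)
    return(reg)
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(reg), as_granges0(w))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  cult_mean <- cult_max <- pct_z <- rep(NA_real_, nrow(reg))
  for (i in seq_len(nrow(reg))) {
    idx <- sh[qh == i]
    dc <- cu$D[idx]
    cult_mean[i] <- if (all(is.na(dc))) NA_real_ else mean(dc, na.rm = TRUE)
    cult_max[i] <- if (all(is.na(dc))) NA_real_ else max(dc, na.rm = TRUE)
    if (!is.null(fst_z))
      pct_z[i] <- 100 * mean(!is.na(fst_z[idx]) & fst_z[idx] >= 3)
  }
  keep <- !((!is.na(cult_mean) & cult_mean > cult_mean_max) |
              (!is.na(cult_max) & cult_max > cult_window_max))
  reg$cult_mean_stat <- cult_mean
  reg$pct_zfst_ge3 <- pct_z
  out <- reg[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "d_threshold") <- thr
  out
}

#' Tajima's D per annotated gene
#'
#' D over the SNPs falling inside each gene interval, at the median
#' called-allele size of those SNPs.  Genes with no segregating SNP get
#' `NA`.
#'
#' @param G A [genotype_matrix()].
#' @param samples Sample ids or index.
#' @param annotation An [annotation_set()] of genes.
#' @return data.frame: name, chrom, start, end, n_snps, D.
#' @export
per_gene_tajimas_d <- function(G, samples, annotation) {
  sc <- site_counts(G, samples)
  pi_site <- site_pi(sc$n_alt, sc$n_called)
  seg <- sc$n_alt > 0L & sc$n_alt < sc$n_called & sc$n_called >= 2L
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(G$chrom, IRanges::IRanges(G$pos + 1L, width = 1L)),
    as_granges0(annotation))
  sp <- split(S4Vectors::queryHits(hits),
              factor(S4Vectors::subjectHits(hits),
                     levels = seq_len(nrow(annotation))))
  D <- rep(NA_real_, nrow(annotation))
  n_snps <- integer(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    idx <- sp[[i]]
    n_snps[i] <- length(idx)
    S <- sum(seg[idx])
    if (S == 0) next
    n_med <- round(median(sc$n_called[idx]))
    if (n_med < 4) next
    D[i] <- tajimas_d(S, sum(pi_site[idx]), n_med)
  }
  data.frame(name = annotation$name, chrom = annotation$chrom,
             start = annotation$start, end = annotation$end,
             n_snps = n_snps, D = D, stringsAsFactors = FALSE)
}
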