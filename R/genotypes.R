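## Shared data model: genotype matrix, population map, annotation set.
## Coordinate convention: every interval in the package is 0-based
## half-open; `pos` in a genotype_matrix is the 0-based site coordinate
## (VCF POS - 1).  Genotype codes count alternative alleles: 0, 1, 2, NA.

#' Genotype matrix of biallelic SNPs
#'
#' Container for multi-sample diploid genotypes at biallelic SNP sites.
#' Sites are rows of `geno`, samples are columns; entries are alternative
#' allele counts (0, 1, 2) or `NA` for missing calls.  Positions are stored
#' 0-based (VCF `POS - 1`) and must be strictly increasing within each
#' chromosome.
#'
#' @param geno Integer matrix, sites x samples, values in {0, 1, 2, NA}.
#' @param chrom Character vector of per-site chromosome ids.
#' @param pos Integer vector of per-site 0-based positions.
#' @param ref,alt Character vectors of single-base reference/alternative
#'   alleles.
#' @param sample_ids Character vector of unique sample names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, chrom, pos, ref, alt, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- nrow(geno)
  if (length(sample_ids) != ncol(geno))
    fs_input_error("sample_ids length (%d) != genotype columns (%d)",
                   length(sample_ids), ncol(geno))
  if (anyDuplicated(sample_ids))
    fs_input_error("duplicate sample ids")
  if (length(sample_ids) < 2)
    fs_input_error("a genotype matrix needs >= 2 samples")
  if (length(chrom) != n_sites || length(pos) != n_sites ||
      length(ref) != n_sites || length(alt) != n_sites)
    fs_input_error("per-site vectors must match the number of sites")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) fs_input_error("genotype codes must be 0, 1, 2 or NA")
  if (n_sites > 0) {
    if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L) || any(ref == alt))
      fs_input_error("sites must be biallelic SNPs (single differing bases)")
    ord <- order(match(chrom, unique(chrom)), pos)
    if (is.unsorted(ord) || any(diff(ord) != 1L))
      fs_input_error("positions must be sorted within chromosomes")
    by_chr <- split(pos, chrom)
    if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))))
      fs_input_error("positions must be strictly increasing within a chromosome")
  }
  colnames(geno) <- sample_ids
  structure(
    list(sample_ids = as.character(sample_ids),
         chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt), geno = geno),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), length(x$sample_ids), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Integer site count.
#' @export
n_sites <- function(G) nrow(G$geno)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param G A `genotype_matrix`.
#' @param sites Logical or integer index over sites (row order preserved).
#' @param samples Sample ids, or logical/integer index over samples.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(G, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(G)) else seq_len(n_sites(G))[sites]
  sj <- resolve_samples(G, samples)
  genotype_matrix(G$geno[si, sj, drop = FALSE], G$chrom[si], G$pos[si],
                  G$ref[si], G$alt[si], G$sample_ids[sj])
}

resolve_samples <- function(G, samples) {
  if (is.null(samples)) return(seq_along(G$sample_ids))
  if (is.character(samples)) {
    idx <- match(samples, G$sample_ids)
    if (anyNA(idx))
      fs_input_error("unknown sample id(s): %s",
                     paste(samples[is.na(idx)], collapse = ", "))
    return(idx)
  }
  seq_along(G$sample_ids)[samples]
}

#' Per-site allele and genotype counts for a sample set
#'
#' The building block of every per-site statistic.  Missing genotypes are
#' dropped per site: `n_called` is twice the number of non-missing samples.
#'
#' @param G A `genotype_matrix`.
#' @param samples Sample ids or index (default: all samples).
#' @return data.frame with per-site columns `n_called` (called alleles),
#'   `n_alt` (alternative allele count) and `n_het` (heterozygous samples).
#' @export
site_counts <- function(G, samples = NULL) {
  sj <- resolve_samples(G, samples)
  g <- G$geno[, sj, drop = FALSE]
  called <- !is.na(g)
  data.frame(
    n_called = 2L * as.integer(rowSums(called)),
    n_alt = as.integer(rowSums(g, na.rm = TRUE)),
    n_het = as.integer(rowSums(g == 1L, na.rm = TRUE)))
}

#' Per-site alternative allele frequency
#' @inheritParams site_counts
#' @return Numeric vector; `NaN` where no samples are called.
#' @export
alt_freq <- function(G, samples = NULL) {
  sc <- site_counts(G, samples)
  sc$n_alt / sc$n_called
}

#' Sample-to-population assignment
#'
#' @param sample Character vector of sample ids.
#' @param group Character vector of group names (e.g. "JS1", "IND").
#' @param role One of "weedy", "cultivated", "wild" per sample.
#' @return data.frame of class `population_map`.
#' @export
population_map <- function(sample, group, role) {
  roles <- c("weedy", "cultivated", "wild")
  if (length(sample) == 0) fs_input_error("no samples in population map")
  if (anyDuplicated(sample))
    fs_input_error("duplicate sample id(s) in population map: %s",
                   paste(unique(sample[duplicated(sample)]), collapse = ", "))
  if (!all(role %in% roles))
    fs_input_error("unknown role(s): %s",
                   paste(setdiff(unique(role), roles), collapse = ", "))
  if (length(group) != length(sample) || length(role) != length(sample))
    fs_input_error("sample, group and role must have equal length")
  if (any(!nzchar(group))) fs_input_error("empty group name")
  structure(
    data.frame(sample = as.character(sample), group = as.character(group),
               role = as.character(role), stringsAsFactors = FALSE),
    class = c("population_map", "data.frame"))
}

#' Select sample ids from a population map
#' @param map A `population_map`.
#' @param group,role Optional filters.
#' @return Character vector of sample ids.
#' @export
pm_samples <- function(map, group = NULL, role = NULL) {
  keep <- rep(TRUE, nrow(map))
  if (!is.null(group)) keep <- keep & map$group %in% group
  if (!is.null(role)) keep <- keep & map$role %in% role
  map$sample[keep]
}

#' Genomic interval annotations (genes, regions)
#'
#' Intervals are 0-based half-open.  Unnamed intervals are auto-named
#' `chrom:start-end`.
#'
#' @param chrom,start,end Interval coordinates.
#' @param name Optional unique names.
#' @param is_te Logical flag: interval is a transposable-element gene.
#' @return data.frame of class `annotation_set`.
#' @export
annotation_set <- function(chrom, start, end, name = NULL, is_te = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end))
    fs_input_error("interval start must be < end (0-based half-open)")
  if (is.null(name)) name <- sprintf("%s:%d-%d", chrom, start, end)
  name <- as.character(name)
  fill <- is.na(name) | !nzchar(name)
  name[fill] <- sprintf("%s:%d-%d", chrom[fill], start[fill], end[fill])
  if (anyDuplicated(name))
    fs_input_error("interval names must be unique")
  is_te <- rep_len(as.logical(is_te), length(chrom))
  structure(
    data.frame(chrom = as.character(chrom), start = start, end = end,
               name = name, is_te = is_te, stringsAsFactors = FALSE),
    class = c("annotation_set", "data.frame"))
}

## data.frame (chrom,start,end,...) -> GRanges, 0-based half-open in,
## GRanges 1-based closed internally.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}
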