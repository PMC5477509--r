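## Readers/writers for the standard formats the pipeline consumes:
## VCF (GT only), population-map TSV, BED annotations, chromosome-length
## TSV, and the result tables.  VCF parsing is delegated to
## Bioconductor's VariantAnnotation; all coordinates are converted to the
## internal 0-based half-open convention on read and back on write.

#' Read genotypes from a VCF file
#'
#' Consumes the GT field of a VCF v4.x file.  Multiallelic records and
#' non-SNP records are skipped (a count is logged); half-missing and fully
#' missing calls become `NA`; phased (`|`) and unphased (`/`) genotypes are
#' treated identically.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param region Optional `"chrom:start-end"` string (1-based, closed) used
#'   to subset sites after reading.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) fs_input_error("VCF not found: %s", path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(
      path, param = VariantAnnotation::ScanVcfParam(info = NA, geno = "GT")),
    error = function(e) fs_input_error("failed to parse VCF %s: %s",
                                       path, conditionMessage(e)))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) fs_input_error("VCF has no GT format field: %s", path)
  keep <- suppressWarnings(VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE))
  n_skip <- sum(!keep)
  if (n_skip > 0)
    fs_log("read_vcf: skipped %d non-SNP/multiallelic record(s)", n_skip)
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  gt <- gt[keep, , drop = FALSE]
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- BiocGenerics::start(rr)
  by_chr <- split(pos1, chrom)
  if (any(vapply(by_chr, is.unsorted, logical(1))))
    fs_input_error("VCF positions are not sorted within chromosomes")
  geno <- gt_to_codes(gt)
  G <- genotype_matrix(
    geno, chrom, pos1 - 1L,
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
    sample_ids = colnames(gt))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) fs_input_error("bad region string: %s", region)
    lo <- as.integer(m[3]) - 1L; hi <- as.integer(m[4])
    G <- gm_subset(G, sites = G$chrom == m[2] & G$pos >= lo & G$pos < hi)
  }
  G
}

## GT string matrix -> integer codes; any "." component -> NA.
gt_to_codes <- function(gt) {
  u <- unique(as.vector(gt))
  norm <- gsub("|", "/", u, fixed = TRUE)
  code <- rep(NA_integer_, length(u))
  code[norm == "0/0"] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm == "1/1"] <- 2L
  matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
         dimnames = dimnames(gt))
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT.  Round-trips through
#' [read_vcf()] losslessly (genotype codes, positions, sample order).
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=feralscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t")), con)
  if (n_sites(G) > 0) {
    gt <- matrix(c("0/0", "0/1", "1/1")[G$geno + 1L], nrow = n_sites(G))
    gt[is.na(gt)] <- "./."
    body <- paste(G$chrom, G$pos + 1L, ".", G$ref, G$alt, ".", "PASS", ".",
                  "GT", sep = "\t")
    writeLines(paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a TSV with a header line `sample<TAB>group<TAB>role`; role is one
#' of `weedy`, `cultivated`, `wild`.
#'
#' @param path Path to the TSV.
#' @return A [population_map()].
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) fs_input_error("population map not found: %s", path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) fs_input_error("cannot read population map %s: %s",
                                       path, conditionMessage(e)))
  need <- c("sample", "group", "role")
  if (!all(need %in% names(df)))
    fs_input_error("population map needs columns: %s", paste(need, collapse = ", "))
  if (nrow(df) == 0) fs_input_error("no samples in population map %s", path)
  population_map(df$sample, df$group, df$role)
}

#' Write a population map
#' @param map A [population_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read interval annotations from a BED file
#'
#' BED is 0-based half-open, matching the internal convention.  Column 4
#' (optional) is the interval name; column 5 (optional) is a TE flag, the
#' literal string `TE` or `non-TE`.  Overlapping intervals are retained
#' as-is (no merging at read time).
#'
#' @param path Path to a 3+ column BED file.
#' @return An [annotation_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) fs_input_error("BED not found: %s", path)
  df <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               comment.char = "#", fill = TRUE),
    error = function(e) fs_input_error("cannot read BED %s: %s",
                                       path, conditionMessage(e)))
  if (ncol(df) < 3) fs_input_error("BED needs >= 3 columns: %s", path)
  name <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  is_te <- if (ncol(df) >= 5) {
    flag <- as.character(df[[5]])
    bad <- !flag %in% c("TE", "non-TE", "", NA)
    if (any(bad, na.rm = TRUE))
      fs_input_error("BED TE flag must be 'TE' or 'non-TE'")
    !is.na(flag) & flag == "TE"
  } else FALSE
  annotation_set(df[[1]], df[[2]], df[[3]], name = name, is_te = is_te)
}

#' Read chromosome lengths
#'
#' Expects `chrom<TAB>length` lines (no header).
#'
#' @param path Path to the TSV.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_lengths <- function(path) {
  if (!file.exists(path)) fs_input_error("chromosome lengths not found: %s", path)
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2) fs_input_error("chromosome length file needs 2 columns")
  len <- as.integer(df[[2]])
  if (anyNA(len) || any(len < 0)) fs_input_error("bad chromosome length")
  setNames(len, as.character(df[[1]]))
}

#' Write a window-statistic table
#'
#' Columns: chrom, start, end, n_snps, then one column per statistic.
#'
#' @param ws data.frame of windowed statistics.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(ws, path) {
  write.table(ws, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region table
#'
#' @param regions data.frame of called regions (see [divergent_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  out <- regions
  if (!is.null(out$genes))
    out$genes <- vapply(out$genes, paste, character(1), collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
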