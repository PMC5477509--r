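## Standing variation vs new mutation: classify weedy SNPs against the
## cultivated progenitor panel and summarize allele-frequency
## differentiation (AFD = alt frequency in weedy minus alt frequency in
## cultivated, the reference genome being the cultivated progenitor).

#' Classify weedy SNPs as standing variation or new mutation
#'
#' A site enters the table iff the alternative allele is observed at least
#' once among the called weedy samples.  It is `standing` iff the
#' alternative allele is also observed at least once among the called
#' cultivated samples, else `new` (allele-presence rule; the site need not
#' be polymorphic within cultivated).  Sites with no called cultivated
#' sample are unclassifiable and excluded (a count is logged).
#'
#' @param G A [genotype_matrix()].
#' @param weedy_samples,cultivated_samples Sample ids or indices.
#' @param wild_samples Optional third panel; when given, variants whose
#'   alternative allele is absent in cultivated but present in wild are
#'   flagged `wild_allele` (putative wild introgression; a flag only).
#' @return data.frame: chrom, pos, origin ("standing"/"new"), afd,
#'   and optionally wild_allele.
#' @export
classify_variants <- function(G, weedy_samples, cultivated_samples,
                              wild_samples = NULL) {
  cw <- site_counts(G, weedy_samples)
  cc <- site_counts(G, cultivated_samples)
  weedy_poly <- cw$n_alt > 0L
  no_cult <- cc$n_called == 0L
  if (any(weedy_poly & no_cult))
    fs_log("classify_variants: %d site(s) unclassifiable (no called cultivated sample)",
           sum(weedy_poly & no_cult))
  keep <- weedy_poly & !no_cult
  origin <- ifelse(cc$n_alt[keep] > 0L, "standing", "new")
  out <- data.frame(
    chrom = G$chrom[keep], pos = G$pos[keep], origin = origin,
    afd = afd(cw$n_alt[keep] / cw$n_called[keep],
              cc$n_alt[keep] / cc$n_called[keep]),
    stringsAsFactors = FALSE)
  if (!is.null(wild_samples)) {
    cwild <- site_counts(G, wild_samples)
    out$wild_allele <- origin == "new" & cwild$n_alt[keep] > 0L
  }
  out
}

#' Allele frequency differentiation
#'
#' Signed difference: alternative-allele frequency in weedy minus the
#' alternative-allele frequency in cultivated rice.
#'
#' @param weedy_alt_freq,cultivated_alt_freq Frequencies in `[0, 1]`
#'   computed over called alleles (vectors).
#' @return AFD in `[-1, 1]`; `NA` where either frequency is undefined.
#' @export
afd <- function(weedy_alt_freq, cultivated_alt_freq) {
  out <- weedy_alt_freq - cultivated_alt_freq
  out[!is.finite(weedy_alt_freq) | !is.finite(cultivated_alt_freq)] <- NA_real_
  out
}

#' AFD distribution by origin class
#'
#' Per origin class (and, when `regions` is given, separately restricted to
#' variants inside those regions): a percentage histogram of AFD over
#' `[-1, 1]` and the percentage of variants with AFD strictly above each
#' threshold.  Percentages are normalized within class over all its
#' classified variants.
#'
#' @param classes Output of [classify_variants()].
#' @param bin_width Histogram bin width (default 0.1).
#' @param thresholds AFD thresholds (default `c(0.7, 0.9)`).
#' @param regions Optional [annotation_set()] of selected regions.
#' @return List with `histogram` (class, scope, bin_low, bin_high, pct) and
#'   `thresholds` (class, scope, threshold, pct) data.frames.  Classes with
#'   no variants get `NA` percentages.
#' @export
afd_distribution <- function(classes, bin_width = 0.1,
                             thresholds = c(0.7, 0.9), regions = NULL) {
  breaks <- seq(-1, 1, by = bin_width)
  if (tail(breaks, 1) < 1) breaks <- c(breaks, 1)
  scopes <- list(genome = rep(TRUE, nrow(classes)))
  if (!is.null(regions)) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(classes$chrom,
                             IRanges::IRanges(classes$pos + 1L, width = 1L)),
      as_granges0(regions))
    inside <- rep(FALSE, nrow(classes))
    inside[unique(S4Vectors::queryHits(hits))] <- TRUE
    scopes$selected <- inside
  }
  hist_rows <- list(); thr_rows <- list()
  for (scope in names(scopes)) {
    for (cl in c("standing", "new")) {
      sel <- scopes[[scope]] & classes$origin == cl & !is.na(classes$afd)
      x <- classes$afd[sel]
      n <- length(x)
      cuts <- if (n > 0)
        table(cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE))
      else rep(NA_integer_, length(breaks) - 1)
      hist_rows[[length(hist_rows) + 1]] <- data.frame(
        class = cl, scope = scope,
        bin_low = head(breaks, -1), bin_high = tail(breaks, -1),
        pct = if (n > 0) 100 * as.numeric(cuts) / n else NA_real_,
        stringsAsFactors = FALSE)
      thr_rows[[length(thr_rows) + 1]] <- data.frame(
        class = cl, scope = scope, threshold = thresholds,
        pct = if (n > 0)
          vapply(thresholds, function(t) 100 * mean(x > t), numeric(1))
        else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(histogram = do.call(rbind, hist_rows),
       thresholds = do.call(rbind, thr_rows))
}
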