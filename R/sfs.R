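## Site-frequency spectra: construction from genotypes, hypergeometric
## projection to a common allele-sample size, folding to minor-allele
## orientation, and singleton masking.  Spectra are built on alternative-
## allele counts (the reference genome is the cultivated progenitor);
## no ancestral-state inference is attempted, folding handles polarity.

new_sfs <- function(counts, n, folded = FALSE, masked = NULL) {
  counts <- if (length(n) == 1) as.numeric(counts) else as.matrix(counts)
  if (is.null(masked)) {
    masked <- if (length(n) == 1) rep(FALSE, n + 1) else
      matrix(FALSE, n[1] + 1, n[2] + 1)
  }
  if (any(counts < 0)) fs_input_error("SFS counts must be >= 0")
  structure(list(counts = counts, n = as.integer(n), folded = isTRUE(folded),
                 masked = masked), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("sfs: %dD, n = %s, %s, %d masked entr%s, total mass %.4g\n",
              length(x$n), paste(x$n, collapse = " x "),
              if (x$folded) "folded" else "unfolded", sum(x$masked),
              if (sum(x$masked) == 1) "y" else "ies", sum(x$counts)))
  invisible(x)
}

## total derived-allele index per cell (0-based), as an array matching counts
sfs_cell_totals <- function(sfs) {
  if (length(sfs$n) == 1) 0:sfs$n
  else outer(0:sfs$n[1], 0:sfs$n[2], `+`)
}

#' Build a site-frequency spectrum from genotypes
#'
#' One-dimensional (one sample set) or joint two-dimensional (two sample
#' sets), indexed by alternative-allele count.  With `n_target = NULL` only
#' sites fully called in the given samples enter (dropped sites are
#' logged); with `n_target` set, each site is hypergeometrically projected
#' from its own per-site called-allele size down to the target size, so
#' sites with missing data contribute fractional mass (sites called below
#' the target are dropped).
#'
#' @param G A [genotype_matrix()].
#' @param samples_axis1 Sample ids/index for axis 1.
#' @param samples_axis2 Optional sample ids/index for axis 2 (joint SFS).
#' @param n_target Optional per-axis projection size(s) in alleles; recycled
#'   across axes.
#' @return An `sfs` object (unfolded).
#' @export
build_sfs <- function(G, samples_axis1, samples_axis2 = NULL,
                      n_target = NULL) {
  axes <- list(site_counts(G, samples_axis1))
  if (!is.null(samples_axis2)) axes <- c(axes, list(site_counts(G, samples_axis2)))
  dims <- length(axes)
  n_full <- vapply(seq_len(dims), function(a) {
    s <- if (a == 1) samples_axis1 else samples_axis2
    2L * length(resolve_samples(G, s))
  }, integer(1))
  nt <- if (is.null(n_target)) n_full else rep_len(as.integer(n_target), dims)
  if (any(nt > n_full))
    fs_param_error("projection size exceeds sample allele count")
  full <- Reduce(`&`, lapply(seq_len(dims), function(a)
    axes[[a]]$n_called >= nt[a]))
  if (any(!full))
    fs_log("build_sfs: dropped %d site(s) called below target size", sum(!full))
  j <- lapply(axes, function(a) a$n_alt[full])
  nc <- lapply(axes, function(a) a$n_called[full])
  counts <- if (dims == 1) numeric(nt[1] + 1) else
    matrix(0, nt[1] + 1, nt[2] + 1)
  n_use <- sum(full)
  if (n_use > 0) {
    ## group sites by their (j, n_called) signature, project each group once
    key <- do.call(paste, c(j, nc, list(sep = "_")))
    for (grp in split(seq_len(n_use), key)) {
      i <- grp[1]; w <- length(grp)
      ws <- lapply(seq_len(dims), function(a)
        hyper_weights(j[[a]][i], nc[[a]][i], nt[a]))
      counts <- counts + w * (if (dims == 1) ws[[1]] else outer(ws[[1]], ws[[2]]))
    }
  }
  new_sfs(counts, nt, folded = FALSE)
}

## hypergeometric projection weights of one site: j alt of n alleles -> m
hyper_weights <- function(j, n, m) {
  if (m == n) { w <- numeric(m + 1); w[j + 1] <- 1; return(w) }
  stats::dhyper(0:m, j, n - j, m)
}

#' Project a site-frequency spectrum to a smaller sample size
#'
#' Each entry with allele count `j` of `n` is redistributed over counts
#' `k = 0..m` with hypergeometric weight `C(j,k) C(n-j,m-k) / C(n,m)`;
#' total site mass is conserved.  Requires an unfolded spectrum.
#'
#' @param sfs An unfolded `sfs`.
#' @param m Target allele-sample size per axis (recycled).
#' @return Projected `sfs`.
#' @export
project_sfs <- function(sfs, m) {
  if (sfs$folded) fs_param_error("project_sfs needs an unfolded spectrum")
  m <- rep_len(as.integer(m), length(sfs$n))
  if (any(m > sfs$n)) fs_param_error("projection size m exceeds n")
  proj <- function(n_from, m_to) {
    W <- vapply(0:n_from, function(j) hyper_weights(j, n_from, m_to),
                numeric(m_to + 1))  # (m+1) x (n+1)
    W
  }
  if (length(sfs$n) == 1) {
    counts <- as.numeric(proj(sfs$n, m[1]) %*% sfs$counts)
  } else {
    counts <- proj(sfs$n[1], m[1]) %*% sfs$counts %*% t(proj(sfs$n[2], m[2]))
  }
  new_sfs(counts, m, folded = FALSE)
}

#' Fold a site-frequency spectrum to minor-allele orientation
#'
#' Entry `k` is added to entry `min(k, n - k)`; for a joint spectrum the
#' fold is on the total allele count across both axes (cells whose total
#' exceeds half the pooled sample size are reflected; cells exactly at
#' half contribute half mass each way).  Entries above the midpoint become
#' structural zeros and are flagged masked.  Idempotent.
#'
#' @param sfs An `sfs`.
#' @return Folded `sfs`.
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) return(sfs)
  tot <- sfs_cell_totals(sfs)
  ntot <- sum(sfs$n)
  rev_all <- function(x) {
    if (length(sfs$n) == 1) rev(x) else x[rev(seq_len(nrow(x))),
                                          rev(seq_len(ncol(x))), drop = FALSE]
  }
  counts <- sfs$counts + rev_all(sfs$counts)
  counts[tot == ntot / 2] <- counts[tot == ntot / 2] / 2
  counts[tot > ntot / 2] <- 0
  masked <- (sfs$masked | rev_all(sfs$masked)) | (tot > ntot / 2)
  new_sfs(counts, sfs$n, folded = TRUE, masked = masked)
}

#' Mask singleton (and monomorphic) entries
#'
#' Flags entries whose total minor-allele count across all axes is 1
#' (singletons) or 0 (the monomorphic corner cells) as masked; masked
#' entries keep their counts but are excluded from likelihood sums.
#'
#' @param sfs An `sfs`.
#' @return `sfs` with updated mask.
#' @export
mask_singletons <- function(sfs) {
  tot <- sfs_cell_totals(sfs)
  minor <- pmin(tot, sum(sfs$n) - tot)
  sfs$masked <- sfs$masked | (minor <= 1)
  sfs
}

#' Normalize an SFS to probabilities over unmasked entries
#' @param sfs An `sfs`.
#' @return `sfs` whose unmasked counts sum to 1 (masked entries set to 0).
#' @export
sfs_normalize <- function(sfs) {
  tot <- sum(sfs$counts[!sfs$masked])
  if (tot <= 0) fs_degenerate_error("SFS has no unmasked mass")
  sfs$counts[sfs$masked] <- 0
  sfs$counts <- sfs$counts / tot
  sfs
}

#' Write an SFS (TSV + JSON sidecar)
#'
#' 1D spectra become a two-column TSV (`k`, `count`); joint spectra a
#' matrix TSV.  A `<path>.json` sidecar records `n`, `folded` and the
#' masked entries (1-based linear indices).
#'
#' @param sfs An `sfs`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  if (length(sfs$n) == 1) {
    write.table(data.frame(k = 0:sfs$n, count = sfs$counts), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(sfs$counts, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(n = sfs$n, folded = sfs$folded, masked = which(sfs$masked)),
    paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read an SFS written by [write_sfs()]
#' @param path TSV path (a `<path>.json` sidecar must exist).
#' @return An `sfs`.
#' @export
read_sfs <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    fs_input_error("SFS file or sidecar missing: %s", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  counts <- if (length(meta$n) == 1)
    read.table(path, header = TRUE, sep = "\t")$count
  else as.matrix(read.table(path, header = FALSE, sep = "\t"))
  out <- new_sfs(counts, meta$n, folded = meta$folded)
  out$masked[meta$masked] <- TRUE
  out
}
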