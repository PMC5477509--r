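## Forward Wright-Fisher simulator of the de-domestication scenario:
## a cultivated source population at mutation-drift equilibrium, a weedy
## offshoot founded through a bottleneck (size N_b for T_b generations)
## that recovers to N_w for T generations, optional symmetric migration
## after the bottleneck, and per-locus viability selection (directional or
## overdominant) in a target population.
##
## Sites recombine freely (each site transmitted independently), so the
## engine tracks per-site genotype counts per population: one generation =
## viability selection on genotype frequencies, gamete formation, recurrent
## biallelic mutation (a mutated gamete flips its allele), migration mixing
## of the gamete pools, and Hardy-Weinberg multinomial resampling to the
## epoch's size.  Desk-scale runs rely on theta-preserving rescaling
## (simulate N/lambda with mu*lambda); see rescale_demography().

#' Genome specification for the simulator
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param sites_per_chrom Number of mutation target sites per chromosome
#'   (recycled); positions are drawn uniformly at simulation time.
#' @param mu Per-site per-generation mutation rate.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, sites_per_chrom, mu) {
  if (mu < 0) fs_param_error("mu must be >= 0")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  sites_per_chrom <- rep_len(as.integer(sites_per_chrom),
                             length(chrom_lengths))
  if (any(sites_per_chrom > chrom_lengths))
    fs_param_error("more target sites than bases on a chromosome")
  structure(list(chrom_lengths = chrom_lengths,
                 sites_per_chrom = sites_per_chrom, mu = mu),
            class = "genome_spec")
}

#' Demographic parameters of the de-domestication scenario
#'
#' @param N_a Ancestral (cultivated) diploid effective size.
#' @param N_b Weedy bottleneck founder size.
#' @param N_w Recovered (present) weedy size.
#' @param T_b Bottleneck duration in generations.
#' @param T_r Generations from recovery to the present.
#' @param m Per-generation migration fraction between cultivated and weedy
#'   after the bottleneck (symmetric; 0 allowed).
#' @return List of class `demography_params`.
#' @export
demography_params <- function(N_a, N_b, N_w, T_b, T_r, m = 0) {
  if (any(c(N_a, N_b, N_w) < 2)) fs_param_error("population sizes must be >= 2")
  if (T_b < 0 || T_r < 0) fs_param_error("durations must be >= 0")
  if (m < 0 || m >= 0.5) fs_param_error("migration fraction must be in [0, 0.5)")
  structure(list(N_a = as.integer(N_a), N_b = as.integer(N_b),
                 N_w = as.integer(N_w), T_b = as.integer(T_b),
                 T_r = as.integer(T_r), m = m),
            class = "demography_params")
}

#' A locus under selection
#'
#' Viability weights: directional `(1, 1+s, 1+2s)` for genotypes
#' (0, 1, 2 alternative alleles); overdominant `(1, 1+s, 1)`.  Selection
#' acts only in `target_pop`, and only after the split.
#'
#' @param chrom,pos Locus position (0-based).
#' @param regime `"directional"` or `"overdominant"`.
#' @param s Selection coefficient, `s > 0`.
#' @param target_pop `"weedy"` or `"cultivated"`.
#' @param init_freq Optional alternative-allele frequency imposed in the
#'   ancestral population at the split (conditions the locus on starting as
#'   standing variation at that frequency); `NA` leaves whatever standing
#'   variation the burn-in produced.
#' @return List of class `selection_locus`.
#' @export
selection_locus <- function(chrom, pos, regime, s, target_pop = "weedy",
                            init_freq = NA_real_) {
  if (!regime %in% c("directional", "overdominant"))
    fs_param_error("unknown selection regime: %s", regime)
  if (s <= 0) fs_param_error("selection coefficient must be > 0")
  if (!target_pop %in% c("weedy", "cultivated"))
    fs_param_error("target_pop must be weedy or cultivated")
  structure(list(chrom = chrom, pos = as.integer(pos), regime = regime,
                 s = s, target_pop = target_pop, init_freq = init_freq),
            class = "selection_locus")
}

#' Theta-preserving rescaling of a demographic scenario
#'
#' Divides every population size and duration by `lambda` and multiplies
#' the mutation rate by `lambda`, conserving `4 N mu` (and every scaled
#' time `T / 2N`), so the expected SFS shape is comparable at desk scale.
#'
#' @param demo A [demography_params()].
#' @param spec A [genome_spec()].
#' @param lambda Rescaling factor (> 1 shrinks the run).
#' @return List with rescaled `demo` and `spec`.
#' @export
rescale_demography <- function(demo, spec, lambda) {
  if (lambda <= 0) fs_param_error("lambda must be > 0")
  demo2 <- demography_params(
    max(2, round(demo$N_a / lambda)), max(2, round(demo$N_b / lambda)),
    max(2, round(demo$N_w / lambda)), round(demo$T_b / lambda),
    round(demo$T_r / lambda), demo$m)
  spec2 <- spec
  spec2$mu <- spec$mu * lambda
  list(demo = demo2, spec = spec2)
}

## One Wright-Fisher generation for per-site genotype counts.
## g: list(n0, n1, n2) integer vectors over sites; returns gamete alt
## frequency after selection + mutation (no sampling yet).
wf_gamete_freq <- function(g, N, mu, w_het = NULL, w_hom = NULL) {
  f0 <- g$n0 / N; f1 <- g$n1 / N; f2 <- g$n2 / N
  if (!is.null(w_het)) {
    f1 <- f1 * w_het; f2 <- f2 * w_hom
    tot <- f0 + f1 + f2
    f0 <- f0 / tot; f1 <- f1 / tot; f2 <- f2 / tot
  }
  p <- f1 / 2 + f2
  p * (1 - mu) + (1 - p) * mu
}

## Hardy-Weinberg multinomial resampling of N diploids at gamete freq p.
wf_resample <- function(p, N) {
  S <- length(p)
  n2 <- rbinom(S, N, p * p)
  n1 <- rbinom(S, N - n2, 2 * p / (1 + p))
  list(n0 = N - n2 - n1, n1 = n1, n2 = n2)
}

## Neutral frequency-only burn-in of the ancestral population.
wf_burn_in <- function(S, N, mu, generations, init_count = 0L) {
  x <- rep(as.integer(init_count), S)
  for (g in seq_len(generations)) {
    p <- x / (2 * N)
    x <- rbinom(S, 2 * N, p * (1 - mu) + (1 - p) * mu)
  }
  x
}

## Multivariate-hypergeometric sample of n diploids from genotype counts.
sample_genotype_counts <- function(g, N, n) {
  s2 <- rhyper(length(g$n2), g$n2, N - g$n2, n)
  s1 <- rhyper(length(g$n1), g$n1, g$n0, n - s2)
  list(n0 = n - s2 - s1, n1 = s1, n2 = s2)
}

#' Simulate the de-domestication scenario
#'
#' Runs the forward Wright-Fisher engine: neutral burn-in of the ancestral
#' cultivated population, split (the weedy founder population of size
#' `N_b` is drawn from the ancestral gene pool), `T_b` bottleneck
#' generations, recovery to `N_w` for `T_r` generations with symmetric
#' migration `m` active only after the bottleneck, per-locus selection in
#' the target population after the split.  At the end, diploid samples are
#' drawn from both populations and every site segregating in the union
#' sample is reported.
#'
#' @param spec A [genome_spec()].
#' @param demo A [demography_params()].
#' @param loci List of [selection_locus()] objects (their positions are
#'   added to the mutation target sites if absent).
#' @param n_sample_weedy,n_sample_cult Diploid sample sizes (must not
#'   exceed the current population sizes).
#' @param burn_in Burn-in generations (default `8 * N_a`).
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @param missing_rate Fraction of output genotype calls set missing at
#'   random (default 0; real panels have missing calls, the statistics
#'   must tolerate them).
#' @return List with `genotypes` ([genotype_matrix()]), `pop_map`
#'   ([population_map()]: groups "weedy"/"cultivated"), `truth`
#'   (data.frame: chrom, pos, origin "standing"/"new" relative to the
#'   split, regime, s, plus the present-day population-level alternative
#'   allele counts `weedy_pop_alt`/`cult_pop_alt`, which let a classifier
#'   be scored against population truth rather than sampling accidents),
#'   and `params` (full parameter record, for the JSON run log).
#' @export
simulate_dedomestication <- function(spec, demo, loci = list(),
                                     n_sample_weedy, n_sample_cult,
                                     burn_in = NULL, seed = 1L,
                                     missing_rate = 0) {
  if (n_sample_cult > demo$N_a)
    fs_param_error("cultivated sample size exceeds population size")
  N_w_final <- if (demo$T_r > 0) demo$N_w else demo$N_b
  if (n_sample_weedy > N_w_final)
    fs_param_error("weedy sample size exceeds population size")
  for (l in loci) {
    if (!l$chrom %in% names(spec$chrom_lengths) ||
        l$pos >= spec$chrom_lengths[[l$chrom]])
      fs_param_error("selection locus %s:%d outside the genome", l$chrom, l$pos)
  }
  burn_in <- burn_in %||% (8L * demo$N_a)
  set.seed(as.integer(seed))

  ## site positions (0-based), selection loci positions guaranteed present
  chroms <- names(spec$chrom_lengths)
  pos_list <- lapply(seq_along(chroms), function(i) {
    p <- sort(sample.int(spec$chrom_lengths[[i]], spec$sites_per_chrom[i])) - 1L
    extra <- vapply(Filter(function(l) l$chrom == chroms[i], loci),
                    `[[`, integer(1), "pos")
    sort(unique(c(p, extra)))
  })
  chrom <- rep(chroms, lengths(pos_list))
  pos <- unlist(pos_list, use.names = FALSE)
  S <- length(pos)
  site_id <- paste(chrom, pos)

  ## per-site selection annotation
  regime <- rep("neutral", S); s_coef <- rep(0, S)
  target <- rep(NA_character_, S); init_f <- rep(NA_real_, S)
  for (l in loci) {
    i <- match(paste(l$chrom, l$pos), site_id)
    regime[i] <- l$regime; s_coef[i] <- l$s
    target[i] <- l$target_pop; init_f[i] <- l$init_freq
  }

  ## burn-in: ancestral cultivated population, neutral, frequency-only
  x_anc <- wf_burn_in(S, demo$N_a, spec$mu, burn_in)

  ## impose conditioned standing frequencies at the split
  cond <- !is.na(init_f)
  x_anc[cond] <- pmax(1L, round(init_f[cond] * 2 * demo$N_a))

  standing <- x_anc > 0L

  ## split: HWE genotype counts for both populations
  p_anc <- x_anc / (2 * demo$N_a)
  g_cult <- wf_resample(p_anc, demo$N_a)
  g_weed <- wf_resample(p_anc, demo$N_b)

  sel_weights <- function(pop) {
    act <- regime != "neutral" & target == pop
    if (!any(act, na.rm = TRUE)) return(NULL)
    w_het <- rep(1, S); w_hom <- rep(1, S)
    dir <- which(act & regime == "directional")
    ov <- which(act & regime == "overdominant")
    w_het[dir] <- 1 + s_coef[dir]; w_hom[dir] <- 1 + 2 * s_coef[dir]
    w_het[ov] <- 1 + s_coef[ov]   # hom weight stays 1
    list(het = w_het, hom = w_hom)
  }
  w_weed <- sel_weights("weedy"); w_cult <- sel_weights("cultivated")

  step <- function(g_w, g_c, N_w_now, m_now) {
    N_w_cur <- g_w$n0[1] + g_w$n1[1] + g_w$n2[1]
    p_w <- wf_gamete_freq(g_w, N_w_cur, spec$mu, w_weed$het, w_weed$hom)
    p_c <- wf_gamete_freq(g_c, demo$N_a, spec$mu, w_cult$het, w_cult$hom)
    if (m_now > 0) {
      p_w2 <- (1 - m_now) * p_w + m_now * p_c
      p_c <- (1 - m_now) * p_c + m_now * p_w
      p_w <- p_w2
    }
    list(w = wf_resample(p_w, N_w_now), c = wf_resample(p_c, demo$N_a))
  }

  for (g in seq_len(demo$T_b)) {
    st <- step(g_weed, g_cult, demo$N_b, 0)
    g_weed <- st$w; g_cult <- st$c
  }
  for (g in seq_len(demo$T_r)) {
    st <- step(g_weed, g_cult, demo$N_w, demo$m)
    g_weed <- st$w; g_cult <- st$c
  }

  ## sample individuals; assign genotype counts to sample slots per site
  sw <- sample_genotype_counts(g_weed, N_w_final, n_sample_weedy)
  sc <- sample_genotype_counts(g_cult, demo$N_a, n_sample_cult)
  lay <- function(cnt, n) {
    t(vapply(seq_len(S), function(i) {
      v <- rep.int(c(0L, 1L, 2L), c(cnt$n0[i], cnt$n1[i], cnt$n2[i]))
      v[sample.int(n)]
    }, integer(n)))
  }
  geno <- cbind(lay(sw, n_sample_weedy), lay(sc, n_sample_cult))
  ids <- c(sprintf("W%03d", seq_len(n_sample_weedy)),
           sprintf("C%03d", seq_len(n_sample_cult)))

  if (missing_rate > 0) {
    drop <- runif(length(geno)) < missing_rate
    geno[drop] <- NA_integer_
  }

  seg <- rowSums(geno, na.rm = TRUE) > 0L &
    rowSums(geno, na.rm = TRUE) < 2L * rowSums(!is.na(geno))
  G <- genotype_matrix(geno[seg, , drop = FALSE], chrom[seg], pos[seg],
                       ref = rep("A", sum(seg)), alt = rep("T", sum(seg)),
                       sample_ids = ids)
  pm <- population_map(
    ids, group = rep(c("weedy", "cultivated"),
                     c(n_sample_weedy, n_sample_cult)),
    role = rep(c("weedy", "cultivated"), c(n_sample_weedy, n_sample_cult)))
  truth <- data.frame(
    chrom = chrom[seg], pos = pos[seg],
    origin = ifelse(standing[seg], "standing", "new"),
    regime = regime[seg], s = s_coef[seg],
    weedy_pop_alt = (g_weed$n1 + 2L * g_weed$n2)[seg],
    cult_pop_alt = (g_cult$n1 + 2L * g_cult$n2)[seg],
    stringsAsFactors = FALSE)
  params <- list(spec = unclass(spec), demo = unclass(demo),
                 loci = lapply(loci, unclass), burn_in = burn_in,
                 n_sample_weedy = n_sample_weedy,
                 n_sample_cult = n_sample_cult,
                 missing_rate = missing_rate, seed = as.integer(seed))
  list(genotypes = G, pop_map = pm, truth = truth, params = params)
}

#' Write a simulation truth table
#'
#' TSV columns: chrom, pos (1-based, matching the VCF), origin, regime, s.
#'
#' @param truth Truth data.frame from [simulate_dedomestication()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#' @param path Truth TSV path.
#' @return data.frame with 0-based `pos` (exact round-trip).
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) fs_input_error("truth table not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  df$pos <- as.integer(df$pos) - 1L
  df
}

#' Bundled de-domestication scenario preset
#'
#' The stated world of the scan-recovery experiments: a 14-Mb two-
#' chromosome genome (8 Mb + 6 Mb, one mutation target site per 800 bp,
#' `mu` chosen so that 4 N_a mu = 0.05 per site at desk scale, giving
#' roughly 20 segregating sites per 100-kb window in a 30-diploid sample),
#' a cultivated population of 400 diploids, and a weedy offshoot through a
#' bottleneck of 50 founders for 25 generations recovering to 400 diploids
#' for 250 generations, without migration.  Five directional "loci"
#' (s = 0.1) sit at named positions on
#' chromosome 1 (standing start frequency 0.1, so the sweep is both real
#' and visible as high allele-frequency differentiation); because sites
#' recombine freely there is no hitchhiking,
#' so each is emulated as a tight cluster of co-selected sites spanning
#' 80 kb around its position (mirroring how the balancing-region width is
#' emulated by a block of overdominant loci rather than by recombination
#' suppression).  One 0.6-Mb block of overdominant loci (s = 0.5, one per
#' 5 kb, so that balanced polymorphism carries an O(1) share of each
#' block window's diversity, as a window-level D signature requires)
#' sits on chromosome 2 at 1.6-2.2 Mb; the balanced alleles start
#' as low-frequency (0.05) standing variation in the cultivated
#' progenitor, so the cultivated panel keeps low Tajima's D over the block
#' while heterozygote advantage drives the weedy copies toward 0.5.
#'
#' @param neutral Drop all selection loci (neutral control of the same
#'   genome and demography).
#' @return List: spec, demo, loci, directional_targets (positions scored by
#'   the recovery tests), balancing_block (chrom/start/end of the block).
#' @export
preset_dedomestication <- function(neutral = FALSE) {
  spec <- genome_spec(c(chr1 = 8e6, chr2 = 6e6),
                      sites_per_chrom = c(10000L, 7500L), mu = 3.125e-5)
  demo <- demography_params(N_a = 400, N_b = 50, N_w = 400, T_b = 25,
                            T_r = 250, m = 0)
  dir_pos <- c(1e6, 2.5e6, 4e6, 5.5e6, 7e6)
  loci <- list()
  if (!neutral) {
    for (p in dir_pos) {
      for (off in seq(-40000L, 40000L, by = 4000L))
        loci[[length(loci) + 1]] <- selection_locus(
          "chr1", p + off, "directional", s = 0.1, init_freq = 0.1)
    }
    for (bp in seq(1.6e6, 2.2e6 - 1, by = 5000L))
      loci[[length(loci) + 1]] <- selection_locus(
        "chr2", bp, "overdominant", s = 0.5, init_freq = 0.05)
  }
  list(spec = spec, demo = demo, loci = loci,
       directional_targets = data.frame(chrom = "chr1", pos = dir_pos),
       balancing_block = data.frame(chrom = "chr2", start = 1.6e6, end = 2.2e6))
}

#' Standing-sweep scenario preset
#'
#' The stated world of the allele-frequency-differentiation experiments:
#' a single 8-Mb chromosome (one target site per 800 bp, 4 N_a mu = 0.05),
#' a milder bottleneck (100 founders for 10 generations, recovery to 400
#' diploids for 150 generations) so the cultivated progenitor keeps its
#' standing alleles at samplable frequency, and five directional sweep
#' clusters (s = 0.15) whose selected alleles start as standing variation
#' at frequency 0.15 in the progenitor.  Under this world the standing
#' class accumulates high AFD inside the selected regions (the sweeps),
#' while new mutations - absent from the progenitor - stay mostly rare.
#'
#' @param neutral Drop all selection loci.
#' @return List: spec, demo, loci, directional_targets.
#' @export
preset_standing_sweep <- function(neutral = FALSE) {
  spec <- genome_spec(c(chr1 = 8e6), sites_per_chrom = 10000L, mu = 3.125e-5)
  demo <- demography_params(N_a = 400, N_b = 100, N_w = 400, T_b = 10,
                            T_r = 150, m = 0)
  dir_pos <- c(1e6, 2.5e6, 4e6, 5.5e6, 7e6)
  loci <- list()
  if (!neutral) {
    for (p in dir_pos) {
      for (off in seq(-40000L, 40000L, by = 4000L))
        loci[[length(loci) + 1]] <- selection_locus(
          "chr1", p + off, "directional", s = 0.15, init_freq = 0.15)
    }
  }
  list(spec = spec, demo = demo, loci = loci,
       directional_targets = data.frame(chrom = "chr1", pos = dir_pos))
}
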