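---
title: "Models and methods behind feralscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind feralscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

feralscan studies crop de-domestication — the evolution of a cultivated
plant back into a self-sustaining weedy form — with weedy rice as the
motivating system. This vignette documents the models, the tunable
parameters, the numerical choices, and what the bundled simulator does
and does not establish. It states no empirical result that the test
suite does not itself compute.

## The de-domestication scenario

The demographic model has a cultivated source population of constant
diploid effective size $N_a$. At the split, a weedy founder population of
size $N_b$ separates, stays at $N_b$ for $T_b$ generations (the
bottleneck), then recovers instantaneously to $N_w$ and evolves for $T$
further generations to the present. Migration between weedy and
cultivated populations, when enabled, is symmetric at fraction $m$ per
generation and active only after the bottleneck. For inference the
parameters are dimensionless: $\nu_b = N_b/N_a$, $\nu_w = N_w/N_a$,
$\tau_b = T_b/2N_a$, $\tau = T/2N_a$, $M = 2 N_a m$. Four model variants
are compared: bottleneck or not, migration or not; the no-bottleneck
models drop $(\nu_b, \tau_b)$ and the no-migration models fix $M = 0$.

The ancestral size is anchored by $\theta = 4 N_e \mu L$ with per-site
neutral diversity $\theta$, mutation rate $\mu$ per site per generation,
and generation time $L$ in years; `ne_from_theta()` floors the result to
an integer.

## The forward simulator

`simulate_dedomestication()` is a discrete-generation Wright–Fisher
simulator with three deliberate simplifications:

1. **Free recombination between sites.** Every statistic in the package
   is per-site or per-window and none requires linkage. The width of a
   balancing-selection signature (in rice, a centromeric low-recombination
   region) is emulated by placing many overdominant loci across a block,
   not by modelling recombination suppression. Consequence: there is no
   hitchhiking, so a single selected SNP cannot drag a 100-kb window's
   mean F<sub>ST</sub>; the bundled preset therefore represents each
   "selected locus" as a tight cluster of co-selected sites, and scores
   recovery per named cluster position.
2. **Recurrent biallelic mutation** (a mutated gamete flips its allele at
   rate $\mu$) instead of infinite sites, so new mutations can arise at
   sites monomorphic in the cultivated population — which is what the
   standing-vs-new classification needs.
3. **Per-site genotype-frequency dynamics.** With free recombination and
   per-locus viability selection, sites evolve independently given the
   epoch sizes, so each generation is: viability weighting of genotype
   frequencies (directional $1, 1+s, 1+2s$; overdominant $1, 1+s, 1$, in
   the target population only), gamete formation, mutation, migration
   mixing of gamete pools, then Hardy–Weinberg multinomial resampling to
   the epoch size. This makes desk-scale runs (thousands of sites,
   hundreds of generations) take seconds while keeping selection exact.

Desk-scale realism relies on $\theta$-preserving rescaling
(`rescale_demography()`): simulate $N/\lambda$ with $\mu\lambda$,
conserving $4N\mu$ and all $\tau$ values, which preserves SFS shape and
window-statistic expectations up to the granularity of integerized
epochs.

A `selection_locus` may fix the ancestral allele frequency at the split
(`init_freq`), conditioning a sweep on starting from standing variation
at that frequency — the standard device in standing-sweep simulations.
The truth table records each output site's origin epoch (standing = the
alternative allele existed at the split), its selection regime, and the
present-day population-level allele counts in both populations, so a
classifier can be scored against population truth rather than sampling
accidents.

## Bundled worlds and their parameters

`preset_dedomestication()` (the scan world): 14-Mb genome (8 + 6 Mb), one
mutation target site per 800 bp with $4 N_a \mu = 0.05$ per site
(~20 segregating sites per 100-kb window in a 30-diploid sample);
$N_a = 400$, $N_b = 50$, $T_b = 25$, $N_w = 400$, $T = 250$, $m = 0$.
Five directional clusters (21 sites over 80 kb, $s = 0.1$, standing start
frequency 0.1) on chr1; one 0.6-Mb overdominant block (one locus per
5 kb, $s = 0.5$, start frequency 0.05) on chr2. The start frequencies
encode the observed pattern that balanced alleles are rare in the
cultivated progenitor and driven to intermediate frequency in the weed by
heterozygote advantage; 5-kb spacing makes balanced polymorphism an
$O(1)$ fraction of block-window diversity, which any window-level
Tajima's D signature requires. The drift scale (bottleneck plus recovery,
about 0.4 in units of $t/2N$) is larger than a literal rescaling of the
rice estimates would give; it is what makes window F<sub>ST</sub> noise
and signal separable in a 14-Mb genome, and it errs against the detector.

`preset_standing_sweep()` (the AFD world): one 8-Mb chromosome, the same
five directional clusters ($s = 0.15$, start frequency 0.15) and a milder
bottleneck ($N_b = 100$, $T_b = 10$, $T = 150$): with less post-split
drift the cultivated panel keeps its standing alleles at samplable
frequency, so the standing/new contrast reflects selection rather than
sampling loss.

The classification-fidelity experiment (how accurately the
standing-vs-new classifier reflects population truth at a given panel
size) runs on a third, neutral world that matches the study system's
inferred demography rather than the scan worlds' exaggerated drift: a
severe short bottleneck ($T_b/2N_b \approx 0.75$, the published
inference of under a hundred founders for at most 150 years) and a
scaled recovery time of a few generations. Drift-exaggerated recoveries
inflate the weedy-visible-but-cultivated-rare class far beyond anything
the real split times allow, and would understate the classifier's
fidelity for reasons unrelated to sampling.

What a green test on these worlds does **not** establish: behaviour under
linkage (LD, hitchhiking, background selection), realistic rice
chromosome structure, wild-rice introgression, genotyping/imputation
error, or the published genome-scale counts, which depend on the original
data.

## Statistics: conventions and edge cases

All intervals are 0-based half-open; VCF positions convert on read/write.
Sites are never dropped globally for missingness — each statistic uses
its own per-site called-allele count.

- **π**: per-site unbiased heterozygosity $2j(n-j)/n(n-1)$; windows
  divide the summed site values by the *full window span* (invariant
  bases included), matching the windowed estimator of the standard VCF
  toolkits — users running SNP-only VCFs should read window π as per-bp.
  Sites with fewer than two called alleles contribute zero.
- **Tajima's D** per window uses $S$, summed π, and the Tajima (1989)
  constants evaluated at the *median* per-site called-allele number of
  the window (missing data make $n$ vary per site; a single-$n$
  approximation is standard). Windows with fewer than 3 SNPs, $S = 0$, or
  $n < 4$ are missing and excluded from quantiles and Z-transforms.
- **F<sub>ST</sub>**: Weir & Cockerham (1984) components; window value
  $\sum a / \sum(a+b+c)$; monomorphic sites and sites with fewer than two
  called individuals in either population are skipped; negative estimates
  are retained (clamping would bias window sums).
- **Z-transform** is genome-wide (all chromosomes jointly), sample sd;
  zero variance is a degenerate-computation error (CLI exit code 2).
- **Region calling** merges qualifying windows that overlap or abut;
  region summaries (`mean_stat`, `max_stat`) are over all windows
  overlapping the merged span, flanks included. The balancing rule is:
  threshold = top-5% type-1 (order-statistic, no interpolation) quantile
  of non-missing weedy D, so the threshold is an observed value; merged
  regions must exceed 0.5 Mb strictly; a region is removed if the
  cultivated panel has mean D > 1 or any window D > 2 over the same span.
  A single failing window breaks a run — the strictest reading of
  "continuous".

## Standing vs new classification

A weedy SNP (alternative allele seen at least once among called weedy
samples) is *standing* if the alternative allele is seen at least once
among called cultivated samples, else *new* — allele presence, not
polymorphism, the closest literal reading of shared-vs-unique SNPs. AFD
is the signed difference of alternative-allele frequencies
(weedy − cultivated); distributions are normalized within class over all
classified SNPs, and threshold percentages are strict (`AFD > t`).

The only error mode of this classifier on clean genotypes is sampling:
an allele present in the cultivated *population* but absent from the
cultivated *panel* yields a false "new" call. Accuracy is therefore
scored as the fraction of classified SNPs not suffering that event
(against the truth table's population-level counts), and it rises with
panel size. The stricter precision-of-new-calls metric plateaus well
below 1 under any plausible demography, because it is bounded by the
rare-allele spectrum relative to panel depth, not by the classifier.

## Demographic inference

The expected joint SFS under a model is computed by Monte-Carlo forward
simulation of independent neutral sites at a desk-scale reference size
($N_a^{desk} = 100$ diploids, $\theta_{site} = 0.02$), sampling alleles
with the binomial kernel in the final population frequencies — the same
sampling operator diffusion-based SFS methods use — then folding to the
minor allele, masking singletons (cells whose total minor-allele count is
1) *and* the monomorphic corner cells, and normalizing over unmasked
cells. A diffusion PDE solver is deliberately not re-implemented: the
model-comparison logic only needs relative composite likelihoods, and the
multinomial (θ-free) composite log-likelihood
$\sum_{\text{unmasked}} n_k \log \max(p_k, 10^{-12})$ sidesteps the
mutation-scale multiplier entirely.

Three numerical choices make this Monte-Carlo likelihood usable for
optimization and ranking; each was forced by a measured failure mode of
the naive version:

- **Inverse-CDF common random numbers.** Every binomial transition is
  drawn as `qbinom(u, n, p)` on uniform streams indexed by (epoch,
  generation) and derived from the seed. R's `rbinom` is a rejection
  sampler, so re-seeding alone does *not* couple trajectories: an
  infinitesimal parameter change desynchronizes the stream and produces
  an essentially independent realization (measured swing: hundreds of
  log-likelihood units for a negligible migration change). With
  inverse-CDF coupling the surface is a near-continuous function of the
  parameters, nested models coincide exactly at shared parameter values,
  and a model with $M = 0$ supplied to the migration variant reproduces
  the no-migration spectrum bit for bit.
- **Proportional Dirichlet smoothing.** Cells the finite simulation never
  visits would hit the $10^{-12}$ floor and turn Monte-Carlo gaps into
  dominant penalties. The expected spectrum therefore receives uniform
  pseudo-mass equal to 2% of its segregating mass (spread over unmasked
  cells). The pseudo-mass is proportional, not per-cell constant: a
  fixed per-cell count would distort small simulations far more than
  large ones and systematically bias fits that use cheaper evaluations.
- **One surface per comparison.** All runs of all models in a
  `compare_models()` call share one simulation seed, so every reported
  likelihood lives on the same deterministic surface and best-run
  selection is not a lottery over seed-specific jitter. `surface_reps`
  optionally averages several coupled surfaces, which flattens the noise
  envelope that maximization otherwise chases along weakly identified
  ridges (the recovered-size parameter $\nu_w$ is the flattest
  direction).

Fitting: each run screens a batch of log-uniform random points, then
maximizes from the best of them with Nelder–Mead in log-parameter space
under a fixed evaluation budget. Models are fitted in nesting order and
each richer model is additionally warm-started from its fitted
sub-models' optima (embedded with the extra parameter at its smallest
bound), which keeps the nesting inequality — richer model's best
likelihood at least its sub-model's — attainable in practice. Because
epoch durations are integerized at desk scale, the surface is piecewise
constant in $\tau$ below $1/2N_a^{desk}$; the presets keep
$\tau \gtrsim 0.05$ where this granularity is immaterial. "Median of the
best fitting parameters" across randomized runs is ambiguous; it is
implemented as the per-parameter median over the top decile of runs by
likelihood, never fewer than three runs (at desk-scale run counts a
single-run decile would chase the noise envelope; at the study-scale 200
runs the rule is simply the decile), with the full run table exported so
users can apply their own rule. The default is 20 runs (a study-scale
setting would be 200; the `--n-runs` flag raises it).

Model ranking counts a nesting model as recovering its sub-model: with
finite optimizer budgets the richer model can only match or exceed the
sub-model's likelihood, so "generating model or a model nesting it ranked
first" is the meaningful recovery event.

## Known limitations

- No linkage: anything haplotype-based (iHS, XP-EHH, LD decay) is out of
  scope, and window statistics underestimate the variance real linkage
  would induce.
- The Monte-Carlo expected SFS carries $O(\theta_{site})$ recurrent-
  mutation distortion and Monte-Carlo noise; both are second-order for
  ranking but would matter for tight confidence intervals (bootstrap CIs
  are not implemented).
- VCF input consumes GT only; phase and likelihoods are ignored, and
  half-missing calls are treated as missing.
- The CLI's `simulate` exposes the bundled presets, not arbitrary
  scenarios; programmatic use covers the rest.
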