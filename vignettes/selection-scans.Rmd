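---
title: "Detecting selective sweeps from two-population phased haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps from two-population phased haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

When one population has been under recent positive selection — a breed
selected for a production trait, an island population adapting to a new
environment — the swept genomic region carries three linked signatures
relative to a reference population: unusually long haplotypes around the
selected site, strong allele-frequency differentiation, and a local excess
of rare variants where diversity is recovering from the sweep. `sweepscan`
computes one statistic per signature from a phased, biallelic-SNP VCF of
two populations, calls outlier windows with a rank-based empirical
P-value framework, and annotates candidate genes. A forward Wright–Fisher
simulator with a controllable sweep provides ground-truthed synthetic data
for power and calibration studies.

All statistics assume fully phased, imputed input (no missing genotypes);
the package refuses anything else at parse time, because every haplotype
statistic silently degrades under sloppy phasing conventions.

### Coordinate conventions

VCF positions are 1-based; every internal interval (windows, genes, BED)
is 0-based half-open. A SNP at 1-based position $p$ belongs to the window
with $\mathrm{start} \le p - 1 < \mathrm{end}$, so window boundaries never
double-count.

## Hard filtering

`apply_hard_filters()` implements the standard GATK-style site filters: a
record fails if its phred-scaled quality is below 30, if the count of
mapping-quality-zero reads exceeds 4 *and* quality-by-depth falls below 5
(a conjunctive rule — either alone is tolerated), or if the phred-scaled
strand-bias score exceeds 200. Comparisons are strict as printed, so
boundary values pass. A missing annotation never triggers its rule
(conservative retention, matching the conjunctive caller semantics); one
warning reports the gap. Filtering is applied to the joint two-population
table, and it is idempotent.

## XP-EHH

Extended haplotype homozygosity at span $[c, x]$ is the probability that
two chromosomes drawn without replacement are identical over the span:

$$\mathrm{EHH}(c,x) = \frac{\sum_g \binom{n_g}{2}}{\binom{n}{2}},$$

where $g$ ranges over identical haplotype strings. The statistic here is
allele-agnostic (all chromosomes, no partition on the core allele): the
boundary rule below is defined "with respect to all chromosomes", and a
per-allele EHH cannot satisfy it. At the core itself EHH is 1 by
convention (the empty extension).

For each core SNP the integration boundary $X$ in each direction is the
SNP within 1 Mb whose EHH *on the pooled chromosomes of both populations*
is closest to 0.04; ties go to the farther SNP (longer integration
support). EHH is then integrated by the trapezoid rule against physical
position, separately per population but over identical intervals, the two
directions are summed, and the score is

$$\mathrm{XP\text{-}EHH}_{raw} = \ln(I_A / I_B),$$

positive when the test population A carries the longer haplotypes.
Integration uses physical distance throughout: no genetic map is assumed
anywhere in the haplotype statistics. Cores with a boundary in only one
direction keep their (one-direction) score and are flagged; a
`drop_one_sided` switch removes them instead. Raw scores are standardized
genome-wide — all cores pooled, population variance (divisor $n$) — to
mean 0, variance 1.

## Windowed outlier calling

The genome is tiled into non-overlapping 50-kb windows; each window's
summary statistic is the **maximum** standardized score among its SNPs.
Because the maximum rises with the number of SNPs, windows are binned by
SNP count in increments of 200 (1–200, 201–400, 401–600, >600), and the
empirical P-value of window $j$ is the fraction of windows *in its bin*
with a strictly greater statistic. Windows with P < 0.01 are significant.
Consequences of this definition worth knowing:

* the top window of each bin always has P = 0;
* equal maxima share a P-value, and an all-tied bin is all P = 0 (flagged
  by the strict ">" rule, documented rather than patched);
* empty windows are masked and take no part in binning;
* a partial terminal window is retained but flagged, with a switch to
  drop it.

By construction the flagged fraction within a bin of $M$ distinct-score
windows cannot exceed $0.01 + 1/M$; the acceptance suite verifies this
calibration on a neutral genome of 1000 windows.

## XP-CLR-style composite likelihood

The second scan models allele-frequency differentiation directly. For a
candidate sweep position and selection strength $s$, a linked neutral
allele at genetic distance $r$ escapes the sweep with probability

$$c = 1 - (2Ns)^{-r/s},$$

clipped to $[0,1]$ ($c = 0$ at the site itself, $c \to 1$ far away). The
latent frequency in the test population is modelled as a two-point
mixture: with weight $p_B$ a component centred at $(1-c) + c\,p_B$, with
weight $1 - p_B$ one at $c\,p_B$, each a normal with drift variance
$\omega\, p_B(1 - p_B)$ censored to $[0,1]$ with boundary point masses.
The drift scale $\omega$ is estimated genome-wide as the mean of
$(p_A - p_B)^2 / (p_B(1-p_B))$ over SNPs polymorphic in B. The sampling
likelihood integrates the binomial over this density on a fixed 512-point
grid; the neutral model is the $c = 1$ collapse.

Per 50-kb window, SNPs polymorphic in B are thinned to at most 400
(seeded uniform draw), and SNP pairs with $r^2 > 0.95$ in B are clustered
by single linkage, each SNP weighted by 1/cluster-size so a cluster
contributes total weight 1. The window score is
$2(\max_{site,s} \ell - \ell_{neutral})$, maximized over candidate sites
every 10 kb and 12 log-spaced $s$ values in $[10^{-4}, 0.5]$, with the
neutral model included in the candidate set so scores are non-negative
(on a finite grid the $c \to 1$ limit is not otherwise attainable).
Genetic distance uses a constant map of 1 cM/Mb (configurable), and
$2N$ defaults to 20,000 — it enters only through $2Ns$. This explicit
mixture model is this package's documented approximation of the classical
cross-population composite likelihood test; bit-compatibility with other
implementations is not a goal. Candidate sweeps are the windows strictly
above the empirical top-1% quantile (R's default quantile definition,
which keeps the rule meaningful for small window counts).

## Allele-frequency spectrum statistics

Minor allele frequencies are the folded fractions $\min(f, 1-f)$. The
rare-allele statistic is the proportion of SNPs with MAF < 0.10 in
sliding 100-kb windows advancing every 20 kb; windows with fewer than 10
SNPs are masked. Tajima's D is computed in non-overlapping 50-kb windows
with the textbook constants; monomorphic windows are masked, and for
$n = 2$ the variance constants vanish, making D indeterminate — the
package reports NaN rather than inventing a value.

Significance for D uses a coalescent null conditioned on the observed
number of segregating sites: each of 10,000 replicates draws a neutral
Kingman genealogy for $n$ samples (the time scale cancels) and places
exactly $S$ mutations on branches with probability proportional to branch
length. The fixed-$S$ conditioning is a deliberate choice: it matches
"random samples given the observed data" and avoids an arbitrary
$\theta$. The P-value is $P(D_{sim} < D_{obs})$, flagged below 0.05. The
null's location for typical $n, S$ was cross-checked against an
independent coalescent simulator during development.

Any lowess smoothing shown in figures is strictly cosmetic and lives only
in the plotting helpers; no statistic is ever smoothed.

## LD decay

$r^2$ between phased 0/1 columns is $D^2/(p(1-p)q(1-q))$, identical to
the squared Pearson correlation; monomorphic columns are undefined and
masked. The decay curve averages $r^2$ over all pairs closer than 10 Mb
in 50-kb distance bins (left-closed, right-open; a pair at exactly 10 Mb
is excluded).

## The synthetic-data generator

`simulate_two_pops()` is a discrete-generation Wright–Fisher forward
simulator: a coalescent-seeded ancestral population of $N$ = 200 diploids
is equilibrated forward for 300 generations under mutation and crossover
(so that recombination, absent from the seeding genealogy, shapes
short-range LD before the split), then split into populations A and B
that evolve independently for `t_split` = 150 generations. Mutation is
infinite-sites at uniform unused integer positions; crossovers are
Poisson along the chromosome; an optional additive sweep (fitnesses
$1, 1+s, 1+2s$) acts at one site in A. Sampling returns the phased
haplotypes of 8 and 6 diploids — the size of a typical small two-breed
re-sequencing contrast — and keeps every variant polymorphic across the
combined sample, including fixed differences.

The default rates (mu = rho = 2.5e-7 per bp per generation, L = 500 kb)
are **scaled parameters, not biological estimates**: they put the
population-scaled diversity at $\theta = 4N\mu L = 100$ (about 1–3
segregating sites per kb in the sample) on a chromosome short enough to
simulate in under a second. Drift is correspondingly exaggerated
(background $F_{ST} \approx 0.3$ at the default split), which the tests
account for.

Design choices that came out of validating the sweep scenario:

* **Hard sweeps only for the `"sweep"` preset.** A standing variant at
  moderate frequency proved a poor sweep emulator at these scaled rates:
  its copies coalesce deep in the genealogy, so their shared haplotype
  extends only $\sim 1/(\rho\,T_{MRCA}) \approx 7$ kb and the "sweep"
  leaves almost no EHH footprint. A new mutation sweeping from one copy
  is identical by descent throughout, with a footprint set by
  $1/(\rho\,t_{fix}) \approx 30$ kb of near-total homozygosity plus an
  escape scale $s/(\rho \ln 2Ns) \approx 70$ kb — the scale of the 50-kb
  windows the scans use. Standing-variant sweeps remain available as an
  option.
* **Conditioning.** The preset conditions on the swept allele reaching
  population frequency 0.9 by sampling time, restarting the post-split
  evolution of A on failure (up to 100 restarts, all consuming one RNG
  stream so runs stay reproducible); `condition_freq` also accepts an
  interval to demand a still-ongoing sweep.
* **Presets.** `"neutral"` is the same demography without selection;
  `"ld_contrast"` bottlenecks population B to 40 diploids so its LD decay
  curve sits visibly above A's.

### What the simulations do and do not show

The generator reproduces the mechanisms the statistics integrate —
haplotype structure from a mechanistic sweep, drift-driven
differentiation, post-sweep rare-allele excess, recombination-limited LD.
It does not emulate variable recombination or mutation rate, gene
conversion, ascertainment bias, phasing or imputation error, population
growth, or migration. Passing tests therefore demonstrate that the
statistics are computed correctly and respond to their target signals at
desk scale; they do not certify power on any real genome.

One desk-scale caveat deserves emphasis: standardization of XP-EHH is
genome-wide, and on a 500-kb "genome" a sweep spans a third of the
chromosome, inflating the moments it is standardized by. Absolute
standardized scores are therefore not comparable across such small
simulated genomes (a sweep run's top score can sit below a neutral run's
99th percentile), while within-run ranks — what the empirical-P framework
actually uses — remain well behaved. The test suite checks within-run
outlier behaviour and rank-based recovery accordingly; on a real
multi-gigabase genome the distinction disappears.

### Problem sizes used by the tests

The suites run entirely on simulated data generated at test time: 20
sweep and 20 neutral replicates at the default conditions for the
power/specificity checks, and a 100-chromosome neutral genome (1000
50-kb windows) for the empirical-P calibration, which
`scripts/acceptance.R` recomputes from scratch.

## Numerical and degenerate-input policy

* Filters: strict inequalities exactly as printed; missing annotation =
  rule not triggered, one warning.
* EHH: profiles are non-increasing by construction; incremental group
  refinement keeps a full profile $O(n \cdot \text{SNPs})$.
* Quadrature: midpoint rule on (0,1) plus boundary masses; likelihoods
  floored at 1e-300 before logging. The drift spike must stay resolvable
  on the grid (sd of at least a few grid steps), which bounds how small
  an $\omega$ is meaningful at a given grid size.
* Ties: boundary-SNP ties go to the farther SNP; empirical-P ties share
  the P-value; all-equal top-fraction input designates nothing.
* Degenerate windows: 0 SNPs → masked everywhere; $S = 0$ → D undefined;
  monomorphic columns → $r^2$ undefined; constant score vectors refuse to
  standardize.
* Reproducibility: every stochastic entry point (thinning, window
  thinning, the simulator, the coalescent null) takes an explicit seed.

## Limitations

* The composite likelihood is an intentionally transparent approximation:
  no singleton-specific terms, constant recombination map, fixed grids.
* The empirical-P framework calls outliers, not absolute significance: on
  a genome with no sweeps it still flags the top fraction per bin.
* One chromosome per VCF read; multi-chromosome genomes are scanned
  chromosome-by-chromosome and pooled at the score level (as the
  calibration suite does).
* iHS/nSL, per-allele EHH decay, demography-aware nulls, and GO-term
  enrichment of candidates are out of scope.
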