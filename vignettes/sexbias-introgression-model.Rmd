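---
title: "Modeling sex-biased archaic introgression on chromosome X and the autosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sex-biased archaic introgression on chromosome X and the autosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archaicx)
```

## The question

Present-day human genomes carry segments ("tracts") of archaic hominin
ancestry, but far less of it on chromosome X than on the autosomes. Two
mechanisms can produce that deficit without invoking hybrid incompatibilities:

1. **Selection asymmetry.** Chromosome X is hemizygous in males, so X-linked
   deleterious archaic variants are exposed to selection at full strength in
   half the population regardless of dominance, while autosomal recessive
   variants hide in heterozygotes (heterosis).
2. **Sex-biased introgression.** An introgressing group with female fraction
   $p$ contributes 2 autosomal haplotypes per individual but only $1 + p$ X
   haplotypes on average, so the expected ratio of entering autosomal to X
   haplotypes is $H^A / H^X = 2 / (1 + p)$: 2 under all-male introgression,
   1 under all-female.

`archaicx` implements a forward simulation in which both mechanisms act, plus
the statistics needed to quantify their consequences, and an empirical
pipeline for per-individual archaic tract calls.

## The simulation model

A recipient population of $N_r$ diploids and a source population of
$N_s = N_r / 100$ diploids evolve in isolation as discrete-generation
Wright-Fisher populations with two sexes. Defaults: $N_r = 25{,}000$,
$N_s = 250$, 20,000 generations of isolation, then a single-generation pulse
replacing 5% of the recipient with migrants bred from the source, then 15,000
more generations. Each offspring draws a mother and a father with probability
proportional to fitness.

**Genome.** One chromosome (100 Mb at full scale) with exons covering a
configurable fraction of it and a piecewise recombination map. Deleterious
mutations arise only in exons at a configurable per-bp rate; each draws a
selection coefficient from the gamma DFE $s \sim \Gamma(k = 0.186,\,
\theta = 0.07068995)$ (fit to human exome variation; about 74% of draws have
$s \le 0.01$). Fitness is multiplicative over sites: $1 - hs$ per
heterozygous site, $1 - s$ per homozygous site, and $1 - s$ per site of a
hemizygous male X, floored at $10^{-9}$. Dominance is genome-wide: $h = 0.5$
("additive") or $h = 0$ ("recessive").

**Inheritance.** Autosomes recombine in both sexes. Chromosome X recombines
only in female meiosis; fathers transmit their single X intact to daughters
and no X to sons. No pseudoautosomal region is simulated (the `par` field of
a `chromosome_map` exists only for the empirical pipeline's filtering and
denominator logic). No Y chromosome, mitochondria, multiple pulses, beneficial
mutations, or hybrid-incompatibility loci.

**Ancestry tracking.** Every haplotype carries an explicit, sorted, merged
set of half-open archaic-ancestry intervals. At the pulse all source
haplotypes are labeled fully archaic; recombination thereafter splits and
re-merges intervals exactly. Coverage of a sampled haplotype is
$c_h = \sum_{t} (t_r - t_l) / L$ over tracts of at least 500 bp. This direct
interval tracking replaces the tree-sequence + identity-by-descent route: the
quantity of interest is descent from pulse-generation introgressors, which
interval propagation computes exactly, making ancestral-history
reconstruction unnecessary.

**The pulse.** Migrants are offspring of source parents (drawn with
replacement, fitness-weighted), so the pulse size can exceed the source
census size, as Wright-Fisher migration allows. In `exact` mode the migrant
count is $m = \mathrm{round}(0.05\,N_r)$ with exactly
$\mathrm{round}(p\,m)$ females; a `stochastic` mode replaces each recipient
independently with probability 0.05 and draws each migrant's sex with
probability $p$, reproducing the run-to-run scatter in realized pulse size
and sex ratio that the exact mode suppresses. The run manifest records both
realized quantities for audit.

**Replacement, not addition.** Whether migrants replace or augment residents
is a free design choice at fixed census size; replacement keeps $N$ constant
and is used throughout.

**Sex assignment.** Offspring sexes are deterministic counts (exactly the
configured female fraction each generation) by default, suppressing
demographic noise at small scaled sizes; a Bernoulli mode is available. The
recipient female fraction defaults to 0.5 and can be made unequal to study a
standing sex-ratio bias.

## Scaling

A scaling factor $Q$ divides population sizes and generation counts by $Q$
and multiplies $s$, the mutation rate, and recombination rates by $Q$,
preserving $2Ns$, $2N\mu$ and $2Nr$. The desk configuration used by the test
suite and the acceptance script is $Q = 10$ with a 10 Mb chromosome
($N_r = 2{,}500$ simulated diploids, 2,000 + 1,500 simulated generations),
which runs a full scenario in seconds. Timecourse generations are reported in
the scaled run's own generation units.

Scaling is not free, and three desk-scale artifacts are worth knowing about:

- **Residual drift.** The 10-fold smaller population and shorter chromosome
  leave much more replicate-to-replicate drift in final mean coverage than
  the full-scale model: replicate standard deviations near 0.009 (autosomes)
  to 0.017 (chromosome X) around means near 0.02. Replicate counts in the
  test suite and acceptance script (2-12 per scenario) were chosen for that
  noise level, and single replicates should never be interpreted alone.
- **DFE truncation on X.** Multiplying $s$ by $Q$ turns every raw
  $s > 1/Q$ into a hemizygous-lethal X variant ($s_{\text{scaled}} > 1$).
  At $Q = 10$ about 2% of the gamma mass is truncated this way (versus 0.2%
  at $Q = 2$), and those variants are stripped from the source's X during
  burn-in. The entering X haplotypes are therefore relatively cleaner than at
  small $Q$, which compresses the autosome-to-X coverage ratio toward 1 in
  the female-biased additive scenarios (male-biased and recessive scenarios
  keep ratios well above 1). The sex-bias-to-coverage correlation on X is
  likewise attenuated (around 0.35 at desk scale) because drift inflates the
  within-scenario spread.
- **Timecourse compression.** One scaled generation spans $Q$ original ones,
  so the generation-1 coverage already reflects $Q$ generations of the fast
  initial purge. For scenarios whose subsequent decay is shallow (recessive
  autosomal under heterosis), the half-decay midpoint then falls in the slow
  drift tail and the half-decay generation lands far later than the fast
  purge itself; for fast-purging scenarios it lands at 2-8 scaled
  generations. Compare half-decay values only between runs at the same
  scaling factor.

## Defaults the source material leaves open

The following values are not fixed by the model description and are package
choices, set once:

- **Deleterious mutation rate** `1.5e-8` per exonic bp per generation - the
  canonical human per-bp rate; treating every exonic mutation as deleterious
  with gamma effects approximates an exome-wide deleterious target.
- **Exon fraction** `0.015` with mean exon length 160 bp - human exome-like
  density; exons alternate with geometric intergenic gaps, rescaled so the
  exonic total hits the target exactly.
- **Recombination** mean rate `1e-8` per bp per generation over 50 pieces
  with lognormal rate variation (sdlog 0.5), renormalized so the
  length-weighted mean is exact. One map, generated once per seed, is shared
  by the autosomal and X simulations, so coverage contrasts cannot come from
  map differences; per-chromosome maps can be supplied as BED files instead.
- **Burn-in initialization**: both populations start mutation-free and
  equilibrate under mutation-selection-drift during the isolation phase. No
  pre-isolation coalescent history is appended; it would only add shared
  neutral variation, which does not enter the ancestry-tract statistics.

## The statistics

- `compute_coverage()`: the coverage statistic with the 500 bp minimum tract
  length. The source text prints the tract condition as $t_r - t_l \le 500$
  but describes coverage as bases "within a contiguous tract of at least
  500 bp"; a $\le$ filter would discard nearly all coverage, so tracts
  **shorter** than 500 bp are excluded.
- `bootstrap_ratio()`: autosomal and X simulations are separate runs with no
  per-individual pairing, so the aut:chrX ratio is the mean of 2,000
  bootstrap replicates of (mean of 10,000 autosomal draws) / (mean of 10,000
  X draws), with an empirical percentile 95% CI. Replicates with a zero X
  mean are redrawn; more than 10% rejections flags the estimate unreliable.
  Empirical data use within-individual ratios instead - the two code paths
  are deliberately distinct.
- `timecourse_summary()` / `half_decay_generation()`: per-generation mean,
  variance, and bootstrap CI; the half-decay generation is the first sampled
  generation at or below the midpoint of the generation-1 and final means,
  with no interpolation (the sampling cadence - every 2 scaled generations to
  40, then every 50 - bounds its resolution). A non-decaying series returns
  generation 1 with a `no_decay` flag.
- `neutral_length_density()`: the neutral expectation for tract lengths is a
  single-parameter exponential with rate $r_{\mathrm{eff}}\,t$ - the standard
  post-admixture approximation. For chromosome X,
  $r_{\mathrm{eff}} = \tfrac{2}{3} r$ because recombination happens only in
  female meiosis and 2 of every 3 transmitted X copies pass through a female.
  The density is exposed unnormalized to histogram counts; comparisons use
  its mean and shape.
- `length_percentile()` uses nearest-rank quantiles so the documented
  examples are integer-exact; `top_fraction_share()` takes the
  $\lceil f n \rceil$ longest tracts, including ties at the cutoff.

## The empirical pipeline

`ingest_tracts()` reads per-haplotype tract-call files (two per individual,
0-based half-open after ingestion; a `pos1` dialect flag converts 1-based
closed input). `filter_tracts()` removes calls with posterior probability
strictly below 0.8, calls with zero supporting archaic-matching SNPs, and X
calls overlapping the pseudoautosomal region by any amount (the whole call is
removed, not trimmed, because the calls - not base pairs - are the filter
unit). `per_bp_rate()` merges calls per haplotype, sums across both
haplotypes and divides by twice the chromosome length, excluding the PAR
length from the X denominator; male X calls are expected in artificially
diploid form (duplicated across both haplotype slots), matching the division
by $2L$. The 500 bp minimum applies only to simulated coverage, never to
empirical calls. `exclude_outliers()` drops individuals with ratio > 50 or
autosomal rate > 0.1 (strict inequalities, applied globally before any
summary). `group_summary()` and `pairwise_welch()` give bootstrap CIs, rank
orderings, and Welch's two-sided unequal-variance t-tests at the
Bonferroni-corrected threshold `alpha / n_pairs` (0.05/6 for four groups).
Welch tests are two-sided, the conventional reading of "significantly
different".

## What the synthetic cohort generator does and does not emulate

`generate_cohort()` produces tract-call files with planted group-level per-bp
rates: filter-passing tracts carry the planted coverage exactly (up to
integer rounding), and decoy tracts - sub-0.8 posteriors or zero SNP support,
allowed to overlap the PAR - are layered on top for the filters to remove.
Tract lengths are gamma-distributed (not exponential) so filter interactions
can be tested independently of the length shape; between-individual
variation is lognormal. The generator emulates the *structure* of real
cohort data (file layout, posterior scores, SNP support, PAR), not its
biology: no linkage between individuals, no shared segregating tracts, no
population structure. Recovery tests on these cohorts validate the pipeline
arithmetic, not any inference about real genomes.

## Numerical and reproducibility choices

- All randomness (R and C++) flows through R's RNG; a single integer seed
  reproduces a run bit-for-bit. Parents are chosen by cumulative-weight
  inversion over a fixed-order individual list.
- Per-gamete crossovers are Poisson with mean equal to the map's total
  genetic length; positions are drawn by inverting the cumulative genetic
  map.
- Fitness floors at $10^{-9}$; a homozygous or hemizygous site with
  $s \ge 1$ (possible after scaling multiplies $s$ by $Q$) clamps the
  genotype to the floor, and such events are counted in the engine
  diagnostics.
- Mutations are identified by id, so homozygosity means identity by descent;
  two mutations at the same position on opposite haplotypes are two
  heterozygous sites.
- Grid experiments derive per-cell seeds as `master_seed + cell_index`.

## Known limitations

- Single chromosome per run; aut:chrX contrasts combine separate runs.
- The desk scale trades replicate-level drift noise for speed; full-scale
  runs ($Q = 2$, 100 Mb) use the same code but hours of compute.
- The gamma DFE and dominance are genome-wide; no chromosome-specific DFEs,
  by design.
- The empirical pipeline consumes SNP-support counts as given; it never
  re-evaluates calls against archaic reference genomes.
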