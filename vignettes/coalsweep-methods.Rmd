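---
title: "Models and methods behind coalsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coalsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalsweep)
```

coalsweep re-implements, as one coherent R package, the computational chain
used to study the recent colonisation of a new habitat by a selfing plant:
coalescent simulation of two-population demographic histories, SFS-based
composite-likelihood demographic inference with AIC model choice and
parametric bootstrap, dual selective-sweep scanning (an SFS-based composite
likelihood ratio and the LD-based omega statistic) with
simulation-calibrated significance cutoffs, sliding-window diversity
statistics, GATK-style variant hard filters, and F2 interval mapping of a
quantitative trait. The motivating system is *Arabidopsis thaliana* from
the Yangtze River basin (popY) and north-western China (popN), but every
component is generic. This vignette records the models, their assumptions,
and the design decisions a maintainer would want explained.

## The coalescent simulator

The simulator (`simulate_panel()`, `expected_sfs()`) implements a two-deme
structured coalescent with:

* piecewise-constant diploid effective sizes per deme;
* a divergence event at which, backwards in time, the two demes merge into
  one ancestral deme of its own (piecewise) size;
* timed migration windows, implemented backwards in time as per-lineage
  deme-switch rates (the convention of SFS simulators such as ms and
  fastsimcoal); asymmetry means the two directional rates differ.

**Ploidy convention.** Sizes are diploid \(N_e\) and two lineages in a deme
of size \(N\) coalesce at rate \(1/(2N)\) per generation. Because highly
selfing strains are sampled as *single haplotypes* (heterozygous sites are
negligible), a sample of \(n\) strains is a sample of \(n\) lineages. We
record this explicitly because ploidy conventions silently change every
inferred size by a factor of two.

**Mutation** is an infinite-sites approximation: each lineage accrues
mutations as a Poisson process with rate \(\mu \times\) (bp covered)
\(\times\) branch length in generations; positions are uniform and integer
collisions are re-drawn (negligible at the simulated densities).

**Recombination** (optional) uses a Hudson-style ancestral recombination
graph: lineages carry lists of ancestral-material segments, recombination
splits a lineage at a uniform point of its breakable span, coalescence
merges segment lists, and intervals whose carrier set reaches the full
sample have found their MRCA and are dropped. This yields \(r^2\) decaying
with physical distance, which the omega scan requires. The default rate is
3.6 cM/Mb (\(3.6\times10^{-8}\)/bp/generation), the genome-wide average for
*A. thaliana*; the mutation rate default is \(7\times10^{-9}\)/bp/generation
and the generation time one year.

The expected SFS does not need recombination (it is
recombination-invariant in expectation), so `expected_sfs()` accumulates
branch lengths by joint descendant-count class over independent
genealogies. A lineage's class is fixed at its creation, so each lineage
contributes `death - birth` once — the accumulator is \(O(\text{events})\)
per genealogy, which is what makes simulation-based likelihood fitting
affordable. The per-replicate engine is C++; one master seed drives
deterministic child seeds so any replicate is reproducible in isolation.

### Built-in demographic templates

`yangtze_demographic_models()` returns four two-deme scenarios (M1 no gene
flow, M2 one migration window, M3 continuous migration, M4 two asymmetric
windows). M4 carries the published best-fit vector: divergence 61,409
generations ago from an ancestral population of 179,724; popY 78,454
shrinking to 45,089 at 7,543 generations ago; popN 26,959 changing to
45,617 at 7,169 generations ago; migration windows 18,652–14,307 and
8,440–7,660 generations ago. Two open points and how we resolved them:

* The printed size trajectory is internally puzzling (the popY change
  78,454 → 45,089 is described as an expansion, the popN change
  26,959 → 45,617 as a reduction). The model type accepts any piecewise
  sizes; the templates encode the printed numbers verbatim and take no
  position on the intended direction.
* The migration *rates* of the windows are not printed, only that both
  flows were weak. The templates default to backward per-lineage rates of
  \(2\times10^{-5}\) (popY→popN) and \(5\times10^{-6}\) (popN→popY) per
  generation — weak enough that they perturb the SFS only mildly, asymmetric
  as the best model requires. Both a per-generation-fraction and a
  2\(Nm\)-migrants convention are supported (`migration_units`), since the
  original parametrization is not recoverable.

## Composite-likelihood demographic fitting

The observed data is a folded joint SFS (we fold because no outgroup
polarization is part of the pipeline; `joint_folded_sfs()` merges each cell
\((i,j)\) with its complement \((n_1-i, n_2-j)\) into the minor
configuration). The fit maximizes the multinomial composite log-likelihood
\(\sum_c n_c \log p_c(\theta)\) where \(p_c\) comes from a Monte-Carlo
expected spectrum. Cells with fewer than 10 *observed* SNPs are masked and
the expectation renormalized over the retained cells; masking on observed
counts is the most direct reading of ignoring "entries with support from
< 10 SNPs". Expected proportions are floored at \(10^{-12}\) so a finite
simulation cannot produce \(-\infty\).

The optimizer is multi-start Nelder–Mead on transformed parameters (sizes
and migration rates on log scale, times linear). Each run starts uniformly
inside the bounds and proceeds through cycles; the simulation count per
likelihood evaluation escalates geometrically across cycles between the
two ends of `sims_schedule` (the classic 100,000 → 1,000,000 schedule at
full scale). Within a cycle, competing parameter values share the same
simulation seeds (common random numbers), which turns a noisy Monte-Carlo
surface into a smooth one that Nelder–Mead can descend; consecutive cycles
with the same simulation count share one Nelder–Mead call carrying the
pooled iteration budget (`nm_iter` per cycle), avoiding repeated simplex
restarts. All runs are finally re-evaluated on one common surface and the
best wins; a fit in which no run ever improved its starting value is
flagged rather than silently returned.

Identifiability deserves a note: because the likelihood uses *normalized*
spectra, a one-epoch (constant-size) model has no identifiable scale — only
parameters that change the SFS *shape* (divergence time, relative sizes,
epoch boundaries) are estimable. The package's recovery experiments
therefore free shape-identifiable parameters one at a time around the M4
truth. At 200,000 SNPs and the reduced desk budget (10 runs × 10 cycles,
20,000 simulations per evaluation) each of the four headline parameters is
recovered with median relative error of a few percent over seeds.

`compare_models()` implements \(AIC = 2k - 2\log CL\) and Akaike weights;
`bootstrap_ci()` simulates SFS datasets at the point estimate (multinomial
draws from a high-precision expected spectrum — the SFS-level equivalent of
simulating unlinked SNPs), refits each with a reduced budget and reports
percentile intervals, counting refit failures explicitly.

## Sweep scans

**CLR.** `clr_scan()` follows the SweepFinder model on the folded spectrum.
The genome-wide background spectrum is treated as symmetric-unfolded; at a
grid point, a site at distance \(d\) escapes the sweep with probability
\(p_e = 1 - e^{-\alpha d}\). Escapees keep background ancestry; the
non-escaped lineages descend star-like from the single sweeping lineage,
whose allele is drawn from the hypergeometrically downsampled background of
the \(B+1\) pre-sweep ancestors (\(B \sim \mathrm{Binomial}(n, p_e)\)).
Conditioning on polymorphism happens after mixing over \(B\); in the
\(p_e \to 0\) limit only the \(B=1\) term survives the conditioning, which
is the limit the implementation uses (the \(B=0\) term is always
monomorphic). \(\alpha\) is maximized over 64 log-spaced per-bp values in
\([10^{-7}, 10^{-1}]\) *plus the background itself* (the
\(p_e \to 1\) neutral limit), so \(\mathrm{CLR} \ge 0\) everywhere by model
nesting. Escape probabilities are looked up on a 256-point grid — the
standard SweepFinder-style discretization. The scan uses SNPs only (no
invariant-site correction), matching a folded-fSFS input, and the default
grid spacing is 10 kb; a published full-genome run sets the grid count
(50,000) instead, and both parametrizations are accepted.

One caution from our testing: the background must be a genome-wide
(recombination-averaged) spectrum. Handing the scan the spectrum of a
single non-recombining locus absorbs the genealogical fluctuation the
statistic is designed to detect.

**Omega.** `omega_scan()` computes, at each grid point, the ratio of the
average within-side \(r^2\) to the average cross-side \(r^2\), maximized
over window extents between `minwin` (10 kb) and `maxwin` (100 kb) on each
side; ties take the leftmost maximizing split. \(r^2\) comes directly from
phased haplotypes (selfing lines are effectively phased). Sides with fewer
than two SNPs yield `NA`, never zero.

**Calibration.** `calibrate_cutoff()` takes scans of neutral datasets
simulated under the fitted demography — the full-scale protocol is 10,000
1-Mb nulls at a 0.01% false-positive rate — and returns the \(1-\)FPR
quantile of the pooled null statistic. With fewer than \(1/\mathrm{FPR}\)
null values it warns and returns the widest available quantile.
`merge_regions()` joins significant grid points within `max_gap` (default:
the grid interval, since "neighbouring targets" is all the protocol
specifies), `intersect_methods()` forms the two-method consensus, and
`genes_in_regions()` reports genes overlapping consensus regions by at
least 1 bp from a leniently parsed GFF3 (malformed rows are skipped and
counted). The published full-scale cutoffs (CLR 27.85, ω 11.92) are
real-data quantities and are deliberately not targets of the desk-scale
package tests.

## Windowed statistics and filters

`nucleotide_diversity()`, `watterson_theta()` and `hudson_fst()` use
200-kb windows with 10-kb steps by default. Per-window denominators use the
full window length, not accessible sites — the simplest reading of the
field's convention, and the difference is a constant factor on synthetic
data. The FST estimator is Hudson's (1992) ratio of averages,
\(1 - \bar{\pi}_{within}/\pi_{between}\), chosen for robustness at low
diversity; windows with zero between-deme diversity are flagged `NA`.
Note the estimator's small-sample behaviour: with identical allele
frequencies in both demes it converges to \(-1/(n-1)\), not exactly 0.

The hard filters mirror a GATK VariantFiltration recipe: Q ≥ 30, MQ ≥ 20,
QD ≥ 10, ReadPosRankSum ≥ −8, DP ≥ 3, FS ≤ 10 (SNPs) / ≤ 200 (indels), no
more than three SNPs per 10 bp, and a per-site call-rate floor (219 of 221
in the motivating design). Decisions worth recording:

* Missing annotations pass their rule (the VariantFiltration behaviour at,
  e.g., sites with only homozygous calls) and are tallied separately.
* The density rule removes *whole* clusters: any 10-bp span (endpoints
  inclusive) holding ≥ 4 SNPs disqualifies all SNPs in the span. Thinning
  clusters to 3 is available behind `action = "thin"`; whether the original
  pipeline removed or thinned is not recoverable, and removal is the
  conservative default.
* Coordinates are 1-based inclusive internally (VCF); BED-style intervals
  are applied with a conservative closed boundary (`start <= pos <= end`),
  so both readings of the 0-based boundary mask a site.

## F2 cross simulation and QTL mapping

Gametes follow a Haldane (no-interference) Markov chain along each
chromosome; F2 genotypes are sums of two independent gametes, so
segregation is 1:2:1. The default map mirrors the study design: 5
chromosomes proportioned like the *A. thaliana* genome at 3.6 cM/Mb
(~429 cM) carrying 32 markers. `flowering_qtl_model()` constructs the
two-QTL truth analytically: additive effects proportioned so the drop-one
variance fractions equal 60.9% and 21.6% at 1:2:1 frequencies and the
homozygote span equals the parental difference (50.33 − 24.87 days),
giving \(a_1 = 7.98\), \(a_2 = 4.75\) days and residual SD 3.02 days.

`interval_mapping()` is Haley–Knott regression on conditional expected
genotype scores at pseudo-markers (default step 1 cM), with conditional
probabilities from the nearest informative flanking markers — exact for a
no-interference F2 and naturally accommodating missing genotypes.
`permutation_threshold()` permutes phenotypes and takes the \(1-\alpha\)
quantile of the genome-wide maximum LOD; on the 86-individual study design
the 5% threshold lands near the published LOD = 2.9 (the publication does
not state how its threshold was derived, so we treat the comparison as
stochastic). Two-QTL variance explained uses the drop-one partition from
the joint Haley–Knott fit, since two simultaneous percentages are
reported; the single-QTL closed form \(1 - 10^{-2\mathrm{LOD}/n}\) is also
provided. `haplotype_association()` defaults to the exact two-sided
Wilcoxon rank-sum test with a Welch-t alternative, and
`candidate_filter()` performs the fine-mapping step of keeping
amino-acid-changing variants in a candidate interval grouped by gene.

## What the synthetic data does and does not emulate

The generators reproduce: the demographic signal in the joint SFS under
the four competing histories; LD decay under uniform recombination;
neutral sweep-null panels for cutoff calibration; Mendelian F2 segregation
with realistic marker sparsity and a two-QTL architecture matching the
published effect sizes. They do **not** emulate: sequencing error, missing
data and call-rate structure (filters are exercised on constructed
records); variable mutation/recombination landscapes; background
selection; residual heterozygosity in "selfing" strains; linked selection
in the nulls (the nulls are neutral by design, as in the original
protocol); or crossover interference. Passing tests therefore demonstrate
correctness of the algorithms under their own model assumptions, not
robustness to every artefact of real resequencing data.

## Problem sizes and numerical choices

Desk-scale defaults keep every check on one CPU: recovery experiments use
200,000-SNP spectra with 20,000 simulations per likelihood evaluation (10
runs × 10 cycles, one Nelder–Mead iteration per cycle); sweep-null
calibrations in the examples use dozens of 50–100-kb panels rather than
10,000 × 1 Mb (the full-scale protocol is supported but long-running, and
the pipeline logs a warning whenever a budget is below full scale);
permutation thresholds use the full 1000 permutations (they are cheap).
Ties in the omega split maximization take the leftmost split; SFS folding
ties (self-complementary cells) keep the lexicographically smaller index;
quantiles are type-7. The composite likelihood scales linearly with total
SNP count, so likelihood values are comparable only at a fixed SNP total.

## Known limitations

* The ARG simulator is quadratic-ish in sample size times recombination
  events; 1-Mb panels with hundreds of haplotypes are minutes, not seconds.
* The CLR implementation conditions on SNPs and ignores invariant sites,
  so its absolute values are not comparable to runs of tools that use
  invariant-site information.
* Composite likelihoods ignore linkage between SFS cells; AIC comparisons
  inherit that approximation (as they do in the tools this mirrors).
* One-deme scale parameters are unidentifiable from normalized spectra
  (see above); fits should free shape-identifiable parameters.
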