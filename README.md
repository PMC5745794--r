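# coalsweep

Population-genomic inference of recent local adaptation, in one R package.
`coalsweep` is aimed at researchers studying how a selfing plant population
colonised a new habitat from two-population resequencing panels and
experimental crosses — the motivating system is *Arabidopsis thaliana* from
the Yangtze River basin (popY, 86 strains) and north-western China (popN,
25 strains). It provides, as tested reusable functions:

* a **structured-coalescent simulator** (C++ core) for one- or two-deme
  histories with piecewise sizes, a divergence event and timed asymmetric
  migration windows, with optional Hudson-style ancestral-recombination-graph
  recombination so LD decays with distance;
* **composite-likelihood demographic fitting** of a folded joint site
  frequency spectrum: multinomial composite likelihood
  `sum_c n_c log p_c(theta)` over spectrum cells (cells with < 10 observed
  SNPs ignored), Monte-Carlo expected spectra, multi-start Nelder–Mead with
  common random numbers and an escalating simulation schedule, AIC / Akaike
  weights for model choice, and parametric-bootstrap confidence intervals;
* **selective-sweep scans**: a SweepFinder-style composite likelihood ratio
  on the folded SFS (escape probability `p_e = 1 - exp(-alpha d)`, alpha
  maximized over a log grid including the neutral limit, so CLR >= 0) and
  the LD-based omega statistic (within-side vs cross-side mean r², windows
  10–100 kb), with cutoffs calibrated on simulated neutral datasets at a
  chosen false-positive rate, region merging, two-method consensus and gene
  overlap from GFF3;
* **windowed statistics**: nucleotide diversity π, Watterson's θ_W and
  Hudson's F_ST in 200-kb / 10-kb sliding windows, joint/marginal folded
  SFS, private-SNP counts and SNP-saturation curves;
* **variant hard filters** (GATK-recipe thresholds, SNP-cluster density
  rule, call-rate rule, noncoding masking) on plain tibbles of site records;
* **F2 QTL mapping**: Haldane-model cross simulation, Haley–Knott interval
  mapping, genome-wide permutation LOD thresholds, drop-one variance
  explained, haplotype association tests and nonsynonymous candidate
  filtering;
* an end-to-end **pipeline** (`run_pipeline()` / `make_report()`) that runs
  simulate → filter → statistics → fit → scan → QTL on synthetic data with a
  checksummed manifest, fully deterministic per seed.

Everything is exercisable on synthetic data generated by the package itself;
no external data is required.

## Worked example

Simulate the two-population design under the built-in best-fit demographic
model (divergence 61,409 generations ago from an ancestral population of
179,724, two weak asymmetric gene-flow windows), then map a flowering-time
cross:

```r
library(coalsweep)

mods <- yangtze_demographic_models()
panel <- simulate_panel(mods$M4, c(86, 25), 2e5, seed = 1)
panel
#> <hap_panel> 111 haplotypes x 4043 segregating sites over 200,000 bp
#>   populations: popN (25), popY (86)

nucleotide_diversity(panel, 2e5, 2e5)$pi   # 0.00457 per bp
hudson_fst(panel, 2e5, 2e5)$fst            # 0.419

sfs <- joint_folded_sfs(panel)
sfs
#> <joint_sfs> folded, sample sizes (86, 25), 4043 SNPs, 1132 masked cells

# F2 cross: 86 individuals, 32 markers, 5 chromosomes, two additive QTLs
cross <- simulate_f2(86, genetic_map(), flowering_qtl_model(), seed = 1)
lod <- interval_mapping(cross)
glance(lod)
#> # A tibble: 1 × 4
#>   max_lod chr     pos     n
#> 1    17.3 chr2     34    86

permutation_threshold(cross, n_perm = 1000, seed = 2)  # 2.91

peaks <- dplyr::bind_rows(lapply(c("chr2", "chr5"), function(ch) {
  s <- lod[lod$chr == ch, ]; s[which.max(s$lod), c("chr", "pos")]
}))
variance_explained(cross, peaks)
#> # A tibble: 2 × 4
#>   chr     pos   lod   pve
#> 1 chr2     34 17.3   56.9
#> 2 chr5     52  5.27  21.0
```

The numbers mean: the synthetic Yangtze panel is strongly differentiated
from the reference population (F_ST ≈ 0.42); the cross recovers its two
planted flowering-time QTLs — the chromosome-2 locus explains ~57% of the
phenotypic variance and the chromosome-5 locus ~21% (the generating truth
is 60.9% / 21.6%), and the genome-wide 5% LOD significance threshold from
1000 permutations is ≈ 2.9.

Fitted objects follow broom conventions (`tidy()`, `glance()`), and result
tables have `autoplot()` methods (sweep scans, LOD curves, windowed
statistics, SFS heat maps).

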