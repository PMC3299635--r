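# rohscan

Case-control analysis of **runs of homozygosity (ROH)** from SNP genotype
panels, for statistical geneticists studying recessive contributions to
disease — the setting where autozygosity, surfacing as extended homozygous
runs, may harbour recessive risk alleles.

The package implements the full analysis chain:

* **Detection** — the sliding-window rule: a 50-SNP window is homozygous if
  it has ≤ 1 heterozygous and ≤ 1 missing call; a SNP belongs to a ROH if
  > 5% of windows spanning it are homozygous; segments must span ≥ 1 Mb,
  ≥ 50 SNPs and ≥ 1 SNP / 50 kb. A brute-force enumeration oracle
  (`brute_force_roh`) verifies the fast caller segment-for-segment.
* **Common/rare separation** — regions where ≥ 1% of all individuals carry
  a ROH ≥ *t* Mb (*t* = 2…5) mark IBS clusters; an overlapping ROH is
  removed as *common* unless its length exceeds the region's retention
  cutoff *mean + 3 SD* of the overlapping ROH lengths, in which case it is
  kept as a likely IBD outlier.
* **Burden** — per length threshold: the proportion of individuals with
  ≥ 1 rare ROH and the per-person ROH rate, compared between cases and
  controls with one-tailed pooled t statistics and label-permutation
  empirical p-values, `p = (1 + r)/(1 + B)`.
* **Logistic models** — Models 1–4 with cumulative covariates: none; the
  method-of-moments inbreeding coefficient
  `f = (O_hom − E_hom)/(N − E_hom)` on an LD-pruned subset; chronological
  age; the first two classical-MDS coordinates of the genome-wide 1 − IBS
  distance matrix.
* **Homozygosity mapping** — pools of overlapping rare ROHs; consensus
  regions (interval intersections spanning ≥ 2 SNPs); case/control
  complete-overlap carrier counts; pointwise permutation p-values with
  max-T family-wise correction (Bonferroni reported alongside); a
  gene-interval variant that merges genes with identical carrier sets.
* **Synthetic data** — genotype panels under Hardy–Weinberg equilibrium
  with per-sample inbreeding F, planted autozygous segments, planted IBS
  clusters, genotyping error/missingness and optional logistic
  case-control effects, so every stage is testable against planted truth.

## Worked example

Simulate 500 individuals with an excess of long autozygous runs in cases
(one planted 9.5 Mb segment in 4% of cases vs 1% of controls), call ROH,
filter to rare runs and test the burden:

```r
library(rohscan)

cfg <- sim_config(
  n_cases = 250, n_controls = 250, n_chromosomes = 5, snps_per_chrom = 2200,
  planted_segments = data.frame(group = c("case", "control"),
                                length_mb = 9.5, count_per_carrier = 1,
                                carrier_fraction = c(0.04, 0.01)),
  missing_rate = 0.002, seed = 7)
sim <- simulate_dataset(cfg)
sim$dataset
#> genotype_dataset: 500 samples x 11000 SNPs on 5 autosome(s)
#>   cases: 250  controls: 250  missing phenotype: 0
#>   missing genotype rate: 0.0020

rohs <- detect_roh(sim$dataset)
nrow(rohs)
#> [1] 12

cls <- classify_rare(rohs, sim$dataset$map, n_samples = 500)
bt <- burden_table(cls$rare, phenotypes_of(sim$dataset),
                   thresholds_mb = c(2, 5, 9), n_perm = 10000, seed = 2)
print(bt[, c("threshold_mb", "rate_cases", "rate_controls",
             "ratio_rate", "p_rate")], row.names = FALSE)
#>  threshold_mb rate_cases rate_controls ratio_rate     p_rate
#>             2       0.04         0.008          5 0.01739826
#>             5       0.04         0.008          5 0.01839816
#>             9       0.04         0.008          5 0.01749825

fd <- inbreeding_f(sim$dataset, ld_prune(sim$dataset))
round(mean(fd$f), 4)
#> [1] 0.0027
```

All 12 planted runs are recovered (10 case, 2 control carriers), the rare
rate ratio is 5 at every threshold and the permutation p-value ≈ 0.018
reflects the case excess; the genome-wide inbreeding coefficient of this
outbred panel is centred at zero. `run_full_pipeline()` chains the same
stages (plus models, mapping, locus-exclusion and long-ROH subgroup
re-analyses) into one run directory with TSV outputs and a text summary;
`inst/scripts/rohscan.R` exposes the stages as shell subcommands.

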