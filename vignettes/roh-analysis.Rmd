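---
title: "Case-control analysis of runs of homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control analysis of runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

Autosomal recessive disease alleles are expected to surface as extended runs
of homozygosity (ROH): chromosomal stretches where a diploid individual's
genotypes are homozygous because both haplotypes descend from a common
ancestor (identity by descent, IBD). Short, population-frequent runs instead
arise by chance sharing of common haplotypes (identity by state, IBS) and
carry no signal about recessive risk. `rohscan` implements a complete
case-control ROH analysis for SNP-chip genotype panels: window-based ROH
detection, separation of common from rare runs, homozygosity burden testing,
covariate-adjusted logistic models, and two permutation-corrected
homozygosity-mapping schemes — together with a synthetic-data generator that
plants known autozygous segments so every stage can be validated against
ground truth.

## ROH detection

Detection follows the classic sliding-window rule. A window of
`window_snps = 50` consecutive SNPs is *homozygous* if it contains at most
`max_het_per_window = 1` heterozygous and `max_missing_per_window = 1`
missing genotypes. Windows never cross chromosome ends. Each SNP receives
the fraction of windows spanning it that are homozygous (the denominator
shrinks near chromosome edges), and a SNP is flagged when that fraction is
*strictly greater than* 5%. Runs of consecutive flagged SNPs — split
wherever adjacent SNPs are more than `max_gap_kb = 1000` apart — become
segments if they contain at least `min_snps = 50` SNPs, span at least
`min_length_kb = 1000` and carry at least 1 SNP per 50 kb
(`min_density_snp_per_kb = 1/50`).

Two parameter choices deserve comment. `min_snps` defaults to 50, not the
more common 100: dense-chip analyses report segments of as few as 50
contiguous homozygous SNPs, which a 100-SNP floor would make impossible.
`max_gap_kb` follows the usual PLINK default of 1 Mb; nothing in the window
rule itself forces a choice, so it is exposed and logged.

Two detection functions share one output contract: `call_roh_sample()` uses
cumulative sums over window counts, and `brute_force_roh()` re-derives the
same answer by enumerating every window explicitly. The test suite asserts
segment-for-segment identity on randomized instances; the brute-force path
exists only as an oracle and is capped at 5,000 SNPs.

One behavioural subtlety of the strict `<= 1 missing` cap: when two missing
calls fall within one window width of each other, every window covering the
SNPs between them fails, the flagged run splits, and a fragment can fall
below the 1 Mb / 50 SNP filters. At 1% missingness this is common enough
that a long planted run is occasionally recovered as two segments whose
inner edges sit well inside the true boundaries. The *outer* boundaries obey
the provable window-smearing bound: a call never extends more than
`window_snps - 1` SNPs beyond the true homozygous run, because a window
fully inside het-dense background essentially never passes. Tests and the
acceptance script therefore check sensitivity (any-overlap recovery) plus
the overshoot bound, not a two-sided absolute offset.

## Common versus rare runs

Short 1–2 Mb ROHs concentrate in clusters shared by large fractions of a
cohort and are overwhelmingly IBS. `classify_rare()` removes them with a
regional rule applied at each minimum-length stratum of 2, 3, 4 and 5 Mb
(at 6 Mb and above, realistic panels no longer show >1%-frequency regions,
but the strata are configurable):

1. build the per-SNP carrier track — the number of distinct individuals,
   cases and controls pooled, with a qualifying ROH covering the SNP;
2. maximal runs of SNPs with carrier fraction ≥ 1% become *common regions*;
3. every qualifying ROH overlapping a region by ≥ 1 bp is flagged common,
   **unless** its length exceeds the region's retention cutoff
   `mean + 3 × SD` of the lengths of all qualifying ROHs overlapping that
   region — such length outliers are likely true IBD runs passing through
   an IBS cluster and are retained.

A ROH flagged in any stratum is common overall; a ROH of at least 2 Mb never
flagged is *rare* and feeds every downstream analysis. Length statistics use
the population SD (divide by *n*): at realistic cluster sizes the difference
from the sample SD is immaterial, but fixing the form makes the cutoff
deterministic. If fewer than two ROHs overlap a region the SD is set to 0
with a logged message; at the 1% threshold on cohort-scale panels this
cannot occur. Whether the 1% rule is applied per SNP or per pre-clustered
region is a genuinely open reading; the per-SNP track with maximal-run
regions is implemented here because it makes the region boundaries a pure
function of the data.

At desk-scale sample sizes the 1% rule bites hard: with 200 individuals a
single carrier crosses the threshold, so nearly every locus with two
overlapping runs becomes a "common region". Simulated designs for the
shared-locus analyses therefore use 1,000 individuals with planted carrier
fractions below 1%, mirroring the regime the rule was designed for
(cohorts of thousands, where a 6-carrier locus sits far below 1%).

## Burden analysis

For each minimum length threshold, `burden_table()` computes per group the
proportion of individuals with at least one qualifying rare ROH and the mean
number of qualifying ROHs per individual (the rate), their case/control
ratios, one-tailed equal-variance t-tests (cases > controls; the Welch form
is a flag away), and empirical p-values obtained by permuting case/control
labels. The permutation statistic is the difference in group means (of the
carrier indicator for the proportion, of the count for the rate); the
add-one estimator `p = (1 + r) / (1 + B)` keeps p-values in (0, 1] and
avoids zero. `n_perm` defaults to 10,000 — large permutation counts such as
10^8 buy accuracy below 10^-4 but are not a sensible default on one CPU;
the estimator is the same either way.

## Covariates and logistic models

Three covariates are computed from the genotypes themselves:

* **LD pruning** (`ld_prune()`): greedy windowed pruning (window 50, step 5,
  r² > 0.2 drops the lower-MAF SNP of the worst pair). The exact parameters
  used by any given study are rarely published; these are the folk-standard
  defaults and are configurable.
* **Inbreeding coefficient f** (`inbreeding_f()`): the method-of-moments
  excess-homozygosity statistic `f = (O_hom − E_hom) / (N − E_hom)` on the
  pruned subset, with the small-sample correction
  `E_het_j = 2 p q · A_j/(A_j − 1)` where `A_j` is the non-missing allele
  count at SNP *j* — the form that makes the expected-heterozygosity term
  unbiased. A fully heterozygous sample approaches f = −1, a fully
  homozygous one f = +1, and an outbred HWE panel is centred at 0.
* **MDS components** (`mds_components()`): classical metric scaling of the
  genome-wide `1 − IBS` distance matrix; the first two coordinates serve as
  ancestry covariates. Components are centred, ordered by eigenvalue, and
  sign-fixed (largest-magnitude loading positive) for reproducibility.

`run_model_series()` fits, for each threshold and each predictor encoding —
the carrier indicator ("proportion") and the per-sample count ("rate") —
four logistic models with cumulative covariate sets: Model 1 unadjusted,
Model 2 + f, Model 3 + age, Model 4 + the two MDS components. Fitting is
ordinary maximum likelihood via IRLS (tolerance 1e-8, at most 100
iterations); complete cases per model, with dropped-sample counts recorded.
Non-convergence and quasi-separation (fitted probabilities pinned to 0/1)
are flagged rather than silently reported. The proportion predictor is the
per-sample binary indicator, the only per-sample encoding consistent with
reporting a single odds ratio per threshold.

## Homozygosity mapping

`pool_roh()` groups overlapping rare ROHs into connected components per
chromosome (≥ 2 members). Each pool's *consensus region* is the intersection
of its member intervals; because overlap is transitive-chained, the full
intersection can be empty, in which case the pool is split into its maximal
sub-groups sharing a common point — for 1-D intervals these are exactly the
maximal cliques of the overlap graph, each yielding its own candidate
consensus. Only intervals containing at least 2 SNPs survive, and identical
intervals from different pools are de-duplicated. An individual *carries* a
region when at least one of their ROHs contains it entirely.

The association statistic per region is the case-carrier count, equivalent
to case excess when group sizes are fixed under permutation. Pointwise
p-values use the add-one permutation estimator. Family-wise correction is
max-T: each region's permutation statistics are standardised by their own
permutation mean and SD, and the corrected p-value is the fraction of
permutations in which *any* region's standardised statistic reaches the
observed one. Plain Bonferroni is emitted alongside for reference; max-T is
the default because carrier counts differ wildly across regions, and
Bonferroni over thousands of highly dependent interval tests is far too
conservative. Gene-based mapping (`gene_mapping()`) applies the same
machinery with gene intervals as the family, counts carriers by full
containment of the gene in a ROH (any-overlap by flag), and merges genes
with identical carrier sets into groups that share a group id and p-value
by construction.

## The synthetic-data generator

`simulate_dataset()` emulates the features of a post-QC GWAS panel that the
pipeline is sensitive to:

* SNP positions are cumulative sums of exponential gaps (mean 6,500 bp,
  ~50 SNPs per 325 kb), so a 1 Mb window of the genome holds ~150 SNPs;
* MAFs are uniform on (0.05, 0.5), matching a QC-filtered chip;
* background genotypes are independent across SNPs, drawn from HWE
  inflated by a per-sample inbreeding coefficient F:
  `P(hom) = p² + pqF, P(het) = 2pq(1−F)`;
* planted autozygous segments overwrite genotypes with homozygous calls
  whose allele is drawn by frequency, then heterozygous miscalls (default
  0.002, segment-only) and missingness (default 0.01, global) are applied;
* `make_common_region()` plants IBS clusters: a configured fraction of
  individuals receive independent homozygous runs with Normal lengths
  truncated at 2 Mb, centred in a region;
* phenotypes are either assigned by index or drawn from a logistic effect
  model on the per-sample count of long planted segments.

What the generator does **not** emulate: background linkage disequilibrium
(an optional block-copy mode exists purely to exercise the pruner),
recombination maps, genotyping batch effects, and realistic allele-frequency
spectra. Consequently the simulations validate the *algorithms* — window
semantics, filtering arithmetic, permutation calibration, estimator
recovery — not chip-specific behaviour on real data: background genotypes
essentially never produce a 1 Mb ROH by chance (the per-SNP heterozygosity
is ~0.36, so fifty consecutive quasi-homozygous SNPs have vanishing
probability), which makes planted-truth recovery sharper than it would be
on real genomes where low-recombination deserts produce borderline runs.

Default test-scale dimensions are 2 chromosomes × a few thousand SNPs and
hundreds to a thousand samples; every simulation in the test suite and the
acceptance script states its size and finishes in seconds to a couple of
minutes on one CPU. With a fixed seed the generator, and every downstream
stage, is byte-reproducible.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; BED input is shifted on
  read. Lengths follow `KB = (POS2 − POS1 + 1)/1000`.
* Genotype codes are minor-allele dosages; orientation (which homozygote is
  which) is irrelevant to every computation and kept only so PED/MAP round
  trips are identities. Frequency ties orient toward the lexicographically
  larger allele.
* Permutation tail counts use `>= observed − 1e-9·max(1, |observed|)` so
  that ties in discrete statistics are counted as exceedances.
* A zero-variance t-test returns a degenerate flag with p ∈ {0, 1/2→1}
  conventions documented on `one_tailed_t()`.
* A region with a constant permutation statistic (e.g. zero carriers) gets
  standardised score 0 and pointwise p = 1.
* `brute_force_roh()` refuses inputs above 5,000 SNPs; it exists to verify,
  not to scale.

## Known limitations

* No genetic-map (cM) lengths and no HMM/likelihood ROH calling; the window
  rule is the method under study.
* The common/rare filter needs cohort-scale *n* for its 1% rule to behave
  as designed; on small panels almost everything is "common", which is the
  correct behaviour of the rule, not an artifact.
* Permutation p-values at desk-scale B bottom out at 1/(B+1); headline
  claims below that resolution require scaling B up.
* The power of the rate test for rare long runs is limited by carrier
  counts: with 500 cases, carrier probabilities of 0.03 vs 0.01 give a
  one-tailed permutation test roughly 60–70% power at α = 0.05, so designs
  expecting near-certain detection need either bigger effects or larger n.
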