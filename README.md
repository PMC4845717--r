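# irdx

Comparing targeted gene-panel sequencing with whole genome sequencing (WGS)
for the molecular diagnosis of inherited retinal dystrophies (IRD).

Diagnostic laboratories moving from a targeted next-generation sequencing
(NGS) panel to WGS need to quantify what the new assay adds: how accurate
each pipeline is at known genotypes, which clinically relevant variants one
platform finds and the other misses, how those findings change each
patient's clinical outcome, and what diagnostic-yield gain to expect across
the whole referral population. `irdx` packages that comparison as a tested,
reusable pipeline for anyone benchmarking genomic diagnostic assays —
clinical bioinformaticians, diagnostic-lab scientists, and methodologists
studying yield projection.

## What it computes

**Genotype concordance.** Against an array truth set of genotype classes
(hom-ref / het / hom-alt) restricted to target regions, a pipeline's calls
are scored per site into a confusion table: sensitivity = tp/(tp+fn) over
truth SNVs, specificity = tn/(tn+fp) over truth hom-ref sites. Discordant
sites adjudicated by an orthogonal gold standard (Sanger) are reclassified
when the array was wrong, yielding adjusted estimates and the truth-set
error rate ε = (#array-wrong)/(#adjudicated).

**Outcome classification.** A rule engine maps each patient's clearly/likely
pathogenic variants, gene inheritance models (AD/AR/XLD/XLR) and phenotype
to one of five outcome categories: confirmed diagnosis, provisional
diagnosis, undiagnosed carrier of a phenotype-relevant recessive trait,
undiagnosed carrier in an unrelated gene, or undiagnosed. Recessive
diagnoses require homozygosity or two heterozygous hits assumed *in trans*;
carrier states in non-causal genes are always retained as reportable
findings.

**Platform differencing.** After parsimony-style normalisation (allele
trimming and left alignment), variants private to one platform are
extracted (deletion identity by reciprocal overlap ≥ 0.8) and categorised:
large deletion, intronic variant, insertion-deletion, informatics miss, or
additional-gene variant.

**Yield uplift.** With the population partitioned into strata *s* of size
N_s, of which n_s were re-sequenced and k_s gained a diagnosis, the
projected uplift over D baseline diagnoses is

    uplift = 100 · Σ_s N_s · (k_s / n_s) / D   [% of baseline diagnoses]

with a parametric-bootstrap percentile CI: each replicate redraws
k\*_s ~ Bin(n_s, k_s/n_s) and optionally the stratum prevalences and D from
Bin(N, ·), and the 2.5/97.5 empirical percentiles of the replicate uplifts
form the interval. `coverageCheck()` validates the interval's empirical
coverage on synthetic truth.

A deterministic study fixture (`studyFixture()`) and a random cohort
generator (`generateCohort()`) provide inputs with the exact structure the
analysis expects, so every stage has a worked-example surface.

## Worked example

```r
library(irdx)
fx <- studyFixture()

# Panel-arm outcomes for the 562-patient referral cohort
out <- classifyCohort(fx$cohort, fx$models, "ngs")
s <- cohortSummary(out)
s$yield_pct        # 50   — half the cohort gets a molecular diagnosis
s$n_diagnosed      # 281  (53 AD, 1 XLD, 13 XLR, 91 AR hom, 123 AR comp-het)
s$n_carrier_patients  # 158 patients carry a reportable single recessive allele

# Genome-pipeline concordance against 4166 array-genotyped sites
buildConcordance(fx$truth_wgs, fx$calls_wgs, fx$panel)
#> ConcordanceTable: tp=928 fn=0 tn=3235 fp=3
#>   sensitivity 100.0%, specificity 99.9%, 3 discordant site(s)

# Head-to-head: merge genome findings into the 46-patient subsample
sub <- fixtureSubsample(fx)
merged <- mergePlatforms(sub)
table(classifyCohort(merged, fx$models, "merged")$category)
# 24 diagnosed after merging, vs 13 on the panel arm: 11 new diagnoses,
# driven by the 14 panel-missed variants returned by:
diffCallsets(cohortCalls(sub, "wgs"), cohortCalls(sub, "ngs"),
             fx$models, fx$known_miss)

# Projected uplift across the referral population (three-stratum weighting)
simulateCI(fx$strata3, fx$baseline_diagnosed, fx$pop_total,
           n_sims = 10000, seed = 1)
#> UpliftEstimate: 27.1 % of baseline (95% CI 12.3-44.1, 10000 sims, seed 1)
#>   expected new diagnoses: 76.24
```

The numbers mean: on the fixture cohort the panel diagnoses 50% of
referrals; re-sequencing the stratified 46-patient subsample with WGS flips
11 of 33 undiagnosed patients to diagnosed; weighting those per-stratum
yields across the population projects roughly a quarter more diagnoses than
the panel alone, with the CI reflecting binomial sampling uncertainty in
every estimated proportion.

An end-to-end run (`writeFixtureBundle("dir"); runPipeline("dir/config.yaml")`)
writes per-stage reports, an audit log and a combined summary; identical
config and seed give a byte-identical bundle.

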