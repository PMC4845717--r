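---
title: "Methods: comparing panel and genome sequencing for retinal disease diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing panel and genome sequencing for retinal disease diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdx)
```

`irdx` implements the analytical core of a two-stage diagnostic comparison:
a referral cohort tested with a targeted gene panel, a stratified subsample
re-sequenced with a whole-genome pipeline, and the machinery to quantify
what the second assay adds. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish.

## Concordance benchmarking

A truth set of array genotypes assigns each prespecified site a class:
homozygous reference, heterozygous, or homozygous alternate. Within target
regions, each truth site is scored against the pipeline's calls:

* truth SNV (het or hom-alt) with any call carrying the truth alternate
  allele at that position → **tp**, otherwise **fn**;
* truth hom-ref with no variant call at the position → **tn**, otherwise
  **fp**.

Sensitivity is tp/(tp+fn), specificity tn/(tn+fp). The default scoring is
*detection-oriented*: a call with the right allele but the wrong zygosity
still counts as detected, because the question is whether the pipeline sees
the variant at all; such sites are logged as zygosity mismatches, and
`genotype_strict = TRUE` switches to genotype-aware scoring in which they
become false negatives. Undefined ratios (no truth SNVs, or no truth
hom-ref sites) are reported as `NA` with an explicit flag — never silently
0 or 1 — so downstream code must confront them.

Truth sets are imperfect. Discordant sites re-assayed with an orthogonal
gold standard (Sanger sequencing) resolve three ways: the pipeline was
right (the array erred), the array was right, or unresolved. Each
pipeline-correct resolution moves its site within its truth row (fn→tp,
fp→tn), which conserves the row totals tp+fn and tn+fp and can only raise
either metric — both properties are asserted in the test suite. The
**truth-set error rate** is the fraction of adjudicated discordances
resolved pipeline-correct. Published adjusted genome-wide accuracy figures
for this study design depend on an adjustment formula that was never
printed; the package therefore exposes the reclassification mechanism and
the error rate, on which any such formula can be layered, and validates the
machinery by recovering a planted error rate of 2.16% from synthetic
instances instead of asserting unpublishable endpoints.

## Outcome classification

The classifier is a pure function of (variant calls, gene models,
phenotype, sex): deterministic and order-independent. Only variants
annotated clearly or likely pathogenic qualify; pathogenicity itself is
taken as an input annotation (no ACMG engine — a deliberate non-goal).
Variants are grouped by gene and each gene's *fit* is assessed against its
inheritance mode:

* **AD/XLD**: one qualifying variant suffices.
* **AR**: a homozygous variant, or two heterozygous variants *assumed in
  trans* — singleton sequencing cannot phase, so trans is the default and an
  explicit `cis` flag collapses a pair to a carrier state.
* **XLR**: homozygous or hemizygous; heterozygous-coded calls are promoted
  to hemizygous for male patients. Sex defaults to unknown, in which case
  XLR requires hom/hemi coding.

A *full* fit additionally requires the patient's phenotype to appear in the
gene's disease associations; a genotype-sufficient gene with the wrong
phenotype is an incidental finding, not a diagnosis. A single qualifying
heterozygote in a recessive gene is a carrier state: *partial* when the
gene matches the phenotype. The patient's category follows: any full fit →
diagnosed; else any partial → undiagnosed carrier (relevant); else any
carrier state → undiagnosed carrier (other); else undiagnosed. Carrier
states in non-selected genes are always retained as reportable findings,
including for diagnosed patients.

Three places in this logic were genuinely open and are implemented as
explicit, replaceable policy:

* **Confirmed vs provisional.** The reference breakdown (10 confirmed vs 3
  provisional among 13 subsample diagnoses) implies a pathogenicity-tiered
  rule without printing it. Default policy: a diagnosis whose causal set
  contains at least one clearly pathogenic variant (and nothing below
  likely pathogenic) is confirmed; all-likely causal sets are provisional.
  `classifyPatient(policy = ...)` swaps the rule.
* **Tie-break across fully fitting genes**: higher pathogenicity tier, then
  alphabetical gene symbol — chosen purely for reproducibility.
* **Syndromic matching**: a gene's phenotype set lists every indication it
  can explain, so an Usher-syndrome gene matches an Usher referral while a
  nonsyndromic-RP-only gene does not; this reproduces the canonical
  worked case (a nonsyndromic-RP gene heterozygote in an Usher patient is a
  phenotype-unrelated carrier finding, not a partial diagnosis).

Causal-variant totals are reported under both homozygote-counting
conventions (`n_causal_variants_hom_once`/`_hom_twice`), because the two
conventions genuinely disagree and published totals cannot adjudicate
between them.

## Merging platforms and differencing call sets

Consecutive screening means the genome arm re-evaluates the panel arm's
findings. `mergePlatforms()` takes the per-patient union after
normalisation; when the same variant appears with conflicting zygosity the
later platform wins and the conflict is logged (this is exactly the
re-evaluation of a homozygous call as heterozygous *in trans* with a
newly found deletion).

`normalizeCalls()` trims shared allele prefix/suffix bases and, given a
local reference context, left-shifts pure indels to their minimal
position; it is idempotent, and the test suite proves on an enumeration of
all encodings of a one-base deletion in a repeat context that equivalent
encodings collapse to one canonical form. Without a reference context
(no-reference mode) trimming alone is performed. Null variants (ref = alt
after trimming) are an error.

`sameVariant()` compares sequence variants exactly on (chrom, pos, ref,
alt) and large deletions by reciprocal overlap of their deleted segments,
threshold 0.8 — the standard structural-variant comparison tolerance,
configurable because breakpoint precision varies by caller. Zygosity is
never part of variant identity.

`diffCallsets()` returns the clinically relevant variants (clearly/likely
pathogenic) private to one platform, categorised with a fixed precedence:
large deletion → additional-gene variant (outside the first-tier panel) →
informatics miss → intronic variant → insertion-deletion. The *only* route
into "informatics miss" is an explicit known-miss list: intronic variants
are classified by their region class even when they fall inside the capture
design's ±50 bp intronic flanks, because a captured-but-unreported intronic
variant and an analysable-but-uncalled variant cannot be distinguished from
coordinates alone. A first-tier-panel coding SNV private to one platform
is, within this taxonomy, necessarily an undeclared informatics miss;
`categorizeVariant()` raises rather than guessing, and `diffCallsets()`
records the failure on the affected record.

## Uplift estimation

With the referral population partitioned into strata of size $N_s$, of
which $n_s$ were re-sequenced and $k_s$ newly diagnosed, the expected
number of new diagnoses is $\sum_s N_s k_s / n_s$ and the uplift is that
count as a percentage of the $D$ baseline diagnoses. The denominator is
relative (percent of baseline diagnoses) because that is how a laboratory
compares assays; `absolute = TRUE` reports percentage points of absolute
yield instead.

The confidence interval is a parametric bootstrap: each replicate redraws
$k^*_s \sim \mathrm{Bin}(n_s, k_s/n_s)$ and, by default, also the stratum
prevalences $N^*_s \sim \mathrm{Bin}(N, N_s/N)$ and $D^* \sim
\mathrm{Bin}(N, D/N)$. Simulating "each of the estimated proportions" is
ambiguous — yield-only simulation produces visibly narrower intervals than
the published ones for plausible strata, so the default simulates all three
sources and `simulate_prevalence = FALSE` restores the yield-only reading;
both are first-class. Numerical choices, stated because reproducibility
demands them: one generator seeded once per run, replicate draws consumed
in stratum order, linear-interpolation empirical quantiles (R type 7) at
the 2.5/97.5 percentiles, and the global RNG state restored on exit. Fixed
seed ⇒ bit-identical output.

Because the replicate distribution is discrete, the empirical 97.5th
percentile can sit one support step from the exact binomial quantile
whenever the CDF passes within Monte-Carlo error of the level; the test
suite compares against quantile bands at the level ± 3 standard errors
rather than pretending the estimator is continuous.

The exact stratification behind the published uplift projection (29%,
95% CI 15–45; 12%, 5–20 after bioinformatics-only fixes) was never printed,
so those numbers are validation context, not assertions. The package
instead validates the estimator against closed-form oracles (hand
arithmetic for the point estimate; exact binomial quantiles for the
degenerate single-stratum CI) and by empirical coverage:
`coverageCheck()` simulates studies from known truth and reports the
fraction of nominal-95% intervals covering the true uplift (0.90–0.99
required over 500 experiments at 2000 replicates each in the acceptance
suite). The shipped fixture carries a two-stratum table
(diagnosed/undiagnosed, the minimal reading) and a three-stratum
alternative splitting out relevant-trait carriers for sensitivity
analysis; the three-stratum point estimate lands near 27% with a CI of
roughly 12–44, consistent with the published projection.

## The synthetic data

`studyFixture()` is pure construction — no RNG; two calls are
byte-identical. It reproduces the reference cohort exactly: 562 patients
with the published phenotype distribution and outcome profile (281
diagnosed: 53 AD / 1 XLD / 13 XLR / 91 AR hom / 123 AR comp-het; 158
carrier-finding patients of whom 61 diagnosed via other genes and 59
undiagnosed relevant-trait carriers); a 46-patient subsample (13/33
diagnosed/undiagnosed) whose genome arm adds exactly the 14 printed
panel-missed variants at their printed hg19 coordinates; and concordance
instances with (616 SNV + 2098 hom-ref, 0 fp) and (928 + 3238, 3 fp) —
the 3-fp count chosen because it is the midpoint of the only counts
consistent with a one-decimal specificity of 99.9% at n = 3238.

Reconstruction choices the fixture makes explicit:

* **Companion alleles.** For each printed heterozygous genome-arm variant
  in a recessive gene whose patient became newly diagnosed, the fixture
  supplies one prior panel-detected heterozygous clearly-pathogenic variant
  in the same gene, making the new finding the second allele. The
  homozygous findings and the dominant-gene frameshift need none, and the
  compound-het pair in one Usher gene completes itself. This is the minimal
  patient-level reconstruction that reproduces 11 of 33 re-diagnoses.
* **Synthetic coordinates.** Cohort variants live on invented 10 kb gene
  loci; only the 14 printed records carry real hg19 coordinates, and their
  ref/alt sequences are synthetic reconstructions consistent with the
  printed cDNA changes. No reference genome is required anywhere.
* **Gene models** are a compact illustrative table (26 genes) following
  standard gene–disease associations, not the full clinical panels. The
  additionally captured noncoding region of the ciliopathy gene in the
  capture design is included as its own panel interval with invented
  bounds, since its true bounds were not published.
* One printed record's cDNA start differs by one base between two published
  descriptions of the same deletion; the fixture follows the tabulated
  form.

`generateCohort()` adds sampling noise around the same skeleton: phenotype
and category drawn per patient at the published prevalences (diagnosed
split 10:3 into confirmed:provisional), variant lists constructed so
classification recovers the drawn category exactly, and genome-arm
re-diagnoses drawn at 11/33 for undiagnosed patients. It emulates cohort
composition and outcome structure only — not allele frequencies, linkage,
locus heterogeneity within a patient, sequencing noise, or pathogenicity
misclassification. Passing tests therefore establish the *logic* of the
pipeline on realistically structured inputs, not performance on real
variant-call data. `generateAccuracyInstance()` likewise plants fn/fp/array
errors at known rates for parameter-recovery tests.

Problem sizes in the shipped tests were chosen to make binomial standard
errors small enough for 3-SE recovery bounds while keeping the default
suite around a minute: cohorts of 150–300 for generator round-trips, ~2000
adjudicated discordances for error-rate recovery, 500 experiments × 2000
replicates for coverage.

## Known limitations

* Pathogenicity is consumed, never computed; pedigree/segregation evidence
  and phase (beyond the `cis` flag) are out of scope.
* Concordance scoring is SNV-only, matching the truth-set technology;
  indel/SV concordance would need different matching rules.
* The differ is asymmetric by design (genome-arm exclusives); run it twice
  for both directions.
* Multi-sample VCFs and breakend notation are unsupported; the VCF subset
  is documented in `?readCallset`, with a TSV dialect as the equally
  supported alternative.
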