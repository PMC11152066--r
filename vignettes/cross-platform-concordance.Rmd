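---
title: "Cross-platform genotype concordance: models, parameters and design choices"
author: "GenoConcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform genotype concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenoConcord)
```

# Scope

GenoConcord answers three questions about a study that genotypes the same
populations on a SNP array and by low-coverage whole-genome sequencing
(WGS): how well the platforms agree, how the array's ascertained marker
panel distorts allele-frequency-based statistics, and how to merge the two
into one analyzable panel. A seed-deterministic simulator of the whole
two-platform design provides ground truth for validating every statistic.
This vignette records the models, the parameters that matter, and the
design decisions that were genuinely open.

# Data model

A `GenotypeMatrix` extends `RangedSummarizedExperiment`: variants are rows
(a `GRanges` restricted to biallelic single-nucleotide variants, with
single-base `ref`/`alt` metadata columns), samples are columns, and the
`calls` assay holds alternate-allele dosage 0/1/2 with `NA` as the missing
sentinel. Missingness is never conflated with dosage 0, and all
arithmetic masks it explicitly. Optional per-call read depth lives in a
`depth` assay and per-variant Phred-scaled quality in `rowData()$qual` —
the two covariates the concordance model uses.

Readers cover VCF (via vcfR; multiallelic and non-SNV records are skipped
*and counted*, half-calls become missing), the variant-major PLINK 1
bed/bim/fam binary layout (the A1 allele is treated as the alternate
allele; the 2-bit codec is implemented against the published byte layout
and checked byte-by-byte in tests), and BED probe maps (0-based half-open
single-base intervals; position = start + 1).

## Filtering

`filterGenotypes()` fixes the stage order: samples above the `mind`
missing-rate bound are dropped first; variant missing rates are then
*recomputed* before applying the `geno` bound; the minor-allele-frequency
bound comes last and is computed from called genotypes only. The order
matters — removing a bad sample can rescue a variant — and is recorded in
the returned `filterReport` so deviations are visible. Emptying the matrix
is deliberately a warning, not an error: pipelines should be able to
report an empty stage rather than die.

# Concordance statistics

All cross-platform statistics operate on a `PairedCalls` object built by
`pairPlatforms()`, which intersects two matrices on (chromosome, position)
and harmonizes alleles: exact matches kept; swapped ref/alt recoded
`2 - d`; strand-complement matches flipped; palindromic (A/T, C/G) sites
whose resolution would need a strand flip dropped and counted (their
orientation is unknowable from genotypes alone — the safe default);
genuine third alleles dropped and counted.

Definitions (per individual, over harmonized sites):

* concordance rate = concordant / (concordant + discordant) over co-called
  sites; individuals with no co-called site get `NA`, never 0;
* allele sensitivity = concordant alternate-allele-carrying sites /
  sites where *either* platform carries the alternate allele (symmetric in
  the platforms);
* class sensitivity (heterozygote or homozygous-alternate): over co-called
  sites where either platform calls the class, the fraction at which a
  given platform calls it. The literature rarely writes this down as a
  formula; this definition was an open choice, made symmetric-denominator
  so the two platforms are directly comparable, and is stated prominently
  here because other choices (e.g. conditioning on the array call as
  truth) give different numbers.

A discordant het-vs-hom pair counts as one discordant site — no partial
credit — because downstream analyses consume hard genotype calls.

`replicateReproducibility()` reports both the mean pairwise concordant
count (with the percent form taken over the *panel size*, the convention
used when array replicate runs are compared after filtering) and the
stricter all-replicates-agree count, because summary numbers in the field
are sometimes one and sometimes the other.

## The depth/quality model

`fitConcordanceLogit()` fits a binomial-logit GLM of the per-observation
concordant/discordant outcome on depth (per call) or site quality (per
variant), mean-centered and scaled to unit variance; the IRLS tolerance is
1e-8 with at most 50 iterations, and complete separation is detected and
flagged. Depth and quality are *never* fitted together: quality is
computed from depth, so the two are collinear by construction. The model
is fixed-effects only; repeated observations within an individual are
acknowledged by the optional `byIndividual = TRUE` stratified fits rather
than a random intercept, a deliberate simplification (the marginal slope
is the quantity of interest; a mixed model would need an additional
dependency and changes the estimand). McFadden's pseudo-R² is reported as
the fit summary.

# Ascertainment-bias diagnostics

`observedHet()` is per-individual observed heterozygosity over non-missing
calls. `foldedSFS()` tallies minor-allele counts `min(ac, 2k - ac)` over
complete-case sites only — no hypergeometric down-projection; projection
machinery belongs to dedicated SFS tools, and complete-case spectra are
exact for the comparison the package makes (panel vs genome-wide sites on
the same samples). The monomorphic bin is reported for accounting but
excluded from `sfsDistance()`, which is the total-variation distance
between spectra normalized over polymorphic bins — panel content fixes
what is polymorphic, so including bin 0 would measure panel size, not
shape. `subsampleSites()` draws sites uniformly without replacement,
seed-stamped in the output metadata, for diversity comparisons at matched
panel sizes.

# Population structure

`wcFst()` implements the Weir–Cockerham variance components for r diploid
populations from per-population sample sizes, allele frequencies and
observed heterozygote proportions. The headline estimate is always the
ratio of sums `sum(a)/sum(a+b+c)`; the mean of per-locus ratios is
computed too (it is sometimes quoted) but never used as the headline.
Negative per-locus components are retained — truncating them biases the
weighted estimate. Loci with an entirely missing population are skipped
with a count; loci monomorphic over all populations are excluded from the
sums. A brute-force reimplementation of the component formulas is kept in
the test suite and must agree to 1e-12.

`pcaGenotypes()` mean-imputes missing calls per variant, centers (scaling
optional, off by default — the common default for genotype PCA), and takes
the SVD. Imputation is confined to PCA: F_ST and spectra always use called
genotypes only, because mean imputation shrinks frequency variance and
would bias both.

`fstRegression()` is ordinary least squares over the lower-triangle pairs
of two pairwise-F_ST matrices; a slope above 1 means the y-platform
magnifies differentiation relative to the x-platform.

# Merging

`mergeDatasets()` runs the staged pipeline: harmonize over the variant
intersection → drop third-allele and ambiguous palindromic sites →
intersect with a concordance-validated site list → intersect with a
Mendelian-inheritance site list → drop variants above the missingness
bound computed over the *union* of samples → LD prune → concatenate
samples. The validated→Mendelian→missingness order is fixed and logged
(narrative descriptions of such pipelines rarely pin the order; fixing and
reporting it makes runs comparable), and the `MergeReport` counts
telescope exactly to the final variant total on every run.

Merged variants are re-oriented to a canonical representation — the
alphabetically smallest of the four equivalent (strand × allele-order)
representations, dosages recoded when ref/alt exchange — so that
`merge(A, B)` and `merge(B, A)` produce identical variant identities and
genotypes up to sample order. Site lists are matched after the same
canonicalization.

Two LD pruners are provided, matching the two idioms in common use:
`ldPrunePairwise()` (window of 50 SNPs advancing by 10; repeatedly remove
the greater-missing member — tie: later position — of the
strongest-correlated pair above r² = 0.3) and `ldPruneVif()` (window of 75
kb of physical span advancing by 50 SNPs; repeatedly remove the variant
with the largest variance-inflation factor, computed from the
ridge-stabilized (epsilon 1e-8) inverse correlation matrix, until all VIF
≤ 2). Both are deterministic; zero-variance variants are treated as
uncorrelated rather than undefined.

# The simulator

`simConfig()` fixes the study conditions; the defaults *are* the study
design the package targets and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| populations | 3 native + 3 invasive | two diverged groups |
| `fNative` | 0.05 | Balding–Nichols drift of the native branch |
| `fInvasive` | 0.20 | additional bottleneck drift, compounded on the native branch |
| `samplesPerPop` | 5 | study samples per population |
| `nLoci` | 20,000 | candidate loci (uniform(0.01, 0.99) ancestral frequency) |
| `discoveryPerGroup` | 18 | discovery samples per group for ascertainment |
| `ascMafMin` | 0.10 | discovery-sample MAF a locus needs to enter a pool |
| `panelSize` | 8,000 | array SNPs, half from each group's pool |
| `chipError` / `chipMissing` | 0.005 / 0.01 | array per-call error / missingness |
| `wgsDepth` | 6.4 | mean Poisson depth (per-sample overrides allowed) |
| `wgsBaseError` | 0.01 | per-read error in the likelihood model |

The population sizes (6 populations × 5 samples) and mean depth mirror a
realistic two-platform comparison at desk scale; the candidate-locus and
panel counts are scaled to keep the full validation suite under a minute
while leaving thousands of sites per spectrum bin. The real chip this
design emulates was ascertained from unequal discovery panels (a few dozen
native, over a hundred invasive specimens); the simulator uses symmetric
discovery samples because the balanced-panel rule, not the discovery n,
drives the bias pattern.

Sequencing calls are flat-prior maximum likelihood over the three
genotypes with alternate-read probabilities `{e, 1/2, 1 - e}`; likelihood
ties break toward the homozygote matching the majority read (deterministic
and conservative for heterozygote calling); per-call quality is the
Phred-scaled gap between the best and second-best log-likelihood, and the
VCF QUAL column carries the per-site mean (VCF has one QUAL per site; the
per-call matrix is kept in `metadata()$callQual` for the logistic model).
Zero-depth calls are missing. Simulated loci are unlinked and are spaced
25 kb apart so the default LD-pruning windows see them as independent;
LD-pruner tests construct correlated columns explicitly instead.

Determinism: every generator operation derives its RNG stream from
`cfg$seed` plus a fixed per-operation offset, so any operation can be
re-run independently and `makeScenario()` fixtures are byte-identical
across runs of the same config.

## What the simulator does and does not emulate

It reproduces the statistical structure the analysis assumes: hierarchical
divergence (invasive populations drift through the native branch, then a
bottleneck), intermediate-frequency balanced ascertainment, array error,
and depth-limited heterozygote undercalling. On simulated data the package
reproduces the qualitative platform contrasts seen in real array/WGS
comparisons: heterozygote sensitivity of ~1.5× WGS trails the array by
tens of percentage points; homozygous concordance exceeds heterozygous
concordance; the ascertained panel's folded SFS loses its singleton mass;
array-based pairwise F_ST regresses on genome-wide WGS F_ST with slope
above 1; and the log-odds of concordance rise with depth. One nuance found
in validation: with a balanced panel the *relative* heterozygosity
inflation (panel het / genome-wide het) is consistently larger for the
bottlenecked group, while the absolute difference need not be — the native
group's baseline heterozygosity is higher. Assertions are therefore made
on the relative form.

It does not emulate read-level artifacts (mapping error, duplicates,
indels), linkage, batch effects between sequencing centers, or
reference-genome liftover. Passing tests on simulated data therefore
validate the estimators and the pipeline logic, not the wet-lab error
model of any particular platform.

# Numerical choices and degenerate inputs

* Undefined rates (zero denominators: no co-called sites, no
  alternate-allele sites, monomorphic spectra) propagate as `NA` and are
  flagged — never reported as 0.
* The logistic fit refuses a zero-variance covariate and flags complete
  separation instead of returning a divergent slope.
* Beta draws with drift F ≤ 1e-6 are clamped (the Beta shapes diverge) and
  the ancestral frequencies returned with a warning.
* Chromosome output order follows first appearance unless an explicit
  order is declared; writers reject undeclared chromosomes rather than
  guessing a sort.
* VIF windows with singular correlation matrices are ridge-stabilized with
  epsilon 1e-8, which sends exact duplicates to effectively infinite VIF —
  the intended behavior.

# Validation summary

The test suite validates every operation against an independent route:
hand-enumerated toy examples for each counting statistic; byte-level
round trips for both binary formats; brute-force reimplementations of the
concordance counts, the variance components (1e-12) and the greedy pruner;
closed-form checks of the logistic two-cell solution and the exact F_ST
limits (fixed difference: a = 0.5, b = c = 0, theta = 1); Balding–Nichols
parameter recovery (F = 0.1 recovered within [0.08, 0.12] from 5,000 loci
× 50 diploids per population); and the qualitative platform-bias patterns
above on the default simulated study. All empirical claims in this
vignette are computed by that suite or by `scripts/acceptance.R`.
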