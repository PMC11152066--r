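# GenoConcord

Cross-platform genotype concordance, SNP-array ascertainment diagnostics,
and array + low-coverage-WGS dataset merging, in one Bioconductor-style R
package.

## The problem

Population-genetic studies of non-model organisms increasingly mix two
genotyping platforms for the same populations: a fixed SNP array (cheap,
reproducible, but built from an ascertained marker panel) and low-coverage
whole-genome sequencing (unbiased site discovery, but noisy genotype calls —
a true heterozygote sequenced at 2–3× is often seen in reads of only one
allele and miscalled homozygous). Before the two data types can be analyzed
together, three questions must be answered:

1. **How well do the platforms agree?** Per-individual and per-site
   concordance, allele sensitivity, heterozygote sensitivity, and how
   concordance depends on sequencing depth and site quality.
2. **How biased is the array?** A panel ascertained for
   intermediate-frequency alleles — balanced between diverged population
   groups — inflates observed heterozygosity (especially for bottlenecked
   populations), depletes rare bins of the folded site-frequency spectrum,
   and shifts F_ST.
3. **Can the datasets be merged?** Allele harmonization (strand flips,
   ref/alt swaps, third-allele exclusion), concordance-validated site
   lists, missingness filtering and LD pruning, with an auditable
   stage-by-stage report.

GenoConcord implements all three, plus a ground-truthed simulator of the
whole two-platform design, so that every statistic can be validated against
known truth.

## The statistics

* **Concordance** for an individual genotyped on both platforms is
  `concordant / (concordant + discordant)` over co-called sites; missing
  calls are tracked separately and never counted as disagreement.
  **Allele sensitivity** is the number of concordantly called
  alternate-allele-carrying sites over the number of sites where either
  platform sees the alternate allele. **Class sensitivity** (e.g.
  heterozygote) is, over co-called sites where either platform calls the
  class, the fraction at which a given platform calls it.
* **Depth/quality dependence** is modeled by a binomial-logit GLM of the
  concordant/discordant outcome on mean-centered, unit-variance depth or
  quality, reported as an odds ratio per scaled unit.
* **Weir–Cockerham F_ST**: per-locus variance components *a* (among
  populations), *b* (among individuals within populations) and *c* (within
  individuals), combined across loci as the weighted ratio of sums
  `theta_W = sum(a) / sum(a+b+c)`.
* **Folded SFS**: counts of minor-allele counts `min(ac, 2k - ac)` over
  complete-case sites of `k` diploids, compared across panels by
  total-variation distance on the polymorphic bins.
* **Simulator**: Balding–Nichols population frequencies
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` around uniform ancestral frequencies, with
  a native branch (F = 0.05) and a compounded bottleneck branch (F = 0.20);
  Hardy–Weinberg genotypes; MAF-threshold panel ascertainment balanced
  between groups; array calls with small error/missingness; sequencing
  calls from Poisson(λ = 6.4) read depth via flat-prior maximum-likelihood
  genotyping with Phred-scaled quality.

## Worked example

```r
library(GenoConcord)

cfg   <- simConfig(seed = 7)                 # 6 pops x 5 samples, 8,000-SNP panel
truth <- ascertainPanel(simulateTruth(cfg), cfg)
chip  <- genotypeChip(truth, cfg)
wgs   <- genotypeWgs(truth, cfg)             # mean depth 6.4x
chip
#> GenotypeMatrix: 8000 variants x 30 samples
#>   genotyping rate: 0.9898

pc <- pairPlatforms(chip, wgs,
                    data.frame(sampleA = sampleIds(chip),
                               sampleB = sampleIds(wgs)))
cs <- concordanceSummary(pc)
round(100 * mean(cs$concordanceRate), 2)
#> [1] 94.23

hs <- classSensitivity(pc, "het")
round(100 * c(chip = mean(hs$sensitivityA), wgs = mean(hs$sensitivityB)), 2)
#>  chip   wgs
#> 94.98 89.53

fitConcordanceLogit(pc, "depth")
#> Binomial-logit concordance model (237180 observations)
#>   slope 0.7874 (SE 0.0106), OR per scaled unit 2.198
#>   covariate scaling: mean 6.412, sd 2.520; McFadden R2 0.0608

wcFst(chip, colData(chip)$group)
#> Weir-Cockerham F_ST over 7992 loci, 2 populations
#>   weighted theta = 0.05335 (mean of ratios 0.04505)
```

The mean cross-platform concordance of 94% says that at a typical co-called
panel site the two platforms report the same dosage; the heterozygote
sensitivities (chip 95.0% vs WGS 89.5% at 6.4×, a gap that widens to tens of
percentage points below 2×) quantify the heterozygote undercalling of
shallow sequencing; the odds of concordance rise by a factor of 2.2 per
standard deviation of depth; and the between-group weighted F_ST of 0.053
reflects the simulated native/invasive divergence.

Merging runs as one audited pipeline:

```r
sc      <- siteConcordance(pc)
valid50 <- validatedSites(sc, 0.5)           # sites concordant in >= 50% of samples
chipM   <- chip; colnames(chipM) <- paste0(sampleIds(chip), "_chip")
wgsM    <- wgs;  colnames(wgsM)  <- paste0(sampleIds(wgs), "_wgs")
merged  <- mergeDatasets(chipM, wgsM, validated = valid50, genoMax = 0.2)
metadata(merged)$mergeReport                 # telescoping stage counts
```

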