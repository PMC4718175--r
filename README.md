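# pairMHC

Tests of MHC-dependent social mate choice in small, male-biased bird
cohorts — the situation created by conservation translocations, where a
surplus of territory-holding males briefly frees females to choose and the
social pairs formed in the first months are a clean readout of preference.

The package is aimed at molecular ecologists working with the typical data
of such systems: a pool of ~10 MHC class I variants scored as
presence/absence per bird (locus assignment unknown because several loci
co-amplify), ~30 microsatellite loci, an amino-acid alignment of the
variant sequences with codon masks for the peptide-binding region (PBR) and
positively selected sites (PSS), and a table of observed pairings and their
fates one year on.

## What it computes

**Metrics.** Per bird: MHC diversity (repertoire size) and standardized
microsatellite heterozygosity Hs (proportion of heterozygous typed loci
over the mean population observed heterozygosity of those loci; cohort mean
= 1). Per dyad: allele sharing

&nbsp;&nbsp;&nbsp;&nbsp;*S*<sub>xy</sub> = 2*N*<sub>xy</sub> / (*N*<sub>x</sub> + *N*<sub>y</sub>),

mean codon-masked amino-acid p-distance over all cross-repertoire variant
pairs, and Queller–Goodnight relatedness *r* (ratio-of-sums over loci,
averaged over the two focal directions).

**Inference.** The core engine compares the *n* observed pairs against the
*n*² − *n* other female × male combinations ("dyads") with a permutation
test on the two-group ANOVA *F* (means) or on |Δvariance|:
*p* = proportion of relabelings whose statistic ≥ the observed one, ties
extreme, 10⁵ resamples by default. Two null universes are available —
uniform label shuffling over all cells, and uniform random re-matching —
plus an exhaustive enumeration oracle for small designs. Around the engine:
a binomial logit model of male pairing status (MHC diversity + age class +
Hs + island) with Nagelkerke *R*², per-allele Fisher exact tests with
Bonferroni correction, Welch *t* / rank-sum comparisons, and divorce
analyses. A synthetic-cohort generator with configurable age,
heterozygosity, MHC-diversity and MHC-compatibility effects makes the whole
pipeline testable and power-checkable without field data.

## Worked example

Simulate a translocated cohort of 34 males and 24 females in which females
actively prefer MHC-dissimilar males (`effectCompat = 5`), then ask whether
the pair-versus-dyad test detects the preference:

```r
library(pairMHC)

cfg    <- cohortConfig(nMales = 34, nFemales = 24, effectCompat = 5, seed = 2024)
cohort <- simulatePairing(genCohort(cfg, island = "denis"), cfg)
cohort
#> Cohort: 58 individuals (34 M, 24 F) on denis
#>   30 microsatellite loci; 10 MHC variants; 58 birds MHC-typed
#>   21 pairing records (21 observed pairs)

d <- buildDyadStatistic(cohort, "sxy")
d
#> DyadStatistic 'sxy': 21 pairs vs 420 dyads (21 F x 21 M)
#>   pair mean 0.384, dyad mean 0.4912

randomizationTest(d, "anova_f", nPerm = 100000,
                  mode = "matching_constrained", seed = 1)
#> RandTestResult (anova_f, matching_constrained): observed = 4.682, p = 0.00278 (278/100000)
```

The 21 observed pairs share fewer MHC alleles (mean *S*<sub>xy</sub> =
0.38) than the 420 possible alternative dyads (0.49), and only 278 of 10⁵
random re-matchings produce an *F* at least as large — the injected
compatibility preference is detected at *p* ≈ 0.003. With all effects at 0
the same pipeline yields uniform *p*-values (that calibration is part of
the test suite). The remaining stages run the same way:
`fitPairingGLM(cohort)` prints the coefficient table with odds ratios and
Nagelkerke *R*², `allelePairStatusTests(cohort)` the per-allele Fisher
table, and `divorceAnalysis(cohort)` the divorce comparisons;
`runPipeline(analysisConfig(...))` executes the whole battery per island
and writes delimited results, a markdown report and a reproducibility
manifest. A thin command-line wrapper is installed at
`inst/scripts/pairmhc.R`.

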