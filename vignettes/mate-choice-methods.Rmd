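---
title: "Testing MHC-dependent social mate choice: models and methods"
author: "pairMHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing MHC-dependent social mate choice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairMHC)
```

## The problem

When a bird population is founded by translocation, more males than females
are typically released, habitat is briefly unsaturated, and every male can
hold a high-quality territory. This removes most of the constraints that
normally mask mate choice, so the social pairs that form in the first months
are an unusually clean readout of female preference. The question this
package addresses is whether those pairings depend on major
histocompatibility complex (MHC) class I characteristics, under three
competing mechanisms:

* **diversity** ("good genes as heterozygosity"): females prefer males
  carrying many MHC variants;
* **good genes sensu stricto**: pairing status tracks the presence of
  specific individual alleles;
* **compatibility**: females prefer males whose MHC complements their own,
  which would shift (or narrow) the distribution of pair similarity relative
  to random expectation.

A fourth question is whether established pair bonds are more likely to break
("divorce") when the male is MHC-poor or the pair MHC-similar.

The data situation is characteristic of such systems: a pool of roughly ten
MHC class I variants typed as presence/absence per bird (several loci
co-amplify, so locus-level genotypes are unavailable), around 30
microsatellite loci for neutral expectations, and an amino-acid alignment of
the variant sequences with codon masks for the peptide-binding region (PBR)
and for putatively positively selected sites (PSS).

## Genetic metrics

All dyadic metrics are functions of two birds, symmetric in their arguments.

**MHC diversity** is the repertoire size: the number of named variants a
bird carries (`mhcDiversity()`). Since a diploid locus contributes at most
two alleles, a bird with $k$ variants must be amplified from at least
$\lceil k/2 \rceil$ loci (`impliedMinLoci()`).

**Allele sharing** between birds $x$ and $y$ is
$$S_{xy} = \frac{2 N_{xy}}{N_x + N_y},$$
where $N_{xy}$ counts shared variants and $N_x, N_y$ are repertoire sizes.
$S_{xy} \in [0,1]$, and equals 1 exactly when the repertoires coincide as
sets (`alleleSharing()`).

**Codon-masked amino-acid p-distance** between two variant sequences is the
proportion of masked codon positions at which the residues differ
(`pDistance()`). The dyadic version (`dyadMeanPDistance()`) averages the
p-distance over *all* cross-repertoire variant pairs $(a, b)$ with $a$ in
$x$'s repertoire and $b$ in $y$'s. Shared variants are included and
contribute zero; whether the original analyses excluded them is not
documented, so inclusion is the default (it keeps the statistic a mean over
a fixed-size universe and makes it a smooth counterpart of $1 - S_{xy}$).

**Standardized heterozygosity** of a bird is
$$H_s = \frac{\text{proportion of typed loci that are heterozygous}}
             {\text{mean population observed heterozygosity over those same loci}},$$
so with complete typing the cohort mean is exactly 1. Standardization uses
*observed* heterozygosity; this matches the conventional Hs definition for
multilocus microsatellite panels.

**Queller–Goodnight relatedness**: with focal bird $x$ carrying alleles
$(a,b)$ and partner $y$ carrying $(c,d)$ at a locus with reference
frequencies $p$,
$$\text{num} = \tfrac12(\delta_{ac}+\delta_{ad}+\delta_{bc}+\delta_{bd}) - p_a - p_b,
\qquad \text{den} = 1 + \delta_{ab} - p_a - p_b .$$
Numerators and denominators are summed over usable loci before dividing, and
the estimate averages the $x$-focal and $y$-focal ratios. Expectations are
0.5 for parent–offspring and full sibs, 0.25 for half sibs, 0 for unrelated
dyads, and the self-comparison is exactly 1. Three numerical rules matter in
practice:

* loci monomorphic in the reference are skipped (their denominator terms
  degenerate);
* loci untyped in either bird are skipped;
* a direction's *summed* denominator can still vanish (a focal bird
  heterozygous only at loci whose two alleles sit at frequency 1/2); the
  estimator then falls back to the pooled form
  $(\sum \text{num}_x + \sum \text{num}_y) / (\sum \text{den}_x + \sum \text{den}_y)$,
  which is the original ratio-of-sums estimator and is almost surely
  non-degenerate.

Reference allele frequencies (`populationReference()`) are computed from all
genotyped birds of the island under analysis, focal dyad included, which
matches common usage of relatedness software; `excludeIds` supports
leave-pair-out frequencies for sensitivity analyses.

## The pair-versus-dyad randomization engine

The central design treats the $n$ observed social pairs as $n$ marked cells
in the $n \times n$ matrix of all paired-female $\times$ paired-male
combinations; the remaining $n^2 - n$ cells are the "dyads" (19 pairs give
342 dyads, 18 give 306). `buildDyadStatistic()` fills this matrix for a
chosen metric; `randomizationTest()` compares the pair cells against the
dyad cells with a one-way two-group ANOVA $F$ statistic (or, for
`varianceRandomizationTest()`, the absolute difference of the two group
variances), then re-labels which cells count as "pairs" and reports
$$p = \frac{\#\{\text{resamples with statistic} \ge \text{observed}\}}{\#\text{resamples}},$$
ties counting as extreme. The default resample count is $10^5$.

Two null universes are implemented because the historical tooling is
ambiguous about which was used:

* `label_shuffle` (default): the pair labels are shuffled without
  replacement over all $n^2$ cells, i.e. a uniform $n$-subset is drawn;
* `matching_constrained`: a uniform random perfect matching is drawn, so
  every resample is itself a valid one-to-one pairing.

The matching-constrained null is the biologically faithful one — under
random mate choice the observed configuration *is* a random matching — and
it is exactly calibrated against the simulator's null by construction. The
label-shuffle null is what "resampled without replacement" describes
operationally in spreadsheet-based randomization tools. When row or column
effects exist in the metric matrix (e.g. a male whose rare repertoire makes
him dissimilar to every female), the two universes can differ; both are
available and should be reported when they disagree qualitatively. The
package's calibration and power suites use `matching_constrained` for this
reason.

Numerical conventions: when the within-group variance is zero the $F$
statistic is defined as 0 if the group means also agree and as an infinite
sentinel otherwise; the sentinel ranks above every finite $F$ in the tail
count, and constant data therefore give $p = 1$. The reported $p$ is the
plain proportion (matching the historical definition); the
$(k+1)/(B+1)$ correction is deliberately not applied, so $p = 0$ is
possible at finite $B$.

`exhaustiveTest()` enumerates every admissible relabeling — all
$\binom{n^2}{n}$ subsets or all $n!$ matchings, within a budget of $10^6$ —
and is the oracle against which the Monte-Carlo engine is verified on small
instances. `groupRandomizationTest()` exposes the same engine for plain
two-group designs (divorced versus stable birds).

## Inferential models

**Male pairing status** is modelled as
`paired ~ mhcDiv + ageClass + hs + island` with binomial errors and logit
link (`fitPairingGLM()`), treatment contrasts with reference level "young"
and the alphabetically first island. The fit reports per-term Wald $z$ and
$p$, odds ratios $e^B$ with Wald 95% CIs $e^{B \pm 1.96\,SE}$, the
likelihood-ratio test against the intercept-only model, and Nagelkerke's
$$R^2 = \frac{1 - \exp\{(D_{\text{model}} - D_{\text{null}})/n\}}
             {1 - \exp\{-D_{\text{null}}/n\}}.$$
An optional quadratic MHC-diversity term probes an intermediate-optimum
preference. Apparent complete separation is refused with the offending term
named rather than reported with meaningless standard errors. (Historical
reports of this model layout sometimes label the Wald $z$ column
"chi-square"; the package reports $z$.)

**Per-allele tests** (`allelePairStatusTests()`): for each variant a
$2 \times 2$ table of carriage against pairing status, two-sided Fisher
exact $p$ by summation of hypergeometric point probabilities not exceeding
the observed table's (the common convention; conventions differ, hence
documented), the sample odds ratio with a flagged 0.5 continuity substitute
when a margin cell is empty, and a Bonferroni critical $p = \alpha/m$ over
the $m$ variants tested (10 variants at $\alpha = 0.05$ give 0.005).

**Divorce** (`divorceAnalysis()`): censored pairings (a member unresighted,
"faithful until death") are excluded; male and female MHC diversity are
compared between divorced and stable individuals with the shared
randomization engine (ANOVA-$F$, label shuffling over group membership),
and pair similarity ($S_{xy}$, PBR and PSS p-distance) with rank-sum tests
using midranks and the continuity- and tie-corrected normal approximation.

## The synthetic-cohort generator

`genCohort()` emulates the study conditions of a male-biased island
translocation so that every analysis stage can be validated end to end:

| parameter | default | rationale |
|---|---|---|
| `nMales`, `nFemales` | 34, 24 | release-cohort scale of a typical island translocation |
| `propOld` | 0.5 | two field-assignable age classes, balanced |
| `nMsatLoci`, `msatAllelesPerLocus` | 30, 6 | microsatellite panel of the study system; per-locus spectra drawn from a symmetric Dirichlet(1) and genotypes from Hardy–Weinberg proportions |
| `mhcPoolSize`, `mhcMin`, `mhcMax` | 10, 2, 8 | the detected class I variant pool; repertoire sizes uniform on [2, 8] |
| `nCodons` | 85 | a 255-bp coding region translates to 85 residues |
| `maskSizes`, `maskOverlap` | pbr = 16, pss = 7, overlap = 3 | 7 of 85 codons typically emerge as PSS with 3 inside the PBR; the PBR size itself is not published for this system, 16 is a plausible exon-3 contact-codon count |
| `propFemalePaired` | 0.85 | roughly the fraction of females observed paired after release |
| `divorceBaseRate` | 8/37 | observed divorce fraction among followed pairings |
| effects | 0 | all choice and divorce effects off: the null process |

Variant sequences are built around a random consensus with a 0.5
substitution probability at masked codons against 0.02 in the background,
giving the masks the elevated diversity that balancing selection leaves on
antigen-binding sites. Pool frequencies are uniform by default;
`poolDirichletAlpha` draws unequal frequencies when wanted.

`simulatePairing()` lets females, in uniform random order, each pair with
probability `propFemalePaired`; a pairing female picks among still-unpaired
males with probability proportional to
$\exp\{\beta_{\text{age}}\,\text{old} + \beta_{hs}\,H_s +
\beta_{\text{div}}\,\text{div} + \beta_{\text{compat}}(1 - S_{xy})\}$
(computed with a softmax shift for numerical stability, so effects like
"+50" behave as dominance limits). Divorce is drawn per pair with log-odds
$\text{logit}(\texttt{divorceBaseRate}) -
\beta_{\text{divorce}}(\text{male div} - \bar{k})$, centred on the
pool-expected repertoire size $\bar{k} = (\texttt{mhcMin}+\texttt{mhcMax})/2$
so that `divorceBaseRate` keeps its meaning when the effect is on. A
uniform arrival order with sequential greedy matching was chosen because no
arrival process is documented; it is simple, reproducible, and under zero
effects reduces to a uniform random perfect matching — exactly the null the
randomization engine assumes. Unpaired birds of both sexes are retained.

All randomness flows from one master seed through labelled sub-streams
(`deriveSeed()`), so stages are independently re-runnable and whole
pipelines are byte-reproducible.

`genRelatedDyads()` builds parent–offspring, full-sib, half-sib and
unrelated genotype pairs by Mendelian transmission at the cohort's true
frequencies; it exists to verify the relatedness estimator's pedigree
expectations, and its reference uses Hardy–Weinberg expected
heterozygosities.

**What the simulator does not emulate**: spatial territory structure,
mortality beyond a resighting flag, extra-pair paternity, genotyping error,
null alleles, and linkage between loci. Passing tests on simulated cohorts
therefore validate the *statistical machinery* — calibration, power
ordering, estimator recovery — not the field realism of any particular
dataset.

## Validation suite design

The test and acceptance suites use problem sizes chosen to make Monte-Carlo
error negligible relative to the tolerance while keeping a default run
short: 20 random 3-pair instances at $10^4$ resamples for the
Monte-Carlo-versus-exhaustive comparison; 200 null cohorts of 20 pairs at
$10^3$ resamples for type-I calibration (rejection rate checked against the
exact binomial 99% interval around 0.05, uniformity with a 1%-level
Kolmogorov–Smirnov bound); 500 dyads per pedigree class for relatedness
recovery within $\pm 0.05$; 2000 males for logit coefficient recovery
within $\pm 0.2$; and 100 replicates per effect level for the power
ordering of the compatibility test. The compatibility effect levels
$\{0, 3, 8\}$ were fixed a priori to span the null, a mid-power regime and
a near-saturated regime for a 20-pair design.

## Known limitations

* The pair-versus-dyad universe is restricted to *paired* birds (the printed
  dyad counts imply this); preferences expressed through remaining unpaired
  are visible only to the pairing-status GLM, not to the similarity tests.
* With $\sim$20 pairs the variance randomization has limited power against
  subtle optimal-similarity preferences; the power suite quantifies this for
  the mean test only.
* Fisher's exact test with a Bonferroni correction over 10 variants is
  conservative; with $\sim$70 males only strong per-allele effects are
  detectable.
* The Queller–Goodnight estimator is noisy at 30 microsatellite loci for any
  single dyad ($SD \approx 0.12$); only group comparisons are meaningful.
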