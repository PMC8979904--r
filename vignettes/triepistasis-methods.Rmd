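---
title: "Estimating three-way additive QTL interactions in doubled haploid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating three-way additive QTL interactions in doubled haploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triepistasis)
```

## The problem

In a doubled haploid (DH) population every line is fully homozygous, so
each marker locus carries one of the two parental alleles and can be coded
−1 or +1.  Quantitative traits measured on such lines are shaped not only
by additive effects of individual loci but also by epistatic interactions
between loci.  Pairwise (additive × additive, *aa*) interactions are
routinely modelled; three-way (additive × additive × additive, *aaa*)
interactions are usually ignored, although nothing guarantees they are
negligible.  This package estimates the *total* aaa effect of the loci
controlling a trait by two routes and compares them:

* a **phenotypic estimator** that uses only the trait distribution, via
  groups of extreme lines;
* a **genotypic estimator** that regresses the trait on selected marker
  columns and their pairwise and triple products.

## The phenotypic estimator

Let $\bar L_{\min}$ and $\bar L_{\max}$ be the trait means of the groups
of lines with minimal and maximal expression, and $\bar L$ the mean over
all lines.  The total aaa effect is estimated as

$$\widehat{aaa}_p = \tfrac12(\bar L_{\max} + \bar L_{\min}) - \bar L.$$

The idea is that the extreme groups consist, ideally, of lines carrying
only trait-decreasing (resp. -increasing) alleles, in which case
even-order contributions cancel in the half-sum and the residual offset
from the population mean reflects interaction effects.  The estimator is
location-invariant and scale-equivariant.

Two caveats are worth stating plainly.  First, the size of the extreme
groups is not canonical.  `select_extreme_groups()` defaults to a
fraction 0.05 of the population (at least one line per group), because
small groups best approximate the "only decreasing/increasing alleles"
ideal; the fraction is exposed (`extreme_fraction`) and results do
depend on it.  Ties at a group boundary are broken by line-id order so
selection is reproducible.  Second, under the ±1 product coding used by
the regression model below, the symmetric half-sum form cancels
*odd*-order (additive and triple-product) contributions of loci fixed at
opposite values in the two extreme groups, not even-order ones.  The
estimator is nevertheless implemented exactly in its classical printed
form; the balanced-design contrast (below) makes the cancellation visible
and a difference form is provided as a diagnostic.

The number of segregating genes ("effective factors") reported alongside
$\widehat{aaa}_p$ is computed with a classical Wright-type range
estimator, $K = \operatorname{round}\{(\bar L_{\max}-\bar
L_{\min})^2/(8\,s_y^2)\}$.  This is a documented stand-in: the
effective-factor literature contains several variants, and
`count_effective_factors()` accepts a replacement function so another
formula can be plugged in without touching the pipeline.

## The genotypic estimator

For $p$ selected markers $l_1,\dots,l_p$ the trait is modelled as

$$\mathbf y = \mathbf 1\mu + \mathbf X\boldsymbol\beta +
\mathbf Z\boldsymbol\gamma + \mathbf W\boldsymbol\delta + \mathbf e,$$

where the columns of $\mathbf X$ are the selected ±1 marker vectors, the
columns of $\mathbf Z$ are all $\binom p2$ pairwise elementwise products,
and the columns of $\mathbf W$ are all $\binom p3$ triple products.  The
coefficients $\boldsymbol\beta$, $\boldsymbol\gamma$ and
$\boldsymbol\delta$ are the additive, aa and aaa effects.  Products are
formed only among the selected markers, i.e. epistasis is modelled only
between loci that already show additive signal — the assumption that
keeps the candidate space tractable.  With
$\mathbf G = [\mathbf 1\; \mathbf X\; \mathbf Z\; \mathbf W]$ of full
rank the estimate is the ordinary least-squares solution
$\widehat{\boldsymbol\alpha} = (\mathbf G'\mathbf G)^{-1}\mathbf
G'\mathbf y$, and the total genotypic aaa effect is the sum of all fitted
triple coefficients,

$$\widehat{aaa}_g = \sum_{k<k'<k''} \widehat{aaa}_{l_k l_{k'} l_{k''}}.$$

### Marker selection

Selection is by stepwise search on the Akaike information criterion, in
three stages mirroring how a practitioner keeps the search feasible on
maps with hundreds of markers:

1. **Per chromosome**: bidirectional stepwise AIC over that chromosome's
   additive terms, from the intercept-only model.
2. **Pooled**: survivors of all chromosomes are combined and the
   selection repeated; the result defines $\mathbf X$.
3. **Interactions**: starting from the full additive model (additive
   terms are never dropped here), the $\mathbf Z \cup \mathbf W$ product
   terms are the candidate pool for a final bidirectional stepwise AIC
   pass.

Every accepted move must strictly decrease AIC (tolerance $10^{-8}$), so
the AIC trace is strictly decreasing; the trace of stage 3 is attached to
the pruned design for auditability.  The AIC is the Gaussian
log-likelihood form, numerically identical to `stats::AIC()` on the
corresponding `lm` fit; only AIC differences matter for selection, but
matching the standard convention keeps values comparable across tools.

The total number of fitted parameters in stage 3 is capped at
`max_params = n − 10` by default.  With $p \approx 30$ selected markers
the candidate pool $\binom p2 + \binom p3$ far exceeds the line count,
and the cap preserves residual degrees of freedom for the t tests.

### Significance and the NS convention

Each fitted triple is tested with a two-sided t test at the
Bonferroni-corrected level $\alpha/m$.  The choice of $m$ matters more
than it may appear.  Correcting only over the interaction terms that
*survived* selection (`m_rule = "model"`) ignores that stepwise AIC
already screened the whole candidate pool and kept the terms with the
largest apparent signal; their t statistics are inflated by that
selection, and in null simulations at the package's study conditions
(150 lines, three 20-marker chromosomes at 10 cM, three additive anchors,
no interactions) the fraction of data sets showing at least one
"significant" triple is close to 0.3.  The package therefore defaults to
`m_rule = "candidates"`: $m$ is the number of interaction terms scored in
stage 3, which is the family that was actually searched.  Under the same
null conditions this brings the spurious-detection rate down to roughly
0.09–0.11 (recomputed by the test suite and by `scripts/acceptance.R`);
the residual excess over the nominal 0.05 is the part of the
selection-inflation that a Bonferroni divisor cannot remove.  The
`"model"` rule remains available for users who want the laxer convention.

When no triple survives the corrected test the genotypic total is
reported as `NS` in the output tables — the estimate is still computed
and kept in the record, but flagged non-significant — together with the
`(markers | significant aaa)` annotation.

### Post-selection shrinkage of retained coefficients

A related caveat applies to the coefficient of a *true* triple effect.
In simulations with a triple effect of 0.8 on three additive anchor loci
(same study conditions as above, 200 replicates), the true triple is
retained in roughly 85–91% of replicates, but its mean fitted
coefficient conditional on retention is about 0.75–0.77 rather than
0.8.  The OLS fit itself is unbiased — refitting the true model without
any selection recovers 0.80 on average — so the deficit is
post-selection shrinkage: on a 10 cM map the candidate triples built
from markers linked to the anchors are strongly correlated with the true
term, and conditioning on the stepwise path (which may admit competitors
or stop early precisely when the noise de-emphasises the shared signal
direction) pulls the retained coefficient toward zero by a few percent.
Users comparing $\widehat{aaa}_g$ across data sets should keep this
systematic attenuation in mind; it shrinks as marker spacing grows and
vanishes for unlinked markers.

## The balanced-design contrast

If the selected markers are unlinked and each segregates exactly 1:1,
the genotypic total can be rewritten per triple in terms of group means:
$\tfrac12(\bar y^{(+)} + \bar y^{(-)}) - \bar y$, where $\bar y^{(+)}$
($\bar y^{(-)}$) is the trait mean over lines whose three markers are all
+1 (all −1).  `contrast_aaa()` computes this symmetric form exactly as
printed.  Note its structural quirk: on a balanced full factorial with a
pure triple effect, $\bar y^{(+)} = -\bar y^{(-)}$ and the symmetric form
is identically zero, while the difference form $\tfrac12(\bar y^{(+)} -
\bar y^{(-)})$ recovers the effect; both are reported
(`include_difference = TRUE`) so the user can see when the symmetric
form is being cancelled by odd symmetry rather than by absence of
effect.  The χ² segregation pre-test (`segregation_chi2()`) checks the
1:1 assumption behind this reduction: $\chi^2 = (n_+ - n_-)^2/(n_+ +
n_-)$ on 1 df per marker.  Distorted markers are flagged, and excluded
only if `exclude_distorted = TRUE` (off by default, α = 0.05), since
flagging is a diagnostic, not a prescription.

## Preprocessing

**Transformation.**  Percentage-scale traits (e.g. lodging, malt
extract, grain protein) are transformed by $\arcsin\sqrt{x/100}$, the
standard variance-stabilizing map from $[0,100]$ to $[0,\pi/2]$ radians.
`check_normality()` (Shapiro–Wilk) is provided as an advisory screen; it
never blocks the pipeline, because the estimators do not formally require
normality — the t tests do, approximately, and the user should know.

**Missing genotypes.**  Sporadic missing marker scores are replaced by
the conditional expectation of the ±1 genotype given the nearest
non-missing flanking markers on the same chromosome, under a Markov
(no-interference) model with the Haldane map function
$r = \tfrac12(1 - e^{-2d/100})$.  With both flanks available the
expectation follows from the two transition probabilities; with one
flank at recombination fraction $r$ it is $s(1-2r)$; with none it is 0
(the 1:1 prior).  Expectations are kept continuous by default because
they preserve information in the regression; `round_to_allele = TRUE`
restores strict ±1 coding (an expectation of exactly 0 maps to +1, a
documented deterministic tie-break).  Kosambi-style interference
modelling is deliberately out of scope; the map-function choice is
isolated in `haldane_r()` should that change.

## The simulator

`simulate_population()` draws each line's genotype as independent Markov
chains over {−1, +1} along each chromosome: the first marker is ±1 with
probability ½, and each subsequent marker flips with the Haldane
recombination fraction of the inter-marker gap.  This matches the
imputation model exactly (same no-interference assumption), guarantees
1:1 segregation in expectation, and makes adjacent-marker correlation
$1-2r$.  Traits are generated as $y = \mu + \sum\beta x + \sum\gamma
xx' + \sum\delta xx'x'' + e$ with i.i.d. Gaussian noise; missing-value
masking is applied *after* trait generation so the architecture
underlying each trait is well defined.  Two presets emulate the shapes
of the classic barley DH mapping populations: `"SxM"` (150 lines, 223
markers on 7 chromosomes at 5.66 cM mean spacing) and `"HxT"` (145
lines, 127 markers at 10.62 cM), each with five additive QTL, one
pairwise and one triple interaction, unit residual SD and 2% missing
genotypes — values chosen once as representative of barley DH trait
analyses, not tuned.

What the simulator does **not** emulate: segregation distortion,
genotyping error, heterozygosity (no F2/BC support), dominance,
genotype-by-environment correlation between traits, non-Gaussian
residuals, and interference.  Passing tests on simulated data therefore
demonstrate correctness of the estimators under the stated genetic
model, not robustness to these real-data features.

## Numerical choices

* OLS is solved by pivoted QR (`lm.fit`); when the model matrix is rank
  deficient, aliased columns are dropped deterministically — the first
  linearly independent column in canonical term order is kept — and
  recorded, rather than refusing to fit, because real marker data alias
  frequently.
* Canonical term order is map order (chromosome, then position), so a
  triple is one term regardless of the order its markers are listed in.
* An exact fit (zero residual variance with residual df remaining) gives
  nonzero coefficients infinite t and p = 0; a saturated fit (zero
  residual df) gives p = NA and the triples are treated as
  non-significant.
* Stepwise acceptance requires an AIC decrease larger than $10^{-8}$, so
  aliased or zero-variance candidates (AIC unchanged or +2) are never
  admitted and duplicated marker columns collapse to one survivor.
* All randomness flows from a single integer seed; the whole
  simulate–estimate–compare pipeline is byte-deterministic given the
  seed, which the test suite asserts on serialized outputs.

## Batch comparison

`run_comparison()` analyzes each trait-by-environment set independently
— transformation, imputation, both estimators — and records the paired
ratio $(\widehat{aaa}_g/\widehat{aaa}_p)\cdot 100$, which is undefined
(excluded from summaries, not coerced to 0 or ∞) when the phenotypic
estimate is zero or the genotypic one is NS.  A failure in one trait is
captured in its record and does not abort the batch, mirroring how such
multi-environment series are analyzed set by set.
`summarize_comparison()` reports how often the genotypic estimate is
smaller than the phenotypic (by magnitude and by signed value — both,
since either reading of "smaller" is defensible) and per-trait quartiles
of the ratio, i.e. the numbers behind a box-and-whisker display;
rendering the plot itself is left to the user.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use 200 replicates for the
triple-recovery study and 500 for the null study at the 150-line,
3 × 20-marker conditions above, 100 random 150 × 10 designs for the OLS
oracle comparison, and a six-trait SxM-like batch for the end-to-end
comparison — sizes chosen to give Monte-Carlo standard errors an order
of magnitude below the effects being checked while keeping a full run in
the low minutes on one core.

## Known limitations

* The extreme-group fraction and the effective-factor formula are
  conventions, not canon; both are exposed and pluggable.
* $\widehat{aaa}_g$ inherits post-selection biases described above:
  moderate attenuation of true retained effects and a spurious-detection
  rate above nominal even with the candidate-pool Bonferroni correction.
  Resampling-based selection inference would address both and is out of
  scope here.
* No interval mapping between markers, no mixed-model kinship
  correction, no permutation thresholds.
* The phenotypic and genotypic estimators answer subtly different
  questions (all loci vs selected loci); their ratio is a descriptive
  comparison, not an efficiency statement.
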