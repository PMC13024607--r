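---
title: "Methods: validating an adolescent gender-stereotype battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating an adolescent gender-stereotype battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gabkit implements the complete psychometric validation workflow for a
three-module adolescent gender-stereotype battery and ships a calibrated
synthetic-cohort generator so the workflow is testable end to end. This
vignette documents the statistical models, the tunable parameters and their
defaults, the numerical choices, and what the simulated cohorts do and do
not emulate.

## Scoring model

GSAS items are 4-point Likert responses scored directly (1–4); after the
exclusion of the one reverse-keyed autonomy item no reverse scoring
remains. Trichotomous items (GRAS, GTI) are scored through a categorical
schema once the item's *stereotype direction* is fixed:

| response role          | Schema A | Schema B |
|------------------------|----------|----------|
| stereotypical          | 2        | 2        |
| egalitarian            | 1        | 0        |
| counter-stereotypical  | 0        | 1        |

Schema A (GRAS default) treats the egalitarian answer as the midpoint of a
traditionalism continuum. Schema B (GTI default) treats it as the zero
point of a *gender-salience* construct: attributing a trait to either
gender reflects engagement with gendered categorisation, so the
counter-stereotypical answer scores 1, not 0. The package keeps raw
responses as letters (`M`/`F`/`E`) and applies schemas only at scoring
time, because the two schemas map the same raw data differently.

Directions are configuration, not constants. `verify_directions()` runs a
two-sided exact binomial test (default α = 0.05) of equal male- versus
female-attribution among non-egalitarian responses; an item whose majority
is not significant stays `undetermined`, and scoring such an item is a hard
error rather than a silent default — miscoded directions can collapse a
scale's reliability from ~0.8 to ~0.36, so the package forces an explicit
decision. Whether a significance threshold or a raw majority is
appropriate is genuinely open; the α parameter covers both (α = 1 gives the
raw-majority rule).

Completeness is handled listwise *within scale*: a person missing a GRAS
item still receives GSAS and GTI scores. Dropped counts are reported on the
scores object.

## Ordinal factor analysis

**Polychoric correlation.** Two-step maximum likelihood: thresholds from
the inverse-normal cumulative margins, then the correlation maximising the
bivariate-normal cell likelihood over (−0.999, 0.999). The bivariate normal
CDF uses the single-integral angle representation with 48-point
Gauss–Legendre quadrature for |ρ| ≤ 0.925 and adaptive quadrature beyond,
keeping errors well under 1e−7 (the test suite checks it against the
closed-form identity Φ₂(0,0,ρ) = 1/4 + asin(ρ)/2π). Zero cells receive
+0.5 smoothing before threshold and likelihood evaluation; this stabilises
boundary estimates on small cross-tabulations and is the only smoothing
applied.

**Extraction and rotation.** Iterated principal-axis factoring starts from
squared multiple correlations and stops when communalities change by less
than `tol` (default 1e−6, capped at `max_iter`). Rotation is direct
oblimin with γ = 0 (quartimin) by gradient projection, with 10 random
orthogonal starts (seeded) keeping the best criterion value; columns are
sign-normalised to majority-positive and ordered by explained variance.
Variance accounting uses the orthogonal extraction's sums of squares —
summing squared *structure* loadings of an oblique solution would
double-count shared variance; the per-factor sums add up to the total
communality, so "percent variance" means the communal share of total item
variance. Communalities above 0.999 are capped and flagged as Heywood
cases.

**Factor retention.** Parallel analysis compares eigenvalues of the
*reduced* (SMC-diagonal) correlation matrix with the same quantity from
1000 datasets whose columns are independently resampled from each item's
margins, matching the principal-axis logic. The reference quantile default
is the **99th percentile**. The common 95th-percentile rule retains a
spurious factor in exactly 5% of null datasets by construction; the 99th
percentile (a standard conservative recommendation) keeps over-extraction
rare while leaving power for real factors essentially untouched — on the
battery's simulated attitude scale the third factor's eigenvalue sits far
above either reference. The quantile and the correlation type
(Pearson default, polychoric optional) are parameters.

**Congruence.** Tucker's φ aligns factors by a greedy best-|φ| matching
and reports sign-aligned coefficients; φ ≥ 0.95 is the usual equivalence
benchmark.

## Reliability

Cronbach's α uses n−1 variance denominators throughout. Its interval is
the classical Feldt construction from the F distribution with (n−1) and
(n−1)(k−1) degrees of freedom; among the Feldt-family variants the 1965
form is implemented. ω and ω_h come from a Schmid–Leiman
orthogonalisation: group factors by PAF + oblimin, a second-order factor
from the inter-factor correlations (for two group factors the second-order
loadings are √r, the standard just-identified choice), and
ω_h = (Σ general loadings)² / total model-implied variance. For
unidimensional scales ω_h = ω by construction. Polychoric α applies the α
formula to the polychoric matrix (unit latent variances), and is never
below the Pearson α on discretised one-factor data — an attenuation
property the tests assert.

## Known-groups statistics, bias decomposition, response styles

Welch's t (Satterthwaite df) and Cohen's d with the Hedges–Olkin
large-sample interval accept either raw samples or printed summary
triplets, so published tables can be checked directly. χ² applies the
Yates correction to 2×2 tables by default — that convention is what
reproduces the published demographic statistics — and reports Cramér's V.
The factorial ANOVA uses Type III sums of squares with sum-to-zero
contrasts (the conventional reporting choice for unbalanced designs; the
one-way η² and the factorial partial η² are otherwise unaffected).
Games–Howell post hocs use Welch-type standard errors with
studentized-range critical values on Satterthwaite df.

The self-attribution gap for an item and target gender is
Δ = p(self-rating) − p(outgroup rating), in percentage points, where
"self-rating" is the proportion of a gender's respondents attributing the
trait to their own gender *among all respondents* (egalitarian responses
are not excluded, matching how endorsement percentages are conventionally
printed). Two-proportion z tests use the pooled standard error, with
Bonferroni control over the m = 20 target–item combinations
(α_adj = 0.0025). Self-Serving Scores summarise Δ in raw percentage points
per trait valence; the valence map ships as overridable configuration, and
a z-scaled standardisation was deliberately not assumed since the raw-point
summary is the one that reproduces printed magnitudes.

Response-style indices: acquiescence (mean raw likert response), extreme
responding (endpoint share, endpoints {1, 4}), and the egalitarian /
stereotypical / counter-stereotypical shares for trichotomous scales.
Problematic patterns: zero variance (all responses identical within a
scale), straight-lining (same *column* on every trichotomous item — for
the likert scale the zero-variance rule already covers the same behaviour),
and extreme acquiescence (> 90% agreement, agreement meaning codes 3 or 4;
both the threshold and the agreement definition are parameters since the
operational definition of "agreement" on a 4-point scale is a choice).

## Norms and cutoffs

Gender-balanced weighting assigns each person 0.5/proportion(own gender),
so the two gender strata contribute equally; weighted means and variances
then satisfy the 50/50 mixture identities exactly, which the tests verify.
Weighted percentiles invert the weighted ECDF with the left-continuous
step convention — the smallest observed (integer) sum score whose weighted
cumulative share reaches the target — because operational cutoffs must be
attainable integer scores. Cutoffs default to P75 (Elevated) and P90
(Alert).

Natural breaks are interior strict local minima of a Gaussian-kernel
weighted density (512-point grid, range padded by three bandwidths,
Silverman bandwidth 0.9·min(sd, IQR/1.34)·n^(−1/5)) whose prominence
relative to the smaller neighbouring peak exceeds 1% of the density
maximum; the floor suppresses ripple minima and is a parameter.

The dip statistic is computed from its definition: the smallest sup-norm
band width t such that a convex-then-concave (unimodal) CDF fits inside
the ECDF band, with feasibility checked by greatest-convex-minorant /
least-concave-majorant constructions on the band envelopes and the width
found by bisection (compiled code; 50 bisection steps, so the value is
exact to ~1e−15 of the bracket). The construction relaxes the
slope-continuation constraints where the convex and concave pieces join at
the mode, which can only make the statistic conservative in rare
configurations; it reproduces the canonical two-point value of 0.25
exactly, and p-values are Monte-Carlo calibrated against uniform samples
of the same size *using the same functional*, so the test's level is
self-consistent (the null calibration is asserted within ±2 points of the
nominal 5%).

The combined classification takes the sorted union of antimode breaks
(rounded up to integer scores) and percentile cutoffs, deduplicated within
a 1-point tolerance with the percentile boundary winning ties. With the
battery's published inputs (breaks 26 and 36; cutoffs 38 and 43) this
yields the five bands 17–25, 26–35, 36–37, 38–42, ≥ 43.

## Criterion validity and aggregation diagnosis

Correlation panels use pairwise-complete Pearson correlations, with one
Benjamini–Hochberg family per stratum panel (pooled, female, male) — the
family partition is a documented choice since finer or coarser partitions
are defensible. The Simpson diagnosis compares the pooled correlation with
its within-stratum counterparts: `sign_reversal` when a significant pooled
correlation is opposed in sign by every significant stratum correlation,
`strata_null` when no stratum is significant at all, `attenuated` when the
pooled magnitude exceeds every stratum magnitude with consistent signs,
`consistent` otherwise.

## The synthetic cohort generator

The generator draws, per person: gender (43.6% female) and school track
(per-gender track distributions of the validation cohort); standardised
per-scale general factors with cross-scale correlations; subscale factors
loading on their scale's general factor with second-order loadings chosen
to reproduce the published inter-factor correlations (attitude scale
Φ: TS–VM 0.68, TS–RC 0.50, VM–RC 0.47; activity scale latent r 0.84);
gender and school shifts on the subscale-factor means (subscale-specific
gender weights proportional to the published subscale effect sizes; school
shifts from the published latent track differences); and ordinal responses
by probit thresholding of λ·factor + unique normal error, with the
published CFA loadings as λ.

Thresholds are equal-spaced cut points with fixed per-item location
offsets (items genuinely differ in endorsement rates; the offsets also
keep accidental always-same-answer responders rare). Their location,
spacing and the latent gender separation are calibrated by root finding on
analytic item moments so that the scale-level means and the average
within-gender SD match the published values (female/male 1.67/2.18,
SDs 0.42/0.53 on the attitude scale; 1.19/1.42, 0.22/0.28 on the activity
scale; 0.78/0.83 on the trait scale). Covariances in the calibration use a
fourth-order tetrachoric (Hermite) series — the first-order linearisation
understates scale variance by ~10% at these loadings. Because the printed
descriptives describe the full sample including its problematic
responders, the calibration first inverts the contamination mixture so
that the *contaminated* synthetic cohort matches the printed values.

Trait items are generated as gender salience: the egalitarian-versus-
gendered split is driven by the latent factor (which is what makes
Schema B coherent and Schema A incoherent on these items, reproducing the
published reliability contrast), while the stereotypical-versus-counter
split among gendered responses is a respondent-gender-specific probability
encoding the published self-attribution asymmetries (independence,
unpredictability, fragility, reasonableness from the printed tables; the
remaining items carry moderate symmetric defaults plus the self-serving
asymmetries implied by the printed valence summaries). The model-implied
attribution proportions are stored in the configuration as the generator's
own targets, since per-gender egalitarian rates cannot all be matched
exactly under a common-threshold invariant model — scale-level means and
effect sizes take priority, then factor structure, then item-level rates.

Criterion scores are linear-Gaussian transforms of the general factors
with per-gender loadings solved (through the cross-scale correlation
matrix and the analytic observed-score attenuations) so the within-gender
correlations hit their targets. The male within-gender distress
correlation is the published +0.066; the female target is +0.05 — the
published female estimate (−0.046) is non-significant at the female sample
size, and a small positive value keeps the generator's designed
"pooled-negative, within-nonnegative" stratified structure sign-definite
under seed-to-seed sampling noise. The distress gender gap is then
calibrated so the pooled attitude–distress correlation reverses to the
published −0.149. Criterion means and SDs are plausible adolescent values
(e.g. K10 on the 10–50 metric, RSES 10–40) and are documented in
`CRITERIA_SPEC`; only the distress gap is calibrated.

Contamination is injected last from its own seed substream (acquiescent
likert responders, default 1.4%; all-same-column responders, default
0.15%), so changing contamination rates does not perturb item draws. One
master seed derives named substreams for demographics, factors, items,
criteria, contamination and missingness; identical seeds give
byte-identical cohorts.

**What the generator does not emulate.** Item wording effects, school
clustering beyond track membership, longitudinal waves, and non-binary
respondents are out of scope. Two visible model-versus-reality gaps are
worth knowing: (a) a clean latent-trait model produces more perfectly
consistent responders (especially all-egalitarian trait-scale responders,
~8% versus ~0.2% in real cohorts) than humans do, so style-screen tests
measure injected contamination as the *excess* over this baseline; (b) the
generated attitude sum-score distribution is a smooth two-component
mixture — the dip test still rejects unimodality, as published, but the
specific published antimode locations (26 and 36) are not reproduced, so
the combined classification is exercised with the published breaks and
cutoffs as inputs. Passing tests on generated cohorts therefore show that
the estimators recover the structure the generator encodes, not that real
data possess that structure.

## Problem sizes used in the tests

The shipped tests run the heavy properties at the sizes the workflow
itself uses: factor recovery and parallel analysis at the EFA half-sample
size (n = 1479, 1000 parallel-analysis replicates, 10 seeds), schema and
norm checks on full-size cohorts (n = 2955), stratified-correlation
sign-structure checks at n = 8000 per seed (chosen so that a true
within-gender correlation of +0.05 stays positive with high probability
under sampling noise), and dip-test calibration with 500 test samples of
n = 200 against a 1500-replicate null table.

## Known limitations

- The polychoric estimator is two-step (not joint) ML; standard errors for
  ρ̂ are not reported.
- Parallel analysis with polychoric reference matrices is supported but
  slow; the Pearson default is the practical choice and agrees on factor
  counts in all scenarios exercised here.
- The dip construction's join relaxation (above) has no observed effect on
  the calibrated level or the benchmark values, but it is not a
  line-for-line reimplementation of the classical algorithm.
- Confirmatory factor analysis, WLSMV estimation, fit indices and
  measurement-invariance testing are deliberately out of scope; published
  CFA loadings enter only as generator inputs.
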