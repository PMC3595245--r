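---
title: "Methods: joint-group structure and patient subgroups in 28-joint synovitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-group structure and patient subgroups in 28-joint synovitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointgroups)
```

## Scope and data model

The package analyses longitudinal binary assessments of the 28 joints
used in rheumatoid arthritis disease-activity scoring: per visit, 28
tenderness and 28 swelling flags. The unit of observation is the
patient-visit row; the canonical column naming is
`<side>_<site>_<symptom>` (e.g. `r_wrist_tender`), with sites
`shoulder, elbow, wrist, knee, mcp1–5, pip1–5` and sides `l`/`r`. Every
joint belongs to one of three fixed groups — large and wrist (8), MCP
(10), PIP (10) — which are a hypothesis under test, not something the
package infers.

Validation is strict: all 56 flags must be present and 0/1. A visit with
any missing flag is rejected at read time rather than zero-filled or
imputed, because no defensible missingness mechanism is available for
physical-exam flags and silently treating "not recorded" as "not
affected" would bias every downstream rate downward.

## Affected rates and laterality

Per-joint affected rates are computed on one assessment per patient,
drawn uniformly over the patient's visits with a seed. Using all visits
would weight frequently seen (typically more active) patients; uniform
per-patient resampling gives every patient the same weight while leaving
the estimator unbiased for the visit-marginal rate.

Rate orders between patient sets, or between tenderness and swelling,
are compared with Spearman's ρ (average ranks for ties). The p-value
uses the asymptotic t approximation, `cor.test(..., exact = FALSE)`;
with 28 joints the exact permutation null is unnecessary and the
approximation is standard.

Laterality is tested on the 14 bilateral sites: a site counts as
right-dominant when its right rate is strictly higher, exact ties are
excluded (they have measure zero on continuous rates and no defensible
half-assignment), and the right-dominant count K out of n untied sites
is referred to Binomial(n, ½). The two-sided p-value is the
minimum-likelihood definition — the sum of probabilities of all outcomes
no more likely than K — which at p = ½ equals the doubled tail; 11 of 14
gives p = 0.0574. The implementation is `stats::binom.test`, whose
two-sided rule is exactly this definition; the test suite verifies it
against full enumeration of the 2^14 outcome space.

A consequence worth stating: with only 14 sites the exact test is
conservative. The rejection region at α = 0.05 is K ≤ 2 or K ≥ 12, so
the attainable size is 2·106/2^14 ≈ 0.013, not 0.05. Simulations under
a symmetric generator therefore reject in roughly 1–2% of cohorts, not
5%; the same test applied per patient to destruction scores (n in the
hundreds) calibrates close to its nominal level. This discreteness is a
property of the exact binomial test at small n, and we report it rather
than substituting an approximate test that the analysis does not use.

## Co-occurrence structure: kappa and the eigen embedding

Pairwise co-occurrence uses Cohen's κ (two raters, two categories):
κ = (p₀ − p_e)/(1 − p_e) from the 2×2 table of a joint pair across
patients. Joints that are constant in the resampled set are degenerate —
κ is reported as `NA`, never imputed, and such joints are dropped from
the embedding with a warning.

The embedding is PCA of the patients × joints binary matrix on the
correlation scale (centred, unit-variance columns). The scale choice
matters and is deliberate: per-joint prevalences differ more than
fourfold, and covariance-scale PCA would order components by prevalence
rather than by co-occurrence pattern. Two numerical conventions make
results reproducible:

- component signs are fixed so that each component's largest-magnitude
  loading is positive (eigenvectors are defined up to sign);
- agreement between seeded resamples is summarised as the absolute
  correlation of loadings over shared joints.

One caveat is documented because it shapes the tests: individual
principal components are identifiable only when their eigenvalues are
separated. In a design with three comparable joint blocks, the second
and third components (the two block contrasts) have nearly equal
population eigenvalues, so those axes can rotate freely between
resamples even at large n, while the spanned subspace — and hence the
group separation measured in it — is stable. The stability tests
therefore assert per-component reproducibility on a two-block design
(distinct eigenvalues) and subspace-level reproducibility (silhouette of
the planted groups in every resample) on the three-block design.

Group separation in the first two components is quantified by the mean
silhouette width (Euclidean distance), on the 28 joints for the
large+wrist versus small-joint split and on the 20 small joints for the
MCP/PIP split — the latter because the dominant large+wrist axis
otherwise compresses the small-joint contrast.

## Patient subgroups

Each evaluation is reduced to three group affected rates,
rate(g) = (tender count + swollen count in g)/|g|, ranging over [0, 2]:
tenderness in four of ten MCP joints alone gives an MCP rate of 0.4;
all PIP joints tender and swollen gives a PIP rate of 2.

Evaluations are sampled at most 6 per patient (uniform, without
replacement) so that frequently assessed patients cannot dominate, and
optionally subsampled to a fixed pooled size; the package does not
hard-code any particular cohort size. Clustering is agglomerative with
Ward's minimum-variance criterion on Euclidean distances of the raw
3-vectors — no standardisation, because the three axes already share the
[0, 2] scale by construction. The tree is `stats::hclust(method =
"ward.D2")`, whose deterministic agglomeration order makes runs
bit-reproducible; the test suite checks its merge heights against an
independently coded Lance–Williams update on a thousand small random
instances. The cut at k = 6 is a fixed hypothesis, mirroring the
six-subgroup structure the analysis is designed around; no model
selection over k is performed. Cluster labels are renumbered 1..k by
ascending mean total rate so that "subgroup 1" is always the
no-synovitis end — the raw agglomeration numbering is arbitrary and
would not be comparable across runs.

Regularity: among patients with exactly 4 or 5 clustered evaluations, a
patient is regular when strictly more than 60% of their evaluations
share one subgroup label. The strict inequality is a deliberate reading
of "more than 60%": 3 of 4 (0.75) qualifies, 3 of 5 (0.60) does not.
Both the threshold and the eligibility window are arguments.

## Destruction analysis

Modified-Sharp element scores (erosion and joint-space narrowing ×
MCP/PIP/wrist region, per side) are normalised to per-group destruction
rates, score-sum/full-score, so a large+wrist sum of 50 against the
group full score of 108 gives 0.463. Full scores are configuration, not
constants: the large+wrist total of 108 is the fixed reference value,
while the MCP and PIP defaults (25 erosion + 20 narrowing per side,
van der Heijde convention) and the erosion/narrowing split of the wrist
group are overridable, because published variants differ. The "wrist"
region means the hand joints other than MCP and PIP.

Right-dominance is tested per element with the same exact binomial test
(patients with equal left and right scores excluded). Subgroup-wise
dominant destruction uses the per-patient paired differences
(large+wrist − MCP) and (large+wrist − PIP) and a two-sided one-sample
t test; groups with fewer than two patients or zero-variance differences
are flagged degenerate rather than tested.

## The synthetic cohort generator

`generate_cohort()` is a latent-Gaussian (multivariate probit) threshold
model. Per visit a 56-dimensional standard normal vector is drawn with
correlation kron([[1, ρ_ts], [ρ_ts, 1]], C): C is the 28×28 joint
correlation, assembled as block compound symmetry (within-group
ρ_within, between-group ρ_between) plus a left–right bump per site
(ρ_sym), projected onto the nearest positive semi-definite matrix by
eigenvalue clipping when the assembled matrix dips below −1e−8; ρ_ts
couples tenderness and swelling. A flag is 1 when its latent coordinate
falls below the normal quantile of its configured marginal. This
construction was chosen because it controls marginals and correlation
independently — the data it emulates are described by per-joint rates
and a correlation structure separately.

Marginals are built per archetype: six activity 3-vectors (probability
of a group's joints being symptomatic), a per-site multiplier encoding
within-group heterogeneity (wrist highest), an additive right-side bonus
(default 0.02), and a multiplicative attenuation of shoulder swelling
(default 0.4) reproducing the tender-but-not-swollen shoulder pattern.
Clamping to [0, 1] happens after all adjustments.

Two mechanisms give within-patient stability. Each patient carries an
archetype; a visit redraws its archetype from the population weights
with probability 1 − visit_stability (default 0.1), modelling transient
flares. Additionally each visit's latent vector mixes a per-patient draw
with visit noise, √ρ_pat · Z_patient + √(1 − ρ_pat) · E_visit, both with
correlation Σ, so the same patient tends to show the same affected
joints at every visit while all cross-sectional marginals and
correlations are exactly unchanged. ρ_pat (default 0.75) was calibrated,
together with the default archetype separation, so that the generator
plants the regularity structure it is specified to plant: with the
defaults, just over 70% of patients with 4–5 clustered evaluations are
regular, matching the qualitative behaviour of real clinic cohorts. The
default archetype activity vectors follow the six canonical patterns (no
synovitis; mild and moderate large+wrist-dominant; MCP-dominant;
PIP-dominant; globally active) with weights near the subgroup shares
seen in clinic populations; the numerical values are free parameters of
the generator, not estimates.

`generate_sharp()` draws element scores binomially over the element full
score with success probability destruction_scale × (archetype activity
of the matching group) plus the right bias, so destruction is correlated
with the synovitis pattern and right scores are stochastically at least
left scores whenever the bias is positive.

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about real data: treatment effects and secular
time trends (activity is stationary within patient), examiner effects,
missing or partially recorded visits, informative visit frequency
(sicker patients visiting more often), and any dependence of Sharp
scores on cumulative rather than current activity. Recovery results on
synthetic cohorts demonstrate that the estimators detect the structure
when present at the configured strength, not that real cohorts contain
it.

## Experiment designs used by the checks

The test suite runs its heavier simulations at sizes chosen to keep the
whole suite fast while leaving comfortable statistical margins; all
seeds are fixed.

- *Joint-structure recovery*: one cohort of 3,000 patients with
  ρ_within = 0.6, ρ_between = 0.1, ρ_sym = 0.7; checks mean within-group
  κ above between-group κ and silhouettes of the known labels in the
  28-joint and 20-joint embeddings.
- *Archetype recovery*: six archetypes with pairwise activity distance
  0.6, ~2,400 evaluations, flat site multipliers, no right bias,
  visit_stability 1, and the block/pair/coupling correlations attenuated
  (0.15/0.05/0.2, ρ_ts 0.3). The attenuation is the experiment's design,
  not a generator default: this check isolates the planted mixture
  structure, and at full co-occurrence correlation the visit-level group
  rates are so overdispersed that no clustering method can attain high
  label agreement — between-archetype variance, not co-occurrence noise,
  is what the experiment must control. Recovery is scored by adjusted
  Rand index against ground truth and by cluster means against the
  planted means.
- *Regularity*: one default cohort (1,314 patients), evaluations capped
  at 6 per patient and subsampled to 5,383.
- *Test-size calibration*: 1,000 symmetric cohorts for each of the two
  binomial tests (200-patient cohorts for per-joint laterality;
  246 scored patients for destruction dominance).

## Known limitations

- The three joint groups and k = 6 are fixed hypotheses; the package
  deliberately offers no data-driven selection of either.
- κ and the embedding are computed on one assessment per patient;
  longitudinal correlation within patients is used only by the
  clustering and regularity stages.
- The exact binomial laterality test is conservative at n = 14 (see
  above); a study needing nominal 5% size at 14 sites would need a
  different design, not a different implementation of this test.
- Destruction full scores beyond the large+wrist total are conventions
  exposed as configuration; results scale with them.
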