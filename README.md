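# jointgroups

Structure of 28-joint synovitis in rheumatoid arthritis: per-joint affected
rates, laterality, joint-group correlation structure, and patient subgroups.

## The problem

Rheumatoid arthritis (RA) disease activity is scored on 28 joints — the
bilateral shoulders, elbows, wrists, knees, MCP1–5 and PIP1–5 — but
composite indices treat every joint interchangeably. In clinic cohorts the
joints are far from interchangeable: affected rates vary several-fold
between joints, involvement is left–right symmetric with a small
right-side excess, and symptoms co-occur in three coherent joint groups —
the **large and wrist joints** (shoulders, elbows, wrists, knees; 8
joints), the **MCP joints** (10) and the **PIP joints** (10). Patient
evaluations in turn fall into a small number of synovitis subgroups that
are stable within a patient over time and relate to radiographic joint
destruction.

`jointgroups` implements this analysis end to end for anyone with
longitudinal 28-joint tenderness/swelling records (and optionally
modified-Sharp scores), and ships a synthetic cohort generator that plants
all of the above structure with known ground truth, so every stage is
testable without clinical data.

## Methods at a glance

- **Affected rates.** One assessment per patient is drawn uniformly
  (seeded); the affected rate of joint *j* is the fraction of patients
  with the symptom at *j*. Rate orders are compared between patient sets
  with Spearman's ρ.
- **Laterality.** For the 14 bilateral sites, the number with a strictly
  higher right-side rate is tested against Binomial(n, ½) with the exact
  two-sided (minimum-likelihood) p-value; ties are excluded.
- **Joint-group structure.** Pairwise co-occurrence is measured with
  Cohen's κ = (p₀ − p_e)/(1 − p_e) over all 378 joint pairs, and the
  patient × joint binary matrix is embedded by correlation-scale PCA; the
  three joint groups separate in the first two components (the MCP/PIP
  split resolved on the 20 small joints alone), quantified by silhouette.
- **Patient subgroups.** Each evaluation is reduced to three group
  affected rates, rate(g) = (tender + swollen joints in g)/|g| ∈ [0, 2];
  evaluations (≤ 6 per patient) are clustered by Ward's minimum-variance
  method and cut at k = 6. A patient with 4–5 evaluations is *regular*
  when > 60% share one subgroup label.
- **Destruction.** Modified-Sharp element scores (erosion/narrowing ×
  MCP/PIP/wrist, per side) give per-group destruction rates
  score-sum/full-score; right-dominance per element uses the same exact
  binomial test, and per-subgroup dominant destruction a paired t on
  (large+wrist − MCP) and (large+wrist − PIP) differences.

## Worked example

```r
library(jointgroups)

cfg <- cohort_config(n_patients = 300, seed = 1)
sim <- generate_cohort(cfg)

one <- resample_one_per_patient(sim$assessments, seed = 2)
profile <- affected_rates(one, "tender")
laterality_test(profile)
#> # A tibble: 1 × 4
#>   n_pairs_tested n_right_dominant n_ties_excluded p_value
#>            <int>            <int>           <int>   <dbl>
#> 1             12               10               2  0.0386
```

Ten of the twelve untied sites have a higher right-side rate (the
generator plants a 0.02 right bias); the exact two-sided binomial p at
n = 12 is 0.0386. With 11 right-dominant sites of 14 the same test gives
0.057.

```r
km <- kappa_matrix(sim$assessments, "tender", seed = 3)
kappa_group_summary(km)
#> # A tibble: 6 × 5
#>   group_a     group_b     within mean_kappa n_pairs
#> 1 large_wrist large_wrist TRUE       0.451       28
#> 2 large_wrist mcp         FALSE      0.0172      80
#> 3 large_wrist pip         FALSE      0.0814      80
#> 4 mcp         mcp         TRUE       0.429       45
#> 5 mcp         pip         FALSE      0.0376     100
#> 6 pip         pip         TRUE       0.275       45
```

Mean κ within each joint group is an order of magnitude above the
between-group values — the three-block structure. Clustering the
evaluations:

```r
feats <- group_rates(sample_evaluations(sim$assessments, seed = 4))
model <- ward_cluster(feats, k = 6)
characterize(model)
#> # A tibble: 6 × 6
#>   subgroup     n  share large_wrist    mcp    pip
#> 1        1   669 0.415       0.0534 0.0420 0.0143
#> 2        2   171 0.106       0.0775 0.0848 0.522
#> 3        3   276 0.171       0.135  0.985  0.130
#> 4        4   391 0.243       1.02   0.177  0.134
#> 5        5    56 0.0347      0.150  0.146  1.38
#> 6        6    49 0.0304      1.04   0.916  1.10
```

Subgroup 1 is the no-synovitis group; subgroups 3 and 4 are MCP- and
large+wrist-dominant; 2 and 5 are PIP-dominant at two activity levels; 6
is active across all groups. `regularity(model)` reports how many
patients with 4–5 evaluations keep one label (here 21 of 26 eligible,
fraction 0.81), and `autoplot()` on any of these objects draws the
corresponding figure.

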