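---
title: "Calibrating computational scores into PP3/BP4 evidence strengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating computational scores into PP3/BP4 evidence strengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package treats variant classification evidence as a likelihood-ratio
problem. A multiplexed assay of variant effect (MAVE) supplies a
quantitative functional score per missense variant; fixed cutoffs turn it
into three classes — loss-of-function (LoF, score < −1.328), functional
(FUNC, score > −0.748) and intermediate (INT, in between). LoF and FUNC
serve as proxies for pathogenic and benign; INT variants are excluded from
calibration because the clinical meaning of partial impairment is unclear.

A computational score (a pathogenicity score in [0, 1], a folding free
energy change ΔΔG in kcal/mol, or a meta-predictor score) is partitioned
into a benignity zone, an uninformative gray zone and a pathogenicity zone.
The evidence carried by a zone is

$$\mathrm{LR}_{zone} = \frac{P(zone \mid \mathrm{LoF})}{P(zone \mid \mathrm{FUNC})},$$

estimated by the ratio of zone frequencies in the two classes. Under the
Bayesian reading of the ACMG/AMP rules, evidence strengths form a geometric
point scale: $\log_2 \mathrm{LR}$ of about 1, 2, 4 and 8 points correspond
to Supporting, Moderate, Strong and Very strong. `map_strength()` snaps
$|\log_2 \mathrm{LR}|$ to the nearest member of $\{1, 2, 4, 8\}$ (ties to
the lower tier) and treats $|\log_2 \mathrm{LR}| < 0.5$ — below the rounding
basin of a single point — as no evidence. Optionally an estimate whose
confidence interval contains 0 is demoted to no evidence; the threshold
search and the cascade use this stricter rule throughout, so that reported
evidence is always statistically supported.

Key modelling assumptions: the MAVE classes are treated as error-free truth
proxies; variants are treated as exchangeable within class (no per-residue
or per-position correlation); and zone probabilities are binomial, which
underlies both the LR point estimate and its interval.

## Confidence intervals

The interval on $\log_2 \mathrm{LR}$ is the asymptotic ratio-of-proportions
interval computed on the natural-log scale,

$$\ln \mathrm{LR} \pm z_{1-\alpha/2}\sqrt{\frac{1-p_1}{x_1} + \frac{1-p_2}{x_2}},$$

then converted to base 2. The construction is standard for diagnostic
likelihood ratios, and with the zone counts used in this package it agrees
with published interval bounds for the same counts to three decimals, which
is why it was adopted over a bootstrap. Zero numerator counts receive a
Haldane–Anscombe correction (0.5 added to all four counts) and are flagged
`corrected` rather than silently patched.

For the diagnostic-test summary (`diagnostic_metrics()`), sensitivity,
specificity and accuracy get Clopper–Pearson exact binomial intervals;
predictive values get the Mercaldo prevalence-form logit intervals,

$$\widehat{\mathrm{var}}(\mathrm{logit}\,\widehat{PPV}) =
  \frac{1-se}{n_1\,se} + \frac{sp}{n_0\,(1-sp)},$$

the construction used by the common online diagnostic calculators, chosen
so that results are comparable with clinically reported tables. The CI
family for predictive values is a deliberate design choice, not a
statistical necessity; the point estimates do not depend on it.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Functional cutoffs | −0.748 / −1.328 | MAVE score | the assay's published class boundaries |
| RSA bins | < 30, 30–60, > 60 | percent | conventional buried / partially buried / exposed split |
| Pathogenicity-score zones | ≤ 0.65 / ≥ 0.75 | score | calibrated gene-specific thresholds |
| Stability-score zones | ≤ +1.5 / ≥ +2.5 | kcal/mol | destabilisation near +2 kcal/mol separates the classes best |
| Meta-predictor zones | ≤ 0.15 / ≥ 0.28 | score | thresholds in current clinical use for this gene |
| `ci_level` | 0.95 | — | reporting convention |
| Null band | \|log2 LR\| < 0.5 | — | below the rounding basin of one point |

Boundary conventions: a MAVE score exactly at a functional cutoff is
assigned INT. The published class definitions use strict inequalities on
both sides, leaving the boundary undefined; INT is the conservative,
evidence-free choice. RSA exactly 30 or 60 falls in the partially buried
bin (closed interval). Where sources disagree on whether buried means
RSA < 30 or RSA ≤ 30, the strict form is used everywhere and the boundary
is configurable via `rsa_binning()`.

## The threshold search

`search_thresholds()` is an exhaustive sweep of all ordered threshold pairs
on a candidate grid rather than a heuristic iteration: grids of a few dozen
candidates over ~1,500 variants evaluate in well under a second, so nothing
cheaper is warranted, and exhaustiveness makes the search its own oracle.
Feasible pairs must earn CI-supported evidence of at least a requested
magnitude on both sides with a bounded gray fraction; the result is the
Pareto front under (weaker-side |log2 LR|, gray fraction), ranked by
achieved point tier and then by gray fraction. Threshold pairs that leave a
zone empty in both classes carry no estimable evidence and are skipped.

## The cascade

`cascade_assign()` routes each variant through a small decision tree (depth
≤ 4) over RSA and two computational scores; `default_cascade()` encodes the
structure found useful in practice: exposed residues (RSA > 60%) can gain
pathogenicity evidence only, while buried/partially buried residues are
graded by pathogenicity-score zones and then stability-score concordance.
Each leaf's LR is computed on the same calibration cohort used for
assignment, and leaves whose CI spans 0 are demoted to GRAY in the emitted
assignments — the demotion is idempotent and surfaces, rather than hides,
underpowered leaves. The cascade is entirely config-driven (`cascade_node()`);
no tree learning is attempted.

Withholding benignity evidence at the surface has a mechanistic rationale:
stability predictors can only certify benignity where pathogenicity acts
through destabilisation, which holds for the protein core but not for
surface residues, whose variants may disrupt interactions without
destabilising the fold.

## The synthetic generator

`generate_mave_cohort()` emulates the statistical structure of a saturation
MAVE across the RING and BRCT domains of a tumour-suppressor protein:

- 1,638 variants, domain split 536:1,102;
- class proportions 337 LoF : 119 INT : 1,182 FUNC;
- an RSA mixture of 879 buried, 331 partially buried and 428 exposed
  residues (uniform RSA within bin; the exposed bin extends to 120% since
  normalised accessibility can exceed 100%);
- functional class drawn conditionally on the RSA bin with impaired
  (LoF + INT) fractions of 42% / 16% / 7%, the LoF:INT split preserving the
  global 337:119 ratio;
- a MAVE score drawn consistently with the class relative to the
  −0.748/−1.328 cutoffs (truncated normals for LoF and FUNC, uniform on the
  intermediate interval);
- per-tool class-conditional score distributions: logit-normal for the
  [0, 1] pathogenicity score, truncated normals for the ΔΔG tools (floor
  −5 kcal/mol) centred on the published per-class means (+6.55/+3.41/+1.04
  for the AlphaFold-template tool, +5.77/+3.09/+0.64 for the PDB-template
  tool), and a truncated normal on [−1.3, 0.8] for the meta-predictor;
- a Gaussian copula coupling the tools, with the strong
  pathogenicity/meta-predictor correlation (r ≈ 0.74) and moderate
  stability-score correlations from the study, and plausible fill-ins
  (0.4–0.6) where no value is published.

Published sources give class means but not spreads. The default scales
(logit-sd 1.7; 0.25; 2.9; 3.2) were chosen once, a priori, to place the
four tools in the published overall discrimination regime (auROC roughly
0.87–0.93), and are config-exposed. The generator's feasibility check
rejects configurations whose RSA-mixture-implied impaired fraction
disagrees with the class proportions by more than 2 percentage points.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: no sequence or per-residue structure (each
variant is independent); within-class score distributions do not depend on
RSA or domain, so RSA effects arise only through composition (the small
number of impaired variants at exposed residues), not through weaker
per-class separation — real cohorts show both; the MAVE score's measurement
error model is not represented; and the intermediate class is drawn
uniformly, whereas real intermediate scores cluster near the boundaries.
Consequently, e.g., the non-significance of exposed-residue benignity
evidence observed in real data is reproduced only in underpowered strata,
not systematically.

`generate_case_control_counts()` draws carrier counts binomially: controls
at the configured baseline frequency, cases at the odds-transformed
frequency implied by the stratum's true odds ratio, with cohort sizes
defaulting to 53,572 cases / 48,048 controls. The recovery property test
uses a baseline carrier frequency of 1e-3 per stratum — within the range
spanned by the published per-stratum counts (≈3e-4 to 2e-3) and large
enough that the small-sample bias of the log odds ratio is negligible
relative to its Monte-Carlo standard error.

## Numerical and degenerate-input choices

- Zero cells anywhere (zone counts, carrier 2×2) → Haldane–Anscombe 0.5,
  always flagged; empty-in-both-classes zones are an error ("no
  benign-zone observations"), not a corrected estimate.
- Strength ties (log2 LR exactly 1.5, 3 or 6) snap to the lower tier.
- auROC uses average ranks, so ties count half; it equals the all-pairs
  Mann–Whitney probability to machine precision.
- The paired bootstrap auROC comparison resamples within class (preserving
  prevalence) and normalises the observed difference by the bootstrap
  standard deviation for a two-sided normal p.
- Rank-sum tests enumerate exactly for two tie-free samples of ≤ 10; the
  tie-corrected normal approximation otherwise.
- Table parsing accepts unicode minus (−) and treats "", "NA", "NaN" as
  missing; missing tool scores are excluded per analysis and counted, never
  imputed.
- One seed governs each generator call via a single RNG stream; pipelines
  re-run with the same config and seed produce byte-identical outputs.

## A surfaced inconsistency

With generic developer thresholds (≤ 0.34) the benignity log2 LR of the
pathogenicity score reaches −4.6, which the nearest-point rule maps to
Strong (4 points), while descriptive accounts sometimes label that regime
"very strong". The package applies the nearest-point rule uniformly and
leaves the discrepancy visible rather than special-casing it.

## Problem sizes

The test suite simulates cohorts of 200–2,000 variants (6,000 for rate
checks), uses 200–400 bootstrap resamples where bootstraps are compared,
and 200 replicates for odds-ratio parameter recovery; these sizes give the
property tests comfortable Monte-Carlo margins while keeping the default
suite fast. The analysis scripts use the full emulated cohort size (1,638)
and 2,000 bootstraps.

## Known limitations

- Calibration treats MAVE classes as ground truth; misclassification of the
  assay propagates directly into the LRs.
- The asymptotic LR interval undercovers for very small zone counts; strata
  with fewer than two variants in either class are flagged rather than
  estimated.
- Case-control burden uses crude carrier odds ratios (no covariate
  adjustment); published association p-values computed under adjusted
  models will differ from the Fisher exact p reported here even when the
  odds ratios agree.
- The cascade's leaf LRs are computed on the same cohort used to choose the
  tree's thresholds; they are calibration summaries, not out-of-sample
  validations.
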