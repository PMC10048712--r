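---
title: "Methods: dual physical and molecular profiling of unidentified crania"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual physical and molecular profiling of unidentified crania}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioprofile)
```

This vignette documents the models behind each stage of the pipeline, the
tunable parameters and their defaults, the synthetic-data generators used
for validation, and the numerical and design choices made where the
procedures admitted more than one reasonable reading.

## Craniometric ancestry classification

The classification model assumes that every reference group and every
unknown cranium is drawn from a multivariate normal distribution over the
same inter-landmark measurements (mm) with a **shared covariance**. Under
that assumption the pooled within-group covariance `W` — computed by
centering each group on its own mean before pooling, with divisor `N − k`
— is the right metric, and the Mahalanobis generalized distance

\[ D^2_g = (x - \mu_g)^\top W^{-1} (x - \mu_g) \]

ranks group affinity. `fit_within_group_pca()` eigendecomposes `W` and
whitens: measurement vectors centered on the panel grand mean are rotated
onto the eigenvectors and scaled by `1/sqrt(eigenvalue)`, so squared
Euclidean distance between whitened scores *is* `D²`. Whether one whitens
the scores or keeps raw PC scores with eigenvalue weighting is
presentationally different but numerically identical for `D²`; we whiten
because it makes the pairwise-distance step a plain `dist()` call. The
test suite checks the identity against the explicit-inverse formula to
1e-8 on random panels.

**Posteriors.** Affinity probabilities use the equal-prior softmax
`exp(-D²/2) / Σ exp(-D²/2)` — the convention of the standard craniometric
classification software. This quantifies *relative* affinity among the
candidate groups only; it says nothing about absolute typicality, which is
why a cranium from an unrepresented population can still receive a high
posterior for its least-distant wrong group.

**Parameters.**

- `retain` (default: all eigenvalues above `1e-10 ×` the largest): how
  many within-group PCs to keep. The default simply drops numerically
  null directions; an explicit count is available when `N − k < p` makes
  `W` singular, and asking for components beyond the rank is an error
  rather than a silent fix.
- Missing measurements are **rejected, not imputed** — an imputation rule
  would be a modeling decision the classification stage has no basis for.
- Exact distance ties are broken by group-name order with a warning.

## Substructure: principal coordinates and the PC1 test

`pairwise_mahalanobis()` stores `D` (not `D²`); squaring happens inside
`principal_coordinates()`. The embedding is Gower's: double-center the
squared distances, `B = -½ J (D∘D) J`, eigendecompose, scale eigenvectors
by `sqrt(λ)`, and keep only axes with eigenvalues above `1e-9 ×` the
largest magnitude (Mahalanobis distance matrices are Euclidean-embeddable,
so negative eigenvalues arise only from round-off). Axis signs are
arbitrary in the algebra, so they are fixed deterministically — each
column's largest-magnitude entry is made positive — to keep plots and
regression tests stable. Cluster membership for the PC1 comparison comes
from the step-one affinities (the published analysis drew its ellipses by
eye, which has no algorithmic counterpart). The group comparison is the
pooled-variance two-sample t-test with `df = n₁ + n₂ − 2`, the convention
confirmed by the degrees of freedom reported for a 10-vs-8 split.

## Morphoscopic methods

**OSSA.** Six ordinal traits (ANS, INA, IOB, NAW, NBC, PBD) are
dichotomized by a recode table, summed to 0–6, and thresholded (sum ≥ 4 ⇒
White, boundary inclusive). The recode table and threshold ship as a
default config taken from the published OSSA method and are fully
overridable; they are calibration inputs, not estimates made here.

**Four-group classifier.** A naive-Bayes model over the 11 ordinal traits:
posterior ∝ prior × Π over scored traits of the group's smoothed level
frequency. Smoothing is additive with constant 0.5 (Jeffreys-style,
configurable); absent traits are skipped so partial crania still classify.
The package deliberately ships **no trait-frequency tables** — the
classifier is the algorithm, the frequencies are user or synthetic input.

**Sex equations.** `P(male) = plogis(a + Σ bᵢ sᵢ)` with positive linear
score male-ward. Published population-specific coefficients are not
reproduced here; `coefficient_template()` gives empty slots to paste them
into, and `fit_sex_equations()` fits equations by logistic regression on
labeled trait data so the decision framework is testable end-to-end with
synthetic panels.

**Conditional decision framework.** The binary class maps White→European,
Black→African. If it matches the four-group top, the matching
population-specific equation set is used; a non-match — including any
Asian or Native American top group, which has no binary counterpart —
forces the pooled set and an *Undetermined* procedure category. Equations
needing the mental eminence are skipped when the mandible is absent.
Unanimous equation sides give *Determined* (M or F); mixed sides give
*Uncertain* with the leaning category by majority (an equal split is
decided by the single most extreme probability — the published material
never exhibits a tie, so this tie-break is a package choice).

## Molecular methods

**Ry sexing.** `ry = n_Y/(n_X+n_Y)` with the normal-approximation 95% CI
`ry ± 1.96 √(ry(1−ry)/n)`, clipped to [0, 1]. At `n_Y = 0` the Wald
interval degenerates to `[0, 0]`; this does not affect calling (the XX
condition compares the upper bound against the male cutoff) but users
wanting a strictly positive upper bound at the boundary should prefer an
exact interval. Zero coverage returns an NA sentinel rather than an error.
Calls: XY when the CI lower bound clears `t_xx` **and** `ry ≥ t_xy`; XX
when the upper bound is below `t_xy` **and** `ry ≤ t_xx`; otherwise
indeterminate. Defaults `t_xx = 0.016`, `t_xy = 0.075` are the published
cutoffs of the ratio method and live in arguments, not constants.

**Genotype PCA.** Pseudo-haploid calls (0/1/missing) are the working
representation throughout, as standard for degraded DNA. SNP filters:
call rate ≥ 0.5 and minor-allele count ≥ 1 (monomorphic SNPs carry no
signal and would divide by a zero scale). Each surviving SNP is centered
on its mean call `p̄` and scaled by `√(p̄(1−p̄))`; missing entries
contribute zero after centering. Unknowns are projected by **least squares
on their observed SNPs only** (the loadings restricted to the observed
set), not by zero-filling: with the 5–95% per-sample missingness typical
of such data, zero-filling shrinks projected samples toward the origin
while restricted least squares does not. Samples with fewer than
`min_overlap = 100` observed model SNPs are skipped with a warning.
Assignment is nearest population-centroid in the top `k = 3` components
(the score plots of interest span PC1–PC3), with the runner-up distance
reported so borderline assignments are visible.

**Haplogroups.** Macro parsing: mtDNA labels take the text before any
parenthetical, then the leading letter — except L lineages, which keep
letter+digit (L0…L6) because the African L clades are reported separately
at that resolution; a `fine` flag extends letter+digit to non-L labels
(U2d → U2). Y labels use the letter before the hyphen in SNP-based
`X-M123` form, otherwise the leading letter. Where a printed label's macro
and parenthetical subclade disagree, the leading macro label wins and both
strings are stored verbatim. Percentages are reported to 2 decimals;
frequency tables can be conditioned on a macro prefix (e.g. shares within
L carriers).

## The packaged profile table and the audit

The fixture ships one record per cranium (n = 21) with the four physical
ancestry/sex classifications, their posteriors, molecular haplogroups, PCA
continent and SNP call counts. Ids are opaque strings kept verbatim
(including internal spaces); tooth stages are stored but never
interpreted. Leaning sex calls M/F and F/M are **ordered categories** —
the first letter is the majority side — because the audit distinguishes
them.

Audit conventions that required a decision:

- *Sex discrepancy vs molecular XY*: a record is discrepant when at least
  one physical column gives an **unqualified F**; leaning F/M alone does
  not count. This is the only reading consistent with the record-level
  data.
- *Ancestry discrepancy*: reported **per method** (craniometric affinity
  outside the African reference groups; four-group top not African;
  binary class not Black). No single figure summarizes the morphoscopic
  methods faithfully, so none is invented; the craniometric count is the
  one robust summary.

## Synthetic data: what it emulates, what it does not

- `simulate_reference_panel()`: multivariate-normal measurement vectors
  with a shared covariance — exactly the classifier's assumption, so
  recovery tests validate the machinery, not the biology. Measurement
  count is fully configurable (Howells-style batteries run to ~57
  variables; tests use 4–6 for speed — the statistical behavior checked
  does not depend on dimension).
- `simulate_morphoscopic()`: traits drawn independently per trait from
  group-level category probabilities — the naive-Bayes generative model.
  Real trait correlations (which the classifier ignores) are not
  emulated.
- `simulate_genotypes()`: Balding–Nichols drift — per SNP an ancestral
  frequency, per population a Beta-distributed drifted frequency with
  parameter FST, Bernoulli haploid calls, uniform missingness.
  Continental-scale structure uses FST 0.15 in the validation runs.
  What is *not* emulated: linkage disequilibrium, ascertainment bias,
  admixture clines, and reference-panel imbalance — so a passing
  assignment test shows the projection/assignment machinery works under
  clean drift, not that intra-continental assignment of real samples is
  reliable (the package's own regional-level caveat).
- `simulate_read_counts()`: binomial Y-alignment counts with
  `p_y_male = 0.09` and `p_y_female = 0.005` — values chosen once to sit
  in the middle of the published male band and safely under the female
  cutoff. Mapping biases and contamination are not emulated.

All simulators are seed-deterministic.

## Validation problem sizes

The acceptance script and test suite rerun the methods at: 3 groups ×
334 test crania for the 10-σ craniometric recovery; 3 populations ×
(50 reference + 10 held-out) individuals × 5000 SNPs at FST 0.15 for
continental assignment; 1000 replicates at 10⁴ alignments for Ry
male-calling power. These sizes give Monte-Carlo error well below the
thresholds being checked while keeping the full suite in seconds.

## Known limitations

- Posteriors are relative among the supplied reference groups; crania
  from unrepresented populations are silently absorbed by the nearest
  represented group (the central caveat of the application domain).
- No secular-change correction is attempted.
- Haplogroup *calling* from sequence data is out of scope; the package
  parses and summarizes labels produced by dedicated callers.
- The printed summaries the audit reproduces cannot be re-derived from
  raw measurements, which are not public; the audit therefore validates
  the decision rules against the record-level table, not the upstream
  measurement pipeline.
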