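---
title: "Dynamic network biomarker analysis of stimulation time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network biomarker analysis of stimulation time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnbsle)
```

## The model

Dynamic network biomarker (DNB) theory describes how a high-dimensional
biological system behaves just before a critical transition: a small group of
molecules — the DNB module — begins to fluctuate strongly and coherently,
while its coupling to the rest of the network weakens. Three statistical
signatures define the module at a given observation point:

1. the standard deviations of its members rise (`sd_in`),
2. the absolute pairwise Pearson correlations among members rise (`pcc_in`),
3. the absolute correlations between members and all other measured
   molecules fall (`pcc_out`).

`dnbsle` folds the three conditions into the canonical composite index

$$I \;=\; \frac{\mathrm{sd}_{in}\cdot \mathrm{pcc}_{in}}{\mathrm{pcc}_{out}+\varepsilon},
\qquad \varepsilon = 10^{-6},$$

which is strictly increasing in the first two statistics and strictly
decreasing in the third; $\varepsilon$ guards the fully-decoupled limit
$\mathrm{pcc}_{out}\to 0$. Correlations enter as absolute values: sign-blind
coupling is the DNB convention, and signed variants are deliberately not
offered.

The intended application is single-cell protein time courses: PBMCs stimulated
with IL-2 and measured by mass cytometry at 0, 0.5, 1, 2 and 4 hours. The
replicate unit for every SD and correlation is the **cell within one
(patient, timepoint) matrix**, after arcsinh transformation (cofactor 5, the
CyTOF convention) and optional uniform subsampling to equal depth (default
2000 cells) so that SD comparisons are not driven by unequal cell counts.
This per-cell reading is the only one under which a per-patient,
per-timepoint score is computable from a single blood draw. An optional
collapse-to-cluster-medians switch exists in the ingest layer for users who
prefer cluster-level summaries, but it is off by default and untested as a
scoring route.

## Per-sample module search and ranking

Exhaustive subset search is infeasible beyond ~20 markers, so candidate
modules come from average-linkage hierarchical clustering on the distance
$1-|r|$: every cluster appearing at any cut height of any timepoint's
dendrogram, with size between 2 and 8 (and leaving at least two non-members),
deduplicated and ordered by size then marker names. On panels of up to 10
markers the search is validated against exhaustive all-subsets enumeration
under the identical ranking key; agreement there bounds the approximation.

Candidates are ranked by the **surge of the composite index relative to the
unstimulated baseline**:

$$\mathrm{key}(M) \;=\; \max_{t>0}\; \frac{I_M(t)}{I_M(0)+\varepsilon},$$

with ties broken by the larger peak index, then lexicographically by member
names (reproducibility over cleverness — every tie-break is deterministic and
logged). Ranking by fold change rather than raw index matches the framing of
the analysis as *dynamic response ability to stimulation* and makes scores
comparable across patients with different resting variance. One consequence,
quantified in the test suite: when the module's baseline intra-correlation
sits at the background level, the baseline index is a ratio of two near-zero
quantities, and the rank-1 candidate is sometimes a sub-pair of the true
module rather than the full set. The per-sample guarantee is therefore
*containment* (planted members, no background contamination); the full module
is restored at the consensus stage by pooling across patients.

Each sample also yields a ranked marker list: the best module's members
ordered by their SD fold change at the module's peak hour, extended with
members of the next-ranked modules (duplicates skipped) to exactly `k = 5`
markers. "Best dynamical markers" are read as *module members*, not
individually scored proteins — an interpretation, recorded here because the
alternative reading exists.

## Consensus core and scoring

Top-`k` lists are pooled across samples and each marker's frequency counted
([marker_frequency]); by default over all samples, with an optional
restriction (e.g. SLE samples only — both conventions appear in recurrence
analyses of this design, so both are supported). Two selection rules:
`top_m` (default `m = 4`) fixes the scoring core at the `m` most recurrent
markers; `min_frequency` (default `f_min = 5`) keeps every marker recurring
in at least `f_min` samples. Boundary ties are broken lexicographically and
always reported.

The fixed core is then scored in every patient at every timepoint —
`score(t) = I(core, t)` with no re-ranking — and the prognostic quantity is
the difference

$$\Delta = \mathrm{score}(2\,h) - \mathrm{score}(4\,h).$$

A resilient system mounts a prompt surge that has already relaxed by 4 h
(large positive $\Delta$); a system near transition responds late or not at
all (small or negative $\Delta$). Hence the outcome rule in
[predict_outcome]: $\Delta \ge$ threshold (default 0, the natural sign rule
for a difference; the boundary case counts as remission, a documented
convention) is a remission trajectory, below it a flare trajectory, with an
optional indeterminate band of configurable half-width. The prediction is
trajectory-level terminology, not a clinical claim.

Association with clinical activity uses Spearman rank correlation (midranks
under ties): exact permutation enumeration of the null for $n \le 9$ —
cohort arms sit at that boundary — and the large-sample $t$ approximation
above. Only two pre-specified variables (SLEDAI, ESR) are examined; no
multiple-testing layer is added.

## The synthetic cohort generator

Because per-patient CyTOF time courses of this design are not publicly
deposited, validation rests on a generator whose defaults *are* the study
conditions: 25 markers, 2000 cells per (patient, timepoint), hours
{0, 0.5, 1, 2, 4}, a planted 4-marker module, and a Gaussian model on the
arcsinh scale (location 2.0 keeps intensities on the nonnegative part of the
scale). Arcsinh-scale CyTOF intensities are approximately continuous, and the
Gaussian choice makes the planted correlation/SD targets exact; heavier-tailed
options are deferred. Trajectories are literal per-timepoint vectors — no
parametric curve — so the planted truth is unambiguous:

| parameter  | 0 h | 0.5 h | 1 h | 2 h | 4 h | meaning |
|------------|-----|-------|-----|-----|-----|---------|
| `rho_in`   | 0.05| 0.20  | 0.45| 0.85| 0.25| intra-module correlation |
| `sigma_in` | 1   | 1.4   | 2.1 | 3   | 1.4 | member SD (arcsinh units) |
| `rho_out`  | 0.15| 0.14  | 0.12| 0.10| 0.14| module-background correlation |

with background `rho_bg = 0.05`, `sigma_bg = 1`. Every implied block
correlation matrix is eigenvalue-checked at construction and infeasible
specifications are rejected naming the offending timepoint. That check is
binding: with a 4-member module among 21 background markers at
`rho_bg = 0.05`, a uniform module-background correlation above ~0.165 is
not positive semi-definite at the baseline where `rho_in = rho_bg`, which is
why `rho_out` starts at 0.15 rather than higher.

Patient heterogeneity is a **response delay** `w` drawn per patient from a
group-specific range (HC 0–0.25, aSLE 0.35–0.95, rSLE 0.05–0.65): the
patient's trajectories are the convex mixture `(1-w)` × canonical + `w` ×
one-step-delayed variant (peak moved from 2 h to 4 h). A pure amplitude
scaling cannot produce the negative score differences the flare arm requires,
which is why delay, not amplitude, is the default axis of group separation
(amplitude scaling is also available). Mixtures of PSD endpoints stay PSD, so
intermediate delays are always valid. SLEDAI and ESR are monotone noisy
functions of `w` honouring the clinical convention (aSLE ⇔ SLEDAI > 5,
rSLE ⇔ SLEDAI ≤ 5), so higher activity accompanies a more delayed, blunted
response — which is what makes the negative Δ/SLEDAI correlation a planted
direction the pipeline must recover, not an artifact of the test.

The latent truth per patient is the score difference computed by the *same
scoring formula on the noiseless population covariance* — truth independent
of sampling noise. The follow-up outcome is drawn with probability
`plogis(slope × latent Δ + noise)`, `slope = Inf` giving the deterministic
sign link and `slope = 0` severing the link entirely (the negative control).

Reproducibility: one master seed expands into per-(patient, timepoint)
substreams by a fixed counter scheme
(`seed·7919 + patient·104729 + timepoint·7907 mod 2³¹−1`; patient-level
randomness uses timepoint key 99), so adding a patient to a cohort never
perturbs another patient's cells.

What the generator does **not** emulate: raw ion counts, spillover, bead
normalisation, doublets, debarcoding errors, cell-population structure
(a single homogeneous population stands in for gated PBMCs — the cell
population on which the original analysis was computed is not stated, and
this assumption is flagged), non-Gaussian tails, and marker-specific
dynamics outside the planted module. Passing tests therefore demonstrate
that the pipeline recovers planted tipping-point structure under realistic
panel/depth/noise scales — not that any particular clinical dataset would
yield the same markers.

## Numerical choices and degenerate inputs

* Pairs involving a zero-variance marker contribute `r = 0` to pair
  averages (count reported), keeping `pcc_out` denominators stable across
  timepoints instead of silently shrinking them.
* An all-constant panel yields an empty candidate list with a warning; a
  missing timepoint is a hard error (no imputation — Δ needs 2 h and 4 h and
  the ranking needs the baseline).
* `module_stats` warns below 50 cells rather than refusing: tiny matrices
  are legitimate in worked examples, unstable in production.
* A double arcsinh transform is an error; the transform state and cofactor
  travel with every matrix and are recorded in the cohort metadata sidecar,
  since SD-based statistics depend on them.
* Cholesky sampling adds a `1e-10` diagonal jitter so exactly singular
  (e.g. perfectly correlated) specifications remain drawable.
* FCS ingest matches channels by the stain name (`$PnS`) falling back to the
  short name (`$PnN`); the bundled reader/writer covers FCS 3.0/3.1
  list-mode float/double/integer data in both byte orders and nothing else.

## Validation scale

The packaged validation (test suite and `scripts/acceptance.R`) runs 50
simulated cohorts of 14 patients (2 HC, 6 aSLE, 6 rSLE; 25 markers, 2000
cells per timepoint) per outcome-link setting, 20 eight-marker fixtures for
the exhaustive-search comparison, and grid/fixture checks of the index laws
— sizes chosen so the full validation completes in a few minutes on one core
while keeping Monte-Carlo margins comfortable.

## Known limitations

* The composite index form is the canonical three-condition criterion; the
  specific internal algorithm of any particular DNB software release is not
  reproduced, and equivalence is asserted only to the criterion itself.
* Fold-change ranking against a near-zero baseline index is noisy per
  sample (see above); conclusions should rest on the consensus core and the
  fixed-core score trajectories, which is how the pipeline is assembled.
* The Δ threshold separating remission from flare trajectories defaults to
  the sign rule; no data-driven cutoff estimation is provided.
* No survival/time-to-flare modelling, no network visualisation, no
  protein-interaction enrichment of core members.
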