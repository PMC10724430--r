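# dnbsle

Dynamic network biomarker (DNB) analysis of single-cell protein
stimulation time courses, built for the question: *can the way a patient's
immune network responds to an IL-2 pulse predict whether their lupus will
remit or flare?*

DNB theory holds that, near a critical transition, a small group of
molecules starts to fluctuate strongly and coherently while decoupling from
the rest of the network. For a marker subset $M$ observed over cells at one
timepoint, with $\mathrm{sd}_{in}$ the mean member SD, $\mathrm{pcc}_{in}$
the mean absolute pairwise Pearson correlation within $M$, and
$\mathrm{pcc}_{out}$ the mean absolute correlation between members and
non-members, the composite index is

$$I = \frac{\mathrm{sd}_{in}\cdot\mathrm{pcc}_{in}}{\mathrm{pcc}_{out}+\varepsilon},\qquad \varepsilon=10^{-6}.$$

The pipeline, aimed at mass-cytometry (CyTOF) measurements of PBMCs at 0,
0.5, 1, 2 and 4 h of IL-2 stimulation:

1. **Ingest** — FCS 3.0/3.1 or delimited tables, arcsinh transform
   (cofactor 5), uniform cell subsampling, cluster abundances and group
   ratios.
2. **Per-sample module search** — average-linkage clustering on $1-|r|$
   generates candidate modules; each is ranked by the surge of $I$ relative
   to the unstimulated baseline, $\max_{t>0} I(t)/(I(0)+\varepsilon)$.
3. **Consensus core** — each sample's top-5 dynamical markers are pooled;
   the most recurrent `m = 4` markers (or all with frequency ≥ 5) form the
   cohort-wide scoring core.
4. **Scoring & prognosis** — the fixed core is scored at every timepoint;
   $\Delta = \mathrm{score}(2h)-\mathrm{score}(4h)$ is correlated with
   SLEDAI/ESR (Spearman) and thresholded (default 0) into
   remission-trajectory vs flare-trajectory calls.
5. **Synthetic cohorts** — a generator with planted tipping-point structure
   (block-correlated Gaussian on the arcsinh scale, per-patient response
   delay, outcome linked to the latent Δ) validates every stage end to end.

See `vignettes/dnb-methods.Rmd` for the model, parameter meanings and design
choices.

## Worked example

```r
library(dnbsle)

params <- simulation_params(seed = 7)          # 25 markers, planted module M01-M04
cohort <- simulate_cohort(params, n_per_group = c(HC = 2, aSLE = 6, rSLE = 6))
out    <- run_dnb(cohort)                      # rank -> pool -> core -> score
out$core
#> <dnb_core> rule top_m (m = 4): M02, M03, M04, M01
print(out$report)
```

The consensus core recovers the planted module exactly. The report prints
per-patient Δ with outcome calls, e.g.

```
 patient_id group  delta prediction   outcome
     aSLE05  aSLE -3.625      flare     flare
     aSLE06  aSLE  8.858  remission remission
     rSLE01  rSLE 15.231  remission remission

Group mean trajectories:
 group score_0 score_0.5 score_1 score_2 score_4
  aSLE  0.3659     0.945   4.230   14.35  11.150
    HC  0.2854     1.876   7.351   24.19   3.146
  rSLE  0.3426     1.480   5.775   18.94   6.092

Spearman correlation of the score difference with clinical activity:
 variable     rho         p  n          method
   SLEDAI -0.9057 8.260e-06 14 t approximation
      ESR -0.9473 2.774e-07 14 t approximation
```

Patients with a prompt, already-relaxed response (large positive Δ) are
remission trajectories; delayed, blunted responders (the active-SLE pattern
— note the flattest group mean) score negative Δ and are called flare
trajectories. Δ correlates negatively with disease activity (SLEDAI) and
inflammation (ESR), and `prediction_accuracy(out$report)` here is 1.0
against the simulated follow-up outcomes.

A thin CLI mirrors the stages: `exec/dnb simulate|run|consensus|score`.

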