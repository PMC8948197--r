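---
title: "Pathway flux scoring and the IM-Index: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway flux scoring and the IM-Index: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imflux)
```

## The model

`imflux` scores per-sample pathway activity from bulk expression through a
layered knowledge network: genes feed molecular species, species participate
in typed reactions, reactions group into pathways, and pathways feed back to
genes only through transcriptional-regulator participants (`tr_a`, `tr_r`) —
there is no separate feedback edge type. Three definitions carry everything:

1. **Species concentration.** The concentration of a species is the product
   of the expression values of its constituent genes, taken on the linear
   (TPM-like) scale. A complex of two genes expressed at 2 and 3 has
   concentration 6. Species marked constant (water, oxygen, and other
   compounds assumed not to change during evaluation) return a fixed value —
   conventionally 1, so they are flux-neutral.
2. **Reaction flux.** Mass action: the rate constant times the product of
   the concentrations of all activating participants (enzyme, gene,
   substrate, transcriptional activator). Every inhibiting participant
   (inhibitor, transcriptional repressor) divides the flux by
   `1 + c(inhibitor)`.
3. **Pathway flux.** The mean of the pathway's reaction fluxes, minus the
   mean *base* flux of its crosstalk partner pathways (zero when it has
   none).

The IM-Index of a sample is
`alpha * sum(signaling-transduction pathway fluxes) + beta * sum(energy-metabolism pathway fluxes)`,
with `alpha = beta = 1` by default. No information is currently available to
set the two weights more finely; they are exposed so users can explore
reweighting, and the index is exactly linear in both.

### Assumptions worth stating

* **Inhibition semantics.** The mass-action formulation does not by itself
  say how an inhibitor enters a product of concentrations — a bare product
  would make inhibitors *increase* flux. We chose divisive attenuation,
  `flux ∝ 1/(1 + c)` per inhibiting participant: zero inhibitor means no
  attenuation, flux stays nonnegative, and attenuation saturates smoothly.
  This is an interpretation, and the one place where a different reading
  would change numbers.
* **Linear scale.** Expression values act as concentration surrogates with
  no log transform: mass action is multiplicative in concentrations. A
  `floor` argument (default 0) substitutes for network genes absent from the
  expression matrix; with the default, a reaction lacking any constituent of
  an activating participant is silenced, which is the mass-action reading of
  an absent reactant. Coverage below 100% is warned about once per run.
* **One-level crosstalk.** The pathway-flux definition is formally circular
  (crosstalk partners have crosstalk of their own). We evaluate exactly one
  level: the subtracted term uses partners' base fluxes only. This
  guarantees termination and a unique value for any link topology, including
  cycles. A consequence users should know: the subtraction can make a
  pathway's reported flux — and in small networks even the whole index —
  anti-correlate with the activity of a partner pathway. Reported fluxes may
  be negative; they are not clamped, and the index sums them raw.

## Statistical battery

* **Group tests.** Kruskal–Wallis (three or more groups) and the two-group
  Wilcoxon rank-sum test, both on midranks with tie correction, via the
  standard R implementations. Two conventions: a totally tied score vector
  returns H = 0, p = 1 (the tie-correction denominator would otherwise be
  0/0, and total ties carry no evidence of group differences); and the
  Wilcoxon p is exact for small tie-free samples, switching to the
  tie-corrected normal approximation otherwise.
* **ROC/AUC.** The AUC is the midrank Mann–Whitney estimator (ties count
  one half), so it equals U/(n⁺·n⁻) and is invariant to monotone transforms
  of the score. Confidence intervals are percentile bootstrap with
  resampling stratified by class, which preserves class counts and keeps the
  AUC defined in every replicate; the default is 2000 replicates.
* **Classifier comparison.** One-sided: the null is that the competing
  marker classifies as well as or better than the index. Each stratified
  replicate resamples the same subjects for both scores and computes
  `d* = auc_index* − auc_other*`; the p-value is
  `(1 + #{d* ≤ 0}) / (n_boot + 1)`. The add-one correction keeps Monte-Carlo
  p-values off exact zero.
* **Odds ratios.** Single-predictor logistic regression on complete
  observations (IRLS, tolerance 1e-8, at most 100 iterations), Wald 95% CI.
  Because a per-unit OR of a continuous index depends on the index's scale,
  the per-SD OR is reported alongside. Complete separation is detected and
  flagged with an infinite-OR sentinel rather than silently reporting a
  diverged coefficient; constant scores are flagged as degenerate.
* **Spearman screening.** Midrank Spearman rho — the Pearson correlation of
  midranks — with a t-approximation p on n − 2 degrees of freedom. This
  midrank form (rather than the classical 1 − 6ΣD²/(n³−n) formula, which
  differs under ties) is used deliberately so tied data are handled
  consistently with the rest of the rank machinery.
* **Differential flux.** Per pathway, Kruskal–Wallis (or Wilcoxon for two
  groups) on the flux column; Bonferroni across the pathways tested,
  `p_adj = min(1, m·p)`. Bonferroni rather than FDR is the convention this
  analysis family reports. Rows come back sorted by raw p.

## The synthetic-data generator

The generator exists so every stage is testable without access to any
proprietary network or patient cohort. It emulates the *statistical
structure* the analysis assumes, not raw RNA-seq:

* **Networks.** Genes are partitioned round-robin into one disjoint pool per
  pathway, and each pathway's species draw constituents from its own pool —
  so a group effect planted on one pathway's feeding genes shifts exactly
  that pathway, and ground truth is crisp. Every reaction has the same
  activating backbone (substrate species + enzyme-or-activator species + one
  direct gene participant, two constituent genes per species by default),
  with an inhibiting participant added at rate `inhibitor_fraction` and a
  constant water-like compound joining some reactions. The homogeneous
  backbone is deliberate: under a multiplicative engine, reactions with
  different activating-factor counts produce pathway fluxes differing by
  orders of magnitude, and a summed index would be dominated by one
  arbitrary pathway. Crosstalk links are independent per ordered pathway
  pair. All six participant roles occur. Generation is deterministic given
  the spec, and requested layer counts are recovered exactly by
  `network_summary()`.
* **Cohorts.** Three groups (malignant / benign / control; default sizes
  78/21/40, echoing the kind of unbalanced nodule cohort this analysis
  targets). Gene baselines are drawn once per gene from
  LogNormal(log 5, 0.25); each sample multiplies its group's effect onto
  driver-pathway feeding genes (defaults 2.0 / 1.4 / 1.0, control as
  reference) and adds per-gene lognormal noise (sd 0.3 on the log scale).
  Drawing the baseline per gene rather than per sample keeps gene identity
  meaningful across the cohort; the per-sample term is the noise. A gene
  "feeds" a driver pathway when it fuels any non-inhibiting participant of
  any of the pathway's reactions — inhibitor fuel is excluded because
  up-shifting it would invert the intended direction.
* **What it does not emulate.** Negative-binomial count noise, library-size
  effects, gene–gene correlation beyond shared species membership, and the
  many-orders-of-magnitude spread of real TPM distributions. The narrow
  baseline spread is a modelling choice (see above); it follows that passing
  recovery tests demonstrate the pipeline's internal correctness and the
  index's behaviour under commensurate pathway fluxes, *not* that the index
  works on raw TPM-scale clinical data, where pathway-magnitude imbalance
  and crosstalk cancellation are real concerns an analyst must assess.

## Validation experiments and problem sizes

The test suite validates the flux engine against an independent brute-force
evaluator on 100 random networks (up to 25 reactions each) at 1e-9 relative
tolerance, checks the AUC against pair enumeration and the Mann–Whitney
identity on 100 random instances with ties, checks the rank tests against
exact enumeration on fixtures of up to 8 samples and the logistic OR against
the closed-form 2×2 cross-product ratio. Signal recovery uses a 30/30/30
cohort over a crosstalk-free 4-pathway network (driver multipliers
2.0/1.4/1.0): mean index ordering malignant > benign > control,
Kruskal–Wallis p < 0.001, malignant-vs-benign AUC ≥ 0.95, and the driver
pathway ranked first. The crosstalk-free recovery network is itself a design
choice: in a miniature network a crosstalk link pointing at the driver
subtracts the driver's base flux from a partner and can cancel the planted
effect in the index sum exactly — an artifact of few-pathway models that
dilutes away at realistic pathway counts; crosstalk correctness is covered
by the oracle-equivalence and round-trip tests instead. Null calibration
uses 100 cohorts of 50 + 50 with all multipliers 1 (AUC within [0.35, 0.65]
at least 95% of the time) and 200 noise-vs-noise classifier comparisons
(rejection at the 5% level at most 10%). These sizes keep the whole suite
comfortably interactive while leaving the Monte-Carlo margins wide.

## Numerical and degenerate-input conventions

* Validation is total and collective: a network file either satisfies every
  structural invariant or is rejected with *all* problems listed.
* Species with no constituents and no constant value are accepted
  structurally but raise a configuration error the moment a concentration is
  requested — the concentration simply is not defined.
* Serialization is canonical: fixed key order, two-space JSON indentation,
  so equal networks produce byte-identical files; the pipeline's
  `stats.json` (floats at 12 significant digits) contains no timestamp, so
  re-runs with the same inputs, config and seed are byte-identical.
* All randomness in a pipeline run flows from one master seed through
  labelled child streams (`child_seed()`), so adding a consumer never
  perturbs another's stream.

## Known limitations

Rate constants default to 1 (no kinetic-database integration), so fluxes are
comparative, not physical. The crosstalk subtraction can cancel genuine
signal in small networks, as discussed. The index weights α and β are
unidentified without external calibration data. And the generator's
lognormal baseline is an assumption — no distributional description of real
cohorts backs it — so synthetic results transfer to real data only to the
extent the commensurability assumption holds there.
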