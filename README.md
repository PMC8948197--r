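# imflux

Pathway flux analysis and an immune-related diagnostic index (IM-Index)
for bulk blood transcriptomes.

## The problem

Peripheral-blood leukocytes carry a system-wide readout of host immunity.
Given a gene-expression profile of a blood sample and a curated knowledge
network — genes, molecular species (RNA, protein, complex, compound), typed
reactions, and pathways labelled as *signaling transduction* or *energy
metabolism* — one can ask how much "information flux" each pathway carries in
that sample, and whether a score summarising those fluxes separates clinical
groups (for instance malignant vs. benign pulmonary nodules vs. healthy
controls). `imflux` implements that whole chain for anyone who wants to score
pathway activity per sample from bulk expression and evaluate the result as a
classifier.

## The model

Concentrations follow mass action on the linear expression (TPM) scale.
For a species *S* with constituent genes *g₁…g_k*,

    c(S) = ∏ᵢ x(gᵢ)          (constant species: c(S) = its fixed value)

For a reaction *R* with rate constant *k_R*, activating participants *A*
(roles: enzyme `e`, gene `g`, substrate `s`, transcriptional activator
`tr_a`) and inhibiting participants *I* (inhibitor `i`, transcriptional
repressor `tr_r`),

    flux(R) = k_R · ∏_{a ∈ A} c(a) / ∏_{i ∈ I} (1 + c(i))

For a pathway *P* with N(P) reactions and crosstalk partners Q,

    flux(P) = (1/N(P)) Σ_{R ∈ P} flux(R) − mean_{Q} base(Q)

where base(Q) is Q's own mean reaction flux (crosstalk is evaluated one
level deep only). The diagnostic score is

    IM-Index = α · Σ_{P ∈ signaling} flux(P) + β · Σ_{P ∈ metabolism} flux(P)

with α = β = 1 by default. The package adds the statistical battery used to
evaluate such a score: Kruskal–Wallis and Wilcoxon rank tests, midrank
ROC/AUC with stratified-bootstrap 95% CIs, one-sided bootstrap comparison of
two classifiers, logistic odds ratios (per unit and per SD), Spearman
screening against biomarkers, and per-pathway differential flux with
Bonferroni correction. A synthetic-data module generates miniature networks
and three-group lognormal cohorts with planted driver-pathway effects so the
full pipeline is testable end to end.

## Worked example

```r
library(imflux)

net <- generate_network(network_spec(n_genes = 40, n_pathways = 4,
                                     reactions_per_pathway = 4,
                                     crosstalk_density = 0, seed = 11))
network_summary(net)
#> Knowledge network: 40 genes, 55 species, 16 reactions, 4 pathways
#>   pathway classes: signaling_transduction=2, energy_metabolism=2
#>   participant roles: e=6, g=16, s=22, tr_a=10, i=5, tr_r=1

coh <- generate_cohort(net, cohort_spec(
  group_sizes = c(malignant = 30, benign = 30, control = 30), seed = 11))

flux  <- compute_flux_matrix(coh$expression, net)
index <- compute_im_index(flux, coh$labels)

kruskal_wallis(index, im_index, group)
#>   statistic    df  p_value     n
#> 1      72.1     2 2.17e-16    90

pair <- dplyr::filter(index, group %in% c("malignant", "benign"))
roc_with_bootstrap(pair, im_index, group, positive = "malignant",
                   n_boot = 2000, seed = 1)
#> ROC: AUC = 0.989 (95% CI 0.964-1.000), 30 pos / 30 neg, 2000 bootstrap replicates

differential_pathway_flux(flux, coh$labels)
#>   pathway_id statistic    p_raw p_bonferroni
#> 1 P01          77.7    1.33e-17     5.31e-17
#> 2 P02           1.87   3.92e- 1     1   e+ 0
#> 3 P03           1.17   5.58e- 1     1   e+ 0
#> 4 P04           0.0853 9.58e- 1     1   e+ 0
```

The cohort plants a 2.0× / 1.4× / 1.0× expression shift on the genes feeding
the first pathway (`P01`) in the malignant / benign / control groups. The
Kruskal–Wallis test confirms the index separates the three groups, the ROC
shows near-perfect malignant-vs-benign discrimination, and `P01` tops the
differential-flux ranking with everything else null. On this cohort the
groups separate completely, so `logistic_odds_ratio()` flags complete
separation and reports an infinite-OR sentinel instead of a spuriously
"converged" estimate.

`autoplot()` works on the index table (group boxplot), the ROC object
(ROC curve) and the flux matrix (heatmap); `tidy()`/`glance()` follow broom
conventions for the ROC, comparison and odds-ratio objects.

`run_pipeline()` (or the thin CLI at `inst/cli/imflux.R`) runs the whole
chain from files — network JSON, expression TSV, labels TSV — and writes
`flux.tsv`, `im_index.tsv` and a `stats.json` report with full run metadata;
re-runs with the same inputs and seed are byte-identical.

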