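---
title: "Cross-study compositional biomarker discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study compositional biomarker discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codamarker)
```

## The problem

Stool metagenomes of melanoma patients differ between those who respond to
immune checkpoint inhibitors (responders, `R`) and those who do not (`NR`),
but individual cohorts rarely agree on *which* species matter. `codamarker`
implements a cross-study strategy for this problem: rank features within each
cohort by a compositional regression coefficient, call the extremes, and keep
only the calls that replicate across cohorts and survive validation in
held-out cohorts. The package covers species profiles, functional gene-group
(KEGG orthology) profiles, donor-derived profiles from fecal microbiota
transplantation (FMT) cohorts, and the linking of functional biomarkers back
to the species that carry them.

Metagenomic profiles are compositions: sequencing depth is arbitrary, so only
ratios between features are informative. Every statistic in the package
respects this — the differential ranking model conditions on per-sample
compositions, group assessment uses log-ratios of feature sets, and
ordination-style testing uses the Aitchison (clr-Euclidean) distance.

## The differential ranking model

For feature $j$ and sample $i$ with response indicator $x_i \in \{0, 1\}$:

$$\mathbf{y}_i \sim \mathrm{Multinomial}\!\left(N_i,\
\mathrm{softmax}(\beta_{0} + x_i \beta_{1})\right)$$

with a ridge penalty $\lambda \lVert \beta_1 \rVert^2$ on the response
coefficients. The softmax link makes the likelihood invariant to adding a
constant to all features' coefficients, so only *relative* enrichment is
estimated; the reported **differential** of feature $j$ is
$\beta_{1j} - \overline{\beta_1}$ (mean-centered across features, the
"feature mean" reference frame). Positive differentials mean relative
enrichment in responders. Differentials are used for *ranking* and
thresholded set logic, never as calibrated effect sizes.

Numerical choices, in order of how much they matter:

* **Compositional conditioning.** Every sample is renormalized to a common
  effective depth (`pseudo_depth`, default 10,000) before fitting. The
  estimand depends only on compositions, so this makes the differentials
  exactly invariant to per-sample depth rescaling; the cost is that a deep
  sample no longer counts more than a shallow one. With raw counts the
  near-maximum-likelihood fit drifts by up to ~0.2 under depth reweighting,
  which is larger than the 0.1 validation threshold the rule system uses —
  an unacceptable sensitivity to a quantity that carries no compositional
  information.
* **Shrinkage, and where it applies.** Intercepts are never penalized:
  shrinking $\beta_0$ biases the fitted baseline abundance of rare features,
  and the group coefficient then absorbs the misfit as a spurious
  differential (empirically, penalizing intercepts made null differentials
  *grow* with $\lambda$). The default $\lambda = 100$ at the default
  pseudo-depth corresponds to a Gaussian prior with SD $\approx 0.07$ on
  log-fold coefficients: a feature needs a few hundred total (pseudo-)counts
  before its differential escapes the prior. The value was calibrated on
  simulated data (held-out seeds) as the middle of a wide flat region
  ($\lambda \in [50, 200]$) in which planted $\ln 4$ effects are always
  recovered in top-20 calls and all-null worlds validate nothing. For
  near-ML estimates (e.g. against analytic oracles) pass a small value.
* **Optimization.** L-BFGS-B with analytic gradients from a zero start;
  convergence at $10^{-8}$ relative objective change, at most 5,000
  iterations. The fit is deterministic; the `seed` argument is recorded in
  `fit_info` only for provenance.
* **Zeros.** The multinomial likelihood tolerates zero counts, so no
  pseudocounts enter the model. A prevalence filter (default: feature present
  in ≥ 10% of samples) is applied before fitting because features observed a
  handful of times have differentials dominated by the prior, not data.
* **Ties.** Rank order and top-k calls break ties by feature id
  (lexicographic), making every output deterministic.

## The rule system

`call_top_k()` marks the $k$ highest positive differentials per dataset as
associated with response (`RMI`) and the $k$ lowest negative ones as
associated with unresponsiveness (`UMI`); $k = 20$ for taxa and $k = 200$ for
gene groups. `consolidate()` then applies two rules across datasets:

1. a feature called in the same direction in **more than one** dataset enters
   the consolidated list;
2. a feature called in the **opposite** direction in even one dataset is
   excluded, regardless of how much support it has.

`validate_biomarkers()` applies the validation pass on held-out cohorts: a
consolidated feature survives only if its differential keeps its sign in
*every* validation cohort and has magnitude at least 0.1 in every validation
cohort. A feature absent from a validation dataset (e.g. removed by the
prevalence filter there) is conservatively treated as a contradiction — the
alternative (skipping the dataset) would let a biomarker validate without
being observed. For the log-ratio assessment of the validated set,
`select_denominator()` takes the features with differentials strictly below
−0.5; if that set is empty the pipeline falls back to the bottom-k calls.

One subtlety: "removing a dataset never adds a consolidated feature" is *not*
a theorem of this rule system — removing the one dataset that carried an
opposite-direction call can rescue a feature excluded by rule 2. The tests
check the qualified version.

## Log-ratio assessment and distances

`log_ratio()` computes, per sample, $\ln(\sum_{\text{numerator}} y /
\sum_{\text{denominator}} y)$. Samples with a zero sum on either side carry
no information about the ratio and are dropped and counted (`n_dropped`)
rather than patched with pseudocounts — the dropped count is part of the
result because a log-ratio computed on 10% of samples means something
different from one computed on all of them. Group comparison uses a
two-sided Wilcoxon rank-sum test: exact enumeration (dynamic programming
over the rank-sum distribution) when both groups have ≤ 12 untied
observations, otherwise the normal approximation with tie and continuity
corrections. Benjamini–Hochberg is the step-up $q_{(i)} = \min_{j \ge i}
m\,p_{(j)}/j$.

`aitchison_distance()` is the Euclidean distance between clr transforms;
pseudocounts (default 1 on counts) are required only when zeros are present.
`permanova()` uses the Gower-centered sum-of-squares decomposition with
freely permuted labels, 10,000 permutations by default, and the add-one
p-value correction, so $p \ge 1/(B+1)$. For FMT time series the repeated
samples of one subject are permuted freely — the same simplification the
source analyses make — which is anticonservative for the response factor;
the vignette flags rather than fixes this because subject-aware permutation
would change the estimand being replicated.

## FMT colonization analysis

Read-level attribution of post-FMT reads to the donor is out of scope;
`classify_species_origin()` is a documented profile-level proxy. A species
present in a post-FMT sample is `donor_derived` if present in the donor
baseline and absent from the recipient's pre-FMT baseline(s),
`recipient_derived` in the mirror case, `common` if present in both (origin
unresolvable from profiles — excluded from donor-derived tables by default),
`new` if in neither. Presence means abundance strictly above a threshold
(default 0: any detection). Raising the threshold can only move species
toward `absent`, never the reverse. Donor-derived tables feed the same
differential ranking machinery, and `variance_decomposition()` runs one
PERMANOVA per factor (donor identity, response) on the same distance matrix
with BH adjustment across factors.

## What the synthetic generator emulates — and what it does not

`generate_case_control_study()` draws per-sample compositions as
$\mathrm{softmax}(\text{baseline} + g\cdot\text{log-fold} +
\text{study bias} + \text{sample noise})$ and multinomial counts at
log-normal depths (CV 0.3, emulating the spread of per-cohort read counts in
published melanoma datasets). Defaults: baseline logits $N(0, 2)$ (a
realistic long-tailed abundance distribution), per-study per-feature bias
$N(0, 0.5)$ (emulating DNA-extraction batch effects), per-sample jitter
$N(0, 0.3)$ (overdispersion relative to the multinomial). Planted effects
default to $\ln 2$–$\ln 4$; published data give no effect-size scale, so
these are chosen for testability, not biological fidelity. Planted features
have their baseline logit floored at −1 (moderate prevalence), because the
reported real biomarkers sit in the 36–99% prevalence range and effects
planted on vanishingly rare species are undetectable by construction.

`generate_multi_study()` gives consistent features a positive effect in
*every* study (discovery and validation) — replication across cohorts is the
phenomenon under study — and inconsistent features a positive effect in two
studies and a negative one in a third, so the exclusion rule has real work to
do. `generate_fmt_cohort()` assigns each recipient one random donor,
alternates R/NR labels, and engrafts donor-specific species with
response-dependent probability; optional `response_linked` species are forced
to be donor-carried and baseline-absent everywhere (otherwise the "planted
engrafter" may be unplantable for most recipients). Donor assignment is
random rather than round-robin because round-robin with alternating labels
confounds donor and response exactly when the donor count is even.

The generator does **not** emulate: strain-level structure, read-level
sampling, taxonomic misclassification, correlated feature dynamics
(interactions), longitudinal drift within a recipient beyond the single
baseline/post mixture, or compositional zeros that are structural rather
than sampling-driven. A green recovery test therefore establishes that the
pipeline's logic and statistics behave as designed under its own model — not
that the biological claims of any particular study are correct.

## Function–taxon linking

The link table (taxon id, gene-group id) is an input, standing in for
assembly-graph context classification of functional features; links are
unweighted presence, and one gene group may link to many species.
`rank_species_by_biomarkers()` counts linked biomarkers per species;
`coverage_of_combination()` computes the fraction of the biomarker set
linked to at least one member of a species combination (monotone under
union); `phylum_contrast()` compares per-species counts between phyla with
pairwise Wilcoxon tests, BH-adjusted. `export_link_network()` emits the
phylum-aggregated bipartite edge list; drawing is out of scope.

## Pipeline determinism

One master seed is split per stage and dataset by hashing labels
(`split_seed()`), so any stage can be re-run in isolation and full reruns are
byte-identical. Configs are JSON (no YAML parser in the supported
environment); every output directory contains `config_echo.json` with the
resolved configuration and package version.

## Known limitations

* Differentials are rank-comparable but not numerically comparable to any
  particular reference implementation of multinomial ranking, because
  training hyperparameters differ; all thresholds in the rule system
  (0.1, −0.5) therefore inherit a dependence on the shrinkage default.
* The profile-level donor-derived proxy cannot resolve `common` species;
  read-level methods can.
* PERMANOVA on FMT time series ignores subject identity (see above).
* The bundled published tables are inputs for the rule-system worked
  examples; recomputations that require the original supplementary
  spreadsheets are not possible offline and are not claimed.
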