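---
title: "Methods: Bayesian-network risk-factor analysis for case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian-network risk-factor analysis for case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibn)
```

## The analytic problem

`epibn` models the dependence structure between a chronic disease (type 2
diabetes, coronary heart disease, or their comorbidity) and its candidate
risk factors in a case-control design: each case group is contrasted with a
shared healthy control group over 27 variables — demographics, family
history, lifestyle, diet, physical examination and laboratory values. The
end product per disease is a discrete Bayesian network: a directed acyclic
graph whose nodes carry conditional probability tables (CPTs), supporting
predictive reasoning (factor evidence in, disease posterior out),
diagnostic reasoning (disease clamped, factor posteriors out), and a
variance-based sensitivity ranking.

A Bayesian network was preferred over logistic regression alone because it
does not require predictor independence, it quantifies direct versus
indirect pathways, and — because inference marginalizes over unobserved
nodes — it yields valid posteriors for records with missing fields, a
routine situation in clinical data.

## Pipeline stages and their assumptions

### Variable screening

Each variable is compared between one case group and the controls:
Pearson's χ² without continuity correction for categorical variables,
Welch's unequal-variance *t* for approximately symmetric continuous
variables, and the tie-corrected normal approximation of the Mann–Whitney
rank-sum test for the two right-skewed laboratory values (fasting blood
glucose, triglycerides — the ones summarized as median and quartiles
rather than mean ± SD). The gate is *P* < 0.05 with no multiplicity
adjustment, matching the original univariate-screening convention; a
`p.adjust` option exists but is off by default.

Two choices deserve a note. The χ² statistic is computed without Yates'
correction because the corrected statistic does not reproduce the
published sex-comparison values while the uncorrected one does. The *t*
test is Welch's by default: the published age statistic is reproduced
within 0.1% from the printed summaries by either flavor, and Welch is
robust to the clearly unequal group variances. Welch-from-summaries uses
the standard Welch–Satterthwaite degrees of freedom. Degenerate inputs
(both samples constant, or fully tied ranks) return a zero statistic with
a warning rather than `NaN`.

### Stepwise logistic selection

Forward selection by the likelihood-ratio criterion: at each step the
candidate with the smallest LR *p*-value below `p_enter = 0.05` joins the
model; after every entry, included variables whose removal LR *p* exceeds
`p_remove = 0.10` are dropped. These thresholds are the classic Forward:LR
defaults. Categorical predictors enter and leave as whole blocks of
reference-coded indicators (the reference is the codebook's control
level). Continuous predictors stay on their raw scale at this stage —
per-unit odds ratios (e.g. a ~3% increase per heart-rate unit) are only
meaningful that way — and are discretized *after* selection, for network
learning only. Fits are maximum likelihood via iteratively reweighted
least squares (`glm`, binomial family, tolerance 1e-10, 50 iterations
max); complete or quasi-complete separation is flagged when any
coefficient exceeds 15 in absolute value or the fit fails to converge.
Ties in entry *p*-values are broken by candidate order, then name, so the
procedure is deterministic. A repeated-model guard stops any
enter/remove cycling when `p_enter` and `p_remove` are set
inconsistently.

Odds-ratio intervals use `z = 1.959964`; this reproduces published
interval bounds to the printed precision. Where a published table lists an
odds ratio below 1 with a positive coefficient magnitude, the package
reports the signed coefficient consistent with `OR = exp(beta)` — the
sign convention, not the magnitude, is the reconcilable difference.

### Discretization codebook

The default codebook reproduces the study's coding scheme: 17 categorical
variables with labelled integer codes and control reference levels, and 10
continuous rules (age bands 18–44/45–59/60+; BMI at 18.5/24/28 kg/m²; SBP
140 mmHg; DBP 90 mmHg; heart rate with a 60–100 inclusive normal band;
FBG 7.0, TG 2.3, TC 6.2 mmol/L). Bins are half-open `[lo, hi)` so the
touching decimal labels (…23.99 | 24.0…) tile the whole real line without
gaps; the heart-rate upper cut is right-closed so that 100 is normal and
101 is fast. Two lipid rules are clinically atypical as published — the
HDL-C abnormality threshold at 2.3 mmol/L and the reversed LDL-C rule
(abnormal below 1.0 mmol/L). Both look like transcription artifacts of
the source table, but absent an erratum they are implemented exactly as
printed; the codebook is a plain declarative object, so a user analysing
real data overrides either rule in one line. Adults are assumed, but ages
below 18 simply fall into the lowest band rather than erroring, so
generator edge cases cannot crash the pipeline.

### Structure learning

Score-based search over DAGs with the decomposable BIC (higher is
better):

$$\mathrm{score}(G) = \sum_i \sum_{j,k} N_{ijk}\,
\ln\frac{N_{ijk}}{N_{ij}} \;-\; \frac{\ln N}{2}\sum_i q_i\,(r_i-1),$$

where node *i* has \(r_i\) states and \(q_i\) parent configurations, with
\(0\ln 0 \equiv 0\). The source analysis names tabu search but not its
scoring criterion; BIC is the de-facto default of score-based tabu
implementations and is what the package uses (a likelihood-only option
exists for teaching). A family whose parent-configuration count exceeds
\(2^{20}\) scores \(-\infty\), which keeps move evaluation bounded without
affecting any realistic search trajectory.

The tabu search starts from the whitelist-only graph and repeatedly
applies the best-scoring legal move (edge addition, deletion or reversal
preserving acyclicity and the constraints) that is not on the tabu list;
a tabu move is admitted if it beats the best score seen (aspiration). The
inverse of each applied move is forbidden for `tenure = 10` iterations;
the search stops after `window = 50` consecutive non-improving iterations
or `max_iter = 1000` total, returning the best DAG encountered.
Equal-scoring moves are broken by (move type, source, target) order, so
the search is deterministic for fixed data. Scored families are cached by
(child, parent-set), which makes each iteration cost one or two fresh
family counts rather than a full rescore.

Expert knowledge enters as edge constraints. The default blacklist
forbids arrows *into* immutable characteristics — age, sex, area and the
family-history nodes — the standard epidemiological encoding of "fixed
attributes cannot be effects"; it is fully overridable. The exact expert
constraints of the original analysis were not published, and the original
arc sets depend on the non-public data, so structural output is validated
by recovery tests on declared ground truths (below), not by matching the
published diagrams.

Learned DAGs are compared up to Markov equivalence via their CPDAG
(skeleton + v-structures + Meek closure rules R1–R3), since
observational data cannot distinguish equivalent orientations.

### Parameter learning and inference

CPTs are pure maximum likelihood, \(\hat\theta_{ijk} = N_{ijk}/N_{ij}\),
with no smoothing — published CPTs contain exact 0.000/1.000 entries,
which only unsmoothed MLE produces. A `smooth` pseudo-count option exists
for users who need strictly positive tables. Parent configurations absent
from training data receive a uniform row and a warning, so downstream
inference stays defined. State vocabularies are passed explicitly from
the codebook so a state absent from the training split is still a valid
(zero-probability) CPT column rather than an unknown label at test time.

Inference is exact variable elimination: CPT factors are conditioned on
the evidence, non-query variables are summed out in min-degree order, and
the result is normalized. Networks here have ≤ ~18 nodes, so junction
trees are unnecessary. Evidence with zero probability under the network
raises an explicit error rather than returning `NaN` — with unsmoothed
CPTs this surfaces genuine structural zeros instead of hiding them.
Classification thresholds the disease posterior at 0.5 by default (the
original cut-off is unstated; the threshold is a parameter and the ROC
sweep makes results threshold-transparent).

### Validation and sensitivity

Hold-out validation uses a seeded stratified 70/30 split
(`floor(0.7 n)` training rows per stratum). Metrics with zero
denominators are reported as `NA`, never as 0. The AUC is computed in its
rank (Mann–Whitney) form, which equals the trapezoidal area under the
threshold-swept curve and handles tied scores exactly; the 95% interval
uses the Hanley–McNeil standard error (the original interval method is
unnamed; a seeded stratified bootstrap is available as an option).

Sensitivity follows the variance-reduction definition used by Netica-style
tools: with the disease valued as a 0/1 indicator,
\(100\,(V - \sum_f P(f)\,V_f)/V\), where \(V = p(1-p)\) is the prior
variance and \(V_f\) the conditional variance given finding state *f*.
The indicator valuation must be fixed for the percentage to be defined;
0/1 is the natural choice for absent/present. For a binary finding the
quantity equals the squared correlation of the two indicators under the
network joint, a convenient cross-check identity. Mutual information
("entropy reduction") is available as a secondary column.

## The synthetic cohort generator

The generator exists because the original hospital records are available
only on request; it makes every pipeline stage testable with no download.
It has two modes.

**Marginal-matching mode** reproduces the published group-level
description: exact group sizes (1175 controls, 1163 T2DM, 982 CAD, 504
comorbidity), every categorical marginal (normalized published counts),
and every continuous summary — normals truncated at zero for mean ± SD
variables, log-normals matched to the median and quartile ratio
(\(\sigma_{\log} = \ln(q_{75}/q_{25})/(2z_{0.75})\)) for the two skewed
labs. Within a group, variables are drawn independently: group-level
summaries carry no joint information, so dependence enters only through
group membership. Consequently the synthetic cohort is *more separable*
than real data — hold-out metrics and AUCs on it (≈0.96–0.99) exceed the
published real-data values (≈0.84–0.88), and passing end-to-end tests
demonstrates pipeline correctness, not real-data performance. Each group
draws from its own fixed-offset substream of the master seed, so results
are reproducible and adding a group never perturbs the others.

Three published summary entries are physiologically impossible as printed
(a comorbidity heart-rate mean of 6.55/min; upper quartiles below the
median for T2DM fasting glucose and for triglycerides). They are treated
as transcription artifacts — restored to 76.55 and to the smallest
leading digit making the quartile exceed the median (11.40, 1.72, 2.21,
1.81, 2.02, 9.73) — with `correct_typos = FALSE` available to keep the
verbatim values.

**Recovery mode** forward-samples from a declared ground-truth network by
ancestral sampling, for structure- and parameter-recovery testing. The
8-node recovery truth used in the tests has every conditional probability
at 0.1 or 0.9 and a fully compelled CPDAG; each v-structure pairs a chain
node with a marginally independent root. That last property matters: if
both colliding parents share a strong common ancestor, a rival structure
sits within a few dozen BIC points of the truth at n = 10⁴ and local
search cannot reliably separate them — a statement about the instance,
not the algorithm. The recovery test is meant to certify the search on a
well-conditioned strong-signal instance, so the fixture is built to be
one.

## Problem sizes in the test suite

The suite validates each stage at the smallest size that makes the check
statistically meaningful: exhaustive-enumeration oracles on 3-node
structures (25 DAGs) and ≤6-node networks (joint enumeration at
1e-10), CPDAG recovery over 20 seeds at n = 10⁴, CPT recovery at
n = 5×10⁴ (±0.02), logistic-coefficient bias over 200 replicates at
n = 5000 (±0.05), screening type-I error over 1000 null replicates at
n = 200/arm (accepted band 3–7% at α = 5%), and three full pipeline
replications on the 3824-row cohort. The complete suite runs in about a
minute on one core.

## Known limitations

* Marginal-matching cohorts cannot exhibit the between-factor dependence
  structure of real records; learned arcs among factors on such data are
  artefacts of group mixing. Use recovery mode to test structure
  learning, and real data for substantive arcs.
* Pure MLE CPTs contain structural zeros; any test record inconsistent
  with them raises an impossible-evidence error by design. Use
  `smooth > 0` if that is undesirable.
* The stepwise procedure inherits the usual caveats of significance-driven
  selection (post-selection inference is not corrected).
* Exact inference scales exponentially with treewidth; the implementation
  targets the ≤ ~20-node networks of this problem class and makes no
  claim beyond it.
* The published figures' worked posteriors (57.6%, 65.8%, …) and the
  published sensitivity magnitudes depend on the non-public data and are
  validated here only as qualitative directions on synthetic
  replications.
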