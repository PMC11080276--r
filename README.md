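# epibn

Discrete Bayesian-network analysis of chronic-disease risk factors in
case-control studies.

`epibn` is an R implementation of the full analytic pipeline used to model
influencing factors of type 2 diabetes mellitus (T2DM), coronary heart
disease (CAD) and their comorbidity from hospital case-control data:

1. **Univariate screening** of each candidate variable against the control
   group — Pearson's χ² for categorical variables, Welch's *t* for
   symmetric continuous variables, the tie-corrected rank-sum *Z* for
   skewed laboratory values — gated at *P* < 0.05.
2. **Forward stepwise logistic regression** by the likelihood-ratio
   criterion (enter at *P* < 0.05, remove at *P* > 0.10; categorical
   variables move as indicator blocks), reporting β, SE, Wald χ², *OR* and
   95% CI.
3. **Discretization** of continuous variables by a declared codebook
   (e.g. SBP < 140 / ≥ 140 mmHg; age 18–44 / 45–59 / 60+).
4. **Structure learning**: tabu search over single-edge moves
   (add/delete/reverse) scored by the decomposable BIC

   ```
   score(G) = Σᵢ Σⱼₖ N_ijk ln(N_ijk / N_ij) − (ln N)/2 · Σᵢ qᵢ(rᵢ − 1)
   ```

   under expert edge constraints (no arrows into immutable
   characteristics), on a stratified 70/30 train split.
5. **Parameter learning**: maximum-likelihood CPTs, θ̂ = N_ijk / N_ij,
   no smoothing (structural zeros stay exact).
6. **Exact inference** by variable elimination — predictive queries
   (risk-factor evidence → disease posterior), diagnostic queries (disease
   clamped → factor posterior shifts), and classification of records with
   arbitrary missing fields (absent variables are marginalized out).
7. **Validation**: hold-out confusion matrix, accuracy / precision /
   sensitivity / specificity, ROC and AUC with a Hanley–McNeil 95%
   interval.
8. **Sensitivity analysis**: percentage variance reduction of the disease
   node per finding, `100 · (V − Σ_f P(f) V_f) / V`, ranked.

Because the original hospital records are not public, the package ships a
**synthetic cohort generator** that reproduces the published group sizes
(1175 controls / 1163 T2DM / 982 CAD / 504 comorbidity), every published
categorical marginal and continuous summary — plus a forward sampler for
declared ground-truth networks used by the structure/parameter recovery
tests.

## Worked example

```r
library(epibn)

cohort <- generate_case_control(reference_profiles(), seed = 20)
model  <- bn_disease_model(cohort, "T2DM", seed = 20)
model
#> <bn_disease_model> T2DM: 17 variables selected -> 18-node net
#> accuracy 0.9644  precision 0.9655  sensitivity 0.9628  specificity 0.9660
#> <roc_result> AUC = 0.9941 (95% CI 0.9885 - 0.9998), 349+/353-

head(model$sensitivity, 5)
#>     variable variance_reduction_pct rank
#> 1  education               43.98372    1
#> 2 occupation               35.73977    2
#> 3        age               22.08927    3
#> 4      sweet               20.10462    4
#> 5       area               17.25865    5

predictive_probability(model$net, "T2DM",
                       list(age = "3", education = "1"))
#> [1] 0.9867141
```

The screening table mirrors the univariate analysis (χ² 16.2 for sex,
*t* ≈ −35 for age between controls and T2DM cases at these group sizes);
the stepwise fit reports protective high education (OR ≈ 0.007 against
the illiterate reference here) and a per-year age OR ≈ 1.14; the
sensitivity ranking puts education and age at the top, the qualitative
pattern reported for the original data. Hold-out metrics on the synthetic
cohort are higher than the published 84–88% / AUC 0.84–0.86 because the
generator draws variables independently within each group, which makes
groups more separable than real correlated records (see the methods
vignette).

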