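# nitromix

Nitrate source apportionment and connectivity–microbiome coupling for
river–lake systems.

`nitromix` is an R package for researchers tracing nitrogen pollution in
freshwater networks with dual nitrate isotopes (δ¹⁵N, δ¹⁸O of NO₃⁻) and
relating it to hydrological connectivity and sediment microbial
communities. It provides, as one tested chain:

1. **Bayesian isotope mixing model** — for sample *i* and isotope *j*,

   *X*ᵢⱼ = Σₖ *p*ₖ *q*ⱼₖ (*S*ⱼₖ + *C*ⱼₖ) / Σₖ *p*ₖ *q*ⱼₖ + εᵢⱼ,
   with *S*ⱼₖ ~ N(μⱼₖ, ωⱼₖ²) the source signatures, *C*ⱼₖ ~ N(λⱼₖ, τⱼₖ²)
   fractionation, εᵢⱼ ~ N(0, σⱼ²) residual error and *p* the simplex of
   source proportions. Fitted by covariance-adaptive MCMC with
   slice-sampling sweeps, Dirichlet/half-normal priors, split-chain Rhat
   and effective-sample-size diagnostics.
2. **Apportionment** — aggregation of posterior source proportions into
   non-point (atmospheric deposition + chemical fertilizer + soil nitrogen)
   vs point (manure & sewage) categories, with per-stratum contribution
   tables.
3. **Community statistics** — Chao1, Shannon, Simpson, Bray–Curtis, PCoA,
   Mantel and ANOSIM, implemented from first principles and cross-checked
   against vegan/ape in the test suite.
4. **Coupling analysis** — correlation suites, a piecewise
   structural-equation path model (standardized OLS submodels), indirect
   effects, and Nash–Sutcliffe efficiency / R² evaluation metrics.
5. **Synthetic data** — seeded generators for isotope mixtures, watershed
   covariate tables with prescribed correlation structure, community count
   tables along a connectivity gradient, and paired distance matrices with
   a target Mantel correlation, so the whole pipeline runs and is testable
   without field data.

## Worked example

```r
library(nitromix)

# dry-season scenario: atmospheric deposition dominates at 43.9%
sc  <- scenario_dry()
iso <- generate_isotope_dataset(sc, seed = 1)     # 100 samples
post <- fit_mixing_model(iso, sc$signatures, mixing_config(seed = 1))
round(100 * colMeans(post$draws_p), 1)
#>   AP   CF   SN   MS
#> 43.3 19.6 19.9 17.3

contribution_table(list(dry = post))[5:6, c("stratum", "name", "mean_pct")]
#>   stratum name mean_pct
#> 5     dry  NPS 82.73312
#> 6     dry   PS 17.26688
```

The posterior means recover the scenario's generating proportions
(43.9/20.0/20.0/16.1%) to within about one percentage point here; the
NPS row is the summed posterior of the three diffuse sources. With four
sources and two isotopes one simplex direction is informed only by the
prior, so the credible intervals (in `posterior_summary(post)`) are wide —
that is a property of dual-isotope data, not of the sampler.

A one-command synthetic end-to-end run (simulation → mixing → apportionment
→ diversity → ordination/tests → coupling/SEM → report):

```r
run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))
```

writes one CSV per result table, a `manifest.json` recording seed and
configuration, and a human-readable `report.md`.

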