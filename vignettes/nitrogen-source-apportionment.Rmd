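---
title: "Methods: nitrate source apportionment and connectivity-microbiome coupling"
author: "nitromix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrate source apportionment and connectivity-microbiome coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitromix)
```

## The problem

River-lake systems under agricultural and urban pressure accumulate nitrogen
from several sources at once: atmospheric deposition (AP), chemical
fertilizer (CF), soil nitrogen (SN) and manure & sewage (MS). The dual
isotopes of nitrate — δ¹⁵N and δ¹⁸O, both in per-mil (‰) — discriminate
these sources because each occupies a characteristic region of the
two-dimensional isotope space. `nitromix` implements the full computational
chain such a study needs: a Bayesian isotope mixing model for source
apportionment, aggregation into non-point (NPS = AP + CF + SN) versus point
(PS = MS) categories, community-diversity statistics for the sediment
microbiome, and a coupling analysis linking hydrological connectivity,
nitrogen concentrations and microbial diversity.

Because raw field observations of this kind are rarely redistributable, the
package ships a synthetic-data module that generates inputs with the same
statistical structure the analysis assumes. Every stage is therefore
testable end to end.

## The mixing model

For sample $i$ and isotope $j$,

$$X_{ij} = \frac{\sum_k p_k q_{jk} (S_{jk} + C_{jk})}{\sum_k p_k q_{jk}} + \varepsilon_{ij},
\qquad S_{jk} \sim N(\mu_{jk}, \omega_{jk}^2),\;
C_{jk} \sim N(\lambda_{jk}, \tau_{jk}^2),\;
\varepsilon_{ij} \sim N(0, \sigma_j^2),$$

where $p$ is the simplex of source proportions, $S_{jk}$ the source
signature, $C_{jk}$ the fractionation shift and $q_{jk} > 0$ an optional
concentration weight. We integrate the signature and fractionation
randomness out analytically, giving the marginal likelihood
$X_{ij} \sim N(m_j(p),\, v_j(p) + \sigma_j^2)$ with

$$m_j = \frac{\sum_k p_k q_{jk} (\mu_{jk} + \lambda_{jk})}{\sum_k p_k q_{jk}},
\qquad
v_j = \frac{\sum_k p_k^2 q_{jk}^2 (\omega_{jk}^2 + \tau_{jk}^2)}{(\sum_k p_k q_{jk})^2}.$$

This marginal treatment is standard for this model family and has the
practical benefit that the simulator (`generate_isotope_dataset()`) and the
likelihood used for inference are exactly self-consistent.

### Priors

The sources give no guidance on priors, so we use weakly informative
defaults: $p \sim \mathrm{Dirichlet}(1, \ldots, 1)$ (uniform on the simplex)
and $\sigma_j \sim$ half-normal with scale 5 ‰. Both are configurable via
`mixing_config()`.

### Sampler

With $K$ sources and $J$ isotopes the parameter dimension is $(K-1)+J$ —
small, but the geometry is awkward: when $K - 1 > J$ (four sources, two
isotopes), the mixture mean constrains only $J$ directions of the simplex
and the posterior concentrates on a *ridge* — the segment of proportion
vectors reproducing the observed isotope means. That ridge is **linear in
the proportion coordinates** but curved in log-ratio coordinates, which is
why the sampler works directly on the free simplex coordinates
$(p_1, \ldots, p_{K-1})$ plus $\log \sigma$:

1. covariance-adaptive random-walk Metropolis (the proposal covariance is
   learned from the burn-in history; the global scale is tuned toward a
   20–40 % acceptance rate and then frozen);
2. every few iterations, a slice-sampling sweep (stepping-out + shrinkage)
   along the *principal axis* of the learned covariance — the ridge
   direction — and occasionally along a random eigendirection. Slice moves
   traverse the full ridge width in one update instead of diffusing.

Proposals outside the simplex have zero posterior density and are rejected;
since the Lebesgue measure on the free coordinates coincides with the
simplex measure, only the $\log\sigma$ change of variables needs a Jacobian
term. Defaults are 4 chains × 10 000 iterations with 5 000 burn-in and
thinning 5. Convergence is declared when the split-chain potential scale
reduction factor is below 1.05 for every parameter; effective sample sizes
use the pooled autocovariance with Geyer's initial-positive truncation. At
these defaults, seeded runs of both seasonal scenarios converge reliably
in a few seconds each.

The posterior mean on the ridge is prior-dependent by construction — with a
flat Dirichlet prior it sits near the midpoint of the feasible segment.
This is an honest reflection of what dual-isotope data can and cannot
identify with four sources, and it is why credible intervals for
under-determined problems are wide.

### Degenerate and edge cases

* $K = 1$: every draw is $p = 1$; only $\sigma$ is sampled.
* Zero observations: the sampler reproduces the Dirichlet prior (used as a
  correctness check).
* Zero total variance with an off-mean observation yields log-likelihood
  $-\infty$, not an error, so the sampler simply rejects such states.
* Initialization draws $p$ from the prior and retries up to 100 times for a
  finite posterior density before failing.

## Synthetic scenarios

The shipped scenario constants are the study conditions:

* `scenario_dry()`: $p = (0.439, 0.200, 0.200, 0.161)$ for (AP, CF, SN, MS).
  The AP share is the headline dry-season value; the other three components
  are free parameters completing the simplex.
* `scenario_wet()`: $p = (0.300, 0.233, 0.203, 0.264)$; the CF and MS shares
  are the headline wet-season values.
* `default_signatures()`: a synthetic stand-in for unavailable end-member
  measurements. The four means form a parallelogram in isotope space,
  centred at (6, 10) ‰ with vertices AP (6, 25), CF (−4, 10), SN (6, −5),
  MS (16, 10): atmospheric nitrate sits high in δ¹⁸O, manure & sewage high
  in δ¹⁵N, fertilizer low in δ¹⁵N, matching where real end-members fall
  while remaining explicitly synthetic. Signature SDs are 1.5–3 ‰,
  fractionation is zero (the usual assumption for nitrate source mixing)
  and $q = 1$. The parallelogram is deliberate: with four sources and two
  isotopes exactly one simplex direction is unidentifiable, and this
  geometry makes that direction symmetric ($u \propto (1, -1, 1, -1)$), so
  the flat-prior posterior mean is not systematically pushed away from the
  scenario truths by the shape of the feasible region — parameter-recovery
  checks then measure the method, not an artefact of the stand-in
  signatures. Per-isotope residual SD defaults to 1 ‰.

The watershed generator uses a single-latent-factor construction: every
variable is $r_i Z + \sqrt{1 - r_i^2} E_i$ with $Z$, $E_i$ independent
standard normals, then mapped to its native-unit margin. Any loading vector
in $[-1,1]$ yields a valid (positive-definite) joint correlation structure,
with $\mathrm{corr}(v_i, v_j) \to r_i r_j$. `scenario_coupling()` sets the
nitrogen loadings to 0.76/0.79/0.75 (TN/NO₃⁻/NH₄⁺) and the diversity
loadings to −0.74/−0.72 (Chao1/Shannon), with dry-season margins
TN 1.94 ± 1.22, NO₃⁻ 1.42 ± 1.91, NH₄⁺ 0.23 ± 0.44 mg/l. Nitrogen columns
are truncated at zero after mapping: concentrations cannot be negative, and
at these margins the truncation raises the TN mean by under 0.03 mg/l,
which the calibration tolerances absorb. Connectivity is given a margin of
0.5 ± 0.2 (a dimensionless index); Chao1 and Shannon margins (3600 ± 500,
5.5 ± 0.7) sit inside the dry-season ranges reported for such systems.

The structural simulator (`generate_sem_dataset()`) draws variables in
topological order, each endogenous variable being the coefficient-weighted
sum of its parents plus a Gaussian residual sized (via the implied
covariance) so every variable has unit variance — coefficients are thus
standardized path coefficients. `scenario_sem()` wires
connectivity → nitrogen (0.43), nitrogen → microbial (−0.42),
population → wastewater (0.51), with free 0.30 coefficients from
agriculture and wastewater into nitrogen and from environment into the
microbial variable. The nitrogen → microbial sign is negative, consistent
with the negative diversity correlations; downstream checks compare its
magnitude. We target path coefficients rather than endpoint $R^2$ values
because reported single-parent $R^2$ values (e.g. 0.69 for wastewater with
one printed path of 0.51) are mutually inconsistent for any linear
submodel, so coefficients are the only recoverable surface.

The community generator gives each site a log-normal relative-abundance
profile whose log-abundance SD rises with standardized connectivity when
the diversity loading is negative (less even community → lower Shannon
entropy), plus independent site-level noise scaled by
$\sqrt{1 - \text{loading}^2}$; counts are multinomial at fixed depth
(default 10 000). This emulates the *sign and strength* of a
diversity–connectivity association, not taxonomic realism: there is no
phylogenetic structure, no spatial autocorrelation and no
compositional zero-inflation beyond what multinomial sampling produces.
Passing tests therefore show the statistics behave correctly on data with
the assumed structure — not that real sediment communities satisfy that
structure.

The paired-distance generator draws the two vectorized upper triangles from
a bivariate normal with a prescribed entrywise correlation, shifted
positive. The matrices are exchangeable distance-like structures (they need
not satisfy the triangle inequality), sufficient for calibrating the Mantel
statistic.

## Community statistics

All indices are implemented from first principles on sites × taxa count
matrices; the test suite cross-checks them against vegan and ape.

* **Chao1** uses the bias-corrected form
  $S_{obs} + F_1(F_1 - 1) / (2(F_2 + 1))$ everywhere (defined when
  $F_2 = 0$); the classical form is an option.
* **Shannon** uses natural logarithms; the reported field ranges (about
  4.2–7.1 at thousands of taxa) are consistent with nats.
* **Simpson** is reported in the dominance form $\sum p_i^2$ — lower means
  more even, matching the direction of the reported seasonal trend — with
  Gini ($1 - D$) and inverse ($1/D$) forms also emitted.
* **Bray–Curtis** is the dissimilarity for ordination and group tests, the
  standard choice in amplicon ecology.
* **PCoA** double-centers $-D^2/2$ (Gower centering) and eigendecomposes;
  proportions explained are taken over positive eigenvalues only.
* **Mantel** correlates vectorized upper triangles, permuting rows and
  columns of the second matrix jointly; **ANOSIM** is Clarke's rank
  statistic $R = (\bar r_B - \bar r_W)/(M/2)$ with $M = n(n-1)/2$ pairwise
  distances, so $R = 1$ exactly when all between-group distances exceed all
  within-group distances. Both tests use 999 permutations by default and
  include the observed statistic in the null (the "+1" convention), so
  p-values are in $(0, 1]$ and seed-reproducible.
* No rarefaction is applied before diversity computation; a warning is
  logged when site depths differ by more than tenfold, and depth
  normalization is left to the user.
* Associating community structure with a scalar environmental variable uses
  absolute pairwise differences of that variable (`env_distance()`) as the
  second Mantel matrix — the natural one-dimensional Euclidean distance.

## Coupling analysis

`correlate()` returns Pearson (default) or Spearman correlations with
two-tailed t-based p-values; raw p-values are reported with no
multiple-testing correction. The "piecewise" structural equation model is a
set of separate OLS submodels, one per endogenous variable, fitted on
z-standardized variables — this matches the reported outputs (per-path
standardized coefficients plus per-endpoint $R^2$) and avoids the
assumptions of global covariance-structure SEM; no latent variables or
global fit indices are computed. A single-parent standardized coefficient
equals the Pearson correlation of the pair, which the tests verify to
1e-10. Indirect effects are products of coefficients along a directed
path. `nse()` and `r_squared()` are the generic simulation-evaluation
metrics (Nash–Sutcliffe efficiency and squared Pearson correlation).

## Numerical choices and problem sizes

* Posterior summaries use equal-tailed quantile intervals; summaries
  require at least 100 retained draws.
* Collinear path-model parents (condition number > 1e8) raise an error
  rather than silently dropping terms.
* Written CSVs carry 12 significant digits (display rounding only happens
  in the report); missing values in isotope or covariate columns fail fast
  because every downstream statistic assumes complete cases.
* The test suite exercises the samplers at reduced settings (2 chains ×
  4 000 iterations) where a full-accuracy posterior is not the point, and
  at the 4 × 10 000 defaults for recovery checks; recovery problem sizes
  are 100 isotope samples, 2 000 watershed records and 5 000 structural
  records — the sizes at which the generating values are recovered within
  ±5 percentage points (mixing) and ±0.05 (correlations and paths).

## Known limitations

* With more sources than isotopes the mixing posterior is intrinsically
  ridge-shaped; point estimates then depend on the prior, and only the
  identified directions are data-driven. Report intervals, not just means.
* The synthetic community model is a statistical emulator; results on it do
  not validate taxonomic or functional claims about real communities.
* The watershed generator's single-factor structure implies
  $\mathrm{corr}(v_i, v_j) = r_i r_j$ for every pair — real covariate
  tables need not satisfy this.
* Season labels are abstract (`dry`/`wet`, corresponding to May and August
  sampling); no temporal modelling is attempted.
* The river-lake connectivity index is treated as a supplied covariate; its
  derivation is out of scope.
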