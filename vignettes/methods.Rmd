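---
title: "Models and methods in sparsetest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sparsetest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sparsetest` implements a multi-site, multi-trait genomic-prediction
workflow for spaced-plant trials of switchgrass (*Panicum virgatum*): a
diverse panel of genotypes from four subpopulations (Gulf, Texas, Midwest,
Coastal), cloned into up to ten common gardens spanning 17 degrees of
latitude, scored for biomass (analysed on the square-root-gram scale),
fall height and flowering time over three years. This vignette explains
each model, the tunable parameters, the numerical decisions, and what the
synthetic-data generator does and does not emulate.

## Marker pipeline

Dosages are diploid-coded 0/1/2 — the panel's tetraploids show disomic
inheritance, so two-allele coding is the correct parameterisation.
`filter_markers()` keeps markers with a missing-call fraction strictly
below 0.2 and minor allele frequency strictly above 0.005;
`impute_missing()` fills remaining gaps with the marker mean;
`realized_relationship()` forms the VanRaden method-1 kinship
`G = WW' / (2 * sum(p(1-p)))` with observed allele frequencies, no
shrinkage and no internal MAF floor (QC is a separate concern). If the
smallest eigenvalue of `G` falls below `-1e-8` the matrix is bent by
adding `|lambda_min| + 1e-6` to the diagonal and the adjustment is
recorded in an attribute.

A frequency-centered GRM is singular by construction (the ones-vector is
in its null space), so model code regularises before factorising: the
REML fitter adds a `1e-6` ridge — enough for a stable inverse, small
enough to leave estimates untouched — while the Gibbs sampler adds
`0.01`. The larger value is deliberate: the sampler updates breeding
values genotype by genotype from conditionals whose precision scales
with `diag(G^-1)`, and a near-singular `G` would make every conditional
nearly degenerate and freeze the chain. A 1% ridge bounds the condition
number at a negligible cost in shrinkage.

## AMMI

`fit_ammi()` decomposes a complete genotype-by-site (or
subpopulation-by-site) table of biomass means into grand mean, centered
marginal effects, and an SVD of the double-centered interaction:
`Y_ij = mu + g_i + l_j + sum_k lambda_k alpha_ik gamma_jk + E_ij`.
"Variance explained" is `lambda_k^2 / sum(lambda^2)` — the denominator is
the genotype-by-environment (GxE) sum of squares only, which is how
fractions such as "PC1 explains 80% of GxE" are meant. Because multi-site
trials are unbalanced, `complete_matrix()` first fills missing cells with
the additive expectation `mu + g_i + l_j`, iterating margin re-estimation
to a `1e-8` fill-change tolerance (at most 500 sweeps). The fill carries
no interaction structure by design — it is the minimum-assumption
completion — and the filled fraction is recorded so users can judge how
much of the table is imputed. SVD signs are pinned per component (largest
absolute site score made positive) so biplots are reproducible run to
run; near-degenerate singular-value pairs (relative gap below `1e-6`) are
flagged rather than re-ordered.

## Multitrait GBLUP (REML)

For traits `t = 1..T` measured as genotype-site means,
`fit_gblup()` fits

`y_ijk = mu_k + s_ik + g_jk + e_ijk`

with site fixed per trait, `vec(g) ~ N(0, Ta (x) G)` with `Ta`
unstructured across traits, and residuals independent with one variance
per trait. Residual covariance across traits is kept diagonal to match
the i.i.d. residual of the printed model; since the three traits are
scored on the same plants this likely transfers some field-heterogeneity
covariance into `Ta` — a known caveat of the design, not of the
implementation. Estimation runs three EM-REML warm-up iterations and then
average-information (AI) updates, step-halving (and falling back to an EM
step) whenever an update would leave the parameter space; convergence is
declared when the largest parameter change drops below `1e-6` (cap 200
iterations). A pure-EM path (`method = "em"`) is kept because its
monotone likelihood trace is a useful diagnostic; both optimizers agree
to `1e-4` on test problems and the AI path typically converges in about
ten iterations. The mixed-model equations are assembled densely and
inverted in full because the trace terms of the EM/AI updates and the
prediction error variances (PEV) need the genotype blocks of the inverse;
this is comfortable up to a few thousand genotype-by-trait effects, the
scale this package targets.

`fit_gblup_grouped()` is the driver for the panel-level analysis pattern:
the same model fitted within each breeding region by subpopulation cell
(so genotype-by-environment interaction stays out of the genetic
correlations), skipping cells with fewer than 30 phenotyped genotypes.

Genetic correlations are `Ta_ab / sqrt(Ta_aa Ta_bb)`. Heritability is
reported on a genotype-difference basis (Cullis-style):
`H2 = 1 - vbar / (2 sigma2_g)` with `vbar` the mean PEV of a BLUP
difference, computed from the genotype block of the inverted coefficient
matrix. The exact published variant of this formula differs between
software; the BLUP-difference form used here is stated explicitly so
results are comparable.

## Bayesian multisite model (Gibbs)

For prediction across sites, mean biomass per site is treated as a set of
correlated response columns (optionally joined by flowering-time and
fall-height surrogate columns built from the KBSM and CLMB reference
sites, which between them cover nearly the whole panel):

`y_ij = mu_j + g_ij + e_ij`, `vec(g) ~ N(0, Ta (x) G)`,
`e_ij ~ N(0, sigma2_j)`.

Columns are z-scored before fitting; predictive ability is a
correlation, so the scale is irrelevant (a back-transform is offered).
The sampler cycles: flat-prior column intercepts; breeding-value rows
`g_i.` drawn genotype-by-genotype from their multivariate normal full
conditional — the conditional prior comes from the precision structure of
`G^-1`, so only `t x t` factorizations are ever formed, never an
`nt x nt` matrix; `Ta` from its inverse-Wishart full conditional
(`IW(nu0 + n, S0 + g'G^-1 g)`); residual variances from scaled
inverse-chi-square full conditionals. Missing cells simply drop out of
the likelihood — no augmentation is needed to predict breeding values.
Priors are weakly informative for standardized data:
`Ta ~ IW(nu = t + 2, S = 0.5 nu I)` and residuals
`~ scaled-inv-chisq(df = 5, scale = 0.5)`. All randomness flows through
R's RNG, so a seed reproduces a chain bit for bit; non-finite draws abort
with the iteration index.

The reference chain is 25,000 iterations, burn-in 200, thinning 5 (4,960
retained draws). Tests and the bundled acceptance script use scaled-down
chains of 800–3,000 iterations: at a few hundred genotypes the posterior
means they produce correlate at 0.99+ with REML BLUPs, which is the
quantity the cross-validation consumes. Split-R-hat on the `Ta` diagonal
is reported as a mixing diagnostic.

## Sparse-testing cross-validation

Validation populations are genotypes with biomass at more than five
sites, excluding admixed individuals (admixed genotypes stay in the
training data; subpopulation membership is required for validation).
Subpopulations with fewer than 60 eligible genotypes are dropped, the
fate of the Gulf subpopulation (51 eligible) in the reference design.
Validation genotypes are assigned to 8 folds (balanced, seeded,
exchangeable in input order); each leave-one-fold-out cycle is repeated 5
times, i.e. 40 model fits per subpopulation per scenario. Scenarios
control what the training response retains for validation genotypes:
nothing (`CV1`); `k` biomass sites sampled uniformly per genotype,
re-randomised each replicate (`CV2_1`..`CV2_5`, with `B1`/`B5` as the
resource-scenario aliases); surrogate columns only (`FT`, `HT`,
`FT_HT`); or one biomass site plus flowering (`B1_FT`). Genotypes with
fewer observed sites than `k` keep all their sites (eligibility makes
this an edge case). Scoring is the Pearson correlation, per site, between
predictions and observed genotype-site means over exactly the cells whose
observations were hidden; the observed 3-year mean is taken as the
operational "observed breeding value". Sites with fewer than 3 scoring
pairs in a fold are excluded; zero-variance predictions score as missing,
never 0. Summaries average site, then fold, then replicate, unweighted.
A structural audit (`cv_audit()`) rebuilds every mask without fitting and
verifies zero training/validation leakage, fold partitioning and the fit
count.

## Synthetic-data generator

The generator supplies the statistical structure the analysis assumes,
at study scale, with no download:

* **Genotypes.** Balding–Nichols: ancestral frequencies uniform on
  (0.05, 0.95), subpopulation frequencies Beta-distributed with
  divergence `F = 0.15`, dosages binomial. Subpopulation sizes default to
  the study's validation populations (Texas 119, Coastal 147, Midwest 67,
  Gulf 51); 10% of genotypes are flagged admixed, matching the share the
  reference AMMI analysis removed. There is no linkage disequilibrium and
  no attempt to mimic real allele-frequency spectra.
* **GxE.** Site-level biomass breeding values are drawn from
  `MVN(0, sigma_g^2 C (x) G)` where `C_ab = exp(-0.12 |lat_a - lat_b|)`.
  The 0.12-per-degree decay puts north–south site correlations near 0.15
  and within-region correlations near 0.8, reproducing the dominant
  north–south GxE axis. A subpopulation-by-region contrast (default 2
  sqrt-g at the latitudinal extremes) makes Midwest/Coastal material
  overperform north and Texas/Gulf south, so subpopulation biplots are
  non-trivial.
* **Surrogates.** Height and flowering breeding values load on the
  genotype's overall biomass factor (the normalized mean of its site
  BVs) with genetic correlations 0.85 and 0.45, and 0.31 with each
  other, via a Cholesky construction; they carry no site-specific GxE,
  mirroring the assumption that surrogate GxE is negligible relative to
  biomass. Because a single site's biomass BV correlates with the
  overall factor at about 0.7–0.8, trait-level correlations of
  surrogates with *site-specific* biomass are correspondingly lower —
  exactly the attenuation a real panel shows.
* **Phenotypes.** Site means follow the latitude gradient (biomass
  declines northward from about 19 to 13 sqrt-g; heights shorten;
  flowering is later). Year-level residual noise is sized per column to
  hit target single-observation heritabilities (biomass 0.6 as the
  study-level default; 0.65/0.70 for height and flowering, reflecting
  that the surrogates are less noisy to score); three yearly records per
  cell; biomass truncated at zero. Maladapted genotypes (site genetic
  value below -4 sqrt-g) at South-region sites are recorded dead
  (biomass 0) with probability 0.5, emulating the zero-inflation of the
  real trial. Replication is thinned so 53% of genotypes sit at 8–10
  sites and 36% at 5 or fewer.

With these defaults about 64% of genotypes clear the more-than-5-sites
eligibility rule, so the Midwest subpopulation (67 x 0.64 ≈ 43 eligible)
falls below the 60-genotype floor and is dropped from CV alongside Gulf;
the cross-validation grid therefore runs on Texas and Coastal. That is a
faithful consequence of combining the study's subpopulation sizes with
its replication profile.

Passing tests on this generator show that the estimators recover the
structure they assume — they do not show robustness to LD, pedigree
structure, spatial field trends, or non-Gaussian trait distributions,
none of which are simulated.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run everything at desk scale:
fixtures of 40–500 genotypes, 200–5,000 markers, Gibbs chains of
800–3,000 iterations (plus one 25,000-iteration bookkeeping run on a
small response), and a CV grid of 2 folds x 1–2 replicates over five
scenarios. These sizes were chosen so a full run completes in minutes on
one core while leaving every qualitative conclusion (scenario ordering,
steep-then-flat gain over observed sites, correlation recovery) stable
across seeds. Every stochastic entry point takes an explicit integer
seed; chains, fold maps and fixtures are bit-reproducible given it.

## Known limitations

* Dosages are diploid-coded; octoploid/polysomic models are out of scope.
* The EM fill for AMMI assumes missingness is unrelated to the
  interaction being estimated; heavily structured missingness will bias
  filled cells toward additivity (the fill fraction is reported).
* Residual covariance across traits is diagonal by default; with traits
  measured on the same plants, genetic correlations can absorb
  field-heterogeneity covariance.
* The dense-MME REML fitter targets hundreds to a few thousand
  genotype-by-trait effects, not biobank scales.
* Predictive abilities are within-subpopulation; across-subpopulation
  prediction is deliberately not evaluated.
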