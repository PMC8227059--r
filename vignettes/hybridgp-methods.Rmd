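---
title: "Genomic prediction in structured testcross hybrid populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in structured testcross hybrid populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`hybridgp` is a simulation and analysis toolkit for genomic prediction (GP)
of testcross hybrid performance in structured maize-style breeding programs.
A typical study crosses candidate lines from several interrelated
populations (a backcross population, doubled haploids from the same cross,
selfed biparental families sharing one parent, and a set of unrelated
breeding materials) to a single tester, evaluates the hybrids for yield in a
handful of environments, and asks two practical questions: how well does GP
transfer between populations of varying relatedness, and how much does
modelling genotype-by-environment (G×E) interaction help when predicting
performance in a specific environment?

The package covers the full chain: meiosis-level simulation of the
populations, SNP quality control and hybrid genotype coding, trial analysis
(BLUEs, ANOVA, heritability), genomic relationship matrices, GBLUP and
multi-environment mixed models, and the standard evaluation schemes
(within-population CV, one-to-one and three-to-one transfer, CV1/CV2).

# The trial model and heritability

Plot-level yield is modelled as

$$y_{ijk} = \mu + g_i + e_j + ge_{ij} + \delta_{(j)k} + \varepsilon_{ijk},$$

with genotype $g_i$, environment $e_j$, interaction $ge_{ij}$, replicate
nested in environment $\delta_{(j)k}$ and residual $\varepsilon$.  `fit_blue()`
fits this with genotype fixed and everything else random (REML via
**lme4**) and returns $\hat\mu + \hat g_i$ per line; on balanced data these
equal line means up to a constant, which is one of the package's oracle
tests.

`anova_ms()` performs the classical balanced decomposition (computed
directly from cell means; unbalanced data are refused with a pointer to
`fit_blue()`), and entry-mean broad-sense heritability is

$$H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_{ge}^2/e + \sigma_\varepsilon^2/(er)}.$$

**Variance-component convention.** Two extraction rules are provided.  The
default (`"error_ms"`) subtracts the *error* mean square from the genotype
mean square, $\hat\sigma_g^2 = (MS_G - MS_{err})/(er)$; this is what common
QTL-trial software reports and is the convention under which the package
reproduces the reference heritabilities 0.63/0.66/0.62/0.74 used in the
acceptance tests.  The textbook expected-mean-squares rule
$\hat\sigma_g^2 = (MS_G - MS_{G\times E})/(er)$ is available as
`"classical"`.  Note the default is *biased upward* for $\sigma_g^2$ by
$\sigma_{ge}^2/e$ when interaction is present; the package's
parameter-recovery tests therefore use `"classical"`, while reproduction of
published tables uses the default.

# Genotype coding

After QC (call rate ≥ 0.97, position metadata present, missing rate ≤ 0.01,
MAF ≥ 0.05, applied in that order; residual missing calls filled by a simple
major-allele or frequency-sampling imputer) the minor allele at each marker
is labelled *A* and lines are coded AA = 1, Aa = 0, aa = −1 (ties at MAF 0.5
broken lexicographically by allele label).  Hybrid codes follow from the
parents: the additive code is the mean of the two parental codes (so
Aa × AA → 0.5, Aa × aa → −0.5) and the dominance code is the expected
heterozygosity of the hybrid (1 for AA × aa, 0.5 for a segregating line by
either homozygote, 0 otherwise).  With a homozygous tester these rules
close over all mating types; the package verifies them against brute-force
Mendelian enumeration.

# Kinship

$K_a = Z Z^\top / \mathrm{mean}(\mathrm{diag}(Z Z^\top))$ and likewise
$K_d$ from the dominance codes $W$.  The cross-product is deliberately
taken on the **uncentred** code matrices — fidelity to the source protocol —
with centring available as an option.  Uncentred testcross codes share a
large constant background (tester contribution plus common parents), which
has two practical consequences documented here because they shaped the test
design: (i) the genetic variance partially absorbs the intercept, so
REML-vs-Gibbs agreement checks are run on the centred variant where the
partition is well identified; (ii) similarity contrasts between populations
sit on top of a high baseline, which is exactly what the reference
populations show.

# GBLUP and solvers

The prediction model is $y = \mu + \xi_a (+ \xi_d) + \varepsilon$ with
$\xi_a \sim N(0, K_a\sigma_a^2)$, $\xi_d \sim N(0, K_d\sigma_d^2)$,
$\varepsilon \sim N(0, I\sigma_\varepsilon^2)$.

*REML (default).*  For one kernel the restricted likelihood is profiled on
the variance ratio after a single eigendecomposition (exact 1-D
optimisation; boundary-checked on $\log\lambda \in [-15, 15]$).  For two or
more kernels the package maximises the restricted likelihood by L-BFGS-B on
log-variances with analytic gradients
$\partial\ell_R/\partial\sigma_i^2 = -\tfrac12[\mathrm{tr}(PK_i) - y^\top P K_i P y]$.
This replaces an EM/average-information iteration envisaged early in the
design: the quasi-Newton parameterisation enforces positivity by
construction, reuses one Cholesky per evaluation, and converged more
reliably on near-singular testcross kinships.  Variances are floored at
1e-10; a singular $V$ triggers a small ridge on the diagonal.

*Gibbs (option).*  A conjugate sampler over $(\mu, \xi, \sigma^2)$ with
scaled-inverse-$\chi^2$(df 5) priors whose scales split the phenotypic
variance equally, mirroring the spirit of Bayesian RKHS fits with their
customary 15,000/1,000 iteration defaults.  It is seed-reproducible and
agrees with REML BLUPs within Monte-Carlo error on well-identified
instances; the prior pulls variance components toward its mode at small n,
which is expected behaviour, not a defect.

Predictions for any line in the kinship are
$\hat\mu + \sigma_a^2 K_a[\cdot, t] V_t^{-1}(y_t - \hat\mu)$ (plus the
dominance analogue), verified against a mixed-model-equation oracle to
1e-6.

# Multi-environment models

Per-environment BLUEs are stacked; three models are fitted, all
additive-only with homogeneous residuals:

* **SE** — single-environment GBLUP, per environment;
* **AE** — one genetic main effect across environments,
  $\mathrm{cov} = G_0\sigma_u^2$ where the $(j,j')$ block of $G_0$ is $K_a$
  over the lines present in both environments (main effect perfectly
  correlated across environments);
* **G×E** — main effect plus environment-specific effects with
  block-diagonal covariance $G_1$; by default each environment block gets
  its own variance $\sigma_{js}^2$ (heterogeneous; a shared-variance option
  exists).

Setting all $\sigma_{js}^2 = 0$ collapses G×E to AE; empirically the REML
fits agree on interaction-free data once the interaction variances shrink
to the floor.  Masked (line, environment) cells are simply absent from the
training system; their predictions come from the covariance cross-blocks,
verified against a conditional-Gaussian oracle.

# Evaluation schemes

Prediction accuracy (PA) is the Pearson correlation of predicted and
observed values in the validation set.  `run_within()` does repeated
five-fold CV (per repeat, PA pools all held-out lines across folds — a
per-fold-average option exists); `run_transfer()` fits once on one or more
training populations and evaluates a disjoint validation population;
`run_cv_multienv()` implements CV1 (a fold's lines masked in *all*
environments) and CV2 (masked in one target environment only, each
environment evaluated in turn).  Fold assignment uses a dedicated seeded
RNG, so model solvers and partitions are independently reproducible.
Negative PAs are reported as-is.

# The synthetic world

`simulate_study()` builds four founder inbreds (donor, recurrent parent, a
second biparental parent, and the tester), then:

* **pop1** (backcross, default 475 lines): donor × recurrent F1, one
  backcross, a random intercross of the BC1F1 plants standing in for
  bulked-pollen pollination, one selfing generation;
* **pop2** (doubled haploids, 72): gametes of BC1F2 plants, doubled;
* **pop3** (selfed families, 60): donor × second-parent F1 selfed to F4
  (families are represented by the F4 plant genotype);
* **pop4** (unrelated, 68): independent homozygous draws at the founder
  allele frequencies.

Meiosis uses a no-interference (Haldane) model on a 10 × 160 cM map with
evenly spaced markers; founder minor-allele frequencies are uniform on
[0.05, 0.5].  Expected design checks — DH/founder homozygosity, BC1F3
recurrent-parent share 0.75, F4 heterozygosity 1/8 — are enforced by tests
against enumeration oracles.

Phenotypes follow the trial model: genetic values are built from `n_qtl`
markers with Normal additive (optionally dominance) effects, centred and
rescaled so their sample variance equals `var_g` *exactly* (this makes
recovery tests sharp and keeps the value linear in the marker codes);
G×E, replicate and residual deviations are iid Normal.  The default
components (`var_g` 1600, `var_ge` 600, `var_rep` 50, `var_error` 3500 kg²
around a 750 kg per-mu mean, 3 environments × 2 replicates) give
$H^2 \approx 0.67$, inside the 0.58–0.74 band typical of multi-environment
maize yield trials.  `var_error` may be a per-environment vector to create
environments of different heritability.

**What the generator does *not* emulate.**  No selection during population
development, no epistasis, no spatial field trends, no genotyping error,
and — importantly — plot-level G×E is drawn iid per line × environment.
Iid interaction carries no kinship-transferable signal, so it cannot by
itself discriminate the G×E model from the AE model.

# Design choices behind the acceptance tests

Two stated-world decisions deserve emphasis because results depend on them.

*Causal loci are excluded from the GP marker panel* in the scheme-ordering
tests.  With the causal markers observed directly, effects estimated in any
population transfer to any other, and prediction into the unrelated
population succeeds — contrary to what real SNP-chip studies (and the
reference study) observe.  Excluding the QTL makes prediction ride on
marker–QTL linkage disequilibrium, which is strong within families and
breaks down across unrelated material; the within > transfer ordering then
emerges for the right reason.

*Multi-environment orderings are tested in the model's own world*: main and
environment-specific effects drawn with covariance $K_a$ (variances 1 and
1.2, residual 0.3).  The G×E-dominant regime gives the CV2 ≥ CV1 and
G×E ≥ AE orderings enough effect size to be detected with the prescribed 20
paired replicates at α = 0.05; at milder ratios (e.g. interaction 0.6,
residual 0.4) the same orderings hold in the mean but 20 replicates lack
power.  The comparison of the three-to-one scheme is made against the
one-to-one PAs from each candidate training population (their mean), which
is the natural reading of "pooled training generally beats single-population
training"; against only the best-matched single population the advantage is
small at this scale.

# Numerical notes

* Balanced ANOVA is computed from cell means — exact, and fast at
  n = 1000 × 3 × 2.
* REML boundary cases: variance floor 1e-10; ridge 1e-6 × mean diagonal on
  Cholesky failure; profile-search bounds checked explicitly.
* Monomorphic marker columns are dropped (with a warning) before PCA
  scaling; constant genotype rows make the similarity matrix undefined and
  raise an error naming the line.
* All stochastic stages take explicit integer seeds; stage-level sub-seeds
  derive deterministically from the master seed, so identical configs give
  byte-identical outputs.

# Known limitations

* The `"error_ms"` heritability convention inflates $\sigma_g^2$ under
  interaction (documented above); choose `"classical"` for unbiased
  component recovery.
* The Gibbs solver samples effects over all lines with a data-indicator
  precision; it is meant for moderate n (hundreds), not biobank scale.
* `fit_multienv` materialises dense covariance blocks over observed cells;
  with e environments and n lines memory is O((ne)²).
* Reproduction of the reference study's supplementary-data results (PCA
  variance percentages, CV1/CV2 PA extremes) requires that study's appendix
  files, which are not redistributable; the package reproduces the
  published heritabilities from the printed mean squares and all structural
  properties on synthetic data, and nothing beyond what its tests compute.
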