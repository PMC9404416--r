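---
title: "Deriving dairy fertility traits and estimating their genetic parameters"
author: "fertgibbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving dairy fertility traits and estimating their genetic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertgibbs)
```

# The problem

Routine dairy genetic evaluation of female fertility often rests on two
calving-based measures — age at first calving and calving interval — both of
which are strongly shaped by management decisions and arrive late in a cow's
life. On-farm herd-management software, however, records every artificial
insemination (AI), every calving and the veterinary pregnancy diagnoses.
From those event histories a much richer set of fertility traits can be
derived, and their heritabilities and genetic correlations estimated with a
pedigree-based animal model.

`fertgibbs` implements that pipeline end to end:

1. **read** raw AI service records and pedigree files (delimited text),
2. **derive** nine heifer and cow fertility traits with the editing rules
   used in dairy evaluation,
3. **build** the pedigree numerator relationship matrix machinery
   (inbreeding, dense A, sparse A-inverse),
4. **fit** multi-trait linear and threshold (liability) animal models by
   Gibbs sampling, with an average-information REML fitter for all-linear
   models as an independent cross-check, and
5. **summarise** the posterior into heritabilities, genetic and phenotypic
   correlations.

Because on-farm data of this kind are private, the package ships an
event-level herd simulator whose ground-truth ledger makes every stage of
the pipeline testable.

# Trait definitions and editing

Nine traits are derived (`trait_specs()`). Heifer traits describe the
pre-first-calving period and use first-parity records only; cow traits are
per-lactation repeated records from the second parity on.

| trait  | class  | type     | definition | edit bounds |
|--------|--------|----------|------------|-------------|
| AFS    | heifer | interval | age at first insemination (months) | 10–30 |
| AFC    | heifer | interval | age at first calving (months) | 20–48 |
| SPCh   | heifer | count    | services to first conception | 1–8 |
| CFS    | cow    | interval | calving to first service (days) | 21–250 |
| DO     | cow    | interval | days open: calving to conception (days) | 21–435 |
| SPC    | cow    | count    | services per conception | 1–8 |
| FS80d  | cow    | success  | first service within 80 d post partum | 1/2 |
| PD100d | cow    | success  | pregnant within 100 d post partum | 1/2 |
| PD200d | cow    | success  | pregnant within 200 d post partum | 1/2 |

Success traits are coded 1 = no, 2 = yes, with inclusive boundaries
("within 80 days" means CFS ≤ 80). Ages are converted from days with the
mean Gregorian month of 30.4375 days and reported to one decimal; all
day-interval arithmetic is exact integer arithmetic on calendar dates.

**Conception attribution.** Raw data record the outcome of each AI event
and the pregnancy diagnoses, but no explicit "conceiving service". The
package attributes conception to the *last* service of an episode (the
services between consecutive calvings, or before the first calving), and
accepts the attribution only when it is confirmed either by a later
`pregnant` diagnosis or by a next calving 260–302 days after that service —
the plausible gestation window for Holsteins. Episodes failing both checks
leave the conception-dependent traits (SPC, DO, the pregnancy success
traits) missing rather than guessed.

**Editing.** Values outside the bounds above are treated as recording
anomalies: they are set to missing and logged, never silently dropped.
Binary traits derived from an excluded interval cascade with it (an
anomalous CFS invalidates FS80d; an anomalous DO invalidates PD100d and
PD200d). Animals with an unknown sire or dam are excluded entirely, since
they cannot contribute to pedigree-based estimation. Each exclusion is one
row of the edit log with a machine-readable reason.

**Seasons and contemporary groups.** Two seasons are used, summer
(October–March) and winter (April–September) — the Southern-hemisphere
dairy convention. Contemporary groups are herd-year-season of *birth* for
heifer rows and of *calving* for cow rows, coded `"<herd>-<year>-<season>"`.
Groups smaller than `min_size` (default 3) are dropped with their rows
logged: a one- or two-animal group cannot separate management from
genetics. Cow rows take parity ℓ + 1 for the record that starts at calving
ℓ, so the first cow record has parity 2, matching the heifer/cow split.

A few derivation conventions were genuinely open and are resolved as
follows: heifers that never conceive keep their AFS but have SPCh and AFC
missing (they are not censored into a pseudo-count); success traits whose
defining interval is underivable (e.g. no conception confirmed) are
missing, not imputed as "no", because an open episode may simply be
truncated by the end of recording; and the age covariates are age at first
insemination (SPCh rows) and age at calving (cow rows), in months.

# Pedigree algebra

The additive-genetic covariance among animals is `A`·σ²a with `A` the
numerator relationship matrix. The package computes:

* **Inbreeding** by the Meuwissen–Luo ancestor-tracing recursion on the
  factorisation A = TDT′ — founders and unknown-parent animals get F = 0;
  the Mendelian-sampling variance of animal *i* is
  d(i) = 1 − 0.25·k − 0.25·(F(s) + F(d)) over its k known parents.
* **Dense A** by the tabular method (capped at 5,000 animals; beyond that
  the caller is directed to the sparse inverse).
* **Sparse A⁻¹** directly by Henderson's rules with inbreeding:
  contributions 1/d(i) to (i,i), −0.5/d(i) to (i, parent) and 0.25/d(i) to
  each parent-parent pair. This gives at most 9 stored values per animal.
  A `inbred = FALSE` toggle reproduces the classical non-inbred rules for
  oracle comparisons.

Unknown parents are treated as unrelated base-population founders (no
genetic groups). Pedigree pruning keeps phenotyped animals plus their full
ancestor closure; animals with unknown birth dates are dropped only when
they are not required ancestors (a required ancestor is retained as a
founder). The tests verify `A · A⁻¹ = I` to 1e−8 on random inbred
pedigrees, positive semi-definiteness of A, and that `diag(A) − 1`
reproduces the inbreeding vector exactly.

# The animal model

For trait *j* on record unit *i* (a heifer row or one cow-lactation row):

```
w_ij = x_ij' b_j + a_{animal(i), j} + pe_{animal(i), j} + e_ij
```

* `b_j` — fixed effects: contemporary group always; parity class and age at
  calving (covariate) for cow traits; age at first insemination for SPCh.
  Reference levels are absorbed (drop-first), and any remaining aliased
  columns are removed by QR rank detection; the reported quantities
  (heritabilities, correlations) are invariant to this choice.
* `a` — additive genetic effect, `var(a) = A ⊗ G0`.
* `pe` — permanent environment, fitted for cow traits when the data carry
  repeated records, `var(pe) = I ⊗ P0`.
* `e` — residual, `var(e_i) = R0` within a record unit.

**Trait blocks.** Heifer traits live on heifer rows and cow traits on cow
rows; the two classes are never observed on the same record unit, so their
residual covariances are not estimable and are fixed at structural zeros
(G0 remains a full 9×9 matrix, so heifer-cow genetic correlations are
estimated). Records missing some traits of their own block are kept and the
missing values augmented each cycle, so trait-wise missingness costs no
records.

**Threshold traits.** The binary success traits are modelled on the
liability scale: a latent Gaussian `w` with a threshold at 0 (category 1
below, 2 above). Liabilities of observed records are sampled from
one-sided truncated normals given the record's other traits; inverse-CDF
sampling is used within 4.5 SD of the truncation point and a
shifted-exponential rejection sampler beyond it.

**Identifiability of the liability scale.** Binary data carry no
information about the residual variance of their own liability, so that
variance must be pinned at 1. An early design iterated the common recipe
"sample R0 unconstrained, then rescale the whole chain state to residual
variance 1 each cycle"; an independent replica showed that this move breaks
detailed balance — the additive variance drifts monotonically into an
absorbing near-zero state. The package instead fixes the
threshold-threshold sub-block of R0 to the identity and draws the free
residual elements from the *exact conditional* of the inverse-Wishart given
that sub-block: with partition (L = linear, T = threshold) and conditional
scale V,

```
D = R_LL − R_LT R_TT⁻¹ R_TL  ~  IW(V_LL − V_LT V_TT⁻¹ V_TL, ν)
B = R_LT R_TT⁻¹ | D          ~  MN(V_LT V_TT⁻¹,  D,  V_TT⁻¹)
R_LL = D + B B',  R_LT = B,  R_TT = I.
```

For a single threshold trait, or a linear-threshold pair, this is exact.
When two or more binary traits enter one analysis their mutual *residual*
covariances become structural zeros under this constraint — their
phenotypic correlations then flow through the genetic and
permanent-environment components only. That is a documented approximation;
genetic correlations are unaffected.

**Separability of single-record binary data.** A binary trait with one
record per animal and an animal-level effect per record is quasi-separable:
the likelihood approaches a constant as the additive variance grows, so
the posterior upper tail is nearly flat and a chain will wander upward
without bound (the classical extreme-category problem). Binary success
traits are therefore analysed — and simulated — as repeated per-lactation
records with a permanent-environment effect, which is also their actual
data structure: animals with discordant categories across lactations bind
the liability scale and make the posterior proper in practice.

**Sampling scheme.** Location effects are updated single-site (fixed-effect
columns) or in small per-animal and per-pe-level trait vectors using the
sparse A⁻¹ column structure; covariance matrices come from their
inverse-Wishart full conditionals (G0 uses the A⁻¹-weighted cross-product
a′A⁻¹a). Records are canonically sorted by (animal, parity) before
sampling, so posterior results are invariant to input row order, and all
randomness flows through R's RNG: a fixed seed reproduces every saved
sample bitwise.

**Priors.** Flat for fixed effects; inverse-Wishart with the minimal proper
degrees of freedom (t + 1 for t traits) and scale 0.1 times the observed
phenotypic variances for G0, P0 and R0. These are weakly informative at the
data sizes intended (thousands of records); both can be overridden through
`gibbs_fit(priors = ...)`.

**Chain defaults.** `chain_config()` defaults to a single chain of 300,000
cycles with 50,000 burn-in and thinning 10, the scale of routine threshold
variance-component estimation. The package's own validation uses 20,000
cycles with 4,000 burn-in at 2,000 phenotyped animals, where the posterior
summaries are stable to well under the tolerances quoted below.

# The AI-REML cross-check

For all-linear models `ai_reml_fit()` provides restricted maximum
likelihood through the stacked (trait-major) mixed-model equations. The
REML log-likelihood is evaluated exactly through the sparse Cholesky factor
of the coefficient matrix (Henderson's identity); the score vector by
central finite differences of that exact likelihood; and the
average-information matrix exactly through the standard quadratic forms
`AI_kl = ½ f_k' P f_l`, where each working vector reduces to a cheap
transform of the BLUP solutions (for an element of G0,
`f = Z â G0⁻¹ S`). Steps that leave the parameter space or reduce the
likelihood are halved, with an expectation–maximisation update (trace terms
from the dense inverse of the coefficient matrix) as the final fallback;
convergence requires a relative log-likelihood change below 1e−8.
Asymptotic standard errors come from the inverse AI matrix.

Scope: linear traits on a single record class, complete records (units
missing any model trait are dropped with a warning), and small trait
counts — the categorical traits and the heifer-cow joint analysis belong to
the Gibbs sampler. Degenerate designs (founders only, one record each, one
contemporary group) make additive and residual variance jointly
unidentifiable; the fitter detects the singular AI matrix and returns with
an identifiability warning instead of a spurious estimate.

A known statistical subtlety, verified numerically during development: the
Gibbs *posterior mean* and the REML *maximum* are different estimators.
They differ by a finite-data term that does not shrink with chain length —
the mean-vs-mode offset of the skewed variance-component posterior (of
order SD²/σ̂²) plus the tilt induced by any proper prior. At 2,000 records
this gap is ≈ 0.005–0.01 for the additive variance, while the Monte-Carlo
SE of a 20,000-cycle chain mean is ≈ 0.003. Agreement should therefore be
judged against the posterior SD (≈ 0.04 here), not against the Monte-Carlo
SE of the chain mean, which measures only sampling noise around the
posterior mean.

# Posterior summaries and diagnostics

`summarize_chain()` computes, at every retained sample,
`h² = σ²a / (σ²a + σ²pe + σ²e)` — the pe term present only for cow traits —
the genetic correlation `G0_ij / √(G0_ii G0_jj)` and the phenotypic
correlation from `T = G0 + P0 + R0`, then averages the per-sample ratios
(ratio first, then mean; the posterior SD is taken over the same per-sample
values). `write_results()` lays the summary out in the conventional square
table: heritabilities on the diagonal, genetic correlations above it,
phenotypic correlations below, in the order AFS, AFC, SPCh, FS80d, PD100d,
PD200d, SPC, CFS, DO.

`diagnostics()` reports, per covariance component, the Geweke z score
(first 10% vs last 50% of the chain, long-run variances from an AR spectral
estimator at frequency zero), the effective sample size
`ESS = n·var(x)/spectrum0(x)`, and the Monte-Carlo SE `sd/√ESS`; components
with |z| > 2 or ESS < 100 are flagged, and the trace series are exported
for plotting. Single chains only — the design follows the one-long-chain
practice of threshold variance-component estimation.

# The herd simulator

`simulate_pedigree()` builds discrete generations in which each offspring
draws a sire from a small pool of the previous generation's males
(half-sib family structure) and a dam from its females. Birth dates advance
two years per generation with day-of-year jitter.

`simulate_service_records()` generates event histories female by female:
first service at a policy age of 16.8 ± 3.5 months (the typical Holstein
descriptive scale); repeat services on a 21 ± 3 day heat cycle until
conception or an eight-service cap; per-service conception as a Bernoulli
draw with probability `pnorm(qnorm(p_base) + u)`, where the baselines 0.65
(heifers) and 0.45 (cows) match mean services-per-conception of about 1.5
and 2.2 and `u ~ N(0, 0.3²)` is an animal-level liability; gestation as a
truncated normal 280 ± 7 d on [260, 302]; a pregnancy diagnosis 42 d after
conception; and later lactations after a 70-d voluntary waiting period plus
a uniform 0–20 d wait for heat. The simulator bookkeeps the true value of
every derivable trait in a ledger, and the test suite requires the
derivation module to reproduce that ledger record for record.

What the simulator deliberately does **not** model: seasonal fertility
effects, culling-for-infertility selection bias, heat-detection failure,
embryonic loss after a positive diagnosis, and herd-level management
differences beyond contemporary-group effects. Passing the recovery tests
therefore shows that the estimation machinery is correct *under the model's
own assumptions*; it does not certify behaviour under the selection and
censoring patterns of real field data.

`simulate_breeding_values()` is the generative counterpart of
`var(a) = A ⊗ G0`: founders draw from N(0, G0) and each descendant is the
parent average plus a Mendelian deviation with covariance d·G0, without
ever forming the dense A. `simulate_phenotypes()` adds contemporary-group
effects, permanent-environment effects (shared across an animal's
records) and residuals with the requested covariance matrices, and
thresholds liabilities into the 1/2 codes for success traits.

# Validation conditions

The package-level validation (the acceptance test file and
`scripts/acceptance.R`) uses conditions chosen once: 3,000-animal pedigrees
(1,000 founders, three generations), 100 sires in use per generation, 2,000
phenotyped animals, 50 contemporary groups with effect SD 0.5, and chains
of 20,000 cycles with 4,000 burn-in. The broad sire force matters: with
only 30 sires per generation the *realized* additive variance drifts
between replicates with an SD of about 0.04 around its nominal value —
genuine genetic drift, confirmed by an independent half-sib ANOVA on the
same data — which would confound a ±0.05 recovery check. One hundred AI
sires per generation is realistic for a Holstein population and keeps the
realized variance close to nominal. Under these conditions the pipeline
recovers a linear heritability of 0.30 within ±0.05, a liability
heritability of 0.25 within ±0.07 and a linear-threshold genetic
correlation of 0.70 within ±0.10, each averaged over three fixed seeds.

# Known limitations

* Residual covariances between heifer and cow traits, and among two or more
  binary traits in one analysis, are structural zeros (see above); the
  corresponding phenotypic correlations are driven by the genetic and
  permanent-environment components.
* `ai_reml_fit()` is a cross-check for small all-linear models, not a
  production REML: it requires complete records and one record class.
* Posterior means of variance components differ from REML maxima by the
  finite-data asymmetry discussed above; this is a property of the
  estimators, not a convergence failure.
* The simulator's conception process is stationary within animal; real
  herds show lactation-stage and seasonal effects that the estimation model
  absorbs only through contemporary groups.
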