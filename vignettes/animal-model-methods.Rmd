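---
title: "Methods: the multi-trait animal model, AI-REML and index selection in pedindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-trait animal model, AI-REML and index selection in pedindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pedindex implements the evaluation chain of a closed-nucleus breeding
program — pedigree relationship algebra, variance-component estimation,
BLUP breeding values, genetic trends and an economic selection index —
together with a simulator of the nucleus itself. This vignette is the
package's account of the underlying methods, the defaults, and the design
decisions a user or maintainer should know about. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The statistical model

Phenotypes are modelled by the multi-trait animal model

$$y = Xb + Za + e, \qquad a \sim N(0,\, A \otimes G_0), \qquad e \sim N(0,\, R),$$

with one additive genetic effect per pedigree animal and trait. $A$ is the
numerator relationship matrix; its diagonal is $1 + F_i$ with $F_i$ the
inbreeding coefficient. $G_0$ and $R_0$ are the $t \times t$ additive and
residual covariance matrices; the residual covariance of an animal's record
vector is the $R_0$ submatrix of its observed traits, so animals with
missing traits (notably males for the sex-limited egg traits) contribute
exactly the information their records carry. Assumptions worth making
explicit: a single additive genetic effect (no maternal, dominance or
permanent-environment terms), homogeneous residual (co)variances across
sexes and hatches, and records missing at random given the fitted fixed
effects.

Fixed effects default to hatch set plus sex, with sex dropped automatically
for traits recorded in one sex only (age at first egg and the cumulative
egg counts), where it would be confounded with the trait's very
missingness. Identifiability uses corner-point constraints: the first
observed level of each factor is the reference. Equations are ordered
fixed effects first, then animals in pedigree order with traits innermost;
solution files are stable under this documented order.

## Pedigree algebra

`pedigree()` validates and topologically sorts records; unknown parents are
treated as unique unrelated founders (no genetic groups — the emulated
program traces all ancestors, so group effects have nothing to attach to).
Self-parentage, cross-sex parent roles, duplicate ids and parentage cycles
are hard errors. `inbreeding()` uses the Meuwissen–Luo algorithm in
compiled code; `a_inverse()` assembles $A^{-1}$ sparsely by Henderson's
rules with the Mendelian-sampling variances
$d_i = 0.5 - 0.25(F_s + F_d)$ (one term replaced by $-0.25$ per unknown
parent), and carries $\log|A| = \sum_i \log d_i$ for the REML likelihood.
The dense tabular `relationship_matrix()` exists for desk-scale work and as
the oracle in the tests; production paths never invert $A$ densely.
$A^{-1}$ is always built with inbreeding; running without it is not
offered, since at six generations of a 180-parent nucleus the inbreeding
correction is small but free.

## Restricted likelihood, AI updates, EM fallback

The REML log-likelihood is evaluated through the mixed-model equations as
$-\tfrac12(\log|R| + \log|G| + \log|C| + y'Py)$, omitting the additive
$-\tfrac12(N-p)\log 2\pi$ constant; each evaluation is one sparse Cholesky
factorisation of the coefficient matrix $C$. The tests verify this against
a dense evaluation via $V = Z(A \otimes G_0)Z' + R$ on small instances.

`ai_reml()` parameterises the problem directly by the distinct elements of
$G_0$ and $R_0$. Each iteration computes

* the **average-information matrix** analytically from working variates
  $f_j = (\partial V/\partial\theta_j) P y$, with
  $\mathrm{AI}_{ij} = \tfrac12 f_i' P f_j$ — all products reduce to sparse
  solves against the current factorisation, with $A$-products done through
  the Cholesky factor of $A^{-1}$;
* the **score** by central finite differences of the exact restricted
  log-likelihood, with per-parameter steps of $10^{-3}$ of each parameter's
  natural scale (the geometric mean of the two traits' phenotypic
  variances). Steps this large keep the difference quotient far above the
  factorisation round-off while the $O(h^2)$ truncation error stays
  orders of magnitude below the convergence tolerance; the tests compare
  the resulting AI/score machinery against a numerical Hessian implicitly
  by checking monotone convergence and oracle limits.

The Newton direction is solved in scale-free parameters with a relative
ridge ($10^{-9}$ of the mean scaled information) — with genetic
correlations near $\pm 1$ the information matrix is close to singular, and
an absolute ridge would otherwise crush the update of small-variance
traits. Proposals are tried at step factors $1, \tfrac12, \tfrac14,
\tfrac18$; any proposal that is non-PD or decreases the likelihood falls
back to an **EM-REML step** expressed through the score,
$G_0^+ = G_0 + (2/q)\, G_0 S_G G_0$ (and analogously for $R_0$ with the
record count), damped further if needed. EM steps are uphill and preserve
positive definiteness, so accepted iterations never decrease the
likelihood (asserted by a test at $10^{-6}$ slack).

Two design decisions depart from an obvious alternative and deserve their
rationale:

* **Direct covariance parameterisation rather than Cholesky factors.** An
  unconstrained Cholesky parameterisation makes non-PD proposals
  impossible but distorts the AI approximation and complicates the EM
  fallback; a direct parameterisation with an explicit EM fallback keeps
  both updates in their textbook form, and the fallback is exactly the
  mechanism that handles boundary-adjacent proposals.
* **Finite-difference scores rather than trace computations.** The exact
  score needs traces of $C^{-1}$ blocks, which at several thousand
  equations cost a dense partial inversion per iteration. Differencing the
  exact likelihood costs two sparse factorisations per parameter and is
  accurate to the tolerances used here. The convergence rule reflects
  this: iteration stops when the likelihood change is below `tol_loglik`
  ($10^{-6}$) and either the relative parameter change is below
  `tol_param` ($10^{-6}$, configurable) or the Newton decrement (the
  quadratic model's predicted remaining gain) is below `tol_loglik` —
  the decrement clause recognises convergence when weakly-informed
  parameters still jitter at the finite-difference noise floor.

Starting values put half the phenotypic variance in $G_0$ and half in
$R_0$ with zero covariances, unless supplied. `max_iter` defaults to 200;
hitting it flags the result as unconverged rather than raising. Standard
errors of heritabilities come from the delta method on the inverse AI
matrix; no profile likelihoods. Runs above four traits are executed as
trait blocks (default four, configurable) by the pipeline; correlations
across blocks are simply not estimated rather than being stitched
together.

## BLUP, accuracies, trends, index

`solve_mme()` returns fixed-effect solutions and EBVs for every pedigree
animal; prediction-error variances come from exact (chunked) inversion of
the coefficient matrix — the intended problem sizes are a few thousand
equations, where this costs seconds. Accuracy is
$\sqrt{1 - \mathrm{PEV}/((1+F)\,\sigma^2_a)}$, clipped to $[0,1]$, with a
PEV materially above $(1+F)\sigma^2_a$ treated as an error (it signals an
inconsistent solve, not a sampling fluke).

`genetic_trend()` reports per-generation mean EBVs and their least-squares
slope; pairwise generation comparisons reuse the LS-means machinery.
Expected progress uses the breeder's equation
$\Delta G = \sigma_A \cdot h \cdot i$ with $h$ the mean accuracy of the
selection candidates and $i = \varphi(z_p)/p$. Two terminology decisions:
the program's "20% selection" is treated as the selected *proportion* and
converted to standardised intensity via the truncated-normal formula; and
the index accuracy is implemented as the Hazel correlation
$r = \sqrt{v'G P^{-1} G v / v'G v}$ (the unrooted ratio $b'Gb/v'Gv$ is
exposed as a secondary diagnostic attribute, since with $b = P^{-1}Gv$
the two coincide on $r^2$ only up to scaling conventions). The index
weights default to 0.25/0.25/0.30/0.20 over body weight, breast
circumference, egg production and age at first egg — growth and egg
complexes weighted 0.5 each — with the age-at-first-egg term subtracted;
the body-weight EBV entering the index defaults to six-week weight (the
recommended selection age) and the egg count to 240-day production, both
configurable. Truncation selection takes the top $\lceil pn \rceil$ per
sex with ties broken by animal id, so selected sets are reproducible.

## What the simulator emulates — and what it does not

`sim_config()`/`simulate_program()` emulate the nucleus structure: 30
sires × 150 dams (5 hens per cock, $N_e = 4N_mN_f/(N_m+N_f) = 100$), six
discrete generations, per-generation hatch counts drawn from 1500–1800
split over three hatch sets, sex assigned 1:1, and roughly 452 birds
recorded per generation (the recorded count that yields ~2,700 phenotyped
birds over six generations; replacements are drawn from recorded birds, and
the exported pedigree is pruned to recorded animals plus ancestors, which
is the pedigree a breeding program would actually keep — a `prune_pedigree
= FALSE` switch keeps every hatched chick). Offspring breeding values are
parent average plus Mendelian sampling with covariance
$0.5(1 - (F_s+F_d)/2)\,G_0$; inbreeding is recomputed each cycle.
Phenotypes are trait mean + hatch effect + sex effect (males, growth
traits) + breeding value + residual; egg traits are recorded on hens only,
and egg counts and ages are simulated continuously then rounded, matching
the Gaussian analysis model. The default multi-trait covariance structure
is assembled from the published KM2 parameter tables
(`km2_variance_components`, correlation matrices), with two documented
repairs: a non-PD correlation matrix is projected to the nearest PD
correlation matrix (`Matrix::nearPD`; in practice the full 11-trait tables
are already PD and the repair is a no-op, as a test verifies), and the
270EP additive variance uses the internally consistent
$\sigma_T^2 - \sigma_e^2 = 222.50$ rather than the printed 2.50, which
contradicts its own row. Default nuisance-effect sizes, chosen once as
plausible for the system: a male body-weight advantage of 80/120/180/250 g
at 4/6/8/10 weeks (none at hatch or for breast circumference, which the
recorded population shows no sex difference for), and hatch-set effects of
∓0.15 phenotypic SD.

Selection modes: `"phenotypic"` (default; a standardised within-sex
phenotypic index with weights renormalised over the traits each animal
expresses), `"oracle"` (index on true breeding values), `"blup"` (re-runs
the animal-model BLUP each cycle; intended for reduced configurations) and
`"none"`. The truncation proportion and the replacement quotas (30 + 150)
are configured independently, because the two are mutually inconsistent in
the emulated program (180 replacements from ~1,650 hatched is ~11%, not
20%); when the top-$p$ pool is smaller than a quota, the next-best
candidates fill it.

Features of real data the generator deliberately does not emulate:
overlapping generations, maternal and common-environment effects,
genotype-by-environment interaction, non-Gaussian egg-count distributions,
mortality/culling other than the recording subset, and marker data.
Passing parameter-recovery tests therefore demonstrate that the estimation
machinery is correct under the stated model — not that the model captures
everything a real nucleus would show.

## Numerical and degenerate-input conventions

Quartiles in the editing filters use linear interpolation of order
statistics (`stats::quantile` type 7), configurable; the outlier rule is
strictly one-sided (`v < Q1 − 1.5·IQR`) and applied within trait globally
by default, with an optional stratification column — whether the original
editing was stratified is unknowable from the published account, so the
global rule is the default and the flag exposes the alternative. A
birth weight exactly at the 26 g threshold is retained ("less than" is
read strictly). Whole-animal removal applies to the birth-weight rules;
every other trait's outliers are masked per trait. Constant vectors have
IQR 0 and lose nothing; all-missing vectors are an error. LS-means use
equal-weight averaging over the other factors' levels (emmeans), pairwise
comparisons are Tukey–Kramer at α = 0.05, and the compact letter display
uses an interval-based insert/absorb on the means ordering. Degenerate
REML inputs: a non-finite likelihood at the start suggests rescaling and
is an error; a trait with zero records is an error at design time; factor
levels without records are dropped with a warning.

## Problem sizes used by the tests

The test suite exercises oracle equivalences (dense GLS/BLUP, dense
$A^{-1}$, dense restricted likelihood) on pedigrees of 40–300 animals and
up to three traits, where dense linear algebra is exact and fast.
Parameter-recovery checks run the full nucleus structure (~2,700
phenotyped) for the univariate and bivariate targets, and reduced
configurations (a few hundred animals per generation, 2–4 traits, 3–4
generations) for distributional properties — null-variance recovery,
drift, realised heritability, the breeder's equation — with replicate
counts chosen so each check completes in seconds to a couple of minutes.
The breeder's-equation check compares realised and predicted gain for the
*first* selection cycle from the unselected base: over repeated cycles the
textbook prediction overstates response because selection itself reduces
the between-family variance (the Bulmer effect), which is a property of
the equation, not of the implementation under test.

## Known limitations

Single additive random effect only; no maternal or permanent-environment
models, no genomic relationships, no heterogeneous residual variances; PEVs
require exact coefficient-matrix inversion and are intended for desk-scale
problems (set `pev = FALSE` to skip); cross-block genetic correlations are
not estimated by the blocked pipeline; and the CLI is a thin wrapper —
anything beyond the documented keys should use the R API directly.
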