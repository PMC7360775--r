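---
title: "Parent-of-origin variance components on pedigrees: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin variance components on pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Parent-of-origin effects (POEs) blur the classical additive model of a
quantitative or binary trait: an allele may act differently depending on
which parent transmitted it (genomic imprinting), the mother's genotype may
act on her offspring's phenotype directly (maternal genetic effect), and
mothers create a shared environment for their sibships (maternal
environmental effect). These three mechanisms produce overlapping
phenotypic signatures in family data, so estimating any one of them while
ignoring the others inflates its apparent contribution. `imprintvc`
implements a ladder of pedigree mixed models that estimates and tests all
three simultaneously from individual/sire/dam records and phenotypes, plus
a logit threshold variant for binary disease status.

# Models

All models share a fixed part `Xb` and a residual `e ~ N(0, I sigma_e^2)`.

**Mendelian (null) models.** Each individual's genotypic value is the sum
of the effects of its two gametes, one inherited from the sire and one
from the dam, with no dependence on the direction of transmission:

* Mendelian model 1: `Y = Xb + Z_g g + e`, with `g` a vector of one effect
  per gamete (2N effects for N individuals) and `Var(g) = G sigma_g^2`,
  where `G` is the gametic relationship matrix (below). Each row of `Z_g`
  carries two unit entries, at the record's paternal and maternal gamete
  slots.
* Mendelian model 2 adds `Z_c c` with `Var(c) = I sigma_c^2` -- one
  maternal environmental (shared household) effect per mother.
* Mendelian model 3 adds `Z_m m` with `Var(m) = A sigma_m^2` -- a maternal
  genetic effect with the additive covariance structure, the dam's value
  applying to each of her records.

**Imprinting model.** Every gamete carries a *pair* of effects: its effect
when paternally transmitted (`g_s`) and when maternally transmitted
(`g_d`). A record picks up `g_s[paternal gamete] + g_d[maternal gamete]`,
and the joint covariance of the stacked pairs is the Kronecker product

```
Var[(g_s, g_d) pairs, gamete-major] = G (x) Sigma,
Sigma = | sigma_s^2   sigma_sd  |
        | sigma_sd    sigma_d^2 |
```

The imprinting variance is the variance of the difference between the two
expression patterns, `sigma_i^2 = sigma_s^2 + sigma_d^2 - 2 sigma_sd`.
When the two patterns coincide (`sigma_s^2 = sigma_d^2 = sigma_sd`),
`Sigma` is rank one, `sigma_i^2 = 0`, and the model *is* the Mendelian
model with `sigma_g^2` equal to the common value -- this exact nesting is
what makes the restricted likelihood-ratio test valid, and the package
verifies it numerically in its test suite. Because maternal imprinting and
maternal genetic/environmental effects mimic each other, the imprinting
model is fitted with the maternal term(s) retained from the Mendelian
ladder; when the two maternal channels cannot be disentangled, both
variants (one with `c`, one with `m`) are fitted and reported.

# Relationship matrices

`additive_matrix()` builds `A` by the tabular method (`a_ii = 1 + F_i`;
inbreeding is read off the diagonal, a single source of truth).
`gametic_matrix()` builds the `2N x 2N` matrix `G` of identity-by-descent
probabilities between gametes by the standard recursion: the gamete an
individual received from parent `p` relates to any earlier gamete `x` as
the average of `p`'s two gametes' relationships to `x`, has a unit
diagonal, and relates to the individual's other gamete by exactly `F_i`.
Both constructions are dense and aimed at desk scale (N up to a few
thousand individuals for `G`); rule-based sparse inverses are out of
scope. Two cross-checks guard the constructions: collapsing `G` over the
four gamete pairs must reproduce `A` to numerical precision, and an
allele-copy gene-dropping oracle (founder gametes carry iid standard
normal effects; a child gamete copies one of its parent's two effects with
probability one half) must reproduce `G` entrywise within Monte-Carlo
error. Since roughly 0.3% of entries are expected outside three Monte-Carlo
standard errors *by chance*, the automated check requires 98.5% of entries
within three SEs and all entries within six -- a genuine construction error
sits hundreds of SEs away at the replicate counts used.

# REML engine

The restricted log-likelihood is evaluated two independent ways, which
serve as mutual oracles (they agree to 1e-8 on randomized instances in the
test suite):

* **direct**: `-0.5 [ (n-p) log 2 pi + log|V| + log|X'V^-1 X| + y'Py ]`,
  with `V` assembled from dense covariance kernels -- under the imprinting
  structure `sigma_s^2 G[pat,pat] + sigma_d^2 G[mat,mat] + sigma_sd
  (G[pat,mat] + G[mat,pat])`, restricted to the phenotyped records'
  gamete slots;
* **mixed-model equations**: the same value through `log|R| + log|G_u| +
  log|C|` and the MME solution, requiring the inverses of `G`, `Sigma`
  and `A` (used at test scale).

Both include the `(n-p) log 2 pi` constant so their values are directly
comparable with the closed-form residual-only REML of a fixed-effects
regression, the zero-variance limit.

**Parameterization and optimization.** `fit_reml()` maximizes over an
unconstrained parameterization: log-Cholesky for `Sigma` (so the positive
semidefinite boundary -- including the rank-1 no-imprinting null -- stays
reachable) and log scale for scalar variances with a floor of 1e-10 to
keep `V` invertible. The ascent is Newton-type with analytic gradients and
the average-information (AI) matrix as the Hessian approximation, with
ridge regularization and step halving; this is the field-standard
AI-REML update and converges in of the order of ten iterations, which is
what makes the replicated simulation studies below affordable. Convergence
requires both a relative log-likelihood change below 1e-8 and a gradient
max-norm below 1e-5 (components absorbed at the boundary automatically
satisfy the gradient criterion on the log scale). The default start is a
deterministic split of the phenotypic variance; seeded random restarts are
available (`reml_control(n_starts = )`), and the ladder pipeline instead
warm-starts each model from the previous one, adding the constrained
(near-Mendelian) point as a candidate start for the imprinting model so
the nested-likelihood dominance `ll_imprinting >= ll_Mendelian` is
respected by construction rather than by luck.

**Uncertainty.** The information matrix is the AI matrix at the optimum on
the unconstrained scale (an expected-information estimate; a
finite-difference observed-information option exists), mapped to the
natural scale by the delta method. At a boundary the information is
singular; the pseudo-inverse is used and the affected standard errors are
to be read as approximations, as is usual for variance components.
Negative REML log-likelihood *differences* between nested models cannot
occur at true optima; when a fitted alternative lands below its null
(statistic clipped at zero), the test result carries a
`negative_stat_flag` -- the signature of a flat likelihood surface -- and
the pipeline surfaces it as a warning instead of hiding it.

# Hypothesis tests

Single added variances (`sigma_c^2`, `sigma_m^2`) are tested by a
one-sided RLRT referred to a plain chi-square with one degree of freedom
-- the convention this model family has used in practice -- with the
textbook boundary mixture `0.5 chi2_0 + 0.5 chi2_1` available by option
(`maternal_null = "boundary"`); the plain-chi-square default is the more
conservative of the two. The imprinting test adds two parameters, one of
them on a boundary, and uses the `0.5 chi2_1 + 0.5 chi2_2` mixture with
equal weights (the standard boundary-theory default; the weights are not
derivable from the data). The mixture survival function treats `chi2_0`
as a point mass at zero, so a zero statistic always yields `p = 1`; the
p-value is not additionally halved beyond the mixture. Calibration under
the no-imprinting null is checked empirically in the acceptance suite
(200 replicates on a fixed pedigree of about 800 phenotyped individuals;
the empirical 5% rejection rate must be compatible with 0.05 by an exact
binomial test).

Fixed effects are tested by incremental Wald F statistics computed at the
fitted variance components: data are whitened by the Cholesky factor of
`V`, terms enter in their declared order, each term's rank increment
counts only columns not linearly dependent on earlier columns (full-dummy
factor coding with singular columns set to zero -- the behavior of the
mixed-model software this reproduces -- which deliberately makes the table
order-dependent), and the denominator mean square is the full model's
whitened residual mean square. With no random effects this reduces
*exactly* to classical sequential ANOVA. Denominator degrees of freedom
are `n - rank(X)`; numerical denominator-DF approximations of specific
packages are not replicated, and every Wald table should be read with
that convention in mind.

# Population parameters

Two formula variants are provided because the conventional reporting of
this model family contains an internal tension: the additive variance
under a Mendelian model is `sigma_a^2 = 2 sigma_g^2` (two gametes per
individual), while the phenotypic variance has conventionally been
written `sigma_p^2 = sigma_g^2 + sigma_e^2 (+ sigma_c^2) (+ sigma_m^2)`
with the per-gamete variance entering once. The `as_printed` variant
(default) implements exactly that convention and flags `h^2 > 1` if it
occurs; the `consistent` variant counts `2 sigma_g^2` inside `sigma_p^2`,
which keeps all ratios in `[0, 1]`, makes them invariant to rescaling all
components, and makes component ratios sum to at most one. Under the
imprinting models `sigma_a^2 = sigma_s^2 + sigma_d^2` and both variants
agree. The relative imprinting variance is `sigma_i^2 / sigma_a^2`.
Standard errors of all ratios come from the delta method on the
variance-component covariance. For threshold fits the phenotypic variance
may or may not include the implicit logit residual `pi^2/3`; both
conventions are computable (`logit_residual =`), and reports state which
was used.

# Threshold model

For a 0/1 status the logit threshold model is fitted by penalized
quasi-likelihood: with class probabilities `mu = exp(eta)/(1 + exp(eta))`,
the working response `z = eta + (y - mu)/[mu(1-mu)]` and weights
`W = mu(1-mu)` define a weighted linear mixed model that is refitted until
`eta` reaches a fixed point (relative change below 1e-6). The
working-scale residual variance is fixed at 1, the standard PQL
dispersion choice. Internally the model is for `P(y = 1)`; the class-zero
convention used in threshold-model reports corresponds to a sign flip of
the fixed effects, and the fit exposes `pi0 = 1 - mu` directly. Two
limitations are inherent and deliberately surfaced rather than papered
over: PQL's criterion is not a true likelihood, so no RLRT is offered on
threshold fits (tests are linear-model-only), and PQL variance components
on binary data are attenuated toward zero, so the package's checks on
them are sign and ordering, not unbiasedness. With all random variances
at zero the scheme is exactly iteratively reweighted least squares, and
the suite verifies equality with ordinary logistic regression to 1e-6.
All-identical responses or vanishing working weights raise a
`SEPARATION` error.

# Synthetic data generator

Registry data of the kind this model family targets are confidential, so
the generator is a first-class module producing data with *exactly* the
assumed structure, not a convenience fixture:

* **Pedigree**: `n_founders` founders (even sex split), random monogamous
  mating within generation, Poisson(`mean_family_size`) offspring per
  couple, alternating sexes, five generations by default -- the depth of
  the study pedigrees this emulates. Birth years advance by generation
  with scatter.
* **Gametic effects**: gene dropping realizes `Var = G (x) Sigma` exactly
  -- founder gametes draw iid bivariate normals with covariance `Sigma`,
  and a non-founder gamete is the parental mean plus a Mendelian-sampling
  residual with covariance `0.5 (1 - F_parent) Sigma`.
* **Maternal effects**: `c` iid per mother; `m` an additive gene-dropped
  trait with variance `sigma_m^2` (dam's value applied to her offspring),
  independent of the direct effects by default -- the fitted models'
  assumption -- with `maternal_gen_corr` available to probe the
  confounding that a direct-maternal covariance would create.
* **Fixed effects**: sex, a 6-level maternal socio-economic factor, a
  linear birth-year trend, and a time-under-observation covariate acting
  through cubic Legendre polynomials.
* **Trait**: continuous (`linear`); `logit_binary`, a Bernoulli draw from
  the logistic probability with an intercept solving a marginal case rate
  of 0.38 by default (a deliberately case-enriched, registry-like rate);
  or `liability_binary`, thresholding the linear phenotype, which exists
  to probe link misspecification. Phenotypes are restricted to the most
  recent two generations, mimicking registries in which ancestors lack
  case/control status.

What passing tests on these data do *not* show: robustness to diagnostic
misclassification, register-coverage drift, non-random mating,
assortative ascertainment within families, or sex-linked (X-chromosomal,
mitochondrial) transmission -- none of which the generator emulates.

# Problem sizes and numerical choices

The replicated studies in the test suite use sizes chosen to keep a full
run on a single desk CPU comfortable while leaving Monte-Carlo error
small enough to be informative: 20 random pedigrees with 1e5 gene-dropping
replicates for the relationship oracle; 100 randomized instances for
evaluator equivalence; parameter recovery with about 3,000 phenotyped
individuals on a fixed five-generation pedigree, 20 replicates, requiring
each component's mean within two Monte-Carlo standard errors of truth;
RLRT calibration with 200 replicates at about 800 phenotyped individuals;
and PQL fixed-effect bias at n = 5,000 over 20 replicates. The
variance-decomposition check of the generator uses a cluster-robust
standard error for the sample variance because family members are
correlated. Degenerate inputs are handled explicitly: unknown parents
become phantom founders unrelated to everything (so every gamete has a
defined origin, including known-dam/unknown-sire cases, which are logged),
duplicate ids and parent cycles are hard errors, records with missing
covariates are dropped with a count rather than imputed, and sparse
ordered factor levels (e.g. birth years) merge forward until each merged
level holds at least the requested count, with a trailing remainder
merging backward.

# Known limitations

Dense linear algebra bounds the practical size (roughly 20,000
individuals for `A`, 5,000 for dense `G`, a few thousand phenotyped
records per REML fit); very large registry analyses would need sparse
MME machinery that is explicitly out of scope here. The AI-REML ascent,
like all REML optimizers, can stall on flat surfaces -- the package
reports rather than conceals this. Standard errors at variance boundaries
are approximate. PQL is known to attenuate variance components for binary
traits; the threshold fits are for effect prediction and concordance
checks, not for unbiased heritability estimation on the liability scale.
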