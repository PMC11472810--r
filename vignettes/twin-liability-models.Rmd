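---
title: "Liability-threshold twin models for binary phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold twin models for binary phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinliab)
```

## The scientific problem

Many developmental phenotypes — here the motivating case is parent-reported
speech and language difficulties (SaLD) screened in a population twin
registry — are recorded as present/absent, yet are more plausibly the visible
tail of a continuous underlying risk. The classical twin design compares
monozygotic (MZ) and dizygotic (DZ) pairs to decompose that risk into
additive genetic (A), shared environmental (C), and non-shared environmental
(E, which also absorbs measurement error) sources. twinliab implements the
full analysis chain for such a study: phenotype coding from questionnaire
items with exclusion rules, descriptive epidemiology, tetrachoric
correlations, and likelihood-based ACE modelling — together with a cohort
simulator, because registry microdata are typically restricted and method
validation has to run on synthetic cohorts with the same structure.

## The liability-threshold model

Each twin carries a latent liability $L \sim N(0, 1)$; the twin is affected
when $L > \tau$, where $\tau = \Phi^{-1}(1 - K)$ and $K$ is the prevalence.
Within a pair, $(L_1, L_2)$ is bivariate normal with correlation

$$r_{MZ} = a^2 + c^2, \qquad r_{DZ} = \tfrac12 a^2 + c^2,$$

because MZ co-twins share all additive-genetic and shared-environmental
variance while DZ co-twins share on average half of the additive-genetic
part. The same $r_{DZ}$ is used for same-sex and opposite-sex DZ pairs: the
design fits no qualitative sex-difference model (a deliberate scope
restriction, matching the analysis the package mirrors), although thresholds
are sex-specific throughout.

A 2×2 concordance table for a zygosity group then has cell probabilities
determined by $(\tau_1, \tau_2, r)$ through the bivariate-normal upper
orthant $P(L_1 > \tau_1, L_2 > \tau_2; r)$, and all model fitting maximises
the joint multinomial likelihood of the group tables.

### The orthant kernel

`bvn_upper_orthant()` evaluates the orthant probability through Plackett's
identity, $P = \Phi(-h)\Phi(-k) + \int_0^r \phi_2(h,k;t)\,dt$, after the
substitution $t = \sin\theta$, which cancels the $1/\sqrt{1-t^2}$ factor in
the bivariate density. The integrand becomes
$\exp\{-(h^2 - 2hk\sin\theta + k^2)/(2\cos^2\theta)\}/2\pi$, an analytic
function of $\theta$ on $[0, \arcsin r]$ that remains perfectly behaved as
$|r| \to 1$ — important here, because MZ correlations for this phenotype sit
near 0.97 and profile searches push $r$ against the boundary. Adaptive
quadrature (`stats::integrate`, relative tolerance $10^{-12}$) delivers
absolute accuracy better than $10^{-10}$; at $h = k = 0$ the closed form
$1/4 + \arcsin(r)/2\pi$ is reproduced to machine precision, and the test
suite cross-checks a grid of values against an independent implementation
(mvtnorm's deterministic Miwa algorithm).

## Model ladder and parameterisation

`fit_saturated()` is the reference model. Unconstrained (the default), every
group gets its own thresholds and correlation, and the fit reproduces the
observed cell proportions exactly, so its $-2\log L$ equals the analytic
multinomial value $-2\sum n_{ij}\log(n_{ij}/N)$. This exactness is the
anchor for likelihood-ratio comparisons, which is why the unconstrained
variant is the default rather than a threshold-constrained one; the
constrained variant (`constraints = "sex_thresholds"`, correlations per
group or per zygosity class) exists to test the assumption that thresholds
are equal across zygosity, and its cost is itself a likelihood-ratio test.

`fit_variance_model()` fits ACE, AE, CE and E. Components are parameterised
as path coefficients $(a, c)$ with $e = \sqrt{1 - a^2 - c^2}$, constrained to
the unit simplex, and squared for reporting — the SEM convention, which keeps
every component in $[0, 1]$ by construction and makes boundary solutions
(e.g. $\hat c^2 = 0$) visible as flagged estimates rather than failures. The
default threshold pattern is one threshold per sex shared across zygosity,
giving the ACE model four free parameters
$(\tau_m, \tau_f, a, c)$; a single shared threshold is available via
`threshold_pattern = "single"`.

Same-sex pairs have no natural within-pair ordering, so `group_tables()`
double-enters them (each pair contributes both orderings at half weight).
This symmetrises the off-diagonal cells, makes within-pair threshold
equality automatic, and leaves all estimates unchanged while keeping the
total weight of each pair at one. Opposite-sex pairs are ordered male-first
and keep sex-specific thresholds.

Degrees of freedom are counted as (independent multinomial cells across
groups) − (free parameters): a symmetrised same-sex table contributes two
independent cells, an opposite-sex table three. Published model-fit tables
for this design sometimes count df against the number of raw observation
records instead; both conventions leave likelihood-ratio statistics
untouched, and only $\Delta(-2\log L)$ and $\Delta$df carry inferential
content here.

### Optimisation

Nelder-Mead from five documented starting points: thresholds always start at
the pooled margin probits; the familial correlation fraction starts at
$\{0.1, 0.3, 0.5, 0.7, 0.9\}$ of its feasible range, split 3:1 between $a^2$
and $c^2$ for ACE. Convergence tolerance is $10^{-10}$ relative on
$-2\log L$; the best converged run is kept and per-start diagnostics are
retained in the fit object. Degenerate tables (empty discordant cells) drive
the correlation to the boundary and are reported with a boundary flag, never
as an error.

### Confidence intervals

All intervals are profile likelihood: the set of component values whose
profiled $-2\log L$ (all other parameters re-optimised) lies within
$\chi^2_{1,0.95} = 3.84$ of the minimum, located by root bisection and
truncated to $[0,1]$ with boundary flags. Because the nuisance surface
changes shape along the profile, each profiled point is optimised from both
a warm start (previous profile point) and a cold start (the full-model
estimates), keeping the better solution; the test suite verifies that the
returned endpoints raise $-2\log L$ by 3.84 and that intervals agree with
the Wald quadratic approximation at interior optima. Likelihood-ratio tests
that pin a variance component at zero (AE vs ACE, E vs CE) use the naive
$\chi^2$ reference, as is conventional in twin modelling; the asymptotic
null there is actually a 50:50 mixture of $\chi^2_0$ and $\chi^2_1$, so
those p-values are conservative.

## Phenotype coding

`code_sald()` maps the ordinal screening item (0 = no, 1 = yes to a certain
degree, 2 = yes) to affected (1 or 2) versus unaffected (0). Exclusions take
precedence over the phenotype — an excluded individual is never counted
affected — mirroring a screening flow in which exclusions are applied before
prevalence is computed:

- both models exclude hearing impairment, acquired language disorder, and
  chromosomal abnormalities (differential-misclassification guards), whether
  flagged from register data or reported as the follow-up cause;
- model 2 (sensitivity analysis) additionally excludes autism — the register
  flag and the parent-reported "autism" follow-up cause merged into a single
  indicator — and intellectual disability.

A missing ordinal response with no exclusion is a distinct
"missing-phenotype" state, dropped from denominators (no imputation).
`pair_analysis_set()` applies the two denominators the analyses need:
prevalence uses every non-excluded individual with a phenotype, while
correlation and variance modelling use only complete pairs. Exclusion is
individual-level: a pair with one excluded twin still contributes its
analysable co-twin to prevalence. Follow-up causes use a controlled category
vocabulary (`cause_categories()`); free-text mapping is out of scope, with
insufficient answers pre-mapped to `not_specified` upstream.

## The cohort simulator

`simulate_cohort()` draws, per zygosity-by-sex group, bivariate-normal
liabilities at the implied correlation, thresholds them at the sex-specific
probit, and emits the questionnaire-style record. Its defaults are the study
conditions the package is validated against: group sizes
2465/2676/3122/2739/5772 pairs (MZ male, MZ female, DZ male, DZ female, DZ
opposite-sex), prevalence 10.61% in males and 5.03% in females, and
generating components $(a^2, c^2, e^2) = (0.75, 0.22, 0.03)$.

Choices a user should know about:

- **Ordinal split.** Affected twins answer 1 vs 2 with probability
  `p_severe` (default 0.5). The analysis collapses the two levels, so this
  is presentation-only; 0.5 is a neutral default.
- **Comorbidity flags** are drawn independently of liability by default,
  with an optional relative-risk parameter enriching autism/ID among
  affected twins, since no joint distribution is published for the
  motivating study. Flag rates themselves default to zero (off).
- **Follow-up causes.** When enabled, an affected twin's parent indicates a
  known cause with rate 512/2424 and answers the open-ended question with
  rate 479/512 — the observed response behaviour in the motivating study —
  with categories drawn from `catss_cause_distribution()` (the observed
  tally of 479 categorised answers) or any user-supplied distribution.
- **Random-number protocol.** One substream per group, derived
  deterministically from the root seed, with a fixed draw order inside each
  group. Adding a group never perturbs the draws of existing groups, and a
  given configuration is byte-reproducible.
- **DZOS correlation** equals the same-sex DZ correlation (no qualitative
  sex-difference process is simulated).

What the simulator deliberately does **not** emulate: age structure and
longitudinal waves, non-response and attrition, quantitative cognitive
scores linked to liability, zygosity misclassification, and any dependence
between follow-up causes and the exclusion flags. Passing recovery tests on
these cohorts therefore demonstrates the correctness of the estimation
machinery under the model's own assumptions — not robustness to the
violations real registry data may contain.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: the
orthant kernel against a closed form and an external algorithm; descriptive
statistics against hand formulas and published summary values that are
exactly computable from printed counts; tetrachoric and ACE estimates
against probability-exact fixture tables (counts proportional to exact cell
probabilities, whose ML optimum is the generating parameter point), a dense
simplex grid search at step 0.005, and an independently coded likelihood.
Stochastic checks use 100 replicate cohorts at the default registry-scale
group sizes (~16,800 pairs each) for bias and profile-interval coverage of
the ACE components, 200 multinomial replicates at 4000 pairs/group for the
power of the AE-vs-ACE likelihood-ratio test under $c^2 = 0.25$, and
200,000 pairs/group for convergence of empirical concordance to the orthant
probabilities (within three Monte-Carlo standard errors). These sizes were
chosen to keep Monte-Carlo error well below the tolerances being asserted
while remaining comfortably runnable on a laptop core.

## Known limitations

- No sex-limitation (quantitative or qualitative) models; opposite-sex
  pairs inform the fit only through the shared 0.5 A weighting.
- The three-level ordinal response is dichotomised, as in the motivating
  analysis; an ordinal liability model would use slightly more information.
- Descriptive confidence intervals ignore twin clustering (individuals are
  not independent), matching the analysis mirrored here; cluster-robust
  intervals would be wider.
- Boundary-component LRT p-values use the naive reference (see above).
- The pooled DZ tetrachoric treats same-sex and opposite-sex DZ pairs as one
  class with common thresholds; `pool_tables(pool = "MZ_DZss_DZOS")`
  separates them when the sexes' thresholds differ materially.
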