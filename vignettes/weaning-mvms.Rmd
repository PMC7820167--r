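---
title: "Estimating age at weaning with multistate hidden Markov mark-recapture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating age at weaning with multistate hidden Markov mark-recapture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Steller sea lion pups are hot-branded on their natal rookeries within weeks
of birth and resighted opportunistically for years afterwards. A juvenile
seen suckling (or laying squarely on top of a female) is definitively
unweaned; a juvenile merely seen tells us nothing about its weaning state.
Estimating *when* animals wean therefore has to separate three confounded
processes: mortality, detection, and the imperfect classification of the
weaning state at each sighting.

`weanmark` implements the multistate Cormack-Jolly-Seber (CJS) model with
state uncertainty that this design calls for. Each animal occupies a latent
state at each primary occasion (a summer, or one of two seasons within a
summer):

* **S** — alive and unweaned,
* **W** — alive and weaned (absorbing: a weaned animal cannot return to S),
* **D** — dead or permanently emigrated (absorbing; confounded, as in any
  CJS model, so survival is *apparent* survival).

Four probability parameters govern the data:

* $\Phi$ — apparent survival over the interval between primaries,
* $\psi_{S:W}$ — probability an unweaned animal weans over an interval,
* $p$ — probability an animal alive in a primary is seen at all,
* $\delta$ — probability a single sighting of a truly unweaned animal
  yields the definitive suckling code "S" (a weaned animal can only ever
  produce "u": its state-detection probability is structurally 0).

## The robust design and the `ns` covariate

The more often a juvenile is seen in a summer, the more likely at least one
sighting catches it suckling. Summarising a summer by its most definitive
code would therefore bias $\psi$ and $\Phi$ through unmodelled detection
heterogeneity. The data are instead encoded with a robust design: each
primary occasion contains up to five secondary slots holding the individual
sighting codes, together with the per-primary count of sightings `ns`.
Resighting is constrained so that $p$ keeps its ordinary CJS meaning ("seen
at all"): for an animal with `ns = 1` the last four secondary slots are
fixed to $p = 0$; with `ns = x > 1`, slots $2..\min(x,5)$ are fixed to
$p = 1$ and slots beyond to 0. Survival between secondaries is fixed to 1.
Under these conventions the probability of classifying a truly unweaned
seen animal correctly within a primary is

$$1 - (1 - \delta)^{ns},$$

which approaches 1 geometrically in `ns` — the reason for the robust
design. Because no latent transition happens within a primary, the
within-primary part of the likelihood factorises into
$p\,\delta^{n_S}(1-\delta)^{n_u}$ for a truly unweaned seen animal (with
$n_S$ definitive and $n_u$ unknown codes among the retained slots), $p$ or
0 for a weaned one, and the complement terms when unseen. The forward
recursion then runs over primaries only; the test suite verifies this
factorisation against exhaustive enumeration over latent paths and proves
total probability sums to one over the full observation space of small
layouts.

When an animal has more than five sightings in a primary, five are
retained: all haul-out sightings first (counterbalancing the high resight
effort at natal rookeries), then a uniform seeded draw from the rookery
sightings; if haul-out sightings alone exceed five, five of them are drawn
uniformly (the tie-break is our choice; nothing in the design dictates
it). `ns` keeps the uncapped count. For primaries where an animal was
unseen, `ns` is set to 1 so that only the first secondary slot ever
carries a free $p$. Adults (ages 4+) carry data only in the first
secondary slot with `ns = 1`. Occasion indices are 1-based throughout,
matching R convention.

Two shipped layouts mirror the study geometries: `seak_layout()` — 18
annual primaries with secondaries only in the nine juvenile-cohort years
(54 history columns) — and `goa_layout()` — 16 years of EARLY/LATE
primaries plus a release-only occasion for the first cohort (161 columns).
In the two-season geometry the EARLY-to-LATE interval is closed to
mortality ($\Phi$ fixed to 1) but open to weaning. Whether the first
cohort's release conditions on the EARLY or LATE season is not dictated by
the data structure; we release at the LATE primary of the birth year and
expose the layout constructor so either convention can be built.

## Parameterisation and fitting

All four parameters use a logit link with design matrices built by R
formulas over per-slot design data (`design_data()`): age, age-class
labels, sex, natal rookery, region, maternal haplotype, mass covariates,
year, season, and the latent-state indicator `weanW` (allowed in $\Phi$
and $p$, where survival and resighting may differ between weaned and
unweaned juveniles; structurally meaningless and rejected in $\psi$ and
$\delta$). Slots with non-`NA` `fix` values bypass the link, which is how
all the fixed-parameter conventions above are expressed. Nonlinear mass
effects enter through `bspline_basis()`, a cubic B-spline with 3-6 degrees
of freedom and interior knots at data quantiles (a standard default; the
knot rule is ours).

Maximum likelihood uses BFGS from $\theta_0 = 0$ on the link scale
(probabilities of one half), relative tolerance $10^{-12}$, with optional
jittered restarts (`starts`, jitter SD 0.5); the headline fits in the
acceptance suite use three starts, replicate sweeps one. The covariance
matrix is the inverse of a central finite-difference Hessian at the
optimum; a singular Hessian falls back to a pseudo-inverse with a warning,
and non-convergence is warned about, never silently accepted. AIC counts
free coefficients only — fixed slots contribute no parameters. Any free
linear predictor exceeding 15 in absolute value sets a `boundary` flag:
such estimates should be read as 0/1 with collapsed intervals (the
published age-3+ weaning probability of 1.000 with interval [1.000, 1.000]
is exactly this situation). Rank-deficient designs warn and name the
aliased columns.

## Derived quantities and uncertainty

Different regions use different seasonal cutoffs, so early-season weaning
estimates are composed with the shared within-summer rate:
$\hat\psi_{0-1L} = \hat\psi_{0-1E} + (1-\hat\psi_{0-1E})\hat\psi_{1E-1L}$
(`compose_seasonal()`, algebraically $1-(1-a)(1-b)$). Cumulative
proportions weaned follow the recursion $W_1 = \psi_{0-1}$,
$W_x = W_{x-1} + (1-W_{x-1})\psi_{x-1,x}$ (`cumulative_weaning()`), and
`weaning_by_group()` applies both to a table of interval estimates shaped
like the packaged `steller_psi_estimates()`.

Confidence intervals for derived quantities use a multivariate normal
parametric bootstrap: draws centred at the MLE with the estimated
covariance matrix, transformed through the links and composition
operations, summarised by equal-tailed percentile intervals
(`bootstrap_ci()`, default 10,000 draws under a fixed seed — the draw
count is our choice, as is percentile rather than normal-theory
summarisation). Sampling on the link scale keeps every derived probability
inside $[0,1]$ by construction. We read "covariance matrix equal to the
negative Hessian" in the usual sense of its inverse; the Hessian itself
has the wrong units to be a covariance.

## Errors-in-variables regression

Relating derived life-history estimates across a handful of rookeries
(e.g. proportion weaned by age 1 against adult female survival) must
acknowledge that both axes are estimates with standard errors; ordinary
least squares would attenuate the slope toward zero. `fit_eiv()` maximises
the likelihood in which observed $(x_i, y_i)$ are normal around latent
$(\xi_i, \alpha + \beta\xi_i)$ with known measurement SDs taken from the
upstream fits. The default *structural* form places $\xi_i \sim N(\mu,
\tau^2)$ — with eight units, profiling incidental $\xi_i$ out invites the
classical inconsistency, and the structural form also yields a clean
likelihood-ratio test of $\beta = 0$. The *functional* form (incidental
$\xi_i$ profiled out) is available behind `method = "functional"`. With
equal errors on both axes both reduce to orthogonal (Deming) regression,
which the tests verify to $10^{-8}$; with all errors zero the fit falls
back to OLS with a note. Optimisation is staged profiling (closed-form GLS
means, 1-D Brent searches over $\tau^2$ and $\beta$) finished with Newton
steps, because Brent alone stalls at the square root of machine epsilon.

## What the simulator emulates — and what it does not

`sim_scenario()` / `simulate_encounters()` generate individual encounter
records with exactly the statistical structure the model assumes:
release in state S in the birth year, discrete-interval survival and
weaning at primary boundaries (within-primary transitions do not occur —
the fitted model is discrete-time, so the generator is too), per-primary
resighting, per-sighting state classification, and haul-out/rookery site
labels. Scenario defaults are the study conditions used throughout the
tests: first-year survival 0.55 and 0.85 at older ages, weaning
probability 0.6 over ages 0-1 and 1-2 and 0.9 afterwards, $p = 0.8$,
$\delta = 0.25$, 3000 releases over four cohorts. The sighting
multiplicity distribution defaults to a geometric truncated to 1..10 with
$P(1) \approx 0.51$, matching the roughly half of juveniles seen exactly
once per summer in the field programmes; its 5+ tail is lighter than the
observed one (17%), which matters only for how often the 5-of-x selection
rule engages. Year effects on $p$ are fixed offsets supplied in the
scenario — the field data do not support estimating between-year variance
components, so the simulator does not invent them.

Real data differ in ways the simulator deliberately ignores: no age
misassignment, no tag loss, no spatial movement or emigration distinct
from death, no photo-identification error, and independence of sightings
within a primary. Passing recovery tests therefore demonstrate that the
estimator is consistent under the model's own assumptions — not that the
assumptions hold in the field.

## Numerical choices and test scales

Degenerate inputs are handled explicitly: impossible observation events
give $-\infty$ log-likelihood (guarded inside optimisation), $0^0 = 1$ in
the emission so $\delta = 0$ or 1 are valid fixed values, zero-variance
bootstrap draws collapse to the point estimate, and empty encounter files
round-trip to empty record sets. The mass-adjustment GLMs are ordinary
Gaussian linear models (mass is continuous; the identity link is the only
sensible reading), with `population` main effects harmlessly aliased
against rookery, exactly as in the published parameter counts.

The test suite exercises the machinery at reduced but honest scales, our
choice for a suite that runs routinely: exhaustive-path equivalence on
histories of up to 3 primaries over 100 random parameter draws; parameter
recovery on 20 replicates of the full 3000-release scenario; bootstrap
coverage on 200 replicates of an 800-release scenario with 1000 draws per
interval; EIV attenuation on 500 replicates of 8 units. The
spline-versus-linear mass-effect comparison uses a threshold-shaped
survival response (sharp decline below average mass, flat above — the
shape reported for Southeast Alaska) at 1000 releases, where a logit-linear
effect demonstrably cannot follow the plateaus.

## Known limitations

Only two live states are supported; random effects and continuous-time
formulations are out of scope. The likelihood conditions on `ns`, so the
sighting-multiplicity process itself is not modelled. Boundary estimates
are flagged rather than profiled. And because the packaged reference
tables are printed point estimates, the acceptance checks reproduce
*derived* arithmetic exactly but cannot re-estimate the underlying fitted
parameters without the original encounter data.
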