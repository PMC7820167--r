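# weanmark

Multistate hidden Markov mark–recapture models for estimating **age at
weaning** in pinnipeds from resighting data with imperfect state detection.

Long-lived otariids such as Steller sea lions (*Eumetopias jubatus*) can
nurse offspring well past age 1, but a juvenile seen in the field is only
*definitively* unweaned when it is caught suckling. Estimating age-specific
weaning probabilities therefore requires separating survival, detection,
and state classification. `weanmark` implements the multistate
Cormack–Jolly–Seber model with state uncertainty used for this problem:
animals occupy latent states **S** (alive, unweaned), **W** (alive, weaned;
absorbing) or **D** (dead; absorbing), governed by apparent survival Φ,
weaning probability ψ<sub>S:W</sub>, resighting probability *p*, and the
per-sighting state-detection probability δ. Capture histories use a robust
design (up to five secondary slots per primary occasion plus a
number-of-sightings covariate `ns`), so the within-primary probability of
detecting the unweaned state grows as 1 − (1 − δ)<sup>ns</sup>. The
likelihood is a hidden Markov forward recursion conditioned on first
release, maximised by quasi-Newton iteration with logit links and
formula-based design matrices.

The package covers the full workflow:

* `sim_scenario()` / `simulate_encounters()` — individual-based simulator
  of encounter records with the model's generative structure;
* `build_history()` / `encode_dataset()` / `assemble_dataset()` —
  robust-design capture-history encoding, including the haul-out-favoring
  5-of-x sighting selection and the Southeast Alaska (54-column) and Gulf
  of Alaska (161-column) occasion layouts;
* `fit_mvms()` / `aic_weights()` — maximum-likelihood fitting and model
  weights;
* `compose_seasonal()` / `cumulative_weaning()` / `bootstrap_ci()` —
  derived weaning schedules with multivariate-normal parametric bootstrap
  intervals;
* `fit_mass_models()` / `adjust_mass()` / `bspline_basis()` — neonatal
  body-mass adjustment for capture age and mass-covariate bases;
* `fit_eiv()` — errors-in-variables regression for comparing derived
  life-history parameters across rookeries;
* `run_pipeline()` — one-call orchestration of simulate → encode → fit →
  derive with logged seeds and checksums.

## Worked example

Simulate a study at the default conditions scaled down to 600 releases,
encode it, and fit the generating model:

```r
library(weanmark)

sc  <- sim_scenario(n_individuals = 600, n_cohorts = 2, n_years = 5, seed = 42)
sim <- simulate_encounters(sc)
ds  <- encode_dataset(sim$records, sim$covariates, sim$layout, seed = 7)
md  <- as_mvms_data(ds)

ddl <- design_data(md)
ddl$psi$wage2 <- ifelse(ddl$psi$wage %in% c("a0", "a1"), "a01", "a2p")
fit <- fit_mvms(md, formulas = list(phi = ~firstyear, psi = ~wage2,
                                    p = ~1, delta = ~1), ddl = ddl)
summary(fit)
#>                term estimate     se      z
#> 1   phi:(Intercept)   1.9127 0.1530 12.499
#> 2     phi:firstyear  -1.7797 0.1812 -9.823
#> 3   psi:(Intercept)   0.4335 0.2368  1.830
#> 4      psi:wage2a2p   1.9992 1.1223  1.781
#> 5     p:(Intercept)   1.3052 0.1005 12.991
#> 6 delta:(Intercept)  -1.1203 0.2444 -4.584
#> logLik -1245.366  AIC 2502.73  npar 6
```

On the probability scale (`plogis`), the fit recovers the generating
values: first-year survival 0.53 (truth 0.55), older-age survival 0.87
(0.85), weaning probability 0.61 at ages 0–2 (0.6) and 0.92 beyond
(0.9), resighting probability 0.79 (0.8) and state detection 0.25 (0.25).

Derived weaning schedules from the packaged reference estimates:

```r
W <- weaning_by_group(steller_psi_estimates())
head(W, 4)
#>    group age         W
#> 1 SEAK_F   1 0.6160000
#> 2 SEAK_F   2 0.8525440
#> 3 SEAK_F   3 0.9859917
#> 4 SEAK_F   4 1.0000000
detection_within_primary(0.226, 5)
#> [1] 0.7222176
```

The first number says 61.6% of Southeast Alaska females are weaned by age
1 and 85.3% by age 2; the last says that with a per-sighting detection
probability of 0.226, five sightings within a summer classify an unweaned
juvenile correctly 72.2% of the time.

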