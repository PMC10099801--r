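# sizecmr

Integrated body-size growth and capture–mark–recapture (CMR) modelling for
animals that keep growing throughout life — small lizards in the first
instance, but nothing in the machinery is reptile-specific.

## The problem

In indeterminate growers, survival and catchability depend on body size
more than on age, but size is a *time-varying individual covariate that is
missing whenever the animal is not caught*. Classical
Cormack–Jolly–Seber (CJS) models cannot use such a covariate directly.
`sizecmr` solves this by coupling two models in one Bayesian hierarchy:

* **Growth.** Each individual follows a Schnute growth curve in its
  mark–recapture (Baker) form, parameterised by a growth coefficient
  `K_i` (year⁻¹) and true sizes `L_iT1`, `L_iT2` at two reference ages
  (`T1 = 0`, hatching, and `T2 = 14` years):

      L_{t+D} = L_t e^{-K D} + (L_T2 - L_T1 e^{-K(T2-T1)}) (1 - e^{-K D}) / (1 - e^{-K(T2-T1)})

  Individual random effects (lognormal on `K_i`, Normal on `L_iT2`) capture
  between-animal heterogeneity; observed snout-to-vent length (SVL) is the
  true size plus Normal measurement error σ_L, so apparent negative
  increments are accommodated rather than discarded. The curve deterministically
  imputes the latent size of every animal in every year after first capture.

* **Survival and recapture.** A hierarchical CJS model with logit-linear
  predictors on standardized SVL, sex (latent for unsexed animals, with a
  Uniform(0,1) sex-ratio prior), quadratic and interaction terms, and
  Normal year random effects:

      logit φ_it = α_s + β_s1 sex + β_s2 x + β_s3 x² + β_s4 sex·x + β_s5 sex·x² + ε_t^φ
      logit p_it = α_p + β_p1 sex + β_p2 x + β_p3 sex·x + ε_t^p

* **Covariate choice.** Gibbs variable selection (GVS): each of the 8
  selectable coefficients carries a Bernoulli(0.5) inclusion indicator,
  with Normal(0, σ²) slabs, σ² ~ Inverse-Gamma(4, 5), and Normal
  pseudopriors moment-matched to a pilot run of the full model. Marginality
  constraints (interactions and the quadratic drop out when a parent term
  is off) reduce the space to 10 survival × 5 recapture admissible models,
  encoded per draw as `mdl = 1 + Σ 2^r g_r`.

* **Derived life history.** Asymptotic size `L∞ = (L_T2 − L_T1 e^{-K(T2−T1)})/(1 − e^{-K(T2−T1)})`,
  age at a given size (inverse curve), age at maturity (50 mm females /
  59 mm males), and expected life span after maturity `l_x = −1/ln φ`, all
  propagated draw-by-draw through the posterior.

Posterior sampling is by a purpose-built Metropolis-within-Gibbs sampler
(Rcpp): latent alive states are marginalised analytically, conjugate draws
are used where available (sex ratio, slab variances, growth-location
hyperparameters), adaptive random walks elsewhere, plus hierarchical block
moves for the weakly identified growth hyperparameters. Convergence is
monitored with split-R̂ on every scalar; anything above 1.1 is flagged.

## Worked example

Simulate a study-scale dataset with known truth and fit the integrated
model (reduced chain lengths for a desk-scale run):

```r
library(sizecmr)

set.seed(42)
sim <- mimic_study(n_individuals = 200)
sim$data
#> Capture data: 200 individuals, 10 occasions, 467 captures (93 males, 104 females, 3 unknown)
#> Observed SVL: 35-79 mm

fit <- fit_model(sim$data,
                 config = sampler_config(n_chains = 3, n_iter = 4000,
                                         burnin = 1600, seed = 1),
                 std = sim$truth$config$std)

summary(fit, params = c("K_m", "K_f", "Linf_m", "Linf_f",
                        "age_mat_m", "age_mat_f", "sigma_L", "psi"))
#>       param       mean     median       lo95       hi95      rhat
#> 1       K_m  0.5486820  0.5485003  0.5067715  0.5924279 1.0328792
#> 2       K_f  0.3859041  0.3853752  0.3447171  0.4316957 1.0152657
#> 3    Linf_m 72.2885324 72.2803843 71.4477780 73.0786330 1.0240226
#> 4    Linf_f 66.4894576 66.4809860 65.4816787 67.5588018 1.0211084
#> 5 age_mat_m  1.9787280  1.9797148  1.8486501  2.1129034 1.0228864
#> 6 age_mat_f  1.8411054  1.8381149  1.6881038  2.0046604 1.0059459
#> 7   sigma_L  0.9648967  0.9628392  0.8602890  1.0752769 1.0051244
#> 8       psi  0.4736171  0.4730921  0.4048809  0.5430505 0.9997725

life_span_posterior(fit)
#> male expected life span after maturity: 7.32 years (95% CRI 3.94-15.91)
#> female expected life span after maturity: 15.73 years (95% CRI 6.40-112.80)
```

The generator's truth here was a median `K` of 0.56 (males) and 0.41
(females) with asymptotic sizes near 72.3 and 65.6 mm and σ_L = 1 mm; the
posterior medians land on those values and the 95% credible intervals
cover them. (At this reduced scale some upper life-span bounds are wide —
survival at the female maturity size is only weakly constrained by 200
individuals.) Covariate selection runs as

```r
pp  <- pilot_run(sim$data, config = sampler_config(n_chains = 2, n_iter = 3000, burnin = 1200))
gvs <- run_gvs(sim$data, pp, config = sampler_config(n_chains = 2, n_iter = 5000, burnin = 1500))
gvs   # prints Pr(Included), the model table, median-probability and best model
```

Real data enter through `read_capture_data("captures.csv")` (long format:
`id, year, svl_mm, sex`, within-year duplicates collapsed to the first
measurement). A command-line wrapper with `simulate | fit | gvs |
summarize | recover` subcommands is installed under `exec/sizecmr`.

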