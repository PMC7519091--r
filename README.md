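# dtdfmix

Diet-tissue discrimination factors (DTDFs) and Bayesian stable-isotope
mixing models for diet-switch feeding trials.

## The problem

Stable-isotope mixing models invert a consumer's (δ¹³C, δ¹⁵N) values into
probabilistic estimates of the proportions p₁…p_K of K candidate diet
sources. Doing that correctly requires the diet-tissue discrimination
factor Δ — the systematic offset between a tissue and the diet it was built
from — for every source × tissue pair. Most studies borrow literature
values (Δ¹³C = 1.0 ± 2.0 ‰, Δ¹⁵N = 3.4 ± 2.0 ‰); feeding experiments show
Δ in fact varies strongly with diet and tissue, and mis-specified Δ
systematically distorts estimated diets.

`dtdfmix` implements the full analysis chain of a diet-switch experiment
(five consumer groups of a freshwater cichlid, muscle and fin tissue,
sampled over 120 days) and its downstream mixing-model comparison:

* **Incorporation kinetics** — one-compartment
  `δX(t) = δX∞ − (δX∞ − δX0) e^(−λt)` and two-compartment
  `δX(t) = δX∞ − (δX∞ − δX0)(p e^(−λ₁t) + (1−p) e^(−λ₂t))` curves, with
  residence times τ = 1/λ and τ_mean = p τ₁ + (1−p) τ₂.
* **Bayesian fitting** (`fit_incorporation_bayes`) by adaptive
  Metropolis MCMC with informative normal priors, Gelman–Rubin PSRF
  diagnostics, and DIC model comparison; parallel NLS fits with AICc
  (`fit_incorporation_nls`).
* **DTDFs** (`estimate_dtdf`) from the equilibrium window (day ≥ 60):
  Δᵢ = δX_tissue,i − δX_diet, as plain averages and as Bayesian posteriors
  of the mean.
* **Mixing model** (`fit_mixing_model`) — Dirichlet-prior simplex MCMC with
  source and discrimination uncertainty, residual-only or
  process + residual error structures, reported as means and 95%
  credibility ranges in percent.
* **Niche geometry** (`standard_ellipse_area`, `convex_hull_area`) — SEA,
  SEA_c and convex hulls in isotope space.
* **Synthetic data** (`simulate_feeding_trial`,
  `simulate_mixture_scenario`) — the full experimental design and the
  hypothetical 4-source / 5-consumer scenario, seeded and deterministic.

## Worked example

```r
library(dtdfmix)

# 1. simulate a diet-switch feeding trial (5 groups x 2 tissues, days 0-120)
samples <- simulate_feeding_trial(design = experiment_design(seed = 1))

# 2. fit the one-compartment incorporation model for group 1 muscle d13C
g1 <- samples[samples$group == 1 & samples$tissue == "muscle", ]
fit <- fit_incorporation_bayes(g1, "d13c", "one",
                               settings = mcmc_settings(n_iter = 20000,
                                                        n_burn = 10000,
                                                        thin = 10, seed = 1))
print(fit)
#> one-compartment Bayesian incorporation fit (d13c, group 1, muscle)
#>   parameter    mean  cr_low cr_high
#> 1       dX0 -22.961 -23.210 -22.718
#> 2     dXinf -19.162 -19.274 -19.048
#> 3    lambda   0.271   0.171   0.646
#> 4     sigma   0.245   0.184   0.334
#> DIC = 1.85; max PSRF = 1.002
```

The curve starts at the pre-switch value δX0 ≈ −23 ‰ and equilibrates at
δX∞ ≈ −19.2 ‰ (the generating values were −22.83 and −19.23); λ ≈ 0.27/day
means the tissue turns over fast:

```r
residence_time(compartment_params(-22.83, -19.23, 0.271))
#> residence time tau = 3.69 days
```

Equilibrium-window DTDFs per source (muscle): negative for the
¹³C-enriched diet, strongly positive ¹⁵N discrimination for the
plant-protein diets:

```r
estimate_dtdf(samples, default_sources(), method = "average")
#>    source tissue delta_c sd_c delta_n sd_n  method
#>   source1 muscle    -4.5 0.18    0.45 0.20 average
#>   source2 muscle     3.4 0.33   -0.31 0.34 average
#>   source3 muscle     2.9 0.21    7.45 0.33 average
#>   source4 muscle     5.3 0.35    7.66 0.17 average
```

A simulated single-source consumer group analysed with matched
discrimination factors is attributed almost entirely to its true source:

```r
src <- hypothetical_sources()
consumers <- simulate_mixture_scenario(src, n_consumers = 30, seed = 1)
est <- fit_mixing_model(
  mixture_problem(consumers[consumers$group == 1, ], src,
                  literature_dtdf(src$name)),
  mcmc_settings(n_iter = 10000, n_burn = 5000, seed = 1))
print(est)
#> Bayesian mixing model (residual error; isotopes: d13c, d15n)
#>   source1    mean = 98.5%, 95% CR = 97.2-99.5%
#>   source2    mean = 0.5%, 95% CR = 0.0-1.5%
#>   source3    mean = 0.3%, 95% CR = 0.0-1.0%
#>   source4    mean = 0.6%, 95% CR = 0.0-1.7%
#>   max PSRF = 1.006
```

End-to-end workflows (`run_hypothetical_workflow`, `run_trial_workflow`)
and a CLI (`dtdfmix_cli()`; subcommands `simulate`, `fit-incorporation`,
`dtdf`, `mix`, `ellipse`, `run-hypothetical`, `run-trial`) tie the stages
together.

## Further reading

The methods vignette (`vignettes/dtdf-methods.Rmd`) documents the models,
priors, sampler design, synthetic-data assumptions and known limitations.
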