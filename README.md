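# coastmix

Quantitative reconstruction of marine vs. terrestrial diet fractions of
individual consumers from bone-collagen stable isotopes (δ¹³C, δ¹⁵N),
for archaeologists and isotope ecologists working in coastal systems
where marine foods are ¹³C- and ¹⁵N-enriched over C₃ terrestrial foods.

The core is a concentration-dependent Bayesian stable isotope mixing
model with process error and uncertain trophic enrichment. Given diet
proportions **p** over K food-source groups, the consumer's tissue value
for element e ∈ {C, N} is modelled as

> δₑ | p ~ Normal( Σₖ wₖ (μₖ + ε_mean),  Σₖ wₖ² (σₖ² + ε_sd²) ),
> wₖ = pₖ cₖ / Σⱼ pⱼ cⱼ,

where (μₖ, σₖ) are the source group's isotopic mean and SD, cₖ its mean
elemental concentration (%C or %N), and ε the trophic enrichment factor
(TEF) distribution for that element. The prior on **p** is
Dirichlet(1,1,1,1); the posterior is sampled by random-walk Metropolis
on the additive-log-ratio transform of the simplex, with auto-tuned
proposal scale and multiple chains. Convergence is gated on Gelman-Rubin
R̂ < 1.05 and Geweke |z| screening with an escalating-run protocol;
marine/terrestrial totals are aggregated per posterior draw.

Around the model sit the supporting stages of the workflow: Suess-effect
and tissue-offset corrections, K-nearest-neighbour randomization tests
of group separation, a generalized Shapiro-Wilk multivariate normality
test, rank-sum comparisons with Holm adjustment, minimum-convex-polygon
plausibility screens for candidate TEFs, a synthetic-data generator with
known truth, and a parameter-recovery / TEF-sensitivity harness.

## Worked example

```r
library(coastmix)

design  <- synthetic_design(seed = 7)        # four-group coastal layout
sources <- generate_sources(design)
gen     <- generate_consumers(design, sources = sources)
dist    <- source_distributions(sources)

# geometric screen of a TEF scenario
tp <- tef_plausibility(gen$consumers, sources, tef_scenario("low_C_high_N"))
#> inside raw: 33 of 35 | inside means: 12

# per-consumer posterior diet fractions
fit <- fit_consumer(gen$consumers[1, ], dist, tef_scenario("low_C_high_N"),
                    mcmc = mcmc_config(seed = 3))
fit
#> Bayesian mixing model fit for consumer SYN001 (scenario low_C_high_N)
#>   3000 retained draws, 3 chains, mean acceptance 0.35
#>   group                    lower upper   mean
#> 1 terrestrial_plant      0.00359 0.227 0.0812
#> 2 terrestrial_vertebrate 0.0192  0.415 0.188
#> 3 marine_invertebrate    0.396   0.851 0.653
#> 4 marine_vertebrate      0.00456 0.214 0.0780

aggregate_sources(fit)
#>   superset     mean ci50_lower ci50_upper ci95_lower ci95_upper
#> 1 terrestrial 0.269      0.212      0.322      0.111      0.447
#> 2 marine      0.731      0.678      0.788      0.553      0.889
```

The per-source rows are 95% equal-tailed credible intervals of the
proportion of (collagen-forming) dietary protein from each group; the
aggregated marine row says this consumer's diet was 55-89% marine at
95% credibility (the generating truth was 0.747). `tidy()`, `glance()`,
`plot_diet_intervals()` and `plot_mixing_polygons()` summarise whole
cohorts; `run_pipeline()` drives the entire workflow from a YAML config
and writes corrected tables, statistics, polygon reports, posterior
summaries and convergence JSONs to a run directory.

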