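# segmorph

Morphometrics and phylogenetic comparative analysis of **relative larval
segment position** in *Drosophila*.

Segment patterning is one of the most robust developmental processes known,
yet it evolves. This package implements the full quantitative pipeline for
asking how: measuring the position of each abdominal denticle belt in
dark-field images of first-instar larvae, expressing it as a fraction of
body length, comparing those fractions across species with the field's
standard frequentist toolkit, and fitting a Bayesian model of trait
evolution on a fixed time-calibrated phylogeny. A synthetic-data module
generates trees, trait histories, individual-level cohorts and
ground-truthed images with the statistical structure the analysis assumes,
so the whole pipeline is testable offline.

## The quantities at the core

For each larva, `X_i` is the distance from the anterior tip to the anterior
border of denticle belt *i* (a proxy for the anterior border of abdominal
segment A*i*), and `Y` is the body length. The trait is

```
p_i = X_i / Y,   i = 1..8           (relative segment position)
```

Cross-species comparison works pairwise per segment — Tukey HSD with the
studentized-range criterion and pooled within-species mean square
(Tukey–Kramer convention for unequal cohort sizes), cross-checked by Welch
t-tests with Bonferroni correction over species pairs × segments. The
headline statistic is the total count of significant (segment, species-pair)
differences and its corrected form, the count divided by the number of
segments. End-removal renormalisations (dropping A8-to-tail, or the
head+thorax) re-express positions on the truncated body and show how much of
the between-species signal one terminal region carries.

Trait evolution is modelled as multivariate Brownian motion on a rooted
ultrametric tree: along a branch of length `t_b` with rate multiplier `r_b`
the trait gains a Gaussian increment with covariance `t_b · r_b · Σ`.
Branch rates follow a strict clock, an uncorrelated lognormal relaxed clock
(UCLN) or an autocorrelated lognormal clock; inference is by
Metropolis-within-Gibbs MCMC with exact Gaussian updates of ancestral node
states, and model fit is compared with stepping-stone marginal likelihoods.
Derived summaries include per-branch normalised change `|Δx| / t_b` (change
per unit time), per-segment evolutionary rates, and correlations of branch
rates between segments as a function of anatomical distance.

## Worked example

```r
library(segmorph)
library(dplyr)

study <- simulate_study(seed = 1)        # 12 species, 105-145 larvae each
rp <- relative_positions(study$measurements)

pd <- tukey_pairwise(rp)
glance(pd)
#> # A tibble: 1 × 6
#>   total corrected_total n_all_segments_pairs n_segments alpha method
#> 1   366            45.8                   24          8  0.05 tukey

coefficient_of_variation(rp)$by_segment |> summarise(mean(mean_cv))
#> 0.0301
pca_segments(rp)$variance_explained[1]
#> PC1: 0.827
head(pd$per_species, 3)
#>   species         n_involving
#> 1 D.pseudoobscura          83
#> 2 D.persimilis             82
#> 3 D.mojavensis             81
```

Read: across the synthetic study, 366 of the 66 × 8 pairwise segment
comparisons differ at α = 0.05 (corrected total 45.8 differences per
segment); 24 of 66 species pairs differ at every segment; the measurement
noise puts the coefficient of variation of relative position at ≈ 0.03; one
principal component dominated by the posterior segments explains ~83% of
individual variation; and the species generated with the largest posterior
deviations are involved in the most differences.

The phylogenetic layer runs per segment on species means:

```r
tips <- rp |> group_by(species, segment) |>
  summarise(p = mean(p), .groups = "drop") |>
  tidyr::pivot_wider(names_from = segment, values_from = p)

post <- run_mcmc(study$tree, setNames(tips$A8, tips$species),
                 branch_rate_model("ucln"), n_iter = 20000, thin = 20, seed = 1)
tidy(post)          # posterior sigma2 and clock spread with 95% CIs
ancestral_states(post)
autoplot(branch_changes(post))   # change-per-unit-time distribution
```

`run_pipeline(pipeline_config(...))` chains simulate → measure → morpho →
stats → phylo and writes CSV outputs plus a JSON run report with seeds and
input digests; a thin command-line wrapper lives at `inst/exec/segmorph`.

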