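---
title: "Measuring and modelling the evolution of larval segment position"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling the evolution of larval segment position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmorph)
library(dplyr)
```

## The trait and its measurement

First-instar *Drosophila* larvae carry eight ventral denticle belts, one per
abdominal segment A1–A8. The anterior border of each belt is a reliable proxy
for the segment's anterior border, and the trait studied throughout this
package is the **relative segment position**: the distance `X` from the
larva's anterior tip to a belt's anterior border divided by the total body
length `Y`. Working with the fraction `p = X/Y` removes overall body-size
differences, so what remains is the allometry of the segmented body plan —
where along the body each segment sits, per cent of larval length.

The measurement chain mirrors a dark-field imaging protocol:
`orient_larva()` segments the bright body on the dark background (Otsu
threshold capped just above the background mode, because dark-field scenes
are tri-modal: background, cuticle, denticle bands), aligns the body's
principal axis horizontally, and decides which end is anterior from the
width profile — the head end tapers over a longer distance than the blunt
posterior — with a fallback that exploits the long head-plus-thorax gap
before the first belt. `detect_belts()` takes the axial intensity profile
(column means over the central body rows), smooths it with a short running
mean, keeps the eight most prominent bright bands, and places each border at
the interpolated half-maximum crossing of its band. Half-maximum edges are
parameter free and stable under overall contrast changes; sub-pixel
interpolation keeps the error well below a pixel on clean images. Real
images would need a supplied pixel size and may need the posterior spiracles
to disambiguate orientation in degenerate cases; the width heuristic is a
documented limitation.

## The synthetic study

Nothing in the test suite depends on downloaded data; a generator module
recreates the statistical structure the analysis assumes.

* **Species profiles.** Twelve species with mean anterior-border positions
  spanning roughly 0.29 (A1) to 0.84 (A8) of body length, mean lengths of
  850–1250 µm, and species-specific deviations that grow from anterior to
  posterior — one species carries a strongly anterior-shifted A8 border
  (long terminal region), another a posterior-shifted one. Deviations are
  centred per segment so the across-species mean is the base profile.
* **Within-species noise.** Each larva's nine inter-boundary spans are the
  mean spans times `exp(independent segment noise)` times `exp(smooth axial
  field)`, where the smooth field is a Gaussian process along the body with
  a squared-exponential kernel (length scale 0.25 body lengths). The smooth
  field is what makes neighbouring segments co-vary more than distant ones;
  no biological measurement pins down this mechanism, so it is the package's
  own modelling choice, and the noise scales
  (segment sd 0.043, field sd 0.055, length CV 0.06) were fixed once so the
  mean coefficient of variation of relative position is ≈ 0.03 and
  within-species correlations decay smoothly with distance. Cohort sizes
  default to 105–145 individuals per species.
* **Images.** `render_larva_image()` draws the body and belts analytically
  in a rotated frame (so any rotation is rendered exactly, with ~1 px soft
  band edges for sub-pixel localisation) and returns the ground truth in
  body-frame pixel coordinates, which rotation does not change.

What the generator does **not** emulate: optical texture of real cuticle,
mounting artefacts, bubbles, uneven illumination, staging variation. Passing
the image round-trip tests therefore demonstrates the correctness of the
geometry and detection logic, not robustness to every real-world artefact.

## Comparative statistics

`fit_interaction_anova()` fits `p ~ species + segment + species:segment`
with fixed effects and sequential sums of squares in that order.
`tukey_pairwise()` runs, per segment, all species pairs through the
studentized-range criterion with the pooled within-species mean square and
the Tukey–Kramer harmonic-mean convention for unbalanced groups;
`ttest_bonferroni()` is the cross-checking route — Welch t-tests multiplied
by (number of species pairs × number of segments). Welch was chosen over the
pooled t because cohort sizes differ and variance homogeneity is not
guaranteed; both routes agree on more than 90% of indicators under the
default conditions. The headline statistic is the total count of significant
(segment, species-pair) differences and the **corrected total** — that count
divided by the number of segments — which makes full-body and end-removed
analyses comparable.

One calibration point deserves emphasis. The species-term F-test is exactly
calibrated (type-I error 0.05) only when observations are independent. Under
the cohort generator, positions within one larva are correlated — through
the smooth axial field and through the shared body-length denominator — and
the F-test becomes anticonservative, just as it would on real larvae. The
type-I calibration check therefore uses a null generator with independent
per-(larva, segment) jitter; on correlated data the ANOVA should be read as
descriptive, with the pairwise procedures carrying the inferential weight.

End removal follows two renormalisations: dropping the terminal region from
A8's anterior border to the tail (`p' = X_i / X_8`, segments A1–A7) and
dropping the head-plus-thorax (`p' = (X_i − X_1) / (Y − X_1)`, segments
A2–A8). On the default synthetic study the corrected total falls by roughly
a fifth when the terminal region is removed and rises slightly when the head
region is removed — the same asymmetry the biological analysis turns on.

`pca_segments()` runs `prcomp` on the mean-centred individuals × 8 matrix
without variance scaling; PC1's sign is fixed so its loading on A8 is
positive, making the correlation tests reproducible. Individual-level PCA is
the default (the variance-explained figure refers to individual variation);
species-mean PCA is available via `level = "species"`. Confidence intervals
throughout are t-based; a bootstrap alternative was considered and rejected
for determinism and speed, since at n ≥ 105 the two coincide closely.

## Brownian-motion model with relaxed clocks

Species mean positions evolve on a fixed, rooted, ultrametric phylogeny
under (multivariate) Brownian motion: along a branch of length `t_b` with
rate multiplier `r_b`, the trait picks up a Gaussian increment with
covariance `t_b · r_b · Σ`. Three branch-rate models are available: a strict
clock (`r_b = 1`), an uncorrelated lognormal clock (independent log-rates,
spread `s_r`), and an autocorrelated lognormal clock (log-rate Brownian
motion with drift variance `ν` per unit time). A fourth candidate —
independent relaxed clocks per segment — is obtained by running the UCLN
model separately per segment, which is also how the per-segment rate figures
are produced; its marginal likelihood is the sum of the per-segment ones.

`bm_loglik()` computes the likelihood by post-order pruning in O(tips),
either with a fixed root state or with the root integrated under an improper
flat prior (the REML / independent-contrasts treatment); the pruning result
matches a brute-force multivariate-normal density on random trees to
floating-point accuracy, and the integrated version equals the numeric
integral of the fixed-root version.

`run_mcmc()` augments the state with the ancestral node states, which makes
every conditional simple: node states have exact Gaussian full conditionals
(Gibbs; the root is truncated to its uniform (0,1) prior by rejection),
`σ²` and the branch rates get random-walk scale moves, and the relaxed-clock
hyperparameters get scale moves against their priors. A Metropolis-only
node-update path is retained purely to cross-validate the Gibbs updates.
Because the likelihood only sees the products `r_b · σ²`, the scale of the
rates is not identified; each recorded sample is therefore re-expressed with
the log branch rates centred at zero, the geometric mean absorbed into
`σ²`. This is a deterministic reparameterisation of the sample — the
centring constraint holds exactly on every draw.

Default priors: `σ²` per segment lognormal with median 0.01 and sd one
decade (positions are fractions and the tree has unit depth, so `σ² = 0.01`
means a marginal sd of 0.1 body-lengths across the tree's depth); `s_r`
exponential with mean 0.587 (the value at which the central 95% of branch
rates spans about a tenfold range); `ν` exponential with mean 0.5; root
uniform on (0,1) per segment. Chains default to 100,000 iterations, thinning
50, 10% burn-in; every scalar parameter's effective sample size is reported
(initial-positive-sequence estimator) and anything below 200 triggers a
warning, never silence. The test suite runs deliberately shorter chains
(2,000–8,000 iterations on 12–20 tips), sizes at which the sampler's output
was checked against closed-form and numeric-grid posteriors.

Derived summaries: `ancestral_states()` (posterior means and credible
intervals per node), `branch_changes()` (the normalised change
`|x_child − x_parent| / t_b`, pooled over samples by default, or over
per-branch posterior means), and `segment_rate_correlations()` (Pearson
correlation over branches of posterior-mean log rates between segment
pairs, against the anatomical distance between the segments). Two numerical
caveats are documented deliberately: on trees with near-zero branches the
normalised change is dominated by prior variance (it grows as `1/√t`), so
branch-level comparisons are only meaningful when branch lengths are within
a reasonable range; and per-branch rates estimated from a single scalar
trait are weakly identified, so rate-correlation patterns are tested with
information pooled across segments and moderate trees.

`marginal_likelihood()` implements stepping-stone sampling over power
posteriors with powers `(k/K)^(1/0.3)` on the states-integrated (pruning)
likelihood, run from the posterior end down to the prior, with a
delta-method Monte-Carlo error per stone. A single stone degenerates to the
arithmetic prior-mean estimator and is flagged unreliable. Model comparisons
are reported as log Bayes factors.

## Degenerate inputs and tie-breaks

Zero-length branches are rejected at tree load. A species with fewer than
two larvae is excluded from summaries with a warning; fewer than three
blocks the correlation profile. Zero within-species variance makes a
correlation undefined — reported as `NA` and excluded from averages, with a
warning. Zero residual variance makes the ANOVA's F undefined and is
flagged. Belt detection errors distinguish "too few bands" (count reported)
from "bands fused" (ambiguity). Every stochastic function takes an explicit
seed and touches no global RNG state.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to finish in minutes on one
core while keeping every comparison meaningful: 200 random trees of 3–6 tips
for the likelihood oracle; 50 replicate datasets for credible-interval
coverage; 10 replicates (12 tips × 8 segments) for branch-rate recovery; 60
larvae across 12 species for the imaging round trip; 1,000 replicate fits
for the ANOVA calibration; 100 instances for the Tukey oracle; and 8
replicates of the 20-tip, 8-segment rate-correlation study. The full-size
synthetic study uses the default 105–145 larvae per species.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(seed = 1)
rp <- relative_positions(study$measurements)

pd <- tukey_pairwise(rp)
glance(pd)                     # total and corrected difference counts
autoplot(pd)                   # species-pair heatmap

summ <- species_summary(rp)
autoplot(summ)                 # per-species segment positions with CIs

tips <- rp |>
  dplyr::group_by(species, segment) |>
  dplyr::summarise(p = mean(p), .groups = "drop") |>
  tidyr::pivot_wider(names_from = segment, values_from = p)

post <- run_mcmc(study$tree, stats::setNames(tips$A8, tips$species),
                 branch_rate_model("ucln"), n_iter = 20000, thin = 20, seed = 1)
tidy(post)                     # sigma2 and clock-spread summaries
autoplot(branch_changes(post)) # distribution of change per unit time
```
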