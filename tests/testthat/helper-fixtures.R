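suppressMessages({
  library(dplyr)
  library(tibble)
})

# build one larva's measurement rows from anterior-border fractions and length
make_larva <- function(bounds, L, species = "sp", larva_id = "l1") {
  stopifnot(length(bounds) == 8)
  spans_next <- diff(c(bounds, 1)) * L
  tibble(species = species, larva_id = larva_id, segment = paste0("A", 1:8),
         x_anterior_um = bounds * L,
         x_posterior_um = bounds * L + 0.3 * spans_next,
         body_length_um = L)
}

# cohort of identical or jittered larvae built directly (independent of the
# package generator), with per-larva relative positions p = bounds * exp(eps)
make_cohort <- function(bounds, L, n, species = "sp", jitter_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    bind_rows(lapply(seq_len(n), function(i) {
      b <- bounds * exp(stats::rnorm(8, 0, jitter_sd))
      b <- pmin(sort(b), 0.99)
      make_larva(b, L, species, sprintf("%s_%03d", species, i))
    }))
  })
}

# ultrametric tree with moderate branch-length spread (Grafen lengths)
grafen_tree <- function(n, seed = 1) {
  tr <- withr::with_seed(seed, ape::compute.brlen(ape::rtree(n), method = "Grafen"))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# one full-size synthetic study shared across test files
.fixture_env <- new.env(parent = emptyenv())
full_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(seed = 20260925)
  .fixture_env$study
}

seg_index_test <- function(s) as.integer(sub("A", "", s))

noiseless_profile <- function(i = 1) {
  pr <- as.list(default_species_profiles()[i, ])
  pr$length_cv <- 0
  pr$segment_noise_sd <- 0
  pr$smooth_noise_scale <- 0
  pr
}
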