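#' Default species profiles for the twelve-species study
#'
#' Returns the generator's study conditions: one profile per species, with
#' mean relative anterior-border positions of abdominal segments A1..A8,
#' mean first-instar body length, and within-species noise settings. The
#' species-specific deviations from the across-species mean grow from
#' anterior to posterior, with *D. mojavensis* carrying a strongly
#' anterior-shifted A8 border (long A8+tail) and *D. persimilis* a
#' posterior-shifted one (short A8+tail); per segment, deviations are
#' centred so the across-species mean equals the base profile.
#'
#' @param n_species number of species profiles (2..12); the first `n_species`
#'   of the default twelve are returned.
#' @return tibble with columns `species`, `mean_boundaries` (list column of
#'   8 fractions), `mean_length_um`, `length_cv`, `segment_noise_sd`,
#'   `smooth_noise_scale`.
#' @export
default_species_profiles <- function(n_species = 12) {
  stopifnot(n_species >= 2, n_species <= 12)
  species <- c("D.melanogaster", "D.simulans", "D.sechellia", "D.yakuba",
               "D.santomea", "D.erecta", "D.ananassae", "D.pseudoobscura",
               "D.persimilis", "D.willistoni", "D.mojavensis", "D.virilis")
  base <- c(0.29, 0.37, 0.45, 0.52, 0.60, 0.68, 0.76, 0.84)
  # posterior-gradient coefficient (deviation amplitude at A8) and uniform shift
  g <- c(-0.005, 0.000, -0.030, 0.010, 0.012, 0.030,
         0.002, 0.025, 0.045, -0.015, -0.055, -0.010)
  u <- c(0.004, 0.002, 0.010, -0.003, -0.005, -0.008,
         0.000, 0.006, 0.008, -0.006, -0.004, -0.004)
  ramp <- (seq_len(8) / 8)^1.5
  dev <- outer(u, rep(1, 8)) + outer(g, ramp)
  dev <- sweep(dev, 2, colMeans(dev))  # centre: across-species mean = base
  bounds <- sweep(dev, 2, base, `+`)
  lengths <- c(1000, 990, 1180, 1020, 1250, 960, 1010, 860, 850, 980, 900, 1150)
  tibble(
    species = species,
    mean_boundaries = lapply(seq_len(12), function(i) bounds[i, ]),
    mean_length_um = lengths,
    length_cv = 0.06,
    segment_noise_sd = 0.043,
    smooth_noise_scale = 0.055
  )[seq_len(n_species), ]
}

#' Simulate a rooted ultrametric binary tree
#'
#' Random coalescent topology (via [ape::rcoal()]) rescaled to unit depth,
#' used as a stand-in for a fixed time-calibrated phylogeny.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed; all randomness is local to the call.
#' @param tip_labels optional character vector of tip labels.
#' @return an [ape] `phylo` object, rooted, binary, ultrametric, depth 1.
#' @export
simulate_tree <- function(n_taxa, seed = 1, tip_labels = NULL) {
  if (!is.numeric(n_taxa) || n_taxa < 2)
    abort("`n_taxa` must be >= 2", class = "segmorph_invalid_argument")
  tree <- withr::with_seed(seed, ape::rcoal(n_taxa, tip.label = tip_labels))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Branch-rate model specification
#'
#' @param kind "strict" (all rates 1), "ucln" (uncorrelated lognormal:
#'   independent log-rates with sd `s_r`), or "acln" (autocorrelated
#'   lognormal: log-rate Brownian motion along the tree with variance `nu`
#'   per unit time).
#' @param s_r sd of log branch rates (ucln).
#' @param nu drift variance per unit time of the log rate (acln).
#' @return a `segmorph_rate_model` list.
#' @export
branch_rate_model <- function(kind = c("strict", "ucln", "acln"), s_r = 0.587, nu = 0.5) {
  kind <- match.arg(kind)
  if (s_r < 0 || nu < 0)
    abort("rate-model hyperparameters must be non-negative", class = "segmorph_invalid_argument")
  structure(list(kind = kind, s_r = s_r, nu = nu), class = "segmorph_rate_model")
}

# draw true per-edge rate multipliers under a rate model (assumes RNG is set)
draw_branch_rates <- function(tree, model) {
  ne <- nrow(tree$edge)
  switch(model$kind,
    strict = rep(1, ne),
    ucln = exp(stats::rnorm(ne, 0, model$s_r)),
    acln = {
      ntip <- length(tree$tip.label)
      lr <- numeric(ntip + tree$Nnode)
      lr[ntip + 1L] <- 0
      ord <- ape::reorder.phylo(tree, "cladewise")
      rate <- numeric(ne)
      for (k in seq_len(ne)) {
        e <- which(tree$edge[, 1] == ord$edge[k, 1] & tree$edge[, 2] == ord$edge[k, 2])
        par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
        lr[chi] <- lr[par] + stats::rnorm(1, 0, sqrt(model$nu * tree$edge.length[e]))
        rate[e] <- exp((lr[par] + lr[chi]) / 2)
      }
      rate
    })
}

#' Evolve traits on a tree under multivariate Brownian motion
#'
#' Simulates node states down the tree: each child state is the parent state
#' plus a multivariate Gaussian increment with covariance `t_b * r_b * sigma2`
#' (branch length times branch-rate multiplier times trait rate matrix).
#' Because relative positions are fractions, any increment that would leave
#' (0,1) in some component is rejected and the whole branch increment redrawn;
#' rejections are counted and returned.
#'
#' @param tree `phylo` tree.
#' @param sigma2 trait rate matrix per unit time (p x p, PSD) or a scalar.
#' @param rate_model a [branch_rate_model()], or a numeric vector of fixed
#'   per-edge multipliers.
#' @param root_state numeric vector of trait values at the root, in (0,1).
#' @param seed integer seed.
#' @return `segmorph_trait_history`: list with `tree`, `node_states`
#'   (matrix, rows = node ids in ape numbering), `branch_rates_true` (per
#'   edge), `sigma2_true`, `rejections`.
#' @export
evolve_traits <- function(tree, sigma2, rate_model = branch_rate_model("strict"),
                          root_state, seed = 1) {
  p <- length(root_state)
  sigma2 <- if (length(sigma2) == 1L) diag(p) * as.numeric(sigma2) else as.matrix(sigma2)
  check_psd(sigma2)
  if (any(root_state <= 0 | root_state >= 1))
    abort("`root_state` components must lie in (0,1)", class = "segmorph_invalid_argument")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  withr::with_seed(seed, {
    rates <- if (is.numeric(rate_model)) rate_model else draw_branch_rates(tree, rate_model)
    states <- matrix(NA_real_, nn, p)
    states[ntip + 1L, ] <- root_state
    ord <- ape::reorder.phylo(tree, "cladewise")
    rej <- 0L
    for (k in seq_len(nrow(ord$edge))) {
      e <- which(tree$edge[, 1] == ord$edge[k, 1] & tree$edge[, 2] == ord$edge[k, 2])
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      v <- tree$edge.length[e] * rates[e]
      repeat {
        cand <- states[par, ] + if (v > 0) drop(rmvn(1, rep(0, p), v * sigma2)) else rep(0, p)
        if (all(cand > 0 & cand < 1)) break
        rej <- rej + 1L
        if (rej > 100000L)
          abort("rejection resampling failed; traits pressed against (0,1)",
                class = "segmorph_boundary_error")
      }
      states[chi, ] <- cand
    }
    rownames(states) <- c(tree$tip.label, paste0("node", (ntip + 1L):nn))
    structure(list(tree = tree, node_states = states, branch_rates_true = rates,
                   sigma2_true = sigma2, rejections = rej),
              class = "segmorph_trait_history")
  })
}

#' Simulate a cohort of larval measurements for one species
#'
#' Each individual gets a body length drawn around the species mean
#' (lognormal with CV `length_cv`), and nine inter-boundary spans (anterior
#' end to A1, A1 to A2, ..., A8 to posterior end) equal to the mean span
#' times `exp(independent segment noise)` times `exp(smooth axial field)`.
#' The smooth field is a Gaussian process along the body axis
#' (squared-exponential kernel, length scale 0.25 body lengths), which makes
#' neighbouring segments co-vary more than distant ones. Denticle-belt
#' posterior borders sit at 0.35 of the local span.
#'
#' @param profile one row of [default_species_profiles()] (or a list with the
#'   same fields).
#' @param n_individuals cohort size (>= 0).
#' @param seed integer seed.
#' @return tidy measurement tibble: `species`, `larva_id`, `segment`,
#'   `x_anterior_um`, `x_posterior_um`, `body_length_um`.
#' @export
simulate_cohort <- function(profile, n_individuals, seed = 1) {
  if (n_individuals < 0)
    abort("`n_individuals` must be >= 0", class = "segmorph_invalid_argument")
  if (is.data.frame(profile)) profile <- as.list(profile[1, ])
  mb <- unlist(profile$mean_boundaries)
  stopifnot(length(mb) == 8, all(diff(mb) > 0), all(mb > 0 & mb < 1))
  if (n_individuals == 0)
    return(tibble(species = character(), larva_id = character(), segment = character(),
                  x_anterior_um = numeric(), x_posterior_um = numeric(),
                  body_length_um = numeric()))
  f <- diff(c(0, mb, 1))                    # 9 mean span fractions
  mid <- (cumsum(f) + c(0, cumsum(f)[-9])) / 2
  sdlog <- sqrt(log(1 + profile$length_cv^2))
  withr::with_seed(seed, {
    n <- n_individuals
    L <- profile$mean_length_um * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    eps <- matrix(stats::rnorm(9L * n, 0, profile$segment_noise_sd), n, 9)
    g <- if (profile$smooth_noise_scale > 0) {
      d <- outer(mid, mid, `-`)
      K <- profile$smooth_noise_scale^2 * exp(-d^2 / (2 * 0.25^2)) + diag(1e-12, 9)
      matrix(stats::rnorm(9L * n), n, 9) %*% chol(K)
    } else matrix(0, n, 9)
    span <- (L * matrix(f, n, 9, byrow = TRUE)) * exp(eps + g)
    bnd <- t(apply(span, 1, cumsum))        # boundary after each span; col 9 = body length
    ant <- bnd[, 1:8, drop = FALSE]
    post <- ant + 0.35 * span[, 2:9, drop = FALSE]
    tibble(
      species = profile$species,
      larva_id = rep(sprintf("%s_%04d", profile$species, seq_len(n)), each = 8L),
      segment = rep(SEGMENTS, n),
      x_anterior_um = as.vector(t(ant)),
      x_posterior_um = as.vector(t(post)),
      body_length_um = rep(bnd[, 9], each = 8L))
  })
}

#' Simulate the full multi-species study
#'
#' Cohorts for every profile (default: the twelve-species conditions with
#' 105-145 individuals per species, sampled uniformly) plus a unit-depth
#' tree whose tips are the profile species.
#'
#' @param profiles profile tibble, as [default_species_profiles()].
#' @param n_per_species `NULL` (draw each species' n uniformly in 105..145),
#'   a single count, or a vector per species.
#' @param seed integer seed.
#' @return list with `measurements` (tidy tibble), `tree` (`phylo`),
#'   `profiles`.
#' @export
simulate_study <- function(profiles = default_species_profiles(),
                           n_per_species = NULL, seed = 1) {
  ns <- nrow(profiles)
  n_per_species <- withr::with_seed(seed, {
    if (is.null(n_per_species)) sample(105:145, ns, replace = TRUE)
    else rep_len(n_per_species, ns)
  })
  meas <- dplyr::bind_rows(lapply(seq_len(ns), function(i)
    simulate_cohort(profiles[i, ], n_per_species[i], seed = seed + 7L * i)))
  tree <- simulate_tree(ns, seed = seed + 101L, tip_labels = profiles$species)
  list(measurements = meas, tree = tree, profiles = profiles)
}

#' Write a measurement table as tidy CSV
#' @param measurements tidy measurement tibble.
#' @param path output file.
#' @export
write_cohort_csv <- function(measurements, path) {
  assert_measurements(measurements)
  readr::write_csv(measurements, path)
  invisible(path)
}

#' Read a tidy measurement CSV
#'
#' Accepts the package's tidy dialect (`species, larva_id, segment,
#' x_anterior_um, x_posterior_um, body_length_um`); extra columns are kept.
#' @param path CSV file.
#' @export
read_measurements <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  assert_measurements(m)
  m
}
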