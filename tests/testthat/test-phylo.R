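test_that("pruning likelihood equals the direct multivariate-normal density", {
  # scalar traits, random trees up to 6 tips, random branch rates
  worst <- 0
  for (case in 1:40) {
    n <- 3 + (case %% 4)
    tr <- simulate_tree(n, seed = case)
    sim <- withr::with_seed(case, list(
      rates = exp(stats::rnorm(nrow(tr$edge), 0, 0.6)),
      x = stats::setNames(stats::rnorm(n, 0.5, 0.1), tr$tip.label),
      s2 = exp(stats::rnorm(1, log(0.02), 0.5)),
      root = stats::runif(1, 0.3, 0.7)))
    tr2 <- tr; tr2$edge.length <- tr$edge.length * sim$rates
    C <- ape::vcv(tr2)[tr$tip.label, tr$tip.label] * sim$s2
    ll_direct <- as.numeric(segmorph:::ldmvnorm(sim$x, sim$root, C))
    ll_prune <- bm_loglik(tr, sim$x, sim$s2, rates = sim$rates, root = sim$root)
    worst <- max(worst, abs(ll_direct - ll_prune) / max(1, abs(ll_direct)))
  }
  expect_lt(worst, 1e-8)
})

test_that("multivariate pruning matches a Kronecker brute force", {
  tr <- simulate_tree(5, seed = 3)
  p <- 3
  sim <- withr::with_seed(11, {
    A <- matrix(stats::rnorm(p * p), p)
    list(S = crossprod(A) / 50 + diag(1e-4, p),
         X = matrix(stats::rnorm(5 * p, 0.5, 0.1), 5,
                    dimnames = list(tr$tip.label, paste0("A", 1:p))),
         root = stats::runif(p, 0.4, 0.6))
  })
  C <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  big <- kronecker(sim$S, C)           # vec ordering: trait-major blocks
  ll_direct <- as.numeric(segmorph:::ldmvnorm(
    as.vector(sim$X - matrix(sim$root, 5, p, byrow = TRUE)), 0, big))
  ll_prune <- bm_loglik(tr, sim$X, sim$S, root = sim$root)
  expect_equal(ll_prune, ll_direct, tolerance = 1e-8)
})

test_that("likelihood identities and edge cases hold", {
  tr1 <- ape::read.tree(text = "(A:1);")
  expect_equal(bm_loglik(tr1, c(A = 0.5), 1, root = 0.5), -0.5 * log(2 * pi),
               tolerance = 1e-10)

  tr <- simulate_tree(8, seed = 2)
  x <- withr::with_seed(4, stats::setNames(stats::runif(8, 0.3, 0.7), tr$tip.label))
  ne <- nrow(tr$edge)
  expect_equal(bm_loglik(tr, x, 0.01, rates = rep(2, ne)),
               bm_loglik(tr, x, 0.02, rates = rep(1, ne)), tolerance = 1e-10)

  # integrated (flat-root) likelihood equals the numeric integral of the
  # fixed-root likelihood over the root state
  ll_int <- bm_loglik(tr, x, 0.01)
  rg <- seq(-1.5, 2.5, length.out = 6000)
  lls <- vapply(rg, function(r) bm_loglik(tr, x, 0.01, root = r), numeric(1))
  mx <- max(lls)
  ll_num <- mx + log(sum(exp(lls - mx)) * diff(rg)[1])
  expect_equal(ll_int, ll_num, tolerance = 1e-6)

  expect_error(bm_loglik(tr, c(bad = 0.5), 0.01),
               class = "segmorph_invalid_argument")
  bad_tree <- tr; bad_tree$edge.length[1] <- 0
  expect_error(validate_phylogeny(bad_tree), class = "segmorph_invalid_argument")
})

test_that("one-iteration chains return a single valid sample", {
  tr <- simulate_tree(4, seed = 6)
  x <- stats::setNames(c(0.4, 0.5, 0.55, 0.6), tr$tip.label)
  post <- suppressWarnings(run_mcmc(tr, x, branch_rate_model("strict"),
                                    n_iter = 1, thin = 1, burnin = 0, seed = 1))
  expect_equal(nrow(post$sigma2), 1)
  expect_true(all(post$sigma2 > 0))
  expect_true(all(post$rates > 0))
  expect_equal(dim(post$node_states), c(1, 7, 1))
  expect_true(all(!is.na(post$node_states)))
  expect_equal(nrow(post$ess), 2)
})

test_that("the sampler reproduces the exact posterior on a two-tip tree", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  x <- c(A = 0.45, B = 0.58)
  post <- suppressWarnings(run_mcmc(tr, x, branch_rate_model("strict"),
                                    n_iter = 200000, thin = 40, seed = 7))
  s <- post$sigma2[, 1]
  # numeric-grid oracle for p(sigma2 | x): lognormal prior, uniform(0,1) root
  ls2 <- seq(log(1e-6), log(10), length.out = 4000)
  s2g <- exp(ls2)
  m <- mean(x); d <- diff(x)
  logpost <- stats::dnorm(ls2, log(0.01), log(10), log = TRUE) +
    stats::dnorm(d, 0, sqrt(2 * s2g), log = TRUE) +
    log(stats::pnorm((1 - m) / sqrt(s2g / 2)) - stats::pnorm(-m / sqrt(s2g / 2)))
  w <- exp(logpost - max(logpost))
  cdf <- cumsum(w) / sum(w)
  u <- stats::approxfun(ls2, cdf, rule = 2)(log(s))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("relaxed-clock samples are centred and recover branch rates", {
  tr <- grafen_tree(12, seed = 1)
  mdl <- branch_rate_model("ucln", s_r = 0.8)
  th <- evolve_traits(tr, diag(8) * 0.01, mdl,
                      root_state = seq(0.3, 0.8, length.out = 8), seed = 77)
  post <- suppressWarnings(run_mcmc(tr, th$node_states[1:12, ],
                                    branch_rate_model("ucln"),
                                    n_iter = 3000, thin = 6, seed = 5))
  # identifiability constraint holds on every sample
  expect_lt(max(abs(rowMeans(log(post$rates)))), 1e-10)
  truth <- log(th$branch_rates_true) - mean(log(th$branch_rates_true))
  rho <- stats::cor(truth, colMeans(log(post$rates)), method = "spearman")
  expect_gt(rho, 0)
})

test_that("Gibbs and Metropolis node updates target the same distribution", {
  tr <- simulate_tree(4, seed = 9)
  x <- stats::setNames(c(0.42, 0.47, 0.58, 0.63), tr$tip.label)
  pg <- suppressWarnings(run_mcmc(tr, x, branch_rate_model("strict"),
                                  n_iter = 20000, thin = 10, seed = 1,
                                  node_move = "gibbs"))
  pm <- suppressWarnings(run_mcmc(tr, x, branch_rate_model("strict"),
                                  n_iter = 60000, thin = 30, seed = 2,
                                  node_move = "metropolis"))
  root <- 5
  expect_lt(abs(mean(pg$node_states[, root, 1]) - mean(pm$node_states[, root, 1])), 0.02)
  expect_lt(abs(stats::sd(pg$node_states[, root, 1]) -
                  stats::sd(pm$node_states[, root, 1])), 0.02)
  expect_lt(abs(mean(log(pg$sigma2)) - mean(log(pm$sigma2))), 0.15)
})

test_that("ancestral states collapse in the low-rate limit and average tips", {
  tr <- simulate_tree(6, seed = 12)
  x <- stats::setNames(rep(0.5, 6), tr$tip.label)
  post <- suppressWarnings(run_mcmc(tr, x, branch_rate_model("strict"),
                                    priors = mcmc_priors(sigma2_meanlog = log(1e-8),
                                                         sigma2_sdlog = 0.2),
                                    n_iter = 2000, thin = 4, seed = 3))
  anc <- ancestral_states(post)
  expect_true(all(abs(anc$mean - 0.5) < 1e-3))

  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  x2 <- c(A = 0.40, B = 0.60)
  post2 <- suppressWarnings(run_mcmc(tr2, x2, branch_rate_model("strict"),
                                     n_iter = 40000, thin = 20, seed = 4))
  anc2 <- ancestral_states(post2)
  expect_lt(abs(anc2$mean[anc2$node == 3] - 0.5), 0.02)

  # credible intervals widen away from the tips (averaged over replicates)
  tr3 <- grafen_tree(8, seed = 5)
  widths <- vapply(1:5, function(r) {
    th <- evolve_traits(tr3, 0.02, root_state = 0.5, seed = 50 + r)
    p <- suppressWarnings(run_mcmc(tr3, th$node_states[1:8, 1],
                                   branch_rate_model("strict"),
                                   n_iter = 3000, thin = 6, seed = r))
    a <- ancestral_states(p)
    a <- a[!a$is_tip, ]
    depth <- ape::node.depth.edgelength(tr3)[a$node]
    c(root = mean(a$ci_high[depth < 1e-9] - a$ci_low[depth < 1e-9]),
      deep = mean(a$ci_high[depth > 0.4] - a$ci_low[depth > 0.4]))
  }, numeric(2))
  expect_gt(mean(widths["root", ]), mean(widths["deep", ]))
})

test_that("branch changes follow their definition and detect a hot branch", {
  tr <- grafen_tree(12, seed = 1)
  th <- evolve_traits(tr, 0.01, root_state = 0.5, seed = 2)
  post <- suppressWarnings(run_mcmc(tr, th$node_states[1:12, 1],
                                    branch_rate_model("strict"),
                                    n_iter = 1500, thin = 5, seed = 1))
  bc <- branch_changes(post)
  # doubling the branch lengths halves every normalised change
  post2 <- post
  post2$tree$edge.length <- post$tree$edge.length * 2
  bc2 <- branch_changes(post2)
  expect_equal(bc2$per_branch$mean_c, bc$per_branch$mean_c / 2, tolerance = 1e-12)
  expect_equal(bc2$pooled, bc$pooled / 2, tolerance = 1e-12)
  expect_true(all(bc$pooled >= 0))

  # a branch evolving 20x faster shows the largest posterior-mean change
  ne <- nrow(tr$edge)
  hits <- vapply(1:10, function(r) {
    e <- withr::with_seed(400 + r, sample(ne, 1))
    rts <- rep(1, ne); rts[e] <- 20
    th <- evolve_traits(tr, diag(8) * 0.005, rate_model = rts,
                        root_state = seq(0.3, 0.8, length.out = 8), seed = 500 + r)
    p <- suppressWarnings(run_mcmc(tr, th$node_states[1:12, ],
                                   branch_rate_model("ucln"),
                                   n_iter = 2000, thin = 5, seed = r))
    pb <- tidy(branch_changes(p)) |>
      dplyr::group_by(edge) |>
      dplyr::summarise(c = mean(mean_c))
    pb$edge[which.max(pb$c)] == e
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("segment rate correlations hit the exact extremes", {
  tr <- grafen_tree(12, seed = 1)
  x <- withr::with_seed(3, stats::setNames(stats::runif(12, 0.4, 0.6), tr$tip.label))
  p1 <- suppressWarnings(run_mcmc(tr, x, branch_rate_model("ucln"),
                                  n_iter = 800, thin = 4, seed = 1))
  p2 <- p1                                   # identical rate samples
  p3 <- p1
  lr <- log(p1$rates)
  p3$rates <- exp(-(lr - rowMeans(lr)) + rowMeans(lr))  # negated centred log rates
  rc <- segment_rate_correlations(list(a = p1, b = p2, c = p3), c(0.3, 0.5, 0.8))
  expect_equal(rc$r[rc$seg_a == "a" & rc$seg_b == "b"], 1, tolerance = 1e-12)
  expect_equal(rc$r[rc$seg_a == "a" & rc$seg_b == "c"], -1, tolerance = 1e-12)
  expect_error(segment_rate_correlations(list(p1), 0.5))
})

test_that("stepping-stone estimates are self-consistent and rank models sanely", {
  tr <- simulate_tree(12, seed = 4)
  th <- evolve_traits(tr, 0.01, root_state = 0.5, seed = 103)
  x <- th$node_states[1:12, 1]
  m1 <- suppressWarnings(marginal_likelihood(tr, x, branch_rate_model("strict"),
                                             n_stones = 8, n_iter_per_stone = 300,
                                             seed = 1))
  m2 <- suppressWarnings(marginal_likelihood(tr, x, branch_rate_model("strict"),
                                             n_stones = 8, n_iter_per_stone = 300,
                                             seed = 2))
  expect_lt(abs(m1$log_ml - m2$log_ml), 3 * sqrt(m1$mc_error^2 + m2$mc_error^2) + 0.3)

  expect_warning(m_one <- marginal_likelihood(tr, x, branch_rate_model("strict"),
                                              n_stones = 1, n_iter_per_stone = 200,
                                              seed = 3),
                 "unreliable")
  expect_false(m_one$reliable)
  expect_true(is.finite(m_one$log_ml))

  # strict-clock data prefer the strict clock in most replicates
  wins <- vapply(1:6, function(r) {
    thr <- evolve_traits(tr, 0.01, root_state = 0.5, seed = 600 + r)
    xr <- thr$node_states[1:12, 1]
    ms <- suppressWarnings(marginal_likelihood(tr, xr, branch_rate_model("strict"),
                                               n_stones = 6, n_iter_per_stone = 200,
                                               seed = r))
    mu <- suppressWarnings(marginal_likelihood(tr, xr, branch_rate_model("ucln"),
                                               n_stones = 6, n_iter_per_stone = 200,
                                               seed = r))
    ms$log_ml > mu$log_ml
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("the autocorrelated clock runs and reports its drift parameter", {
  tr <- grafen_tree(10, seed = 2)
  th <- evolve_traits(tr, 0.01, branch_rate_model("acln", nu = 0.5),
                      root_state = 0.5, seed = 8)
  post <- suppressWarnings(run_mcmc(tr, th$node_states[1:10, 1],
                                    branch_rate_model("acln"),
                                    n_iter = 2000, thin = 5, seed = 1))
  expect_true(all(post$nu > 0))
  expect_true("nu" %in% tidy(post)$parameter)
  expect_lt(max(abs(rowMeans(log(post$rates)))), 1e-10)
})
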