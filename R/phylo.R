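#' Validate a phylogeny for comparative analysis
#'
#' Requires a rooted binary tree, ultrametric within `tol`, with strictly
#' positive branch lengths.
#'
#' @param tree `phylo` object.
#' @param tol ultrametricity tolerance (default 1e-6, relative).
#' @return the tree, invisibly.
#' @export
validate_phylogeny <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) abort("not a phylo object", class = "segmorph_invalid_argument")
  if (!ape::is.rooted(tree)) abort("tree must be rooted", class = "segmorph_invalid_argument")
  if (!ape::is.binary(tree)) abort("tree must be binary", class = "segmorph_invalid_argument")
  if (any(tree$edge.length <= 1e-9))
    abort("zero-length branches are not allowed", class = "segmorph_invalid_argument")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol * max(depths))
    abort("tree is not ultrametric", class = "segmorph_invalid_argument")
  invisible(tree)
}

#' Read and validate a Newick phylogeny
#' @param path Newick file.
#' @inheritParams validate_phylogeny
#' @export
read_phylogeny <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  validate_phylogeny(tree, tol)
  tree
}

# tip trait input -> matrix aligned with tree$tip.label
prep_tip_means <- function(tree, tip_means) {
  if (is.data.frame(tip_means)) {
    tm <- as.matrix(tip_means[, setdiff(names(tip_means), "species"), drop = FALSE])
    rownames(tm) <- tip_means$species
    tip_means <- tm
  }
  if (is.null(dim(tip_means))) tip_means <- matrix(tip_means, ncol = 1,
                                                   dimnames = list(names(tip_means), "trait"))
  miss <- setdiff(tree$tip.label, rownames(tip_means))
  if (length(miss))
    abort(paste("tip trait values missing for:", paste(miss, collapse = ", ")),
          class = "segmorph_invalid_argument")
  tip_means[tree$tip.label, , drop = FALSE]
}

# log N(d; 0, V * Sigma) for a list of contrasts; chS = chol(Sigma)
ld_contrast <- function(d, V, chS) {
  p <- length(d)
  z <- backsolve(chS, d, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(chS))) - 0.5 * p * log(V) - 0.5 * sum(z^2) / V
}

#' Brownian-motion log-likelihood by pruning
#'
#' Gaussian likelihood of tip means under (multivariate) Brownian motion on
#' a fixed tree, with per-branch covariance contribution
#' `t_b * r_b * sigma2`, computed by Felsenstein's post-order pruning in
#' O(tips). With `root = "integrated"` the root state is integrated out
#' under an improper flat prior (the REML / independent-contrast
#' likelihood); a numeric `root` adds the root-state density term.
#'
#' @param tree `phylo` object.
#' @param tip_means named vector (one trait) or species x traits matrix /
#'   tibble with a `species` column.
#' @param sigma2 trait rate per unit time: scalar or PSD matrix.
#' @param rates per-edge rate multipliers (default all 1), in
#'   `tree$edge` order.
#' @param root `"integrated"` or a numeric root state.
#' @return log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, tip_means, sigma2, rates = NULL, root = "integrated") {
  X <- prep_tip_means(tree, tip_means)
  p <- ncol(X)
  scalar <- p == 1L
  s2 <- if (length(sigma2) == 1L) as.numeric(sigma2) else check_psd(sigma2)
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    v <- tree$edge.length[1] * (rates %||% 1)
    if (identical(root, "integrated"))
      abort("a fixed root is required for a single tip", class = "segmorph_invalid_argument")
    if (scalar) return(stats::dnorm(X[1, 1], root, sqrt(v * s2), log = TRUE))
    return(as.numeric(ldmvnorm(X[1, ], root, v * s2)))
  }
  rates <- rates %||% rep(1, nrow(tree$edge))
  if (length(rates) != nrow(tree$edge))
    abort("`rates` must have one entry per edge", class = "segmorph_invalid_argument")
  if (any(rates <= 0)) abort("rates must be positive", class = "segmorph_invalid_argument")
  nn <- ntip + tree$Nnode
  v_child <- numeric(nn)           # branch variance multiplier above each node
  v_child[tree$edge[, 2]] <- tree$edge.length * rates
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  chS <- if (!scalar) chol(s2)
  val <- matrix(NA_real_, nn, p)
  val[1:ntip, ] <- X
  q <- numeric(nn)
  ll <- 0
  for (u in po_nodes) {
    ch <- kids[[as.character(u)]]
    x1 <- val[ch[1], ]; V1 <- v_child[ch[1]] + q[ch[1]]
    for (m in seq_along(ch)[-1]) {
      x2 <- val[ch[m], ]; V2 <- v_child[ch[m]] + q[ch[m]]
      d <- x1 - x2; Vc <- V1 + V2
      ll <- ll + if (scalar) {
        -0.5 * (log(2 * pi * Vc * s2) + d^2 / (Vc * s2))
      } else ld_contrast(d, Vc, chS)
      x1 <- (V2 * x1 + V1 * x2) / Vc
      V1 <- V1 * V2 / Vc
    }
    val[u, ] <- x1
    q[u] <- V1
  }
  if (!identical(root, "integrated")) {
    rt <- ntip + 1L
    d <- val[rt, ] - root
    ll <- ll + if (scalar) -0.5 * (log(2 * pi * q[rt] * s2) + d^2 / (q[rt] * s2))
               else ld_contrast(d, q[rt], chS)
  }
  ll
}

#' Priors and proposal settings for the trait-evolution MCMC
#'
#' Defaults: per-segment rate `sigma2 ~ lognormal(median 0.01, sd one
#' decade)`; relaxed-clock spread `s_r ~ Exponential(mean 0.587)`; ACLN
#' drift `nu ~ Exponential(mean 0.5)`; root state uniform on (0,1) per
#' segment; correlation matrix (multivariate mode) uniform over valid
#' correlation matrices.
#'
#' @param sigma2_meanlog,sigma2_sdlog lognormal prior on each per-segment rate.
#' @param s_r_mean mean of the exponential prior on the UCLN log-rate sd.
#' @param nu_mean mean of the exponential prior on the ACLN drift variance.
#' @param root_lower,root_upper uniform root-state prior bounds.
#' @param prop named list of random-walk proposal sds.
#' @export
mcmc_priors <- function(sigma2_meanlog = log(0.01), sigma2_sdlog = log(10),
                        s_r_mean = 0.587, nu_mean = 0.5,
                        root_lower = 0, root_upper = 1,
                        prop = list(sigma2 = 0.5, rate = 0.7, s_r = 0.5,
                                    nu = 0.5, corr = 0.15, node = 0.03)) {
  list(sigma2_meanlog = sigma2_meanlog, sigma2_sdlog = sigma2_sdlog,
       s_r_mean = s_r_mean, nu_mean = nu_mean,
       root_lower = root_lower, root_upper = root_upper, prop = prop)
}

# branch log-density of node states for one trait column set
branch_ll_all <- function(X, par, chi, v, s2vec, chR = NULL) {
  d <- X[chi, , drop = FALSE] - X[par, , drop = FALSE]
  if (is.null(chR)) {
    tot <- 0
    for (j in seq_along(s2vec))
      tot <- tot + sum(stats::dnorm(d[, j], 0, sqrt(v * s2vec[j]), log = TRUE))
    tot
  } else {
    sdv <- sqrt(s2vec)
    z <- backsolve(chR, t(d) / sdv, transpose = TRUE)
    p <- length(s2vec)
    sum(-0.5 * p * log(2 * pi) - sum(log(diag(chR))) - sum(log(sdv)) -
          0.5 * p * log(v) - 0.5 * colSums(z^2) / v)
  }
}

#' MCMC over Brownian rates, branch-rate multipliers and ancestral states
#'
#' Metropolis-within-Gibbs sampler for segment-position evolution on a fixed
#' ultrametric tree: random-walk scale moves on each per-segment rate
#' `sigma2_j` (and, in correlated mode, on the trait correlation matrix),
#' scale moves on each branch's rate multiplier under the chosen clock
#' model, and exact Gaussian Gibbs updates of every ancestral node state
#' (the root under its uniform prior). For relaxed clocks the rate scale is
#' confounded with `sigma2`; reported samples are identified by centring
#' the log branch rates to mean zero and absorbing the scale into `sigma2`.
#'
#' @param tree `phylo`, ultrametric (see [validate_phylogeny()]).
#' @param tip_means named vector, matrix or tibble of species trait means.
#' @param model a [branch_rate_model()].
#' @param priors a [mcmc_priors()] list.
#' @param n_iter iterations (>= 1).
#' @param thin keep every `thin`-th iteration.
#' @param burnin fraction of iterations discarded (default 0.1).
#' @param seed integer seed.
#' @param correlated estimate a between-segment correlation matrix
#'   (multivariate mode) instead of independent segments.
#' @param node_move `"gibbs"` (exact full conditionals) or `"metropolis"`
#'   (random-walk; retained as a cross-validation path for the Gibbs
#'   updates).
#' @param ess_warn warn when any reported parameter's effective sample size
#'   falls below this (default 200; 0 disables).
#' @return a `segmorph_phylo_posterior`: samples of `sigma2` (draws x
#'   traits), `rates` (draws x edges), `node_states` (draws x nodes x
#'   traits), `s_r`/`nu`, `loglik`, plus `ess` and the inputs.
#' @export
run_mcmc <- function(tree, tip_means, model = branch_rate_model("ucln"),
                     priors = mcmc_priors(), n_iter = 10000, thin = 10,
                     burnin = 0.1, seed = 1, correlated = FALSE,
                     node_move = c("gibbs", "metropolis"), ess_warn = 200) {
  node_move <- match.arg(node_move)
  validate_phylogeny(tree)
  if (n_iter < 1) abort("`n_iter` must be >= 1", class = "segmorph_invalid_argument")
  X0 <- prep_tip_means(tree, tip_means)
  p <- ncol(X0)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ne <- nrow(tree$edge)
  par <- tree$edge[, 1]; chi <- tree$edge[, 2]; tl <- tree$edge.length
  root <- ntip + 1L
  internal <- (ntip + 1L):nn
  # adjacency: for each node, (edge index, neighbour node) pairs
  adj <- vector("list", nn)
  for (e in seq_len(ne)) {
    adj[[par[e]]] <- rbind(adj[[par[e]]], c(e, chi[e]))
    adj[[chi[e]]] <- rbind(adj[[chi[e]]], c(e, par[e]))
  }
  pr <- priors; pp <- pr$prop
  withr::with_seed(seed, {
    X <- matrix(NA_real_, nn, p)
    X[1:ntip, ] <- X0
    # initialise internal states at the mean of the tips below each node
    desc <- function(u) if (u <= ntip) u else unlist(lapply(chi[par == u], desc))
    for (u in internal) X[u, ] <- colMeans(X0[desc(u), , drop = FALSE])
    ls2 <- rep(pr$sigma2_meanlog, p)
    l_edge <- rep(0, ne)       # UCLN log rates
    l_node <- rep(0, nn)       # ACLN node log rates
    s_r <- pr$s_r_mean; nu <- pr$nu_mean
    R <- diag(p); chR <- if (correlated && p > 1) chol(R) else NULL
    edge_rates <- function() switch(model$kind,
      strict = rep(1, ne),
      ucln = exp(l_edge),
      acln = exp((l_node[par] + l_node[chi]) / 2))
    rts <- edge_rates()
    v <- tl * rts
    s2 <- exp(ls2)
    bll <- branch_ll_all(X, par, chi, v, s2, chR)
    keep <- unique(pmin(n_iter, seq(thin, max(n_iter, thin), by = thin)))
    keep <- keep[keep >= max(1, ceiling(burnin * n_iter))]
    if (!length(keep)) keep <- n_iter
    nd <- length(keep)
    out_s2 <- matrix(NA_real_, nd, p)
    out_rates <- matrix(NA_real_, nd, ne)
    out_nodes <- array(NA_real_, c(nd, nn, p))
    out_sr <- numeric(nd); out_nu <- numeric(nd); out_ll <- numeric(nd)
    out_R <- if (correlated && p > 1) array(NA_real_, c(nd, p, p))
    ki <- 1L
    for (it in seq_len(n_iter)) {
      ## ancestral node states
      for (u in internal) {
        a <- adj[[u]]
        w <- 1 / v[a[, 1]]
        tau <- sum(w)
        mu <- colSums(X[a[, 2], , drop = FALSE] * w) / tau
        if (node_move == "gibbs") {
          if (is.null(chR)) {
            draw <- function() stats::rnorm(p, mu, sqrt(s2 / tau))
          } else {
            S <- diag(sqrt(s2)) %*% R %*% diag(sqrt(s2))
            draw <- function() mu + drop(rmvn(1, rep(0, p), S / tau))
          }
          if (u == root) {
            ok <- FALSE
            for (att in 1:100) {
              cand <- draw()
              if (all(cand > pr$root_lower & cand < pr$root_upper)) { ok <- TRUE; break }
            }
            if (ok) X[u, ] <- cand
          } else X[u, ] <- draw()
        } else {
          cand <- X[u, ] + stats::rnorm(p, 0, pp$node)
          if (u == root && any(cand <= pr$root_lower | cand >= pr$root_upper)) next
          # local Metropolis using the adjacent branch terms
          ll_old <- sum(vapply(seq_len(nrow(a)), function(i) {
            d <- X[u, ] - X[a[i, 2], ]
            sum(stats::dnorm(d, 0, sqrt(v[a[i, 1]] * s2), log = TRUE))
          }, numeric(1)))
          Xc <- X; Xc[u, ] <- cand
          ll_new <- sum(vapply(seq_len(nrow(a)), function(i) {
            d <- Xc[u, ] - Xc[a[i, 2], ]
            sum(stats::dnorm(d, 0, sqrt(v[a[i, 1]] * s2), log = TRUE))
          }, numeric(1)))
          if (log(stats::runif(1)) < ll_new - ll_old) X[u, ] <- cand
        }
      }
      bll <- branch_ll_all(X, par, chi, v, s2, chR)
      ## sigma2 scale moves (per trait)
      for (j in seq_len(p)) {
        cand <- ls2; cand[j] <- ls2[j] + stats::rnorm(1, 0, pp$sigma2)
        s2c <- exp(cand)
        bll_c <- branch_ll_all(X, par, chi, v, s2c, chR)
        lr <- bll_c - bll +
          stats::dnorm(cand[j], pr$sigma2_meanlog, pr$sigma2_sdlog, log = TRUE) -
          stats::dnorm(ls2[j], pr$sigma2_meanlog, pr$sigma2_sdlog, log = TRUE)
        if (log(stats::runif(1)) < lr) { ls2 <- cand; s2 <- s2c; bll <- bll_c }
      }
      ## correlation moves
      if (correlated && p > 1) {
        ij <- sample(p, 2)
        Rc <- R
        Rc[ij[1], ij[2]] <- Rc[ij[2], ij[1]] <-
          R[ij[1], ij[2]] + stats::rnorm(1, 0, pp$corr)
        if (abs(Rc[ij[1], ij[2]]) < 1) {
          ev <- min(eigen(Rc, symmetric = TRUE, only.values = TRUE)$values)
          if (ev > 1e-8) {
            chRc <- chol(Rc)
            bll_c <- branch_ll_all(X, par, chi, v, s2, chRc)
            if (log(stats::runif(1)) < bll_c - bll) { R <- Rc; chR <- chRc; bll <- bll_c }
          }
        }
      }
      ## branch-rate moves
      if (model$kind == "ucln") {
        for (e in seq_len(ne)) {
          cand <- l_edge[e] + stats::rnorm(1, 0, pp$rate)
          vc <- tl[e] * exp(cand)
          d <- X[chi[e], ] - X[par[e], ]
          ll_old <- if (is.null(chR)) sum(stats::dnorm(d, 0, sqrt(v[e] * s2), log = TRUE))
                    else ld_contrast(d, v[e], chol(diag(sqrt(s2)) %*% R %*% diag(sqrt(s2))))
          ll_new <- if (is.null(chR)) sum(stats::dnorm(d, 0, sqrt(vc * s2), log = TRUE))
                    else ld_contrast(d, vc, chol(diag(sqrt(s2)) %*% R %*% diag(sqrt(s2))))
          lr <- ll_new - ll_old +
            stats::dnorm(cand, 0, s_r, log = TRUE) - stats::dnorm(l_edge[e], 0, s_r, log = TRUE)
          if (log(stats::runif(1)) < lr) { l_edge[e] <- cand; v[e] <- vc }
        }
        ## s_r move
        cand <- s_r * exp(stats::rnorm(1, 0, pp$s_r))
        lr <- sum(stats::dnorm(l_edge, 0, cand, log = TRUE)) -
          sum(stats::dnorm(l_edge, 0, s_r, log = TRUE)) +
          stats::dexp(cand, 1 / pr$s_r_mean, log = TRUE) -
          stats::dexp(s_r, 1 / pr$s_r_mean, log = TRUE) + log(cand) - log(s_r)
        if (log(stats::runif(1)) < lr) s_r <- cand
        bll <- branch_ll_all(X, par, chi, v, s2, chR)
      } else if (model$kind == "acln") {
        for (u in seq_len(nn)[-root]) {
          cand_ln <- l_node
          cand_ln[u] <- l_node[u] + stats::rnorm(1, 0, pp$rate)
          a <- adj[[u]]
          es <- a[, 1]
          vc <- v
          vc[es] <- tl[es] * exp((cand_ln[par[es]] + cand_ln[chi[es]]) / 2)
          ll_old <- sum(vapply(es, function(e)
            sum(stats::dnorm(X[chi[e], ] - X[par[e], ], 0, sqrt(v[e] * s2), log = TRUE)),
            numeric(1)))
          ll_new <- sum(vapply(es, function(e)
            sum(stats::dnorm(X[chi[e], ] - X[par[e], ], 0, sqrt(vc[e] * s2), log = TRUE)),
            numeric(1)))
          pr_old <- sum(stats::dnorm(l_node[chi] - l_node[par], 0, sqrt(nu * tl), log = TRUE))
          pr_new <- sum(stats::dnorm(cand_ln[chi] - cand_ln[par], 0, sqrt(nu * tl), log = TRUE))
          if (log(stats::runif(1)) < ll_new - ll_old + pr_new - pr_old) {
            l_node <- cand_ln; v <- vc
          }
        }
        cand <- nu * exp(stats::rnorm(1, 0, pp$nu))
        lr <- sum(stats::dnorm(l_node[chi] - l_node[par], 0, sqrt(cand * tl), log = TRUE)) -
          sum(stats::dnorm(l_node[chi] - l_node[par], 0, sqrt(nu * tl), log = TRUE)) +
          stats::dexp(cand, 1 / pr$nu_mean, log = TRUE) -
          stats::dexp(nu, 1 / pr$nu_mean, log = TRUE) + log(cand) - log(nu)
        if (log(stats::runif(1)) < lr) nu <- cand
        bll <- branch_ll_all(X, par, chi, v, s2, chR)
      }
      ## record
      if (ki <= nd && it == keep[ki]) {
        rts <- edge_rates()
        g <- exp(mean(log(rts)))          # identifiability: centre log rates
        out_s2[ki, ] <- s2 * g
        out_rates[ki, ] <- rts / g
        out_nodes[ki, , ] <- X
        out_sr[ki] <- s_r; out_nu[ki] <- nu; out_ll[ki] <- bll
        if (!is.null(out_R)) out_R[ki, , ] <- R
        ki <- ki + 1L
      }
    }
    nd_used <- ki - 1L
    idx <- seq_len(nd_used)
    traits <- colnames(X0) %||% paste0("trait", seq_len(p))
    ess_tab <- tibble(
      parameter = c(paste0("sigma2_", traits), "loglik",
                    if (model$kind == "ucln") "s_r",
                    if (model$kind == "acln") "nu"),
      ess = c(apply(out_s2[idx, , drop = FALSE], 2, ess), ess(out_ll[idx]),
              if (model$kind == "ucln") ess(out_sr[idx]),
              if (model$kind == "acln") ess(out_nu[idx])))
    low <- ess_tab$ess < ess_warn
    if (ess_warn > 0 && any(low))
      warn(paste0("low effective sample size (< ", ess_warn, ") for: ",
                  paste(ess_tab$parameter[low], collapse = ", ")))
    structure(list(
      tree = tree, model = model, priors = priors, traits = traits,
      tip_means = X0, n_iter = n_iter, thin = thin, seed = seed,
      sigma2 = out_s2[idx, , drop = FALSE],
      rates = out_rates[idx, , drop = FALSE],
      node_states = out_nodes[idx, , , drop = FALSE],
      s_r = if (model$kind == "ucln") out_sr[idx],
      nu = if (model$kind == "acln") out_nu[idx],
      corr = if (!is.null(out_R)) out_R[idx, , , drop = FALSE],
      loglik = out_ll[idx], ess = ess_tab),
      class = "segmorph_phylo_posterior")
  })
}

#' Posterior summaries of ancestral node states
#'
#' @param posterior a `segmorph_phylo_posterior`.
#' @param conf credible level (default 0.95).
#' @return tibble `node, node_label, trait, mean, ci_low, ci_high, is_tip`.
#' @export
ancestral_states <- function(posterior, conf = 0.95) {
  stopifnot(inherits(posterior, "segmorph_phylo_posterior"))
  a <- (1 - conf) / 2
  tree <- posterior$tree
  ntip <- length(tree$tip.label)
  nn <- dim(posterior$node_states)[2]
  labs <- c(tree$tip.label, paste0("node", (ntip + 1):nn))
  purrr::map_dfr(seq_len(nn), function(u) {
    purrr::map_dfr(seq_along(posterior$traits), function(j) {
      s <- posterior$node_states[, u, j]
      tibble(node = u, node_label = labs[u], trait = posterior$traits[j],
             mean = mean(s),
             ci_low = unname(stats::quantile(s, a)),
             ci_high = unname(stats::quantile(s, 1 - a)),
             is_tip = u <= ntip)
    })
  })
}

#' Normalised per-branch change in segment position
#'
#' For each posterior sample, branch and trait, the absolute child-minus-
#' parent state difference divided by the branch length (change per unit
#' time); summarised per branch and pooled for the overall distribution.
#'
#' @param posterior a `segmorph_phylo_posterior`.
#' @param pool `"samples"` (pool every posterior sample; default) or
#'   `"means"` (pool per-branch posterior means).
#' @return a `segmorph_branch_changes`: list with `per_branch` tibble and
#'   `pooled` numeric vector.
#' @export
branch_changes <- function(posterior, pool = c("samples", "means")) {
  stopifnot(inherits(posterior, "segmorph_phylo_posterior"))
  pool <- match.arg(pool)
  tree <- posterior$tree
  par <- tree$edge[, 1]; chi <- tree$edge[, 2]; tl <- tree$edge.length
  nd <- dim(posterior$node_states)[1]
  per <- purrr::map_dfr(seq_len(nrow(tree$edge)), function(e) {
    purrr::map_dfr(seq_along(posterior$traits), function(j) {
      c_b <- abs(posterior$node_states[, chi[e], j] -
                   posterior$node_states[, par[e], j]) / tl[e]
      tibble(edge = e, parent = par[e], child = chi[e], length = tl[e],
             trait = posterior$traits[j],
             mean_c = mean(c_b), median_c = stats::median(c_b),
             q95 = unname(stats::quantile(c_b, 0.95)))
    })
  })
  pooled <- if (pool == "samples") {
    as.vector(abs(posterior$node_states[, chi, , drop = FALSE] -
                    posterior$node_states[, par, , drop = FALSE]) /
                rep(tl, each = nd))
  } else per$mean_c
  structure(list(per_branch = per, pooled = pooled, pool = pool),
            class = "segmorph_branch_changes")
}

#' Correlation of branch rates between segments vs anatomical distance
#'
#' Given one posterior per segment (fitted on the same tree), computes the
#' Pearson correlation, over branches, of posterior-mean log branch rates
#' for every segment pair, paired with the anatomical distance between the
#' segments' mean relative positions.
#'
#' @param posteriors named list of `segmorph_phylo_posterior` (one per
#'   segment, same tree).
#' @param mean_positions numeric vector of mean relative positions, one per
#'   posterior, same order.
#' @return a `segmorph_rate_correlations` tibble: `seg_a, seg_b, r,
#'   distance, separation`.
#' @export
segment_rate_correlations <- function(posteriors, mean_positions) {
  stopifnot(length(posteriors) == length(mean_positions))
  ne <- vapply(posteriors, function(x) ncol(x$rates), integer(1))
  if (length(unique(ne)) != 1)
    abort("posteriors are not on the same tree", class = "segmorph_invalid_argument")
  if (ne[1] < 3) abort("need >= 3 branches", class = "segmorph_invalid_argument")
  nm <- names(posteriors) %||% paste0("segment", seq_along(posteriors))
  lr <- vapply(posteriors, function(x) colMeans(log(x$rates)), numeric(ne[1]))
  pairs <- utils::combn(length(posteriors), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble(seg_a = nm[a], seg_b = nm[b],
           r = stats::cor(lr[, a], lr[, b]),
           distance = abs(mean_positions[a] - mean_positions[b]),
           separation = b - a)
  })
  structure(out, class = c("segmorph_rate_correlations", class(out)))
}

# one Metropolis sweep on the collapsed (states-integrated) posterior,
# targeting prior x likelihood^beta; returns updated state and loglik
power_sweep <- function(state, beta, tree, X, model, pr) {
  ll_fun <- function(st) {
    rates <- switch(model$kind,
      strict = NULL,
      ucln = exp(st$l),
      acln = exp((st$l[tree$edge[, 1]] + st$l[tree$edge[, 2]]) / 2))
    sum(vapply(seq_len(ncol(X)), function(j)
      bm_loglik(tree, X[, j, drop = FALSE], exp(st$ls2[j]), rates), numeric(1)))
  }
  pp <- pr$prop
  ## sigma2
  for (j in seq_along(state$ls2)) {
    cand <- state; cand$ls2[j] <- state$ls2[j] + stats::rnorm(1, 0, pp$sigma2)
    llc <- ll_fun(cand)
    lr <- beta * (llc - state$ll) +
      stats::dnorm(cand$ls2[j], pr$sigma2_meanlog, pr$sigma2_sdlog, log = TRUE) -
      stats::dnorm(state$ls2[j], pr$sigma2_meanlog, pr$sigma2_sdlog, log = TRUE)
    if (log(stats::runif(1)) < lr) { state <- cand; state$ll <- llc }
  }
  if (model$kind == "ucln") {
    for (e in seq_along(state$l)) {
      cand <- state; cand$l[e] <- state$l[e] + stats::rnorm(1, 0, pp$rate)
      llc <- ll_fun(cand)
      lr <- beta * (llc - state$ll) +
        stats::dnorm(cand$l[e], 0, state$s_r, log = TRUE) -
        stats::dnorm(state$l[e], 0, state$s_r, log = TRUE)
      if (log(stats::runif(1)) < lr) { state <- cand; state$ll <- llc }
    }
    cand_sr <- state$s_r * exp(stats::rnorm(1, 0, pp$s_r))
    lr <- sum(stats::dnorm(state$l, 0, cand_sr, log = TRUE)) -
      sum(stats::dnorm(state$l, 0, state$s_r, log = TRUE)) +
      stats::dexp(cand_sr, 1 / pr$s_r_mean, log = TRUE) -
      stats::dexp(state$s_r, 1 / pr$s_r_mean, log = TRUE) +
      log(cand_sr) - log(state$s_r)
    if (log(stats::runif(1)) < lr) state$s_r <- cand_sr
  } else if (model$kind == "acln") {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    par <- tree$edge[, 1]; chi <- tree$edge[, 2]; tl <- tree$edge.length
    for (u in seq_along(state$l)[-root]) {
      cand <- state; cand$l[u] <- state$l[u] + stats::rnorm(1, 0, pp$rate)
      llc <- ll_fun(cand)
      lr <- beta * (llc - state$ll) +
        sum(stats::dnorm(cand$l[chi] - cand$l[par], 0, sqrt(state$nu * tl), log = TRUE)) -
        sum(stats::dnorm(state$l[chi] - state$l[par], 0, sqrt(state$nu * tl), log = TRUE))
      if (log(stats::runif(1)) < lr) { state <- cand; state$ll <- llc }
    }
    cand_nu <- state$nu * exp(stats::rnorm(1, 0, pp$nu))
    lr <- sum(stats::dnorm(state$l[chi] - state$l[par], 0, sqrt(cand_nu * tl), log = TRUE)) -
      sum(stats::dnorm(state$l[chi] - state$l[par], 0, sqrt(state$nu * tl), log = TRUE)) +
      stats::dexp(cand_nu, 1 / pr$nu_mean, log = TRUE) -
      stats::dexp(state$nu, 1 / pr$nu_mean, log = TRUE) + log(cand_nu) - log(state$nu)
    if (log(stats::runif(1)) < lr) state$nu <- cand_nu
  }
  state
}

#' Stepping-stone marginal likelihood
#'
#' Estimates the log marginal likelihood of a clock model by stepping-stone
#' sampling over `n_stones` power posteriors with powers `(k/K)^(1/0.3)`
#' (Beta(0.3, 1) quantiles). The trait likelihood integrates ancestral
#' states analytically (pruning, flat-root REML treatment). With
#' `n_stones = 1` the estimator degenerates to the arithmetic prior-mean
#' estimator and is flagged unreliable.
#'
#' @inheritParams run_mcmc
#' @param n_stones number of stones K (power intervals).
#' @param n_iter_per_stone MCMC sweeps per stone (first stone doubles as
#'   warm-up after `burnin_per_stone` discarded sweeps).
#' @param burnin_per_stone sweeps discarded at the start of each stone.
#' @return a `segmorph_marginal_lik`: list with `log_ml`, `mc_error`,
#'   `per_stone` tibble, `reliable`, `model`.
#' @export
marginal_likelihood <- function(tree, tip_means, model = branch_rate_model("ucln"),
                                priors = mcmc_priors(), n_stones = 8,
                                n_iter_per_stone = 400, burnin_per_stone = 100,
                                seed = 1) {
  validate_phylogeny(tree)
  X <- prep_tip_means(tree, tip_means)
  K <- n_stones
  betas <- (seq(0, K) / K)^(1 / 0.3)
  withr::with_seed(seed, {
    nl <- switch(model$kind, strict = 0, ucln = nrow(tree$edge),
                 acln = length(tree$tip.label) + tree$Nnode)
    state <- list(ls2 = rep(priors$sigma2_meanlog, ncol(X)),
                  l = rep(0, nl), s_r = priors$s_r_mean, nu = priors$nu_mean)
    state$ll <- {
      rates <- switch(model$kind, strict = NULL, ucln = exp(state$l),
                      acln = exp((state$l[tree$edge[, 1]] + state$l[tree$edge[, 2]]) / 2))
      sum(vapply(seq_len(ncol(X)), function(j)
        bm_loglik(tree, X[, j, drop = FALSE], exp(state$ls2[j]), rates), numeric(1)))
    }
    per_stone <- vector("list", K)
    low_ess <- FALSE
    # run stones from the posterior end (beta = 1) down to the prior
    for (k in rev(seq_len(K))) {
      beta_k <- betas[k]           # sample at the lower power of the interval
      lls <- numeric(n_iter_per_stone)
      for (i in seq_len(n_iter_per_stone + burnin_per_stone)) {
        state <- power_sweep(state, beta_k, tree, X, model, priors)
        if (i > burnin_per_stone) lls[i - burnin_per_stone] <- state$ll
      }
      dbeta_k <- betas[k + 1] - betas[k]
      w <- dbeta_k * lls
      m <- max(w)
      log_rk <- m + log(mean(exp(w - m)))
      e_ll <- ess(lls)
      if (e_ll < 50) low_ess <- TRUE
      # delta-method MC error of log mean exp(w)
      vr <- stats::var(exp(w - m)) / max(1, e_ll)
      mc <- sqrt(vr) / mean(exp(w - m))
      per_stone[[k]] <- tibble(stone = k, beta = beta_k, delta_beta = dbeta_k,
                               log_ratio = log_rk, mc_error = mc, ess = e_ll)
    }
    per_stone <- dplyr::bind_rows(per_stone)
    reliable <- K > 1 && !low_ess
    if (!reliable)
      warn(if (K == 1) "single-stone estimate (prior arithmetic mean): unreliable"
           else "low per-stone ESS: marginal-likelihood estimate may be unreliable")
    structure(list(log_ml = sum(per_stone$log_ratio),
                   mc_error = sqrt(sum(per_stone$mc_error^2)),
                   per_stone = per_stone, reliable = reliable,
                   model = model, n_stones = K, seed = seed),
              class = "segmorph_marginal_lik")
  })
}
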