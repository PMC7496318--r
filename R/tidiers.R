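#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the ANOVA table
#' @param x a `segmorph_anova`.
#' @param ... ignored.
#' @export
tidy.segmorph_anova <- function(x, ...) x$table

#' @export
glance.segmorph_anova <- function(x, ...) {
  tab <- x$table
  ss <- tab$sumsq
  tibble(r_squared = sum(ss[tab$term != "Residuals"]) / sum(ss),
         df_residual = tab$df[tab$term == "Residuals"],
         degenerate = x$degenerate)
}

#' Tidy PCA loadings
#' @param x a `segmorph_pca`.
#' @param ... ignored.
#' @export
tidy.segmorph_pca <- function(x, ...) {
  rot <- x$pca$rotation
  tibble(segment = rep(rownames(rot), ncol(rot)),
         component = rep(colnames(rot), each = nrow(rot)),
         loading = as.vector(rot))
}

#' @export
glance.segmorph_pca <- function(x, ...) {
  tibble(pc1_variance = unname(x$variance_explained[1]),
         rank = x$rank, level = x$level,
         pc1_length_p = if (!is.null(x$cor_pc1_length)) x$cor_pc1_length$p_value
                        else NA_real_)
}

#' Tidy pairwise difference counts
#' @param x a `segmorph_pairdiff`.
#' @param ... ignored.
#' @export
tidy.segmorph_pairdiff <- function(x, ...) x$pair_counts

#' @export
glance.segmorph_pairdiff <- function(x, ...) {
  tibble(total = x$total, corrected_total = x$corrected_total,
         n_all_segments_pairs = x$n_all_segments_pairs,
         n_segments = x$n_segments, alpha = x$alpha, method = x$method)
}

#' Tidy species summary (per species and segment)
#' @param x a `segmorph_species_summary`.
#' @param ... ignored.
#' @export
tidy.segmorph_species_summary <- function(x, ...) x$by_segment

#' @export
glance.segmorph_species_summary <- function(x, ...) {
  tibble(n_species = nrow(x$by_species),
         max_total_deviation = max(x$by_species$total_deviation),
         most_deviant = x$by_species$species[which.max(x$by_species$total_deviation)])
}

#' Tidy within-species correlation profile
#' @param x a `segmorph_corprofile`.
#' @param ... ignored.
#' @export
tidy.segmorph_corprofile <- function(x, ...) x$summary

#' Tidy posterior parameter summaries
#' @param x a `segmorph_phylo_posterior`.
#' @param conf credible level.
#' @param ... ignored.
#' @export
tidy.segmorph_phylo_posterior <- function(x, conf = 0.95, ...) {
  a <- (1 - conf) / 2
  out <- purrr::map_dfr(seq_along(x$traits), function(j) {
    s <- x$sigma2[, j]
    tibble(parameter = paste0("sigma2_", x$traits[j]), mean = mean(s),
           ci_low = unname(stats::quantile(s, a)),
           ci_high = unname(stats::quantile(s, 1 - a)))
  })
  if (!is.null(x$s_r))
    out <- dplyr::bind_rows(out, tibble(parameter = "s_r", mean = mean(x$s_r),
                                        ci_low = unname(stats::quantile(x$s_r, a)),
                                        ci_high = unname(stats::quantile(x$s_r, 1 - a))))
  if (!is.null(x$nu))
    out <- dplyr::bind_rows(out, tibble(parameter = "nu", mean = mean(x$nu),
                                        ci_low = unname(stats::quantile(x$nu, a)),
                                        ci_high = unname(stats::quantile(x$nu, 1 - a))))
  out
}

#' @export
glance.segmorph_phylo_posterior <- function(x, ...) {
  tibble(model = x$model$kind, n_draws = nrow(x$sigma2),
         min_ess = min(x$ess$ess), mean_loglik = mean(x$loglik))
}

#' Tidy per-stone marginal-likelihood contributions
#' @param x a `segmorph_marginal_lik`.
#' @param ... ignored.
#' @export
tidy.segmorph_marginal_lik <- function(x, ...) x$per_stone

#' @export
glance.segmorph_marginal_lik <- function(x, ...) {
  tibble(model = x$model$kind, log_ml = x$log_ml, mc_error = x$mc_error,
         n_stones = x$n_stones, reliable = x$reliable)
}

#' Tidy per-branch normalised change summaries
#' @param x a `segmorph_branch_changes`.
#' @param ... ignored.
#' @export
tidy.segmorph_branch_changes <- function(x, ...) x$per_branch

#' @export
print.segmorph_phylo_posterior <- function(x, ...) {
  cat("<segmorph_phylo_posterior>", x$model$kind, "clock,",
      nrow(x$sigma2), "draws,", length(x$traits), "trait(s)\n")
  print(tidy(x))
  invisible(x)
}

#' @export
print.segmorph_pairdiff <- function(x, ...) {
  cat("<segmorph_pairdiff>", x$method, "alpha =", x$alpha, "\n",
      x$total, "significant (segment, pair) differences over",
      x$n_segments, "segments; corrected total", x$corrected_total, "\n")
  invisible(x)
}
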