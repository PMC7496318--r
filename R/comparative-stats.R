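#' Interaction ANOVA of relative segment position
#'
#' Fits `p ~ species + segment + species:segment` with fixed effects and
#' sequential (type-I) sums of squares, in that order.
#'
#' @param table relative-position tibble (`species, larva_id, segment, p`).
#' @return a `segmorph_anova`: list with `fit` (aov), `table` (tidy tibble),
#'   `degenerate` (TRUE when the residual variance is zero).
#' @export
fit_interaction_anova <- function(table) {
  cells <- table |> dplyr::count(.data$species, .data$segment)
  full <- tidyr::expand_grid(species = unique(table$species),
                             segment = unique(table$segment)) |>
    dplyr::left_join(cells, by = c("species", "segment"))
  if (any(is.na(full$n)))
    abort(paste0("empty species x segment cells: ",
                 paste(full$species[is.na(full$n)], full$segment[is.na(full$n)],
                       sep = ":", collapse = ", ")),
          class = "segmorph_invalid_argument")
  dat <- dplyr::mutate(table, species = factor(.data$species), segment = factor(.data$segment))
  fit <- stats::aov(p ~ species * segment, data = dat)
  sm <- summary(fit)[[1]]
  tab <- tibble(term = trimws(rownames(sm)), df = sm$Df, sumsq = sm$`Sum Sq`,
                meansq = sm$`Mean Sq`, statistic = sm$`F value`, p_value = sm$`Pr(>F)`)
  degen <- tab$meansq[tab$term == "Residuals"] < .Machine$double.eps * max(tab$meansq, 1)
  if (degen) warn("zero residual variance: F statistics are undefined")
  structure(list(fit = fit, table = tab, degenerate = degen), class = "segmorph_anova")
}

new_pairdiff <- function(per_segment, species, segments, alpha, method) {
  k <- length(species)
  pairs <- utils::combn(species, 2)
  pair_counts <- tibble(
    species_a = pairs[1, ], species_b = pairs[2, ],
    n_differing = vapply(seq_len(ncol(pairs)), function(i)
      sum(vapply(per_segment, function(m) m[pairs[1, i], pairs[2, i]], logical(1))),
      integer(1)))
  per_species <- tibble(
    species = species,
    n_involving = vapply(species, function(s)
      sum(pair_counts$n_differing[pair_counts$species_a == s | pair_counts$species_b == s]),
      integer(1)))
  per_segment_counts <- tibble(
    segment = segments,
    n_differing = unname(vapply(per_segment, function(m) sum(m[upper.tri(m)]), integer(1))))
  total <- sum(pair_counts$n_differing)
  structure(list(
    per_segment = per_segment, pair_counts = pair_counts,
    per_species = dplyr::arrange(per_species, dplyr::desc(.data$n_involving)),
    per_segment_counts = per_segment_counts,
    total = total, n_segments = length(segments),
    corrected_total = total / length(segments),
    n_all_segments_pairs = sum(pair_counts$n_differing == length(segments)),
    alpha = alpha, method = method), class = "segmorph_pairdiff")
}

drop_small_species <- function(table, min_n = 2) {
  counts <- table |> dplyr::distinct(.data$species, .data$larva_id) |> dplyr::count(.data$species)
  small <- counts$species[counts$n < min_n]
  if (length(small)) {
    warn(paste("excluding species with <", min_n, "larvae:", paste(small, collapse = ", ")))
    table <- dplyr::filter(table, !(.data$species %in% small))
  }
  table
}

#' Tukey HSD pairwise species comparisons per segment
#'
#' For each segment, a one-way layout of species is tested with the
#' studentized-range criterion: the pooled within-species mean square of
#' that segment's one-way fit gives the error variance, and unbalanced
#' species pairs use the Tukey-Kramer convention (the harmonic mean of the
#' two sample sizes in the standard error). Indicators of significance at
#' `alpha` are aggregated into a pairwise-difference matrix.
#'
#' @param table relative-position tibble.
#' @param alpha significance level (default 0.05).
#' @return a `segmorph_pairdiff` (see [count_and_correct()]).
#' @export
tukey_pairwise <- function(table, alpha = 0.05) {
  table <- drop_small_species(table)
  species <- sort(unique(table$species))
  segments <- intersect(SEGMENTS, unique(table$segment))
  k <- length(species)
  per_segment <- lapply(segments, function(sg) {
    d <- dplyr::filter(table, .data$segment == sg)
    st <- d |> dplyr::group_by(.data$species) |>
      dplyr::summarise(m = mean(.data$p), v = stats::var(.data$p), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::arrange(.data$species)
    df <- sum(st$n) - k
    mse <- sum((st$n - 1) * st$v) / df
    sig <- matrix(FALSE, k, k, dimnames = list(species, species))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / st$n[i] + 1 / st$n[j]))
      q <- abs(st$m[i] - st$m[j]) / se
      p <- stats::ptukey(q, k, df, lower.tail = FALSE)
      sig[i, j] <- sig[j, i] <- p < alpha
    }
    sig
  })
  names(per_segment) <- segments
  new_pairdiff(per_segment, species, segments, alpha, "tukey")
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' A two-sample t-test per segment and species pair; each p-value is
#' multiplied by the number of species pairs times the number of segments
#' (capped at 1) before comparison with `alpha`.
#'
#' @inheritParams tukey_pairwise
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return a `segmorph_pairdiff`.
#' @export
ttest_bonferroni <- function(table, alpha = 0.05, var_equal = FALSE) {
  table <- drop_small_species(table)
  species <- sort(unique(table$species))
  segments <- intersect(SEGMENTS, unique(table$segment))
  k <- length(species)
  m_corr <- choose(k, 2) * length(segments)
  per_segment <- lapply(segments, function(sg) {
    d <- dplyr::filter(table, .data$segment == sg)
    sig <- matrix(FALSE, k, k, dimnames = list(species, species))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      x <- d$p[d$species == species[i]]
      y <- d$p[d$species == species[j]]
      p <- stats::t.test(x, y, var.equal = var_equal)$p.value
      sig[i, j] <- sig[j, i] <- min(1, p * m_corr) < alpha
    }
    sig
  })
  names(per_segment) <- segments
  new_pairdiff(per_segment, species, segments, alpha, "ttest_bonferroni")
}

#' Totals, per-segment correction and rankings for a difference matrix
#'
#' The corrected total is the overall count of significant (segment, species
#' pair) differences divided by the number of segments, i.e. the average
#' number of differing species pairs per segment.
#'
#' @param matrix a `segmorph_pairdiff`.
#' @param n_segments divisor (defaults to the matrix's segment count).
#' @return list with `total`, `corrected_total`, `per_species` ranking,
#'   `per_segment_counts`, `pair_counts`, `n_all_segments_pairs`.
#' @export
count_and_correct <- function(matrix, n_segments = matrix$n_segments) {
  stopifnot(inherits(matrix, "segmorph_pairdiff"))
  if (n_segments == 0)
    abort("`n_segments` must be positive", class = "segmorph_invalid_argument")
  list(total = matrix$total,
       corrected_total = matrix$total / n_segments,
       per_species = matrix$per_species,
       per_segment_counts = matrix$per_segment_counts,
       pair_counts = matrix$pair_counts,
       n_all_segments_pairs = matrix$n_all_segments_pairs)
}

#' Within-species correlations between segment positions
#'
#' Pearson correlation, across individuals of one species, between the
#' relative positions of every unordered segment pair, together with the
#' pair's mean relative distance and whether A8 is involved; plus
#' across-species averages with t-based 95% confidence intervals, split by
#' A8 involvement.
#'
#' @param table relative-position tibble.
#' @return a `segmorph_corprofile`: list with `pairs` (per species) and
#'   `summary` (across species, per segment pair).
#' @export
within_species_correlations <- function(table) {
  counts <- table |> dplyr::distinct(.data$species, .data$larva_id) |> dplyr::count(.data$species)
  if (any(counts$n < 3))
    abort("every species needs >= 3 individuals", class = "segmorph_invalid_argument")
  segments <- intersect(SEGMENTS, unique(table$segment))
  pairs_idx <- utils::combn(segments, 2)
  res <- purrr::map_dfr(unique(table$species), function(sp) {
    wide <- table |> dplyr::filter(.data$species == sp) |>
      dplyr::select("larva_id", "segment", "p") |>
      tidyr::pivot_wider(names_from = "segment", values_from = "p")
    purrr::map_dfr(seq_len(ncol(pairs_idx)), function(i) {
      a <- pairs_idx[1, i]; b <- pairs_idx[2, i]
      x <- wide[[a]]; y <- wide[[b]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warn(sprintf("zero variance for %s or %s in %s: correlation undefined", a, b, sp))
        r <- NA_real_; pv <- NA_real_
      } else {
        ct <- stats::cor.test(x, y)
        r <- unname(ct$estimate); pv <- ct$p.value
      }
      tibble(species = sp, seg_a = a, seg_b = b, r = r, p_value = pv,
             distance = abs(mean(x) - mean(y)),
             separation = abs(seg_index(b) - seg_index(a)),
             involves_a8 = "A8" %in% c(a, b))
    })
  })
  summ <- res |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$seg_a, .data$seg_b, .data$separation, .data$involves_a8) |>
    dplyr::summarise(mean_r = mean(.data$r), sd_r = stats::sd(.data$r),
                     n_species = dplyr::n(), mean_distance = mean(.data$distance),
                     .groups = "drop") |>
    dplyr::mutate(
      ci_low = .data$mean_r - stats::qt(0.975, pmax(1, .data$n_species - 1)) *
        .data$sd_r / sqrt(.data$n_species),
      ci_high = .data$mean_r + stats::qt(0.975, pmax(1, .data$n_species - 1)) *
        .data$sd_r / sqrt(.data$n_species))
  structure(list(pairs = res, summary = summ), class = "segmorph_corprofile")
}

#' Body-length analyses
#'
#' Three checks of whether body length structures segment-position change:
#' a least-squares regression of the per-pair count of differing segments on
#' the pair's absolute mean-length difference (R-squared and slope p-value);
#' a Wilcoxon rank-sum test comparing mean body lengths of species grouped
#' by their majority shift direction; and, when a [pca_segments()] result
#' with a length test is supplied, the PC1-vs-length Pearson test.
#'
#' @param summary a `segmorph_species_summary` (with body lengths).
#' @param matrix a `segmorph_pairdiff`.
#' @param pca optional `segmorph_pca` computed with `body_length`.
#' @return list with `length_regression`, `direction_wilcoxon`,
#'   `pc1_length`.
#' @export
length_analyses <- function(summary, matrix, pca = NULL) {
  stopifnot(inherits(summary, "segmorph_species_summary"),
            inherits(matrix, "segmorph_pairdiff"))
  if (!"mean_length_um" %in% names(summary$by_species))
    abort("summary lacks body lengths", class = "segmorph_invalid_argument")
  sp <- summary$by_species
  if (nrow(sp) < 3) abort(">= 3 species required", class = "segmorph_invalid_argument")
  len <- stats::setNames(sp$mean_length_um, sp$species)
  pc <- matrix$pair_counts |>
    dplyr::mutate(abs_dlen = abs(len[.data$species_a] - len[.data$species_b]))
  if (stats::var(pc$n_differing) == 0) {
    warn("all pair counts equal: regression R-squared set to 0")
    reg <- list(r_squared = 0, slope = 0, p_value = NA_real_, n_pairs = nrow(pc))
  } else {
    fit <- stats::lm(n_differing ~ abs_dlen, data = pc)
    sm <- summary(fit)
    reg <- list(r_squared = sm$r.squared, slope = stats::coef(fit)[["abs_dlen"]],
                p_value = sm$coefficients["abs_dlen", "Pr(>|t|)"], n_pairs = nrow(pc))
  }
  grp <- dplyr::mutate(sp, direction = ifelse(.data$n_anterior >= .data$n_posterior,
                                              "anterior", "posterior"))
  wil <- if (length(unique(grp$direction)) == 2) {
    wt <- stats::wilcox.test(mean_length_um ~ direction, data = grp, exact = TRUE)
    list(statistic = unname(wt$statistic), p_value = wt$p.value)
  } else {
    warn("all species share one majority direction: Wilcoxon test undefined")
    list(statistic = NA_real_, p_value = NA_real_)
  }
  list(length_regression = reg, direction_wilcoxon = wil,
       pc1_length = if (!is.null(pca)) pca$cor_pc1_length)
}
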