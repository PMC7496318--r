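#' Relative segment positions
#'
#' Converts absolute belt-border distances into fractions of body length:
#' the relative position of a segment is the distance from the larva's
#' anterior tip to the segment's anterior border divided by total body
#' length.
#'
#' @param measurements tidy measurement tibble (`species`, `larva_id`,
#'   `segment`, `x_anterior_um`, `x_posterior_um`, `body_length_um`).
#' @return tibble `species, larva_id, segment, p`.
#' @export
relative_positions <- function(measurements) {
  assert_measurements(measurements)
  if (any(measurements$body_length_um <= 0))
    abort("body length must be positive", class = "segmorph_invalid_argument")
  measurements |>
    dplyr::transmute(.data$species, .data$larva_id, .data$segment,
                     p = .data$x_anterior_um / .data$body_length_um)
}

#' Recompute relative positions after removing a terminal region
#'
#' `end = "a8tail"` removes the region from A8's anterior border to the
#' posterior tip: the truncated body length is the distance to A8's anterior
#' border, and A1..A7 are rescaled to it. `end = "ht"` removes the head plus
#' thorax: the origin moves to A1's anterior border and A2..A8 are rescaled
#' to the remaining length.
#'
#' @param measurements tidy measurement tibble.
#' @param end `"a8tail"` or `"ht"`.
#' @return tibble `species, larva_id, segment, p` with 7 segments per larva.
#' @export
remove_end <- function(measurements, end = c("a8tail", "ht")) {
  end <- match.arg(end)
  assert_measurements(measurements)
  wide <- measurements |>
    dplyr::select("species", "larva_id", "segment", "x_anterior_um", "body_length_um") |>
    tidyr::pivot_wider(names_from = "segment", values_from = "x_anterior_um")
  if (!all(SEGMENTS %in% names(wide)))
    abort("all eight segments A1..A8 are required", class = "segmorph_invalid_argument")
  X <- as.matrix(wide[, SEGMENTS])
  if (end == "a8tail") {
    denom <- X[, 8]
    if (any(denom <= 0)) abort("degenerate denominator", class = "segmorph_invalid_argument")
    p <- X[, 1:7] / denom
    segs <- SEGMENTS[1:7]
  } else {
    denom <- wide$body_length_um - X[, 1]
    if (any(denom <= 0)) abort("degenerate denominator", class = "segmorph_invalid_argument")
    p <- (X[, 2:8] - X[, 1]) / denom
    segs <- SEGMENTS[2:8]
  }
  tibble(species = rep(wide$species, each = 7L),
         larva_id = rep(wide$larva_id, each = 7L),
         segment = rep(segs, nrow(wide)),
         p = as.vector(t(p)))
}

#' Per-species, per-segment summary with deviations from the grand mean
#'
#' Means and normal-theory (t-based) 95% confidence intervals per species and
#' segment, the deviation of each species' mean from the unweighted
#' across-species grand mean of that segment, its direction (anterior =
#' negative deviation, i.e. shifted toward the head) and magnitude, the
#' per-species total deviation, and per-species mean body length with CI
#' when the input carries `body_length_um`.
#'
#' @param table relative-position tibble (`species, larva_id, segment, p`),
#'   optionally with `body_length_um`.
#' @param conf confidence level (default 0.95).
#' @return a `segmorph_species_summary`: list with `by_segment`,
#'   `by_species`, `grand_mean`.
#' @export
species_summary <- function(table, conf = 0.95) {
  counts <- table |> dplyr::distinct(.data$species, .data$larva_id) |> dplyr::count(.data$species)
  small <- counts$species[counts$n < 2]
  if (length(small)) {
    warn(paste("excluding species with < 2 larvae:", paste(small, collapse = ", ")))
    table <- dplyr::filter(table, !(.data$species %in% small))
  }
  a <- 1 - conf
  seg <- table |>
    dplyr::group_by(.data$species, .data$segment) |>
    dplyr::summarise(mean_p = mean(.data$p), sd_p = stats::sd(.data$p),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(se = .data$sd_p / sqrt(.data$n),
                  ci95_low = .data$mean_p - stats::qt(1 - a / 2, .data$n - 1) * .data$se,
                  ci95_high = .data$mean_p + stats::qt(1 - a / 2, .data$n - 1) * .data$se)
  grand <- seg |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(grand_mean_p = mean(.data$mean_p), .groups = "drop")
  seg <- seg |>
    dplyr::left_join(grand, by = "segment") |>
    dplyr::mutate(deviation = .data$mean_p - .data$grand_mean_p,
                  direction = ifelse(.data$deviation < 0, "anterior", "posterior"),
                  magnitude = abs(.data$deviation))
  by_species <- seg |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(total_deviation = sum(.data$magnitude),
                     n_anterior = sum(.data$direction == "anterior"),
                     n_posterior = sum(.data$direction == "posterior"), .groups = "drop")
  if ("body_length_um" %in% names(table)) {
    len <- table |>
      dplyr::distinct(.data$species, .data$larva_id, .data$body_length_um) |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(mean_length_um = mean(.data$body_length_um),
                       sd_length = stats::sd(.data$body_length_um),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        length_ci_low = .data$mean_length_um -
          stats::qt(1 - a / 2, .data$n - 1) * .data$sd_length / sqrt(.data$n),
        length_ci_high = .data$mean_length_um +
          stats::qt(1 - a / 2, .data$n - 1) * .data$sd_length / sqrt(.data$n)) |>
      dplyr::select(-"n")
    by_species <- dplyr::left_join(by_species, len, by = "species")
  }
  structure(list(by_segment = seg, by_species = by_species, grand_mean = grand),
            class = "segmorph_species_summary")
}

#' Coefficient of variation of relative positions
#'
#' CV (sd/mean) of relative position per species and segment, plus the
#' across-species mean CV per segment.
#'
#' @param table relative-position tibble.
#' @return list with `by_species_segment` and `by_segment` tibbles.
#' @export
coefficient_of_variation <- function(table) {
  counts <- table |> dplyr::distinct(.data$species, .data$larva_id) |> dplyr::count(.data$species)
  if (any(counts$n < 2))
    abort("every species needs >= 2 larvae for a CV", class = "segmorph_invalid_argument")
  by_ss <- table |>
    dplyr::group_by(.data$species, .data$segment) |>
    dplyr::summarise(cv = stats::sd(.data$p) / mean(.data$p), .groups = "drop")
  by_seg <- by_ss |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(mean_cv = mean(.data$cv), .groups = "drop")
  list(by_species_segment = by_ss, by_segment = by_seg)
}

#' Posterior-border positions and belt widths
#'
#' Relative posterior-border position (`x_posterior / Y`) and relative belt
#' width (`(x_posterior - x_anterior) / Y`) per larva and segment.
#'
#' @param measurements tidy measurement tibble.
#' @return tibble `species, larva_id, segment, p_posterior, width`.
#' @export
belt_metrics <- function(measurements) {
  assert_measurements(measurements)
  if (any(measurements$body_length_um <= 0))
    abort("body length must be positive", class = "segmorph_invalid_argument")
  measurements |>
    dplyr::transmute(.data$species, .data$larva_id, .data$segment,
                     p_posterior = .data$x_posterior_um / .data$body_length_um,
                     width = (.data$x_posterior_um - .data$x_anterior_um) / .data$body_length_um)
}

#' PCA of relative segment positions
#'
#' Principal components of the individuals x segments matrix of mean-centred
#' relative positions (no variance scaling), with PC1's sign fixed so its
#' loading on the most posterior segment is positive. Optionally computed on
#' species means instead of individuals. Pearson tests of PC1 against each
#' segment's relative position, and against body length when lengths are
#' supplied, are included.
#'
#' @param table relative-position tibble.
#' @param level `"individual"` (default) or `"species"` (species means).
#' @param body_length optional tibble `species, larva_id, body_length_um`
#'   (or a measurement table) for the PC1-vs-length test.
#' @return a `segmorph_pca`: list with `pca` (prcomp), `scores`,
#'   `variance_explained`, `cor_pc1_segments`, `cor_pc1_length`, `rank`.
#' @export
pca_segments <- function(table, level = c("individual", "species"), body_length = NULL) {
  level <- match.arg(level)
  if (level == "species") {
    table <- table |>
      dplyr::group_by(.data$species, .data$segment) |>
      dplyr::summarise(p = mean(.data$p), .groups = "drop") |>
      dplyr::mutate(larva_id = .data$species)
  }
  wide <- table |>
    dplyr::select("species", "larva_id", "segment", "p") |>
    tidyr::pivot_wider(names_from = "segment", values_from = "p") |>
    dplyr::arrange(.data$species, .data$larva_id)
  segs <- intersect(SEGMENTS, names(wide))
  X <- as.matrix(wide[, segs])
  if (nrow(X) <= ncol(X))
    abort("need more rows than segments for a PCA", class = "segmorph_invalid_argument")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > fit$sdev[1] * 1e-10)
  # sign convention: PC1 loads positively on the most posterior segment
  if (fit$rotation[length(segs), 1] < 0) {
    fit$rotation[, 1] <- -fit$rotation[, 1]
    fit$x[, 1] <- -fit$x[, 1]
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  cor_seg <- purrr::map_dfr(segs, function(s) {
    ct <- stats::cor.test(fit$x[, 1], X[, s])
    tibble(segment = s, r = unname(ct$estimate), p_value = ct$p.value)
  })
  cor_len <- NULL
  if (!is.null(body_length)) {
    bl <- body_length |>
      dplyr::distinct(.data$species, .data$larva_id, .data$body_length_um)
    key <- dplyr::left_join(wide[, c("species", "larva_id")], bl,
                            by = c("species", "larva_id"))
    if (!any(is.na(key$body_length_um))) {
      ct <- stats::cor.test(fit$x[, 1], key$body_length_um)
      cor_len <- tibble(r = unname(ct$estimate), p_value = ct$p.value)
    }
  }
  structure(list(pca = fit, level = level,
                 scores = dplyr::bind_cols(wide[, c("species", "larva_id")],
                                           as_tibble(fit$x)),
                 variance_explained = stats::setNames(ve, colnames(fit$rotation)),
                 cor_pc1_segments = cor_seg, cor_pc1_length = cor_len, rank = rank),
            class = "segmorph_pca")
}
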