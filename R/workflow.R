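#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Any field can be
#' overridden; unspecified fields take the defaults below.
#'
#' @param stages character vector among `"simulate"`, `"measure"`,
#'   `"morpho"`, `"stats"`, `"phylo"`.
#' @param seed master seed; stage seeds are derived from it and recorded.
#' @param out_dir output directory (created if needed).
#' @param measurements path to a tidy measurement CSV (required for
#'   `morpho`/`stats` when `simulate` is not requested).
#' @param tree path to a Newick tree (required for `phylo` when `simulate`
#'   is not requested).
#' @param n_per_species cohort sizes for `simulate` (default: uniform in
#'   105..145 per species).
#' @param n_image_larvae larvae per species to route through the imaging
#'   stage (render + re-measure) when `measure` is requested.
#' @param method `"tukey"` or `"ttest"` for the pairwise comparisons.
#' @param alpha significance level.
#' @param remove_end `"none"`, `"a8tail"` or `"ht"` (applied in addition to
#'   the full-body analysis).
#' @param phylo_model,phylo_iter,phylo_thin rate model and chain settings
#'   for the per-segment phylogenetic runs.
#' @export
pipeline_config <- function(stages = c("simulate", "morpho", "stats", "phylo"),
                            seed = 1, out_dir = tempfile("segmorph_run_"),
                            measurements = NULL, tree = NULL,
                            n_per_species = NULL, n_image_larvae = 0,
                            method = c("tukey", "ttest"), alpha = 0.05,
                            remove_end = c("none", "a8tail", "ht"),
                            phylo_model = "ucln", phylo_iter = 20000,
                            phylo_thin = 20) {
  list(stages = stages, seed = seed, out_dir = out_dir,
       measurements = measurements, tree = tree,
       n_per_species = n_per_species, n_image_larvae = n_image_larvae,
       method = match.arg(method), alpha = alpha,
       remove_end = match.arg(remove_end),
       phylo_model = phylo_model, phylo_iter = phylo_iter,
       phylo_thin = phylo_thin)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in dependency order (simulate, measure,
#' morpho, stats, phylo), writes each stage's outputs under
#' `config$out_dir`, and returns (and writes) a JSON run report with
#' settings, seeds, input digests, collected warnings and headline numbers.
#'
#' @param config a [pipeline_config()] list or a YAML path.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  stages <- cfg$stages
  known <- c("simulate", "measure", "morpho", "stats", "phylo")
  if (length(setdiff(stages, known)))
    abort(paste("unknown stage:", paste(setdiff(stages, known), collapse = ", ")),
          class = "segmorph_config_error")
  needs_meas <- any(c("measure", "morpho", "stats") %in% stages)
  if (needs_meas && !("simulate" %in% stages) && is.null(cfg$measurements))
    abort("stages morpho/stats/measure need `measurements` or the simulate stage",
          class = "segmorph_config_error")
  if ("phylo" %in% stages && !("simulate" %in% stages) &&
      (is.null(cfg$tree) || (is.null(cfg$measurements) && !any(c("morpho") %in% stages))))
    abort("stage phylo needs `tree` (and measurements) or the simulate stage",
          class = "segmorph_config_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  report <- list(package = "segmorph",
                 version = as.character(utils::packageVersion("segmorph")),
                 seed = cfg$seed, config = cfg[setdiff(names(cfg), "stages")],
                 stages = list())
  digests <- list()
  out <- function(name) file.path(cfg$out_dir, name)
  measurements <- NULL; tree <- NULL

  if ("simulate" %in% stages) {
    study <- simulate_study(n_per_species = cfg$n_per_species, seed = cfg$seed)
    measurements <- study$measurements
    tree <- study$tree
    write_cohort_csv(measurements, out("measurements.csv"))
    ape::write.tree(tree, out("tree.nwk"))
    report$stages$simulate <- list(
      n_species = nrow(study$profiles),
      n_larvae = dplyr::n_distinct(measurements$larva_id),
      files = c("measurements.csv", "tree.nwk"))
    digests <- c(digests, as.list(tools::md5sum(c(out("measurements.csv"), out("tree.nwk")))))
  }
  if (!is.null(cfg$measurements)) {
    measurements <- read_measurements(cfg$measurements)
    digests[[cfg$measurements]] <- unname(tools::md5sum(cfg$measurements))
  }
  if (!is.null(cfg$tree)) {
    tree <- read_phylogeny(cfg$tree)
    digests[[cfg$tree]] <- unname(tools::md5sum(cfg$tree))
  }

  if ("measure" %in% stages && cfg$n_image_larvae > 0) {
    remeasured <- withCallingHandlers({
      ids <- measurements |> dplyr::distinct(.data$species, .data$larva_id) |>
        dplyr::group_by(.data$species) |>
        dplyr::slice_head(n = cfg$n_image_larvae) |> dplyr::ungroup()
      purrr::map_dfr(seq_len(nrow(ids)), function(i) {
        mi <- dplyr::filter(measurements, .data$larva_id == ids$larva_id[i])
        img <- render_larva_image(mi, rotation_deg = (cfg$seed + i * 37) %% 360,
                                  seed = cfg$seed + i)
        measure_image(img, species = ids$species[i], larva_id = ids$larva_id[i])
      })
    }, warning = note)
    write_cohort_csv(remeasured, out("measurements_imaged.csv"))
    # imaging validation subset: compare re-measured relative positions with
    # the direct measurements; downstream stages keep the full dataset
    joined <- dplyr::inner_join(
      dplyr::transmute(remeasured, .data$larva_id, .data$segment,
                       p_img = .data$x_anterior_um / .data$body_length_um),
      dplyr::transmute(measurements, .data$larva_id, .data$segment,
                       p_ref = .data$x_anterior_um / .data$body_length_um),
      by = c("larva_id", "segment"))
    report$stages$measure <- list(
      n_imaged = dplyr::n_distinct(remeasured$larva_id),
      max_abs_position_error = max(abs(joined$p_img - joined$p_ref)),
      files = "measurements_imaged.csv")
  }

  if ("morpho" %in% stages) {
    rp <- relative_positions(measurements) |>
      dplyr::left_join(dplyr::distinct(measurements, .data$larva_id, .data$body_length_um),
                       by = "larva_id")
    summ <- withCallingHandlers(species_summary(rp), warning = note)
    cv <- coefficient_of_variation(rp)
    pca <- pca_segments(rp, body_length = measurements)
    readr::write_csv(rp, out("relative_positions.csv"))
    readr::write_csv(summ$by_segment, out("species_summary.csv"))
    readr::write_csv(cv$by_species_segment, out("cv.csv"))
    report$stages$morpho <- list(
      mean_cv = mean(cv$by_segment$mean_cv),
      pc1_variance = unname(pca$variance_explained[1]),
      files = c("relative_positions.csv", "species_summary.csv", "cv.csv"))
    if (cfg$remove_end != "none") {
      rp_re <- remove_end(measurements, cfg$remove_end)
      readr::write_csv(rp_re, out(paste0("relative_positions_", cfg$remove_end, ".csv")))
    }
  }

  if ("stats" %in% stages) {
    rp <- relative_positions(measurements)
    pd <- withCallingHandlers(
      if (cfg$method == "tukey") tukey_pairwise(rp, cfg$alpha)
      else ttest_bonferroni(rp, cfg$alpha), warning = note)
    cc <- count_and_correct(pd)
    readr::write_csv(pd$pair_counts, out("pair_counts.csv"))
    for (sg in names(pd$per_segment))
      utils::write.table(pd$per_segment[[sg]], out(paste0("sig_", sg, ".tsv")),
                         sep = "\t", quote = FALSE)
    headline <- list(method = cfg$method, alpha = cfg$alpha,
                     total_differences = cc$total,
                     corrected_total = cc$corrected_total,
                     n_all_segments_pairs = cc$n_all_segments_pairs)
    if (cfg$remove_end != "none") {
      rp_re <- remove_end(measurements, cfg$remove_end)
      pd_re <- withCallingHandlers(
        if (cfg$method == "tukey") tukey_pairwise(rp_re, cfg$alpha)
        else ttest_bonferroni(rp_re, cfg$alpha), warning = note)
      headline$corrected_total_removed <- count_and_correct(pd_re)$corrected_total
    }
    report$stages$stats <- c(headline, list(files = "pair_counts.csv"))
  }

  if ("phylo" %in% stages) {
    rp <- relative_positions(measurements)
    tipm <- rp |>
      dplyr::group_by(.data$species, .data$segment) |>
      dplyr::summarise(p = mean(.data$p), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "segment", values_from = "p")
    segs <- intersect(SEGMENTS, names(tipm))
    posts <- withCallingHandlers(
      lapply(seq_along(segs), function(j) {
        tm <- stats::setNames(tipm[[segs[j]]], tipm$species)
        run_mcmc(tree, tm, branch_rate_model(cfg$phylo_model),
                 n_iter = cfg$phylo_iter, thin = cfg$phylo_thin,
                 seed = cfg$seed + 1000L + j, ess_warn = 200)
      }), warning = note)
    names(posts) <- segs
    anc <- purrr::map_dfr(segs, function(sg) {
      dplyr::mutate(ancestral_states(posts[[sg]]), segment = sg)
    })
    readr::write_csv(anc, out("ancestral_states.csv"))
    rate_summ <- purrr::map_dfr(segs, function(sg) {
      s2 <- posts[[sg]]$sigma2[, 1]
      tibble(segment = sg, mean_sigma2 = mean(s2),
             ci_low = unname(stats::quantile(s2, 0.025)),
             ci_high = unname(stats::quantile(s2, 0.975)))
    })
    readr::write_csv(rate_summ, out("segment_rates.csv"))
    bc <- branch_changes(posts[[1]])
    readr::write_csv(bc$per_branch, out("branch_changes_A1.csv"))
    meanp <- vapply(segs, function(sg) mean(tipm[[sg]]), numeric(1))
    rc <- segment_rate_correlations(posts, meanp)
    readr::write_csv(as_tibble(rc), out("rate_correlations.csv"))
    report$stages$phylo <- list(
      model = cfg$phylo_model, n_iter = cfg$phylo_iter,
      segment_rates = stats::setNames(rate_summ$mean_sigma2, rate_summ$segment),
      min_ess = min(vapply(posts, function(p) min(p$ess$ess), numeric(1))),
      files = c("ancestral_states.csv", "segment_rates.csv", "rate_correlations.csv"))
  }

  report$input_digests <- digests
  report$warnings <- warnings_log
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
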