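base_bounds <- c(0.30, 0.37, 0.45, 0.52, 0.60, 0.68, 0.76, 0.84)

test_that("interaction ANOVA reports sequential SS and flags degeneracy", {
  tab <- relative_positions(bind_rows(
    make_cohort(base_bounds, 1000, 20, "s1", jitter_sd = 0.02, seed = 1),
    make_cohort(base_bounds + 0.01, 1000, 20, "s2", jitter_sd = 0.02, seed = 2)))
  fit <- fit_interaction_anova(tab)
  expect_equal(fit$table$term, c("species", "segment", "species:segment", "Residuals"))
  expect_false(fit$degenerate)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$df_residual, fit$table$df[4])

  # zero-noise balanced toy: residual variance zero, flagged
  tab0 <- relative_positions(bind_rows(
    make_cohort(base_bounds, 1000, 3, "s1"), make_cohort(base_bounds, 1000, 3, "s2")))
  expect_warning(f0 <- fit_interaction_anova(tab0), "zero residual variance")
  expect_true(f0$degenerate)

  # empty cells are refused with a cell report
  gap <- tab[!(tab$species == "s1" & tab$segment == "A3"), ]
  expect_error(fit_interaction_anova(gap), class = "segmorph_invalid_argument")
})

test_that("ANOVA detects a uniform species shift", {
  hits <- vapply(1:20, function(r) {
    tab <- relative_positions(bind_rows(
      make_cohort(base_bounds, 1000, 100, "s1", jitter_sd = 0.04, seed = r),
      make_cohort(base_bounds + 0.05, 1000, 100, "s2", jitter_sd = 0.04,
                  seed = 1000 + r)))
    fit <- fit_interaction_anova(tab)
    fit$table$p_value[fit$table$term == "species"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 20 * 0.99 - 1e-9)
})

test_that("Tukey pairwise matrices behave on null and overwhelming effects", {
  same <- relative_positions(bind_rows(
    make_cohort(base_bounds, 1000, 30, "s1", jitter_sd = 0.02, seed = 3),
    make_cohort(base_bounds, 1000, 30, "s2", jitter_sd = 0.02, seed = 3),
    make_cohort(base_bounds, 1000, 30, "s3", jitter_sd = 0.02, seed = 3)))
  pd0 <- tukey_pairwise(same)
  expect_equal(pd0$total, 0)
  expect_equal(count_and_correct(pd0)$corrected_total, 0)

  # two groups separated by ten within-group sds
  jit <- 0.002
  apart <- relative_positions(bind_rows(
    make_cohort(base_bounds, 1000, 50, "lo", jitter_sd = jit, seed = 4),
    make_cohort(base_bounds + 10 * jit * mean(base_bounds), 1000, 50, "hi",
                jitter_sd = jit, seed = 5)))
  pd1 <- tukey_pairwise(apart)
  expect_equal(pd1$total, 8)
  pd1t <- ttest_bonferroni(apart)
  expect_equal(pd1t$total, 8)
})

test_that("Tukey indicators match a studentized-range oracle on small instances", {
  mismatches <- 0L
  for (case in 1:30) {
    tab <- withr::with_seed(case, {
      k <- 3
      bind_rows(lapply(1:k, function(g) {
        n <- sample(5:12, 1)
        mu <- 0.5 + stats::rnorm(1, 0, 0.02)
        tibble(species = paste0("g", g), larva_id = paste0("g", g, "_", 1:n),
               segment = "A1", p = stats::rnorm(n, mu, 0.03))
      }))
    })
    pd <- tukey_pairwise(tab)
    # oracle: critical value from the studentized-range quantile function
    st <- tab |> group_by(species) |>
      summarise(m = mean(p), v = var(p), n = n(), .groups = "drop")
    df <- sum(st$n) - 3
    mse <- sum((st$n - 1) * st$v) / df
    qcrit <- qtukey(0.95, 3, df)
    for (i in 1:2) for (j in (i + 1):3) {
      sig_oracle <- abs(st$m[i] - st$m[j]) >
        qcrit * sqrt(mse / 2 * (1 / st$n[i] + 1 / st$n[j]))
      sig_pkg <- pd$per_segment$A1[st$species[i], st$species[j]]
      if (sig_oracle != sig_pkg) mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("balanced Tukey indicators agree with stats::TukeyHSD", {
  tab <- withr::with_seed(9, bind_rows(lapply(1:4, function(g)
    tibble(species = paste0("g", g), larva_id = paste0("g", g, "_", 1:10),
           segment = "A1", p = stats::rnorm(10, 0.5 + g * 0.015, 0.02)))))
  pd <- tukey_pairwise(tab)
  fit <- stats::aov(p ~ species, data = tab)
  th <- stats::TukeyHSD(fit)$species
  for (rn in rownames(th)) {
    gs <- strsplit(rn, "-")[[1]]
    expect_equal(unname(pd$per_segment$A1[gs[1], gs[2]]),
                 unname(th[rn, "p adj"] < 0.05))
  }
})

test_that("Bonferroni correction uses pairs x segments and caps at one", {
  st <- full_study()
  rp <- relative_positions(st$measurements)
  one_pair <- rp |> filter(species %in% c("D.melanogaster", "D.simulans"))
  # manual Welch p for one segment, corrected by 66 * 8 = 528
  d <- one_pair |> filter(segment == "A5")
  p_raw <- t.test(p ~ species, data = d)$p.value
  pd <- ttest_bonferroni(rp)
  sig_manual <- min(1, p_raw * choose(12, 2) * 8) < 0.05
  expect_equal(unname(pd$per_segment$A5["D.melanogaster", "D.simulans"]), sig_manual)
})

test_that("difference-matrix identities hold on the full synthetic study", {
  st <- full_study()
  rp <- relative_positions(st$measurements)
  pd <- tukey_pairwise(rp)
  expect_equal(pd$total, sum(pd$pair_counts$n_differing))
  expect_equal(pd$total, sum(pd$per_segment_counts$n_differing))
  expect_equal(sum(pd$per_species$n_involving), 2 * pd$total)
  for (m in pd$per_segment) expect_true(isSymmetric(m))
  cc <- count_and_correct(pd)
  expect_equal(cc$corrected_total, pd$total / 8)
  expect_error(count_and_correct(pd, 0), class = "segmorph_invalid_argument")

  # removing A8 changes only A8-involving entries
  pd7 <- tukey_pairwise(filter(rp, segment != "A8"))
  for (sg in paste0("A", 1:7))
    expect_equal(pd7$per_segment[[sg]], pd$per_segment[[sg]])
  expect_equal(count_and_correct(pd7, 7)$corrected_total,
               (pd$total - pd$per_segment_counts$n_differing[8]) / 7)
})

test_that("Tukey and Bonferroni agree on clear and null effects", {
  st <- full_study()
  rp <- relative_positions(st$measurements)
  pd_t <- tukey_pairwise(rp)
  pd_b <- ttest_bonferroni(rp)
  agree <- mean(unlist(pd_t$per_segment) == unlist(pd_b$per_segment))
  expect_gte(agree, 0.90)
})

test_that("within-species correlations flag degenerate inputs", {
  # only whole-body length varies: all relative positions constant
  fixed <- bind_rows(lapply(1:5, function(i)
    make_larva(base_bounds, 900 + i * 50, "sp", paste0("l", i))))
  expect_warning(cp <- within_species_correlations(relative_positions(fixed)),
                 "zero variance")
  expect_true(all(is.na(cp$pairs$r)))

  # one shared additive axial shift: all correlations are exactly one
  shifted <- bind_rows(lapply(1:6, function(i) {
    m <- make_larva(base_bounds, 1000, "sp", paste0("l", i))
    m$x_anterior_um <- m$x_anterior_um + i
    m
  }))
  cp1 <- within_species_correlations(relative_positions(shifted))
  expect_equal(cp1$pairs$r, rep(1, 28), tolerance = 1e-10)
  expect_equal(sum(cp1$pairs$involves_a8), 7)

  expect_error(within_species_correlations(
    relative_positions(make_cohort(base_bounds, 1000, 2, "sp", 0.01))),
    class = "segmorph_invalid_argument")
})

test_that("correlation decay: adjacent pairs beat distant pairs", {
  m <- simulate_cohort(default_species_profiles()[2, ], 1500, seed = 31)
  cp <- within_species_correlations(relative_positions(m))
  r_adj <- mean(cp$pairs$r[cp$pairs$separation == 1])
  r_far <- mean(cp$pairs$r[cp$pairs$separation == 4])
  expect_gt(r_adj, r_far)
})

test_that("length analyses behave on constructed extremes", {
  # species designed so pair counts are an exact linear function of
  # |delta length|: lengths 1000/1100/1300 -> |dL| = 100, 300, 200 and
  # differing-segment sets of size 2, 6, 4
  lens <- c(a = 1000, b = 1100, c = 1300)
  shift <- rep(0, 8)
  shifts <- list(a = shift,
                 b = replace(shift, 1:2, 0.04),
                 c = replace(shift, 1:6, 0.04))
  coh <- bind_rows(lapply(names(lens), function(s)
    make_cohort(base_bounds + shifts[[s]], lens[s], 10, s, jitter_sd = 5e-4,
                seed = 200 + match(s, names(lens)))))
  rp <- relative_positions(coh) |>
    left_join(distinct(coh, larva_id, body_length_um), by = "larva_id")
  summ <- species_summary(rp)
  pd <- tukey_pairwise(rp)
  counts <- pd$pair_counts |> arrange(species_a, species_b)
  expect_equal(counts$n_differing, c(2L, 6L, 4L))
  la <- length_analyses(summ, pd)
  expect_gt(la$length_regression$r_squared, 0.999)
  # and it matches a direct least-squares fit on the same pairs
  lendiff <- abs(lens[pd$pair_counts$species_a] - lens[pd$pair_counts$species_b])
  oracle <- summary(lm(pd$pair_counts$n_differing ~ lendiff))$r.squared
  expect_equal(la$length_regression$r_squared, oracle, tolerance = 1e-10)

  # identical length distributions across direction groups: Wilcoxon p = 1
  lens2 <- c(a = 1000, b = 1300, c = 1100, d = 1200)
  shifts2 <- c(a = -0.03, b = -0.01, c = 0.01, d = 0.03)
  coh2 <- bind_rows(lapply(names(lens2), function(s)
    make_cohort(base_bounds + shifts2[s], lens2[s], 8, s, jitter_sd = 0.001,
                seed = match(s, names(lens2)))))
  rp2 <- relative_positions(coh2) |>
    left_join(distinct(coh2, larva_id, body_length_um), by = "larva_id")
  la2 <- length_analyses(species_summary(rp2), tukey_pairwise(rp2))
  expect_equal(la2$direction_wilcoxon$p_value, 1)
})
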