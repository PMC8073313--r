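test_that("all generators are deterministic given the seed", {
  expect_identical(
    gen_species_table("muscle", seed = 4),
    gen_species_table("muscle", seed = 4)
  )
  expect_identical(
    gen_cell_cohort(condition_presets("AA"), n_cells = 5, seed = 4),
    gen_cell_cohort(condition_presets("AA"), n_cells = 5, seed = 4)
  )
  expect_identical(
    gen_trajectory(n_lipids_per_leaflet = 4, n_frames = 2, seed = 4),
    gen_trajectory(n_lipids_per_leaflet = 4, n_frames = 2, seed = 4)
  )
  expect_identical(
    gen_pressure_series(5, n = 20, seed = 4),
    gen_pressure_series(5, n = 20, seed = 4)
  )
  expect_identical(
    gen_image_stack(3, seed = 4),
    gen_image_stack(3, seed = 4)
  )
  # jitter = 0: the table is the preset itself, independent of seed
  expect_equal(
    gen_species_table("NT", jitter = 0, seed = 1)$abundance_pct,
    gen_species_table("NT", jitter = 0, seed = 99)$abundance_pct
  )
})

test_that("species presets carry the expected unsaturation signatures", {
  nt <- gen_species_table("NT", seed = 8)
  expect_lt(db_index(nt)[["dbgt2"]], 5) # untreated myoblasts: nearly no PUFA

  dha <- gen_species_table("DHA", seed = 8)
  modal <- dha$species[which.max(dha$abundance_pct)]
  expect_equal(modal, "38:6") # DHA feeding makes PC 38:6 the modal species
  expect_gt(db_index(dha)[["dbgt2"]], db_index(dha)[["db0"]])

  muscle <- gen_species_table("muscle", seed = 8)
  expect_gt(db_index(muscle)[["dbgt2"]], 40) # muscle is PUFA-dominated
  expect_gt(dha_aa_ratio(muscle), 1) # and DHA- rather than AA-enriched
  expect_lt(dha_aa_ratio(gen_species_table("lung", seed = 8)), 1)

  expect_error(gen_species_table("spleen"), "unknown preset")
})

test_that("generated peak lists annotate back to the generating table", {
  g <- gen_species_table("AA", seed = 10, peaks = TRUE)
  tab <- annotate_peaks(g$peaks, paste("PC", g$table$species),
    tolerance_ppm = 5, sample_label = "AA"
  )
  merged <- merge(as.data.frame(g$table), as.data.frame(tab),
    by = "species", suffixes = c("_true", "_ann")
  )
  expect_equal(merged$abundance_pct_ann, merged$abundance_pct_true,
    tolerance = 1e-6
  )
})

test_that("frozen count-law calibrations satisfy their defining equations", {
  # independent closed-form checks of the packaged zero-inflated NB numbers:
  # each condition must reproduce its printed mean, its printed SD
  # (SEM * sqrt(n)) and its printed distribution feature
  cal <- lipomech:::.COUNT_CALIBRATION
  zinb_sd <- function(p) {
    m <- (1 - p$pi) * p$mu
    sqrt((1 - p$pi) * (p$mu + p$mu^2 / p$size + p$mu^2) - m^2)
  }

  nt <- cal$NT
  expect_equal((1 - nt$pi) * nt$mu, 3.8, tolerance = 1e-9)
  expect_equal(
    nt$pi + (1 - nt$pi) * dnbinom(0, size = nt$size, mu = nt$mu),
    0.34,
    tolerance = 1e-5
  )
  expect_equal(zinb_sd(nt), 0.3 * sqrt(152), tolerance = 1e-5)

  aa <- cal$AA
  expect_equal((1 - aa$pi) * aa$mu, 4.2, tolerance = 1e-9)
  expect_equal(
    (1 - aa$pi) * sum(dnbinom(1:5, size = aa$size, mu = aa$mu)),
    0.48,
    tolerance = 1e-5
  )
  expect_equal(zinb_sd(aa), 0.4 * sqrt(103), tolerance = 1e-5)

  dh <- cal$DHA
  expect_equal((1 - dh$pi) * dh$mu, 11.4, tolerance = 1e-9)
  expect_equal(
    (1 - dh$pi) * pnbinom(10, size = dh$size, mu = dh$mu, lower.tail = FALSE),
    0.50,
    tolerance = 1e-5
  )
  expect_equal(zinb_sd(dh), 0.7 * sqrt(148), tolerance = 1e-5)
})

test_that("cohort ground truth matches the drawn laws", {
  params <- condition_presets("DHA")
  co <- gen_cell_cohort(params, n_cells = 200, seed = 33)
  truth <- co$truth_cells
  # count mean within 3 sampling sigma of the calibrated mean
  sdc <- sd(truth$vld_count)
  expect_lt(abs(mean(truth$vld_count) - 11.4), 3 * sdc / sqrt(200))
  # one 515 trace per drawn VLD
  expect_equal(nrow(co$truth_rois), sum(truth$vld_count))
  expect_equal(
    nrow(unique(co$traces515[, c("cell_id", "roi_id")])),
    sum(truth$vld_count)
  )
  # breakage truth consistent
  expect_true(all(is.na(truth$t_breakage[!truth$broken])))
  expect_true(all(truth$t_breakage[truth$broken] > 0))
})

test_that("breakage_prob = 0 cohorts never cross the breakage threshold", {
  co <- gen_cell_cohort(condition_presets("NT_VLD"), n_cells = 30, seed = 13)
  res <- analyze_cohort(co)
  expect_false(any(res$cells$broken))
})

test_that("noise-free cohorts recover each drawn inflection within a sample", {
  # moderate spreads keep every drawn logistic well resolved at 5-s sampling
  params <- condition_params("tight",
    n_cells = 12, count_mean = 11.4, count_zero = 0.02,
    count_size = 4.721091, count_pi = 0.02, count_mu = 11.4 / 0.98,
    tvmax_mean = 301, tvmax_sd = 30, vmax_mean = 0.024, vmax_sd = 0.005,
    plateau_mean = 2, plateau_sd = 0.2,
    surface_increase_mean = 17, surface_increase_sd = 3,
    t_surface_max_mean = 137.7, t_surface_max_sd = 20,
    breakage_prob = 0, t_breakage_mean = 500, t_breakage_sd = 50
  )
  co <- gen_cell_cohort(params, n_cells = 12, seed = 17, noise_sd = 0)
  res <- analyze_cohort(co)
  m <- merge(res$kinetics, co$truth_rois, by = c("cell_id", "roi_id"))
  expect_true(all(m$event_detected))
  expect_lte(max(abs(m$tvmax.x - m$tvmax.y)), co$frame_interval + 1e-9)
  expect_equal(m$vmax.x, m$vmax.y, tolerance = 0.06)
  expect_equal(m$plateau.x, m$plateau.y, tolerance = 0.05)
})

test_that("inconsistent condition parameters are rejected", {
  expect_error(
    condition_params("bad",
      n_cells = 5, count_mean = -1, count_zero = 0.1,
      count_size = 1, count_pi = 0, count_mu = 1,
      tvmax_mean = 100, tvmax_sd = 10, vmax_mean = 0.01, vmax_sd = 0.001,
      surface_increase_mean = 10, surface_increase_sd = 1,
      t_surface_max_mean = 100, t_surface_max_sd = 10,
      breakage_prob = 0.1, t_breakage_mean = 100, t_breakage_sd = 10
    ),
    "non-positive"
  )
  expect_error(
    condition_params("bad",
      n_cells = 5, count_mean = 1, count_zero = 0.1,
      count_size = 1, count_pi = 0, count_mu = 1,
      tvmax_mean = 100, tvmax_sd = 10, vmax_mean = 0.01, vmax_sd = 0.001,
      surface_increase_mean = 10, surface_increase_sd = 1,
      t_surface_max_mean = 100, t_surface_max_sd = 10,
      breakage_prob = 1.7, t_breakage_mean = 100, t_breakage_sd = 10
    ),
    "breakage_prob"
  )
  expect_error(condition_presets("XX"), "unknown condition")
})

test_that("trajectory generator respects laws, leaflets and the box", {
  tr <- gen_trajectory(
    n_lipids_per_leaflet = 16,
    angle_law = list(type = "delta", value = 45),
    distance_law = list(type = "delta", value = 2),
    beads_per_chain = 4, n_frames = 2, seed = 19
  )
  expect_equal(length(tr$frames), 2)
  # mirrored truth: half at 45, half at 135
  expect_equal(mean(tr$truth$angle == 45), 0.5)
  expect_equal(mean(tr$truth$angle == 135), 0.5)
  # distances exact
  v <- lipomech:::chain_vectors(tr$frames, tr$topology)
  expect_equal(sqrt(rowSums(v^2)), rep(2, nrow(v)), tolerance = 1e-9)
  # bead bookkeeping
  expect_equal(nrow(tr$topology), 32 * 2 * 4)
  expect_false(anyDuplicated(tr$topology$bead_index) > 0)

  expect_error(
    gen_trajectory(
      n_lipids_per_leaflet = 2,
      distance_law = list(type = "delta", value = 8),
      box = c(30, 30, 10), seed = 1
    ),
    "half the box"
  )
})

test_that("pressure generator hits target tension in expectation", {
  exact <- gen_pressure_series(0, noise_sd = 0, n = 10, seed = 2)
  expect_equal(surface_tension(exact)$gamma, 0)
  exact7 <- gen_pressure_series(7, Lz = 12, noise_sd = 0, n = 10, seed = 2)
  expect_equal(surface_tension(exact7)$gamma, 7, tolerance = 1e-9)
})
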