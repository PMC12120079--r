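# Synthetic generators: fields, mixing experiments, screen plates.

test_that("empty and noiseless fields honour their exactness contracts", {
  blank <- make_field(field_spec(shape = c(64, 64), n_cells = 0, noise_sd = 0))
  expect_equal(n_labels(blank$cell_mask), 0)
  expect_equal(n_labels(blank$nuclei_mask), 0)
  expect_equal(nrow(blank$true_mean), 0)

  f <- make_field(field_spec(shape = c(300, 300), n_cells = 12,
                             diameter_px = 40, margin = 25, noise_sd = 0,
                             seed = 5))
  expect_equal(n_labels(f$cell_mask), 12)
  recs <- extract_cell_records(f$cell_mask, f$stack)
  truth <- f$true_mean[f$true_mean$channel == "mNG", ]
  expect_equal(recs$mean_mNG, truth$true_mean[match(recs$cell_id, truth$label)],
               tolerance = 1e-12)
})

test_that("fields are bit-identical for the same seed and differ across seeds", {
  spec <- field_spec(shape = c(128, 128), n_cells = 6, diameter_px = 30,
                     noise_sd = 2, seed = 9)
  f1 <- make_field(spec); f2 <- make_field(spec)
  expect_identical(f1$cell_mask, f2$cell_mask)
  expect_identical(f1$stack$channels, f2$stack$channels)
  expect_identical(f1$true_mean, f2$true_mean)
  f3 <- make_field(field_spec(shape = c(128, 128), n_cells = 6,
                              diameter_px = 30, noise_sd = 2, seed = 10))
  expect_false(identical(f1$cell_mask, f3$cell_mask))
})

test_that("nuclei are concentric, label-matched and cover ~ the set area fraction", {
  f <- make_field(field_spec(shape = c(400, 400), n_cells = 10,
                             diameter_px = 44, margin = 30,
                             nucleus_area_fraction = 0.85, noise_sd = 0,
                             seed = 3))
  expect_setequal(unique(f$nuclei_mask[f$nuclei_mask > 0]),
                  unique(f$cell_mask[f$cell_mask > 0]))
  # per label: nucleus strictly inside the cell
  for (lb in unique(f$cell_mask[f$cell_mask > 0])) {
    nuc <- which(f$nuclei_mask == lb)
    expect_true(all(f$cell_mask[nuc] == lb))
    frac <- length(nuc) / sum(f$cell_mask == lb)
    expect_gt(frac, 0.7); expect_lt(frac, 0.95)
  }
})

test_that("infeasible packings raise a placement error naming the density", {
  expect_error(make_field(field_spec(shape = c(40, 40), n_cells = 100,
                                     diameter_px = 20,
                                     min_center_distance = 15)),
               class = "microcyto_placement_error", regexp = "density")
})

test_that("doublet labels merge two ellipses with summed fluorescence", {
  f <- make_field(field_spec(shape = c(400, 400), n_cells = 10,
                             diameter_px = 36, margin = 30,
                             min_center_distance = 80,
                             doublet_fraction = 0.2, noise_sd = 0, seed = 7))
  expect_length(f$doublet_ids, 2)
  areas <- table(f$cell_mask[f$cell_mask > 0])
  singlet_mean <- mean(areas[!(names(areas) %in% f$doublet_ids)])
  for (id in f$doublet_ids)
    expect_gt(areas[[as.character(id)]], 1.2 * singlet_mean)
})

test_that("mixing experiment honours its truth-label contracts", {
  none <- make_mixing_experiment(mix_spec(n_cells = 2000, doublet_rate = 0,
                                          seed = 2))
  expect_false(any(none$records$heterotypic))
  expect_false(any(none$records$is_doublet))

  expect_error(mix_spec(mix_fraction = 1), class = "microcyto_value_error")
  expect_error(mix_spec(doublet_rate = 1), class = "microcyto_value_error")

  # heterotypic doublet fraction ~ r * 2p(1-p): the 0.90% / 1.80% arithmetic
  mx <- make_mixing_experiment(mix_spec(n_cells = 50000, mix_fraction = 0.5,
                                        doublet_rate = 0.018, seed = 6))
  frac_het <- mean(mx$records$heterotypic)
  p_expect <- 0.018 * 2 * 0.5 * 0.5       # = 0.009
  se <- sqrt(p_expect * (1 - p_expect) / 50000)
  expect_lt(abs(frac_het - p_expect), 3 * se)
})

test_that("gated mixing summary recovers the injected doublet rate", {
  spec <- mix_spec(n_cells = 50000, mix_fraction = 0.5, doublet_rate = 0.03,
                   control_n = 20000, seed = 11)
  mx <- make_mixing_experiment(spec)
  gates <- compute_gates(mx$controls, percentile = 99.9)
  s <- mixing_summary(mx$records, gates, spec$channels, spec$mix_fraction)
  se <- sqrt(0.03 * 0.97 / 50000)
  expect_lt(abs(s$doublet_rate - 0.03), 2 * 3 * se)  # x2: rate = 2 x frac_double
  expect_gte(s$doublet_rate, s$frac_double)
  # both single-positive fractions near 50%
  expect_lt(abs(s$frac_pos_a - 0.5), 0.02)
  expect_lt(abs(s$frac_pos_b - 0.5), 0.02)
})

test_that("screen plates honour truth surfaces and the 8 x 11 design", {
  zero <- make_screen_plate(plate_spec(pe_ng = c(5, 10), mlh1_ng = c(0, 4.5),
                                       efficiency = function(pe, m) 0 * pe,
                                       control_n = 300, seed = 4))
  expect_false(any(zero$records$true_positive))

  pl <- make_screen_plate(plate_spec(control_n = 400, seed = 13))
  expect_equal(nrow(pl$truth), 88)
  expect_setequal(unique(pl$records$condition),
                  c(pl$truth$condition, "no_plasmid"))
  gates <- suppressWarnings(compute_gates(
    pl$records[pl$records$condition == "no_plasmid", ], percentile = 99.9))
  s <- screen_summary(pl$records, "mNG", "no_plasmid", gates = gates,
                      condition_cols = c("PE_ng", "MLH1_ng"),
                      all_conditions = c(pl$truth$condition, "no_plasmid"))
  expect_equal(sum(!s$empty & s$condition != "no_plasmid") +
                 sum(s$empty), 88)

  # constant proliferation 1: control-relative counts near 1 (Poisson tolerance)
  flat <- make_screen_plate(plate_spec(pe_ng = c(5, 10), mlh1_ng = c(0, 1),
                                       proliferation = function(pe, m) 1 + 0 * pe,
                                       control_n = 2000, seed = 21))
  g2 <- compute_gates(flat$records[flat$records$condition == "no_plasmid", ],
                      percentile = 99.9)
  s2 <- screen_summary(flat$records, "mNG", "no_plasmid", gates = g2)
  expect_true(all(abs(s2$rel_proliferation - 1) < 4 * sqrt(2 / 2000)))
})

test_that("screen recovery: efficiencies within binomial error, argmax total matches truth", {
  pl <- make_screen_plate(plate_spec(control_n = 800, seed = 17))
  gates <- suppressWarnings(compute_gates(
    pl$records[pl$records$condition == "no_plasmid", ], percentile = 99.9))
  s <- screen_summary(pl$records, "mNG", "no_plasmid", gates = gates,
                      condition_cols = c("PE_ng", "MLH1_ng"))
  joined <- dplyr::inner_join(s, pl$truth,
                              by = c("condition", "PE_ng", "MLH1_ng"))
  se <- sqrt(joined$efficiency * (1 - joined$efficiency) / joined$n_cells)
  # allow the 0.1% gating false-positive floor on top of binomial error
  expect_true(all(abs(joined$frac_positive - joined$efficiency) <=
                    3 * se + 0.002 + 3 * sqrt(0.001 / joined$n_cells)))
  # the best-total condition matches the truth surface's expected optimum
  truth_opt <- joined$condition[which.max(joined$expected_n * joined$efficiency)]
  obs_opt <- joined$condition[which.max(joined$total_positive)]
  truth_tot <- joined$expected_n * joined$efficiency
  expect_gte(truth_tot[joined$condition == obs_opt] / max(truth_tot), 0.8)
  expect_true(truth_opt %in% joined$condition)
})
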