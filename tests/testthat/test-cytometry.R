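# Per-cell quantification, gating, SNR/CV, normalization, doublet rate,
# throughput and plate-screen summaries.

test_that("mean intensities are in-segment pixel sums over pixel counts", {
  mask <- matrix(0L, 10, 10)
  mask[1:10, 1:10] <- 0L
  mask[2:6, 2:6] <- 1L                       # 25 px
  ch <- matrix(5, 10, 10)
  stack <- channel_stack(list(mNG = ch))
  rec <- extract_cell_records(mask, stack, well = "A1", condition = "WT")
  expect_equal(rec$mean_mNG, 5.0)
  expect_equal(rec$area_px, 25L)

  # pixels valued {1,2,3,4} -> mean 2.5
  m2 <- matrix(0L, 2, 2); m2[] <- 1L
  s2 <- channel_stack(list(f = matrix(c(1, 2, 3, 4), 2, 2)))
  expect_equal(extract_cell_records(m2, s2)$mean_f, 2.5)

  expect_error(extract_cell_records(matrix(0L, 3, 3),
                                    channel_stack(list(a = matrix(1, 4, 4)))),
               class = "microcyto_value_error")
})

test_that("extraction is mask-additive: splitting a segment preserves the pixel sum", {
  set.seed(3)
  img <- matrix(runif(400, 0, 100), 20, 20)
  whole <- matrix(0L, 20, 20); whole[4:15, 4:15] <- 1L
  split <- whole; split[4:15, 10:15] <- 2L
  stack <- channel_stack(list(f = img))
  r_whole <- extract_cell_records(whole, stack)
  r_split <- extract_cell_records(split, stack)
  expect_equal(sum(r_split$mean_f * r_split$area_px),
               r_whole$mean_f * r_whole$area_px)
  expect_equal(sum(r_split$area_px), r_whole$area_px)
})

test_that("optional background subtraction removes the out-of-segment median", {
  mask <- matrix(0L, 8, 8); mask[3:5, 3:5] <- 1L
  img <- matrix(10, 8, 8); img[mask == 1L] <- 42
  stack <- channel_stack(list(f = img))
  expect_equal(extract_cell_records(mask, stack)$mean_f, 42)
  expect_equal(extract_cell_records(mask, stack, background_subtract = TRUE)$mean_f,
               32)
})

test_that("percentile gates use linear interpolation between order statistics", {
  controls <- tibble::tibble(mean_mNG = as.numeric(0:999))
  g <- compute_gates(controls, percentile = 50)
  expect_equal(g$threshold, 499.5)                    # analytic median of 0..999
  expect_equal(glance(g)$control_n, 1000)

  const <- tibble::tibble(mean_mNG = rep(7, 1000))
  for (p in c(1, 50, 99.9))
    expect_equal(compute_gates(const, percentile = p)$threshold, 7)

  set.seed(8)
  big <- tibble::tibble(mean_mNG = rnorm(10000))
  g999 <- compute_gates(big, percentile = 99.9)
  expect_gt(g999$threshold, 2.9)                       # normal 99.9% quantile ~ 3.09
  expect_lt(g999$threshold, 3.3)

  expect_error(compute_gates(controls[0, ]), class = "microcyto_value_error")
  expect_warning(compute_gates(tibble::tibble(mean_mNG = rnorm(100))),
                 regexp = "poorly resolved")
})

test_that("gating is strictly greater-than: ties are negative", {
  controls <- tibble::tibble(mean_mNG = rep(10, 2000))
  g <- compute_gates(controls)
  recs <- tibble::tibble(cell_id = 1:3, mean_mNG = c(10, 10 + 1e-9, 9))
  gated <- apply_gates(recs, g)
  expect_identical(gated$positive_mNG, c(FALSE, TRUE, FALSE))
  expect_error(apply_gates(tibble::tibble(mean_mApple = 1), g),
               class = "microcyto_key_error")
})

test_that("gating at percentile q flags about (100 - q)% of held-out controls", {
  set.seed(12)
  train <- tibble::tibble(mean_mNG = rlnorm(20000, 2, 0.8))
  holdout <- tibble::tibble(mean_mNG = rlnorm(20000, 2, 0.8))
  for (q in c(99, 99.9)) {
    g <- compute_gates(train, percentile = q)
    fpr <- mean(apply_gates(holdout, g)$positive_mNG)
    p <- (100 - q) / 100
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(fpr - p), 4 * se)
  }
})

test_that("snr and cv match their analytic worked examples", {
  s <- signal_stats(c(10, 10, 10), c(-1, 1))
  expect_equal(s$snr, 10 / sqrt(2))

  s2 <- signal_stats(c(8, 12), c(-1, 1))
  expect_equal(s2$cv, sqrt(8) / 10)
  expect_equal(tidy(s2)$cv, s2$cv)

  expect_error(signal_stats(c(1, 2), c(5, 5)), class = "microcyto_undefined_error")
  expect_error(signal_stats(c(0, 2), c(0, 2)), class = "microcyto_undefined_error")
  expect_error(signal_stats(1, c(1, 2)), class = "microcyto_value_error")
})

test_that("snr and cv recover closed forms on large normal samples", {
  set.seed(44)
  n <- 1e4; mu_p <- 50; s_p <- 8; s_n <- 2
  pos <- rnorm(n, mu_p, s_p); neg <- rnorm(n, 0, s_n)
  st <- signal_stats(pos, neg)
  # 3 SEs via delta-method-free simulation bounds: SE(mean)/sd terms dominate
  expect_lt(abs(st$snr - mu_p / s_n), 3 * (mu_p / s_n) * sqrt(2 / n))
  expect_lt(abs(st$cv - s_p / mu_p), 3 * (s_p / mu_p) * sqrt(2 / n))
})

test_that("normalization maps group means onto the references exactly", {
  v <- c(0, 0, 1, 1)
  pos <- c(FALSE, FALSE, TRUE, TRUE)
  out <- normalize_to_reference(v, pos, c(0, 100))
  expect_equal(attr(out, "a"), 100); expect_equal(attr(out, "b"), 0)
  expect_equal(as.numeric(out), c(0, 0, 100, 100))

  # identity when already on the reference scale
  out2 <- normalize_to_reference(v, pos, c(0, 1))
  expect_equal(attr(out2, "a"), 1); expect_equal(attr(out2, "b"), 0)

  set.seed(9)
  v3 <- c(rnorm(500, 3, 1), rnorm(300, 40, 6))
  pos3 <- rep(c(FALSE, TRUE), c(500, 300))
  out3 <- normalize_to_reference(v3, pos3, c(10, 1000))
  expect_equal(mean(out3[!pos3]), 10, tolerance = 1e-9)
  expect_equal(mean(out3[pos3]), 1000, tolerance = 1e-9)

  expect_error(normalize_to_reference(c(1, 1), c(FALSE, TRUE), c(5, 5)),
               class = "microcyto_degenerate_error")
})

test_that("snr and cv are invariant under the normalization's affine map", {
  set.seed(10)
  neg <- rnorm(2000, 5, 2); pos <- rnorm(2000, 80, 10)
  st0 <- signal_stats(pos, neg)
  v <- c(neg, pos); grp <- rep(c(FALSE, TRUE), each = 2000)
  out <- normalize_to_reference(v, grp, c(100, 5000))
  st1 <- signal_stats(out[grp], out[!grp])
  expect_equal(st1$snr, st0$snr, tolerance = 1e-12)
  expect_equal(st1$cv, st0$cv, tolerance = 1e-12)
})

test_that("doublet rate doubles the double-positive fraction for a 50/50 mix", {
  expect_equal(doublet_rate(0.0090, 0.5), 0.018)
  expect_equal(doublet_rate(0, 0.3), 0)
  # linear in frac_double; minimized at p = 0.5 for fixed frac_double
  expect_equal(doublet_rate(0.02, 0.5), 2 * doublet_rate(0.01, 0.5))
  rates <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8),
                  function(p) doublet_rate(0.01, p), double(1))
  expect_equal(which.min(rates), 3L)
  expect_error(doublet_rate(0.1, 0), class = "microcyto_value_error")
  expect_error(doublet_rate(0.1, 1), class = "microcyto_value_error")
  expect_error(doublet_rate(0.6, 0.5), class = "microcyto_value_error")
})

test_that("throughput: fields per well to match a flow-equivalent cell count", {
  expect_identical(fields_per_well(3300, 50000), 16L)
  expect_identical(fields_per_well(1000, 1000), 1L)
  expect_error(fields_per_well(0, 100), class = "microcyto_value_error")
})

test_that("screen summary computes efficiency, survival and totals per condition", {
  recs <- tibble::tibble(
    cell_id = 1:600,
    condition = rep(c("edited", "no_plasmid"), c(200, 400)),
    positive_mNG = c(rep(c(TRUE, FALSE), c(50, 150)), rep(FALSE, 400)))
  s <- screen_summary(recs, "mNG", "no_plasmid")
  ed <- s[s$condition == "edited", ]
  expect_equal(ed$frac_positive, 0.25)
  expect_equal(ed$rel_proliferation, 0.5)
  expect_equal(ed$total_positive, 50L)
  expect_equal(s$rel_proliferation[s$condition == "no_plasmid"], 1.0)
  expect_equal(sum(s$n_cells), nrow(recs))     # counts partition the records

  # zero-cell conditions are emitted flagged
  s2 <- screen_summary(recs, "mNG", "no_plasmid",
                       all_conditions = c("edited", "no_plasmid", "ghost"))
  g <- s2[s2$condition == "ghost", ]
  expect_true(g$empty); expect_equal(g$n_cells, 0L); expect_true(is.na(g$frac_positive))

  expect_error(screen_summary(recs, "mNG", "missing_ctrl"),
               class = "microcyto_value_error")
  expect_error(screen_summary(dplyr::select(recs, -"positive_mNG"), "mNG",
                              "no_plasmid"),
               class = "microcyto_key_error")
})
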