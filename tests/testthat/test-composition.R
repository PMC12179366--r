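test_that("rule-based segmentation reproduces the generator labels on clean data", {
  ph <- small_thigh(seed = 7, n_slices = 2L, b0_range_hz = c(-40, 40))
  p <- thigh_protocol()
  sep <- separate_stack(acquire(ph, p, noise_spec(0)))
  pdff <- compute_pdff(sep, yields = readout_yield_factors(p))
  labels <- segment_rule_based(pdff, sep$water$unprep, sep$fat$unprep)
  expect_gte(mean(labels == ph$labels), 0.99)
})

test_that("an all-water image produces no fat labels", {
  tb <- make_tube_phantom(c(0, 0), grid = c(48, 48), radius_vox = 8)
  p <- thigh_protocol()
  sep <- separate_stack(acquire(tb, p, noise_spec(0)))
  pdff <- compute_pdff(sep, yields = readout_yield_factors(p))
  labels <- segment_rule_based(pdff, sep$water$unprep, sep$fat$unprep)
  lc <- label_codes()
  expect_false(any(labels %in% lc[c("subcutaneous_fat", "intermuscular_fat")]))
})

test_that("the 50% PDFF threshold is strict", {
  # a 9x9 foreground with one interior candidate voxel
  pdff <- array(10, c(9, 9, 1))
  w <- array(1, c(9, 9, 1)); f <- array(0.1, c(9, 9, 1))
  pdff[5, 5, 1] <- 49.9
  lab1 <- segment_rule_based(pdff, w, f, floor = 0.5)
  expect_equal(lab1[5, 5, 1], unname(label_codes()[["muscle"]]))
  pdff[5, 5, 1] <- 50
  lab2 <- segment_rule_based(pdff, w, f, floor = 0.5)
  expect_equal(lab2[5, 5, 1], unname(label_codes()[["intermuscular_fat"]]))
})

test_that("empty foreground is a degenerate input", {
  z <- array(0, c(8, 8, 1))
  expect_error(segment_rule_based(z, z, z, floor = 1), "degenerate")
})

test_that("composition metrics follow their defining formulas on uniform maps", {
  lc <- label_codes()
  labels <- array(lc[["muscle"]], c(10, 10, 1))
  pdff <- array(2.3, c(10, 10, 1))
  p <- thigh_protocol(); p$n_slices <- 1L
  maps <- list(pdff = pdff, voxel_mm = c(2, 2, 3.5))
  rep_ <- compute_composition(maps, labels, p)
  expect_equal(rep_$mff_intra_pct, 2.3)
  expect_equal(rep_$mfv_inter_ml, 0)
  expect_equal(rep_$mfv_total_ml, rep_$mfv_intra_ml)
  expect_equal(rep_$muscle_pct, 100)
  expect_equal(rep_$muscle_ml, 100 * 2 * 2 * 3.5 / 1000)
  expect_equal(rep_$mfv_intra_ml, rep_$muscle_ml * 0.023)
  expect_error(compute_composition(maps, labels * 0L, p), "degenerate")
})

test_that("slab correction scales volumes by 59.5/17.5 for the five-slice protocol", {
  lc <- label_codes()
  labels <- array(lc[["muscle"]], c(6, 6, 5))
  pdff <- array(5, c(6, 6, 5))
  maps <- list(pdff = pdff, voxel_mm = c(2, 2, 3.5))
  p_gap <- thigh_protocol()                       # 10.5 mm gaps
  p_contig <- thigh_protocol(); p_contig$slice_gap <- 0
  r_gap <- compute_composition(maps, labels, p_gap)
  r_contig <- compute_composition(maps, labels, p_contig)
  expect_equal(r_gap$muscle_ml / r_contig$muscle_ml, 59.5 / 17.5)
  expect_equal(r_gap$mfv_intra_ml / r_contig$mfv_intra_ml, 59.5 / 17.5)
  # fractions are volume ratios: unchanged by the slab factor
  expect_equal(r_gap$mff_intra_pct, r_contig$mff_intra_pct)
})

test_that("fat volume additivity and thigh-area conservation hold end-to-end", {
  ph <- small_thigh(seed = 3, n_slices = 1L)
  p <- match_slices(thigh_protocol(), ph)
  sep <- separate_stack(acquire(ph, p, noise_spec(0)))
  pdff <- compute_pdff(sep, yields = readout_yield_factors(p))
  labels <- segment_rule_based(pdff, sep$water$unprep, sep$fat$unprep)
  rep_ <- compute_composition(list(pdff = pdff, voxel_mm = ph$voxel_mm),
                              labels, p)
  expect_equal(rep_$mfv_total_ml, rep_$mfv_intra_ml + rep_$mfv_inter_ml)
  # label fractions of the thigh cross-section sum to one
  lc <- label_codes()
  thigh <- labels != lc[["background"]]
  fracs <- vapply(lc[-1L], function(code) sum(labels == code) / sum(thigh),
                  numeric(1))
  expect_equal(sum(fracs), 1)
})

test_that("composition metrics are invariant to global intensity scaling", {
  ph <- small_thigh(seed = 5, n_slices = 1L)
  p <- match_slices(thigh_protocol(), ph)
  stack <- acquire(ph, p, noise_spec(0.002, seed = 1))
  stack2 <- stack
  stack2$data <- stack2$data * 5.3
  reports <- lapply(list(stack, stack2), function(s) {
    sep <- separate_stack(s)
    pdff <- compute_pdff(sep, yields = readout_yield_factors(p))
    labels <- segment_rule_based(pdff, sep$water$unprep, sep$fat$unprep)
    compute_composition(list(pdff = pdff, voxel_mm = ph$voxel_mm), labels, p)
  })
  expect_equal(unclass(reports[[1L]]), unclass(reports[[2L]]),
               tolerance = 1e-9)
})

test_that("conventional-CSE T1 correction restores spin-density fat fractions", {
  p <- protocol_preset("cse_conventional")
  a <- p$flip_center * pi / 180
  yield <- function(t1) {
    e1 <- exp(-p$tr / t1)
    sin(a) * (1 - e1) / (1 - cos(a) * e1)
  }
  # fat yields more steady-state signal than muscle water at 20deg/20ms
  expect_gt(yield(370) / yield(1400), 1)
  # simulate the T1-weighted acquisition of a 10% fat voxel and reconstruct
  te <- build_echo_schedule(p)$unique_te
  truth_ff <- 0.10
  s <- forward_voxel_signal(0.90 * yield(1400), truth_ff * yield(370),
                            b0_hz = 10, r2star = 40, te)
  out <- separate_voxel(s, te, b0_grid = seq(-300, 300, 2))
  pdff_raw <- 100 * Mod(out$best$F) / (Mod(out$best$F) + Mod(out$best$W))
  expect_gt(pdff_raw, 100 * truth_ff)           # uncorrected overestimates
  corr <- t1_correct_cse(out$best$F, out$best$W, p)
  pdff_corr <- 100 * Mod(corr$f) / (Mod(corr$f) + Mod(corr$w))
  expect_equal(pdff_corr, 100 * truth_ff, tolerance = 0.2 / (100 * truth_ff))
  # equal T1s: correction is a common factor, PDFF exactly unchanged
  eq <- t1_correct_cse(out$best$F, out$best$W, p, t1_fat = 800,
                       t1_water = 800)
  expect_equal(100 * Mod(eq$f) / (Mod(eq$f) + Mod(eq$w)), pdff_raw,
               tolerance = 1e-12)
  # TR much longer than both T1s: factors approach one
  p_long <- p; p_long$tr <- 1e7
  id <- t1_correct_cse(1 + 0i, 1 + 0i, p_long)
  expect_equal(unname(id$yield), rep(sin(a), 2L), tolerance = 1e-6)
  expect_error(t1_correct_cse(1, 1, p, t1_fat = -5), "non-physical")
})

test_that("the full pipeline recovers phantom ground truth at SNR 50", {
  ph <- make_thigh_phantom(matrix_size = c(64L, 32L), n_slices = 2L,
                           mff_intra_pct = 2.3, t1_water_ms = 1409,
                           b0_range_hz = c(-40, 40), seed = 7)
  p <- match_slices(thigh_protocol(), ph)
  stack <- acquire(ph, p, noise_for_snr(p, 50, seed = 8))
  sep <- separate_stack(stack)
  pdff <- compute_pdff(sep, yields = readout_yield_factors(p))
  lut <- build_lookup(p, t1_grid = seq(100, 5000, by = 2))
  t1 <- estimate_t1water(sep$water$prep, sep$water$unprep, lut, p)
  labels <- segment_rule_based(pdff, sep$water$unprep, sep$fat$unprep)
  rep_ <- compute_composition(list(pdff = pdff, t1_water = t1,
                                   r2star = sep$r2star_map,
                                   voxel_mm = ph$voxel_mm), labels, p)
  truth <- ph$truth
  for (field in c("mff_intra_pct", "mff_inter_pct", "mfv_intra_ml",
                  "mfv_inter_ml", "mfv_total_ml", "muscle_ml", "scf_ml",
                  "muscle_pct", "t1_water_ms", "r2star_s1")) {
    expect_lt(abs(rep_[[field]] - truth[[field]]) / abs(truth[[field]]),
              0.02, label = field)
  }
})
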