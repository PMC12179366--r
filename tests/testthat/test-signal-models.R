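test_that("fat phasor is unity at TE 0 and never exceeds unit magnitude", {
  m <- default_fat_model()
  expect_equal(fat_phasor(0, 2.89, m), 1 + 0i)
  te <- seq(0, 20, by = 0.05)
  expect_true(all(Mod(fat_phasor(te, 2.89, m)) <= 1 + 1e-12))
})

test_that("fat peak frequencies follow the gyromagnetic conversion", {
  expect_equal(fat_peak_frequencies(fat_spectral_model(1, 1), 2.89),
               123.045796, tolerance = 1e-6)
  expect_equal(fat_peak_frequencies(fat_spectral_model(3.33, 1), 2.89),
               409.7425, tolerance = 1e-4)
})

test_that("single-peak phasor returns to unity after one full period", {
  m1 <- fat_spectral_model(1, 1)
  period_ms <- 1000 / fat_peak_frequencies(m1, 2.89)
  expect_equal(fat_phasor(period_ms, 2.89, m1), 1 + 0i, tolerance = 1e-12)
})

test_that("fat model normalizes weights and keeps the raw values", {
  m <- default_fat_model()
  expect_equal(sum(m$relative_weights), 1)
  expect_equal(attr(m, "raw_weights"),
               c(0.0870, 0.693, 0.1280, 0.0040, 0.0390, 0.0480))
  expect_error(fat_spectral_model(c(1, 2), 1), "length")
  expect_error(fat_spectral_model(1, -1), "nonnegative")
})

test_that("spoiled GRE signal reaches full spin density at long TR", {
  v <- tissue_voxel(0.8, 0.2)
  s <- spgr_signal(v, flip = 40, tr = 1e7, te = 0)
  expect_equal(Mod(s), (0.8 + 0.2) * sin(40 * pi / 180), tolerance = 1e-6)
  v0 <- tissue_voxel(1, 0)
  expect_equal(spgr_signal(v0, 90, 1e7, 0), 1 + 0i, tolerance = 1e-6)
  expect_error(spgr_signal(v, flip = 0, tr = 10, te = 1), "flip")
})

test_that("the Ernst angle maximizes the spoiled GRE signal", {
  v <- tissue_voxel(1, 0, t1_water = 1400)
  tr <- 20
  e1 <- exp(-tr / 1400)
  ernst <- acos(e1) * 180 / pi
  grid <- seq(1, 90, by = 0.25)
  s <- vapply(grid, function(a) Mod(spgr_signal(v, a, tr, 0)), numeric(1))
  expect_equal(grid[which.max(s)], ernst, tolerance = 0.3)
})

test_that("prepared SR-CSE signal vanishes as T1 grows without bound", {
  p <- thigh_protocol()
  v <- tissue_voxel(1, 0, t1_water = 1e9)
  s <- simulate_srcse_readout(v, p, prepared = TRUE)
  expect_lt(max(Mod(s)), 1e-4)
})

test_that("one-line readout reproduces the closed-form saturation recovery", {
  pd <- degenerate_protocol()
  for (t1 in c(800, 1400, 1537.2, 2500)) {
    v <- tissue_voxel(1, 0, t1_water = t1)
    r <- unname(Mod(simulate_srcse_readout(v, pd, TRUE)[1L]) /
      Mod(simulate_srcse_readout(v, pd, FALSE)[1L]))
    expect_equal(r, 1 - exp(-1537.2 / t1), tolerance = 1e-9,
                 info = paste("T1 =", t1))
  }
  # the named values: T1 = sat time gives 1 - 1/e; T1 = 1400 gives 0.6665
  v <- tissue_voxel(1, 0, t1_water = 1537.2)
  r <- unname(Mod(simulate_srcse_readout(v, pd, TRUE)[1L]) /
    Mod(simulate_srcse_readout(v, pd, FALSE)[1L]))
  expect_equal(r, 1 - exp(-1), tolerance = 1e-9)
})

test_that("full-protocol readout-history shift of the recovery ratio is stable", {
  # the complete 56-line ramped train raises the T1=1400 ratio above the
  # closed form 0.66646; the simulated value is frozen as a regression
  # fixture
  p <- thigh_protocol()
  v <- tissue_voxel(1, 0, t1_water = 1400, t2star = 25)
  r <- unname(Mod(simulate_srcse_readout(v, p, TRUE)[1L]) /
    Mod(simulate_srcse_readout(v, p, FALSE)[1L]))
  expect_equal(r, 0.6922038976, tolerance = 1e-8)
  expect_gt(r, 1 - exp(-1537.2 / 1400))
})

test_that("prepared shot errors when the saturation time is too short", {
  p <- thigh_protocol()
  p$sat_time_center <- 100            # < 28 lines x 10.98 ms
  v <- tissue_voxel(1, 0)
  expect_error(simulate_srcse_readout(v, p, prepared = TRUE),
               "sat_time_center")
})

test_that("simulators are deterministic", {
  p <- thigh_protocol()
  v <- tissue_voxel(0.9, 0.1, b0_offset_hz = 12)
  expect_identical(simulate_srcse_readout(v, p, TRUE),
                   simulate_srcse_readout(v, p, TRUE))
  expect_identical(simulate_molli(v), simulate_molli(v))
  expect_identical(simulate_sasha(v), simulate_sasha(v))
})

test_that("ideal MOLLI samples lie on A - B exp(-t/T1) with B/A = 2", {
  v <- tissue_voxel(1, 0, t1_water = 1400)
  m <- simulate_molli(v, perturb = FALSE)
  p <- protocol_preset("molli_533")
  scale <- sin(35 * pi / 180) * exp(-p$te_first_pair[1L] / v$t2star)
  expect_equal(Re(m$signal) / scale, 1 - 2 * exp(-m$t_inv / 1400),
               tolerance = 1e-9)
  fit <- fit_molli(m$t_inv, m$signal)
  expect_equal(fit$t1, 1400, tolerance = 1e-6)
  expect_equal(fit$B / fit$A, 2, tolerance = 1e-6)
})

test_that("single-compartment MOLLI recovers each compartment's T1", {
  fat_only <- tissue_voxel(0, 1, t1_fat = 370)
  water_only <- tissue_voxel(1, 0, t1_water = 1400)
  tf <- fit_molli(simulate_molli(fat_only, perturb = FALSE)$t_inv,
                  simulate_molli(fat_only, perturb = FALSE)$signal)
  tw <- fit_molli(simulate_molli(water_only, perturb = FALSE)$t_inv,
                  simulate_molli(water_only, perturb = FALSE)$signal)
  expect_equal(tf$t1, 370, tolerance = 1e-5)
  expect_equal(tw$t1, 1400, tolerance = 1e-5)
})

test_that("ideal SASHA samples lie on 1 - exp(-t/T1) and saturate to the anchor", {
  v <- tissue_voxel(1, 0, t1_water = 1400)
  p <- protocol_preset("sasha")
  p$sat_times_ms <- c(200, 600, 1200, 2000, 30000)
  s <- simulate_sasha(v, p, perturb = FALSE)
  scale <- Mod(s$signal[is.infinite(s$sat_time)])
  fin <- is.finite(s$sat_time)
  expect_equal(Mod(s$signal[fin]) / scale,
               1 - exp(-s$sat_time[fin] / 1400), tolerance = 1e-9)
  # a very long saturation time reaches the unprepared anchor
  expect_equal(Mod(s$signal[s$sat_time == 30000]), scale, tolerance = 1e-6)
})

test_that("unprepared readout yields differ between water and fat T1s", {
  y <- readout_yield_factors(thigh_protocol())
  expect_gt(y[["fat"]], y[["water"]])     # short-T1 fat recovers more in-train
  # one-line readout leaves no history: yields equal sin(flip)
  yd <- readout_yield_factors(degenerate_protocol())
  expect_equal(unname(yd), rep(sin(30 * pi / 180), 2), tolerance = 1e-12)
})
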