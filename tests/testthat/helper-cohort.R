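# End-to-end female-cohort recovery experiment shared by the acceptance
# tests: subjects drawn from the female normative distributions
# (T1_Water 1445 +/- 23 ms, MFF_Intra 2.6 +/- 1.0 %), each forward
# simulated as a thigh phantom, acquired at SNR 50, reconstructed, and
# summarized. Cached so several tests can reuse one run.
female_cohort_recovery <- local({
  cache <- NULL
  function(n_subjects = 12L, seed = 20L) {
    if (!is.null(cache)) return(cache)
    p <- protocol_preset("srcse_thigh")
    lut <- build_lookup(p, t1_grid = seq(100, 5000, by = 2))
    set.seed(seed)
    t1_true <- rnorm(n_subjects, 1445, 23)
    mff_true <- pmax(rnorm(n_subjects, 2.6, 1.0), 0.3)
    rows <- lapply(seq_len(n_subjects), function(i) {
      ph <- make_thigh_phantom(matrix_size = c(64L, 32L), n_slices = 1L,
                               mff_intra_pct = mff_true[i],
                               mff_intra_sd_pct = 0.8,
                               t1_water_ms = t1_true[i],
                               b0_range_hz = c(-30, 30),
                               seed = seed + i)
      pp <- match_slices(p, ph)
      stack <- acquire(ph, pp, noise_for_snr(pp, 50, seed = seed + 100L + i))
      sep <- separate_stack(stack, opts = list(b0_step = 4))
      pdff <- compute_pdff(sep, yields = readout_yield_factors(pp))
      t1 <- estimate_t1water(sep$water$prep, sep$water$unprep, lut)
      labels <- segment_rule_based(pdff, sep$water$unprep, sep$fat$unprep)
      rep_ <- compute_composition(list(pdff = pdff, t1_water = t1,
                                       r2star = sep$r2star_map,
                                       voxel_mm = ph$voxel_mm), labels, pp)
      data.frame(t1_true = ph$truth$t1_water_ms,
                 mff_true = ph$truth$mff_intra_pct,
                 t1_est = rep_$t1_water_ms,
                 mff_est = rep_$mff_intra_pct)
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})
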