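# Closed-form and Bloch-simulated signal models for two-compartment
# (water + multi-peak fat) voxels under SR-CSE, spoiled GRE, MOLLI and SASHA.
#
# Conventions: longitudinal magnetization is a fraction of equilibrium,
# perfect spoiling between TRs, perfect (instantaneous) saturation and
# inversion. Times in ms, off-resonance in Hz.

#' Construct a tissue voxel
#'
#' A two-compartment voxel with water and fat proton densities, compartment
#' T1s, a shared apparent T2* and an off-resonance offset. Default T1s are
#' 1400 ms for muscle water and 370 ms for fat at 2.89 T.
#'
#' @param rho_water,rho_fat Proton densities (arbitrary units, >= 0).
#' @param t1_water,t1_fat Longitudinal relaxation times (ms).
#' @param t2star Shared apparent transverse decay time (ms); R2* = 1000/t2star
#'   in 1/s.
#' @param b0_offset_hz Off-resonance frequency offset (Hz).
#' @param t2_water,t2_fat Intrinsic compartment T2s (ms), used only by the
#'   balanced-readout MOLLI/SASHA simulators (driven relaxation depends on
#'   T2, not T2*).
#' @return An object of class `srcse_voxel`.
#' @export
tissue_voxel <- function(rho_water, rho_fat, t1_water = 1400, t1_fat = 370,
                         t2star = 25, b0_offset_hz = 0,
                         t2_water = 35, t2_fat = 130) {
  if (rho_water < 0 || rho_fat < 0)
    stop("densities must be nonnegative", call. = FALSE)
  if (t1_water <= 0 || t1_fat <= 0 || t2star <= 0 ||
      t2_water <= 0 || t2_fat <= 0)
    stop("relaxation times must be positive", call. = FALSE)
  structure(list(rho_water = rho_water, rho_fat = rho_fat,
                 t1_water = t1_water, t1_fat = t1_fat,
                 t2star = t2star, b0_offset_hz = b0_offset_hz,
                 t2_water = t2_water, t2_fat = t2_fat),
            class = "srcse_voxel")
}

#' True proton density fat fraction of a voxel
#' @param v An `srcse_voxel`.
#' @return PDFF in percent.
#' @export
voxel_pdff <- function(v) 100 * v$rho_fat / (v$rho_fat + v$rho_water)

#' Spoiled gradient-echo steady-state signal of a two-compartment voxel
#'
#' Per compartment the steady-state amplitude is
#' \eqn{\rho \sin\alpha (1 - E_1) / (1 - \cos\alpha E_1)} with
#' \eqn{E_1 = \exp(-TR/T_1)}; the fat compartment is additionally modulated
#' by the multi-peak chemical-shift phasor, and the total is dephased by the
#' off-resonance offset and damped by T2* decay at the echo time.
#'
#' @param v An `srcse_voxel`.
#' @param flip Flip angle (degrees), in (0, 180).
#' @param tr Repetition time (ms).
#' @param te Echo time(s) (ms).
#' @param model Fat spectral model.
#' @param field Field strength (T) for the chemical-shift frequencies.
#' @return Complex signal, one value per `te`.
#' @export
spgr_signal <- function(v, flip, tr, te, model = default_fat_model(),
                        field = 2.89) {
  if (flip <= 0 || flip >= 180)
    stop("flip angle must lie in (0, 180) degrees", call. = FALSE)
  a <- flip * pi / 180
  yield <- function(t1) {
    e1 <- exp(-tr / t1)
    sin(a) * (1 - e1) / (1 - cos(a) * e1)
  }
  sw <- v$rho_water * yield(v$t1_water)
  sf <- v$rho_fat * yield(v$t1_fat)
  (sw + sf * fat_phasor(te, field, model)) *
    exp(2i * pi * v$b0_offset_hz * te / 1000) * exp(-te / v$t2star)
}

# Longitudinal magnetization (fraction of equilibrium) of one compartment at
# the central k-space line of the ramped single-shot train. Vectorized over
# t1. Perfect spoiling; perfect saturation when prepared, full relaxation
# before the shot otherwise.
srcse_mz_center <- function(t1, p, ramp, prepared) {
  a <- ramp$angles * pi / 180
  cidx <- ramp$center_line_index
  e_tr <- exp(-p$tr / t1)
  if (prepared) {
    if (is.na(p$sat_time_center))
      stop("invalid protocol: sat_time_center required for prepared readout",
           call. = FALSE)
    t_pre <- p$sat_time_center - cidx * p$tr
    if (t_pre < 0)
      stop("invalid protocol: sat_time_center shorter than time to reach the central line",
           call. = FALSE)
    mz <- 1 - exp(-t_pre / t1)
  } else {
    mz <- rep(1, length(t1))
  }
  if (cidx >= 1L) {
    for (j in seq_len(cidx)) {          # lines 0 .. cidx-1 precede the centre
      mz <- mz * cos(a[j])
      mz <- 1 - (1 - mz) * e_tr
    }
  }
  mz
}

# Vectorized core of the SR-CSE readout: complex signal at the central
# k-space line for each echo time, for vectors of voxel parameters.
# Returns an (n_voxel x n_te) complex matrix.
srcse_center_signal <- function(rho_water, rho_fat, t1_water, t1_fat,
                                t2star, b0_hz, p, te, prepared,
                                model = default_fat_model(), ramp = NULL) {
  if (is.null(ramp)) ramp <- build_flip_ramp(p)
  sin_c <- sin(ramp$angles[ramp$center_line_index + 1L] * pi / 180)
  mz_w <- srcse_mz_center(t1_water, p, ramp, prepared)
  mz_f <- srcse_mz_center(t1_fat, p, ramp, prepared)
  cf <- fat_phasor(te, p$field_strength, model)              # length n_te
  aw <- rho_water * mz_w * sin_c                             # n_voxel
  af <- rho_fat * mz_f * sin_c
  # (n_voxel x n_te): water + fat*phasor, then off-resonance and T2* decay
  sig <- outer(aw, rep(1 + 0i, length(te))) + outer(af, cf)
  phase <- exp(2i * pi * outer(b0_hz, te) / 1000)
  decay <- exp(-outer(1 / t2star, te))
  sig * phase * decay
}

#' Simulate the SR-CSE readout of a single voxel
#'
#' Evolves the per-compartment longitudinal magnetization line by line
#' through the ramped-flip single-shot train (perfect spoiling between TRs).
#' With `prepared = TRUE` the magnetization is perfectly saturated and
#' recovers such that the central k-space line is acquired `sat_time_center`
#' after the saturation pulse; without preparation full relaxation is assumed
#' before the shot. The returned value is the complex transverse signal
#' generated at the central k-space line for each echo time, including the
#' fat chemical-shift phasor, off-resonance phase, and T2* decay.
#'
#' @param v An `srcse_voxel`.
#' @param p An SR-CSE `srcse_protocol`.
#' @param prepared Logical: saturation-recovery prepared shot?
#' @param model Fat spectral model.
#' @param ramp Optional `srcse_flip_ramp` overriding `build_flip_ramp(p)`
#'   (used e.g. to study readout-history effects with degenerate ramps).
#' @param te Echo times (ms); defaults to the protocol's unique TEs.
#' @return Complex vector named by echo time.
#' @export
simulate_srcse_readout <- function(v, p, prepared = TRUE,
                                   model = default_fat_model(),
                                   ramp = NULL, te = NULL) {
  validate_protocol(p)
  if (is.null(te)) te <- build_echo_schedule(p)$unique_te
  s <- srcse_center_signal(v$rho_water, v$rho_fat, v$t1_water, v$t1_fat,
                           v$t2star, v$b0_offset_hz, p, te, prepared,
                           model, ramp)
  stats::setNames(as.vector(s), format(te))
}

# Event-driven single-compartment Mz sampler for inversion/saturation
# prepared balanced single-shot imaging. During a readout train the
# magnetization undergoes driven relaxation toward M0 * T1star/T1 with rate
# 1/T1star = cos^2(a/2)/T1 + sin^2(a/2)/T2 (the classical balanced-SSFP
# apparent relaxation); between trains it relaxes freely with T1. `events`
# is a data.frame with columns time (ms) and type ("invert", "saturate",
# "readout"); readout events give the time of the FIRST train pulse.
# Returns Mz at the central line of each readout, in event order.
sample_mz_train <- function(t1, t2, events, flip_deg, n_lines, center_idx,
                            tr_readout, perturb = TRUE) {
  a <- flip_deg * pi / 180
  r1s <- cos(a / 2)^2 / t1 + sin(a / 2)^2 / t2
  mz_inf <- (1 / r1s) / t1
  relax <- function(mz, dt) 1 - (1 - mz) * exp(-dt / t1)
  driven <- function(mz, dt) mz_inf - (mz_inf - mz) * exp(-dt * r1s)
  train_ms <- n_lines * tr_readout
  mz <- 1
  t_cur <- min(events$time)
  out <- numeric(0)
  for (k in order(events$time)) {
    ev <- events[k, ]
    mz <- relax(mz, ev$time - t_cur)
    t_cur <- ev$time
    if (ev$type == "invert") {
      mz <- -mz
    } else if (ev$type == "saturate") {
      mz <- 0
    } else if (perturb) {
      out <- c(out, driven(mz, center_idx * tr_readout))
      mz <- driven(mz, train_ms)
      t_cur <- t_cur + train_ms
    } else {
      out <- c(out, relax(mz, center_idx * tr_readout))
      mz <- relax(mz, train_ms)
      t_cur <- t_cur + train_ms
    }
  }
  out
}

# Combine per-compartment Mz samples into the complex sampled signal at the
# stated TE and flip.
combine_compartments <- function(v, mz_w, mz_f, flip_deg, te, field, model) {
  sin(flip_deg * pi / 180) *
    (v$rho_water * mz_w + v$rho_fat * mz_f * fat_phasor(te, field, model)) *
    exp(2i * pi * v$b0_offset_hz * te / 1000) * exp(-te / v$t2star)
}

#' Simulate a 5(3)3 MOLLI acquisition of a voxel
#'
#' Two inversion blocks (5 images, 3 recovery beats, 3 images) on a regular
#' R-R grid with perfect inversions. Each image is a balanced single-shot
#' train modelled as driven relaxation of Mz (rate
#' \eqn{\cos^2(\alpha/2)/T_1 + \sin^2(\alpha/2)/T_2}); the sample is taken
#' at the central k-space line. With `perturb = FALSE` ideal
#' inversion-recovery samples \eqn{1 - 2 e^{-t/T_1}} are returned (full
#' recovery assumed before each inversion).
#'
#' @param v An `srcse_voxel`.
#' @param p A MOLLI protocol (see [protocol_preset()]).
#' @param perturb Simulate the readout perturbation of Mz?
#' @param model Fat spectral model.
#' @return A data.frame with `t_inv` (ms since the governing inversion) and
#'   complex `signal`, 8 rows, ordered by acquisition.
#' @export
simulate_molli <- function(v, p = protocol_preset("molli_533"),
                           perturb = TRUE, model = default_fat_model()) {
  validate_protocol(p)
  rr <- p$rr_ms
  if (is.null(rr) || rr <= 0) stop("rr_ms must be positive", call. = FALSE)
  sch <- p$scheme %||% c(5L, 3L, 3L)
  ti <- p$ti_ms %||% c(100, 180)
  n1 <- sch[1L]; n_rec <- sch[2L]; n2 <- sch[3L]
  cidx <- p$center_line_index
  # centre-of-k-space times; readout starts cidx lines earlier
  c1 <- ti[1L] + (seq_len(n1) - 1L) * rr
  t_inv2 <- (n1 + n_rec) * rr
  c2 <- t_inv2 + ti[2L] + (seq_len(n2) - 1L) * rr
  t_inv <- c(c1, c2 - t_inv2)
  if (perturb) {
    events <- rbind(
      data.frame(time = 0, type = "invert"),
      data.frame(time = c1 - cidx * p$tr, type = "readout"),
      data.frame(time = t_inv2, type = "invert"),
      data.frame(time = c2 - cidx * p$tr, type = "readout"))
    mz_w <- sample_mz_train(v$t1_water, v$t2_water, events, p$flip_center,
                            p$n_kspace_lines, cidx, p$tr, TRUE)
    mz_f <- sample_mz_train(v$t1_fat, v$t2_fat, events, p$flip_center,
                            p$n_kspace_lines, cidx, p$tr, TRUE)
  } else {
    mz_w <- 1 - 2 * exp(-t_inv / v$t1_water)
    mz_f <- 1 - 2 * exp(-t_inv / v$t1_fat)
  }
  te <- p$te_first_pair[1L]
  sig <- combine_compartments(v, mz_w, mz_f, p$flip_center, te,
                              p$field_strength, model)
  data.frame(t_inv = t_inv, signal = sig)
}

#' Simulate a SASHA acquisition of a voxel
#'
#' One saturation-prepared single-shot image per saturation time (time
#' measured from the saturation pulse to the central k-space line) plus one
#' unprepared (infinite-recovery) anchor image. The readout train is
#' modelled as in [simulate_molli()]; with `perturb = FALSE` ideal
#' saturation-recovery samples \eqn{1 - e^{-t/T_1}} are returned.
#'
#' @param v An `srcse_voxel`.
#' @param p A SASHA protocol (see [protocol_preset()]); `sat_times_ms` holds
#'   the saturation-time samples.
#' @param perturb Simulate the readout perturbation of Mz?
#' @param model Fat spectral model.
#' @return A data.frame with `sat_time` (ms; `Inf` for the anchor) and
#'   complex `signal`.
#' @export
simulate_sasha <- function(v, p = protocol_preset("sasha"),
                           perturb = TRUE, model = default_fat_model()) {
  validate_protocol(p)
  sat_times <- p$sat_times_ms
  if (is.null(sat_times) || any(sat_times <= 0))
    stop("sat_times_ms must be positive", call. = FALSE)
  cidx <- p$center_line_index
  t_pre <- sat_times - cidx * p$tr
  if (any(t_pre < 0))
    stop("saturation time shorter than time to reach the central line",
         call. = FALSE)
  st <- c(sat_times, Inf)
  one <- function(t1, t2, sat) {
    if (!perturb) return(if (is.finite(sat)) 1 - exp(-sat / t1) else 1)
    ev <- if (is.finite(sat)) {
      rbind(data.frame(time = 0, type = "saturate"),
            data.frame(time = sat - cidx * p$tr, type = "readout"))
    } else {
      data.frame(time = 0, type = "readout")   # fully relaxed anchor
    }
    sample_mz_train(t1, t2, ev, p$flip_center, p$n_kspace_lines, cidx,
                    p$tr, TRUE)
  }
  mz_w <- vapply(st, function(s) one(v$t1_water, v$t2_water, s), numeric(1))
  mz_f <- vapply(st, function(s) one(v$t1_fat, v$t2_fat, s), numeric(1))
  te <- p$te_first_pair[1L]
  sig <- combine_compartments(v, mz_w, mz_f, p$flip_center, te,
                              p$field_strength, model)
  data.frame(sat_time = st, signal = sig)
}

#' Unprepared readout signal-yield factors for water and fat
#'
#' The ramped single-shot train leaves a small T1-dependent weighting in the
#' unprepared (spin-density) images. These factors are the Bloch-simulated
#' per-compartment amplitudes (Mz at the central line times sin of the
#' central flip) for nominal compartment T1s; dividing the separated water
#' and fat images by them restores spin-density proportionality before PDFF
#' is computed.
#'
#' @param p An SR-CSE `srcse_protocol`.
#' @param t1_water,t1_fat Nominal compartment T1s (ms).
#' @param ramp Optional flip ramp override.
#' @return Named numeric vector `c(water =, fat =)`.
#' @export
readout_yield_factors <- function(p, t1_water = 1400, t1_fat = 370,
                                  ramp = NULL) {
  validate_protocol(p)
  if (is.null(ramp)) ramp <- build_flip_ramp(p)
  sin_c <- sin(ramp$angles[ramp$center_line_index + 1L] * pi / 180)
  c(water = srcse_mz_center(t1_water, p, ramp, FALSE) * sin_c,
    fat = srcse_mz_center(t1_fat, p, ramp, FALSE) * sin_c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
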