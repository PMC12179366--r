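# Digital phantoms (tube and thigh), noisy multi-echo acquisition, and
# synthetic normative cohorts with known ground truth.

#' Tissue label codes used by phantoms and segmentation
#'
#' @return Named integer vector: background 0, muscle 1, subcutaneous_fat 2,
#'   intermuscular_fat 3, bone 4, skin 5.
#' @export
label_codes <- function() {
  c(background = 0L, muscle = 1L, subcutaneous_fat = 2L,
    intermuscular_fat = 3L, bone = 4L, skin = 5L)
}

#' Complex-noise specification
#'
#' @param sd Standard deviation of each of the real and imaginary noise
#'   channels (signal units).
#' @param seed Integer seed for reproducible acquisition noise.
#' @return An object of class `srcse_noise`.
#' @export
noise_spec <- function(sd, seed = NULL) {
  if (sd < 0) stop("noise sd must be nonnegative", call. = FALSE)
  structure(list(sd = sd, seed = seed), class = "srcse_noise")
}

#' Noise specification for a target muscle SNR
#'
#' SNR is defined against the unprepared central-line signal amplitude of a
#' unit-density pure-water muscle voxel under the given protocol.
#'
#' @param p An SR-CSE protocol.
#' @param snr Target signal-to-noise ratio.
#' @param seed Integer seed.
#' @return An `srcse_noise`.
#' @export
noise_for_snr <- function(p, snr, seed = NULL) {
  amp <- unname(readout_yield_factors(p)["water"])
  noise_spec(amp / snr, seed)
}

empty_volumes <- function(dims) {
  z <- array(0, dims)
  list(rho_water = z, rho_fat = z,
       t1_water = array(1000, dims), t1_fat = array(370, dims),
       t2star = array(25, dims), b0_hz = array(0, dims))
}

new_phantom <- function(labels, vol, voxel_mm, slice_thickness, slice_gap,
                        truth, extra = list()) {
  structure(c(list(labels = labels, vol = vol, voxel_mm = voxel_mm,
                   slice_thickness = slice_thickness, slice_gap = slice_gap,
                   truth = truth), extra),
            class = "srcse_phantom")
}

# slab correction factor: slab thickness over summed slice thickness
slab_factor <- function(n_slices, slice_thickness, slice_gap) {
  (n_slices * slice_thickness + (n_slices - 1) * slice_gap) /
    (n_slices * slice_thickness)
}

# Ground-truth composition recomputed exactly from the parameter volumes,
# using the same conventions as compute_composition().
phantom_truth <- function(labels, vol, voxel_mm, slice_thickness, slice_gap,
                          n_slices) {
  lc <- label_codes()
  vvol_ml <- prod(voxel_mm) / 1000
  sf <- slab_factor(n_slices, slice_thickness, slice_gap)
  ff <- vol$rho_fat / pmax(vol$rho_fat + vol$rho_water, .Machine$double.eps)
  msk_m <- labels == lc["muscle"]
  msk_i <- labels == lc["intermuscular_fat"]
  msk_s <- labels == lc["subcutaneous_fat"]
  n_thigh <- sum(labels != lc["background"])
  mfv_intra <- sum(ff[msk_m]) * vvol_ml * sf
  mfv_inter <- sum(ff[msk_i]) * vvol_ml * sf
  compartment_ml <- (sum(msk_m) + sum(msk_i)) * vvol_ml * sf
  list(
    mff_intra_pct = if (any(msk_m)) mean(100 * ff[msk_m]) else NA_real_,
    mff_inter_pct = if (compartment_ml > 0)
      100 * mfv_inter / compartment_ml else NA_real_,
    mfv_intra_ml = mfv_intra,
    mfv_inter_ml = mfv_inter,
    mfv_total_ml = mfv_intra + mfv_inter,
    muscle_ml = sum(msk_m) * vvol_ml * sf,
    scf_ml = sum(msk_s) * vvol_ml * sf,
    muscle_pct = if (n_thigh > 0) 100 * sum(msk_m) / n_thigh else NA_real_,
    t1_water_ms = if (any(msk_m)) mean(vol$t1_water[msk_m]) else NA_real_,
    r2star_s1 = if (any(msk_m)) mean(1000 / vol$t2star[msk_m]) else NA_real_)
}

#' Tube phantom with known fat fractions and water T1s
#'
#' Disjoint homogeneous disks ("tubes") on a zero-signal background, one per
#' requested fat fraction / water T1 pair, emulating agar fat-water
#' calibration phantoms with increasing fat content.
#'
#' @param ff Fat fractions of the tubes (0-1 scale).
#' @param t1_water Water T1 per tube (ms); recycled if scalar.
#' @param grid Matrix size `c(nx, ny)`.
#' @param n_slices Number of slices.
#' @param voxel_mm Voxel size `c(dx, dy, dz)` in mm.
#' @param radius_vox Tube radius in voxels.
#' @param t1_fat,t2star,b0_hz Shared tissue parameters (ms, ms, Hz); `b0_hz`
#'   may be a scalar or an `(nx, ny)` matrix applied to every slice.
#' @param slice_gap Gap between slices (mm); defaults to contiguous slices.
#' @return An `srcse_phantom`; `$tube_id` holds the per-voxel tube index
#'   (0 = background) and `$truth$tubes` the per-tube ground truth.
#' @export
make_tube_phantom <- function(ff, t1_water = 1400, grid = c(96, 96),
                              n_slices = 1L, voxel_mm = c(2, 2, 3.5),
                              radius_vox = 9, t1_fat = 370, t2star = 25,
                              b0_hz = 0, slice_gap = 0) {
  n_tube <- length(ff)
  t1_water <- rep_len(t1_water, n_tube)
  if (any(ff < 0 | ff > 1)) stop("ff must lie in [0, 1]", call. = FALSE)
  dims <- c(grid, n_slices)
  # lay tubes on a square grid of cells; error if they cannot fit disjointly
  per_row <- ceiling(sqrt(n_tube))
  cell <- floor(min(grid) / per_row)
  if (cell < 2 * radius_vox + 2)
    stop("geometry error: tubes overlap or exceed the grid", call. = FALSE)
  labels <- array(0L, dims)
  tube_id <- array(0L, dims)
  vol <- empty_volumes(dims)
  xs <- matrix(rep(seq_len(grid[1L]), grid[2L]), grid[1L])
  ys <- matrix(rep(seq_len(grid[2L]), each = grid[1L]), grid[1L])
  b0_mat <- if (is.matrix(b0_hz)) b0_hz else matrix(b0_hz, grid[1L], grid[2L])
  for (k in seq_len(n_tube)) {
    r <- (k - 1) %/% per_row
    c <- (k - 1) %% per_row
    cx <- c * cell + cell / 2
    cy <- r * cell + cell / 2
    disk <- (xs - cx)^2 + (ys - cy)^2 <= radius_vox^2
    for (z in seq_len(n_slices)) {
      sl <- array(FALSE, dims); sl[, , z] <- disk
      labels[sl] <- label_codes()[["muscle"]]
      tube_id[sl] <- k
      vol$rho_water[sl] <- 1 - ff[k]
      vol$rho_fat[sl] <- ff[k]
      vol$t1_water[sl] <- t1_water[k]
      vol$t1_fat[sl] <- t1_fat
      vol$t2star[sl] <- t2star
    }
  }
  for (z in seq_len(n_slices)) vol$b0_hz[, , z] <- b0_mat
  vvol_ml <- prod(voxel_mm) / 1000
  sfac <- slab_factor(n_slices, voxel_mm[3L], slice_gap)
  tubes <- data.frame(
    tube = seq_len(n_tube),
    pdff_pct = 100 * ff,
    t1_water_ms = t1_water,
    volume_ml = vapply(seq_len(n_tube),
                       function(k) sum(tube_id == k) * vvol_ml * sfac,
                       numeric(1)))
  tubes$fat_volume_ml <- tubes$volume_ml * ff
  truth <- phantom_truth(labels, vol, voxel_mm, voxel_mm[3L], slice_gap,
                         n_slices)
  truth$tubes <- tubes
  new_phantom(labels, vol, voxel_mm, voxel_mm[3L], slice_gap, truth,
              extra = list(tube_id = tube_id))
}

#' Parametric two-thigh digital phantom
#'
#' Builds a thigh-like label geometry on each half of the field of view:
#' a 1-voxel skin rim, a subcutaneous-fat annulus, a muscle interior crossed
#' by intermuscular-fat septa (spokes), and a low-signal bone disk. Muscle
#' voxels receive intramuscular fat fractions drawn from a truncated
#' Gaussian around the target mean; the draw is deterministic for a fixed
#' seed.
#'
#' @param matrix_size Grid `c(nx, ny)`; at least 64 in x.
#' @param fov Field of view `c(x, y)` in mm (both thighs along x).
#' @param n_slices,slice_thickness,slice_gap Slice prescription.
#' @param thigh_radius_mm Outer thigh radius (mm).
#' @param scf_thickness_mm Subcutaneous-fat annulus thickness (mm).
#' @param bone_radius_mm Bone disk radius (mm).
#' @param n_septa Number of intermuscular fat spokes per thigh.
#' @param septa_width_mm Width of each spoke (mm); must be smaller than the
#'   muscle radius.
#' @param mff_intra_pct Target mean intramuscular fat fraction (percent).
#' @param mff_intra_sd_pct Voxelwise heterogeneity SD (percent); 0 gives
#'   identical muscle voxels.
#' @param t1_water_ms Muscle water T1 (ms, one value per subject).
#' @param r2star_s1 Muscle R2* (1/s).
#' @param b0_range_hz Linear left-to-right off-resonance ramp `c(lo, hi)`
#'   across the FOV (Hz).
#' @param seed Integer seed for the heterogeneity draw.
#' @return An `srcse_phantom` with exact ground-truth summary in `$truth`.
#' @export
make_thigh_phantom <- function(matrix_size = c(128L, 64L), fov = c(450, 225),
                               n_slices = 5L, slice_thickness = 3.5,
                               slice_gap = 10.5, thigh_radius_mm = 75,
                               scf_thickness_mm = 12, bone_radius_mm = 12,
                               n_septa = 3L, septa_width_mm = 4,
                               mff_intra_pct = 2.3, mff_intra_sd_pct = 0.8,
                               t1_water_ms = 1400, r2star_s1 = 42,
                               b0_range_hz = c(0, 0), seed = 1L) {
  if (matrix_size[1L] < 64L) stop("grid must be at least 64 in x", call. = FALSE)
  vox <- c(fov / matrix_size, slice_thickness)
  if (2 * thigh_radius_mm > fov[2L] || 4 * thigh_radius_mm > fov[1L])
    stop("geometry error: two thighs do not fit the FOV", call. = FALSE)
  muscle_radius <- thigh_radius_mm - scf_thickness_mm - vox[1L]
  if (septa_width_mm >= muscle_radius)
    stop("geometry error: septa wider than the muscle radius", call. = FALSE)
  lc <- label_codes()
  dims <- c(matrix_size, n_slices)
  labels2d <- matrix(lc[["background"]], matrix_size[1L], matrix_size[2L])
  xmm <- (matrix(rep(seq_len(matrix_size[1L]), matrix_size[2L]),
                 matrix_size[1L]) - 0.5) * vox[1L]
  ymm <- (matrix(rep(seq_len(matrix_size[2L]), each = matrix_size[1L]),
                 matrix_size[1L]) - 0.5) * vox[2L]
  centers_x <- c(fov[1L] / 4, 3 * fov[1L] / 4)
  center_y <- fov[2L] / 2
  for (cx in centers_x) {
    r <- sqrt((xmm - cx)^2 + (ymm - center_y)^2)
    th <- atan2(ymm - center_y, xmm - cx)
    inside <- r <= thigh_radius_mm
    labels2d[inside] <- lc[["muscle"]]
    labels2d[inside & r > thigh_radius_mm - scf_thickness_mm] <-
      lc[["subcutaneous_fat"]]
    labels2d[inside & r > thigh_radius_mm - vox[1L]] <- lc[["skin"]]
    # intermuscular fat spokes through the muscle interior
    if (n_septa > 0L) {
      for (k in seq_len(n_septa)) {
        ang <- (k - 1) * pi / n_septa
        d <- abs((xmm - cx) * sin(ang) - (ymm - center_y) * cos(ang))
        spoke <- labels2d == lc[["muscle"]] & inside &
          d <= septa_width_mm / 2 & r <= muscle_radius
        labels2d[spoke] <- lc[["intermuscular_fat"]]
      }
    }
    bone <- r <= bone_radius_mm
    labels2d[bone] <- lc[["bone"]]
  }
  labels <- array(rep(labels2d, n_slices), dims)
  vol <- empty_volumes(dims)
  set.seed(as.integer(seed))
  msk <- function(code) labels == code
  n_m <- sum(msk(lc[["muscle"]]))
  ff_m <- stats::rnorm(n_m, mff_intra_pct / 100, mff_intra_sd_pct / 100)
  ff_m <- pmin(pmax(ff_m, 0), 0.6)
  assign_tissue <- function(code, rho, ff, t1w, t2s) {
    m <- msk(code)
    vol$rho_water[m] <<- rho * (1 - ff)
    vol$rho_fat[m] <<- rho * ff
    vol$t1_water[m] <<- t1w
    vol$t2star[m] <<- t2s
  }
  m <- msk(lc[["muscle"]])
  vol$rho_water[m] <- 1 - ff_m
  vol$rho_fat[m] <- ff_m
  vol$t1_water[m] <- t1_water_ms
  vol$t2star[m] <- 1000 / r2star_s1
  assign_tissue(lc[["subcutaneous_fat"]], 1, 0.92, 1400, 20)
  assign_tissue(lc[["intermuscular_fat"]], 1, 0.90, 1400, 20)
  assign_tissue(lc[["bone"]], 0.02, 0, 1000, 10)
  assign_tissue(lc[["skin"]], 0.8, 0.05, 1400, 15)
  b0_2d <- b0_range_hz[1L] +
    (b0_range_hz[2L] - b0_range_hz[1L]) * (xmm / fov[1L])
  vol$b0_hz <- array(rep(b0_2d, n_slices), dims)
  truth <- phantom_truth(labels, vol, vox, slice_thickness, slice_gap,
                         n_slices)
  new_phantom(labels, vol, vox, slice_thickness, slice_gap, truth,
              extra = list(seed = as.integer(seed)))
}

#' Simulate a noisy SR-CSE acquisition of a phantom
#'
#' Computes the Bloch-simulated central-line signal of every voxel for the
#' unprepared and saturation-prepared series at every acquired echo, adds
#' independent complex Gaussian noise per acquired echo and preparation, and
#' averages duplicated echo times into one effective sample (so a duplicated
#' TE carries twice the least-squares weight downstream).
#'
#' @param phantom An `srcse_phantom`.
#' @param p An SR-CSE `srcse_protocol`.
#' @param noise An `srcse_noise`; `noise_spec(0)` gives a noiseless stack.
#' @param model Fat spectral model.
#' @return An object of class `srcse_stack`: complex `data` array with
#'   dimensions (x, y, z, TE, preparation), `te` (unique, sorted),
#'   `te_weights`, `protocol`, `voxel_mm`.
#' @export
acquire <- function(phantom, p, noise = noise_spec(0), model = default_fat_model()) {
  stopifnot(inherits(phantom, "srcse_phantom"))
  validate_protocol(p)
  sch <- build_echo_schedule(p)
  dims <- dim(phantom$labels)
  nvox <- prod(dims)
  v <- phantom$vol
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  data <- array(complex(real = 0), c(dims, length(sch$unique_te), 2L))
  dimnames(data) <- c(rep(list(NULL), 3L),
                      list(format(sch$unique_te), c("unprep", "prep")))
  ramp <- build_flip_ramp(p)
  tol <- 1e-9
  for (prep in c(FALSE, TRUE)) {
    sig <- srcse_center_signal(as.vector(v$rho_water), as.vector(v$rho_fat),
                               as.vector(v$t1_water), as.vector(v$t1_fat),
                               as.vector(v$t2star), as.vector(v$b0_hz),
                               p, sch$te_list, prep, model, ramp)
    if (noise$sd > 0) {
      sig <- sig + complex(
        real = stats::rnorm(length(sig), 0, noise$sd),
        imaginary = stats::rnorm(length(sig), 0, noise$sd))
    }
    for (j in seq_along(sch$unique_te)) {
      cols <- which(abs(sch$te_list - sch$unique_te[j]) <= tol)
      avg <- if (length(cols) > 1L) rowMeans(sig[, cols, drop = FALSE])
             else sig[, cols]
      data[, , , j, prep + 1L] <- array(avg, dims)
    }
  }
  structure(list(data = data, te = sch$unique_te, te_weights = sch$weights,
                 protocol = p, voxel_mm = phantom$voxel_mm),
            class = "srcse_stack")
}

#' Default generative model for synthetic normative cohorts
#'
#' Per-metric linear models in age and sex (`metric = intercept +
#' beta_age * age + beta_male * male + residual`) with sex-specific Gaussian
#' residual SDs. The coefficients are the package's normative defaults for
#' healthy adult thigh muscle at 2.89 T; residual SDs reproduce the observed
#' within-sex dispersion. Volume metrics are on the acquired-slices scale of
#' the covariate models (apply the slab factor 3.4 to compare with
#' slab-corrected volumes).
#'
#' @return Named list of metric model specifications.
#' @export
default_cohort_model <- function() {
  m <- function(intercept, beta_age, beta_male, sd_male, sd_female,
                lower = 0, upper = Inf) {
    list(intercept = intercept, beta_age = beta_age, beta_male = beta_male,
         sd_male = sd_male, sd_female = sd_female, lower = lower,
         upper = upper)
  }
  list(
    t1w_ms        = m(1433.3, 0.2,  -35.3,  22,   23),
    mff_intra_pct = m(0.97,   0.03, -0.24,  0.8,  1.0,  upper = 100),
    mff_inter_pct = m(5.84,   0.10, -3.28,  2.9,  4.8,  upper = 100),
    mff_total_pct = m(6.71,   0.11, -2.91,  3.1,  4.2,  upper = 100),
    scf_ml        = m(164.5,  1.2,  -127.7, 44,   90),
    muscle_ml     = m(334.2, -0.8,  95.5,   48,   48),
    muscle_pct    = m(63.2,  -0.2,  21.5,   7.6,  9.7,  upper = 100),
    mfv_inter_ml  = m(19.8,   0.2,  -2.1,   12,   11),
    mfv_intra_ml  = m(3.11,   0.09, 1.63,   3.5,  2.6),
    mfv_total_ml  = m(23.0,   0.3,  -0.5,   15,   12.6),
    r2star_s1     = m(39.0,   0.05, 0.41,   2,    2))
}

#' Generate a synthetic normative cohort
#'
#' Ages are drawn uniformly over `age_range`; each metric follows its linear
#' age/sex model with Gaussian residuals (sex-specific SD), clipped to the
#' metric's physical range. BMI is drawn from sex-specific normals
#' (24.4 +/- 4.1 male, 24.9 +/- 3.0 female) for use by the BMI group
#' comparisons.
#'
#' @param n_male,n_female Group sizes.
#' @param model Metric model list as from [default_cohort_model()]; every
#'   requested metric must have a complete coefficient set.
#' @param metrics Which metrics to generate (default: all in `model`).
#' @param age_range Uniform age range in years.
#' @param seed Integer seed.
#' @return A data.frame with `subject`, `age`, `sex`, `male`, `bmi` and one
#'   column per metric.
#' @export
make_cohort <- function(n_male, n_female, model = default_cohort_model(),
                        metrics = names(model), age_range = c(18, 76),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_male + n_female
  male <- c(rep(1L, n_male), rep(0L, n_female))
  age <- stats::runif(n, age_range[1L], age_range[2L])
  out <- data.frame(subject = seq_len(n), age = age,
                    sex = ifelse(male == 1L, "male", "female"), male = male)
  out$bmi <- pmax(stats::rnorm(n, ifelse(male == 1L, 24.4, 24.9),
                               ifelse(male == 1L, 4.1, 3.0)), 15)
  for (met in metrics) {
    spec <- model[[met]]
    need <- c("intercept", "beta_age", "beta_male", "sd_male", "sd_female")
    if (is.null(spec) || !all(need %in% names(spec)) ||
        any(!vapply(spec[need], is.numeric, logical(1))))
      stop("config error: missing coefficients for metric ", met,
           call. = FALSE)
    sd_i <- ifelse(male == 1L, spec$sd_male, spec$sd_female)
    val <- spec$intercept + spec$beta_age * age + spec$beta_male * male +
      stats::rnorm(n, 0, sd_i)
    out[[met]] <- pmin(pmax(val, spec$lower %||% -Inf), spec$upper %||% Inf)
  }
  out
}
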