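# Rule-based thigh segmentation and muscle / fat composition reporting with
# slice-gap correction; conventional-CSE T1 correction.

#' Rule-based segmentation of thigh quantitative maps
#'
#' A deterministic stand-in for learned segmentation, driven entirely by the
#' separated maps: background falls below a signal floor; enclosed
#' low-signal disks become bone; the outermost one-voxel rim of each
#' foreground component becomes skin; fat-dominant voxels (PDFF >= 50,
#' strict: 49.9 stays muscle) connected to the subcutaneous annulus under
#' the skin become subcutaneous fat and all other fat-dominant voxels become
#' intermuscular fat; everything else is muscle. Connectivity is 4-neighbour
#' within each slice.
#'
#' @param pdff PDFF map (percent; `NaN` allowed).
#' @param water,fat Magnitude (or complex) water and fat maps on the same
#'   grid.
#' @param floor Signal floor on |W| + |F|; default 5x the median background
#'   magnitude (estimated from the low-signal quartile).
#' @return Integer array of [label_codes()] values.
#' @export
segment_rule_based <- function(pdff, water, fat, floor = NULL) {
  w <- Mod(water); f <- Mod(fat)
  dims <- dim(w)
  if (length(dims) == 2L) {
    dims <- c(dims, 1L)
    dim(w) <- dims; dim(f) <- dims; dim(pdff) <- dims
  }
  tot <- w + f
  tot[is.na(tot)] <- 0
  if (is.null(floor)) {
    lo <- tot[tot <= 0.25 * stats::quantile(tot, 0.99)]
    bg <- if (length(lo)) stats::median(lo) else 0
    floor <- max(5 * bg, 0.02 * stats::quantile(tot, 0.95))
  }
  if (!any(tot >= floor))
    stop("degenerate input: empty foreground", call. = FALSE)
  lc <- label_codes()
  labels <- array(lc[["background"]], dims)
  for (z in seq_len(dims[3L])) {
    fg <- tot[, , z] >= floor
    if (!any(fg)) next
    # background components: those touching the image border are outside,
    # enclosed ones are bone
    bgc <- EBImage::bwlabel(!fg)
    border_ids <- unique(c(bgc[1L, ], bgc[dims[1L], ], bgc[, 1L],
                           bgc[, dims[2L]]))
    border_ids <- setdiff(border_ids, 0L)
    outside <- bgc > 0L & matrix(bgc %in% border_ids, dims[1L], dims[2L])
    bone <- !fg & !outside
    # skin: foreground voxels 4-adjacent to the outside
    out_pad <- rbind(TRUE, cbind(TRUE, outside, TRUE), TRUE)
    nb_out <- out_pad[1:dims[1L], 2:(dims[2L] + 1L)] |
      out_pad[3:(dims[1L] + 2L), 2:(dims[2L] + 1L)] |
      out_pad[2:(dims[1L] + 1L), 1:dims[2L]] |
      out_pad[2:(dims[1L] + 1L), 3:(dims[2L] + 2L)]
    skin <- fg & nb_out
    pd <- pdff[, , z]
    fat_dom <- fg & !skin & !is.na(pd) & pd >= 50
    # subcutaneous fat: fat components adjacent to skin; the rest is
    # intermuscular
    scf <- matrix(FALSE, dims[1L], dims[2L])
    if (any(fat_dom)) {
      fc <- EBImage::bwlabel(fat_dom)
      skin_pad <- rbind(FALSE, cbind(FALSE, skin, FALSE), FALSE)
      nb_skin <- skin_pad[1:dims[1L], 2:(dims[2L] + 1L)] |
        skin_pad[3:(dims[1L] + 2L), 2:(dims[2L] + 1L)] |
        skin_pad[2:(dims[1L] + 1L), 1:dims[2L]] |
        skin_pad[2:(dims[1L] + 1L), 3:(dims[2L] + 2L)]
      scf_ids <- setdiff(unique(fc[fat_dom & nb_skin]), 0L)
      scf <- fc > 0L & matrix(fc %in% scf_ids, dims[1L], dims[2L])
    }
    sl <- matrix(lc[["background"]], dims[1L], dims[2L])
    sl[fg] <- lc[["muscle"]]
    sl[fat_dom & scf] <- lc[["subcutaneous_fat"]]
    sl[fat_dom & !scf] <- lc[["intermuscular_fat"]]
    sl[bone] <- lc[["bone"]]
    sl[skin] <- lc[["skin"]]
    labels[, , z] <- sl
  }
  storage.mode(labels) <- "integer"
  labels
}

#' Muscle and fat composition report
#'
#' Computes the composition metrics from co-registered quantitative maps and
#' a label map: MFF_Intra is the mean PDFF over muscle voxels; fat volumes
#' are PDFF-weighted voxel sums (MFV_Intra over muscle, MFV_Inter over
#' intermuscular fat); MFF_Inter and MFF_Total are referenced to the muscle
#' compartment (muscle plus intermuscular fat); all volumes are scaled by
#' the slab factor `slab_thickness(p) / (n_slices * slice_thickness)` so
#' that they represent the full slab including slice gaps; T1 and R2* are
#' muscle means with `NaN` exclusion.
#'
#' @param maps List with `pdff` (percent), optional `t1_water` (ms) and
#'   `r2star` (1/s) arrays, and `voxel_mm` (length 3).
#' @param labels Integer label array ([label_codes()] values).
#' @param p Protocol supplying the slice prescription.
#' @return An object of class `srcse_composition` (a named list of metrics).
#' @export
compute_composition <- function(maps, labels, p) {
  lc <- label_codes()
  msk_m <- labels == lc[["muscle"]]
  if (!any(msk_m)) stop("degenerate input: no muscle voxels", call. = FALSE)
  msk_i <- labels == lc[["intermuscular_fat"]]
  msk_s <- labels == lc[["subcutaneous_fat"]]
  vvol_ml <- prod(maps$voxel_mm) / 1000
  sf <- slab_thickness(p) / (p$n_slices * p$slice_thickness)
  pd <- maps$pdff / 100
  pd_m <- pd[msk_m]; pd_m <- pd_m[!is.na(pd_m)]
  pd_i <- pd[msk_i]; pd_i <- pd_i[!is.na(pd_i)]
  n_thigh <- sum(labels != lc[["background"]])
  mfv_intra <- sum(pd_m) * vvol_ml * sf
  mfv_inter <- sum(pd_i) * vvol_ml * sf
  compartment_ml <- (sum(msk_m) + sum(msk_i)) * vvol_ml * sf
  mean_or_na <- function(x, m) {
    v <- x[m]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  structure(list(
    scf_ml = sum(msk_s) * vvol_ml * sf,
    muscle_ml = sum(msk_m) * vvol_ml * sf,
    muscle_pct = 100 * sum(msk_m) / n_thigh,
    mfv_intra_ml = mfv_intra,
    mfv_inter_ml = mfv_inter,
    mfv_total_ml = mfv_intra + mfv_inter,
    mff_intra_pct = 100 * mean(pd_m),
    mff_inter_pct = 100 * mfv_inter / compartment_ml,
    mff_total_pct = 100 * (mfv_intra + mfv_inter) / compartment_ml,
    t1_water_ms = if (!is.null(maps$t1_water))
      mean_or_na(maps$t1_water, msk_m) else NA_real_,
    r2star_s1 = if (!is.null(maps$r2star))
      mean_or_na(maps$r2star, msk_m) else NA_real_,
    n_muscle_vox = sum(msk_m), slab_factor = sf),
    class = "srcse_composition")
}

#' @export
as.data.frame.srcse_composition <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' T1 correction of conventional-CSE fat and water images
#'
#' Conventional multi-echo gradient echo carries T1 weighting that inflates
#' the apparent fat signal (fat's short T1 yields more steady-state signal
#' than muscle water at TR 20 ms / 20 degrees). Dividing each compartment
#' image by its spoiled-GRE steady-state yield
#' \eqn{\sin\alpha (1 - E_1)/(1 - \cos\alpha E_1)} restores spin-density
#' proportionality.
#'
#' @param f,w Fat and water images (complex or magnitude).
#' @param p The conventional-CSE protocol (flip and TR are taken from it).
#' @param t1_fat,t1_water Assumed compartment T1s (ms, positive).
#' @return List with corrected `f` and `w` and the `yield` factors used.
#' @export
t1_correct_cse <- function(f, w, p = protocol_preset("cse_conventional"),
                           t1_fat = 370, t1_water = 1400) {
  if (t1_fat <= 0 || t1_water <= 0)
    stop("non-physical T1 inputs", call. = FALSE)
  a <- p$flip_center * pi / 180
  yield <- function(t1) {
    e1 <- exp(-p$tr / t1)
    sin(a) * (1 - e1) / (1 - cos(a) * e1)
  }
  yf <- yield(t1_fat); yw <- yield(t1_water)
  list(f = f / yf, w = w / yw, yield = c(fat = yf, water = yw))
}
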