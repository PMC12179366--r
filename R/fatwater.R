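# Chemical-shift-encoded fat-water separation with joint B0 / R2*
# estimation (variable projection over a candidate grid, seeded
# region-growing field-map smoothness) and PDFF computation.

# weighted design matrix for candidates: columns [water, fat] at decay r2
fw_design <- function(te, c_te, sqrtw, r2) {
  d <- exp(-te * r2 / 1000)
  cbind(d * sqrtw, d * c_te * sqrtw)
}

# orthogonal-complement projector P = I - A (A^H A)^-1 A^H  (nte x nte)
fw_projector <- function(A) {
  G <- Conj(t(A)) %*% A
  diag(nrow(A)) - A %*% solve(G, Conj(t(A)))
}

# parabolic sub-grid refinement around an interior grid minimum
parabolic_min <- function(x0, h, y0, y1, y2) {
  den <- y0 - 2 * y1 + y2
  delta <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (y0 - y2) / den, 0)
  x0 + pmin(pmax(delta, -0.5), 0.5) * h
}

# weighted complex LS solve for (W, F) at fixed b0 (already demodulated) and
# voxelwise r2; vectorized. sd: N x nte demodulated weighted signals.
solve_wf <- function(sd, te, c_te, sqrtw, r2) {
  d <- exp(-outer(r2, te) / 1000)                      # N x nte
  a1 <- sweep(d, 2, sqrtw, `*`)                        # real
  a2 <- sweep(d, 2, sqrtw * c_te, `*`)                 # complex
  g11 <- rowSums(a1^2)
  g12 <- rowSums(a1 * a2)                              # conj(a1) a2, a1 real
  g22 <- rowSums(Mod(a2)^2)
  h1 <- rowSums(a1 * sd)
  h2 <- rowSums(Conj(a2) * sd)
  det <- g11 * g22 - Mod(g12)^2
  W <- (g22 * h1 - g12 * h2) / det
  F <- (g11 * h2 - Conj(g12) * h1) / det
  fit <- a1 * W + a2 * F
  resid <- sqrt(rowSums(Mod(sd - fit)^2))
  list(W = W, F = F, resid = resid)
}

#' Variable-projection residual surface of a single voxel
#'
#' For every (B0, R2*) candidate on a grid, solves the linear fat-water
#' system at the given echo times by complex least squares and records the
#' residual; the global minimum is refined by parabolic interpolation in B0
#' and R2*. Duplicated echo times should be pre-averaged and passed as
#' weights (multiplicity), giving them double least-squares weight.
#'
#' @param signal Complex signal per unique TE.
#' @param te Unique echo times (ms), at least 3, distinct.
#' @param model Fat spectral model.
#' @param b0_grid Field-map candidates (Hz).
#' @param r2_grid R2* candidates (1/s), nonnegative.
#' @param weights Per-TE multiplicity weights (default 1).
#' @param field Field strength (T).
#' @return List with `residual` (length(b0_grid) x length(r2_grid) matrix),
#'   the grids, and `best`: refined `b0`, `r2star`, complex `W`, `F`,
#'   `residual`, and `pdff` (percent).
#' @export
separate_voxel <- function(signal, te, model = default_fat_model(),
                           b0_grid = seq(-600, 600, by = 2),
                           r2_grid = seq(0, 300, by = 2),
                           weights = NULL, field = 2.89) {
  nte <- length(te)
  if (nte < 3L) stop("underdetermined: need at least 3 unique echoes",
                     call. = FALSE)
  if (any(duplicated(te))) stop("echo times must be distinct", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nte)
  sqrtw <- sqrt(weights)
  c_te <- fat_phasor(te, field, model)
  nb <- length(b0_grid); nr <- length(r2_grid)
  # stack transposed projectors so residuals for one b0 come from one GEMV
  tP <- lapply(r2_grid, function(r2) t(fw_projector(fw_design(te, c_te, sqrtw, r2))))
  Pbig <- do.call(cbind, tP)                            # nte x (nr*nte)
  res <- matrix(NA_real_, nb, nr)
  sw <- signal * sqrtw
  for (b in seq_len(nb)) {
    sd <- sw * exp(-2i * pi * b0_grid[b] * te / 1000)
    v <- sd %*% Pbig                                    # 1 x (nr*nte)
    res[b, ] <- colSums(matrix(Mod(v)^2, nte))
  }
  ij <- which(res == min(res), arr.ind = TRUE)[1L, ]
  bi <- ij[1L]; ri <- ij[2L]
  b0_hat <- if (bi > 1L && bi < nb) {
    parabolic_min(b0_grid[bi], b0_grid[2L] - b0_grid[1L],
                  res[bi - 1L, ri], res[bi, ri], res[bi + 1L, ri])
  } else b0_grid[bi]
  r2_hat <- if (ri > 1L && ri < nr) {
    parabolic_min(r2_grid[ri], r2_grid[2L] - r2_grid[1L],
                  res[bi, ri - 1L], res[bi, ri], res[bi, ri + 1L])
  } else r2_grid[ri]
  r2_hat <- max(r2_hat, 0)
  # continuous polish of the grid+parabolic estimate (exactness on
  # noiseless model-matched input)
  obj <- function(par) {
    A <- fw_design(te, c_te, sqrtw, max(par[2L], 0))
    sd <- sw * exp(-2i * pi * par[1L] * te / 1000)
    sum(Mod(fw_projector(A) %*% sd)^2)
  }
  opt <- stats::optim(c(b0_hat, r2_hat), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 500))
  b0_hat <- opt$par[1L]
  r2_hat <- max(opt$par[2L], 0)
  sd <- matrix(sw * exp(-2i * pi * b0_hat * te / 1000), 1L)
  fit <- solve_wf(sd, te, c_te, sqrtw, r2_hat)
  best <- list(b0 = b0_hat, r2star = r2_hat, W = fit$W[1L], F = fit$F[1L],
               residual = fit$resid[1L],
               pdff = 100 * Mod(fit$F[1L]) /
                 (Mod(fit$F[1L]) + Mod(fit$W[1L])))
  list(residual = res, b0_grid = b0_grid, r2_grid = r2_grid, best = best)
}

default_separation_opts <- function() {
  list(b0_range = 600, b0_step = 2, r2_max = 300, r2_coarse_step = 50,
       r2_step = 2, max_jump_hz = 60, floor = NULL)
}

#' Separate a multi-echo SR-CSE stack into water and fat
#'
#' B0 and R2* are estimated once from the unprepared series (higher SNR):
#' a coarse variable-projection residual profile over the B0 candidate grid
#' (minimized over a coarse R2* set) is computed per voxel, the field map is
#' resolved by seeded region growing from the most reliable voxel with
#' neighbouring voxels restricted to a +/- `max_jump_hz` window (penalizing
#' water-fat-swap jumps), B0 is refined by parabolic interpolation, R2* by a
#' fine 1-D grid with parabolic refinement. The same (B0, R2*) maps then
#' resolve water and fat by weighted complex least squares for both the
#' unprepared and prepared series, which therefore share bitwise-identical
#' field and R2* maps.
#'
#' @param stack An `srcse_stack` containing unprepared and prepared series.
#' @param model Fat spectral model.
#' @param opts List overriding `default_separation_opts()`: `b0_range`,
#'   `b0_step` (Hz), `r2_max`, `r2_coarse_step`, `r2_step` (1/s),
#'   `max_jump_hz`, `floor` (signal units; default 5x the median background
#'   magnitude).
#' @return An object of class `srcse_separation`: complex `water` and `fat`
#'   map lists (`$unprep`, `$prep`), `b0_map` (Hz), `r2star_map` (1/s),
#'   `residual_map`, logical `mask`, `floor`, `protocol`, `voxel_mm`.
#' @export
separate_stack <- function(stack, model = default_fat_model(), opts = list()) {
  stopifnot(inherits(stack, "srcse_stack"))
  o <- utils::modifyList(default_separation_opts(), opts)
  te <- stack$te
  w <- stack$te_weights
  sqrtw <- sqrt(w)
  field <- stack$protocol$field_strength
  c_te <- fat_phasor(te, field, model)
  dims <- dim(stack$data)[1:3]
  nte <- length(te)
  nvox <- prod(dims)
  Su <- matrix(stack$data[, , , , 1L], nvox, nte)
  Sp <- matrix(stack$data[, , , , 2L], nvox, nte)
  energy <- sqrt(rowSums(Mod(Su)^2))
  if (!any(energy > 0)) stop("degenerate input: all-zero stack", call. = FALSE)
  floor_ <- o$floor
  if (is.null(floor_)) {
    lo <- energy[energy <= 0.25 * stats::quantile(energy, 0.99)]
    bg <- if (length(lo)) stats::median(lo) else 0
    floor_ <- max(5 * bg, 0.02 * stats::quantile(energy, 0.95))
  }
  mask <- energy > floor_
  if (!any(mask)) stop("degenerate input: no voxels above the signal floor",
                       call. = FALSE)
  idx <- which(mask)
  N <- length(idx)
  Suw <- sweep(Su[idx, , drop = FALSE], 2, sqrtw, `*`)
  B <- seq(-o$b0_range, o$b0_range, by = o$b0_step)
  nb <- length(B)
  r2c <- seq(0, o$r2_max, by = o$r2_coarse_step)
  tPc <- lapply(r2c, function(r2) t(fw_projector(fw_design(te, c_te, sqrtw, r2))))
  profile <- matrix(Inf, N, nb)
  for (b in seq_len(nb)) {
    ph <- exp(-2i * pi * B[b] * te / 1000)
    Sd <- sweep(Suw, 2, ph, `*`)
    for (tp in tPc) {
      r <- rowSums(Mod(Sd %*% tp)^2)
      lower <- r < profile[, b]
      profile[lower, b] <- r[lower]
    }
  }
  b0i <- grow_field_map(profile, B, idx, dims, energy[idx], o$max_jump_hz)
  # parabolic B0 refinement where the minimum is interior
  b0_v <- B[b0i]
  interior <- b0i > 1L & b0i < nb
  if (any(interior)) {
    ii <- which(interior)
    y0 <- profile[cbind(ii, b0i[ii] - 1L)]
    y1 <- profile[cbind(ii, b0i[ii])]
    y2 <- profile[cbind(ii, b0i[ii] + 1L)]
    b0_v[ii] <- parabolic_min(B[b0i[ii]], o$b0_step, y0, y1, y2)
  }
  # fine R2* search at the refined per-voxel B0
  Sd <- Suw * exp(-2i * pi * outer(b0_v, te) / 1000)
  r2f <- seq(0, o$r2_max, by = o$r2_step)
  nr <- length(r2f)
  resM <- matrix(NA_real_, N, nr)
  for (r in seq_len(nr)) {
    tp <- t(fw_projector(fw_design(te, c_te, sqrtw, r2f[r])))
    resM[, r] <- rowSums(Mod(Sd %*% tp)^2)
  }
  r2j <- max.col(-resM, ties.method = "first")
  r2_v <- r2f[r2j]
  interior <- r2j > 1L & r2j < nr
  if (any(interior)) {
    ii <- which(interior)
    y0 <- resM[cbind(ii, r2j[ii] - 1L)]
    y1 <- resM[cbind(ii, r2j[ii])]
    y2 <- resM[cbind(ii, r2j[ii] + 1L)]
    r2_v[ii] <- pmax(parabolic_min(r2f[r2j[ii]], o$r2_step, y0, y1, y2), 0)
  }
  fit_u <- solve_wf(Sd, te, c_te, sqrtw, r2_v)
  Spd <- sweep(Sp[idx, , drop = FALSE], 2, sqrtw, `*`) *
    exp(-2i * pi * outer(b0_v, te) / 1000)
  fit_p <- solve_wf(Spd, te, c_te, sqrtw, r2_v)
  as_map <- function(vals, complex = FALSE) {
    m <- array(if (complex) NA_complex_ else NA_real_, dims)
    m[idx] <- vals
    m
  }
  structure(list(
    water = list(unprep = as_map(fit_u$W, TRUE), prep = as_map(fit_p$W, TRUE)),
    fat = list(unprep = as_map(fit_u$F, TRUE), prep = as_map(fit_p$F, TRUE)),
    b0_map = as_map(b0_v), r2star_map = as_map(r2_v),
    residual_map = as_map(fit_u$resid),
    mask = array(mask, dims), floor = floor_,
    protocol = stack$protocol, voxel_mm = stack$voxel_mm),
    class = "srcse_separation")
}

# Seeded region growing of the field map. profile: N x nb residual profiles
# (masked voxels); returns the chosen b0 grid index per voxel. Each
# component is seeded at its highest-energy voxel with the global residual
# minimum; neighbours take the best candidate within max_jump of the voxel
# they were reached from.
grow_field_map <- function(profile, B, idx, dims, energy, max_jump) {
  N <- nrow(profile)
  nb <- length(B)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  pos <- arrayInd(idx, dims)
  vox_of <- array(0L, dims)
  vox_of[idx] <- seq_len(N)
  b0i <- integer(N)
  visited <- logical(N)
  queue <- integer(N)
  ord <- order(-energy)
  for (s in ord) {
    if (visited[s]) next
    b0i[s] <- which.min(profile[s, ])
    visited[s] <- TRUE
    queue[1L] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      ref <- B[b0i[v]]
      win <- which(abs(B - ref) <= max_jump)
      x <- pos[v, 1L]; y <- pos[v, 2L]; z <- pos[v, 3L]
      for (d in 1:6) {
        xx <- x + (d == 1L) - (d == 2L)
        yy <- y + (d == 3L) - (d == 4L)
        zz <- z + (d == 5L) - (d == 6L)
        if (xx < 1L || xx > nx || yy < 1L || yy > ny || zz < 1L || zz > nz)
          next
        u <- vox_of[xx, yy, zz]
        if (u == 0L || visited[u]) next
        b0i[u] <- win[which.min(profile[u, win])]
        visited[u] <- TRUE
        tail <- tail + 1L
        queue[tail] <- u
      }
    }
  }
  b0i
}

#' Compute a PDFF map from a separation result
#'
#' PDFF = 100 f / (f + w) from the unprepared (spin-density weighted)
#' series, set to `NaN` where the combined signal falls below the floor and
#' clipped to [0, 100]. The default combination is phase-consistent: both
#' compartments are rotated by the phase of their sum and the real parts
#' are used, which keeps PDFF unbiased in noise at low fat fractions;
#' `combine = "magnitude"` uses |W| and |F| instead (positively biased at
#' low FF at finite SNR). Optional per-compartment yield factors (see
#' [readout_yield_factors()]) are divided out first to remove the residual
#' T1-weighting of the ramped readout.
#'
#' @param res An `srcse_separation`.
#' @param floor Signal floor on w + f (signal units); defaults to the
#'   separation mask (voxels outside it are `NaN`).
#' @param yields Optional named vector `c(water =, fat =)`.
#' @param series `"unprep"` (default) or `"prep"`.
#' @param combine `"real"` (phase-consistent, default) or `"magnitude"`.
#' @return Numeric array of PDFF in percent, bounded in [0, 100].
#' @export
compute_pdff <- function(res, floor = NULL, yields = NULL,
                         series = c("unprep", "prep"),
                         combine = c("real", "magnitude")) {
  stopifnot(inherits(res, "srcse_separation"))
  series <- match.arg(series)
  combine <- match.arg(combine)
  W <- res$water[[series]]
  F <- res$fat[[series]]
  if (combine == "real") {
    ph <- exp(-1i * Arg(W + F))
    w <- Re(W * ph)
    f <- Re(F * ph)
  } else {
    w <- Mod(W)
    f <- Mod(F)
  }
  if (!is.null(yields)) {
    w <- w / yields[["water"]]
    f <- f / yields[["fat"]]
  }
  tot <- w + f
  pdff <- pmin(pmax(100 * f / tot, 0), 100)
  dim(pdff) <- dim(w)
  pdff[!res$mask] <- NaN
  if (!is.null(floor)) pdff[tot < floor] <- NaN
  pdff
}
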