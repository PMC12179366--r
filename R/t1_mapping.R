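# Water-specific T1 via Bloch-simulation lookup table; MOLLI/SASHA
# recovery-curve fitting; fat-related T1-bias modelling.

#' Build the saturation-recovery lookup table
#'
#' For every T1 on the grid the prepared/unprepared central-line signal
#' ratio of a pure-water voxel is computed with the full line-by-line Bloch
#' simulation of the ramped single-shot train, so readout-history effects
#' are baked into the inversion. The ratio must be strictly monotone
#' (decreasing) in T1; a fingerprint binds the table to its protocol.
#'
#' @param p An SR-CSE `srcse_protocol`.
#' @param t1_grid T1 grid in ms (ascending; default 100-5000 ms, 1 ms step).
#' @param ramp Optional flip-ramp override (must then also be used when
#'   simulating the data to be inverted).
#' @return An object of class `srcse_lut`: `t1_grid`, `ratio_grid`,
#'   `fingerprint`.
#' @export
build_lookup <- function(p, t1_grid = seq(100, 5000, by = 1), ramp = NULL) {
  validate_protocol(p)
  if (is.unsorted(t1_grid, strictly = TRUE))
    stop("t1_grid must be strictly ascending", call. = FALSE)
  if (is.null(ramp)) ramp <- build_flip_ramp(p)
  mz_p <- srcse_mz_center(t1_grid, p, ramp, prepared = TRUE)
  mz_u <- srcse_mz_center(t1_grid, p, ramp, prepared = FALSE)
  ratio <- mz_p / mz_u
  if (any(diff(ratio) >= 0))
    stop("lookup build error: signal ratio not strictly monotone in T1",
         call. = FALSE)
  structure(list(t1_grid = t1_grid, ratio_grid = ratio,
                 fingerprint = protocol_fingerprint(p)),
            class = "srcse_lut")
}

#' Estimate water T1 from prepared and unprepared water images
#'
#' Per voxel the magnitude ratio |W_prepared| / |W_unprepared| is inverted
#' through the lookup table by linear interpolation; ratios outside the
#' table range give `NaN` (never clamped, so out-of-range biases stay
#' visible).
#'
#' @param w_prepared,w_unprepared Co-registered water maps (complex or
#'   magnitude arrays of identical dimension).
#' @param lut An `srcse_lut`.
#' @param protocol Optional protocol; if given, its fingerprint must match
#'   the table's.
#' @return Array of T1 in ms (`NaN` outside the table range or where the
#'   input is missing).
#' @export
estimate_t1water <- function(w_prepared, w_unprepared, lut, protocol = NULL) {
  stopifnot(inherits(lut, "srcse_lut"))
  if (!is.null(protocol) &&
      !identical(protocol_fingerprint(protocol), lut$fingerprint))
    stop("protocol mismatch: lookup table was built for a different protocol",
         call. = FALSE)
  if (!identical(dim(w_prepared), dim(w_unprepared)) &&
      !(is.null(dim(w_prepared)) && is.null(dim(w_unprepared)) &&
        length(w_prepared) == length(w_unprepared)))
    stop("maps must share dimensions", call. = FALSE)
  ratio <- Mod(w_prepared) / Mod(w_unprepared)
  # ratio decreases with T1: interpolate on the reversed (ascending) grid
  t1 <- stats::approx(x = rev(lut$ratio_grid), y = rev(lut$t1_grid),
                      xout = as.vector(ratio), rule = 1)$y
  t1[is.na(t1)] <- NaN
  out <- array(t1, dim = if (is.null(dim(w_prepared)))
    length(w_prepared) else dim(w_prepared))
  if (is.null(dim(w_prepared))) out <- as.vector(out)
  out
}

t1_fit_result <- function(t1, A, B, residual, ok) {
  structure(list(t1 = t1, A = A, B = B, residual = residual, ok = ok),
            class = "srcse_t1fit")
}

#' Fit a MOLLI inversion-recovery curve
#'
#' Fits the three-parameter model |A - B exp(-t/T1*)| to magnitude samples
#' by nonlinear least squares with polarity restoration (every initial-sign
#' split is tried and the best fit kept), then applies the Look-Locker
#' correction T1 = T1* (B/A - 1).
#'
#' @param t_inv Times since inversion (ms), at least 4.
#' @param signal Complex or magnitude samples.
#' @return An `srcse_t1fit` with `t1` (ms, `NaN` on failure), `A`, `B`,
#'   `residual` (rms), `ok`.
#' @export
fit_molli <- function(t_inv, signal) {
  if (length(t_inv) < 4L) stop("need at least 4 samples", call. = FALSE)
  o <- order(t_inv)
  t <- t_inv[o]
  y_abs <- Mod(signal)[o]
  if (stats::sd(y_abs) < 1e-12 * max(abs(y_abs), 1)) {
    return(t1_fit_result(NaN, mean(y_abs), 0, 0, FALSE))  # degenerate: flat
  }
  best <- NULL
  for (nflip in 0:length(t)) {
    y <- y_abs * c(rep(-1, nflip), rep(1, length(t) - nflip))
    a0 <- max(y)
    b0 <- a0 - min(y)
    t10 <- max(stats::median(t), 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A - B * exp(-t / T1s),
                        start = list(A = a0, B = b0, T1s = t10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(t1_fit_result(NaN, NA_real_, NA_real_, NA_real_, FALSE))
  cf <- stats::coef(best$fit)
  if (cf[["A"]] <= 0 || cf[["B"]] <= 0 || cf[["T1s"]] <= 0)
    return(t1_fit_result(NaN, cf[["A"]], cf[["B"]], sqrt(best$rss / length(t)), FALSE))
  t1 <- cf[["T1s"]] * (cf[["B"]] / cf[["A"]] - 1)
  t1_fit_result(t1, cf[["A"]], cf[["B"]], sqrt(best$rss / length(t)), TRUE)
}

#' Fit a SASHA saturation-recovery curve
#'
#' Fits the two-parameter model S(t) = A (1 - exp(-t/T1)) by nonlinear least
#' squares; the unprepared anchor enters as `t = Inf`. Fits whose T1
#' standard error exceeds the estimate are flagged as ill-conditioned.
#'
#' @param sat_time Saturation times (ms); may include `Inf` for the anchor.
#' @param signal Complex or magnitude samples.
#' @return An `srcse_t1fit` (`B` is `NA`; the model has no offset term).
#' @export
fit_sasha <- function(sat_time, signal) {
  if (length(sat_time) < 3L) stop("need at least 3 samples", call. = FALSE)
  y <- Mod(signal)
  t <- sat_time
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-t / T1)),
                      start = list(A = a0, T1 = max(stats::median(t[is.finite(t)]), 1)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(t1_fit_result(NaN, NA_real_, NA_real_, NA_real_, FALSE))
  cf <- stats::coef(fit)
  rms <- sqrt(mean(stats::resid(fit)^2))
  se <- tryCatch(summary(fit)$coefficients["T1", "Std. Error"],
                 error = function(e) Inf)
  ok <- is.finite(cf[["T1"]]) && cf[["T1"]] > 0 &&
    is.finite(se) && se < abs(cf[["T1"]])
  t1_fit_result(if (cf[["T1"]] > 0) cf[["T1"]] else NaN,
                cf[["A"]], NA_real_, rms, ok)
}

#' Linear fat-bias model between two T1 methods
#'
#' Ordinary least squares of the per-ROI T1 difference (method minus
#' reference) on the ROI fat fraction: slope in ms per %FF, intercept in ms
#' (the constant bias), and R-squared.
#'
#' @param t1_method,t1_ref Paired ROI T1 values (ms), length >= 3.
#' @param ff ROI fat fractions (percent), same length, non-constant.
#' @return An object of class `srcse_bias_model`: `slope`, `intercept`,
#'   `r_squared`, `n_rois`, and the underlying `lm` fit.
#' @export
fit_bias_model <- function(t1_method, t1_ref, ff) {
  n <- length(ff)
  if (length(t1_method) != n || length(t1_ref) != n || n < 3L)
    stop("inputs must be equal length >= 3", call. = FALSE)
  if (stats::sd(ff) == 0)
    stop("rank error: fat fraction has zero variance", call. = FALSE)
  d <- t1_method - t1_ref
  fit <- stats::lm(d ~ ff)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n_rois = n, fit = fit),
            class = "srcse_bias_model")
}

#' Deterministic circular ROI sampling of a map
#'
#' Places `n` circular ROIs at seed-reproducible positions inside a mask and
#' returns the ROI means of each supplied map. Used to emulate ROI-based
#' method comparison on synthetic maps.
#'
#' @param maps Named list of arrays sharing one grid.
#' @param mask Logical array of candidate centre voxels.
#' @param n Number of ROIs.
#' @param radius_vox ROI radius in voxels.
#' @param seed Integer seed.
#' @return Data.frame with `roi`, centre coordinates, and one column of ROI
#'   means per map.
#' @export
sample_rois <- function(maps, mask, n, radius_vox = 2, seed = 1L) {
  dims <- dim(mask)
  set.seed(as.integer(seed))
  cand <- which(mask)
  if (length(cand) < n) stop("mask too small for requested ROIs", call. = FALSE)
  centers <- sample(cand, n)
  pos <- arrayInd(centers, dims)
  out <- data.frame(roi = seq_len(n), x = pos[, 1L], y = pos[, 2L],
                    z = if (ncol(pos) >= 3L) pos[, 3L] else 1L)
  xg <- matrix(rep(seq_len(dims[1L]), dims[2L]), dims[1L])
  yg <- matrix(rep(seq_len(dims[2L]), each = dims[1L]), dims[1L])
  for (nm in names(maps)) out[[nm]] <- NA_real_
  for (i in seq_len(n)) {
    disk <- (xg - out$x[i])^2 + (yg - out$y[i])^2 <= radius_vox^2
    for (nm in names(maps)) {
      m <- maps[[nm]]
      sl <- if (length(dims) >= 3L && !is.na(dim(m)[3L]) && length(dim(m)) >= 3L)
        m[, , out$z[i]] else m
      out[[nm]][i] <- mean(sl[disk], na.rm = TRUE)
    }
  }
  out
}
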