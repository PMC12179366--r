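# Multi-peak fat spectral model and its complex chemical-shift phasor.

GYROMAGNETIC_MHZ_PER_T <- 42.5764

#' Construct a fat spectral model
#'
#' Peak offsets are stored in ppm relative to water; weights are normalized
#' to sum to one (the raw weights are kept as an attribute).
#'
#' @param peak_offsets_ppm Chemical-shift offsets relative to water (ppm).
#' @param relative_weights Nonnegative relative peak weights, same length.
#' @return An object of class `srcse_fat_model`.
#' @export
fat_spectral_model <- function(peak_offsets_ppm, relative_weights) {
  if (length(peak_offsets_ppm) != length(relative_weights))
    stop("offsets and weights must have the same length", call. = FALSE)
  if (any(relative_weights < 0) || !all(is.finite(peak_offsets_ppm)) ||
      !all(is.finite(relative_weights)))
    stop("weights must be nonnegative and offsets finite", call. = FALSE)
  s <- sum(relative_weights)
  if (s <= 0) stop("weights must not all be zero", call. = FALSE)
  structure(list(peak_offsets_ppm = as.numeric(peak_offsets_ppm),
                 relative_weights = as.numeric(relative_weights) / s),
            raw_weights = as.numeric(relative_weights),
            class = "srcse_fat_model")
}

#' The default six-peak fat model
#'
#' Peak locations relative to water at 3.73, 3.33, 2.52, 1.93, 0.383 and
#' -0.67 ppm with relative weights 0.0870, 0.693, 0.1280, 0.0040, 0.0390 and
#' 0.0480 (normalized internally).
#'
#' @return An `srcse_fat_model`.
#' @export
default_fat_model <- function() {
  fat_spectral_model(
    peak_offsets_ppm = c(3.73, 3.33, 2.52, 1.93, 0.383, -0.67),
    relative_weights = c(0.0870, 0.693, 0.1280, 0.0040, 0.0390, 0.0480))
}

#' Peak frequencies of a fat model at a given field strength
#'
#' @param model An `srcse_fat_model`.
#' @param b0 Field strength (T).
#' @return Frequencies in Hz (gyromagnetic ratio 42.5764 MHz/T).
#' @export
fat_peak_frequencies <- function(model, b0) {
  model$peak_offsets_ppm * GYROMAGNETIC_MHZ_PER_T * b0
}

#' Complex fat phasor at given echo times
#'
#' Returns \eqn{\sum_p w_p \exp(i 2\pi f_p TE / 1000)} with \eqn{f_p} the
#' peak frequency in Hz and TE in ms. With normalized weights the phasor is
#' exactly 1 at TE = 0 and its magnitude never exceeds 1.
#'
#' @param te Echo time(s) in ms.
#' @param b0 Field strength (T).
#' @param model An `srcse_fat_model` (default: six-peak model).
#' @return Complex vector, one value per TE.
#' @export
fat_phasor <- function(te, b0, model = default_fat_model()) {
  if (any(te < 0)) stop("te must be nonnegative", call. = FALSE)
  f <- fat_peak_frequencies(model, b0)                       # Hz
  ph <- outer(te / 1000, f)                                  # s * Hz
  as.vector(exp(2i * pi * ph) %*% model$relative_weights)
}
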