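# Shared fixtures: protocols, degenerate readout, tiny phantoms.

thigh_protocol <- function() protocol_preset("srcse_thigh")

# one-line readout: the central line is the only excitation, so the
# prepared/unprepared ratio equals the closed-form saturation recovery
degenerate_protocol <- function(sat_time = 1537.2) {
  srcse_protocol(field_strength = 2.89, te_first_pair = c(2.51, 4.79),
                 te_increment = 1.14, n_te_shifts = 3L, tr = 10.98,
                 n_kspace_lines = 1L, center_line_index = 0L,
                 flip_center = 30, sat_time_center = sat_time,
                 slice_thickness = 3.5, n_slices = 1L)
}

# forward model of a single model-matched voxel (no readout history):
# s(te) = (W + F c(te)) exp(i 2 pi b0 te) exp(-r2* te)
forward_voxel_signal <- function(W, F, b0_hz, r2star, te, field = 2.89,
                                 model = default_fat_model()) {
  (W + F * fat_phasor(te, field, model)) *
    exp(2i * pi * b0_hz * te / 1000) * exp(-te * r2star / 1000)
}

small_thigh <- function(seed = 7, n_slices = 1L, ...) {
  make_thigh_phantom(matrix_size = c(64L, 32L), n_slices = n_slices,
                     seed = seed, ...)
}

# protocol whose slice prescription matches a phantom (slab arithmetic)
match_slices <- function(p, phantom) {
  p$n_slices <- dim(phantom$labels)[3L]
  p$slice_thickness <- phantom$slice_thickness
  p$slice_gap <- phantom$slice_gap
  p
}
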