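# Shared fixtures: the anchor parameter set of the published studies
# (phi = pi/6, d1 = 0.2, F = 0.3, d2 = 0.6, L1 = L2 = 0.2, M = 2, Q = 0.1,
# r0 = 0.2) and single-lesion variants.

caption_forces <- function() force_field(M = 2, F_grav = 0.3, phi = pi / 6)

two_lesion_geometry <- function(delta1 = 0.1, delta2 = 0.1) {
  vessel_geometry(list(
    abnormal_segment(delta1, 0.2, 0.2, "stenosis"),
    abnormal_segment(delta2, 0.2, 0.6, "dilatation")
  ))
}

stenosis_only_config <- function(height = 0.1) {
  cfg <- default_config()
  cfg$geometry$segments[[1]]$height <- height
  cfg$geometry$segments[[2]]$height <- 0
  cfg
}

dilatation_only_config <- function(height = 0.1) {
  cfg <- default_config()
  cfg$geometry$segments[[1]]$height <- 0
  cfg$geometry$segments[[2]]$height <- height
  cfg
}

# Grid used by the brute-force verifiers
verification_grid <- function() {
  expand.grid(H = c(0.7, 0.85, 1.0, 1.1),
              r0 = c(0, 0.1, 0.2, 0.3),
              drive = c(0.5, 1, 2))
}
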