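# Deterministic response rules used across staircase tests.

# Always correct strictly above a boundary expressed in signal elements.
step_observer <- function(threshold_elements, total_elements) {
  function(coherence_pct) coherence_pct > 100 * threshold_elements /
    total_elements
}

# Per-update displacements of a frame sequence, unwrapped to the torus.
displacements <- function(seq) {
  w <- seq$geometry$window_width_deg
  h <- seq$geometry$window_height_deg
  lapply(seq_len(seq$n_images - 1L), function(u) {
    cbind(
      cohermetrics:::unwrap_displacement(
        seq$frames[[u + 1L]][, 1] - seq$frames[[u]][, 1], w),
      cohermetrics:::unwrap_displacement(
        seq$frames[[u + 1L]][, 2] - seq$frames[[u]][, 2], h))
  })
}
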