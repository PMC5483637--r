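# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# 0/1 labels in the study's composition (positive class first).
study_labels <- function(n_ms = 10L, n_hc = 13L) {
  c(rep(1L, n_ms), rep(0L, n_hc))
}

# A small grid shared by imaging tests.
tiny_dims <- c(6L, 6L, 3L)

# Uniform-truth participant: task + gas runs with known fractional changes.
uniform_participant <- function(delta_bold = 0.0118, delta_cbf = 0.9268,
                                m = 0.0511, dims = tiny_dims, snr = Inf,
                                seed = 1L, design = task_design(seed = 5L)) {
  list(
    task = make_task_run(delta_bold, delta_cbf, design = design, dims = dims,
                         snr = snr, seed = seed),
    gas = make_gas_run(m = m, delta_cbf_hc = 1.5, dims = dims, snr = snr,
                       seed = seed + 1000L),
    gm = array(0.9, dims),
    occ = array(TRUE, dims),
    truth = list(delta_bold = delta_bold, delta_cbf = delta_cbf, m = m)
  )
}

# A perfectly separated predictor on the study's group sizes whose
# leave-one-out boundaries never coincide with a held-out point.
separated_predictor <- function() {
  c(1:10, 13.5 + 0:12)
}

# Five countable lesions (>= 3 voxels at 1 mm^3) plus one 2 mm^3 decoy.
phantom_spec <- function() {
  list(
    list(center = c(10, 10, 4), voxels = 5L),
    list(center = c(22, 8, 3), voxels = 8L),
    list(center = c(8, 22, 5), voxels = 3L),
    list(center = c(22, 22, 5), voxels = 12L),
    list(center = c(16, 16, 6), voxels = 6L),
    list(center = c(12, 25, 4), voxels = 2L)  # below the 3 mm^3 rule
  )
}
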