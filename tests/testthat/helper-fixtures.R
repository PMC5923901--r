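# Shared small fixtures, all generated in code.

# Coarse parameter grid for exhaustive round-trip tests.
coarse_grid <- function() {
  parameter_grid(t1_ms = seq(200, 2000, by = 200),
                 t2star_ms = seq(20, 120, by = 20),
                 b1 = c(0.8, 1, 1.2))
}

# Single-slice timeline with n uniformly spaced readouts of the default trains.
uniform_timeline <- function(n = 24, duration_ms = 5000, overhead_ms = 80,
                             id = sprintf("fix-n%d-d%g", n, duration_ms)) {
  pat <- interpolate_patterns(default_patterns(), n)
  slice_timeline(allocate_event_times(n, duration_ms, overhead_ms),
                 pat$te_ms, pat$flip_deg, timeline_id = id)
}

# Brain phantom whose tissue parameters and B1 field lie exactly on the
# default dictionary grids, so noiseless matching must recover them exactly.
grid_valued_brain <- function(shape = c(32, 32), n_slices = 1, seed = 1L,
                              noise_sigma = 0) {
  ph <- make_digital_brain(shape, n_slices = n_slices, seed = seed,
                           noise_sigma = noise_sigma)
  ph$tissue_table$t1_ms <- c(750, 1200, 4000, 1290)
  ph$tissue_table$t2star_ms <- c(56, 52, 200, 96)
  b1g <- default_b1_grid()
  ph$b1_field[] <- b1g[pmax(1, findInterval(ph$b1_field, b1g - 0.05))]
  ph
}
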