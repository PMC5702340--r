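# Shared fixtures.  Everything is generated in code; heavyweight objects are
# cached for the session via the package-level caches.

# control steady state at the default pacing protocol (cached after first use)
qq_steady_state <- function() {
  control_steady_state(tol = 1e-6, max_beats = 1500)
}

# bepridil-like published binding parameters (ground truth for fixtures)
qq_bepridil <- function() {
  b <- herg_binding_table()
  b <- b[b$drug == "bepridil", ]
  binding_from_log10(b$log10_Kmax, b$log10_EC50n, b$n, b$log10_Ku,
                     b$Vhalftrap)
}

# coarse-grid Milnes protocol used by fitting fixtures (100 ms measurement
# grid keeps CMA-ES/bootstrap affordable; the model is exact on any grid)
qq_protocol <- function(grid_ms = 100) {
  milnes_protocol(grid_ms = grid_ms)
}

# small noiseless linear-regime dataset + mean response
qq_noiseless_linear <- function() {
  spec <- synthetic_drug_spec("bep0", qq_bepridil(), cmax = 100,
                              milnes_conc = c(50, 100, 200, 300),
                              cells_per_conc = 1,
                              trace_sd = 0, cell_scale_sd = 0)
  ds <- make_synthetic_milnes(spec, seed = 1, protocol = qq_protocol())
  list(spec = spec, ds = ds, ybar = mean_response(ds))
}

# triangular action potential trace: rest -88, peak +40 at t_peak, linear
# repolarization back to rest by t_end, 1 ms grid over [0, cl]
qq_triangle_ap <- function(cl = 2000, t_peak = 5, t_end = 400,
                           v_rest = -88, v_peak = 40) {
  t <- seq(0, cl, by = 1)
  v <- ifelse(t <= t_peak, v_rest + (v_peak - v_rest) * t / t_peak,
       ifelse(t <= t_end,
              v_peak - (v_peak - v_rest) * (t - t_peak) / (t_end - t_peak),
              v_rest))
  list(time_ms = t, vm = v)
}
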