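# Synthetic-data generators: exactness at zero noise, seeding, statistical
# structure, fixture panels.

test_that("zero-noise Milnes generation equals the model prediction", {
  spec <- synthetic_drug_spec("z", qq_bepridil(), cmax = 100,
                              milnes_conc = c(100, 300), cells_per_conc = 2,
                              trace_sd = 0, cell_scale_sd = 0)
  prot <- qq_protocol()
  ds <- make_synthetic_milnes(spec, seed = 9, protocol = prot)
  truth <- simulate_milnes(qq_bepridil(), prot, 300)
  idx <- which(ds$conc == 300)
  for (i in idx) expect_equal(ds$traces[[i]], truth$frac)
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- synthetic_drug_spec("p", qq_bepridil(), cmax = 100,
                              milnes_conc = c(100, 300), cells_per_conc = 3)
  prot <- qq_protocol()
  d1 <- make_synthetic_milnes(spec, seed = 5, protocol = prot)
  d2 <- make_synthetic_milnes(spec, seed = 5, protocol = prot)
  expect_identical(d1$traces, d2$traces)
  d3 <- make_synthetic_milnes(spec, seed = 6, protocol = prot)
  expect_false(identical(d1$traces, d3$traces))
  p1 <- make_synthetic_doseresponse(
    synthetic_drug_spec("p", qq_bepridil(),
                        hill = list(ICaL = hill_params(6, 1)), cmax = 1000),
    "ICaL", 7)
  p2 <- make_synthetic_doseresponse(
    synthetic_drug_spec("p", qq_bepridil(),
                        hill = list(ICaL = hill_params(6, 1)), cmax = 1000),
    "ICaL", 7)
  expect_identical(p1, p2)
})

test_that("the mean response converges to truth as cells increase
           (law of large numbers)", {
  prot <- qq_protocol(grid_ms = 500)
  truth <- simulate_milnes(qq_bepridil(), prot, 300)$frac
  err <- vapply(c(4, 16, 64), function(nc) {
    spec <- synthetic_drug_spec("l", qq_bepridil(), cmax = 100,
                                milnes_conc = 300, cells_per_conc = nc)
    ds <- make_synthetic_milnes(spec, seed = nc, protocol = prot)
    mr <- mean_response(ds)
    sqrt(mean((mr$mean[[1]] - truth)^2))
  }, 0)
  expect_true(all(diff(err) < 0))
  # roughly 1/sqrt(n): from 4 to 64 cells the error should drop ~4x
  expect_lt(err[3], err[1] / 2)
})

test_that("zero-noise dose-response is exact and round-trips through the
           NLS fit", {
  hp <- hill_params(6, 1)
  spec <- synthetic_drug_spec("r", qq_bepridil(),
                              hill = list(INaL = hp),
                              cmax = hill_ic50(hp),
                              dr_conc = hill_ic50(hp) * c(0.11, 0.33, 1, 3, 9),
                              dr_sd = 0)
  pts <- make_synthetic_doseresponse(spec, "INaL", 1)
  at_ic50 <- pts$block[abs(pts$conc - hill_ic50(hp)) < 1e-9]
  expect_true(all(at_ic50 == 50))
  fit <- fit_hill_nls(pts)
  expect_equal(fit$pIC50, 6, tolerance = 1e-3)
  expect_equal(fit$h, 1, tolerance = 1e-3)
  expect_error(make_synthetic_doseresponse(spec, "IKs", 1), "null effect")
})

test_that("fixture panels have the documented structure and ground truths", {
  p12 <- fixture_panel("training12-like")
  expect_length(p12, 12)
  expect_equal(binding_rate_emax(p12$bepridil$binding, 300), 7.98,
               tolerance = 0.002)
  labs <- risk_labels()
  expect_equal(unname(vapply(p12, `[[`, integer(1), "category")[labs$drug]),
               labs$category)
  # null effects mirror the published N/A pairs (e.g. bepridil IK1)
  expect_null(p12$bepridil$hill$IK1)
  expect_s3_class(p12$bepridil$hill$ICaL, "hill_params")
  s9 <- fixture_panel("separable9")
  expect_length(s9, 9)
  expect_equal(sort(unname(vapply(s9, `[[`, integer(1), "category"))),
               rep(0:2, each = 3))
  pn <- fixture_panel("null")
  expect_true(all(vapply(pn, function(s) s$binding$Kmax == 0, logical(1))))
  expect_error(fixture_panel("bogus"))
})

test_that("null-panel drugs reproduce the control qNet when propagated", {
  ss <- qq_steady_state()
  pn <- fixture_panel("null")
  s <- drug_effect_sample(pn[[1]]$binding, pn[[1]]$hill, pn[[1]]$cmax,
                          drug = pn[[1]]$name)
  r <- run_drug_simulation(s, 1, beats = 3, analysis_beats = 1,
                           steady_state = ss)
  init <- ss; init[["qNet"]] <- 0
  ctrl <- run_pacing(init, pacing_protocol(beats = 3), keep_beats = 1, dt = 1)
  expect_equal(r$qnet, compute_qnet(ctrl$beats[[1]], cl = 2000),
               tolerance = 1e-9)
})

test_that("synthetic uncertainty inputs have the documented shape and
           center on the truth", {
  spec <- fixture_panel("separable9")$int2
  inp <- synthetic_uncertainty_inputs(spec, 200, seed = 3)
  expect_equal(dim(inp$herg), c(200, 5))
  expect_equal(mean(inp$herg[, "log10_Ku"]), log10(spec$binding$Ku),
               tolerance = 0.01)
  i1 <- synthetic_uncertainty_inputs(spec, 10, seed = 4)
  i2 <- synthetic_uncertainty_inputs(spec, 10, seed = 4)
  expect_identical(i1, i2)
})
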