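# Beat classification, qNet computation, beat selection, drug simulation.

test_that("classify_beat applies the depolarization and EAD rules on
           constructed traces", {
  # never exceeds 0 mV: excluded, no EAD evaluation
  t <- seq(0, 2000, by = 1)
  v_low <- rep(-88, length(t)); v_low[5:20] <- -30
  s <- classify_beat(t, v_low)
  expect_false(s$depolarized)
  expect_false(s$ead)
  expect_true(is.na(s$dvdt_repol))
  # monotone repolarization: negative dvdt_repol, no EAD
  ap <- qq_triangle_ap()
  s2 <- classify_beat(ap$time_ms, ap$vm)
  expect_true(s2$depolarized)
  expect_lt(s2$dvdt_repol, 0)
  expect_false(s2$ead)
  # a +5 mV bump between the 30% and 90% repolarization levels: EAD
  vp <- 40; vt <- -88
  lvl30 <- vp - 0.3 * (vp - vt); lvl90 <- vp - 0.9 * (vp - vt)
  v3 <- ap$vm
  bump_at <- which(v3 < (lvl30 + lvl90) / 2 & ap$time_ms > 5)[1]
  v3[bump_at + 0:10] <- v3[bump_at + 0:10] + c(0:5, 4:0)
  s3 <- classify_beat(ap$time_ms, v3)
  expect_gt(s3$dvdt_repol, 0)
  expect_true(s3$ead)
  # non-uniform grid rejected
  expect_error(classify_beat(c(0, 1, 3, 4), c(-88, 10, -50, -88)),
               "uniform")
})

test_that("the three-case dvdt_repol window rule selects the right window", {
  # case 2: repolarizes past 30% but not 90% -- slope from the tail counts
  ap <- qq_triangle_ap(t_end = 400)
  vp <- 40; vt <- -88
  lvl90 <- vp - 0.9 * (vp - vt)
  v <- pmax(ap$vm, lvl90 + 5) # clamp above the 90% level
  v[1] <- vt # takeoff unchanged
  # make the tail rise slightly: reactivation after partial repolarization
  v[1500:2001] <- v[1500:2001] + seq(0, 5, length.out = 502)
  s <- classify_beat(ap$time_ms, v)
  expect_true(is.na(s$t_repol90))
  expect_false(is.na(s$t_repol30))
  expect_gt(s$dvdt_repol, 0)
  # case 3: never repolarizes 30% -- window from the peak
  v2 <- pmax(ap$vm, vp - 0.2 * (vp - vt))
  v2[1] <- vt
  s2 <- classify_beat(ap$time_ms, v2)
  expect_true(is.na(s2$t_repol30))
  expect_true(is.finite(s2$dvdt_repol))
})

test_that("compute_qnet and the trapezoid oracle agree on analytic cases", {
  # summed current 1 uA/uF for 1 s then -0.5 uA/uF for 1 s -> 0.5 uC/uF
  t <- seq(0, 2000, by = 1)
  inet <- ifelse(t < 1000, 1, -0.5)
  qn <- cumsum(c(0, diff(t) * (head(inet, -1) + tail(inet, -1)) / 2)) / 1000
  beat <- data.frame(time_ms = t, Inet = inet, qNet = qn)
  # the sampled step discontinuity costs one trapezoid panel (~0.15%)
  expect_equal(compute_qnet(beat, cl = 2000), 0.5, tolerance = 5e-3)
  expect_equal(qnet_trapz(beat), 0.5, tolerance = 5e-3)
  # all-zero current
  beat0 <- data.frame(time_ms = t, Inet = 0, qNet = 0)
  expect_equal(compute_qnet(beat0), 0)
  expect_equal(qnet_trapz(beat0), 0)
  expect_error(compute_qnet(beat[1:100, ], cl = 2000), "shorter")
})

test_that("select_qnet_beat: max dvdt_repol, earliest on ties, failed
           depolarizations never selected", {
  mk <- function(dep, dv) structure(list(depolarized = dep, dvdt_repol = dv,
                                         ead = dv > 0),
                                    class = "beat_summary")
  same <- replicate(5, mk(TRUE, -0.3), simplify = FALSE)
  expect_equal(select_qnet_beat(same), 1L)
  one_ead <- list(mk(TRUE, -0.3), mk(TRUE, 0.4), mk(TRUE, -0.2))
  expect_equal(select_qnet_beat(one_ead), 2L)
  with_fail <- list(mk(FALSE, 99), mk(TRUE, -0.5))
  expect_equal(select_qnet_beat(with_fail), 2L)
  expect_true(is.na(select_qnet_beat(list(mk(FALSE, 1), mk(FALSE, 2)))))
})

test_that("a zero-effect sample reproduces the control qNet", {
  ss <- qq_steady_state()
  s0 <- drug_effect_sample(drug_binding_params(0, 1, 1, 1e-3, -100),
                           list(), cmax = 100, drug = "none")
  r <- run_drug_simulation(s0, 1, beats = 3, analysis_beats = 1,
                           steady_state = ss)
  expect_equal(r$classification, "normal")
  init <- ss; init[["qNet"]] <- 0
  ctrl <- run_pacing(init, pacing_protocol(beats = 3), keep_beats = 1, dt = 1)
  q_ctrl <- compute_qnet(ctrl$beats[[1]], cl = 2000)
  expect_equal(r$qnet, q_ctrl, tolerance = 1e-6)
})

test_that("strong hERG-only block induces EADs; balanced inward block
           raises qNet", {
  ss <- qq_steady_state()
  # strong pure-IKr synthetic blocker (open-state binding multiplier >> 1)
  bp_strong <- binding_from_log10(6, 6 - log10(0.20), 1, -3, -1)
  s_ikr <- drug_effect_sample(bp_strong, list(), cmax = 100, drug = "ikr")
  r_ikr <- run_drug_simulation(s_ikr, 1, beats = 30, analysis_beats = 10,
                               steady_state = ss)
  expect_equal(r_ikr$classification, "EAD")
  # same hERG block plus inward-current (ICaL + INaL) block: balanced
  hill_bal <- list(ICaL = hill_params(7, 1), INaL = hill_params(7, 1))
  s_bal <- drug_effect_sample(bp_strong, hill_bal, cmax = 100, drug = "bal")
  r_bal <- run_drug_simulation(s_bal, 1, beats = 30, analysis_beats = 10,
                               steady_state = ss)
  expect_gt(r_bal$qnet, r_ikr$qnet)
})

test_that("propagation pairs samples deterministically and accounts for
           every sample", {
  panel <- fixture_panel("separable9")
  spec <- panel$int1
  inp <- synthetic_uncertainty_inputs(spec, 4, seed = 42)
  samples <- pair_uncertainty_samples(inp$herg, inp$hills, spec$cmax,
                                      n_samples = 4, drug = spec$name)
  expect_length(samples, 4)
  expect_equal(vapply(samples, `[[`, integer(1), "index"), 1:4)
  ss <- qq_steady_state()
  qd <- propagate_uncertainty(samples, multiples = 1, beats = 6,
                              analysis_beats = 2, steady_state = ss)
  pm <- qd$per_multiple[[1]]
  expect_equal(length(pm$qnet) + pm$n_depol_fail, pm$n_total)
  qd2 <- propagate_uncertainty(samples, multiples = 1, beats = 6,
                               analysis_beats = 2, steady_state = ss)
  expect_identical(pm$qnet, qd2$per_multiple[[1]]$qnet)
  # single sample: point distribution, zero-width interval
  qd1 <- propagate_uncertainty(samples[1], multiples = 1, beats = 6,
                               analysis_beats = 2, steady_state = ss)
  ci <- qd1$per_multiple[[1]]$ci
  expect_equal(unname(ci[1]), unname(ci[2]))
  # too few rows in the sources is an error
  expect_error(pair_uncertainty_samples(inp$herg, inp$hills, spec$cmax,
                                        n_samples = 10), "rows")
})

test_that("median qNet of a pure IKr blocker is non-increasing in
           concentration", {
  ss <- qq_steady_state()
  bp <- binding_from_log10(6, 6 - log10(0.04), 1, -3, -85)
  s <- drug_effect_sample(bp, list(), cmax = 100, drug = "mono")
  qn <- vapply(c(0.5, 1, 2, 4), function(m)
    run_drug_simulation(s, m, beats = 20, analysis_beats = 5,
                        steady_state = ss)$qnet, 0)
  expect_true(all(diff(qn) <= 1e-4))
})
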