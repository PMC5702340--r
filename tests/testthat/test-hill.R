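# Hill dose-response: block curve, NLS fit, DRAM posterior, extrapolation.

test_that("hill_block: half-maximum at IC50, zero at zero, published
           ranolazine evaluation, monotonicity", {
  for (h in c(0.5, 1, 2.7)) {
    hp <- hill_params(6, h)
    expect_equal(hill_block(hp, hill_ic50(hp)), 50)
  }
  expect_equal(hill_block(hill_params(6, 1), 0), 0)
  # ranolazine late-sodium optimum at the highest tested concentration
  expect_equal(hill_block(hill_params(5.1033, 0.945), 23000), 73.3,
               tolerance = 0.1 / 73.3)
  hp <- hill_params(5, 1.3)
  D <- c(0, 10^seq(0, 6, by = 0.5))
  expect_true(all(diff(hill_block(hp, D)) >= 0))
  # monotone in pIC50 at fixed D
  b <- vapply(seq(1, 9, by = 1), function(p)
    hill_block(hill_params(p, 1.3), 500), 0)
  expect_true(all(diff(b) >= 0))
})

test_that("fit_hill_nls recovers noiseless parameters and flags
           unconstrained data", {
  hp <- hill_params(6, 1)
  ic50 <- hill_ic50(hp)
  conc <- ic50 * c(0.11, 0.33, 1, 3, 9) # spans ~10-90% block
  pts <- dose_response_points(conc, hill_block(hp, conc))
  fit <- fit_hill_nls(pts)
  expect_equal(fit$pIC50, 6, tolerance = 1e-3)
  expect_equal(fit$h, 1, tolerance = 1e-3)
  expect_false(fit$unconstrained)
  # all observed block <= 12%: unconstrained flag
  conc2 <- ic50 * c(0.01, 0.03, 0.1)
  pts2 <- dose_response_points(conc2, hill_block(hp, conc2))
  expect_lt(max(pts2$block), 12.1)
  expect_true(fit_hill_nls(pts2)$unconstrained)
  # degenerate all-zero block: boundary fit, flagged
  pts3 <- dose_response_points(c(1, 10, 100), c(0, 0, 0))
  expect_true(fit_hill_nls(pts3)$unconstrained)
  expect_error(fit_hill_nls(dose_response_points(c(1, 1), c(10, 12))),
               "distinct")
})

test_that("duplicating every replicate leaves the least-squares fit
           unchanged", {
  hp <- hill_params(5.5, 0.8)
  conc <- hill_ic50(hp) * c(0.2, 1, 5)
  set.seed(4)
  block <- hill_block(hp, conc) + rnorm(3, 0, 3)
  f1 <- fit_hill_nls(dose_response_points(conc, block))
  f2 <- fit_hill_nls(dose_response_points(rep(conc, 2), rep(block, 2)))
  expect_equal(f1$pIC50, f2$pIC50, tolerance = 1e-6)
  expect_equal(f1$h, f2$h, tolerance = 1e-6)
})

test_that("mcmc_hill is seed-deterministic, respects bounds, and keeps the
           variance trace positive", {
  hp <- hill_params(6, 1)
  spec <- synthetic_drug_spec("d", drug_binding_params(1, 1, 1, 1e-3, -100),
                              hill = list(INaL = hp), cmax = hill_ic50(hp),
                              dr_conc = hill_ic50(hp) * c(0.25, 0.5, 1, 2))
  pts <- make_synthetic_doseresponse(spec, "INaL", 21)
  init <- fit_hill_nls(pts)
  c1 <- mcmc_hill(pts, init, n_saved = 300, seed = 9, burn_in = 2000)
  c2 <- mcmc_hill(pts, init, n_saved = 300, seed = 9, burn_in = 2000)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$sigma2, c2$sigma2)
  expect_true(all(c1$draws[, "pIC50"] >= -1 & c1$draws[, "pIC50"] <= 19))
  expect_true(all(c1$draws[, "h"] >= 0 & c1$draws[, "h"] <= 10))
  expect_true(all(c1$sigma2 > 0))
})

test_that("well-constrained posterior covers the truth (reduced coverage
           study)", {
  hp <- hill_params(6, 1)
  covered <- 0L
  reps <- 10
  for (r in seq_len(reps)) {
    spec <- synthetic_drug_spec("d", drug_binding_params(1, 1, 1, 1e-3, -100),
                                hill = list(INaL = hp),
                                cmax = hill_ic50(hp),
                                dr_conc = hill_ic50(hp) * c(0.25, 0.5, 1, 2, 4))
    pts <- make_synthetic_doseresponse(spec, "INaL", 300 + r)
    init <- fit_hill_nls(pts)
    ch <- suppressWarnings(
      mcmc_hill(pts, init, n_saved = 500, seed = r, burn_in = 4000))
    ci <- credible_interval(ch$draws[, "pIC50"])
    if (ci[1] <= 6 && 6 <= ci[2]) covered <- covered + 1L
    # posterior mean within 2 posterior SDs of the truth
    expect_lt(abs(mean(ch$draws[, "pIC50"]) - 6),
              2.5 * sd(ch$draws[, "pIC50"]) + 0.05)
  }
  expect_gte(covered, 8)
})

test_that("truncated data produce the inverse IC50-h ridge", {
  # moderately truncated: max block ~12% over a decade of concentrations
  hp <- hill_params(6, 1)
  ic50 <- hill_ic50(hp)
  spec <- synthetic_drug_spec("t", drug_binding_params(1, 1, 1, 1e-3, -100),
                              hill = list(INaL = hp), cmax = ic50,
                              dr_conc = ic50 * c(0.02, 0.05, 0.1, 0.15),
                              dr_sd = 3)
  pts <- make_synthetic_doseresponse(spec, "INaL", 12)
  init <- fit_hill_nls(pts)
  expect_true(init$unconstrained)
  ch <- suppressWarnings(mcmc_hill(pts, init, n_saved = 1000, seed = 6,
                                   burn_in = 5000))
  # inverse relationship between log10(IC50) and h
  expect_lt(cor(-ch$draws[, "pIC50"], ch$draws[, "h"]), -0.5)
})

test_that("block_ci behaves at degenerate chains and widens with
           extrapolation on truncated data", {
  ch0 <- structure(list(draws = cbind(pIC50 = rep(6, 50), h = rep(1, 50)),
                        sigma2 = rep(1, 50)), class = "mcmc_chain")
  ci <- block_ci(ch0, 1000)
  expect_equal(unname(ci[1]), unname(ci[2]))
  expect_equal(unname(ci[1]), hill_block(hill_params(6, 1), 1000))
  # truncated-regime chain: wider CI at 10x Chigh than at 1x
  hp <- hill_params(6, 1)
  ic50 <- hill_ic50(hp)
  spec <- synthetic_drug_spec("t", drug_binding_params(1, 1, 1, 1e-3, -100),
                              hill = list(INaL = hp), cmax = ic50,
                              dr_conc = ic50 * c(0.02, 0.05, 0.1, 0.15),
                              dr_sd = 3)
  pts <- make_synthetic_doseresponse(spec, "INaL", 13)
  ch <- suppressWarnings(mcmc_hill(pts, fit_hill_nls(pts), n_saved = 500,
                                   seed = 7, burn_in = 4000))
  chigh <- max(pts$conc)
  w1 <- diff(block_ci(ch, chigh))
  w10 <- diff(block_ci(ch, 10 * chigh))
  expect_gt(w10, w1)
  # posterior contains the NLS point estimate (chain initialized there)
  fit <- fit_hill_nls(pts)
  b_nls <- hill_block(fit, chigh)
  ci1 <- block_ci(ch, chigh)
  expect_gte(b_nls, ci1[1] - 1)
  expect_lte(b_nls, ci1[2] + 1)
})

test_that("null-block data give a posterior-predictive range close to the
           full 0-100 at far extrapolation", {
  set.seed(77)
  conc <- c(10, 30, 100)
  pts <- dose_response_points(rep(conc, each = 4),
                              rnorm(12, 0, 3)) # no signal at all
  init <- fit_hill_nls(pts)
  expect_true(init$unconstrained)
  ch <- suppressWarnings(mcmc_hill(pts, init, n_saved = 1000, seed = 8,
                                   burn_in = 5000))
  w <- diff(block_ci(ch, 25 * max(conc)))
  expect_gt(w, 90)
})

test_that("extrapolation_uncertainty widths and the 60% reliability rule", {
  ch0 <- structure(list(draws = cbind(pIC50 = rep(6, 50), h = rep(1, 50)),
                        sigma2 = rep(1, 50)), class = "mcmc_chain")
  ex <- extrapolation_uncertainty(ch0, Chigh = 1000)
  expect_equal(unname(ex$width), rep(0, 4))
  expect_true(is.na(ex$reliable))
  # strong-block data (mean ~80% at Chigh) are flagged reliable
  hp <- hill_params(6, 1)
  ic50 <- hill_ic50(hp)
  spec <- synthetic_drug_spec("s", drug_binding_params(1, 1, 1, 1e-3, -100),
                              hill = list(INaL = hp), cmax = ic50,
                              dr_conc = ic50 * c(0.25, 1, 4))
  pts <- make_synthetic_doseresponse(spec, "INaL", 31)
  ch <- suppressWarnings(mcmc_hill(pts, fit_hill_nls(pts), n_saved = 500,
                                   seed = 10, burn_in = 4000))
  ex2 <- extrapolation_uncertainty(ch, Chigh = max(pts$conc), points = pts)
  expect_true(ex2$reliable)
  # weak-block data are not
  spec3 <- synthetic_drug_spec("w", drug_binding_params(1, 1, 1, 1e-3, -100),
                               hill = list(INaL = hp), cmax = ic50,
                               dr_conc = ic50 * c(0.02, 0.05, 0.1))
  pts3 <- make_synthetic_doseresponse(spec3, "INaL", 32)
  ch3 <- suppressWarnings(mcmc_hill(pts3, fit_hill_nls(pts3), n_saved = 300,
                                    seed = 11, burn_in = 4000))
  ex3 <- extrapolation_uncertainty(ch3, Chigh = max(pts3$conc), points = pts3)
  expect_false(ex3$reliable)
})
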