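# Proportional-odds risk classification, LOOCV, knockout machinery.

test_that("prediction_error reproduces every published per-drug value from
           its category fractions", {
  ref <- read.csv(system.file("extdata", "loocv_reference.csv",
                              package = "qnetuq"))
  for (i in seq_len(nrow(ref))) {
    P <- c(ref$P0[i], ref$P1[i], ref$P2[i])
    expect_equal(prediction_error(P / sum(P), ref$category[i]), ref$error[i],
                 tolerance = 2e-3,
                 label = paste("row", ref$drug[i], ref$multiple[i]))
  }
  expect_equal(prediction_error(c(0, 0.5455, 0.4545), 1), 0.4545)
  expect_equal(prediction_error(c(0.0373, 0.0580, 0.9047), 2), 0.1326)
  expect_equal(prediction_error(c(0, 1, 0), 1), 0)
})

test_that("the published per-concentration mean errors follow from the
           per-drug table", {
  ref <- read.csv(system.file("extdata", "loocv_reference.csv",
                              package = "qnetuq"))
  m1 <- mean(ref$error[ref$multiple == 1])
  m10 <- mean(ref$error[ref$multiple == 10])
  expect_equal(round(m1, 2), 0.09)
  expect_equal(round(m10, 2), 0.23)
})

test_that("proportional-odds fit separates three separated clusters and is
           location-equivariant", {
  set.seed(1)
  q <- c(rnorm(40, 0.06, 0.002), rnorm(40, 0.03, 0.002),
         rnorm(40, 0.00, 0.002))
  y <- rep(c(0L, 1L, 2L), each = 40)
  m <- suppressWarnings(fit_proportional_odds(q, y))
  pred <- predict_category(m, q)
  expect_equal(pred$category, y)
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-12))
  # shifting qNet shifts intercepts but not assignments
  m2 <- suppressWarnings(fit_proportional_odds(q + 0.5, y))
  pred2 <- predict_category(m2, q + 0.5)
  expect_equal(pred2$category, y)
  expect_error(fit_proportional_odds(q[1:40], y[1:40]), "degenerate")
})

test_that("two-category data reduce to binary logistic regression", {
  set.seed(2)
  q <- c(rnorm(60, 0.05, 0.01), rnorm(60, 0.02, 0.01))
  y <- rep(c(0L, 1L), each = 60)
  m <- fit_proportional_odds(q, y)
  g <- glm(y ~ q, family = binomial())
  # cumulative-logit with one threshold: P(Y=1) = plogis(beta*q - zeta)
  expect_equal(m$beta, unname(coef(g)[2]), tolerance = 1e-3)
  expect_equal(m$zeta[1], -unname(coef(g)[1]), tolerance = 1e-3)
  pred <- predict_category(m, q)
  expect_equal(pred$category, as.integer(fitted(g) > 0.5))
})

test_that("the implementation agrees with the MASS::polr oracle on
           non-separated data", {
  skip_if_not_installed("MASS")
  set.seed(3)
  q <- c(rnorm(80, 0.050, 0.012), rnorm(80, 0.035, 0.012),
         rnorm(80, 0.020, 0.012))
  y <- rep(c(0L, 1L, 2L), each = 80)
  m <- fit_proportional_odds(q, y)
  pm <- MASS::polr(factor(y) ~ q, method = "logistic")
  expect_equal(m$beta, unname(coef(pm)[1]), tolerance = 1e-3)
  expect_equal(m$zeta, unname(pm$zeta), tolerance = 1e-3)
})

test_that("predict_category resolves ties to the lower category", {
  m <- structure(list(zeta = c(-1, 1), beta = 0, K = 3L,
                      converged = TRUE, value = 0),
                 class = "ordinal_model")
  # with beta = 0 the probabilities are fixed: c(0.269, 0.462, 0.269)
  p <- predict_category(m, 0)
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)
  m2 <- structure(list(zeta = c(0), beta = 0, K = 2L,
                       converged = TRUE, value = 0),
                  class = "ordinal_model")
  p2 <- predict_category(m2, 123)
  expect_equal(p2$category, 0L) # exact 0.5/0.5 tie -> lower
})

test_that("loocv separates engineered categories, is order-invariant, and
           degrades only the perturbed fold", {
  set.seed(4)
  qnet_by_drug <- list()
  for (i in 1:4) qnet_by_drug[[paste0("low", i)]] <- rnorm(30, 0.060, 0.001)
  for (i in 1:4) qnet_by_drug[[paste0("mid", i)]] <- rnorm(30, 0.035, 0.001)
  for (i in 1:4) qnet_by_drug[[paste0("hi", i)]] <- rnorm(30, 0.010, 0.001)
  labels <- setNames(rep(c(0L, 1L, 2L), each = 4), names(qnet_by_drug))
  res <- suppressWarnings(loocv(qnet_by_drug, labels))
  expect_equal(res$mean_error, 0)
  # within-drug sample order is irrelevant
  shuffled <- lapply(qnet_by_drug, sample)
  res2 <- suppressWarnings(loocv(shuffled, labels))
  expect_equal(res2$per_drug$error, res$per_drug$error)
  # heavy-tailed outliers in one high-risk drug raise that drug's own error
  pert <- qnet_by_drug
  pert$hi1 <- c(pert$hi1, rnorm(15, 0.060, 0.001)) # safe-looking outliers
  res3 <- suppressWarnings(loocv(pert, labels))
  err3 <- setNames(res3$per_drug$error, res3$per_drug$drug)
  expect_gt(err3[["hi1"]], res$per_drug$error[res$per_drug$drug == "hi1"])
})

test_that("loocv with one sample per drug reduces to classical LOOCV", {
  q <- list(a = 0.06, b = 0.058, c = 0.03, d = 0.032, e = 0.01, f = 0.012)
  labels <- setNames(c(0L, 0L, 1L, 1L, 2L, 2L), names(q))
  res <- suppressWarnings(loocv(q, labels))
  expect_equal(nrow(res$per_drug), 6)
  expect_true(all(res$per_drug$error %in% c(0, 1, 2)))
})

test_that("knockout_current zeroes exactly the named effect and round-trips", {
  bp <- binding_from_log10(6, 7, 1, -3, -50)
  s <- drug_effect_sample(bp, list(ICaL = hill_params(6, 1)), cmax = 100)
  ko_ical <- knockout_current(list(s), "ICaL")[[1]]
  expect_null(ko_ical$hill$ICaL)
  expect_equal(ko_ical$binding$Kmax, bp$Kmax)
  ko_ikr <- knockout_current(list(s), "IKr")[[1]]
  expect_equal(ko_ikr$binding$Kmax, 0)
  expect_equal(ko_ikr$hill$ICaL$pIC50, 6)
  # knocking out a current the sample does not block changes nothing
  ko_ito <- knockout_current(list(s), "Ito")[[1]]
  expect_identical(ko_ito, s)
  expect_error(knockout_current(list(s), "IKx"), "unknown")
})
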