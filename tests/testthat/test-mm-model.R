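test_that("dataset assembly centres hospital covariates and matches a hand-built design", {
  expect_equal(centerHospitalCovariate(c(85, 95, 105)), c(-1, 0, 1))

  persons <- data.frame(
    person_id = paste0("p", 1:6),
    y = c(0L, 1L, 0L, 2L, 0L, 1L),
    t = c(1, 2, 3, 1, 2, 3),
    age = c(0, 1, 2, 0, 1, 2),
    stringsAsFactors = FALSE)
  W <- Matrix::sparseMatrix(
    i = 1:6, j = c(1, 1, 2, 2, 1, 2), x = 1, dims = c(6, 2),
    dimnames = list(persons$person_id, c("H1", "H2")))
  occ <- c(H1 = 85, H2 = 105)
  ds <- buildMmDataset(persons, list(hospital = W), outcome = "y",
                       offset = "t", fixed = "age",
                       hospitalCovariates = list(occupancy = occ))
  # hand-built: intercept, age, centred/rescaled occupancy via unit weights
  expect_equal(unname(ds@X),
               unname(cbind(1, persons$age, c(-1, -1, 1, 1, -1, 1))))
  expect_equal(colnames(ds@X), c("(Intercept)", "age", "occupancy"))
  expect_equal(ds@y, persons$y)
  expect_equal(ds@offset, persons$t)

  bad <- persons; bad$t[2] <- 0
  expect_error(buildMmDataset(bad, list(hospital = W), outcome = "y",
                              offset = "t"), "positive follow-up")
  # persons without weights are dropped with a message, not silently
  W5 <- W[1:5, ]
  expect_message(
    ds5 <- buildMmDataset(persons, list(hospital = W5), outcome = "y", offset = "t"),
    "dropped")
  expect_equal(length(ds5@y), 5L)
})

test_that("Poisson deviance matches hand-evaluated log-likelihoods", {
  expect_equal(poissonDeviance(0, 1), 2)
  expect_equal(poissonDeviance(1, 1), 2)
  y <- c(0, 1, 2, 5); mu <- c(0.5, 1.5, 2, 4)
  byHand <- -2 * sum(y * log(mu) - mu - log(factorial(y)))
  expect_equal(poissonDeviance(y, mu), byHand)
})

test_that("the sampler is deterministic given a seed and its deviance trace is recomputable", {
  sm <- smallMmData()
  ctl <- mcmcControl(burnin = 200, samples = 300, seed = 11)
  f1 <- fitMmPoisson(sm$dataset, control = ctl)
  f2 <- fitMmPoisson(sm$dataset, control = ctl)
  expect_identical(betaSamples(f1), betaSamples(f2))
  expect_identical(sigma2Samples(f1), sigma2Samples(f2))
  expect_identical(uSamples(f1), uSamples(f2))

  # stored deviance equals -2 * Poisson log-likelihood at the sampled state
  for (k in c(1L, 150L, 300L)) {
    mu <- sm$dataset@offset *
      exp(as.numeric(sm$dataset@X %*% betaSamples(f1)[k, ]) +
            as.numeric(sm$dataset@classifications$hospital %*% uSamples(f1)[k, ]))
    expect_equal(devianceTrace(f1)[k], poissonDeviance(sm$dataset@y, mu),
                 tolerance = 1e-8)
  }
  expect_true(all(sigma2Samples(f1) > 0))
  expect_equal(nrow(betaSamples(f1)), 300L)
})

test_that("posterior covers the generating parameters on single-membership data", {
  sm <- smallMmData(n = 1200, J = 8, seed = 5, sigma = 0.5)
  fit <- fitMmPoisson(sm$dataset, control = mcmcControl(burnin = 500,
                                                        samples = 2000, seed = 2))
  b <- betaSamples(fit)
  ci0 <- quantile(b[, 1], c(.025, .975))
  cix <- quantile(b[, 2], c(.025, .975))
  expect_gt(-1.5, ci0[1]); expect_lt(-1.5, ci0[2])
  expect_gt(0.3, cix[1]); expect_lt(0.3, cix[2])
  # posterior u medians track the true effects
  uhat <- apply(uSamples(fit), 2L, median)
  expect_gt(cor(uhat, sm$u), 0.8)
})

test_that("a cross-classified fit with the second variance pinned to zero equals the single-classification fit", {
  sm <- smallMmData(n = 300, J = 5, seed = 21)
  # second classification: arbitrary grouping, pinned at u = 0, sigma2 = 1e-12
  W2 <- Matrix::sparseMatrix(i = 1:300, j = rep(1:10, 30), x = 1,
                             dims = c(300, 10),
                             dimnames = list(sm$persons$person_id, paste0("S", 1:10)))
  ds2 <- buildMmDataset(sm$persons, list(hospital = sm$W, area = W2),
                        outcome = "y", offset = "t", fixed = "x")
  ctl <- mcmcControl(burnin = 200, samples = 500, seed = 33)
  fit1 <- fitMmPoisson(sm$dataset, control = ctl)
  fit2 <- fitMmPoisson(ds2, control = ctl,
                       fixU = c(FALSE, TRUE), fixSigma2 = c(FALSE, TRUE),
                       uInit = list(NULL, numeric(10)),
                       sigma2Init = c(NA, 1e-12))
  # pinning consumes no RNG, so the chains agree draw for draw
  expect_equal(unname(sigma2Samples(fit2)[, "hospital"]),
               unname(sigma2Samples(fit1)[, "hospital"]))
  expect_equal(unname(betaSamples(fit2)), unname(betaSamples(fit1)))
  expect_true(all(uSamples(fit2, "area") == 0))
})

test_that("cross-classified models partition variance over both classifications", {
  sys <- generateSystem(simConfig(nAreas = 24, nHospitals = 8,
                                  personsPerArea = 120, nSla = 9,
                                  sigma2Sla = 0.3), seed = 14)
  flows <- computeAreaWeights(sys$admissions)
  W <- personWeightMatrix(flows, sys$persons)$W
  slas <- sort(unique(sys$persons$sla_id))
  Wsla <- Matrix::sparseMatrix(
    i = seq_len(nrow(sys$persons)), j = match(sys$persons$sla_id, slas), x = 1,
    dims = c(nrow(sys$persons), length(slas)),
    dimnames = list(sys$persons$person_id, slas))
  ds <- buildMmDataset(sys$persons, list(hospital = W, sla = Wsla),
                       fixed = c("age_band", "sex", "health_score"))
  fit <- fitMmPoisson(ds, control = mcmcControl(burnin = 500, samples = 2000,
                                                seed = 19))
  s2 <- sigma2Samples(fit)
  expect_equal(colnames(s2), c("hospital", "sla"))
  # the strong SLA signal (0.3) is visible on its own classification
  ciSla <- quantile(s2[, "sla"], c(.025, .975))
  expect_gt(ciSla[2], 0.1)
  expect_gt(mean(s2[, "sla"]), mean(s2[, "hospital"]))
  expect_true(all(s2 > 0))
})

test_that("posterior summaries are exchangeable under person permutation", {
  sm <- smallMmData(n = 800, J = 6, seed = 8, sigma = 0.4)
  set.seed(4242)
  perm <- sample(nrow(sm$persons))
  personsP <- sm$persons[perm, ]
  dsP <- buildMmDataset(personsP, list(hospital = sm$W[perm, ]),
                        outcome = "y", offset = "t", fixed = "x")
  ctl <- mcmcControl(burnin = 400, samples = 2000, seed = 9)
  f1 <- fitMmPoisson(sm$dataset, control = ctl)
  f2 <- fitMmPoisson(dsP, control = ctl)
  expect_equal(mean(sigma2Samples(f1)), mean(sigma2Samples(f2)), tolerance = 0.25)
  expect_equal(colMeans(betaSamples(f1)), colMeans(betaSamples(f2)),
               tolerance = 0.05)
})

test_that("fixing u gives exact conjugate inverse-gamma conditional draws for sigma2", {
  sm <- smallMmData(n = 100, J = 6, seed = 3)
  uFix <- c(0.4, -0.2, 0.1, -0.5, 0.3, -0.1)
  fit <- fitMmPoisson(sm$dataset, control = mcmcControl(burnin = 0, samples = 2000,
                                                        seed = 77),
                      fixU = TRUE, uInit = list(uFix))
  draws <- sigma2Samples(fit)[, 1]
  a <- 0.001 + 6 / 2
  b <- 0.001 + sum(uFix^2) / 2
  # inverse-gamma moments: mean b/(a-1), var b^2/((a-1)^2 (a-2))
  expect_equal(mean(draws), b / (a - 1), tolerance = 0.1)
  expect_equal(var(draws), b^2 / ((a - 1)^2 * (a - 2)), tolerance = 0.35)
})

test_that("diagnostics report sensible effective sample sizes", {
  set.seed(101)
  n <- 4000
  iid <- rnorm(n)
  expect_equal(chainEss(iid), n, tolerance = 0.2)
  expect_equal(chainEss(rep(1.3, n)), 0)
  # AR(1) with rho = 0.5 has ESS ~ n (1-rho)/(1+rho) = n/3
  rho <- 0.5
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(chainEss(ar), n * (1 - rho) / (1 + rho), tolerance = 0.25)

  sm <- smallMmData()
  fit <- fitMmPoisson(sm$dataset, control = mcmcControl(burnin = 200,
                                                        samples = 400, seed = 6))
  d <- mmDiagnostics(fit)
  expect_true(all(c("ess", "geweke_z", "flag") %in% names(d$parameters)))
  expect_true(all(d$parameters$ess >= 0))
  expect_true(is.list(d$acceptance))
})
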