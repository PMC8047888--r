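test_that("log joint density matches a term-by-term hand computation", {
  ## 3 units, 2 years, everything fixed; the oracle sums literal formulas
  net <- chainNetwork(3, seed = 4)
  H <- covariates(net)
  E <- rbind(c(10, 20), c(NA, 15), c(5, 0))
  C <- rbind(c(1, 3), c(NA, 2), c(0, 0))
  data <- new("RemovalData", network = net, years = c("1", "2"),
              effort = E, captures = C)
  p <- GompertzParams(alpha = 0.4, lambda = -0.2,
                      beta = c(0.1, -0.05, 0.2, 0, 0.05), beta6 = -0.3,
                      gamma = 0.6, sigmaRho = 0.7, sigmaOmega = 0.25,
                      sigmaE = 0.35, sigma1 = 1.2,
                      rho = c(0.1, -0.2, 0.15), omega = 0.05)
  mu <- rbind(c(-0.5, 0.2), c(0.3, -0.1), c(0.0, 0.4))

  lpois <- function(c_, m) -m + c_ * log(m) - lgamma(c_ + 1)
  lnorm <- function(x, m, s) -0.5 * log(2 * pi * s^2) - (x - m)^2 / (2 * s^2)
  obs <- lpois(1, 10 * exp(-0.5)) + lpois(3, 20 * exp(0.2)) +
    lpois(2, 15 * exp(-0.1)) + log(dpois(0, 5 * exp(0))) + 0
  ## process: effort enters as trap-days / 100, missing effort as 0
  fx <- drop(H %*% p@beta)
  m2 <- p@alpha + p@lambda * mu[, 1] + fx +
    p@beta6 * c(10, 0, 5) / 100 + p@rho + p@omega[1]
  proc <- sum(lnorm(mu[, 2], m2, 0.35))
  init <- sum(lnorm(mu[, 1], 0, 1.2))
  yearEff <- lnorm(0.05, 0, 0.25)
  W <- adjacencyMatrix(net)
  Q <- (diag(rowSums(W)) - 0.6 * W) / 0.7^2
  car <- 0.5 * log(det(Q)) - 1.5 * log(2 * pi) -
    0.5 * drop(p@rho %*% Q %*% p@rho)
  priors <- lnorm(0.4, 0, 100) + lnorm(-0.2, 0, 100) +
    sum(lnorm(p@beta, 0, 100)) + lnorm(-0.3, 0, 100) +
    log(2) + lnorm(0.25, 0, 10) + log(2) + lnorm(1.2, 0, 10) -
    2 * log(10)
  oracle <- obs + proc + init + yearEff + car + priors

  expect_equal(logJointDensity(data, p, mu), oracle, tolerance = 1e-12)
})

test_that("log joint density is -Inf outside the parameter support", {
  net <- chainNetwork(3, seed = 4)
  E <- matrix(10, 3, 2); C <- matrix(1, 3, 2)
  data <- new("RemovalData", network = net, years = c("1", "2"),
              effort = E, captures = C)
  mu <- matrix(0, 3, 2)
  base <- list(alpha = 0, lambda = 0, beta = rep(0, 5), beta6 = 0,
               rho = rep(0, 3), omega = 0)
  mk <- function(...) do.call(GompertzParams, modifyList(base, list(...)))
  expect_true(is.finite(logJointDensity(data, mk(gamma = 0.5), mu)))
  expect_identical(logJointDensity(data, mk(gamma = 0.999999), mu) > -Inf,
                   TRUE)
  ## gamma at or beyond the boundary of (0,1) is rejected by the class,
  ## and zero variances by the density itself
  expect_error(mk(gamma = 1.5), "gamma")
  p0 <- mk(gamma = 0.5)
  p0@sigmaE <- 0
  expect_identical(logJointDensity(data, p0, mu), -Inf)
  p1 <- mk(gamma = 0.5)
  p1@sigmaRho <- 11            # beyond the flat-positive prior bound
  expect_identical(logJointDensity(data, p1, mu), -Inf)
})

test_that("split R-hat behaves on stationary, separated and degenerate chains", {
  set.seed(1)
  ch <- matrix(rnorm(4000), 1000, 4)
  r <- computeRhat(ch)
  expect_gte(r, 0.999)
  expect_lte(r, 1.05)

  far <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  expect_gt(computeRhat(far), 3)

  expect_equal(computeRhat(list(c(1, 1), c(1, 1))), 1)
  expect_error(computeRhat(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("split R-hat matches a hand-worked small example", {
  ## chains (1,2,3,4) and (2,3,4,5); halves (1,2),(3,4),(2,3),(4,5):
  ## W = 0.5, var(means) = 5/3, n/2 = 2 ->
  ## Rhat = sqrt(1/2 + (5/3)/(1/2)) = sqrt(23/6)
  expect_equal(computeRhat(cbind(1:4, 2:5)), sqrt(1 / 2 + (5 / 3) / 0.5))
})

test_that("MCMC fit returns the configured draw counts and diagnostics", {
  sf <- smallFit()
  fit <- sf$fit
  ## retained draws = nChains * (nIter - nWarmup) / thin
  expect_equal(nDraws(fit), 2L * (800L - 400L) %/% 2L)
  expect_equal(fit@nKept, nrow(drawsMatrix(fit)))
  expect_equal(sort(unique(fit@chain)), 1:2)
  cn <- colnames(drawsMatrix(fit))
  expect_true(all(c("alpha", "lambda", "beta1", "beta6", "gamma",
                    "sigma_rho", "sigma_omega", "sigma_e", "sigma_1",
                    "rho[8]", "omega[5]", "mu[8,6]") %in% cn))
  expect_true(all(names(rhat(fit)) == cn))
  expect_true(all(drawsMatrix(fit)[, "gamma"] > 0 &
                    drawsMatrix(fit)[, "gamma"] < 1))
})

test_that("MCMC fit is reproducible given the seed", {
  sim <- generateDataset(nUnits = 5L, nYears = 4L, initialUnits = 5L,
                         missingFraction = 0, seed = 21L)
  f1 <- suppressWarnings(fitMCMC(sim$data, nChains = 2L, nIter = 300L,
                                 nWarmup = 150L, thin = 1L, seed = 5L))
  f2 <- suppressWarnings(fitMCMC(sim$data, nChains = 2L, nIter = 300L,
                                 nWarmup = 150L, thin = 1L, seed = 5L))
  expect_identical(drawsMatrix(f1), drawsMatrix(f2))
})

test_that("posterior predictive P-values are calibrated and bounded", {
  sf <- smallFit()
  pp <- posteriorPredictiveCheck(sf$fit, sf$sim$data, seed = 3)
  expect_length(pp, 6L)
  expect_true(all(pp >= 0 & pp <= 1))
  ## the model generated these data, so discrepancies should be mild
  expect_true(mean(pp > 0.05 & pp < 0.95) >= 0.5)
})

test_that("extreme data discrepancy drives the Bayesian P-value to zero", {
  sf <- smallFit()
  d <- sf$sim$data
  C <- captureMatrix(d)
  C[!is.na(C)] <- C[!is.na(C)] + 100000L   # observed far above replicates
  dBig <- new("RemovalData", network = network(d), years = years(d),
              effort = effortMatrix(d), captures = C)
  pp <- posteriorPredictiveCheck(sf$fit, dBig, seed = 3)
  expect_true(all(pp == 0))
})

test_that("fixed-effect contribution hits its analytic extremes", {
  net <- chainNetwork(6, seed = 2)
  set.seed(3)
  ## beta = 0, spatially varying rho -> delta = 0
  p0 <- makePosterior(net, alpha = rep(1, 4), lambda = rep(0, 4),
                      beta = matrix(0, 4, 5), beta6 = rep(-0.2, 4),
                      rho = matrix(rnorm(24), 4, 6))
  c0 <- fixedEffectContribution(p0, net)
  expect_equal(c0@median, 0)
  ## constant rho, non-zero beta -> delta = 1
  p1 <- makePosterior(net, alpha = rep(1, 4), lambda = rep(0, 4),
                      beta = matrix(rnorm(20), 4, 5), beta6 = rep(-0.2, 4),
                      rho = matrix(0.7, 4, 6))
  c1 <- fixedEffectContribution(p1, net)
  expect_equal(c1@median, 1)
  expect_true(all(c1@delta >= 0 & c1@delta <= 1))
  ## both degenerate -> draw excluded, not NaN
  p2 <- makePosterior(net, alpha = 1, lambda = 0, beta = matrix(0, 1, 5),
                      beta6 = -0.2, rho = matrix(0.7, 1, 6))
  expect_error(fixedEffectContribution(p2, net), NA)
  expect_equal(fixedEffectContribution(p2, net)@excluded, 1L)
})

test_that("observation likelihood is invariant to record order", {
  sim <- generateDataset(nUnits = 6L, nYears = 4L, initialUnits = 5L,
                         seed = 31L)
  dir1 <- withr::local_tempdir()
  writeDataset(sim$data, dir1)
  rem <- read.csv(file.path(dir1, "removal.csv"), comment.char = "#")
  set.seed(1)
  rem <- rem[sample(nrow(rem)), ]
  write.csv(rem, file.path(dir1, "removal_shuffled.csv"), row.names = FALSE)
  d1 <- loadDataset(file.path(dir1, "removal.csv"),
                    file.path(dir1, "covariates.csv"),
                    file.path(dir1, "adjacency.csv"))
  d2 <- loadDataset(file.path(dir1, "removal_shuffled.csv"),
                    file.path(dir1, "covariates.csv"),
                    file.path(dir1, "adjacency.csv"))
  p <- sim$params
  expect_identical(logJointDensity(d1, p, sim$mu),
                   logJointDensity(d2, p, sim$mu))
})

test_that("a near-nonspatial fit agrees with an independent non-spatial sampler", {
  ## data generated without spatial structure or covariate effects; the
  ## full spatial model should recover the same density dependence and
  ## effort effect as a dedicated non-spatial Gompertz state-space fit
  ## written directly in JAGS
  I <- 6L; T <- 8L
  net <- chainNetwork(I, seed = 13)
  p <- GompertzParams(alpha = 1.2, lambda = -0.2, beta = rep(0, 5),
                      beta6 = -0.3, sigmaRho = 1e-4, sigmaOmega = 1e-4,
                      sigmaE = 0.25, sigma1 = 0.8, rho = rep(0, I))
  set.seed(99)
  E <- matrix(runif(I * T, 200, 2500), I, T)   # effort variation
  sim <- simulatePopulation(net, p, E, seed = 17)
  full <- suppressWarnings(fitMCMC(sim$data, nChains = 2L, nIter = 1500L,
                                   nWarmup = 500L, thin = 2L, seed = 2L))

  reduced <- "model {
    for (i in 1:I) {
      mu[i, 1] ~ dnorm(0, tau1)
      for (t in 1:Tm1) {
        mu[i, t + 1] ~ dnorm(alpha + lambda * mu[i, t] + beta6 * E100[i, t],
                             taue)
      }
      for (t in 1:T) { C[i, t] ~ dpois(E[i, t] * exp(mu[i, t])) }
    }
    alpha ~ dnorm(0, 1.0E-4); lambda ~ dnorm(0, 1.0E-4)
    beta6 ~ dnorm(0, 1.0E-4)
    sigma_e ~ dunif(0, 10); taue <- pow(sigma_e, -2)
    sigma_1 ~ dnorm(0, 0.01) T(0,); tau1 <- pow(sigma_1, -2)
  }"
  jd <- list(I = I, T = T, Tm1 = T - 1L, E = E,
             E100 = E[, 1:(T - 1)] / 100, C = captureMatrix(sim$data))
  jm <- rjags::jags.model(textConnection(reduced), data = jd, n.chains = 2,
                          n.adapt = 500, quiet = TRUE,
                          inits = list(
                            list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = 1),
                            list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = 2)))
  update(jm, 500, progress.bar = "none")
  red <- rjags::coda.samples(jm, c("alpha", "lambda", "beta6"),
                             n.iter = 1000, progress.bar = "none")
  redMean <- summary(red)$statistics[, "Mean"]

  dm <- drawsMatrix(full)
  expect_lt(abs(mean(dm[, "lambda"]) - redMean[["lambda"]]), 0.1)
  expect_lt(abs(mean(dm[, "beta6"]) - redMean[["beta6"]]), 0.1)
})
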