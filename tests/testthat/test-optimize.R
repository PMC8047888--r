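## 2-unit corner-solution toy: one draw with per-unit equilibrium
## densities (10, 1) at zero effort and marginal coefficient -1 per
## trap-day; the optimum puts the whole budget on unit 1
cornerToy <- function() {
  net <- chainNetwork(2, seed = 1)
  ## c_i = 100 exp(alpha + rho_i), b = beta6/100 = -1 (lambda = 0)
  ps <- makePosterior(net, alpha = log(0.1), lambda = 0,
                      beta = matrix(0, 1, 5), beta6 = -100,
                      rho = matrix(c(0, log(0.1)), 1, 2))
  list(net = net, ps = ps)
}

## independent brute-force oracle: grid search over E1 at step 1e-3
cornerOracle <- function(Etotal = 2) {
  e1 <- seq(0, Etotal, by = 1e-3)
  U <- 10 * exp(-e1) + 1 * exp(-(Etotal - e1))
  e1[which.min(U)]
}

test_that("softmax allocation satisfies the budget exactly", {
  a <- softmaxAllocation(c(0, 0), 300)
  expect_equal(unname(effortVector(a)), c(100, 100, 100))
  b <- softmaxAllocation(c(log(2), 0), 300)
  expect_equal(unname(effortVector(b)), c(150, 75, 75))
  set.seed(4)
  for (rep in 1:20) {
    al <- softmaxAllocation(rnorm(30, 0, 4), 12345)
    expect_equal(sum(effortVector(al)), 12345, tolerance = 1e-12)
    expect_true(all(effortVector(al) >= 0))
  }
  ## large auxiliary values must not overflow
  big <- softmaxAllocation(c(800, 0), 100)
  expect_equal(sum(effortVector(big)), 100)
  expect_error(softmaxAllocation(c(Inf, 0), 1), "finite")
})

test_that("improvement percentages reproduce the ratio definition", {
  expect_equal(improvementPercent(329.656, 340.573), 3.2055, tolerance = 1e-4)
  expect_equal(improvementPercent(329.656, 341.0381), 3.3375,
               tolerance = 1e-4)
  expect_equal(improvementPercent(5, 5), 0)
  expect_error(improvementPercent(1, 0), "Uref")
})

test_that("all three optimizers find the corner solution of the 2-unit toy", {
  toy <- cornerToy()
  e1Star <- cornerOracle(2)
  expect_equal(e1Star, 2)           # the oracle itself picks the corner

  sa <- optimizeSA(toy$ps, toy$net, 2, steps = 20000, seed = 3)
  expect_equal(unname(effortVector(sa$allocation))[1], 2, tolerance = 0.01)

  gr <- optimizeGreedy(toy$ps, toy$net, 2)
  expect_equal(unname(effortVector(gr)), c(2, 0), tolerance = 1e-9)

  kk <- kktWaterfilling(toy$ps, toy$net, 2)
  expect_equal(unname(effortVector(kk))[1], 2, tolerance = 1e-6)
})

test_that("identical units receive identical effort", {
  I <- 6L
  ps <- homogeneousPosterior(I, N = 15, seed = 2)
  net <- chainNetwork(I, seed = 2)
  Et <- 6000
  kk <- kktWaterfilling(ps, net, Et)
  expect_equal(unname(effortVector(kk)), rep(Et / I, I), tolerance = 1e-6)
  gr <- optimizeGreedy(ps, net, Et, increment = Et / 600)
  expect_true(max(abs(effortVector(gr) - Et / I)) <= Et / 600 + 1e-9)
  sa <- optimizeSA(ps, net, Et, steps = 20000, seed = 5)
  uUnif <- objectiveU(ps, net, uniformAllocation(net, Et))@U
  expect_lte(sa$result@U, uUnif + 1e-9)
})

test_that("greedy is deterministic and breaks ties by lowest unit index", {
  ps <- homogeneousPosterior(4, N = 10, seed = 3)
  net <- chainNetwork(4, seed = 3)
  g1 <- optimizeGreedy(ps, net, 100, increment = 100)
  ## a single increment goes to the first of the tied units
  expect_equal(unname(effortVector(g1)), c(100, 0, 0, 0))
  g2 <- optimizeGreedy(ps, net, 1000)
  g3 <- optimizeGreedy(ps, net, 1000)
  expect_identical(effortVector(g2), effortVector(g3))
  expect_error(optimizeGreedy(ps, net, 100, increment = 0), "increment")
})

test_that("SA, greedy and water-filling agree on random convex instances", {
  cases <- list(c(I = 10, N = 50, seed = 101),
                c(I = 30, N = 120, seed = 102))
  for (cs in cases) {
    ps <- randomPosterior(cs["I"], cs["N"], seed = cs["seed"])
    net <- generateRiverNetwork(cs["I"], branching = 0.2,
                                seed = cs["seed"])
    Et <- 400 * cs["I"]
    uOf <- function(alloc) objectiveU(ps, net, alloc)@U
    uKK <- uOf(kktWaterfilling(ps, net, Et))
    uGR <- uOf(optimizeGreedy(ps, net, Et))
    uSA <- optimizeSA(ps, net, Et, steps = 15000, seed = 1)$result@U
    expect_lt(abs(uGR - uKK) / uKK, 0.01)
    expect_lt(abs(uSA - uKK) / uKK, 0.01)
    expect_gte(uSA, uKK - 1e-9 * uKK)   # KKT is the exact optimum
  }
})

test_that("water-filling refuses non-convex coefficient configurations", {
  net <- chainNetwork(3, seed = 1)
  psMixed <- makePosterior(net, alpha = c(1, 1), lambda = c(0, 0),
                           beta = matrix(0, 2, 5), beta6 = c(-0.3, 0.2))
  expect_error(kktWaterfilling(psMixed, net, 100), "non-convex")
  psFlat <- makePosterior(net, alpha = 1, lambda = 0,
                          beta = matrix(0, 1, 5), beta6 = 0.1)
  expect_error(kktWaterfilling(psFlat, net, 100), "never reduces")
})

test_that("scenario table has coherent objectives and improvements", {
  I <- 10L
  ps <- randomPosterior(I, 60, seed = 12)
  net <- generateRiverNetwork(I, branching = 0.2, seed = 12)
  set.seed(7)
  base <- runif(I, 50, 400)
  tab <- scenarioTable(ps, net, Allocation(base, unitIds = unitIds(net)),
                       multipliers = c(1, 2, 4), steps = 10000, seed = 2)
  expect_equal(tab$multiplier, c(1, 2, 4))
  ## optimal never worse than either reference (up to SA tolerance)
  expect_true(all(tab$U_OA <= pmin(tab$U_UA, tab$U_AA) * (1 + 1e-6)))
  expect_true(all(diff(tab$U_OA) < 0))   # more budget never hurts
  expect_equal(tab$impr_vs_UA, 100 * (1 - tab$U_OA / tab$U_UA))
  expect_equal(tab$d_OA, tab$U_OA / (100 * I))
  expect_true(all(tab$impr_vs_UA >= -1e-6))
})

test_that("spatially homogeneous systems gain nothing from optimization", {
  I <- 8L
  ps <- homogeneousPosterior(I, N = 25, seed = 6)
  net <- chainNetwork(I, seed = 6)
  tab <- scenarioTable(ps, net, uniformAllocation(net, 4000),
                       multipliers = c(1, 3), steps = 10000, seed = 3)
  expect_true(all(abs(tab$impr_vs_UA) < 0.05))
  expect_true(all(abs(tab$impr_vs_AA) < 0.05))
})

test_that("optimizer outputs are valid allocations", {
  ps <- randomPosterior(9, 40, seed = 8)
  net <- generateRiverNetwork(9, branching = 0.2, seed = 8)
  for (al in list(optimizeSA(ps, net, 900, steps = 5000,
                             seed = 1)$allocation,
                  optimizeGreedy(ps, net, 900),
                  kktWaterfilling(ps, net, 900))) {
    expect_true(validObject(al))
    expect_equal(sum(effortVector(al)), 900, tolerance = 1e-9)
    expect_true(all(effortVector(al) >= 0))
  }
})
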