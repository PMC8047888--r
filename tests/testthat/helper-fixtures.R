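## shared builders for the test suite; everything is generated in code

## chain network with K covariates
chainNetwork <- function(I, K = 5L, seed = 1L) {
  generateRiverNetwork(I, branching = 0, seed = seed, nCovariates = K)
}

## hand-build a PosteriorSamples object from explicit per-draw parameter
## values, bypassing MCMC; used to test the posterior-consuming modules
## against known coefficients.
## alpha, lambda, beta6, sigmaOmega, sigmaE: length-N vectors (recycled);
## beta: N x K matrix; rho: N x I matrix; muT: N x I matrix of final-year
## latent states.
makePosterior <- function(network, alpha, lambda, beta, beta6,
                          rho = NULL, muT = NULL, sigmaOmega = 0.2,
                          sigmaE = 0.3, gamma = 0.5, sigmaRho = 0.5,
                          sigma1 = 1, nYears = 2L) {
  I <- nUnits(network)
  K <- ncol(covariates(network))
  N <- max(length(alpha), length(lambda), length(beta6),
           if (is.null(beta)) 0L else nrow(as.matrix(beta)),
           if (is.null(rho)) 0L else nrow(as.matrix(rho)))
  rec <- function(x) rep_len(x, N)
  if (is.null(beta)) beta <- matrix(0, N, K)
  beta <- matrix(as.matrix(beta), N, K)
  if (is.null(rho)) rho <- matrix(0, N, I)
  rho <- matrix(as.matrix(rho), N, I)
  if (is.null(muT)) muT <- matrix(0, N, I)
  cols <- cbind(alpha = rec(alpha), lambda = rec(lambda))
  for (k in seq_len(K)) cols <- cbind(cols, beta[, k])
  cols <- cbind(cols, rec(beta6), rec(gamma), rec(sigmaRho),
                rec(sigmaOmega), rec(sigmaE), rec(sigma1), rho)
  nm <- c("alpha", "lambda", paste0("beta", seq_len(K)),
          "beta6", "gamma", "sigma_rho", "sigma_omega",
          "sigma_e", "sigma_1", sprintf("rho[%d]", seq_len(I)))
  muCols <- NULL
  for (t in seq_len(nYears)) {
    muCols <- cbind(muCols, if (t == nYears) muT else matrix(0, N, I))
    nm <- c(nm, sprintf("mu[%d,%d]", seq_len(I), t))
  }
  ## omega columns for completeness
  om <- matrix(0, N, max(nYears - 1L, 1L))
  draws <- cbind(cols, om, muCols)
  colnames(draws) <- c(nm[seq_len(ncol(cols))],
                       sprintf("omega[%d]", seq_len(ncol(om))),
                       nm[-seq_len(ncol(cols))])
  new("PosteriorSamples", draws = draws,
      chain = rep(1L, N), nChains = 1L, nWarmup = 0L,
      nKept = N, thin = 1L, rhat = numeric(0),
      unitIds = unitIds(network), years = as.character(seq_len(nYears)))
}

## a network whose units are exchangeable for symmetry tests: zero
## covariate effects and zero spatial field in every draw
homogeneousPosterior <- function(I, N = 20L, seed = 1L) {
  set.seed(seed)
  net <- chainNetwork(I, seed = seed)
  makePosterior(net,
                alpha = rnorm(N, 1.5, 0.1),
                lambda = runif(N, -0.3, 0.2),
                beta = matrix(0, N, 5L),
                beta6 = rnorm(N, -0.3, 0.05))
}

## random convex allocation instance: heterogeneous units, all draws with
## negative effort effect
randomPosterior <- function(I, N, seed) {
  set.seed(seed)
  net <- generateRiverNetwork(I, branching = 0.2, seed = seed)
  makePosterior(net,
                alpha = rnorm(N, 1.8, 0.2),
                lambda = runif(N, -0.4, 0.3),
                beta = matrix(rnorm(N * 5, 0, 0.1), N, 5L),
                beta6 = -abs(rnorm(N, 0.3, 0.08)),
                rho = matrix(rnorm(N * I, 0, 0.6), N, I))
}

## one small real MCMC fit shared across test files (memoised)
.fitCache <- new.env(parent = emptyenv())
smallFit <- function() {
  if (is.null(.fitCache$fit)) {
    sim <- generateDataset(nUnits = 8L, nYears = 6L, initialUnits = 8L,
                           missingFraction = 0.05, seed = 11L)
    fit <- suppressWarnings(
      fitMCMC(sim$data, nChains = 2L, nIter = 800L, nWarmup = 400L,
              thin = 2L, seed = 7L))
    .fitCache$fit <- list(sim = sim, fit = fit)
  }
  .fitCache$fit
}
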