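#' Construct a GompertzParams object
#'
#' @param alpha,lambda,beta,beta6,gamma,sigmaRho,sigmaOmega,sigmaE,sigma1
#'   see [GompertzParams-class].
#' @param rho,omega optional pre-specified spatial field / year effects;
#'   left empty they are drawn freshly by [simulatePopulation()].
#' @return a validated [GompertzParams-class].
#' @export
GompertzParams <- function(alpha, lambda, beta, beta6, gamma = 0.5,
                           sigmaRho = 0.5, sigmaOmega = 0.2, sigmaE = 0.3,
                           sigma1 = 1, rho = numeric(0),
                           omega = numeric(0)) {
  new("GompertzParams", alpha = alpha, lambda = lambda, beta = beta,
      beta6 = beta6, gamma = gamma, sigmaRho = sigmaRho,
      sigmaOmega = sigmaOmega, sigmaE = sigmaE, sigma1 = sigma1,
      rho = rho, omega = omega)
}

#' Default generating parameters of the synthetic study conditions
#'
#' Values typical of a controlled snapping-turtle removal system:
#' strong positive growth at low density (`alpha = 1.9`), weak oscillatory
#' density dependence (`lambda = -0.16`), removal effect `beta6 = -0.26`
#' per 100 trap-days, and modest covariate effects.
#'
#' @return a [GompertzParams-class].
#' @export
defaultTrueParams <- function() {
  GompertzParams(alpha = 1.9, lambda = -0.16,
                 beta = c(-0.05, -0.04, 0.18, 0.11, 0.01), beta6 = -0.26,
                 gamma = 0.5, sigmaRho = 0.5, sigmaOmega = 0.2,
                 sigmaE = 0.3, sigma1 = 1)
}

## independent sub-streams from one master seed, so the spatial field,
## process noise and observation layers are individually reproducible
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the Gompertz state-space process and removal observations
#'
#' Runs the forward model: initial states \eqn{\mu_{i,1} \sim N(0,
#' \sigma_1^2)}, the Gompertz recursion with covariates, effort effect
#' (effort scaled by 100 trap-days), CAR field, year effects and unit-year
#' noise, then Poisson captures \eqn{C_{i,t} \sim Pois(E_{i,t}
#' e^{\mu_{i,t}})} wherever effort is observed. Missing effort cells (`NA`)
#' produce missing captures; the effort term in the process model treats
#' them as zero trap-days.
#'
#' @param network a [RiverNetwork-class].
#' @param params a [GompertzParams-class]; if `rho`/`omega` slots are empty
#'   they are drawn (CAR / N(0, sigmaOmega^2)).
#' @param effort I x T matrix of trap-days (`NA` = unit-year not trapped).
#' @param seed optional master seed (sub-streams: field, process,
#'   observation).
#' @return list with `mu` (I x T latent log relative densities), `data`
#'   (a [RemovalData-class]) and `params` (with `rho`, `omega` filled in).
#' @export
simulatePopulation <- function(network, params, effort, seed = NULL) {
  I <- nUnits(network)
  effort <- as.matrix(effort)
  if (nrow(effort) != I) stop("effort must have one row per unit")
  T <- ncol(effort)
  if (any(effort < 0, na.rm = TRUE)) stop("negative effort")
  if (length(params@beta) != ncol(covariates(network)))
    stop("length(beta) must match the number of covariates")
  if (!is.null(seed)) {
    ss <- .subSeeds(seed, 3L)
  } else ss <- rep(list(NULL), 3L)

  rho <- params@rho
  if (length(rho) == 0L) {
    rho <- if (params@sigmaRho > 0)
      sampleCARField(network, params@gamma, params@sigmaRho,
                     seed = ss[[1L]])
    else rep(0, I)
  } else if (length(rho) != I) stop("rho must have length I")

  if (!is.null(ss[[2L]])) set.seed(ss[[2L]])
  omega <- params@omega
  if (length(omega) == 0L) omega <- rnorm(max(T - 1L, 0L), 0,
                                          params@sigmaOmega)
  else if (length(omega) != T - 1L) stop("omega must have length T - 1")

  E100 <- effort / 100
  E100[is.na(E100)] <- 0
  fixed <- drop(covariates(network) %*% params@beta)
  mu <- matrix(NA_real_, I, T, dimnames = list(unitIds(network), NULL))
  mu[, 1L] <- rnorm(I, 0, params@sigma1)
  for (t in seq_len(T - 1L))
    mu[, t + 1L] <- params@alpha + params@lambda * mu[, t] + fixed +
      params@beta6 * E100[, t] + rho + omega[t] +
      rnorm(I, 0, params@sigmaE)

  if (!is.null(ss[[3L]])) set.seed(ss[[3L]])
  C <- matrix(NA_real_, I, T)
  obs <- !is.na(effort)
  C[obs] <- rpois(sum(obs), effort[obs] * exp(mu[obs]))

  years <- as.character(seq_len(T))
  dimnames(mu) <- dimnames(C) <- dimnames(effort) <-
    list(unitIds(network), years)
  params@rho <- as.numeric(rho)
  params@omega <- omega
  data <- new("RemovalData", network = network, years = years,
              effort = effort, captures = C)
  list(mu = mu, data = data, params = params)
}

## default effort schedule of the synthetic study conditions: trap lines
## persist across years, so each unit gets a Gamma-distributed base
## effort (mean trap-days, coefficient of variation cv) with modest
## lognormal year-to-year jitter; units enter the program staggered and
## a small fraction of remaining unit-years is missing at random
.defaultEffort <- function(I, T, mean = 2000, cv = 0.4, initialUnits = 41L,
                           missingFraction = 0.05, yearJitter = 0.15) {
  shape <- 1 / cv^2
  base <- rgamma(I, shape = shape, scale = mean / shape)
  E <- base * matrix(exp(rnorm(I * T, -yearJitter^2 / 2, yearJitter)),
                     I, T)
  if (initialUnits < I && T > 1L) {
    entry <- sample(2:min(6L, T), I - initialUnits, replace = TRUE)
    for (j in seq_along(entry))
      E[initialUnits + j, seq_len(entry[j] - 1L)] <- NA
  }
  if (missingFraction > 0) {
    idx <- which(!is.na(E))
    drop <- sample(idx, round(missingFraction * length(idx)))
    E[drop] <- NA
  }
  E
}

#' Generate a complete synthetic removal dataset
#'
#' Packages the network generator, CAR field and population simulator into
#' one reproducible scenario, defaulting to the study conditions: 75 river
#' sections observed over 9 annual steps, effort of ~2000 trap-days per
#' trapped unit-year (Gamma, CV 0.6), 41 units trapped from the first year
#' with the remainder entering in years 2-6, and 5% of remaining unit-years
#' missing at random.
#'
#' @param nUnits,nYears dimensions of the scenario.
#' @param params generating [GompertzParams-class]
#'   (default [defaultTrueParams()]).
#' @param effort optional I x T effort matrix; generated if `NULL`.
#' @param branching network branching probability.
#' @param effortMean,effortCV mean and across-unit coefficient of
#'   variation of the persistent per-unit trap-day effort.
#' @param initialUnits units already trapped in year 1.
#' @param missingFraction random missing unit-year fraction.
#' @param seed master seed (sub-streams: network, effort, population).
#' @return list with `data`, `mu`, `params`, `network`.
#' @export
generateDataset <- function(nUnits = 75L, nYears = 9L,
                            params = defaultTrueParams(), effort = NULL,
                            branching = 0.1, effortMean = 2000,
                            effortCV = 0.4, initialUnits = 41L,
                            missingFraction = 0.05, seed = 1L) {
  if (nUnits < 2L || nYears < 1L) stop("need nUnits >= 2 and nYears >= 1")
  ss <- .subSeeds(seed, 3L)
  net <- generateRiverNetwork(nUnits, branching = branching, seed = ss[1L])
  if (is.null(effort)) {
    set.seed(ss[2L])
    effort <- .defaultEffort(nUnits, nYears, mean = effortMean,
                             cv = effortCV,
                             initialUnits = min(initialUnits, nUnits),
                             missingFraction = missingFraction)
  } else {
    effort <- as.matrix(effort)
    if (!all(dim(effort) == c(nUnits, nYears)))
      stop("effort must be an nUnits x nYears matrix")
  }
  sim <- simulatePopulation(net, params, effort, seed = ss[3L])
  c(sim, list(network = net))
}
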