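## JAGS model. The CAR field enters as one joint multivariate-normal node
## with precision (D - gamma W) * tau_rho, identical to the per-unit
## conditionals N(gamma * mean of neighbours * ..., sigma_rho^2 / k_i).
## Priors: effectively-flat Normal(0, sd 100) on regression parameters,
## half-Normal(scale 10) on sigma_omega and sigma_1, Uniform(0, 10) on
## sigma_e and sigma_rho, Uniform(0, 1) on gamma.
.jagsModelString <- function() {
"model {
  for (i in 1:I) {
    mu[i, 1] ~ dnorm(0, tau1)
    fix[i] <- inprod(beta[1:K], H[i, 1:K])
    for (t in 1:Tm1) {
      mu[i, t + 1] ~ dnorm(alpha + lambda * mu[i, t] + fix[i] +
                           beta6 * E100[i, t] + rho[i] + omega[t], taue)
    }
  }
  for (t in 1:Tm1) { omega[t] ~ dnorm(0, tauom) }
  for (n in 1:Nobs) {
    C[n] ~ dpois(Eobs[n] * exp(mu[unit[n], year[n]]))
  }
  rho[1:I] ~ dmnorm(zeros[1:I], Prho[1:I, 1:I])
  for (i in 1:I) { for (j in 1:I) {
    Prho[i, j] <- (D[i, j] - gamma * W[i, j]) * taurho
  } }
  alpha  ~ dnorm(0, 1.0E-4)
  lambda ~ dnorm(0, 1.0E-4)
  for (k in 1:K) { beta[k] ~ dnorm(0, 1.0E-4) }
  beta6 ~ dnorm(0, 1.0E-4)
  gamma ~ dunif(0, 1)
  sigma_rho ~ dunif(0, 10)
  taurho <- pow(sigma_rho, -2)
  sigma_e ~ dunif(0, 10)
  taue <- pow(sigma_e, -2)
  sigma_omega ~ dnorm(0, 0.01) T(0,)
  tauom <- pow(sigma_omega, -2)
  sigma_1 ~ dnorm(0, 0.01) T(0,)
  tau1 <- pow(sigma_1, -2)
}"
}

.jagsData <- function(data) {
  net <- network(data)
  E <- effortMatrix(data); C <- captureMatrix(data)
  I <- nrow(E); T <- ncol(E)
  obs <- which(!is.na(E))
  E100 <- E[, seq_len(T - 1L), drop = FALSE] / 100
  E100[is.na(E100)] <- 0
  W <- adjacencyMatrix(net)
  list(I = I, Tm1 = T - 1L, K = ncol(covariates(net)),
       H = unname(covariates(net)), E100 = unname(E100),
       Nobs = length(obs), C = as.integer(C[obs]), Eobs = as.numeric(E[obs]),
       unit = as.integer((obs - 1L) %% I + 1L),
       year = as.integer((obs - 1L) %/% I + 1L),
       W = unname(W), D = diag(rowSums(W)), zeros = rep(0, I))
}

## translate JAGS variable names to the package's columnar schema
.renameDrawColumns <- function(nm) {
  nm <- sub("^beta\\[(\\d+)\\]$", "beta\\1", nm)
  nm
}

#' Fit the spatial Gompertz state-space model by MCMC
#'
#' Samples the joint posterior of the observation model (Poisson captures
#' proportional to effort times relative density), the Gompertz process
#' model with covariates, effort effect (per 100 trap-days), proper CAR
#' spatial field, year effects and unit-year noise, and the latent log
#' relative densities, using JAGS. The default configuration retains
#' `nChains * (nIter - nWarmup) / thin = 5000` draws. Split-R-hat is
#' computed for every monitored scalar; a warning (not an error) is raised
#' if any exceeds the 1.1 convergence criterion.
#'
#' @param data a [RemovalData-class].
#' @param nChains,nIter,nWarmup,thin MCMC configuration (defaults: 4 chains
#'   of 10000 iterations, 5000 warmup, thinning 4).
#' @param seed master seed controlling all chains.
#' @param quiet suppress JAGS progress output.
#' @return a [PosteriorSamples-class].
#' @export
fitMCMC <- function(data, nChains = 4L, nIter = 10000L, nWarmup = 5000L,
                    thin = 4L, seed = 1L, quiet = TRUE) {
  stopifnot(is(data, "RemovalData"))
  validObject(data)
  if (nChains < 1L || nIter <= nWarmup || thin < 1L)
    stop("invalid MCMC configuration")
  jd <- .jagsData(data)
  if (jd$K >= 6L)
    stop("at most 5 environmental covariates are supported")
  if (any(!is.finite(jd$Eobs)) || any(!is.finite(jd$C)))
    stop("non-finite data")
  I <- jd$I; T <- jd$Tm1 + 1L; K <- jd$K

  ## overdispersed but sane chain starts around the crude CPUE surface
  E <- effortMatrix(data); C <- captureMatrix(data)
  mu0 <- log((C + 0.5) / pmax(E, 1))
  mu0[is.na(mu0)] <- mean(mu0, na.rm = TRUE)
  chainSeeds <- .subSeeds(seed, nChains)
  inits <- lapply(seq_len(nChains), function(ch) {
    set.seed(chainSeeds[ch])
    list(alpha = rnorm(1, 0, 1), lambda = runif(1, -0.5, 0.5),
         beta = rnorm(K, 0, 0.2), beta6 = rnorm(1, 0, 0.2),
         gamma = runif(1, 0.2, 0.8),
         sigma_rho = runif(1, 0.2, 1), sigma_e = runif(1, 0.2, 1),
         sigma_omega = runif(1, 0.1, 0.5), sigma_1 = runif(1, 0.5, 2),
         mu = mu0 + matrix(rnorm(I * T, 0, 0.1), I, T),
         rho = rep(0, I),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = chainSeeds[ch])
  })

  nAdapt <- max(100L, min(1000L, nWarmup %/% 2L))
  jm <- rjags::jags.model(textConnection(.jagsModelString()), data = jd,
                          inits = inits, n.chains = nChains,
                          n.adapt = nAdapt, quiet = quiet)
  if (nWarmup > nAdapt) update(jm, nWarmup - nAdapt,
                               progress.bar = if (quiet) "none" else "text")
  monitor <- c("alpha", "lambda", "beta", "beta6", "gamma", "sigma_rho",
               "sigma_omega", "sigma_e", "sigma_1", "rho", "omega", "mu")
  sam <- rjags::coda.samples(jm, monitor, n.iter = nIter - nWarmup,
                             thin = thin,
                             progress.bar = if (quiet) "none" else "text")

  perChain <- nrow(sam[[1L]])
  mats <- lapply(sam, as.matrix)
  draws <- do.call(rbind, mats)
  colnames(draws) <- .renameDrawColumns(colnames(draws))
  keep <- c("alpha", "lambda", paste0("beta", seq_len(K)), "beta6", "gamma",
            "sigma_rho", "sigma_omega", "sigma_e", "sigma_1",
            sprintf("rho[%d]", seq_len(I)),
            sprintf("omega[%d]", seq_len(T - 1L)),
            as.vector(outer(seq_len(I), seq_len(T),
                            function(i, t) sprintf("mu[%d,%d]", i, t))))
  keep <- intersect(keep, colnames(draws))
  draws <- draws[, keep, drop = FALSE]

  rh <- vapply(colnames(draws), function(cn) {
    computeRhat(matrix(draws[, cn], nrow = perChain, ncol = nChains))
  }, numeric(1))
  if (any(rh >= 1.1, na.rm = TRUE))
    warning(sprintf(
      "convergence criterion Rhat < 1.1 not met for %d parameter(s); worst: %s = %.3f",
      sum(rh >= 1.1, na.rm = TRUE), names(rh)[which.max(rh)], max(rh,
      na.rm = TRUE)))

  new("PosteriorSamples", draws = draws,
      chain = rep(seq_len(nChains), each = perChain),
      nChains = as.integer(nChains), nWarmup = as.integer(nWarmup),
      nKept = nrow(draws), thin = as.integer(thin), rhat = rh,
      unitIds = unitIds(data), years = years(data))
}

#' Split-R-hat potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic on split chains: each chain is
#' halved, and R-hat compares between- and within-sequence variance across
#' the resulting 2m sequences. If no sequence has any variance and all
#' sequence means agree, 1 is returned by convention.
#'
#' @param chains a matrix with one column per chain (iterations in rows),
#'   or a list of equal-length numeric vectors.
#' @return R-hat (>= 1 up to floating error).
#' @export
computeRhat <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains")
  if (nrow(chains) < 2L) stop("chains must have length >= 2")
  n2 <- nrow(chains) %/% 2L
  halves <- cbind(chains[seq_len(n2), , drop = FALSE],
                  chains[nrow(chains) - n2 + seq_len(n2), , drop = FALSE])
  m <- colMeans(halves)
  v <- apply(halves, 2L, var)
  W <- mean(v)
  B <- var(m)                     # = B/n in the usual notation
  if (!is.finite(W) || W == 0) {
    return(if (isTRUE(all.equal(max(m) - min(m), 0))) 1 else Inf)
  }
  sqrt((n2 - 1) / n2 + B / W)
}

#' Posterior predictive check of annual total captures
#'
#' For each retained draw, replicate captures are simulated from
#' \eqn{Pois(E_{i,t} e^{\mu_{i,t}})} over the observed unit-years and
#' summed per year. The Bayesian P-value per year is
#' \eqn{P(\sum_i C^{rep} \ge \sum_i C^{obs})} with ties counted half.
#' Values near 0 or 1 flag misfit.
#'
#' @param samples a [PosteriorSamples-class] fitted to `data`.
#' @param data the [RemovalData-class] used for fitting.
#' @param seed optional seed for the replicate draws.
#' @return named numeric vector of per-year Bayesian P-values in `[0, 1]`.
#' @export
posteriorPredictiveCheck <- function(samples, data, seed = NULL) {
  stopifnot(is(samples, "PosteriorSamples"), is(data, "RemovalData"))
  E <- effortMatrix(data); C <- captureMatrix(data)
  I <- nrow(E); T <- ncol(E)
  if (!identical(samples@unitIds, unitIds(data)) ||
      !identical(samples@years, years(data)))
    stop("samples were not fitted to this dataset")
  if (!is.null(seed)) set.seed(seed)
  N <- nDraws(samples)
  p <- setNames(numeric(T), years(data))
  for (t in seq_len(T)) {
    obs <- which(!is.na(E[, t]) & E[, t] > 0)
    totObs <- sum(C[obs, t])
    cols <- sprintf("mu[%d,%d]", obs, t)
    lam <- exp(samples@draws[, cols, drop = FALSE]) *
      rep(E[obs, t], each = N)
    totRep <- rowSums(matrix(rpois(length(lam), lam), nrow = N))
    p[t] <- mean(totRep > totObs) + 0.5 * mean(totRep == totObs)
  }
  p
}

#' Relative contribution of measured environmental factors
#'
#' Per draw, compares the across-unit variance V1 of the covariate linear
#' predictor \eqn{\sum_k \beta_k H_{ki}} with the variance V2 of the CAR
#' spatial field \eqn{\rho_i}: \eqn{\delta = V_1 / (V_1 + V_2)}. A small
#' delta means spatial heterogeneity in growth is dominated by unmeasured
#' factors.
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the fitted [RiverNetwork-class].
#' @return a [ContributionSummary-class].
#' @export
fixedEffectContribution <- function(samples, network) {
  stopifnot(is(samples, "PosteriorSamples"), is(network, "RiverNetwork"))
  if (!identical(samples@unitIds, unitIds(network)))
    stop("samples and network unit ids disagree")
  H <- covariates(network)
  K <- ncol(H)
  B <- samples@draws[, paste0("beta", seq_len(K)), drop = FALSE]
  Rho <- samples@draws[, sprintf("rho[%d]", seq_len(nrow(H))),
                       drop = FALSE]
  LP <- B %*% t(H)                      # draws x units
  V1 <- apply(LP, 1L, var)
  V2 <- apply(Rho, 1L, var)
  tot <- V1 + V2
  ok <- tot > 0
  delta <- V1[ok] / tot[ok]
  new("ContributionSummary", delta = delta, median = median(delta),
      ci = unname(quantile(delta, c(0.025, 0.975))),
      excluded = as.integer(sum(!ok)))
}

## log density of the proper CAR field given a precision matrix
.logCARDensity <- function(rho, Q) {
  R <- tryCatch(chol(Q), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  sum(log(diag(R))) - length(rho) / 2 * log(2 * pi) -
    0.5 * drop(crossprod(R %*% rho))
}

#' Log joint density of one parameter draw
#'
#' The exact (unnormalized-free) log target the sampler explores:
#' observation likelihood over observed unit-years, Gompertz process
#' density, CAR field density, year-effect and initial-state densities,
#' and the prior terms. Missing unit-years contribute no observation term;
#' their effort enters the process model as 0. Returns `-Inf` outside the
#' support (gamma outside (0,1), non-positive SDs, SDs above the prior
#' bounds).
#'
#' @param data a [RemovalData-class].
#' @param params a [GompertzParams-class] with `rho` (length I) and
#'   `omega` (length T-1) filled in.
#' @param mu I x T matrix of latent log relative densities.
#' @return a single finite number, or `-Inf` outside the support.
#' @export
logJointDensity <- function(data, params, mu) {
  net <- network(data)
  E <- effortMatrix(data); C <- captureMatrix(data)
  I <- nrow(E); T <- ncol(E)
  mu <- as.matrix(mu)
  if (!all(dim(mu) == c(I, T))) stop("mu must be an I x T matrix")
  if (length(params@rho) != I) stop("rho must have length I")
  if (T > 1L && length(params@omega) != T - 1L)
    stop("omega must have length T - 1")
  if (length(params@beta) != ncol(covariates(net)))
    stop("beta length must match the covariates")

  if (params@gamma <= 0 || params@gamma >= 1) return(-Inf)
  if (params@sigmaRho <= 0 || params@sigmaE <= 0 ||
      params@sigmaOmega <= 0 || params@sigma1 <= 0) return(-Inf)
  if (params@sigmaRho > 10 || params@sigmaE > 10) return(-Inf)

  obs <- !is.na(E)
  lp <- sum(dpois(C[obs], E[obs] * exp(mu[obs]), log = TRUE))

  E100 <- E / 100
  E100[is.na(E100)] <- 0
  fixed <- drop(covariates(net) %*% params@beta)
  for (t in seq_len(T - 1L)) {
    m <- params@alpha + params@lambda * mu[, t] + fixed +
      params@beta6 * E100[, t] + params@rho + params@omega[t]
    lp <- lp + sum(dnorm(mu[, t + 1L], m, params@sigmaE, log = TRUE))
  }
  lp <- lp + sum(dnorm(mu[, 1L], 0, params@sigma1, log = TRUE))
  if (T > 1L)
    lp <- lp + sum(dnorm(params@omega, 0, params@sigmaOmega, log = TRUE))
  lp <- lp + .logCARDensity(params@rho,
                            .carPrecision(net, params@gamma,
                                          params@sigmaRho))

  ## priors (matching the sampler): Normal(0, 100) on regression terms,
  ## half-Normal(10) on sigma_omega/sigma_1, Uniform(0,10) on
  ## sigma_e/sigma_rho, Uniform(0,1) on gamma
  lp <- lp +
    dnorm(params@alpha, 0, 100, log = TRUE) +
    dnorm(params@lambda, 0, 100, log = TRUE) +
    sum(dnorm(params@beta, 0, 100, log = TRUE)) +
    dnorm(params@beta6, 0, 100, log = TRUE) +
    log(2) + dnorm(params@sigmaOmega, 0, 10, log = TRUE) +
    log(2) + dnorm(params@sigma1, 0, 10, log = TRUE) +
    2 * log(1 / 10)
  lp
}

## extract one draw of the model parameters (plus latent mu) from a
## PosteriorSamples row, as a GompertzParams + mu matrix
.drawParams <- function(samples, i) {
  d <- samples@draws[i, ]
  I <- length(samples@unitIds); T <- length(samples@years)
  K <- sum(grepl("^beta[0-9]+$", colnames(samples@draws))) - 1L
  mu <- matrix(d[as.vector(outer(seq_len(I), seq_len(T),
                                 function(a, b) sprintf("mu[%d,%d]", a, b)))],
               I, T)
  list(params = GompertzParams(
         alpha = d[["alpha"]], lambda = d[["lambda"]],
         beta = unname(d[paste0("beta", seq_len(K))]),
         beta6 = d[["beta6"]], gamma = d[["gamma"]],
         sigmaRho = d[["sigma_rho"]], sigmaOmega = d[["sigma_omega"]],
         sigmaE = d[["sigma_e"]], sigma1 = d[["sigma_1"]],
         rho = unname(d[sprintf("rho[%d]", seq_len(I))]),
         omega = unname(d[sprintf("omega[%d]", seq_len(max(T - 1L, 0L)))])),
       mu = mu)
}
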