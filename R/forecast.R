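#' Forward-simulate density trajectories under a fixed allocation
#'
#' For each retained posterior draw, starts from that draw's final-year
#' latent state and iterates the Gompertz process model forward with fresh
#' year effects (shared across units within a year, N(0, sigma_omega^2))
#' and unit-year noise (N(0, sigma_e^2)), holding the allocation fixed
#' every year. This propagates both parameter uncertainty (across draws)
#' and process stochasticity (within draws).
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the fitted [RiverNetwork-class].
#' @param allocation an [Allocation-class] applied every simulated year.
#' @param horizon number of years to simulate (>= 1; default 20).
#' @param seed optional seed; the run is reproducible given the seed.
#' @param target management target density used for the per-year summary
#'   (default 0.03).
#' @return a [TrajectoryEnsemble-class].
#' @export
forwardSimulate <- function(samples, network, allocation, horizon = 20L,
                            seed = NULL, target = 0.03) {
  stopifnot(is(samples, "PosteriorSamples"))
  if (horizon < 1L) stop("horizon must be >= 1")
  I <- length(samples@unitIds)
  T <- length(samples@years)
  E <- effortVector(allocation)
  if (length(E) != I) stop("allocation length must match the fitted units")
  if (!is.null(seed)) set.seed(seed)
  d <- samples@draws
  N <- nrow(d)
  H <- covariates(network)
  K <- ncol(H)
  lin <- d[, "alpha"] +
    d[, paste0("beta", seq_len(K)), drop = FALSE] %*% t(H) +
    d[, sprintf("rho[%d]", seq_len(I)), drop = FALSE] +
    rep(d[, "beta6"] / 100, I) * rep(E, each = N)   # draws x units
  lambda <- d[, "lambda"]
  sOm <- d[, "sigma_omega"]; sE <- d[, "sigma_e"]
  mu <- d[, sprintf("mu[%d,%d]", seq_len(I), T), drop = FALSE]
  mu <- matrix(mu, N, I)
  dens <- array(NA_real_, c(N, I, horizon))
  for (h in seq_len(horizon)) {
    om <- rnorm(N, 0, sOm)                           # shared across units
    e <- matrix(rnorm(N * I, 0, rep(sE, I)), N, I)
    mu <- lin + lambda * mu + om + e
    dens[, , h] <- exp(mu)
  }
  areaMean <- apply(dens, c(1L, 3L), mean)           # draws x horizon
  sm <- data.frame(
    year = seq_len(horizon),
    mean_density = colMeans(areaMean),
    q05 = apply(areaMean, 2L, quantile, 0.05),
    q50 = apply(areaMean, 2L, quantile, 0.50),
    q95 = apply(areaMean, 2L, quantile, 0.95),
    frac_below_target = colMeans(areaMean < target))
  new("TrajectoryEnsemble", densities = dens, allocation = allocation,
      summary = sm, target = target)
}

#' First simulation year below a target density
#'
#' Per draw, the first simulated year whose whole-area mean relative
#' density falls strictly below the threshold; `NA` if the threshold is
#' not reached within the horizon.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param threshold target density, > 0 (default 0.03).
#' @return list with `perDraw` (integer years, `NA` = not reached),
#'   `median` (ensemble median year, `NA` if fewer than half the draws
#'   reach the target) and `fracReached`.
#' @export
timeToThreshold <- function(ensemble, threshold = 0.03) {
  if (threshold <= 0) stop("threshold must be > 0")
  areaMean <- apply(ensemble@densities, c(1L, 3L), mean)
  hit <- areaMean < threshold
  perDraw <- apply(hit, 1L, function(z) {
    w <- which(z)
    if (length(w)) w[1L] else NA_integer_
  })
  fracReached <- mean(!is.na(perDraw))
  med <- if (fracReached >= 0.5) {
    ## order-statistic median so "not reached" tails cannot average in
    as.integer(quantile(ifelse(is.na(perDraw), Inf, perDraw), 0.5,
                        type = 1L))
  } else NA_integer_
  list(perDraw = perDraw, median = med, fracReached = fracReached)
}
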