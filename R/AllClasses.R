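#' @import methods
#' @importFrom stats rnorm rpois runif rgamma dpois dnorm quantile var sd
#'   median setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib removalOpt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## breadth-first search connectivity check on an undirected edge list
.isConnected <- function(nUnits, edges) {
  if (nUnits == 1L) return(TRUE)
  adj <- vector("list", nUnits)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(nUnits)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' River network of spatial management units
#'
#' An undirected graph of spatial units (e.g. 200-m river sections) carrying
#' standardized environmental covariates. Neighbourhood structure (the sets
#' \eqn{\delta_i} and counts \eqn{k_i}) is derived from the edge list and
#' drives the proper CAR spatial prior.
#'
#' @slot unitIds character vector of unit labels (length I).
#' @slot covariates numeric I x K matrix of environmental covariates, each
#'   column standardized to mean 0, SD 1.
#' @slot edges integer matrix with two columns; each row is an unordered
#'   pair of unit indices sharing an edge. No self-edges, no duplicates.
#' @export
setClass("RiverNetwork",
  slots = c(unitIds = "character", covariates = "matrix", edges = "matrix"))

setValidity("RiverNetwork", function(object) {
  I <- length(object@unitIds)
  msgs <- character()
  if (I < 2L) msgs <- c(msgs, "need at least 2 units")
  if (anyDuplicated(object@unitIds)) msgs <- c(msgs, "duplicated unit ids")
  H <- object@covariates
  if (!is.numeric(H) || nrow(H) != I)
    msgs <- c(msgs, "covariates must be a numeric matrix with one row per unit")
  else if (ncol(H) > 0L) {
    mu <- colMeans(H)
    s <- apply(H, 2L, sd)
    if (any(abs(mu) > 1e-6) || any(abs(s - 1) > 1e-6))
      msgs <- c(msgs, "covariate columns must be standardized (mean 0, SD 1)")
  }
  E <- object@edges
  if (!is.numeric(E) || ncol(E) != 2L)
    msgs <- c(msgs, "edges must be a two-column matrix")
  else {
    E <- matrix(as.integer(E), ncol = 2L)
    if (nrow(E) == 0L) msgs <- c(msgs, "no edges: graph cannot be connected")
    else {
      if (any(E < 1L) || any(E > I)) msgs <- c(msgs, "edge indices out of range")
      else {
        if (any(E[, 1L] == E[, 2L])) msgs <- c(msgs, "self-edges not allowed")
        key <- paste(pmin(E[, 1L], E[, 2L]), pmax(E[, 1L], E[, 2L]))
        if (anyDuplicated(key)) msgs <- c(msgs, "duplicated edges")
        k <- tabulate(c(E[, 1L], E[, 2L]), nbins = I)
        if (any(k == 0L))
          msgs <- c(msgs, "isolated unit(s): every unit needs >= 1 neighbour")
        else if (!.isConnected(I, E))
          msgs <- c(msgs, "graph is not connected")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Removal records on a river network
#'
#' Unit-by-year matrices of capture effort (trap-days) and capture counts.
#' A unit-year where no traps were set is missing (`NA`) in both matrices;
#' zero effort with a positive catch is impossible under the Poisson
#' observation model and is rejected.
#'
#' @slot network a [RiverNetwork-class].
#' @slot years character vector of ordered year labels (length T).
#' @slot effort numeric I x T matrix of trap-days, `NA` = not trapped.
#' @slot captures numeric I x T matrix of non-negative integer counts,
#'   `NA` exactly where effort is `NA`.
#' @export
setClass("RemovalData",
  slots = c(network = "RiverNetwork", years = "character",
            effort = "matrix", captures = "matrix"))

setValidity("RemovalData", function(object) {
  I <- length(object@network@unitIds)
  T <- length(object@years)
  E <- object@effort; C <- object@captures
  msgs <- character()
  if (T < 1L) msgs <- c(msgs, "need at least one year")
  if (!all(dim(E) == c(I, T)) || !all(dim(C) == c(I, T)))
    return("effort and captures must both be I x T matrices")
  if (!identical(is.na(E), is.na(C)))
    msgs <- c(msgs, "captures must be missing exactly where effort is missing")
  eo <- E[!is.na(E)]; co <- C[!is.na(C)]
  if (any(eo < 0)) msgs <- c(msgs, "negative effort")
  if (any(co < 0) || any(co != round(co)))
    msgs <- c(msgs, "captures must be non-negative integers")
  bad <- which(!is.na(E) & E == 0 & C > 0)
  if (length(bad))
    msgs <- c(msgs, sprintf("captures > 0 with zero effort in %d cell(s)",
                            length(bad)))
  if (length(msgs)) msgs else TRUE
})

#' Generating parameters of the Gompertz state-space model
#'
#' One complete parameter set of the process and observation model: the
#' Gompertz recursion
#' \deqn{\mu_{i,t+1} = \alpha + \lambda \mu_{i,t} + \sum_k \beta_k H_{ki} +
#'   \beta_6 E_{i,t}/100 + \rho_i + \omega_t + e_{i,t}}
#' with CAR spatial field \eqn{\rho}, year effects \eqn{\omega} and
#' Poisson captures \eqn{C_{i,t} \sim Pois(E_{i,t} e^{\mu_{i,t}})}.
#' Used both as simulation truth and as a single posterior draw.
#'
#' @slot alpha intercept of the log population growth rate.
#' @slot lambda density dependence; `|lambda| < 1` gives an equilibrium.
#' @slot beta covariate effects per +1 SD (length = ncol(covariates)).
#' @slot beta6 effort effect per 100 trap-days (negative = removal works).
#' @slot gamma CAR spatial dependence, in (0, 1).
#' @slot sigmaRho,sigmaOmega,sigmaE,sigma1 SDs of the CAR increments, year
#'   effects, unit-year process noise and initial state.
#' @slot rho spatial field (length I), may be empty to be drawn.
#' @slot omega year effects for transitions 1..T-1, may be empty.
#' @export
setClass("GompertzParams",
  slots = c(alpha = "numeric", lambda = "numeric", beta = "numeric",
            beta6 = "numeric", gamma = "numeric",
            sigmaRho = "numeric", sigmaOmega = "numeric",
            sigmaE = "numeric", sigma1 = "numeric",
            rho = "numeric", omega = "numeric"),
  prototype = list(rho = numeric(0), omega = numeric(0)))

setValidity("GompertzParams", function(object) {
  msgs <- character()
  for (nm in c("alpha", "lambda", "beta6", "gamma",
               "sigmaRho", "sigmaOmega", "sigmaE", "sigma1"))
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      msgs <- c(msgs, paste(nm, "must be a single finite number"))
  if (length(msgs)) return(msgs)
  if (object@gamma <= 0 || object@gamma >= 1)
    msgs <- c(msgs, "gamma must be in (0, 1)")
  for (nm in c("sigmaRho", "sigmaOmega", "sigmaE", "sigma1"))
    if (slot(object, nm) < 0) msgs <- c(msgs, paste(nm, "must be >= 0"))
  if (length(msgs)) msgs else TRUE
})

#' Retained MCMC draws of the state-space model
#'
#' A draws-by-parameter matrix with named columns (`alpha`, `lambda`,
#' `beta1`..`beta6`, `gamma`, `sigma_rho`, `sigma_omega`, `sigma_e`,
#' `sigma_1`, `rho[i]`, `omega[t]`, `mu[i,t]`), plus chain bookkeeping and
#' per-parameter split-R-hat.
#'
#' @slot draws numeric matrix, one row per retained draw.
#' @slot chain integer chain id per retained draw.
#' @slot nChains,nWarmup,nKept,thin MCMC configuration actually used.
#' @slot rhat named numeric vector of split-R-hat values.
#' @slot unitIds,years labels carried over from the fitted dataset.
#' @export
setClass("PosteriorSamples",
  slots = c(draws = "matrix", chain = "integer",
            nChains = "integer", nWarmup = "integer", nKept = "integer",
            thin = "integer", rhat = "numeric",
            unitIds = "character", years = "character"))

setValidity("PosteriorSamples", function(object) {
  msgs <- character()
  if (nrow(object@draws) != object@nKept)
    msgs <- c(msgs, "nKept must equal the number of retained draws")
  if (length(object@chain) != nrow(object@draws))
    msgs <- c(msgs, "chain id vector must match the number of draws")
  if (is.null(colnames(object@draws)))
    msgs <- c(msgs, "draws must have named columns")
  if (length(msgs)) msgs else TRUE
})

#' Spatial allocation of capture effort
#'
#' Non-negative per-unit efforts (trap-days) summing to a fixed total.
#'
#' @slot effort named numeric vector of trap-days per unit.
#' @slot total the fixed total effort E_total.
#' @export
setClass("Allocation", slots = c(effort = "numeric", total = "numeric"))

setValidity("Allocation", function(object) {
  msgs <- character()
  if (any(!is.finite(object@effort)) || any(object@effort < 0))
    msgs <- c(msgs, "effort entries must be finite and >= 0")
  if (length(object@total) != 1L || !is.finite(object@total) ||
      object@total < 0)
    msgs <- c(msgs, "total must be a single non-negative number")
  else if (abs(sum(object@effort) - object@total) >
           1e-6 * max(object@total, 1))
    msgs <- c(msgs, "sum(effort) must equal total (tolerance 1e-6 * total)")
  if (length(msgs)) msgs else TRUE
})

#' Posterior-averaged equilibrium-density objective
#'
#' The value of the management objective \eqn{U(E)}: the posterior mean over
#' retained draws of the whole-area equilibrium density
#' \eqn{K(E) = \sum_i 100\,e^{\mu^*_i}} (per-100-trap-day reporting scale).
#'
#' @slot U objective value (posterior mean of K).
#' @slot meanRelativeDensity U / (100 I): whole-area mean expected CPUE.
#' @slot perDrawK per-draw K values (valid draws only).
#' @slot invalidDraws number of draws excluded because `|lambda| >= 1`.
#' @export
setClass("ObjectiveResult",
  slots = c(U = "numeric", meanRelativeDensity = "numeric",
            perDrawK = "numeric", invalidDraws = "integer"))

#' Posterior summary of the fixed-effect contribution
#'
#' Per-draw values of \eqn{\delta = V_1/(V_1+V_2)} where V1 is the
#' across-unit variance of the covariate linear predictor and V2 that of
#' the CAR field, with median and 95% interval.
#'
#' @slot delta per-draw delta values in `[0, 1]`.
#' @slot median posterior median.
#' @slot ci 2.5% and 97.5% quantiles.
#' @slot excluded draws dropped because V1 + V2 = 0.
#' @export
setClass("ContributionSummary",
  slots = c(delta = "numeric", median = "numeric", ci = "numeric",
            excluded = "integer"))

#' Forward-simulated density trajectories
#'
#' Posterior-predictive trajectories of relative density exp(mu) under a
#' fixed allocation, one trajectory per retained draw.
#'
#' @slot densities draws x units x horizon array of relative densities.
#' @slot allocation the [Allocation-class] held fixed each year.
#' @slot summary per-year data.frame: mean density, quantiles, fraction of
#'   draws below the management target.
#' @slot target the management target density used in `summary`.
#' @export
setClass("TrajectoryEnsemble",
  slots = c(densities = "array", allocation = "Allocation",
            summary = "data.frame", target = "numeric"))
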