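#' Construct a RiverNetwork
#'
#' @param unitIds character vector of unit labels.
#' @param covariates numeric matrix (units x covariates), columns
#'   standardized to mean 0, SD 1.
#' @param edges two-column matrix of unit index pairs (or unit id pairs).
#' @return a validated [RiverNetwork-class].
#' @export
RiverNetwork <- function(unitIds, covariates, edges) {
  unitIds <- as.character(unitIds)
  if (is.character(edges)) {
    edges <- cbind(match(edges[, 1L], unitIds), match(edges[, 2L], unitIds))
    if (anyNA(edges)) stop("edge refers to unknown unit id")
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  covariates <- as.matrix(covariates)
  rownames(covariates) <- unitIds
  new("RiverNetwork", unitIds = unitIds, covariates = covariates,
      edges = edges)
}

#' Generate a random branching river network
#'
#' Builds a random tree emulating a river subdivided into consecutive
#' sections: unit i+1 normally attaches to unit i (a chain), and with
#' probability `branching` attaches instead to a uniformly chosen earlier
#' unit, creating a confluence. Covariates are drawn independently standard
#' normal and re-standardized column-wise so each column has exactly mean 0
#' and SD 1.
#'
#' @param nUnits number of spatial units (>= 2).
#' @param branching probability in `[0, 1]` that a new unit starts a side
#'   branch instead of extending the chain.
#' @param seed optional integer seed.
#' @param nCovariates number of covariate columns (default 5: paddy,
#'   dry_crop, slope, flow_accum, road).
#' @return a [RiverNetwork-class]; always a connected tree with
#'   `nUnits - 1` edges.
#' @export
generateRiverNetwork <- function(nUnits, branching = 0, seed = NULL,
                                 nCovariates = 5L) {
  if (length(nUnits) != 1L || nUnits < 2L)
    stop("nUnits must be a single integer >= 2")
  if (branching < 0 || branching > 1)
    stop("branching must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  nUnits <- as.integer(nUnits)
  parent <- integer(nUnits - 1L)
  for (i in 2:nUnits) {
    parent[i - 1L] <-
      if (i > 2L && runif(1) < branching) sample.int(i - 2L, 1L) else i - 1L
  }
  edges <- cbind(parent, 2:nUnits)
  H <- matrix(rnorm(nUnits * nCovariates), nUnits, nCovariates)
  H <- scale(H)
  attr(H, "scaled:center") <- NULL
  attr(H, "scaled:scale") <- NULL
  cn <- c("paddy", "dry_crop", "slope", "flow_accum", "road")
  colnames(H) <- if (nCovariates == 5L) cn else
    paste0("cov", seq_len(nCovariates))
  RiverNetwork(sprintf("u%03d", seq_len(nUnits)), H, edges)
}

## joint precision matrix of the proper CAR field: (D - gamma W) / sigma^2.
## Its conditionals are N(gamma * sum_{j in delta_i} rho_j / k_i,
## sigma^2 / k_i), the form used in the process model.
.carPrecision <- function(network, gamma, sigmaRho) {
  if (length(gamma) != 1L || gamma <= 0 || gamma >= 1)
    stop("gamma must be in (0, 1)")
  if (length(sigmaRho) != 1L || sigmaRho <= 0)
    stop("sigmaRho must be > 0")
  W <- adjacencyMatrix(network)
  D <- diag(rowSums(W))
  (D - gamma * W) / sigmaRho^2
}

#' Draw from the proper CAR spatial prior
#'
#' Exact joint draw(s) of the spatial field \eqn{\rho} whose full
#' conditionals are
#' \eqn{\rho_i \mid \rho_{-i} \sim N(\gamma \sum_{j \in \delta_i} \rho_j /
#' k_i,\; \sigma_\rho^2 / k_i)}, obtained from the equivalent joint
#' multivariate normal with precision \eqn{(D - \gamma W)/\sigma_\rho^2}
#' via a Cholesky factor.
#'
#' @param network a [RiverNetwork-class].
#' @param gamma spatial dependence, in (0, 1).
#' @param sigmaRho conditional SD scale, > 0.
#' @param seed optional integer seed.
#' @param nDraws number of independent draws.
#' @return a named length-I vector, or an I x `nDraws` matrix if
#'   `nDraws > 1`.
#' @export
sampleCARField <- function(network, gamma, sigmaRho, seed = NULL,
                           nDraws = 1L) {
  Q <- .carPrecision(network, gamma, sigmaRho)
  R <- tryCatch(chol(Q), error = function(e)
    stop("CAR precision matrix is not positive definite"))
  if (!is.null(seed)) set.seed(seed)
  I <- nrow(Q)
  Z <- matrix(rnorm(I * nDraws), I, nDraws)
  X <- backsolve(R, Z)
  rownames(X) <- unitIds(network)
  if (nDraws == 1L) X[, 1L] else X
}
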