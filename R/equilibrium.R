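#' Construct an Allocation
#'
#' @param effort non-negative trap-days per unit (optionally named).
#' @param total fixed total effort; defaults to `sum(effort)`.
#' @param unitIds optional unit labels.
#' @return a validated [Allocation-class].
#' @export
Allocation <- function(effort, total = sum(effort), unitIds = NULL) {
  effort <- as.numeric(effort)
  if (!is.null(unitIds)) names(effort) <- unitIds
  new("Allocation", effort = effort, total = total)
}

#' Uniform allocation of a total effort
#'
#' @param x a [RiverNetwork-class], [RemovalData-class] or unit count.
#' @param total total effort in trap-days.
#' @return an [Allocation-class] with equal per-unit effort.
#' @export
uniformAllocation <- function(x, total) {
  ids <- if (is.numeric(x)) sprintf("u%03d", seq_len(x)) else unitIds(x)
  Allocation(rep(total / length(ids), length(ids)), total = total,
             unitIds = ids)
}

#' Actual (latest-year) effort allocation of a removal dataset
#'
#' Extracts the per-unit effort pattern of one observed year as an
#' [Allocation-class], the natural reference ("actual") scenario. A unit
#' not trapped in that year is filled with its mean effort over the years
#' it was trapped (0 if never trapped), so a temporary gap does not read
#' as a deliberate zero-effort policy.
#'
#' @param data a [RemovalData-class].
#' @param year year label or index (default: the latest year).
#' @return an [Allocation-class].
#' @export
actualAllocation <- function(data, year = length(years(data))) {
  E <- effortMatrix(data)
  j <- if (is.character(year)) match(year, years(data)) else year
  if (is.na(j) || j < 1L || j > ncol(E)) stop("unknown year")
  e <- E[, j]
  fill <- rowMeans(E, na.rm = TRUE)
  fill[is.nan(fill)] <- 0
  e[is.na(e)] <- fill[is.na(e)]
  Allocation(e, unitIds = unitIds(data))
}

#' Per-unit equilibrium log density of one parameter draw
#'
#' The deterministic fixed point of the Gompertz recursion with year
#' effects and process noise set to zero:
#' \deqn{\mu^*_i = \frac{\alpha + \sum_k \beta_k H_{ki} + \beta_6 E_i/100 +
#'   \rho_i}{1 - \lambda}.}
#' Requires `|lambda| < 1`; effort is supplied in trap-days.
#'
#' @param params a [GompertzParams-class] with `rho` of length I.
#' @param network a [RiverNetwork-class].
#' @param allocation an [Allocation-class] (per-unit trap-days per year).
#' @return named length-I vector of equilibrium log relative densities.
#' @export
equilibriumLogDensity <- function(params, network, allocation) {
  if (abs(params@lambda) >= 1)
    stop("|lambda| >= 1: no equilibrium for this draw")
  I <- nUnits(network)
  if (length(params@rho) != I) stop("rho must have length I")
  E <- effortVector(allocation)
  if (length(E) != I) stop("allocation length must match the network")
  lin <- params@alpha + drop(covariates(network) %*% params@beta) +
    params@beta6 * E / 100 + params@rho
  setNames(lin / (1 - params@lambda), unitIds(network))
}

## per-draw objective coefficients: K_n(E) = sum_i c[i,n] exp(b[n] E_i)
## with c on the per-100-trap-day reporting scale. Draws with
## |lambda| >= 1 have no equilibrium and are excluded (counted).
.eqCoefficients <- function(samples, network) {
  stopifnot(is(samples, "PosteriorSamples"))
  if (!identical(samples@unitIds, unitIds(network)))
    stop("samples and network unit ids disagree")
  d <- samples@draws
  I <- length(samples@unitIds)
  K <- ncol(covariates(network))
  lambda <- d[, "lambda"]
  valid <- abs(lambda) < 1
  lin <- d[, "alpha"] +
    d[, paste0("beta", seq_len(K)), drop = FALSE] %*%
      t(covariates(network)) +
    d[, sprintf("rho[%d]", seq_len(I)), drop = FALSE]   # draws x units
  oneML <- 1 - lambda[valid]
  cmat <- t(100 * exp(lin[valid, , drop = FALSE] / oneML))   # units x draws
  b <- d[valid, "beta6"] / (100 * oneML)
  list(cmat = cmat, b = b, invalid = as.integer(sum(!valid)))
}

.objectiveFromCoefs <- function(coefs, effort) {
  K <- cppObjectivePerDraw(coefs$cmat, coefs$b, effort)
  new("ObjectiveResult", U = mean(K),
      meanRelativeDensity = mean(K) / (100 * nrow(coefs$cmat)),
      perDrawK = K, invalidDraws = coefs$invalid)
}

#' Posterior-averaged equilibrium-density objective U(E)
#'
#' For each retained draw n with `|lambda| < 1`, the whole-area equilibrium
#' density \eqn{K_n(E) = \sum_i 100\, e^{\mu^*_{i,n}}} is evaluated at the
#' allocation (the factor 100 puts the objective on the per-100-trap-day
#' reporting scale); U(E) is the mean of \eqn{K_n} over valid draws, and
#' the mean relative density is U / (100 I), i.e. the expected whole-area
#' mean CPUE per trap-day. Draws without an equilibrium are excluded and
#' counted, never silently included.
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the fitted [RiverNetwork-class].
#' @param allocation an [Allocation-class].
#' @return an [ObjectiveResult-class].
#' @export
objectiveU <- function(samples, network, allocation) {
  coefs <- .eqCoefficients(samples, network)
  if (length(coefs$b) == 0L)
    stop("all draws have |lambda| >= 1: objective undefined")
  E <- effortVector(allocation)
  if (length(E) != nrow(coefs$cmat))
    stop("allocation length must match the network")
  .objectiveFromCoefs(coefs, E)
}

#' Compare mean relative density against a management target
#'
#' @param result an [ObjectiveResult-class].
#' @param target target mean CPUE (strict inequality; default 0.03, the
#'   Chiba management target).
#' @return list with `met` (TRUE iff mean relative density < target) and
#'   `margin` (target minus achieved density; positive = met).
#' @export
meanCpueVsTarget <- function(result, target = 0.03) {
  if (target <= 0) stop("target must be > 0")
  d <- result@meanRelativeDensity
  list(met = d < target, margin = target - d)
}
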