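#' Softmax reparameterization of the effort simplex
#'
#' Maps I-1 unbounded auxiliary variables to a strictly positive
#' allocation summing exactly to `Etotal`:
#' \eqn{E_i = E_{total} e^{a_i} / (1 + \sum_j e^{a_j})} for i < I and
#' \eqn{E_I = E_{total} / (1 + \sum_j e^{a_j})}. The computation is
#' max-shifted against overflow and the last component is taken as the
#' exact remainder so the budget constraint holds to machine precision.
#'
#' @param a numeric vector of I-1 finite auxiliary variables.
#' @param Etotal total effort, > 0.
#' @param unitIds optional unit labels (length I).
#' @return an [Allocation-class] with all entries > 0.
#' @export
softmaxAllocation <- function(a, Etotal, unitIds = NULL) {
  if (any(!is.finite(a))) stop("auxiliary variables must be finite")
  if (Etotal <= 0) stop("Etotal must be > 0")
  z <- c(a, 0)
  w <- exp(z - max(z))
  E <- Etotal * w / sum(w)
  E[length(E)] <- Etotal - sum(E[-length(E)])
  Allocation(E, total = Etotal, unitIds = unitIds)
}

## inverse of the softmax map (up to the shared additive constant):
## a_i = log(E_i / E_I), with zero efforts floored to keep a finite
.allocationToAux <- function(effort, Etotal) {
  eps <- 1e-9 * Etotal
  e <- pmax(effort, eps)
  log(e[-length(e)] / e[length(e)])
}

#' Percent improvement of one allocation scenario over another
#'
#' @param Uopt objective under the improved (optimal) allocation.
#' @param Uref objective under the reference allocation (> 0).
#' @return `100 * (1 - Uopt / Uref)`.
#' @export
improvementPercent <- function(Uopt, Uref) {
  if (Uref <= 0) stop("Uref must be > 0")
  100 * (1 - Uopt / Uref)
}

#' Greedy allocation of effort increments
#'
#' Splits the budget into equal increments and repeatedly assigns one
#' increment to the unit with the highest current posterior-mean
#' equilibrium density given the effort assigned so far. Ties are broken
#' by the lowest unit index. Because the objective is a sum of per-unit
#' convex (exponentially decreasing) terms, this marginal-greedy rule is
#' near-exact.
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the fitted [RiverNetwork-class].
#' @param Etotal total effort, > 0.
#' @param increment effort per step (default `Etotal / 1000`).
#' @return an [Allocation-class].
#' @export
optimizeGreedy <- function(samples, network, Etotal,
                           increment = Etotal / 1000) {
  if (increment <= 0) stop("increment must be > 0")
  if (Etotal <= 0) stop("Etotal must be > 0")
  coefs <- .eqCoefficients(samples, network)
  .greedyFromCoefs(coefs, Etotal, increment, unitIds(network))
}

.greedyFromCoefs <- function(coefs, Etotal, increment, ids) {
  I <- nrow(coefs$cmat)
  nFull <- floor(Etotal / increment)
  incs <- rep(increment, nFull)
  rem <- Etotal - nFull * increment
  if (rem > 1e-12 * Etotal) incs <- c(incs, rem)
  E <- numeric(I)
  dens <- rowMeans(coefs$cmat)      # posterior-mean density at E = 0
  for (s in seq_along(incs)) {
    j <- which.max(dens)            # first max = lowest index on ties
    E[j] <- E[j] + incs[s]
    dens[j] <- mean(coefs$cmat[j, ] * exp(coefs$b * E[j]))
  }
  Allocation(E, total = Etotal, unitIds = ids)
}

#' Minimize the equilibrium objective by simulated annealing
#'
#' Searches the softmax-reparameterized allocation simplex with
#' single-coordinate Gaussian proposals and exponential cooling,
#' restarting from the greedy solution (or a uniform allocation). The
#' best-found allocation is returned; because the objective is convex in
#' the allocation, the annealer acts as a polish step on the greedy start
#' and its result is bounded below by the exact KKT solution.
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the fitted [RiverNetwork-class].
#' @param Etotal total effort, > 0.
#' @param steps number of proposal steps (default 2e5).
#' @param t0 initial temperature (objective units).
#' @param cooling multiplicative cooling per sweep of I-1 proposals.
#' @param propSD SD of the Gaussian proposal on one auxiliary coordinate.
#' @param init `"greedy"` (default) or `"uniform"` starting allocation.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return list with `allocation` ([Allocation-class]) and `result`
#'   ([ObjectiveResult-class]).
#' @export
optimizeSA <- function(samples, network, Etotal, steps = 2e5, t0 = 1.0,
                       cooling = 0.995, propSD = 0.5,
                       init = c("greedy", "uniform"), seed = 1L) {
  if (Etotal <= 0) stop("Etotal must be > 0")
  init <- match.arg(init)
  coefs <- .eqCoefficients(samples, network)
  ids <- unitIds(network)
  I <- nrow(coefs$cmat)
  start <- if (init == "greedy")
    effortVector(.greedyFromCoefs(coefs, Etotal, Etotal / 1000, ids))
  else rep(Etotal / I, I)
  a0 <- .allocationToAux(start, Etotal)
  set.seed(seed)
  fit <- cppAnnealAllocation(a0, Etotal, coefs$cmat, coefs$b,
                             as.integer(steps), t0, cooling, propSD)
  ## keep the best of {annealed, start, uniform}: the returned solution
  ## is never worse than its own starting point or the uniform split
  cand <- list(fit$effort, start, rep(Etotal / I, I))
  us <- vapply(cand, function(e)
    mean(cppObjectivePerDraw(coefs$cmat, coefs$b, e)), numeric(1))
  E <- cand[[which.min(us)]]
  alloc <- Allocation(E, total = Etotal, unitIds = ids)
  list(allocation = alloc, result = .objectiveFromCoefs(coefs, E))
}

#' Exact KKT water-filling solution of the allocation problem
#'
#' Solves \eqn{\min \sum_i f_i(E_i)} subject to \eqn{\sum_i E_i =
#' E_{total}}, \eqn{E_i \ge 0}, where \eqn{f_i(E) = \frac1N \sum_n c_{i,n}
#' e^{b_n E}} is the posterior-mean equilibrium density of unit i
#' (convex and decreasing when every draw has a negative effort effect).
#' The KKT conditions equalize the marginal derivatives on the active set;
#' the shared multiplier is found by bisection, the per-unit inverses by a
#' vectorized inner bisection. This is deterministic and serves as the
#' exact optimum against which the stochastic optimizers are verified.
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the fitted [RiverNetwork-class].
#' @param Etotal total effort, > 0.
#' @param tol relative KKT/budget tolerance.
#' @return an [Allocation-class].
#' @export
kktWaterfilling <- function(samples, network, Etotal, tol = 1e-9) {
  if (Etotal <= 0) stop("Etotal must be > 0")
  coefs <- .eqCoefficients(samples, network)
  if (any(coefs$b >= 0)) {
    if (any(coefs$b < 0))
      stop("non-convex configuration: some draws have beta6/(1-lambda) >= 0 while others are negative")
    stop("beta6/(1-lambda) >= 0 in all draws: effort never reduces density, no interior optimum")
  }
  cmat <- coefs$cmat; b <- coefs$b
  I <- nrow(cmat)
  ## g_i(E) = -f_i'(E) = -(1/N) sum_n c_in b_n exp(b_n E) > 0, decreasing
  gAt <- function(E)
    -rowMeans(cmat * rep(b, each = I) * exp(outer(E, b)))
  g0 <- gAt(rep(0, I))
  ## per-unit E_i(nu): solve g_i(E) = nu (0 if g_i(0) <= nu)
  Eof <- function(nu) {
    active <- g0 > nu
    E <- numeric(I)
    if (!any(active)) return(E)
    lo <- rep(0, I); hi <- rep(1, I)
    repeat {                               # expand upper brackets
      gh <- gAt(hi)
      bad <- active & (gh > nu)
      if (!any(bad)) break
      hi[bad] <- hi[bad] * 2
      if (max(hi) > 1e12) break
    }
    for (k in 1:100) {
      mid <- (lo + hi) / 2
      gm <- gAt(mid)
      below <- gm > nu                     # need more effort
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    E[active] <- ((lo + hi) / 2)[active]
    E
  }
  nuLo <- 0; nuHi <- max(g0)
  ## S(nu) = sum E_i(nu) is decreasing; bisect to the budget
  for (k in 1:200) {
    nu <- (nuLo + nuHi) / 2
    S <- sum(Eof(nu))
    if (S > Etotal) nuLo <- nu else nuHi <- nu
    if (abs(S - Etotal) < tol * Etotal) break
  }
  E <- Eof(nu)
  s <- sum(E)
  E <- if (s > 0) E * (Etotal / s) else rep(Etotal / I, I)
  Allocation(E, total = Etotal, unitIds = unitIds(network))
}

#' Scenario comparison table across effort multipliers
#'
#' For each multiplier m of the base (actual) total effort, evaluates the
#' objective U and mean relative density under three allocations of
#' m x E_total: uniform (equal split), actual (the base pattern scaled by
#' m) and optimal (simulated annealing), plus the percent improvements of
#' the optimal scenario over the other two.
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the fitted [RiverNetwork-class].
#' @param baseAllocation the reference [Allocation-class] (e.g. the actual
#'   latest-year effort pattern).
#' @param multipliers positive multipliers of the base total effort.
#' @param steps,seed,... passed to [optimizeSA()].
#' @return data.frame with columns `multiplier, U_UA, U_AA, U_OA, d_UA,
#'   d_AA, d_OA, impr_vs_UA, impr_vs_AA`.
#' @export
scenarioTable <- function(samples, network, baseAllocation,
                          multipliers = 1:8, steps = 2e5, seed = 1L, ...) {
  if (length(multipliers) == 0L) stop("multipliers must be non-empty")
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  coefs <- .eqCoefficients(samples, network)
  I <- nUnits(network)
  base <- effortVector(baseAllocation)
  if (length(base) != I) stop("base allocation does not match the network")
  E0 <- totalEffort(baseAllocation)
  rows <- lapply(seq_along(multipliers), function(j) {
    m <- multipliers[j]
    Et <- m * E0
    uUA <- .objectiveFromCoefs(coefs, rep(Et / I, I))
    uAA <- .objectiveFromCoefs(coefs, base * m)
    opt <- optimizeSA(samples, network, Et, steps = steps,
                      seed = seed + j - 1L, ...)
    uOA <- opt$result
    data.frame(multiplier = m, U_UA = uUA@U, U_AA = uAA@U, U_OA = uOA@U,
               d_UA = uUA@meanRelativeDensity,
               d_AA = uAA@meanRelativeDensity,
               d_OA = uOA@meanRelativeDensity,
               impr_vs_UA = improvementPercent(uOA@U, uUA@U),
               impr_vs_AA = improvementPercent(uOA@U, uAA@U))
  })
  do.call(rbind, rows)
}
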