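#' @rdname RiverNetwork-class
#' @param object,x an object.
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))
#' @rdname RiverNetwork-class
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))
#' @rdname RiverNetwork-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname RiverNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname RiverNetwork-class
#' @export
setGeneric("neighborCounts", function(x) standardGeneric("neighborCounts"))
#' @rdname RiverNetwork-class
#' @export
setGeneric("neighborSets", function(x) standardGeneric("neighborSets"))
#' @rdname RiverNetwork-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname RemovalData-class
#' @export
setGeneric("network", function(x) standardGeneric("network"))
#' @rdname RemovalData-class
#' @export
setGeneric("years", function(x) standardGeneric("years"))
#' @rdname RemovalData-class
#' @export
setGeneric("effortMatrix", function(x) standardGeneric("effortMatrix"))
#' @rdname RemovalData-class
#' @export
setGeneric("captureMatrix", function(x) standardGeneric("captureMatrix"))
#' @rdname PosteriorSamples-class
#' @export
setGeneric("drawsMatrix", function(x) standardGeneric("drawsMatrix"))
#' @rdname PosteriorSamples-class
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))
#' @rdname PosteriorSamples-class
#' @export
setGeneric("rhat", function(x) standardGeneric("rhat"))
#' @rdname Allocation-class
#' @export
setGeneric("effortVector", function(x) standardGeneric("effortVector"))
#' @rdname Allocation-class
#' @export
setGeneric("totalEffort", function(x) standardGeneric("totalEffort"))

#' @rdname RiverNetwork-class
#' @export
setMethod("unitIds", "RiverNetwork", function(x) x@unitIds)
#' @rdname RiverNetwork-class
#' @export
setMethod("nUnits", "RiverNetwork", function(x) length(x@unitIds))
#' @rdname RiverNetwork-class
#' @export
setMethod("covariates", "RiverNetwork", function(x) x@covariates)
#' @rdname RiverNetwork-class
#' @export
setMethod("edges", "RiverNetwork", function(x) x@edges)
#' @rdname RiverNetwork-class
#' @export
setMethod("neighborCounts", "RiverNetwork", function(x)
  setNames(tabulate(c(x@edges[, 1L], x@edges[, 2L]),
                    nbins = length(x@unitIds)), x@unitIds))
#' @rdname RiverNetwork-class
#' @export
setMethod("neighborSets", "RiverNetwork", function(x) {
  I <- length(x@unitIds)
  out <- rep(list(integer(0)), I)
  for (r in seq_len(nrow(x@edges))) {
    a <- x@edges[r, 1L]; b <- x@edges[r, 2L]
    out[[a]] <- c(out[[a]], b)
    out[[b]] <- c(out[[b]], a)
  }
  names(out) <- x@unitIds
  lapply(out, sort)
})
#' @rdname RiverNetwork-class
#' @export
setMethod("adjacencyMatrix", "RiverNetwork", function(x) {
  I <- length(x@unitIds)
  W <- matrix(0, I, I, dimnames = list(x@unitIds, x@unitIds))
  W[x@edges] <- 1
  W[x@edges[, 2:1, drop = FALSE]] <- 1
  W
})

#' @rdname RemovalData-class
#' @export
setMethod("network", "RemovalData", function(x) x@network)
#' @rdname RemovalData-class
#' @export
setMethod("years", "RemovalData", function(x) x@years)
#' @rdname RemovalData-class
#' @export
setMethod("effortMatrix", "RemovalData", function(x) x@effort)
#' @rdname RemovalData-class
#' @export
setMethod("captureMatrix", "RemovalData", function(x) x@captures)
#' @rdname RemovalData-class
#' @export
setMethod("unitIds", "RemovalData", function(x) x@network@unitIds)
#' @rdname RemovalData-class
#' @export
setMethod("nUnits", "RemovalData", function(x) length(x@network@unitIds))

#' @rdname PosteriorSamples-class
#' @export
setMethod("drawsMatrix", "PosteriorSamples", function(x) x@draws)
#' @rdname PosteriorSamples-class
#' @export
setMethod("nDraws", "PosteriorSamples", function(x) nrow(x@draws))
#' @rdname PosteriorSamples-class
#' @export
setMethod("rhat", "PosteriorSamples", function(x) x@rhat)
#' @rdname PosteriorSamples-class
#' @export
setMethod("unitIds", "PosteriorSamples", function(x) x@unitIds)

#' @rdname Allocation-class
#' @export
setMethod("effortVector", "Allocation", function(x) x@effort)
#' @rdname Allocation-class
#' @export
setMethod("totalEffort", "Allocation", function(x) x@total)

setMethod("show", "RiverNetwork", function(object) {
  k <- tabulate(c(object@edges[, 1L], object@edges[, 2L]),
                nbins = length(object@unitIds))
  cat("RiverNetwork:", length(object@unitIds), "units,",
      nrow(object@edges), "edges,",
      ncol(object@covariates), "covariates\n")
  cat("  neighbour counts k_i:", paste(range(k), collapse = "-"), "\n")
})

setMethod("show", "RemovalData", function(object) {
  E <- object@effort
  cat("RemovalData:", nrow(E), "units x", ncol(E), "years\n")
  cat(sprintf("  observed unit-years: %d/%d; total effort %.0f trap-days; total captures %d\n",
              sum(!is.na(E)), length(E), sum(E, na.rm = TRUE),
              as.integer(sum(object@captures, na.rm = TRUE))))
})

setMethod("show", "GompertzParams", function(object) {
  cat("GompertzParams: alpha =", object@alpha, " lambda =", object@lambda,
      " beta6 =", object@beta6, "\n")
  cat("  beta:", paste(signif(object@beta, 3), collapse = ", "), "\n")
  cat(sprintf("  gamma = %.3g, sigma (rho, omega, e, 1) = %.3g, %.3g, %.3g, %.3g\n",
              object@gamma, object@sigmaRho, object@sigmaOmega,
              object@sigmaE, object@sigma1))
})

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", nrow(object@draws), "retained draws (",
      object@nChains, "chains, warmup", object@nWarmup, ", thin",
      object@thin, ")\n")
  if (length(object@rhat))
    cat(sprintf("  max split-Rhat: %.4f\n", max(object@rhat, na.rm = TRUE)))
})

setMethod("show", "Allocation", function(object) {
  cat("Allocation:", length(object@effort), "units, total",
      format(object@total), "trap-days\n")
})

setMethod("show", "ObjectiveResult", function(object) {
  cat(sprintf("ObjectiveResult: U = %.4f, mean relative density = %.4f (%d invalid draws)\n",
              object@U, object@meanRelativeDensity, object@invalidDraws))
})

setMethod("show", "ContributionSummary", function(object) {
  cat(sprintf("Fixed-effect contribution delta: median %.3f (95%% CI %.3f-%.3f), %d draw(s) excluded\n",
              object@median, object@ci[1L], object@ci[2L], object@excluded))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  d <- dim(object@densities)
  cat("TrajectoryEnsemble:", d[1L], "draws x", d[2L], "units x", d[3L],
      "years\n")
})
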