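## interchange formats: all CSVs are UTF-8, dot-decimal, with a mandatory
## header row; a leading "# key=value ..." comment line carries provenance
## (seed, config hash) and is skipped on read.

.readCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

.writeCsv <- function(df, path, meta = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", paste(names(meta), unlist(meta), sep = "=",
                                  collapse = " ")), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  ## small polynomial rolling hash; provenance marker, not cryptographic
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Load a removal dataset from interchange CSVs
#'
#' Reads long-format removal records (`unit_id, year, effort_trap_days,
#' captures`; an absent row is a missing unit-year), a per-unit covariate
#' table (`unit_id` + covariate columns) and an undirected adjacency edge
#' list (`unit_id_a, unit_id_b`). Unit order is the row order of the
#' covariates file. Unknown unit ids, duplicate unit-year rows, negative
#' values and positive captures at zero effort are load errors.
#'
#' @param removalCsv,covariatesCsv,adjacencyCsv file paths.
#' @param standardize re-standardize covariate columns to mean 0 / SD 1
#'   (default TRUE, with a warning when the input columns were not
#'   standardized already).
#' @return a [RemovalData-class].
#' @export
loadDataset <- function(removalCsv, covariatesCsv, adjacencyCsv,
                        standardize = TRUE) {
  cov <- .readCsv(covariatesCsv)
  if (!"unit_id" %in% names(cov)) stop("covariates file needs a unit_id column")
  ids <- as.character(cov$unit_id)
  if (anyDuplicated(ids)) stop("duplicated unit_id in covariates file")
  H <- as.matrix(cov[, setdiff(names(cov), "unit_id"), drop = FALSE])
  if (!is.numeric(H)) stop("covariate columns must be numeric")
  off <- max(abs(colMeans(H)), abs(apply(H, 2L, sd) - 1))
  if (off > 1e-6) {
    if (!standardize)
      stop("covariate columns are not standardized (mean 0, SD 1)")
    warning("covariate columns were not standardized; re-standardizing")
  }
  if (standardize && off > 1e-6) {
    H <- scale(H)
    attr(H, "scaled:center") <- NULL
    attr(H, "scaled:scale") <- NULL
  }

  adj <- .readCsv(adjacencyCsv)
  need <- c("unit_id_a", "unit_id_b")
  if (!all(need %in% names(adj)))
    stop("adjacency file needs columns unit_id_a, unit_id_b")
  badA <- setdiff(unique(c(adj$unit_id_a, adj$unit_id_b)), ids)
  if (length(badA))
    stop("unknown unit id(s) in adjacency file: ",
         paste(badA, collapse = ", "))
  edges <- cbind(match(as.character(adj$unit_id_a), ids),
                 match(as.character(adj$unit_id_b), ids))
  net <- RiverNetwork(ids, H, edges)

  rem <- .readCsv(removalCsv)
  need <- c("unit_id", "year", "effort_trap_days", "captures")
  if (!all(need %in% names(rem)))
    stop("removal file needs columns ", paste(need, collapse = ", "))
  badR <- setdiff(unique(as.character(rem$unit_id)), ids)
  if (length(badR))
    stop("unknown unit id(s) in removal file: ",
         paste(badR, collapse = ", "))
  key <- paste(rem$unit_id, rem$year)
  if (anyDuplicated(key))
    stop("duplicate (unit, year) rows in removal file: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(rem$effort_trap_days < 0)) stop("negative effort in removal file")
  if (any(rem$captures < 0)) stop("negative captures in removal file")
  yrs <- as.character(sort(unique(rem$year)))
  I <- length(ids); T <- length(yrs)
  E <- matrix(NA_real_, I, T, dimnames = list(ids, yrs))
  C <- matrix(NA_real_, I, T, dimnames = list(ids, yrs))
  ri <- match(as.character(rem$unit_id), ids)
  ci <- match(as.character(rem$year), yrs)
  E[cbind(ri, ci)] <- rem$effort_trap_days
  C[cbind(ri, ci)] <- rem$captures
  new("RemovalData", network = net, years = yrs, effort = E, captures = C)
}

#' Write a removal dataset to interchange CSVs
#'
#' Inverse of [loadDataset()]: writes the three CSVs (removal records in
#' long format with missing unit-years absent, covariates, adjacency edge
#' list) into `dir`.
#'
#' @param data a [RemovalData-class].
#' @param dir output directory (created if needed).
#' @param seed optional seed to embed in the provenance comment.
#' @return invisibly, the three file paths.
#' @export
writeDataset <- function(data, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- network(data)
  meta <- list(seed = seed, config = .configHash(list(unitIds(net),
                                                      years(data))))
  E <- effortMatrix(data); C <- captureMatrix(data)
  obs <- which(!is.na(E), arr.ind = TRUE)
  rem <- data.frame(unit_id = unitIds(net)[obs[, 1L]],
                    year = years(data)[obs[, 2L]],
                    effort_trap_days = E[obs], captures = as.integer(C[obs]))
  rem <- rem[order(rem$unit_id, rem$year), ]
  cov <- data.frame(unit_id = unitIds(net), covariates(net),
                    check.names = FALSE)
  ed <- edges(net)
  adj <- data.frame(unit_id_a = unitIds(net)[pmin(ed[, 1L], ed[, 2L])],
                    unit_id_b = unitIds(net)[pmax(ed[, 1L], ed[, 2L])])
  paths <- file.path(dir, c("removal.csv", "covariates.csv",
                            "adjacency.csv"))
  .writeCsv(rem, paths[1L], meta)
  .writeCsv(cov, paths[2L], meta)
  .writeCsv(adj, paths[3L], meta)
  invisible(paths)
}

#' Save / load posterior draws losslessly
#'
#' `savePosterior()` writes the draws as a columnar CSV (one row per
#' retained draw, full floating precision) plus a JSON sidecar with the
#' MCMC configuration, chain ids and split-R-hat table.
#' `loadPosterior()` restores an identical [PosteriorSamples-class];
#' a truncated or schema-mismatched file is an error, never a partial
#' object.
#'
#' @param samples a [PosteriorSamples-class].
#' @param drawsPath CSV path for the draws.
#' @param metaPath JSON path for the metadata (default: drawsPath +
#'   `.meta.json`).
#' @param seed optional seed to embed in the provenance metadata.
#' @return `savePosterior()`: invisibly the paths; `loadPosterior()`: the
#'   restored object.
#' @export
savePosterior <- function(samples, drawsPath,
                          metaPath = paste0(drawsPath, ".meta.json"),
                          seed = NA) {
  stopifnot(is(samples, "PosteriorSamples"))
  df <- as.data.frame(samples@draws, check.names = FALSE)
  con <- file(drawsPath, "w", encoding = "UTF-8")
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = TRUE)
  close(con)
  meta <- list(nChains = samples@nChains, nWarmup = samples@nWarmup,
               nKept = samples@nKept, thin = samples@thin,
               chain = samples@chain, rhat = as.list(samples@rhat),
               unitIds = samples@unitIds, years = samples@years,
               seed = seed,
               config = .configHash(list(samples@nChains, samples@nWarmup,
                                         samples@thin)))
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(drawsPath, metaPath))
}

#' @rdname savePosterior
#' @export
loadPosterior <- function(drawsPath,
                          metaPath = paste0(drawsPath, ".meta.json")) {
  if (!file.exists(drawsPath)) stop("file not found: ", drawsPath)
  if (!file.exists(metaPath)) stop("file not found: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  df <- read.csv(drawsPath, check.names = FALSE)
  draws <- as.matrix(df)
  I <- length(meta$unitIds); T <- length(meta$years)
  expect <- c("alpha", "lambda", "beta6", "gamma", "sigma_rho",
              "sigma_omega", "sigma_e", "sigma_1",
              sprintf("rho[%d]", seq_len(I)))
  missingCols <- setdiff(expect, colnames(draws))
  if (length(missingCols))
    stop("posterior file is missing column(s): ",
         paste(missingCols, collapse = ", "))
  if (nrow(draws) != meta$nKept)
    stop(sprintf("posterior file is truncated: %d rows, expected %d",
                 nrow(draws), meta$nKept))
  new("PosteriorSamples", draws = draws,
      chain = as.integer(meta$chain), nChains = as.integer(meta$nChains),
      nWarmup = as.integer(meta$nWarmup), nKept = as.integer(meta$nKept),
      thin = as.integer(meta$thin),
      rhat = unlist(meta$rhat), unitIds = as.character(meta$unitIds),
      years = as.character(meta$years))
}

#' Read / write an allocation CSV
#'
#' Allocations are exchanged as `unit_id, effort_trap_days` CSVs.
#'
#' @param allocation an [Allocation-class].
#' @param path CSV path.
#' @param seed optional provenance seed.
#' @return `writeAllocation()`: invisibly the path; `readAllocation()`:
#'   an [Allocation-class].
#' @export
writeAllocation <- function(allocation, path, seed = NA) {
  df <- data.frame(unit_id = names(effortVector(allocation)),
                   effort_trap_days = unname(effortVector(allocation)))
  .writeCsv(df, path, meta = list(seed = seed,
                                  total = totalEffort(allocation)))
  invisible(path)
}

#' @rdname writeAllocation
#' @export
readAllocation <- function(path) {
  df <- .readCsv(path)
  if (!all(c("unit_id", "effort_trap_days") %in% names(df)))
    stop("allocation file needs columns unit_id, effort_trap_days")
  Allocation(df$effort_trap_days, unitIds = as.character(df$unit_id))
}
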