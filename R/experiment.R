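## Experiment module: enumerate the (condition x network x replicate)
## design, run simulate -> infer -> evaluate for all methods, and emit
## the results table and the median/ratio summary backing the
## per-time-point performance curves.

.ALL_METHODS <- c("bc3net", "c3net", "clr", "mrnet", "aracne")
.ALL_CONDITIONS <- c("normal", "constant", "spike")
.DEFAULT_GRID <- c(0, 0.5, 1, 2, 2.5, 3, 3.5, 5, 10, 30, 50)

#' Experiment configuration
#'
#' Builds the configuration list consumed by [buildManifest()] and
#' [runExperiment()]. Defaults describe the desk-scale design: 100-gene
#' networks of both topologies, all three environmental conditions, the
#' 11-point observational time grid, E = 10 replicate datasets of S = 100
#' samples, and all five inference methods. \code{fullScale = TRUE}
#' switches to the population-scale design (E = 100, S = 300).
#'
#' @param n Gene count.
#' @param p Erdős–Rényi edge probability (default 2/(n-1)).
#' @param activatorFraction Activator probability for generated edges.
#' @param networks Character subset of c("erdos_renyi", "scale_free"), or
#'   a named list of \linkS4class{SignedNetwork} objects.
#' @param conditions Character subset of c("normal", "constant",
#'   "spike").
#' @param grid Observation times.
#' @param E Replicates per time point.
#' @param S Samples per dataset.
#' @param methods Character subset of c("bc3net", "c3net", "clr",
#'   "mrnet", "aracne").
#' @param estimator MI estimator for the inference stage.
#' @param step,sigmaDyn,jitterSd,measSd Simulator settings (see
#'   [generateEnsemble()]).
#' @param Ec,Es,ts,dtSpike Stimulus settings (NA magnitudes resolve
#'   against the kinetic parameters).
#' @param alpha,P Significance level and permutation count of the null
#'   MI threshold.
#' @param zThreshold CLR z-score cutoff.
#' @param B,alphaEnsemble BC3NET bagging settings.
#' @param masterSeed Master seed expanded into per-job streams.
#' @param fullScale If TRUE, use E = 100, S = 300.
#' @return A named list of class \code{grnbenchConfig}.
#' @export
experimentConfig <- function(n = 100, p = NULL, activatorFraction = 0.7,
                             networks = c("erdos_renyi", "scale_free"),
                             conditions = .ALL_CONDITIONS,
                             grid = .DEFAULT_GRID,
                             E = 10, S = 100, methods = .ALL_METHODS,
                             estimator = "pearson",
                             step = 0.01, sigmaDyn = 0.05, jitterSd = 0.2,
                             measSd = 0.1, Ec = NA_real_, Es = NA_real_,
                             ts = 1.0, dtSpike = 0.2,
                             alpha = 0.05, P = 200, zThreshold = 2,
                             B = 50, alphaEnsemble = 0.05,
                             masterSeed = 1, fullScale = FALSE) {
  if (fullScale) { E <- 100; S <- 300 }
  cfg <- list(n = n, p = if (is.null(p)) 2 / (n - 1) else p,
              activatorFraction = activatorFraction, networks = networks,
              conditions = conditions, grid = grid, E = E, S = S,
              methods = methods, estimator = estimator, step = step,
              sigmaDyn = sigmaDyn, jitterSd = jitterSd, measSd = measSd,
              Ec = Ec, Es = Es, ts = ts, dtSpike = dtSpike, alpha = alpha,
              P = P, zThreshold = zThreshold, B = B,
              alphaEnsemble = alphaEnsemble, masterSeed = masterSeed)
  class(cfg) <- "grnbenchConfig"
  cfg
}

#' Read an experiment configuration from a YAML file
#'
#' Unknown keys are an error (naming the key); missing keys take the
#' [experimentConfig()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
readConfig <- function(path) {
  ## YAML 1.1 would read the bare key "n" as a boolean; keep it literal
  keepN <- list(
    "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE,
    "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE)
  vals <- yaml::read_yaml(path, handlers = keepN)
  known <- names(formals(experimentConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(experimentConfig, vals)
}

.validateConfig <- function(config) {
  if (!inherits(config, "grnbenchConfig")) {
    if (is.list(config)) config <- do.call(experimentConfig, config)
    else stop("'config' must be an experimentConfig() list")
  }
  if (config$E < 1) stop("config error: 'E' must be >= 1")
  if (config$S < 2) stop("config error: 'S' must be >= 2")
  if (length(config$grid) < 1) stop("config error: 'grid' must be nonempty")
  if (length(config$methods) < 1) stop("config error: at least one method")
  if (!all(config$methods %in% .ALL_METHODS))
    stop("config error: unknown method(s): ",
         paste(setdiff(config$methods, .ALL_METHODS), collapse = ", "))
  if (length(config$conditions) < 1) stop("config error: at least one condition")
  if (!all(config$conditions %in% .ALL_CONDITIONS))
    stop("config error: unknown condition(s): ",
         paste(setdiff(config$conditions, .ALL_CONDITIONS), collapse = ", "))
  if (length(config$networks) < 1) stop("config error: at least one network")
  config
}

#' Enumerate the simulation design (dry run)
#'
#' Deterministically enumerates every (condition, network, replicate) job
#' of the configured design and derives the dataset and inference counts
#' without running anything: T x E datasets per network-condition,
#' T x E x |methods| inferred networks per network-condition, and their
#' totals over the condition x network grid.
#'
#' @param config A configuration from [experimentConfig()].
#' @return A \linkS4class{DesignManifest}.
#' @examples
#' m <- buildManifest(experimentConfig(fullScale = TRUE))
#' manifestCounts(m)  # 1100 / 5500 per network-condition; 6600 / 33000 total
#' @export
buildManifest <- function(config) {
  config <- .validateConfig(config)
  netNames <- if (is.list(config$networks)) names(config$networks)
              else config$networks
  jobs <- expand.grid(condition = config$conditions, network = netNames,
                      replicate = seq_len(config$E),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jobs <- jobs[order(jobs$condition, jobs$network, jobs$replicate), ]
  rownames(jobs) <- NULL
  jobs$seed <- mapply(function(co, ne, e)
    deriveSeed(config$masterSeed, co, ne, "replicate", e),
    jobs$condition, jobs$network, jobs$replicate)
  T <- length(config$grid)
  nm <- length(config$methods)
  counts <- list(
    datasetsPerNetworkCondition = T * config$E,
    inferredPerNetworkCondition = T * config$E * nm,
    totalDatasets = length(config$conditions) * length(netNames) * T * config$E,
    totalInferred = length(config$conditions) * length(netNames) * T *
      config$E * nm)
  new("DesignManifest", config = unclass(config), jobs = jobs, counts = counts)
}

#' Derived counts of a DesignManifest
#' @param manifest A \linkS4class{DesignManifest}.
#' @return Named list of dataset and inferred-network counts.
#' @export
manifestCounts <- function(manifest) manifest@counts

setMethod("show", "DesignManifest", function(object) {
  cfg <- object@config
  cat("DesignManifest\n")
  cat(sprintf("  conditions: %s\n", paste(cfg$conditions, collapse = ", ")))
  nn <- if (is.list(cfg$networks)) names(cfg$networks) else cfg$networks
  cat(sprintf("  networks:   %s (n = %d)\n", paste(nn, collapse = ", "), cfg$n))
  cat(sprintf("  grid:       T = %d time points; E = %d; S = %d\n",
              length(cfg$grid), cfg$E, cfg$S))
  cat(sprintf("  methods:    %s\n", paste(cfg$methods, collapse = ", ")))
  with(object@counts, {
    cat(sprintf("  datasets per network-condition:  %d\n",
                datasetsPerNetworkCondition))
    cat(sprintf("  inferred  per network-condition: %d\n",
                inferredPerNetworkCondition))
    cat(sprintf("  total datasets: %d; total inferred networks: %d\n",
                totalDatasets, totalInferred))
  })
  invisible(NULL)
})

## Build the ground-truth networks of a manifest (one per topology tag).
.manifestNetworks <- function(config) {
  if (is.list(config$networks)) return(config$networks)
  nets <- lapply(config$networks, function(tag) {
    sd <- deriveSeed(config$masterSeed, "topology", tag)
    switch(tag,
      erdos_renyi = erdosRenyiNetwork(config$n, config$p,
                                      config$activatorFraction, seed = sd),
      scale_free = scaleFreeNetwork(config$n,
                                    activatorFraction = config$activatorFraction,
                                    seed = sd),
      stop("config error: unknown network tag: ", tag))
  })
  names(nets) <- config$networks
  nets
}

## One job: simulate S trajectories of one replicate under one condition
## on one network, then infer + evaluate every method at every time.
.runJob <- function(config, net, netName, condition, e, params) {
  profile <- .resolveProfile(
    stimulusProfile(condition, Ec = config$Ec, Es = config$Es,
                    ts = config$ts, dtSpike = config$dtSpike), params)
  ens <- generateEnsemble(net, profile, config$grid, E = 1, S = config$S,
                          seed = deriveSeed(config$masterSeed, condition,
                                            netName, "sim", e),
                          params = params, step = config$step,
                          sigmaDyn = config$sigmaDyn,
                          jitterSd = config$jitterSd, measSd = config$measSd,
                          networkId = netName)
  rows <- vector("list", length(config$grid) * length(config$methods))
  k <- 0L
  for (i in seq_along(config$grid)) {
    ds <- ens[[i]]
    sig <- nullMIThreshold(ds, config$estimator, alpha = config$alpha,
                           P = config$P,
                           seed = deriveSeed(config$masterSeed, condition,
                                             netName, "null", e, i))
    M <- miMatrix(ds, config$estimator)
    for (method in config$methods) {
      est <- switch(method,
        c3net = inferC3NET(M, sig),
        clr = inferCLR(M, config$zThreshold),
        mrnet = inferMRNET(M, sig),
        aracne = inferARACNE(M, sig),
        bc3net = inferBC3NET(ds, B = config$B, alphaEdge = config$alpha,
                             alphaEnsemble = config$alphaEnsemble,
                             estimator = config$estimator,
                             seed = deriveSeed(config$masterSeed, condition,
                                               netName, "bc3net", e, i),
                             P = config$P))
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(condition = condition, network = netName, method = method,
                   time_index = i, time = config$grid[i], replicate = e),
        scoreNetwork(est, net))
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Run the full simulate - infer - evaluate experiment
#'
#' Executes every job of the manifest: per (condition, network,
#' replicate), S stochastic trajectories are simulated over the time
#' grid, sliced into T single-time-point datasets, each dataset is handed
#' to every configured inference method, and the resulting networks are
#' scored against the ground truth. Jobs are independent (per-job derived
#' seeds) and resumable: with an \code{outDir}, each finished job is
#' written as a TSV and existing job files are skipped on re-run, so the
#' final results table is identical no matter how the run was
#' interrupted. A failing job is recorded and the run continues.
#'
#' @param manifest A \linkS4class{DesignManifest} (or a configuration,
#'   which is passed through [buildManifest()]).
#' @param outDir Optional output directory for per-job TSVs, the combined
#'   results table (\code{results.tsv}) and the median/ratio summary
#'   (\code{summary.tsv}).
#' @param verbose Print per-job progress.
#' @return A list with \code{results} (one row per condition, network,
#'   method, time, replicate: TP, FP, FN, precision, recall, fscore),
#'   \code{summary} (median F and ratio to the steady-state median per
#'   condition, network, method, time), and \code{failures} (data frame
#'   of failed jobs, if any).
#' @export
runExperiment <- function(manifest, outDir = NULL, verbose = FALSE) {
  if (!is(manifest, "DesignManifest")) manifest <- buildManifest(manifest)
  config <- manifest@config
  nets <- .manifestNetworks(config)
  paramsList <- lapply(names(nets), function(nm)
    sampleKineticParams(nets[[nm]],
                        deriveSeed(config$masterSeed, "kinetics", nm)))
  names(paramsList) <- names(nets)
  if (!is.null(outDir)) {
    jobDir <- file.path(outDir, "jobs")
    dir.create(jobDir, recursive = TRUE, showWarnings = FALSE)
  }
  jobs <- manifest@jobs
  out <- vector("list", nrow(jobs))
  failures <- list()
  for (j in seq_len(nrow(jobs))) {
    cond <- jobs$condition[j]; netName <- jobs$network[j]
    e <- jobs$replicate[j]
    jobFile <- if (!is.null(outDir))
      file.path(jobDir, sprintf("%s_%s_e%03d.tsv", cond, netName, e))
    if (!is.null(outDir) && file.exists(jobFile)) {
      out[[j]] <- read.delim(jobFile, stringsAsFactors = FALSE)
      next
    }
    if (verbose)
      message(sprintf("[%d/%d] %s / %s / replicate %d",
                      j, nrow(jobs), cond, netName, e))
    res <- tryCatch(
      .runJob(config, nets[[netName]], netName, cond, e,
              paramsList[[netName]]),
      error = function(err) err)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(condition = cond, network = netName, replicate = e,
                   error = conditionMessage(res))
      next
    }
    if (!is.null(outDir))
      write.table(res, jobFile, sep = "\t", quote = FALSE, row.names = FALSE)
    out[[j]] <- res
  }
  results <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  summary <- .summarizeResults(results, config)
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame()
  if (!is.null(outDir)) {
    write.table(results, file.path(outDir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(outDir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(results = results, summary = summary, failures = failures)
}

## Median F and ratio-to-steady-state per (condition, network, method, t).
.summarizeResults <- function(results, config) {
  if (is.null(results) || nrow(results) == 0) return(data.frame())
  groups <- split(results,
                  list(results$condition, results$network, results$method),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    sc <- data.frame(timeIndex = g$time_index, time = g$time,
                     replicate = g$replicate, fscore = g$fscore)
    fs <- summarizeFScores(sc)
    cbind(data.frame(condition = g$condition[1], network = g$network[1],
                     method = g$method[1]), fscoreSummary(fs))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$network, out$method, out$timeIndex), ]
}
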