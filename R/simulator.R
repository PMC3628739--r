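## Simulator module: stochastic kinetic model of transcription regulation
## integrated on the ground-truth network under an environmental
## condition, read out at the observational time grid.
##
## Dynamics per gene i:
##   dx_i/dt = V_i * A_i(x) * R_i(x) + u_i(t) - lambda_i * x_i
## with Hill occupancy h(x; K, m) = x^m / (x^m + K^m),
## A_i = mean of h over activator parents (1 if none, soft-OR) and
## R_i = prod over repressor parents of (1 - h) (soft-AND-NOT), so the
## transcription term stays bounded in [0, V_i]. Integration is explicit
## Euler-Maruyama with multiplicative dynamics noise and the state
## clipped at 0.

#' Construct a StimulusProfile
#'
#' @param condition One of "normal" (no stimulus), "constant" (rich
#'   media, constant additive input Ec) or "spike" (transient spike-in of
#'   magnitude Es * r during [ts, ts + dtSpike)).
#' @param Ec,Es Stimulus magnitudes (concentration/time); NA means
#'   "resolve against the kinetic parameters at run time" (Ec = 0.5 *
#'   median(V), Es = 2 * median(V)).
#' @param ts Spike onset time (default 1.0).
#' @param dtSpike Spike duration (default 0.2).
#' @return A \linkS4class{StimulusProfile}.
#' @examples
#' stimulusProfile("spike", Es = 2, ts = 1, dtSpike = 0.2)
#' @export
stimulusProfile <- function(condition = c("normal", "constant", "spike"),
                            Ec = NA_real_, Es = NA_real_,
                            ts = 1.0, dtSpike = 0.2) {
  condition <- match.arg(condition)
  new("StimulusProfile", condition = condition, Ec = as.numeric(Ec),
      Es = as.numeric(Es), ts = as.numeric(ts), dtSpike = as.numeric(dtSpike))
}

## Fill NA magnitudes from kinetic parameters.
.resolveProfile <- function(profile, params) {
  med <- median(params@V)
  if (is.na(profile@Ec)) profile@Ec <- 0.5 * med
  if (is.na(profile@Es)) profile@Es <- 2 * med
  profile
}

#' External stimulus received by each gene at time t
#'
#' Evaluates the per-gene external input u(t) of an environmental
#' condition: 0 under "normal"; Ec for every gene at all times under
#' "constant"; Es * r inside the spike window [ts, ts + dtSpike) and 0
#' outside it under "spike".
#'
#' @param profile A \linkS4class{StimulusProfile} with concrete (non-NA)
#'   magnitudes.
#' @param t Time (>= 0).
#' @param r Per-gene uniform random factors in [0, 1] (condition "spike"
#'   only; recycled against genes).
#' @return Numeric vector of stimulus values, one per element of
#'   \code{r}.
#' @examples
#' p <- stimulusProfile("spike", Es = 2, ts = 1, dtSpike = 0.2)
#' stimulusValue(p, t = 1.1, r = 0.5)  # 1.0: inside the window
#' stimulusValue(p, t = 2.0, r = 0.5)  # 0: the spike is over
#' @export
stimulusValue <- function(profile, t, r = 1) {
  stopifnot(is(profile, "StimulusProfile"))
  if (t < 0) stop("'t' must be >= 0")
  switch(profile@condition,
    normal = rep(0, length(r)),
    constant = {
      if (is.na(profile@Ec)) stop("Ec is unresolved (NA) in this profile")
      rep(profile@Ec, length(r))
    },
    spike = {
      if (is.na(profile@Es)) stop("Es is unresolved (NA) in this profile")
      if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
      if (t >= profile@ts && t < profile@ts + profile@dtSpike)
        profile@Es * r
      else rep(0, length(r))
    },
    stop("unknown condition tag: ", profile@condition))
}

#' Sample kinetic parameters for a network
#'
#' Draws the gene-specific kinetics once per network: V_i ~ U[0.5, 1.5],
#' lambda_i ~ U[0.2, 1.0], per-edge thresholds K ~ U[0.2, 1.0] scaled by
#' the regulator's characteristic level V_src/lambda_src (so half-maximal
#' regulation sits inside the regulator's dynamic range), Hill exponent
#' m = 2.
#'
#' @param net A \linkS4class{SignedNetwork}.
#' @param seed Integer seed.
#' @return A \linkS4class{KineticParams}.
#' @export
sampleKineticParams <- function(net, seed = NULL) {
  n <- nGenes(net)
  .withSeed(seed, {
    V <- runif(n, 0.5, 1.5)
    lambda <- runif(n, 0.2, 1.0)
    A <- adjacencyMatrix(net)
    K <- matrix(0, n, n, dimnames = dimnames(A))
    idx <- which(A != 0, arr.ind = TRUE)
    if (nrow(idx))
      K[idx] <- runif(nrow(idx), 0.2, 1.0) * V[idx[, 1]] / lambda[idx[, 1]]
    new("KineticParams", V = V, lambda = lambda, K = K, m = 2)
  })
}

## ------------------------------------------------------------------------
## Core integrator, vectorized over trajectories.
## X: S x n state; V, lambda: S x n (per-trajectory jittered) matrices;
## returns list of S x n snapshots, one per grid time.
## ------------------------------------------------------------------------
.integrateMatrix <- function(net, V, lambda, K, m, profile, X0, grid,
                             step = 0.01, sigmaDyn = 0.05, rMat = NULL) {
  n <- nGenes(net)
  S <- nrow(X0)
  A <- adjacencyMatrix(net)
  idx <- which(A != 0, arr.ind = TRUE)
  src <- idx[, 1]; tgt <- idx[, 2]
  sgn <- A[idx]
  Kvec <- K[idx]
  act <- sgn > 0; rep_ <- sgn < 0
  ## indicator matrices grouping edges by target gene
  Mact <- matrix(0, sum(act), n)
  if (sum(act)) Mact[cbind(seq_len(sum(act)), tgt[act])] <- 1
  Mrep <- matrix(0, sum(rep_), n)
  if (sum(rep_)) Mrep[cbind(seq_len(sum(rep_)), tgt[rep_])] <- 1
  degAct <- colSums(Mact)
  noAct <- degAct == 0
  degActSafe <- pmax(degAct, 1)

  gi <- round(grid / step)
  if (any(abs(grid - gi * step) > 1e-8))
    stop("all grid times must be multiples of the integration step")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid times must be strictly increasing")
  nSteps <- max(gi)
  spike <- profile@condition == "spike"
  if (spike && is.null(rMat)) rMat <- matrix(1, S, n)

  snaps <- vector("list", length(grid))
  X <- X0
  recordAt <- match(0:nSteps, gi)

  regulation <- function(X) {
    if (length(src) == 0) return(matrix(1, S, n))
    H <- X[, src, drop = FALSE]^m
    H <- H / (H + matrix(Kvec^m, S, length(Kvec), byrow = TRUE))
    Areg <- matrix(1, S, n)
    if (sum(act)) {
      s <- H[, act, drop = FALSE] %*% Mact
      Areg <- sweep(s, 2, degActSafe, "/")
      Areg[, noAct] <- 1
    }
    Rreg <- matrix(1, S, n)
    if (sum(rep_)) {
      L <- log1p(-pmin(H[, rep_, drop = FALSE], 1 - 1e-12))
      Rreg <- exp(L %*% Mrep)
    }
    Areg * Rreg
  }

  sq <- sqrt(step)
  for (k in 0:nSteps) {
    if (!is.na(recordAt[k + 1])) snaps[[recordAt[k + 1]]] <- X
    if (k == nSteps) break
    t <- k * step
    f <- V * regulation(X)
    u <- switch(profile@condition,
      normal = 0,
      constant = profile@Ec,
      spike = if (t >= profile@ts && t < profile@ts + profile@dtSpike)
                profile@Es * rMat else 0)
    X <- X + (f + u - lambda * X) * step
    if (sigmaDyn > 0)
      X <- X + sigmaDyn * X * sq * matrix(rnorm(S * n), S, n)
    X[X < 0] <- 0
    if (anyNA(X) || any(!is.finite(X)))
      stop(sprintf("non-finite state during integration at t = %g", t + step))
  }
  snaps
}

#' Simulate a single expression trajectory
#'
#' Integrates the regulation model on a network with fixed kinetic
#' parameters from a given initial state, by explicit Euler(-Maruyama)
#' with the state clipped at 0, and returns the trajectory at the
#' requested observation times. With \code{noise = 0} the result is
#' deterministic.
#'
#' @param net A \linkS4class{SignedNetwork}.
#' @param params A \linkS4class{KineticParams} for the network.
#' @param profile A \linkS4class{StimulusProfile} (concrete magnitudes).
#' @param x0 Nonnegative initial state vector (length n).
#' @param grid Strictly increasing observation times, each a multiple of
#'   \code{step}.
#' @param step Integration step (> 0), default 0.01.
#' @param noise Multiplicative dynamics noise coefficient sigma_dyn (the
#'   increment is \code{noise * x * sqrt(step) * N(0,1)}); 0 disables it.
#' @param seed Integer seed for the noise stream.
#' @param r Per-gene spike factors in [0, 1] (condition "spike");
#'   defaults to 1 for every gene.
#' @return Numeric T x n matrix of expression values, rows named by time.
#' @examples
#' net <- signedNetwork(matrix(0, 1, 1))
#' par <- new("KineticParams", V = 1, lambda = 1,
#'            K = matrix(0, 1, 1), m = 2)
#' tr <- simulateTrajectory(net, par, stimulusProfile("normal"),
#'                          x0 = 0, grid = c(0, 5), step = 0.01)
#' tr["5", 1]  # ~ 1 - exp(-5) = 0.9933 up to Euler error
#' @export
simulateTrajectory <- function(net, params, profile, x0, grid,
                               step = 0.01, noise = 0, seed = NULL,
                               r = NULL) {
  n <- nGenes(net)
  if (length(x0) != n) stop("'x0' must have one value per gene")
  if (any(x0 < 0)) stop("'x0' must be nonnegative")
  if (step <= 0) stop("'step' must be > 0")
  profile <- .resolveProfile(profile, params)
  rMat <- if (!is.null(r)) matrix(r, 1, n) else NULL
  snaps <- .withSeed(seed,
    .integrateMatrix(net, matrix(params@V, 1, n),
                     matrix(params@lambda, 1, n), params@K, params@m,
                     profile, matrix(x0, 1, n), grid, step,
                     sigmaDyn = noise, rMat = rMat))
  out <- do.call(rbind, snaps)
  dimnames(out) <- list(format(grid, trim = TRUE), geneIds(net))
  out
}

#' Construct an ExpressionDataset
#'
#' @param values Numeric S x n matrix, samples by genes, nonnegative.
#' @param geneIds Gene labels (default: column names).
#' @param timeIndex,time,replicate,condition,networkId Dataset tags.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
expressionDataset <- function(values, geneIds = colnames(values),
                              timeIndex = NA_integer_, time = NA_real_,
                              replicate = NA_integer_,
                              condition = NA_character_,
                              networkId = NA_character_) {
  values <- as.matrix(values)
  if (is.null(geneIds)) geneIds <- .defaultGeneIds(ncol(values))
  assay <- t(values)
  rownames(assay) <- geneIds
  colnames(assay) <- sprintf("S%d", seq_len(ncol(assay)))
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(expr = assay))
  new("ExpressionDataset", se, timeIndex = as.integer(timeIndex),
      time = as.numeric(time), replicate = as.integer(replicate),
      condition = as.character(condition), networkId = as.character(networkId))
}

#' @describeIn exprValues samples-by-genes matrix of an ExpressionDataset
#' @export
setMethod("exprValues", "ExpressionDataset",
          function(object) t(SummarizedExperiment::assay(object)))

#' @describeIn nGenes gene count of an ExpressionDataset
#' @export
setMethod("nGenes", "ExpressionDataset", function(object) nrow(object))

setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf(
    "ExpressionDataset: %d samples x %d genes | condition=%s network=%s t[%s]=%s replicate=%s\n",
    ncol(object), nrow(object), object@condition, object@networkId,
    object@timeIndex, format(object@time), object@replicate))
})

#' Generate the ensemble of expression datasets for one condition
#'
#' Implements the ensemble design: for each of the E replicates, S
#' independent stochastic trajectories are integrated over the full time
#' grid and read out at every grid time, so the T datasets of a replicate
#' share trajectories (a time series later sliced by observation time).
#' Inter-sample variability comes from per-trajectory lognormal jitter on
#' V and lambda (sd \code{jitterSd}), random initial states x(0) ~
#' U[0, 0.1 V/lambda], multiplicative dynamics noise, and multiplicative
#' lognormal measurement noise (sd \code{measSd}) applied at readout.
#' Deterministic for a fixed seed, replicate by replicate (each replicate
#' owns a derived sub-seed).
#'
#' @param net A \linkS4class{SignedNetwork}.
#' @param profile A \linkS4class{StimulusProfile}; NA magnitudes are
#'   resolved against the kinetic parameters.
#' @param grid Observation times (strictly increasing multiples of
#'   \code{step}).
#' @param E Number of replicate datasets per time point (>= 1).
#' @param S Samples per dataset (>= 2; mutual information estimation is
#'   impossible below that).
#' @param seed Integer master seed.
#' @param params Optional \linkS4class{KineticParams}; sampled from the
#'   seed when missing.
#' @param step Integration step.
#' @param sigmaDyn Dynamics noise coefficient (default 0.05).
#' @param jitterSd Lognormal sd of the per-trajectory V and lambda jitter
#'   (default 0.2).
#' @param measSd Lognormal sd of the measurement noise (default 0.1).
#' @param networkId Tag recorded on every dataset.
#' @return A list of T x E \linkS4class{ExpressionDataset} objects,
#'   ordered replicate-major, named \code{e<e>_t<i>}.
#' @examples
#' net <- erdosRenyiNetwork(5, seed = 1)
#' ens <- generateEnsemble(net, stimulusProfile("normal"),
#'                         grid = c(0, 1), E = 2, S = 5, seed = 1)
#' length(ens)  # T * E = 4
#' @export
generateEnsemble <- function(net, profile, grid, E, S, seed = 1,
                             params = NULL, step = 0.01, sigmaDyn = 0.05,
                             jitterSd = 0.2, measSd = 0.1,
                             networkId = "network") {
  if (E < 1) stop("'E' must be >= 1")
  if (S < 2) stop("'S' must be >= 2 (MI estimation needs at least 2 samples)")
  n <- nGenes(net)
  if (is.null(params)) params <- sampleKineticParams(net, deriveSeed(seed, "params"))
  profile <- .resolveProfile(profile, params)
  spike <- profile@condition == "spike"
  out <- vector("list", length(grid) * E)
  k <- 0L
  for (e in seq_len(E)) {
    se <- deriveSeed(seed, profile@condition, networkId, "replicate", e)
    sets <- .withSeed(se, {
      Vmat <- matrix(params@V, S, n, byrow = TRUE) *
        matrix(rlnorm(S * n, 0, jitterSd), S, n)
      Lmat <- matrix(params@lambda, S, n, byrow = TRUE) *
        matrix(rlnorm(S * n, 0, jitterSd), S, n)
      ## initial states span the gene's full dynamic range [0, V/lambda]:
      ## the population starts in diverse states, and the contraction of
      ## this spread onto the attractor is what makes transient data more
      ## informative than steady-state data
      X0 <- matrix(runif(S * n), S, n) * Vmat / Lmat
      rMat <- if (spike) matrix(runif(S * n), S, n) else NULL
      snaps <- .integrateMatrix(net, Vmat, Lmat, params@K, params@m,
                                profile, X0, grid, step, sigmaDyn, rMat)
      lapply(snaps, function(X) X * matrix(rlnorm(S * n, 0, measSd), S, n))
    })
    for (i in seq_along(grid)) {
      k <- k + 1L
      D <- sets[[i]]
      colnames(D) <- geneIds(net)
      out[[k]] <- expressionDataset(D, geneIds(net), timeIndex = i,
                                    time = grid[i], replicate = e,
                                    condition = profile@condition,
                                    networkId = networkId)
      names(out)[k] <- sprintf("e%d_t%d", e, i)
    }
  }
  attr(out, "grid") <- grid
  attr(out, "params") <- params
  out
}

## ------------------------------------------------------------------------
## Dataset serialization: TSV, header = gene ids, one row per sample
## ------------------------------------------------------------------------

#' Write an expression dataset as TSV
#'
#' Tab-separated matrix with a header row of gene ids and one row per
#' sample, at 15 significant digits so that a round trip through
#' [readExpressionDataset()] reproduces the values to well below 1e-9.
#'
#' @param ds An \linkS4class{ExpressionDataset}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeExpressionDataset <- function(ds, path) {
  X <- exprValues(ds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(X), collapse = "\t"), con)
  write.table(format(X, digits = 15, trim = TRUE, scientific = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an expression dataset from TSV
#'
#' @param path Path to a file written by [writeExpressionDataset()].
#' @param geneIds Optional gene ids to validate the header against; a
#'   mismatch is an error.
#' @param ... Tags passed to [expressionDataset()].
#' @return An \linkS4class{ExpressionDataset}.
#' @export
readExpressionDataset <- function(path, geneIds = NULL, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty expression file: ", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "numeric")
  if (nrow(df) == 0) stop("expression file has no samples: ", path)
  X <- as.matrix(df)
  if (any(!is.finite(X))) stop("non-numeric or missing cells in: ", path)
  if (!is.null(geneIds) && !identical(colnames(X), as.character(geneIds)))
    stop("header gene ids do not match the expected gene ids")
  expressionDataset(X, colnames(X), ...)
}
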