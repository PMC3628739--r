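#' @import methods
#' @importFrom stats cor median quantile runif rnorm rlnorm sd setNames
#'   p.adjust pbinom
#' @importFrom utils read.delim write.table head
NULL

## ------------------------------------------------------------------------
## SignedNetwork: the ground-truth regulatory graph G_true
## ------------------------------------------------------------------------

#' SignedNetwork: a signed directed regulatory network
#'
#' Container for the ground-truth regulatory structure driving the
#' expression simulator: a directed graph over genes whose edges carry a
#' sign, +1 for activation and -1 for repression. The canonical
#' representation is the signed adjacency matrix \code{A[i, j]} giving the
#' sign of the regulation gene i -> gene j (0 for no edge); self-loops are
#' forbidden.
#'
#' @slot geneIds Character vector of gene labels (column/row order of the
#'   adjacency matrix).
#' @slot adjacency Integer matrix with entries in \{-1, 0, +1\} and zero
#'   diagonal; rows are regulators, columns targets.
#' @seealso [erdosRenyiNetwork()], [scaleFreeNetwork()], [readEdgeList()]
#' @exportClass SignedNetwork
setClass("SignedNetwork",
  representation(geneIds = "character", adjacency = "matrix"))

setValidity("SignedNetwork", function(object) {
  A <- object@adjacency
  n <- length(object@geneIds)
  if (!is.numeric(A)) return("adjacency must be numeric")
  if (nrow(A) != n || ncol(A) != n)
    return("adjacency dimensions must match the number of gene ids")
  if (anyDuplicated(object@geneIds)) return("gene ids must be unique")
  if (!all(A %in% c(-1, 0, 1))) return("adjacency entries must be -1, 0 or +1")
  if (any(diag(A) != 0)) return("self-loops are not allowed (diagonal must be 0)")
  TRUE
})

## ------------------------------------------------------------------------
## KineticParams: per-gene/per-edge kinetics of the transcription model
## ------------------------------------------------------------------------

#' KineticParams: kinetic parameters of the regulation model
#'
#' Gene-specific kinetic parameters of the transcription model: maximal
#' transcription rates V (concentration/time), first-order degradation
#' rates lambda (1/time), per-edge Hill regulation thresholds K
#' (concentration, stored as a matrix aligned with the network adjacency)
#' and the Hill exponent m.
#'
#' @slot V Numeric vector, per-gene maximal transcription rate (>= 0).
#' @slot lambda Numeric vector, per-gene degradation rate (> 0).
#' @slot K Numeric matrix, K[i, j] > 0 is the threshold of regulator i
#'   acting on target j (0 where no edge).
#' @slot m Numeric scalar Hill exponent (>= 1).
#' @seealso [sampleKineticParams()]
#' @exportClass KineticParams
setClass("KineticParams",
  representation(V = "numeric", lambda = "numeric", K = "matrix",
                 m = "numeric"))

setValidity("KineticParams", function(object) {
  if (any(object@V < 0)) return("V must be nonnegative")
  if (any(object@lambda <= 0)) return("lambda must be positive")
  if (length(object@lambda) != length(object@V))
    return("V and lambda must have equal length")
  if (object@m < 1) return("Hill exponent m must be >= 1")
  if (any(object@K < 0)) return("K thresholds must be nonnegative")
  TRUE
})

## ------------------------------------------------------------------------
## StimulusProfile: environmental condition
## ------------------------------------------------------------------------

#' StimulusProfile: an environmental condition
#'
#' Describes the external stimulus a simulated cell population experiences:
#' \describe{
#'   \item{normal}{no external stimulation (observational data);}
#'   \item{constant}{growth in rich media, a constant positive input Ec
#'     added to every gene's dynamics at all times;}
#'   \item{spike}{a transient spike-in stimulation: each gene receives
#'     Es * r (r uniform on [0,1], redrawn per gene and trajectory) during
#'     the window [ts, ts + dtSpike), and nothing outside it.}
#' }
#' Ec and Es may be NA in a profile attached to an ensemble run, in which
#' case they are resolved against the kinetic parameters (Ec = 0.5 *
#' median(V), Es = 2 * median(V)).
#'
#' @slot condition One of "normal", "constant", "spike".
#' @slot Ec Constant stimulus magnitude (condition "constant").
#' @slot Es Spike magnitude scale (condition "spike").
#' @slot ts Spike onset time.
#' @slot dtSpike Spike duration (> 0).
#' @seealso [stimulusProfile()], [stimulusValue()]
#' @exportClass StimulusProfile
setClass("StimulusProfile",
  representation(condition = "character", Ec = "numeric", Es = "numeric",
                 ts = "numeric", dtSpike = "numeric"))

setValidity("StimulusProfile", function(object) {
  if (!object@condition %in% c("normal", "constant", "spike"))
    return("condition must be one of 'normal', 'constant', 'spike'")
  if (!is.na(object@Ec) && object@Ec < 0) return("Ec must be >= 0")
  if (!is.na(object@Es) && object@Es < 0) return("Es must be >= 0")
  if (object@dtSpike <= 0) return("dtSpike must be > 0")
  TRUE
})

## ------------------------------------------------------------------------
## ExpressionDataset: one D_e(t_i), an S x n snapshot of the population
## ------------------------------------------------------------------------

#' ExpressionDataset: a single-time-point expression dataset
#'
#' A \linkS4class{SummarizedExperiment} holding one simulated dataset
#' D_e(t_i): S samples (columns) by n genes (rows) of nonnegative
#' expression values, all measured at one observational time point, tagged
#' with the generating condition, network, time index and replicate.
#'
#' @slot timeIndex Integer position of the observation time on the grid.
#' @slot time Numeric observation time.
#' @slot replicate Integer replicate (dataset) index e.
#' @slot condition Character condition tag.
#' @slot networkId Character tag of the generating network.
#' @seealso [expressionDataset()], [generateEnsemble()], [exprValues()]
#' @import SummarizedExperiment
#' @exportClass ExpressionDataset
setClass("ExpressionDataset",
  contains = "SummarizedExperiment",
  representation(timeIndex = "integer", time = "numeric",
                 replicate = "integer", condition = "character",
                 networkId = "character"))

setValidity("ExpressionDataset", function(object) {
  x <- SummarizedExperiment::assay(object)
  if (!is.numeric(x)) return("expression values must be numeric")
  if (any(!is.finite(x))) return("expression values must be finite")
  if (any(x < 0)) return("expression values must be nonnegative")
  TRUE
})

## ------------------------------------------------------------------------
## BinnedCounts: histogram counts feeding the discrete entropy estimators
## ------------------------------------------------------------------------

#' BinnedCounts: histogram counts for entropy estimation
#'
#' Bin occupancy counts of a discretized sample: a vector (1-D marginal
#' histogram) or matrix (2-D joint histogram) of nonnegative counts n_k
#' summing to the sample size N.
#'
#' @slot counts Numeric vector or matrix of bin counts.
#' @slot N Integer total sample count, sum(counts).
#' @seealso [binCounts()], [entropyEmpirical()], [entropyMillerMadow()]
#' @exportClass BinnedCounts
setClass("BinnedCounts", representation(counts = "array", N = "integer"))

setValidity("BinnedCounts", function(object) {
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (sum(object@counts) != object@N) return("counts must sum to N")
  if (object@N < 1) return("N must be >= 1")
  TRUE
})

## ------------------------------------------------------------------------
## MIMatrix: pairwise mutual information
## ------------------------------------------------------------------------

#' MIMatrix: symmetric matrix of pairwise mutual information estimates
#'
#' Gene-by-gene mutual information estimates in bits, symmetric with the
#' diagonal set to 0 and all entries clipped at 0, as consumed by the
#' inference algorithms.
#'
#' @slot geneIds Character gene labels.
#' @slot values Numeric symmetric matrix of MI estimates (bits).
#' @slot estimator Character estimator tag ("empirical", "miller_madow"
#'   or "pearson").
#' @seealso [miMatrix()]
#' @exportClass MIMatrix
setClass("MIMatrix",
  representation(geneIds = "character", values = "matrix",
                 estimator = "character"))

setValidity("MIMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (nrow(v) != length(object@geneIds))
    return("values dimensions must match gene ids")
  if (any(!is.finite(v))) return("MI values must be finite")
  if (any(v < 0)) return("MI values must be nonnegative (clipped at 0)")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-10)))
    return("values must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be 0")
  TRUE
})

## ------------------------------------------------------------------------
## EdgeSignificance: permutation-null binarization layer
## ------------------------------------------------------------------------

#' EdgeSignificance: permutation null distribution for edge significance
#'
#' Null MI values obtained from column-wise independently permuted copies
#' of a dataset, together with the significance level alpha and the
#' derived cutoff (the empirical (1 - alpha) quantile of the null). Shared
#' by all MI-thresholded inference methods so their binarization is
#' comparable.
#'
#' @slot nullSamples Numeric pooled null MI values.
#' @slot alpha Numeric significance level in (0, 1).
#' @slot threshold Numeric derived MI cutoff.
#' @seealso [nullMIThreshold()]
#' @exportClass EdgeSignificance
setClass("EdgeSignificance",
  representation(nullSamples = "numeric", alpha = "numeric",
                 threshold = "numeric"))

setValidity("EdgeSignificance", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (length(object@nullSamples) < 1) return("nullSamples must be nonempty")
  TRUE
})

## ------------------------------------------------------------------------
## InferredNetwork: binary undirected estimate G_est
## ------------------------------------------------------------------------

#' InferredNetwork: a binary undirected network estimate
#'
#' The output of an inference algorithm: a symmetric 0/1 adjacency matrix
#' with zero diagonal over the same genes as the input data, tagged with
#' the method and the parameters used.
#'
#' @slot geneIds Character gene labels.
#' @slot adjacency Numeric symmetric 0/1 matrix, zero diagonal.
#' @slot method Character method tag.
#' @slot params List of parameters the method was run with.
#' @seealso [inferC3NET()], [inferBC3NET()], [inferCLR()], [inferMRNET()],
#'   [inferARACNE()]
#' @exportClass InferredNetwork
setClass("InferredNetwork",
  representation(geneIds = "character", adjacency = "matrix",
                 method = "character", params = "list"))

setValidity("InferredNetwork", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (nrow(A) != length(object@geneIds))
    return("adjacency dimensions must match gene ids")
  if (!all(A %in% c(0, 1))) return("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0)) return("diagonal must be 0")
  if (!identical(unname(A), unname(t(A)))) return("adjacency must be symmetric")
  TRUE
})

## ------------------------------------------------------------------------
## FScoreSeries: per-time-point F-score distributions and ratios
## ------------------------------------------------------------------------

#' FScoreSeries: F-scores across observational time points
#'
#' Aggregates the E per-replicate F-scores observed at each time point of
#' the grid into medians and ratios to the steady-state (final time point)
#' median, the quantity the benchmark reports.
#'
#' @slot scores Data frame with columns timeIndex, time, replicate, fscore.
#' @slot summary Data frame with columns timeIndex, time, median, ratio;
#'   ratio is NA (undefined, not 0) when the steady-state median is 0.
#' @slot steadyIndex Integer time index designated as steady state.
#' @seealso [summarizeFScores()]
#' @exportClass FScoreSeries
setClass("FScoreSeries",
  representation(scores = "data.frame", summary = "data.frame",
                 steadyIndex = "integer"))

## ------------------------------------------------------------------------
## DesignManifest: dry-run enumeration of the whole simulation design
## ------------------------------------------------------------------------

#' DesignManifest: enumeration of the simulation design
#'
#' Deterministic enumeration of every (condition, network, replicate) job
#' of an experiment, together with the derived dataset and inference
#' counts, computable without running any job (dry-run accounting).
#'
#' @slot config List, the validated configuration.
#' @slot jobs Data frame with one row per (condition, network, replicate)
#'   job, including the per-job derived seed.
#' @slot counts List of derived counts: datasetsPerNetworkCondition,
#'   inferredPerNetworkCondition, totalDatasets, totalInferred.
#' @seealso [buildManifest()], [runExperiment()]
#' @exportClass DesignManifest
setClass("DesignManifest",
  representation(config = "list", jobs = "data.frame", counts = "list"))
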