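## Mutual information module. All logarithms are base 2; MI is reported
## in bits and clipped at 0 so downstream score comparisons are always
## well defined.

#' Discretize a sample vector into bin counts
#'
#' Assigns every sample to exactly one bin, with right-open bins except
#' the last (which is closed). \code{equal_width} splits the observed
#' range into b equal intervals; \code{equal_frequency} uses sample
#' quantiles as break points. A constant vector under
#' \code{equal_frequency} falls back to a single bin (this is documented
#' behaviour, not an error).
#'
#' @param x Numeric sample vector (length >= 1).
#' @param b Number of bins (>= 1).
#' @param rule Binning rule, "equal_width" or "equal_frequency".
#' @return A \linkS4class{BinnedCounts}.
#' @examples
#' binCounts(c(1, 2, 3, 4), b = 2)         # counts 2, 2
#' @export
binCounts <- function(x, b, rule = c("equal_width", "equal_frequency")) {
  rule <- match.arg(rule)
  idx <- .binIndex(x, b, rule)
  counts <- tabulate(idx, nbins = max(idx))
  new("BinnedCounts", counts = as.array(counts), N = length(x))
}

## Bin assignment shared by the 1-D and 2-D histograms.
.binIndex <- function(x, b, rule) {
  if (length(x) < 1) stop("'x' must be nonempty")
  if (b < 1) stop("'b' must be >= 1")
  if (b == 1) return(rep(1L, length(x)))
  breaks <- switch(rule,
    equal_width = seq(min(x), max(x), length.out = b + 1),
    equal_frequency = unique(quantile(x, probs = seq(0, 1, length.out = b + 1),
                                      names = FALSE)))
  breaks <- unique(breaks)
  if (length(breaks) <= 2) return(rep(1L, length(x)))  # constant fallback
  ## [b_k, b_{k+1}) bins, the last closed on the right
  i <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(i)
}

#' Empirical (plug-in) entropy of binned counts
#'
#' The maximum-likelihood entropy of the observed frequency distribution,
#' \eqn{H_{emp} = -\sum_k (n_k/N) \log_2 (n_k/N)}, with 0 log 0 taken as
#' 0. Bounded by \eqn{\log_2 b}.
#'
#' @param counts A \linkS4class{BinnedCounts} (1-D vector or 2-D joint
#'   matrix of counts), or a bare numeric vector/matrix of counts.
#' @return Entropy in bits.
#' @examples
#' entropyEmpirical(binCounts(runif(100), 4))
#' entropyEmpirical(c(25, 25, 25, 25))  # 2 bits
#' @export
entropyEmpirical <- function(counts) {
  nk <- .countsOf(counts)
  N <- sum(nk)
  p <- nk[nk > 0] / N
  -sum(p * log2(p))
}

#' Miller-Madow bias-corrected entropy
#'
#' The empirical entropy plus the first-order bias correction
#' \eqn{(b - 1) / (2N)}, where b is the number of occupied (nonempty)
#' bins or cells and N the sample count. Always >= the empirical
#' estimate.
#'
#' @inheritParams entropyEmpirical
#' @return Entropy in bits.
#' @examples
#' entropyMillerMadow(c(50, 25, 25))  # 1.5 + 2/200 at N = 100
#' @export
entropyMillerMadow <- function(counts) {
  nk <- .countsOf(counts)
  N <- sum(nk)
  b <- sum(nk > 0)
  entropyEmpirical(nk) + (b - 1) / (2 * N)
}

.countsOf <- function(counts) {
  if (is(counts, "BinnedCounts")) counts@counts else counts
}

#' Mutual information from marginal and joint entropies
#'
#' \eqn{I(X, Y) = H(X) + H(Y) - H(X, Y)}, clipped at 0 (bias-corrected
#' entropy combinations can dip slightly below 0).
#'
#' @param Hx,Hy,Hxy Entropies in bits.
#' @return MI in bits, nonnegative.
#' @export
miFromEntropies <- function(Hx, Hy, Hxy) {
  pmax(0, Hx + Hy - Hxy)
}

#' Gaussian mutual information from a correlation coefficient
#'
#' The bivariate-normal closed form \eqn{I = -\frac{1}{2}\log_2(1 -
#' \rho^2)} (exact for normally distributed variables), with \eqn{|\rho|}
#' clamped at \eqn{1 - 10^{-12}} to keep the value finite.
#'
#' @param rho Pearson correlation coefficient(s).
#' @return MI in bits, nonnegative.
#' @examples
#' gaussianMI(0.9)  # -0.5 * log2(0.19)
#' @export
gaussianMI <- function(rho) {
  rho <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
  v <- -0.5 * log2(1 - rho^2)
  v[v < 0] <- 0  # preserves dim for matrix input
  v
}

#' Pearson (Gaussian) mutual information between two sample vectors
#'
#' Estimates MI through the sample Pearson correlation and the
#' bivariate-normal closed form. A constant vector (undefined
#' correlation) yields 0 with a message.
#'
#' @param x,y Numeric sample vectors of equal length (N >= 3).
#' @return MI in bits.
#' @export
miPearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("at least 3 samples are required")
  if (sd(x) == 0 || sd(y) == 0) {
    message("constant vector: Pearson correlation undefined, MI set to 0")
    return(0)
  }
  gaussianMI(cor(x, y))
}

## Discrete MI between two pre-binned index vectors.
.miDiscrete <- function(ix, iy, bx, by, estimator) {
  jointCounts <- tabulate(ix + bx * (iy - 1L), nbins = bx * by)
  cx <- tabulate(ix, nbins = bx)
  cy <- tabulate(iy, nbins = by)
  H <- if (estimator == "miller_madow") entropyMillerMadow else entropyEmpirical
  miFromEntropies(H(cx), H(cy), H(jointCounts))
}

#' Pairwise mutual information matrix of a dataset
#'
#' Computes the symmetric gene-by-gene MI matrix feeding every inference
#' method, with the chosen estimator: \code{"pearson"} (Gaussian closed
#' form, the default used for the main experiments), \code{"empirical"}
#' (plug-in entropy on a discretized sample) or \code{"miller_madow"}
#' (bias-corrected discrete entropies; the 2-D correction counts the
#' nonempty cells of the joint histogram). The diagonal is 0 and all
#' entries are clipped at 0.
#'
#' @param ds An \linkS4class{ExpressionDataset} or a samples-by-genes
#'   numeric matrix (S >= 3).
#' @param estimator One of "pearson", "empirical", "miller_madow".
#' @param bins Bin count for the discrete estimators; default
#'   \code{ceiling(sqrt(S))}.
#' @param rule Binning rule for the discrete estimators.
#' @return An \linkS4class{MIMatrix}.
#' @examples
#' X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' miValues(miMatrix(X))
#' @export
miMatrix <- function(ds, estimator = c("pearson", "empirical", "miller_madow"),
                     bins = NULL, rule = "equal_width") {
  estimator <- match.arg(estimator)
  X <- if (is(ds, "ExpressionDataset")) exprValues(ds) else as.matrix(ds)
  if (nrow(X) < 3) stop("at least 3 samples are required")
  ids <- colnames(X)
  if (is.null(ids)) ids <- .defaultGeneIds(ncol(X))
  M <- .miMatrixValues(X, estimator, bins, rule)
  dimnames(M) <- list(ids, ids)
  new("MIMatrix", geneIds = ids, values = M, estimator = estimator)
}

.miMatrixValues <- function(X, estimator, bins = NULL, rule = "equal_width") {
  n <- ncol(X)
  if (estimator == "pearson") {
    C <- suppressWarnings(cor(X))
    C[!is.finite(C)] <- 0  # constant columns
    M <- gaussianMI(C)
  } else {
    if (is.null(bins)) bins <- ceiling(sqrt(nrow(X)))
    idxs <- lapply(seq_len(n), function(j) .binIndex(X[, j], bins, rule))
    bs <- vapply(idxs, max, 1L)
    M <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        M[i, j] <- .miDiscrete(idxs[[i]], idxs[[j]], bs[i], bs[j], estimator)
      }
    }
    M <- M + t(M)
  }
  M[lower.tri(M)] <- t(M)[lower.tri(M)]  # exact symmetry
  diag(M) <- 0
  M
}

#' @describeIn miValues MI values of an MIMatrix
#' @export
setMethod("miValues", "MIMatrix", function(object) object@values)

#' @describeIn geneIds gene labels of an MIMatrix
#' @export
setMethod("geneIds", "MIMatrix", function(object) object@geneIds)

#' @describeIn nGenes gene count of an MIMatrix
#' @export
setMethod("nGenes", "MIMatrix", function(object) length(object@geneIds))

setMethod("show", "MIMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("MIMatrix (%s): %d genes; off-diagonal MI in [%.4g, %.4g] bits\n",
              object@estimator, nGenes(object), min(v), max(v)))
})

#' Write / read an MI matrix as TSV
#'
#' Tab-separated n x n matrix with the gene ids as header row and first
#' column.
#'
#' @param M An \linkS4class{MIMatrix}.
#' @param path File path.
#' @return \code{writeMIMatrix}: invisibly, the path;
#'   \code{readMIMatrix}: an \linkS4class{MIMatrix}.
#' @export
writeMIMatrix <- function(M, path) {
  df <- data.frame(gene = geneIds(M),
                   format(miValues(M), digits = 15, trim = TRUE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMIMatrix
#' @param estimator Estimator tag recorded on the object read back.
#' @export
readMIMatrix <- function(path, estimator = "pearson") {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(ids, ids)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  new("MIMatrix", geneIds = ids, values = v, estimator = estimator)
}
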