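## Inference module: from-scratch implementations of C3NET, BC3NET, CLR,
## MRNET and ARACNE, mapping a mutual-information matrix (or a dataset,
## for the bagging of BC3NET) to a binary undirected network estimate.
##
## Binarization principle: a single permutation-null MI threshold (the
## (1 - alpha) quantile of MI values computed from column-wise
## independently permuted copies of the data) is shared by the
## MI-thresholded methods, and CLR uses a z-score cutoff on its
## row-standardized statistic, so that the five methods are binarized
## under one calibration principle and stay comparable.

.newInferred <- function(geneIds, A, method, params = list()) {
  storage.mode(A) <- "double"
  dimnames(A) <- list(geneIds, geneIds)
  new("InferredNetwork", geneIds = geneIds, adjacency = A,
      method = method, params = params)
}

#' Permutation-null MI threshold for edge significance
#'
#' Pools MI values from P column-wise independently permuted copies of a
#' dataset (permutation destroys all between-gene dependence while
#' preserving every marginal) and derives the empirical (1 - alpha)
#' quantile as the significance cutoff shared by the MI-thresholded
#' inference methods.
#'
#' @param ds An \linkS4class{ExpressionDataset} or samples-by-genes
#'   matrix.
#' @param estimator MI estimator, as in [miMatrix()].
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param P Number of permuted copies (>= 100; the quantile is too
#'   unstable below that).
#' @param seed Integer seed.
#' @param bins,rule Passed to the discrete estimators.
#' @return An \linkS4class{EdgeSignificance}.
#' @export
nullMIThreshold <- function(ds, estimator = "pearson", alpha = 0.05,
                            P = 200, seed = NULL, bins = NULL,
                            rule = "equal_width") {
  if (P < 100) stop("'P' must be >= 100 for a stable quantile")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  X <- if (is(ds, "ExpressionDataset")) exprValues(ds) else as.matrix(ds)
  S <- nrow(X)
  pool <- .withSeed(seed, {
    unlist(lapply(seq_len(P), function(p) {
      Xp <- apply(X, 2, sample, size = S)
      M <- .miMatrixValues(Xp, estimator, bins, rule)
      M[upper.tri(M)]
    }), use.names = FALSE)
  })
  new("EdgeSignificance", nullSamples = pool, alpha = alpha,
      threshold = quantile(pool, 1 - alpha, names = FALSE))
}

#' @describeIn miThreshold cutoff of an EdgeSignificance
#' @export
setMethod("miThreshold", "EdgeSignificance", function(object) object@threshold)

setMethod("show", "EdgeSignificance", function(object) {
  cat(sprintf("EdgeSignificance: %d null MI values, alpha = %g, threshold = %.4g bits\n",
              length(object@nullSamples), object@alpha, object@threshold))
})

## ------------------------------------------------------------------------
## C3NET: per-gene maximal mutual information
## ------------------------------------------------------------------------

## Core C3NET selection: per gene i take j* = argmax_j W[i, j] (ties to
## the lowest index via which.max) and keep the pair iff keep[i, j*].
.c3netSelect <- function(W, keep) {
  n <- nrow(W)
  A <- matrix(0, n, n)
  diag(W) <- -Inf
  for (i in seq_len(n)) {
    j <- which.max(W[i, ])
    if (keep[i, j]) { A[i, j] <- 1; A[j, i] <- 1 }
  }
  A
}

#' C3NET network inference
#'
#' Conservative causal core: each gene nominates its maximally
#' mutually-informative partner, and the pair becomes an edge iff its MI
#' exceeds the significance threshold. The result has at most n edges.
#'
#' @param M An \linkS4class{MIMatrix}.
#' @param sig An \linkS4class{EdgeSignificance}.
#' @return An \linkS4class{InferredNetwork}.
#' @export
inferC3NET <- function(M, sig) {
  W <- miValues(M)
  A <- .c3netSelect(W, W > miThreshold(sig))
  .newInferred(geneIds(M), A, "c3net", list(alpha = sig@alpha,
                                            threshold = miThreshold(sig)))
}

## ------------------------------------------------------------------------
## BC3NET: bagging of C3NET over bootstrap resamples
## ------------------------------------------------------------------------

#' BC3NET network inference (bagged C3NET)
#'
#' Runs a C3NET-style selection on B bootstrap resamples of the samples
#' and aggregates: within each resample, a gene's nominated pair is kept
#' iff its Benjamini-Hochberg-adjusted permutation p-value is at most
#' \code{alphaEdge}; an edge enters the ensemble network iff its
#' selection count over the B bags is significant under a one-sided
#' binomial test against the mean per-edge selection probability of the
#' ensemble, at level \code{alphaEnsemble}. With \code{B = 1} the result
#' is the single bag's network (degenerate bagging).
#'
#' @param ds An \linkS4class{ExpressionDataset} or samples-by-genes
#'   matrix.
#' @param B Number of bootstrap resamples (>= 1), default 50.
#' @param alphaEdge Per-bag edge significance level (BH-adjusted).
#' @param alphaEnsemble Ensemble binomial-test level.
#' @param estimator MI estimator.
#' @param seed Integer seed.
#' @param P Permutations for the shared null distribution.
#' @param bins,rule Passed to the discrete estimators.
#' @return An \linkS4class{InferredNetwork}.
#' @export
inferBC3NET <- function(ds, B = 50, alphaEdge = 0.05, alphaEnsemble = 0.05,
                        estimator = "pearson", seed = NULL, P = 200,
                        bins = NULL, rule = "equal_width") {
  if (B < 1) stop("'B' must be >= 1")
  X <- if (is(ds, "ExpressionDataset")) exprValues(ds) else as.matrix(ds)
  S <- nrow(X); n <- ncol(X)
  ids <- colnames(X); if (is.null(ids)) ids <- .defaultGeneIds(n)
  ## Null distribution matched to the bootstrap: duplicated rows inflate
  ## MI estimates, so each permuted copy is bootstrap-resampled first.
  if (P < 100) stop("'P' must be >= 100 for stable p-values")
  pool <- .withSeed(if (is.null(seed)) NULL else deriveSeed(seed, "null"), {
    unlist(lapply(seq_len(P), function(p) {
      Xp <- apply(X, 2, sample, size = S)        # destroy dependence
      Xp <- Xp[sample(S, S, replace = TRUE), , drop = FALSE]  # then resample
      Mp <- .miMatrixValues(Xp, estimator, bins, rule)
      Mp[upper.tri(Mp)]
    }), use.names = FALSE)
  })
  nullSorted <- sort(pool)
  nNull <- length(nullSorted)
  up <- upper.tri(matrix(0, n, n))
  counts <- matrix(0, n, n)
  .withSeed(if (is.null(seed)) NULL else deriveSeed(seed, "boot"), {
    for (b in seq_len(B)) {
      Xb <- X[sample(S, S, replace = TRUE), , drop = FALSE]
      Mb <- .miMatrixValues(Xb, estimator, bins, rule)
      ## permutation p-values per pair, BH-adjusted across the pairs
      pv <- (1 + nNull - findInterval(Mb[up], nullSorted)) / (1 + nNull)
      padj <- p.adjust(pv, method = "BH")
      keep <- matrix(FALSE, n, n)
      keep[up] <- padj <= alphaEdge
      keep <- keep | t(keep)
      counts <- counts + .c3netSelect(Mb, keep)
    }
  })
  if (B == 1) {
    A <- counts
  } else {
    ## mean per-edge selection probability over the ensemble of all
    ## candidate pairs; one-sided binomial test per pair, Bonferroni-
    ## corrected so the ensemble test controls the family-wise rate
    cnt <- counts[up]
    npairs <- n * (n - 1) / 2
    A <- matrix(0, n, n)
    if (any(cnt > 0)) {
      p0 <- sum(cnt) / (B * npairs)
      pens <- pbinom(cnt - 1, B, p0, lower.tail = FALSE)
      keepIdx <- which(up)[pens <= alphaEnsemble / npairs & cnt > 0]
      A[keepIdx] <- 1
      A <- A + t(A)
    }
  }
  .newInferred(ids, A, "bc3net",
               list(B = B, alphaEdge = alphaEdge,
                    alphaEnsemble = alphaEnsemble, estimator = estimator))
}

## ------------------------------------------------------------------------
## CLR: row-standardized (local) mutual information
## ------------------------------------------------------------------------

#' CLR network inference (context likelihood of relatedness)
#'
#' Standardizes each MI value against its row background: z_i(j) =
#' max(0, (M[i,j] - mu_i) / sigma_i) with mu_i, sigma_i the mean and
#' standard deviation of row i's off-diagonal entries, combines the two
#' directions as w_ij = sqrt(z_i(j)^2 + z_j(i)^2), and keeps the edge iff
#' w_ij exceeds \code{zThreshold}. A zero-variance row contributes z = 0.
#'
#' @param M An \linkS4class{MIMatrix} (n >= 3).
#' @param zThreshold Joint z-score cutoff, default 2.
#' @return An \linkS4class{InferredNetwork}.
#' @export
inferCLR <- function(M, zThreshold = 2) {
  W <- miValues(M)
  n <- nrow(W)
  if (n < 3) stop("CLR requires at least 3 genes")
  off <- !diag(n)
  mu <- rowSums(W * off) / (n - 1)
  s2 <- rowSums((W - mu)^2 * off) / (n - 1)  # population variance of the row background
  sdv <- sqrt(pmax(s2, 0))
  Z <- (W - mu) / ifelse(sdv > 0, sdv, Inf)  # sigma = 0 rows contribute 0
  if (any(sdv == 0))
    message(sum(sdv == 0), " zero-variance row(s): contributing z = 0")
  Z[Z < 0] <- 0
  Wjoint <- sqrt(Z^2 + t(Z)^2)
  A <- (Wjoint > zThreshold) * off
  A <- 1 * (A | t(A))
  .newInferred(geneIds(M), A, "clr", list(zThreshold = zThreshold))
}

## ------------------------------------------------------------------------
## MRNET: greedy maximum-relevance minimum-redundancy selection
## ------------------------------------------------------------------------

#' MRNET network inference (maximum relevance, minimum redundancy)
#'
#' For each target gene, regulators are selected by greedy forward mRMR:
#' at every step the candidate maximizing relevance minus redundancy,
#' s_j = M[t, j] - mean over already-selected k of M[j, k], is added;
#' selection stops when the best score drops to the significance floor
#' (the null MI threshold) or below. A pair's score is the maximum over
#' the two selection directions, and edges are the pairs whose score
#' exceeds the threshold. Ties break toward the lowest gene index.
#'
#' @param M An \linkS4class{MIMatrix}.
#' @param sig An \linkS4class{EdgeSignificance}.
#' @return An \linkS4class{InferredNetwork}.
#' @export
inferMRNET <- function(M, sig) {
  W <- miValues(M)
  n <- nrow(W)
  thr <- miThreshold(sig)
  score <- matrix(0, n, n)  # score[t, j]: mRMR score of j for target t
  for (t in seq_len(n)) {
    cand <- setdiff(seq_len(n), t)
    selected <- integer(0)
    redSum <- numeric(n)  # running sum of M[j, selected]
    while (length(cand) > 0) {
      s <- W[t, cand] -
        if (length(selected)) redSum[cand] / length(selected) else 0
      best <- which.max(s)  # first maximum = lowest gene index
      if (s[best] <= max(0, thr)) break
      j <- cand[best]
      score[t, j] <- s[best]
      selected <- c(selected, j)
      cand <- cand[-best]
      redSum <- redSum + W[, j]
    }
  }
  pairScore <- pmax(score, t(score))
  A <- 1 * (pairScore > thr)
  diag(A) <- 0
  .newInferred(geneIds(M), A, "mrnet",
               list(alpha = sig@alpha, threshold = thr))
}

## ------------------------------------------------------------------------
## ARACNE: significance thresholding + data processing inequality
## ------------------------------------------------------------------------

#' ARACNE network inference (pairwise MI with DPI pruning)
#'
#' Starts from the pairs whose MI exceeds the significance threshold and
#' applies the data processing inequality: within every triangle
#' (i, j, k) of retained edges, the edge (i, j) is removed iff
#' M[i,j] < min(M[i,k], M[j,k]) - eps. Removals are computed
#' simultaneously against the original MI matrix (not sequentially), so
#' the result is independent of edge order and always a subset of the
#' thresholded network. Ties (equal weights) are kept: removal requires
#' strict inequality.
#'
#' @param M An \linkS4class{MIMatrix}.
#' @param sig An \linkS4class{EdgeSignificance}.
#' @param eps DPI tolerance (>= 0), default 0.
#' @return An \linkS4class{InferredNetwork}.
#' @export
inferARACNE <- function(M, sig, eps = 0) {
  if (eps < 0) stop("'eps' must be >= 0")
  W <- miValues(M)
  n <- nrow(W)
  adj <- W > miThreshold(sig)
  diag(adj) <- FALSE
  remove <- matrix(FALSE, n, n)
  if (n >= 3) {
    for (k in seq_len(n)) {
      ek <- adj[, k]
      if (sum(ek) < 2) next
      ## triangles through k: pairs (i, j) with i-k and j-k both edges
      tri <- outer(ek, ek, "&")
      wk <- W[, k]
      minik <- pmin(matrix(wk, n, n), matrix(wk, n, n, byrow = TRUE))
      remove <- remove | (adj & tri & (W < minik - eps))
    }
  }
  A <- 1 * (adj & !remove)
  .newInferred(geneIds(M), A, "aracne",
               list(alpha = sig@alpha, threshold = miThreshold(sig),
                    eps = eps))
}
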