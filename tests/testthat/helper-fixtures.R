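## Small fixtures built in code, shared across test files.

## A hand-specified MIMatrix from a symmetric matrix of values.
makeMI <- function(v, estimator = "pearson") {
  v <- as.matrix(v)
  diag(v) <- 0
  ids <- sprintf("G%d", seq_len(nrow(v)))
  dimnames(v) <- list(ids, ids)
  new("MIMatrix", geneIds = ids, values = v, estimator = estimator)
}

## An EdgeSignificance with a fixed threshold (bypassing permutation).
makeSig <- function(threshold, alpha = 0.05) {
  new("EdgeSignificance", nullSamples = c(0, threshold), alpha = alpha,
      threshold = threshold)
}

## An InferredNetwork from an unordered edge list over n genes.
makeInferred <- function(n, pairs, method = "test") {
  ids <- sprintf("G%d", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in pairs) { A[p[1], p[2]] <- 1; A[p[2], p[1]] <- 1 }
  new("InferredNetwork", geneIds = ids, adjacency = A, method = method,
      params = list())
}

## A SignedNetwork from a directed signed edge list (src, tgt, sign).
makeSigned <- function(n, edges) {
  ids <- sprintf("G%d", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) A[e[1], e[2]] <- e[3]
  signedNetwork(A, ids)
}

## Samples-by-genes matrix of independent Gaussian noise.
nullData <- function(S, n, seed) {
  set.seed(seed)
  matrix(rnorm(S * n), S, n,
         dimnames = list(NULL, sprintf("G%d", seq_len(n))))
}

## A Markov-chain-coupled 3-gene dataset X -> Y -> Z.
chainData <- function(S, rho = 0.95, seed = 1) {
  set.seed(seed)
  x <- rnorm(S)
  y <- rho * x + rnorm(S, 0, sqrt(1 - rho^2))
  z <- rho * y + rnorm(S, 0, sqrt(1 - rho^2))
  cbind(G1 = x, G2 = y, G3 = z)
}
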