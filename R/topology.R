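## Topology module: generation, loading and serialization of the signed
## directed regulatory networks that define the coupling of the
## dynamical system.

.defaultGeneIds <- function(n) sprintf("G%d", seq_len(n))

#' Construct a SignedNetwork from a signed adjacency matrix
#'
#' @param adjacency Square numeric matrix with entries in \{-1, 0, +1\}
#'   and zero diagonal; rows are regulators, columns targets.
#' @param geneIds Character gene labels; defaults to the matrix dimnames
#'   or G1..Gn.
#' @return A \linkS4class{SignedNetwork}.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- 1; A[2, 3] <- -1
#' signedNetwork(A)
#' @export
signedNetwork <- function(adjacency, geneIds = NULL) {
  if (is.null(geneIds)) {
    geneIds <- if (!is.null(rownames(adjacency))) rownames(adjacency)
               else .defaultGeneIds(nrow(adjacency))
  }
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(geneIds, geneIds)
  new("SignedNetwork", geneIds = as.character(geneIds), adjacency = adjacency)
}

#' Generate a signed Erdős–Rényi regulatory network
#'
#' Each ordered non-self gene pair becomes a directed edge independently
#' with probability \code{p}; each edge is an activator (+1) with
#' probability \code{activatorFraction} and a repressor (-1) otherwise.
#' The default \code{p = 2/(n - 1)} gives an expected out-degree of 2,
#' the sparse regime regulatory-network inference methods target.
#'
#' @param n Gene count (>= 2).
#' @param p Edge probability in [0, 1].
#' @param activatorFraction Probability an edge is an activator.
#' @param seed Integer seed; equal arguments give identical networks.
#' @return A \linkS4class{SignedNetwork} with \code{n} genes.
#' @examples
#' net <- erdosRenyiNetwork(10, p = 0.1, seed = 1)
#' edgeCount(net)
#' @export
erdosRenyiNetwork <- function(n, p = 2 / (n - 1), activatorFraction = 0.7,
                              seed = NULL) {
  if (!is.numeric(n) || n < 2) stop("'n' must be an integer >= 2")
  if (!is.numeric(p) || p < 0 || p > 1) stop("'p' must be a probability in [0, 1]")
  if (activatorFraction < 0 || activatorFraction > 1)
    stop("'activatorFraction' must be in [0, 1]")
  n <- as.integer(n)
  .withSeed(seed, {
    g <- igraph::sample_gnp(n, p, directed = TRUE, loops = FALSE)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    idx <- which(A != 0)
    signs <- ifelse(runif(length(idx)) < activatorFraction, 1, -1)
    A[idx] <- signs
    signedNetwork(A, .defaultGeneIds(n))
  })
}

#' Generate a degree-heterogeneous (yeast-like) regulatory network
#'
#' Synthetic stand-in for a transcriptional regulatory subnetwork such as
#' the one of \emph{S. cerevisiae}: preferential-attachment wiring
#' produces a few high-out-degree master regulators and many low-degree
#' targets, i.e. the degree heterogeneity typical of curated regulatory
#' maps, with signs assigned as in [erdosRenyiNetwork()]. It emulates the
#' degree structure only; a real curated network can be substituted via
#' [readEdgeList()].
#'
#' @param n Gene count (>= 2).
#' @param edgesPerGene Edges attached per incoming gene during
#'   preferential attachment (default 2, matching the Erdős–Rényi
#'   expected degree).
#' @param activatorFraction Probability an edge is an activator.
#' @param seed Integer seed.
#' @return A \linkS4class{SignedNetwork} with \code{n} genes.
#' @examples
#' net <- scaleFreeNetwork(100, seed = 1)
#' max(rowSums(adjacencyMatrix(net) != 0))  # hub out-degree
#' @export
scaleFreeNetwork <- function(n, edgesPerGene = 2, activatorFraction = 0.7,
                             seed = NULL) {
  if (!is.numeric(n) || n < 2) stop("'n' must be an integer >= 2")
  n <- as.integer(n)
  .withSeed(seed, {
    g <- igraph::sample_pa(n, power = 1, m = edgesPerGene, directed = TRUE)
    ## sample_pa points new -> old, concentrating IN-degree on early hubs;
    ## regulators should have high OUT-degree, so reverse all edges.
    g <- igraph::reverse_edges(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    A[A > 1] <- 1
    diag(A) <- 0
    idx <- which(A != 0)
    signs <- ifelse(runif(length(idx)) < activatorFraction, 1, -1)
    A[idx] <- signs
    signedNetwork(A, .defaultGeneIds(n))
  })
}

## ------------------------------------------------------------------------
## Edge-list serialization: `source<TAB>target<TAB>sign`
## ------------------------------------------------------------------------

#' Read a signed edge list into a SignedNetwork
#'
#' Parses a tab-separated file with columns source, target, sign
#' (+1/-1); an optional header line starting with \code{#} is skipped.
#' Malformed lines, unknown sign tokens and self-loops raise an error
#' naming the offending line.
#'
#' @param path Path to the edge-list file.
#' @param geneIds Optional character vector fixing the gene set and order;
#'   defaults to the genes seen in the file, in order of first appearance.
#' @return A \linkS4class{SignedNetwork}.
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path, geneIds = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0 && is.null(geneIds))
    stop("edge-list file is empty: ", path)
  src <- character(0); tgt <- character(0); sgn <- numeric(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop(sprintf("malformed edge-list line %d (expected 3 tab-separated fields): '%s'",
                   i, lines[[i]]))
    s <- switch(trimws(parts[3]), "+1" = 1, "1" = 1, "-1" = -1,
                stop(sprintf("unknown sign token on line %d: '%s'", i, parts[3])))
    if (parts[1] == parts[2])
      stop(sprintf("self-loop on line %d: '%s'", i, lines[[i]]))
    src <- c(src, parts[1]); tgt <- c(tgt, parts[2]); sgn <- c(sgn, s)
  }
  if (is.null(geneIds)) geneIds <- unique(c(rbind(src, tgt)))
  bad <- setdiff(c(src, tgt), geneIds)
  if (length(bad))
    stop("edge endpoints not in the gene set: ", paste(bad, collapse = ", "))
  n <- length(geneIds)
  A <- matrix(0, n, n, dimnames = list(geneIds, geneIds))
  ij <- cbind(match(src, geneIds), match(tgt, geneIds))
  if (anyDuplicated(ij))
    stop("duplicate (source, target) pair in edge list")
  A[ij] <- sgn
  signedNetwork(A, geneIds)
}

#' Write a network as a signed edge list
#'
#' Serializes a \linkS4class{SignedNetwork} (or an
#' \linkS4class{InferredNetwork}, whose sign-blind edges are written as
#' +1) to the tab-separated \code{source<TAB>target<TAB>sign} format with
#' a \code{#source target sign} header. Round trip with [readEdgeList()]
#' is the identity.
#'
#' @param net A network object.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
  et <- edgeTable(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#source\ttarget\tsign", con)
  if (nrow(et))
    writeLines(sprintf("%s\t%s\t%s", et$source, et$target,
                       ifelse(et$sign >= 0, "+1", "-1")), con)
  invisible(path)
}

## ------------------------------------------------------------------------
## Accessors and show methods
## ------------------------------------------------------------------------

#' @describeIn geneIds gene labels of a SignedNetwork
#' @export
setMethod("geneIds", "SignedNetwork", function(object) object@geneIds)

#' @describeIn adjacencyMatrix signed adjacency of a SignedNetwork
#' @export
setMethod("adjacencyMatrix", "SignedNetwork", function(object) object@adjacency)

#' @describeIn nGenes gene count of a SignedNetwork
#' @export
setMethod("nGenes", "SignedNetwork", function(object) length(object@geneIds))

#' @describeIn edgeCount directed edge count of a SignedNetwork
#' @export
setMethod("edgeCount", "SignedNetwork",
          function(object) sum(object@adjacency != 0))

#' @describeIn edgeTable directed signed edges of a SignedNetwork
#' @export
setMethod("edgeTable", "SignedNetwork", function(object) {
  idx <- which(object@adjacency != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(source = object@geneIds[idx[, 1]],
             target = object@geneIds[idx[, 2]],
             sign = object@adjacency[idx],
             stringsAsFactors = FALSE)
})

setMethod("show", "SignedNetwork", function(object) {
  m <- sum(object@adjacency != 0)
  cat(sprintf("SignedNetwork: %d genes, %d directed edges (%d activating, %d repressing)\n",
              length(object@geneIds), m, sum(object@adjacency > 0),
              sum(object@adjacency < 0)))
})

#' @describeIn geneIds gene labels of an InferredNetwork
#' @export
setMethod("geneIds", "InferredNetwork", function(object) object@geneIds)

#' @describeIn adjacencyMatrix binary adjacency of an InferredNetwork
#' @export
setMethod("adjacencyMatrix", "InferredNetwork", function(object) object@adjacency)

#' @describeIn nGenes gene count of an InferredNetwork
#' @export
setMethod("nGenes", "InferredNetwork", function(object) length(object@geneIds))

#' @describeIn edgeCount unordered edge count of an InferredNetwork
#' @export
setMethod("edgeCount", "InferredNetwork",
          function(object) sum(object@adjacency[upper.tri(object@adjacency)]))

#' @describeIn edgeTable undirected edges of an InferredNetwork (each
#'   unordered pair written once, source < target by gene order, sign +1)
#' @export
setMethod("edgeTable", "InferredNetwork", function(object) {
  A <- object@adjacency
  A[lower.tri(A, diag = TRUE)] <- 0
  idx <- which(A != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(source = object@geneIds[idx[, 1]],
             target = object@geneIds[idx[, 2]],
             sign = rep(1, nrow(idx)),
             stringsAsFactors = FALSE)
})

setMethod("show", "InferredNetwork", function(object) {
  cat(sprintf("InferredNetwork (%s): %d genes, %d undirected edges\n",
              object@method, length(object@geneIds), edgeCount(object)))
})
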