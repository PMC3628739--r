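#' Gene identifiers of a network or matrix object
#'
#' @param object A \linkS4class{SignedNetwork}, \linkS4class{MIMatrix} or
#'   \linkS4class{InferredNetwork}.
#' @return Character vector of gene labels.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' Adjacency matrix of a network object
#'
#' For a \linkS4class{SignedNetwork} the entries are -1/0/+1 (signed,
#' directed); for an \linkS4class{InferredNetwork} they are 0/1
#' (undirected, symmetric).
#'
#' @param object A network object.
#' @return Numeric matrix with gene ids as dimnames.
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' Number of genes in an object
#' @param object A network, MI matrix or expression dataset object.
#' @return Integer gene count.
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' Number of edges in a network
#'
#' Directed edges for a \linkS4class{SignedNetwork}, unordered gene pairs
#' for an \linkS4class{InferredNetwork}.
#' @param object A network object.
#' @return Integer edge count.
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' Edge table of a network
#'
#' @param object A network object.
#' @return Data frame with columns \code{source}, \code{target},
#'   \code{sign} (sign is +1 for every edge of an inferred, sign-blind
#'   network).
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' Expression values of a dataset
#'
#' Returns the samples-by-genes numeric matrix of an
#' \linkS4class{ExpressionDataset} (the transpose of the underlying
#' genes-by-samples assay).
#' @param object An \linkS4class{ExpressionDataset}.
#' @return Numeric S x n matrix, columns named by gene ids.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' Mutual information values of an MIMatrix
#' @param object An \linkS4class{MIMatrix}.
#' @return Numeric symmetric matrix (bits), gene ids as dimnames.
#' @export
setGeneric("miValues", function(object) standardGeneric("miValues"))

#' Significance threshold of an EdgeSignificance object
#' @param object An \linkS4class{EdgeSignificance}.
#' @return Numeric MI cutoff.
#' @export
setGeneric("miThreshold", function(object) standardGeneric("miThreshold"))
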