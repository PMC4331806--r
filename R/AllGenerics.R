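#' Accessors for ISHC data classes
#'
#' Small accessor generics for the package's S4 containers: `nodes()`,
#' `edges()` and `edgeWeights()` for [PPINetwork-class], `complexes()` for
#' [ComplexSet-class], `clusters()` and `epsilon()` for [Clustering-class].
#'
#' @param x a `PPINetwork`, `ComplexSet` or `Clustering` object.
#' @return `nodes()`: character vector of protein identifiers. `edges()`:
#'   two-column integer matrix of endpoint indices. `edgeWeights()`: numeric
#'   vector of weights. `complexes()`: list of character vectors.
#'   `clusters()`: list of integer index vectors. `epsilon()`: the
#'   synchronization radius that produced the clustering.
#'
#' @examples
#' net <- plantedPartitionNetwork(c(3, 3), pIn = 1, pOut = 0, seed = 1)$network
#' nodes(net)
#' head(edges(net))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("epsilon", function(x) standardGeneric("epsilon"))

#' @rdname accessors
#' @export
setMethod("nodes", "PPINetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edges", "PPINetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("edgeWeights", "PPINetwork", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("complexes", "ComplexSet", function(x) x@complexes)

#' @rdname accessors
#' @export
setMethod("clusters", "Clustering", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("epsilon", "Clustering", function(x) x@epsilon)

setMethod("show", "PPINetwork", function(object) {
    cat(sprintf("PPINetwork with %d nodes and %d edges\n",
                length(object@nodes), nrow(object@edges)))
    if (length(object@nodes)) {
        shown <- utils::head(object@nodes, 5L)
        cat("  nodes: ", paste(shown, collapse = ", "),
            if (length(object@nodes) > 5L) ", ..." else "", "\n", sep = "")
    }
    if (length(object@weights)) {
        w <- range(object@weights)
        cat(sprintf("  weights in [%.4g, %.4g]\n", w[1L], w[2L]))
    }
    invisible(NULL)
})

setMethod("show", "ComplexSet", function(object) {
    sz <- lengths(object@complexes)
    cat(sprintf("ComplexSet '%s': %d complexes", object@label, length(sz)))
    if (length(sz))
        cat(sprintf(" (sizes %d-%d, median %g)", min(sz), max(sz),
                    stats::median(sz)))
    cat("\n")
    invisible(NULL)
})

setMethod("show", "Clustering", function(object) {
    sz <- lengths(object@clusters)
    cat(sprintf(
        "Clustering of %d objects into %d clusters (epsilon = %.6g, %d sync steps)\n",
        sum(sz), length(sz), object@epsilon, object@nSyncSteps))
    if (length(sz))
        cat(sprintf("  cluster sizes: %s\n",
                    paste(sort(sz, decreasing = TRUE), collapse = " ")))
    invisible(NULL)
})

setMethod("show", "FAParams", function(object) {
    cat(sprintf(
        "FAParams: %d fireflies x %d iterations (beta0=%g, gamma=%g, alpha=%g)\n",
        object@nFireflies, object@maxiter, object@beta0, object@gamma,
        object@alpha))
    cat(sprintf("  search interval: [%s, %s], seed %d\n",
                format(object@epsMin), format(object@epsMax), object@seed))
    invisible(NULL)
})
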