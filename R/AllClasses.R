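#' @import methods
NULL

#' PPINetwork: an undirected, weighted protein-protein interaction graph
#'
#' Stores an interaction network as an ordered node vector plus one row per
#' unordered edge. Edge endpoints are 1-based indices into `nodes(x)` with
#' the smaller index first; every weight is a strictly positive interaction
#' strength (1 for unweighted data). Self-loops and duplicate pairs are
#' rejected by the validity method; isolated nodes are allowed.
#'
#' @slot nodes character vector of protein identifiers (case-sensitive,
#'   first-appearance order from the source file).
#' @slot edges integer matrix with two columns (`from`, `to`), one row per
#'   unordered edge, `from < to`.
#' @slot weights numeric vector of edge weights, parallel to the rows of
#'   `edges`.
#'
#' @seealso [readEdgeList()], [plantedPartitionNetwork()]
#' @export
setClass("PPINetwork",
    representation(
        nodes = "character",
        edges = "matrix",
        weights = "numeric"
    ),
    prototype(
        nodes = character(),
        edges = matrix(integer(), ncol = 2L,
                       dimnames = list(NULL, c("from", "to"))),
        weights = numeric()
    )
)

setValidity("PPINetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!is.numeric(e) || ncol(e) != 2L)
        return("'edges' must be a two-column integer matrix")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node identifiers must be unique")
    if (nrow(e) != length(object@weights))
        msg <- c(msg, "'weights' must have one entry per edge")
    if (nrow(e) > 0) {
        n <- length(object@nodes)
        if (any(e < 1L) || any(e > n))
            msg <- c(msg, "edge endpoints must index into 'nodes'")
        if (any(e[, 1L] == e[, 2L]))
            msg <- c(msg, "self-loops are not allowed")
        if (any(e[, 1L] > e[, 2L]))
            msg <- c(msg, "edges must be stored with the smaller index first")
        if (anyDuplicated(paste(e[, 1L], e[, 2L])))
            msg <- c(msg, "duplicate edges are not allowed")
        if (any(!is.finite(object@weights)) || any(object@weights <= 0))
            msg <- c(msg, "all edge weights must be finite and > 0")
    }
    if (length(msg)) msg else TRUE
})

#' ComplexSet: a collection of protein complexes or clusters
#'
#' A list of node-identifier sets, used both for reference complex catalogues
#' (which may overlap and may omit network nodes) and for serialized
#' clustering results. Every complex must be non-empty.
#'
#' @slot complexes list of character vectors of member identifiers.
#' @slot label single string naming the set (e.g. `"planted"`,
#'   `"reference"`).
#'
#' @seealso [readComplexes()], [writeClusters()], [precisionRecallF()]
#' @export
setClass("ComplexSet",
    representation(complexes = "list", label = "character"),
    prototype(complexes = list(), label = "complexes")
)

setValidity("ComplexSet", function(object) {
    msg <- character()
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    ok <- vapply(object@complexes,
                 function(x) is.character(x) && length(x) > 0, logical(1))
    if (!all(ok))
        msg <- c(msg, "every complex must be a non-empty character vector")
    if (length(msg)) msg else TRUE
})

#' Clustering: a partition produced by synchronization clustering
#'
#' A hard partition of the embedded objects: every object index belongs to
#' exactly one cluster (singletons allowed — they are the method's outliers).
#' The radius `epsilon` that produced the partition and the number of
#' synchronization steps taken are retained for provenance.
#'
#' @slot clusters list of integer vectors of object indices; pairwise
#'   disjoint, jointly covering `1:n`.
#' @slot epsilon the synchronization neighborhood radius used.
#' @slot nSyncSteps number of coordinate-update sweeps performed before all
#'   objects were absorbed into closures.
#' @slot nodeNames optional character vector mapping object indices back to
#'   protein identifiers (length `n` or empty).
#'
#' @seealso [shcCluster()], [modularityObjective()]
#' @export
setClass("Clustering",
    representation(
        clusters = "list",
        epsilon = "numeric",
        nSyncSteps = "integer",
        nodeNames = "character"
    ),
    prototype(clusters = list(), epsilon = NA_real_, nSyncSteps = 0L,
              nodeNames = character())
)

setValidity("Clustering", function(object) {
    msg <- character()
    idx <- unlist(object@clusters, use.names = FALSE)
    if (length(idx)) {
        if (!is.integer(idx))
            msg <- c(msg, "cluster members must be integer indices")
        else if (!identical(sort(idx), seq_len(length(idx))))
            msg <- c(msg, "clusters must partition 1:n (disjoint cover)")
    }
    if (length(object@nodeNames) &&
        length(object@nodeNames) != length(idx))
        msg <- c(msg, "'nodeNames' must have one name per object")
    if (length(msg)) msg else TRUE
})

#' FAParams: firefly-algorithm settings
#'
#' Parameters of the firefly search over the synchronization radius.
#' Defaults are the settings used throughout the method's evaluation:
#' 6 fireflies, 30 iterations, maximum attractiveness `beta0 = 1`, light
#' absorption `gamma = 1`, step size `alpha = 0.9`. The search interval
#' `[epsMin, epsMax]` may be left `NA` to be derived from the embedding
#' (mean nearest-neighbor distance up to the maximum pairwise distance).
#'
#' @slot nFireflies swarm size (>= 1).
#' @slot beta0 maximum attractiveness at distance zero (> 0).
#' @slot gamma light absorption coefficient (>= 0); larger values localize
#'   the attraction.
#' @slot alpha random step size in `[0, 1]`.
#' @slot maxiter number of swarm iterations (>= 1).
#' @slot epsMin,epsMax bounds of the radius search interval (`NA` = derive
#'   from the data).
#' @slot seed integer seed driving initialization and all random moves.
#'
#' @seealso [faParams()], [optimizeEpsilon()], [fireflySearch()]
#' @export
setClass("FAParams",
    representation(
        nFireflies = "integer",
        beta0 = "numeric",
        gamma = "numeric",
        alpha = "numeric",
        maxiter = "integer",
        epsMin = "numeric",
        epsMax = "numeric",
        seed = "integer"
    ),
    prototype(nFireflies = 6L, beta0 = 1, gamma = 1, alpha = 0.9,
              maxiter = 30L, epsMin = NA_real_, epsMax = NA_real_, seed = 1L)
)

setValidity("FAParams", function(object) {
    msg <- character()
    if (object@nFireflies < 1L) msg <- c(msg, "'nFireflies' must be >= 1")
    if (object@maxiter < 1L) msg <- c(msg, "'maxiter' must be >= 1")
    if (object@beta0 <= 0) msg <- c(msg, "'beta0' must be > 0")
    if (object@gamma < 0) msg <- c(msg, "'gamma' must be >= 0")
    if (object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "'alpha' must lie in [0, 1]")
    if (!is.na(object@epsMin) && !is.na(object@epsMax) &&
        !(object@epsMin > 0 && object@epsMin < object@epsMax))
        msg <- c(msg, "need 0 < epsMin < epsMax")
    if (length(msg)) msg else TRUE
})
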