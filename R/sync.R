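#' Epsilon-neighborhood of an object
#'
#' Indices of all other objects whose Euclidean distance to object `i` is at
#' most `eps` (boundary included). The object itself is not returned,
#' although it always belongs to its own closed neighborhood — the dynamics
#' and the closure test account for that internally.
#'
#' @param coords numeric matrix of object coordinates (one row per object).
#' @param i object index.
#' @param eps neighborhood radius (> 0).
#' @return integer vector of neighbor indices.
#' @export
epsilonNeighborhood <- function(coords, i, eps) {
    stopifnot(is.matrix(coords))
    if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
        stop("'eps' must be a single value > 0")
    d2 <- colSums((t(coords) - coords[i, ])^2)
    out <- which(d2 <= eps^2)
    out[out != i]
}

# Boolean eps-adjacency among the given rows (self excluded).
epsAdjacency <- function(pts, eps) {
    adj <- as.matrix(stats::dist(pts)) <= eps
    diag(adj) <- FALSE
    adj
}

#' Find epsilon-neighborhood closures
#'
#' An epsilon-neighborhood closure is a set of objects each of whose closed
#' eps-neighborhoods (within the active set) equals the set itself — i.e. a
#' connected component of the eps-graph that is also a clique under the
#' radius. Such a set is guaranteed to synchronize fully under the
#' dynamics, so it can be declared a cluster without further simulation.
#' An object with no active neighbor forms a singleton closure (the
#' method's outlier behavior). Objects in components that are not closures
#' appear in none of the returned sets.
#'
#' @param coords numeric matrix of object coordinates.
#' @param eps neighborhood radius (> 0).
#' @param active indices of the objects still in play (default: all).
#' @return list of integer vectors (subsets of `active`), possibly empty.
#' @export
findClosures <- function(coords, eps, active = seq_len(nrow(coords))) {
    if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
        stop("'eps' must be a single value > 0")
    if (!length(active))
        return(list())
    pts <- coords[active, , drop = FALSE]
    adj <- epsAdjacency(pts, eps)
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        adj, mode = "undirected"))
    out <- list()
    for (cid in seq_len(comp$no)) {
        member <- which(comp$membership == cid)
        # closure <=> every member sees all the others within eps
        if (all(rowSums(adj[member, member, drop = FALSE]) ==
                length(member) - 1L))
            out[[length(out) + 1L]] <- active[member]
    }
    out
}

#' One synchronization sweep
#'
#' Synchronous (Jacobi-style) application of the Kuramoto-like coordinate
#' update to every active object `x`:
#' \deqn{x_d(t+1) = x_d(t) + \frac{1}{|N_\epsilon(x)|}
#'   \sum_{y \in N_\epsilon(x)} \sin(y_d(t) - x_d(t))}
#' per dimension `d`, all updates computed from the time-`t` snapshot.
#' `N_eps(x)` is the closed neighborhood of the literal radius definition
#' (it contains `x` itself, whose term contributes `sin(0) = 0` to the sum
#' but does count in the normalization — this cancellation is what makes
#' closures contract onto their centroid instead of overshooting).
#' Objects outside `active`, and active objects with no active neighbor,
#' are left untouched.
#'
#' @inheritParams findClosures
#' @return the updated coordinate matrix (same shape as `coords`).
#' @export
syncStep <- function(coords, eps, active = seq_len(nrow(coords))) {
    if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
        stop("'eps' must be a single value > 0")
    if (!length(active))
        return(coords)
    pts <- coords[active, , drop = FALSE]
    adj <- epsAdjacency(pts, eps)
    out <- coords
    for (a in seq_along(active)) {
        nb <- which(adj[a, ])
        if (!length(nb))
            next
        delta <- sin(sweep(pts[nb, , drop = FALSE], 2L, pts[a, ], "-"))
        out[active[a], ] <- pts[a, ] + colSums(delta) / (length(nb) + 1L)
    }
    out
}

#' Synchronization-based hierarchical clustering at a fixed radius
#'
#' The SHC inner loop: (a) detect epsilon-neighborhood closures among the
#' unmarked objects and freeze each as a finished cluster; (b) if objects
#' remain, run one synchronization sweep over them (marked objects neither
#' move nor attract) and repeat. Because closures contract onto their
#' centroids, typical configurations resolve in a handful of sweeps; if
#' `maxSteps` is exhausted the remaining eps-graph connected components are
#' emitted as clusters with a warning.
#'
#' @param X embedding matrix ([embedNetwork()]); row names become
#'   `nodeNames` of the result.
#' @param eps synchronization neighborhood radius (> 0).
#' @param maxSteps cap on synchronization sweeps (default 100).
#' @return a [Clustering-class]: a full partition of the rows of `X`,
#'   clusters ordered by smallest member index.
#'
#' @examples
#' X <- rbind(c(1, 0, 0), c(1, 0.01, 0), c(-1, 0, 0), c(-1, 0.01, 0))
#' rownames(X) <- letters[1:4]
#' shcCluster(X, eps = 0.5)   # two 2-object clusters, zero sweeps
#' @export
shcCluster <- function(X, eps, maxSteps = 100L) {
    stopifnot(is.matrix(X))
    if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
        stop("'eps' must be a single value > 0")
    if (maxSteps < 1L)
        stop("'maxSteps' must be >= 1")
    n <- nrow(X)
    coords <- X
    active <- seq_len(n)
    found <- list()
    steps <- 0L
    repeat {
        cls <- findClosures(coords, eps, active)
        if (length(cls)) {
            found <- c(found, cls)
            active <- setdiff(active, unlist(cls, use.names = FALSE))
        }
        if (!length(active))
            break
        if (steps >= maxSteps) {
            warning(sprintf(
                "%d object(s) did not form closures within %d sweeps; %s",
                length(active), maxSteps,
                "clustering them as eps-graph components"))
            adj <- epsAdjacency(coords[active, , drop = FALSE], eps)
            comp <- igraph::components(
                igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
            found <- c(found, lapply(seq_len(comp$no), function(cid)
                active[comp$membership == cid]))
            break
        }
        coords <- syncStep(coords, eps, active)
        steps <- steps + 1L
    }
    found <- lapply(found, function(ix) sort(as.integer(ix)))
    found <- found[order(vapply(found, `[`, 1L, 1L))]
    new("Clustering", clusters = found, epsilon = eps, nSyncSteps = steps,
        nodeNames = if (is.null(rownames(X))) character() else rownames(X))
}

# Mean distance to the j-th nearest neighbor, for j in `ks`.
meanKnnDistance <- function(X, ks) {
    D <- as.matrix(stats::dist(X))
    sorted <- apply(D, 1L, sort)           # column per object, self first
    vapply(ks, function(j) mean(sorted[j + 1L, ]), 0)
}

#' Hierarchical grid search for the synchronization radius
#'
#' The baseline radius optimizer: start at `eps0`, the mean distance of
#' every object to its 3rd nearest neighbor, and scan upward in increments
#' of `deltaEps`, the mean 4th-nearest-neighbor distance minus `eps0`.
#' Clustering is run at each level and scored with `objective`; the scan
#' stops after `maxLevels` levels or as soon as one cluster swallows all
#' objects. Ties favor the smaller radius. Degenerate geometries where the
#' increment is not positive fall back to an even subdivision of
#' `(max pairwise distance - eps0)` with a warning.
#'
#' @param X embedding matrix with at least 5 rows.
#' @param objective function mapping a [Clustering-class] to a real score
#'   (larger is better), e.g. a closure over [modularityObjective()].
#' @param maxLevels maximum number of radius levels to evaluate.
#' @param maxSteps per-clustering sweep cap, passed to [shcCluster()].
#' @return list with elements `epsilon`, `clustering`, `value`, and `path`
#'   (data.frame of every `epsilon`/`value` pair evaluated).
#' @export
hierarchicalSearch <- function(X, objective, maxLevels = 20L,
                               maxSteps = 100L) {
    stopifnot(is.matrix(X), is.function(objective))
    if (nrow(X) < 5L)
        stop("hierarchical search needs at least 5 objects")
    if (maxLevels < 1L)
        stop("'maxLevels' must be >= 1")
    knn <- meanKnnDistance(X, c(3L, 4L))
    eps0 <- knn[1L]
    deltaEps <- knn[2L] - knn[1L]
    maxDist <- max(stats::dist(X))
    if (deltaEps <= 0) {
        warning("non-positive radius increment; falling back to an even grid")
        deltaEps <- (maxDist - eps0) / maxLevels
    }
    if (eps0 <= 0)
        eps0 <- deltaEps
    best <- NULL
    evals <- data.frame(epsilon = numeric(), value = numeric())
    for (lvl in seq_len(maxLevels)) {
        eps <- eps0 + (lvl - 1L) * deltaEps
        if (eps <= 0)
            next
        cl <- shcCluster(X, eps, maxSteps)
        val <- objective(cl)
        evals <- rbind(evals, data.frame(epsilon = eps, value = val))
        if (is.null(best) || val > best$value)   # strict: ties keep small eps
            best <- list(epsilon = eps, clustering = cl, value = val)
        if (length(cl@clusters) == 1L)
            break
    }
    c(best, list(path = evals))
}
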