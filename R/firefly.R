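#' Construct firefly-algorithm parameters
#'
#' @param nFireflies swarm size (default 6).
#' @param beta0 maximum attractiveness (default 1).
#' @param gamma light absorption coefficient (default 1).
#' @param alpha random step size in `[0, 1]` (default 0.9).
#' @param maxiter swarm iterations (default 30).
#' @param epsMin,epsMax radius search interval; leave `NA` to derive from
#'   the embedding (mean nearest-neighbor distance, max pairwise distance).
#' @param seed integer seed for initialization and the random moves.
#' @return a validated [FAParams-class].
#' @export
faParams <- function(nFireflies = 6L, beta0 = 1, gamma = 1, alpha = 0.9,
                     maxiter = 30L, epsMin = NA_real_, epsMax = NA_real_,
                     seed = 1L) {
    new("FAParams", nFireflies = as.integer(nFireflies), beta0 = beta0,
        gamma = gamma, alpha = alpha, maxiter = as.integer(maxiter),
        epsMin = as.numeric(epsMin), epsMax = as.numeric(epsMax),
        seed = as.integer(seed))
}

#' Firefly light intensity at distance r
#'
#' `I = I0 * exp(-gamma * r)`: the brightness of a firefly as perceived
#' from distance `r`, `I0` being the objective value at its position.
#'
#' @param I0 intensity at the source (`r = 0`).
#' @param gamma light absorption coefficient (>= 0).
#' @param r distance (>= 0).
#' @export
lightIntensity <- function(I0, gamma, r) {
    stopifnot(all(r >= 0))
    I0 * exp(-gamma * r)
}

#' Firefly attractiveness at distance r
#'
#' `beta = beta0 * exp(-gamma * r^2)`: the pull a brighter firefly exerts
#' on a dimmer one, decaying with the squared distance.
#'
#' @param beta0 maximum attractiveness (`r = 0`).
#' @inheritParams lightIntensity
#' @export
attractiveness <- function(beta0, gamma, r) {
    stopifnot(all(r >= 0))
    beta0 * exp(-gamma * r^2)
}

#' One firefly position update
#'
#' `x_i' = x_i + beta * (x_j - x_i) + alpha * (u - 1/2)` — deterministic
#' attraction toward the brighter firefly `x_j` plus a centered random
#' perturbation; `u` is supplied by the caller (uniform on `[0, 1]`).
#'
#' @param xi,xj positions of the moving and the brighter firefly.
#' @param beta attractiveness, from [attractiveness()].
#' @param alpha step size in `[0, 1]`.
#' @param u uniform random draw in `[0, 1]`.
#' @export
moveFirefly <- function(xi, xj, beta, alpha, u) {
    xi + beta * (xj - xi) + alpha * (u - 0.5)
}

#' Firefly search over a scalar objective
#'
#' The core one-dimensional firefly algorithm, independent of clustering:
#' positions are initialized uniformly at random in
#' `[epsMin, epsMax]`; each iteration evaluates every firefly's intensity
#' `I0 = f(position)` (memoized on the position rounded to 12 decimals),
#' then sweeps the swarm in index order — every firefly `i` other than the
#' currently brightest moves toward each firefly `j` whose
#' iteration-start intensity exceeds its own, with attractiveness
#' `beta0 * exp(-gamma * |x_i - x_j|^2)` and a fresh uniform draw per move.
#' Positions are clipped to the interval. A non-finite objective value is
#' treated as `-Inf` with a warning.
#'
#' @param f objective function of a single numeric argument (maximized).
#' @param params a [FAParams-class]; `epsMin`/`epsMax` must be set.
#' @return list with `epsilon` (best position ever evaluated), `value`,
#'   `trace` (data.frame `iteration`, `bestEpsilon`, `bestValue`; the
#'   running best is non-decreasing), and `positions` (final swarm).
#' @export
fireflySearch <- function(f, params = faParams()) {
    stopifnot(is.function(f), is(params, "FAParams"))
    validObject(params)
    if (is.na(params@epsMin) || is.na(params@epsMax))
        stop("'epsMin' and 'epsMax' must be set for fireflySearch()")
    nF <- params@nFireflies
    memo <- new.env(parent = emptyenv())
    evalAt <- function(x) {
        key <- sprintf("%.12f", round(x, 12L))
        if (exists(key, envir = memo, inherits = FALSE))
            return(memo[[key]])
        v <- f(x)
        if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
            warning(sprintf(
                "objective returned a non-finite value at %g; using -Inf", x))
            v <- -Inf
        }
        memo[[key]] <- v
        v
    }
    withSeed(params@seed, {
        pos <- stats::runif(nF, params@epsMin, params@epsMax)
        bestEps <- NA_real_
        bestVal <- -Inf
        trace <- data.frame(iteration = seq_len(params@maxiter),
                            bestEpsilon = NA_real_, bestValue = NA_real_)
        for (iter in seq_len(params@maxiter)) {
            I <- vapply(pos, evalAt, 0)
            top <- which.max(I)
            if (I[top] > bestVal) {
                bestVal <- I[top]
                bestEps <- pos[top]
            }
            trace$bestEpsilon[iter] <- bestEps
            trace$bestValue[iter] <- bestVal
            for (i in seq_len(nF)) {
                if (i == top)            # the brightest firefly holds still
                    next
                for (j in seq_len(nF)) {
                    if (I[j] <= I[i])
                        next
                    beta <- attractiveness(params@beta0, params@gamma,
                                           abs(pos[i] - pos[j]))
                    pos[i] <- moveFirefly(pos[i], pos[j], beta,
                                          params@alpha, stats::runif(1L))
                    pos[i] <- min(max(pos[i], params@epsMin), params@epsMax)
                }
            }
        }
        list(epsilon = bestEps, value = bestVal, trace = trace,
             positions = pos)
    })
}

#' Optimize the synchronization radius with the firefly algorithm
#'
#' Wires [fireflySearch()] into the clustering pipeline: each firefly's
#' intensity is the modularity objective of the SHC clustering at its
#' radius, `objective(shcCluster(X, eps))`. Search bounds default to the
#' mean nearest-neighbor distance (below which everything is a singleton)
#' and the maximum pairwise distance (above which everything is one
#' cluster).
#'
#' @param X embedding matrix from [embedNetwork()].
#' @param net the [PPINetwork-class] the embedding came from (used by the
#'   default objective).
#' @param params a [FAParams-class].
#' @param rho modularity mixing exponent for the default objective
#'   (default 0.8).
#' @param objective optional replacement scoring function
#'   (`Clustering -> numeric`); when supplied, `net` and `rho` are unused.
#' @param maxSteps per-clustering sweep cap for [shcCluster()].
#' @return list with `epsilon`, `clustering` (a [Clustering-class]),
#'   `value`, `trace`, and `positions`.
#'
#' @examples
#' sim <- plantedPartitionNetwork(rep(6, 2), pIn = 1, pOut = 0, seed = 1)
#' X <- embedNetwork(sim$network)
#' fit <- optimizeEpsilon(X, sim$network, faParams(seed = 1))
#' fit$clustering
#' @export
optimizeEpsilon <- function(X, net, params = faParams(), rho = 0.8,
                            objective = NULL, maxSteps = 100L) {
    stopifnot(is.matrix(X))
    if (is.null(objective)) {
        stopifnot(is(net, "PPINetwork"))
        objective <- function(cl) modularityObjective(cl, net, rho)
    }
    p <- params
    if (is.na(p@epsMin) || is.na(p@epsMax)) {
        d <- stats::dist(X)
        if (is.na(p@epsMin))
            p@epsMin <- max(meanKnnDistance(X, 1L), .Machine$double.eps)
        if (is.na(p@epsMax))
            p@epsMax <- max(d)
        validObject(p)
    }
    res <- fireflySearch(function(eps) objective(shcCluster(X, eps, maxSteps)),
                         p)
    res$clustering <- shcCluster(X, res$epsilon, maxSteps)
    res[c("epsilon", "clustering", "value", "trace", "positions")]
}
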