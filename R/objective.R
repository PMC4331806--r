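#' Weighted modularity objective of a clustering
#'
#' Scores a partition of the network by summing, over clusters `H`, the
#' product of an unweighted and a weighted cohesion factor:
#'
#' \deqn{fval = \sum_H \left(\frac{2 m_H}{2 m_H + n_H}\right)^{\rho}
#'   \left(\frac{w_{in}(H)}{w_{in}(H) + w_{out}(H)}\right)^{1-\rho}}
#'
#' `m_H` counts internal edges and `n_H` boundary edges (edges joining `H`
#' to the rest of the network), so the first factor is the cluster's
#' in-degree `2 m_H` over its total degree. The second factor is the same
#' ratio with edge weights (`w_in` doubles internal weights; the
#' denominator is the total weighted degree of the cluster's nodes). The
#' exponent `rho` shifts emphasis between the topological and the weighted
#' term: `rho = 1` keeps only the former, `rho = 0` only the latter. A
#' cluster with no incident edges at all (an isolated singleton)
#' contributes 0, so each cluster's contribution lies in `[0, 1]` and
#' `fval` is at most the number of clusters. Larger is better.
#'
#' @param clustering a [Clustering-class] partitioning all network nodes
#'   (indices follow the network's node order).
#' @param net the [PPINetwork-class].
#' @param rho mixing exponent in `[0, 1]` (default 0.8).
#' @param perCluster if `TRUE`, also return each cluster's contribution.
#' @return the objective value, or (with `perCluster = TRUE`) a list
#'   `list(fval, contributions)`.
#'
#' @examples
#' sim <- plantedPartitionNetwork(c(3, 3), pIn = 1, pOut = 0, seed = 1)
#' cl <- new("Clustering", clusters = list(1:3, 4:6))
#' modularityObjective(cl, sim$network)  # two clean triangles: 1 + 1
#' @export
modularityObjective <- function(clustering, net, rho = 0.8,
                                perCluster = FALSE) {
    stopifnot(is(clustering, "Clustering"), is(net, "PPINetwork"))
    if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
        stop("'rho' must be a single value in [0, 1]")
    n <- length(net@nodes)
    idx <- unlist(clustering@clusters, use.names = FALSE)
    if (!identical(sort(idx), seq_len(n)))
        stop("clustering must partition the network's nodes")
    if (length(clustering@nodeNames) &&
        !identical(clustering@nodeNames, net@nodes))
        stop("clustering node names do not match the network")

    nc <- length(clustering@clusters)
    memb <- integer(n)
    memb[idx] <- rep.int(seq_len(nc), lengths(clustering@clusters))

    e <- net@edges
    w <- net@weights
    ci <- memb[e[, 1L]]
    cj <- memb[e[, 2L]]
    internal <- ci == cj

    mH <- tabulate(ci[internal], nc)
    nH <- tabulate(c(ci[!internal], cj[!internal]), nc)
    wIn <- 2 * as.vector(tapply2(w[internal], ci[internal], nc))
    wOut <- as.vector(tapply2(c(w[!internal], w[!internal]),
                              c(ci[!internal], cj[!internal]), nc))

    degTot <- 2 * mH + nH
    wTot <- wIn + wOut
    f1 <- ifelse(degTot > 0, (2 * mH / pmax(degTot, 1))^rho, 0)
    f2 <- ifelse(wTot > 0, (wIn / pmax(wTot, 1e-300))^(1 - rho), 0)
    contrib <- ifelse(degTot > 0 & wTot > 0, f1 * f2, 0)
    if (perCluster)
        list(fval = sum(contrib), contributions = contrib)
    else
        sum(contrib)
}

# Grouped sums with fixed group count (tabulate for weights).
tapply2 <- function(values, groups, nGroups) {
    out <- numeric(nGroups)
    if (length(values)) {
        s <- rowsum(values, groups)
        out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
}
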