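# Build a network from edge-list lines through the public reader.
mkNet <- function(..., defaultWeight = 1) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(c(...), tf)
    readEdgeList(tf, defaultWeight)
}

# Random Erdos-Renyi-ish network via the planted generator (one module).
randomNet <- function(n, p = 0.5, weighted = TRUE, seed = 1) {
    plantedPartitionNetwork(
        n, pIn = p, pOut = 0,
        weightLaw = if (weighted) "uniform" else "constant",
        seed = seed)$network
}

# Two tight, well-separated 5-point blobs on orthogonal axes.
twoBlobX <- function() {
    X <- rbind(
        t(vapply(0:4, function(k) c(1, 0.02 * k, 0), numeric(3))),
        t(vapply(0:4, function(k) c(0, 1, 0.02 * k), numeric(3))))
    rownames(X) <- sprintf("m%d_%d", rep(1:2, each = 5), rep(1:5, 2))
    X
}

# Exhaustive-subset oracle for the epsilon-neighborhood-closure definition:
# S is a closure iff for every x in S the closed eps-neighborhood of x
# within the active set equals S.
bruteClosures <- function(coords, eps, active = seq_len(nrow(coords))) {
    m <- length(active)
    nb <- lapply(seq_len(m), function(k) {
        d <- sqrt(colSums(
            (t(coords[active, , drop = FALSE]) - coords[active[k], ])^2))
        active[d <= eps][active[d <= eps] != active[k]]
    })
    res <- list()
    for (mask in seq_len(2^m - 1L)) {
        inS <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
        S <- active[inS]
        ok <- all(vapply(which(inS), function(k)
            setequal(c(nb[[k]], active[k]), S), logical(1)))
        if (ok)
            res[[length(res) + 1L]] <- sort(S)
    }
    res
}

# Edge-by-edge recount of the modularity objective, independent of the
# vectorized implementation.
bruteModularity <- function(clusterList, net, rho) {
    e <- edges(net)
    w <- edgeWeights(net)
    total <- 0
    for (H in clusterList) {
        mH <- 0L; nH <- 0L; wIn <- 0; wOut <- 0
        for (r in seq_len(nrow(e))) {
            aIn <- e[r, 1L] %in% H
            bIn <- e[r, 2L] %in% H
            if (aIn && bIn) {
                mH <- mH + 1L
                wIn <- wIn + 2 * w[r]
            } else if (aIn || bIn) {
                nH <- nH + 1L
                wOut <- wOut + w[r]
            }
        }
        if (2L * mH + nH == 0L || wIn + wOut == 0)
            next
        total <- total +
            (2 * mH / (2 * mH + nH))^rho * (wIn / (wIn + wOut))^(1 - rho)
    }
    total
}

# Double-loop recount of the edge-similarity formula from neighbor sets.
bruteSimilarity <- function(net, eta) {
    n <- length(nodes(net))
    e <- edges(net)
    w <- edgeWeights(net)
    W <- matrix(0, n, n)
    for (r in seq_len(nrow(e))) {
        W[e[r, 1L], e[r, 2L]] <- w[r]
        W[e[r, 2L], e[r, 1L]] <- w[r]
    }
    A <- matrix(0, n, n)
    for (r in seq_len(nrow(e))) {
        i <- e[r, 1L]; j <- e[r, 2L]
        Ni <- which(W[i, ] > 0)
        Nj <- which(W[j, ] > 0)
        Iij <- intersect(Ni, Nj)
        t1 <- eta * (length(Iij) + 1) / min(length(Ni), length(Nj))
        t2 <- (1 - eta) * (sum(W[i, Iij]) * sum(W[j, Iij])) /
            (sum(W[i, Ni]) * sum(W[j, Nj]))
        A[i, j] <- A[j, i] <- t1 + t2
    }
    A
}

# Partition clusters as an order-independent canonical form.
canonClusters <- function(clusterList) {
    if (!length(clusterList))
        return(list())
    cl <- lapply(clusterList, function(x) as.integer(sort(x)))
    cl[order(vapply(cl, `[`, 1L, 1L))]
}
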