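#' Edge-similarity matrix of a PPI network
#'
#' Builds the symmetric similarity matrix `A` whose nonzero entries live on
#' the network's edges. For an edge (i, j) the similarity mixes two edge
#' aggregation coefficients:
#'
#' \deqn{A_{ij} = \eta \frac{|N_i \cap N_j| + 1}{\min(|N_i|, |N_j|)} +
#'   (1-\eta) \frac{\sum_{k \in I_{ij}} w(i,k) \cdot
#'                  \sum_{k \in I_{ij}} w(j,k)}
#'                 {\sum_{s \in N_i} w(i,s) \cdot
#'                  \sum_{t \in N_j} w(j,t)}}
#'
#' where `N_i` is the neighbor set of node i and `I_ij = N_i ∩ N_j` the
#' common neighbors. The first term is the degree-based edge clustering
#' coefficient (the `+1` counts the edge itself and may push the term above
#' one for heavily shared neighborhoods; it is deliberately not clamped),
#' the second its weighted analogue; `eta` balances the two. Non-edges and
#' the diagonal are zero.
#'
#' @param net a [PPINetwork-class] with at least 2 nodes.
#' @param eta mixing weight in `[0, 1]` between the unweighted and weighted
#'   terms (default 0.5).
#' @return a dense symmetric `n x n` matrix with node dimnames.
#'
#' @examples
#' tf <- tempfile(); writeLines(c("a\tb", "b\tc", "a\tc"), tf)
#' A <- edgeSimilarity(readEdgeList(tf), eta = 0.5)
#' A["a", "b"]  # 0.5 * (1+1)/2 + 0.5 * (1*1)/(2*2) = 0.625
#' @export
edgeSimilarity <- function(net, eta = 0.5) {
    stopifnot(is(net, "PPINetwork"))
    if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta > 1)
        stop("'eta' must be a single value in [0, 1]")
    n <- length(net@nodes)
    if (n < 2L)
        stop("network must have at least 2 nodes")
    W <- weightMatrix(net)
    B <- (W > 0) + 0
    deg <- rowSums(B)
    strength <- rowSums(W)
    common <- B %*% B          # common[i,j] = |N_i ∩ N_j|
    WB <- W %*% B              # WB[i,j] = sum_{k in I_ij} w(i,k)

    A <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
    if (nrow(net@edges)) {
        i <- net@edges[, 1L]
        j <- net@edges[, 2L]
        ij <- cbind(i, j)
        ji <- cbind(j, i)
        t1 <- eta * (common[ij] + 1) / pmin(deg[i], deg[j])
        t2 <- (1 - eta) * (WB[ij] * WB[ji]) / (strength[i] * strength[j])
        A[ij] <- t1 + t2
        A[ji] <- t1 + t2
    }
    A
}

#' Symmetrically degree-normalized similarity matrix
#'
#' Given a similarity matrix `A` with row sums `D_ii`, returns
#' `L_ij = A_ij / sqrt(D_ii * D_jj)`, with `L_ij = 0` whenever either row
#' sum is zero (isolated objects keep an all-zero row and column). `L` is a
#' normalized adjacency — its cluster structure lives at the top of the
#' spectrum, and all eigenvalues lie in `[-1, 1]`.
#'
#' @param A symmetric nonnegative matrix (as from [edgeSimilarity()]).
#' @return a symmetric matrix of the same shape.
#' @export
normalizedMatrix <- function(A) {
    stopifnot(is.matrix(A), nrow(A) == ncol(A))
    D <- rowSums(A)
    s <- sqrt(D)
    L <- A / outer(s, s)
    L[!is.finite(L)] <- 0      # rows/cols with D == 0
    L
}

#' Spectral embedding into k dimensions
#'
#' Rows of the returned matrix are the coordinates on which the
#' synchronization dynamics run: the eigenvectors of the k algebraically
#' largest eigenvalues of `L` (decreasing order), sign-fixed so each
#' eigenvector's first nonzero entry is positive, then row-normalized to
#' unit Euclidean norm. All-zero rows (isolated objects) stay zero. The
#' default `k = 3` gives the three-dimensional oscillator coordinates used
#' throughout the pipeline.
#'
#' @param L symmetric matrix, typically from [normalizedMatrix()].
#' @param k number of embedding dimensions (`nrow(L) >= k`).
#' @param rowNormalize if `FALSE`, return the raw (orthonormal, sign-fixed)
#'   eigenvectors without row scaling.
#' @return an `n x k` matrix; row names carried over from `L`.
#' @export
spectralEmbed <- function(L, k = 3L, rowNormalize = TRUE) {
    stopifnot(is.matrix(L), nrow(L) == ncol(L))
    n <- nrow(L)
    if (n < k)
        stop(sprintf("need at least k = %d objects, got %d", k, n))
    eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
    V <- eig$vectors[, seq_len(k), drop = FALSE]
    for (c in seq_len(k)) {
        nz <- which(abs(V[, c]) > 1e-12)
        if (length(nz) && V[nz[1L], c] < 0)
            V[, c] <- -V[, c]
    }
    rownames(V) <- rownames(L)
    colnames(V) <- paste0("x", seq_len(k))
    if (!rowNormalize)
        return(V)
    nrm <- sqrt(rowSums(V^2))
    V / ifelse(nrm > 0, nrm, 1)
}

#' Embed a PPI network end to end
#'
#' Convenience composition of [edgeSimilarity()], [normalizedMatrix()] and
#' [spectralEmbed()]: the preprocessing stage of the pipeline.
#'
#' @inheritParams edgeSimilarity
#' @inheritParams spectralEmbed
#' @return an `n x k` embedding matrix with protein identifiers as row
#'   names.
#' @export
embedNetwork <- function(net, eta = 0.5, k = 3L) {
    spectralEmbed(normalizedMatrix(edgeSimilarity(net, eta)), k)
}

#' Write an embedding as TSV
#'
#' `node_id<TAB>x1<TAB>x2<TAB>x3`, full double precision.
#'
#' @param X embedding matrix with row names.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeEmbedding <- function(X, path) {
    stopifnot(is.matrix(X), !is.null(rownames(X)))
    rows <- apply(X, 1L, function(v)
        paste(formatC(v, format = "g", digits = 17), collapse = "\t"))
    writeLines(paste(rownames(X), rows, sep = "\t"), path)
    invisible(path)
}
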