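# Run expr under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Symmetric dense weight matrix of a network; zero diagonal.
weightMatrix <- function(net) {
    n <- length(net@nodes)
    W <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
    if (nrow(net@edges)) {
        W[net@edges] <- net@weights
        W[net@edges[, c(2L, 1L), drop = FALSE]] <- net@weights
    }
    W
}

# Construct a PPINetwork from parallel endpoint-index vectors.
newPPINetwork <- function(nodes, from, to, weights) {
    lo <- pmin(from, to)
    hi <- pmax(from, to)
    o <- order(lo, hi)
    e <- cbind(from = as.integer(lo[o]), to = as.integer(hi[o]))
    new("PPINetwork", nodes = nodes, edges = e,
        weights = as.numeric(weights[o]))
}
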