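#' Simulate a planted-partition PPI network with ground-truth modules
#'
#' Stochastic-block-model generator used throughout the test bench: nodes
#' are split into modules of the given sizes, every intra-module pair
#' becomes an edge independently with probability `pIn` and every
#' inter-module pair with probability `pOut`. This emulates exactly the
#' structure the clustering method assumes — dense complexes with sparse
#' boundaries — without attempting the degree heterogeneity of real
#' interactome screens. Node identifiers are `m<module>_<index>` so
#' failures stay human-readable. Fully reproducible from `seed`; the
#' caller's RNG stream is left untouched.
#'
#' @param moduleSizes integer vector, one entry (>= 1) per planted module;
#'   total >= 2.
#' @param pIn intra-module edge probability in `[0, 1]`.
#' @param pOut inter-module edge probability in `[0, 1]`; a warning is
#'   emitted if `pIn <= pOut` (no planted structure).
#' @param weightLaw `"constant"` (all weights 1) or `"uniform"` (weights
#'   uniform on `wRange`).
#' @param wRange lower/upper weight bounds for `weightLaw = "uniform"`.
#' @param seed integer seed.
#' @return list with `network` (a [PPINetwork-class]) and `complexes` (a
#'   [ComplexSet-class] of the planted modules, label `"planted"`).
#'
#' @examples
#' sim <- plantedPartitionNetwork(rep(8, 3), pIn = 0.9, pOut = 0.02, seed = 1)
#' sim$network
#' sim$complexes
#' @export
plantedPartitionNetwork <- function(moduleSizes, pIn, pOut,
                                    weightLaw = c("constant", "uniform"),
                                    wRange = c(0.5, 1.5), seed = 1L) {
    weightLaw <- match.arg(weightLaw)
    moduleSizes <- as.integer(moduleSizes)
    if (any(moduleSizes < 1L))
        stop("every module size must be >= 1")
    n <- sum(moduleSizes)
    if (n < 2L)
        stop("need at least 2 nodes in total")
    stopifnot(pIn >= 0, pIn <= 1, pOut >= 0, pOut <= 1)
    if (pIn <= pOut)
        warning("pIn <= pOut: the planted structure is not identifiable")

    module <- rep.int(seq_along(moduleSizes), moduleSizes)
    within <- sequence(moduleSizes)
    ids <- sprintf("m%d_%d", module, within)

    # all unordered pairs in fixed (i, j > i) order
    i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    p <- ifelse(module[i] == module[j], pIn, pOut)

    withSeed(seed, {
        keep <- stats::runif(length(p)) < p
        w <- if (weightLaw == "constant")
            rep(1, sum(keep))
        else
            stats::runif(sum(keep), wRange[1L], wRange[2L])
        net <- newPPINetwork(ids, i[keep], j[keep], w)
        cs <- new("ComplexSet",
                  complexes = split(ids, module),
                  label = "planted")
        list(network = net, complexes = cs)
    })
}
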