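#' Run the full clustering pipeline on an edge-list file
#'
#' End-to-end driver: read the network, build the 3-D spectral embedding,
#' optimize the synchronization radius (firefly algorithm by default, or
#' the hierarchical grid search), and write the artifacts to `outDir`:
#' `clusters.tsv` (the partition, [writeClusters()] format), `trace.tsv`
#' (per-iteration best radius/objective for the firefly optimizer, or the
#' evaluated grid for the hierarchical search), and `manifest.txt` (every
#' parameter plus the seed and package version — sufficient to reproduce
#' the run). Identical inputs and seeds produce byte-identical artifacts.
#'
#' @param edges path to the edge-list file ([readEdgeList()] format), or a
#'   [PPINetwork-class] directly.
#' @param outDir output directory (created if missing).
#' @param eta similarity mixing weight (default 0.5).
#' @param rho modularity mixing exponent (default 0.8).
#' @param optimizer `"fa"` (firefly, the default) or `"grid"`
#'   (hierarchical search).
#' @param params [FAParams-class] for the firefly optimizer; its `seed`
#'   is overridden by `seed`.
#' @param maxLevels levels for the hierarchical search.
#' @param seed integer seed (drives the firefly optimizer; the rest of the
#'   pipeline is deterministic).
#' @param defaultWeight weight for two-column edge lines.
#' @return invisibly, a list with `clustering`, `epsilon`, `value`,
#'   `trace`, and the artifact paths.
#' @export
runCluster <- function(edges, outDir, eta = 0.5, rho = 0.8,
                       optimizer = c("fa", "grid"), params = faParams(),
                       maxLevels = 20L, seed = 1L, defaultWeight = 1) {
    optimizer <- match.arg(optimizer)
    net <- if (is(edges, "PPINetwork")) edges
           else readEdgeList(edges, defaultWeight)
    X <- embedNetwork(net, eta)
    if (optimizer == "fa") {
        params@seed <- as.integer(seed)
        fit <- optimizeEpsilon(X, net, params, rho)
        trace <- fit$trace
    } else {
        fit <- hierarchicalSearch(
            X, function(cl) modularityObjective(cl, net, rho), maxLevels)
        trace <- fit$path
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    clustersPath <- file.path(outDir, "clusters.tsv")
    tracePath <- file.path(outDir, "trace.tsv")
    manifestPath <- file.path(outDir, "manifest.txt")
    writeClusters(fit$clustering, clustersPath)
    utils::write.table(
        format(trace, digits = 17, trim = TRUE, scientific = FALSE),
        tracePath, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(
        sprintf("package\tISHC %s", as.character(utils::packageVersion("ISHC"))),
        sprintf("optimizer\t%s", optimizer),
        sprintf("eta\t%.17g", eta),
        sprintf("rho\t%.17g", rho),
        sprintf("seed\t%d", as.integer(seed)),
        sprintf("nFireflies\t%d", params@nFireflies),
        sprintf("beta0\t%.17g", params@beta0),
        sprintf("gamma\t%.17g", params@gamma),
        sprintf("alpha\t%.17g", params@alpha),
        sprintf("maxiter\t%d", params@maxiter),
        sprintf("maxLevels\t%d", as.integer(maxLevels)),
        sprintf("epsilon\t%.17g", fit$epsilon),
        sprintf("objective\t%.17g", fit$value)
    ), manifestPath)
    invisible(list(clustering = fit$clustering, epsilon = fit$epsilon,
                   value = fit$value, trace = trace,
                   paths = c(clusters = clustersPath, trace = tracePath,
                             manifest = manifestPath)))
}

#' Evaluate predicted clusters against reference complexes
#'
#' Computes precision, recall and f-measure ([precisionRecallF()]) and,
#' when the network is supplied and the prediction covers it, the
#' modularity objective. Optionally writes a two-column
#' `metric<TAB>value` TSV.
#'
#' @param pred predicted clusters: path to a cluster file, a
#'   [ComplexSet-class], or a [Clustering-class] with node names.
#' @param ref reference complexes: path or [ComplexSet-class].
#' @param net optional [PPINetwork-class] (or edge-list path) for the
#'   modularity objective.
#' @param rho modularity mixing exponent.
#' @param out optional output TSV path.
#' @return named numeric vector of metrics.
#' @export
evaluateClusters <- function(pred, ref, net = NULL, rho = 0.8, out = NULL) {
    if (is.character(pred)) pred <- readComplexes(pred, label = "predicted")
    if (is.character(ref)) ref <- readComplexes(ref)
    if (is.character(net)) net <- readEdgeList(net)
    prf <- precisionRecallF(pred, ref)
    metrics <- c(precision = prf$precision, recall = prf$recall,
                 f_measure = prf$fMeasure)
    if (!is.null(net)) {
        predSet <- if (is(pred, "Clustering")) asComplexSet(pred) else pred
        memb <- lapply(predSet@complexes, function(m) match(m, net@nodes))
        covered <- sort(unlist(memb, use.names = FALSE))
        if (!anyNA(covered) && identical(covered,
                                         seq_along(net@nodes))) {
            cl <- new("Clustering",
                      clusters = lapply(memb, as.integer),
                      nodeNames = net@nodes)
            metrics <- c(metrics,
                         fval = modularityObjective(cl, net, rho))
        }
    }
    if (!is.null(out))
        writeLines(sprintf("%s\t%.6f", names(metrics), metrics), out)
    metrics
}
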