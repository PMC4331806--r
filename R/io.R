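#' Read a PPI network from a tab-separated edge list
#'
#' Parses a two- or three-column edge list (`nodeA nodeB [weight]`,
#' whitespace- or tab-separated). Lines starting with `#` and blank lines
#' are ignored. Two-column lines receive `defaultWeight`; duplicate pairs
#' (in either orientation) collapse to a single edge keeping the maximum
#' weight, so concatenating a file with itself is a no-op. Self-loop lines
#' are skipped with a warning (their node is still registered). Node order
#' is first-appearance order.
#'
#' @param path path to the edge-list file.
#' @param defaultWeight weight assigned to two-column lines (default 1, the
#'   unweighted convention).
#' @return a [PPINetwork-class].
#'
#' @examples
#' tf <- tempfile()
#' writeLines(c("a\tb", "b\tc\t2.5", "# comment", "a\tb\t3"), tf)
#' net <- readEdgeList(tf)
#' nodes(net)       # a, b, c
#' edgeWeights(net) # 3 (max of duplicates), 2.5
#' @export
readEdgeList <- function(path, defaultWeight = 1) {
    if (!is.numeric(defaultWeight) || defaultWeight <= 0)
        stop("'defaultWeight' must be > 0")
    raw <- readLines(path)
    keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
    lineNo <- which(keep)
    parts <- strsplit(trimws(raw[keep]), "[ \t]+")
    len <- lengths(parts)
    if (any(bad <- !(len %in% c(2L, 3L))))
        stop(sprintf("line %d: expected 2 or 3 columns, found %d",
                     lineNo[which(bad)[1L]], len[which(bad)[1L]]))
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    w <- rep(as.numeric(defaultWeight), length(parts))
    has3 <- len == 3L
    if (any(has3)) {
        wRaw <- suppressWarnings(
            as.numeric(vapply(parts[has3], `[`, "", 3L)))
        if (anyNA(wRaw))
            stop(sprintf("line %d: weight is not a number",
                         lineNo[has3][which(is.na(wRaw))[1L]]))
        w[has3] <- wRaw
    }
    if (any(w <= 0))
        stop(sprintf("line %d: edge weight must be > 0",
                     lineNo[which(w <= 0)[1L]]))

    # node order = first appearance, scanning each line left to right
    nodeOrder <- unique(as.vector(rbind(a, b)))

    loop <- a == b
    if (any(loop)) {
        warning(sprintf("skipped %d self-loop line(s) (first at line %d)",
                        sum(loop), lineNo[which(loop)[1L]]))
        a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
    }
    if (!length(a))
        return(new("PPINetwork", nodes = nodeOrder))

    i <- match(a, nodeOrder)
    j <- match(b, nodeOrder)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    key <- paste(lo, hi)
    first <- !duplicated(key)
    wMax <- tapply(w, key, max)
    newPPINetwork(nodeOrder, lo[first], hi[first],
                  as.numeric(wMax[key[first]]))
}

#' Write a PPI network as a tab-separated edge list
#'
#' Inverse of [readEdgeList()]: one `nodeA<TAB>nodeB<TAB>weight` line per
#' edge, in the network's stored edge order, weights at full double
#' precision. Reading the file back reproduces the node set, edge set and
#' weights exactly.
#'
#' @param net a [PPINetwork-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(net, path) {
    stopifnot(is(net, "PPINetwork"))
    e <- net@edges
    lines <- sprintf("%s\t%s\t%s",
                     net@nodes[e[, 1L]], net@nodes[e[, 2L]],
                     formatC(net@weights, format = "g", digits = 17))
    iso <- setdiff(seq_along(net@nodes), unique(as.vector(e)))
    if (length(iso))
        lines <- c(lines,
                   sprintf("# isolated nodes: %s",
                           paste(net@nodes[iso], collapse = "\t")))
    writeLines(lines, path)
    invisible(path)
}

#' Read a reference complex catalogue
#'
#' One complex per line, tab-separated protein identifiers (the usual
#' complex-list layout of curated catalogues such as MIPS). Blank lines are
#' skipped; line order is preserved. Complexes may overlap and need not
#' cover the network.
#'
#' @param path path to the complex file.
#' @param label name stored on the returned set.
#' @return a [ComplexSet-class].
#' @export
readComplexes <- function(path, label = "reference") {
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw))]
    if (!length(raw))
        stop("no complexes: file is empty")
    new("ComplexSet",
        complexes = strsplit(trimws(raw), "[ \t]+"),
        label = label)
}

#' Coerce a Clustering to a ComplexSet of protein identifiers
#'
#' @param clustering a [Clustering-class] whose `nodeNames` slot is set (it
#'   is, whenever the clustering came from an embedding with row names), or
#'   any clustering together with an explicit `nodeNames` vector.
#' @param nodeNames optional identifier vector overriding the slot.
#' @param label label for the resulting set.
#' @return a [ComplexSet-class] with one complex per cluster.
#' @export
asComplexSet <- function(clustering, nodeNames = NULL, label = "clusters") {
    stopifnot(is(clustering, "Clustering"))
    nm <- if (is.null(nodeNames)) clustering@nodeNames else nodeNames
    n <- sum(lengths(clustering@clusters))
    if (length(nm) != n)
        stop("node names are required to name cluster members")
    new("ComplexSet",
        complexes = lapply(clustering@clusters, function(ix) nm[ix]),
        label = label)
}

#' Write clusters or complexes to a tab-separated file
#'
#' One cluster per line, members tab-separated. Output order is
#' deterministic: members sorted lexicographically within a cluster,
#' clusters by decreasing size then by lexicographic first member, so
#' identical partitions always serialize to identical bytes.
#'
#' @param x a [ComplexSet-class], or a [Clustering-class] carrying node
#'   names.
#' @param path output file path.
#' @param ... passed through to the `ComplexSet` method.
#' @return invisibly, `path`.
#' @export
setGeneric("writeClusters", function(x, path, ...)
    standardGeneric("writeClusters"))

#' @rdname writeClusters
#' @export
setMethod("writeClusters", "ComplexSet", function(x, path, ...) {
    if (!length(x@complexes))
        stop("refusing to write an empty cluster set")
    members <- lapply(x@complexes,
                      function(m) sort(m, method = "radix"))
    o <- order(-lengths(members),
               vapply(members, `[`, "", 1L), method = "radix")
    writeLines(vapply(members[o], paste, "", collapse = "\t"), path)
    invisible(path)
})

#' @rdname writeClusters
#' @export
setMethod("writeClusters", "Clustering", function(x, path, ...) {
    writeClusters(asComplexSet(x, ...), path)
})
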