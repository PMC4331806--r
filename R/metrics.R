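#' Harmonic mean of precision and recall
#'
#' `2 * p * r / (p + r)`, with the convention that it is 0 when both
#' arguments are 0.
#'
#' @param precision,recall values in `[0, 1]` (vectorized).
#' @export
fMeasure <- function(precision, recall) {
    ifelse(precision + recall > 0,
           2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and f-measure against a reference complex set
#'
#' Maximum-matching-score evaluation of predicted clusters against
#' reference complexes. Each predicted cluster is credited with its largest
#' node overlap with any single reference complex; precision is the sum of
#' these credits over the total number of clustered nodes. Recall mirrors
#' this from the reference side: each complex is credited with its largest
#' overlap with any predicted cluster, summed over the multiset total of
#' complex members (overlapping complexes count their shared proteins once
#' per complex). Matching is independent per cluster — several clusters may
#' credit the same complex. The f-measure is the harmonic mean of the two.
#'
#' @param pred predicted clusters: a [ComplexSet-class], or a
#'   [Clustering-class] carrying node names.
#' @param ref reference complexes: a [ComplexSet-class].
#' @return list with `precision`, `recall`, `fMeasure`, and the per-cluster
#'   / per-complex best-overlap vectors (`clusterOverlap`,
#'   `complexOverlap`).
#'
#' @examples
#' p <- new("ComplexSet", complexes = list(c("a", "b")))
#' r <- new("ComplexSet", complexes = list(c("a", "c")))
#' precisionRecallF(p, r)[c("precision", "recall", "fMeasure")]  # 0.5 each
#' @export
precisionRecallF <- function(pred, ref) {
    if (is(pred, "Clustering"))
        pred <- asComplexSet(pred)
    stopifnot(is(pred, "ComplexSet"), is(ref, "ComplexSet"))
    P <- pred@complexes
    R <- ref@complexes
    if (!length(P) || !length(R))
        stop("both predicted and reference sets must be non-empty")
    ov <- vapply(P, function(c.)
        vapply(R, function(f.) length(intersect(c., f.)), 0L),
        integer(length(R)))
    ov <- matrix(ov, nrow = length(R))   # complexes x clusters
    clusterBest <- apply(ov, 2L, max)
    complexBest <- apply(ov, 1L, max)
    precision <- sum(clusterBest) / sum(lengths(P))
    recall <- sum(complexBest) / sum(lengths(R))
    list(precision = precision, recall = recall,
         fMeasure = fMeasure(precision, recall),
         clusterOverlap = clusterBest, complexOverlap = complexBest)
}

#' Pearson correlation coefficient
#'
#' Standardized-product form of the sample correlation,
#' `r = (1/(n-1)) * sum(((x - mean(x))/S_x) * ((y - mean(y))/S_y))`,
#' with `S` the sample standard deviation (`n - 1` denominator). Used to
#' relate the modularity objective to external cluster quality across runs.
#'
#' @param x,y numeric vectors of equal length (>= 2), neither constant.
#' @return the correlation in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
    stopifnot(is.numeric(x), is.numeric(y))
    n <- length(x)
    if (n != length(y) || n < 2L)
        stop("'x' and 'y' must have equal length >= 2")
    sx <- stats::sd(x)
    sy <- stats::sd(y)
    if (sx == 0 || sy == 0)
        stop("correlation undefined for constant input")
    sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (n - 1)
}
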