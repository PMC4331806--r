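test_that("epsilon neighborhoods include the boundary, exclude self", {
    pts <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(2, 0, 0))
    expect_equal(epsilonNeighborhood(pts, 1, eps = 0.5), 2L)  # exact boundary
    expect_equal(epsilonNeighborhood(pts, 1, eps = 0.49), integer(0))
    expect_equal(epsilonNeighborhood(pts, 2, eps = 1.5), c(1L, 3L))
    expect_error(epsilonNeighborhood(pts, 1, eps = 0), "> 0")

    solo <- matrix(c(1, 2, 3), nrow = 1)
    expect_equal(epsilonNeighborhood(solo, 1, eps = 5), integer(0))
})

test_that("neighborhood membership is symmetric", {
    set.seed(42)
    pts <- matrix(runif(30), ncol = 3)
    for (eps in c(0.2, 0.5, 1)) {
        inN <- function(i, j) j %in% epsilonNeighborhood(pts, i, eps)
        for (i in 1:10) for (j in 1:10) {
            if (i != j) expect_identical(inN(i, j), inN(j, i))
        }
    }
})

test_that("closures match the definition on constructed cases", {
    # four mutually close points plus one far outlier
    pts <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0), c(0.1, 0.1, 0),
                 c(5, 5, 5))
    cls <- findClosures(pts, eps = 0.2)
    expect_equal(canonClusters(cls), list(1:4, 5L))  # outlier = singleton

    # chain at exact spacing eps: a component but not a closure
    chain <- cbind(c(0, 1, 2), 0, 0)
    expect_equal(findClosures(chain, eps = 1), list())
    expect_error(findClosures(chain, eps = -1), "> 0")
    expect_equal(findClosures(chain, eps = 1, active = integer(0)), list())
})

test_that("closures agree with exhaustive enumeration of the definition", {
    set.seed(7)
    for (rep in 1:30) {
        n <- sample(2:8, 1)
        pts <- matrix(runif(3 * n, 0, 2), ncol = 3)
        eps <- runif(1, 0.2, 1.5)
        active <- sort(sample(n, sample(seq_len(n), 1)))
        got <- canonClusters(findClosures(pts, eps, active))
        want <- canonClusters(bruteClosures(pts, eps, active))
        expect_equal(got, want)
    }
})

test_that("sync update fixes isolated and coincident objects", {
    pts <- rbind(c(0, 0, 0), c(0, 0, 0), c(9, 9, 9))
    expect_equal(syncStep(pts, eps = 1), pts)  # coincident pair + isolated

    # marked (inactive) objects neither move nor attract: with only one
    # object active its neighborhood is empty and nothing changes
    pts2 <- rbind(c(0, 0, 0), c(0.5, 0, 0))
    expect_equal(syncStep(pts2, eps = 1, active = 2L), pts2)
    # both active: both move
    both <- syncStep(pts2, eps = 1)
    expect_false(isTRUE(all.equal(both, pts2)))
})

test_that("sync update moves a pair per the coupling formula", {
    pts <- rbind(c(0, 0, 0), c(0.5, 0, 0))
    out <- syncStep(pts, eps = 1)
    # each object averages sin() pulls over its closed neighborhood (self
    # included in the count): displacement sin(0.5)/2 toward the partner
    expect_equal(out[1, 1], sin(0.5) / 2, tolerance = 1e-15)
    expect_equal(out[2, 1], 0.5 - sin(0.5) / 2, tolerance = 1e-15)
    expect_equal(out[, 2:3], pts[, 2:3])
})

test_that("closure diameter contracts monotonically under the dynamics", {
    set.seed(11)
    for (rep in 1:5) {
        n <- sample(3:7, 1)
        centre <- runif(3, -1, 1)
        pts <- sweep(matrix(runif(3 * n, -0.4, 0.4), ncol = 3), 2, centre, "+")
        eps <- 1.5  # everything mutually within eps: a closure
        expect_equal(canonClusters(findClosures(pts, eps)),
                     list(seq_len(n)))
        d <- max(dist(pts))
        for (step in 1:50) {
            pts <- syncStep(pts, eps)
            dNew <- max(dist(pts))
            expect_lte(dNew, d + 1e-12)
            d <- dNew
        }
        expect_lt(d, 1e-6)
    }
})

test_that("shc clustering handles the degenerate radii immediately", {
    set.seed(3)
    pts <- matrix(runif(15), ncol = 3)
    allIn <- shcCluster(pts, eps = 10)
    expect_equal(length(clusters(allIn)), 1L)
    expect_equal(allIn@nSyncSteps, 0L)

    allOut <- shcCluster(pts, eps = 1e-6)
    expect_equal(length(clusters(allOut)), 5L)
    expect_equal(allOut@nSyncSteps, 0L)
    expect_error(shcCluster(pts, eps = 1, maxSteps = 0L), "maxSteps")
})

test_that("shc clustering separates two tight blobs", {
    X <- twoBlobX()
    cl <- shcCluster(X, eps = 0.3)
    expect_equal(canonClusters(clusters(cl)), list(1:5, 6:10))
    expect_identical(cl@nodeNames, rownames(X))
    expect_equal(epsilon(cl), 0.3)
})

test_that("shc clustering always returns a partition, deterministically", {
    set.seed(19)
    for (rep in 1:8) {
        n <- sample(5:15, 1)
        pts <- matrix(runif(3 * n, 0, 1.5), ncol = 3)
        eps <- runif(1, 0.1, 0.8)
        cl <- suppressWarnings(shcCluster(pts, eps))
        expect_identical(sort(unlist(clusters(cl))), seq_len(n))
        cl2 <- suppressWarnings(shcCluster(pts, eps))
        expect_identical(clusters(cl), clusters(cl2))
    }
})

test_that("shc clustering is permutation-equivariant", {
    set.seed(23)
    pts <- matrix(runif(36), ncol = 3)
    eps <- 0.45
    base <- canonClusters(clusters(suppressWarnings(shcCluster(pts, eps))))
    for (rep in 1:3) {
        perm <- sample(nrow(pts))
        got <- clusters(suppressWarnings(shcCluster(pts[perm, ], eps)))
        mapped <- canonClusters(lapply(got, function(ix) perm[ix]))
        expect_equal(mapped, base)
    }
})

test_that("hierarchical search starts at the 3-NN radius, ties to smallest", {
    X <- twoBlobX()
    D <- as.matrix(dist(X))
    knn <- apply(D, 1, sort)
    eps0 <- mean(knn[4, ])  # 3rd neighbor after self

    one <- hierarchicalSearch(X, function(cl) 1, maxLevels = 1L)
    expect_equal(one$epsilon, eps0)

    const <- hierarchicalSearch(X, function(cl) 42, maxLevels = 10L)
    expect_equal(const$epsilon, eps0)  # constant objective: smallest radius
    expect_true(all(diff(const$path$epsilon) > 0))
})

test_that("hierarchical search finds the two-blob structure", {
    X <- twoBlobX()
    want2 <- function(cl) as.numeric(length(clusters(cl)) == 2L)
    res <- hierarchicalSearch(X, want2, maxLevels = 30L)
    expect_equal(res$value, 1)
    expect_equal(canonClusters(clusters(res$clustering)), list(1:5, 6:10))
})

test_that("degenerate geometry falls back to an even radius grid", {
    # octahedron vertices: 3rd and 4th neighbor distances tie exactly
    X <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
    expect_warning(
        res <- hierarchicalSearch(X, function(cl) length(clusters(cl)),
                                  maxLevels = 5L),
        "increment")
    expect_true(is.finite(res$value))
    expect_error(hierarchicalSearch(X[1:4, ], function(cl) 1), "at least 5")
})
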