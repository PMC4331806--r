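test_that("intensity, attractiveness and moves follow the FA formulas", {
    expect_equal(lightIntensity(5, 1, 0), 5)
    expect_equal(lightIntensity(3, 0, 10), 3)
    expect_equal(lightIntensity(1, 1, 1), exp(-1))

    expect_equal(attractiveness(2, 1, 0), 2)
    expect_equal(attractiveness(1, 1, 1), exp(-1))
    r <- seq(0, 3, by = 0.1)
    expect_true(all(diff(attractiveness(1, 0.7, r)) <= 0))
    expect_error(attractiveness(1, 1, -1), "r")

    expect_equal(moveFirefly(2, 5, beta = 0, alpha = 0, u = 0.9), 2)
    expect_equal(moveFirefly(2, 5, beta = 1, alpha = 0, u = 0.1), 5)
    expect_equal(moveFirefly(2, 5, beta = 0.25, alpha = 0.9, u = 0.5),
                 2 + 0.25 * 3)
})

test_that("firefly parameters are validated", {
    expect_error(faParams(nFireflies = 0), "nFireflies")
    expect_error(faParams(alpha = 1.5), "alpha")
    expect_error(faParams(beta0 = 0), "beta0")
    expect_error(faParams(gamma = -1), "gamma")
    expect_error(faParams(maxiter = 0), "maxiter")
    expect_error(faParams(epsMin = 2, epsMax = 1), "epsMin")
    p <- faParams()
    expect_equal(p@nFireflies, 6L)
    expect_equal(p@maxiter, 30L)
    expect_equal(c(p@beta0, p@gamma, p@alpha), c(1, 1, 0.9))
})

test_that("a single firefly never moves", {
    p <- faParams(nFireflies = 1L, seed = 7L, epsMin = 1, epsMax = 2)
    res <- fireflySearch(function(x) -(x - 1.6)^2, p)
    set.seed(7L)
    init <- runif(1, 1, 2)
    expect_equal(res$positions, init)
    expect_equal(res$epsilon, init)
    expect_equal(res$value, -(init - 1.6)^2)
})

test_that("search is reproducible, clipped, with non-decreasing best", {
    f <- function(x) exp(-(x - 3)^2)
    p <- faParams(seed = 42L, epsMin = 0.5, epsMax = 9)
    res1 <- fireflySearch(f, p)
    res2 <- fireflySearch(f, p)
    expect_identical(res1, res2)
    expect_true(all(res1$positions >= 0.5 & res1$positions <= 9))
    expect_true(all(diff(res1$trace$bestValue) >= 0))
    expect_equal(nrow(res1$trace), 30L)

    res3 <- fireflySearch(f, faParams(seed = 43L, epsMin = 0.5, epsMax = 9))
    expect_false(identical(res1$epsilon, res3$epsilon))
})

test_that("no intensity differences means no movement when alpha is zero", {
    p <- faParams(alpha = 0, seed = 5L, epsMin = 0.01, epsMax = 1)
    res <- fireflySearch(function(x) 1, p)
    set.seed(5L)
    expect_equal(res$positions, runif(6, 0.01, 1))
})

test_that("non-finite objective values demote a firefly with a warning", {
    f <- function(x) if (x > 0.5) NaN else x
    p <- faParams(nFireflies = 4L, maxiter = 2L, seed = 2L,
                  epsMin = 0.01, epsMax = 1)
    w <- capture_warnings(res <- fireflySearch(f, p))
    expect_true(any(grepl("non-finite", w)))
    expect_true(is.finite(res$value))
    expect_lte(res$epsilon, 0.5)
})

test_that("firefly search tracks a grid search on a smooth objective", {
    f <- function(x) 1 / (1 + (x - 6.3)^2)
    grid <- seq(0.01, 10, length.out = 1000)
    gridBest <- grid[which.max(f(grid))]
    for (seed in 1:5) {
        res <- fireflySearch(f, faParams(seed = seed, epsMin = 0.01,
                                         epsMax = 10))
        expect_lt(abs(res$epsilon - gridBest), 2 * 0.9)
    }
})

test_that("radius optimizer matches the hierarchical baseline on blobs", {
    # geometric two-blob fixture, scored against its two-module network
    X <- twoBlobX()
    net <- plantedPartitionNetwork(c(5, 5), pIn = 1, pOut = 0,
                                   seed = 4)$network
    obj <- function(cl) modularityObjective(cl, net, 0.8)
    fa <- optimizeEpsilon(X, net, faParams(seed = 1L))
    hs <- hierarchicalSearch(X, obj, maxLevels = 20L)
    expect_gte(fa$value, hs$value)
    expect_equal(canonClusters(clusters(fa$clustering)), list(1:5, 6:10))
    expect_equal(obj(fa$clustering), fa$value)
})

test_that("auto bounds come from the embedding geometry", {
    X <- twoBlobX()
    net <- plantedPartitionNetwork(c(5, 5), pIn = 1, pOut = 0,
                                   seed = 1)$network
    fit <- optimizeEpsilon(X, net, faParams(seed = 3L),
                           objective = function(cl) length(clusters(cl)))
    D <- as.matrix(dist(X))
    nn1 <- mean(apply(D, 1, function(r) sort(r)[2]))
    expect_gte(fit$epsilon, nn1)
    expect_lte(fit$epsilon, max(D))
})
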