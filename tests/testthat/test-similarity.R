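test_that("variation vectors follow the printed rate/velocity formulas", {
    t0 <- as.Date("2015-01-01")
    t1 <- t0 + 183
    v <- variationVector(10, 9, t0, t1)
    expect_equal(unname(v["rate"]), -0.1)
    expect_equal(unname(v["velocity"]), -1 / (183 / 30.4375))

    expect_equal(unname(variationVector(5, 5, t0, t1)), c(0, 0))
    expect_error(variationVector(0, 1, t0, t1), "zero value")
    expect_error(variationVector(1, 2, t1, t0), "time gap")
})

test_that("Mahalanobis distance matches hand-computed quadratic forms", {
    expect_equal(mahalanobisDistance(c(3, 4), c(0, 0), diag(2),
                                     regularize = FALSE), 5)
    expect_equal(mahalanobisDistance(c(1, 2), c(1, 2), diag(2)), 0)
    # S = diag(4, 1): explicit inverse gives (2-0)^2 / 4 = 1
    expect_equal(mahalanobisDistance(c(2, 0), c(0, 0), diag(c(4, 1)),
                                     regularize = FALSE), 1)
    # generic oracle: chol-free quadratic form
    set.seed(7)
    M <- matrix(rnorm(4), 2); S <- crossprod(M) + diag(2)
    xi <- rnorm(2); xj <- rnorm(2)
    expect_equal(mahalanobisDistance(xi, xj, S, regularize = FALSE),
                 sqrt(drop(t(xi - xj) %*% solve(S) %*% (xi - xj))),
                 tolerance = 1e-12)
})

test_that("the regularized Mahalanobis distance is a metric", {
    set.seed(42)
    M <- matrix(rnorm(4), 2); S <- crossprod(M) + 0.5 * diag(2)
    pts <- matrix(rnorm(3 * 200), ncol = 2)
    for (i in seq_len(200 / 2)) {
        a <- pts[3 * i - 2, ]; b <- pts[3 * i - 1, ]; c_ <- pts[3 * i, ]
        dab <- mahalanobisDistance(a, b, S)
        dba <- mahalanobisDistance(b, a, S)
        expect_gte(dab, 0)
        expect_equal(dab, dba, tolerance = 1e-12)
        expect_lte(mahalanobisDistance(a, c_, S),
                   dab + mahalanobisDistance(b, c_, S) + 1e-12)
    }
})

test_that("distances scale as 1/sigma under S = sigma^2 I", {
    set.seed(3)
    xi <- rnorm(2); xj <- rnorm(2)
    eu <- sqrt(sum((xi - xj)^2))
    expect_equal(mahalanobisDistance(xi, xj, 4 * diag(2),
                                     regularize = FALSE), eu / 2,
                 tolerance = 1e-12)
})

test_that("pairwise slice distances equal brute-force Euclidean under identity S", {
    set.seed(11)
    V <- matrix(rnorm(6), 3, 2)  # d = 3 hand-set variation vectors
    D <- tensorMTL:::.pairwiseMahalanobis(V, chol(diag(2)))
    for (i in 1:3) for (j in 1:3)
        expect_equal(D[i, j], sqrt(sum((V[i, ] - V[j, ])^2)),
                     tolerance = 1e-10)
})

test_that("similarity tensors are symmetric, bounded and reproducible", {
    sim <- smallSim(n = 10, d = 5)
    X <- tensorValues(sim$tensors[[1]])
    for (k in seq_len(dim(X)[3])) {
        expect_equal(X[, , k], t(X[, , k]), tolerance = 1e-12)
        expect_equal(diag(X[, , k]), rep(0, 5))
    }
    expect_gte(min(X), 0)
    expect_lte(max(X), 1)  # normalized slices

    # identical patients give identical slices
    cohort <- makeToyCohort(n = 1, d = 4)
    vals <- SummarizedExperiment::assay(cohort)
    big <- LongitudinalCohort(cbind(vals, vals, vals),
                              rep(c("Q1", "Q2", "Q3"), each = 2),
                              rep(c("BL", "M06"), 3),
                              rep(examDates(cohort), 3),
                              rep("AD", 6),
                              biomarkerNames = rownames(vals))
    tens <- buildSimilarityTensor(big)
    expect_equal(tensorValues(tens)[, , 1], tensorValues(tens)[, , 2])
    expect_equal(tensorValues(tens)[, , 1], tensorValues(tens)[, , 3])
})

test_that("a patient with identical variation vectors yields a zero slice", {
    # two biomarkers changing identically -> identical variation vectors
    vals <- matrix(c(10, 20, 9, 18), 2, 2) * c(1, 2)
    vals <- matrix(c(10, 10, 9, 9), 2, 2)
    cohort <- LongitudinalCohort(vals, c("P1", "P1"), c("BL", "M06"),
                                 as.Date(c("2015-01-01", "2015-07-01")),
                                 c("AD", "AD"))
    tens <- buildSimilarityTensor(cohort, normalize = FALSE)
    expect_equal(tensorValues(tens)[, , 1], matrix(0, 2, 2))
})

test_that("the correction mask is strictly upper triangular and halves symmetric sums", {
    expect_equal(correctionMask(3, 3),
                 matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3))
    expect_equal(correctionMask(1, 1), matrix(0, 1, 1))
    set.seed(2)
    M <- matrix(rnorm(25), 5); M <- M + t(M); diag(M) <- 0
    expect_equal(sum(correctionMask(5, 5) * M), sum(M) / 2,
                 tolerance = 1e-12)
})

test_that("tensor construction validates its inputs", {
    cohort <- makeToyCohort(n = 2, d = 3)
    vals <- SummarizedExperiment::assay(cohort)
    vals[1, 1] <- NA
    SummarizedExperiment::assays(cohort)$biomarkers <- vals
    expect_error(buildSimilarityTensor(cohort), "missing")

    one <- makeToyCohort(n = 2, d = 3)
    expect_error(buildSimilarityTensor(one[1, ]), "at least 2")
})
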