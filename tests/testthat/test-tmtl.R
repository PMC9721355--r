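test_that("CP reconstruction matches the brute-force triple loop", {
    ones <- matrix(1, 3, 1)
    expect_equal(cpReconstruct(ones, ones, matrix(1, 2, 1)),
                 array(1, dim = c(3, 3, 2)))

    set.seed(21)
    A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(10), 5, 2)
    C <- matrix(rnorm(8), 4, 2)
    expect_lt(max(abs(cpReconstruct(A, B, C) - bruteForceCP(A, B, C))),
              1e-12)
    # multilinearity
    expect_equal(cpReconstruct(3 * A, B, C), 3 * cpReconstruct(A, B, C),
                 tolerance = 1e-12)
    expect_error(cpReconstruct(A, B, C[, 1, drop = FALSE]), "rank")
})

test_that("CP-ALS recovers a noiseless low-rank tensor", {
    set.seed(33)
    A <- matrix(rnorm(8 * 3), 8, 3); B <- matrix(rnorm(8 * 3), 8, 3)
    C <- matrix(rnorm(6 * 3), 6, 3)
    X <- cpReconstruct(A, B, C)
    fit <- cpDecompose(X, 3, sweeps = 50)
    expect_lt(fit$relErr, 1e-6)
    # deterministic: same input, same factors
    fit2 <- cpDecompose(X, 3, sweeps = 50)
    expect_identical(fit$A, fit2$A)
    expect_error(cpDecompose(X, 20), "rank")
})

test_that("soft-thresholding is the l1 proximal operator", {
    expect_equal(softThreshold(c(3, -0.5, 0), 1), c(2, 0, 0))
    Z <- matrix(c(-2, 0.3, 1.4, 0), 2, 2)
    expect_equal(softThreshold(Z, 0), Z)
    # prox definition oracle: per-entry fine grid search
    set.seed(14)
    z <- rnorm(20, sd = 2); tau <- 0.7
    grid <- seq(-6, 6, by = 1e-4)
    for (zi in z) {
        best <- grid[which.min(0.5 * (grid - zi)^2 + tau * abs(grid))]
        expect_equal(softThreshold(zi, tau), best, tolerance = 1e-3)
    }
})

test_that("predictSample equals the double-loop evaluation of the U-sum", {
    inst <- randomInstance(d = 3, r = 1, seed = 2)
    expect_equal(predictSample(inst$A, inst$B, matrix(0, 3, 3), inst$K,
                               inst$X), 0)
    ones3 <- matrix(1, 3, 1)
    expect_equal(predictSample(ones3, ones3, matrix(1, 3, 3),
                               correctionMask(3, 3), matrix(1, 3, 3)), 3)
    for (seed in 1:25) {
        inst <- randomInstance(d = sample(3:6, 1), r = sample(1:3, 1),
                               seed = seed)
        expect_equal(predictSample(inst$A, inst$B, inst$W, inst$K, inst$X),
                     bruteForcePredict(inst$A, inst$B, inst$W, inst$K,
                                       inst$X),
                     tolerance = 1e-12)
    }
    expect_error(predictSample(inst$A, inst$B, inst$W, inst$K,
                               matrix(1, 2, 2)), "shape")
})

test_that("objective values equal their term-by-term oracles", {
    d <- 4; n <- 5; r <- 2
    X <- array(0, dim = c(d, d, n))
    zero <- matrix(0, d, r)
    expect_equal(tmtlObjectiveSingle(X, rep(0, n), zero, zero,
                                     matrix(0, n, r), matrix(0, d, d),
                                     correctionMask(d, d), 1, 1), 0)
    set.seed(8)
    X <- array(abs(rnorm(d * d * n)), dim = c(d, d, n))
    for (k in seq_len(n)) {
        X[, , k] <- X[, , k] + t(X[, , k]); diag(X[, , k]) <- 0
    }
    A <- matrix(rnorm(d * r), d, r); B <- matrix(rnorm(d * r), d, r)
    C <- matrix(rnorm(n * r), n, r); W <- matrix(rnorm(d * d), d, d)
    K <- correctionMask(d, d)
    y <- rnorm(n); y[2] <- NA
    lambda <- 0.7; beta <- 0.13
    yhat <- vapply(seq_len(n), function(k)
        bruteForcePredict(A, B, W, K, X[, , k]), numeric(1))
    oracle <- 0.5 * sum((yhat - y)[!is.na(y)]^2) +
        lambda / 2 * sum((X - bruteForceCP(A, B, C))^2) +
        beta * (sum(abs(W)) + sum(abs(A)) + sum(abs(B)) + sum(abs(C)))
    expect_equal(tmtlObjectiveSingle(X, y, A, B, C, W, K, lambda, beta),
                 oracle, tolerance = 1e-10)

    # perfect prediction with lambda = beta = 0 is exactly zero
    expect_equal(tmtlObjectiveSingle(X, yhat, A, B, C, W, K, 0, 0), 0,
                 tolerance = 1e-12)

    # joint: theta = 0 reduces to the sum of singles; identical weights
    # contribute no smoothness
    tpts <- 3
    Y <- matrix(rnorm(n * tpts), n, tpts)
    Al <- replicate(tpts, A, simplify = FALSE)
    Bl <- replicate(tpts, B, simplify = FALSE)
    Cl <- replicate(tpts, C, simplify = FALSE)
    Warr <- array(W, dim = c(d, d, tpts))
    op <- buildP(tpts, 0.4)
    sumSingles <- sum(vapply(seq_len(tpts), function(i)
        tmtlObjectiveSingle(X, Y[, i], A, B, C, W, K, lambda, beta),
        numeric(1)))
    expect_equal(tmtlObjectiveJoint(X, Y, Al, Bl, Cl, Warr, K, lambda,
                                    beta, 0, op), sumSingles,
                 tolerance = 1e-10)
    expect_equal(tmtlObjectiveJoint(X, Y, Al, Bl, Cl, Warr, K, lambda,
                                    beta, 5, op), sumSingles,
                 tolerance = 1e-10)  # identical W_t: penalty term is 0
})

test_that("the solver descends monotonically and is deterministic", {
    sim <- smallSim(n = 20, d = 6, seed = 17)
    p <- tmtlParams(maxIter = 40, seed = 3)
    m1 <- fitTMTL(sim$tensors[[1]], sim$scores, p)
    tr <- objectiveTrace(m1)
    expect_true(all(diff(tr) <= 1e-10))
    m2 <- fitTMTL(sim$tensors[[1]], sim$scores, p)
    expect_identical(weightStack(m1), weightStack(m2))

    m0 <- fitTMTL(sim$tensors[[1]], sim$scores, tmtlParams(maxIter = 0))
    expect_length(objectiveTrace(m0), 1L)
    expect_equal(sum(weightStack(m0) != 0), 0L)  # W initialized at zero
})

test_that("fit validates inputs", {
    sim <- smallSim(n = 10, d = 5, seed = 2)
    Y <- scoreMatrix(sim$scores)
    expect_error(fitTMTL(sim$tensors[[1]], Y, tmtlParams(rank = 10)),
                 "rank")
    Ybad <- Y; Ybad[1, 1] <- Inf
    expect_error(fitTMTL(sim$tensors[[1]], Ybad, tmtlParams()),
                 "non-finite")
})

test_that("a noiseless forward-model cohort is fitted to near-zero error", {
    spec <- syntheticSpec(nPatients = 40, nBiomarkers = 8,
                          scoreNoiseFrac = 0, seed = 23)
    sim <- simulateCohort(spec, nStages = 1)
    p <- tmtlParams(lambda = 0.01, beta = 1e-4, theta = 0.01,
                    maxIter = 400, tol = 1e-10)
    m <- fitTMTL(sim$tensors[[1]], sim$scores, p)
    yh <- predict(m, sim$tensors[[1]])
    Y <- scoreMatrix(sim$scores)
    trainRMSE <- mean(vapply(seq_len(ncol(Y)), function(i)
        rmse(Y[, i], yh[, i]), numeric(1)))
    expect_lt(trainRMSE, 1e-2)
})

test_that("predictions ignore the strictly-lower triangle of the slices", {
    sim <- smallSim(n = 12, d = 6, seed = 31)
    p <- tmtlParams(maxIter = 20)
    m <- fitTMTL(sim$tensors[[1]], sim$scores, p)
    X <- tensorValues(sim$tensors[[1]])
    base <- predict(m, X)
    set.seed(1)
    Xp <- X
    low <- which(lower.tri(matrix(0, 6, 6)))
    for (k in seq_len(dim(X)[3]))
        Xp[, , k][low] <- Xp[, , k][low] + runif(length(low))
    expect_equal(predict(m, Xp), base, tolerance = 1e-12)

    # reduction to predictSample on a single slice
    one <- predict(m, X[, , 1, drop = FALSE])
    fac <- latentFactors(m)
    expect_equal(unname(one[1, 2]),
                 predictSample(fac$A[[2]], fac$B[[2]],
                               weightStack(m)[, , 2], m@K, X[, , 1]),
                 tolerance = 1e-12)
    expect_equal(predict(m, array(0, dim = dim(X)))[, 1],
                 rep(0, dim(X)[3]))
})

test_that("sparsity is monotone in the l1 weight", {
    sim <- smallSim(n = 20, d = 6, seed = 13)
    nnz <- vapply(c(0.01, 0.1, 0.5, 2), function(b) {
        m <- fitTMTL(sim$tensors[[1]], sim$scores,
                     tmtlParams(beta = b, maxIter = 60, seed = 1))
        sum(weightStack(m) != 0)
    }, numeric(1))
    expect_true(all(diff(nnz) <= 0))
})
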