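test_that("rmse matches hand arithmetic and is symmetric", {
    expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
    expect_equal(rmse(1:5, 1:5), 0)
    set.seed(6)
    y <- rnorm(10); yh <- rnorm(10)
    expect_equal(rmse(y, yh), rmse(yh, y))
    expect_error(rmse(numeric(), numeric()))
})

test_that("nmse equals its loop-based oracle and handles degenerate input", {
    set.seed(12)
    Y <- matrix(rnorm(40, 20, 4), 10, 4)
    Yh <- Y + matrix(rnorm(40), 10, 4)
    Y[3, 2] <- NA
    oracle <- 0; denom <- 0
    for (i in 1:4) {
        obs <- which(!is.na(Y[, i]))
        oracle <- oracle + sum((Y[obs, i] - Yh[obs, i])^2) / sd(Y[obs, i])
        denom <- denom + length(obs)
    }
    expect_equal(nmse(Y, Yh), oracle / denom, tolerance = 1e-12)
    expect_equal(nmse(Y, ifelse(is.na(Y), 0, Y)), 0)

    # single time point: nmse = rmse^2 / sigma
    y <- matrix(rnorm(20, 5, 2), 20, 1)
    yh <- y + rnorm(20)
    expect_equal(nmse(y, yh), rmse(y, yh)^2 / sd(y), tolerance = 1e-12)

    expect_error(nmse(matrix(1, 5, 1), matrix(0, 5, 1)), "zero-variance")
})

test_that("relationship ranking sorts the masked upper triangle stably", {
    W <- matrix(0, 6, 6); W[2, 5] <- 0.9
    r <- rankRelationships(W, paste0("b", 1:6), k = 1)
    expect_equal(r$biomarker1, "b2")
    expect_equal(r$biomarker2, "b5")
    expect_equal(r$weight, 0.9)

    rz <- rankRelationships(matrix(0, 4, 4), paste0("b", 1:4), k = 3)
    expect_equal(rz$weight, rep(0, 3))
    expect_equal(rz$biomarker1, c("b1", "b1", "b2"))  # stable index order
    expect_equal(rz$biomarker2, c("b2", "b3", "b3"))

    set.seed(18)
    W <- matrix(rnorm(36), 6, 6)
    K <- correctionMask(6, 6)
    r <- rankRelationships(W, paste0("b", 1:6), k = 15)
    expect_equal(r$weight[order(-abs(r$weight))], r$weight)
    expect_equal(sort(abs(r$weight), decreasing = TRUE),
                 sort(abs(W[K == 1]), decreasing = TRUE))

    # lower-triangle perturbations are irrelevant
    Wp <- W; Wp[lower.tri(Wp)] <- rnorm(15)
    expect_equal(rankRelationships(Wp, paste0("b", 1:6), k = 15), r)

    expect_error(rankRelationships(W, k = 16), "exceeds")
})

test_that("BrainNet-style export writes parseable node/edge files", {
    W <- matrix(0, 4, 4); W[1, 3] <- -2; W[2, 4] <- 1
    r <- rankRelationships(W, paste0("b", 1:4), k = 2)
    prefix <- withr::local_tempfile()
    paths <- exportBrainNet(r, paste0("b", 1:4), prefix)
    node <- read.table(paths[1])
    edge <- unname(as.matrix(read.table(paths[2])))
    expect_equal(nrow(node), 4)
    expect_equal(dim(edge), c(4, 4))
    expect_equal(edge[1, 3], 2)  # magnitude
    expect_equal(edge, t(edge))
})

test_that("the split protocol returns a complete deterministic report", {
    sim <- smallSim(n = 30, d = 6, seed = 61)
    grid1 <- data.frame(beta = 0.1)
    rep1 <- runProtocol(sim$tensors[[1]], sim$scores, grid1,
                        nRepeats = 1, cvFolds = 3,
                        baseParams = tmtlParams(maxIter = 30), seed = 7)
    pt <- perTimeRMSE(rep1)
    expect_equal(nrow(pt), 4L)
    expect_true(all(is.finite(pt$rmseMean)))
    expect_true(all(is.na(pt$rmseSD)))  # single repeat has no SD
    expect_length(overallNMSE(rep1), 2L)

    rep2 <- runProtocol(sim$tensors[[1]], sim$scores, grid1,
                        nRepeats = 1, cvFolds = 3,
                        baseParams = tmtlParams(maxIter = 30), seed = 7)
    expect_identical(perTimeRMSE(rep1), perTimeRMSE(rep2))
})

test_that("grid search never selects a dominated hyperparameter setting", {
    sim <- smallSim(n = 30, d = 6, seed = 67)
    grid <- data.frame(beta = c(0.01, 0.1, 1))
    rep_ <- runProtocol(sim$tensors[[1]], sim$scores, grid,
                        nRepeats = 2, cvFolds = 3,
                        baseParams = tmtlParams(maxIter = 25), seed = 5)
    for (i in seq_along(rep_@cvTables)) {
        tab <- rep_@cvTables[[i]]
        chosenBeta <- rep_@chosen$beta[i]
        expect_equal(tab$valRMSE[tab$beta == chosenBeta],
                     min(tab$valRMSE))
    }
})

test_that("protocol rejects degenerate split sizes", {
    sim <- smallSim(n = 10, d = 5, seed = 71)
    expect_error(runProtocol(sim$tensors[[1]], sim$scores,
                             data.frame(beta = 0.1), nRepeats = 1,
                             cvFolds = 5), "too few")
})
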