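#' Root mean square error
#'
#' \code{sqrt(||y - yhat||_2^2 / n)} over the jointly observed entries.
#'
#' @param y,yhat numeric vectors of equal length (NA pairs are dropped).
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
    stopifnot(length(y) == length(yhat))
    obs <- !is.na(y) & !is.na(yhat)
    if (!any(obs)) stop("no observed (y, yhat) pairs")
    sqrt(sum((y[obs] - yhat[obs])^2) / sum(obs))
}

#' Normalized mean square error over all time points
#'
#' \code{sum_i ||Y_i - Yhat_i||_2^2 / sigma(Y_i)} divided by
#' \code{sum_i n_i}, where \code{sigma(Y_i)} is the standard deviation of
#' the observed targets at time point i and \code{n_i} their count. The
#' normalization makes errors comparable across time points with
#' different score spread.
#'
#' @param Y,Yhat n x t matrices (NA in \code{Y} = missing target).
#' @return non-negative scalar.
#' @export
nmse <- function(Y, Yhat) {
    Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
    stopifnot(all(dim(Y) == dim(Yhat)))
    num <- 0; den <- 0
    for (i in seq_len(ncol(Y))) {
        obs <- !is.na(Y[, i]) & !is.na(Yhat[, i])
        ni <- sum(obs)
        if (ni == 0L) next
        s <- sd(Y[obs, i])
        if (!is.finite(s) || s == 0)
            stop("zero-variance targets at time point ", i)
        num <- num + sum((Y[obs, i] - Yhat[obs, i])^2) / s
        den <- den + ni
    }
    if (den == 0L) stop("no observed targets")
    num / den
}

#' Rank biomarker-pair weights
#'
#' Masks a weight matrix by the strictly-upper-triangular correction mask
#' and returns the k pairs with the largest absolute weight, in
#' descending order of magnitude (the reported \code{weight} keeps its
#' sign). Ties are broken by upper-triangle index order (column-major),
#' so the output is stable.
#'
#' @param W d x d weight matrix (one time point).
#' @param names biomarker names (length d).
#' @param K correction mask (defaults to [correctionMask()]).
#' @param k number of pairs to return (default 10).
#' @return data.frame with columns \code{biomarker1}, \code{biomarker2},
#'   \code{weight}, \code{rank}; \code{biomarker1}'s index < that of
#'   \code{biomarker2}.
#' @export
rankRelationships <- function(W, names = NULL, K = NULL, k = 10L) {
    W <- as.matrix(W)
    d <- nrow(W)
    if (is.null(names)) names <- paste0("b", seq_len(d))
    if (is.null(K)) K <- correctionMask(d, ncol(W))
    Wm <- W * K
    idx <- which(K == 1, arr.ind = TRUE)
    if (k > nrow(idx))
        stop("k exceeds the number of upper-triangular pairs (",
             nrow(idx), ")")
    w <- Wm[idx]
    ord <- order(-abs(w), idx[, 2], idx[, 1])[seq_len(k)]
    data.frame(biomarker1 = names[idx[ord, 1]],
               biomarker2 = names[idx[ord, 2]],
               weight = w[ord], rank = seq_len(k),
               stringsAsFactors = FALSE)
}

#' Export a ranking as BrainNet-Viewer-style node/edge files
#'
#' Writes plain-text \code{.node} (label, synthetic circular layout
#' coordinates, category color code, degree-scaled size) and \code{.edge}
#' (d x d absolute-weight matrix restricted to the ranked pairs) files.
#' The coordinates are a synthetic layout, not anatomical positions.
#'
#' @param ranking data.frame from [rankRelationships()].
#' @param names all biomarker names (defines node order).
#' @param prefix output path prefix (writes \code{<prefix>.node} and
#'   \code{<prefix>.edge}).
#' @param categories optional category tag per biomarker (mapped to the
#'   node color column).
#' @return invisibly, the two file paths.
#' @export
exportBrainNet <- function(ranking, names, prefix, categories = NULL) {
    d <- length(names)
    if (is.null(categories)) categories <- rep("NA", d)
    ang <- 2 * pi * (seq_len(d) - 1) / d
    E <- matrix(0, d, d)
    i1 <- match(ranking$biomarker1, names)
    i2 <- match(ranking$biomarker2, names)
    if (anyNA(i1) || anyNA(i2)) stop("ranking names not all present")
    E[cbind(i1, i2)] <- abs(ranking$weight)
    E <- E + t(E)
    node <- data.frame(x = round(50 * cos(ang), 3),
                       y = round(50 * sin(ang), 3), z = 0,
                       color = as.integer(factor(categories)),
                       size = rowSums(E > 0) + 1, label = names)
    nodePath <- paste0(prefix, ".node")
    edgePath <- paste0(prefix, ".edge")
    utils::write.table(node, nodePath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(E, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(c(nodePath, edgePath))
}

#' Default hyperparameter search grid
#'
#' A modest grid over the regularization weights and the temporal mixing
#' parameter; one row per candidate. Columns absent from a custom grid
#' fall back to the base [tmtlParams()] defaults.
#'
#' @return data.frame with columns \code{lambda}, \code{beta},
#'   \code{theta}, \code{alpha}.
#' @export
defaultGrid <- function() {
    expand.grid(lambda = 0.1, beta = c(1e-3, 1e-2),
                theta = c(0.1, 1), alpha = c(0, 0.5))
}

.paramsFromRow <- function(row, base) {
    p <- base
    if (!is.null(row$lambda)) p@lambda <- row$lambda
    if (!is.null(row$beta)) p@beta <- row$beta
    if (!is.null(row$theta)) p@theta <- row$theta
    if (!is.null(row$rank)) p@rank <- as.integer(row$rank)
    if (!is.null(row$alpha)) p@alphas <- row$alpha
    p
}

.fitAny <- function(tensors, Y, params, ensemble, nu) {
    if (ensemble) fitEnsemble(tensors, Y, params, nu = nu)
    else fitTMTL(tensors[[1]], Y, params)
}

.predictAny <- function(model, tensors) {
    if (is(model, "BoostingEnsemble")) predictEnsemble(model, tensors)
    else predict(model, tensors[[1]])
}

#' Repeated train/test evaluation protocol
#'
#' For each repeat: split the patients 9:1 into training and test sets,
#' select hyperparameters by k-fold cross-validation on the training
#' patients (mean validation rMSE across folds and time points, ties
#' broken by grid order), refit on the full training set and evaluate on
#' the held-out patients. Splits are always at the patient level. Reports
#' mean and SD of per-time-point test rMSE and of the overall nMSE over
#' the repeats.
#'
#' @param tensors a \linkS4class{SimilarityTensor} or chronological list
#'   of them (a list of length > 1 fits the boosting ensemble).
#' @param scores \linkS4class{ScoreTable} or n x t matrix with patient
#'   rownames.
#' @param grid data.frame of hyperparameter candidates (see
#'   [defaultGrid()]); a single row skips cross-validation.
#' @param nRepeats number of random splits (default 20).
#' @param splitRatio training fraction (default 0.9).
#' @param cvFolds cross-validation folds (default 5).
#' @param seed base seed; repeat i uses \code{seed + i}.
#' @param baseParams \linkS4class{TMTLParams} supplying values not in the
#'   grid.
#' @param nu ensemble shrinkage (only used with multiple tensors).
#' @return an \linkS4class{EvaluationReport}.
#' @export
runProtocol <- function(tensors, scores, grid = defaultGrid(),
                        nRepeats = 20L, splitRatio = 0.9, cvFolds = 5L,
                        seed = 1L, baseParams = tmtlParams(), nu = 1) {
    if (is(tensors, "SimilarityTensor")) tensors <- list(tensors)
    ensemble <- length(tensors) > 1L
    Y <- if (is(scores, "ScoreTable")) scoreMatrix(scores) else
        as.matrix(scores)
    pats <- tensorPatients(tensors[[1]])
    if (!is.null(rownames(Y))) {
        idx <- match(pats, rownames(Y))
        if (anyNA(idx)) stop("tensor patients missing from the score table")
        Y <- Y[idx, , drop = FALSE]
    }
    n <- length(pats); tp <- ncol(Y)
    nTest <- max(1L, round((1 - splitRatio) * n))
    if (n - nTest < cvFolds * 2L)
        stop("too few training samples for ", cvFolds, "-fold CV")
    tpNames <- colnames(Y)
    if (is.null(tpNames)) tpNames <- paste0("t", seq_len(tp))

    rmseMat <- matrix(NA_real_, nRepeats, tp)
    nmseVec <- numeric(nRepeats)
    chosen <- vector("list", nRepeats)
    cvTables <- vector("list", nRepeats)

    for (rep_ in seq_len(nRepeats)) {
        .withSeed(seed + rep_, {
            testIdx <- sort(sample.int(n, nTest))
            trainIdx <- setdiff(seq_len(n), testIdx)
            folds <- sample(rep_len(seq_len(cvFolds), length(trainIdx)))
            cvTab <- grid
            cvTab$valRMSE <- NA_real_
            if (nrow(grid) > 1L) {
                for (g in seq_len(nrow(grid))) {
                    p <- .paramsFromRow(grid[g, , drop = FALSE], baseParams)
                    errs <- numeric(cvFolds)
                    for (f in seq_len(cvFolds)) {
                        va <- trainIdx[folds == f]
                        tr <- trainIdx[folds != f]
                        m <- .fitAny(lapply(tensors, subsetTensor, tr),
                                     Y[tr, , drop = FALSE], p, ensemble, nu)
                        ph <- .predictAny(m, lapply(tensors, subsetTensor, va))
                        errs[f] <- mean(vapply(seq_len(tp), function(i) {
                            yv <- Y[va, i]
                            if (all(is.na(yv))) return(NA_real_)
                            rmse(yv, ph[, i])
                        }, numeric(1)), na.rm = TRUE)
                    }
                    cvTab$valRMSE[g] <- mean(errs)
                }
                best <- which.min(cvTab$valRMSE)
            } else best <- 1L
            pBest <- .paramsFromRow(grid[best, , drop = FALSE], baseParams)
            m <- .fitAny(lapply(tensors, subsetTensor, trainIdx),
                         Y[trainIdx, , drop = FALSE], pBest, ensemble, nu)
            ph <- .predictAny(m, lapply(tensors, subsetTensor, testIdx))
            yTest <- Y[testIdx, , drop = FALSE]
            rmseMat[rep_, ] <- vapply(seq_len(tp), function(i) {
                if (all(is.na(yTest[, i]))) return(NA_real_)
                rmse(yTest[, i], ph[, i])
            }, numeric(1))
            nmseVec[rep_] <- nmse(yTest, ph)
            chosen[[rep_]] <- cbind(repeat_ = rep_,
                                    grid[best, , drop = FALSE])
            cvTables[[rep_]] <- cvTab
        })
    }
    perTime <- data.frame(timePoint = tpNames,
                          rmseMean = colMeans(rmseMat, na.rm = TRUE),
                          rmseSD = apply(rmseMat, 2, sd, na.rm = TRUE))
    new("EvaluationReport", perTime = perTime,
        nmseMean = mean(nmseVec), nmseSD = sd(nmseVec),
        chosen = do.call(rbind, chosen), cvTables = cvTables,
        nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

#' @describeIn EvaluationReport-class per-time-point rMSE summary.
#' @param object an \code{EvaluationReport}.
#' @export
perTimeRMSE <- function(object) object@perTime

#' @describeIn EvaluationReport-class overall nMSE mean and SD.
#' @export
overallNMSE <- function(object)
    c(mean = object@nmseMean, sd = object@nmseSD)

#' Serialize an evaluation report to JSON
#' @param object an \linkS4class{EvaluationReport}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(object, path) {
    jsonlite::write_json(list(perTime = object@perTime,
                              nmse = list(mean = object@nmseMean,
                                          sd = object@nmseSD),
                              chosen = object@chosen,
                              nRepeats = object@nRepeats,
                              seed = object@seed),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport:", object@nRepeats, "repeat(s)\n")
    pt <- object@perTime
    for (i in seq_len(nrow(pt)))
        cat(sprintf("  %-5s rMSE = %.4f +/- %.4f\n", pt$timePoint[i],
                    pt$rmseMean[i], pt$rmseSD[i]))
    cat(sprintf("  nMSE = %.4f +/- %.4f\n", object@nmseMean, object@nmseSD))
    invisible(NULL)
})
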