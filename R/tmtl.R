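#' Hyperparameter constructor
#'
#' @param lambda CP-fit weight (default 0.1).
#' @param beta shared l1 weight on W, A, B, C (default 1e-3).
#' @param theta temporal-smoothness weight (default 0.1).
#' @param rank CP rank r (default 3).
#' @param alphas temporal mixing parameters (scalar recycled to length
#'   t - 2 at fit time; default 0, i.e. plain first-difference smoothing).
#' @param maxIter maximum outer iterations (default 500).
#' @param tol relative objective-change tolerance (default 1e-5).
#' @param seed integer seed recorded with the fit (the solver itself is
#'   deterministic given the data).
#' @param sharedFactors share one (A, B, C) across time points instead of
#'   per-time-point factors (default FALSE).
#' @return a \linkS4class{TMTLParams} object.
#' @export
tmtlParams <- function(lambda = 0.1, beta = 1e-3, theta = 0.1, rank = 3,
                       alphas = numeric(), maxIter = 500L, tol = 1e-5,
                       seed = 1L, sharedFactors = FALSE) {
    new("TMTLParams", lambda = lambda, beta = beta, theta = theta,
        rank = as.integer(rank), alphas = as.numeric(alphas),
        maxIter = as.integer(maxIter), tol = tol, seed = as.integer(seed),
        sharedFactors = sharedFactors)
}

#' Predict one sample's score from one similarity slice
#'
#' The model's prediction rule: \code{yhat = sum_ij U_ij} with
#' \code{U = (A B') o K o W o X_n} (o = elementwise product). Only the
#' strict upper triangle survives the duplicate-data mask K.
#'
#' @param A,B latent factor matrices (d x r).
#' @param W weight matrix (d x d).
#' @param K correction mask from [correctionMask()].
#' @param Xn one patient's d x d similarity slice.
#' @return scalar prediction.
#' @export
predictSample <- function(A, B, W, K, Xn) {
    d1 <- nrow(A); d2 <- nrow(B)
    if (!all(dim(W) == c(d1, d2)) || !all(dim(K) == c(d1, d2)) ||
        !all(dim(Xn) == c(d1, d2)))
        stop("shape mismatch between factors, W, K and the slice")
    sum((A %*% t(B)) * K * W * Xn)
}

# n-vector of predictions for all slices (Xmat = (d1*d2) x n unfolding).
.predictVec <- function(A, B, W, K, Xmat) {
    M <- (A %*% t(B)) * K * W
    as.vector(crossprod(Xmat, as.vector(M)))
}

#' Single-time-point objective
#'
#' \code{L_t = 1/2 ||yhat_t - y_t||^2 + lambda/2 ||X - [[A,B,C]]||_F^2 +
#' beta (||W||_1 + ||A||_1 + ||B||_1 + ||C||_1)}, with missing targets
#' excluded from the empirical term (they still contribute to the CP fit).
#'
#' @param X 3-way array or \linkS4class{SimilarityTensor}.
#' @param y length-n target vector (NA = missing).
#' @param A,B,C,W parameter matrices for this time point.
#' @param K correction mask.
#' @param lambda,beta regularization weights.
#' @return scalar objective value (>= 0).
#' @export
tmtlObjectiveSingle <- function(X, y, A, B, C, W, K, lambda, beta) {
    if (is(X, "SimilarityTensor")) X <- tensorValues(X)
    Xmat <- matrix(X, prod(dim(X)[1:2]), dim(X)[3])
    yhat <- .predictVec(A, B, W, K, Xmat)
    obs <- !is.na(y)
    emp <- 0.5 * sum((yhat[obs] - y[obs])^2)
    cp <- 0.5 * lambda * .cpResid2(sum(X^2), .unfold1(X), A, B, C)
    l1 <- beta * (sum(abs(W)) + sum(abs(A)) + sum(abs(B)) + sum(abs(C)))
    emp + cp + l1
}

#' Joint objective over all time points
#'
#' \code{sum_t L_t + theta ||W_f P(alpha)||_F^2}, where \code{W_f} is the
#' (d1*d2) x t unfolding of the weight stack.
#'
#' @inheritParams tmtlObjectiveSingle
#' @param Y n x t target matrix (NA = missing).
#' @param A,B,C lists of per-time-point factor matrices.
#' @param W d x d x t weight stack.
#' @param theta smoothness weight.
#' @param op a \linkS4class{SmoothnessOperator} for t time points.
#' @return scalar objective value (>= 0).
#' @export
tmtlObjectiveJoint <- function(X, Y, A, B, C, W, K, lambda, beta, theta, op) {
    if (is(X, "SimilarityTensor")) X <- tensorValues(X)
    t <- ncol(Y)
    tot <- 0
    for (i in seq_len(t))
        tot <- tot + tmtlObjectiveSingle(X, Y[, i], A[[i]], B[[i]], C[[i]],
                                         W[, , i], K, lambda, beta)
    Wf <- matrix(W, ncol = t)
    tot + theta * smoothnessPenalty(Wf, op)
}

# One monotone proximal-gradient step on a block: returns the updated
# block, the (possibly enlarged) curvature estimate L, and the new smooth
# value. fSmooth(x) must return the block's smooth objective.
.proxStep <- function(x, fx, grad, L, l1w, fSmooth) {
    repeat {
        xn <- softThreshold(x - grad / L, l1w / L)
        dx <- xn - x
        fn <- fSmooth(xn)
        if (fn <= fx + sum(grad * dx) + 0.5 * L * sum(dx^2) + 1e-12)
            return(list(x = xn, L = L, f = fn))
        L <- 2 * L
        if (L > 1e16) return(list(x = x, L = L, f = fx))
    }
}

#' Fit the tensor multi-task model
#'
#' Minimizes the joint objective (prediction loss + CP factorization fit
#' + l1 sparsity + generalized temporal smoothness) by block proximal
#' gradient descent. Per outer iteration the blocks are updated in the
#' order A_t, B_t, C_t (each time point) and then the whole weight stack
#' W jointly, so the smoothness coupling across time points is handled
#' exactly. Each block step uses a monotone backtracking line search, so
#' the recorded objective trace is non-increasing. Factors are
#' initialized from a short deterministic CP-ALS run on X; W starts at
#' zero, hence its support never leaves the strict upper triangle.
#'
#' @param X a \linkS4class{SimilarityTensor} or d x d x n array.
#' @param Y an n x t target matrix (NA = missing) or
#'   \linkS4class{ScoreTable}; rows are matched to the tensor's patients
#'   when both carry ids.
#' @param params a \linkS4class{TMTLParams} object.
#' @return a fitted \linkS4class{TMTLModel}.
#' @seealso [predict,TMTLModel-method], [tmtlParams()]
#' @export
fitTMTL <- function(X, Y, params = tmtlParams()) {
    tens <- NULL
    if (is(X, "SimilarityTensor")) { tens <- X; X <- tensorValues(X) }
    if (is(Y, "ScoreTable")) Y <- scoreMatrix(Y)
    Y <- as.matrix(Y)
    if (!is.null(tens) && !is.null(rownames(Y))) {
        idx <- match(tensorPatients(tens), rownames(Y))
        if (anyNA(idx))
            stop("tensor patients missing from the score table: ",
                 paste(tensorPatients(tens)[is.na(idx)], collapse = ", "))
        Y <- Y[idx, , drop = FALSE]
    }
    dms <- dim(X)
    d1 <- dms[1]; d2 <- dms[2]; n <- dms[3]; t <- ncol(Y)
    if (nrow(Y) != n) stop("Y must have one row per tensor slice")
    if (n < 2) stop("need at least 2 samples")
    if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in X")
    if (any(!is.finite(Y[!is.na(Y)]))) stop("non-finite values in Y")
    r <- params@rank
    if (r > min(d1, d2)) stop("rank exceeds min(d1, d2)")
    lambda <- params@lambda; beta <- params@beta; theta <- params@theta

    op <- buildP(t, params@alphas)
    PPt <- op@P %*% t(op@P)
    K <- correctionMask(d1, d2)
    Xmat <- matrix(X, d1 * d2, n)
    X1 <- .unfold1(X); X2 <- .unfold2(X); X3 <- .unfold3(X)
    normX2 <- sum(X^2)
    Yobs <- !is.na(Y)
    Y0 <- Y; Y0[!Yobs] <- 0

    shared <- params@sharedFactors
    fac <- .withSeed(params@seed, .cpALS(X, r, sweeps = .INIT_SWEEPS))
    A <- rep(list(fac$A), t); B <- rep(list(fac$B), t)
    C <- rep(list(fac$C), t)
    W <- array(0, dim = c(d1, d2, t))

    predAll <- function() {
        vapply(seq_len(t),
               function(i) .predictVec(A[[i]], B[[i]], W[, , i], K, Xmat),
               numeric(n))
    }
    resid <- function(yh) { E <- yh - Y0; E[!Yobs] <- 0; E }
    cpR2 <- function(i) .cpResid2(normX2, X1, A[[i]], B[[i]], C[[i]])
    jointObj <- function() {
        yh <- predAll(); E <- resid(yh)
        emp <- 0.5 * sum(E^2)
        cp <- if (lambda > 0)
            0.5 * lambda * sum(vapply(seq_len(t), cpR2, numeric(1))) else 0
        l1 <- beta * (sum(abs(W)) +
                      sum(vapply(A, function(m) sum(abs(m)), numeric(1))) +
                      sum(vapply(B, function(m) sum(abs(m)), numeric(1))) +
                      sum(vapply(C, function(m) sum(abs(m)), numeric(1))))
        sm <- theta * sum((matrix(W, ncol = t) %*% op@P)^2)
        emp + cp + l1 + sm
    }

    trace <- jointObj()
    innerW <- 25L
    LA <- rep(1, t); LB <- rep(1, t); LC <- rep(1, t); LW <- 1
    tMult <- if (shared) t else 1  # shared factors see every L_t's CP term

    iter <- 0L
    while (iter < params@maxIter) {
        iter <- iter + 1L
        LA <- pmax(LA / 2, 1e-8); LB <- pmax(LB / 2, 1e-8)
        LC <- pmax(LC / 2, 1e-8); LW <- max(LW / 2, 1e-8)

        tset <- if (shared) 1L else seq_len(t)
        for (i in tset) {
            ## --- A block ---
            Bi <- B[[i]]; Ci <- C[[i]]
            KRcb <- .khatriRao(Ci, Bi)
            XKR <- X1 %*% KRcb
            Gcb <- crossprod(Ci) * crossprod(Bi)
            fA <- function(Anew) {
                emp <- 0
                for (j in (if (shared) seq_len(t) else i)) {
                    yh <- .predictVec(Anew, B[[j]], W[, , j], K, Xmat)
                    e <- yh - Y0[, j]; e[!Yobs[, j]] <- 0
                    emp <- emp + 0.5 * sum(e^2)
                }
                cp <- normX2 - 2 * sum(Anew * XKR) +
                    sum(crossprod(Anew) * Gcb)
                emp + 0.5 * lambda * tMult * max(cp, 0)
            }
            gA <- matrix(0, d1, r)
            for (j in (if (shared) seq_len(t) else i)) {
                yh <- .predictVec(A[[i]], B[[j]], W[, , j], K, Xmat)
                e <- yh - Y0[, j]; e[!Yobs[, j]] <- 0
                SE <- matrix(Xmat %*% e, d1, d2)
                gA <- gA + (K * W[, , j] * SE) %*% B[[j]]
            }
            gA <- gA + lambda * tMult * (A[[i]] %*% Gcb - XKR)
            st <- .proxStep(A[[i]], fA(A[[i]]), gA, LA[i], beta * tMult, fA)
            LA[i] <- st$L
            if (shared) A <- rep(list(st$x), t) else A[[i]] <- st$x

            ## --- B block ---
            Ai <- A[[i]]; Ci <- C[[i]]
            KRca <- .khatriRao(Ci, Ai)
            XKR2 <- X2 %*% KRca
            Gca <- crossprod(Ci) * crossprod(Ai)
            fB <- function(Bnew) {
                emp <- 0
                for (j in (if (shared) seq_len(t) else i)) {
                    yh <- .predictVec(A[[j]], Bnew, W[, , j], K, Xmat)
                    e <- yh - Y0[, j]; e[!Yobs[, j]] <- 0
                    emp <- emp + 0.5 * sum(e^2)
                }
                cp <- normX2 - 2 * sum(Bnew * XKR2) +
                    sum(crossprod(Bnew) * Gca)
                emp + 0.5 * lambda * tMult * max(cp, 0)
            }
            gB <- matrix(0, d2, r)
            for (j in (if (shared) seq_len(t) else i)) {
                yh <- .predictVec(A[[j]], B[[i]], W[, , j], K, Xmat)
                e <- yh - Y0[, j]; e[!Yobs[, j]] <- 0
                SE <- matrix(Xmat %*% e, d1, d2)
                gB <- gB + crossprod(K * W[, , j] * SE, A[[j]])
            }
            gB <- gB + lambda * tMult * (B[[i]] %*% Gca - XKR2)
            st <- .proxStep(B[[i]], fB(B[[i]]), gB, LB[i], beta * tMult, fB)
            LB[i] <- st$L
            if (shared) B <- rep(list(st$x), t) else B[[i]] <- st$x

            ## --- C block (CP term only) ---
            Ai <- A[[i]]; Bi <- B[[i]]
            KRba <- .khatriRao(Bi, Ai)
            XKR3 <- X3 %*% KRba
            Gba <- crossprod(Bi) * crossprod(Ai)
            fC <- function(Cnew) {
                cp <- normX2 - 2 * sum(Cnew * XKR3) +
                    sum(crossprod(Cnew) * Gba)
                0.5 * lambda * tMult * max(cp, 0)
            }
            gC <- lambda * tMult * (C[[i]] %*% Gba - XKR3)
            st <- .proxStep(C[[i]], fC(C[[i]]), gC, LC[i], beta * tMult, fC)
            LC[i] <- st$L
            if (shared) C <- rep(list(st$x), t) else C[[i]] <- st$x
        }

        ## --- W block (all time points jointly; several inner proximal
        ## steps since this block dominates the fit) ---
        fW <- function(Wnew) {
            emp <- 0
            for (j in seq_len(t)) {
                yh <- .predictVec(A[[j]], B[[j]], Wnew[, , j], K, Xmat)
                e <- yh - Y0[, j]; e[!Yobs[, j]] <- 0
                emp <- emp + 0.5 * sum(e^2)
            }
            emp + theta * sum((matrix(Wnew, ncol = t) %*% op@P)^2)
        }
        gradW <- function(Wat) {
            g <- array(0, dim = c(d1, d2, t))
            for (j in seq_len(t)) {
                yh <- .predictVec(A[[j]], B[[j]], Wat[, , j], K, Xmat)
                e <- yh - Y0[, j]; e[!Yobs[, j]] <- 0
                SE <- matrix(Xmat %*% e, d1, d2)
                g[, , j] <- (A[[j]] %*% t(B[[j]])) * K * SE
            }
            if (theta > 0)
                g <- g + array(2 * theta * (matrix(Wat, ncol = t) %*% PPt),
                               dim = dim(g))
            g
        }
        ## monotone FISTA: extrapolated proximal steps, falling back to a
        ## plain step whenever the composite objective would increase
        FWcur <- fW(W) + beta * sum(abs(W))
        Wprev <- W
        tk <- 1
        for (kInner in seq_len(innerW)) {
            tkNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
            V <- W + ((tk - 1) / tkNew) * (W - Wprev)
            fV <- fW(V)
            stV <- .proxStep(V, fV, gradW(V), LW, beta, fW)
            LW <- stV$L
            FWcand <- stV$f + beta * sum(abs(stV$x))
            if (FWcand <= FWcur + 1e-12) {
                Wprev <- W; W <- stV$x; FWcur <- FWcand; tk <- tkNew
            } else {
                st <- .proxStep(W, fW(W), gradW(W), LW, beta, fW)
                LW <- st$L
                moved <- sum((st$x - W)^2)
                Wprev <- W; W <- st$x
                FWcur <- st$f + beta * sum(abs(st$x))
                tk <- 1
                if (moved <= 1e-20) break
            }
        }

        obj <- jointObj()
        prev <- trace[length(trace)]
        trace <- c(trace, obj)
        if (abs(prev - obj) <= params@tol * max(1, abs(prev))) break
    }

    bn <- if (!is.null(tens)) tens@biomarkerNames else
        paste0("b", seq_len(d1))
    new("TMTLModel", facA = A, facB = B, facC = C, W = W, K = K,
        params = params,
        objective = trace,
        interval = if (!is.null(tens)) tens@interval else c(NA, NA),
        biomarkerNames = bn,
        patientIDs = if (!is.null(tens)) tensorPatients(tens) else
            as.character(seq_len(n)),
        timeLabels = if (!is.null(colnames(Y))) colnames(Y) else
            paste0("t", seq_len(t)),
        fitted = TRUE)
}

#' Predict scores for new similarity slices
#'
#' Applies the prediction rule per sample and time point using the fitted
#' A_t, B_t, W_t and the mask K; the sample factors C_t are part of the
#' training-time CP fit only and are not needed for new samples.
#'
#' @param object a fitted \linkS4class{TMTLModel}.
#' @param newdata a \linkS4class{SimilarityTensor} or d x d x n array
#'   with the training biomarker dimensions.
#' @param ... ignored.
#' @return n x t matrix of predicted scores.
#' @export
setMethod("predict", "TMTLModel", function(object, newdata, ...) {
    if (!object@fitted) stop("model is not fitted")
    pats <- NULL
    if (is(newdata, "SimilarityTensor")) {
        pats <- tensorPatients(newdata)
        newdata <- tensorValues(newdata)
    }
    dms <- dim(newdata)
    if (length(dms) != 3L || !all(dms[1:2] == dim(object@W)[1:2]))
        stop("newdata dimensions do not match the training tensor")
    Xmat <- matrix(newdata, dms[1] * dms[2], dms[3])
    t <- length(object@timeLabels)
    out <- vapply(seq_len(t), function(i)
        .predictVec(object@facA[[i]], object@facB[[i]], object@W[, , i],
                    object@K, Xmat), numeric(dms[3]))
    out <- matrix(out, nrow = dms[3])
    dimnames(out) <- list(pats, object@timeLabels)
    out
})

#' @describeIn TMTLModel-class the d x d x t sparse weight stack.
#' @param object a \code{TMTLModel}.
#' @export
weightStack <- function(object) object@W

#' @describeIn TMTLModel-class the objective trace (one value after
#'   initialization and per outer iteration; non-increasing).
#' @export
objectiveTrace <- function(object) object@objective

#' @describeIn TMTLModel-class per-time-point latent factors as a list
#'   with elements \code{A}, \code{B}, \code{C}.
#' @export
latentFactors <- function(object)
    list(A = object@facA, B = object@facB, C = object@facC)

setMethod("show", "TMTLModel", function(object) {
    d <- dim(object@W)
    cat("TMTLModel: d =", d[1], "| t =", d[3],
        "| rank =", object@params@rank, "\n")
    cat("  interval:", paste(object@interval, collapse = "->"),
        "| n(train) =", length(object@patientIDs), "\n")
    nz <- sum(object@W != 0)
    cat("  nonzero weights:", nz, "| iterations:",
        length(object@objective) - 1L, "| final objective:",
        signif(utils::tail(object@objective, 1), 6), "\n")
    invisible(NULL)
})
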