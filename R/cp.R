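#' Reconstruct a tensor from CP factors
#'
#' \code{X[i,j,k] = sum_q A[i,q] B[j,q] C[k,q]}: the sum of r rank-one
#' outer products \code{a_q o b_q o c_q}.
#'
#' @param A,B,C factor matrices with a common number of columns r.
#' @return array of dim \code{c(nrow(A), nrow(B), nrow(C))}.
#' @export
cpReconstruct <- function(A, B, C) {
    A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
    if (ncol(A) != ncol(B) || ncol(B) != ncol(C))
        stop("factor matrices must share the same rank")
    M1 <- A %*% t(.khatriRao(C, B))   # mode-1 unfolding
    array(M1, dim = c(nrow(A), nrow(B), nrow(C)))
}

# <X, [[A,B,C]]> and ||[[A,B,C]]||_F^2 without forming the full tensor.
.cpInner <- function(X1, KRcb, A) sum(A * (X1 %*% KRcb))
.cpNorm2 <- function(A, B, C)
    sum(crossprod(A) * crossprod(B) * crossprod(C))

# Squared CP residual ||X - [[A,B,C]]||_F^2 given precomputed pieces.
.cpResid2 <- function(normX2, X1, A, B, C) {
    KRcb <- .khatriRao(C, B)
    r2 <- normX2 - 2 * .cpInner(X1, KRcb, A) + .cpNorm2(A, B, C)
    max(r2, 0)
}

# ALS sweeps used when warm-starting the solver's factors (and by the
# synthetic-data forward model, which mirrors the warm start).
.INIT_SWEEPS <- 5L

# Deterministic CP-ALS: HOSVD-style init (leading singular vectors of each
# unfolding, sign-fixed so the largest-magnitude loading is positive),
# then ALS sweeps with a small ridge; column norms balanced equally across
# the three factors at the end. Deterministic given X, so identical inputs
# give identical factors.
.cpALS <- function(X, r, sweeps = 10L, ridge = 1e-8) {
    dms <- dim(X)
    if (r > min(dms[1], dms[2]))
        stop("rank exceeds min(d1, d2)")
    X1 <- .unfold1(X); X2 <- .unfold2(X); X3 <- .unfold3(X)
    init <- function(M, r) {
        sv <- svd(M, nu = r, nv = 0)
        U <- sv$u[, seq_len(r), drop = FALSE]
        for (q in seq_len(r)) {
            m <- which.max(abs(U[, q]))
            if (U[m, q] < 0) U[, q] <- -U[, q]
        }
        U
    }
    A <- init(X1, r); B <- init(X2, r)
    C <- init(if (nrow(X3) >= r) X3 else rbind(X3, X3), r)[seq_len(dms[3]), ,
                                                           drop = FALSE]
    solveFac <- function(Munf, KR, G1, G2) {
        G <- crossprod(G1) * crossprod(G2)
        t(solve(G + ridge * diag(r), t(Munf %*% KR)))
    }
    for (s in seq_len(sweeps)) {
        A <- solveFac(X1, .khatriRao(C, B), C, B)
        B <- solveFac(X2, .khatriRao(C, A), C, A)
        C <- solveFac(X3, .khatriRao(B, A), B, A)
    }
    # balance: give each component equal norm across A, B, C
    for (q in seq_len(r)) {
        na <- sqrt(sum(A[, q]^2)); nb <- sqrt(sum(B[, q]^2))
        nc <- sqrt(sum(C[, q]^2))
        g <- (na * nb * nc)^(1 / 3)
        if (na > 0) A[, q] <- A[, q] / na * g
        if (nb > 0) B[, q] <- B[, q] / nb * g
        if (nc > 0) C[, q] <- C[, q] / nc * g
    }
    list(A = A, B = B, C = C)
}

#' CP (CANDECOMP/PARAFAC) decomposition by alternating least squares
#'
#' Decomposes a 3-way array into r rank-one components. Initialization is
#' deterministic (leading singular vectors of the mode unfoldings), so
#' repeated calls on the same tensor give identical factors.
#'
#' @param X numeric 3-way array or \linkS4class{SimilarityTensor}.
#' @param rank number of components r (<= min(d1, d2)).
#' @param sweeps ALS sweeps (default 10).
#' @return list with factor matrices \code{A}, \code{B}, \code{C} and the
#'   relative reconstruction error \code{relErr}.
#' @export
cpDecompose <- function(X, rank, sweeps = 10L) {
    if (is(X, "SimilarityTensor")) X <- tensorValues(X)
    fac <- .cpALS(X, rank, sweeps = sweeps)
    normX2 <- sum(X^2)
    r2 <- .cpResid2(normX2, .unfold1(X), fac$A, fac$B, fac$C)
    fac$relErr <- sqrt(r2 / max(normX2, .Machine$double.eps))
    fac
}
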