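# Mean Gregorian month, days. Used to convert exam-date gaps to months for
# the velocity denominator ("per month" without a defined month length).
.DAYS_PER_MONTH <- 30.4375

.monthsBetween <- function(early, late) {
    as.numeric(difftime(late, early, units = "days")) / .DAYS_PER_MONTH
}

# Khatri-Rao (column-wise Kronecker) product; row index of Q varies fastest,
# matching R's column-major tensor unfoldings.
.khatriRao <- function(P, Q) {
    np <- nrow(P); nq <- nrow(Q)
    P[rep(seq_len(np), each = nq), , drop = FALSE] *
        Q[rep.int(seq_len(nq), np), , drop = FALSE]
}

# Mode unfoldings of a d1 x d2 x n array (column-major; lower modes fastest).
.unfold1 <- function(X) matrix(X, dim(X)[1], dim(X)[2] * dim(X)[3])
.unfold2 <- function(X) matrix(aperm(X, c(2, 1, 3)), dim(X)[2],
                               dim(X)[1] * dim(X)[3])
.unfold3 <- function(X) t(matrix(X, dim(X)[1] * dim(X)[2], dim(X)[3]))

# Evaluate code under a temporary RNG state.
.withSeed <- function(seed, expr) {
    if (!is.null(seed) && !is.na(seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        } else {
            on.exit(rm(".Random.seed", envir = globalenv()))
        }
        set.seed(as.integer(seed))
    }
    force(expr)
}

#' Elementwise soft-thresholding
#'
#' The proximal operator of \code{tau * ||.||_1}:
#' \code{sign(z) * max(|z| - tau, 0)} applied entrywise. Used for every
#' l1-penalized block update of the solver.
#'
#' @param Z numeric vector, matrix or array.
#' @param tau non-negative threshold.
#' @return object shaped like \code{Z}.
#' @examples
#' softThreshold(c(3, -0.5, 0), 1)
#' @export
softThreshold <- function(Z, tau) {
    stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0)
    sign(Z) * pmax(abs(Z) - tau, 0)
}

#' Duplicate-data correction mask
#'
#' Strictly upper-triangular matrix of ones. Because each similarity slice
#' is symmetric, every biomarker pair appears twice; masking with K keeps
#' exactly one copy of each off-diagonal pair (and drops the zero
#' diagonal), so for a symmetric M with zero diagonal
#' \code{sum(K * M) == sum(M) / 2}.
#'
#' @param d1,d2 matrix dimensions (>= 1).
#' @return binary d1 x d2 matrix with \code{K[i, j] = 1} iff \code{j > i}.
#' @examples
#' correctionMask(3, 3)
#' @export
correctionMask <- function(d1, d2) {
    stopifnot(d1 >= 1, d2 >= 1)
    K <- matrix(0, d1, d2)
    K[upper.tri(K)] <- 1
    K
}
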