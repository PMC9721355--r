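#' First-difference matrix H
#'
#' The t x (t-1) matrix with \code{H[i,i] = 1}, \code{H[i+1,i] = -1} and 0
#' elsewhere, so column i of \code{W \%*\% H} is the plain progression
#' \code{delta w_i = w_i - w_{i+1}} between consecutive time points.
#'
#' @param t number of prediction time points (>= 2).
#' @return t x (t-1) matrix.
#' @examples
#' buildH(3)
#' @export
buildH <- function(t) {
    t <- as.integer(t)
    if (t < 2L) stop("need at least 2 time points")
    H <- matrix(0, t, t - 1L)
    idx <- seq_len(t - 1L)
    H[cbind(idx, idx)] <- 1
    H[cbind(idx + 1L, idx)] <- -1
    H
}

#' Generalized temporal-smoothness operator P(alpha)
#'
#' \code{P = H D_1(alpha_1) ... D_{t-2}(alpha_{t-2})}, where each
#' \code{D_i} is the identity except \code{D_i[i, i+1] = alpha_i} and
#' \code{D_i[i+1, i+1] = 1 - alpha_i}. Column i of \code{W \%*\% P}
#' realizes the recursion \code{Delta w_1 = delta w_1},
#' \code{Delta w_i = alpha_{i-1} Delta w_{i-1} + (1 - alpha_{i-1}) delta
#' w_i}: each stage's penalized progression blends the plain progression
#' with all preceding ones, the way a clinician weighs current against
#' earlier symptoms. With all alphas 0, \code{P = H} (plain
#' first-difference smoothness).
#'
#' @param t number of prediction time points (>= 2).
#' @param alphas numeric of length \code{t - 2} (or a scalar, recycled),
#'   each in [0, 1]. Empty/omitted means all zeros.
#' @return a \linkS4class{SmoothnessOperator}.
#' @export
buildP <- function(t, alphas = numeric()) {
    t <- as.integer(t)
    if (t < 2L) stop("need at least 2 time points")
    nA <- max(t - 2L, 0L)
    if (length(alphas) == 0L) alphas <- rep(0, nA)
    if (length(alphas) == 1L && nA > 1L) alphas <- rep(alphas, nA)
    if (length(alphas) != nA)
        stop("alphas must have length t - 2 = ", nA)
    if (nA && (min(alphas) < 0 || max(alphas) > 1))
        stop("alphas must lie in [0, 1]")
    H <- buildH(t)
    Dlist <- vector("list", nA)
    P <- H
    for (i in seq_len(nA)) {
        D <- diag(t - 1L)
        D[i, i + 1L] <- alphas[i]
        D[i + 1L, i + 1L] <- 1 - alphas[i]
        Dlist[[i]] <- D
        P <- P %*% D
    }
    new("SmoothnessOperator", tPoints = t, alphas = as.numeric(alphas),
        H = H, D = Dlist, P = P)
}

#' Temporal-smoothness penalty
#'
#' The squared Frobenius norm \code{||W_f P(alpha)||_F^2} of the unfolded
#' weight matrix times the smoothness operator. Zero iff all penalized
#' progressions vanish, e.g. when every time point shares the same
#' weights.
#'
#' @param Wf (d1*d2) x t unfolding of the weight stack (or any matrix
#'   with t columns).
#' @param op a \linkS4class{SmoothnessOperator} built for t time points.
#' @return non-negative scalar.
#' @export
smoothnessPenalty <- function(Wf, op) {
    stopifnot(is(op, "SmoothnessOperator"))
    Wf <- as.matrix(Wf)
    if (ncol(Wf) != op@tPoints)
        stop("Wf has ", ncol(Wf), " columns but the operator expects ",
             op@tPoints)
    sum((Wf %*% op@P)^2)
}

setMethod("show", "SmoothnessOperator", function(object) {
    cat("SmoothnessOperator: t =", object@tPoints, "| alphas =",
        if (length(object@alphas)) paste(signif(object@alphas, 3),
                                         collapse = " ") else "(none)", "\n")
    invisible(NULL)
})
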