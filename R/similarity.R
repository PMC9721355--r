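#' Morphological variation vector of one biomarker
#'
#' From two consecutive scans of the same biomarker: the dimensionless
#' rate of change \code{(x_late - x_early) / x_early} and the velocity
#' \code{(x_late - x_early) / months}, with the month length fixed at
#' 30.4375 days (mean Gregorian month).
#'
#' @param xEarly,xLate biomarker values at the earlier/later visit.
#' @param tEarly,tLate exam \code{Date}s; \code{tLate} must be after
#'   \code{tEarly}.
#' @return numeric \code{c(rate, velocity)}.
#' @examples
#' variationVector(10, 9, as.Date("2010-01-01"),
#'                 as.Date("2010-01-01") + 6 * 30.4375)
#' @export
variationVector <- function(xEarly, xLate, tEarly, tLate) {
    months <- .monthsBetween(tEarly, tLate)
    if (any(months <= 0)) stop("non-positive time gap between visits")
    if (any(xEarly == 0))
        stop("zero value at the earlier visit: rate of change undefined")
    c(rate = (xLate - xEarly) / xEarly,
      velocity = (xLate - xEarly) / months)
}

#' Variation vectors of a patient cohort over a scan interval
#'
#' @param cohort a preprocessed \linkS4class{LongitudinalCohort} (no
#'   missing cells; every patient has both visits of the interval).
#' @param interval ordered visit pair, e.g. \code{c("BL", "M06")}.
#' @return list of d x 2 matrices (columns rate, velocity), one per
#'   patient, names = patient ids (ordered as first encountered).
#' @export
variationVectors <- function(cohort, interval = c("BL", "M06")) {
    stopifnot(length(interval) == 2L, all(interval %in% .VISIT_LEVELS))
    cd <- colData(cohort)
    vals <- assay(cohort)
    if (anyNA(vals)) stop("cohort has missing cells; impute first")
    pats <- unique(cd$patientID)
    out <- vector("list", length(pats))
    names(out) <- pats
    for (p in pats) {
        iE <- which(cd$patientID == p & cd$visitCode == interval[1])
        iL <- which(cd$patientID == p & cd$visitCode == interval[2])
        if (length(iE) != 1L || length(iL) != 1L)
            stop("patient ", p, " lacks a ", paste(interval, collapse = "->"),
                 " scan pair; filter the cohort first")
        xE <- vals[, iE]; xL <- vals[, iL]
        if (any(xE == 0))
            stop("patient ", p, ", biomarker(s) ",
                 paste(rownames(vals)[xE == 0], collapse = ", "),
                 ": zero value at ", interval[1],
                 "; rate of change undefined")
        months <- .monthsBetween(cd$examDate[iE], cd$examDate[iL])
        if (months <= 0) stop("patient ", p, ": non-positive scan gap")
        out[[p]] <- cbind(rate = (xL - xE) / xE,
                          velocity = (xL - xE) / months)
    }
    out
}

# Ridge-regularized covariance: S + eps * mean(diag(S)) * I. A fully
# degenerate S (zero trace, e.g. all variation vectors identical) falls
# back to the identity -- any S gives distance 0 between identical vectors.
.regularizeCovariance <- function(S, eps = 1e-6) {
    tr <- sum(diag(S))
    p <- nrow(S)
    if (!is.finite(tr) || tr <= .Machine$double.eps) return(diag(p))
    S + eps * (tr / p) * diag(p)
}

#' Mahalanobis distance between two variation vectors
#'
#' \code{sqrt((x_i - x_j)' S^{-1} (x_i - x_j))}: scale-free similarity of
#' two biomarkers' variation trends under covariance \code{S}. With
#' \code{S} the identity it reduces to the Euclidean distance.
#'
#' @param xi,xj numeric vectors of equal length.
#' @param S covariance matrix (symmetric positive definite after the ridge
#'   regularization applied when \code{regularize = TRUE}).
#' @param regularize apply the \code{S + eps * mean(diag(S)) * I} ridge
#'   (default TRUE).
#' @return non-negative scalar, symmetric in \code{xi} and \code{xj}.
#' @examples
#' mahalanobisDistance(c(3, 4), c(0, 0), diag(2))  # 5
#' @export
mahalanobisDistance <- function(xi, xj, S, regularize = TRUE) {
    stopifnot(length(xi) == length(xj), nrow(S) == length(xi))
    if (regularize) S <- .regularizeCovariance(S)
    ch <- tryCatch(chol(S), error = function(e)
        stop("covariance matrix is singular after regularization"))
    z <- backsolve(ch, xi - xj, transpose = TRUE)
    sqrt(sum(z^2))
}

# Pairwise Mahalanobis distances among the rows of V (d x p) given a
# Cholesky factor of S; returns a symmetric d x d matrix, zero diagonal.
.pairwiseMahalanobis <- function(V, chS) {
    Z <- V %*% backsolve(chS, diag(ncol(V)))  # whiten: rows z_i = S^{-1/2} v_i
    D2 <- outer(rowSums(Z^2), rowSums(Z^2), "+") - 2 * tcrossprod(Z)
    D2[D2 < 0] <- 0
    D <- sqrt(D2)
    diag(D) <- 0
    D
}

#' Build the biomarker-pair similarity tensor
#'
#' For each patient, computes the d x 2 variation vectors over the given
#' scan interval and the d x d matrix of pairwise Mahalanobis distances
#' between them; the n slices are stacked into a d x d x n tensor. Slices
#' are symmetric with zero diagonal. With \code{normalize = TRUE}
#' (default) each slice is min-max scaled to [0, 1].
#'
#' @param cohort preprocessed \linkS4class{LongitudinalCohort}.
#' @param interval ordered visit pair, default \code{c("BL", "M06")}.
#' @param covarianceScope \code{"per-patient"} (covariance of that
#'   patient's d variation vectors; default) or \code{"pooled"} (all
#'   patients' vectors).
#' @param normalize min-max scale each slice to [0, 1] (default TRUE).
#' @return a \linkS4class{SimilarityTensor}.
#' @export
buildSimilarityTensor <- function(cohort, interval = c("BL", "M06"),
                                  covarianceScope = c("per-patient", "pooled"),
                                  normalize = TRUE) {
    covarianceScope <- match.arg(covarianceScope)
    vv <- variationVectors(cohort, interval)
    d <- nrow(vv[[1]])
    if (d < 2) stop("need at least 2 biomarkers")
    n <- length(vv)
    X <- array(0, dim = c(d, d, n))
    chPooled <- NULL
    if (covarianceScope == "pooled") {
        S <- .regularizeCovariance(cov(do.call(rbind, vv)))
        chPooled <- chol(S)
    }
    for (k in seq_len(n)) {
        ch <- chPooled
        if (is.null(ch))
            ch <- chol(.regularizeCovariance(cov(vv[[k]])))
        D <- .pairwiseMahalanobis(vv[[k]], ch)
        if (normalize) {
            rng <- range(D)
            if (rng[2] > rng[1]) D <- (D - rng[1]) / (rng[2] - rng[1])
        }
        X[, , k] <- D
    }
    new("SimilarityTensor", values = X, interval = interval,
        biomarkerNames = rownames(vv[[1]]), patientIDs = names(vv),
        normalized = normalize, covarianceScope = covarianceScope)
}

#' @describeIn SimilarityTensor-class the d x d x n array of distances.
#' @param x a \code{SimilarityTensor}.
#' @export
tensorValues <- function(x) x@values

#' @describeIn SimilarityTensor-class the ordered visit pair.
#' @export
tensorInterval <- function(x) x@interval

#' @describeIn SimilarityTensor-class patient ids along the third mode.
#' @export
tensorPatients <- function(x) x@patientIDs

setMethod("show", "SimilarityTensor", function(object) {
    d <- dim(object@values)
    cat("SimilarityTensor ", d[1], "x", d[2], "x", d[3], " (",
        paste(object@interval, collapse = "->"), "), ",
        object@covarianceScope, " covariance",
        if (object@normalized) ", slices scaled to [0,1]", "\n", sep = "")
    invisible(NULL)
})

#' Subset a similarity tensor by patient
#' @param x a \linkS4class{SimilarityTensor}.
#' @param patients integer indices or patient ids.
#' @return a \linkS4class{SimilarityTensor} with the selected slices.
#' @export
subsetTensor <- function(x, patients) {
    if (is.character(patients)) {
        idx <- match(patients, x@patientIDs)
        if (anyNA(idx)) stop("unknown patient id(s)")
    } else idx <- patients
    new("SimilarityTensor",
        values = x@values[, , idx, drop = FALSE], interval = x@interval,
        biomarkerNames = x@biomarkerNames, patientIDs = x@patientIDs[idx],
        normalized = x@normalized, covarianceScope = x@covarianceScope)
}
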