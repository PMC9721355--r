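.intervalLabel <- function(tens) paste(tens@interval, collapse = ":")

#' Fit a gradient-boosting ensemble over consecutive scan intervals
#'
#' Stage 1 fits the score matrix from the first interval's similarity
#' tensor; each later stage fits a fresh tensor multi-task model to the
#' residuals of the cumulative prediction, using that interval's tensor.
#' With shrinkage \code{nu}, the cumulative prediction adds
#' \code{nu * prediction_s} per stage (the first stage is unshrunk unless
#' \code{shrinkFirst}). This is the dynamic-prediction workflow: each new
#' MRI detection adds one stage.
#'
#' @param tensors ordered list of \linkS4class{SimilarityTensor}s
#'   (chronological intervals, e.g. BL:M06, M06:M12, M12:M24) sharing the
#'   same patients in the same order.
#' @param Y n x t target matrix or \linkS4class{ScoreTable}.
#' @param params a \linkS4class{TMTLParams} shared by all stages.
#' @param nu shrinkage in (0, 1], default 1 (pure residual fitting).
#' @param shrinkFirst also shrink the first stage (default FALSE).
#' @return a \linkS4class{BoostingEnsemble}.
#' @export
fitEnsemble <- function(tensors, Y, params = tmtlParams(), nu = 1,
                        shrinkFirst = FALSE) {
    if (is(tensors, "SimilarityTensor")) tensors <- list(tensors)
    stopifnot(length(tensors) >= 1L)
    pats <- tensorPatients(tensors[[1]])
    for (tt in tensors)
        if (!identical(tensorPatients(tt), pats))
            stop("all stage tensors must share the same patient set and order")
    if (is(Y, "ScoreTable")) Y <- scoreMatrix(Y)
    Y <- as.matrix(Y)
    if (!is.null(rownames(Y))) {
        idx <- match(pats, rownames(Y))
        if (anyNA(idx)) stop("tensor patients missing from the score table")
        Y <- Y[idx, , drop = FALSE]
    }
    stages <- vector("list", length(tensors))
    R <- Y
    for (s in seq_along(tensors)) {
        stages[[s]] <- fitTMTL(tensors[[s]], R, params)
        w <- if (s == 1L && !shrinkFirst) 1 else nu
        pred <- predict(stages[[s]], tensors[[s]])
        R <- R - w * pred
    }
    new("BoostingEnsemble", stages = stages,
        intervals = vapply(tensors, .intervalLabel, character(1)),
        nu = nu, shrinkFirst = shrinkFirst, patientIDs = pats,
        timeLabels = stages[[1]]@timeLabels)
}

#' Cumulative ensemble prediction
#'
#' Sums the (shrunken) predictions of the first \code{uptoStage} stages,
#' so a patient with only s scans available gets the best forecast those
#' scans support; passing more stages as new scans arrive sharpens it.
#'
#' @param ens a \linkS4class{BoostingEnsemble}.
#' @param tensors list of \linkS4class{SimilarityTensor}s (or arrays),
#'   one per used stage, in stage order.
#' @param uptoStage number of stages to accumulate (default: all).
#' @return n x t matrix of predictions.
#' @export
predictEnsemble <- function(ens, tensors, uptoStage = length(ens@stages)) {
    if (is(tensors, "SimilarityTensor")) tensors <- list(tensors)
    uptoStage <- as.integer(uptoStage)
    if (uptoStage < 1L || uptoStage > length(ens@stages))
        stop("uptoStage must be between 1 and ", length(ens@stages))
    if (length(tensors) < uptoStage)
        stop("missing tensor for a requested stage")
    out <- NULL
    for (s in seq_len(uptoStage)) {
        w <- if (s == 1L && !ens@shrinkFirst) 1 else ens@nu
        p <- w * predict(ens@stages[[s]], tensors[[s]])
        out <- if (is.null(out)) p else out + p
    }
    out
}

#' @describeIn BoostingEnsemble-class the per-stage fitted models.
#' @param object a \code{BoostingEnsemble}.
#' @export
ensembleStages <- function(object) object@stages

setMethod("show", "BoostingEnsemble", function(object) {
    cat("BoostingEnsemble:", length(object@stages), "stage(s) [",
        paste(object@intervals, collapse = ", "), "], nu =", object@nu, "\n")
    invisible(NULL)
})
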