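#' @import methods
#' @importFrom stats cov sd rnorm runif predict quantile
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.VISIT_LEVELS <- c("BL", "M06", "M12", "M24")
.GROUP_LEVELS <- c("AD", "MCI", "CN")
.SCORE_POINTS <- c("M12", "M24", "M36", "M48")
.CATEGORIES <- c("CV", "SV", "SA", "TA", "TS")
.SCORE_RANGES <- list(MMSE = c(0, 30), `ADAS-Cog` = c(0, 70))

#' Longitudinal biomarker cohort
#'
#' A \linkS4class{SummarizedExperiment} holding one column per
#' (patient, visit) record and one row per biomarker. The single assay
#' \code{"biomarkers"} stores measurement values (\code{NA} = missing);
#' \code{colData} carries \code{patientID}, \code{visitCode}
#' (\code{BL}, \code{M06}, \code{M12}, \code{M24}), \code{examDate} and
#' diagnosis \code{group} (\code{AD}, \code{MCI}, \code{CN}); rowData
#' carries the biomarker \code{category} (one of CV, SV, SA, TA, TS:
#' cortical volume, white-matter volume, surface area, mean cortical
#' thickness, SD of cortical thickness).
#'
#' @seealso [LongitudinalCohort()], [loadCohort()], [filterFeatures()]
#' @export
setClass("LongitudinalCohort", contains = "SummarizedExperiment")

setValidity("LongitudinalCohort", function(object) {
    cd <- colData(object)
    need <- c("patientID", "visitCode", "examDate", "group")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    if (!all(as.character(cd$visitCode) %in% .VISIT_LEVELS))
        return("visitCode values must be one of BL, M06, M12, M24")
    if (!all(as.character(cd$group) %in% .GROUP_LEVELS))
        return("group values must be one of AD, MCI, CN")
    key <- paste(cd$patientID, cd$visitCode)
    if (anyDuplicated(key))
        return(paste("duplicated (patient, visit) records:",
                     paste(unique(key[duplicated(key)]), collapse = ", ")))
    TRUE
})

#' Cognitive score table
#'
#' Scores at the prediction time points (M12, M24, M36, M48), one row per
#' patient; \code{NA} marks a missing assessment. \code{scoreKind} is
#' \code{"MMSE"} (range 0-30), \code{"ADAS-Cog"} (range 0-70) or any
#' other label (then no range check applies).
#'
#' @slot scores numeric matrix, patients x time points, rownames = patient
#'   ids, colnames = time-point labels.
#' @slot scoreKind single character label.
#' @seealso [ScoreTable()], [filterScoreFollowups()]
#' @export
setClass("ScoreTable",
         representation(scores = "matrix", scoreKind = "character"))

setValidity("ScoreTable", function(object) {
    s <- object@scores
    if (!is.numeric(s)) return("scores must be a numeric matrix")
    if (nrow(s) > 0 && is.null(rownames(s)))
        return("scores must have patient rownames")
    if (anyDuplicated(rownames(s))) return("duplicated patient ids")
    if (ncol(s) > 0 && is.null(colnames(s)))
        return("scores must have time-point colnames")
    if (length(object@scoreKind) != 1L) return("scoreKind must be length 1")
    TRUE
})

#' Biomarker-pair similarity tensor
#'
#' A d x d x n array whose slice k is the symmetric matrix of Mahalanobis
#' distances between patient k's biomarker variation vectors over one scan
#' interval. Slices have zero diagonal and non-negative entries; when
#' \code{normalized} each slice is min-max scaled to [0, 1].
#'
#' @slot values numeric array d x d x n.
#' @slot interval character(2), e.g. \code{c("BL", "M06")}.
#' @slot biomarkerNames character(d).
#' @slot patientIDs character(n).
#' @slot normalized logical flag.
#' @slot covarianceScope \code{"per-patient"} or \code{"pooled"}.
#' @seealso [buildSimilarityTensor()]
#' @export
setClass("SimilarityTensor",
         representation(values = "array", interval = "character",
                        biomarkerNames = "character", patientIDs = "character",
                        normalized = "logical", covarianceScope = "character"))

setValidity("SimilarityTensor", function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be a 3-way array")
    d1 <- dim(v)[1]; d2 <- dim(v)[2]; n <- dim(v)[3]
    if (d1 != d2) return("slices must be square (d1 == d2)")
    if (length(object@biomarkerNames) != d1)
        return("biomarkerNames length must equal d")
    if (length(object@patientIDs) != n)
        return("patientIDs length must equal number of slices")
    if (anyNA(v) || any(!is.finite(v))) return("tensor entries must be finite")
    if (min(v) < -1e-8) return("tensor entries must be non-negative")
    for (k in seq_len(n)) {
        sl <- v[, , k]
        if (max(abs(sl - t(sl))) > 1e-8)
            return(sprintf("slice %d is not symmetric", k))
        if (max(abs(diag(sl))) > 1e-8)
            return(sprintf("slice %d has nonzero diagonal", k))
    }
    if (length(object@interval) != 2L) return("interval must be length 2")
    TRUE
})

#' Generalized temporal-smoothness operator
#'
#' Holds the first-difference matrix H (t x (t-1)), the mixing matrices
#' D_i(alpha_i) and their product P(alpha) = H D_1 ... D_{t-2}. Column i of
#' W P is the blended progression Delta w_i, which mixes the current
#' stage's weight change with all preceding changes through the alphas.
#'
#' @slot tPoints integer number of prediction time points t (>= 2).
#' @slot alphas numeric(t-2), each in [0, 1].
#' @slot H t x (t-1) first-difference matrix.
#' @slot D list of t-2 mixing matrices, each (t-1) x (t-1).
#' @slot P t x (t-1) product matrix.
#' @seealso [buildP()], [smoothnessPenalty()]
#' @export
setClass("SmoothnessOperator",
         representation(tPoints = "integer", alphas = "numeric",
                        H = "matrix", D = "list", P = "matrix"))

setValidity("SmoothnessOperator", function(object) {
    t <- object@tPoints
    if (t < 2L) return("need at least 2 time points")
    if (length(object@alphas) != max(t - 2L, 0L))
        return("alphas must have length t - 2")
    if (length(object@alphas) &&
        (min(object@alphas) < 0 || max(object@alphas) > 1))
        return("alphas must lie in [0, 1]")
    if (!all(dim(object@H) == c(t, t - 1L))) return("H must be t x (t-1)")
    if (!all(dim(object@P) == c(t, t - 1L))) return("P must be t x (t-1)")
    TRUE
})

#' Hyperparameters of the tensor multi-task model
#'
#' @slot lambda weight of the CP-factorization fit term (>= 0).
#' @slot beta weight of the l1 penalty shared by W, A, B, C (>= 0).
#' @slot theta weight of the temporal-smoothness penalty (>= 0).
#' @slot rank number of CP latent factors r (>= 1).
#' @slot alphas temporal mixing parameters, length t - 2 (recycled from a
#'   scalar at fit time; empty means all zero, i.e. P = H).
#' @slot maxIter maximum outer iterations.
#' @slot tol relative objective-change stopping tolerance.
#' @slot seed integer seed recorded with the fit.
#' @slot sharedFactors if TRUE a single (A, B, C) is shared across time
#'   points instead of per-time-point factors.
#' @seealso [tmtlParams()], [fitTMTL()]
#' @export
setClass("TMTLParams",
         representation(lambda = "numeric", beta = "numeric", theta = "numeric",
                        rank = "integer", alphas = "numeric",
                        maxIter = "integer", tol = "numeric", seed = "integer",
                        sharedFactors = "logical"))

setValidity("TMTLParams", function(object) {
    if (object@lambda < 0 || object@beta < 0 || object@theta < 0)
        return("lambda, beta, theta must be non-negative")
    if (object@rank < 1L) return("rank must be >= 1")
    if (length(object@alphas) &&
        (min(object@alphas) < 0 || max(object@alphas) > 1))
        return("alphas must lie in [0, 1]")
    if (object@maxIter < 0L) return("maxIter must be >= 0")
    if (object@tol <= 0) return("tol must be > 0")
    TRUE
})

#' Fitted tensor multi-task model
#'
#' Per prediction time point t the model holds CP latent factors A_t
#' (d x r), B_t (d x r), C_t (n x r) and the sparse weight matrix W_t
#' (d x d, support restricted to the strict upper triangle by the
#' duplicate-data correction mask K). The objective trace records the
#' joint objective after initialization and each outer iteration and is
#' non-increasing.
#'
#' @seealso [fitTMTL()], [predict,TMTLModel-method]
#' @export
setClass("TMTLModel",
         representation(facA = "list", facB = "list", facC = "list",
                        W = "array", K = "matrix", params = "TMTLParams",
                        objective = "numeric", interval = "character",
                        biomarkerNames = "character", patientIDs = "character",
                        timeLabels = "character", fitted = "logical"))

setValidity("TMTLModel", function(object) {
    t <- length(object@timeLabels)
    if (length(dim(object@W)) != 3L || dim(object@W)[3] != t)
        return("W must be d x d x t")
    if (length(object@facA) != t || length(object@facB) != t ||
        length(object@facC) != t)
        return("factor lists must have one matrix per time point")
    TRUE
})

#' Gradient-boosting ensemble of tensor multi-task models
#'
#' Ordered stages, one per consecutive scan interval (BL->M06, M06->M12,
#' M12->M24, ...). Stage 1 fits the scores; stage s > 1 fits the residual
#' of the cumulative prediction. The ensemble prediction truncated at
#' stage s supports dynamic forecasting as new scans arrive.
#'
#' @slot stages list of \linkS4class{TMTLModel}.
#' @slot intervals character labels like \code{"BL:M06"}, chronological.
#' @slot nu shrinkage in (0, 1] applied to stage contributions.
#' @slot shrinkFirst if FALSE (default) the first stage is unshrunk.
#' @seealso [fitEnsemble()], [predictEnsemble()]
#' @export
setClass("BoostingEnsemble",
         representation(stages = "list", intervals = "character",
                        nu = "numeric", shrinkFirst = "logical",
                        patientIDs = "character", timeLabels = "character"))

setValidity("BoostingEnsemble", function(object) {
    if (!length(object@stages)) return("ensemble needs at least one stage")
    if (length(object@intervals) != length(object@stages))
        return("one interval label per stage")
    if (anyDuplicated(object@intervals)) return("repeated stage intervals")
    starts <- match(sub(":.*", "", object@intervals), .VISIT_LEVELS)
    if (anyNA(starts) || is.unsorted(starts, strictly = TRUE))
        return("stage intervals must be chronologically ordered")
    if (object@nu <= 0 || object@nu > 1) return("nu must be in (0, 1]")
    TRUE
})

#' Evaluation report of the repeated split protocol
#'
#' @slot perTime data.frame with per-time-point mean and SD of test rMSE
#'   over repeats.
#' @slot nmseMean,nmseSD overall normalized MSE summary over repeats.
#' @slot chosen data.frame of selected hyperparameters per repeat.
#' @slot cvTables list (per repeat) of the cross-validation grid tables.
#' @slot nRepeats,seed protocol bookkeeping.
#' @seealso [runProtocol()]
#' @export
setClass("EvaluationReport",
         representation(perTime = "data.frame", nmseMean = "numeric",
                        nmseSD = "numeric", chosen = "data.frame",
                        cvTables = "list", nRepeats = "integer",
                        seed = "integer"))
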