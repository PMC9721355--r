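#' Construct a score table
#'
#' @param scores numeric matrix (patients x time points) or a long
#'   data.frame with columns \code{patientID}, \code{timePoint},
#'   \code{score}.
#' @param scoreKind label, e.g. \code{"MMSE"} or \code{"ADAS-Cog"}.
#' @return a \linkS4class{ScoreTable}. Values outside the known score
#'   range (MMSE 0-30, ADAS-Cog 0-70) trigger a validation warning; they
#'   are never silently clamped.
#' @export
ScoreTable <- function(scores, scoreKind = "MMSE") {
    if (is.data.frame(scores)) {
        need <- c("patientID", "timePoint", "score")
        if (!all(need %in% colnames(scores)))
            stop("long score table needs columns: ",
                 paste(need, collapse = ", "))
        pats <- unique(as.character(scores$patientID))
        tps <- intersect(.SCORE_POINTS, unique(as.character(scores$timePoint)))
        if (!length(tps))
            tps <- unique(as.character(scores$timePoint))
        m <- matrix(NA_real_, length(pats), length(tps),
                    dimnames = list(pats, tps))
        m[cbind(match(as.character(scores$patientID), pats),
                match(as.character(scores$timePoint), tps))] <- scores$score
        scores <- m
    }
    scores <- as.matrix(scores)
    storage.mode(scores) <- "double"
    obj <- new("ScoreTable", scores = scores, scoreKind = scoreKind)
    rng <- .SCORE_RANGES[[scoreKind]]
    if (!is.null(rng)) {
        bad <- sum(scores < rng[1] | scores > rng[2], na.rm = TRUE)
        if (bad > 0)
            warning(sprintf("%d %s score(s) outside [%g, %g]",
                            bad, scoreKind, rng[1], rng[2]))
    }
    obj
}

#' Load cognitive scores from a delimited file
#'
#' @param path file with columns (after mapping) patient id, time point
#'   (M12/M24/M36/M48) and score value.
#' @param schema named list mapping \code{patientID}, \code{timePoint},
#'   \code{score} to column names.
#' @param scoreKind score label.
#' @param sep field separator.
#' @return a \linkS4class{ScoreTable}.
#' @export
loadScores <- function(path, schema = list(patientID = "PTID",
                                           timePoint = "VISCODE",
                                           score = "SCORE"),
                       scoreKind = "MMSE", sep = ",") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (!all(unlist(schema) %in% colnames(df)))
        stop("schema error: missing columns in score file")
    ScoreTable(data.frame(patientID = df[[schema$patientID]],
                          timePoint = df[[schema$timePoint]],
                          score = df[[schema$score]]), scoreKind)
}

#' @describeIn ScoreTable-class the patients x time points score matrix.
#' @param x a \code{ScoreTable}.
#' @export
scoreMatrix <- function(x) x@scores

#' @describeIn ScoreTable-class the score kind label.
#' @export
scoreKind <- function(x) x@scoreKind

#' Remove patients with missing follow-up assessments
#'
#' Longitudinal modelling needs complete follow-up: patients missing a
#' score at any required time point are dropped from the table. An empty
#' \code{requiredPoints} is vacuous and returns the table unchanged.
#'
#' @param scores a \linkS4class{ScoreTable}.
#' @param requiredPoints subset of \code{c("M12","M24","M36","M48")}.
#' @return filtered \linkS4class{ScoreTable}.
#' @export
filterScoreFollowups <- function(scores,
                                 requiredPoints = colnames(scoreMatrix(scores))) {
    stopifnot(all(requiredPoints %in% .SCORE_POINTS))
    m <- scoreMatrix(scores)
    if (!length(requiredPoints)) return(scores)
    have <- intersect(requiredPoints, colnames(m))
    if (length(have) < length(requiredPoints)) {
        keep <- rep(FALSE, nrow(m))  # required point absent from table
    } else {
        keep <- rowSums(is.na(m[, have, drop = FALSE])) == 0L
    }
    new("ScoreTable", scores = m[keep, , drop = FALSE],
        scoreKind = scores@scoreKind)
}

setMethod("show", "ScoreTable", function(object) {
    m <- object@scores
    cat("ScoreTable (", object@scoreKind, "): ", nrow(m), " patients x ",
        ncol(m), " time points [", paste(colnames(m), collapse = " "),
        "], ", sum(is.na(m)), " missing\n", sep = "")
    invisible(NULL)
})
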