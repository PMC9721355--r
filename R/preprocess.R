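#' Drop biomarkers with too many missing values
#'
#' Removes every biomarker whose fraction of missing cells across all
#' retained records STRICTLY exceeds \code{maxMissingFraction} ("more than
#' half of the sample" is read as a strict inequality, so a feature
#' missing in exactly half the records is kept at the default threshold).
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param maxMissingFraction threshold in (0, 1]; default 0.5.
#' @return the filtered cohort; feature order preserved.
#' @export
filterFeatures <- function(cohort, maxMissingFraction = 0.5) {
    stopifnot(maxMissingFraction > 0, maxMissingFraction <= 1)
    frac <- rowMeans(is.na(assay(cohort)))
    keep <- frac <= maxMissingFraction
    if (!any(keep))
        stop("all features exceed the missingness threshold")
    cohort[keep, ]
}

#' Keep only patients with both baseline and M06 scans
#'
#' The variation vectors need two consecutive scans, so patients lacking
#' either the BL or the M06 record are excluded.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @return the filtered cohort (possibly empty, with a warning).
#' @export
filterBaselinePatients <- function(cohort) {
    filterFollowupVisits(cohort, c("BL", "M06"))
}

#' Keep only patients with a full set of follow-up scans
#'
#' For dynamic prediction with the boosting ensemble every stage interval
#' needs its pair of scans, so only patients having every visit in
#' \code{requiredVisits} are retained.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param requiredVisits subset of \code{c("BL","M06","M12","M24")}.
#' @return the filtered cohort.
#' @export
filterFollowupVisits <- function(cohort, requiredVisits) {
    stopifnot(all(requiredVisits %in% .VISIT_LEVELS))
    if (ncol(cohort) == 0L || !length(requiredVisits)) return(cohort)
    cd <- colData(cohort)
    keepPat <- vapply(split(cd$visitCode, cd$patientID),
                      function(v) all(requiredVisits %in% v), logical(1))
    pats <- names(keepPat)[keepPat]
    out <- cohort[, cd$patientID %in% pats]
    if (ncol(out) == 0L) warning("no patients satisfy the visit requirement")
    out
}

#' Mean-impute missing biomarker values
#'
#' Each missing cell is replaced by the arithmetic mean of that
#' biomarker's observed values. By default the mean pools all retained
#' records (all visits and diagnosis groups); \code{byVisit = TRUE}
#' stratifies the mean per visit code instead.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param byVisit stratify imputation per visit code (default FALSE).
#' @return cohort with no missing biomarker cells; observed cells are
#'   untouched and per-feature observed means are preserved exactly.
#' @export
imputeMean <- function(cohort, byVisit = FALSE) {
    vals <- assay(cohort)
    if (!anyNA(vals)) return(cohort)
    if (any(rowSums(!is.na(vals)) == 0L))
        stop("feature(s) with no observed values: ",
             paste(rownames(vals)[rowSums(!is.na(vals)) == 0L],
                   collapse = ", "),
             " (filter them before imputing)")
    fill <- function(M) {
        mu <- rowMeans(M, na.rm = TRUE)
        idx <- which(is.na(M), arr.ind = TRUE)
        M[idx] <- mu[idx[, 1]]
        M
    }
    if (byVisit) {
        vc <- visitCodes(cohort)
        for (v in unique(vc)) {
            sel <- vc == v
            sub <- vals[, sel, drop = FALSE]
            if (any(rowSums(!is.na(sub)) == 0L))
                stop("feature with no observed values in visit ", v)
            vals[, sel] <- fill(sub)
        }
    } else {
        vals <- fill(vals)
    }
    assays(cohort)$biomarkers <- vals
    cohort
}

#' @importFrom SummarizedExperiment assays<-
NULL

#' Standard preprocessing pipeline
#'
#' Applies, in order: exclusion of patients lacking the required scans,
#' removal of features missing in more than \code{maxMissingFraction} of
#' records, and mean imputation of the remaining gaps. The result has zero
#' missing cells.
#'
#' @inheritParams filterFeatures
#' @inheritParams filterFollowupVisits
#' @param byVisit passed to [imputeMean()].
#' @return preprocessed cohort.
#' @export
preprocessCohort <- function(cohort, requiredVisits = c("BL", "M06"),
                             maxMissingFraction = 0.5, byVisit = FALSE) {
    cohort <- filterFollowupVisits(cohort, requiredVisits)
    cohort <- filterFeatures(cohort, maxMissingFraction)
    imputeMean(cohort, byVisit = byVisit)
}
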