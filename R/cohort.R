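#' Construct a longitudinal cohort
#'
#' @param values numeric matrix, biomarkers x records (one column per
#'   (patient, visit) record); \code{NA} marks missing measurements.
#' @param patientID,visitCode,group character vectors, one per record.
#' @param examDate \code{Date} vector, one per record.
#' @param biomarkerNames optional row names (defaults to existing rownames
#'   or \code{b1..bd}).
#' @param category optional biomarker category tags (CV, SV, SA, TA, TS).
#' @return a \linkS4class{LongitudinalCohort}, columns ordered by
#'   (patient, visit).
#' @details Within each patient, exam dates must increase with visit order
#'   (BL < M06 < M12 < M24); violations raise a warning since they usually
#'   indicate date entry errors upstream.
#' @export
LongitudinalCohort <- function(values, patientID, visitCode, examDate, group,
                               biomarkerNames = NULL, category = NULL) {
    values <- as.matrix(values)
    if (is.null(biomarkerNames))
        biomarkerNames <- rownames(values)
    if (is.null(biomarkerNames))
        biomarkerNames <- paste0("b", seq_len(nrow(values)))
    rownames(values) <- biomarkerNames
    if (is.null(category))
        category <- rep_len(.CATEGORIES, nrow(values))
    visitCode <- as.character(visitCode)
    ord <- order(patientID, match(visitCode, .VISIT_LEVELS))
    values <- values[, ord, drop = FALSE]
    cd <- DataFrame(patientID = as.character(patientID)[ord],
                    visitCode = visitCode[ord],
                    examDate = examDate[ord],
                    group = as.character(group)[ord])
    colnames(values) <- paste(cd$patientID, cd$visitCode, sep = ".")
    obj <- new("LongitudinalCohort", SummarizedExperiment(
        assays = list(biomarkers = values), colData = cd,
        rowData = DataFrame(category = category)))
    .checkDateOrder(obj)
    obj
}

.checkDateOrder <- function(cohort) {
    cd <- colData(cohort)
    for (p in unique(cd$patientID)) {
        sel <- cd$patientID == p
        o <- order(match(cd$visitCode[sel], .VISIT_LEVELS))
        dts <- cd$examDate[sel][o]
        if (is.unsorted(as.numeric(dts), strictly = TRUE))
            warning(sprintf(
                "patient %s: exam dates do not increase with visit order", p))
    }
    invisible(cohort)
}

#' Load a longitudinal cohort from a delimited file
#'
#' Reads a CSV/TSV export (one row per patient visit) and maps its columns
#' onto the cohort schema. All unmapped numeric columns are treated as
#' biomarkers.
#'
#' @param path file path.
#' @param schema named list with entries \code{patientID}, \code{visitCode},
#'   \code{examDate}, \code{group} giving the corresponding column names,
#'   and optionally \code{biomarkers} (character vector of biomarker
#'   columns; default: every remaining column).
#' @param sep field separator (default \code{","}).
#' @param categories optional category tag per biomarker column.
#' @return a \linkS4class{LongitudinalCohort}.
#' @details Dates are parsed as ISO-8601 (\code{YYYY-MM-DD}); records with
#'   unparseable dates are reported in an error. Duplicate
#'   (patient, visit) rows and missing mapped columns are errors.
#' @export
loadCohort <- function(path, schema = list(patientID = "PTID",
                                           visitCode = "VISCODE",
                                           examDate = "EXAMDATE",
                                           group = "DX"),
                       sep = ",", categories = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0L) stop("empty cohort file: ", path)
    need <- c("patientID", "visitCode", "examDate", "group")
    mapped <- unlist(schema[need])
    if (length(mapped) < 4L || !all(mapped %in% colnames(df)))
        stop("schema error: required columns missing from file: ",
             paste(setdiff(mapped, colnames(df)), collapse = ", "))
    biom <- schema$biomarkers
    if (is.null(biom)) biom <- setdiff(colnames(df), mapped)
    if (!length(biom)) stop("no biomarker columns found")
    dates <- as.Date(df[[schema$examDate]], format = "%Y-%m-%d")
    if (anyNA(dates))
        stop("unparseable exam dates in rows: ",
             paste(which(is.na(dates)), collapse = ", "))
    vals <- t(as.matrix(df[, biom, drop = FALSE]))
    storage.mode(vals) <- "double"
    LongitudinalCohort(vals, df[[schema$patientID]], df[[schema$visitCode]],
                       dates, df[[schema$group]], biomarkerNames = biom,
                       category = categories)
}

#' Write a cohort back to a delimited file
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param path output file.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path, sep = ",") {
    cd <- colData(cohort)
    df <- data.frame(PTID = cd$patientID, VISCODE = cd$visitCode,
                     EXAMDATE = as.character(cd$examDate), DX = cd$group,
                     t(assay(cohort)), check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @describeIn LongitudinalCohort-class patient id per record (column).
#' @param x a \code{LongitudinalCohort}.
#' @export
patientIDs <- function(x) colData(x)$patientID

#' @describeIn LongitudinalCohort-class visit code per record.
#' @export
visitCodes <- function(x) colData(x)$visitCode

#' @describeIn LongitudinalCohort-class exam date per record.
#' @export
examDates <- function(x) colData(x)$examDate

#' @describeIn LongitudinalCohort-class diagnosis group per record.
#' @export
diagnosisGroups <- function(x) colData(x)$group

#' @describeIn LongitudinalCohort-class biomarker names.
#' @export
biomarkerNames <- function(x) rownames(x)

#' @describeIn LongitudinalCohort-class biomarker category tags.
#' @export
biomarkerCategories <- function(x) rowData(x)$category

setMethod("show", "LongitudinalCohort", function(object) {
    cd <- colData(object)
    cat("LongitudinalCohort:", nrow(object), "biomarkers,",
        length(unique(cd$patientID)), "patients,", ncol(object), "records\n")
    cat("  visits:", paste(sort(unique(cd$visitCode)), collapse = " "), "\n")
    grp <- table(cd$group[!duplicated(cd$patientID)])
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = " "), "\n")
    nmiss <- sum(is.na(assay(object)))
    cat("  missing cells:", nmiss, "\n")
    invisible(NULL)
})
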