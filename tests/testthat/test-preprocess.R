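test_that("loadCohort parses a toy file and enforces integrity", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeToyCSV(path, toyRows())
    cohort <- loadCohort(path)
    expect_s4_class(cohort, "LongitudinalCohort")
    expect_equal(length(unique(patientIDs(cohort))), 2L)
    expect_equal(nrow(cohort), 2L)  # d inferred from unmapped columns
    expect_setequal(biomarkerNames(cohort), c("hippocampus", "entorhinal"))

    dup <- rbind(toyRows(), toyRows()[1, ])
    writeToyCSV(path, dup)
    expect_error(loadCohort(path), "duplicated")

    writeToyCSV(path, toyRows()[0, ])
    expect_error(loadCohort(path), "empty")

    bad <- toyRows(); bad$PTID <- NULL
    writeToyCSV(path, bad)
    expect_error(loadCohort(path), "schema")

    badDate <- toyRows(); badDate$EXAMDATE[2] <- "not-a-date"
    writeToyCSV(path, badDate)
    expect_error(loadCohort(path), "unparseable")
})

test_that("filterFeatures drops features missing in strictly more than the threshold", {
    cohort <- makeToyCohort(n = 5, d = 3)  # 10 records
    vals <- SummarizedExperiment::assay(cohort)
    vals[1, 1:6] <- NA  # 6/10 missing -> dropped
    vals[2, 1:5] <- NA  # exactly half -> kept
    SummarizedExperiment::assays(cohort)$biomarkers <- vals
    out <- filterFeatures(cohort, 0.5)
    expect_equal(biomarkerNames(out), c("b2", "b3"))

    clean <- makeToyCohort()
    expect_equal(dim(filterFeatures(clean)), dim(clean))

    allNA <- makeToyCohort(n = 2, d = 2)
    SummarizedExperiment::assays(allNA)$biomarkers[] <- NA
    expect_error(filterFeatures(allNA), "all features")
})

test_that("baseline/follow-up patient filters apply the scan requirements", {
    cohort <- makeToyCohort(n = 4, d = 2, visits = c("BL", "M06", "M12"))
    cd <- SummarizedExperiment::colData(cohort)
    # P01 loses M06 (BL only among required); P02 loses BL; P03 loses M12
    drop <- (cd$patientID == "P01" & cd$visitCode == "M06") |
        (cd$patientID == "P02" & cd$visitCode == "BL") |
        (cd$patientID == "P03" & cd$visitCode == "M12")
    cohort <- cohort[, !drop]
    out <- filterBaselinePatients(cohort)
    expect_setequal(unique(patientIDs(out)), c("P03", "P04"))

    out2 <- filterFollowupVisits(cohort, c("BL", "M06", "M12"))
    expect_setequal(unique(patientIDs(out2)), "P04")

    # BL+M06 requirement is the baseline filter
    expect_identical(
        SummarizedExperiment::assay(filterFollowupVisits(cohort,
                                                         c("BL", "M06"))),
        SummarizedExperiment::assay(filterBaselinePatients(cohort)))

    full <- makeToyCohort(n = 3)
    expect_equal(dim(filterBaselinePatients(full)), dim(full))
    empty <- full[, 0]
    expect_equal(ncol(filterFollowupVisits(empty, "BL")), 0L)
})

test_that("imputeMean fills with the observed feature mean and nothing else", {
    cohort <- makeToyCohort(n = 2, d = 2)
    vals <- SummarizedExperiment::assay(cohort)
    vals[1, ] <- c(2, 4, NA, NA)
    SummarizedExperiment::assays(cohort)$biomarkers <- vals
    out <- imputeMean(cohort)
    v <- SummarizedExperiment::assay(out)
    expect_equal(unname(v[1, 3:4]), c(3, 3))
    expect_equal(v[2, ], vals[2, ])  # untouched

    clean <- makeToyCohort()
    expect_identical(SummarizedExperiment::assay(imputeMean(clean)),
                     SummarizedExperiment::assay(clean))

    allNA <- makeToyCohort(n = 2, d = 2)
    SummarizedExperiment::assays(allNA)$biomarkers[1, ] <- NA
    expect_error(imputeMean(allNA), "no observed")
})

test_that("imputation preserves the per-feature observed mean exactly", {
    for (seed in 1:5) {
        cohort <- makeToyCohort(n = 6, d = 5, seed = seed)
        vals <- SummarizedExperiment::assay(cohort)
        set.seed(seed + 100)
        vals[sample(length(vals), 8)] <- NA
        pre <- rowMeans(vals, na.rm = TRUE)
        SummarizedExperiment::assays(cohort)$biomarkers <- vals
        post <- rowMeans(SummarizedExperiment::assay(imputeMean(cohort)))
        expect_equal(post, pre, tolerance = 1e-12)
    }
})

test_that("filters are idempotent and the pipeline removes all missingness", {
    for (seed in 1:4) {
        spec <- syntheticSpec(nPatients = 12, nBiomarkers = 6,
                              featureMissingRate = 0.1,
                              visitMissingRate = 0.1, seed = seed)
        cohort <- generateTrajectories(spec)
        f1 <- filterBaselinePatients(cohort)
        expect_identical(SummarizedExperiment::assay(
            filterBaselinePatients(f1)), SummarizedExperiment::assay(f1))
        f2 <- filterFeatures(f1, 0.5)
        expect_identical(SummarizedExperiment::assay(filterFeatures(f2, 0.5)),
                         SummarizedExperiment::assay(f2))
        out <- imputeMean(f2)
        expect_false(anyNA(SummarizedExperiment::assay(out)))
    }
})

test_that("score follow-up filtering removes incomplete patients only", {
    m <- matrix(c(20, 18, NA, 22, 21, 20, 25, NA, 24),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "P3"),
                                c("M12", "M24", "M36")))
    st <- ScoreTable(m, "MMSE")
    out <- filterScoreFollowups(st, c("M12", "M24", "M36"))
    expect_equal(rownames(scoreMatrix(out)), "P2")

    out2 <- filterScoreFollowups(st, "M12")
    expect_equal(nrow(scoreMatrix(out2)), 3L)

    out3 <- filterScoreFollowups(st, character())
    expect_identical(scoreMatrix(out3), scoreMatrix(st))

    # a required point absent from the table removes everyone
    out4 <- filterScoreFollowups(st, c("M12", "M48"))
    expect_equal(nrow(scoreMatrix(out4)), 0L)
})

test_that("score tables warn on out-of-range values without clamping", {
    m <- matrix(c(31, 20), 1, 2,
                dimnames = list("P1", c("M12", "M24")))
    expect_warning(st <- ScoreTable(m, "MMSE"), "outside")
    expect_equal(scoreMatrix(st)["P1", "M12"], 31)  # not clamped
})
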