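#' Specification of a synthetic longitudinal cohort
#'
#' Defines the study conditions the generator emulates: group-dependent
#' biomarker drift over a jittered visit schedule, a sparse
#' upper-triangular ground-truth weight stack that drifts slowly over the
#' prediction time points (the structure the temporal-smoothness prior
#' encodes), CP latent factors taken from the cohort's own similarity
#' tensor, and homoscedastic Gaussian score noise scaled to the signal.
#'
#' @param nPatients number of patients (default 100).
#' @param nBiomarkers number of biomarkers d (default 20), tagged
#'   round-robin with the five categories CV, SV, SA, TA, TS.
#' @param rank ground-truth CP rank r* (default 3).
#' @param timePoints prediction time-point labels (default M12..M48).
#' @param visitMonths named nominal visit months (default BL=0, M06=6,
#'   M12=12, M24=24).
#' @param groupProbs diagnosis mix (default AD .3, MCI .4, CN .3).
#' @param dateJitterDays uniform exam-date jitter, days (default 15; the
#'   baseline visit anchors the schedule and is not jittered).
#' @param biomarkerNoiseSD relative measurement noise inside the
#'   trajectory model \code{baseline * (1 + rate * months + noise)}
#'   (default 0.01).
#' @param scoreNoiseFrac score noise SD as a fraction of the per-time-point
#'   signal SD (default 0.1).
#' @param supportDensity fraction of upper-triangular cells carrying a
#'   nonzero ground-truth weight (default 0.1).
#' @param weightDrift SD of the on-support perturbation applied between
#'   consecutive time points (default 0.05).
#' @param stageWeights relative signal magnitude contributed by each scan
#'   interval (default \code{c(1, 0.4, 0.2)}: every interval carries
#'   signal, later ones less).
#' @param featureMissingRate,visitMissingRate,scoreMissingRate
#'   missingness rates in [0, 1] (defaults 0).
#' @param seed generator seed.
#' @return a \code{SyntheticSpec} object.
#' @export
syntheticSpec <- function(nPatients = 100L, nBiomarkers = 20L, rank = 3L,
                          timePoints = c("M12", "M24", "M36", "M48"),
                          visitMonths = c(BL = 0, M06 = 6, M12 = 12,
                                          M24 = 24),
                          groupProbs = c(AD = 0.3, MCI = 0.4, CN = 0.3),
                          dateJitterDays = 15, biomarkerNoiseSD = 0.01,
                          scoreNoiseFrac = 0.1, supportDensity = 0.1,
                          weightDrift = 0.05,
                          stageWeights = c(1, 0.4, 0.2),
                          featureMissingRate = 0, visitMissingRate = 0,
                          scoreMissingRate = 0, seed = 1L) {
    stopifnot(abs(sum(groupProbs) - 1) < 1e-8,
              all(c(featureMissingRate, visitMissingRate,
                    scoreMissingRate) >= 0),
              all(c(featureMissingRate, visitMissingRate,
                    scoreMissingRate) <= 1))
    structure(list(nPatients = as.integer(nPatients),
                   nBiomarkers = as.integer(nBiomarkers),
                   rank = as.integer(rank), timePoints = timePoints,
                   visitMonths = visitMonths, groupProbs = groupProbs,
                   dateJitterDays = dateJitterDays,
                   biomarkerNoiseSD = biomarkerNoiseSD,
                   scoreNoiseFrac = scoreNoiseFrac,
                   supportDensity = supportDensity,
                   weightDrift = weightDrift, stageWeights = stageWeights,
                   featureMissingRate = featureMissingRate,
                   visitMissingRate = visitMissingRate,
                   scoreMissingRate = scoreMissingRate,
                   seed = as.integer(seed)),
              class = "SyntheticSpec")
}

# Mean monthly drift per diagnosis group; atrophy-like categories shrink
# fastest in AD, then MCI, then CN. Surface area declines more slowly.
.GROUP_RATES <- c(AD = -0.004, MCI = -0.002, CN = -0.0005)
.CAT_SCALE <- c(CV = 3000, SV = 5000, SA = 2000, TA = 2.5, TS = 0.5)
.CAT_RATE_FACTOR <- c(CV = 1, SV = 1, SA = 0.5, TA = 1, TS = 1)

#' Generate longitudinal biomarker trajectories
#'
#' Each biomarker follows \code{baseline * (1 + rate * months + noise)}
#' with a group- and biomarker-specific monthly rate (AD declining
#' fastest, CN slowest), exam dates on the nominal schedule with uniform
#' jitter, and optional missingness. The drawn per-(biomarker, group)
#' monthly rates are stored in \code{metadata()} under
#' \code{"groupRates"}.
#'
#' @param spec a [syntheticSpec()].
#' @return a \linkS4class{LongitudinalCohort}.
#' @export
generateTrajectories <- function(spec) {
    .withSeed(spec$seed, {
        n <- spec$nPatients; d <- spec$nBiomarkers
        visits <- names(spec$visitMonths)
        cats <- rep_len(.CATEGORIES, d)
        bnames <- sprintf("%s.Region%02d", cats, seq_len(d))
        groups <- sample(names(spec$groupProbs), n, replace = TRUE,
                         prob = spec$groupProbs)
        pids <- sprintf("P%03d", seq_len(n))
        # per-biomarker multiplier shared by groups; preserves ordering
        u <- runif(d, 0.5, 1.5)
        rates <- outer(u * .CAT_RATE_FACTOR[cats], .GROUP_RATES)
        colnames(rates) <- names(.GROUP_RATES)
        baseline <- matrix(.CAT_SCALE[cats] * exp(rnorm(n * d, 0, 0.2)),
                           d, n)
        enroll <- as.Date("2010-01-15") + sample.int(365, n, replace = TRUE)
        nv <- length(visits)
        vals <- matrix(NA_real_, d, n * nv)
        pid <- character(n * nv); vc <- character(n * nv)
        dts <- rep(as.Date(NA), n * nv); grp <- character(n * nv)
        col <- 0L
        for (k in seq_len(n)) {
            for (v in seq_len(nv)) {
                col <- col + 1L
                m <- spec$visitMonths[v]
                jit <- if (m == 0 || spec$dateJitterDays == 0) 0 else
                    sample.int(2 * spec$dateJitterDays + 1, 1) -
                        spec$dateJitterDays - 1
                pid[col] <- pids[k]; vc[col] <- visits[v]
                dts[col] <- enroll[k] + round(m * .DAYS_PER_MONTH) + jit
                grp[col] <- groups[k]
                eps <- rnorm(d, 0, spec$biomarkerNoiseSD)
                vals[, col] <- baseline[, k] *
                    (1 + rates[, groups[k]] * m + eps)
            }
        }
        if (spec$featureMissingRate > 0) {
            drop <- runif(length(vals)) < spec$featureMissingRate
            vals[drop] <- NA
        }
        keepCol <- rep(TRUE, ncol(vals))
        if (spec$visitMissingRate > 0)
            keepCol <- runif(ncol(vals)) >= spec$visitMissingRate
        cohort <- LongitudinalCohort(vals[, keepCol, drop = FALSE],
                                     pid[keepCol], vc[keepCol],
                                     dts[keepCol], grp[keepCol],
                                     biomarkerNames = bnames,
                                     category = cats)
        metadata(cohort)$groupRates <- rates
        cohort
    })
}

#' Ground-truth parameters for a synthetic cohort
#'
#' The latent factors of each stage are the CP decomposition of that
#' stage's own similarity tensor (computed with [cpDecompose()] at rank
#' r*), so the generative forward model uses exactly the latent structure
#' the estimator assumes. The weight stack \code{W*} is sparse on the
#' strict upper triangle and drifts slowly across time points
#' (\code{W*_{t+1} = W*_t} plus a small on-support perturbation); stage s
#' weights are scaled by \code{stageWeights[s]}.
#'
#' @param spec a [syntheticSpec()].
#' @param tensors chronological list of \linkS4class{SimilarityTensor}s
#'   built from the generated cohort.
#' @return a \code{SyntheticTruth} list with one element per stage
#'   (\code{A}, \code{B}, \code{C}, \code{W} of dim d x d x t) plus the
#'   mask \code{K}.
#' @export
makeTruth <- function(spec, tensors) {
    if (is(tensors, "SimilarityTensor")) tensors <- list(tensors)
    d <- spec$nBiomarkers; tp <- length(spec$timePoints)
    K <- correctionMask(d, d)
    upper <- which(K == 1)
    stages <- .withSeed(spec$seed + 1L, lapply(seq_along(tensors),
                                               function(s) {
        # same short deterministic CP-ALS run the estimator warm-starts
        # from, so the forward model is exactly realizable by the fit
        fac <- cpDecompose(tensors[[s]], spec$rank, sweeps = .INIT_SWEEPS)
        W <- array(0, dim = c(d, d, tp))
        nSup <- max(1L, round(spec$supportDensity * length(upper)))
        sup <- sample(upper, nSup)
        w1 <- matrix(0, d, d)
        w1[sup] <- sample(c(-1, 1), nSup, replace = TRUE) *
            runif(nSup, 0.5, 1.5)
        W[, , 1] <- w1 * spec$stageWeights[min(s, length(spec$stageWeights))]
        for (i in seq_len(tp - 1L)) {
            wn <- W[, , i]
            wn[sup] <- wn[sup] + rnorm(nSup, 0, spec$weightDrift)
            W[, , i + 1L] <- wn
        }
        list(A = fac$A, B = fac$B, C = fac$C, W = W)
    }))
    structure(list(stages = stages, K = K, timePoints = spec$timePoints),
              class = "SyntheticTruth")
}

# Noiseless forward-model scores: sum over stages of the prediction rule
# applied with the ground-truth factors and weights.
.noiselessScores <- function(tensors, truth) {
    if (is(tensors, "SimilarityTensor")) tensors <- list(tensors)
    nS <- min(length(tensors), length(truth$stages))
    tp <- dim(truth$stages[[1]]$W)[3]
    n <- length(tensorPatients(tensors[[1]]))
    out <- matrix(0, n, tp,
                  dimnames = list(tensorPatients(tensors[[1]]),
                                  truth$timePoints))
    for (s in seq_len(nS)) {
        X <- tensorValues(tensors[[s]])
        Xmat <- matrix(X, prod(dim(X)[1:2]), dim(X)[3])
        tr <- truth$stages[[s]]
        for (i in seq_len(tp))
            out[, i] <- out[, i] +
                .predictVec(tr$A, tr$B, tr$W[, , i], truth$K, Xmat)
    }
    out
}

#' Generate cognitive-score targets from the forward model
#'
#' Scores are the noiseless forward-model predictions (sum over stages of
#' the masked elementwise product rule) plus homoscedastic Gaussian noise
#' whose SD is \code{scoreNoiseFrac} times the per-time-point signal SD,
#' with optional missingness. Doubling \code{W*} doubles the noiseless
#' scores (the rule is linear in the weights).
#'
#' @param spec a [syntheticSpec()].
#' @param tensors list of stage \linkS4class{SimilarityTensor}s.
#' @param truth output of [makeTruth()].
#' @return a \linkS4class{ScoreTable} (kind \code{"synthetic"}; no
#'   clinical range check applies).
#' @export
generateTargets <- function(spec, tensors, truth) {
    noiseless <- .noiselessScores(tensors, truth)
    .withSeed(spec$seed + 2L, {
        Y <- noiseless
        for (i in seq_len(ncol(Y))) {
            s <- sd(noiseless[, i])
            if (is.finite(s) && s > 0 && spec$scoreNoiseFrac > 0)
                Y[, i] <- Y[, i] + rnorm(nrow(Y), 0,
                                         spec$scoreNoiseFrac * s)
        }
        if (spec$scoreMissingRate > 0)
            Y[runif(length(Y)) < spec$scoreMissingRate] <- NA
        ScoreTable(Y, scoreKind = "synthetic")
    })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: generates trajectories, preprocesses them
#' (requiring every scheduled visit), builds one similarity tensor per
#' consecutive scan interval, draws the ground truth and the score
#' targets.
#'
#' @param spec a [syntheticSpec()].
#' @param nStages number of scan intervals to build tensors for (default:
#'   all consecutive pairs in the visit schedule).
#' @param covarianceScope,normalize passed to [buildSimilarityTensor()].
#' @return list with elements \code{cohort}, \code{tensors},
#'   \code{truth} (including \code{$noiseless}) and \code{scores}.
#' @export
simulateCohort <- function(spec = syntheticSpec(), nStages = NULL,
                           covarianceScope = "per-patient",
                           normalize = TRUE) {
    cohort <- generateTrajectories(spec)
    visits <- names(spec$visitMonths)
    cohort <- preprocessCohort(cohort, requiredVisits = visits)
    if (is.null(nStages)) nStages <- length(visits) - 1L
    tensors <- lapply(seq_len(nStages), function(s)
        buildSimilarityTensor(cohort, interval = visits[c(s, s + 1L)],
                              covarianceScope = covarianceScope,
                              normalize = normalize))
    truth <- makeTruth(spec, tensors)
    truth$noiseless <- .noiselessScores(tensors, truth)
    scores <- generateTargets(spec, tensors, truth)
    list(cohort = cohort, tensors = tensors, truth = truth,
         scores = scores)
}
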