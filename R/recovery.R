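#' Compare a fitted weight stack with a ground truth
#'
#' Measures how well the estimator recovered a known sparse weight stack:
#' the Pearson correlation between the vectorized upper-triangular
#' entries, and the support-recovery F1 score. Because the l1 proximal
#' solver leaves tiny residual entries, the recovered support is defined
#' as cells whose magnitude exceeds \code{supportThreshold} times the
#' largest recovered magnitude (default 5\%); the truth's support is its
#' exactly-nonzero cells.
#'
#' @param What,Wtrue d x d x t weight stacks (fitted, ground truth).
#' @param supportThreshold relative magnitude cut-off defining the
#'   recovered support (default 0.05).
#' @return named numeric: \code{correlation}, \code{f1},
#'   \code{precision}, \code{recall}, \code{nnz}.
#' @export
weightRecovery <- function(What, Wtrue, supportThreshold = 0.05) {
    stopifnot(all(dim(What) == dim(Wtrue)))
    d <- dim(What)[1]
    up <- which(array(rep(correctionMask(d, dim(What)[2]),
                          dim(What)[3]), dim = dim(What)) == 1)
    w <- What[up]; wt <- Wtrue[up]
    mx <- max(abs(w))
    sel <- if (mx > 0) abs(w) > supportThreshold * mx else rep(FALSE,
                                                               length(w))
    tp <- wt != 0
    prec <- if (any(sel)) sum(sel & tp) / sum(sel) else 0
    rec <- sum(sel & tp) / sum(tp)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(correlation = stats::cor(w, wt), f1 = f1, precision = prec,
      recall = rec, nnz = sum(sel))
}

#' Weight-recovery experiment on synthetic cohorts
#'
#' For each seed: simulate a cohort from the forward model, fit the
#' tensor multi-task model on the first scan interval, and measure
#' [weightRecovery()] against the generating weight stack. Reports the
#' per-seed metrics and their means.
#'
#' @param seeds integer vector of generator seeds.
#' @param spec a [syntheticSpec()] template; its \code{seed} is replaced
#'   per run.
#' @param params estimator settings (default: the package defaults with
#'   a long optimization budget suitable for recovery studies).
#' @return list with \code{perSeed} (matrix) and \code{mean} (named
#'   numeric).
#' @export
recoveryExperiment <- function(seeds = 1:5, spec = syntheticSpec(),
                               params = tmtlParams(lambda = 0.1,
                                                   beta = 0.2, theta = 1,
                                                   alphas = 0.5,
                                                   maxIter = 1000L,
                                                   tol = 1e-9)) {
    res <- vapply(seeds, function(s) {
        spec$seed <- as.integer(s)
        sim <- simulateCohort(spec, nStages = 1)
        fit <- fitTMTL(sim$tensors[[1]], sim$scores, params)
        weightRecovery(weightStack(fit), sim$truth$stages[[1]]$W)
    }, numeric(5))
    list(perSeed = t(res), mean = rowMeans(res))
}

#' Dynamic-prediction experiment: does accuracy improve with more scans?
#'
#' For each seed: simulate a multi-interval cohort in which every scan
#' interval carries signal, hold out a patient-level test set, fit the
#' boosting ensemble on the training patients and compare the mean test
#' rMSE (across time points) of the 1-stage and full-ensemble
#' predictions. The headline qualitative property is that additional MRI
#' detections should not hurt: the full ensemble beats or matches the
#' single-scan model in most repetitions.
#'
#' @param seeds integer vector of generator seeds.
#' @param spec a [syntheticSpec()] template (default: 80 patients, 12
#'   biomarkers; the template's \code{seed} is replaced per run).
#' @param params per-stage estimator settings.
#' @param testFraction held-out patient fraction (default 0.2).
#' @return list with \code{perSeed} data.frame (stage-1 and final-stage
#'   test rMSE, improvement flag) and \code{improvedFraction}.
#' @export
boostingExperiment <- function(seeds = 1:20,
                               spec = syntheticSpec(nPatients = 80L,
                                                    nBiomarkers = 12L),
                               params = tmtlParams(lambda = 0.1,
                                                   beta = 0.1, theta = 1,
                                                   alphas = 0.5,
                                                   maxIter = 300L,
                                                   tol = 1e-7),
                               testFraction = 0.2) {
    rows <- lapply(seeds, function(s) {
        spec$seed <- as.integer(s)
        sim <- simulateCohort(spec)
        Y <- scoreMatrix(sim$scores)
        n <- length(tensorPatients(sim$tensors[[1]]))
        te <- .withSeed(s, sort(sample.int(n, max(2L, round(testFraction *
                                                            n)))))
        trn <- setdiff(seq_len(n), te)
        ens <- fitEnsemble(lapply(sim$tensors, subsetTensor, trn),
                           Y[trn, , drop = FALSE], params)
        teT <- lapply(sim$tensors, subsetTensor, te)
        nS <- length(sim$tensors)
        meanRMSE <- function(pred) mean(vapply(seq_len(ncol(Y)),
            function(i) rmse(Y[te, i], pred[, i]), numeric(1)))
        e1 <- meanRMSE(predictEnsemble(ens, teT, 1L))
        eS <- meanRMSE(predictEnsemble(ens, teT, nS))
        data.frame(seed = s, rmseStage1 = e1, rmseFinal = eS,
                   improved = eS <= e1)
    })
    perSeed <- do.call(rbind, rows)
    list(perSeed = perSeed, improvedFraction = mean(perSeed$improved))
}
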