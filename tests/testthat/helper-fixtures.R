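# Small in-code fixtures shared across the test files.

# Toy cohort: `n` patients with BL + M06 (and optionally later visits),
# d biomarkers, deterministic values.
makeToyCohort <- function(n = 3, d = 4, visits = c("BL", "M06"),
                          seed = 1) {
    set.seed(seed)
    months <- c(BL = 0, M06 = 6, M12 = 12, M24 = 24)[visits]
    pid <- rep(sprintf("P%02d", seq_len(n)), each = length(visits))
    vis <- rep(visits, n)
    base <- as.Date("2015-03-01")
    dts <- base + rep((seq_len(n) - 1) * 7, each = length(visits)) +
        round(months[vis] * 30.4375)
    vals <- matrix(100 + rnorm(d * length(pid)), d, length(pid))
    grp <- rep(c("AD", "MCI", "CN"), length.out = n)[
        match(pid, sprintf("P%02d", seq_len(n)))]
    LongitudinalCohort(vals, pid, vis, dts, grp,
                       biomarkerNames = paste0("b", seq_len(d)))
}

# Write a toy cohort CSV with the default loadCohort schema.
writeToyCSV <- function(path, rows) {
    write.csv(rows, path, row.names = FALSE, quote = FALSE)
    path
}

toyRows <- function() {
    data.frame(PTID = c("P1", "P1", "P2", "P2"),
               VISCODE = c("BL", "M06", "BL", "M06"),
               EXAMDATE = c("2015-01-01", "2015-07-02",
                            "2015-02-01", "2015-08-03"),
               DX = c("AD", "AD", "CN", "CN"),
               hippocampus = c(3000, 2900, 3500, 3490),
               entorhinal = c(1800, 1750, 2000, 1995))
}

# Random small model pieces for oracle tests.
randomInstance <- function(d = 4, r = 2, seed = 1) {
    set.seed(seed)
    list(A = matrix(rnorm(d * r), d, r), B = matrix(rnorm(d * r), d, r),
         W = matrix(rnorm(d * d), d, d), X = matrix(abs(rnorm(d * d)), d, d),
         K = correctionMask(d, d))
}

# Brute-force double-loop evaluation of the prediction rule.
bruteForcePredict <- function(A, B, W, K, Xn) {
    d1 <- nrow(A); d2 <- nrow(B)
    tot <- 0
    AB <- A %*% t(B)
    for (i in seq_len(d1))
        for (j in seq_len(d2))
            tot <- tot + AB[i, j] * K[i, j] * W[i, j] * Xn[i, j]
    tot
}

# Brute-force triple-loop CP reconstruction.
bruteForceCP <- function(A, B, C) {
    out <- array(0, dim = c(nrow(A), nrow(B), nrow(C)))
    for (i in seq_len(nrow(A)))
        for (j in seq_len(nrow(B)))
            for (k in seq_len(nrow(C)))
                out[i, j, k] <- sum(A[i, ] * B[j, ] * C[k, ])
    out
}

# Independent recursion oracle for the temporal-smoothness columns.
recursionOracle <- function(W, alphas) {
    t <- ncol(W)
    delta <- sapply(seq_len(t - 1), function(i) W[, i] - W[, i + 1])
    delta <- matrix(delta, nrow = nrow(W))
    Delta <- delta
    if (t >= 3)
        for (i in 2:(t - 1))
            Delta[, i] <- alphas[i - 1] * Delta[, i - 1] +
                (1 - alphas[i - 1]) * delta[, i]
    Delta
}

# Small simulated study reused by several files.
smallSim <- function(n = 30, d = 8, seed = 5, nStages = 1) {
    simulateCohort(syntheticSpec(nPatients = n, nBiomarkers = d,
                                 seed = seed), nStages = nStages)
}
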