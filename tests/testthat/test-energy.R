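m <- loadContactEnergyMatrix()

test_that("proportional exposure and burial follow the reference-area ratio", {
    tab <- loadASANormalization()
    expect_equal(proportionalExposure("G", 104, tab), 1)
    expect_equal(proportionalExposure("A", 0, tab), 0)
    expect_equal(proportionalExposure("A", 258, tab), 1)        # clipped 2.0
    expect_equal(proportionalExposure("A", 258, tab, clip = FALSE), 2)
    expect_error(proportionalExposure("A", -1, tab), "non-negative")
    expect_error(proportionalExposure("X", 10, tab), "X")
    expect_equal(proportionalBurial(c(0, 1, 0.25)), c(1, 0, 0.75))
    expect_error(proportionalBurial(1.2), "\\[0,1\\]")
})

test_that("PSEE closed forms hold at full burial and zero burial", {
    prof <- pseeProfile(strrep("A", 30), rep(1, 30), pseeConfig(9), m)
    # interior: 18 identical A-A terms over divisor 18
    expect_equal(prof$psee[10:21], rep(-1.65, 12))
    # terminal truncation with constant 2*CR divisor shrinks magnitude
    expect_equal(prof$psee[1], -1.65 * 9 / 18)
    pb <- rep(0.5, 5); pb[3] <- 0
    expect_equal(pseeProfile("ARNDC", pb, pseeConfig(2), m)$psee[3], 0)
    # hand-checked three-residue case, CR 1
    expect_equal(pseeProfile("ARN", rep(0.5, 3), pseeConfig(1), m)$psee[2],
                 0.2575)
})

test_that("PSEE matches the explicit-neighbourhood brute-force oracle", {
    set.seed(421)
    e <- energyMatrix(m)
    for (rep_i in 1:200) {
        L <- sample(3:60, 1)
        res <- sample(AA_STANDARD, L, replace = TRUE)
        pb <- runif(L)
        cr <- sample(c(1L, 3L, 9L), 1)
        sym <- rep_i %% 5 == 0
        byc <- rep_i %% 7 == 0
        cfg <- pseeConfig(cr, symmetrize = sym, normalizeByCount = byc)
        got <- suppressWarnings(
            pseeProfile(res, pb, cfg, m, magnitudeWarn = Inf)$psee)
        want <- oracle_psee(res, pb, cr, e, sym, byc)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("PSEE is linear in the target burial and affine in partner burial", {
    set.seed(11)
    res <- sample(AA_STANDARD, 25, replace = TRUE)
    pb <- runif(25)
    cfg <- pseeConfig(3)
    base <- pseeProfile(res, pb, cfg, m)$psee
    lam <- 0.37
    pb2 <- pb; pb2[12] <- pb[12] * lam
    scaled <- pseeProfile(res, pb2, cfg, m)$psee
    expect_equal(scaled[12], base[12] * lam)
    # partner perturbation moves the target PSEE linearly
    pb3 <- pb; pb3[13] <- 0
    pb4 <- pb; pb4[13] <- 1
    half <- pb; half[13] <- 0.5
    p0 <- pseeProfile(res, pb3, cfg, m)$psee[12]
    p1 <- pseeProfile(res, pb4, cfg, m)$psee[12]
    expect_equal(pseeProfile(res, half, cfg, m)$psee[12], (p0 + p1) / 2)
})

test_that("boundary PSEE magnitude never exceeds the per-count normalization", {
    set.seed(5)
    for (i in 1:20) {
        L <- sample(5:40, 1)
        res <- sample(AA_STANDARD, L, replace = TRUE)
        pb <- runif(L)
        cr <- 9L
        a <- suppressWarnings(pseeProfile(res, pb, pseeConfig(cr), m,
                                          magnitudeWarn = Inf)$psee)
        b <- suppressWarnings(pseeProfile(res, pb,
                pseeConfig(cr, normalizeByCount = TRUE), m,
                magnitudeWarn = Inf)$psee)
        expect_true(all(abs(a) <= abs(b) + 1e-12))
    }
})

test_that("non-standard residues are marked unavailable, not zeroed", {
    expect_warning(prof <- pseeProfile("AXRNA", rep(0.5, 5), pseeConfig(1), m),
                   "non-standard")
    expect_true(is.na(prof$psee[2]))
    expect_false(any(is.na(prof$psee[-2])))
    # the X position is excluded as a partner too: position 1 sees nobody
    expect_equal(prof$psee[1], 0)
    expect_error(pseeProfile("AXA", rep(1, 3), pseeConfig(1), m,
                             strict = TRUE), "non-standard")
    expect_error(pseeProfile("ARN", rep(0.5, 2), pseeConfig(1), m),
                 "mismatch")
})

test_that("extreme PSEE magnitudes trigger the cysteine diagnostic", {
    expect_warning(pseeProfile(strrep("C", 10), rep(1, 10), pseeConfig(2), m),
                   "exceeds")
})

test_that("class means, counts and midpoint threshold follow the label split", {
    s <- meanPseeByLabel(c(-1, -2, 0, 1), c("O", "O", "D", "D"))
    expect_equal(s$class_means[["O"]], -1.5)
    expect_equal(s$class_means[["D"]], 0.5)
    expect_equal(unname(s$class_counts), c(2L, 2L))
    expect_equal(s$threshold, -0.5)
    u <- meanPseeByLabel(rep(-0.5, 6), rep("O", 6))
    expect_equal(u$class_means[["O"]], -0.5)
    expect_equal(s$threshold, midpointThreshold(-1.5, 0.5))
    expect_error(meanPseeByLabel(c(-1, 1), c("X", "X")), "usable")
    # class present only at unavailable positions is named in the error
    expect_error(meanPseeByLabel(c(NA, 1), c("O", "D")), "'O'")
})

test_that("midpoint threshold is equidistant from both means", {
    expect_equal(midpointThreshold(-1.00, -0.391), -0.6955)
    expect_equal(midpointThreshold(-0.5, -0.5), -0.5)
    expect_equal(midpointThreshold(0, 0), 0)
    set.seed(2)
    for (i in 1:50) {
        a <- rnorm(1); b <- rnorm(1)
        t <- midpointThreshold(a, b)
        expect_equal(t - a, b - t)
    }
    expect_error(midpointThreshold(NaN, 0), "finite")
})

test_that("threshold classification puts the boundary on the ordered side", {
    t <- -0.6955
    expect_equal(classifyByThreshold(c(-1, 0, t), t), c("O", "D", "O"))
    expect_true(is.na(classifyByThreshold(NA_real_, t)))
    expect_error(classifyByThreshold(0, Inf), "finite")
})

test_that("region means aggregate residues and stratify disordered lengths", {
    psee <- seq(-1, 1, length.out = 100)
    regs <- data.frame(start = c(1, 10, 20, 50, 4),
                       end = c(3, 19, 49, 99, 4),
                       label = c("D", "D", "D", "D", "O"))
    out <- regionMeanPsee(psee, regs)
    expect_equal(out$length, c(3L, 10L, 30L, 50L, 1L))
    expect_equal(out$stratum, c("<=5", "6-20", "21-40", ">=41", NA))
    expect_equal(out$mean_psee[5], psee[4])
    expect_equal(out$mean_psee[1], mean(psee[1:3]))
    # stratum boundaries: 5 vs 6, 20 vs 21, 40 vs 41
    b <- regionMeanPsee(psee, data.frame(start = c(1, 1, 1, 1),
                                         end = c(5, 6, 40, 41),
                                         label = "D"))
    expect_equal(b$stratum, c("<=5", "6-20", "21-40", ">=41"))
    expect_error(regionMeanPsee(psee, data.frame(start = 5, end = 2,
                                                 label = "O")), "invalid")
    expect_error(regionMeanPsee(psee, data.frame(start = 1, end = 101,
                                                 label = "O")), "invalid")
})

test_that("contact-radius sweep recomputes everything per CR and argmaxes MCC", {
    ds <- generateDataset(syntheticSpec(nSequences = 8L, seed = 7L))
    sw <- sweepContactRadius(ds, 4:12, m)
    expect_equal(sw$sweep$cr, 4:12)
    expect_true(sw$best_cr %in% 4:12)
    expect_true(all(sw$sweep$mcc[sw$sweep$cr == sw$best_cr] >= sw$sweep$mcc))
    expect_true(all(sw$sweep$mean_ordered < sw$sweep$mean_disordered))
    expect_true(all(abs(sw$sweep$threshold -
        (sw$sweep$mean_ordered + sw$sweep$mean_disordered) / 2) < 1e-12))
    one <- sweepContactRadius(ds, 9L, m)
    expect_equal(nrow(one$sweep), 1L)
    expect_equal(one$best_cr, 9L)
    allO <- list(list(sequence = "ARNDARND", pBur = rep(0.5, 8),
                      labels = rep("O", 8)))
    expect_error(sweepContactRadius(allO, 4:5, m), "both")
})

test_that("hydrophobicity correlation is Pearson on per-residue-type means", {
    h <- loadHydrophobicity()
    expect_equal(hydrophobicityCorrelation(-h$index, h), -1)
    expect_equal(hydrophobicityCorrelation(h$index, h), 1)
    expect_equal(hydrophobicityCorrelation(c(A = 1, C = 2, D = 4),
                                           list(index = c(A = 1, C = 2, D = 3))),
                 0.98198, tolerance = 1e-4)
    expect_error(hydrophobicityCorrelation(c(A = 1, C = 1, D = 1),
                                           list(index = c(A = 1, C = 2, D = 3))),
                 "constant")
    expect_error(hydrophobicityCorrelation(c(A = 1, C = 2), h), "at least 3")
})
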