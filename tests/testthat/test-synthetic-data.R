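test_that("dictionary generator honours size, collision rate and determinism", {
    d1 <- makeMirnaDictionary(1, 0, seed = 1)
    sp <- mirnaSpecies(d1)
    expect_equal(nrow(sp), 2L)
    expect_setequal(sp$role, c("mature", "passenger"))
    expect_false(substr(sp$sequence[1], 1, 13) == substr(sp$sequence[2], 1, 13))

    # brute-force count of species sitting in shared-13-mer groups
    d <- makeMirnaDictionary(100, 0.1, seed = 7)
    sp <- mirnaSpecies(d)
    pref <- substr(sp$sequence, 1, 13)
    shared <- sum(table(pref)[table(pref) > 1])
    expect_gte(shared, 9)
    expect_lte(shared, 11)
    # only mature species are placed in collision groups
    sharedNames <- sp$name[pref %in% names(table(pref))[table(pref) > 1]]
    expect_true(all(sp$role[sp$name %in% sharedNames] == "mature"))

    expect_identical(makeMirnaDictionary(100, 0.1, seed = 7), d)
    d2 <- makeMirnaDictionary(100, 0.1, seed = 8)
    expect_false(identical(mirnaSpecies(d2)$sequence, sp$sequence))

    expect_error(makeMirnaDictionary(0, 0), "nHairpins")
    expect_error(makeMirnaDictionary(5, 1), "prefixCollisionRate")
})

test_that("simulated counts follow the stated expectation formula", {
    d <- makeMirnaDictionary(10, 0, seed = 2)
    n <- length(mirnaNames(d))
    # Poisson limit: no effects, dispersion ~ 0, unit size factors
    tr <- simulationTruth(d, baseAbundance = 2000, dispersion = 0,
                          sizeFactorTruth = stats::setNames(
                              rep(1, 6), names(twoGroupDesign())),
                          seed = 5)
    tab <- simulateIsoformCounts(d, tr)
    mu <- S4Vectors::metadata(tab)$truth$mu
    cts <- isoCounts(tab)
    nz <- mu > 5
    z <- (cts[nz] - mu[nz]) / sqrt(mu[nz])
    expect_gt(mean(abs(z) <= 3), 0.985)
    expect_lt(abs(mean(z)), 4 / sqrt(sum(nz)))

    # determinism
    expect_identical(isoCounts(simulateIsoformCounts(d, tr)), cts)

    # short-isoform effect: lfc_short = +1 below 19 nt doubles the
    # KO/control ratio of short-length cells (Monte-Carlo over >= 1000
    # replicate cells)
    prof <- matrix(rep(c(rep(0.5 / 4, 4), rep(0, 5), 0.5,
                         rep(0, 9)), each = 2 * 600),
                   nrow = 2 * 600,
                   dimnames = list(NULL, as.character(13:31)))
    dBig <- makeMirnaDictionary(600, 0, seed = 3)
    rownames(prof) <- mirnaNames(dBig)
    trS <- simulationTruth(dBig, shortLfc = 1, baseAbundance = 400,
                           dispersion = 0,
                           sizeFactorTruth = stats::setNames(
                               rep(1, 6), names(twoGroupDesign())),
                           lengthProfile = prof, seed = 9)
    tabS <- simulateIsoformCounts(dBig, trS)
    is15 <- isoLength(tabS) == 15
    ko <- rowSums(isoCounts(tabS)[is15, 1:3])
    ctl <- rowSums(isoCounts(tabS)[is15, 4:6])
    expect_equal(sum(ko) / sum(ctl), 2, tolerance = 0.03)
    # unaffected canonical length stays at ratio 1
    is22 <- isoLength(tabS) == 22
    expect_equal(sum(isoCounts(tabS)[is22, 1:3]) /
                 sum(isoCounts(tabS)[is22, 4:6]), 1, tolerance = 0.03)
})

test_that("FASTQ synthesis emits the right reads and contamination load", {
    d <- smallDict()
    design <- twoGroupDesign()
    # single count of (mirA-5p, 22) in one sample
    cts <- matrix(0L, nrow = 2, ncol = 1,
                  dimnames = list(NULL, "s1"))
    cts[1, 1] <- 1L
    tab <- IsoformCountTable(cts, mirna = c("mirA-5p", "mirB-5p"),
                             length = c(22L, 14L))
    fq <- countsToFastq(tab, d, DEFAULT_ADAPTER, contaminationRate = 0,
                        dir = withr::local_tempdir(), seed = 3)
    lines <- readLines(fq[["s1"]])
    expect_length(lines, 4L)
    expect_true(startsWith(lines[2],
        substr(mirnaSpecies(d)$sequence[1], 1, 22)))

    # a 14-nt isoform read starts with the first 14 nt of the species
    cts[, 1] <- c(0L, 1L)
    tab14 <- IsoformCountTable(cts, mirna = c("mirA-5p", "mirB-5p"),
                               length = c(22L, 14L))
    fq14 <- countsToFastq(tab14, d, DEFAULT_ADAPTER, 0,
                          dir = withr::local_tempdir(), seed = 3)
    read <- readLines(fq14[["s1"]])[2]
    expect_true(startsWith(read,
        paste0(substr(mirnaSpecies(d)$sequence[3], 1, 14), DEFAULT_ADAPTER)))

    # contamination 0.5 on 1000 true reads: 1500 +/- binomial error
    ctsBig <- matrix(c(1000L, 0L), nrow = 2, dimnames = list(NULL, "s1"))
    tabBig <- IsoformCountTable(ctsBig, mirna = c("mirA-5p", "mirB-5p"),
                                length = c(22L, 22L))
    fqBig <- countsToFastq(tabBig, d, DEFAULT_ADAPTER,
                           contaminationRate = 0.5,
                           dir = withr::local_tempdir(), seed = 11)
    nReads <- length(readLines(fqBig[["s1"]])) / 4
    expect_gt(nReads, 1500 - 4 * sqrt(1000 * 0.25))
    expect_lt(nReads, 1500 + 4 * sqrt(1000 * 0.25))

    # sidecar truth records the generating counts
    truth <- jsonlite::read_json(attr(fqBig, "truth"), simplifyVector = TRUE)
    expect_equal(truth$counts$s1, c(1000L, 0L))
})

test_that("gel simulation is exact at zero noise and reproducible", {
    gt <- coipGelTruth(0.7, 0.01, noiseCv = 0)
    gel <- simulateCoipGel(gt)
    lanes <- gelLanes(gel)
    expect_equal(lanes$intensity[lanes$bait_label == "none"],
                 rep(100, 2))   # background exactly for fraction-0 lanes
    # background-subtracted ratio of the two bound lanes is 70
    z <- lanes$intensity[lanes$bait_label == "ZSWIM8"] - 100
    expect_equal(z[1] / z[2], 70)

    gtN <- coipGelTruth(0.7, 0.01, noiseCv = 0.1, seed = 42)
    expect_identical(gelLanes(simulateCoipGel(gtN)),
                     gelLanes(simulateCoipGel(gtN)))
    gtN2 <- coipGelTruth(0.7, 0.01, noiseCv = 0.1, seed = 43)
    expect_false(identical(gelLanes(simulateCoipGel(gtN2)),
                           gelLanes(simulateCoipGel(gtN))))

    # control-lane contract is enforced
    expect_error(gelTruth("t", "ZSWIM8", 30, 0.5), "T6B")
})

test_that("titration simulation matches the isotherm limits", {
    df <- 1 / 2^(0:7)
    # saturation: excess RISC, negligible Kd -> plateau at fmax
    cv <- simulateTitration(1e6, df, 2, 1e-3, 0.8, 0, seed = 1)
    expect_equal(cv@fractionBound, rep(0.8, 8), tolerance = 1e-4)
    # infinite-Kd limit: nothing binds
    cv0 <- simulateTitration(10, df, 2, 1e9, 0.8, 0, seed = 1)
    expect_lt(max(cv0@fractionBound), 1e-6)
    expect_error(simulateTitration(-1, df, 2, 1, 0.8), "stockTruth")
})
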