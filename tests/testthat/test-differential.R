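test_that("isoform summing equals a brute-force per-miRNA sum", {
    withr::with_seed(31, {
        mirna <- rep(paste0("m", 1:8), each = 5)
        len <- rep(18:22, 8)
        cts <- matrix(rpois(40 * 6, 20), nrow = 40,
                      dimnames = list(NULL, names(twoGroupDesign())))
        tab <- IsoformCountTable(cts, mirna, len)
        summed <- sumIsoforms(tab)
        for (m in unique(mirna))
            expect_equal(unname(summed[m, ]),
                         unname(colSums(cts[mirna == m, , drop = FALSE])))
        expect_identical(attr(summed, "provenance"), "summed")
    })
})

test_that("expression filter applies the strict >5 and total >=30 rules", {
    design <- twoGroupDesign()
    m <- rbind(
        kept    = c(6, 6, 0,   6, 6, 6),    # 2 KO libraries > 5, total 30
        noLib   = c(5, 5, 5,  30, 30, 20),  # no KO library strictly > 5
        oneLib  = c(100, 0, 0, 0, 0, 0),    # only one KO library > 5
        lowTot  = c(6, 6, 0,   5, 5, 1))    # total 23 < 30
    colnames(m) <- names(design)
    expect_identical(filterExpressed(m, design), "kept")
    badDesign <- stats::setNames(rep("KO", 6), names(design))
    expect_error(filterExpressed(m, badDesign), "two groups")
})

test_that("median-of-ratios size factors match oracles and are equivariant", {
    design <- twoGroupDesign()
    withr::with_seed(32, {
        m <- matrix(rnbinom(51 * 6, mu = 100, size = 10) + 1L, nrow = 51,
                    dimnames = list(paste0("g", 1:51), names(design)))
    })
    attr(m, "provenance") <- "summed"
    sf <- estimateSizeFactors(m)
    # brute-force median-of-ratios, written independently
    ref <- rowSums(m > 0) == 6
    geo <- exp(rowMeans(log(m[ref, ])))
    for (j in 1:6)
        expect_equal(as.numeric(sf)[j], median(m[ref, j] / geo))
    # agreement with the DESeq2 reference implementation (odd reference
    # count, so the two median conventions coincide exactly)
    expect_equal(unname(as.numeric(sf)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-12)
    # identical libraries -> all factors 1
    ident <- matrix(rep(m[, 1], 6), ncol = 6,
                    dimnames = dimnames(m))
    expect_equal(unname(as.numeric(estimateSizeFactors(ident))), rep(1, 6))
    # doubling one library doubles its factor relative to the others
    dbl <- m; dbl[, 3] <- 2 * dbl[, 3]
    sfd <- as.numeric(estimateSizeFactors(dbl))
    expect_equal(sfd[3] / sfd[1], 2 * as.numeric(sf)[3] / as.numeric(sf)[1],
                 tolerance = 1e-12)
    expect_error(estimateSizeFactors(matrix(c(0, 1, 1, 0), 2)),
                 "positive counts")
})

test_that("fold-change estimator is antisymmetric and recovers the truth", {
    design <- twoGroupDesign()
    sf <- unitSizeFactors()
    withr::with_seed(33, {
        m <- matrix(rnbinom(200 * 6, mu = 1000, size = 20), nrow = 200,
                    dimnames = list(paste0("g", 1:200), names(design)))
    })
    res <- estimateFoldChanges(m, design, sf)
    swapped <- design
    swapped[] <- ifelse(design == "KO", "control", "KO")
    resSw <- estimateFoldChanges(m, swapped, sf)
    expect_equal(resSw$lfc, -res$lfc)
    expect_equal(resSw$se, res$se)
    # equal group means -> lfc 0
    eq <- matrix(rep(c(10, 20, 30), 4)[1:6], nrow = 1, byrow = TRUE,
                 dimnames = list("g", names(design)))
    eq[1, ] <- c(10, 20, 30, 10, 20, 30)
    expect_equal(unname(estimateFoldChanges(eq, design, sf)$lfc), 0)

    # Monte-Carlo recovery: true lfc 1, base 1000, dispersion 0.05
    withr::with_seed(34, {
        mu <- cbind(matrix(2000, 300, 3), matrix(1000, 300, 3))
        mc <- matrix(rnbinom(300 * 6, mu = as.numeric(mu), size = 20),
                     nrow = 300, dimnames = list(paste0("t", 1:300),
                                                 names(design)))
    })
    rec <- estimateFoldChanges(mc, design, sf)
    expect_lt(abs(mean(rec$lfc) - 1), 0.1)

    expect_error(
        estimateFoldChanges(
            matrix(c(0, 0, 0, 1, 1, 1), nrow = 1,
                   dimnames = list("g", names(design))),
            design, sf, pseudocount = 0),
        "undefined")
})

test_that("BH adjustment satisfies the step-up identities", {
    expect_equal(adjustBH(0.03), 0.03)
    expect_equal(adjustBH(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(adjustBH(rep(0.2, 5)), rep(0.2, 5))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sensitivity classification combines the three approaches", {
    d <- smallDict()
    design <- twoGroupDesign()
    sf <- unitSizeFactors()
    # mirA mature strongly up with flat passenger; mirB flat everywhere
    # (fixed counts, so the expected flags are unambiguous)
    summed <- rbind("mirA-5p" = c(4000, 4400, 4800, 1000, 1100, 1200),
                    "mirA-3p" = c(480, 500, 520, 470, 510, 520),
                    "mirB-5p" = c(950, 1000, 1050, 940, 1010, 1060),
                    "mirB-3p" = c(280, 300, 320, 290, 300, 310))
    colnames(summed) <- names(design)
    res <- estimateFoldChanges(summed[c("mirA-5p", "mirB-5p"), ], design, sf)
    cls <- classifyPotentiallySensitive(res, summed, d, design, sf,
                                        externalList = "mirB-5p")
    tab <- stabilityTable(cls)
    a <- which(tab$mirna == "mirA-5p"); b <- which(tab$mirna == "mirB-5p")
    expect_true(tab$flag_padj[a])
    expect_true(tab$flag_passenger[a])   # mature separated above passenger
    expect_false(tab$flag_padj[b])
    expect_false(tab$flag_passenger[b])
    expect_true(tab$flag_annotation[b])  # external annotation only
    expect_setequal(excludedMirnas(cls), c("mirA-5p", "mirB-5p"))
    expect_true(all(tab$padj >= tab$p, na.rm = TRUE))

    # a missing passenger yields a warning and an undefined flag
    dNoPas <- MirnaDictionary(
        name = c("mirA-5p", "mirA-3p"),
        sequence = mirnaSpecies(d)$sequence[1:2],
        hairpinId = "hpA", arm = c("5p", "3p"),
        role = c("mature", "passenger"))
    expect_warning(
        cls2 <- classifyPotentiallySensitive(
            res[1, ], summed["mirA-5p", , drop = FALSE], dNoPas, design, sf),
        "passenger")
    expect_false(stabilityTable(cls2)$flag_passenger[1])
})

test_that("isoform fold changes need summed-provenance size factors and match a direct recomputation", {
    d <- smallDict()
    design <- twoGroupDesign()
    tr <- simulationTruth(d, baseAbundance = 800, seed = 36)
    tab <- simulateIsoformCounts(d, tr)
    summed <- sumIsoforms(tab)
    sf <- estimateSizeFactors(summed)
    iso <- isoformFoldChanges(tab, design, sf)
    it <- isoformTable(iso)
    # direct per-cell recomputation of the fold change
    cts <- isoCounts(tab)
    norm <- sweep(cts, 2, as.numeric(sf), "/")
    for (i in sample(nrow(it), 10)) {
        row <- which(isoMirna(tab) == it$mirna[i] &
                     isoLength(tab) == it$length[i])
        lfcRef <- log2((mean(norm[row, design == "KO"]) + 0.5) /
                       (mean(norm[row, design == "control"]) + 0.5))
        expect_equal(it$lfc[i], lfcRef)
    }
    # excluded miRNAs contribute no rows
    iso2 <- isoformFoldChanges(tab, design, sf, exclude = "mirA-5p")
    expect_false("mirA-5p" %in% isoformTable(iso2)$mirna)
    # provenance contract
    badSf <- SizeFactors(as.numeric(sf), provenance = "isoform")
    names(badSf) <- names(sf)
    expect_error(isoformFoldChanges(tab, design, badSf), "provenance")
})

test_that("22-nt centering is exact and matches a hand-computed median", {
    tab <- S4Vectors::DataFrame(
        mirna = c("a", "b", "c", "a", "b"),
        length = c(22L, 22L, 22L, 15L, 15L),
        lfc = c(0.1, 0.3, 0.5, 1.0, -0.2),
        se = 0.1, p = 0.5)
    iso <- new("IsoformFoldChanges", table = tab, centered = FALSE,
               median22 = NA_real_)
    cen <- centerOn22nt(iso)
    expect_equal(cen@median22, 0.3)
    expect_equal(isoformTable(cen)$centered_lfc,
                 tab$lfc - 0.3)
    expect_equal(median(isoformTable(cen)$centered_lfc[tab$length == 22]), 0)
    # constant fold changes center to exactly zero
    tabC <- tab; tabC$lfc <- 0.7
    cenC <- centerOn22nt(new("IsoformFoldChanges", table = tabC,
                             centered = FALSE, median22 = NA_real_))
    expect_true(all(isoformTable(cenC)$centered_lfc == 0))
    tabNo22 <- tab[tab$length != 22, ]
    expect_error(centerOn22nt(new("IsoformFoldChanges", table = tabNo22,
                                  centered = FALSE, median22 = NA_real_)),
                 "cannot center")
})

test_that("short-isoform test is null-calibrated and antisymmetric", {
    mkIso <- function(shortVals) {
        n <- length(shortVals)
        tab <- S4Vectors::DataFrame(
            mirna = paste0("m", seq_len(n + 3)),
            length = c(rep(15L, n), rep(22L, 3)),
            lfc = c(shortVals, 0, 0, 0),
            se = 0.1, p = 0.5,
            centered_lfc = c(shortVals, 0, 0, 0))
        new("IsoformFoldChanges", table = tab, centered = TRUE,
            median22 = 0)
    }
    expect_gte(shortIsoformTest(mkIso(rep(0, 10)))$p, 0.5)
    withr::with_seed(37, { x <- abs(rnorm(40, 0.5, 0.2)) })
    up <- shortIsoformTest(mkIso(x))
    dn <- shortIsoformTest(mkIso(-x))
    expect_lt(up$p, 0.05)
    expect_equal(up$direction, 1)
    expect_gte(dn$p, 0.5)
    expect_equal(dn$direction, -1)
    expect_equal(dn$effect, -up$effect)
    expect_error(shortIsoformTest(mkIso(rep(0.1, 3))), "shorter than")
})
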