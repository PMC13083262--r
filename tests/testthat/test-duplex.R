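GUIDE <- "TGGAAGACTAGTGATTTTGTTGTT"   # 24-nt miR-7-like guide

test_that("seed-site finding equals a brute-force substring scan", {
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    seedRc <- rc(substr(GUIDE, 2, 8))
    tgt <- paste0("AAAA", seedRc, "CCCC", seedRc, "GG")
    hits <- findSeedSite(GUIDE, tgt)
    # independent scan over every target position
    ref <- which(vapply(seq_len(nchar(tgt) - 6),
                        function(i) substr(tgt, i, i + 6) == seedRc,
                        logical(1)))
    expect_identical(hits, as.integer(ref))
    expect_length(findSeedSite(GUIDE, strrep("A", 50)), 0)
    # RNA alphabet is accepted
    expect_identical(findSeedSite(gsub("T", "U", GUIDE),
                                  gsub("T", "U", tgt)), hits)
    expect_error(findSeedSite("TGGAAGACTAGTG", tgt), "14 nt")
    expect_error(findSeedSite(GUIDE, "ACGTNACGT"), "alphabet")
})

test_that("3'-register search equals exhaustive enumeration", {
    withr::with_seed(51, {
        for (i in 1:40) {
            Lg <- sample(20:24, 1)
            guide <- paste(sample(c("A", "C", "G", "T"), Lg, replace = TRUE),
                           collapse = "")
            lg <- sample(0:4, 1)
            tp <- sample(0:(Lg - 8L - lg), 1)
            target <- designTarget(guide, threePrimePairs = tp,
                                   loopGuide = lg,
                                   loopTarget = sample(0:6, 1),
                                   flank5 = sample(0:10, 1),
                                   flank3 = sample(0:10, 1), seed = i)
            if (nchar(target) > 60) next
            sites <- findSeedSite(guide, target)
            for (s in sites) for (gu in c(FALSE, TRUE)) {
                got <- alignThreePrime(guide, target, s, gu = gu)
                ref <- refEnumerateRegisters(guide, target, s, gu = gu)
                expect_equal(got$length, unname(ref["len"]))
                if (got$length > 0) {
                    expect_equal(got$loopTarget, unname(ref["lt"]))
                    expect_equal(got$loopGuide, unname(ref["lg"]))
                }
            }
        }
    })
})

test_that("canonical architectures are classified as designed", {
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    # fully complementary target: 3' block abuts the seed, loops 0
    full <- annotateDuplex(GUIDE, rc(GUIDE))
    expect_equal(full@architecture, "full")
    expect_equal(full@totalPaired, nchar(GUIDE) - 1L)  # nt 1 never pairs
    expect_equal(full@loopGuide + full@loopTarget, 0L)

    # seed-only design
    seedOnly <- annotateDuplex(GUIDE, designTarget(GUIDE, 0, flank5 = 8,
                                                   flank3 = 8))
    expect_equal(seedOnly@architecture, "seed_only")

    # 7-nt 3'-supplementary design
    supp <- annotateDuplex(GUIDE, designTarget(GUIDE, 7, loopGuide = 2,
                                               loopTarget = 2, flank5 = 8,
                                               flank3 = 8, seed = 3))
    expect_equal(length(supp@threePrimeSpan), 7L)
    expect_equal(supp@architecture, "supplementary")

    # trigger-like design: extensive 3' pairing to the guide 3' end
    # across a central internal loop
    trig <- annotateDuplex(GUIDE, designTarget(GUIDE, 13, loopGuide = 3,
                                               loopTarget = 5, flank5 = 12,
                                               flank3 = 6, seed = 4))
    expect_equal(trig@architecture, "tdmd_like")
    expect_gte(length(trig@threePrimeSpan), 8L)
    expect_equal(trig@loopGuide, 3L)
    expect_equal(trig@loopTarget, 5L)
    expect_equal(trig@flank5, 12L)

    expect_equal(annotateDuplex(GUIDE, strrep("ACGG", 10))@architecture,
                 "no_site")
})

test_that("annotation is invariant to added flanks; spans shift, lengths do not", {
    base <- designTarget(GUIDE, 13, loopGuide = 3, loopTarget = 5,
                         flank5 = 5, flank3 = 5, seed = 6)
    a0 <- annotateDuplex(GUIDE, base)
    ext5 <- paste0(substr(strrep("CAGCA", 20), 1, 85), base)
    a1 <- annotateDuplex(GUIDE, ext5)
    expect_equal(a1@architecture, a0@architecture)
    expect_equal(length(a1@threePrimeSpan), length(a0@threePrimeSpan))
    expect_equal(a1@loopGuide, a0@loopGuide)
    expect_equal(a1@loopTarget, a0@loopTarget)
    expect_equal(a1@seedSite, a0@seedSite + 85L)
    expect_equal(a1@flank5, a0@flank5 + 85L)   # 85 nt of extra 5' flank
    expect_equal(a1@flank3, a0@flank3)
})

test_that("extending 3' complementarity never shrinks the paired span", {
    prev <- -1L
    for (tp in c(0, 2, 4, 6, 8, 10, 13)) {
        tgt <- designTarget(GUIDE, tp, loopGuide = 1, loopTarget = 3,
                            flank5 = 6, flank3 = 6, seed = 7)
        span <- length(annotateDuplex(GUIDE, tgt)@threePrimeSpan)
        expect_gte(span, prev)
        prev <- span
    }
})

test_that("G:U wobble pairing is honoured only behind the flag", {
    # plant a wobble at the first 3' position: guide G across target T
    g <- "TGAGGTAGTAGGTTGTATAGTTGA"
    tgt <- designTarget(g, 10, loopGuide = 0, loopTarget = 0,
                        flank5 = 4, flank3 = 4, seed = 8)
    # mutate the target base pairing guide nt 9 (a wobble if guide has G/T)
    ann <- annotateDuplex(g, tgt)
    s <- ann@seedSite
    gu9 <- substr(g, 9, 9)
    wob <- c(A = NA, C = NA, G = "T", T = "G")[[gu9]]
    tgtW <- tgt
    substr(tgtW, s - 1, s - 1) <- wob
    strict <- annotateDuplex(g, tgtW, gu = FALSE)
    loose <- annotateDuplex(g, tgtW, gu = TRUE)
    expect_gt(length(loose@threePrimeSpan), length(strict@threePrimeSpan))
})
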