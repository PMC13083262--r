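# small deterministic fixtures shared across test files

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

smallDict <- function() {
    MirnaDictionary(
        name = c("mirA-5p", "mirA-3p", "mirB-5p", "mirB-3p"),
        sequence = c("TGAGGTAGTAGGTTGTATAGTT",
                     "CTATACAATCTACTGTCTTTCC",
                     "TGGAAGACTAGTGATTTTGTTG",
                     "CAACAAATCACAGTCTGCCATA"),
        hairpinId = c("hpA", "hpA", "hpB", "hpB"),
        arm = c("5p", "3p", "5p", "3p"),
        role = c("mature", "passenger", "mature", "passenger"),
        context3p = c("GATTCCGCTG", "ACGTACGTAC", "TTGACCGAAT", "GGCATTCAGA"))
}

twoGroupDesign <- function() {
    stats::setNames(c(rep("KO", 3), rep("control", 3)),
                    c(paste0("KO_", 1:3), paste0("control_", 1:3)))
}

unitSizeFactors <- function(design = twoGroupDesign()) {
    SizeFactors(stats::setNames(rep(1, length(design)), names(design)),
                provenance = "summed")
}

# a standard two-target co-IP gel truth: trigger vs seed-only at one
# ZSWIM8 concentration, with the obligatory 0 nM and T6B control lanes
coipGelTruth <- function(fTrigger, fSeedOnly, conc = 30, noiseCv = 0,
                         seed = 1L) {
    gelTruth(
        targetLabel = rep(c("trigger", "seed_only"), each = 3),
        baitLabel = rep(c("none", "ZSWIM8", "T6B"), 2),
        baitConc = rep(c(0, conc, NA), 2),
        trueFractionBound = c(0, fTrigger, 1, 0, fSeedOnly, 1),
        noiseCv = noiseCv, seed = seed)
}

# independent brute-force adapter scanner: leftmost placement where the
# adapter (or an adapter prefix reaching the read end, overlap >=
# minOverlap) matches with at most floor(rate * overlap) mismatches
refAdapterScan <- function(seq, adapter, minOverlap, rate = 0) {
    s <- strsplit(seq, "")[[1]]
    a <- strsplit(adapter, "")[[1]]
    n <- length(s); la <- length(a)
    for (p in seq_len(n)) {
        ov <- min(la, n - p + 1L)
        full <- ov == la
        atEnd <- (p + ov - 1L) == n
        if (!full && !atEnd) next
        if (!full && ov < minOverlap) next
        if (sum(s[p:(p + ov - 1L)] != a[seq_len(ov)]) <= floor(rate * ov))
            return(p)
    }
    NA_integer_
}

# independent exhaustive 3'-register enumeration with its own pairing
# rules; returns best (length, loopTarget, loopGuide) under the same
# ordering contract as alignThreePrime
refEnumerateRegisters <- function(guide, target, seedSite,
                                  maxLoopGuide = 8, maxLoopTarget = 16,
                                  gu = FALSE) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    isPair <- function(gb, tb) {
        if (comp[[gb]] == tb) return(TRUE)
        if (gu && ((gb == "G" && tb == "T") || (gb == "T" && tb == "G")))
            return(TRUE)
        FALSE
    }
    g <- strsplit(guide, "")[[1]]
    t <- strsplit(target, "")[[1]]
    cand <- list()
    for (lg in 0:maxLoopGuide) for (lt in 0:maxLoopTarget) {
        k <- 0L
        repeat {
            gp <- 9L + lg + k
            tp <- seedSite - 1L - lt - k
            if (gp > length(g) || tp < 1L || !isPair(g[gp], t[tp])) break
            k <- k + 1L
        }
        cand[[length(cand) + 1L]] <- c(len = k, lt = lt, lg = lg)
    }
    m <- do.call(rbind, cand)
    m <- m[order(-m[, "len"], m[, "lt"], m[, "lg"]), , drop = FALSE]
    m[1L, ]
}

# numerical oracle for the binding equilibrium: solve
# (A - x)(B - x) = Kd * x for the complex concentration x by bisection
# plus Newton refinement, independent of the closed form
refEquilibriumFraction <- function(stock, df, targetTotal, kd, fmax) {
    A <- df * stock; B <- targetTotal
    f <- function(x) (A - x) * (B - x) - kd * x
    x <- uniroot(f, c(0, min(A, B)), tol = .Machine$double.eps^0.75)$root
    for (i in 1:8) {   # Newton polish
        fp <- -(A - x) - (B - x) - kd
        x <- x - f(x) / fp
    }
    x / B * fmax
}
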