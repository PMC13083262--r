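.pairMatrix <- function(gu = FALSE) {
    # DNA space; guide base -> complementary target base(s)
    wc <- list(A = "T", C = "G", G = "C", T = "A")
    if (gu) {
        wc$G <- c("C", "T")   # guide G : target U
        wc$T <- c("A", "G")   # guide U : target G
    }
    wc
}

.paired <- function(g, t, pm) t %in% pm[[g]]

#' Find seed-match sites in a target
#'
#' Returns every 1-based target position at which the reverse complement
#' of the guide seed (nucleotides 2-8) occurs contiguously, i.e. every
#' perfect 7-mer seed match (Watson-Crick-Franklin pairing only).
#'
#' @param guide miRNA guide sequence, 5' to 3', >= 14 nt.
#' @param target target sequence, 5' to 3'.
#' @return integer vector of match start positions (possibly empty).
#' @export
findSeedSite <- function(guide, target) {
    .checkAlphabet(guide, "guide")
    .checkAlphabet(target, "target")
    if (nchar(guide) < 14L)
        stop("guide must be at least 14 nt", call. = FALSE)
    g <- .dnaNorm(guide)
    t <- .dnaNorm(target)
    seedRc <- .revComp(substr(g, .SEED_START, .SEED_END))
    hits <- gregexpr(paste0("(?=", seedRc, ")"), t, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Best 3'-region pairing register
#'
#' Given a seed match, searches all internal-loop combinations
#' (unpaired guide nucleotides after position 8, unpaired target
#' nucleotides 5' of the seed match) within the given bounds, and
#' returns the register maximizing the number of contiguous pairs
#' between the guide 3' region (nucleotides >= 9) and the target. Ties
#' are broken by smaller target loop, then smaller guide loop.
#'
#' @param guide,target sequences, 5' to 3'.
#' @param seedSite 1-based target position of the seed match (from
#'   \code{\link{findSeedSite}}).
#' @param maxLoopGuide,maxLoopTarget loop-search bounds (defaults 8 and
#'   16 nt).
#' @param gu allow G:U wobble pairs (default FALSE:
#'   Watson-Crick-Franklin only).
#' @return list with \code{length} (contiguous 3' pairs, possibly 0),
#'   \code{loopGuide}, \code{loopTarget}, \code{guideStart},
#'   \code{guideEnd}, \code{targetStart}, \code{targetEnd} (NA when
#'   \code{length} is 0).
#' @export
alignThreePrime <- function(guide, target, seedSite, maxLoopGuide = 8L,
                            maxLoopTarget = 16L, gu = FALSE) {
    g <- strsplit(.dnaNorm(guide), "")[[1L]]
    t <- strsplit(.dnaNorm(target), "")[[1L]]
    if (seedSite < 1L || seedSite + 6L > length(t))
        stop("seedSite does not fit in the target", call. = FALSE)
    pm <- .pairMatrix(gu)
    Lg <- length(g)
    best <- list(length = 0L, loopGuide = 0L, loopTarget = 0L)
    for (lt in 0:maxLoopTarget) {
        for (lg in 0:maxLoopGuide) {
            gs <- 9L + lg
            ts <- seedSite - 1L - lt
            k <- 0L
            while (gs + k <= Lg && ts - k >= 1L &&
                   .paired(g[gs + k], t[ts - k], pm))
                k <- k + 1L
            if (k > best$length)
                best <- list(length = k, loopGuide = lg, loopTarget = lt)
        }
    }
    if (best$length == 0L)
        return(list(length = 0L, loopGuide = 0L, loopTarget = 0L,
                    guideStart = NA_integer_, guideEnd = NA_integer_,
                    targetStart = NA_integer_, targetEnd = NA_integer_))
    gs <- 9L + best$loopGuide
    ts <- seedSite - 1L - best$loopTarget
    list(length = best$length, loopGuide = best$loopGuide,
         loopTarget = best$loopTarget,
         guideStart = gs, guideEnd = gs + best$length - 1L,
         targetStart = ts - best$length + 1L, targetEnd = ts)
}

#' Annotate a miRNA-target duplex
#'
#' Finds all seed matches, computes the best 3'-region register for
#' each, annotates the site with maximal total pairing (seed block plus
#' 3' block), measures the internal loop on both strands and the target
#' flank lengths outside the outermost paired nucleotides, and
#' classifies the architecture. Guide nucleotide 1 is never counted as
#' paired.
#'
#' @inheritParams alignThreePrime
#' @return a \linkS4class{DuplexAnnotation} (architecture
#'   \code{"no_site"} when no seed match exists).
#' @export
annotateDuplex <- function(guide, target, maxLoopGuide = 8L,
                           maxLoopTarget = 16L, gu = FALSE) {
    sites <- findSeedSite(guide, target)
    g <- .dnaNorm(guide)
    t <- .dnaNorm(target)
    if (!length(sites))
        return(new("DuplexAnnotation", guide = g, target = t,
                   seedSite = NA_integer_, seedSpan = integer(0),
                   threePrimeSpan = integer(0), loopGuide = 0L,
                   loopTarget = 0L, flank5 = 0L, flank3 = 0L,
                   totalPaired = 0L, targetPairedRange = integer(0),
                   architecture = "no_site"))
    aligns <- lapply(sites, function(s)
        alignThreePrime(g, t, s, maxLoopGuide, maxLoopTarget, gu))
    totals <- 7L + vapply(aligns, `[[`, integer(1), "length")
    i <- which.max(totals)
    s <- sites[i]
    al <- aligns[[i]]
    tpSpan <- if (al$length > 0L) al$guideStart:al$guideEnd else integer(0)
    leftmost <- if (al$length > 0L) al$targetStart else s
    rightmost <- s + 6L
    ann <- new("DuplexAnnotation", guide = g, target = t,
               seedSite = s, seedSpan = .SEED_START:.SEED_END,
               threePrimeSpan = tpSpan,
               loopGuide = if (al$length > 0L) al$loopGuide else 0L,
               loopTarget = if (al$length > 0L) al$loopTarget else 0L,
               flank5 = leftmost - 1L,
               flank3 = nchar(t) - rightmost,
               totalPaired = totals[i],
               targetPairedRange = c(leftmost, rightmost),
               architecture = "no_site")
    ann@architecture <- classifyArchitecture(ann)
    validObject(ann)
    ann
}

#' Classify duplex architecture
#'
#' Operational class definitions (thresholds configurable):
#' \itemize{
#'   \item \code{full}: both loops absent and total pairing reaches at
#'     least guide length minus 2 (nucleotide 1 never pairs);
#'   \item \code{tdmd_like}: at least \code{minTdmdPairs} contiguous 3'
#'     pairs reaching within \code{maxEndGap} nt of the guide 3' end,
#'     across an internal loop of at least 1 nt on either strand;
#'   \item \code{seed_only}: at most 2 3'-region pairs;
#'   \item \code{supplementary}: everything else (limited 3' pairing, or
#'     extensive pairing that stops short of the guide 3' end).
#' }
#'
#' @param ann a \linkS4class{DuplexAnnotation}.
#' @param minTdmdPairs minimum 3'-pairing length for the TDMD-like call
#'   (default 8).
#' @param maxEndGap maximum unpaired guide nucleotides at the 3' end for
#'   the TDMD-like call (default 3).
#' @return one of \code{"no_site"}, \code{"seed_only"},
#'   \code{"supplementary"}, \code{"tdmd_like"}, \code{"full"}.
#' @export
classifyArchitecture <- function(ann, minTdmdPairs = 8L, maxEndGap = 3L) {
    stopifnot(is(ann, "DuplexAnnotation"))
    if (!length(ann@seedSpan)) return("no_site")
    Lg <- nchar(ann@guide)
    tpLen <- length(ann@threePrimeSpan)
    lastPaired <- if (tpLen) max(ann@threePrimeSpan) else .SEED_END
    if (ann@loopGuide == 0L && ann@loopTarget == 0L &&
        ann@totalPaired >= Lg - 2L)
        return("full")
    if (tpLen >= minTdmdPairs && (Lg - lastPaired) <= maxEndGap &&
        (ann@loopGuide + ann@loopTarget) >= 1L)
        return("tdmd_like")
    if (tpLen <= 2L) return("seed_only")
    "supplementary"
}

setMethod("show", "DuplexAnnotation", function(object) {
    cat(sprintf("DuplexAnnotation: %s\n", object@architecture))
    if (object@architecture != "no_site") {
        cat(sprintf("  seed match at target %d; 3' pairing %d nt (guide %s); loops guide %d / target %d; flanks 5' %d / 3' %d nt; %d nt paired\n",
                    object@seedSite, length(object@threePrimeSpan),
                    if (length(object@threePrimeSpan))
                        sprintf("%d-%d", min(object@threePrimeSpan),
                                max(object@threePrimeSpan)) else "-",
                    object@loopGuide, object@loopTarget,
                    object@flank5, object@flank3, object@totalPaired))
    }
})

#' Design a synthetic target with a chosen pairing architecture
#'
#' Builds a target sequence for a given guide by reverse-complementing
#' the requested guide blocks and inserting loop and flank nucleotides;
#' used to construct trigger-like, seed-only, 3'-supplementary and fully
#' complementary targets for tests and examples.
#'
#' @param guide guide sequence, 5' to 3'.
#' @param threePrimePairs number of guide 3'-region nucleotides (from
#'   position \code{9 + loopGuide} onward) to pair.
#' @param loopGuide,loopTarget internal-loop lengths (nt) on each strand.
#' @param flank5,flank3 target flank sequences (character) or lengths to
#'   fill with random nucleotides.
#' @param seed RNG seed for the random loop/flank fill.
#' @return target sequence (DNA space, 5' to 3').
#' @export
designTarget <- function(guide, threePrimePairs = 0L, loopGuide = 0L,
                         loopTarget = 0L, flank5 = 0L, flank3 = 0L,
                         seed = 1L) {
    g <- .dnaNorm(guide)
    Lg <- nchar(g)
    gs <- 9L + loopGuide
    if (threePrimePairs > 0L && gs + threePrimePairs - 1L > Lg)
        stop("3' pairing extends past the guide 3' end", call. = FALSE)
    .withSeed(seed, {
        fill <- function(x) if (is.character(x)) .dnaNorm(x) else
            if (x > 0L) .randomDna(1L, x) else ""
        seedBlock <- .revComp(substr(g, .SEED_START, .SEED_END))
        tpBlock <- if (threePrimePairs > 0L)
            .revComp(substr(g, gs, gs + threePrimePairs - 1L)) else ""
        # target reads 5'->3': [5' flank][3'-pairing block][loop][seed block][3' flank]
        loop <- fill(loopTarget)
        # avoid accidental extension of the 3' block across the loop
        paste0(fill(flank5), tpBlock, loop, seedBlock, fill(flank3))
    })
}
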