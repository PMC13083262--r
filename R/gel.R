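#' Quantify co-IP gel lanes
#'
#' Implements the band-quantification convention of the co-IP assay:
#' the mean of the blank rectangles estimates the image background, the
#' 0 nM (no-bait) lane estimates bait-independent recovery, and the T6B
#' lane (pan-AGO bait) defines full recovery. Per lane,
#' \deqn{value = \frac{(band - blank) - (band_{0nM} - blank)}
#'                    {(band_{T6B} - blank) - (band_{0nM} - blank)}}
#' Negative values are clipped at 0 with a warning. The result is
#' invariant to rescaling all intensities by a positive constant.
#'
#' @param gel a \linkS4class{GelQuant} with, per target, exactly one
#'   no-bait (\code{bait_label == "none"}) lane and one T6B lane.
#' @return a \link[S4Vectors]{DataFrame} with columns
#'   \code{target_label}, \code{bait_conc} and \code{normalized} for the
#'   non-control lanes.
#' @export
quantifyGel <- function(gel) {
    stopifnot(is(gel, "GelQuant"))
    lanes <- gel@lanes
    blank <- mean(gel@blanks)
    out <- list()
    for (tg in unique(lanes$target_label)) {
        sub <- lanes[lanes$target_label == tg, , drop = FALSE]
        i0 <- which(sub$bait_label == "none")
        iT <- which(sub$bait_label == "T6B")
        if (length(i0) != 1L)
            stop(sprintf("target '%s' lacks a single 0 nM (no-bait) lane", tg),
                 call. = FALSE)
        if (length(iT) != 1L)
            stop(sprintf("target '%s' lacks a single T6B lane", tg),
                 call. = FALSE)
        b0 <- sub$intensity[i0] - blank
        bT <- sub$intensity[iT] - blank
        denom <- bT - b0
        if (denom <= 0)
            stop(sprintf("target '%s': T6B signal does not exceed the 0 nM signal", tg),
                 call. = FALSE)
        rest <- sub[-c(i0, iT), , drop = FALSE]
        val <- ((rest$intensity - blank) - b0) / denom
        if (any(val < 0)) {
            warning("negative normalized binding clipped at 0")
            val <- pmax(val, 0)
        }
        out[[tg]] <- DataFrame(target_label = rest$target_label,
                               bait_conc = rest$bait_conc,
                               normalized = val)
    }
    do.call(rbind, unname(out))
}

#' Fold enrichment of a trigger over a reference target
#'
#' Ratio of normalized binding, trigger over reference, at each shared
#' bait concentration. Reference values at or below \code{floor} yield a
#' censored lower bound (\code{fold = trigger / floor},
#' \code{censored = TRUE}), so "greater than N-fold" statements remain
#' representable when the reference band is at background.
#'
#' @param quant a quantified lane table from \code{\link{quantifyGel}}.
#' @param trigger,reference target labels to compare.
#' @param floor censoring floor for the reference signal (default 1e-3).
#' @return a \link[S4Vectors]{DataFrame} with columns \code{bait_conc},
#'   \code{fold}, \code{censored}, plus a \code{"maxFold"} attribute
#'   (the maximum of the fold series) and \code{"maxCensored"}.
#' @export
enrichmentRatio <- function(quant, trigger, reference, floor = 1e-3) {
    tr <- quant[quant$target_label == trigger, , drop = FALSE]
    rf <- quant[quant$target_label == reference, , drop = FALSE]
    shared <- intersect(tr$bait_conc, rf$bait_conc)
    if (!length(shared))
        stop("no shared bait concentrations between the two targets",
             call. = FALSE)
    shared <- sort(shared)
    trv <- tr$normalized[match(shared, tr$bait_conc)]
    rfv <- rf$normalized[match(shared, rf$bait_conc)]
    cens <- rfv <= floor
    fold <- ifelse(cens, trv / floor, trv / rfv)
    out <- DataFrame(bait_conc = shared, fold = fold, censored = cens)
    imax <- which.max(fold)
    attr(out, "maxFold") <- fold[imax]
    attr(out, "maxCensored") <- cens[imax]
    out
}

#' Bait concentration required for a given pull-down level
#'
#' Linear interpolation in log-concentration between the two observed
#' points bracketing the requested normalized-binding level; a level
#' equal to an observed value returns that concentration exactly.
#'
#' @param conc bait concentrations (> 0), strictly increasing.
#' @param normalized normalized binding values at those concentrations.
#' @param level requested pull-down level; must be bracketed by (or equal
#'   to one of) the observed values.
#' @return interpolated concentration, in the units of \code{conc}.
#' @export
concAtPulldown <- function(conc, normalized, level) {
    if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
    ord <- order(conc)
    conc <- conc[ord]
    normalized <- normalized[ord]
    hit <- which(normalized == level)
    if (length(hit)) return(conc[hit[1L]])
    # first adjacent pair straddling the level
    lo <- normalized[-length(normalized)]
    hi <- normalized[-1L]
    br <- which((lo < level & hi > level) | (lo > level & hi < level))
    if (!length(br))
        stop(sprintf("level %g is not bracketed by the observed values [%g, %g]",
                     level, min(normalized), max(normalized)), call. = FALSE)
    i <- br[1L]
    w <- (level - normalized[i]) / (normalized[i + 1L] - normalized[i])
    exp(log(conc[i]) + w * (log(conc[i + 1L]) - log(conc[i])))
}
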