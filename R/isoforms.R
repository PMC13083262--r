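#' Per-isoform fold changes
#'
#' Applies the two-group fold-change estimator to individual
#' (miRNA, length) rows, using size factors previously computed on the
#' summed counts (enforced through the \code{SizeFactors} provenance
#' mark). Isoforms of excluded miRNAs are dropped, as are rows with no
#' reads in any sample.
#'
#' @param table an \linkS4class{IsoformCountTable}.
#' @param design named sample-to-group map.
#' @param sizeFactors \code{\link{SizeFactors}} with provenance
#'   \code{"summed"}.
#' @param include optional character vector of miRNAs to keep (default:
#'   all in the table).
#' @param exclude miRNAs to drop (e.g. \code{\link{excludedMirnas}}).
#' @param pseudocount added to normalized group means (default 0.5).
#' @return an \linkS4class{IsoformFoldChanges} (not yet centered).
#' @export
isoformFoldChanges <- function(table, design, sizeFactors,
                               include = NULL, exclude = character(0),
                               pseudocount = 0.5) {
    stopifnot(is(table, "IsoformCountTable"))
    if (!is(sizeFactors, "SizeFactors") ||
        !identical(sizeFactors@provenance, "summed"))
        stop("size factors must carry provenance 'summed' (compute them on sumIsoforms output)",
             call. = FALSE)
    mirna <- isoMirna(table)
    keep <- !(mirna %in% exclude)
    if (!is.null(include)) keep <- keep & mirna %in% include
    cts <- isoCounts(table)[keep, , drop = FALSE]
    rd <- DataFrame(mirna = mirna[keep], length = isoLength(table)[keep])
    nz <- rowSums(cts) > 0
    cts <- cts[nz, , drop = FALSE]
    rd <- rd[nz, , drop = FALSE]
    rownames(cts) <- paste0(rd$mirna, "_", rd$length)
    res <- .twoGroupNb(cts, design, sizeFactors, pseudocount)
    tab <- DataFrame(mirna = rd$mirna, length = rd$length,
                     lfc = res$lfc, se = res$se, p = res$p)
    new("IsoformFoldChanges", table = tab, centered = FALSE,
        median22 = NA_real_)
}

#' Center isoform fold changes on the 22-nt median
#'
#' Subtracts the median log2 fold change of all 22-nt species from every
#' isoform's fold change, so the 22-nt distribution is centered at zero
#' (as expected if canonical-length isoforms are insensitive to loss of
#' ZSWIM8).
#'
#' @param iso an \linkS4class{IsoformFoldChanges}.
#' @param referenceLength centering length (default 22 nt).
#' @return the object with \code{centered_lfc} filled; the median of the
#'   centered values at the reference length is exactly 0.
#' @export
centerOn22nt <- function(iso, referenceLength = 22L) {
    stopifnot(is(iso, "IsoformFoldChanges"))
    tab <- iso@table
    ref <- tab$lfc[tab$length == referenceLength & is.finite(tab$lfc)]
    if (!length(ref))
        stop(sprintf("no %d-nt entries with finite fold changes; cannot center",
                     referenceLength), call. = FALSE)
    med <- median(ref)
    tab$centered_lfc <- tab$lfc - med
    new("IsoformFoldChanges", table = tab, centered = TRUE, median22 = med)
}

#' @describeIn isoformFoldChanges fold-change table accessor.
#' @param iso an \code{IsoformFoldChanges}.
#' @export
isoformTable <- function(iso) iso@table

setMethod("show", "IsoformFoldChanges", function(object) {
    cat(sprintf("IsoformFoldChanges: %d (miRNA, length) rows, %d miRNAs%s\n",
                nrow(object@table), length(unique(object@table$mirna)),
                if (isTRUE(object@centered))
                    sprintf("; centered (22-nt median %.4g subtracted)",
                            object@median22)
                else " (not centered)"))
})

#' Short-isoform depletion test
#'
#' One-sided Wilcoxon signed-rank test of the centered log2 fold changes
#' of isoforms shorter than \code{shortThreshold} against zero, with
#' alternative "greater": if ZSWIM8 destabilizes extensively trimmed
#' miRNAs, short isoforms accumulate upon knockout and their centered
#' fold changes shift positive.
#'
#' @param iso a centered \linkS4class{IsoformFoldChanges}.
#' @param shortThreshold isoforms strictly shorter than this enter the
#'   test (default 19 nt).
#' @param minIsoforms minimum number of short isoforms required
#'   (default 5).
#' @return list with \code{statistic} (signed-rank V), \code{p},
#'   \code{effect} (median centered log2 fold change),
#'   \code{direction} (+1/-1/0) and \code{n}.
#' @export
shortIsoformTest <- function(iso, shortThreshold = 19L, minIsoforms = 5L) {
    stopifnot(is(iso, "IsoformFoldChanges"))
    if (!isTRUE(iso@centered))
        stop("center the fold changes (centerOn22nt) before testing",
             call. = FALSE)
    tab <- iso@table
    x <- tab$centered_lfc[tab$length < shortThreshold &
                          is.finite(tab$centered_lfc)]
    if (length(x) < minIsoforms)
        stop(sprintf("only %d isoforms shorter than %d nt; need >= %d",
                     length(x), shortThreshold, minIsoforms),
             call. = FALSE)
    wt <- suppressWarnings(wilcox.test(x, mu = 0, alternative = "greater"))
    eff <- median(x)
    list(statistic = unname(wt$statistic), p = wt$p.value, effect = eff,
         direction = sign(eff), n = length(x))
}
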