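#' Sum length isoforms per miRNA
#'
#' Collapses an isoform count table to a miRNA-by-sample matrix by summing
#' counts over lengths 13-31. The returned matrix is marked with
#' provenance \code{"summed"}, which \code{\link{estimateSizeFactors}}
#' propagates and \code{\link{isoformFoldChanges}} requires.
#'
#' @param table an \linkS4class{IsoformCountTable}.
#' @return an integer matrix (miRNA x sample) with a \code{"provenance"}
#'   attribute.
#' @export
sumIsoforms <- function(table) {
    stopifnot(is(table, "IsoformCountTable"))
    m <- rowsum(isoCounts(table), group = isoMirna(table), reorder = TRUE)
    attr(m, "provenance") <- "summed"
    m
}

#' Expression filter on summed counts
#'
#' Keeps a miRNA if and only if it has more than 5 reads (strictly) in at
#' least two knockout libraries and at least 30 reads in total across all
#' six libraries. Applied to raw (unnormalized) summed counts.
#'
#' @param summed miRNA x sample count matrix from
#'   \code{\link{sumIsoforms}}.
#' @param design named character vector mapping samples to \code{"KO"} or
#'   \code{"control"} (two groups required).
#' @param minPerKoLibrary,minKoLibraries,minTotal filter parameters
#'   (defaults 5, 2, 30).
#' @return character vector of retained miRNA names.
#' @export
filterExpressed <- function(summed, design, minPerKoLibrary = 5,
                            minKoLibraries = 2L, minTotal = 30) {
    .checkDesign(design, colnames(summed))
    ko <- names(design)[design == "KO"]
    passKo <- rowSums(summed[, ko, drop = FALSE] > minPerKoLibrary) >=
        minKoLibraries
    passTotal <- rowSums(summed[, names(design), drop = FALSE]) >= minTotal
    rownames(summed)[passKo & passTotal]
}

#' Per-sample size factors (with provenance)
#'
#' @param values positive numeric vector named by sample.
#' @param provenance the matrix the factors were computed on
#'   (\code{"summed"} for per-miRNA summed counts).
#' @return a \code{SizeFactors} object (numeric vector subclass).
#' @export
SizeFactors <- function(values, provenance = "unknown") {
    new("SizeFactors", values, provenance = provenance)
}

#' @rdname SizeFactors-class
#' @name SizeFactors-class
#' @aliases SizeFactors-class
#' @slot provenance character scalar recording the matrix the factors
#'   were derived from.
#' @exportClass SizeFactors
setClass("SizeFactors", contains = "numeric",
         slots = c(provenance = "character"))

setValidity("SizeFactors", function(object) {
    if (any(object@.Data <= 0)) return("size factors must be > 0")
    TRUE
})

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference miRNAs
#' of the ratio of that sample's count to the per-miRNA geometric mean
#' across samples; reference miRNAs are those with positive counts in
#' every sample.
#'
#' @param summed miRNA x sample count matrix (typically from
#'   \code{\link{sumIsoforms}}, restricted to expressed miRNAs).
#' @return a \code{\link{SizeFactors}} vector named by sample, carrying
#'   the input's provenance.
#' @export
estimateSizeFactors <- function(summed) {
    m <- as.matrix(summed)
    ref <- rowSums(m > 0) == ncol(m)
    if (!any(ref))
        stop("no miRNA has positive counts in every sample; cannot normalize",
             call. = FALSE)
    refm <- m[ref, , drop = FALSE]
    geo <- exp(rowMeans(log(refm)))
    sf <- apply(refm, 2L, function(col) median(col / geo))
    SizeFactors(setNames(sf, colnames(m)),
                provenance = attr(summed, "provenance") %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-group negative-binomial fold-change core used at the summed,
# passenger and isoform levels.
#
# lfc  = log2((mean normalized KO + pc) / (mean normalized control + pc))
# se   = delta-method SE using the NB variance model mu*a + disp*mu^2,
#        with a per-row method-of-moments dispersion pooled across both
#        groups and floored at 1e-8
# p    = two-sided Wald statistic referred to a t distribution with
#        Welch-Satterthwaite degrees of freedom (small-sample calibration
#        at n = 3 per group)
.twoGroupNb <- function(counts, design, sizeFactors, pseudocount = 0.5,
                        dispFloor = 1e-8) {
    counts <- as.matrix(counts)
    .checkDesign(design, colnames(counts))
    sf <- as.numeric(sizeFactors)[match(colnames(counts),
                                        names(sizeFactors))]
    if (anyNA(sf))
        stop("size factors missing for some samples", call. = FALSE)
    norm <- sweep(counts, 2L, sf, "/")
    ko <- design[colnames(counts)] == "KO"
    nK <- sum(ko); nC <- sum(!ko)
    if (nK < 2L || nC < 2L)
        stop("need at least 2 samples per group", call. = FALSE)
    muK <- rowMeans(norm[, ko, drop = FALSE])
    muC <- rowMeans(norm[, !ko, drop = FALSE])
    if (pseudocount == 0 && any(muK == 0 | muC == 0))
        stop("a group mean of zero with pseudocount 0 leaves the fold change undefined",
             call. = FALSE)
    aK <- mean(1 / sf[ko]); aC <- mean(1 / sf[!ko])
    vK <- apply(norm[, ko, drop = FALSE], 1L, var)
    vC <- apply(norm[, !ko, drop = FALSE], 1L, var)
    num <- (nK - 1) * (vK - muK * aK) + (nC - 1) * (vC - muC * aC)
    den <- (nK - 1) * muK^2 + (nC - 1) * muC^2
    disp <- ifelse(den > 0, pmax(num / den, dispFloor), dispFloor)
    varK <- muK * aK + disp * muK^2
    varC <- muC * aC + disp * muC^2
    A <- varK / nK / (muK + pseudocount)^2
    B <- varC / nC / (muC + pseudocount)^2
    lfc <- log2((muK + pseudocount) / (muC + pseudocount))
    se <- sqrt(A + B) / log(2)
    dfw <- ifelse(A + B > 0,
                  (A + B)^2 / (A^2 / (nK - 1) + B^2 / (nC - 1)), NA_real_)
    stat <- ifelse(se > 0, lfc / se, NA_real_)
    p <- ifelse(is.na(stat), NA_real_, 2 * pt(-abs(stat), dfw))
    DataFrame(mirna = rownames(counts), baseMeanKO = unname(muK),
              baseMeanControl = unname(muC), lfc = unname(lfc),
              se = unname(se), dispersion = unname(disp),
              stat = unname(stat), df = unname(dfw), p = unname(p))
}

#' Two-group fold-change estimation on summed counts
#'
#' Transparent negative-binomial estimator of the knockout/control log2
#' fold change per miRNA: the ratio of pseudocounted group means of
#' size-factor-normalized counts, a delta-method standard error using a
#' per-miRNA method-of-moments NB dispersion (pooled across groups,
#' floored at 1e-8), and a two-sided Wald statistic referred to a t
#' distribution with Welch-Satterthwaite degrees of freedom.
#'
#' @param summed miRNA x sample count matrix (filtered).
#' @param design named sample-to-group map (\code{"KO"}/\code{"control"}).
#' @param sizeFactors per-sample \code{\link{SizeFactors}} (or named
#'   numeric).
#' @param pseudocount added to the normalized group means (default 0.5).
#' @return a \link[S4Vectors]{DataFrame} with columns \code{mirna},
#'   \code{baseMeanKO}, \code{baseMeanControl}, \code{lfc}, \code{se},
#'   \code{dispersion}, \code{stat}, \code{df}, \code{p}.
#' @export
estimateFoldChanges <- function(summed, design, sizeFactors,
                                pseudocount = 0.5) {
    .twoGroupNb(summed, design, sizeFactors, pseudocount)
}

#' Benjamini-Hochberg adjustment (plug-in surface)
#'
#' Step-up BH with monotonicity enforcement, via
#' \code{\link[stats]{p.adjust}}. Alternative adjusters (e.g. a
#' bi-beta-uniform-mixture model) can be substituted anywhere a
#' \code{padjFun} argument is accepted; BH is the default throughout.
#'
#' @param p p-values in [0, 1] (NA allowed).
#' @return adjusted p-values.
#' @export
adjustBH <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    p.adjust(p, method = "BH")
}

#' Classify potentially ZSWIM8-sensitive miRNAs
#'
#' Combines the three sensitivity calls used to exclude miRNAs whose
#' dominant isoform may undergo TDMD: (1) BH-adjusted p below
#' \code{alpha} with a positive log2 fold change; (2) the mature fold
#' change separated from the passenger-strand fold change beyond their
#' joint standard errors (directional by default: mature above
#' passenger, as expected if ZSWIM8 alters degradation rather than
#' production); (3) membership in an external list of previously called
#' sensitive miRNAs. Passenger fold changes are computed from the
#' unfiltered summed counts (passengers are often lowly expressed), with
#' counts of multiple passengers summed before estimation. The excluded
#' set is the union of the three flags and the significant set.
#'
#' @param results output of \code{\link{estimateFoldChanges}} on the
#'   filtered summed counts.
#' @param summedAll unfiltered summed count matrix (all collapsed
#'   entries).
#' @param dict the \linkS4class{MirnaDictionary} (for the
#'   mature-to-passenger hairpin map).
#' @param design,sizeFactors as in \code{\link{estimateFoldChanges}};
#'   the size factors are those computed on the summed counts.
#' @param externalList species names previously annotated as sensitive
#'   (matched against collapsed-entry member names).
#' @param alpha significance threshold for flag 1 (default 0.05).
#' @param directional if FALSE, flag 2 fires on separation in either
#'   direction.
#' @param significant optional logical vector (parallel to
#'   \code{results}) marking the significantly up-regulated set; default
#'   is flag 1 itself (the BH stand-in for the upstream
#'   mixture-model call).
#' @param pseudocount passed to the passenger fold-change estimator.
#' @param padjFun p-value adjuster (default \code{\link{adjustBH}}).
#' @return a \linkS4class{StabilityResult}.
#' @export
classifyPotentiallySensitive <- function(results, summedAll, dict, design,
                                         sizeFactors,
                                         externalList = character(0),
                                         alpha = 0.05, directional = TRUE,
                                         significant = NULL,
                                         pseudocount = 0.5,
                                         padjFun = adjustBH) {
    padj <- padjFun(results$p)
    flag1 <- !is.na(padj) & padj < alpha & results$lfc > 0

    # passenger fold changes at the collapsed level, from unfiltered counts
    index <- buildCollapsedIndex(dict)
    sp <- mirnaSpecies(dict)
    speciesColl <- setNames(
        rep(index@collapsedNames, lengths(index@members)),
        unlist(index@members))
    pasByHairpin <- split(sp$name[sp$role == "passenger"],
                          sp$hairpin_id[sp$role == "passenger"])

    pasCounts <- matrix(NA_real_, nrow = nrow(results),
                        ncol = ncol(summedAll),
                        dimnames = list(results$mirna, colnames(summedAll)))
    hasPas <- logical(nrow(results))
    for (i in seq_len(nrow(results))) {
        members <- strsplit(results$mirna[i], "/", fixed = TRUE)[[1]]
        hp <- unique(sp$hairpin_id[match(members, sp$name)])
        pas <- unique(unlist(pasByHairpin[hp[!is.na(hp)]]))
        pas <- setdiff(pas, members)
        if (!length(pas)) next
        pasRows <- unique(speciesColl[pas])
        miss <- setdiff(pasRows, rownames(summedAll))
        if (length(miss)) {
            warning(sprintf("passenger entries absent from counts for '%s'; passenger flag undefined",
                            results$mirna[i]))
            next
        }
        hasPas[i] <- TRUE
        pasCounts[i, ] <- colSums(summedAll[pasRows, , drop = FALSE])
    }

    pasLfc <- pasSe <- rep(NA_real_, nrow(results))
    if (any(hasPas)) {
        pr <- .twoGroupNb(pasCounts[hasPas, , drop = FALSE], design,
                          sizeFactors, pseudocount)
        pasLfc[hasPas] <- pr$lfc
        pasSe[hasPas] <- pr$se
    }
    sep <- (results$lfc - results$se) > (pasLfc + pasSe)
    if (!directional)
        sep <- sep | ((pasLfc - pasSe) > (results$lfc + results$se))
    flag2 <- !is.na(sep) & sep

    flag3 <- vapply(strsplit(results$mirna, "/", fixed = TRUE),
                    function(m) any(m %in% externalList) ||
                        any(results$mirna %in% externalList &
                            results$mirna %in% paste(m, collapse = "/")),
                    logical(1))
    if (is.null(significant)) significant <- flag1

    tab <- DataFrame(results)
    tab$padj <- padj
    tab$passenger_lfc <- pasLfc
    tab$passenger_se <- pasSe
    tab$flag_padj <- flag1
    tab$flag_passenger <- flag2
    tab$flag_annotation <- flag3
    tab$excluded <- flag1 | flag2 | flag3 | significant
    new("StabilityResult", table = tab, design = design)
}

#' @describeIn classifyPotentiallySensitive result table accessor.
#' @param x a \code{StabilityResult}.
#' @export
stabilityTable <- function(x) x@table

#' @describeIn classifyPotentiallySensitive names of excluded miRNAs.
#' @export
excludedMirnas <- function(x) x@table$mirna[x@table$excluded]

setMethod("show", "StabilityResult", function(object) {
    tab <- object@table
    cat(sprintf("StabilityResult: %d miRNAs; %d flagged by padj, %d by passenger separation, %d by annotation; %d excluded\n",
                nrow(tab), sum(tab$flag_padj), sum(tab$flag_passenger),
                sum(tab$flag_annotation), sum(tab$excluded)))
    show(head(tab[, c("mirna", "lfc", "se", "p", "padj", "excluded")], 5L))
})

#' One-call differential stability analysis
#'
#' Sums isoforms, applies the expression filter, estimates
#' median-of-ratios size factors on the filtered summed counts, computes
#' fold changes, and classifies potentially sensitive miRNAs.
#'
#' @inheritParams classifyPotentiallySensitive
#' @param table an \linkS4class{IsoformCountTable}.
#' @param dict the dictionary used to build the table.
#' @return a list with \code{result} (\linkS4class{StabilityResult}),
#'   \code{sizeFactors}, \code{summed}, and \code{kept} (filter
#'   survivors).
#' @export
stabilityAnalysis <- function(table, dict, design,
                              externalList = character(0),
                              pseudocount = 0.5, alpha = 0.05,
                              directional = TRUE) {
    summed <- sumIsoforms(table)
    kept <- filterExpressed(summed, design)
    if (!length(kept))
        stop("no miRNA passes the expression filter", call. = FALSE)
    filt <- summed[kept, , drop = FALSE]
    attr(filt, "provenance") <- "summed"
    sf <- estimateSizeFactors(filt)
    res <- estimateFoldChanges(filt, design, sf, pseudocount)
    cls <- classifyPotentiallySensitive(res, summed, dict, design, sf,
                                        externalList = externalList,
                                        alpha = alpha,
                                        directional = directional,
                                        pseudocount = pseudocount)
    list(result = cls, sizeFactors = sf, summed = summed, kept = kept)
}
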