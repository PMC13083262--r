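.isoLengths <- function() .MIN_ISO_LEN:.MAX_ISO_LEN

#' Default isomiR length profile
#'
#' A unimodal distribution over lengths 13-31 nt peaking at the reference
#' length (22 nt for canonical miRNAs): exponential decay away from the
#' mode on 17-25 nt, plus a small uniform 3'-trimming tail over 13-16 nt.
#'
#' @param mode modal isoform length (nt).
#' @param decay exponential decay per nt away from the mode.
#' @param trimTail total mass assigned to the 13-16-nt trimming tail.
#' @return a probability vector over lengths 13..31.
#' @export
defaultLengthProfile <- function(mode = 22L, decay = 1.1, trimTail = 0.004) {
    len <- .isoLengths()
    w <- ifelse(len >= 17L & len <= 25L, exp(-abs(len - mode) / decay), 0)
    w <- w / sum(w) * (1 - trimTail)
    w[len < 17L] <- trimTail / sum(len < 17L)
    names(w) <- as.character(len)
    w
}

#' Construct ground truth for an isoform-count simulation
#'
#' Defaults emulate the study design: 3 knockout vs 3 control libraries,
#' log-normal per-species abundances, dispersion 0.05, modest library-size
#' variation, and a TDMD effect of +2 log2 units (4-fold accumulation upon
#' knockout, typical of reported ZSWIM8-sensitive miRNAs) on a chosen set
#' of sensitive species.
#'
#' @param dict a \linkS4class{MirnaDictionary}; one count series is
#'   simulated per species.
#' @param tdmdSpecies names of species carrying a true TDMD effect.
#' @param tdmdLfc true log2 knockout/control effect for those species.
#' @param shortLfc additional true log2 effect applied to isoforms shorter
#'   than \code{shortThreshold} (all species).
#' @param baseAbundance expected count at the modal length; scalar or
#'   per-species named vector. Default draws log-normal around 500.
#' @param dispersion negative-binomial dispersion; scalar or named vector.
#' @param sizeFactorTruth per-sample true scale factors (named by sample);
#'   default draws log-normal with 20% CV.
#' @param lengthProfile per-species matrix over lengths 13..31, or NULL
#'   for \code{\link{defaultLengthProfile}} everywhere.
#' @param shortThreshold isoforms strictly shorter than this get
#'   \code{shortLfc} (default 19 nt).
#' @param nKo,nControl samples per group (default 3 and 3).
#' @param seed integer seed used for the random defaults here and for
#'   count generation in \code{\link{simulateIsoformCounts}}.
#' @return a \linkS4class{SimulationTruth}.
#' @export
simulationTruth <- function(dict, tdmdSpecies = character(0), tdmdLfc = 2,
                            shortLfc = 0, baseAbundance = NULL,
                            dispersion = 0.05, sizeFactorTruth = NULL,
                            lengthProfile = NULL, shortThreshold = 19L,
                            nKo = 3L, nControl = 3L, seed = 1L) {
    spNames <- mirnaNames(dict)
    n <- length(spNames)
    samples <- c(sprintf("KO_%d", seq_len(nKo)),
                 sprintf("control_%d", seq_len(nControl)))
    design <- setNames(c(rep("KO", nKo), rep("control", nControl)), samples)
    .withSeed(seed, {
        if (is.null(baseAbundance))
            baseAbundance <- rlnorm(n, meanlog = log(500), sdlog = 1)
        if (is.null(sizeFactorTruth)) {
            sf <- rlnorm(length(samples), 0, sqrt(log(1 + 0.2^2)))
            sizeFactorTruth <- setNames(sf / exp(mean(log(sf))), samples)
        }
        baseAbundance <- .perSpecies(baseAbundance, spNames, "baseAbundance")
        dispersion <- .perSpecies(dispersion, spNames, "dispersion")
        lfcTdmd <- setNames(rep(0, n), spNames)
        bad <- setdiff(tdmdSpecies, spNames)
        if (length(bad))
            stop("tdmdSpecies not in dictionary: ",
                 paste(bad, collapse = ", "), call. = FALSE)
        lfcTdmd[tdmdSpecies] <- tdmdLfc
        lfcShort <- .perSpecies(shortLfc, spNames, "shortLfc")
        if (is.null(lengthProfile)) {
            lengthProfile <- matrix(rep(defaultLengthProfile(), each = n),
                                    nrow = n,
                                    dimnames = list(spNames,
                                                    as.character(.isoLengths())))
        }
        if (is.null(names(sizeFactorTruth)))
            names(sizeFactorTruth) <- samples
        new("SimulationTruth", design = design,
            baseAbundance = baseAbundance,
            lengthProfile = lengthProfile, lfcTdmd = lfcTdmd,
            lfcShort = lfcShort, dispersion = dispersion,
            sizeFactorTruth = sizeFactorTruth,
            shortThreshold = as.integer(shortThreshold),
            seed = as.integer(seed))
    })
}

.perSpecies <- function(x, spNames, what) {
    if (length(x) == 1L) x <- rep(x, length(spNames))
    if (length(x) != length(spNames))
        stop(sprintf("'%s' must be scalar or one value per species", what),
             call. = FALSE)
    setNames(as.numeric(x), spNames)
}

#' Assemble an IsoformCountTable
#'
#' @param counts integer matrix, rows parallel to \code{mirna}/\code{length},
#'   columns are samples.
#' @param mirna collapsed miRNA name per row.
#' @param length isoform length per row (13-31 nt).
#' @param colData optional per-sample \link[S4Vectors]{DataFrame} with
#'   provenance counters.
#' @return an \linkS4class{IsoformCountTable}.
#' @export
IsoformCountTable <- function(counts, mirna, length, colData = NULL) {
    counts <- as.matrix(counts)
    mode(counts) <- "integer"
    rd <- DataFrame(mirna = as.character(mirna), length = as.integer(length))
    rownames(counts) <- paste0(rd$mirna, "_", rd$length)
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = colData)
    new("IsoformCountTable", se)
}

#' @describeIn IsoformCountTable counts matrix accessor.
#' @param x an \code{IsoformCountTable}.
#' @export
isoCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn IsoformCountTable collapsed miRNA name per row.
#' @export
isoMirna <- function(x) SummarizedExperiment::rowData(x)$mirna

#' @describeIn IsoformCountTable isoform length per row.
#' @export
isoLength <- function(x) SummarizedExperiment::rowData(x)$length

setMethod("show", "IsoformCountTable", function(object) {
    cat(sprintf("IsoformCountTable: %d (miRNA, length) rows x %d samples; %d miRNAs, lengths %d-%d nt\n",
                nrow(object), ncol(object),
                length(unique(isoMirna(object))),
                min(isoLength(object)), max(isoLength(object))))
    cd <- SummarizedExperiment::colData(object)
    if ("total_reads" %in% colnames(cd))
        cat("  reads/sample: ",
            paste(sprintf("%s=%d", rownames(cd), cd$total_reads),
                  collapse = ", "), "\n", sep = "")
})

#' Simulate an isoform-resolved count table
#'
#' Draws negative-binomial counts for every (species, length, sample)
#' cell. The expected count of species \eqn{i} at length \eqn{l} in sample
#' \eqn{j} is
#' \deqn{sf_j \cdot base_i \cdot profile_{il} \cdot
#'       2^{g_j (lfcTdmd_i + lfcShort_{il})}}
#' where \eqn{g_j} is 1 for knockout samples and 0 for controls, the
#' length profile is renormalized so the modal length carries
#' \eqn{base_i}, and \eqn{lfcShort_{il}} applies only when
#' \eqn{l < shortThreshold}. Species sharing a 13-nt prefix are emitted
#' under their collapsed name (counts summed), so the table matches what
#' the read-mapping pipeline can recover. Dispersions below 1e-10 fall
#' back to Poisson sampling.
#'
#' @param dict a \linkS4class{MirnaDictionary}.
#' @param truth a \linkS4class{SimulationTruth} built on the same
#'   dictionary.
#' @return an \linkS4class{IsoformCountTable}; ground truth (including the
#'   per-cell expectation matrix) is embedded in \code{metadata()$truth}.
#' @export
simulateIsoformCounts <- function(dict, truth) {
    stopifnot(is(dict, "MirnaDictionary"), is(truth, "SimulationTruth"))
    spNames <- mirnaNames(dict)
    if (!identical(sort(spNames), sort(names(truth@baseAbundance))))
        stop("truth species do not match the dictionary", call. = FALSE)
    design <- truth@design
    samples <- names(design)
    lens <- .isoLengths()
    nL <- length(lens)
    prof <- truth@lengthProfile[spNames, , drop = FALSE]
    # normalize so baseAbundance is the expected count at the modal length
    modalW <- apply(prof, 1L, max)
    base <- truth@baseAbundance[spNames] / ifelse(modalW > 0, modalW, 1)

    shortMask <- lens < truth@shortThreshold
    g <- as.numeric(design == "KO")

    nS <- length(spNames)
    mu <- array(0, dim = c(nS, nL, length(samples)),
                dimnames = list(spNames, as.character(lens), samples))
    for (j in seq_along(samples)) {
        eff <- outer(truth@lfcTdmd[spNames], rep(1, nL)) +
            outer(truth@lfcShort[spNames], as.numeric(shortMask))
        mu[, , j] <- truth@sizeFactorTruth[samples[j]] * base * prof *
            2^(g[j] * eff)
    }

    counts <- .withSeed(truth@seed, {
        out <- array(0L, dim = dim(mu), dimnames = dimnames(mu))
        disp <- truth@dispersion[spNames]
        for (i in seq_len(nS)) {
            m <- as.numeric(mu[i, , ])
            if (disp[i] < 1e-10) {
                out[i, , ] <- rpois(length(m), m)
            } else {
                out[i, , ] <- rnbinom(length(m), mu = m, size = 1 / disp[i])
            }
        }
        out
    })

    # collapse species sharing a 13-nt prefix to their collapsed entry
    idx <- buildCollapsedIndex(dict)
    sp <- mirnaSpecies(dict)
    pref <- substr(sp$sequence, 1L, .PREFIX_LEN)
    collName <- idx@collapsedNames[match(pref, idx@prefixes)]

    rows <- expand.grid(mirna = unique(collName), length = lens,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$mirna, rows$length), , drop = FALSE]
    mat <- matrix(0L, nrow = nrow(rows), ncol = length(samples),
                  dimnames = list(NULL, samples))
    muColl <- matrix(0, nrow = nrow(rows), ncol = length(samples),
                     dimnames = list(NULL, samples))
    key <- paste0(rows$mirna, "_", rows$length)
    for (i in seq_len(nS)) {
        k <- match(paste0(collName[i], "_", lens), key)
        mat[k, ] <- mat[k, ] + counts[i, , ]
        muColl[k, ] <- muColl[k, ] + mu[i, , ]
    }

    cd <- DataFrame(
        sample = samples, group = unname(design),
        total_reads = colSums(mat),
        adapter_rejected = 0L, quality_rejected = 0L,
        too_short = 0L, too_long = 0L, unassigned = 0L,
        assigned = colSums(mat), row.names = samples)
    tab <- IsoformCountTable(mat, rows$mirna, rows$length, colData = cd)
    metadata(tab)$truth <- list(
        truth = truth, mu = muColl, speciesToCollapsed = setNames(collName, spNames))
    validObject(tab)
    tab
}
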