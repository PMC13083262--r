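#' Synthesize FASTQ libraries from an isoform count table
#'
#' The inverse of the read-processing pipeline: every count unit becomes
#' one read consisting of the isoform sequence (the collapsed entry's
#' first member, truncated or 3'-context-extended to the isoform length),
#' the 3' adapter, and random filler up to a fixed read length. Good reads
#' carry per-base qualities drawn uniformly from Q32-Q40. On top of the
#' true reads, a binomially drawn number of contaminating reads is added:
#' half unmappable (random inserts, good quality) and half low-quality
#' (all bases at or below Q30), exercising the unassigned and
#' quality-rejected bins.
#'
#' @param table an \linkS4class{IsoformCountTable}.
#' @param dict the \linkS4class{MirnaDictionary} the table was built on.
#' @param adapter 3' adapter sequence (>= 6 nt).
#' @param contaminationRate expected contaminating reads per true read.
#' @param dir output directory (created if needed).
#' @param readLength fixed read length (nt); reads longer than this from
#'   insert + adapter alone are emitted unpadded, never truncated.
#' @param seed integer seed.
#' @return named character vector of FASTQ paths (one per sample), with a
#'   \code{"truth"} attribute giving the sidecar JSON path that records
#'   the generating counts.
#' @export
countsToFastq <- function(table, dict, adapter, contaminationRate = 0,
                          dir = tempfile("fastq"), readLength = 60L,
                          seed = 1L) {
    if (nchar(adapter) < 6L) stop("adapter must be >= 6 nt", call. = FALSE)
    .assertScalar(contaminationRate, "contaminationRate", lower = 0)
    adapter <- .dnaNorm(adapter)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    index <- buildCollapsedIndex(dict)
    firstMember <- vapply(index@members, `[`, character(1), 1L)
    names(firstMember) <- index@collapsedNames

    cts <- isoCounts(table)
    mirna <- isoMirna(table)
    len <- isoLength(table)
    samples <- colnames(cts)
    paths <- setNames(file.path(dir, paste0(samples, ".fastq")), samples)

    .withSeed(seed, {
        for (s in samples) {
            n <- cts[, s]
            keep <- n > 0L
            inserts <- character(0)
            if (any(keep)) {
                member <- firstMember[mirna[keep]]
                if (anyNA(member))
                    stop("table contains entries absent from the dictionary",
                         call. = FALSE)
                isoSeq <- mapply(function(m, l) isoformSequence(dict, m, l),
                                 member, len[keep])
                inserts <- rep(isoSeq, n[keep])
            }
            nTrue <- length(inserts)
            nExtra <- if (contaminationRate > 0 && nTrue > 0)
                rbinom(1L, nTrue, min(contaminationRate, 1)) else 0L
            nBadQ <- nExtra %/% 2L
            nUnmap <- nExtra - nBadQ
            contamIns <- .randomDna(nExtra, 22L)

            mkRead <- function(ins) {
                if (!length(ins)) return(character(0))
                core <- paste0(ins, adapter)
                pad <- pmax(readLength - nchar(core), 0L)
                paste0(core, vapply(pad, function(p)
                    if (p > 0) paste(sample(c("A", "C", "G", "T"), p,
                                            replace = TRUE), collapse = "")
                    else "", character(1)))
            }
            goodReads <- mkRead(c(inserts, contamIns[seq_len(nUnmap)]))
            badReads <- mkRead(contamIns[nUnmap + seq_len(nBadQ)])

            qualFor <- function(reads, lo, hi)
                vapply(nchar(reads), function(L)
                    .phredToChar(sample(lo:hi, L, replace = TRUE)),
                    character(1))
            allReads <- c(goodReads, badReads)
            allQuals <- c(qualFor(goodReads, 32L, 40L),
                          qualFor(badReads, 2L, 30L))
            ord <- sample.int(length(allReads))
            xs <- Biostrings::QualityScaledDNAStringSet(
                Biostrings::DNAStringSet(allReads[ord]),
                Biostrings::PhredQuality(allQuals[ord]))
            names(xs) <- sprintf("%s_read%06d", s, seq_along(xs))
            if (file.exists(paths[[s]])) file.remove(paths[[s]])
            Biostrings::writeQualityScaledXStringSet(xs, paths[[s]])
        }
    })

    truthPath <- file.path(dir, "truth.json")
    jsonlite::write_json(
        list(samples = samples,
             adapter = adapter,
             contaminationRate = contaminationRate,
             counts = data.frame(mirna = mirna, length = len,
                                 as.data.frame(cts))),
        truthPath, auto_unbox = TRUE, digits = NA)
    attr(paths, "truth") <- truthPath
    paths
}
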