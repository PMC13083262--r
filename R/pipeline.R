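#' Trim a 3' sequencing adapter
#'
#' Finds the leftmost occurrence of the adapter in each read, allowing a
#' truncated adapter prefix at the read 3' end provided the overlap is at
#' least \code{minOverlap} nt, and removes the adapter and everything 3'
#' of it. Reads in which no adapter is found are flagged as rejected
#' (a return state, not an error). With \code{maxMismatchRate > 0}, up to
#' \code{floor(rate * overlap)} mismatches are tolerated per placement.
#'
#' @param seqs character vector of read sequences.
#' @param quals character vector of Phred+33 quality strings (or NULL).
#' @param adapter adapter sequence (non-empty).
#' @param minOverlap minimum adapter prefix length at the read end.
#' @param maxMismatchRate tolerated mismatch fraction per placement
#'   (default 0 = exact).
#' @return a \link[S4Vectors]{DataFrame} with columns \code{insert},
#'   \code{quality}, \code{found} (logical) and \code{adapterStart}.
#' @export
trimAdapter <- function(seqs, quals = NULL, adapter, minOverlap = 4L,
                        maxMismatchRate = 0) {
    if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
    adapter <- .dnaNorm(adapter)
    seqs <- .dnaNorm(seqs)
    la <- nchar(adapter)
    len <- nchar(seqs)
    if (maxMismatchRate == 0) {
        pos <- regexpr(adapter, seqs, fixed = TRUE)
        pos <- ifelse(pos > 0L, as.integer(pos), NA_integer_)
        # truncated adapter at the read end: longest (= leftmost) overlap
        todo <- is.na(pos)
        for (k in seq(min(la - 1L, max(len)), minOverlap)) {
            if (!any(todo)) break
            hit <- todo & len >= k &
                substr(seqs, len - k + 1L, len) == substr(adapter, 1L, k)
            pos[hit] <- len[hit] - k + 1L
            todo <- todo & !hit
        }
    } else {
        pos <- vapply(seq_along(seqs), function(i)
            .scanAdapter(seqs[i], adapter, minOverlap, maxMismatchRate),
            integer(1))
        pos[pos == 0L] <- NA_integer_
    }
    found <- !is.na(pos)
    insert <- ifelse(found, substr(seqs, 1L, ifelse(found, pos - 1L, 0L)), NA)
    qual <- if (is.null(quals)) rep(NA_character_, length(seqs)) else
        ifelse(found, substr(quals, 1L, ifelse(found, pos - 1L, 0L)), NA)
    DataFrame(insert = insert, quality = qual, found = found,
              adapterStart = pos)
}

# brute-force mismatch-tolerant scan; returns 0 when no placement matches
.scanAdapter <- function(seq, adapter, minOverlap, rate) {
    n <- nchar(seq)
    la <- nchar(adapter)
    s <- strsplit(seq, "")[[1]]
    a <- strsplit(adapter, "")[[1]]
    for (p in seq_len(n)) {
        ov <- min(la, n - p + 1L)
        if (ov < la && (p + ov - 1L) < n) next   # truncated matches only at end
        if (ov < minOverlap && ov < la) next
        mm <- sum(s[p:(p + ov - 1L)] != a[seq_len(ov)])
        if (mm <= floor(rate * ov)) return(p)
    }
    0L
}

#' Mean-quality read filter
#'
#' Keeps a read if and only if its mean base quality strictly exceeds the
#' threshold, so reads with a quality score of 30 or below are discarded
#' under the default.
#'
#' @param seqs character vector of sequences (used for length checks).
#' @param quals Phred+33 quality strings, same lengths as \code{seqs}.
#' @param qThreshold quality threshold (default 30).
#' @return logical vector: TRUE = keep.
#' @export
qualityFilter <- function(seqs, quals, qThreshold = 30) {
    if (length(seqs) != length(quals) ||
        any(nchar(seqs) != nchar(quals)))
        stop("sequence and quality strings must have matching lengths",
             call. = FALSE)
    if (!length(seqs)) return(logical(0))
    q <- .charToPhred(quals)
    means <- vapply(q, function(x) if (length(x)) mean(x) else NaN, numeric(1))
    means > qThreshold
}

#' Build a 13-nt prefix index with collapsing
#'
#' Hashes the first 13 nt of every dictionary species (U/T-normalized);
#' species sharing a prefix are collapsed into a single entry whose name
#' joins all member names with \code{"/"} in dictionary order.
#'
#' @param dict a \linkS4class{MirnaDictionary}; all sequences must be at
#'   least 13 nt.
#' @return a \linkS4class{CollapsedIndex}.
#' @export
buildCollapsedIndex <- function(dict) {
    sp <- mirnaSpecies(dict)
    if (nrow(sp) && any(nchar(sp$sequence) < .PREFIX_LEN))
        stop("dictionary contains species shorter than 13 nt", call. = FALSE)
    pref <- substr(sp$sequence, 1L, .PREFIX_LEN)
    uniq <- unique(pref)
    members <- lapply(uniq, function(p) sp$name[pref == p])
    new("CollapsedIndex", prefixes = uniq,
        collapsedNames = vapply(members, paste, character(1), collapse = "/"),
        members = members)
}

setMethod("show", "CollapsedIndex", function(object) {
    cat(sprintf("CollapsedIndex: %d prefixes, %d species (%d collapsed entries with >1 member)\n",
                length(object@prefixes), sum(lengths(object@members)),
                sum(lengths(object@members) > 1L)))
})

#' @describeIn buildCollapsedIndex collapsed entry names.
#' @param index a \code{CollapsedIndex}.
#' @export
collapsedNames <- function(index) index@collapsedNames

#' Assign trimmed inserts to collapsed miRNA entries
#'
#' String-matches the first 13 nt of each insert against the prefix index.
#' Inserts shorter than 13 nt are \code{too_short}; prefix-matched inserts
#' longer than 31 nt are \code{too_long}; prefix-matched inserts of
#' 13-31 nt are assigned with length equal to the full insert length;
#' everything else is \code{unassigned}.
#'
#' @param inserts character vector of adapter-trimmed insert sequences.
#' @param index a \linkS4class{CollapsedIndex}.
#' @return a \link[S4Vectors]{DataFrame} with columns \code{status}
#'   (\code{assigned}/\code{unassigned}/\code{too_short}/\code{too_long}),
#'   \code{mirna} and \code{length}.
#' @export
assignRead <- function(inserts, index) {
    inserts <- .dnaNorm(inserts)
    len <- nchar(inserts)
    hit <- match(substr(inserts, 1L, .PREFIX_LEN), index@prefixes)
    status <- rep("unassigned", length(inserts))
    status[len < .MIN_ISO_LEN] <- "too_short"
    matched <- len >= .MIN_ISO_LEN & !is.na(hit)
    status[matched & len > .MAX_ISO_LEN] <- "too_long"
    status[matched & len <= .MAX_ISO_LEN] <- "assigned"
    mirna <- ifelse(status == "assigned", index@collapsedNames[hit],
                    NA_character_)
    DataFrame(status = status, mirna = mirna,
              length = ifelse(status == "assigned", len, NA_integer_))
}

#' Tabulate assignments into an isoform count table
#'
#' Aggregates per-read assignments into counts over the full grid of
#' (collapsed entry, length 13-31) cells, and fills the per-sample
#' provenance counters so that assigned + unassigned + too_short +
#' too_long + adapter_rejected + quality_rejected equals the total reads.
#'
#' @param assignments named list (one element per sample, unique names)
#'   of DataFrames as returned by \code{\link{assignRead}}.
#' @param index the \linkS4class{CollapsedIndex} defining the row universe.
#' @param adapterRejected,qualityRejected per-sample counts of reads
#'   dropped before assignment (scalars are recycled).
#' @return an \linkS4class{IsoformCountTable}.
#' @export
tabulateIsoforms <- function(assignments, index, adapterRejected = 0L,
                             qualityRejected = 0L) {
    samples <- names(assignments)
    if (is.null(samples) || anyDuplicated(samples))
        stop("assignments must be named by unique sample names",
             call. = FALSE)
    adapterRejected <- rep_len(as.integer(adapterRejected), length(samples))
    qualityRejected <- rep_len(as.integer(qualityRejected), length(samples))

    entries <- index@collapsedNames
    lens <- .isoLengths()
    rows <- expand.grid(mirna = entries, length = lens,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$mirna, rows$length), , drop = FALSE]
    key <- paste0(rows$mirna, "_", rows$length)

    mat <- matrix(0L, nrow = nrow(rows), ncol = length(samples),
                  dimnames = list(NULL, samples))
    counters <- matrix(0L, nrow = length(samples), ncol = 4L,
                       dimnames = list(samples, c("too_short", "too_long",
                                                  "unassigned", "assigned")))
    for (j in seq_along(samples)) {
        a <- assignments[[j]]
        if (nrow(a)) {
            tb <- table(factor(a$status, levels = colnames(counters)))
            counters[j, ] <- as.integer(tb)
            ok <- a$status == "assigned"
            if (any(ok)) {
                cnt <- table(factor(paste0(a$mirna[ok], "_", a$length[ok]),
                                    levels = key))
                mat[, j] <- as.integer(cnt)
            }
        }
    }
    cd <- DataFrame(
        sample = samples,
        total_reads = as.integer(rowSums(counters) + adapterRejected +
                                 qualityRejected),
        adapter_rejected = adapterRejected,
        quality_rejected = qualityRejected,
        too_short = counters[, "too_short"],
        too_long = counters[, "too_long"],
        unassigned = counters[, "unassigned"],
        assigned = counters[, "assigned"],
        row.names = samples)
    tab <- IsoformCountTable(mat, rows$mirna, rows$length, colData = cd)
    validObject(tab)
    tab
}

#' Run the full small-RNA read-processing pipeline
#'
#' FASTQ to isoform count table: adapter trimming, mean-quality filtering
#' of the trimmed insert, 13-nt prefix assignment with collapsing, and
#' 13-31-nt length tabulation with provenance counters.
#'
#' @param fastqFiles character vector of FASTQ paths, named by sample
#'   (basenames are used when unnamed).
#' @param dict a \linkS4class{MirnaDictionary}.
#' @param adapter 3' adapter sequence.
#' @param minOverlap,maxMismatchRate adapter-matching parameters, see
#'   \code{\link{trimAdapter}}.
#' @param qThreshold mean-quality threshold, see
#'   \code{\link{qualityFilter}}.
#' @return an \linkS4class{IsoformCountTable}.
#' @export
mapSmallRna <- function(fastqFiles, dict, adapter, minOverlap = 4L,
                        maxMismatchRate = 0, qThreshold = 30) {
    if (is.null(names(fastqFiles)))
        names(fastqFiles) <- sub("\\.f(ast)?q$", "", basename(fastqFiles))
    index <- buildCollapsedIndex(dict)
    assignments <- list()
    adapterRej <- qualityRej <- integer(length(fastqFiles))
    for (j in seq_along(fastqFiles)) {
        reads <- Biostrings::readDNAStringSet(fastqFiles[[j]],
                                              format = "fastq",
                                              with.qualities = TRUE)
        seqs <- as.character(reads)
        quals <- as.character(S4Vectors::mcols(reads)$qualities)
        tr <- trimAdapter(seqs, quals, adapter, minOverlap, maxMismatchRate)
        adapterRej[j] <- sum(!tr$found)
        ins <- tr$insert[tr$found]
        q <- tr$quality[tr$found]
        nonEmpty <- nchar(ins) > 0L
        keep <- rep(FALSE, length(ins))
        keep[nonEmpty] <- qualityFilter(ins[nonEmpty], q[nonEmpty],
                                        qThreshold)
        # zero-length inserts carry no bases to judge; they fall through
        # to the too_short bin rather than the quality filter
        keep[!nonEmpty] <- TRUE
        qualityRej[j] <- sum(!keep)
        assignments[[j]] <- assignRead(ins[keep], index)
    }
    names(assignments) <- names(fastqFiles)
    tabulateIsoforms(assignments, index, adapterRej, qualityRej)
}
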